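# Config files use a plain `key = value` dialect with one `[section]` per
# module; values are auto-converted to numbers/logicals where possible.
# CLI flags override config-file values, which override the defaults.

#' Parse a key = value config file
#'
#' @param path Path to the config file. Lines are `key = value` grouped under
#'   `[section]` headers; `#` starts a comment; blank lines are ignored.
#' @return A named list of sections, each a named list of values.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) {
    sf_abort(sprintf("config file '%s' does not exist", path), "segfuse_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- "global"
  out[[section]] <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[.+\\]$", line)) {
      section <- sub("^\\[(.+)\\]$", "\\1", line)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    if (!grepl("=", line, fixed = TRUE)) {
      sf_abort(sprintf("%s:%d: malformed line (expected 'key = value'): %s",
                       path, i, lines[i]), "segfuse_config_error")
    }
    key <- trimws(sub("=.*$", "", line))
    val <- trimws(sub("^[^=]*=", "", line))
    if (!nzchar(key)) {
      sf_abort(sprintf("%s:%d: empty key", path, i), "segfuse_config_error")
    }
    out[[section]][[key]] <- convert_config_value(val)
  }
  out
}

convert_config_value <- function(val) {
  if (grepl(",", val, fixed = TRUE)) {
    return(lapply(trimws(strsplit(val, ",", fixed = TRUE)[[1]]), convert_config_value))
  }
  if (tolower(val) %in% c("true", "false")) return(as.logical(toupper(val)))
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  val
}

# Build a fusion_config from a parsed config [fusion] section plus CLI
# overrides (a named list; NULL entries ignored).
config_from_sections <- function(sections, overrides = list()) {
  base <- sections[["fusion"]] %||% list()
  merged <- utils::modifyList(base, Filter(Negate(is.null), overrides))
  known <- c("algorithm", "line_mode", "closing", "middle_tiebreak",
             "target_index", "staple_max_iter", "staple_tol", "staple_threshold")
  extra <- merged[setdiff(names(merged), known)]
  args <- merged[intersect(names(merged), known)]
  args$extra <- extra
  do.call(fusion_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
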