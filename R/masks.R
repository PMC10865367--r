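#' Binary segmentation mask
#'
#' A `binary_mask` wraps an H x W logical matrix in which `TRUE` marks the
#' foreground object. A valid mask contains at least one foreground pixel and,
#' after hole filling, exactly one 8-connected foreground component: the tool
#' fuses one object per mask.
#'
#' @param px Logical matrix; `TRUE` is foreground.
#' @param source Optional provenance string (usually a file path).
#' @param validate Check the single-object invariants (default `TRUE`).
#' @return An object of class `binary_mask` with elements `px` and `source`.
#' @examples
#' m <- matrix(FALSE, 9, 9); m[3:7, 3:7] <- TRUE
#' binary_mask(m)
#' @export
binary_mask <- function(px, source = NULL, validate = TRUE) {
  if (!is.matrix(px)) sf_abort("mask pixels must be a matrix", "segfuse_format_error")
  if (!is.logical(px)) {
    px <- matrix(as.logical(px != 0), nrow(px))
  }
  if (validate) validate_mask_px(px, source)
  structure(list(px = px, source = source), class = "binary_mask")
}

validate_mask_px <- function(px, source = NULL) {
  where <- if (is.null(source)) "" else sprintf(" in '%s'", source)
  if (!any(px)) {
    sf_abort(sprintf("empty segmentation%s: no foreground pixels", where),
             "segfuse_empty_error")
  }
  nc <- n_components(fill_holes_px(px), conn = 8)
  if (nc > 1L) {
    sf_abort(sprintf(
      "multi-object mask%s: %d foreground components after hole filling (expected 1)",
      where, nc), "segfuse_multi_object_error")
  }
  invisible(px)
}

#' @export
dim.binary_mask <- function(x) dim(x$px)

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<%s> %d x %d, %d foreground px%s\n",
              class(x)[1], nrow(x$px), ncol(x$px), sum(x$px),
              if (is.null(x$source)) "" else paste0(", source: ", x$source)))
  invisible(x)
}

#' @export
as.matrix.binary_mask <- function(x, ...) x$px

# Accept a binary_mask (or subclass) or a plain logical/0-1 matrix.
as_px <- function(x) {
  if (inherits(x, "binary_mask")) return(x$px)
  if (is.matrix(x)) return(if (is.logical(x)) x else matrix(x != 0, nrow(x)))
  sf_abort("expected a binary_mask or a logical matrix", "segfuse_format_error")
}

new_region_mask <- function(px, source = NULL) {
  structure(list(px = px, source = source),
            class = c("region_mask", "binary_mask"))
}

new_contour_line <- function(px, mode, source = NULL) {
  structure(list(px = px, mode = mode, source = source),
            class = c("contour_line", "binary_mask"))
}

#' Ordered set of same-shape segmentations
#'
#' Bundles two or more [binary_mask] objects of identical dimensions. The
#' order is significant: the index identifies the rater, which matters for
#' the Average Target From Input algorithm and for STAPLE's per-rater
#' performance estimates.
#'
#' @param masks List of [binary_mask] objects (or logical matrices).
#' @return An object of class `segmentation_set` with elements `masks` and `n`.
#' @examples
#' a <- matrix(FALSE, 9, 9); a[3:7, 3:7] <- TRUE
#' b <- matrix(FALSE, 9, 9); b[2:8, 2:8] <- TRUE
#' segmentation_set(list(binary_mask(a), binary_mask(b)))
#' @export
segmentation_set <- function(masks) {
  if (!is.list(masks) || length(masks) < 2L) {
    sf_abort(sprintf("a segmentation set needs at least 2 masks, got %d",
                     length(masks)), "segfuse_arity_error")
  }
  masks <- lapply(masks, function(m) {
    if (inherits(m, "binary_mask")) m else binary_mask(m)
  })
  d1 <- dim(masks[[1]]$px)
  for (i in seq_along(masks)[-1]) {
    di <- dim(masks[[i]]$px)
    if (!identical(di, d1)) {
      nm <- function(k) {
        s <- masks[[k]]$source
        if (is.null(s)) sprintf("mask %d", k) else sprintf("mask %d ('%s')", k, s)
      }
      sf_abort(sprintf("dimension mismatch: %s is %dx%d but %s is %dx%d",
                       nm(1), d1[1], d1[2], nm(i), di[1], di[2]),
               "segfuse_shape_error")
    }
  }
  structure(list(masks = masks, n = length(masks)), class = "segmentation_set")
}

#' @export
print.segmentation_set <- function(x, ...) {
  cat(sprintf("<segmentation_set> %d masks of %d x %d\n",
              x$n, nrow(x$masks[[1]]$px), ncol(x$masks[[1]]$px)))
  invisible(x)
}

#' Read a binary segmentation mask from a raster image
#'
#' Supports single-page PNG, TIFF and uncompressed BMP (8/16-bit, grayscale
#' or RGB). RGB images are collapsed to luminance; a pixel is foreground iff
#' its value is strictly greater than zero, so both 0/1 and 0/255 masks load
#' without a threshold option.
#'
#' @param path Path to the image file.
#' @return A [binary_mask].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    sf_abort(sprintf("cannot read '%s': no such file", path), "segfuse_format_error")
  }
  ext <- tolower(tools::file_ext(path))
  gray <- tryCatch(
    switch(ext,
      png = read_png_gray(path),
      tif = ,
      tiff = read_tiff_gray(path),
      bmp = read_bmp_gray(path),
      sf_abort(sprintf("unsupported image format '.%s' for '%s' (use png, tiff or bmp)",
                       ext, path), "segfuse_format_error")
    ),
    segfuse_error = function(e) stop(e),
    error = function(e) {
      sf_abort(sprintf("cannot decode '%s': %s", path, conditionMessage(e)),
               "segfuse_format_error")
    }
  )
  binary_mask(gray > 0, source = path)
}

collapse_gray <- function(a) {
  if (length(dim(a)) == 2L) return(a)
  nch <- dim(a)[3]
  if (nch >= 3L) {
    # Rec. 601 luma; exact channel equality reduces to the channel value
    0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  } else {
    a[, , 1]
  }
}

read_png_gray <- function(path) {
  collapse_gray(png::readPNG(path))
}

read_tiff_gray <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) > 1L) {
    sf_abort(sprintf("'%s' is a multi-page TIFF; 3D stacks are not supported (split into 2D sections first)",
                     path), "segfuse_format_error")
  }
  collapse_gray(pages[[1]])
}

#' Write a mask or contour as an 8-bit raster image
#'
#' Foreground is written as 255, background as 0. The format follows the file
#' extension (png, tif/tiff or bmp). Reading the written file back with
#' [read_mask()] reproduces the boolean grid bit-exactly. The file is written
#' atomically (temporary file + rename), so a failure never leaves a partial
#' output.
#'
#' @param mask A [binary_mask], contour line, or logical matrix.
#' @param path Output path; the parent directory must exist.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  px <- as_px(mask)
  if (!any(px)) {
    sf_abort("refusing to write an empty segmentation", "segfuse_empty_error")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    sf_abort(sprintf("cannot write '%s': directory '%s' does not exist", path, dir),
             "segfuse_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  img <- matrix(as.numeric(px), nrow(px))
  tmp <- tempfile(tmpdir = dir, fileext = paste0(".", ext))
  ok <- tryCatch({
    switch(ext,
      png = png::writePNG(img, tmp),
      tif = ,
      tiff = tiff::writeTIFF(img, tmp, bits.per.sample = 8L),
      bmp = write_bmp_gray(px, tmp),
      sf_abort(sprintf("unsupported output format '.%s' (use png, tiff or bmp)", ext),
               "segfuse_format_error")
    )
    TRUE
  }, error = function(e) {
    unlink(tmp)
    stop(e)
  })
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    sf_abort(sprintf("cannot write '%s'", path), "segfuse_io_error")
  }
  invisible(path)
}

#' Load an ordered segmentation set from image files
#'
#' @param paths Character vector of at least two image paths; the order of the
#'   paths defines the rater index (1-based).
#' @return A [segmentation_set].
#' @export
load_set <- function(paths) {
  if (length(paths) < 2L) {
    sf_abort(sprintf("need at least 2 segmentations, got %d", length(paths)),
             "segfuse_arity_error")
  }
  segmentation_set(lapply(paths, read_mask))
}

# ---- minimal uncompressed BMP codec ----------------------------------------
# No installed R package reads BMP; the format is simple enough to handle the
# uncompressed 8/24/32-bit variants directly.

.le_int <- function(raw, offset, size, signed = FALSE) {
  # signed = FALSE is only honoured for 1/2-byte reads; 4-byte header fields
  # here never approach 2^31 so a signed read is exact
  readBin(raw[(offset + 1):(offset + size)], "integer", size = size,
          endian = "little", signed = if (size > 2) TRUE else signed)
}

read_bmp_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM") {
    sf_abort(sprintf("'%s' is not a BMP file", path), "segfuse_format_error")
  }
  data_off <- .le_int(raw, 10, 4)
  hdr_size <- .le_int(raw, 14, 4)
  width <- .le_int(raw, 18, 4, signed = TRUE)
  height <- .le_int(raw, 22, 4, signed = TRUE)
  bpp <- .le_int(raw, 28, 2)
  compression <- .le_int(raw, 30, 4)
  if (compression != 0 || !(bpp %in% c(8L, 24L, 32L))) {
    sf_abort(sprintf("'%s': only uncompressed 8/24/32-bit BMP is supported", path),
             "segfuse_format_error")
  }
  topdown <- height < 0
  h <- abs(height)
  row_size <- ((bpp * width + 31L) %/% 32L) * 4L
  gray <- matrix(0, h, width)
  if (bpp == 8L) {
    pal_off <- 14L + hdr_size
    n_colors <- .le_int(raw, 46, 4)
    if (n_colors == 0) n_colors <- 256L
    pal <- matrix(as.integer(raw[(pal_off + 1):(pal_off + 4 * n_colors)]),
                  ncol = 4, byrow = TRUE)  # B, G, R, reserved
    pal_gray <- (0.299 * pal[, 3] + 0.587 * pal[, 2] + 0.114 * pal[, 1]) / 255
  }
  for (i in seq_len(h)) {
    src_row <- if (topdown) i else h - i + 1L
    off <- data_off + (src_row - 1L) * row_size
    if (bpp == 8L) {
      idx <- as.integer(raw[(off + 1):(off + width)])
      gray[i, ] <- pal_gray[idx + 1L]
    } else {
      step <- bpp %/% 8L
      bytes <- as.integer(raw[(off + 1):(off + step * width)])
      b <- bytes[seq(1, by = step, length.out = width)]
      g <- bytes[seq(2, by = step, length.out = width)]
      r <- bytes[seq(3, by = step, length.out = width)]
      gray[i, ] <- (0.299 * r + 0.587 * g + 0.114 * b) / 255
    }
  }
  gray
}

write_bmp_gray <- function(px, path) {
  h <- nrow(px)
  w <- ncol(px)
  row_size <- ((24L * w + 31L) %/% 32L) * 4L
  img_size <- row_size * h
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(54L + img_size), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(54L, con, size = 4, endian = "little")      # pixel data offset
  writeBin(40L, con, size = 4, endian = "little")      # BITMAPINFOHEADER
  writeBin(as.integer(w), con, size = 4, endian = "little")
  writeBin(as.integer(h), con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(24L, con, size = 2, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")       # no compression
  writeBin(as.integer(img_size), con, size = 4, endian = "little")
  writeBin(rep(0L, 4), con, size = 4, endian = "little")  # dpi + palette fields
  pad <- row_size - 3L * w
  for (i in h:1) {
    vals <- as.integer(px[i, ]) * 255L
    row <- as.raw(rep(vals, each = 3L))
    if (pad > 0) row <- c(row, as.raw(rep(0L, pad)))
    writeBin(row, con)
  }
  invisible(path)
}
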