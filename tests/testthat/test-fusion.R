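nested_square_set <- function() {
  inner <- square_px(16, 16, 6, 10, 6, 10)   # 5x5
  outer <- square_px(16, 16, 4, 12, 4, 12)   # 9x9
  segmentation_set(list(binary_mask(inner), binary_mask(outer)))
}

test_that("Largest is the perimeter of the union, Smallest of the intersection", {
  set <- nested_square_set()
  cfg <- function(a) fusion_config(a, line_mode = "internal")
  big <- fuse(set, cfg("largest"))
  expect_identical(big$px, oracle_internal_boundary(square_px(16, 16, 4, 12, 4, 12)))
  small <- fuse(set, cfg("smallest"))
  expect_identical(small$px, oracle_internal_boundary(square_px(16, 16, 6, 10, 6, 10)))
  # overlapping disks: oracle = boolean OR + per-pixel boundary scan
  a <- disk_px(32, 32, 16, 13, 8)
  b <- disk_px(32, 32, 16, 19, 8)
  set2 <- segmentation_set(list(binary_mask(a), binary_mask(b)))
  out <- fuse(set2, cfg("largest"))
  expect_identical(out$px, oracle_internal_boundary(a | b))
  # idempotence on identical inputs
  same <- segmentation_set(list(binary_mask(a), binary_mask(a), binary_mask(a)))
  expect_identical(fuse(same, cfg("largest"))$px, oracle_internal_boundary(a))
  expect_identical(fuse(same, cfg("smallest"))$px, oracle_internal_boundary(a))
})

test_that("disjoint inputs raise empty-intersection or multi-object errors", {
  a <- disk_px(32, 32, 10, 10, 5)
  b <- disk_px(32, 32, 24, 24, 5)
  set <- segmentation_set(list(binary_mask(a), binary_mask(b)))
  cfg <- function(a) fusion_config(a, line_mode = "internal")
  expect_error(fuse(set, cfg("smallest")), class = "segfuse_empty_intersection_error")
  expect_error(fuse(set, cfg("largest")), class = "segfuse_multi_object_error")
})

test_that("Average Smallest And Largest skeletonizes the band onto the midline", {
  # nested concentric disks radii 6 and 10 -> ring at radius 8 +/- 1
  a <- disk_px(28, 28, 14, 14, 6)
  b <- disk_px(28, 28, 14, 14, 10)
  set <- segmentation_set(list(binary_mask(a), binary_mask(b)))
  out <- fuse(set, fusion_config("avg_smallest_largest", line_mode = "internal"))
  expect_true(is_closed(out))
  idx <- which(out$px, arr.ind = TRUE)
  radii <- sqrt((idx[, 1] - 14)^2 + (idx[, 2] - 14)^2)
  expect_true(all(abs(radii - 8) <= 1))
  # nested concentric squares 5x5 and 9x9 -> 7x7 ring +/- 1 px (Chebyshev)
  sq <- nested_square_set()
  out2 <- fuse(sq, fusion_config("avg_smallest_largest", line_mode = "internal"))
  idx2 <- which(out2$px, arr.ind = TRUE)
  cheb <- pmax(abs(idx2[, 1] - 8), abs(idx2[, 2] - 8))
  expect_true(all(cheb >= 2 & cheb <= 4))
  expect_true(is_closed(out2))
  # identical inputs degenerate to the common perimeter
  same <- segmentation_set(list(binary_mask(b), binary_mask(b)))
  expect_identical(fuse(same, fusion_config("avg_smallest_largest", line_mode = "internal"))$px,
                   oracle_internal_boundary(b))
})

test_that("nearest_member minimizes distance with row-then-col tie-breaking", {
  cont <- matrix(FALSE, 8, 8); cont[3, 3] <- TRUE; cont[6, 6] <- TRUE
  expect_equal(nearest_member(c(1, 1), cont), c(3L, 3L))
  tie <- matrix(FALSE, 8, 8); tie[1, 4] <- TRUE; tie[4, 1] <- TRUE
  expect_equal(nearest_member(c(1, 1), tie), c(1L, 4L))    # smaller row wins
  expect_equal(nearest_member(c(3, 3), cont), c(3L, 3L))   # on the contour
})

test_that("group_consensus handles pairs, collinear sets and polygons", {
  expect_equal(group_consensus(rbind(c(0, 0), c(2, 2))), c(1, 1))
  expect_equal(group_consensus(rbind(c(0, 0), c(1, 1), c(4, 4))), c(2, 2))
  expect_equal(group_consensus(rbind(c(0, 0), c(0, 2), c(2, 0), c(2, 2))), c(1, 1))
})

test_that("Average Target fuses concentric contours onto the radial midline", {
  a <- disk_px(30, 30, 15, 15, 6)
  b <- disk_px(30, 30, 15, 15, 10)
  set <- segmentation_set(list(binary_mask(a), binary_mask(b)))
  for (target in c("avg_target_largest", "avg_target_smallest")) {
    out <- fuse(set, fusion_config(target, line_mode = "internal"))
    expect_true(is_closed(out), label = target)
    idx <- which(out$px, arr.ind = TRUE)
    radii <- sqrt((idx[, 1] - 15)^2 + (idx[, 2] - 15)^2)
    expect_true(all(abs(radii - 8) <= 1.5), label = target)
  }
  # identical inputs: every group collapses onto the input contour
  same <- segmentation_set(list(binary_mask(b), binary_mask(b), binary_mask(b)))
  out2 <- fuse(same, fusion_config("avg_target_input", target_index = 2,
                                   line_mode = "internal"))
  ji <- oracle_jaccard(segfuse:::fill_holes_px(out2$px), b)
  expect_gte(ji, 0.99)
  # target index beyond the set size violates the config invariant
  expect_error(fuse(set, fusion_config("avg_target_input", target_index = 3)),
               class = "segfuse_config_error")
  expect_error(fuse(set, fusion_config("avg_target_input")),
               class = "segfuse_config_error")
})

test_that("Middle removes extremes floor((N-1)/2) times and returns one input", {
  cfg <- fusion_config("middle", line_mode = "internal")
  # three strictly area-ordered nested rings -> bit-identical middle ring
  rings <- lapply(c(4, 7, 10), function(r) binary_mask(disk_px(28, 28, 14, 14, r)))
  out <- fuse(segmentation_set(rings), cfg)
  expect_equal(attr(out, "middle_iterations"), 1)
  expect_identical(out$px, extract_line(rings[[2]], "internal")$px)
  # N = 6: exactly floor(5/2) = 2 removal iterations, 2 survivors
  six <- lapply(c(4, 5, 6, 7, 8, 9), function(r) binary_mask(disk_px(28, 28, 14, 14, r)))
  out6 <- fuse(segmentation_set(six), cfg)
  expect_equal(attr(out6, "middle_iterations"), 2)
  expect_equal(sort(attr(out6, "middle_survivors")), c(3, 4))
  # N = 2 with tiebreak = average is bit-identical to Average Smallest And Largest
  two <- segmentation_set(six[c(2, 5)])
  mid2 <- fuse(two, fusion_config("middle", middle_tiebreak = "average",
                                  line_mode = "internal"))
  asl2 <- fuse(two, fusion_config("avg_smallest_largest", line_mode = "internal"))
  expect_identical(mid2$px, asl2$px)
  # tiebreak = largest / smallest dispatch to those algorithms
  expect_identical(
    fuse(two, fusion_config("middle", middle_tiebreak = "largest", line_mode = "internal"))$px,
    fuse(two, fusion_config("largest", line_mode = "internal"))$px)
  expect_identical(
    fuse(two, fusion_config("middle", middle_tiebreak = "smallest", line_mode = "internal"))$px,
    fuse(two, fusion_config("smallest", line_mode = "internal"))$px)
})

test_that("STAPLE returns the input on unanimity and follows the majority pair", {
  a <- disk_px(32, 32, 16, 16, 9)
  same <- segmentation_set(lapply(1:4, function(i) binary_mask(a)))
  out <- fuse(same, fusion_config("staple", line_mode = "internal"))
  expect_identical(segfuse:::fill_holes_px(out$px), a)
  # two identical raters and their complement: consensus = the majority pair
  fit <- staple_consensus(list(a, a, !a))
  expect_identical(fit$region, a)
  expect_gte(fit$performance$sensitivity[1], 0.99)
  expect_lte(fit$performance$specificity[3], 0.01)
})

test_that("STAPLE EM agrees with an independent plain EM implementation", {
  truth <- make_shape(shape_spec("disk", canvas = c(64, 64), radius = 18))
  specs <- lapply(1:4, function(i) rater_spec("bernoulli", p = 0.85, q = 0.97, seed = i))
  raw <- attr(simulate_raters(truth, specs), "raw")
  fit <- staple_consensus(raw, max_iter = 100)
  oracle <- oracle_staple_em(raw, n_iter = 1000)
  expect_equal(fit$performance$sensitivity, oracle$p, tolerance = 0.01)
  expect_equal(fit$performance$specificity, oracle$q, tolerance = 0.01)
  expect_lt(mean(abs(as.vector(fit$w) - oracle$w)), 0.01)
})

test_that("order-independent algorithms are permutation invariant", {
  truth <- make_shape(shape_spec("disk", canvas = c(64, 64), radius = 20))
  set <- boundary_set(truth, n = 5, amplitude = 2, seed = 3)
  perm <- segmentation_set(set$masks[c(4, 1, 5, 3, 2)])
  for (alg in c("largest", "smallest", "avg_smallest_largest", "middle", "staple")) {
    cfg <- fusion_config(alg, line_mode = "internal")
    expect_identical(fuse(set, cfg)$px, fuse(perm, cfg)$px, label = alg)
  }
})

test_that("the fused region is sandwiched between Smallest and Largest", {
  truth <- make_shape(shape_spec("disk", canvas = c(64, 64), radius = 20))
  for (seed in 1:5) {
    set <- boundary_set(truth, n = 4, amplitude = 2, seed = seed)
    cfg <- function(a) fusion_config(a, line_mode = "internal")
    S <- segfuse:::fill_holes_px(fuse(set, cfg("smallest"))$px)
    L <- segfuse:::fill_holes_px(fuse(set, cfg("largest"))$px)
    M <- segfuse:::fill_holes_px(fuse(set, cfg("avg_smallest_largest"))$px)
    band <- segfuse:::dilate_sq(M, 1)
    expect_true(all(!S | band))              # S inside M up to 1 px
    expect_true(all(!M | segfuse:::dilate_sq(L, 1)))  # M inside L up to 1 px
  }
})

test_that("the dispatcher validates algorithm names and plugins register once", {
  set <- nested_square_set()
  err <- expect_error(fuse(set, fusion_config("foo")), class = "segfuse_config_error")
  for (alg in c("largest", "smallest", "avg_smallest_largest", "middle", "staple")) {
    expect_match(conditionMessage(err), alg)
  }
  register_algorithm("test_centroid_box", function(set, config) {
    u <- segfuse:::fill_holes_px(Reduce(`|`, lapply(set$masks, function(m) m$px)))
    region_perimeter(binary_mask(u), "internal")
  }, params_schema = list(pad = list(type = "integer", default = 0L)))
  on.exit(rm("test_centroid_box", envir = segfuse:::.registry), add = TRUE)
  expect_true("test_centroid_box" %in% list_algorithms())
  out <- fuse(set, fusion_config("test_centroid_box"))
  expect_true(is_closed(out))
  expect_error(register_algorithm("largest", identity),
               class = "segfuse_registration_error")
  # schema validation: wrong type is named in the error
  err2 <- expect_error(
    fuse(set, fusion_config("test_centroid_box", extra = list(pad = "three"))),
    class = "segfuse_validation_error")
  expect_match(conditionMessage(err2), "pad")
})
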