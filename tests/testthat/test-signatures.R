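test_that("a polygon covering a 2x2 constant block yields exactly its pixels", {
  vals <- array(0.25, dim = c(4, 4, 2))
  scn <- toy_scene(vals, wl = c(450, 550), px = 30, x0 = 0, y0 = 120)
  # pixels (1:2, 1:2): x in [0, 60], y in [60, 120]
  reg <- list(rect_region(0, 60, 60, 120, "3111"))
  s <- extract_class_samples(scn, reg)
  expect_named(s, "3111")
  expect_equal(dim(s$`3111`$sample_matrix), c(4L, 2L))
  expect_true(all(s$`3111`$sample_matrix == 0.25))
  expect_equal(sort(paste(s$`3111`$provenance$row, s$`3111`$provenance$col)),
               sort(c("1 1", "1 2", "2 1", "2 2")))
})

test_that("a sliver polygon containing no pixel center errors per class", {
  vals <- array(0.25, dim = c(4, 4, 1))
  scn <- toy_scene(vals, wl = 450, px = 30, x0 = 0, y0 = 120)
  # sliver in the top-left pixel corner, missing its center at (15, 105)
  sliver <- rect_region(0, 118, 2, 120, "3112")
  expect_error(extract_class_samples(scn, list(sliver)),
               "zero sampled pixels: 3112")
  expect_error(extract_class_samples(scn, list()), "empty")
})

test_that("boundary pixels count as inside (center-containment rule)", {
  vals <- array(0.1, dim = c(2, 2, 1))
  scn <- toy_scene(vals, wl = 450, px = 30, x0 = 0, y0 = 60)
  # polygon edge passes exactly through the center (15, 45) of pixel (1,1)
  reg <- rect_region(15, 45, 60, 60, "3111")
  s <- extract_class_samples(scn, list(reg))
  expect_true(any(s$`3111`$provenance$row == 1 & s$`3111`$provenance$col == 1))
})

test_that("per-class counts on a generated scene match the labeled blocks", {
  spec <- forest_area_spec(area = 1, seed = 13, block_px = 5)
  gen <- generate_scene(spec)
  s <- extract_class_samples(gen$scene, gen$regions)
  expect_equal(unname(vapply(s, function(x) nrow(x$sample_matrix), 0L)),
               rep(25L, 4L))
})

test_that("third-level sets are the union of their fourth-level sets", {
  spec <- forest_area_spec(area = 2, seed = 21, block_px = 6)
  gen <- generate_scene(spec)
  s4 <- extract_class_samples(gen$scene, gen$regions, level = "fourth")
  s3 <- extract_class_samples(gen$scene, gen$regions, level = "third")
  expect_setequal(names(s3), c("311", "312"))
  key <- function(s) sort(paste(s$provenance$row, s$provenance$col))
  expect_equal(key(s3$`311`),
               sort(c(key(s4$`3111`), key(s4$`3112`), key(s4$`3115`))))
  expect_equal(key(s3$`312`), sort(c(key(s4$`3121`), key(s4$`3122`))))
  # and the matrices match row-for-row once aligned on provenance
  k3 <- paste(s3$`312`$provenance$row, s3$`312`$provenance$col)
  m3 <- s3$`312`$sample_matrix[order(k3), , drop = FALSE]
  m4 <- rbind(s4$`3121`$sample_matrix, s4$`3122`$sample_matrix)
  k4 <- c(paste(s4$`3121`$provenance$row, s4$`3121`$provenance$col),
          paste(s4$`3122`$provenance$row, s4$`3122`$provenance$col))
  expect_equal(m3, m4[order(k4), , drop = FALSE])
})

test_that("extraction is invariant to region order", {
  spec <- forest_area_spec(area = 1, seed = 31, block_px = 4)
  gen <- generate_scene(spec)
  s1 <- extract_class_samples(gen$scene, gen$regions)
  s2 <- extract_class_samples(gen$scene, rev(gen$regions))
  for (code in names(s1)) {
    expect_equal(s1[[code]]$sample_matrix, s2[[code]]$sample_matrix)
  }
})

test_that("pixels claimed by two classes are excluded and reported", {
  vals <- array(0.5, dim = c(2, 4, 1))
  scn <- toy_scene(vals, wl = 450, px = 30, x0 = 0, y0 = 60)
  r1 <- rect_region(0, 0, 90, 60, "3111", "rA")    # cols 1-3
  r2 <- rect_region(30, 0, 120, 60, "3112", "rB")  # cols 2-4 -> cols 2-3 disputed
  expect_message(s <- extract_class_samples(scn, list(r1, r2)), "two classes")
  expect_equal(attr(s, "conflicting_pixels"), 4L)
  expect_equal(nrow(s$`3111`$sample_matrix), 2L)  # col 1 only
  expect_equal(nrow(s$`3112`$sample_matrix), 2L)  # col 4 only
  # two polygons of the SAME class may share pixels freely
  r2b <- rect_region(30, 0, 120, 60, "3111", "rB")
  s2 <- extract_class_samples(scn, list(r1, r2b))
  expect_equal(nrow(s2$`3111`$sample_matrix), 8L)
})

test_that("pixels with nodata in any band are excluded", {
  vals <- array(0.5, dim = c(2, 2, 2))
  vals[1, 1, 2] <- NA
  scn <- toy_scene(vals, wl = c(450, 550), px = 30, x0 = 0, y0 = 60)
  s <- extract_class_samples(scn, list(rect_region(0, 0, 60, 60, "3111")))
  expect_equal(nrow(s$`3111`$sample_matrix), 3L)
  expect_false(any(is.na(s$`3111`$sample_matrix)))
})

test_that("class_band_stats computes n-1 moments and rejects n < 2", {
  s <- toy_samples(matrix(c(0.1, 0.2, 0.3), ncol = 1))
  st <- class_band_stats(s)
  expect_equal(st$mu, 0.2)
  expect_equal(st$sigma, 0.1)
  expect_equal(st$n, 3L)
  expect_error(class_band_stats(toy_samples(matrix(0.5, ncol = 1))), "at least 2")
  # permutation invariance
  s2 <- toy_samples(matrix(c(0.3, 0.1, 0.2), ncol = 1))
  st2 <- class_band_stats(s2)
  expect_equal(st2$mu, st$mu)
  expect_equal(st2$sigma, st$sigma)
  # covariance: symmetric, diagonal equals sigma^2
  m <- matrix(rnorm(200, 0.4, 0.05), ncol = 2)
  stc <- class_band_stats(toy_samples(m), with_covariance = TRUE)
  expect_equal(stc$covariance, t(stc$covariance))
  expect_equal(diag(stc$covariance), stc$sigma^2)
})

test_that("large-sample moments converge to the truth (Monte Carlo)", {
  set.seed(314)
  n <- 1e4
  m <- matrix(rnorm(n, 0.30, 0.05), ncol = 1)
  st <- class_band_stats(toy_samples(m))
  expect_lt(abs(st$mu - 0.30), 4 * 0.05 / sqrt(n))  # 0.002
  expect_lt(abs(st$sigma - 0.05), 4 * 0.05 / sqrt(2 * (n - 1)))
})

test_that("median_signature takes per-band medians with even-n midpoints", {
  expect_equal(median_signature(toy_samples(matrix(c(0.1, 0.2, 0.3),
                                                   ncol = 1)))$median, 0.2)
  expect_equal(median_signature(toy_samples(matrix(c(0.1, 0.3),
                                                   ncol = 1)))$median, 0.2)
  expect_equal(median_signature(toy_samples(matrix(0.37, 5, 2)))$median,
               c(0.37, 0.37))
})

test_that("aggregate_code maps fourth-level codes to third-level parents", {
  expect_equal(aggregate_code(c("3111", "3112", "3115", "3121", "3122")),
               c("311", "311", "311", "312", "312"))
  expect_equal(aggregate_code(c("311", "312")), c("311", "312"))
})
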