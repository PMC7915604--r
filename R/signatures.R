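#' Extract per-class reflectance samples from labeled polygons
#'
#' A pixel is sampled for a class iff its center lies inside (or on the
#' boundary of) one of that class's polygons. Pixels with nodata in any band
#' are excluded. Pixels claimed by polygons of two different classes are
#' excluded and reported (real reference polygons are digitized to be pure
#' and disjoint, so this is a data-quality guard). At `level = "third"` the
#' fourth-level codes are aggregated to their third-level parents before
#' sampling (3111/3112/3115 -> 311; 3121/3122 -> 312).
#'
#' @param scn A [scene()].
#' @param regions List of [class_region()] in the scene CRS.
#' @param level `"fourth"` (codes as given) or `"third"` (aggregated).
#' @return Named list of `class_sample_set` objects, one per class, each with
#'   `class_code`, `sample_matrix` (`n_pixels x n_bands`), `provenance`
#'   (`data.frame(region_id, row, col)`) and `sensor`. The number of pixels
#'   excluded for conflicting claims is attached as attribute
#'   `"conflicting_pixels"`.
#' @export
extract_class_samples <- function(scn, regions, level = c("fourth", "third")) {
  level <- match.arg(level)
  stopifnot(inherits(scn, "scene"))
  if (!length(regions)) stop("empty polygon set")
  g <- scn$grid
  xc <- grid_x_centers(g)
  yc <- grid_y_centers(g)

  codes <- vapply(regions, function(r) r$class_code, character(1))
  if (level == "third") codes <- aggregate_code(codes)

  # per pixel: claiming class (0 = none), or -1 once two classes claim it
  claim <- matrix(0L, g$nrow, g$ncol)
  claim_region <- matrix(NA_character_, g$nrow, g$ncol)
  class_levels <- unique(codes)
  for (k in seq_along(regions)) {
    ring <- regions[[k]]$ring
    ci <- match(codes[k], class_levels)
    rows <- which(yc <= max(ring[, 2]) & yc >= min(ring[, 2]))
    cols <- which(xc >= min(ring[, 1]) & xc <= max(ring[, 1]))
    if (!length(rows) || !length(cols)) next
    pts <- expand.grid(row = rows, col = cols)
    inside <- points_in_ring(xc[pts$col], yc[pts$row], ring)
    pts <- pts[inside, , drop = FALSE]
    if (!nrow(pts)) next
    idx <- cbind(pts$row, pts$col)
    prev <- claim[idx]
    fresh <- prev == 0L
    same <- prev == ci
    conflict <- !fresh & !same & prev != -1L
    claim[idx[fresh, , drop = FALSE]] <- ci
    claim_region[idx[fresh, , drop = FALSE]] <- regions[[k]]$region_id
    if (any(conflict)) claim[idx[conflict, , drop = FALSE]] <- -1L
  }
  n_conflict <- sum(claim == -1L)
  if (n_conflict > 0) {
    message(n_conflict, " pixel(s) claimed by two classes were excluded")
    claim[claim == -1L] <- 0L
  }

  nb <- dim(scn$values)[3]
  vals <- scn$values
  if (!is.na(scn$nodata)) vals[vals == scn$nodata] <- NA
  bad <- apply(is.na(vals), c(1, 2), any)

  out <- list()
  empty <- character(0)
  for (ci in seq_along(class_levels)) {
    sel <- which(claim == ci & !bad, arr.ind = TRUE)
    if (!nrow(sel)) { empty <- c(empty, class_levels[ci]); next }
    sel <- sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
    m <- matrix(NA_real_, nrow(sel), nb)
    for (b in seq_len(nb)) m[, b] <- vals[, , b][sel]
    out[[class_levels[ci]]] <- structure(
      list(class_code = class_levels[ci], sample_matrix = m,
           provenance = data.frame(region_id = claim_region[sel],
                                   row = sel[, 1], col = sel[, 2],
                                   stringsAsFactors = FALSE),
           sensor = scn$sensor),
      class = "class_sample_set")
  }
  if (length(empty)) {
    stop("classes with zero sampled pixels: ", paste(empty, collapse = ", "))
  }
  attr(out, "conflicting_pixels") <- n_conflict
  out
}

#' Aggregate fourth-level codes to the third nomenclature level
#'
#' `"3111"`, `"3112"`, `"3115"` -> `"311"`; `"3121"`, `"3122"` -> `"312"`.
#' Codes already at the third level pass through unchanged.
#'
#' @param codes Character vector of class codes.
#' @return Character vector of third-level codes.
#' @export
aggregate_code <- function(codes) {
  ifelse(nchar(codes) > 3, substr(codes, 1, 3), codes)
}

#' Per-band class statistics
#'
#' The class summaries feeding the separability metrics: per-band sample mean
#' and sample standard deviation (n - 1 denominator), optionally the full
#' between-band sample covariance matrix.
#'
#' @param samples A `class_sample_set` (see [extract_class_samples()]).
#' @param with_covariance Also compute the `bands x bands` covariance.
#' @return A `class_band_stats` object: `class_code`, `n`, `wavelength_nm`,
#'   `mu`, `sigma`, and `covariance` when requested.
#' @export
class_band_stats <- function(samples, with_covariance = FALSE) {
  stopifnot(inherits(samples, "class_sample_set"))
  m <- samples$sample_matrix
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 pixels to estimate a standard deviation")
  mu <- colMeans(m)
  sigma <- apply(m, 2, stats::sd)
  out <- list(class_code = samples$class_code, n = n,
              wavelength_nm = sensor_wavelengths(samples$sensor),
              mu = mu, sigma = sigma)
  if (with_covariance) out$covariance <- stats::cov(m)
  structure(out, class = "class_band_stats")
}

#' Median spectral signature of a class
#'
#' Per-band median reflectance (midpoint of the two central order statistics
#' for even n). Used for signature plots and summaries; the separability
#' metrics use mean/sd instead.
#'
#' @param samples A `class_sample_set`.
#' @return `data.frame(wavelength_nm, median)`.
#' @export
median_signature <- function(samples) {
  stopifnot(inherits(samples, "class_sample_set"))
  m <- samples$sample_matrix
  if (nrow(m) < 1L) stop("empty sample set")
  data.frame(wavelength_nm = sensor_wavelengths(samples$sensor),
             median = apply(m, 2, stats::median))
}

#' Export class samples or signatures as tidy CSV
#'
#' One row per (class, band, pixel) for samples, or per (class, band) for
#' signatures.
#'
#' @param sample_sets Named list from [extract_class_samples()].
#' @param path Output CSV path.
#' @param what `"signatures"` (per-band median) or `"samples"` (every pixel).
#' @return `path`, invisibly.
#' @export
export_signatures_csv <- function(sample_sets, path,
                                  what = c("signatures", "samples")) {
  what <- match.arg(what)
  rows <- lapply(sample_sets, function(s) {
    wl <- sensor_wavelengths(s$sensor)
    if (what == "signatures") {
      data.frame(class_code = s$class_code,
                 band_index = seq_along(wl), wavelength_nm = wl,
                 value = apply(s$sample_matrix, 2, stats::median))
    } else {
      nb <- ncol(s$sample_matrix)
      data.frame(class_code = s$class_code,
                 band_index = rep(seq_len(nb), each = nrow(s$sample_matrix)),
                 wavelength_nm = rep(wl, each = nrow(s$sample_matrix)),
                 value = as.vector(s$sample_matrix))
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
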