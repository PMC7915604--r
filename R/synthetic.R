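## Synthetic two-sensor scenes with known per-class Gaussian statistics.
## The generator is the pipeline's ground-truth oracle: every downstream
## stage can be checked against the parameters that produced the cube.

# evaluate with a private, restorable RNG stream so scene generation is
# reproducible and does not disturb the caller's random state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

#' Broadleaf-forest reflectance baseline
#'
#' A stylized leaf-on forest canopy reflectance curve shared by all synthetic
#' classes: low visible reflectance with a green peak and red absorption dip,
#' the red-edge rise to a NIR plateau near 0.45, and the two liquid-water
#' absorption troughs around 1450 and 1940 nm. Piecewise-linear in wavelength.
#'
#' @return A function mapping wavelength (nm) to mean reflectance in `[0, 1]`.
#' @export
forest_reflectance_baseline <- function() {
  knots_nm <- c(400, 490, 550, 660, 690, 740, 780, 1000, 1130, 1300,
                1450, 1660, 1800, 1940, 2100, 2250, 2500)
  refl <- c(0.05, 0.06, 0.10, 0.05, 0.06, 0.35, 0.43, 0.45, 0.44, 0.41,
            0.18, 0.30, 0.27, 0.10, 0.21, 0.20, 0.10)
  stats::approxfun(knots_nm, refl, rule = 2)
}

#' Specify the spectral distribution of a synthetic class
#'
#' Each class reflects as `baseline(lambda) + sum(window offsets)` with
#' independent Gaussian pixel noise of standard deviation
#' `sd_spectrum(lambda)`. Contrast windows are where the class departs from
#' the shared baseline, i.e. where it is spectrally discriminable.
#'
#' @param class_code Nomenclature code, e.g. `"3111"`.
#' @param mean_spectrum Function of wavelength (nm) -> mean reflectance, or a
#'   `data.frame(wavelength_nm, value)` interpolated linearly. Default:
#'   [forest_reflectance_baseline()].
#' @param sd_spectrum Per-wavelength noise standard deviation: a single
#'   positive number, a function, or a `data.frame(wavelength_nm, value)`.
#'   Default 0.01 (small enough that `[0,1]` clipping is negligible).
#' @param contrast_windows List of `c(lo_nm, hi_nm, offset)` triples; inside
#'   `[lo, hi]` the class mean is shifted by `offset` from the baseline.
#' @return An object of class `class_spectrum_spec`.
#' @export
class_spectrum_spec <- function(class_code,
                                mean_spectrum = forest_reflectance_baseline(),
                                sd_spectrum = 0.01,
                                contrast_windows = list()) {
  as_fun <- function(x, what) {
    if (is.function(x)) return(x)
    if (is.data.frame(x)) {
      stopifnot(all(c("wavelength_nm", "value") %in% names(x)))
      return(stats::approxfun(x$wavelength_nm, x$value, rule = 2))
    }
    if (is.numeric(x) && length(x) == 1L) return(function(wl) rep(x, length(wl)))
    stop(sprintf("`%s` must be a function, a table or a scalar", what))
  }
  mean_fun <- as_fun(mean_spectrum, "mean_spectrum")
  sd_fun <- as_fun(sd_spectrum, "sd_spectrum")
  for (w in contrast_windows) {
    if (length(w) != 3L || w[1] >= w[2]) {
      stop("each contrast window is c(lo_nm, hi_nm, offset) with lo < hi")
    }
  }
  structure(list(class_code = as.character(class_code), mean_fun = mean_fun,
                 sd_fun = sd_fun, contrast_windows = contrast_windows),
            class = "class_spectrum_spec")
}

#' Class mean and standard deviation at given wavelengths
#'
#' The generating-parameter oracle: the exact mean (baseline plus window
#' offsets) and sd of a synthetic class at each wavelength, before clipping.
#'
#' @param spec A [class_spectrum_spec()].
#' @param wavelengths_nm Numeric vector of wavelengths.
#' @return `data.frame(wavelength_nm, mean, sd)`.
#' @export
class_true_stats <- function(spec, wavelengths_nm) {
  mu <- spec$mean_fun(wavelengths_nm)
  for (w in spec$contrast_windows) {
    inside <- wavelengths_nm >= w[1] & wavelengths_nm <= w[2]
    mu[inside] <- mu[inside] + w[3]
  }
  data.frame(wavelength_nm = wavelengths_nm, mean = mu,
             sd = spec$sd_fun(wavelengths_nm))
}

#' Specify a synthetic labeled scene
#'
#' @param grid A [grid_def()] for the scene.
#' @param layout `data.frame` with columns `row0, row1, col0, col1,
#'   class_code`: inclusive 1-based pixel-index blocks, each labeled with
#'   exactly one class. Blocks must not overlap.
#' @param classes List of [class_spectrum_spec()]; every layout code must
#'   appear exactly once.
#' @param sensor A [sensor_model()].
#' @param crs CRS label.
#' @param seed Integer seed for the pixel noise.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(grid, layout, classes, sensor, crs = "EPSG:32632",
                       seed = 1L) {
  stopifnot(inherits(grid, "grid_def"), inherits(sensor, "sensor_model"))
  need <- c("row0", "row1", "col0", "col1", "class_code")
  if (!is.data.frame(layout) || !all(need %in% names(layout))) {
    stop("`layout` needs columns ", paste(need, collapse = ", "))
  }
  codes <- vapply(classes, function(cl) cl$class_code, character(1))
  if (anyDuplicated(codes)) stop("duplicate class codes in `classes`")
  missing_codes <- setdiff(unique(layout$class_code), codes)
  if (length(missing_codes)) {
    stop("layout classes missing from `classes`: ",
         paste(missing_codes, collapse = ", "))
  }
  if (any(layout$row0 < 1 | layout$col0 < 1 |
          layout$row1 > grid$nrow | layout$col1 > grid$ncol |
          layout$row0 > layout$row1 | layout$col0 > layout$col1)) {
    stop("layout blocks fall outside the grid or are inverted")
  }
  occupied <- matrix(FALSE, grid$nrow, grid$ncol)
  for (i in seq_len(nrow(layout))) {
    blk <- occupied[layout$row0[i]:layout$row1[i], layout$col0[i]:layout$col1[i]]
    if (any(blk)) stop("layout blocks overlap")
    occupied[layout$row0[i]:layout$row1[i], layout$col0[i]:layout$col1[i]] <- TRUE
  }
  wl <- sensor_wavelengths(sensor)
  for (cl in classes) {
    ts <- class_true_stats(cl, wl)
    if (any(ts$mean < 0 | ts$mean > 1)) {
      stop("class ", cl$class_code, ": mean spectrum leaves [0,1] on the sensor grid")
    }
    if (any(ts$sd <= 0)) stop("class ", cl$class_code, ": sd must be > 0")
    for (w in cl$contrast_windows) {
      if (w[2] < min(wl) || w[1] > max(wl)) {
        stop("class ", cl$class_code, ": contrast window outside the sensor range")
      }
    }
  }
  structure(list(grid = grid, layout = layout, classes = classes,
                 sensor = sensor, crs = crs, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Default block layout for a set of classes
#'
#' One square block per class, side `block_px`, laid out left to right on a
#' single row of blocks. With the default 32 px side each class contributes
#' 1024 pixels, comfortably above the sample sizes needed for stable per-band
#' statistics.
#'
#' @param class_codes Character vector of class codes.
#' @param block_px Block side in pixels.
#' @param gap_px Unlabeled gap between blocks (background pixels).
#' @return `data.frame` usable as a [scene_spec()] layout.
#' @export
block_layout <- function(class_codes, block_px = 32L, gap_px = 2L) {
  k <- length(class_codes)
  col0 <- 1L + (seq_len(k) - 1L) * (block_px + gap_px)
  data.frame(row0 = 1L, row1 = block_px, col0 = col0,
             col1 = col0 + block_px - 1L, class_code = class_codes,
             stringsAsFactors = FALSE)
}

# default fourth-level class set; offsets sit in the discriminative regions
# vegetation studies report: blue, red edge, NIR plateau, SWIR beyond the
# 1800 nm water feature. 3111 is the unshifted reference class.
default_class_specs <- function(sd = 0.01) {
  list(
    class_spectrum_spec("3111", sd_spectrum = sd),
    class_spectrum_spec("3112", sd_spectrum = sd,
                        contrast_windows = list(c(700, 745, 0.05))),
    class_spectrum_spec("3115", sd_spectrum = sd,
                        contrast_windows = list(c(405, 445, 0.06))),
    class_spectrum_spec("3121", sd_spectrum = sd,
                        contrast_windows = list(c(1340, 1400, 0.06))),
    class_spectrum_spec("3122", sd_spectrum = sd,
                        contrast_windows = list(c(1790, 1860, 0.07)))
  )
}

#' Preset scene specifications mirroring the two study areas
#'
#' Area 1 carries four fourth-level forest types (3111 deciduous evergreen,
#' 3112 deciduous broadleaf, 3115 azonal, 3121 Mediterranean coniferous);
#' Area 2 adds 3122 (mountain coniferous) for five. Both aggregate to the
#' third-level broadleaf/coniferous split (311 vs 312). Each class occupies a
#' 32 x 32 pixel block at 30 m.
#'
#' @param area `1` or `2`.
#' @param sensor Sensor model (default `make_sensor("hyper")`).
#' @param seed Integer seed.
#' @param sd Per-class noise standard deviation.
#' @param block_px Class block side in pixels.
#' @return A [scene_spec()].
#' @export
forest_area_spec <- function(area = 1, sensor = make_sensor("hyper"),
                             seed = 1L, sd = 0.01, block_px = 32L) {
  stopifnot(area %in% c(1, 2))
  specs <- default_class_specs(sd = sd)
  codes <- c("3111", "3112", "3115", "3121", if (area == 2) "3122")
  specs <- Filter(function(cl) cl$class_code %in% codes, specs)
  layout <- block_layout(codes, block_px = block_px)
  g <- grid_def(x0 = 7e5, y0 = 48e5, px = sensor$ground_resolution_m,
                py = sensor$ground_resolution_m,
                nrow = block_px, ncol = max(layout$col1))
  scene_spec(g, layout, specs, sensor, seed = seed)
}

#' Generate a labeled synthetic scene
#'
#' Every pixel of class `c` in band `b` is an independent draw from
#' `Normal(mean_c(lambda_b), sd_c(lambda_b)^2)`, clipped to `[0, 1]`.
#' Unlabeled pixels are `NA` (nodata). Identical specs and seeds give
#' identical cubes. The returned polygons trace the labeled blocks in map
#' coordinates and carry the class codes.
#'
#' @param spec A [scene_spec()].
#' @return `list(scene = scene, regions = list of class_region)`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  g <- spec$grid
  wl <- sensor_wavelengths(spec$sensor)
  nb <- length(wl)
  codes <- vapply(spec$classes, function(cl) cl$class_code, character(1))
  true_stats <- lapply(spec$classes, class_true_stats, wavelengths_nm = wl)
  names(true_stats) <- codes

  vals <- with_local_seed(spec$seed, {
    v <- array(NA_real_, dim = c(g$nrow, g$ncol, nb))
    for (i in seq_len(nrow(spec$layout))) {
      blk <- spec$layout[i, ]
      ts <- true_stats[[blk$class_code]]
      nr <- blk$row1 - blk$row0 + 1L
      nc <- blk$col1 - blk$col0 + 1L
      for (b in seq_len(nb)) {
        draw <- stats::rnorm(nr * nc, mean = ts$mean[b], sd = ts$sd[b])
        v[blk$row0:blk$row1, blk$col0:blk$col1, b] <-
          pmin(1, pmax(0, matrix(draw, nr, nc)))
      }
    }
    v
  })

  regions <- lapply(seq_len(nrow(spec$layout)), function(i) {
    blk <- spec$layout[i, ]
    # map-coordinate rectangle of the block (pixel outer edges)
    x_lo <- g$x0 + (blk$col0 - 1L) * g$px
    x_hi <- g$x0 + blk$col1 * g$px
    y_hi <- g$y0 - (blk$row0 - 1L) * g$py
    y_lo <- g$y0 - blk$row1 * g$py
    class_region(rbind(c(x_lo, y_lo), c(x_hi, y_lo), c(x_hi, y_hi), c(x_lo, y_hi)),
                 blk$class_code, sprintf("r%03d", i))
  })

  scn <- scene(vals, g, spec$crs, spec$sensor)
  attr(scn, "true_stats") <- true_stats
  list(scene = scn, regions = regions)
}

#' Simulate a multispectral view from a hyperspectral cube
#'
#' Lets both synthetic "sensors" observe the same field: each multispectral
#' band is the unweighted mean of the hyperspectral bands whose centers fall
#' inside `[center - fwhm/2, center + fwhm/2]`. The grid is unchanged.
#'
#' @param hyper A hyperspectral [scene()].
#' @param multi_sensor Target [sensor_model()] (default `make_sensor("multi")`).
#' @param fwhm_nm Per-band averaging window widths in nm, recycled to the
#'   band count. Default [s2_band_fwhm()].
#' @return A [scene()] on the same grid bound to `multi_sensor`.
#' @export
simulate_multi_from_hyper <- function(hyper, multi_sensor = make_sensor("multi"),
                                      fwhm_nm = s2_band_fwhm()) {
  stopifnot(inherits(hyper, "scene"), inherits(multi_sensor, "sensor_model"))
  hwl <- sensor_wavelengths(hyper$sensor)
  mwl <- sensor_wavelengths(multi_sensor)
  fwhm <- rep_len(as.numeric(fwhm_nm), length(mwl))
  d <- dim(hyper$values)
  out <- array(NA_real_, dim = c(d[1], d[2], length(mwl)))
  for (b in seq_along(mwl)) {
    sel <- which(hwl >= mwl[b] - fwhm[b] / 2 & hwl <= mwl[b] + fwhm[b] / 2)
    if (!length(sel)) {
      stop(sprintf("band %d (%.1f nm): no hyperspectral band in its %.1f nm window",
                   b, mwl[b], fwhm[b]))
    }
    sub <- hyper$values[, , sel, drop = FALSE]
    out[, , b] <- rowMeans(matrix(sub, nrow = d[1] * d[2],
                                  ncol = length(sel)), na.rm = FALSE)
  }
  scene(out, hyper$grid, hyper$crs, multi_sensor, nodata = hyper$nodata)
}
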