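#' Construct a sensor model
#'
#' A sensor model is an ordered set of spectral bands (center wavelength plus a
#' detector tag) at a stated ground resolution. Band indices are 1-based and
#' contiguous; bands are kept in ascending wavelength order within each
#' detector block.
#'
#' @param name Sensor name (e.g. `"hyper"`, `"multi"`).
#' @param bands `data.frame` with columns `center_nm` (numeric, > 0),
#'   `detector` (character, typically `"VNIR"`, `"SWIR"` or `"MSI"`) and
#'   optionally `name` (band label such as `"b11"`).
#' @param ground_resolution_m Ground sample distance in metres (> 0).
#'
#' @return An object of class `sensor_model` with elements `name`, `bands`
#'   (with an `index` column prepended) and `ground_resolution_m`.
#' @export
sensor_model <- function(name, bands, ground_resolution_m) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.data.frame(bands) || !all(c("center_nm", "detector") %in% names(bands))) {
    stop("`bands` must be a data.frame with columns 'center_nm' and 'detector'")
  }
  if (nrow(bands) < 1L) stop("sensor must have at least one band")
  if (any(!is.finite(bands$center_nm)) || any(bands$center_nm <= 0)) {
    stop("band center wavelengths must be positive and finite")
  }
  if (any(!nzchar(bands$detector))) stop("every band needs a non-empty detector tag")
  if (!is.numeric(ground_resolution_m) || ground_resolution_m <= 0) {
    stop("`ground_resolution_m` must be > 0")
  }
  if (is.null(bands$name)) bands$name <- NA_character_
  # ascending wavelength within each detector block; detector blocks keep
  # their first-appearance order (VNIR before SWIR for the hyper preset)
  det_order <- match(bands$detector, unique(bands$detector))
  bands <- bands[order(det_order, bands$center_nm), , drop = FALSE]
  bands <- data.frame(index = seq_len(nrow(bands)),
                      center_nm = bands$center_nm,
                      detector = bands$detector,
                      name = bands$name,
                      stringsAsFactors = FALSE)
  structure(list(name = name, bands = bands,
                 ground_resolution_m = ground_resolution_m),
            class = "sensor_model")
}

#' @export
print.sensor_model <- function(x, ...) {
  cat(sprintf("<sensor_model> %s: %d bands, %g m\n", x$name, nrow(x$bands),
              x$ground_resolution_m))
  tab <- table(x$bands$detector)
  for (d in names(tab)) {
    rng <- range(x$bands$center_nm[x$bands$detector == d])
    cat(sprintf("  %s: %d bands, %.1f-%.1f nm\n", d, tab[[d]], rng[1], rng[2]))
  }
  invisible(x)
}

#' Wavelengths of a sensor model
#' @param sensor A `sensor_model`.
#' @return Numeric vector of band center wavelengths in nm, in band order.
#' @export
sensor_wavelengths <- function(sensor) {
  stopifnot(inherits(sensor, "sensor_model"))
  sensor$bands$center_nm
}

# Published Sentinel-2A central wavelengths / bandwidths (nm) for the ten
# land-monitoring bands (b1, b9, b10 are atmospheric, 60 m, and excluded).
s2_band_table <- function() {
  data.frame(
    name = c("b2", "b3", "b4", "b5", "b6", "b7", "b8", "b8a", "b11", "b12"),
    center_nm = c(492.4, 559.8, 664.6, 704.1, 740.5, 782.8, 832.8, 864.7,
                  1613.7, 2202.4),
    fwhm_nm = c(66, 36, 31, 15, 15, 20, 106, 21, 91, 175),
    stringsAsFactors = FALSE)
}

#' Full width at half maximum of the multispectral preset bands
#'
#' Per-band spectral widths (nm) used by [simulate_multi_from_hyper()] to
#' average hyperspectral bands into the ten Sentinel-2-like bands.
#'
#' @return Named numeric vector of FWHM in nm, one per band of
#'   `make_sensor("multi")`.
#' @export
s2_band_fwhm <- function() {
  tab <- s2_band_table()
  stats::setNames(tab$fwhm_nm, tab$name)
}

#' Sensor presets: hyperspectral and multispectral
#'
#' `"hyper"` is a PRISMA-like imaging spectrometer: 239 bands at 30 m, 66 VNIR
#' spanning 400-1010 nm and 173 SWIR spanning 920-2500 nm, with exactly 9
#' wavelength-coincident VNIR/SWIR band pairs in the detector overlap region.
#' Exact per-band centers of the real instrument are not published as a simple
#' table, so the preset uses an even VNIR grid, pins the 9 coincident SWIR
#' centers to the last 9 VNIR centers, and fills the rest of the SWIR range
#' evenly; every stated band count is honoured.
#'
#' `"multi"` is the Sentinel-2 MSI at its published central wavelengths for the
#' ten land-monitoring bands (b2-b8, b8a, b11, b12; the 60 m atmospheric bands
#' b1, b9, b10 are excluded), resampled to a 30 m grid.
#'
#' @param kind `"hyper"` or `"multi"`.
#' @return A [sensor_model()].
#' @examples
#' nrow(make_sensor("hyper")$bands)  # 239
#' nrow(make_sensor("multi")$bands)  # 10
#' @export
make_sensor <- function(kind = c("hyper", "multi")) {
  kind <- match.arg(kind)
  if (kind == "hyper") {
    vnir <- seq(400, 1010, length.out = 66L)
    coincident <- vnir[58:66]            # 9 VNIR centers inside 920-1010 nm
    n_rest <- 173L - 1L - 9L
    step <- (2500 - 1010) / (n_rest)
    swir <- sort(c(920, coincident, seq(1010 + step, 2500, length.out = n_rest)))
    bands <- data.frame(
      center_nm = c(vnir, swir),
      detector = rep(c("VNIR", "SWIR"), c(length(vnir), length(swir))),
      name = NA_character_, stringsAsFactors = FALSE)
    sensor_model("hyper", bands, 30)
  } else {
    tab <- s2_band_table()
    bands <- data.frame(center_nm = tab$center_nm, detector = "MSI",
                        name = tab$name, stringsAsFactors = FALSE)
    sensor_model("multi", bands, 30)
  }
}

#' Drop SWIR bands that duplicate VNIR wavelengths
#'
#' Imaging spectrometers with separate VNIR and SWIR detectors acquire a few
#' bands twice in the detector overlap region. For each VNIR/SWIR pair whose
#' centers differ by at most `overlap_tolerance_nm`, the SWIR member is
#' removed and the VNIR member retained; all other bands are kept in order.
#' Idempotent; a sensor with no coincident pairs is returned unchanged
#' (indices are renumbered to stay contiguous).
#'
#' @param sensor A `sensor_model` with detector tags.
#' @param overlap_tolerance_nm Maximum center distance (nm) for two bands to
#'   count as coincident. Default 0.5 nm.
#' @return A `sensor_model` with the duplicated SWIR bands removed.
#' @examples
#' nrow(drop_overlap_bands(make_sensor("hyper"))$bands)  # 230
#' @export
drop_overlap_bands <- function(sensor, overlap_tolerance_nm = 0.5) {
  stopifnot(inherits(sensor, "sensor_model"))
  b <- sensor$bands
  vnir <- b$center_nm[b$detector == "VNIR"]
  drop <- rep(FALSE, nrow(b))
  if (length(vnir)) {
    is_swir <- b$detector == "SWIR"
    if (any(is_swir)) {
      nearest <- vapply(b$center_nm[is_swir],
                        function(w) min(abs(w - vnir)), numeric(1))
      drop[is_swir] <- nearest <= overlap_tolerance_nm
    }
  }
  if (!any(drop)) return(sensor)
  sensor_model(sensor$name, b[!drop, c("center_nm", "detector", "name")],
               sensor$ground_resolution_m)
}
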