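#' Define a north-up raster grid
#'
#' Pixel indices are 1-based; the pixel with row `i`, column `j` covers the
#' half-open map rectangle `[x0 + (j-1) px, x0 + j px) x (y0 - i py, y0 - (i-1) py]`
#' so its center is at `(x0 + (j - 0.5) px, y0 - (i - 0.5) py)`. Only
#' axis-aligned, north-up grids are supported (no rotation terms).
#'
#' @param x0,y0 Map coordinates of the grid's top-left corner.
#' @param px,py Pixel size in map units along x and y (both > 0; y decreases
#'   with increasing row).
#' @param nrow,ncol Grid dimensions.
#' @return A `grid_def` list.
#' @export
grid_def <- function(x0, y0, px, py, nrow, ncol) {
  stopifnot(px > 0, py > 0, nrow >= 1, ncol >= 1)
  structure(list(x0 = x0, y0 = y0, px = px, py = py,
                 nrow = as.integer(nrow), ncol = as.integer(ncol)),
            class = "grid_def")
}

grid_x_centers <- function(g) g$x0 + (seq_len(g$ncol) - 0.5) * g$px
grid_y_centers <- function(g) g$y0 - (seq_len(g$nrow) - 0.5) * g$py

#' Construct a reflectance scene
#'
#' A scene binds a rows x cols x bands reflectance array to a georeferencing
#' grid, a CRS label and a [sensor_model()]. Reflectance is nominally in
#' `[0, 1]`; out-of-range values are permitted but flagged with a warning.
#' Missing pixels are `NA` (serialized as IEEE NaN) or an explicit numeric
#' `nodata` sentinel.
#'
#' @param values Numeric array `rows x cols x bands`.
#' @param grid A [grid_def()] whose `nrow`/`ncol` match `values`.
#' @param crs CRS label (free text, e.g. `"EPSG:32632"`). Scenes are only
#'   comparable when their labels match; no reprojection is performed.
#' @param sensor A [sensor_model()] with as many bands as `values`.
#' @param nodata Optional numeric sentinel marking missing pixels.
#' @return An object of class `scene`.
#' @export
scene <- function(values, grid, crs, sensor, nodata = NA_real_) {
  stopifnot(inherits(grid, "grid_def"), inherits(sensor, "sensor_model"))
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-d array (rows x cols x bands)")
  }
  d <- dim(values)
  if (d[1] != grid$nrow || d[2] != grid$ncol) {
    stop("array dimensions do not match the grid definition")
  }
  if (d[3] != nrow(sensor$bands)) {
    stop(sprintf("band-count mismatch: array has %d bands, sensor has %d",
                 d[3], nrow(sensor$bands)))
  }
  if (!is.character(crs) || length(crs) != 1L || !nzchar(crs)) {
    stop("`crs` must be a non-empty character label")
  }
  v <- values
  if (!is.na(nodata)) v[v == nodata] <- NA
  rng <- range(v, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1)) {
    warning(sprintf("reflectance outside [0,1]: range %.4g..%.4g", rng[1], rng[2]))
  }
  structure(list(values = values, grid = grid, crs = crs, sensor = sensor,
                 nodata = nodata),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<scene> %d x %d px, %d bands (%s), %g m, %s\n",
              d[1], d[2], d[3], x$sensor$name, x$grid$px, x$crs))
  invisible(x)
}

## ---- ENVI-dialect raster I/O -------------------------------------------
## Plain-text .hdr + band-sequential binary payload; the header carries the
## wavelength list, map info, CRS label and detector tags so that
## write_scene -> read_scene is the identity on values and metadata.

envi_paths <- function(raster_path) {
  base <- sub("\\.(dat|hdr|envi|img)$", "", raster_path)
  list(dat = paste0(base, ".dat"), hdr = paste0(base, ".hdr"))
}

envi_list <- function(x) paste0("{", paste(x, collapse = ", "), "}")

#' Write a scene as an ENVI-dialect raster
#'
#' Writes a band-sequential (BSQ) float64 binary file plus an ASCII `.hdr`
#' header holding grid, CRS, wavelength and detector metadata. `NA` pixels are
#' stored as IEEE NaN; an explicit `nodata` sentinel is recorded as
#' `data ignore value`.
#'
#' @param scn A [scene()].
#' @param raster_path Output path; `.dat`/`.hdr` extensions are managed.
#' @return The path of the binary file, invisibly.
#' @export
write_scene <- function(scn, raster_path) {
  stopifnot(inherits(scn, "scene"))
  d <- dim(scn$values)
  if (d[3] < 1L) stop("cannot write a scene with zero bands")
  p <- envi_paths(raster_path)
  g <- scn$grid
  b <- scn$sensor$bands
  hdr <- c(
    "ENVI",
    "description = {reflectance cube written by forestsep}",
    sprintf("samples = %d", g$ncol),
    sprintf("lines = %d", g$nrow),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    sprintf("map info = {Arbitrary, 1, 1, %.10g, %.10g, %.10g, %.10g}",
            g$x0, g$y0, g$px, g$py),
    sprintf("coordinate system string = {%s}", scn$crs),
    sprintf("sensor type = %s", scn$sensor$name),
    sprintf("ground resolution = %.10g", scn$sensor$ground_resolution_m),
    "wavelength units = Nanometers",
    sprintf("wavelength = %s", envi_list(sprintf("%.10g", b$center_nm))),
    sprintf("band detectors = %s", envi_list(b$detector))
  )
  if (any(!is.na(b$name))) {
    hdr <- c(hdr, sprintf("band names = %s",
                          envi_list(ifelse(is.na(b$name), "", b$name))))
  }
  if (!is.na(scn$nodata)) {
    hdr <- c(hdr, sprintf("data ignore value = %.10g", scn$nodata))
  }
  writeLines(hdr, p$hdr)
  con <- file(p$dat, "wb")
  on.exit(close(con))
  # BSQ: full band planes in band order; R arrays are column-major so the
  # plane must be transposed to row-major line order
  for (k in seq_len(d[3])) {
    plane <- t(scn$values[, , k])
    writeBin(as.numeric(plane), con, size = 8, endian = "little")
  }
  invisible(p$dat)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  # fold multi-line {...} blocks onto the key line
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (startsWith(val, "{")) {
        while (!grepl("}", val, fixed = TRUE) && i < length(lines)) {
          i <- i + 1L
          val <- paste(val, trimws(lines[i]))
        }
        val <- gsub("^\\{|\\}$", "", trimws(val))
      }
      out[[tolower(key)]] <- val
    }
    i <- i + 1L
  }
  out
}

envi_split <- function(x) trimws(strsplit(x, ",")[[1]])

#' Read an ENVI-dialect raster into a scene
#'
#' Accepts the `.dat`/`.hdr` pairs written by [write_scene()] and, more
#' generally, BSQ ENVI rasters with float32/float64 payloads. A wavelength per
#' band must be available, either from the header's `wavelength = {...}` block
#' or from a two-column sidecar CSV (`band_index, wavelength_nm`). Wavelengths
#' below 100 are assumed to be in micrometres and converted to nm with a
#' warning.
#'
#' @param raster_path Path to the binary or header file.
#' @param wavelengths_source Optional path to a sidecar CSV overriding the
#'   header wavelengths.
#' @return A [scene()].
#' @export
read_scene <- function(raster_path, wavelengths_source = NULL) {
  p <- envi_paths(raster_path)
  if (!file.exists(p$hdr)) stop("header not found: ", p$hdr)
  if (!file.exists(p$dat)) stop("raster payload not found: ", p$dat)
  h <- parse_envi_header(p$hdr)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("header missing fields: ", paste(miss, collapse = ", "))
  ns <- as.integer(h$samples); nl <- as.integer(h$lines); nb <- as.integer(h$bands)
  if (tolower(h$interleave) != "bsq") stop("only BSQ interleave is supported")
  dtype <- as.integer(h[["data type"]])
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type: ", dtype))
  endian <- if (!is.null(h[["byte order"]]) && as.integer(h[["byte order"]]) == 1L)
    "big" else "little"

  if (is.null(h[["map info"]])) stop("header has no map info (grid definition)")
  mi <- envi_split(h[["map info"]])
  g <- grid_def(x0 = as.numeric(mi[4]), y0 = as.numeric(mi[5]),
                px = as.numeric(mi[6]), py = as.numeric(mi[7]),
                nrow = nl, ncol = ns)
  if (is.null(h[["coordinate system string"]])) {
    stop("header has no coordinate system string (CRS)")
  }
  crs <- h[["coordinate system string"]]

  if (!is.null(wavelengths_source)) {
    wtab <- utils::read.csv(wavelengths_source)
    if (!all(c("band_index", "wavelength_nm") %in% names(wtab))) {
      stop("wavelength sidecar needs columns band_index, wavelength_nm")
    }
    wl <- wtab$wavelength_nm[order(wtab$band_index)]
  } else if (!is.null(h$wavelength)) {
    wl <- as.numeric(envi_split(h$wavelength))
  } else {
    stop("no wavelength source: header lacks a wavelength block and no sidecar given")
  }
  if (length(wl) != nb) {
    stop(sprintf("wavelength count (%d) does not match band count (%d)",
                 length(wl), nb))
  }
  if (all(wl < 100)) {
    warning("wavelengths < 100: assuming micrometres, converting to nm")
    wl <- wl * 1000
  }

  detectors <- if (!is.null(h[["band detectors"]])) envi_split(h[["band detectors"]])
               else rep("VNIR", nb)
  bnames <- if (!is.null(h[["band names"]])) {
    nm <- envi_split(h[["band names"]]); nm[!nzchar(nm)] <- NA; nm
  } else rep(NA_character_, nb)
  gres <- if (!is.null(h[["ground resolution"]])) as.numeric(h[["ground resolution"]])
          else g$px
  sname <- if (!is.null(h[["sensor type"]])) h[["sensor type"]] else "unknown"
  sens <- sensor_model(sname,
                       data.frame(center_nm = wl, detector = detectors,
                                  name = bnames, stringsAsFactors = FALSE),
                       gres)
  if (!identical(sens$bands$center_nm, wl)) {
    # file band order must win over the canonical detector/wavelength sort
    sens$bands <- data.frame(index = seq_len(nb), center_nm = wl,
                             detector = detectors, name = bnames,
                             stringsAsFactors = FALSE)
  }

  con <- file(p$dat, "rb")
  on.exit(close(con))
  vals <- array(NA_real_, dim = c(nl, ns, nb))
  for (k in seq_len(nb)) {
    plane <- readBin(con, "numeric", n = nl * ns, size = size, endian = endian)
    vals[, , k] <- matrix(plane, nrow = nl, ncol = ns, byrow = TRUE)
  }
  nodata <- if (!is.null(h[["data ignore value"]]))
    as.numeric(h[["data ignore value"]]) else NA_real_
  vals[is.nan(vals)] <- NA
  suppressWarnings(scene(vals, g, crs, sens, nodata = nodata))
}

#' Nearest-neighbor resampling onto a target grid
#'
#' Each output pixel takes the value of the input pixel whose center is
#' nearest the output pixel center; distance ties are broken toward the
#' smaller row, then the smaller column index. No reprojection: the scene and
#' target CRS labels must match, and the grids must overlap. The output value
#' multiset is always a subset of the input values (nothing is interpolated).
#'
#' @param scn A [scene()].
#' @param target A [grid_def()] in the same CRS.
#' @param target_crs CRS label of the target grid (defaults to the scene's).
#' @return A [scene()] on the target grid.
#' @export
resample_nearest <- function(scn, target, target_crs = scn$crs) {
  stopifnot(inherits(scn, "scene"), inherits(target, "grid_def"))
  if (!identical(target_crs, scn$crs)) {
    stop("CRS mismatch: reprojection is out of scope")
  }
  g <- scn$grid
  src_bbox <- c(g$x0, g$x0 + g$ncol * g$px, g$y0 - g$nrow * g$py, g$y0)
  tgt_bbox <- c(target$x0, target$x0 + target$ncol * target$px,
                target$y0 - target$nrow * target$py, target$y0)
  if (tgt_bbox[1] >= src_bbox[2] || tgt_bbox[2] <= src_bbox[1] ||
      tgt_bbox[3] >= src_bbox[4] || tgt_bbox[4] <= src_bbox[3]) {
    stop("grids do not overlap")
  }
  sx <- grid_x_centers(g); sy <- grid_y_centers(g)
  tx <- grid_x_centers(target); ty <- grid_y_centers(target)
  # axis-aligned grids: the 2-d nearest center factorizes per axis.
  # which.min returns the first (= smaller index) position on ties, which is
  # the smaller column for x and the smaller row for y.
  jmap <- vapply(tx, function(x) which.min(abs(sx - x)), integer(1))
  imap <- vapply(ty, function(y) which.min(abs(sy - y)), integer(1))
  vals <- scn$values[imap, jmap, , drop = FALSE]
  suppressWarnings(scene(vals, target, scn$crs, scn$sensor, nodata = scn$nodata))
}
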