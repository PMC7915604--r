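# shared fixture builders; everything is generated in code at test time

# minimal sensor with explicit wavelengths
toy_sensor <- function(wl, detector = "VNIR", name = "toy", res = 30) {
  sensor_model(name, data.frame(center_nm = wl, detector = detector,
                                stringsAsFactors = FALSE), res)
}

# constant-valued scene on a small north-up grid
toy_scene <- function(values, wl = seq(450, by = 100, length.out = dim(values)[3]),
                      px = 30, x0 = 0, y0 = 1000, crs = "EPSG:32632") {
  g <- grid_def(x0, y0, px, px, dim(values)[1], dim(values)[2])
  suppressWarnings(scene(values, g, crs, toy_sensor(wl), nodata = NA_real_))
}

# fabricate per-band class statistics without going through extraction
toy_stats <- function(class_code, mu, sigma, wl = seq(450, by = 100,
                                                      length.out = length(mu)),
                      n = 100L) {
  structure(list(class_code = class_code, n = n, wavelength_nm = wl,
                 mu = mu, sigma = sigma),
            class = "class_band_stats")
}

# fabricate a class_sample_set from a plain matrix
toy_samples <- function(m, class_code = "3111",
                        wl = seq(450, by = 100, length.out = ncol(m))) {
  structure(list(class_code = class_code, sample_matrix = m,
                 provenance = data.frame(region_id = "r001",
                                         row = seq_len(nrow(m)), col = 1L),
                 sensor = toy_sensor(wl)),
            class = "class_sample_set")
}

# rectangle region in map coordinates
rect_region <- function(x_lo, y_lo, x_hi, y_hi, class_code, region_id = "r001") {
  class_region(rbind(c(x_lo, y_lo), c(x_hi, y_lo), c(x_hi, y_hi), c(x_lo, y_hi)),
               class_code, region_id)
}

gsum <- function(mu, var) gaussian_class_summary(mu, var)
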