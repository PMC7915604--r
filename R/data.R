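#' Published reference values: per-pair maximum separability
#'
#' The per-pair maximum separability values (with the wavelength column as
#' printed) reported by the original two-area PRISMA vs Sentinel-2 forest
#' discrimination campaign, for the fourth nomenclature level. Shipped as a
#' plain CSV; used as input when checking the package's B-to-JM functional
#' relation against the published numbers.
#'
#' Caveats carried over from the printed source: the `wavelength` column
#' mixes values that cannot be nm positions (48, 100, 236, ...) and a few
#' cells are internally inconsistent with their own row (e.g. JM printed as
#' 140 where the B value implies approximately 1.84, and B/JM pairs such as
#' 2.55 whose transform does not match the printed JM). Rows are reproduced
#' verbatim; consumers should rely on the B column and the transform, not on
#' every printed cell.
#'
#' @return `data.frame(area, pair, sensor, wavelength, B, JM, M, TD)` where
#'   `sensor` is `"hyper"` (PRISMA) or `"multi"` (Sentinel-2).
#' @export
reference_best_separability <- function() {
  path <- system.file("extdata", "reference_best_separability.csv",
                      package = "forestsep", mustWork = TRUE)
  utils::read.csv(path, colClasses = c(pair = "character"))
}

#' Published reference values: per-area mean separability improvements
#'
#' The per-study-area mean percentage increments of the hyperspectral over
#' the multispectral sensor reported by the same campaign: 50% and 30% for
#' the third nomenclature level (coniferous vs broadleaf), 120% and 84% for
#' the fourth (five forest types). Averaging each pair across areas with
#' [overall_improvement()] yields the headline 40% and 102% figures.
#'
#' @return `list(third = c(50, 30), fourth = c(120, 84))`, percent.
#' @export
reference_area_improvements <- function() {
  list(third = c(50, 30), fourth = c(120, 84))
}
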