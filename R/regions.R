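#' Construct a labeled class region
#'
#' A polygon (single outer ring, no holes) carrying a land-cover class code,
#' in the same CRS as the scene it labels. Codes follow the hierarchical
#' forest nomenclature used throughout the package: third level `"311"`
#' (broadleaf) / `"312"` (coniferous), locally refined fourth level `"3111"`,
#' `"3112"`, `"3115"`, `"3121"`, `"3122"`.
#'
#' @param ring Numeric matrix `n x 2` of (x, y) vertices, `n >= 3`; the ring
#'   is closed implicitly.
#' @param class_code Class code (character or coercible).
#' @param region_id Identifier, unique within a region set.
#' @return An object of class `class_region`.
#' @export
class_region <- function(ring, class_code, region_id) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2L || nrow(ring) < 3L) {
    stop("`ring` must be an n x 2 matrix with n >= 3")
  }
  if (any(!is.finite(ring))) stop("ring vertices must be finite")
  # drop an explicit closing vertex
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3L) stop("degenerate ring")
  structure(list(ring = unname(ring), class_code = as.character(class_code),
                 region_id = as.character(region_id)),
            class = "class_region")
}

#' Point-in-polygon test (boundary-inclusive)
#'
#' Even-odd ray casting with points on an edge or vertex counted as inside.
#' This is the pixel-selection rule used by [extract_class_samples()]: a pixel
#' belongs to a region iff its center lies inside or on the boundary.
#'
#' @param x,y Point coordinates (vectors of equal length).
#' @param ring `n x 2` vertex matrix (open or closed).
#' @return Logical vector.
#' @export
points_in_ring <- function(x, y, ring) {
  ring <- as.matrix(ring)
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) { ring <- ring[-n, , drop = FALSE]; n <- n - 1L }
  xs <- ring[, 1]; ys <- ring[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, length(x))
  onedge <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    x1 <- xs[k]; y1 <- ys[k]; x2 <- xe[k]; y2 <- ye[k]
    # boundary: collinear and within the segment's bounding box
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    onseg <- abs(cross) <= 1e-9 * max(1, abs(x2 - x1) + abs(y2 - y1)) &
      x >= pmin(x1, x2) - 1e-12 & x <= pmax(x1, x2) + 1e-12 &
      y >= pmin(y1, y2) - 1e-12 & y <= pmax(y1, y2) + 1e-12
    onedge <- onedge | onseg
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | onedge
}

#' Write class regions to GeoJSON
#'
#' @param regions List of [class_region()].
#' @param path Output `.geojson` path.
#' @param crs Optional CRS label stored as a foreign `crs` member.
#' @return `path`, invisibly.
#' @export
write_regions_geojson <- function(regions, path, crs = NULL) {
  stopifnot(length(regions) >= 1L)
  feats <- lapply(regions, function(r) {
    ring <- rbind(r$ring, r$ring[1, , drop = FALSE])  # GeoJSON rings are closed
    list(type = "Feature",
         properties = list(class_code = r$class_code, region_id = r$region_id),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  if (!is.null(crs)) fc$crs_label <- crs
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read class regions from GeoJSON
#'
#' Expects a FeatureCollection of single-ring Polygons whose properties carry
#' `class_code` (required) and `region_id` (generated when absent).
#'
#' @param path Path to a `.geojson` file.
#' @return List of [class_region()]; the file's `crs_label`, when present, is
#'   attached as attribute `"crs"`.
#' @export
read_regions_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$type) || fc$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection")
  }
  regions <- lapply(seq_along(fc$features), function(i) {
    f <- fc$features[[i]]
    if (f$geometry$type != "Polygon") stop("only Polygon geometries are supported")
    code <- f$properties$class_code
    if (is.null(code)) stop("feature without a class_code property")
    rid <- f$properties$region_id
    if (is.null(rid)) rid <- sprintf("r%03d", i)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) as.numeric(unlist(p))))
    class_region(ring, code, rid)
  })
  if (!is.null(fc$crs_label)) attr(regions, "crs") <- fc$crs_label
  regions
}
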