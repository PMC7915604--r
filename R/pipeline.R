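pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "_")
}

#' Enumerate unordered class pairs
#'
#' All `k (k - 1) / 2` unordered pairs of distinct codes, in canonical order
#' (codes sorted within the pair and pairs sorted lexicographically).
#'
#' @param class_codes Vector of at least two distinct class codes.
#' @return `data.frame(class_a, class_b, pair)`.
#' @examples
#' nrow(enumerate_pairs(c("3111", "3112", "3115", "3121", "3122")))  # 10
#' @export
enumerate_pairs <- function(class_codes) {
  codes <- sort(unique(as.character(class_codes)))
  if (length(codes) < 2L) stop("need at least 2 distinct class codes")
  cmb <- utils::combn(codes, 2)
  data.frame(class_a = cmb[1, ], class_b = cmb[2, ],
             pair = pair_key(cmb[1, ], cmb[2, ]),
             stringsAsFactors = FALSE)
}

#' Band-by-band pairwise separability table
#'
#' For every unordered class pair, every band and every requested metric, the
#' univariate (d = 1) separability from the classes' per-band mean and
#' standard deviation, with the `[0, 1]`-normalized value attached. Bands
#' where a metric is undefined even after variance flooring are recorded as
#' `NA` and counted in the `"qc"` attribute.
#'
#' @param stats_list List of `class_band_stats` (see [class_band_stats()]);
#'   all classes must share the same band list.
#' @param metrics Subset of `c("M", "B", "JM", "TD")`.
#' @param jm_sqrt JM convention flag.
#' @param eps Variance floor for degenerate bands.
#' @return `data.frame(class_a, class_b, pair, band_index, wavelength_nm,
#'   metric, value, normalized)` with every (pair, band, metric) exactly once.
#' @export
pairwise_separability <- function(stats_list, metrics = c("M", "B", "JM", "TD"),
                                  jm_sqrt = FALSE, eps = 1e-10) {
  metrics <- match.arg(metrics, c("M", "B", "JM", "TD"), several.ok = TRUE)
  stopifnot(length(stats_list) >= 2L)
  codes <- vapply(stats_list, function(s) s$class_code, character(1))
  names(stats_list) <- codes
  wl <- stats_list[[1]]$wavelength_nm
  for (s in stats_list) {
    if (!isTRUE(all.equal(s$wavelength_nm, wl))) {
      stop("band-list mismatch across classes")
    }
    if (s$n < 2L) stop("class ", s$class_code, " has n < 2")
  }
  pairs <- enumerate_pairs(codes)
  nb <- length(wl)
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- stats_list[[pairs$class_a[i]]]
    b <- stats_list[[pairs$class_b[i]]]
    uni <- separability_univariate(a$mu, a$sigma^2, b$mu, b$sigma^2,
                                   jm_sqrt = jm_sqrt, eps = eps)
    blocks <- lapply(metrics, function(m) {
      v <- uni[[m]]
      data.frame(class_a = pairs$class_a[i], class_b = pairs$class_b[i],
                 pair = pairs$pair[i], band_index = seq_len(nb),
                 wavelength_nm = wl, metric = m, value = v,
                 normalized = normalize_metric(ifelse(is.na(v), 0, v), m,
                                               jm_sqrt = jm_sqrt),
                 stringsAsFactors = FALSE)
    })
    res[[i]] <- do.call(rbind, blocks)
  }
  out <- do.call(rbind, res)
  out$normalized[is.na(out$value)] <- NA_real_
  attr(out, "qc") <- c(n_undefined = sum(is.na(out$value)))
  attr(out, "jm_sqrt") <- jm_sqrt
  rownames(out) <- NULL
  out
}

#' Best band for one class pair and metric
#'
#' The maximum separability over bands and the wavelength attaining it, ties
#' broken toward the lowest wavelength. `NA` (undefined) bands are excluded
#' from the maximum.
#'
#' @param table A [pairwise_separability()] table.
#' @param pair Canonical pair key (e.g. `"3111_3112"`).
#' @param metric One of the table's metrics.
#' @param sensor_name Optional sensor label carried into the result.
#' @return One-row `data.frame(pair, metric, max_value, wavelength_nm,
#'   band_index, sensor)`.
#' @export
best_band <- function(table, pair, metric, sensor_name = NA_character_) {
  sel <- table[table$pair == pair & table$metric == metric &
                 !is.na(table$value), , drop = FALSE]
  if (!nrow(sel)) stop(sprintf("no defined values for pair %s, metric %s",
                               pair, metric))
  sel <- sel[order(-sel$value, sel$wavelength_nm), , drop = FALSE]
  data.frame(pair = pair, metric = metric, max_value = sel$value[1],
             wavelength_nm = sel$wavelength_nm[1],
             band_index = sel$band_index[1], sensor = sensor_name,
             stringsAsFactors = FALSE)
}

#' Per-pair maxima for every metric in a table
#'
#' @param table A [pairwise_separability()] table.
#' @param sensor_name Sensor label attached to every row.
#' @return `data.frame` of [best_band()] rows, one per (pair, metric).
#' @export
pair_best <- function(table, sensor_name = NA_character_) {
  combos <- unique(table[, c("pair", "metric")])
  rows <- mapply(function(p, m) best_band(table, p, m, sensor_name),
                 combos$pair, combos$metric, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Best wavelength by the average of the normalized metrics
#'
#' Per band, the arithmetic mean of the four normalized metric values for a
#' pair; returns the band maximizing that mean (lowest-wavelength
#' tie-break). This is the statistic behind best-wavelength matrices: raw
#' averaging would be dominated by the unbounded B and M criteria, so the
#' `[0, 1]`-normalized values are averaged.
#'
#' @param table A [pairwise_separability()] table containing all four metrics.
#' @param pair Canonical pair key.
#' @return `list(wavelength_nm, band_index, mean_normalized)`.
#' @export
mean_metric_best_wavelength <- function(table, pair) {
  sel <- table[table$pair == pair, , drop = FALSE]
  have <- unique(sel$metric)
  missing_m <- setdiff(c("M", "B", "JM", "TD"), have)
  if (length(missing_m)) {
    stop("pair ", pair, ": missing metric(s) ", paste(missing_m, collapse = ", "))
  }
  agg <- stats::aggregate(normalized ~ band_index + wavelength_nm, data = sel,
                          FUN = mean)
  agg <- agg[order(-agg$normalized, agg$wavelength_nm), , drop = FALSE]
  list(wavelength_nm = agg$wavelength_nm[1], band_index = agg$band_index[1],
       mean_normalized = agg$normalized[1])
}

#' Best-wavelength matrix over all pairs
#'
#' @param table A [pairwise_separability()] table with all four metrics.
#' @return `data.frame(pair, class_a, class_b, wavelength_nm, band_index,
#'   mean_normalized)`, one row per pair.
#' @export
best_wavelength_matrix <- function(table) {
  pairs <- unique(table[, c("pair", "class_a", "class_b")])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    bw <- mean_metric_best_wavelength(table, pairs$pair[i])
    data.frame(pair = pairs$pair[i], class_a = pairs$class_a[i],
               class_b = pairs$class_b[i], wavelength_nm = bw$wavelength_nm,
               band_index = bw$band_index, mean_normalized = bw$mean_normalized,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
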