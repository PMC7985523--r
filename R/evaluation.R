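#' Relative and absolute sO2 estimation errors
#'
#' The relative error is `|est - gt| / gt`; rows with `gt = 0` are undefined
#' and returned as `NA` (summaries exclude them with a recorded count). The
#' absolute error is reported in percentage points, `100 * |est - gt|`.
#'
#' @param est,gt estimated and ground-truth sO2 fractions.
#' @return numeric vector of errors.
#' @export
relative_error <- function(est, gt) {
  out <- abs(est - gt) / gt
  out[gt <= 0] <- NA_real_
  out
}

#' @rdname relative_error
#' @export
absolute_error_pp <- function(est, gt) {
  100 * abs(est - gt)
}

#' Median and interquartile range of an error sequence
#'
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); alternative interpolation rules differ only
#' at the fourth decimal for the sample sizes used here.
#'
#' @param errors numeric vector; `NA` entries (e.g. excluded `gt = 0` rows)
#'   are dropped and counted.
#' @return list with `median`, `q25`, `q75`, `n`, `n_excluded`.
#' @export
summarize_errors <- function(errors) {
  n_excl <- sum(is.na(errors))
  errors <- errors[!is.na(errors)]
  if (!length(errors)) stopf("no finite errors to summarize")
  q <- unname(stats::quantile(errors, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2], q25 = q[1], q75 = q[3], n = length(errors),
       n_excluded = n_excl)
}

#' Full sO2 error summary
#'
#' Combines the relative and absolute error metrics into one report.
#'
#' @param est,gt estimated and ground-truth sO2 fractions.
#' @return object of class `error_summary` with medians and interquartile
#'   ranges of the relative error (fraction) and absolute error (percentage
#'   points), plus counts.
#' @export
error_summary <- function(est, gt) {
  stopifnot(length(est) == length(gt), length(est) >= 1)
  rel <- summarize_errors(relative_error(est, gt))
  abs_ <- summarize_errors(absolute_error_pp(est, gt))
  structure(list(median_relative = rel$median,
                 iqr_relative = c(rel$q25, rel$q75),
                 median_absolute_pp = abs_$median,
                 iqr_absolute_pp = c(abs_$q25, abs_$q75),
                 n = abs_$n, n_excluded_relative = rel$n_excluded),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary> n = %d\n", x$n))
  cat(sprintf("  relative: median %.1f%%, IQR (%.1f%%, %.1f%%)%s\n",
              100 * x$median_relative, 100 * x$iqr_relative[1],
              100 * x$iqr_relative[2],
              if (x$n_excluded_relative > 0)
                sprintf(" [%d gt=0 rows excluded]", x$n_excluded_relative)
              else ""))
  cat(sprintf("  absolute: median %.1f pp, IQR (%.1f, %.1f) pp\n",
              x$median_absolute_pp, x$iqr_absolute_pp[1],
              x$iqr_absolute_pp[2]))
  invisible(x)
}

#' Severinghaus oxygen dissociation curve
#'
#' Converts partial oxygen pressure to hemoglobin oxygen saturation with the
#' standard empirical form `so2 = (23400 / (po2^3 + 150 po2) + 1)^-1`. The
#' curve is strictly increasing and bounded in (0, 1); the constants are
#' overridable.
#'
#' @param po2 partial oxygen pressure in mmHg (> 0).
#' @param k numerator constant (default 23400).
#' @param c linear coefficient (default 150).
#' @return sO2 fraction(s).
#' @export
severinghaus_so2 <- function(po2, k = 23400, c = 150) {
  if (any(po2 <= 0)) stopf("po2 must be positive (mmHg)")
  1 / (k / (po2^3 + c * po2) + 1)
}

#' @rdname severinghaus_so2
#' @param so2 saturation fraction(s) in (0, 1); inverted by root-solving.
#' @export
severinghaus_po2 <- function(so2, k = 23400, c = 150) {
  vapply(so2, function(s) {
    if (s <= 0 || s >= 1) stopf("so2 must lie strictly between 0 and 1")
    stats::uniroot(function(p) severinghaus_so2(p, k, c) - s,
                   lower = 1e-6, upper = 5000, tol = 1e-10)$root
  }, numeric(1))
}

#' ROI statistic tracked over time
#'
#' Per-frame summary of sO2 estimates inside a region of interest:
#' mean with standard deviation (flow-phantom style) or median with IQR
#' half-width. Frames whose mask holds no finite estimate give `NA`.
#'
#' @param so2_maps 3D array `[n_frames, ny, nz]` or list of matrices.
#' @param mask logical ROI matrix.
#' @param statistic `"mean"` or `"median"`.
#' @return data frame with columns `frame`, `value`, `dispersion`, `n`.
#' @export
roi_time_series <- function(so2_maps, mask, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (is.list(so2_maps)) {
    arr <- array(NA_real_, dim = c(length(so2_maps), dim(so2_maps[[1]])))
    for (i in seq_along(so2_maps)) arr[i, , ] <- so2_maps[[i]]
    so2_maps <- arr
  }
  if (!identical(dim(so2_maps)[2:3], dim(mask)))
    stopf("mask shape does not match the maps")
  nfr <- dim(so2_maps)[1]
  out <- data.frame(frame = seq_len(nfr), value = NA_real_,
                    dispersion = NA_real_, n = 0L)
  for (t in seq_len(nfr)) {
    v <- so2_maps[t, , ][mask]
    v <- v[is.finite(v)]
    out$n[t] <- length(v)
    if (!length(v)) next
    if (statistic == "mean") {
      out$value[t] <- mean(v)
      out$dispersion[t] <- stats::sd(v)
    } else {
      out$value[t] <- stats::median(v)
      out$dispersion[t] <- diff(stats::quantile(v, c(0.25, 0.75))) / 2
    }
  }
  out
}

#' Dynamic range of a time series of estimates
#'
#' Maximum and minimum of the per-frame statistic; used to compare how much
#' of the physiological range a method's response spans.
#'
#' @param series numeric vector or the data frame from [roi_time_series()].
#' @return named vector `c(max, min)`.
#' @export
dynamic_range <- function(series) {
  if (is.data.frame(series)) series <- series$value
  series <- series[is.finite(series)]
  if (!length(series)) stopf("series holds no finite values")
  c(max = max(series), min = min(series))
}
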