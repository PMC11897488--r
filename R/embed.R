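#' Sliding-window (delay) embedding of a time series
#'
#' Maps a scalar series f into the point cloud
#' \eqn{t \mapsto (f(t), f(t+\tau), \ldots, f(t+M\tau))}, t = 1, ..., N - M*tau,
#' turning temporal structure into geometry. With the defaults `m = 2`,
#' `tau = 1` (a window of three consecutive samples) every point lives in
#' \eqn{R^3} and a length-N series yields N - 2 points.
#'
#' @param x Numeric series of length N.
#' @param m Embedding dimension M (window covers M+1 samples).
#' @param tau Time lag in samples.
#' @param scale If `TRUE`, z-score the series before embedding (off by
#'   default; raw amplitudes carry signal).
#' @return A numeric matrix with N - M*tau rows (time order preserved) and
#'   M + 1 columns.
#' @examples
#' embed_series(c(1, 2, 3, 4))          # rows (1,2,3), (2,3,4)
#' @export
embed_series <- function(x, m = 2, tau = 1, scale = FALSE) {
  m <- assert_count(m, "m"); tau <- assert_count(tau, "tau")
  x <- as.numeric(x)
  n <- length(x)
  if (n <= m * tau)
    abort(sprintf("series too short: length %d with M = %d, tau = %d needs N > %d",
                  n, m, tau, m * tau),
          class = "topofc_series_too_short")
  if (scale) {
    s <- sd(x)
    if (s == 0) abort("cannot z-score a constant series")
    x <- (x - mean(x)) / s
  }
  k <- n - m * tau
  out <- vapply(0:m, function(j) x[(1 + j * tau):(k + j * tau)], numeric(k))
  dimnames(out) <- list(NULL, paste0("x", seq_len(m + 1)))
  out
}

#' Embed every ROI series of a panel
#'
#' Applies [embed_series()] to each subject x ROI row of a panel, returning a
#' tibble with one point-cloud matrix per row in the `cloud` list-column.
#'
#' @param panel Panel tibble (see [generate_cohort()]).
#' @inheritParams embed_series
#' @return Tibble with columns `subject_id`, `group`, `roi_id`, `network`,
#'   `cloud` (list of matrices).
#' @export
embed_panel <- function(panel, m = 2, tau = 1, scale = FALSE) {
  tc <- time_cols(panel)
  vals <- as.matrix(panel[, tc, drop = FALSE])
  tibble(subject_id = panel$subject_id, group = panel$group,
         roi_id = panel$roi_id, network = panel$network,
         cloud = lapply(seq_len(nrow(vals)), function(i)
           embed_series(vals[i, ], m = m, tau = tau, scale = scale)))
}
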