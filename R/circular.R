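# Circular statistics on wingbeat phases (degrees). The circular median is
# the angle minimising the mean circular absolute deviation; quartiles are
# the 25%/75% cumulative-mass points of the data unwrapped around the
# median.

circ_dev <- function(theta_deg, m_deg) {
  d <- abs(theta_deg - m_deg) %% 360
  pmin(d, 360 - d)
}

#' Circular median and quartiles of phase angles
#'
#' `circ_median()` minimises the mean circular absolute deviation over a
#' fine grid of candidate angles (0.1 deg resolution, using binned masses so
#' large samples stay cheap). `circ_quartiles()` unwraps the sample into
#' `(median - 180, median + 180]` and takes ordinary 25%/75% quantiles,
#' i.e. the cumulative-mass quartiles around the circular median.
#'
#' @param theta_deg Angles in degrees.
#' @param grid_deg Candidate-grid resolution for the median, degrees.
#' @return `circ_median()`: one angle in `[0, 360)`. `circ_quartiles()`:
#'   named vector `c(q25, q50, q75)` (q25 may exceed q75 numerically after
#'   wrapping back to `[0, 360)`).
#' @export
circ_median <- function(theta_deg, grid_deg = 0.1) {
  theta_deg <- theta_deg[!is.na(theta_deg)]
  if (!length(theta_deg)) return(NA_real_)
  theta <- theta_deg %% 360
  if (length(theta) <= 720) {
    cand <- sort(unique(c(theta, (theta + 180) %% 360)))
    dev <- vapply(cand, function(m) mean(circ_dev(theta, m)), numeric(1))
    return(cand[which.min(dev)])
  }
  # binned evaluation for large samples
  nb <- round(360 / grid_deg)
  cnt <- tabulate(pmin(nb, floor(theta / grid_deg) + 1L), nbins = nb)
  centers <- (seq_len(nb) - 0.5) * grid_deg
  keep <- cnt > 0
  cand <- centers
  dev <- vapply(cand, function(m) {
    sum(cnt[keep] * circ_dev(centers[keep], m)) / sum(cnt)
  }, numeric(1))
  cand[which.min(dev)]
}

#' @rdname circ_median
#' @export
circ_quartiles <- function(theta_deg) {
  theta_deg <- theta_deg[!is.na(theta_deg)]
  if (!length(theta_deg)) return(c(q25 = NA_real_, q50 = NA_real_, q75 = NA_real_))
  m <- circ_median(theta_deg)
  unwrapped <- ((theta_deg - m + 180) %% 360) - 180 + m
  q <- quantile(unwrapped, c(0.25, 0.75), names = FALSE, type = 7)
  c(q25 = q[1] %% 360, q50 = m, q75 = q[2] %% 360)
}
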