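#' Onset latency of a band modulation time course
#'
#' Two-stage onset estimate for a single trial's band time course on the
#' `[-100, 400]` ms reversal window.  Stage 1: the first time point at which
#' the series stays beyond a percentile threshold of its own samples (below
#' the 25th percentile for the narrow band, whose modulation is a decrease;
#' above the 75th for the broad band) for at least `hold_ms` (40 ms); trials
#' that never satisfy the criterion are discarded.  Stage 2: a 200 ms window
#' centered on that point is segmented into 50 ms bins with 80% overlap, a
#' linear regression is fit to each bin, and the onset is the first time
#' point of the bin combining the steepest (sign-adjusted) slope with the
#' smallest residual error: among bins whose slope is within 5% of the
#' steepest, the one with the smallest residual sum of squares wins.
#'
#' @param time_ms sample times (ms relative to the reversal).
#' @param values band modulation values at `time_ms`.
#' @param polarity "below" (narrow band) or "above" (broad band).
#' @param hold_ms minimum time beyond threshold (default 40 ms).
#' @param bin_ms,bin_overlap regression bin length (default 50 ms) and
#'   overlap fraction (default 0.8).
#' @param slope_tol bins with slope within this fraction of the steepest are
#'   eligible for the residual tie-break (default 0.05).
#' @return list with `onset_ms` (NA if discarded), `discarded` (logical),
#'   `reason` (character), `threshold`.
#' @export
#' @examples
#' t <- seq(-100, 400)
#' x <- ifelse(t < 100, 0, -(t - 100) / 50)  # ramp down from 100 ms
#' onset_latency_trial(t, x, "below")$onset_ms
onset_latency_trial <- function(time_ms, values, polarity = c("below", "above"),
                                hold_ms = 40, bin_ms = 50, bin_overlap = 0.8,
                                slope_tol = 0.05) {
  polarity <- match.arg(polarity)
  stopifnot(length(time_ms) == length(values))
  dt <- median(diff(time_ms))
  if (diff(range(time_ms)) < 200 - 1e-9)
    return(list(onset_ms = NA_real_, discarded = TRUE,
                reason = "series shorter than the 200 ms analysis window",
                threshold = NA_real_))
  thr <- unname(quantile(values, if (polarity == "below") 0.25 else 0.75))
  beyond <- if (polarity == "below") values < thr else values > thr
  need <- max(1L, ceiling(hold_ms / dt))
  r <- rle(beyond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= need)
  if (length(ok) == 0)
    return(list(onset_ms = NA_real_, discarded = TRUE,
                reason = "threshold never held for the minimum duration",
                threshold = thr))
  t0 <- time_ms[starts[ok[1]]]

  sel <- time_ms >= t0 - 100 & time_ms <= t0 + 100
  tw <- time_ms[sel]
  xw <- values[sel]
  nbin <- max(2L, round(bin_ms / dt))
  step <- max(1L, round(nbin * (1 - bin_overlap)))
  b0 <- seq(1L, length(tw) - nbin + 1L, by = step)
  slope <- resid <- tstart <- numeric(length(b0))
  for (i in seq_along(b0)) {
    idx <- b0[i]:(b0[i] + nbin - 1L)
    ft <- lm(xw[idx] ~ tw[idx])
    slope[i] <- coef(ft)[2]
    resid[i] <- sum(ft$residuals^2)
    tstart[i] <- tw[b0[i]]
  }
  eff <- if (polarity == "below") -slope else slope
  best <- max(eff)
  cand <- which(eff >= best * (1 - slope_tol) - 1e-15)
  pick <- cand[which.min(resid[cand])]
  list(onset_ms = tstart[pick], discarded = FALSE, reason = NA_character_,
       threshold = thr)
}

#' Onset latencies for a set of trials
#'
#' Applies [onset_latency_trial] to every row of a trial x time matrix.
#'
#' @param time_ms common time axis (ms relative to the reversal).
#' @param trials matrix, one trial per row.
#' @param polarity "below" (NB) or "above" (BB).
#' @param ... further arguments to [onset_latency_trial].
#' @return data.frame with columns `trial`, `onset_ms`, `discarded`,
#'   `reason`.
#' @export
onset_latency <- function(time_ms, trials, polarity = c("below", "above"),
                          ...) {
  polarity <- match.arg(polarity)
  trials <- as.matrix(trials)
  res <- lapply(seq_len(nrow(trials)), function(i)
    onset_latency_trial(time_ms, trials[i, ], polarity, ...))
  data.frame(trial = seq_len(nrow(trials)),
             onset_ms = vapply(res, `[[`, 1, "onset_ms"),
             discarded = vapply(res, `[[`, TRUE, "discarded"),
             reason = vapply(res, `[[`, "", "reason"))
}
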