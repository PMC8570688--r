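#' Morse-wavelet scalogram
#'
#' Continuous wavelet transform with the analytic generalized Morse wavelet,
#' symmetry parameter `gamma = 3` and time-bandwidth product `tb = 60`
#' (so `beta = tb/gamma = 20`), evaluated by frequency-domain filtering on a
#' logarithmic frequency grid.
#'
#' @param lfp an `lfp_trace` or numeric vector.
#' @param fs sampling rate (Hz) if `lfp` is a bare vector; traces are
#'   expected at 1 kHz for the standard analysis.
#' @param freq_range `[lo, hi]` output frequency range (Hz).
#' @param voices frequencies per octave on the log-spaced grid.
#' @param gamma,tb Morse symmetry and time-bandwidth parameters.
#' @return object of class `scalogram`: list with `time_ms`, `freq` (Hz,
#'   increasing), `magnitude` (freq x time matrix, >= 0), `fs`, and the
#'   wavelet parameters.
#' @export
#' @examples
#' x <- sin(2 * pi * 60 * seq(0, 1, by = 1e-3))
#' sc <- morse_scalogram(x, fs = 1000)
#' sc$freq[which.max(rowMeans(sc$magnitude))]  # ~60
morse_scalogram <- function(lfp, fs = NULL, freq_range = c(10, 120),
                            voices = 12, gamma = 3, tb = 60) {
  if (inherits(lfp, "lfp_trace")) {
    x <- lfp$values
    fs <- lfp$fs
  } else {
    if (is.null(fs)) stop("fs required for a bare numeric trace", call. = FALSE)
    x <- as.numeric(lfp)
  }
  n <- length(x)
  beta <- tb / gamma
  wp <- (beta / gamma)^(1 / gamma)  # peak radian frequency of the wavelet
  n_oct <- log2(freq_range[2] / freq_range[1])
  freqs <- freq_range[1] * 2^(seq(0, n_oct, by = 1 / voices))
  omega <- 2 * pi * (0:(n - 1)) / n  # radian frequency per fft bin
  omega[omega > pi] <- 0             # keep only non-negative frequencies
  xf <- fft(x - mean(x))
  mag <- matrix(0, nrow = length(freqs), ncol = n)
  lognorm <- beta / gamma * (1 + log(gamma / beta))  # log of (e*gamma/beta)^(beta/gamma)
  for (i in seq_along(freqs)) {
    scale <- wp / (2 * pi * freqs[i] / fs)
    w <- omega * scale
    psi <- numeric(n)
    pos <- w > 0
    # analytic Morse filter, peak value 2 (L1-type normalization)
    psi[pos] <- 2 * exp(lognorm + beta * log(w[pos]) - w[pos]^gamma)
    mag[i, ] <- Mod(fft(xf * psi, inverse = TRUE) / n)
  }
  structure(list(time_ms = (seq_len(n) - 1) * 1000 / fs, freq = freqs,
                 magnitude = mag, fs = fs, gamma = gamma, tb = tb,
                 voices = voices),
            class = "scalogram")
}

#' Segment a scalogram around contrast reversals
#'
#' Cuts `[-pre, post]` ms windows around each reversal time and averages the
#' magnitude across them.  Reversals whose window falls (even partly) within
#' the first `exclude_onset_s` seconds after screen onset, or outside the
#' trace, are skipped (the onset evokes flash-like responses that are not
#' contrast responses).
#'
#' @param scal a `scalogram`.
#' @param reversal_times_s reversal times (s, relative to trace start).
#' @param pre_ms,post_ms window extent around the reversal (default -100 to
#'   +400 ms).
#' @param exclude_onset_s exclusion zone after screen onset (default 0.5 s).
#' @return object of class `scalogram` with `time_ms` relative to the
#'   reversal and `n_segments` attached; error if no usable segment remains.
#' @export
segment_scalogram <- function(scal, reversal_times_s, pre_ms = 100,
                              post_ms = 400, exclude_onset_s = 0.5) {
  stopifnot(inherits(scal, "scalogram"))
  dt <- 1000 / scal$fs
  n <- ncol(scal$magnitude)
  npre <- round(pre_ms / dt)
  npost <- round(post_ms / dt)
  acc <- NULL
  used <- 0L
  for (tr in reversal_times_s * 1000) {
    if (tr - pre_ms < exclude_onset_s * 1000) next
    i0 <- round(tr / dt) + 1L
    lo <- i0 - npre
    hi <- i0 + npost
    if (lo < 1L || hi > n) next
    seg <- scal$magnitude[, lo:hi, drop = FALSE]
    acc <- if (is.null(acc)) seg else acc + seg
    used <- used + 1L
  }
  if (used == 0L)
    stop("segmentation error: no reversal window fits inside the trace",
         call. = FALSE)
  structure(list(time_ms = seq(-npre, npost) * dt, freq = scal$freq,
                 magnitude = acc / used, fs = scal$fs, gamma = scal$gamma,
                 tb = scal$tb, voices = scal$voices, n_segments = used),
            class = "scalogram")
}

#' Scalogram modulation relative to a reference
#'
#' Pointwise `(M - M_ref) / M_ref` of two magnitude maps on the same
#' time-frequency grid (e.g. contrast K vs the mean K = 30 map).
#'
#' @param scal a `scalogram`.
#' @param reference a `scalogram` on the same grid, or a per-frequency
#'   vector (a stationary reference).
#' @return a `scalogram`-shaped object whose `magnitude` holds the
#'   (sign-carrying) modulation fractions.
#' @export
scalogram_modulation <- function(scal, reference) {
  ref <- if (inherits(reference, "scalogram")) reference$magnitude
         else matrix(reference, nrow = length(scal$freq),
                     ncol = ncol(scal$magnitude))
  if (!all(dim(ref) == dim(scal$magnitude)))
    stop("scalogram grids do not match", call. = FALSE)
  if (any(ref <= 0))
    stop("degenerate reference: zero magnitude", call. = FALSE)
  out <- scal
  out$magnitude <- (scal$magnitude - ref) / ref
  out
}

#' Derive band limits from a modulation profile
#'
#' Applies the threshold rule that defines the gamma sub-bands: the broad
#' band (BB) is the set of frequencies whose modulation exceeds the
#' threshold (default 20%), expected to form two disjoint ranges; the narrow
#' band (NB) is the interval between them.
#'
#' @param freq frequency grid (Hz, increasing).
#' @param modulation modulation values on `freq` (a frequency profile, e.g.
#'   the time-averaged K = 90 vs K = 0 scalogram modulation), or a
#'   `modulation_curve`.
#' @param threshold modulation threshold (fraction, default 0.2).
#' @return object of class `band_definition`: list with `nb` (c(lo, hi) or
#'   NULL), `bb` (matrix of ranges), `threshold`, `empty` flag.
#' @export
#' @examples
#' f <- seq(10, 110, by = 1)
#' m <- ifelse((f >= 20 & f < 45) | (f > 65 & f <= 95), 0.5,
#'             ifelse(f >= 45 & f <= 65, -0.3, 0))
#' derive_band_limits(f, m)$nb  # c(45, 65)
derive_band_limits <- function(freq, modulation = NULL, threshold = 0.2) {
  if (inherits(freq, "modulation_curve")) {
    modulation <- freq$modulation
    freq <- freq$freq
  }
  stopifnot(length(freq) == length(modulation))
  above <- modulation > threshold
  if (!any(above)) {
    return(structure(list(nb = NULL, bb = NULL, threshold = threshold,
                          empty = TRUE),
                     class = "band_definition"))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  bb <- cbind(freq[runs[, 1]], freq[runs[, 2]])
  nb <- if (nrow(bb) >= 2) c(bb[1, 2], bb[2, 1]) else NULL
  structure(list(nb = nb, bb = bb, threshold = threshold, empty = FALSE),
            class = "band_definition")
}

#' Default gamma band definition
#'
#' The canonical bands of the analysis: NB = [45, 65] Hz, BB = [20, 45] and
#' [65, 95] Hz.
#'
#' @return a `band_definition`.
#' @export
default_bands <- function() {
  structure(list(nb = c(45, 65),
                 bb = rbind(c(20, 45), c(65, 95)),
                 threshold = 0.2, empty = FALSE),
            class = "band_definition")
}

#' Band modulation time course
#'
#' Per-time median of a scalogram modulation map across the frequencies of
#' one band.
#'
#' @param mod_scal a modulation map from [scalogram_modulation] (or any
#'   `scalogram`-shaped object).
#' @param band band ranges: a two-element vector, a matrix of ranges, or a
#'   `band_definition` together with `which`.
#' @param which for a `band_definition`: "nb" or "bb".
#' @return list with `time_ms` and `values` (median modulation per time).
#' @export
band_timecourse <- function(mod_scal, band, which = c("nb", "bb")) {
  if (inherits(band, "band_definition")) {
    which <- match.arg(which)
    band <- if (which == "nb") band$nb else band$bb
  }
  if (is.null(dim(band))) band <- matrix(band, ncol = 2, byrow = TRUE)
  sel <- rep(FALSE, length(mod_scal$freq))
  for (i in seq_len(nrow(band)))
    sel <- sel | (mod_scal$freq >= band[i, 1] & mod_scal$freq <= band[i, 2])
  if (!any(sel)) stop("band outside the scalogram frequency grid", call. = FALSE)
  vals <- apply(mod_scal$magnitude[sel, , drop = FALSE], 2, median)
  list(time_ms = mod_scal$time_ms, values = vals)
}
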