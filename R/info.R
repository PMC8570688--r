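#' Equipopulated discretization of a response variable
#'
#' Discretizes a continuous response (e.g. per-trial band power modulation)
#' into `n_bins` bins containing (up to a remainder of one) the same number
#' of trials, which maximizes the response entropy and is robust to
#' outliers.  Assignment is rank-based, so it is deterministic even with
#' ties; a warning is issued when ties force equal values into different
#' bins.
#'
#' @param values response samples.
#' @param n_bins number of bins (default 10).
#' @return list with `bin` (1-based indices), `edges` (empirical quantile
#'   boundaries, length `n_bins + 1`), `n_bins`.
#' @export
#' @examples
#' b <- equipopulated_bins(rnorm(100), 10)
#' table(b$bin)  # ten bins of ten
equipopulated_bins <- function(values, n_bins = 10) {
  n <- length(values)
  if (n_bins > n)
    stop("n_bins must not exceed the number of samples", call. = FALSE)
  rk <- rank(values, ties.method = "first")
  bin <- ceiling(rk * n_bins / n)
  # tie check: does any equal-value group straddle a bin boundary?
  split_ties <- anyDuplicated(values) &&
    any(vapply(split(bin, match(values, values)), function(b)
      length(unique(b)) > 1L, TRUE))
  if (split_ties)
    warning("ties straddle bin boundaries; deterministic rank-based assignment used")
  edges <- unname(quantile(values, probs = seq(0, 1, length.out = n_bins + 1)))
  list(bin = as.integer(bin), edges = edges, n_bins = as.integer(n_bins))
}

#' Discretized stimulus-response pairing
#'
#' Couples per-trial stimulus labels (contrast K) with the equipopulated bin
#' index of the response, pooled over all trials and recordings.
#'
#' @param stimulus per-trial stimulus labels.
#' @param response per-trial continuous responses (same length), or an
#'   already-discretized integer bin vector (used as is).
#' @param n_bins number of equipopulated bins (default 10).
#' @return object of class `discretized_response`: list with `stimulus`,
#'   `bin`, `edges`, `n_bins`, `n_trials`.
#' @export
discretize_response <- function(stimulus, response, n_bins = 10) {
  stopifnot(length(stimulus) == length(response))
  if (is.integer(response) && !anyNA(response) && min(response) >= 1L) {
    bin <- response
    edges <- NULL
    n_bins <- max(response)
  } else {
    eb <- equipopulated_bins(as.numeric(response), n_bins)
    bin <- eb$bin
    edges <- eb$edges
  }
  structure(list(stimulus = stimulus, bin = bin, edges = edges,
                 n_bins = as.integer(n_bins), n_trials = length(stimulus)),
            class = "discretized_response")
}

.joint_table <- function(disc) {
  table(factor(disc$stimulus), factor(disc$bin, levels = seq_len(disc$n_bins)))
}

.plugin_mi_table <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  ps <- rowSums(p)
  pr <- colSums(p)
  nz <- p > 0
  outer_p <- outer(ps, pr)
  sum(p[nz] * log2(p[nz] / outer_p[nz]))
}

# Bayesian estimate of the number of relevant (nonzero-probability) response
# bins from an empirical distribution (the Panzeri-Treves counting procedure).
.pt_bayescount <- function(pr, n_trials, dim = length(pr)) {
  prnz <- pr[pr > .Machine$double.eps]
  r_naive <- length(prnz)
  if (r_naive >= dim) return(r_naive)
  r_expected <- r_naive - sum((1 - prnz)^n_trials)
  delta_prev <- dim
  delta <- abs(r_naive - r_expected)
  xtr <- 0
  while (delta < delta_prev && (r_naive + xtr) < dim) {
    xtr <- xtr + 1
    gam <- xtr * (1 - (n_trials / (n_trials + r_naive))^(1 / n_trials))
    pbayes <- ((1 - gam) / (n_trials + r_naive)) * (prnz * n_trials + 1)
    r_expected <- sum(1 - (1 - pbayes)^n_trials) +
      xtr * (1 - (1 - gam / xtr)^n_trials)
    delta_prev <- delta
    delta <- abs(r_naive + xtr - r_expected)
  }
  r <- r_naive + xtr - 1
  if (delta < delta_prev) r <- r + 1
  r
}

# analytic limited-sampling bias of the plugin MI (bits)
.pt_bias <- function(tab) {
  n <- sum(tab)
  n_resp <- ncol(tab)
  r_tot <- .pt_bayescount(colSums(tab) / n, n, n_resp)
  r_s <- apply(tab, 1, function(row) {
    ns <- sum(row)
    if (ns == 0) return(0)
    .pt_bayescount(row / ns, ns, n_resp)
  })
  (sum(pmax(r_s - 1, 0)) - (r_tot - 1)) / (2 * n * log(2))
}

# quadratic-extrapolation + bootstrap corrected MI: the plugin information
# is extrapolated to infinite trial count (quadratic in 1/N over 100/50/25%
# subsets), and the shuffled-label information, extrapolated identically, is
# subtracted so that residual extrapolation bias cancels.
.mi_qe <- function(stimulus, bin, n_bins, n_draws = 20, n_shuffles = 20) {
  n <- length(stimulus)
  disc_tab <- function(s, b)
    table(factor(s), factor(b, levels = seq_len(n_bins)))
  sizes <- c(n, round(0.5 * n), round(0.25 * n))
  inv_n <- 1 / sizes
  extrap <- function(means) solve(cbind(1, inv_n, inv_n^2), means)[1]

  means <- c(.plugin_mi_table(disc_tab(stimulus, bin)),
             vapply(sizes[2:3], function(m) {
               mean(vapply(seq_len(n_draws), function(d) {
                 idx <- sample.int(n, m)
                 .plugin_mi_table(disc_tab(stimulus[idx], bin[idx]))
               }, 0))
             }, 0))
  sh_means <- vapply(sizes, function(m) {
    mean(vapply(seq_len(n_shuffles), function(d) {
      idx <- if (m == n) seq_len(n) else sample.int(n, m)
      .plugin_mi_table(disc_tab(sample(stimulus)[idx], bin[idx]))
    }, 0))
  }, 0)
  extrap(means) - extrap(sh_means)
}

#' Mutual information between stimulus and discretized response
#'
#' Plugin mutual information
#' `I = sum_k sum_r p(k, r) log2( p(k, r) / (p(k) p(r)) )` from the empirical
#' joint table, with a limited-sampling bias correction: "pt" subtracts the
#' analytic Panzeri-Treves bias term (with Bayesian relevant-bin counting),
#' "qe" uses quadratic extrapolation over 100/50/25% trial subsets plus a
#' shuffled-label bootstrap term, "none" returns the plugin value.
#'
#' @param disc a [discretize_response] object.
#' @param correction "pt" (default), "qe", or "none".
#' @param n_draws,n_shuffles subset draws per fraction and label shuffles for
#'   the "qe" correction.
#' @param seed optional seed for the "qe" resampling.
#' @return object of class `mi_estimate`: list with `plugin` (bits),
#'   `corrected` (bits; may be negative), `method`, `n_trials`.
#' @export
#' @examples
#' d <- discretize_response(rep(1:5, 40), rep(1:5, 40) + rnorm(200, 0, 1e-3))
#' mutual_information(d, "none")$plugin  # ~ log2(5)
mutual_information <- function(disc, correction = c("pt", "qe", "none"),
                               n_draws = 20, n_shuffles = 20, seed = NULL) {
  correction <- match.arg(correction)
  stopifnot(inherits(disc, "discretized_response"))
  if (length(unique(disc$stimulus)) < 2)
    stop("undefined information: need at least two stimulus levels", call. = FALSE)
  tab <- .joint_table(disc)
  plugin <- .plugin_mi_table(tab)
  corrected <- switch(correction,
    none = plugin,
    pt = plugin - .pt_bias(tab),
    qe = {
      if (!is.null(seed)) {
        old <- .save_seed(); on.exit(.restore_seed(old))
        set.seed(as.integer(seed))
      }
      .mi_qe(disc$stimulus, disc$bin, disc$n_bins, n_draws, n_shuffles)
    })
  structure(list(plugin = plugin, corrected = corrected, method = correction,
                 n_trials = disc$n_trials),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("MI: %.4f bits (plugin %.4f, %s correction, n = %d)\n",
              x$corrected, x$plugin, x$method, x$n_trials))
  invisible(x)
}

#' Bootstrap significance threshold for mutual information
#'
#' Shuffles the stimulus labels `n_surrogates` times, recomputes the
#' (bias-corrected) information for each surrogate, and returns the
#' requested percentile (default the 95th, the p = 0.05 criterion).
#'
#' @param disc a [discretize_response] object.
#' @param n_surrogates number of label shuffles (>= 100; default 200).
#' @param percentile percentile of the surrogate distribution (default 95).
#' @param correction bias correction applied to each surrogate (default
#'   "pt", matching the estimate it gates).
#' @param seed optional seed.
#' @return threshold in bits.
#' @export
significance_threshold_bootstrap <- function(disc, n_surrogates = 200,
                                             percentile = 95,
                                             correction = "pt", seed = NULL) {
  if (n_surrogates < 100)
    stop("n_surrogates must be at least 100", call. = FALSE)
  if (!is.null(seed)) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(as.integer(seed))
  }
  vals <- vapply(seq_len(n_surrogates), function(i) {
    d <- disc
    d$stimulus <- sample(d$stimulus)
    mutual_information(d, correction)$corrected
  }, 0)
  unname(quantile(vals, percentile / 100))
}

#' Range-restricted information
#'
#' Information about one contrast sub-range: the stimulus-response
#' association is destroyed in the complementary range (responses permuted
#' among those trials only), the mutual information is recomputed for each
#' of `n_permutations` permutations (default 500), and the average is
#' returned with a quadratic-extrapolation + bootstrap bias term.
#'
#' @param disc a [discretize_response] with numeric stimulus (contrast K).
#' @param restricted_range "low" (information about K < `k_split`) or "high".
#' @param k_split boundary contrast (default 30).
#' @param n_permutations permutations of the complementary range (default
#'   500).
#' @param n_bias_permutations permutations on which the QE bias term is
#'   evaluated and averaged (default 20).
#' @param seed optional seed.
#' @return object of class `mi_estimate` with extra fields
#'   `n_permutations_used` and `restricted_range`.
#' @export
range_restricted_information <- function(disc,
                                         restricted_range = c("low", "high"),
                                         k_split = 30, n_permutations = 500,
                                         n_bias_permutations = 20,
                                         seed = NULL) {
  restricted_range <- match.arg(restricted_range)
  stopifnot(inherits(disc, "discretized_response"))
  k <- as.numeric(disc$stimulus)
  keepers <- if (restricted_range == "low") k < k_split else k > k_split
  others <- !keepers
  if (!any(keepers))
    stop("restricted range contains no trials", call. = FALSE)
  if (!any(others)) {
    warning("complementary range empty; returning unrestricted information")
    out <- mutual_information(disc, "qe", seed = seed)
    out$n_permutations_used <- 0L
    out$restricted_range <- restricted_range
    return(out)
  }
  if (!is.null(seed)) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(as.integer(seed))
  }
  oth_idx <- which(others)
  permuted_bins <- function() {
    b <- disc$bin
    b[oth_idx] <- b[sample(oth_idx)]
    b
  }
  plugin_vals <- vapply(seq_len(n_permutations), function(i) {
    .plugin_mi_table(table(factor(disc$stimulus),
                           factor(permuted_bins(), levels = seq_len(disc$n_bins))))
  }, 0)
  bias_vals <- vapply(seq_len(n_bias_permutations), function(i) {
    b <- permuted_bins()
    plug <- .plugin_mi_table(table(factor(disc$stimulus),
                                   factor(b, levels = seq_len(disc$n_bins))))
    plug - .mi_qe(disc$stimulus, b, disc$n_bins)
  }, 0)
  plugin <- mean(plugin_vals)
  structure(list(plugin = plugin, corrected = plugin - mean(bias_vals),
                 method = "qe", n_trials = disc$n_trials,
                 n_permutations_used = length(plugin_vals),
                 restricted_range = restricted_range),
            class = "mi_estimate")
}

#' Stimulus-specific information
#'
#' Specific (surprise) information carried by the response about one
#' stimulus value: `I(K = k; R) = sum_r p(r | k) log2( p(r | k) / p(r) )`.
#'
#' @param disc a [discretize_response] object.
#' @return named vector of specific informations, one per stimulus level
#'   (bits).
#' @export
specific_information <- function(disc) {
  tab <- .joint_table(disc)
  n <- sum(tab)
  pr <- colSums(tab) / n
  out <- apply(tab, 1, function(row) {
    ns <- sum(row)
    if (ns == 0) return(0)
    prk <- row / ns
    nz <- prk > 0
    sum(prk[nz] * log2(prk[nz] / pr[nz]))
  })
  out
}

#' Minimum-information redundancy
#'
#' Redundancy between two responses about the stimulus, measured as the
#' expected value over stimuli of the smaller stimulus-specific information:
#' `Red = sum_k p(k) min( I(K = k; NB), I(K = k; BB) )`.  Non-negative and
#' bounded by the smaller marginal information in the specific-surprise
#' average sense.
#'
#' @param disc_nb,disc_bb two [discretize_response] objects over the same
#'   trials (identical stimulus vectors).
#' @return redundancy in bits.
#' @export
redundancy_min_information <- function(disc_nb, disc_bb) {
  if (disc_nb$n_trials != disc_bb$n_trials ||
      !identical(as.character(disc_nb$stimulus), as.character(disc_bb$stimulus)))
    stop("alignment error: the two responses must share the same trials",
         call. = FALSE)
  si_nb <- specific_information(disc_nb)
  si_bb <- specific_information(disc_bb)
  pk <- table(factor(disc_nb$stimulus)) / disc_nb$n_trials
  sum(as.numeric(pk) * pmin(si_nb, si_bb))
}

#' Synergy decomposition of two band responses
#'
#' Decomposes the joint information the two gamma bands carry about the
#' stimulus: `Syn = I(K; NB, BB) - [I(K; NB) + I(K; BB)] + Red`, where the
#' joint response is the (NB bin, BB bin) pair and `Red` is the
#' minimum-information redundancy.
#'
#' @param disc_nb,disc_bb two [discretize_response] objects over the same
#'   trials.
#' @param correction bias correction for the three information terms
#'   (default "pt").
#' @return object of class `synergy_decomposition`: list with `joint`,
#'   `marginal_nb`, `marginal_bb`, `redundancy`, `synergy` (all bits,
#'   corrected) and the plugin variants `*_plugin`.
#' @export
synergy <- function(disc_nb, disc_bb, correction = "pt") {
  if (disc_nb$n_trials != disc_bb$n_trials ||
      !identical(as.character(disc_nb$stimulus), as.character(disc_bb$stimulus)))
    stop("alignment error: the two responses must share the same trials",
         call. = FALSE)
  joint_bin <- (disc_nb$bin - 1L) * disc_bb$n_bins + disc_bb$bin
  disc_joint <- structure(list(stimulus = disc_nb$stimulus, bin = joint_bin,
                               edges = NULL,
                               n_bins = disc_nb$n_bins * disc_bb$n_bins,
                               n_trials = disc_nb$n_trials),
                          class = "discretized_response")
  mi_j <- mutual_information(disc_joint, correction)
  mi_nb <- mutual_information(disc_nb, correction)
  mi_bb <- mutual_information(disc_bb, correction)
  red <- redundancy_min_information(disc_nb, disc_bb)
  structure(list(joint = mi_j$corrected, marginal_nb = mi_nb$corrected,
                 marginal_bb = mi_bb$corrected, redundancy = red,
                 synergy = mi_j$corrected -
                   (mi_nb$corrected + mi_bb$corrected) + red,
                 joint_plugin = mi_j$plugin, marginal_nb_plugin = mi_nb$plugin,
                 marginal_bb_plugin = mi_bb$plugin,
                 synergy_plugin = mi_j$plugin -
                   (mi_nb$plugin + mi_bb$plugin) + red),
            class = "synergy_decomposition")
}

#' @export
print.synergy_decomposition <- function(x, ...) {
  cat(sprintf(
    "joint %.4f | NB %.4f | BB %.4f | redundancy %.4f | synergy %.4f bits\n",
    x$joint, x$marginal_nb, x$marginal_bb, x$redundancy, x$synergy))
  invisible(x)
}
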