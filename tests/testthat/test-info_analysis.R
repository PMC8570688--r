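disc_from <- function(stim, bin, n_bins = max(bin)) {
  discretize_response(stim, as.integer(bin), n_bins = n_bins)
}

test_that("equipopulated bins split samples evenly at empirical quantiles", {
  b <- equipopulated_bins(rnorm(100), 10)
  expect_true(all(table(b$bin) == 10))
  b2 <- equipopulated_bins(1:10, 10)
  expect_equal(b2$bin, 1:10)
  # response entropy is maximal under the identity binning
  p <- table(b2$bin) / 10
  expect_equal(-sum(p * log2(p)), log2(10))
  set.seed(8)
  b3 <- equipopulated_bins(rnorm(1000), 10)
  expect_true(all(abs(table(b3$bin) - 100) <= 1))
  expect_equal(unname(b3$edges[2:10]), qnorm(seq(0.1, 0.9, 0.1)),
               tolerance = 0.15)
  expect_warning(equipopulated_bins(rep(1, 50), 5), "ties")
  expect_error(equipopulated_bins(1:5, 10), "exceed")
})

test_that("plugin information matches the exhaustive oracle on random tables", {
  set.seed(42)
  for (rep_i in 1:20) {
    ns <- sample(2:6, 1)
    nr <- sample(2:10, 1)
    tab <- matrix(rpois(ns * nr, 3), ns, nr)
    tab[rowSums(tab) == 0, 1] <- 1
    stim <- rep(seq_len(ns), times = rowSums(tab))
    bin <- unlist(lapply(seq_len(ns), function(i) rep(seq_len(nr), tab[i, ])))
    d <- disc_from(stim, bin, nr)
    mi <- mutual_information(d, "none")
    expect_equal(mi$plugin, oracle_mi(tab), tolerance = 1e-12)
    expect_equal(unname(specific_information(d)), oracle_specific(tab),
                 tolerance = 1e-12)
    # symmetry of the plugin value
    expect_equal(oracle_mi(t(tab)), mi$plugin, tolerance = 1e-12)
  }
})

test_that("redundancy and synergy match brute-force evaluation", {
  set.seed(7)
  for (rep_i in 1:10) {
    n <- 120
    stim <- sample(1:3, n, replace = TRUE)
    nb <- pmin(pmax(stim + sample(0:2, n, TRUE), 1), 5)
    bb <- pmin(pmax(4 - stim + sample(0:2, n, TRUE), 1), 5)
    dn <- disc_from(stim, nb, 5)
    db <- disc_from(stim, bb, 5)
    red <- redundancy_min_information(dn, db)
    tn <- table(factor(stim), factor(nb, levels = 1:5))
    tb <- table(factor(stim), factor(bb, levels = 1:5))
    pk <- as.numeric(table(factor(stim))) / n
    red_oracle <- sum(pk * pmin(oracle_specific(tn), oracle_specific(tb)))
    expect_equal(red, red_oracle, tolerance = 1e-12)
    expect_gte(red, 0)
    s <- synergy(dn, db, correction = "none")
    joint <- interaction(nb, bb, drop = FALSE)
    tj <- table(factor(stim), joint)
    expect_equal(s$joint, oracle_mi(tj), tolerance = 1e-12)
    expect_equal(s$synergy,
                 oracle_mi(tj) - oracle_mi(tn) - oracle_mi(tb) + red_oracle,
                 tolerance = 1e-12)
  }
})

test_that("a duplicated response is fully redundant with zero synergy", {
  set.seed(3)
  stim <- rep(1:5, each = 30)
  resp <- as.integer(ceiling(runif(150) * 6) + (stim - 3) * 2 + 6)
  d1 <- disc_from(stim, resp, max(resp))
  d2 <- disc_from(stim, resp, max(resp))
  s <- synergy(d1, d2, correction = "none")
  expect_equal(s$redundancy, s$marginal_nb, tolerance = 1e-12)
  expect_equal(s$synergy, 0, tolerance = 1e-12)
})

test_that("a deterministic channel carries log2(S) bits", {
  stim <- rep(1:5, each = 40)
  d <- disc_from(stim, stim, 5)
  expect_equal(mutual_information(d, "none")$plugin, log2(5), tolerance = 1e-12)
  thr <- significance_threshold_bootstrap(d, n_surrogates = 100, seed = 1)
  expect_gt(mutual_information(d, "pt")$corrected, 3 * thr)
})

test_that("shuffled responses carry no significant corrected information", {
  set.seed(12)
  stim <- rep(1:5, each = 40)
  resp <- sample(rnorm(200))
  d <- discretize_response(stim, resp, 10)
  mi <- mutual_information(d, "pt")
  thr <- significance_threshold_bootstrap(d, n_surrogates = 150, seed = 2)
  expect_lt(mi$corrected, thr)
  expect_lt(abs(mi$corrected), 0.1)
  expect_gte(mi$plugin, 0)
})

test_that("coarsening the binning cannot create information", {
  set.seed(5)
  stim <- rep(1:4, each = 50)
  resp <- stim + rnorm(200)
  i10 <- mutual_information(discretize_response(stim, resp, 10), "none")$plugin
  i5 <- mutual_information(discretize_response(stim, resp, 5), "none")$plugin
  expect_lt(i5, i10 + 0.05)
})

test_that("PT-corrected information is unbiased on independent data", {
  set.seed(31)
  vals <- replicate(200, {
    stim <- rep(1:5, each = 60)
    resp <- rnorm(300)
    mutual_information(discretize_response(stim, resp, 10), "pt")$corrected
  })
  expect_lt(abs(mean(vals)), 0.01)
})

test_that("range-restricted information isolates the informative range", {
  set.seed(17)
  K <- rep(c(0, 10, 20, 30, 50, 90), each = 40)
  # response depends on K only below 30; pure noise above
  resp <- ifelse(K < 30, -K / 10, 0) + rnorm(length(K), 0, 0.3)
  d <- discretize_response(K, resp, 10)
  lo <- range_restricted_information(d, "low", n_permutations = 100, seed = 1)
  hi <- range_restricted_information(d, "high", n_permutations = 100, seed = 1)
  full <- mutual_information(d, "qe", seed = 1)
  expect_gt(lo$corrected, 0.5 * full$corrected)
  expect_lt(hi$corrected, 0.25 * lo$corrected)
  # fully shuffled responses carry nothing in either range
  d0 <- discretize_response(K, sample(resp), 10)
  lo0 <- range_restricted_information(d0, "low", n_permutations = 100, seed = 2)
  expect_lt(abs(lo0$corrected), 0.08)
})

test_that("the default permutation count is honored", {
  set.seed(2)
  K <- rep(c(0, 10, 50, 90), each = 15)
  d <- discretize_response(K, rnorm(60), 5)
  out <- range_restricted_information(d, "low")
  expect_equal(out$n_permutations_used, 500)
})

test_that("the bootstrap threshold reduces to a percentile of surrogates", {
  set.seed(9)
  stim <- rep(1:4, each = 30)
  d <- discretize_response(stim, rnorm(120), 6)
  t95 <- significance_threshold_bootstrap(d, 120, 95, seed = 5)
  t50 <- significance_threshold_bootstrap(d, 120, 50, seed = 5)
  expect_gt(t95, t50)
  expect_error(significance_threshold_bootstrap(d, 50), "at least 100")
})

test_that("complementary channels are synergistic about the full range", {
  set.seed(23)
  K <- rep(c(0, 10, 20, 30, 50, 90), each = 48)
  nb <- ifelse(K < 30, 30 - K, 0) / 10 + rnorm(length(K), 0, 0.4)
  bb <- ifelse(K > 30, K - 30, 0) / 20 + rnorm(length(K), 0, 0.4)
  dn <- discretize_response(K, nb, 10)
  db <- discretize_response(K, bb, 10)
  s <- synergy(dn, db)
  expect_gt(s$synergy, 0)
  expect_gt(s$joint, s$marginal_nb)
  expect_gt(s$joint, s$marginal_bb)
  # two pure-noise bands: every term small
  s0 <- synergy(discretize_response(K, rnorm(length(K)), 10),
                discretize_response(K, rnorm(length(K)), 10))
  expect_lt(abs(s0$marginal_nb), 0.05)
  expect_lt(abs(s0$marginal_bb), 0.05)
})
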