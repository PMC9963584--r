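test_that("five-number summary and moments on a small symmetric set", {
  s <- summarize_distribution(c(1, 2, 3, 4, 5))
  expect_equal(s$n, 5)
  expect_equal(s$mean, 3)
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$q0, 1)
  expect_equal(s$q4, 5)
  expect_equal(s$skewness, 0)
  expect_error(summarize_distribution(c(1, 2, 3)), "at least 4")
})

test_that("degenerate constant input keeps order statistics, drops moments", {
  s <- summarize_distribution(rep(2.5, 10))
  expect_true(all(c(s$q0, s$q1, s$median, s$q3, s$q4, s$mean) == 2.5))
  expect_true(is.na(s$skewness) && is.na(s$excess_kurtosis))
  # single unit-mass histogram bin
  expect_equal(sum(s$histogram$density * diff(s$histogram$bin_edges)), 1)
})

test_that("normal draws have near-zero skewness and excess kurtosis", {
  set.seed(101)
  x <- rnorm(1e5, mean = 3, sd = 0.4)
  s <- summarize_distribution(x)
  se_skew <- sqrt(6 / s$n)
  se_kurt <- sqrt(24 / s$n)
  expect_lt(abs(s$skewness), 4 * se_skew)
  expect_lt(abs(s$excess_kurtosis), 4 * se_kurt)
})

test_that("summaries are permutation-invariant and scale-equivariant", {
  set.seed(7)
  x <- rexp(500) + 1
  s1 <- summarize_distribution(x)
  s2 <- summarize_distribution(sample(x))
  for (f in c("mean", "median", "q1", "q3", "skewness", "excess_kurtosis"))
    expect_equal(s1[[f]], s2[[f]])
  s3 <- summarize_distribution(3 * x)
  expect_equal(s3$mean, 3 * s1$mean)
  expect_equal(s3$q1, 3 * s1$q1)
  expect_equal(s3$q4, 3 * s1$q4)
  expect_equal(s3$skewness, s1$skewness, tolerance = 1e-12)
  expect_equal(s3$excess_kurtosis, s1$excess_kurtosis, tolerance = 1e-12)
})

test_that("histogram densities integrate to one and KDE annotations exist", {
  set.seed(15)
  for (x in list(rnorm(300), rexp(1000), rpois(500, 14))) {
    s <- summarize_distribution(x, integer_bins = is.integer(x))
    integral <- sum(s$histogram$density * diff(s$histogram$bin_edges))
    expect_equal(integral, 1, tolerance = 1e-12)
    expect_named(s$kde_at, c("q0", "q1", "median", "q3", "q4", "mean"))
    expect_true(all(s$kde_at >= 0))
  }
})

test_that("positively skewed input shows mean > median and skewness > 0", {
  set.seed(23)
  x <- rlnorm(2000, sdlog = 0.6)
  s <- summarize_distribution(x)
  expect_gt(s$mean, s$median)
  expect_gt(s$skewness, 0)
})

test_that("normality check accepts normal, rejects exponential and constants", {
  set.seed(31)
  good <- normality_check(rnorm(1e4, 5, 2))
  expect_true(good$consistent)
  expect_lt(good$statistic, good$threshold)
  bad <- normality_check(rexp(1e4))
  expect_false(bad$consistent)
  const <- normality_check(rep(1, 50))
  expect_false(const$consistent)
  expect_true(const$degenerate)
  expect_error(normality_check(rnorm(10)), "at least 20")
})

test_that("state comparison classifies Rmax against the Rw quartiles", {
  met <- data.frame(frame = 1:40, nf = rep(15, 40), nv = 24, ne = 37,
                    volume = seq(28, 32, length.out = 40),
                    surface = 50, cage_radius = 4.5,
                    rw = seq(1.6, 1.8, length.out = 40),
                    rw_doubled = 2 * seq(1.6, 1.8, length.out = 40),
                    alpha = 1.5, converged = TRUE)
  rdf_lo <- structure(list(Rmax = 1.55, Rmin = 3.3, n_at_Rmax = 2,
                           n_at_Rmin = 9, R0 = 1.2),
                      class = "rdf_result")
  rdf_in <- structure(list(Rmax = 1.70, Rmin = 3.3, n_at_Rmax = 2,
                           n_at_Rmin = 9, R0 = 1.2),
                      class = "rdf_result")
  rdf_hi <- structure(list(Rmax = 1.95, Rmin = 3.3, n_at_Rmax = 2,
                           n_at_Rmin = 9, R0 = 1.2),
                      class = "rdf_result")
  tab <- compare_states(list(lo = list(metrics = met, rdf = rdf_lo),
                             mid = list(metrics = met, rdf = rdf_in),
                             hi = list(metrics = met, rdf = rdf_hi)))
  expect_equal(tab$rmax_vs_rw, c("below_Q1", "within_IQR", "above_Q3"))
  # identical inputs give identical rows (determinism)
  expect_equal(tab$rw_mean[1], tab$rw_mean[2])
  expect_equal(tab$volume_q3[1], tab$volume_q3[3])
  # absent RDF features are flagged, not guessed
  tab2 <- compare_states(list(a = list(metrics = met, rdf = NULL)))
  expect_true(is.na(tab2$Rmax) && is.na(tab2$rmax_vs_rw))
})
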