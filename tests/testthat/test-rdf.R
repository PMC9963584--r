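# Synthetic rdf_result with a prescribed g(r) curve, for feature extraction
# tests that need exact control of the profile.
synthetic_rdf <- function(g, bin_width = 0.05, rho = 0.0333) {
  edges <- seq(0, by = bin_width, length.out = length(g) + 1)
  structure(list(bin_edges = edges,
                 r = (edges[-1] + edges[-length(edges)]) / 2,
                 g = g, counts = g, rho = rho, n_frames = 1L,
                 R0 = NA_real_, Rmax = NA_real_, Rmin = NA_real_,
                 n_at_Rmax = NA_real_, n_at_Rmin = NA_real_),
            class = "rdf_result")
}

test_that("single pair lands in the bin containing its distance", {
  pos <- rbind(c(1, 1, 1), c(4, 1, 1), c(9, 9, 9), c(9, 9, 1), c(1, 9, 9))
  cfg <- configuration(pos, 20, species = c("Or", rep("Ow", 4)))
  rdf <- compute_rdf(list(cfg), bin_width = 0.2, r_cut = 10)
  hit <- which(rdf$counts > 0)
  expect_true(3.0 >= rdf$bin_edges[hit[1]] && 3.0 <= rdf$bin_edges[hit[1] + 1])
})

test_that("ideal gas gives g = 1 within counting noise and no features", {
  n <- 400
  L <- (n / 0.0334)^(1 / 3)
  frames <- lapply(1:200, function(k) make_poisson(n + 1, L, seed = 500 + k))
  rdf <- compute_rdf(frames, bin_width = 0.1, r_cut = 8)
  # per-bin Poisson counting noise: sd(g) = 1/sqrt(expected count)
  expected <- rdf$n_frames * rdf$rho * 4 * pi / 3 * diff(rdf$bin_edges^3)
  z <- (rdf$g - 1) * sqrt(expected)
  inner <- z[-1]  # first bin holds ~0 expected counts
  # Poisson null: a few isolated 3-sigma excursions are expected among ~80
  # bins; systematic deviation or any 5-sigma bin is not
  expect_lte(sum(abs(inner) > 3), 3)
  expect_true(all(abs(inner) < 5))
  expect_lt(abs(mean(inner)), 3 / sqrt(length(inner)))
  ideal <- synthetic_rdf(rep(1, 100))
  feat <- suppressWarnings(find_peak_features(ideal))
  expect_true(is.na(feat$Rmax) && is.na(feat$Rmin))
})

test_that("lattice environment: first shell appears at the spacing, n = 6", {
  a <- 3.0
  rdf <- compute_rdf(list(make_lattice("sc", 4, a)), bin_width = 0.05)
  first <- rdf$r[which(rdf$g > 0)[1]]
  expect_lt(abs(first - a), 0.05)
  rdf$R0 <- 0
  # midpoint quadrature bias is (bin/ r)^2 / 12 relative, ~2e-5 here
  expect_equal(running_coordination(rdf, a + 0.2), 6, tolerance = 1e-4)
})

test_that("constructed peak/dip curves yield the first peak's features", {
  r <- (seq_len(140) - 0.5) * 0.05
  g <- 1 + 1.5 * exp(-(r - 2.8)^2 / 0.08) - 0.6 * exp(-(r - 3.4)^2 / 0.02)
  g[r < 2.2] <- 0
  rdf <- synthetic_rdf(g)
  feat <- find_peak_features(rdf)
  expect_equal(feat$Rmax, 2.8, tolerance = 0.026)
  expect_equal(feat$Rmin, 3.4, tolerance = 0.026)
  expect_lt(feat$R0, feat$Rmax)
  # two-peak curve: only the FIRST peak is reported
  g2 <- 1 + 1.5 * exp(-(r - 2.8)^2 / 0.05) - 0.8 * exp(-(r - 3.6)^2 / 0.05) +
    0.7 * exp(-(r - 4.8)^2 / 0.05)
  g2[r < 2.2] <- 0
  feat2 <- find_peak_features(synthetic_rdf(g2))
  expect_equal(feat2$Rmax, 2.8, tolerance = 0.026)
  expect_lt(feat2$Rmin, 4.0)
})

test_that("running coordination reproduces the closed form for g = 1", {
  rho <- 0.03
  rdf <- synthetic_rdf(rep(1, 200), bin_width = 0.02, rho = rho)
  rdf$R0 <- 0
  # midpoint quadrature of r^2 on uniform bins has a known exact sum
  upper <- 3
  exact <- 4 / 3 * pi * rho * upper^3
  got <- running_coordination(rdf, upper)
  expect_equal(got, exact, tolerance = (0.02^2) / 12 * upper * 4 * pi * rho /
                 exact)
  expect_warning(got0 <- running_coordination(rdf, -1), "below R0")
  expect_equal(got0, 0)
  rdf$R0 <- 1
  expect_equal(running_coordination(rdf, 1), 0)
})

test_that("integrated g agrees with direct neighbor counting", {
  frames <- lapply(1:20, function(k) make_poisson(200, 12, seed = 900 + k))
  rdf <- compute_rdf(frames, bin_width = 0.05, r_cut = 6)
  rdf$R0 <- 0
  for (upper in c(2.5, 4, 5.5)) {
    direct <- mean(vapply(frames, function(f) {
      d <- minimum_image(
        matrix(f$positions[1, ], 199, 3, byrow = TRUE),
        f$positions[-1, , drop = FALSE], 12)
      sum(rowSums(d^2) < upper^2)
    }, numeric(1)))
    expect_equal(running_coordination(rdf, upper), direct,
                 tolerance = max(0.02, 0.5 / max(direct, 1)))
  }
})

test_that("non-decreasing running integral and range validation", {
  frames <- lapply(1:5, function(k) make_poisson(150, 10, seed = 40 + k))
  rdf <- compute_rdf(frames, bin_width = 0.1)
  rdf$R0 <- 0
  ns <- vapply(seq(0.5, 5, by = 0.5), function(u)
    running_coordination(rdf, u), numeric(1))
  expect_true(all(diff(ns) >= -1e-12))
  expect_error(compute_rdf(frames, bin_width = 0.1, r_cut = 6),
               "half the box")
  expect_error(compute_rdf(list(), 0.1), "no frames")
})

test_that("printed-form integral drops the Jacobian and says so", {
  rdf <- synthetic_rdf(rep(1, 100), bin_width = 0.05, rho = 0.02)
  rdf$R0 <- 0
  expect_message(
    v <- running_coordination(rdf, 2, strict_printed_form = TRUE),
    "Jacobian")
  expect_equal(v, 4 * pi * 0.02 * 2, tolerance = 1e-9)
})
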