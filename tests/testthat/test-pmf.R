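kT300 <- ringpmf::kB * 300

test_that("direct_histogram_pmf inverts Boltzmann densities", {
  set.seed(41)
  # uniform samples -> flat profile
  u <- runif(2e4, 0, 1)
  pu <- direct_histogram_pmf(u, bin_width = 0.1)
  expect_lt(max(pu$G, na.rm = TRUE), 0.05)
  # Gaussian samples, sd sigma -> G = kBT x^2 / (2 sigma^2) up to a constant
  sigma <- 0.5
  x <- rnorm(2e5, 0, sigma)
  x <- x[abs(x) <= 3 * sigma]
  ph <- direct_histogram_pmf(x, bin_width = 0.05)
  sel <- which(abs(ph$bin_centers) <= 2 * sigma & !is.na(ph$G))
  Gtrue <- kT300 * ph$bin_centers^2 / (2 * sigma^2)
  Gtrue <- Gtrue - min(Gtrue[sel])
  expect_lt(max(abs(ph$G[sel] - Gtrue[sel])), 0.05)
})

test_that("wham agrees with the direct-histogram oracle on unbiased data", {
  set.seed(42)
  sigma <- sqrt(kT300 / 2.0)
  x <- rnorm(3e5, 0, sigma)
  x <- x[abs(x) <= 1.2]
  pw <- wham(list(umbrella_window(0, 1e-9, x)), bin_width = 0.05)
  ph <- direct_histogram_pmf(x, bin_width = 0.05)
  sel <- which(!is.na(pw$G) & !is.na(ph$G))
  expect_lt(max(abs(pw$G[sel] - ph$G[sel])), 0.05)
  # and both recover the generating potential U = 0.5 * 2 * x^2
  in1 <- sel[abs(pw$bin_centers[sel]) <= 1]
  Gtrue <- 0.5 * 2.0 * pw$bin_centers^2
  expect_lt(max(abs(pw$G[in1] - (Gtrue[in1] - min(Gtrue[in1])))), 0.1)
})

test_that("wham is flat on a flat potential and symmetric on a mirror setup", {
  # exact Boltzmann sampling of the biased windows on a flat landscape:
  # each window's density is Gaussian around its centre with var kBT/k
  set.seed(43)
  kT <- ringpmf::kB * 300
  centers <- seq(-1, 1, length.out = 9)
  wins <- lapply(centers, function(c0)
    umbrella_window(c0, 100, rnorm(1e5, c0, sqrt(kT / 100))))
  prof <- wham(wins, bin_width = 0.05)
  core <- which(prof$bin_centers >= -1 & prof$bin_centers <= 1 & !is.na(prof$G))
  expect_lt(max(prof$G[core]) - min(prof$G[core]), 0.1)
  # mirror symmetry of the recovered profile about x = 0
  Gc <- prof$G[core]
  expect_lt(max(abs(Gc - rev(Gc))), 0.1)
  # probability conservation before the log transform
  P <- exp(-prof$G[!is.na(prof$G)] / (ringpmf::kB * prof$temperature))
  expect_equal(sum(P / sum(P * prof$bin_width) * prof$bin_width), 1,
               tolerance = 1e-10)
})

test_that("wham is invariant to window order and to the bias convention pairing", {
  pot <- surrogate_potential(data.frame(x = c(0, 1), y = c(0, 2)))
  wins <- generate_umbrella_dataset(pot, n_windows = 6, rc_range = c(-0.2, 1.2),
                                    k = 80, n_equil = 1000, n_prod = 5000,
                                    seed = 44)
  a <- wham(wins, bin_width = 0.05)
  b <- wham(rev(wins), bin_width = 0.05)
  expect_equal(a$G, b$G, tolerance = 1e-6)
  # 1/2 k (x-c)^2 with k equals k'(x-c)^2 with k' = k/2
  wins_half <- lapply(wins, function(w)
    umbrella_window(w$center, w$k / 2, w$samples))
  c_ <- wham(wins_half, bin_width = 0.05, half_k = FALSE)
  expect_equal(a$G, c_$G, tolerance = 1e-8)
})

test_that("wham reports a connectivity error when window histograms do not overlap", {
  w1 <- umbrella_window(0, 100, rnorm(500, 0, 0.05))
  w2 <- umbrella_window(3, 100, rnorm(500, 3, 0.05))
  expect_error(wham(list(w1, w2)), "overlap",
               class = "ringpmf_connectivity_error")
})

test_that("landmarks recovers the printed stationary points from the exact profile", {
  pot <- surrogate_potential()   # nodes (1.5, 0), (2.17, 19), (3.2, 5)
  x <- seq(1.3, 3.5, by = 0.01)
  prof <- make_profile(x, surrogate_energy(pot, x)$energy)
  lm <- landmarks(prof, reactant_window = c(1.3, 1.9),
                  product_window = c(2.9, 3.5))
  # positions to 5e-3 A: the quadratic refinement is biased by O(h) where
  # the curvature jumps across a stationary node (wall vs spline segment)
  expect_lt(abs(lm$reactant_min - 1.5), 5e-3)
  expect_lt(abs(lm$ts_pos - 2.17), 5e-3)
  expect_lt(abs(lm$product_min - 3.2), 5e-3)
  expect_equal(lm$barrier, 19.0, tolerance = 1e-3)
  expect_equal(lm$delta_g, 5.0, tolerance = 1e-3)
  expect_true(lm$reactant_min < lm$ts_pos && lm$ts_pos < lm$product_min)
})

test_that("landmarks handles symmetric wells and missing maxima", {
  x <- seq(-2, 2, by = 0.01)
  dw <- (x^2 - 1)^2          # symmetric double well, minima at +/-1
  lm <- landmarks(make_profile(x, dw), reactant_window = c(-1.5, -0.5),
                  product_window = c(0.5, 1.5))
  expect_equal(lm$delta_g, 0, tolerance = 1e-10)
  expect_equal(lm$ts_pos, 0, tolerance = 1e-6)
  # single well then monotonic rise: no interior maximum
  mono <- x^2
  expect_error(landmarks(make_profile(x, mono),
                         reactant_window = c(-0.5, 0.5),
                         product_window = c(1.5, 2)),
               "interior maximum", class = "ringpmf_landmark_error")
})

test_that("profile_sd measures anchored pointwise spread", {
  x <- seq(1, 2.98, by = 0.02)   # even bin count
  G <- (x - 2)^2
  a <- make_profile(x, G)
  expect_equal(profile_sd(a, a, range = c(1, 3)), 0)
  # constant offset disappears after re-anchoring
  b <- make_profile(x, G + 3.7)
  expect_equal(profile_sd(a, b, range = c(1, 3)), 0, tolerance = 1e-12)
  # +0.5 on exactly half the bins away from the anchor -> sqrt(0.25/2)
  Gc <- G
  away <- order(G, decreasing = TRUE)[seq_len(length(x) / 2)]
  Gc[away] <- Gc[away] + 0.5
  cc <- make_profile(x, Gc)
  expect_equal(profile_sd(a, cc, range = c(1, 3)), sqrt(0.25 / 2),
               tolerance = 1e-12)
  expect_error(profile_sd(a, b, range = c(10, 11)), "bins")
})

test_that("halving the bin width leaves the recovered barrier nearly unchanged", {
  pot <- surrogate_potential(data.frame(x = c(1.5, 2.17, 3.2), y = c(0, 6, 2)))
  wins <- generate_umbrella_dataset(pot, n_windows = 24, k = 200,
                                    n_equil = 2000, n_prod = 6000, seed = 45)
  lm1 <- landmarks(wham(wins, bin_width = 0.02))
  lm2 <- landmarks(wham(wins, bin_width = 0.01))
  expect_lt(abs(lm1$barrier - lm2$barrier), 0.2)
})

test_that("wham_pmf methods print, summarise, and interpolate", {
  pot <- surrogate_potential(data.frame(x = c(0, 0.5, 1), y = c(0, 1.5, 0.5)))
  wins <- generate_umbrella_dataset(pot, n_windows = 8, rc_range = c(-0.1, 1.1),
                                    k = 100, n_equil = 500, n_prod = 3000,
                                    seed = 46)
  prof <- wham(wins, bin_width = 0.05)
  expect_output(print(prof), "WHAM free-energy profile")
  s <- summary(prof, reactant_window = c(-0.1, 0.3),
               product_window = c(0.7, 1.1))
  expect_s3_class(s, "summary.wham_pmf")
  g <- predict(prof, c(0.25, 0.5))
  expect_true(all(is.finite(g)))
  expect_true(is.na(predict(prof, 99)))
})
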