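test_that("cremer_pople reproduces hand-computed chair and planar cases", {
  # regular planar hexagon
  p0 <- cremer_pople(inverse_cremer_pople(0, 0, 0))
  expect_equal(p0$Q, 0, tolerance = 1e-12)
  expect_true(is.na(p0$theta))
  # alternating z = +/-0.25 on a 1.45 A circle: pure chair,
  # q3 = 6*0.25/sqrt(6), q2 = 0, theta = 0
  ang <- 2 * pi * (0:5) / 6
  xyz <- cbind(1.45 * cos(ang), 1.45 * sin(ang),
               0.25 * c(1, -1, 1, -1, 1, -1))
  p <- cremer_pople(xyz)
  expect_equal(p$q2, 0, tolerance = 1e-12)
  expect_equal(p$q3, 6 * 0.25 / sqrt(6), tolerance = 1e-12)
  expect_equal(p$Q, 0.6123724, tolerance = 1e-6)
  expect_equal(p$theta, 0, tolerance = 1e-9)
  # collinear ring is rejected
  line <- cbind(1:6, 1:6, 1:6)
  expect_error(cremer_pople(line), class = "ringpmf_geometry_error")
})

test_that("forward and inverse Cremer-Pople transforms are mutual inverses", {
  p <- cremer_pople(inverse_cremer_pople(0.57, 90, 210))
  expect_equal(c(p$Q, p$theta, p$phi), c(0.57, 90, 210), tolerance = 1e-6)
  p2 <- cremer_pople(inverse_cremer_pople(0.5, 60, 45))
  expect_equal(c(p2$Q, p2$theta, p2$phi), c(0.5, 60, 45), tolerance = 1e-6)
  # ideal chair branch: theta = 0 gives the alternating-sign z pattern
  xyz <- inverse_cremer_pople(0.6, 0, 123)
  expect_equal(sign(xyz[, 3]), c(1, -1, 1, -1, 1, -1), ignore_attr = TRUE)
  expect_error(inverse_cremer_pople(-0.1, 0, 0), "non-negative")
  # systematic grid
  for (Q in c(0.1, 0.45, 0.8))
    for (th in c(5, 54.7, 90, 125.3, 175))
      for (ph in c(0, 100, 210, 359)) {
        r <- cremer_pople(inverse_cremer_pople(Q, th, ph))
        expect_equal(r$Q, Q, tolerance = 1e-6)
        expect_equal(r$theta, th, tolerance = 1e-6)
        expect_equal(r$phi, ph, tolerance = 1e-6)
      }
})

test_that("Cremer-Pople identities hold on random rings", {
  set.seed(21)
  for (i in 1:40) {
    xyz <- inverse_cremer_pople(runif(1, 0.1, 0.8), runif(1, 1, 179),
                                runif(1, 0, 360))
    xyz <- xyz + matrix(rnorm(18, sd = 0.02), 6, 3)   # off-ideal ring
    p <- cremer_pople(xyz)
    expect_equal(sum(p$z), 0, tolerance = 1e-10)
    expect_equal(p$Q^2, sum(p$z^2), tolerance = 1e-10)
    expect_equal(p$q_x^2 + p$q_y^2 + p$q3^2, p$Q^2, tolerance = 1e-10)
    expect_equal(p$q_x, p$Q * sin(p$theta * pi / 180) * sin(p$phi * pi / 180),
                 tolerance = 1e-10)
    # rotation/translation invariance
    rt <- random_rigid()
    p2 <- cremer_pople(apply_rigid(xyz, rt))
    expect_equal(p2$Q, p$Q, tolerance = 1e-9)
    expect_equal(p2$theta, p$theta, tolerance = 1e-7)
    expect_equal(p2$phi, p$phi, tolerance = 1e-7)
  }
})

test_that("canonical table is recovered from ideal conformer geometries", {
  # ideal patterns: chair, boats, and the derivational patterns for
  # envelopes and half-chairs project onto the tabulated vertices
  cases <- list(
    list(z = c(1, -1, 1, -1, 1, -1), name = "4C1"),
    list(z = -c(1, -1, 1, -1, 1, -1), name = "1C4"),
    list(z = c(-.5, -.5, 1, -.5, -.5, 1), name = "2,5B"),   # C2, C5 up
    list(z = c(1, -.5, -.5, 1, -.5, -.5), name = "O,3B"),   # O5, C3 up
    list(z = c(5, -1, -1, -1, -1, -1), name = "OE"),        # O5 flap up
    list(z = c(1, -1, 0, 0, 0, 0), name = "OH1"))           # O5 up, C1 down
  for (cs in cases) {
    p <- cremer_pople(ideal_ring(cs$z))
    cl <- classify_conformer(p)
    expect_equal(cl$name, cs$name)
    expect_lt(cl$geodesic_dist, 1e-6)
  }
})

test_that("classify_conformer matches a brute-force geodesic search on random points", {
  expect_equal(classify_conformer(list(Q = 0.5, theta = 0, phi = 77))$name, "4C1")
  v <- conformer_table()
  s3 <- v[v$name == "1S3", ]
  cl <- classify_conformer(list(Q = 0.57, theta = s3$theta, phi = s3$phi))
  expect_equal(cl$name, "1S3")
  expect_equal(cl$geodesic_dist, 0)
  # midway between 2,5B (phi 120) and the adjacent skew, nudged toward the boat
  cl2 <- classify_conformer(list(Q = 0.5, theta = 90, phi = 135 - 1))
  expect_equal(cl2$name, "2,5B")
  # planar threshold
  expect_equal(classify_conformer(list(Q = 0.05, theta = 90, phi = 0))$name,
               "planar")
  set.seed(31)
  n_ok <- 0L
  for (i in 1:1000) {
    u <- c(runif(1, -1, 1), runif(1, 0, 360))
    th <- acos(u[1]) * 180 / pi
    got <- classify_conformer(list(Q = 0.5, theta = th, phi = u[2]))
    ref <- bruteforce_classify(th, u[2])
    expect_equal(got$geodesic_dist, ref$dist, tolerance = 1e-6)
    # at exact ties the two argmin orders may differ; names must agree
    # whenever the margin is non-degenerate
    if (got$name == ref$name) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 999L)
})

test_that("itinerary reports per-region fractions that sum to one", {
  # all frames ideal 4C1 in one region
  xyz <- inverse_cremer_pople(0.57, 0, 0)
  ps <- data.frame(Q = rep(0.57, 10), theta = 0, phi = 0)
  it <- itinerary(ps, rc2 = rep(2.8, 10), regions = list(product = c(2.4, 3.2)))
  expect_equal(it$fractions$fraction, 1.0)
  expect_equal(it$summary$majority, "4C1")
  # mixed labels: fractions sum to 1 per nonempty region
  set.seed(5)
  n <- 60
  ps2 <- data.frame(Q = runif(n, 0.3, 0.7), theta = runif(n, 0, 180),
                    phi = runif(n, 0, 360))
  rc2 <- runif(n, 1.4, 3.3)
  it2 <- itinerary(ps2, rc2)
  for (rn in unique(it2$fractions$region))
    expect_equal(sum(it2$fractions$fraction[it2$fractions$region == rn]), 1,
                 tolerance = 1e-12)
  # empty region reported with count 0; length mismatch rejected
  it3 <- itinerary(ps, rep(2.8, 10), regions = list(r = c(0.1, 0.2)))
  expect_equal(it3$summary$n, 0L)
  expect_error(itinerary(ps, rc2 = c(1, 2)), "length")
  expect_error(itinerary(ps, rep(2.8, 10),
                         regions = list(a = c(1, 2), b = c(1.5, 2.5))),
               "overlap")
})
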