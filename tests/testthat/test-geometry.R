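test_that("atom_distance evaluates Euclidean distances and validates labels", {
  fr <- md_frame(c("A", "B", "C", "D"),
                 rbind(c(0, 0, 0), c(3, 4, 0), c(1, 1, 1), c(2, 3, 4)))
  expect_equal(atom_distance(fr, "A", "B"), 5.0)
  expect_equal(atom_distance(fr, "B", "A"), 5.0)
  expect_equal(atom_distance(fr, "A", "A"), 0.0)
  expect_equal(atom_distance(fr, "C", "D"), sqrt(14))
  expect_error(atom_distance(fr, "A", "Zz"), "Zz",
               class = "ringpmf_label_error")
})

test_that("distance obeys symmetry and the triangle inequality on random triples", {
  set.seed(101)
  for (i in 1:25) {
    fr <- md_frame(c("p", "q", "r"), matrix(rnorm(9, sd = 4), 3, 3))
    dpq <- atom_distance(fr, "p", "q")
    dqr <- atom_distance(fr, "q", "r")
    dpr <- atom_distance(fr, "p", "r")
    expect_equal(dpq, atom_distance(fr, "q", "p"))
    expect_lte(dpr, dpq + dqr + 1e-12)
  }
})

test_that("evaluate_rc is a weighted distance sum, linear in the weights", {
  fr <- md_frame(c("C1", "O4", "Ow", "H"),
                 rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(0, 0, 0.5)))
  single <- rc_spec("d1", data.frame(a = "C1", b = "O4", w = 1))
  expect_equal(evaluate_rc(fr, single), atom_distance(fr, "C1", "O4"))
  # difference of equal distances vanishes
  sym <- rc_spec("rc", data.frame(a = c("C1", "C1"), b = c("O4", "O4"),
                                  w = c(1, -1)))
  expect_equal(evaluate_rc(fr, sym), 0.0)
  # three-term sum: distances 1, 2, 0.5
  triple <- rc_spec("sum", data.frame(a = c("C1", "C1", "C1"),
                                      b = c("O4", "Ow", "H"),
                                      w = c(1, 1, 1)))
  expect_equal(evaluate_rc(fr, triple), 3.5)
  doubled <- rc_spec("sum2", data.frame(a = c("C1", "C1", "C1"),
                                        b = c("O4", "Ow", "H"),
                                        w = c(2, 2, 2)))
  expect_equal(evaluate_rc(fr, doubled), 2 * evaluate_rc(fr, triple))
  expect_error(rc_spec("bad", data.frame(a = "A", b = "B", w = 0)), "nonzero")
})

test_that("ring_plane_angle separates axial from equatorial bonds", {
  hexagon <- inverse_cremer_pople(0, 0, 0)   # planar ring in the xy-plane
  fr <- md_frame(c(rownames(hexagon), "X", "Ax", "Eq", "D45"),
                 rbind(hexagon,
                       c(0, 0, 0),      # ring centre
                       c(0, 0, 1.4),    # along the normal
                       c(1, 1, 0),      # in-plane
                       c(1, 0, 1)))     # 45 deg elevation
  ring <- rownames(hexagon)
  expect_equal(ring_plane_angle(fr, ring, c("X", "Ax")), 90.0)
  expect_equal(ring_plane_angle(fr, ring, c("X", "Eq")), 0.0)
  expect_equal(ring_plane_angle(fr, ring, c("X", "D45")), 45.0)
})

test_that("ring_plane_angle is invariant under global rotation", {
  set.seed(7)
  xyz <- inverse_cremer_pople(0.55, 72, 33)
  base <- rbind(xyz, Bnd = c(0.8, -0.3, 1.1))
  fr <- md_frame(rownames(base), base)
  a0 <- ring_plane_angle(fr, rownames(xyz), c("O5", "Bnd"))
  for (i in 1:10) {
    rt <- random_rigid()
    fr2 <- md_frame(rownames(base), apply_rigid(base, rt))
    expect_equal(ring_plane_angle(fr2, rownames(xyz), c("O5", "Bnd")), a0,
                 tolerance = 1e-9)
  }
})

test_that("hbond_present applies distance and angle cutoffs and reports geometry", {
  # linear D-H...A, H...A = 1.8 A
  fr <- md_frame(c("D", "H", "A"),
                 rbind(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0)))
  hb <- hbond_present(fr, "D", "H", "A")
  expect_true(hb$present)
  expect_equal(hb$d_ha, 1.8)
  expect_equal(hb$angle, 180)
  # beyond the distance cutoff
  fr2 <- md_frame(c("D", "H", "A"),
                  rbind(c(0, 0, 0), c(1, 0, 0), c(4.5, 0, 0)))
  expect_false(hbond_present(fr2, "D", "H", "A")$present)
  # passes distance, fails only the angle test: angle D-H...A = 100 deg
  ang <- 100 * pi / 180
  fr3 <- md_frame(c("D", "H", "A"),
                  rbind(c(1, 0, 0), c(0, 0, 0),
                        2.0 * c(cos(ang), sin(ang), 0)))
  hb3 <- hbond_present(fr3, "D", "H", "A", d_cut = 2.5, angle_cut = 120)
  expect_false(hb3$present)
  expect_equal(hb3$d_ha, 2.0)
  expect_equal(hb3$angle, 100)
})

test_that("kabsch_rmsd vanishes under rigid motion and matches a brute-force search", {
  set.seed(11)
  coords <- matrix(rnorm(24, sd = 2), 8, 3)
  labs <- paste0("a", 1:8)
  frA <- md_frame(labs, coords)
  expect_equal(kabsch_rmsd(frA, frA), 0.0)
  frT <- md_frame(labs, sweep(coords, 2L, -c(5, 5, 5)))
  expect_equal(kabsch_rmsd(frA, frT), 0.0, tolerance = 1e-10)
  for (i in 1:10) {
    rt <- random_rigid()
    frR <- md_frame(labs, apply_rigid(coords, rt))
    expect_lt(kabsch_rmsd(frA, frR), 1e-8)
  }
  # square with one corner pushed 0.4 A out of plane vs brute-force minimum
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  sq2 <- sq
  sq2[3, 3] <- 0.4
  fr1 <- md_frame(paste0("s", 1:4), sq)
  fr2 <- md_frame(paste0("s", 1:4), sq2)
  got <- kabsch_rmsd(fr1, fr2)
  expect_equal(got, bruteforce_min_rmsd(sq, sq2), tolerance = 1e-3)
  expect_error(kabsch_rmsd(fr1, fr2, selection = c("s1", "s2")), "3 atoms")
})

test_that("kabsch_rmsd agrees with bio3d's fitted RMSD", {
  skip_if_not_installed("bio3d")
  set.seed(13)
  A <- matrix(rnorm(30), 10, 3)
  B <- A + matrix(rnorm(30, sd = 0.3), 10, 3)
  frA <- md_frame(paste0("x", 1:10), A)
  frB <- md_frame(paste0("x", 1:10), B)
  ref <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
  expect_equal(kabsch_rmsd(frA, frB), ref, tolerance = 1e-3)
})

test_that("monitor_series tabulates one column per coordinate over frames", {
  frames <- lapply(0:4, function(i)
    md_frame(c("C1", "O4"), rbind(c(0, 0, 0), c(1 + 0.1 * i, 0, 0)),
             time = i * 0.5))
  specs <- list(RC2 = rc_spec("RC2", data.frame(a = "C1", b = "O4", w = 1)))
  ms <- monitor_series(frames, specs)
  expect_equal(ms$frame_index, 0:4)
  expect_equal(ms$RC2, 1 + 0.1 * (0:4))
})
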