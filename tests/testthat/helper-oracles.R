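# Independent oracles and fixture builders used across the suite.

# random rigid transform (proper rotation + translation)
random_rigid <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
  list(R = R, t = stats::rnorm(3, sd = 3))
}

apply_rigid <- function(coords, rt) sweep(coords %*% t(rt$R), 2L, -rt$t)

# Brute-force minimum RMSD over rotation space: coarse Euler-angle grid
# followed by Nelder-Mead refinement. Independent of the SVD route.
bruteforce_min_rmsd <- function(A, B, grid_n = 12) {
  Ac <- sweep(A, 2L, colMeans(A))
  Bc <- sweep(B, 2L, colMeans(B))
  rot <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rz1 <- rbind(c(ca[1], -sa[1], 0), c(sa[1], ca[1], 0), c(0, 0, 1))
    Ry <- rbind(c(ca[2], 0, sa[2]), c(0, 1, 0), c(-sa[2], 0, ca[2]))
    Rz2 <- rbind(c(ca[3], -sa[3], 0), c(sa[3], ca[3], 0), c(0, 0, 1))
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((Ac - Bc %*% rot(ang))^2)))
  best <- Inf; best_ang <- c(0, 0, 0)
  gr <- seq(0, 2 * pi, length.out = grid_n + 1L)[-(grid_n + 1L)]
  for (a1 in gr) for (a2 in gr[gr <= pi]) for (a3 in gr) {
    v <- obj(c(a1, a2, a3))
    if (v < best) { best <- v; best_ang <- c(a1, a2, a3) }
  }
  o <- stats::optim(best_ang, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 5000))
  o$value
}

# Brute-force nearest canonical conformer via 3-D unit vectors and acos of
# the dot product (independent of the package's spherical-law formula).
bruteforce_classify <- function(theta, phi) {
  tab <- conformer_table()
  tovec <- function(t, p) {
    t <- t * pi / 180; p <- p * pi / 180
    c(sin(t) * sin(p), sin(t) * cos(p), cos(t))
  }
  u <- tovec(theta, phi)
  d <- apply(tab, 1L, function(r) {
    v <- tovec(as.numeric(r["theta"]), as.numeric(r["phi"]))
    acos(max(-1, min(1, sum(u * v)))) * 180 / pi
  })
  k <- which.min(d)
  list(name = tab$name[k], dist = d[k])
}

# Ideal displacement patterns for canonical conformer families, placed on
# a regular hexagon; used to regenerate the canonical table from geometry.
ideal_ring <- function(z, radius = 1.45) {
  ang <- 2 * pi * (0:5) / 6
  z <- z - mean(z)
  z <- z * 0.5 / max(abs(z))          # generic amplitude
  cbind(radius * cos(ang), radius * sin(ang), z)
}

# a small analytic double-well profile on an exact grid
make_profile <- function(x, G, temperature = 300) {
  ringpmf:::new_pmf_profile(x, G, counts = rep(1L, length(x)),
                            temperature = temperature,
                            bin_width = x[2] - x[1])
}
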