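# Desk-scale synthetic data: an analytic landmark potential standing in
# for the QM/MM free-energy surface, an overdamped Langevin sampler for
# umbrella windows on it, and ring-geometry trajectories tracing a
# prescribed conformational itinerary.

#' Analytic landmark potential
#'
#' A one-dimensional free-energy surface built by cubic Hermite
#' interpolation through a table of landmark nodes, with harmonic walls
#' beyond the outermost nodes. Nodes flagged stationary get zero slope, so
#' the listed positions are exact minima/maxima of the surface; energy and
#' first derivative are continuous everywhere. The default nodes place the
#' reactant minimum at 1.5 Angstrom (0 kcal/mol), the transition state at
#' 2.17 Angstrom (19 kcal/mol) and the product minimum at 3.2 Angstrom
#' (5 kcal/mol) — the landmark set of an inverting glycoside hydrolase
#' glycosidic-bond cleavage profile.
#'
#' @param nodes data.frame with columns `x` (strictly increasing, Angstrom)
#'   and `y` (kcal/mol).
#' @param stationary logical vector: force zero slope at each node
#'   (default all `TRUE`). Non-stationary interior nodes get centred
#'   finite-difference slopes.
#' @param wall_k stiffness of the harmonic walls outside the outer nodes,
#'   kcal/mol/Angstrom^2 (default 100).
#' @return Object of class `surrogate_potential`.
#' @export
#' @examples
#' pot <- surrogate_potential()
#' surrogate_energy(pot, c(1.5, 2.17, 3.2))
surrogate_potential <- function(nodes = data.frame(x = c(1.5, 2.17, 3.2),
                                                   y = c(0, 19, 5)),
                                stationary = rep(TRUE, nrow(nodes)),
                                wall_k = 100) {
  stopifnot(is.data.frame(nodes), nrow(nodes) >= 2L,
            all(is.finite(nodes$x)), all(is.finite(nodes$y)),
            length(stationary) == nrow(nodes), wall_k > 0)
  if (any(diff(nodes$x) <= 0)) stop("node positions must be strictly increasing")
  n <- nrow(nodes)
  m <- numeric(n)
  fd <- diff(nodes$y) / diff(nodes$x)
  for (i in seq_len(n)) {
    if (stationary[i]) next
    m[i] <- if (i == 1L) fd[1L] else if (i == n) fd[n - 1L]
            else (fd[i - 1L] + fd[i]) / 2
  }
  structure(list(x = nodes$x, y = nodes$y, m = m,
                 stationary = as.logical(stationary), wall_k = wall_k),
            class = "surrogate_potential")
}

#' @export
print.surrogate_potential <- function(x, ...) {
  cat("<surrogate_potential: nodes",
      paste(sprintf("(%.3g, %.3g)", x$x, x$y), collapse = " "),
      sprintf("; wall %g kcal/mol/A^2>\n", x$wall_k))
  invisible(x)
}

#' Evaluate the landmark potential and its gradient
#'
#' Exact analytic energy and first derivative of a
#' [surrogate_potential()]; vectorised over `x`.
#'
#' @param potential a `surrogate_potential`.
#' @param x positions, Angstrom.
#' @return List with numeric vectors `energy` (kcal/mol) and `gradient`
#'   (kcal/mol/Angstrom).
#' @export
surrogate_energy <- function(potential, x) {
  p <- potential
  x <- as.numeric(x)
  stopifnot(all(is.finite(x)))
  n <- length(p$x)
  E <- numeric(length(x))
  Gr <- numeric(length(x))

  lo <- x < p$x[1L]
  hi <- x > p$x[n]
  if (any(lo)) {
    d <- x[lo] - p$x[1L]
    E[lo] <- p$y[1L] + p$m[1L] * d + 0.5 * p$wall_k * d^2
    Gr[lo] <- p$m[1L] + p$wall_k * d
  }
  if (any(hi)) {
    d <- x[hi] - p$x[n]
    E[hi] <- p$y[n] + p$m[n] * d + 0.5 * p$wall_k * d^2
    Gr[hi] <- p$m[n] + p$wall_k * d
  }
  mid <- !(lo | hi)
  if (any(mid)) {
    i <- findInterval(x[mid], p$x, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), n - 1L)
    h <- p$x[i + 1L] - p$x[i]
    t <- (x[mid] - p$x[i]) / h
    t2 <- t * t
    t3 <- t2 * t
    h00 <- 2 * t3 - 3 * t2 + 1
    h10 <- t3 - 2 * t2 + t
    h01 <- -2 * t3 + 3 * t2
    h11 <- t3 - t2
    E[mid] <- h00 * p$y[i] + h10 * h * p$m[i] + h01 * p$y[i + 1L] +
      h11 * h * p$m[i + 1L]
    d00 <- 6 * t2 - 6 * t
    d10 <- 3 * t2 - 4 * t + 1
    d01 <- -6 * t2 + 6 * t
    d11 <- 3 * t2 - 2 * t
    Gr[mid] <- (d00 * p$y[i] + d01 * p$y[i + 1L]) / h +
      d10 * p$m[i] + d11 * p$m[i + 1L]
  }
  list(energy = E, gradient = Gr)
}

# Largest curvature magnitude of the potential (for the sampler stability
# bound): Hermite segments attain max |y''| at their endpoints.
surrogate_max_curvature <- function(p) {
  n <- length(p$x)
  h <- diff(p$x)
  cmax <- p$wall_k
  for (i in seq_len(n - 1L)) {
    dy <- p$y[i + 1L] - p$y[i]
    # y''(t)/h^2 at t = 0, 1 for Hermite basis
    c0 <- abs((6 * dy - h[i] * (4 * p$m[i] + 2 * p$m[i + 1L])) / h[i]^2)
    c1 <- abs((-6 * dy + h[i] * (2 * p$m[i] + 4 * p$m[i + 1L])) / h[i]^2)
    cmax <- max(cmax, c0, c1)
  }
  cmax
}

# Run a body with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(seed)
  expr
}

#' Sample one umbrella window by overdamped Langevin dynamics
#'
#' Euler-Maruyama integration of overdamped Langevin dynamics on the
#' biased potential `U(x) + 1/2 k (x - center)^2`:
#' \deqn{x \leftarrow x - \frac{D}{k_BT}\,\nabla U_{tot}(x)\,\Delta t
#'   + \sqrt{2 D \Delta t}\;\mathcal{N}(0, 1).}
#' The stationary distribution of the exact dynamics is the Boltzmann
#' density of the biased potential, which is what umbrella sampling
#' assumes; the finite step size introduces an O(dt) discretisation bias
#' (see the methods vignette). The first `n_equil` steps are discarded.
#' Bit-reproducible for a fixed seed.
#'
#' @param potential a `surrogate_potential`.
#' @param center,k harmonic bias centre (Angstrom) and force constant
#'   (kcal/mol/Angstrom^2). `k = 0` disables the bias.
#' @param temperature in K.
#' @param dt integration step (nominal time units; one unit corresponds to
#'   0.001 ps under the package's calibration, so the defaults mirror a
#'   10 ps + 10 ps window protocol).
#' @param D diffusion coefficient, Angstrom^2 per time unit.
#' @param n_equil,n_prod discarded and retained step counts.
#' @param seed integer RNG seed (required).
#' @param x0 starting position (default the bias centre).
#' @return Numeric vector of `n_prod` sampled positions.
#' @export
langevin_sample <- function(potential, center, k, temperature = 300,
                            dt = 0.1, D = 0.001,
                            n_equil = 10000, n_prod = 10000,
                            seed, x0 = center) {
  stopifnot(inherits(potential, "surrogate_potential"), k >= 0,
            n_prod >= 1L, n_equil >= 0L)
  if (missing(seed)) stop("a seed is required")
  kT <- kB * temperature
  stab <- dt * D * (k + surrogate_max_curvature(potential)) / kT
  if (stab >= 0.5)
    stop(errorCondition(
      sprintf("unstable integration: dt*D*(k + max curvature)/kBT = %.3g >= 0.5", stab),
      class = c("ringpmf_parameter_error", "ringpmf_error", "error")))
  ntot <- n_equil + n_prod
  with_seed(seed, {
    noise <- sqrt(2 * D * dt) * stats::rnorm(ntot)
    mob <- D * dt / kT
    x <- x0
    out <- numeric(n_prod)
    p <- potential
    np <- length(p$x)
    for (s in seq_len(ntot)) {
      # inline scalar gradient of the Hermite/wall potential
      if (x < p$x[1L]) {
        g <- p$m[1L] + p$wall_k * (x - p$x[1L])
      } else if (x > p$x[np]) {
        g <- p$m[np] + p$wall_k * (x - p$x[np])
      } else {
        i <- findInterval(x, p$x, rightmost.closed = TRUE)
        if (i >= np) i <- np - 1L
        h <- p$x[i + 1L] - p$x[i]
        t <- (x - p$x[i]) / h
        g <- ((6 * t * t - 6 * t) * (p$y[i] - p$y[i + 1L])) / h +
          (3 * t * t - 4 * t + 1) * p$m[i] + (3 * t * t - 2 * t) * p$m[i + 1L]
      }
      g <- g + k * (x - center)
      x <- x - mob * g + noise[s]
      if (s > n_equil) out[s - n_equil] <- x
    }
    out
  })
}

#' Generate a full synthetic umbrella-sampling dataset
#'
#' Places `n_windows` harmonic windows evenly across `rc_range` and samples
#' each with [langevin_sample()]. Per-window sub-seeds are drawn once from
#' the master seed, so the dataset is a pure function of its parameters and
#' the seed, and windows can be regenerated independently in any order.
#' The defaults emulate a 42-window umbrella-sampling campaign over
#' 1.3-3.5 Angstrom with a 500 kcal/mol/Angstrom^2 restraint and
#' 10 ps equilibration + 10 ps production per window.
#'
#' @param potential a `surrogate_potential`.
#' @param n_windows number of windows (>= 2; default 42).
#' @param rc_range span of window centres, Angstrom (default `c(1.3, 3.5)`).
#' @param k bias force constant (default 500).
#' @param temperature,dt,D,n_equil,n_prod passed to [langevin_sample()].
#' @param seed master seed (required).
#' @return List of [umbrella_window()] objects.
#' @export
generate_umbrella_dataset <- function(potential, n_windows = 42,
                                      rc_range = c(1.3, 3.5), k = 500,
                                      temperature = 300, dt = 0.1, D = 0.001,
                                      n_equil = 10000, n_prod = 10000, seed) {
  stopifnot(n_windows >= 2L)
  if (missing(seed)) stop("a master seed is required")
  centers <- seq(rc_range[1L], rc_range[2L], length.out = n_windows)
  subseeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_windows))
  lapply(seq_len(n_windows), function(i) {
    s <- tryCatch(
      langevin_sample(potential, centers[i], k, temperature, dt, D,
                      n_equil, n_prod, seed = subseeds[i]),
      error = function(e) stop(errorCondition(
        sprintf("window %d (center %.3f A): %s", i, centers[i], conditionMessage(e)),
        class = class(e))))
    umbrella_window(centers[i], k, s, label = sprintf("w%02d", i))
  })
}

#' Conformational path on the Cremer-Pople sphere
#'
#' Defines how the ring puckering state evolves with the reaction
#' coordinate: an ordered list of (rc2, Q, theta, phi) anchors joined by
#' great-circle arcs in (theta, phi) and linear interpolation in Q. The
#' progress variable along each arc is warped by a symmetric logistic of
#' the given `sharpness`, so the conformation dwells near the anchors and
#' switches over a narrow rc2 range — mirroring the abrupt conformational
#' change observed near a glycosylation transition state. The default path
#' runs 1S3 (reactant, rc2 = 1.5, Q = 0.57) -> 2,5B (transition state,
#' rc2 = 2.17, Q = 0.45) -> 4C1 (product, rc2 = 2.8, Q = 0.57).
#'
#' @param anchors data.frame with columns `rc2` (increasing), `Q` (> 0),
#'   `theta`, `phi` (degrees).
#' @param angular_sd isotropic angular noise, degrees (default 8).
#' @param amplitude_sd noise on Q, Angstrom (default 0.03).
#' @param sharpness logistic steepness of the progress warp (default 12;
#'   larger = more abrupt switching).
#' @return Object of class `pucker_path`.
#' @export
pucker_path <- function(anchors = data.frame(rc2 = c(1.5, 2.17, 2.8),
                                             Q = c(0.57, 0.45, 0.57),
                                             theta = c(90, 90, 0),
                                             phi = c(210, 120, 120)),
                        angular_sd = 8, amplitude_sd = 0.03, sharpness = 12) {
  stopifnot(is.data.frame(anchors), nrow(anchors) >= 2L,
            all(diff(anchors$rc2) > 0), all(anchors$Q > 0),
            angular_sd >= 0, amplitude_sd >= 0, sharpness > 0)
  structure(list(anchors = anchors, angular_sd = angular_sd,
                 amplitude_sd = amplitude_sd, sharpness = sharpness),
            class = "pucker_path")
}

sph_to_vec <- function(theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  c(sin(th) * sin(ph), sin(th) * cos(ph), cos(th))
}

vec_to_sph <- function(v) {
  v <- v / sqrt(sum(v^2))
  theta <- acos(max(-1, min(1, v[3L]))) * 180 / pi
  phi <- if (abs(v[1L]) < 1e-12 && abs(v[2L]) < 1e-12) 0
         else (atan2(v[1L], v[2L]) * 180 / pi) %% 360
  c(theta = theta, phi = phi)
}

# spherical linear interpolation between unit vectors
slerp <- function(u, v, t) {
  cosw <- max(-1, min(1, sum(u * v)))
  w <- acos(cosw)
  if (w < 1e-12) return(u)
  (sin((1 - t) * w) * u + sin(t * w) * v) / sin(w)
}

# symmetric normalised logistic warp on [0, 1]
logistic_warp <- function(t, s) {
  f <- function(u) 1 / (1 + exp(-s * (u - 0.5)))
  (f(t) - f(0)) / (f(1) - f(0))
}

#' Puckering state along the path, with noise
#'
#' Evaluates a [pucker_path()] at one rc2 value (clamped to the anchor
#' span): great-circle interpolation of (theta, phi), linear interpolation
#' of Q, both under the path's logistic progress warp, then noise — the
#' sphere point is rotated by a N(0, angular_sd) angle about a random axis
#' perpendicular to it (isotropic angular perturbation) and Q is jittered
#' by N(0, amplitude_sd). Uses the current RNG state; seed via
#' [generate_ring_trajectory()] or `set.seed()` for reproducibility.
#'
#' @param path a `pucker_path`.
#' @param rc2 reaction-coordinate value, Angstrom.
#' @param noise logical; `FALSE` gives the deterministic path point.
#' @return Named numeric vector `c(Q, theta, phi)`.
#' @export
pucker_path_state <- function(path, rc2, noise = TRUE) {
  a <- path$anchors
  n <- nrow(a)
  rc2 <- max(a$rc2[1L], min(a$rc2[n], rc2))
  i <- findInterval(rc2, a$rc2, rightmost.closed = TRUE)
  i <- min(max(i, 1L), n - 1L)
  traw <- (rc2 - a$rc2[i]) / (a$rc2[i + 1L] - a$rc2[i])
  t <- logistic_warp(traw, path$sharpness)
  u <- slerp(sph_to_vec(a$theta[i], a$phi[i]),
             sph_to_vec(a$theta[i + 1L], a$phi[i + 1L]), t)
  Q <- (1 - t) * a$Q[i] + t * a$Q[i + 1L]
  if (noise) {
    if (path$angular_sd > 0) {
      # random tangent axis, rotate u by alpha about it
      r <- stats::rnorm(3)
      ax <- r - sum(r * u) * u
      nax <- sqrt(sum(ax^2))
      if (nax > 1e-12) {
        ax <- ax / nax
        alpha <- stats::rnorm(1, sd = path$angular_sd) * pi / 180
        w <- c(ax[2L] * u[3L] - ax[3L] * u[2L],
               ax[3L] * u[1L] - ax[1L] * u[3L],
               ax[1L] * u[2L] - ax[2L] * u[1L])
        u <- cos(alpha) * u + sin(alpha) * w
      }
    }
    if (path$amplitude_sd > 0)
      Q <- max(1e-6, Q + stats::rnorm(1, sd = path$amplitude_sd))
  }
  s <- vec_to_sph(u)
  c(Q = Q, theta = unname(s["theta"]), phi = unname(s["phi"]))
}

#' Generate a synthetic ring trajectory along the itinerary
#'
#' One six-atom ring frame (labels O5, C1..C5) per rc2 value, built by
#' [inverse_cremer_pople()] from the noisy [pucker_path_state()].
#' Deterministic under a fixed seed.
#'
#' @param path a `pucker_path`.
#' @param rc2_series numeric vector of reaction-coordinate values.
#' @param ring_radius in-plane ring radius, Angstrom.
#' @param seed integer RNG seed (required).
#' @return List of [md_frame()] objects with attribute `rc2`.
#' @export
generate_ring_trajectory <- function(path, rc2_series, ring_radius = 1.45,
                                     seed) {
  stopifnot(length(rc2_series) >= 1L)
  if (missing(seed)) stop("a seed is required")
  frames <- with_seed(seed, lapply(seq_along(rc2_series), function(i) {
    st <- pucker_path_state(path, rc2_series[i])
    xyz <- inverse_cremer_pople(st["Q"], st["theta"], st["phi"], ring_radius)
    md_frame(rownames(xyz), xyz,
             elements = c("O", "C", "C", "C", "C", "C"),
             time = (i - 1L) * 1.0)
  }))
  attr(frames, "rc2") <- as.numeric(rc2_series)
  frames
}
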