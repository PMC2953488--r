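# WHAM reconstruction of one-dimensional potentials of mean force from
# harmonic umbrella-sampling windows, plus landmark extraction.

#' Boltzmann constant in kcal/mol/K
#' @export
kB <- 0.0019872041

#' Construct an umbrella window
#'
#' One biased sampling window: a harmonic restraint `w(x) = 1/2 k (x - c)^2`
#' (the 1/2 is included here; set `half_k = FALSE` in [wham()] for the
#' `k (x - c)^2` convention) and the reaction-coordinate values sampled
#' under it.
#'
#' @param center bias centre, Angstrom.
#' @param k force constant, kcal/mol/Angstrom^2 (> 0).
#' @param samples numeric vector of sampled RC values (finite, >= 1).
#' @param label optional window label.
#' @return Object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, k, samples, label = NULL) {
  samples <- as.numeric(samples)
  if (!is.finite(center)) stop("window center must be finite")
  if (!is.finite(k) || k <= 0) stop("force constant must be positive")
  if (length(samples) < 1L || !all(is.finite(samples)))
    stop("samples must be a nonempty finite numeric vector")
  if (is.null(label)) label <- sprintf("c%.4f", center)
  structure(list(center = center, k = k, samples = samples,
                 label = as.character(label)),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("<umbrella_window %s: center %.3f A, k %g kcal/mol/A^2, %d samples>\n",
              x$label, x$center, x$k, length(x$samples)))
  invisible(x)
}

# Common binned grid for a sample set: edges aligned to multiples of the
# bin width so independently computed profiles share bin centers.
pmf_grid <- function(xmin, xmax, bin_width) {
  lo <- floor(xmin / bin_width) * bin_width
  hi <- ceiling(xmax / bin_width) * bin_width
  nb <- max(1L, round((hi - lo) / bin_width))
  list(edges = lo + bin_width * (0:nb), centers = lo + bin_width * ((1:nb) - 0.5))
}

new_pmf_profile <- function(bin_centers, G, counts, temperature, bin_width,
                            class = "pmf_profile", extra = list()) {
  pop <- counts > 0L
  G[!pop] <- NA_real_
  G[pop] <- G[pop] - min(G[pop])
  structure(c(list(bin_centers = bin_centers, G = G, counts = counts,
                   temperature = temperature, bin_width = bin_width), extra),
            class = unique(c(class, "pmf_profile")))
}

#' Reconstruct a free-energy profile by WHAM
#'
#' Fits the unbiased probability density along the reaction coordinate to
#' the samples of a set of harmonically biased umbrella windows by the
#' weighted histogram analysis method: the self-consistency equations
#' \deqn{P(\xi) = \frac{\sum_i n_i(\xi)}{\sum_j N_j
#'   \exp[(F_j - w_j(\xi))/k_BT]},\qquad
#'   F_j = -k_BT \ln \sum_\xi P(\xi) \exp[-w_j(\xi)/k_BT]}
#' are iterated until the largest change in any window free energy F_j
#' falls below `tol * kB * T`. The returned profile is
#' `G = -kB T log P`, with P normalised to unit integral first and G
#' anchored to zero at its minimum over populated bins.
#'
#' @param windows list of [umbrella_window()] objects.
#' @param bin_width histogram bin width, Angstrom (default 0.02).
#' @param temperature in K (default 300).
#' @param tol dimensionless convergence tolerance on F_j in units of kB*T
#'   (default 1e-7).
#' @param max_iter iteration cap (default 1e5).
#' @param half_k if `TRUE` (default) the bias is `1/2 k (x - c)^2`; if
#'   `FALSE`, `k (x - c)^2`. Use the same convention as the sampler.
#' @return Object of class `wham_pmf` (and `pmf_profile`) with fields
#'   `bin_centers`, `G` (kcal/mol, `NA` on empty bins), `counts`,
#'   `temperature`, `bin_width`, `window_f` (converged F_j, kcal/mol),
#'   `iterations`, `residual`.
#' @seealso [landmarks()], [profile_sd()], [direct_histogram_pmf()]
#' @export
wham <- function(windows, bin_width = 0.02, temperature = 300,
                 tol = 1e-7, max_iter = 1e5, half_k = TRUE) {
  stopifnot(length(windows) >= 1L)
  for (w in windows)
    if (!inherits(w, "umbrella_window")) stop("windows must be umbrella_window objects")
  if (tol <= 0) stop("tol must be positive")
  kT <- kB * temperature
  allx <- unlist(lapply(windows, `[[`, "samples"))
  g <- pmf_grid(min(allx), max(allx), bin_width)
  nb <- length(g$centers)
  nw <- length(windows)

  counts_w <- vapply(windows, function(w)
    tabulate(findInterval(w$samples, g$edges, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins = nb),
    integer(nb))
  counts_w <- matrix(counts_w, nrow = nb)
  n_b <- rowSums(counts_w)

  pop <- which(n_b > 0L)
  gap <- pop[1L]:pop[length(pop)]
  empt <- setdiff(gap, pop)
  if (length(empt) > 0L)
    stop(errorCondition(
      sprintf("window histograms do not overlap: empty bin(s) near %.3f A split the sampled range",
              g$centers[empt[1L]]),
      class = c("ringpmf_connectivity_error", "ringpmf_error", "error")))

  half <- if (half_k) 0.5 else 1
  kvec <- vapply(windows, `[[`, numeric(1), "k")
  cvec <- vapply(windows, `[[`, numeric(1), "center")
  # bias energies on populated bins only: nb_pop x nw
  W <- half * sweep(outer(g$centers[pop], cvec, "-")^2, 2L, kvec, "*")
  B <- exp(-W / kT)
  Nj <- vapply(windows, function(w) length(w$samples), numeric(1))
  nb_pop <- n_b[pop]

  f <- numeric(nw)              # F_j / kT
  resid <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    denom <- as.vector(B %*% (Nj * exp(f)))
    P <- nb_pop / denom
    z <- as.vector(crossprod(B, P))
    f_new <- -log(z)
    f_new <- f_new - f_new[1L]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tol) break
  }
  if (resid >= tol)
    stop(errorCondition(
      sprintf("WHAM did not converge in %d iterations (last residual %.3g kT, tol %.3g)",
              max_iter, resid, tol),
      class = c("ringpmf_convergence_error", "ringpmf_error", "error")))

  P <- P / sum(P * bin_width)
  G <- rep(NA_real_, nb)
  G[pop] <- -kT * log(P)
  new_pmf_profile(g$centers, G, n_b, temperature, bin_width,
                  class = "wham_pmf",
                  extra = list(window_f = kT * f, iterations = it,
                               residual = resid, n_windows = nw))
}

#' Direct Boltzmann-inversion profile from unbiased samples
#'
#' Brute-force reference estimator: histogram the samples, normalise to a
#' density and apply `G = -kB T log(density)`, anchored at zero. On
#' unbiased data this is the definitional free-energy profile and serves as
#' the independent oracle against which [wham()] is validated.
#'
#' @param samples numeric vector of RC values.
#' @param bin_width histogram bin width, Angstrom.
#' @param temperature in K.
#' @return A `pmf_profile` object.
#' @export
direct_histogram_pmf <- function(samples, bin_width = 0.02, temperature = 300) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L || !all(is.finite(samples)))
    stop("samples must be a nonempty finite numeric vector")
  kT <- kB * temperature
  g <- pmf_grid(min(samples), max(samples), bin_width)
  n_b <- tabulate(findInterval(samples, g$edges, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = length(g$centers))
  dens <- n_b / (sum(n_b) * bin_width)
  G <- ifelse(n_b > 0L, -kT * log(dens), NA_real_)
  new_pmf_profile(g$centers, G, n_b, temperature, bin_width)
}

# Quadratic refinement of an extremum through a bin and its two neighbours;
# returns c(x, y) of the parabola vertex, or the raw point at grid edges.
quad_refine <- function(x, y, i) {
  if (i <= 1L || i >= length(x) || anyNA(y[(i - 1L):(i + 1L)]))
    return(c(x[i], y[i]))
  h <- x[i + 1L] - x[i]
  a <- (y[i + 1L] + y[i - 1L] - 2 * y[i]) / (2 * h^2)
  b <- (y[i + 1L] - y[i - 1L]) / (2 * h)
  if (a == 0) return(c(x[i], y[i]))
  dx <- -b / (2 * a)
  c(x[i] + dx, y[i] + b * dx + a * dx^2)
}

#' Extract stationary-point landmarks from a free-energy profile
#'
#' Locates the reactant-side minimum, the interior maximum (transition
#' state) and the product-side minimum of a profile, refining each by a
#' quadratic fit through the extremal bin and its two neighbours, and
#' reports the barrier height and reaction free energy.
#'
#' @param profile a `pmf_profile` (e.g. from [wham()]).
#' @param reactant_window,product_window length-2 numeric intervals
#'   (Angstrom) bracketing the two minima.
#' @return Object of class `pmf_landmarks`: list with `reactant_min`,
#'   `ts_pos`, `product_min` (Angstrom), `barrier`, `delta_g` (kcal/mol).
#' @export
landmarks <- function(profile, reactant_window = c(1.3, 1.9),
                      product_window = c(2.9, 3.5)) {
  stopifnot(inherits(profile, "pmf_profile"))
  x <- profile$bin_centers
  G <- profile$G
  sel_r <- which(x >= reactant_window[1L] & x <= reactant_window[2L] & !is.na(G))
  sel_p <- which(x >= product_window[1L] & x <= product_window[2L] & !is.na(G))
  if (length(sel_r) == 0L) stop("reactant window contains no populated bins")
  if (length(sel_p) == 0L) stop("product window contains no populated bins")
  ir <- sel_r[which.min(G[sel_r])]
  ip <- sel_p[which.min(G[sel_p])]
  if (ip <= ir) stop("product minimum does not lie beyond the reactant minimum")
  interior <- (ir + 1L):(ip - 1L)
  interior <- interior[!is.na(G[interior])]
  if (length(interior) == 0L)
    stop(errorCondition("no interior maximum between the two minima",
                        class = c("ringpmf_landmark_error", "ringpmf_error", "error")))
  its <- interior[which.max(G[interior])]
  if (its == ir + 1L && G[ir] > G[its] || its == ip - 1L && G[ip] > G[its])
    stop(errorCondition("no interior maximum between the two minima",
                        class = c("ringpmf_landmark_error", "ringpmf_error", "error")))
  if (G[its] <= max(G[ir], G[ip]))
    stop(errorCondition("no interior maximum between the two minima",
                        class = c("ringpmf_landmark_error", "ringpmf_error", "error")))
  r <- quad_refine(x, G, ir)
  p <- quad_refine(x, G, ip)
  t <- quad_refine(x, G, its)
  structure(list(reactant_min = r[1L], ts_pos = t[1L], product_min = p[1L],
                 barrier = t[2L] - r[2L], delta_g = p[2L] - r[2L]),
            class = "pmf_landmarks")
}

#' @export
print.pmf_landmarks <- function(x, ...) {
  cat(sprintf(paste0(
    "Free-energy landmarks\n",
    "  reactant minimum : %.3f A\n",
    "  transition state : %.3f A\n",
    "  product minimum  : %.3f A\n",
    "  barrier          : %.2f kcal/mol\n",
    "  delta G          : %.2f kcal/mol\n"),
    x$reactant_min, x$ts_pos, x$product_min, x$barrier, x$delta_g))
  invisible(x)
}

#' Pointwise spread between two free-energy profiles
#'
#' Root-mean-square pointwise difference between two profiles over a
#' reaction-coordinate range, computed on common populated bins (matched by
#' centre to within half a bin width) after re-anchoring each profile to
#' zero at its own minimum within `anchor_window` (by default the global
#' minimum). Used to quantify run-to-run reproducibility of a
#' reconstructed profile.
#'
#' @param a,b `pmf_profile` objects on compatible grids.
#' @param range length-2 interval (Angstrom) over which to compare.
#' @param anchor_window optional interval in which each profile's anchoring
#'   minimum is sought; default: its global minimum.
#' @return RMS difference in kcal/mol.
#' @export
profile_sd <- function(a, b, range, anchor_window = NULL) {
  stopifnot(inherits(a, "pmf_profile"), inherits(b, "pmf_profile"))
  anchor <- function(p) {
    x <- p$bin_centers
    sel <- if (is.null(anchor_window)) !is.na(p$G)
           else (x >= anchor_window[1L] & x <= anchor_window[2L] & !is.na(p$G))
    if (!any(sel)) stop("anchor window contains no populated bins")
    p$G - min(p$G[sel])
  }
  Ga <- anchor(a)
  Gb <- anchor(b)
  bw <- min(a$bin_width, b$bin_width)
  ia <- which(a$bin_centers >= range[1L] & a$bin_centers <= range[2L] & !is.na(Ga))
  if (length(ia) == 0L) stop("no populated bins of `a` in range")
  ib <- vapply(a$bin_centers[ia], function(x) {
    j <- which.min(abs(b$bin_centers - x))
    if (abs(b$bin_centers[j] - x) < bw / 2 && !is.na(Gb[j])) j else NA_integer_
  }, integer(1))
  keep <- !is.na(ib)
  if (!any(keep)) stop("profiles share no common populated bins in range")
  sqrt(mean((Ga[ia[keep]] - Gb[ib[keep]])^2))
}

# ---- methods for the fitted-profile class ----------------------------------

#' @export
print.wham_pmf <- function(x, ...) {
  pop <- sum(x$counts > 0L)
  cat(sprintf(paste0(
    "WHAM free-energy profile\n",
    "  %d windows, %d samples, %d/%d populated bins of %.3g A\n",
    "  T = %g K; converged in %d iterations (residual %.2g kT)\n",
    "  range: G in [0, %.2f] kcal/mol over [%.3f, %.3f] A\n"),
    x$n_windows, sum(x$counts), pop, length(x$counts), x$bin_width,
    x$temperature, x$iterations, x$residual,
    max(x$G, na.rm = TRUE), min(x$bin_centers), max(x$bin_centers)))
  invisible(x)
}

#' @export
summary.wham_pmf <- function(object, reactant_window = c(1.3, 1.9),
                             product_window = c(2.9, 3.5), ...) {
  lm <- tryCatch(landmarks(object, reactant_window, product_window),
                 error = function(e) NULL)
  structure(list(profile = object, landmarks = lm), class = "summary.wham_pmf")
}

#' @export
print.summary.wham_pmf <- function(x, ...) {
  print(x$profile)
  if (!is.null(x$landmarks)) print(x$landmarks)
  else cat("  (no landmark set could be extracted)\n")
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, xlab = "RC2 (Å)",
                             ylab = "G (kcal/mol)", type = "l", ...) {
  graphics::plot(x$bin_centers, x$G, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Interpolate a profile at new coordinate values
#'
#' Linear interpolation of the free energy over populated bins; `NA`
#' outside the populated range.
#'
#' @param object a `pmf_profile`.
#' @param newdata numeric vector of RC values (Angstrom).
#' @param ... unused.
#' @return Numeric vector of free energies, kcal/mol.
#' @export
predict.pmf_profile <- function(object, newdata, ...) {
  ok <- !is.na(object$G)
  stats::approx(object$bin_centers[ok], object$G[ok], xout = newdata,
                rule = 1)$y
}
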