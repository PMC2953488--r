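# Cremer-Pople puckering analysis for six-membered sugar rings.
#
# Ring atoms are always taken in the order O5, C1, C2, C3, C4, C5
# (j = 1..6). With the sign conventions below, theta = 0 corresponds to the
# 4C1 chair and theta = 180 to 1C4, the common carbohydrate convention.
# Absolute phi values are convention-dependent (atom ordering and phase
# origin); conformer names, not raw phi, are the quantity to compare across
# codes.

cp_angles <- 2 * pi * (0:5) / 6

# Unit normal of the Cremer-Pople mean plane. The orientation is fixed so
# that a ring traversed O5 -> C1 -> ... -> C5 counterclockwise in the
# xy-plane gets normal +z; this is what makes theta = 0 the 4C1 chair.
cp_mean_plane_normal <- function(rc) {
  cen <- colMeans(rc)
  rcc <- sweep(rc, 2L, cen)
  if (svd(rcc, nu = 0, nv = 0)$d[2L] < 1e-10)
    stop(errorCondition("ring atoms are collinear; mean plane undefined",
                        class = c("ringpmf_geometry_error", "ringpmf_error", "error")))
  rp <- colSums(rcc * sin(cp_angles))   # R'
  rpp <- colSums(rcc * cos(cp_angles))  # R''
  n <- c(rpp[2L] * rp[3L] - rpp[3L] * rp[2L],
         rpp[3L] * rp[1L] - rpp[1L] * rp[3L],
         rpp[1L] * rp[2L] - rpp[2L] * rp[1L])   # R'' x R'
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12)
    stop(errorCondition("degenerate ring geometry; mean plane undefined",
                        class = c("ringpmf_geometry_error", "ringpmf_error", "error")))
  n / nn
}

#' Cremer-Pople puckering coordinates of a six-membered ring
#'
#' Computes the total puckering amplitude Q, the polar angle theta and the
#' pseudorotation phase phi of a pyranose-type ring, together with the
#' planar Stoddart projections `q_x = Q sin(theta) sin(phi)` and
#' `q_y = Q sin(theta) cos(phi)` and the chair component `q3 = Q cos(theta)`.
#'
#' The construction is the standard one: translate to the geometric centre,
#' build the unique mean plane from the two trigonometrically weighted sum
#' vectors (out-of-plane displacements z_j then sum to zero by
#' construction), and project the z_j onto the m = 2 and m = 3 puckering
#' modes:
#' \deqn{q_2\cos\phi_2 = \sqrt{1/3}\,\sum_j z_j \cos(4\pi(j-1)/6),\quad
#'       q_2\sin\phi_2 = -\sqrt{1/3}\,\sum_j z_j \sin(4\pi(j-1)/6),}
#' \deqn{q_3 = \sqrt{1/6}\,\sum_j (-1)^{j-1} z_j,}
#' with \eqn{Q^2 = q_2^2 + q_3^2} and \eqn{\cos\theta = q_3/Q}.
#'
#' @param ring_coords 6 x 3 numeric matrix of ring-atom coordinates in the
#'   order O5, C1, C2, C3, C4, C5 (Angstrom).
#' @return An object of class `pucker_coords`: list with `Q`, `theta`
#'   (degrees, `[0, 180]`), `phi` (degrees, `[0, 360)`), `q_x`, `q_y`, `q2`,
#'   `q3` and the displacement vector `z`. For a planar ring (Q below 1e-8)
#'   `theta` and `phi` are `NA`.
#' @export
#' @examples
#' xyz <- inverse_cremer_pople(0.57, 90, 210)
#' cremer_pople(xyz)
cremer_pople <- function(ring_coords) {
  rc <- as.matrix(ring_coords)
  stopifnot(nrow(rc) == 6L, ncol(rc) == 3L)
  if (!all(is.finite(rc))) stop("non-finite ring coordinates")
  n <- cp_mean_plane_normal(rc)
  cen <- colMeans(rc)
  z <- as.vector(sweep(rc, 2L, cen) %*% n)
  q2c <- sqrt(1 / 3) * sum(z * cos(2 * cp_angles))
  q2s <- -sqrt(1 / 3) * sum(z * sin(2 * cp_angles))
  q3 <- sqrt(1 / 6) * sum(z * c(1, -1, 1, -1, 1, -1))
  q2 <- sqrt(q2c^2 + q2s^2)
  Q <- sqrt(q2^2 + q3^2)
  if (Q < 1e-8) {
    theta <- NA_real_
    phi <- NA_real_
  } else {
    theta <- atan2(q2, q3) * 180 / pi
    phi <- (atan2(q2s, q2c) * 180 / pi) %% 360
    if (360 - phi < 1e-9) phi <- 0   # keep phi in [0, 360)
  }
  structure(list(Q = Q, theta = theta, phi = phi,
                 q_x = q2s, q_y = q2c, q2 = q2, q3 = q3, z = z),
            class = "pucker_coords")
}

#' @export
print.pucker_coords <- function(x, ...) {
  cat(sprintf("<pucker_coords: Q = %.4f A, theta = %s, phi = %s>\n",
              x$Q,
              if (is.na(x$theta)) "NA (planar)" else sprintf("%.2f deg", x$theta),
              if (is.na(x$phi)) "NA" else sprintf("%.2f deg", x$phi)))
  invisible(x)
}

#' Build ring coordinates with prescribed puckering coordinates
#'
#' Places the six ring atoms at equal angles on a circle of radius
#' `ring_radius` in the xy-plane and assigns out-of-plane displacements
#' \deqn{z_j = \sqrt{1/3}\, q_2 \cos(\phi + 4\pi(j-1)/6)
#'       + \sqrt{1/6}\, q_3 (-1)^{j-1},}
#' with \eqn{q_2 = Q\sin\theta}, \eqn{q_3 = Q\cos\theta}. For Q > 0,
#' [cremer_pople()] of the result recovers (Q, theta, phi) exactly, making
#' this the generator half of a round-trip identity.
#'
#' @param Q puckering amplitude, Angstrom (>= 0).
#' @param theta polar angle, degrees.
#' @param phi phase angle, degrees.
#' @param ring_radius in-plane ring radius, Angstrom (default 1.45, a
#'   typical pyranose value).
#' @return 6 x 3 coordinate matrix with rownames O5, C1, ..., C5.
#' @export
inverse_cremer_pople <- function(Q, theta, phi, ring_radius = 1.45) {
  if (Q < 0) stop("Q must be non-negative")
  if (ring_radius <= 0) stop("ring_radius must be positive")
  th <- theta * pi / 180
  ph <- phi * pi / 180
  q2 <- Q * sin(th)
  q3 <- Q * cos(th)
  z <- sqrt(1 / 3) * q2 * cos(ph + 2 * cp_angles) +
    sqrt(1 / 6) * q3 * c(1, -1, 1, -1, 1, -1)
  xyz <- cbind(ring_radius * cos(cp_angles), ring_radius * sin(cp_angles), z)
  rownames(xyz) <- c("O5", "C1", "C2", "C3", "C4", "C5")
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

#' Canonical conformer table
#'
#' The 38 canonical pyranose conformers and their (theta, phi) positions on
#' the Cremer-Pople sphere under this package's conventions (atom order O5,
#' C1..C5; theta = 0 is 4C1): the two chairs at the poles, boats and
#' skew-boats alternating every 30 degrees of phi on the equator, and
#' envelopes (theta = 54.74 / 125.26) interleaved with half-chairs
#' (theta = 50.77 / 129.23) every 30 degrees on the two tropics. The table
#' was derived by projecting ideal chair/boat/twist/envelope/half-chair
#' displacement patterns onto the q2/q3 puckering modes; it agrees with the
#' standard carbohydrate assignments (e.g. 1S3 at theta 90, phi 210).
#'
#' @return data.frame with columns `name`, `theta`, `phi`.
#' @export
conformer_table <- function() {
  th_E <- 180 / pi * atan2(sqrt(2), 1)       # 54.7356: envelopes
  th_H <- 180 / pi * atan2(1, sqrt(2 / 3))   # 50.7685: half-chairs
  data.frame(
    name = c(
      "4C1", "1C4",
      # equator: boats at even multiples of 30, skews at odd
      "O,3B", "3S1", "B1,4", "5S1", "2,5B", "2SO",
      "BO,3", "1S3", "1,4B", "1S5", "B2,5", "OS2",
      # northern tropic (theta < 90)
      "OE", "OH1", "E1", "2H1", "2E", "2H3",
      "E3", "4H3", "4E", "4H5", "E5", "OH5",
      # southern tropic
      "3E", "3H4", "E4", "5H4", "5E", "5HO",
      "EO", "1HO", "1E", "1H2", "E2", "3H2"),
    theta = c(
      0, 180,
      rep(90, 12),
      rep(c(th_E, th_H), 6),
      rep(c(180 - th_E, 180 - th_H), 6)),
    phi = c(
      0, 0,
      seq(0, 330, by = 30),
      seq(0, 330, by = 30),
      seq(0, 330, by = 30)),
    stringsAsFactors = FALSE)
}

# Great-circle distance on the sphere, degrees; vectorized over (t1, p1).
cp_geodesic <- function(t1, p1, t2, p2) {
  t1 <- t1 * pi / 180; p1 <- p1 * pi / 180
  t2 <- t2 * pi / 180; p2 <- p2 * pi / 180
  cosd <- cos(t1) * cos(t2) + sin(t1) * sin(t2) * cos(p1 - p2)
  acos(pmax(-1, pmin(1, cosd))) * 180 / pi
}

# Vectorized nearest-vertex classification; returns data.frame(name, dist).
classify_theta_phi <- function(theta, phi) {
  tab <- conformer_table()
  nm <- character(length(theta))
  gd <- numeric(length(theta))
  for (i in seq_along(theta)) {
    d <- cp_geodesic(tab$theta, tab$phi, theta[i], phi[i])
    k <- which.min(d)   # ties broken by table order
    nm[i] <- tab$name[k]
    gd[i] <- d[k]
  }
  data.frame(name = nm, dist = gd, stringsAsFactors = FALSE)
}

#' Classify a ring conformation by nearest canonical conformer
#'
#' Assigns the canonical conformer whose (theta, phi) vertex minimises the
#' great-circle distance to the observed puckering angles. Rings with
#' amplitude below the planarity threshold are labelled `"planar"` (theta
#' and phi are numerically unstable as Q approaches 0). Classification is
#' nearest-vertex only; no region polygons are drawn on the sphere.
#'
#' @param p a `pucker_coords` object (or a list with `Q`, `theta`, `phi`).
#' @param planarity_threshold amplitude below which the ring is reported
#'   planar (Angstrom, default 0.1).
#' @return List with `name` (conformer string) and `geodesic_dist`
#'   (degrees; `NA` for planar rings).
#' @export
#' @examples
#' classify_conformer(cremer_pople(inverse_cremer_pople(0.57, 90, 210)))
classify_conformer <- function(p, planarity_threshold = 0.1) {
  if (!is.na(p$Q) && p$Q < planarity_threshold)
    return(list(name = "planar", geodesic_dist = NA_real_))
  cl <- classify_theta_phi(p$theta, p$phi)
  list(name = cl$name, geodesic_dist = cl$dist)
}

#' Puckering series for a ring trajectory
#'
#' Convenience wrapper: computes Cremer-Pople coordinates and conformer
#' labels for every frame of a trajectory.
#'
#' @param frames list of [md_frame()] objects.
#' @param ring six atom labels in ring order (default O5, C1..C5).
#' @param planarity_threshold passed to [classify_conformer()].
#' @return data.frame with columns `frame_index`, `Q`, `theta`, `phi`,
#'   `q_x`, `q_y`, `conformer`, `geodesic_dist`.
#' @export
pucker_series <- function(frames, ring = c("O5", "C1", "C2", "C3", "C4", "C5"),
                          planarity_threshold = 0.1) {
  rows <- lapply(seq_along(frames), function(i) {
    p <- cremer_pople(frame_coords(frames[[i]], ring))
    cl <- classify_conformer(p, planarity_threshold)
    data.frame(frame_index = i - 1L, Q = p$Q, theta = p$theta, phi = p$phi,
               q_x = p$q_x, q_y = p$q_y, conformer = cl$name,
               geodesic_dist = cl$geodesic_dist, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Conformational itinerary summary along a reaction coordinate
#'
#' Bins puckering observations into named reaction-coordinate regions and
#' reports, per region, the population fraction of each conformer label and
#' the mean and standard deviation of the Stoddart projections (q_x, q_y).
#' Frames outside all regions are ignored; fractions within each nonempty
#' region sum to one.
#'
#' @param pucker a data.frame with columns `Q`, `theta`, `phi` (e.g. from
#'   [pucker_series()]) or a list of `pucker_coords`.
#' @param rc2 numeric vector of reaction-coordinate values, same length.
#' @param regions named list of length-2 numeric intervals (Angstrom),
#'   non-overlapping. Default: the reactant, transition-state and product
#'   windows 1.5-1.8, 2.0-2.3 and 2.4-3.2 Angstrom.
#' @param planarity_threshold passed to the classifier.
#' @return Object of class `pucker_itinerary`: list with `summary` (one row
#'   per region: `region`, `n`, `majority`, `qx_mean`, `qx_sd`, `qy_mean`,
#'   `qy_sd`) and `fractions` (`region`, `conformer`, `count`, `fraction`).
#' @export
itinerary <- function(pucker, rc2,
                      regions = list(reactant = c(1.5, 1.8),
                                     ts = c(2.0, 2.3),
                                     product = c(2.4, 3.2)),
                      planarity_threshold = 0.1) {
  if (!is.data.frame(pucker))
    pucker <- do.call(rbind, lapply(pucker, function(p)
      data.frame(Q = p$Q, theta = p$theta, phi = p$phi,
                 q_x = p$q_x, q_y = p$q_y)))
  if (nrow(pucker) != length(rc2))
    stop("pucker series and rc2 series have different lengths")
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop("regions must be named")
  reg <- do.call(rbind, lapply(regions, function(r) sort(as.numeric(r))))
  o <- order(reg[, 1L])
  if (any(reg[o, 1L][-1L] < reg[o, 2L][-length(regions)]))
    stop("regions overlap")
  if (is.null(pucker$q_x)) {
    th <- pucker$theta * pi / 180
    ph <- pucker$phi * pi / 180
    pucker$q_x <- pucker$Q * sin(th) * sin(ph)
    pucker$q_y <- pucker$Q * sin(th) * cos(ph)
  }
  lab <- ifelse(pucker$Q < planarity_threshold, "planar",
                classify_theta_phi(pucker$theta, pucker$phi)$name)
  sum_rows <- list()
  frac_rows <- list()
  for (rn in names(regions)) {
    r <- regions[[rn]]
    sel <- which(rc2 >= r[1L] & rc2 <= r[2L])
    n <- length(sel)
    if (n == 0L) {
      sum_rows[[rn]] <- data.frame(region = rn, n = 0L, majority = NA_character_,
                                   qx_mean = NA_real_, qx_sd = NA_real_,
                                   qy_mean = NA_real_, qy_sd = NA_real_,
                                   stringsAsFactors = FALSE)
      next
    }
    tb <- sort(table(lab[sel]), decreasing = TRUE)
    frac_rows[[rn]] <- data.frame(region = rn, conformer = names(tb),
                                  count = as.integer(tb),
                                  fraction = as.numeric(tb) / n,
                                  stringsAsFactors = FALSE)
    sum_rows[[rn]] <- data.frame(
      region = rn, n = n, majority = names(tb)[1L],
      qx_mean = mean(pucker$q_x[sel]),
      qx_sd = stats::sd(pucker$q_x[sel]),
      qy_mean = mean(pucker$q_y[sel]),
      qy_sd = stats::sd(pucker$q_y[sel]),
      stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, c(sum_rows, make.row.names = FALSE)),
                 fractions = do.call(rbind, c(frac_rows, make.row.names = FALSE)),
                 regions = regions),
            class = "pucker_itinerary")
}

#' @export
print.pucker_itinerary <- function(x, ...) {
  cat("Conformational itinerary by reaction-coordinate region\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
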