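#' Construct a coordinate frame
#'
#' A frame holds one time point of a trajectory: a set of uniquely labelled
#' atoms with Cartesian coordinates in Angstrom. Labels are free strings and
#' are matched exactly by all geometric operations; no PDB-style name
#' normalisation is applied.
#'
#' @param labels character vector of unique atom labels.
#' @param coords numeric matrix, one row per atom, three columns (x, y, z),
#'   in Angstrom.
#' @param elements optional character vector of element symbols; defaults to
#'   the label with trailing digits stripped.
#' @param time optional time stamp in ps.
#' @return An object of class `md_frame`.
#' @export
#' @examples
#' fr <- md_frame(c("A", "B"), rbind(c(0, 0, 0), c(3, 4, 0)))
#' atom_distance(fr, "A", "B")
md_frame <- function(labels, coords, elements = NULL, time = NA_real_) {
  labels <- as.character(labels)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(labels) < 1L) stop("a frame needs at least one atom")
  if (nrow(coords) != length(labels) || ncol(coords) != 3L)
    stop("coords must be a length(labels) x 3 matrix")
  if (anyDuplicated(labels))
    stop("duplicate atom labels in frame: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (!all(is.finite(coords))) stop("non-finite coordinates in frame")
  if (is.null(elements)) elements <- sub("[0-9']+$", "", labels)
  rownames(coords) <- labels
  structure(list(labels = labels, elements = as.character(elements),
                 xyz = coords, time = as.numeric(time)),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("<md_frame: %d atoms%s>\n", length(x$labels),
              if (is.finite(x$time)) sprintf(", t = %g ps", x$time) else ""))
  invisible(x)
}

# Resolve labels against a frame, with an informative error.
frame_coords <- function(frame, labels) {
  idx <- match(labels, frame$labels)
  if (anyNA(idx)) {
    bad <- labels[is.na(idx)]
    stop(errorCondition(
      paste0("atom label(s) not found in frame: ", paste(bad, collapse = ", ")),
      class = c("ringpmf_label_error", "ringpmf_error", "error")))
  }
  frame$xyz[idx, , drop = FALSE]
}

#' Interatomic distance
#'
#' Euclidean distance between two labelled atoms of a frame, in Angstrom.
#'
#' @param frame an [md_frame()].
#' @param a,b atom labels.
#' @return Distance in Angstrom (scalar, non-negative).
#' @export
atom_distance <- function(frame, a, b) {
  p <- frame_coords(frame, c(a, b))
  sqrt(sum((p[1L, ] - p[2L, ])^2))
}

#' Define a reaction coordinate as a weighted sum of distances
#'
#' A reaction-coordinate specification is a named linear combination of
#' interatomic distances. Single-term specs express plain bond distances
#' (e.g. the glycosidic C1-O4 distance used as the cleavage coordinate);
#' two-term specs with weights +1/-1 express distance differences such as
#' proton-transfer coordinates.
#'
#' @param name name of the coordinate.
#' @param terms a data.frame (or list of lists) with columns/fields
#'   `a`, `b` (atom labels) and `w` (nonzero signed weight).
#' @return An object of class `rc_spec`.
#' @export
#' @examples
#' rc2 <- rc_spec("RC2", data.frame(a = "C1", b = "O4", w = 1))
rc_spec <- function(name, terms) {
  if (is.data.frame(terms)) {
    terms <- lapply(seq_len(nrow(terms)), function(i)
      list(a = as.character(terms$a[i]), b = as.character(terms$b[i]),
           w = as.numeric(terms$w[i])))
  }
  if (length(terms) < 1L) stop("rc_spec needs at least one term")
  for (t in terms) {
    if (!all(c("a", "b", "w") %in% names(t)))
      stop("each term needs fields a, b, w")
    if (!is.finite(t$w) || t$w == 0) stop("term weights must be finite and nonzero")
  }
  structure(list(name = as.character(name), terms = terms), class = "rc_spec")
}

#' @export
print.rc_spec <- function(x, ...) {
  tt <- vapply(x$terms, function(t)
    sprintf("%+g*d(%s,%s)", t$w, t$a, t$b), character(1))
  cat(sprintf("<rc_spec %s = %s>\n", x$name, paste(tt, collapse = " ")))
  invisible(x)
}

#' Evaluate a reaction coordinate on a frame
#'
#' Computes the weighted sum of interatomic distances defined by an
#' [rc_spec()]. The value is linear in the weights and, for single-term
#' specs of weight one, equals [atom_distance()].
#'
#' @param frame an [md_frame()].
#' @param spec an [rc_spec()].
#' @return Coordinate value in Angstrom.
#' @export
evaluate_rc <- function(frame, spec) {
  stopifnot(inherits(spec, "rc_spec"))
  sum(vapply(spec$terms, function(t)
    t$w * atom_distance(frame, t$a, t$b), numeric(1)))
}

#' Read reaction-coordinate specifications from JSON
#'
#' The file holds an array of objects
#' `{"name": ..., "terms": [{"a": ..., "b": ..., "w": ...}, ...]}`.
#'
#' @param path path to a JSON file.
#' @return A named list of [rc_spec()] objects.
#' @export
read_rc_specs <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  specs <- lapply(raw, function(s) rc_spec(s$name, s$terms))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Hydrogen-bond geometry test
#'
#' Applies the common geometric hydrogen-bond criterion: the bond is present
#' when the H...acceptor distance does not exceed `d_cut` and the
#' donor-H...acceptor angle is at least `angle_cut`. The measured geometry is
#' returned whether or not the criterion is met. The defaults (2.5 Angstrom,
#' 120 degrees) comfortably cover both ordinary hydrogen bonds (H...A around
#' 1.8-2.0 Angstrom) and the short shared-proton contacts (1.0-1.3 Angstrom)
#' seen near a proton-transfer transition state.
#'
#' @param frame an [md_frame()].
#' @param donor,hydrogen,acceptor atom labels (distinct).
#' @param d_cut maximum H...acceptor distance, Angstrom.
#' @param angle_cut minimum donor-H...acceptor angle, degrees.
#' @return A list with `present` (logical), `d_ha` (Angstrom) and
#'   `angle` (degrees).
#' @export
hbond_present <- function(frame, donor, hydrogen, acceptor,
                          d_cut = 2.5, angle_cut = 120) {
  if (anyDuplicated(c(donor, hydrogen, acceptor)))
    stop("donor, hydrogen and acceptor labels must be distinct")
  p <- frame_coords(frame, c(donor, hydrogen, acceptor))
  v1 <- p[1L, ] - p[2L, ]           # H -> donor
  v2 <- p[3L, ] - p[2L, ]           # H -> acceptor
  d_ha <- sqrt(sum(v2^2))
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * d_ha)
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  list(present = (d_ha <= d_cut) && (ang >= angle_cut),
       d_ha = d_ha, angle = ang)
}

#' Angle between a bond and the ring mean plane
#'
#' Measures the elevation of a bond vector out of the Cremer-Pople mean
#' plane of a six-membered ring: 90 degrees means perpendicular to the plane
#' (axial), 0 degrees in-plane (equatorial). The mean plane is the one used
#' by [cremer_pople()], so the axial/equatorial calls are consistent with
#' the puckering analysis; a pseudo-axial glycosidic bond in a distorted
#' skew-boat reads close to 90 degrees.
#'
#' @param frame an [md_frame()].
#' @param ring six atom labels in ring order (O5, C1, ..., C5).
#' @param bond a length-2 character vector of atom labels; the bond vector
#'   points from the first to the second.
#' @return Angle in degrees, in `[0, 90]`.
#' @export
ring_plane_angle <- function(frame, ring, bond) {
  stopifnot(length(ring) == 6L, length(bond) == 2L)
  rc <- frame_coords(frame, ring)
  n <- cp_mean_plane_normal(rc)
  p <- frame_coords(frame, bond)
  v <- p[2L, ] - p[1L, ]
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("zero-length bond vector")
  asin(max(-1, min(1, abs(sum(v * n)) / nv))) * 180 / pi
}

#' Minimum RMSD after optimal superposition (Kabsch)
#'
#' Root-mean-square deviation between matching atom selections of two
#' frames, minimised over all rigid rotations and translations by the
#' Kabsch singular-value-decomposition algorithm (proper rotations only;
#' reflections are excluded). The result is invariant to any rigid
#' transform applied to either input, which makes it the standard drift
#' monitor for, e.g., enzyme backbone stability during production MD.
#'
#' @param frameA,frameB [md_frame()] objects.
#' @param selection atom labels present in both frames, in matching order;
#'   at least three non-collinear atoms.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(frameA, frameB, selection = frameA$labels) {
  A <- frame_coords(frameA, selection)
  B <- frame_coords(frameB, selection)
  if (nrow(A) != nrow(B)) stop("selection lengths differ between frames")
  if (nrow(A) < 3L) stop("need at least 3 atoms for superposition")
  Ac <- sweep(A, 2L, colMeans(A))
  Bc <- sweep(B, 2L, colMeans(B))
  s <- svd(crossprod(Bc, Ac))        # 3x3 covariance
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  Brot <- Bc %*% R
  sqrt(mean(rowSums((Ac - Brot)^2)))
}

#' Evaluate monitor series over a trajectory
#'
#' Applies a set of reaction-coordinate specs to every frame of a
#' trajectory and returns a tidy per-frame table (0-based frame index).
#'
#' @param frames list of [md_frame()] objects.
#' @param specs named list of [rc_spec()] objects.
#' @return data.frame with columns `frame_index`, `time_ps` and one column
#'   per spec.
#' @export
monitor_series <- function(frames, specs) {
  stopifnot(length(frames) >= 1L)
  vals <- vapply(frames, function(fr)
    vapply(specs, function(s) evaluate_rc(fr, s), numeric(1)),
    numeric(length(specs)))
  vals <- if (length(specs) == 1L) matrix(vals, nrow = 1L) else vals
  out <- data.frame(
    frame_index = seq_along(frames) - 1L,
    time_ps = vapply(frames, function(fr) fr$time, numeric(1)))
  m <- as.data.frame(t(vals))
  names(m) <- names(specs)
  cbind(out, m)
}
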