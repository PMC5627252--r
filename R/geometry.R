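#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation and translation minimising the RMSD of `mobile`
#' onto `reference` (SVD formulation with determinant correction so that
#' reflections are never returned -- required for chiral molecules).
#'
#' @param mobile n x 3 coordinate matrix.
#' @param reference n x 3 coordinate matrix, same n.
#' @return list of class `fc_rigid_fit`: `rotation` (3 x 3, det +1),
#'   `translation` (length-3), `fit_rmsd` (Angstrom). The fitted coordinates
#'   are `mobile %*% t(rotation) + translation` (rows).
#' @export
kabsch_fit <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("mobile and reference must be matching n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 points for a rigid fit")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  # degenerate (all collinear) geometry has rank < 2 covariance
  if (qr(X)$rank < 2 || qr(Y)$rank < 2)
    stop("degenerate geometry: points are collinear")
  H <- crossprod(X, Y)                      # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)               # maps row-vectors via x R^T
  translation <- as.numeric(cr - R %*% cm)
  fitted <- X %*% t(R)
  fit_rmsd <- sqrt(sum((fitted - Y)^2) / n)
  structure(list(rotation = R, translation = translation,
                 fit_rmsd = fit_rmsd),
            class = "fc_rigid_fit")
}

#' @export
print.fc_rigid_fit <- function(x, ...) {
  cat(sprintf("fc_rigid_fit: fit_rmsd = %.4f A\n", x$fit_rmsd))
  invisible(x)
}

#' Apply a rigid fit to coordinates
#' @param coords n x 3 matrix.
#' @param fit an `fc_rigid_fit`.
#' @return transformed n x 3 matrix.
#' @export
apply_fit <- function(coords, fit) {
  stopifnot(inherits(fit, "fc_rigid_fit"))
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, fit$translation, `+`)
}

#' Selection-based RMSD after superposition
#'
#' Superposes `frame` onto `reference` using only `fit_selection`, then
#' measures the RMSD over `measure_selection` under that same transform
#' (never re-fit on the measured atoms). This is the protocol used for the
#' C'E loop and GlcNAc1 descriptors: fit on the Calpha anchors, measure the
#' loop heavy atoms.
#'
#' @param frame n x 3 coordinates of the snapshot.
#' @param reference n x 3 coordinates of the reference structure.
#' @param fit_selection atom indices used for the superposition.
#' @param measure_selection atom indices the RMSD is computed over.
#' @return RMSD in Angstrom.
#' @export
rmsd_after_fit <- function(frame, reference, fit_selection,
                           measure_selection) {
  if (length(fit_selection) == 0 || length(measure_selection) == 0)
    stop("empty selection")
  fit <- kabsch_fit(frame[fit_selection, , drop = FALSE],
                    reference[fit_selection, , drop = FALSE])
  moved <- apply_fit(frame[measure_selection, , drop = FALSE], fit)
  ref <- reference[measure_selection, , drop = FALSE]
  sqrt(sum((moved - ref)^2) / length(measure_selection))
}

#' Minimum pairwise distance between two coordinate sets
#'
#' Exact minimum Euclidean distance over all pairs; used for glycan-protein
#' minimum-distance series and geometric contact criteria.
#'
#' @param coords_a nA x 3 matrix.
#' @param coords_b nB x 3 matrix.
#' @return minimum distance, Angstrom.
#' @export
min_heavy_distance <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) == 0 || nrow(coords_b) == 0)
    stop("empty coordinate set")
  # |a-b|^2 = |a|^2 + |b|^2 - 2 a.b, minimised over all pairs
  aa <- rowSums(coords_a^2)
  bb <- rowSums(coords_b^2)
  d2 <- outer(aa, bb, `+`) - 2 * tcrossprod(coords_a, coords_b)
  sqrt(max(0, min(d2)))
}

#' Geometric center (unweighted centroid)
#' @param coords n x 3 matrix.
#' @return length-3 vector.
#' @export
geometric_center <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) stop("empty coordinate set")
  colMeans(coords)
}

#' Angle defined by three points
#'
#' @param p1,p2,p3 length-3 vectors; the angle is at `p2`.
#' @return angle in degrees, in \[0, 180\].
#' @export
angle_deg <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) stop("degenerate angle: coincident points")
  ct <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Dihedral (torsion) angle defined by four points
#'
#' IUPAC sign convention: looking along p2 -> p3, a clockwise rotation of the
#' far bond is positive; cis-planar is 0, trans-planar is 180.
#'
#' @param p1,p2,p3,p4 length-3 vectors.
#' @return dihedral in degrees, in (-180, 180\].
#' @export
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("degenerate dihedral: three consecutive points collinear")
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Radius of gyration
#'
#' Square root of the weighted mean squared distance from the weighted
#' centroid. Defaults to uniform weights; pass atomic masses for the
#' mass-weighted convention (the package's trajectory-level wrapper does so
#' for heavy atoms by default).
#'
#' @param coords n x 3 matrix.
#' @param weights positive per-atom weights; uniform if `NULL`.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(coords, weights = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) stop("empty coordinate set")
  if (is.null(weights)) weights <- rep(1, nrow(coords))
  if (length(weights) != nrow(coords)) stop("weights length mismatch")
  if (any(weights <= 0)) stop("weights must be positive")
  w <- weights / sum(weights)
  ctr <- colSums(coords * w)
  sqrt(sum(w * rowSums(sweep(coords, 2, ctr)^2)))
}

# Standard atomic masses for the elements that occur in protein/glycan
# heavy-atom work (fallback 12 for unknowns keeps weights positive).
.ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974)

element_masses <- function(elements) {
  m <- .ATOMIC_MASSES[elements]
  m[is.na(m)] <- 12.011
  unname(m)
}
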