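#' Construct a rigid transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (Angstrom).
#' @return an object of class `rigid_transform`. Applied as `x %*% t(R) + t`
#'   for row-vector coordinates.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("rotation is not orthonormal")
  }
  if (abs(det(rotation) - 1) > 1e-8) {
    stop("rotation has determinant != +1 (improper rotation)")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rigid_transform(t(t$rotation), -as.numeric(crossprod(t$rotation, t$translation)))
}

#' Rotation matrix about an arbitrary axis
#' @param axis length-3 direction (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix (Rodrigues formula).
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to coordinates or a structure
#'
#' @param t a `rigid_transform`.
#' @param x an n x 3 coordinate matrix, a `chain_structure`, or a
#'   `dimer_structure` (both chains are moved jointly).
#' @return transformed copy of `x`.
#' @export
apply_transform <- function(t, x) {
  stopifnot(inherits(t, "rigid_transform"))
  if (inherits(x, "dimer_structure")) {
    x$receptor <- apply_transform(t, x$receptor)
    x$ligand <- apply_transform(t, x$ligand)
    return(x)
  }
  if (inherits(x, "chain_structure")) {
    m <- as.matrix(x$atoms[, c("x", "y", "z")])
    m2 <- apply_transform(t, m)
    x$atoms$x <- m2[, 1]; x$atoms$y <- m2[, 2]; x$atoms$z <- m2[, 3]
    return(x)
  }
  m <- as.matrix(x)
  stopifnot(ncol(m) == 3L)
  sweep(m %*% t(t$rotation), 2, t$translation, `+`)
}

#' Root-mean-square deviation between paired coordinate sets
#'
#' No superposition is performed; points are paired in order.
#'
#' @param a,b n x 3 coordinate matrices with equal row counts (n >= 1).
#' @return RMSD in Angstrom.
#' @export
rmsd_coords <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("coordinate count mismatch: ", nrow(a), " vs ", nrow(b))
  if (nrow(a) < 1L) stop("need at least one point")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares optimal rotation + translation mapping `moving` onto
#' `fixed`, computed with the SVD form of the Kabsch algorithm. The sign of
#' the smallest singular vector pair is corrected so that only proper
#' rotations (no reflections) are returned.
#'
#' @param moving,fixed n x 3 coordinate matrices, n >= 3, paired in order.
#' @return list with `transform` (a `rigid_transform`) and `rmsd`, the
#'   post-superposition RMSD in Angstrom.
#' @export
superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed)) stop("coordinate count mismatch")
  if (nrow(moving) < 3L) stop("need at least 3 points for superposition")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  A <- sweep(moving, 2, cm); B <- sweep(fixed, 2, cf)
  H <- crossprod(A, B)          # 3x3 covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-12) stop("degenerate (collinear) point geometry")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- cf - as.numeric(R %*% cm)
  tf <- rigid_transform(R, tr)
  list(transform = tf, rmsd = rmsd_coords(apply_transform(tf, moving), fixed))
}
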