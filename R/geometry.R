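# geometry: rigid-body superposition (Kabsch) and RMSD primitives.

#' Least-squares rigid superposition of two coordinate sets
#'
#' Computes the proper rigid transform (rotation with determinant +1 plus
#' translation) that minimises the RMSD of \code{mobile} onto
#' \code{reference}, via the SVD form of the Kabsch algorithm with an
#' explicit determinant correction for the reflection branch. All paired
#' atoms are fitted once, unweighted; there is no outlier rejection.
#'
#' @param mobile,reference n x 3 coordinate matrices with matching rows,
#'   n >= 3, not all collinear.
#' @return list with \code{transform} (a \linkS4class{RigidTransform})
#'   and \code{rmsd}, the post-fit RMSD in Angstrom.
#' @examples
#' a <- matrix(rnorm(24), ncol = 3)
#' superpose(a, a)$rmsd
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop(sprintf("coordinate sets differ in size: %d vs %d points",
                 nrow(mobile), nrow(reference)))
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 points")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  X <- sweep(mobile, 2, mc); Y <- sweep(reference, 2, rc)
  sv <- svd(crossprod(X, Y))                 # H = X^T Y, 3x3
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate geometry: point set is (nearly) collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- rc - as.vector(R %*% mc)
  fitted <- t(R %*% t(mobile)) + matrix(t, n, 3, byrow = TRUE)
  list(transform = RigidTransform(rotation = R, translation = t),
       rmsd = rmsdNoFit(fitted, reference))
}

#' RMSD between paired points without fitting
#'
#' Root-mean-square of pointwise Euclidean distances, with no
#' superposition. This is the quantity taken over the peptide after the
#' receptors have been superposed (ligand RMSD).
#'
#' @param a,b n x 3 coordinate matrices with matching rows, n >= 1.
#' @return RMSD in Angstrom.
#' @export
rmsdNoFit <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop(sprintf("coordinate sets differ in size: %d vs %d points",
                 nrow(a), nrow(b)))
  if (nrow(a) < 1) stop("need at least one point")
  sqrt(sum((a - b)^2) / nrow(a))
}

#' Apply a rigid transform to points
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @param points n x 3 coordinate matrix.
#' @return transformed n x 3 matrix; all pairwise distances preserved.
#' @export
applyTransform <- function(transform, points) {
  points <- as.matrix(points)
  t(transform@rotation %*% t(points)) +
    matrix(transform@translation, nrow(points), 3, byrow = TRUE)
}

#' Compose two rigid transforms
#'
#' \code{composeTransform(a, b)} is the transform applying \code{b}
#' first, then \code{a}.
#'
#' @param a,b \linkS4class{RigidTransform} objects.
#' @return a \linkS4class{RigidTransform}.
#' @export
composeTransform <- function(a, b) {
  RigidTransform(rotation = a@rotation %*% b@rotation,
                 translation = as.vector(a@rotation %*% b@translation) +
                   a@translation)
}

#' Invert a rigid transform
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @return the inverse \linkS4class{RigidTransform}.
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  RigidTransform(rotation = Rt,
                 translation = -as.vector(Rt %*% transform@translation))
}

# Uniform random rotation matrix via quaternion sampling (seeded by the
# caller's RNG state).
randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Seeded uniform random rigid transform
#'
#' Rotation sampled uniformly over SO(3) via unit quaternions; the
#' translation components are i.i.d. normal with the given spread.
#'
#' @param seed integer seed.
#' @param translationSd standard deviation of each translation component
#'   (A).
#' @return a \linkS4class{RigidTransform}.
#' @export
randomTransform <- function(seed, translationSd = 10) {
  withSeed(seed, {
    R <- randomRotation()
    t <- stats::rnorm(3, sd = translationSd)
    RigidTransform(rotation = R, translation = t)
  })
}
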