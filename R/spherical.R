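#' Real spherical harmonics with component normalization
#'
#' Evaluates the real spherical harmonics \eqn{Y_\ell} for \eqn{\ell = 0, 1, 2}
#' on (not necessarily unit) direction vectors.  "Component" normalization is
#' used: every component has unit mean square over the unit sphere, so the
#' squared norm of the degree-\eqn{\ell} block averages to \eqn{2\ell+1}.
#' Component order within a block is fixed (documented below) and every
#' rotation acts on a block through the corresponding real Wigner matrix
#' \eqn{D^{(\ell)}}, computable with [wigner_d_real()].
#'
#' Block layouts: \eqn{\ell=0}: the constant 1; \eqn{\ell=1}:
#' \eqn{\sqrt{3}\,(x, y, z)/r}; \eqn{\ell=2}:
#' \eqn{(\sqrt{15}xy, \sqrt{15}yz, \tfrac{\sqrt5}{2}(3z^2-1), \sqrt{15}xz,
#' \tfrac{\sqrt{15}}{2}(x^2-y^2))} on the unit sphere.
#'
#' @param vecs numeric matrix (n x 3) of direction vectors, or a length-3
#'   vector.  Vectors must be nonzero: spherical harmonics of coincident
#'   atoms are undefined.
#' @param l_max highest degree, 0, 1 or 2.
#' @return numeric matrix (n x (l_max+1)^2), degree blocks concatenated in
#'   order \eqn{\ell = 0, 1, \dots}.
#' @export
sph_harmonics <- function(vecs, l_max) {
  if (is.null(dim(vecs))) vecs <- matrix(vecs, nrow = 1)
  stopifnot(ncol(vecs) == 3, l_max %in% 0:2)
  r <- sqrt(rowSums(vecs^2))
  if (any(!is.finite(r)) || any(r < 1e-12)) {
    stop("zero-length (or non-finite) direction vector: coincident atoms?")
  }
  u <- vecs / r
  out <- matrix(1, nrow(vecs), (l_max + 1)^2)
  if (l_max >= 1) {
    out[, 2:4] <- sqrt(3) * u
  }
  if (l_max >= 2) {
    x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
    out[, 5] <- sqrt(15) * x * y
    out[, 6] <- sqrt(15) * y * z
    out[, 7] <- sqrt(5) / 2 * (3 * z^2 - 1)
    out[, 8] <- sqrt(15) * x * z
    out[, 9] <- sqrt(15) / 2 * (x^2 - y^2)
  }
  out
}

#' Real Wigner rotation matrix for one degree
#'
#' Returns the matrix \eqn{D^{(\ell)}(R)} acting on the real spherical-harmonic
#' basis of [sph_harmonics()], i.e. \eqn{Y_\ell(R v) = D^{(\ell)}(R)\,
#' Y_\ell(v)} for every vector \eqn{v}.  \eqn{D^{(0)} = 1} and
#' \eqn{D^{(1)} = R} by construction of the basis; higher degrees are solved
#' exactly (up to round-off) by least squares on a fixed over-complete probe
#' set, which spans the harmonic polynomial space.
#'
#' @param R 3x3 rotation (or improper rotation) matrix.
#' @param l degree, 0, 1 or 2.
#' @return (2l+1) x (2l+1) orthogonal matrix.
#' @export
wigner_d_real <- function(R, l) {
  stopifnot(l %in% 0:2, all(dim(R) == c(3, 3)))
  if (l == 0) return(matrix(1, 1, 1))
  if (l == 1) return(R)
  probes <- .sph_probe_vectors()
  Y <- sph_harmonics(probes, l)[, (l^2 + 1):((l + 1)^2), drop = FALSE]
  Yr <- sph_harmonics(probes %*% t(R), l)[, (l^2 + 1):((l + 1)^2), drop = FALSE]
  # Yr = Y %*% t(D)  =>  solve in the least-squares sense (exact: Y spans)
  t(qr.solve(Y, Yr))
}

# Fixed, well-spread probe directions (deterministic; > 2l+1 of them).
.sph_probe_vectors <- function() {
  g <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1),
    c(0, 1 / g, g), c(0, -1 / g, g), c(g, 0, 1 / g), c(-g, 0, 1 / g),
    c(1 / g, g, 0), c(1 / g, -g, 0), c(0.3, 0.5, 0.81), c(0.9, 0.1, 0.4)
  )
  v / sqrt(rowSums(v^2))
}

#' Rotation matrix from axis and angle
#'
#' @param axis length-3 axis (need not be normalized).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Random rotation matrix
#'
#' Draws a rotation uniformly w.r.t. Haar measure (QR of a Gaussian matrix,
#' sign-fixed, determinant +1).  Uses the current RNG state.
#'
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# ---- Clebsch-Gordan couplings in the real basis -----------------------------

.cg_cache <- new.env(parent = emptyenv())

#' Real Clebsch-Gordan coupling tensor
#'
#' Returns the (unique up to sign/scale) rotation-invariant trilinear coupling
#' \eqn{C_{m_1 m_2 m_3}} between real spherical-harmonic degrees
#' \eqn{(\ell_1, \ell_2, \ell_3)}: contracting two features transforming as
#' \eqn{\ell_1} and \eqn{\ell_2} with \eqn{C} yields a feature transforming as
#' \eqn{\ell_3}.  Computed once per triple as the null space of
#' \eqn{I - D^{(\ell_1)} \otimes D^{(\ell_2)} \otimes D^{(\ell_3)}} accumulated
#' over a fixed set of rotations, normalized to unit Frobenius norm with a
#' deterministic sign convention, then cached.
#'
#' @param l1,l2,l3 degrees (each 0..2) satisfying the triangle inequality.
#' @return array with dim `c(2*l1+1, 2*l2+1, 2*l3+1)`.
#' @export
cg_real <- function(l1, l2, l3) {
  stopifnot(l1 %in% 0:2, l2 %in% 0:2, l3 %in% 0:2)
  if (l3 < abs(l1 - l2) || l3 > l1 + l2) {
    stop(sprintf("degrees (%d,%d,%d) violate the triangle inequality", l1, l2, l3))
  }
  key <- paste(l1, l2, l3, sep = "_")
  if (!is.null(.cg_cache[[key]])) return(.cg_cache[[key]])
  d1 <- 2 * l1 + 1; d2 <- 2 * l2 + 1; d3 <- 2 * l3 + 1
  n <- d1 * d2 * d3
  # Fixed rotations: enough generic elements to cut the invariant subspace.
  rots <- list(
    rotation_matrix(c(1, 0, 0), 0.83),
    rotation_matrix(c(0, 1, 0), 1.31),
    rotation_matrix(c(0, 0, 1), 2.17),
    rotation_matrix(c(1, 2, 3), 0.57),
    rotation_matrix(c(-2, 1, 1.5), 1.91)
  )
  M <- matrix(0, n, n)
  for (R in rots) {
    D <- kronecker(wigner_d_real(R, l3),
                   kronecker(wigner_d_real(R, l2), wigner_d_real(R, l1)))
    M <- M + crossprod(diag(n) - D)
  }
  e <- eigen(M, symmetric = TRUE)
  nullity <- sum(e$values < 1e-8)
  if (nullity != 1) {
    stop(sprintf("invariant subspace for (%d,%d,%d) has dimension %d, expected 1",
                 l1, l2, l3, nullity))
  }
  v <- e$vectors[, n]
  v <- v / sqrt(sum(v^2))
  pivot <- which(abs(v) > 1e-6)[1]
  if (v[pivot] < 0) v <- -v
  C <- array(v, dim = c(d1, d2, d3))
  .cg_cache[[key]] <- C
  C
}

#' Nonzero entries of a real coupling tensor
#'
#' Sparse view of [cg_real()] used by the convolution inner loops: one row per
#' entry with |C| above threshold.
#'
#' @param l1,l2,l3 degrees as in [cg_real()].
#' @return data.frame with columns `m1`, `m2`, `m3` (1-based) and `c`.
#' @keywords internal
cg_entries <- function(l1, l2, l3) {
  C <- cg_real(l1, l2, l3)
  idx <- which(abs(C) > 1e-10, arr.ind = TRUE)
  data.frame(m1 = idx[, 1], m2 = idx[, 2], m3 = idx[, 3], c = C[idx])
}
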