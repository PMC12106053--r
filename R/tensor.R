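# Diffusion-tensor primitives: the 6-component storage convention, the
# canonical eigendecomposition, and the three minicolumn-referenced metrics.
#
# Tensors are symmetric 3x3 matrices of diffusivities (mm^2/s). The packed
# 6-vector follows the lower-triangular NIfTI convention:
#   Dxx, Dxy, Dyy, Dxz, Dyz, Dzz

SYM6_IDX <- rbind(c(1L, 1L), c(2L, 1L), c(2L, 2L), c(3L, 1L), c(3L, 2L), c(3L, 3L))

#' Pack a symmetric 3x3 tensor into 6 components
#'
#' Lower-triangular order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), the convention used
#' for 6-volume tensor NIfTI files.
#'
#' @param D Symmetric 3x3 matrix.
#' @return Numeric vector of length 6.
#' @export
tensor_to_sym6 <- function(D) {
  D[SYM6_IDX]
}

#' Unpack 6 tensor components into a symmetric 3x3 matrix
#'
#' @param v Numeric vector of length 6 in (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz) order.
#' @return Symmetric 3x3 matrix.
#' @export
sym6_to_tensor <- function(v) {
  matrix(c(v[1], v[2], v[4],
           v[2], v[3], v[5],
           v[4], v[5], v[6]), 3L, 3L)
}

#' Canonical eigendecomposition of a diffusion tensor
#'
#' Eigenvalues are returned in non-increasing order; negative eigenvalues
#' (which can arise from noisy tensor fits) are clamped to zero and counted.
#' Each eigenvector's sign is fixed so that its largest-magnitude component
#' is positive, giving a deterministic canonical form.
#'
#' @param D Symmetric 3x3 tensor (mm^2/s).
#' @param tol Relative symmetry tolerance.
#' @return List with `values` (length 3, descending, clamped at 0),
#'   `vectors` (3x3, columns e1,e2,e3, orthonormal) and `n_clamped`.
#' @export
eig_tensor <- function(D, tol = 1e-8) {
  if (!is.matrix(D) || !all(dim(D) == c(3L, 3L))) {
    stop("invalid tensor: expected a 3x3 matrix", call. = FALSE)
  }
  scale <- max(abs(D), .Machine$double.eps)
  if (max(abs(D - t(D))) > tol * scale) {
    stop("invalid tensor: matrix is not symmetric within tolerance",
         call. = FALSE)
  }
  e <- eigen((D + t(D)) / 2, symmetric = TRUE)
  n_clamped <- sum(e$values < 0)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (j in 1:3) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  list(values = vals, vectors = vecs, n_clamped = n_clamped)
}

check_unit <- function(v, name) {
  n <- sqrt(sum(v * v))
  if (abs(n - 1) > 1e-6) {
    stop(sprintf("invalid direction: %s is not a unit vector (|v| = %g)",
                 name, n), call. = FALSE)
  }
  invisible(n)
}

#' Angle between the principal diffusion direction and the radial axis
#'
#' AngleR is the angle (radians) between the radial minicolumn axis and the
#' principal diffusion direction, treated axially: sign flips of either
#' vector do not change the result, so AngleR lies in [0, pi/2].
#'
#' @param e1 Principal eigenvector (unit).
#' @param r Radial minicolumn axis (unit).
#' @return Angle in radians in [0, pi/2].
#' @export
angler <- function(e1, r) {
  check_unit(e1, "e1")
  check_unit(r, "r")
  acos(min(1, abs(sum(e1 * r))))
}

#' Principal diffusion component parallel to the radial axis
#'
#' ParlPD projects the principal diffusivity onto the radial minicolumn axis.
#' The default definition is the linear projection lambda1 * |e1 . r|; a
#' squared-cosine variant is available via `variant`.
#'
#' @param lambda1 Principal eigenvalue (mm^2/s, >= 0).
#' @param e1 Principal eigenvector (unit).
#' @param r Radial axis (unit).
#' @param variant `"linear"` (default) for lambda1*|e1.r|, `"squared"` for
#'   lambda1*(e1.r)^2.
#' @return Diffusivity in [0, lambda1].
#' @export
parlpd <- function(lambda1, e1, r, variant = c("linear", "squared")) {
  variant <- match.arg(variant)
  if (lambda1 < 0) stop("invalid tensor: lambda1 must be >= 0", call. = FALSE)
  check_unit(e1, "e1")
  check_unit(r, "r")
  ct <- min(1, abs(sum(e1 * r)))
  if (variant == "linear") lambda1 * ct else lambda1 * ct^2
}

#' Combined diffusion components perpendicular to the radial axis
#'
#' PerpPD+ combines all diffusion components perpendicular to the radial
#' minicolumn axis, including the secondary and tertiary eigencomponents.
#' The default definition is the rotation-invariant quadratic form
#' sum_i lambda_i * (1 - (e_i . r)^2) = trace(D) - r' D r. Variants:
#' `"quadrature"` returns sqrt(sum_i (lambda_i * sin(theta_i))^2 restricted
#' to perpendicular projections) and `"principal"` uses only lambda1's
#' perpendicular component.
#'
#' @param lambda Eigenvalue triple, non-increasing.
#' @param E 3x3 matrix of eigenvectors (columns e1,e2,e3, orthonormal).
#' @param r Radial axis (unit).
#' @param variant Formula variant; default `"trace"`.
#' @return Diffusivity in [0, sum(lambda)].
#' @export
perppd_plus <- function(lambda, E, r,
                        variant = c("trace", "quadrature", "principal")) {
  variant <- match.arg(variant)
  if (any(diff(lambda) > 1e-12)) {
    stop("invalid tensor: eigenvalues must be non-increasing", call. = FALSE)
  }
  check_unit(r, "r")
  proj2 <- as.numeric(crossprod(E, r))^2   # (e_i . r)^2
  switch(variant,
    trace = sum(lambda * (1 - proj2)),
    quadrature = sqrt(sum((lambda * sqrt(pmax(0, 1 - proj2)))^2)),
    principal = lambda[1] * (1 - proj2[1])
  )
}

# Eigendecompose a matrix of packed tensors (n x 6) in one pass.
# Returns list(values n x 3 descending-clamped, vectors 3 x 3 x n, n_clamped).
eig_sym6_many <- function(m6) {
  n <- nrow(m6)
  vals <- matrix(0, n, 3L)
  vecs <- array(0, c(3L, 3L, n))
  clamped <- 0L
  for (i in seq_len(n)) {
    v <- m6[i, ]
    D <- matrix(c(v[1], v[2], v[4],
                  v[2], v[3], v[5],
                  v[4], v[5], v[6]), 3L, 3L)
    e <- eigen(D, symmetric = TRUE)
    clamped <- clamped + sum(e$values < 0)
    vals[i, ] <- pmax(e$values, 0)
    vecs[, , i] <- e$vectors
  }
  list(values = vals, vectors = vecs, n_clamped = clamped)
}
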