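# Independent brute-force oracles and small fixture builders shared by the
# test files. The oracles deliberately re-derive quantities from first
# principles (direct formula loops) rather than calling package internals.

# Product-limit estimate by the direct formula: loop over sorted unique
# times, multiply survival by (1 - d/n) with n = #{time >= t}.
km_oracle <- function(time, event) {
  ut <- sort(unique(time))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / n)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

# Two-group log-rank by per-event-time 2x2 hypergeometric moments.
logrank_oracle_2g <- function(time, event, group) {
  glev <- unique(group)
  stopifnot(length(glev) == 2L)
  et <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in et) {
    at <- time >= t
    N <- sum(at)
    d <- sum(event == 1 & time == t)
    n1 <- sum(at & group == glev[1])
    O <- O + sum(event == 1 & time == t & group == glev[1])
    E <- E + d * n1 / N
    if (N > 1) V <- V + d * n1 * (N - n1) * (N - d) / (N^2 * (N - 1))
  }
  if (V <= 0) return(0)
  (O - E)^2 / V
}

# Benjamini-Hochberg step-up by explicit rank scan.
bh_oracle <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  reject <- rep(FALSE, m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  reject
}

# 3-D rotation matrices used in equivariance tests.
axis_permutation <- function() {
  matrix(c(0, 1, 0,
           0, 0, 1,
           1, 0, 0), 3L, 3L, byrow = TRUE)  # x->z, y->x, z->y (proper)
}

rotation_xyz <- function(a, b, c) {
  Rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# Apply a rigid rotation to a surface model and tensor volume together.
rotate_surfaces <- function(surfaces, R) {
  surfaces$white <- surfaces$white %*% t(R)
  surfaces$pial <- surfaces$pial %*% t(R)
  surfaces$geometry <- NULL
  surfaces
}

rotate_volume <- function(vol, R) {
  dims <- dim(vol$data)[1:3]
  flat <- matrix(vol$data, prod(dims), 6L)
  for (i in seq_len(nrow(flat))) {
    D <- sym6_to_tensor(flat[i, ])
    flat[i, ] <- tensor_to_sym6(R %*% D %*% t(R))
  }
  vol$data <- array(flat, c(dims, 6L))
  A <- diag(4)
  A[1:3, 1:3] <- R
  vol$affine <- A %*% vol$affine
  vol
}

# Small slab phantom with surfaces and tensor volume in one call.
make_phantom <- function(n_vertices = 64, kappa = 1e7, seed = 1,
                         shape = "slab", noise_sd = 0, voxel_mm = 1,
                         thickness_mm = 2.5,
                         eigvals = c(1.2e-3, 0.6e-3, 0.4e-3)) {
  spec <- phantom_spec(shape = shape, n_vertices = n_vertices,
                       thickness_mm = thickness_mm, voxel_mm = voxel_mm,
                       kappa = kappa, eigvals = eigvals,
                       noise_sd = noise_sd, seed = seed)
  surf <- gen_surface_pair(spec)
  vol <- gen_tensor_field(surf, spec)
  list(spec = spec, surf = surf, vol = vol)
}
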