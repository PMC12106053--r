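# Synthetic cortical phantoms: paired white/pial surfaces with a known
# radial organization, and diffusion-tensor volumes whose principal
# directions scatter about the radial axis with controllable (Watson)
# concentration. These provide ground truth for the profile metrics.

#' Specification of a synthetic cortical phantom
#'
#' @param shape `"slab"` (flat cortical patch, radial axis = +z) or
#'   `"spherical_shell"` (cortical shell, radial axis = outward normal).
#' @param n_vertices Requested vertex count (>= 4). The spherical shell uses
#'   an icosahedral subdivision and returns the smallest such mesh with at
#'   least this many vertices.
#' @param thickness_mm Cortical thickness (mm, > 0); pial = white + thickness
#'   along the radial axis.
#' @param voxel_mm Isotropic voxel size of the tensor grid (mm, > 0).
#' @param kappa Watson concentration (>= 0) of principal diffusion directions
#'   about the radial axis. 0 = uniformly random axes; values >= 1e6 are
#'   treated as the perfectly radial limit.
#' @param eigvals Tensor eigenvalues (mm^2/s), strictly positive and
#'   non-increasing.
#' @param noise_sd Gaussian noise SD added to each tensor component (mm^2/s).
#' @param radius_mm Inner (white) radius of the spherical shell (mm).
#' @param seed Integer seed; identical specs generate identical phantoms.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("slab", "spherical_shell"),
                         n_vertices = 400L,
                         thickness_mm = 2.5,
                         voxel_mm = 1,
                         kappa = 20,
                         eigvals = c(1.2e-3, 0.6e-3, 0.4e-3),
                         noise_sd = 0,
                         radius_mm = 30,
                         seed = 1L) {
  shape <- match.arg(shape)
  if (!is.numeric(n_vertices) || length(n_vertices) != 1L || n_vertices < 4) {
    stop("invalid phantom spec: n_vertices must be a count >= 4", call. = FALSE)
  }
  if (!is.numeric(thickness_mm) || thickness_mm <= 0) {
    stop("invalid phantom spec: thickness_mm must be > 0", call. = FALSE)
  }
  if (!is.numeric(voxel_mm) || voxel_mm <= 0) {
    stop("invalid phantom spec: voxel_mm must be > 0", call. = FALSE)
  }
  if (!is.numeric(kappa) || kappa < 0) {
    stop("invalid phantom spec: kappa must be >= 0", call. = FALSE)
  }
  if (length(eigvals) != 3L || any(eigvals <= 0) || any(diff(eigvals) > 0)) {
    stop("invalid phantom spec: eigvals must be positive and non-increasing",
         call. = FALSE)
  }
  if (noise_sd < 0) {
    stop("invalid phantom spec: noise_sd must be >= 0", call. = FALSE)
  }
  if (radius_mm <= 0) {
    stop("invalid phantom spec: radius_mm must be > 0", call. = FALSE)
  }
  structure(list(shape = shape,
                 n_vertices = as.integer(n_vertices),
                 thickness_mm = thickness_mm,
                 voxel_mm = voxel_mm,
                 kappa = kappa,
                 eigvals = as.numeric(eigvals),
                 noise_sd = noise_sd,
                 radius_mm = radius_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# ---- Watson axial sampling ---------------------------------------------

# Sample t = |cos(theta)| on [0, 1] with density proportional to
# exp(kappa * t^2). kappa = 0 reduces to the uniform-axis case (t ~ U(0,1)).
# Rejection sampling with a uniform proposal; acceptance ~ 1/(2*kappa) for
# large kappa, vectorized in batches.
rwatson_cos <- function(n, kappa) {
  if (kappa == 0) return(stats::runif(n))
  out <- numeric(0)
  acc_rate <- max(exp(-kappa) , min(1, 1 / kappa))
  while (length(out) < n) {
    m <- ceiling((n - length(out)) / acc_rate) + 100L
    m <- min(m, 5e6)
    t <- stats::runif(m)
    keep <- stats::runif(m) < exp(kappa * (t * t - 1))
    out <- c(out, t[keep])
  }
  out[seq_len(n)]
}

# Orthonormal vectors perpendicular to each row of the n x 3 matrix `mu`.
perp_basis <- function(mu) {
  n <- nrow(mu)
  h <- matrix(rep(c(1, 0, 0), each = n), n, 3L)
  swap <- abs(mu[, 1]) > 0.9
  h[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3L)
  u <- cbind(h[, 2] * mu[, 3] - h[, 3] * mu[, 2],
             h[, 3] * mu[, 1] - h[, 1] * mu[, 3],
             h[, 1] * mu[, 2] - h[, 2] * mu[, 1])
  u <- u / sqrt(rowSums(u * u))
  v <- cbind(mu[, 2] * u[, 3] - mu[, 3] * u[, 2],
             mu[, 3] * u[, 1] - mu[, 1] * u[, 3],
             mu[, 1] * u[, 2] - mu[, 2] * u[, 1])
  list(u = u, v = v)
}

#' Sample axes from a Watson distribution
#'
#' Draws axially symmetric unit vectors whose density is proportional to
#' exp(kappa * (mu . x)^2), by rejection sampling of |cos(theta)| and a
#' uniform azimuth. Axis sign is irrelevant downstream; vectors are returned
#' in the hemisphere of `mu`. `kappa >= 1e6` returns `mu` exactly (the
#' perfectly radial limit); `kappa = 0` is uniform on the sphere (as axes).
#'
#' @param n Number of draws.
#' @param mu Mean axis: length-3 unit vector, or an n x 3 matrix of unit rows.
#' @param kappa Concentration (>= 0).
#' @return n x 3 matrix of unit vectors.
#' @export
rwatson_axis <- function(n, mu, kappa) {
  if (is.null(dim(mu))) mu <- matrix(mu, n, 3L, byrow = TRUE)
  if (nrow(mu) != n || ncol(mu) != 3L) {
    stop("mu must be a length-3 vector or an n x 3 matrix", call. = FALSE)
  }
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (kappa >= 1e6) return(mu)
  t <- rwatson_cos(n, kappa)
  phi <- stats::runif(n, 0, 2 * pi)
  b <- perp_basis(mu)
  s <- sqrt(pmax(0, 1 - t * t))
  mu * t + b$u * (s * cos(phi)) + b$v * (s * sin(phi))
}

# ---- Surface construction ----------------------------------------------

icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1,  p, 0), c(1,  p, 0), c(-1, -p, 0), c(1, -p, 0),
             c(0, -1,  p), c(0, 1,  p), c(0, -1, -p), c(0, 1, -p),
             c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  v <- v / sqrt(rowSums(v * v))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_sphere <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  ek <- key(edges[, 1], edges[, 2])
  uk <- unique(ek)
  mid_idx <- stats::setNames(seq_along(uk) + nrow(v), uk)
  ue <- edges[!duplicated(ek), , drop = FALSE]
  mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids * mids))
  v2 <- rbind(v, mids)
  m12 <- mid_idx[key(f[, 1], f[, 2])]
  m23 <- mid_idx[key(f[, 2], f[, 3])]
  m31 <- mid_idx[key(f[, 3], f[, 1])]
  f2 <- rbind(cbind(f[, 1], m12, m31),
              cbind(f[, 2], m23, m12),
              cbind(f[, 3], m31, m23),
              cbind(m12, m23, m31))
  list(vertices = v2, faces = unname(f2))
}

# Region names for n vertices taken in spatial order: up to 34 contiguous,
# nearly equal blocks.
label_blocks <- function(n) {
  k <- min(34L, n)
  dk_regions()[as.integer(cut(seq_len(n), breaks = k, labels = FALSE))]
}

#' Generate a paired white/pial surface model
#'
#' Builds index-matched white and pial meshes separated by the requested
#' thickness along the radial axis, with per-vertex Desikan-Killiany labels
#' assigned in contiguous patches and a hemisphere split at x = 0.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `surface_model`: `white`, `pial` (n x 3 mm),
#'   `faces` (triangle indices), `labels` (data frame: vertex_index, region,
#'   hemisphere) and `geometry` metadata.
#' @export
gen_surface_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  if (spec$shape == "slab") {
    nx <- ceiling(sqrt(spec$n_vertices))
    ny <- ceiling(spec$n_vertices / nx)
    g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
    g <- g[order(g$ix, g$iy), , drop = FALSE][seq_len(spec$n_vertices), ]
    x <- g$ix - (nx + 1) / 2
    y <- g$iy - (ny + 1) / 2
    white <- cbind(x, y, 0)
    pial <- cbind(x, y, spec$thickness_mm)
    # triangulate grid cells whose four corners were all kept
    idx <- matrix(NA_integer_, nx, ny)
    idx[cbind(g$ix, g$iy)] <- seq_len(nrow(g))
    faces <- NULL
    if (nx > 1 && ny > 1) {
      a <- idx[-nx, -ny]; b <- idx[-1, -ny]; cc <- idx[-1, -1]; d <- idx[-nx, -1]
      ok <- !(is.na(a) | is.na(b) | is.na(cc) | is.na(d))
      faces <- rbind(cbind(a[ok], b[ok], cc[ok]), cbind(a[ok], cc[ok], d[ok]))
    }
    if (is.null(faces)) faces <- matrix(integer(0), 0L, 3L)
    hemi <- ifelse(x < 0, "lh", "rh")
    region <- character(nrow(white))
    for (h in unique(hemi)) {
      sel <- which(hemi == h)
      ord <- sel[order(x[sel], y[sel])]
      region[ord] <- label_blocks(length(ord))
    }
    geometry <- list(shape = "slab", thickness = spec$thickness_mm,
                     xlim = range(x), ylim = range(y), spacing = 1)
  } else {
    mesh <- icosahedron()
    while (nrow(mesh$vertices) < spec$n_vertices) mesh <- subdivide_sphere(mesh)
    u <- mesh$vertices
    white <- u * spec$radius_mm
    pial <- u * (spec$radius_mm + spec$thickness_mm)
    faces <- mesh$faces
    hemi <- ifelse(u[, 1] < 0, "lh", "rh")
    az <- atan2(u[, 2], u[, 1])
    region <- character(nrow(u))
    for (h in unique(hemi)) {
      sel <- which(hemi == h)
      ord <- sel[order(u[sel, 3], az[sel])]
      region[ord] <- label_blocks(length(ord))
    }
    geometry <- list(shape = "spherical_shell", thickness = spec$thickness_mm,
                     radius = spec$radius_mm)
  }
  labels <- data.frame(vertex_index = seq_len(nrow(white)),
                       region = region, hemisphere = hemi,
                       stringsAsFactors = FALSE)
  structure(list(white = unname(white), pial = unname(pial),
                 faces = faces, labels = labels, geometry = geometry),
            class = "surface_model")
}

# ---- Tensor field construction -----------------------------------------

# Radial unit direction and cortical membership of world points, from the
# phantom geometry (the same geometry the surfaces were built from).
phantom_field <- function(pts, geometry) {
  if (geometry$shape == "slab") {
    inside <- pts[, 3] >= 0 & pts[, 3] <= geometry$thickness &
      pts[, 1] >= geometry$xlim[1] - 0.5 & pts[, 1] <= geometry$xlim[2] + 0.5 &
      pts[, 2] >= geometry$ylim[1] - 0.5 & pts[, 2] <= geometry$ylim[2] + 0.5
    r <- matrix(rep(c(0, 0, 1), each = nrow(pts)), ncol = 3L)
  } else {
    rad <- sqrt(rowSums(pts * pts))
    inside <- rad >= geometry$radius & rad <= geometry$radius + geometry$thickness
    r <- pts / pmax(rad, 1e-12)
  }
  list(inside = inside, r = r)
}

#' Generate a synthetic diffusion-tensor volume for a phantom
#'
#' Fills a voxel grid covering the surfaces. In cortical voxels each tensor
#' has the spec's eigenvalues and a principal eigenvector drawn from a
#' Watson distribution centred on the local radial axis with concentration
#' `kappa`; outside the cortex tensors are isotropic with the same mean
#' diffusivity. Optional Gaussian component noise is followed by eigenvalue
#' clamping to keep every tensor symmetric positive-definite.
#'
#' @param surfaces A `surface_model` from [gen_surface_pair()].
#' @param spec The [phantom_spec()] used to build the surfaces.
#' @return Object of class `tensor_volume`: `data` (nx x ny x nz x 6 array,
#'   packed lower-triangular), `affine` (voxel-to-world 4x4), `mask`
#'   (logical cortical mask) and `voxel_mm`.
#' @export
gen_tensor_field <- function(surfaces, spec) {
  stopifnot(inherits(surfaces, "surface_model"), inherits(spec, "phantom_spec"))
  set.seed(spec$seed + 1L)
  vox <- spec$voxel_mm
  allv <- rbind(surfaces$white, surfaces$pial)
  lo <- apply(allv, 2, min) - 2 * vox
  hi <- apply(allv, 2, max) + 2 * vox
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / vox)) + 1L)
  affine <- diag(c(vox, vox, vox, 1))
  affine[1:3, 4] <- lo
  if (abs(det(affine)) < 1e-12) {
    stop("invalid geometry: degenerate voxel-to-world affine", call. = FALSE)
  }
  ijk <- as.matrix(expand.grid(i = 0:(dims[1] - 1L),
                               j = 0:(dims[2] - 1L),
                               k = 0:(dims[3] - 1L)))
  pts <- sweep(ijk * vox, 2, lo, "+")
  fld <- phantom_field(pts, surfaces$geometry)
  n_all <- nrow(pts)
  lam <- spec$eigvals
  iso <- mean(lam)
  m6 <- matrix(rep(c(iso, 0, iso, 0, 0, iso), each = n_all), n_all, 6L)
  sel <- which(fld$inside)
  if (length(sel) > 0L) {
    rr <- fld$r[sel, , drop = FALSE]
    e1 <- rwatson_axis(length(sel), rr, spec$kappa)
    b <- perp_basis(e1)
    psi <- stats::runif(length(sel), 0, 2 * pi)
    e2 <- b$u * cos(psi) + b$v * sin(psi)
    e3 <- b$u * -sin(psi) + b$v * cos(psi)
    sym6 <- function(a, bb, cc) {
      cbind(lam[1] * a[, 1] * a[, 1] + lam[2] * bb[, 1] * bb[, 1] + lam[3] * cc[, 1] * cc[, 1],
            lam[1] * a[, 1] * a[, 2] + lam[2] * bb[, 1] * bb[, 2] + lam[3] * cc[, 1] * cc[, 2],
            lam[1] * a[, 2] * a[, 2] + lam[2] * bb[, 2] * bb[, 2] + lam[3] * cc[, 2] * cc[, 2],
            lam[1] * a[, 1] * a[, 3] + lam[2] * bb[, 1] * bb[, 3] + lam[3] * cc[, 1] * cc[, 3],
            lam[1] * a[, 2] * a[, 3] + lam[2] * bb[, 2] * bb[, 3] + lam[3] * cc[, 2] * cc[, 3],
            lam[1] * a[, 3] * a[, 3] + lam[2] * bb[, 3] * bb[, 3] + lam[3] * cc[, 3] * cc[, 3])
    }
    m6[sel, ] <- sym6(e1, e2, e3)
  }
  n_clamped <- 0L
  if (spec$noise_sd > 0) {
    m6[sel, ] <- m6[sel, , drop = FALSE] +
      matrix(stats::rnorm(length(sel) * 6L, 0, spec$noise_sd), ncol = 6L)
    floor_val <- 1e-6 * iso
    for (i in sel) {
      e <- eig_sym6_row(m6[i, ])
      if (any(e$values < floor_val)) {
        n_clamped <- n_clamped + sum(e$values < floor_val)
        vals <- pmax(e$values, floor_val)
        D <- e$vectors %*% diag(vals) %*% t(e$vectors)
        m6[i, ] <- D[SYM6_IDX]
      }
    }
  }
  data <- array(m6, c(dims, 6L))
  mask <- array(fld$inside, dims)
  structure(list(data = data, affine = affine, mask = mask,
                 voxel_mm = vox, n_clamped = n_clamped),
            class = "tensor_volume")
}

eig_sym6_row <- function(v) {
  D <- matrix(c(v[1], v[2], v[4],
                v[2], v[3], v[5],
                v[4], v[5], v[6]), 3L, 3L)
  eigen(D, symmetric = TRUE)
}
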