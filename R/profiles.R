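# Radial cortical profiles and the per-profile / per-region aggregation of
# the diffusivity metrics. A profile is a straight line from a white-surface
# vertex to its index-matched pial vertex; its direction is the radial
# minicolumn axis against which AngleR, ParlPD and PerpPD+ are referenced.

#' Build radial cortical profiles from a surface pair
#'
#' One profile per vertex: the radial axis is (pial - white)/|pial - white|
#' and sample points are evenly spaced from the white to the pial vertex,
#' inclusive of both endpoints. Vertices whose white-pial separation is
#' below `min_length_mm` are flagged excluded (degenerate cortex), not
#' dropped with an error.
#'
#' @param surfaces A `surface_model`.
#' @param n_samples Samples per profile (>= 2).
#' @param min_length_mm Exclusion threshold on white-pial separation (mm).
#' @return Object of class `cortical_profiles`: `vertex_index`, `r` (n x 3
#'   unit rows), `length_mm`, `excluded`, and `points` (n x n_samples x 3).
#' @export
build_profiles <- function(surfaces, n_samples = 7L, min_length_mm = 0.5) {
  stopifnot(inherits(surfaces, "surface_model"))
  if (n_samples < 2L) {
    stop("n_samples must be >= 2", call. = FALSE)
  }
  d <- surfaces$pial - surfaces$white
  len <- sqrt(rowSums(d * d))
  excluded <- len < min_length_mm
  if (all(len < .Machine$double.eps)) {
    stop("empty profile set: every vertex pair has zero length", call. = FALSE)
  }
  r <- d / pmax(len, .Machine$double.eps)
  n <- nrow(d)
  frac <- seq(0, 1, length.out = n_samples)
  pts <- array(0, c(n, n_samples, 3L))
  for (s in seq_len(n_samples)) {
    pts[, s, ] <- surfaces$white + d * frac[s]
  }
  structure(list(vertex_index = seq_len(n), r = r, length_mm = len,
                 excluded = excluded, n_samples = as.integer(n_samples),
                 points = pts),
            class = "cortical_profiles")
}

# World points -> voxel (0-based, fractional) coordinates.
world_to_voxel <- function(pts, affine) {
  inv <- solve(affine)
  sweep(pts %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], "+")
}

# Sample packed tensors at world points. Returns list(m6, inmask).
# nearest: tensor of the nearest voxel; trilinear: componentwise
# interpolation over the 8 surrounding voxels (re-eigendecomposed by the
# caller). Mask membership always uses the nearest voxel.
sample_tensors <- function(pts, vol, interpolation = c("nearest", "trilinear")) {
  interpolation <- match.arg(interpolation)
  dims <- dim(vol$data)[1:3]
  ijk <- world_to_voxel(pts, vol$affine)
  nn <- round(ijk)
  inside <- nn[, 1] >= 0 & nn[, 1] <= dims[1] - 1 &
            nn[, 2] >= 0 & nn[, 2] <= dims[2] - 1 &
            nn[, 3] >= 0 & nn[, 3] <= dims[3] - 1
  inmask <- rep(FALSE, nrow(pts))
  lin_nn <- rep(NA_integer_, nrow(pts))
  ok <- which(inside)
  if (length(ok) > 0L) {
    lin_nn[ok] <- 1L + nn[ok, 1] + dims[1] * (nn[ok, 2] + dims[2] * nn[ok, 3])
    inmask[ok] <- as.vector(vol$mask)[lin_nn[ok]]
  }
  m6 <- matrix(NA_real_, nrow(pts), 6L)
  nvox <- prod(dims)
  flat <- matrix(vol$data, nvox, 6L)
  if (interpolation == "nearest") {
    m6[ok, ] <- flat[lin_nn[ok], , drop = FALSE]
  } else {
    f0 <- pmin(pmax(floor(ijk), 0), matrix(dims - 1, nrow(pts), 3L, byrow = TRUE))
    w <- ijk - f0
    acc <- matrix(0, nrow(pts), 6L)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      cx <- pmin(f0[, 1] + dx, dims[1] - 1)
      cy <- pmin(f0[, 2] + dy, dims[2] - 1)
      cz <- pmin(f0[, 3] + dz, dims[3] - 1)
      wt <- (if (dx == 1) w[, 1] else 1 - w[, 1]) *
            (if (dy == 1) w[, 2] else 1 - w[, 2]) *
            (if (dz == 1) w[, 3] else 1 - w[, 3])
      lin <- 1L + cx + dims[1] * (cy + dims[2] * cz)
      acc <- acc + flat[lin, , drop = FALSE] * wt
    }
    m6[ok, ] <- acc[ok, , drop = FALSE]
  }
  list(m6 = m6, inmask = inmask)
}

# Per-sample metrics for packed tensors against per-sample radial axes.
# Deduplicates identical voxel tensors is left to callers; here every row is
# eigendecomposed. Returns data.frame(angler, parlpd, perppd_plus).
metrics_rows <- function(m6, r) {
  e <- eig_sym6_many(m6)
  n <- nrow(m6)
  ang <- numeric(n); par <- numeric(n); perp <- numeric(n)
  for (i in seq_len(n)) {
    E <- e$vectors[, , i]
    ct <- abs(sum(E[, 1] * r[i, ]))
    ang[i] <- acos(min(1, ct))
    par[i] <- e$values[i, 1] * min(1, ct)
    proj2 <- as.numeric(crossprod(E, r[i, ]))^2
    perp[i] <- sum(e$values[i, ] * (1 - proj2))
  }
  data.frame(angler = ang, parlpd = par, perppd_plus = perp)
}

#' Compute profile-averaged metrics for one cortical profile
#'
#' Metrics are computed per sample point against the profile's single radial
#' axis and then unweighted-averaged over the samples that fall inside the
#' cortical mask; out-of-mask samples are dropped. If no sample is
#' measurable the profile is flagged unmeasurable rather than raising.
#'
#' @param profile List with `points` (n_samples x 3), `r` (unit radial axis)
#'   and optionally `excluded`.
#' @param vol A `tensor_volume`.
#' @param interpolation `"nearest"` (default) or `"trilinear"`.
#' @return List with `angler`, `parlpd`, `perppd_plus` (NA when
#'   unmeasurable) and `measurable`.
#' @export
profile_metrics <- function(profile, vol,
                            interpolation = c("nearest", "trilinear")) {
  interpolation <- match.arg(interpolation)
  if (isTRUE(profile$excluded)) {
    stop("profile is flagged excluded (degenerate white-pial pair)",
         call. = FALSE)
  }
  pts <- profile$points
  if (is.null(dim(pts)) || ncol(pts) != 3L) {
    stop("profile$points must be an n_samples x 3 matrix", call. = FALSE)
  }
  smp <- sample_tensors(pts, vol, interpolation)
  keep <- which(smp$inmask)
  if (length(keep) == 0L) {
    return(list(angler = NA_real_, parlpd = NA_real_,
                perppd_plus = NA_real_, measurable = FALSE))
  }
  r <- matrix(profile$r, length(keep), 3L, byrow = TRUE)
  m <- metrics_rows(smp$m6[keep, , drop = FALSE], r)
  list(angler = mean(m$angler), parlpd = mean(m$parlpd),
       perppd_plus = mean(m$perppd_plus), measurable = TRUE)
}

#' Compute per-vertex metrics for all profiles of a surface model
#'
#' Batch equivalent of [profile_metrics()] over every non-excluded profile.
#' With nearest-neighbour interpolation, tensors are eigendecomposed once
#' per distinct voxel rather than once per sample.
#'
#' @param surfaces A `surface_model`.
#' @param vol A `tensor_volume`.
#' @param n_samples Samples per profile.
#' @param interpolation `"nearest"` or `"trilinear"`.
#' @return Data frame: vertex_index, region, hemisphere, angler, parlpd,
#'   perppd_plus, measurable.
#' @export
compute_vertex_metrics <- function(surfaces, vol, n_samples = 7L,
                                   interpolation = c("nearest", "trilinear")) {
  interpolation <- match.arg(interpolation)
  prof <- build_profiles(surfaces, n_samples)
  n <- length(prof$vertex_index)
  ns <- prof$n_samples
  pts <- matrix(aperm(prof$points, c(2, 1, 3)), n * ns, 3L)
  vert_of <- rep(seq_len(n), each = ns)
  smp <- sample_tensors(pts, vol, interpolation)
  usable <- smp$inmask & !prof$excluded[vert_of]
  ang <- par <- perp <- rep(NA_real_, n * ns)
  idx <- which(usable)
  if (length(idx) > 0L) {
    m6u <- smp$m6[idx, , drop = FALSE]
    if (interpolation == "nearest") {
      key <- do.call(paste, c(as.data.frame(m6u), sep = "|"))
      first <- !duplicated(key)
      e <- eig_sym6_many(m6u[first, , drop = FALSE])
      map <- match(key, key[first])
    } else {
      e <- eig_sym6_many(m6u)
      map <- seq_along(idx)
    }
    rr <- prof$r[vert_of[idx], , drop = FALSE]
    for (q in seq_along(idx)) {
      j <- map[q]
      E <- e$vectors[, , j]
      ct <- abs(sum(E[, 1] * rr[q, ]))
      ang[idx[q]] <- acos(min(1, ct))
      par[idx[q]] <- e$values[j, 1] * min(1, ct)
      proj2 <- as.numeric(crossprod(E, rr[q, ]))^2
      perp[idx[q]] <- sum(e$values[j, ] * (1 - proj2))
    }
  }
  agg <- function(x) {
    v <- tapply(x, vert_of, function(z) {
      z <- z[!is.na(z)]
      if (length(z) == 0L) NA_real_ else mean(z)
    })
    as.numeric(v)
  }
  out <- data.frame(vertex_index = seq_len(n),
                    region = surfaces$labels$region,
                    hemisphere = surfaces$labels$hemisphere,
                    angler = agg(ang), parlpd = agg(par),
                    perppd_plus = agg(perp),
                    stringsAsFactors = FALSE)
  out$measurable <- !is.na(out$angler)
  out
}

#' Aggregate per-vertex metrics to regions and a signature meta-region
#'
#' Regional value = unweighted mean over the region's measurable vertices;
#' signature value = unweighted mean over the member-region means, pooling
#' both hemispheres. Regions with no measurable vertex are reported missing
#' and skipped (with a warning) when the signature is formed.
#'
#' @param vertex_metrics Data frame from [compute_vertex_metrics()] (or any
#'   frame with vertex_index, region, hemisphere, angler, parlpd,
#'   perppd_plus, measurable).
#' @param region_set Character vector of signature member regions.
#' @return List of class `regional_metrics`: `regions` (data frame per
#'   region x hemisphere) and `signature` (named metric means).
#' @export
aggregate_metrics <- function(vertex_metrics,
                              region_set = diffusivity_signature_regions()) {
  check_region_names(region_set, "signature region set")
  check_region_names(unique(vertex_metrics$region), "vertex labels")
  vm <- vertex_metrics
  keyf <- interaction(vm$region, vm$hemisphere, drop = TRUE)
  meas <- vm$measurable
  per <- do.call(rbind, lapply(levels(keyf), function(k) {
    sel <- keyf == k & meas
    rows <- vm[keyf == k, ]
    data.frame(region = rows$region[1], hemisphere = rows$hemisphere[1],
               angler = if (any(sel)) mean(vm$angler[sel]) else NA_real_,
               parlpd = if (any(sel)) mean(vm$parlpd[sel]) else NA_real_,
               perppd_plus = if (any(sel)) mean(vm$perppd_plus[sel]) else NA_real_,
               n_vertices = sum(sel), stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  member <- per[per$region %in% region_set, , drop = FALSE]
  usable <- !is.na(member$angler)
  if (any(!usable)) {
    warning(sprintf("signature computed without %d empty member region value(s)",
                    sum(!usable)))
  }
  member <- member[usable, , drop = FALSE]
  signature <- c(angler = mean(member$angler),
                 parlpd = mean(member$parlpd),
                 perppd_plus = mean(member$perppd_plus))
  structure(list(regions = per, signature = signature,
                 region_set = region_set),
            class = "regional_metrics")
}
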