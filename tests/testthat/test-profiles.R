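# Radial profile construction, per-profile metric averaging, and the
# region/signature aggregation conventions.

test_that("profile sample points are evenly spaced between the surfaces", {
  surf <- structure(list(
    white = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
    pial = rbind(c(0, 0, 2.5), c(1, 0, 2.5), c(2, 0, 0)),  # 3rd degenerate
    faces = matrix(integer(0), 0, 3),
    labels = data.frame(vertex_index = 1:3, region = "precuneus",
                        hemisphere = "lh"),
    geometry = NULL), class = "surface_model")
  prof <- build_profiles(surf, n_samples = 6)
  expect_equal(prof$points[1, , 3], seq(0, 2.5, by = 0.5))
  expect_equal(prof$r[1, ], c(0, 0, 1))
  expect_false(prof$excluded[1])
  expect_true(prof$excluded[3])   # white == pial: flagged, no exception
  expect_error(build_profiles(surf, n_samples = 1), "n_samples")
})

test_that("an all-degenerate surface raises the empty-profile-set error", {
  surf <- structure(list(
    white = rbind(c(0, 0, 0), c(1, 0, 0)),
    pial = rbind(c(0, 0, 0), c(1, 0, 0)),
    faces = matrix(integer(0), 0, 3),
    labels = data.frame(vertex_index = 1:2, region = "insula",
                        hemisphere = "lh"),
    geometry = NULL), class = "surface_model")
  expect_error(build_profiles(surf), "empty profile set")
})

test_that("slab phantom profiles all point along the slab normal", {
  ph <- make_phantom(n_vertices = 36, seed = 5)
  prof <- build_profiles(ph$surf)
  expect_true(all(abs(prof$r[, 3] - 1) < 1e-12))
})

test_that("a perfectly radial phantom yields AngleR = 0 along every profile", {
  ph <- make_phantom(n_vertices = 49, kappa = 1e7, seed = 6)
  prof <- build_profiles(ph$surf)
  p1 <- list(points = prof$points[1, , ], r = prof$r[1, ])
  m <- profile_metrics(p1, ph$vol)
  expect_true(m$measurable)
  expect_lt(m$angler, 1e-6)
  expect_equal(m$parlpd, ph$spec$eigvals[1], tolerance = 1e-9)
  expect_equal(m$perppd_plus, sum(ph$spec$eigvals[2:3]), tolerance = 1e-9)
})

test_that("uniform tensor fields give sample-count-independent profile metrics", {
  ph <- make_phantom(n_vertices = 49, kappa = 1e7, seed = 6)
  prof <- build_profiles(ph$surf, n_samples = 2)
  p_few <- list(points = prof$points[5, , ], r = prof$r[5, ])
  prof9 <- build_profiles(ph$surf, n_samples = 9)
  p_many <- list(points = prof9$points[5, , ], r = prof9$r[5, ])
  m_few <- profile_metrics(p_few, ph$vol)
  m_many <- profile_metrics(p_many, ph$vol)
  expect_equal(m_few$angler, m_many$angler, tolerance = 1e-12)
  expect_equal(m_few$perppd_plus, m_many$perppd_plus, tolerance = 1e-12)
})

test_that("profiles entirely outside the mask are flagged unmeasurable", {
  ph <- make_phantom(n_vertices = 36, seed = 7)
  far <- cbind(rep(0, 5), rep(0, 5), seq(50, 60, length.out = 5))
  m <- profile_metrics(list(points = far, r = c(0, 0, 1)), ph$vol)
  expect_false(m$measurable)
  expect_true(is.na(m$angler))
})

test_that("trilinear interpolation agrees with nearest on a uniform field", {
  ph <- make_phantom(n_vertices = 49, kappa = 1e7, seed = 8)
  # make the field uniform everywhere (not just in-mask) so boundary
  # interpolation cannot blend in the isotropic background
  dims <- dim(ph$vol$data)[1:3]
  flat <- matrix(ph$vol$data, prod(dims), 6L)
  uni <- flat[which(as.vector(ph$vol$mask))[1], ]
  ph$vol$data <- array(matrix(uni, prod(dims), 6L, byrow = TRUE),
                       c(dims, 6L))
  vm_n <- compute_vertex_metrics(ph$surf, ph$vol, interpolation = "nearest")
  vm_t <- compute_vertex_metrics(ph$surf, ph$vol, interpolation = "trilinear")
  keep <- vm_n$measurable & vm_t$measurable
  expect_gt(sum(keep), 0)
  expect_equal(vm_t$perppd_plus[keep], vm_n$perppd_plus[keep],
               tolerance = 1e-6)
})

test_that("metrics are equivariant under an axis-permuting rigid rotation", {
  ph <- make_phantom(n_vertices = 49, kappa = 3, seed = 9)
  vm <- compute_vertex_metrics(ph$surf, ph$vol)
  R <- axis_permutation()
  vm_rot <- compute_vertex_metrics(rotate_surfaces(ph$surf, R),
                                   rotate_volume(ph$vol, R))
  keep <- vm$measurable & vm_rot$measurable
  for (col in c("angler", "parlpd", "perppd_plus")) {
    expect_equal(vm_rot[[col]][keep], vm[[col]][keep], tolerance = 1e-6)
  }
})

test_that("signature disarray increases monotonically as concentration falls", {
  kappas <- c(100, 20, 5, 1, 0)
  ok_angler <- ok_perp <- TRUE
  for (seed in 1:5) {
    sig <- sapply(kappas, function(k) {
      ph <- make_phantom(n_vertices = 400, kappa = k, seed = seed)
      vm <- compute_vertex_metrics(ph$surf, ph$vol)
      suppressWarnings(aggregate_metrics(vm)$signature)
    })
    ok_angler <- ok_angler && all(diff(sig["angler", ]) > 0)
    ok_perp <- ok_perp && all(diff(sig["perppd_plus", ]) > 0)
  }
  expect_true(ok_angler)
  expect_true(ok_perp)
})

test_that("disarray separates CU-like from AD-like phantoms in the right direction", {
  # higher disarray (lower kappa) stands in for the dementia-like cortex;
  # signature PerpPD+ must come out higher there
  cu <- make_phantom(n_vertices = 100, kappa = 30, seed = 10)
  ad <- make_phantom(n_vertices = 100, kappa = 3, seed = 10)
  sig_cu <- aggregate_metrics(compute_vertex_metrics(cu$surf, cu$vol))$signature
  sig_ad <- aggregate_metrics(compute_vertex_metrics(ad$surf, ad$vol))$signature
  expect_gt(sig_ad[["perppd_plus"]], sig_cu[["perppd_plus"]])
  expect_gt(sig_ad[["angler"]], sig_cu[["angler"]])
})

test_that("aggregation follows the region-mean conventions", {
  vm <- data.frame(
    vertex_index = 1:6,
    region = rep(c("precuneus", "fusiform", "insula"), each = 2),
    hemisphere = "lh",
    angler = c(1, 1, 3, 3, 9, 9),
    parlpd = c(1, 1, 3, 3, 9, 9) * 1e-3,
    perppd_plus = c(1, 1, 3, 3, 9, 9) * 1e-3,
    measurable = TRUE)
  ag <- aggregate_metrics(vm, region_set = c("precuneus", "fusiform"))
  # signature = mean of region means (2), not mean of vertices
  expect_equal(ag$signature[["angler"]], 2)
  expect_equal(ag$regions$angler[ag$regions$region == "insula"], 9)

  # constant input: every region and the signature equal the constant
  vm$angler <- 5; vm$parlpd <- 5; vm$perppd_plus <- 5
  ag2 <- aggregate_metrics(vm, region_set = c("precuneus", "insula"))
  expect_true(all(ag2$regions$angler == 5))
  expect_equal(ag2$signature[["angler"]], 5)

  # empty region: missing marker propagated, warning, signature from the rest
  vm$measurable[vm$region == "fusiform"] <- FALSE
  expect_warning(
    ag3 <- aggregate_metrics(vm, region_set = c("precuneus", "fusiform")),
    "empty member region")
  expect_true(is.na(ag3$regions$angler[ag3$regions$region == "fusiform"]))
  expect_equal(ag3$signature[["angler"]], 5)

  expect_error(aggregate_metrics(vm, region_set = c("precuneus", "nonsense")),
               "unknown region")
})
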