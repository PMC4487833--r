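# Cohort sampler: copula targets, marginals, determinism, derived identities

test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_subjects = 30, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_cohort(cohort_config(n_subjects = 30, seed = 43))
  expect_false(identical(a$rStO2, c2$rStO2))
})

test_that("independent latents are sampled uncorrelated", {
  cfg <- cohort_config(n_subjects = 5000, latent_corr = diag(10), seed = 7)
  z <- attr(generate_cohort(cfg), "drivers")
  r <- cor(z)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("designed driver correlations are realized by the copula", {
  m <- diag(10)
  dimnames(m) <- list(rownames(default_latent_corr()),
                      colnames(default_latent_corr()))
  m["rStO2", "Ki67_T"] <- m["Ki67_T", "rStO2"] <- 0.9
  cfg <- cohort_config(n_subjects = 5000, latent_corr = m, seed = 3)
  z <- attr(generate_cohort(cfg), "drivers")
  expect_lt(abs(cor(z[, "rStO2"], z[, "Ki67_T"]) - 0.9), 0.03)
})

test_that("a non-PSD correlation matrix is rejected naming the eigenvalue", {
  m <- diag(10)
  m[1, 2] <- m[2, 1] <- 0.99
  m[2, 3] <- m[3, 2] <- 0.99
  m[1, 3] <- m[3, 1] <- -0.9
  err <- tryCatch(cohort_config(latent_corr = m),
                  dothisto_config = function(e) e)
  expect_s3_class(err, "dothisto_config")
  expect_match(conditionMessage(err), "eigenvalue")
  expect_true(is.numeric(err$eigenvalue) && err$eigenvalue < 0)
})

test_that("marginals match their configured truncated-normal laws", {
  cfg <- cohort_config(n_subjects = 10000, seed = 5)
  co <- generate_cohort(cfg)
  for (nm in c("rStO2", "rTHC", "Ki67_T", "compact_T")) {
    p <- cfg$marginals[[nm]]
    x <- if (nm == "Ki67_T") co$Ki67_T else co[[nm]]
    ks <- suppressWarnings(stats::ks.test(
      x, function(q) dothisto:::ptruncnorm(q, p[1], p[2], p[3], p[4])))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("rTHC and rStO2 are algebraically consistent, never free", {
  cfg <- cohort_config(n_subjects = 200, seed = 9)
  co <- generate_cohort(cfg)
  ref <- cfg$normal_ref
  expect_equal(co$rStO2, co$rHbO2 / co$rTHC, tolerance = 1e-12)
  expect_equal(co$rTHC,
               (co$rHbO2 * ref$HbO2_N + co$rHb * ref$Hb_N) /
                 (ref$HbO2_N + ref$Hb_N),
               tolerance = 1e-12)
  expect_true(all(co$compact_T <= 1 & co$compact_N <= 1))
})

test_that("phantom forward model is the exact Beer mix at the center voxel", {
  s <- make_subject(center = c(0, 0, 0), axes = c(7, 7, 7))
  ph <- render_phantom(s, mua_sigma = 0)
  ext <- default_extinction()
  cidx <- round(ph$center_mm / ph$grid$voxel_mm)
  hbo2_t <- s$rHbO2 * 20; hb_t <- s$rHb * 10
  for (i in seq_len(nrow(ext))) {
    expect_equal(ph$vols$mua[[i]][cidx[1], cidx[2], cidx[3]],
                 ext$eps_hbo2[i] * hbo2_t + ext$eps_hb[i] * hb_t,
                 tolerance = 1e-12)
  }
})

test_that("phantom absorption is linear in concentrations", {
  s <- make_subject()
  ph1 <- render_phantom(s, mua_sigma = 0,
                        normal_ref = list(HbO2_N = 20, Hb_N = 10,
                                          musp_N = 0.8, BFI_N = 1e-8))
  ph2 <- render_phantom(s, mua_sigma = 0,
                        normal_ref = list(HbO2_N = 40, Hb_N = 20,
                                          musp_N = 0.8, BFI_N = 1e-8))
  expect_equal(ph2$vols$mua[[1]], 2 * ph1$vols$mua[[1]], tolerance = 1e-12)
})

test_that("a contrast-free subject renders a homogeneous volume and no mask", {
  s <- make_subject(rStO2 = 1, rTHC = 1, rmusp = 1)
  ph <- render_phantom(s, mua_sigma = 0)
  expect_equal(diff(range(ph$vols$mua[[1]])), 0)
  hint <- seed_box(dim(ph$hbo2), round(ph$center_mm), 4)
  expect_error(grow_tumor_region(ph$vols$mua[[1]], hint),
               class = "dothisto_no_contrast")
})

test_that("out-of-grid tumors are rejected", {
  s <- make_subject(center = c(20, 0, 0), axes = c(9, 9, 9))
  expect_error(render_phantom(s), class = "dothisto_geometry")
})

test_that("rendered half-maximum contour matches the Gaussian-edge analytic radius", {
  # spherical tumor, 2:1 concentration contrast, wide 2 mm blend
  s <- make_subject(rStO2 = 1, rTHC = 2, rmusp = 1, axes = c(8, 8, 8))
  ph <- render_phantom(s, mua_sigma = 0, blend_sigma = 2)
  contrast <- ph$vols$mua[[1]] - min(ph$vols$mua[[1]])
  cidx <- round(ph$center_mm / ph$grid$voxel_mm)
  prof <- contrast[, cidx[2], cidx[3]]
  half <- max(prof) / 2
  xr <- which(prof >= half)
  measured_r <- (max(xr) - min(xr)) / 2
  analytic_r <- 8 + 2 * sqrt(2 * log(2))
  expect_lt(abs(measured_r - analytic_r), 1)
})

test_that("noise-free g2 scans reproduce the forward model and decay ordering", {
  s <- make_subject(rBF = 2)
  opt <- tissue_optics()
  scan <- simulate_g2_scan(s, opt, g2_sigma = 0, seed = 4)
  curves <- g2_scan_curves(scan)
  for (cv in curves) {
    bfi <- if (cv$label == "tumor") 2e-8 else 1e-8
    expect_equal(cv$g2, g2_model(cv$tau, bfi, 0.5, opt), tolerance = 1e-12)
  }
  # faster decay for tumor: delay where g2 - 1 falls to beta/2 is smaller
  half_delay <- function(cv) cv$tau[which(cv$g2 - 1 <= 0.25)[1]]
  labs <- vapply(curves, function(cv) cv$label, character(1))
  expect_lt(max(vapply(curves[labs == "tumor"], half_delay, numeric(1))),
            min(vapply(curves[labs == "normal"], half_delay, numeric(1))))
})

test_that("noise-free scan fits recover the true relative blood flow", {
  s <- make_subject(rBF = 2.7)
  scan <- simulate_g2_scan(s, g2_sigma = 0, seed = 8)
  fits <- lapply(g2_scan_curves(scan), fit_bfi)
  expect_lt(abs(compute_rbf(fits)$rbf / 2.7 - 1), 1e-3)
})

test_that("slides with zero Ki67 carry no DAB outside vessels", {
  s <- make_subject(Ki67_T = 0, Ki67_N = 0)
  sl <- render_slide(s, slide_layout(width_px = 512, height_px = 384,
                                     n_nuclei_tumor = 40,
                                     n_nuclei_normal = 30, n_artifacts = 0),
                     slide_jitter = 0, seed = 6)
  conc <- stain_deconvolve(rgb_to_od(sl$image))
  vb <- sl$objects[sl$objects$class == "vessel", ]
  out_vessel <- matrix(TRUE, nrow(conc$dab), ncol(conc$dab))
  for (i in seq_len(nrow(vb))) {
    r <- sqrt(vb$vessel_area_um2[i] / pi) / sl$image$scale + 3
    rows <- max(1, floor(vb$y[i] - r)):min(nrow(out_vessel),
                                           ceiling(vb$y[i] + r))
    cols <- max(1, floor(vb$x[i] - r)):min(ncol(out_vessel),
                                           ceiling(vb$x[i] + r))
    out_vessel[rows, cols] <- FALSE
  }
  expect_lt(max(conc$dab[out_vessel]), 0.15)
})

test_that("rendered object ground truth is internally consistent", {
  s <- make_subject()
  sl <- render_slide(s, seed = 10)
  nuc <- sl$objects[sl$objects$class == "nucleus", ]
  # recorded compactness equals 4*pi*A/P^2 of the recorded analytic shape
  expect_equal(compactness(nuc$area_um2, nuc$perimeter_um), nuc$compactness,
               tolerance = 1e-6)
  expect_true(all(nuc$compactness <= 1 + 1e-9))
  # exact positive counts drive the recorded percentages
  tn <- nuc[nuc$tissue == "tumor", ]
  expect_equal(100 * sum(tn$positive) / nrow(tn), sl$truth$ki67_t_pct)
})

test_that("impossible object densities raise a layout error", {
  s <- make_subject()
  tiny <- slide_layout(width_px = 160, height_px = 120,
                       n_nuclei_tumor = 400, n_nuclei_normal = 10,
                       auto_expand = FALSE)
  # on a fixed canvas placement must fail loudly rather than overlap
  expect_error(
    render_slide(make_subject(compact_T = 0.95, compact_N = 0.95), tiny,
                 seed = 1),
    class = "dothisto_layout")
})

test_that("slide rendering is deterministic per seed and re-randomizes placement", {
  s <- make_subject()
  lay <- slide_layout(width_px = 512, height_px = 384,
                      n_nuclei_tumor = 40, n_nuclei_normal = 30)
  a <- render_slide(s, lay, seed = 21)
  b <- render_slide(s, lay, seed = 21)
  expect_identical(a$image$rgb, b$image$rgb)
  c2 <- render_slide(s, lay, seed = 22)
  expect_false(identical(a$image$rgb, c2$image$rgb))
  # summary ground truth is seed-invariant where it is count-determined
  expect_equal(a$truth$ki67_t_pct, c2$truth$ki67_t_pct)
})
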