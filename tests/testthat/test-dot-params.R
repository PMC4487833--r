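# Chromophore unmixing, StO2 maps, FWHM segmentation, tumor-to-normal ratios

test_that("unmixing returns zero concentrations for zero absorption", {
  ext <- default_extinction()
  dims <- c(4, 4, 4)
  vols <- absorption_volumes(
    lapply(seq_len(nrow(ext)), function(i) array(0, dims)),
    array(0.8, dims), ext$wavelength_nm, c(1, 1, 1))
  cm <- fit_chromophores(vols, ext)
  expect_equal(max(abs(cm$HbO2)), 0)
  expect_equal(max(abs(cm$Hb)), 0)
})

test_that("a single-chromophore spectrum is identified exactly", {
  ext <- default_extinction()
  dims <- c(3, 3, 3)
  vols <- absorption_volumes(
    lapply(seq_len(nrow(ext)), function(i) array(ext$eps_hbo2[i] * 25, dims)),
    array(0.8, dims), ext$wavelength_nm, c(1, 1, 1))
  cm <- fit_chromophores(vols, ext)
  expect_equal(cm$HbO2, array(25, dims), tolerance = 1e-10)
  expect_equal(cm$Hb, array(0, dims), tolerance = 1e-10)
  expect_lt(max(cm$residual), 1e-10)
})

test_that("missing or duplicated wavelengths are spectral-design errors", {
  ext <- default_extinction()
  dims <- c(2, 2, 2)
  vols <- absorption_volumes(list(array(1e-3, dims), array(1e-3, dims)),
                             array(0.8, dims), c(700, 800), c(1, 1, 1))
  expect_error(fit_chromophores(vols, ext),
               class = "dothisto_spectral_design")
  expect_error(extinction_table(c(690, 690), c(1e-4, 1e-4), c(4e-4, 4e-4)),
               class = "dothisto_spectral_design")
})

test_that("closed-form NNLS agrees with a per-voxel numerical oracle", {
  set.seed(31)
  ext <- default_extinction()
  E <- as.matrix(ext[, c("eps_hbo2", "eps_hb")])
  # spectra from mixed-sign 'concentrations' plus noise exercise the
  # boundary (clamped) branches
  C_true <- rbind(runif(120, -10, 40), runif(120, -10, 40))
  Y <- E %*% C_true + matrix(rnorm(4 * 120, 0, 2e-4), 4)
  B <- dothisto:::nnls2(E, Y)
  for (j in seq_len(ncol(Y))) {
    oracle <- optim(c(10, 10), function(p)
      sum((E %*% pmax(p, 0) - Y[, j])^2), method = "L-BFGS-B",
      lower = c(0, 0), upper = c(100, 100))
    rss_pkg <- sum((E %*% B[, j] - Y[, j])^2)
    expect_lte(rss_pkg, oracle$value + 1e-12)
    expect_true(all(B[, j] >= 0))
  }
})

test_that("unmixing inverts the noise-free forward phantom to near machine precision", {
  s <- make_subject()
  ph <- render_phantom(s, mua_sigma = 0)
  cm <- fit_chromophores(ph$vols, default_extinction())
  expect_lt(max(abs(cm$HbO2 - ph$hbo2) / ph$hbo2), 1e-10)
  expect_lt(max(abs(cm$Hb - ph$hb) / ph$hb), 1e-10)
})

test_that("two-wavelength unmixing equals the direct 2x2 solve", {
  ext <- extinction_table(c(690, 830), c(6.4e-5, 2.2e-4), c(4.7e-4, 1.6e-4))
  E <- as.matrix(ext[, c("eps_hbo2", "eps_hb")])
  set.seed(12)
  conc <- rbind(runif(50, 5, 40), runif(50, 2, 20))
  Y <- E %*% conc
  dims <- c(50, 1, 1)
  vols <- absorption_volumes(list(array(Y[1, ], dims), array(Y[2, ], dims)),
                             array(0.8, dims), ext$wavelength_nm, c(1, 1, 1))
  cm <- fit_chromophores(vols, ext)
  direct <- solve(E, Y)
  expect_equal(as.vector(cm$HbO2), direct[1, ], tolerance = 1e-9)
  expect_equal(as.vector(cm$Hb), direct[2, ], tolerance = 1e-9)
})

test_that("StO2 handles symmetric, boundary and degenerate voxels", {
  map <- list(HbO2 = array(c(10, 5, 0, 0), c(4, 1, 1)),
              Hb = array(c(10, 0, 0, 2), c(4, 1, 1)))
  s <- compute_sto2(map)
  expect_equal(s[1, 1, 1], 0.5)
  expect_equal(s[2, 1, 1], 1.0)
  expect_true(is.na(s[3, 1, 1]))          # masked, no NaN propagation
  expect_equal(s[4, 1, 1], 0)
  expect_identical(attr(s, "undefined_mask")[, 1, 1],
                   c(FALSE, FALSE, TRUE, FALSE))
})

test_that("half-maximum radius of a Gaussian blob matches sigma*sqrt(2 ln 2)", {
  blob <- gaussian_blob(sigma = 4, peak = 7)
  hint <- seed_box(dim(blob), c(21, 21, 21), 3)
  tm <- grow_tumor_region(blob, hint)
  expect_identical(tm$seed_voxel, c(21L, 21L, 21L))
  prof <- which(tm$mask[, 21, 21])
  measured_r <- (max(prof) - min(prof)) / 2
  expect_lt(abs(measured_r - 4 * sqrt(2 * log(2))), 1)
  # equivalent-volume radius agrees too
  r_eq <- (3 * sum(tm$mask) / (4 * pi))^(1 / 3)
  expect_lt(abs(r_eq - 4 * sqrt(2 * log(2))), 1)
})

test_that("region growing respects connectivity: a second blob is excluded", {
  a <- gaussian_blob(dims = c(61, 41, 41), sigma = 3, peak = 1,
                     center = c(15, 21, 21)) +
    gaussian_blob(dims = c(61, 41, 41), sigma = 3, peak = 1,
                  center = c(47, 21, 21))
  hint <- seed_box(dim(a), c(15, 21, 21), 3)
  tm <- grow_tumor_region(a, hint)
  expect_true(all(which(tm$mask, arr.ind = TRUE)[, 1] < 31))
})

test_that("constant volumes raise the no-contrast error", {
  flat <- array(1, c(10, 10, 10))
  expect_error(grow_tumor_region(flat, seed_box(dim(flat), c(5, 5, 5), 2)),
               class = "dothisto_no_contrast")
})

test_that("segmentation is invariant under positive rescaling and ties break low", {
  blob <- gaussian_blob(sigma = 3)
  hint <- seed_box(dim(blob), c(21, 21, 21), 4)
  m1 <- grow_tumor_region(blob, hint)
  m2 <- grow_tumor_region(blob * 7.3, hint)
  expect_identical(m1$mask, m2$mask)
  # two equal maxima: lowest linear index wins
  twin <- array(0, c(9, 9, 9))
  twin[3, 5, 5] <- twin[7, 5, 5] <- 1
  tm <- grow_tumor_region(twin, array(TRUE, dim(twin)))
  expect_identical(tm$seed_voxel, c(3L, 5L, 5L))
})

test_that("mask volume shrinks monotonically as the cutoff rises", {
  blob <- gaussian_blob(sigma = 4)
  hint <- seed_box(dim(blob), c(21, 21, 21), 3)
  vols <- vapply(c(0.5, 0.6, 0.7, 0.8),
                 function(cf) sum(grow_tumor_region(blob, hint,
                                                    cutoff = cf)$mask),
                 numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("relative params are unity on homogeneous volumes", {
  dims <- c(10, 10, 10)
  map <- list(HbO2 = array(20, dims), Hb = array(10, dims),
              THC = array(30, dims))
  map$StO2 <- compute_sto2(map)
  mask <- array(FALSE, dims); mask[4:6, 4:6, 4:6] <- TRUE
  rp <- relative_params(map, array(0.8, dims), mask)
  expect_equal(unname(c(rp$rHbO2, rp$rHb, rp$rTHC, rp$rStO2, rp$rmusp)),
               rep(1, 5), tolerance = 1e-12)
})

test_that("two-region phantom ratios match the hand computation", {
  dims <- c(10, 10, 10)
  hbo2 <- array(20, dims); hb <- array(10, dims)
  mask <- array(FALSE, dims); mask[4:6, 4:6, 4:6] <- TRUE
  hbo2[mask] <- 40 # tumor HbO2 doubled, Hb equal
  map <- list(HbO2 = hbo2, Hb = hb, THC = hbo2 + hb)
  map$StO2 <- compute_sto2(map)
  rp <- relative_params(map, array(0.8, dims), mask)
  expect_equal(rp$rHbO2, 2, tolerance = 1e-12)
  expect_equal(rp$rHb, 1, tolerance = 1e-12)
  expect_equal(rp$rTHC, (2 * 20 + 10) / (20 + 10), tolerance = 1e-12)
  # identity: rStO2 = rHbO2 / rTHC to machine precision
  expect_equal(rp$rStO2, rp$rHbO2 / rp$rTHC, tolerance = 1e-15)
})

test_that("cohort-rendered ratios are recovered within 2 percent, noise-free", {
  co <- generate_cohort(cohort_config(n_subjects = 4, seed = 23))
  for (i in seq_len(4)) {
    s <- co[i, ]
    ph <- render_phantom(s, mua_sigma = 0)
    cm <- fit_chromophores(ph$vols, default_extinction())
    attn <- pmax(cm$THC - median(cm$THC), 0)
    tm <- grow_tumor_region(attn, seed_box(dim(attn), round(ph$center_mm), 4))
    rp <- relative_params(cm, ph$vols$musp, tm)
    expect_lt(abs(rp$rStO2 / s$rStO2 - 1), 0.02)
    expect_lt(abs(rp$rTHC / s$rTHC - 1), 0.02)
    expect_lt(abs(rp$rHbO2 / s$rHbO2 - 1), 0.02)
    expect_lt(abs(rp$rHb / s$rHb - 1), 0.02)
    expect_lt(abs(rp$rmusp / s$rmusp - 1), 0.02)
  }
})

test_that("a full-grid mask is a geometry error", {
  dims <- c(6, 6, 6)
  map <- list(HbO2 = array(20, dims), Hb = array(10, dims),
              THC = array(30, dims))
  map$StO2 <- compute_sto2(map)
  expect_error(relative_params(map, array(0.8, dims), array(TRUE, dims)),
               class = "dothisto_geometry")
})
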