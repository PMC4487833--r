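# Stain optics, artifact exclusion, nuclei, vessels, compactness

test_that("optical density follows its defining decades", {
  rgb <- array(255, c(2, 3, 3))
  rgb[1, 2, ] <- 25.5   # one decade down in all channels
  img <- slide_image(rgb, scale = 0.5)
  od <- rgb_to_od(img)
  expect_equal(od[1, 1, ], c(0, 0, 0))
  expect_equal(od[1, 2, ], c(1, 1, 1), tolerance = 1e-3)
})

test_that("a pure-DAB pixel has its OD vector along the DAB stain axis", {
  st <- stain_vectors()
  hema <- matrix(0, 4, 4); dab <- matrix(0, 4, 4)
  dab[2, 2] <- 0.8
  img <- compose_slide(hema, dab, stains = st)
  od <- rgb_to_od(img)
  v <- od[2, 2, ]
  angle <- acos(sum(v * st[, "dab"]) /
                  sqrt(sum(v^2))) * 180 / pi
  expect_lt(angle, 2)
})

test_that("stain deconvolution separates mixed pixels", {
  hema <- matrix(0, 5, 5); dab <- matrix(0, 5, 5)
  hema[2, 2] <- 0.7; dab[3, 3] <- 0.5
  hema[4, 4] <- 0.6; dab[4, 4] <- 0.4
  conc <- stain_deconvolve(rgb_to_od(compose_slide(hema, dab)))
  expect_equal(conc$hematoxylin[2, 2], 0.7, tolerance = 0.02)
  expect_equal(conc$dab[3, 3], 0.5, tolerance = 0.02)
  expect_equal(conc$hematoxylin[4, 4], 0.6, tolerance = 0.02)
  expect_equal(conc$dab[4, 4], 0.4, tolerance = 0.02)
  expect_lt(conc$dab[2, 2], 0.05)
})

test_that("dark-artifact masking counts blobs and respects the size filter", {
  rgb <- array(230, c(100, 100, 3))
  paint_disc <- function(rgb, cy, cx, r, val) {
    for (dy in -r:r) for (dx in -r:r) {
      if (dy^2 + dx^2 <= r^2) rgb[cy + dy, cx + dx, ] <- val
    }
    rgb
  }
  img0 <- slide_image(rgb, scale = 0.5)
  expect_equal(sum(flag_dark_artifacts(img0)), 0)
  # three blobs above the 200 um^2 floor (r = 18 px -> ~254 um^2)
  rgb <- paint_disc(rgb, 25, 25, 18, 5)
  rgb <- paint_disc(rgb, 25, 75, 18, 5)
  rgb <- paint_disc(rgb, 75, 50, 18, 5)
  # one below it (r = 8 px -> ~50 um^2)
  rgb <- paint_disc(rgb, 75, 85, 8, 5)
  m <- flag_dark_artifacts(slide_image(rgb, scale = 0.5))
  lab <- EBImage::bwlabel(m)
  expect_equal(max(lab), 3)
  expect_false(m[75, 85])
})

test_that("a blank ROI yields zero nuclei rather than an error", {
  img <- compose_slide(matrix(0, 60, 60), matrix(0, 60, 60))
  nuc <- detect_nuclei(rgb_to_od(img), rect_roi(5, 55, 5, 55), img$scale)
  expect_equal(nrow(nuc), 0)
})

test_that("rendered nuclei are re-counted and re-classified accurately", {
  # 200 non-touching nuclei, 30 of them positive (15 %)
  s <- make_subject(Ki67_T = 15, Ki67_N = 0)
  lay <- slide_layout(n_nuclei_tumor = 200, n_nuclei_normal = 10,
                      n_artifacts = 0)
  sl <- render_slide(s, lay, seed = 17)
  od <- rgb_to_od(sl$image)
  conc <- stain_deconvolve(od)
  cls <- vapply(sl$rois, function(r) r$tissue_class, character(1))
  nuc <- do.call(rbind, lapply(sl$rois[cls == "tumor"], function(roi)
    detect_nuclei(od, roi, sl$image$scale, conc = conc)))
  expect_lt(abs(nrow(nuc) - 200), 3)
  expect_lt(abs(sum(nuc$positive) - 30), 2)
})

test_that("nuclei under the artifact mask are excluded from counts", {
  s <- make_subject()
  lay <- slide_layout(width_px = 512, height_px = 384,
                      n_nuclei_tumor = 40, n_nuclei_normal = 10,
                      n_artifacts = 0)
  sl <- render_slide(s, lay, seed = 19)
  od <- rgb_to_od(sl$image)
  roi <- sl$rois[[1]]
  n0 <- nrow(detect_nuclei(od, roi, sl$image$scale))
  # blanket half of the ROI with a fake artifact mask
  art <- matrix(FALSE, dim(od)[1], dim(od)[2])
  art[1:192, 1:256] <- TRUE
  n1 <- nrow(detect_nuclei(od, roi, sl$image$scale, artifact_mask = art))
  expect_lt(n1, n0)
})

test_that("Ki67 percentages follow the area-weighted ROI average", {
  mk_nuc <- function(n, pos) data.frame(positive = seq_len(n) <= pos)
  expect_equal(ki67_percent(list(list(area_um2 = 50,
                                      nuclei = mk_nuc(20, 3)))), 15.0)
  two <- list(list(area_um2 = 100, nuclei = mk_nuc(10, 1)),   # 10 %
              list(area_um2 = 300, nuclei = mk_nuc(10, 3)))   # 30 %
  expect_equal(ki67_percent(two), 25.0)
  expect_equal(ki67_percent(list(list(area_um2 = 10,
                                      nuclei = mk_nuc(5, 0)))), 0.0)
  expect_true(is_undefined(ki67_percent(list(list(area_um2 = 10,
                                                  nuclei = mk_nuc(0, 0))))))
})

test_that("Ki67 percent is invariant under ROI subdivision", {
  set.seed(4)
  nuc <- data.frame(positive = runif(60) < 0.3)
  whole <- list(list(area_um2 = 500, nuclei = nuc))
  halves <- list(list(area_um2 = 250, nuclei = nuc[1:30, , drop = FALSE]),
                 list(area_um2 = 250, nuclei = nuc[31:60, , drop = FALSE]))
  expect_equal(ki67_percent(whole), ki67_percent(halves), tolerance = 1e-12)
})

test_that("relative Ki67 handles identity, arithmetic and missing normal expression", {
  expect_equal(relative_ki67(12, 12), 1.0)
  expect_equal(relative_ki67(20, 5), 4.0)
  expect_true(is_undefined(relative_ki67(20, 0)))
})

test_that("a rendered annulus is one closed vessel with the analytic area", {
  # outer radius 20 um at 0.5 um/px
  n <- 140; cx <- 70
  d2 <- outer((1:n - cx)^2, (1:n - cx)^2, "+")
  dab <- matrix(0, n, n)
  dab[d2 <= 40^2 & d2 >= 34^2] <- 0.9
  img <- compose_slide(matrix(0, n, n), dab)
  v <- detect_vessels(rgb_to_od(img), rect_roi(2, 138, 2, 138), img$scale)
  expect_equal(nrow(v$detections), 1)
  expect_true(v$detections$closed[1])
  expect_lt(abs(v$detections$vessel_area_um2[1] / (pi * 20^2) - 1), 0.05)
  expect_equal(v$n_closed, 1)
})

test_that("an open arc is detected but excluded from vessel metrics", {
  n <- 140; cx <- 70
  xx <- outer(rep(1, n), 1:n) - cx
  yy <- outer(1:n, rep(1, n)) - cx
  d2 <- xx^2 + yy^2
  ang <- atan2(yy, xx)
  dab <- matrix(0, n, n)
  dab[d2 <= 40^2 & d2 >= 34^2 & abs(ang) > 0.2 * pi] <- 0.9 # 20 % gap
  img <- compose_slide(matrix(0, n, n), dab)
  v <- detect_vessels(rgb_to_od(img), rect_roi(2, 138, 2, 138), img$scale)
  expect_equal(nrow(v$detections), 1)
  expect_false(v$detections$closed[1])
  expect_equal(v$n_closed, 0)
  expect_equal(as.numeric(v$mvd), 0)
  expect_true(is_undefined(v$mva))
})

test_that("an empty ROI yields zero vessel density", {
  img <- compose_slide(matrix(0, 60, 60), matrix(0, 60, 60))
  v <- detect_vessels(rgb_to_od(img), rect_roi(5, 55, 5, 55), img$scale)
  expect_equal(nrow(v$detections), 0)
  expect_equal(as.numeric(v$mvd), 0)
})

test_that("vessel metrics are invariant to 90-degree rotation and scale like um^2", {
  n <- 120
  d2 <- outer((1:n - 40)^2, (1:n - 70)^2, "+")
  dab <- matrix(0, n, n)
  dab[d2 <= 30^2 & d2 >= 24^2] <- 0.9
  img <- compose_slide(matrix(0, n, n), dab)
  roi <- rect_roi(2, 118, 2, 118)
  v1 <- detect_vessels(rgb_to_od(img), roi, 0.5)
  rot <- img$rgb
  rot <- aperm(rot, c(2, 1, 3))[n:1, , , drop = FALSE] # rotate 90 degrees
  v2 <- detect_vessels(rgb_to_od(slide_image(rot, 0.5)), roi, 0.5)
  expect_equal(v1$detections$vessel_area_um2, v2$detections$vessel_area_um2,
               tolerance = 1e-9)
  v4 <- detect_vessels(rgb_to_od(img), roi, 1.0)
  expect_equal(v4$detections$vessel_area_um2,
               4 * v1$detections$vessel_area_um2, tolerance = 1e-9)
})

test_that("compactness closed forms: circle unity, square pi/4, ellipse oracle", {
  expect_equal(compactness(pi * 3^2, 2 * pi * 3), 1, tolerance = 1e-15)
  expect_equal(compactness(2.5^2, 4 * 2.5), pi / 4, tolerance = 1e-15)
  # 2:1 ellipse against the numerically exact arc-length perimeter
  th <- seq(0, 2 * pi, length.out = 20001)[-20001]
  c_poly <- polygon_compactness(2 * cos(th), sin(th))
  c_exact <- 4 * pi * (pi * 2) / ellipse_perimeter_exact(2, 1)^2
  expect_equal(c_poly, c_exact, tolerance = 5e-4)
  expect_equal(round(c_poly, 3), round(c_exact, 3))
})

test_that("compactness decreases with ellipse elongation and caps at unity", {
  qs <- c(1, 0.8, 0.6, 0.4, 0.2)
  cs <- vapply(qs, dothisto:::ellipse_compactness, numeric(1))
  expect_true(all(diff(cs) < 0))
  expect_equal(cs[1], 1, tolerance = 1e-12)
  # raster discs stay near/below unity with the smoothed-contour perimeter
  for (r in c(6, 10, 16)) {
    m <- raster_ellipse(r, r)
    oc <- EBImage::ocontour(EBImage::Image(m * 1))[[1]]
    p <- dothisto:::contour_perimeter(oc)
    expect_lt(abs(4 * pi * sum(m) / p^2 - 1), 0.06)
  }
})

test_that("nuclear compactness aggregates per-nucleus values", {
  nuc <- data.frame(area_um2 = c(pi * 9, 16), perimeter_um = c(2 * pi * 3, 16))
  nc <- nuclear_compactness(nuc[, c("area_um2", "perimeter_um")])
  expect_equal(nc$per_nucleus, c(1, pi / 4), tolerance = 1e-12)
  expect_equal(nc$mean, (1 + pi / 4) / 2, tolerance = 1e-12)
  expect_true(is_undefined(nuclear_compactness(nuc[0, ])$mean))
})
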