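# Shared fixtures and independent oracles used across test files.

# a one-row "subject" with explicit truth values (bypasses the copula)
make_subject <- function(rStO2 = 1.1, rTHC = 1.6, rBF = 2, rmusp = 1.2,
                         Ki67_T = 12, Ki67_N = 3, MVA = 700, MVD = 1.5e-4,
                         compact_T = 0.72, compact_N = 0.85,
                         center = c(0, 0, 0), axes = c(7, 7, 7),
                         HbO2_N = 20, Hb_N = 10) {
  rHbO2 <- rStO2 * rTHC
  rHb <- (rTHC * (HbO2_N + Hb_N) - rHbO2 * HbO2_N) / Hb_N
  data.frame(subject_id = "T001",
             rStO2 = rStO2, rTHC = rTHC, rHbO2 = rHbO2, rHb = rHb,
             rBF = rBF, rmusp = rmusp,
             Ki67_T = Ki67_T, Ki67_N = Ki67_N, Ki67_N_latent = Ki67_N,
             has_normal_ki67 = Ki67_N > 0,
             MVA_true = MVA, MVD_true = MVD,
             compact_T = compact_T, compact_N = compact_N,
             center_dx = center[1], center_dy = center[2],
             center_dz = center[3],
             ax_a = axes[1], ax_b = axes[2], ax_c = axes[3])
}

# independent brute-force two-sided permutation p-value for a correlation
# (recursive enumeration; deliberately a different algorithm from the
# package's Heap's-method enumerator)
brute_perm_p <- function(x, y) {
  all_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  cx <- x - mean(x); cy <- y - mean(y)
  obs <- abs(sum(cx * cy))
  ps <- all_perms(seq_along(y))
  mean(vapply(ps, function(p) abs(sum(cx * cy[p])) >= obs - 1e-12,
              logical(1)))
}

# rasterize an axis-aligned ellipse mask (pixel centers at integers)
raster_ellipse <- function(a, b, theta = 0, pad = 6) {
  n <- 2 * ceiling(max(a, b)) + 2 * pad + 1
  cx <- (n + 1) / 2
  xx <- outer(rep(1, n), seq_len(n)) - cx
  yy <- outer(seq_len(n), rep(1, n)) - cx
  xr <- (xx * cos(theta) + yy * sin(theta)) / a
  yr <- (-xx * sin(theta) + yy * cos(theta)) / b
  (xr^2 + yr^2) <= 1
}

# exact ellipse circumference by numerical quadrature of the arc length
ellipse_perimeter_exact <- function(a, b) {
  4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                       0, pi / 2, rel.tol = 1e-12)$value
}

# compose a slide_image directly from stain amount matrices (noise-free)
compose_slide <- function(hema, dab, scale = 0.5,
                          stains = stain_vectors()) {
  H <- nrow(hema); W <- ncol(hema)
  rgb <- array(0, c(H, W, 3))
  for (c3 in 1:3) {
    od_c <- hema * stains[c3, 1] + dab * stains[c3, 2]
    rgb[, , c3] <- pmin(pmax(round(255 * 10^(-od_c)), 0), 255)
  }
  slide_image(rgb, scale)
}

rect_roi <- function(x0, x1, y0, y1, tissue_class = "tumor") {
  roi_annotation(cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1)),
                 tissue_class)
}

# isotropic 3-D Gaussian blob on a cubic grid
gaussian_blob <- function(dims = c(41, 41, 41), sigma = 4, peak = 1,
                          center = (dims + 1) / 2) {
  x <- seq_len(dims[1]); y <- seq_len(dims[2]); z <- seq_len(dims[3])
  r2 <- outer(outer((x - center[1])^2, (y - center[2])^2, "+"),
              (z - center[3])^2, "+")
  peak * exp(-r2 / (2 * sigma^2))
}
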