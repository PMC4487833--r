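# Synthetic cohort: latent truth sampling and raw-data rendering --------------

latent_names <- c("rStO2", "rTHC", "rBF", "rmusp", "Ki67_T", "Ki67_N",
                  "MVA", "MVD", "compact_T", "compact_N")

#' Default latent correlation structure
#'
#' Correlations among the primary latent drivers, chosen to mimic the sign
#' pattern of the optical-histological associations the pipeline is built to
#' detect: tissue oxygenation with tumor proliferation (0.9), total
#' hemoglobin and scattering with mean vessel area, oxygenation with nuclear
#' compactness, and blood flow with proliferation.  Unnamed pairs are
#' uncorrelated.
#'
#' @return 10 x 10 positive-semi-definite correlation matrix over
#'   `rStO2, rTHC, rBF, rmusp, Ki67_T, Ki67_N, MVA, MVD, compact_T, compact_N`.
#' @export
default_latent_corr <- function() {
  k <- length(latent_names)
  m <- diag(k)
  dimnames(m) <- list(latent_names, latent_names)
  set_pair <- function(m, a, b, r) {
    m[a, b] <- m[b, a] <- r
    m
  }
  m <- set_pair(m, "rStO2", "Ki67_T", 0.9)
  m <- set_pair(m, "rTHC", "MVA", 0.6)
  m <- set_pair(m, "rmusp", "MVA", 0.45)
  m <- set_pair(m, "rTHC", "rmusp", 0.35)
  m <- set_pair(m, "rStO2", "compact_T", 0.30)
  m <- set_pair(m, "rBF", "Ki67_T", 0.20)
  m
}

default_marginals <- function() {
  # truncated-normal marginals (mean, sd, lower, upper) per latent; near-
  # linear transforms of the Gaussian drivers so designed correlations carry
  # through to the rendered parameters with little attenuation
  list(
    rStO2     = c(1.08, 0.06, 0.85, 1.35),
    rTHC      = c(1.60, 0.25, 1.05, 2.60),
    rBF       = c(2.20, 0.80, 0.60, 5.50),
    rmusp     = c(1.15, 0.12, 0.75, 1.70),
    Ki67_T    = c(12.0, 6.00, 0.05, 35.0),
    Ki67_N    = c(2.50, 1.80, 0.05, 9.00),
    MVA       = c(700, 220, 150, 1800),
    MVD       = c(1.5e-4, 5e-5, 5e-5, 3e-4),
    compact_T = c(0.72, 0.06, 0.45, 0.92),
    compact_N = c(0.85, 0.04, 0.55, 0.97)
  )
}

qtruncnorm <- function(u, mean, sd, lower, upper) {
  fa <- pnorm((lower - mean) / sd)
  fb <- pnorm((upper - mean) / sd)
  mean + sd * qnorm(fa + u * (fb - fa))
}

ptruncnorm <- function(q, mean, sd, lower, upper) {
  fa <- pnorm((lower - mean) / sd)
  fb <- pnorm((upper - mean) / sd)
  p <- (pnorm((q - mean) / sd) - fa) / (fb - fa)
  pmin(pmax(p, 0), 1)
}

#' Cohort configuration
#'
#' @param n_subjects number of subjects (21 by default, the size of the
#'   tissue cohort the pipeline emulates).
#' @param latent_corr symmetric positive-semi-definite correlation matrix
#'   over the ten latent drivers (see [default_latent_corr()]).
#' @param normal_ref normal-tissue reference values:
#'   `HbO2_N` (uM), `Hb_N` (uM), `musp_N` (mm^-1), `BFI_N` (cm^2/s).
#'   Plausible normal-breast values; pure defaults, flagged as placeholders
#'   (absolute normal-breast hemoglobin is not an output of the ratio-based
#'   analysis).
#' @param noise rendering noise scales: `mua_sigma` (mm^-1, additive on
#'   absorption volumes), `g2_sigma` (additive on autocorrelation curves),
#'   `slide_jitter` (relative jitter of stain amounts).
#' @param p_no_normal_ki67 probability that a subject shows no Ki67
#'   expression in normal tissue (such subjects drop out of relative-Ki67
#'   analyses; 0.5 mirrors the 9-of-18 split of the emulated cohort).
#' @param marginals list of `c(mean, sd, lower, upper)` truncated-normal
#'   marginal parameters per latent.
#' @param seed integer master seed; all randomness flows from it through a
#'   hierarchical sub-stream scheme (subject index x modality).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 21,
                          latent_corr = default_latent_corr(),
                          normal_ref = list(HbO2_N = 20, Hb_N = 10,
                                            musp_N = 0.8, BFI_N = 1e-8),
                          noise = list(mua_sigma = 1e-4, g2_sigma = 0.005,
                                       slide_jitter = 0.05),
                          p_no_normal_ki67 = 0.5,
                          marginals = default_marginals(),
                          seed = 1L) {
  dh_assert(is_count(n_subjects), "dothisto_config",
            "n_subjects must be a positive integer")
  latent_corr <- as.matrix(latent_corr)
  dh_assert(identical(dim(latent_corr), c(10L, 10L)),
            "dothisto_config", "latent_corr must be 10 x 10")
  dh_assert(max(abs(latent_corr - t(latent_corr))) < 1e-12,
            "dothisto_config", "latent_corr must be symmetric")
  dh_assert(max(abs(diag(latent_corr) - 1)) < 1e-12, "dothisto_config",
            "latent_corr must have unit diagonal")
  ev <- eigen(latent_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    dh_error("dothisto_config",
             sprintf("latent_corr is not positive semi-definite (eigenvalue %.4g)",
                     min(ev)),
             eigenvalue = min(ev))
  }
  for (nm in c("HbO2_N", "Hb_N", "musp_N", "BFI_N")) {
    dh_assert(is_number(normal_ref[[nm]]) && normal_ref[[nm]] > 0,
              "dothisto_config",
              paste("normal_ref$", nm, " must be strictly positive", sep = ""))
  }
  dh_assert(all(names(default_marginals()) %in% names(marginals)),
            "dothisto_config", "marginals must cover all ten latents")
  structure(list(n_subjects = as.integer(n_subjects),
                 latent_corr = latent_corr, normal_ref = normal_ref,
                 noise = noise, p_no_normal_ki67 = p_no_normal_ki67,
                 marginals = marginals, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a cohort of subjects with known latent truth
#'
#' Samples the ten primary latents from a Gaussian copula with the
#' configured correlation matrix and truncated-normal marginals, then
#' derives the algebraically dependent quantities: `rHbO2 = rStO2 * rTHC`
#' and `rHb = (rTHC * THC_N - rHbO2 * HbO2_N) / Hb_N`, so that
#' `rTHC = (rHbO2 HbO2_N + rHb Hb_N) / (HbO2_N + Hb_N)` and
#' `rStO2 = rHbO2 / rTHC` hold exactly (the saturation and total-hemoglobin
#' ratios are never free parameters).  Tumor geometry (ellipsoid center
#' offset and semi-axes, mm) is drawn per subject.
#'
#' @param config a [cohort_config()].
#' @return `data.frame` of class `subject_cohort`, one row per subject, with
#'   the latent drivers, derived ratios, geometry, and a
#'   `has_normal_ki67` flag; the Gaussian driver matrix is attached as
#'   attribute `"drivers"` and the configuration as `"config"`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  dh_assert(inherits(config, "cohort_config"), "dothisto_config",
            "config must be a cohort_config")
  n <- config$n_subjects
  with_seed(substream_seed(config$seed, 0L, 1L), {
    eg <- eigen(config$latent_corr, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    A <- eg$vectors %*% diag(sqrt(lam))
    Z <- matrix(rnorm(n * 10), n, 10) %*% t(A)
    colnames(Z) <- latent_names
    U <- pnorm(Z)
    X <- vapply(latent_names, function(nm) {
      p <- config$marginals[[nm]]
      qtruncnorm(U[, nm], p[1], p[2], p[3], p[4])
    }, numeric(n))
    if (n == 1) X <- matrix(X, 1, dimnames = list(NULL, latent_names))
    X <- as.data.frame(X)
    has_norm <- runif(n) >= config$p_no_normal_ki67
    center <- matrix(runif(3 * n, -3, 3), n, 3)
    axes <- matrix(runif(3 * n, 5, 9), n, 3)
  })
  ref <- config$normal_ref
  thc_n <- ref$HbO2_N + ref$Hb_N
  rhbo2 <- X$rStO2 * X$rTHC
  rhb <- (X$rTHC * thc_n - rhbo2 * ref$HbO2_N) / ref$Hb_N
  dh_assert(all(rhb > 0), "dothisto_config",
            "marginals imply non-positive tumor deoxyhemoglobin")
  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    rStO2 = X$rStO2, rTHC = X$rTHC, rHbO2 = rhbo2, rHb = rhb,
    rBF = X$rBF, rmusp = X$rmusp,
    Ki67_T = X$Ki67_T,
    Ki67_N = ifelse(has_norm, X$Ki67_N, 0),
    Ki67_N_latent = X$Ki67_N,
    has_normal_ki67 = has_norm,
    MVA_true = X$MVA, MVD_true = X$MVD,
    compact_T = X$compact_T, compact_N = X$compact_N,
    center_dx = center[, 1], center_dy = center[, 2], center_dz = center[, 3],
    ax_a = axes[, 1], ax_b = axes[, 2], ax_c = axes[, 3]
  )
  attr(out, "drivers") <- Z
  attr(out, "config") <- config
  class(out) <- c("subject_cohort", "data.frame")
  out
}

#' @export
print.subject_cohort <- function(x, ...) {
  cat("synthetic cohort:", nrow(x), "subjects\n")
  print.data.frame(head(as.data.frame(x)[, c("subject_id", "rStO2", "rTHC",
                                             "rHbO2", "rHb", "rBF",
                                             "Ki67_T", "Ki67_N")]),
                   digits = 3)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

# Phantom rendering -------------------------------------------------------------

#' Voxel grid geometry for phantom rendering
#' @param dims integer length-3 voxel counts.
#' @param voxel_mm voxel edge length(s) in mm.
#' @export
phantom_grid <- function(dims = c(48, 48, 48), voxel_mm = 1) {
  voxel_mm <- rep(voxel_mm, length.out = 3)
  dh_assert(all(dims >= 8) && all(voxel_mm > 0), "dothisto_geometry",
            "grid must have >= 8 voxels per axis and positive voxel size")
  list(dims = as.integer(dims), voxel_mm = voxel_mm)
}

#' Render a multi-wavelength absorption phantom for one subject
#'
#' Builds 3-D oxy/deoxyhemoglobin concentration fields: normal background at
#' the reference concentrations, an ellipsoidal tumor carrying the subject's
#' tumor-to-normal contrast, blended into the background by a Gaussian edge
#' profile in the distance from the ellipsoid surface (so the half-maximum
#' contour of the contrast has an analytic location).  Absorption at each
#' wavelength is the exact spectral Beer mix
#' `mu_a = eps_HbO2 * HbO2 + eps_Hb * Hb` plus optional Gaussian noise, and
#' reduced scattering carries the `rmusp` contrast with the same profile.
#'
#' @param subject one row of a [generate_cohort()] data frame.
#' @param grid a [phantom_grid()].
#' @param ext an [extinction_table()].
#' @param normal_ref normal-tissue reference list (see [cohort_config()]).
#' @param mua_sigma additive absorption noise (mm^-1).
#' @param blend_sigma Gaussian edge width (mm).
#' @param seed integer seed for the noise.
#' @return List of class `phantom`: `vols` ([absorption_volumes()]),
#'   `truth_mask` (the analytic half-maximum-contrast region), concentration
#'   fields `hbo2`, `hb`, `musp`, the blend profile `f`, and the geometry.
#' @export
render_phantom <- function(subject, grid = phantom_grid(),
                           ext = default_extinction(),
                           normal_ref = list(HbO2_N = 20, Hb_N = 10,
                                             musp_N = 0.8, BFI_N = 1e-8),
                           mua_sigma = 0, blend_sigma = 0.3, seed = 1L) {
  dims <- grid$dims; vx <- grid$voxel_mm
  ext_mm <- dims * vx
  center <- ext_mm / 2 + c(subject$center_dx, subject$center_dy,
                           subject$center_dz)
  axes <- c(subject$ax_a, subject$ax_b, subject$ax_c)
  g <- prod(axes)^(1 / 3) # surface-distance scale (exact for a sphere)
  d_half <- blend_sigma * sqrt(2 * log(2))
  u_half <- 1 + d_half / g
  lo <- center - axes * u_half
  hi <- center + axes * u_half
  if (any(lo < 0) || any(hi > ext_mm)) {
    dh_error("dothisto_geometry",
             "tumor ellipsoid (with half-maximum halo) extends outside the grid")
  }
  x <- (seq_len(dims[1]) - 0.5) * vx[1]
  y <- (seq_len(dims[2]) - 0.5) * vx[2]
  z <- (seq_len(dims[3]) - 0.5) * vx[3]
  u2 <- outer(outer(((x - center[1]) / axes[1])^2,
                    ((y - center[2]) / axes[2])^2, "+"),
              ((z - center[3]) / axes[3])^2, "+")
  u <- sqrt(u2)
  f <- array(1, dims)
  outside <- u > 1
  f[outside] <- exp(-((u[outside] - 1) * g)^2 / (2 * blend_sigma^2))
  truth_mask <- u <= u_half

  hbo2_t <- subject$rHbO2 * normal_ref$HbO2_N
  hb_t <- subject$rHb * normal_ref$Hb_N
  hbo2 <- normal_ref$HbO2_N + (hbo2_t - normal_ref$HbO2_N) * f
  hb <- normal_ref$Hb_N + (hb_t - normal_ref$Hb_N) * f
  musp <- normal_ref$musp_N * (1 + (subject$rmusp - 1) * f)

  mua <- with_seed(substream_seed(seed, 0L, 2L), {
    lapply(seq_len(nrow(ext)), function(i) {
      m <- ext$eps_hbo2[i] * hbo2 + ext$eps_hb[i] * hb
      if (mua_sigma > 0) m <- m + array(rnorm(length(m), 0, mua_sigma), dims)
      m
    })
  })
  vols <- absorption_volumes(mua, musp, ext$wavelength_nm, vx)
  structure(list(vols = vols, truth_mask = truth_mask,
                 hbo2 = hbo2, hb = hb, musp = musp, f = f,
                 center_mm = center, axes_mm = axes, u_half = u_half,
                 grid = grid),
            class = "phantom")
}

# DCS scan simulation ----------------------------------------------------------

#' Simulate a DCS line scan across the tumor
#'
#' Generates autocorrelation curves for `n_points` probe positions spaced
#' along a line straddling the tumor: a contiguous central block of
#' positions is labelled tumor (blood flow index `rBF * BFI_N`), the rest
#' normal (`BFI_N`), each rendered through the semi-infinite correlation
#' diffusion forward model [g2_model()] with additive Gaussian noise.
#'
#' @param subject one cohort row (uses `rBF`).
#' @param optics a [tissue_optics()].
#' @param bfi_n normal-tissue blood flow index (cm^2/s).
#' @param n_points number of scan positions (10-12 in practice).
#' @param n_tumor number of contiguous tumor-labelled positions.
#' @param tau delay grid (s).
#' @param beta coherence factor used for all curves.
#' @param g2_sigma additive Gaussian noise scale on g2.
#' @param seed integer seed.
#' @return `data.frame` of class `g2_scan` with columns `position_index`,
#'   `label`, `tau_s`, `g2`; true BFI values attached as attribute
#'   `"truth"`.
#' @export
simulate_g2_scan <- function(subject, optics = tissue_optics(),
                             bfi_n = 1e-8, n_points = 11, n_tumor = 3,
                             tau = 10^seq(-6, -2, length.out = 60),
                             beta = 0.5, g2_sigma = 0.005, seed = 1L) {
  dh_assert(is_count(n_points) && n_points >= 4, "dothisto_config",
            "n_points must be an integer >= 4")
  dh_assert(is_count(n_tumor) && n_tumor < n_points, "dothisto_config",
            "n_tumor must be below n_points")
  first_t <- floor((n_points - n_tumor) / 2) + 1
  labels <- rep("normal", n_points)
  labels[first_t:(first_t + n_tumor - 1)] <- "tumor"
  bfi_t <- subject$rBF * bfi_n
  rows <- with_seed(substream_seed(seed, 0L, 3L), {
    lapply(seq_len(n_points), function(i) {
      bfi <- if (labels[i] == "tumor") bfi_t else bfi_n
      g2 <- g2_model(tau, bfi, beta, optics)
      if (g2_sigma > 0) g2 <- g2 + rnorm(length(tau), 0, g2_sigma)
      data.frame(position_index = i, label = labels[i], tau_s = tau, g2 = g2)
    })
  })
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(bfi_tumor = bfi_t, bfi_normal = bfi_n,
                             rbf = subject$rBF, beta = beta)
  class(out) <- c("g2_scan", "data.frame")
  out
}

#' Split a scan data frame into g2_curve objects
#' @param scan a `g2_scan` (or equivalent long-format data frame).
#' @return list of [g2_curve()] objects, one per position.
#' @export
g2_scan_curves <- function(scan) {
  lapply(split(as.data.frame(scan), scan$position_index), function(d) {
    g2_curve(d$tau_s, d$g2, label = d$label[1],
             position_index = d$position_index[1])
  })
}

# Slide rendering ----------------------------------------------------------------

#' Slide layout specification for the IHC renderer
#'
#' @param width_px,height_px canvas size in pixels.
#' @param scale_um_px microns per pixel (0.5 mimics a x20 scan).
#' @param n_nuclei_tumor,n_nuclei_normal nuclei per tissue region.
#' @param open_vessel_frac fraction of vessels rendered as open arcs, which
#'   a closed-cross-section rule must reject (default 0.2).
#' @param n_artifacts near-black dye-cluster blobs added per slide.
#' @param nucleus_radius_um,nucleus_radius_sd mean/SD of the equivalent
#'   nucleus radius (um).
#' @param vessel_wall_um endothelial wall thickness (um).
#' @param artifact_radius_um artifact blob radius (um).
#' @param margin_px placement margin around regions.
#' @param auto_expand grow the canvas for subjects whose elongated nuclei or
#'   large vessels would exceed the non-overlapping packing regime (object
#'   counts and sizes are preserved).  With `FALSE`, such subjects raise a
#'   layout error instead.
#' @export
slide_layout <- function(width_px = 1024, height_px = 640, scale_um_px = 0.5,
                         n_nuclei_tumor = 120, n_nuclei_normal = 80,
                         open_vessel_frac = 0.2, n_artifacts = 3,
                         nucleus_radius_um = 3.5, nucleus_radius_sd = 0.4,
                         vessel_wall_um = 3, artifact_radius_um = 10,
                         margin_px = 8, auto_expand = TRUE) {
  structure(list(width_px = width_px, height_px = height_px,
                 scale_um_px = scale_um_px,
                 n_nuclei_tumor = n_nuclei_tumor,
                 n_nuclei_normal = n_nuclei_normal,
                 open_vessel_frac = open_vessel_frac,
                 n_artifacts = n_artifacts,
                 nucleus_radius_um = nucleus_radius_um,
                 nucleus_radius_sd = nucleus_radius_sd,
                 vessel_wall_um = vessel_wall_um,
                 artifact_radius_um = artifact_radius_um,
                 margin_px = margin_px, auto_expand = auto_expand),
            class = "slide_layout")
}

# rejection-sample non-overlapping disc centers inside [x0,x1] x [y0,y1],
# avoiding a horizontal band (the ROI split line) and previously placed discs
place_discs <- function(n, radii, x0, x1, y0, y1, band = NULL,
                        placed = NULL, max_attempts = 3000) {
  if (n == 0) {
    return(placed %||% data.frame(x = numeric(0), y = numeric(0),
                                  r = numeric(0)))
  }
  region_area <- (x1 - x0) * (y1 - y0)
  new_area <- sum(pi * radii^2)
  old_area <- if (is.null(placed)) 0 else {
    in_region <- placed$x >= x0 & placed$x <= x1 &
      placed$y >= y0 & placed$y <= y1
    sum(pi * placed$r[in_region]^2)
  }
  if ((new_area + old_area) / region_area > 0.50) {
    dh_error("dothisto_layout",
             sprintf("object density %.0f %% exceeds the packing limit",
                     100 * (new_area + old_area) / region_area))
  }
  xs <- if (is.null(placed)) numeric(0) else placed$x
  ys <- if (is.null(placed)) numeric(0) else placed$y
  rs <- if (is.null(placed)) numeric(0) else placed$r
  for (i in seq_len(n)) {
    r <- radii[i]
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      cx <- runif(1, x0 + r, x1 - r)
      cy <- runif(1, y0 + r, y1 - r)
      if (!is.null(band) && cy + r > band[1] && cy - r < band[2]) next
      if (length(xs) &&
          any((xs - cx)^2 + (ys - cy)^2 < (rs + r + 1)^2)) next
      ok <- TRUE
      break
    }
    if (!ok) {
      dh_error("dothisto_layout",
               "could not place objects without overlap (packing limit)")
    }
    xs <- c(xs, cx); ys <- c(ys, cy); rs <- c(rs, r)
  }
  data.frame(x = xs, y = ys, r = rs)
}

# paint an ellipse (or annulus/arc) into amount matrices; returns pixel count
paint_ellipse <- function(canvas, cx, cy, a, b, theta, amount) {
  h <- nrow(canvas); w <- ncol(canvas)
  rmax <- max(a, b)
  cols <- max(1, floor(cx - rmax) + 1):min(w, ceiling(cx + rmax) + 1)
  rows <- max(1, floor(cy - rmax) + 1):min(h, ceiling(cy + rmax) + 1)
  xs <- cols - 1; ys <- rows - 1
  dx <- outer(ys - cy, xs - cx, function(yy, xx) xx)
  dy <- outer(ys - cy, xs - cx, function(yy, xx) yy)
  xr <- (dx * cos(theta) + dy * sin(theta)) / a
  yr <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- xr^2 + yr^2 <= 1
  sub <- canvas[rows, cols]
  sub[inside] <- sub[inside] + amount
  canvas[rows, cols] <- sub
  list(canvas = canvas, n_px = sum(inside))
}

paint_annulus <- function(canvas, cx, cy, r_out, r_in, amount,
                          gap_angle = NULL, gap_width = 0) {
  h <- nrow(canvas); w <- ncol(canvas)
  cols <- max(1, floor(cx - r_out) + 1):min(w, ceiling(cx + r_out) + 1)
  rows <- max(1, floor(cy - r_out) + 1):min(h, ceiling(cy + r_out) + 1)
  xs <- cols - 1; ys <- rows - 1
  dx <- outer(ys, xs, function(yy, xx) xx - cx)
  dy <- outer(ys, xs, function(yy, xx) yy - cy)
  rr <- sqrt(dx^2 + dy^2)
  inside <- rr <= r_out & rr >= r_in
  if (!is.null(gap_angle)) {
    ang <- atan2(dy, dx)
    dd <- abs(((ang - gap_angle + pi) %% (2 * pi)) - pi)
    inside <- inside & dd > gap_width / 2
  }
  sub <- canvas[rows, cols]
  sub[inside] <- sub[inside] + amount
  canvas[rows, cols] <- sub
  canvas
}

#' Render an IHC slide with known ground truth
#'
#' Draws a two-region slide (tumor tissue left, normal tissue right), each
#' covered by two rectangular ROIs.  Nuclei are filled ellipses whose axis
#' ratio realizes the subject's nuclear-compactness latent; negative nuclei
#' carry hematoxylin only, Ki67-positive nuclei hematoxylin plus DAB (exact
#' positive counts are fixed from the subject's Ki67 fractions).  Vessels
#' are DAB-stained annuli with known lumen and wall areas, a configured
#' fraction of them rendered as open arcs that a closed-cross-section rule
#' must reject, and near-black artifact blobs are added.  Pixels follow
#' Beer-Lambert mixing of the two stain vectors in optical density.
#'
#' @param subject one cohort row.
#' @param layout a [slide_layout()].
#' @param stains stain vector matrix.
#' @param slide_jitter relative stain-amount jitter.
#' @param seed integer seed.
#' @return List of class `ihc_slide`: `image` ([slide_image()]), `rois`
#'   (list of [roi_annotation()]), `truth` (per-object data frame plus the
#'   slide-level truth: Ki67 percentages actually drawn, closed-vessel mean
#'   areas, compactness means, artifact count).
#' @export
render_slide <- function(subject, layout = slide_layout(),
                         stains = stain_vectors(), slide_jitter = 0.05,
                         seed = 1L) {
  L <- layout
  s <- L$scale_um_px
  W <- L$width_px; H <- L$height_px; m <- L$margin_px
  # auto-expand the canvas for subjects whose strongly elongated nuclei (or
  # large vessels) would push rejection-sampled placement past its packing
  # regime; object counts and sizes are preserved, only space is added
  halo_nucleus <- function(compact_mean, n) {
    a <- (L$nucleus_radius_um + L$nucleus_radius_sd) / s /
      sqrt(ellipse_axis_ratio(max(compact_mean - 0.08, 0.35)))
    n * pi * (a + 1)^2
  }
  r_v <- sqrt(subject$MVA_true / pi) / s + 4
  halo_t <- halo_nucleus(subject$compact_T, L$n_nuclei_tumor) +
    0.18 * (W / 2 - 2 * m) * (H - 2 * m) + L$n_artifacts * pi *
    (L$artifact_radius_um / s + 2)^2
  halo_n <- halo_nucleus(subject$compact_N, L$n_nuclei_normal)
  region_px <- (W / 2 - 2 * m) * (H - 2 * m)
  f <- max(1, halo_t / (0.36 * region_px), halo_n / (0.36 * region_px))
  if (!isTRUE(L$auto_expand)) f <- 1
  if (f > 1) {
    W <- 2 * ceiling(W * sqrt(f) / 2)
    H <- 2 * ceiling(H * sqrt(f) / 2)
  }
  x_split <- W / 2
  band <- c(H / 2 - 2, H / 2 + 2) # keep objects off the ROI split line
  with_seed(substream_seed(seed, 0L, 4L), {
    hema <- matrix(0, H, W)
    dab <- matrix(0, H, W)
    objects <- list()

    # vessel population (tumor region only): count from the MVD latent,
    # capped by an area budget so vessel-rich, large-vessel subjects still
    # pack on the canvas (MVA stays faithful; MVD saturates at the cap)
    troi_area_px <- (x_split - 2 * m) * (H - 2 * m)
    troi_area_um2 <- troi_area_px * s^2
    r_bar <- sqrt(subject$MVA_true / pi)
    halo_px <- (r_bar / s + 4)^2 * pi
    n_cap <- max(3L, floor(0.18 * troi_area_px / halo_px))
    n_vessels <- max(3L, min(n_cap, round(subject$MVD_true * troi_area_um2)))
    n_open <- round(L$open_vessel_frac * n_vessels)
    r_out_um <- pmin(pmax(rnorm(n_vessels, r_bar, 0.15 * r_bar), 6), 26)
    r_out <- r_out_um / s
    wall <- L$vessel_wall_um / s
    vpos <- place_discs(n_vessels, r_out + 2, m, x_split - m, m, H - m,
                        band = band)
    is_open <- seq_len(n_vessels) <= n_open
    for (i in seq_len(n_vessels)) {
      amt <- 0.9 * (1 + rnorm(1, 0, slide_jitter))
      gap <- if (is_open[i]) runif(1, 0, 2 * pi) else NULL
      dab <- paint_annulus(dab, vpos$x[i], vpos$y[i], r_out[i],
                           max(r_out[i] - wall, 1), amt,
                           gap_angle = gap, gap_width = 2 * pi * 0.2)
      objects[[length(objects) + 1]] <- data.frame(
        class = "vessel", tissue = "tumor", positive = NA,
        x = vpos$x[i], y = vpos$y[i],
        area_um2 = pi * (r_out[i] * s)^2,
        perimeter_um = 2 * pi * r_out[i] * s,
        compactness = NA_real_,
        closed = !is_open[i],
        vessel_area_um2 = pi * (r_out[i] * s)^2,
        vascular_area_um2 = pi * ((r_out[i] * s)^2 -
                                    (max(r_out[i] - wall, 1) * s)^2))
    }

    # artifacts (anywhere on the slide)
    art_r <- L$artifact_radius_um / s
    apos <- place_discs(L$n_artifacts, rep(art_r, L$n_artifacts) + 2,
                        m, W - m, m, H - m, band = band,
                        placed = vpos)
    apos <- tail(apos, L$n_artifacts)
    for (i in seq_len(L$n_artifacts)) {
      res <- paint_ellipse(hema, apos$x[i], apos$y[i], art_r, art_r, 0, 2.2)
      hema <- res$canvas
      res <- paint_ellipse(dab, apos$x[i], apos$y[i], art_r, art_r, 0, 2.2)
      dab <- res$canvas
      objects[[length(objects) + 1]] <- data.frame(
        class = "artifact", tissue = NA, positive = NA,
        x = apos$x[i], y = apos$y[i], area_um2 = pi * (art_r * s)^2,
        perimeter_um = NA_real_, compactness = NA_real_, closed = NA,
        vessel_area_um2 = NA_real_, vascular_area_um2 = NA_real_)
    }

    # nuclei per tissue region with exact positive counts
    draw_nuclei <- function(n, pct_pos, region, compact_mean, placed) {
      k_pos <- round(n * pct_pos / 100)
      r_um <- pmin(pmax(rnorm(n, L$nucleus_radius_um, L$nucleus_radius_sd),
                        2.2), 5.5)
      r_px <- r_um / s
      comp <- pmin(pmax(rnorm(n, compact_mean, 0.04), 0.4), 0.98)
      qv <- vapply(comp, ellipse_axis_ratio, numeric(1))
      pos <- place_discs(n, r_px / sqrt(qv) + 1,
                         region[1], region[2], region[3], region[4],
                         band = band, placed = placed)
      pos <- tail(pos, n)
      is_pos <- seq_len(n) %in% sample.int(n, k_pos)
      rows <- vector("list", n)
      for (i in seq_len(n)) {
        q <- qv[i]
        a <- r_px[i] / sqrt(q); b <- r_px[i] * sqrt(q)
        th <- runif(1, 0, pi)
        amt_h <- 0.8 * (1 + rnorm(1, 0, slide_jitter))
        res <- paint_ellipse(hema, pos$x[i], pos$y[i], a, b, th, amt_h)
        hema <<- res$canvas
        if (is_pos[i]) {
          amt_d <- 0.6 * (1 + rnorm(1, 0, slide_jitter))
          res2 <- paint_ellipse(dab, pos$x[i], pos$y[i], a, b, th, amt_d)
          dab <<- res2$canvas
        }
        rows[[i]] <- data.frame(
          class = "nucleus",
          tissue = if (region[2] <= x_split) "tumor" else "normal",
          positive = is_pos[i], x = pos$x[i], y = pos$y[i],
          area_um2 = pi * a * b * s^2,
          perimeter_um = ellipse_perimeter(a, b) * s,
          compactness = comp[i], closed = NA,
          vessel_area_um2 = NA_real_, vascular_area_um2 = NA_real_)
      }
      list(rows = do.call(rbind, rows), k_pos = k_pos,
           placed = rbind(placed, pos))
    }
    placed <- rbind(vpos, apos)
    tn <- draw_nuclei(L$n_nuclei_tumor, subject$Ki67_T,
                      c(m, x_split - m, m, H - m), subject$compact_T, placed)
    nn <- draw_nuclei(L$n_nuclei_normal, subject$Ki67_N,
                      c(x_split + m, W - m, m, H - m), subject$compact_N,
                      tn$placed)
    objects <- c(objects, list(tn$rows), list(nn$rows))

    # compose RGB through Beer-Lambert OD mixing
    base_od <- 0.012
    rgb <- array(0, c(H, W, 3))
    for (c3 in 1:3) {
      od_c <- hema * stains[c3, 1] + dab * stains[c3, 2] +
        base_od * sum(stains[c3, ])
      I <- 255 * 10^(-od_c) + matrix(rnorm(H * W, 0, 1.2), H, W)
      rgb[, , c3] <- pmin(pmax(round(I), 0), 255)
    }
  })

  pad <- 3
  rect_poly <- function(x0, x1, y0, y1) {
    cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  }
  rois <- list(
    roi_annotation(rect_poly(m - pad, x_split - m + pad, m - pad, H / 2 - 1),
                   "tumor"),
    roi_annotation(rect_poly(m - pad, x_split - m + pad, H / 2 + 1, H - m + pad),
                   "tumor"),
    roi_annotation(rect_poly(x_split + m - pad, W - m + pad, m - pad, H / 2 - 1),
                   "normal"),
    roi_annotation(rect_poly(x_split + m - pad, W - m + pad, H / 2 + 1,
                             H - m + pad), "normal")
  )
  obj <- do.call(rbind, objects)
  closed_v <- obj$class == "vessel" & obj$closed %in% TRUE
  # vessel-area truth follows the measurement convention: per-ROI means,
  # ROI-area-weighted over ROIs that contain closed vessels (the two tumor
  # ROIs split at H/2 and have equal area)
  roi_of <- ifelse(obj$y < H / 2, 1L, 2L)
  roi_mean <- function(v) {
    ms <- vapply(1:2, function(r) {
      sel <- closed_v & roi_of == r
      if (any(sel)) mean(v[sel]) else NA_real_
    }, numeric(1))
    mean(ms, na.rm = TRUE)
  }
  truth <- list(
    ki67_t_pct = 100 * tn$k_pos / layout$n_nuclei_tumor,
    ki67_n_pct = 100 * nn$k_pos / layout$n_nuclei_normal,
    mva = roi_mean(obj$vessel_area_um2),
    mean_vascular_area = roi_mean(obj$vascular_area_um2),
    n_vessels_closed = sum(closed_v),
    n_vessels_open = sum(obj$class == "vessel") - sum(closed_v),
    n_artifacts = sum(obj$class == "artifact"),
    compact_t = mean(obj$compactness[obj$class == "nucleus" &
                                       obj$tissue == "tumor"]),
    compact_n = mean(obj$compactness[obj$class == "nucleus" &
                                       obj$tissue == "normal"])
  )
  structure(list(image = slide_image(rgb, s), rois = rois,
                 objects = obj, truth = truth, layout = layout),
            class = "ihc_slide")
}

#' @export
print.ihc_slide <- function(x, ...) {
  print(x$image)
  cat(sprintf("  truth: Ki67 T %.1f %% / N %.1f %%, %d closed + %d open vessels, %d artifacts\n",
              x$truth$ki67_t_pct, x$truth$ki67_n_pct,
              x$truth$n_vessels_closed, x$truth$n_vessels_open,
              x$truth$n_artifacts))
  invisible(x)
}
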