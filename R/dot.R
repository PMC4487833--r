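# DOT chromophore maps, tumor segmentation and tumor-to-normal ratios ---------

#' Assemble a multi-wavelength absorption volume set
#'
#' Container for reconstructed 3-D absorption volumes (one per wavelength) and
#' the reduced-scattering volume at the reference wavelength.  All grids must
#' be congruent; negative absorption values (reconstruction noise) are clipped
#' to zero and flagged.
#'
#' @param mua named list of 3-D arrays (mm^-1), names = wavelength in nm, or a
#'   list parallel to `wavelengths`.
#' @param musp 3-D array (mm^-1), reduced scattering at the reference
#'   wavelength, congruent with the absorption grids.
#' @param wavelengths numeric, strictly increasing wavelengths (nm).
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @return An object of class `absorption_volumes`.
#' @export
absorption_volumes <- function(mua, musp, wavelengths, voxel_size) {
  dh_assert(is.list(mua) && length(mua) == length(wavelengths),
            "dothisto_geometry", "one absorption grid per wavelength required")
  dh_assert(!is.unsorted(wavelengths, strictly = TRUE), "dothisto_geometry",
            "wavelengths must be strictly increasing")
  dh_assert(length(voxel_size) == 3 && all(voxel_size > 0),
            "dothisto_geometry", "voxel_size must be 3 positive lengths (mm)")
  dims <- dim(mua[[1]])
  dh_assert(length(dims) == 3, "dothisto_geometry", "grids must be 3-D")
  for (g in mua) {
    dh_assert(identical(dim(g), dims), "dothisto_geometry",
              "absorption grids are not congruent")
  }
  dh_assert(identical(dim(musp), dims), "dothisto_geometry",
            "musp grid is not congruent with absorption grids")
  clipped <- FALSE
  mua <- lapply(mua, function(g) {
    if (any(g < 0)) {
      clipped <<- TRUE
      g[g < 0] <- 0
    }
    g
  })
  names(mua) <- as.character(wavelengths)
  structure(list(mua = mua, musp = musp,
                 wavelengths = as.numeric(wavelengths),
                 voxel_size = as.numeric(voxel_size),
                 clipped = clipped),
            class = "absorption_volumes")
}

#' @export
print.absorption_volumes <- function(x, ...) {
  cat("absorption volumes:", paste(dim(x$mua[[1]]), collapse = " x "),
      "voxels,", length(x$wavelengths), "wavelengths (",
      paste(x$wavelengths, collapse = ", "), "nm ),",
      "voxel", paste(x$voxel_size, collapse = " x "), "mm\n")
  invisible(x)
}

# Closed-form non-negative least squares for a 2-column design: if the
# unconstrained solution is infeasible the optimum lies on a boundary, and
# with 2 variables the candidate boundary solutions (one concentration zero)
# can be enumerated exactly.  Vectorized over voxels.
nnls2 <- function(E, Y) {
  EtE <- crossprod(E)
  B <- solve(EtE, crossprod(E, Y)) # unconstrained, 2 x nvox
  bad <- which(B[1, ] < 0 | B[2, ] < 0)
  if (length(bad)) {
    Yb <- Y[, bad, drop = FALSE]
    e1 <- E[, 1]; e2 <- E[, 2]
    c1 <- pmax(0, colSums(e1 * Yb) / sum(e1 * e1)) # Hb = 0 branch
    c2 <- pmax(0, colSums(e2 * Yb) / sum(e2 * e2)) # HbO2 = 0 branch
    y2 <- colSums(Yb^2)
    rss1 <- y2 - 2 * c1 * colSums(e1 * Yb) + c1^2 * sum(e1 * e1)
    rss2 <- y2 - 2 * c2 * colSums(e2 * Yb) + c2^2 * sum(e2 * e2)
    use1 <- rss1 <= rss2
    B[1, bad] <- ifelse(use1, c1, 0)
    B[2, bad] <- ifelse(use1, 0, c2)
  }
  B
}

#' Unmix absorption volumes into chromophore concentration maps
#'
#' Solves, voxel by voxel, the spectral Beer-Lambert system
#' `mu_a(lambda) = eps_HbO2(lambda) * HbO2 + eps_Hb(lambda) * Hb`
#' by least squares with non-negativity constraints on the concentrations
#' (physical default; set `nonneg = FALSE` for the unconstrained diagnostic
#' solution).  Water and lipid are deliberately omitted: only the
#' hemoglobin-derived parameters are carried through the pipeline.
#'
#' @param vols an [absorption_volumes()] object.
#' @param ext an [extinction_table()] covering every wavelength in `vols`.
#' @param nonneg constrain concentrations to be non-negative (default TRUE).
#' @return An object of class `chromophore_map`: 3-D arrays `HbO2`, `Hb`,
#'   `THC` (= HbO2 + Hb, uM), `StO2` (fraction, `NA` where THC is below
#'   tolerance), and `residual` (per-voxel spectral residual norm, mm^-1).
#' @export
fit_chromophores <- function(vols, ext, nonneg = TRUE) {
  dh_assert(inherits(vols, "absorption_volumes"), "dothisto_geometry",
            "vols must be an absorption_volumes object")
  dh_assert(inherits(ext, "extinction_table"), "dothisto_spectral_design",
            "ext must be an extinction_table")
  idx <- match(vols$wavelengths, ext$wavelength_nm)
  dh_assert(!anyNA(idx), "dothisto_spectral_design",
            paste("extinction table lacks wavelengths:",
                  paste(vols$wavelengths[is.na(idx)], collapse = ", ")))
  E <- as.matrix(ext[idx, c("eps_hbo2", "eps_hb")])
  dims <- dim(vols$mua[[1]])
  Y <- do.call(rbind, lapply(vols$mua, as.vector)) # nlambda x nvox
  B <- if (nonneg) nnls2(E, Y) else solve(crossprod(E), crossprod(E, Y))
  res <- sqrt(colSums((E %*% B - Y)^2))
  hbo2 <- array(B[1, ], dims)
  hb <- array(B[2, ], dims)
  out <- structure(list(HbO2 = hbo2, Hb = hb, THC = hbo2 + hb,
                        StO2 = NULL, residual = array(res, dims),
                        voxel_size = vols$voxel_size),
                   class = "chromophore_map")
  out$StO2 <- compute_sto2(out)
  out
}

#' @export
print.chromophore_map <- function(x, ...) {
  cat("chromophore map:", paste(dim(x$HbO2), collapse = " x "), "voxels\n")
  cat(sprintf("  HbO2 %.2f uM, Hb %.2f uM, StO2 %.3f (volume means)\n",
              mean(x$HbO2), mean(x$Hb), mean(x$StO2, na.rm = TRUE)))
  invisible(x)
}

#' Tissue oxygen saturation map from a chromophore map
#'
#' `StO2 = HbO2 / (HbO2 + Hb)` wherever total hemoglobin exceeds `tol`;
#' voxels with no appreciable hemoglobin are masked `NA` (the saturation is
#' undefined there, and masking prevents 0/0 propagation).
#'
#' @param map a `chromophore_map`.
#' @param tol total-hemoglobin tolerance (uM) below which StO2 is undefined.
#' @return 3-D array of saturations in `[0, 1]` with `NA` where undefined and
#'   an `undefined_mask` attribute (logical array).
#' @export
compute_sto2 <- function(map, tol = 1e-3) {
  thc <- map$HbO2 + map$Hb
  undef <- !(thc > tol)
  sto2 <- map$HbO2 / thc
  sto2[undef] <- NA_real_
  attr(sto2, "undefined_mask") <- undef
  sto2
}

neighbor_offsets <- function(connectivity) {
  stopifnot(connectivity %in% c(6, 26))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  off
}

#' Grow the tumor region from the attenuation maximum with a half-maximum cutoff
#'
#' Finds the maximum-intensity voxel of `attn` inside the seed hint region
#' (the hint mirrors selecting an approximate tumor location on radiological
#' images), then grows a 3-D region: the connected component containing the
#' seed of all voxels with `attn >= cutoff * attn(seed)`.  The threshold is
#' taken relative to the seed maximum (full width at half maximum for the
#' default `cutoff = 0.5`), not referenced to background.  Ties for the
#' maximum resolve to the lowest linear index, deterministically.
#'
#' @param attn 3-D array, typically the absorption volume at 786 nm.
#' @param seed_hint logical array congruent with `attn` marking the search
#'   region for the seed (e.g. from [seed_box()]).
#' @param cutoff fraction of the seed intensity defining the region (0.5 =
#'   half maximum).
#' @param connectivity 26 (default) or 6 neighborhood.
#' @return Object of class `tumor_mask`: logical array `mask`, `seed_voxel`
#'   (index triplet), `touches_boundary` flag (a region reaching the grid
#'   edge warns, since the normal-tissue complement may be truncated).
#' @export
grow_tumor_region <- function(attn, seed_hint, cutoff = 0.5,
                              connectivity = 26) {
  dims <- dim(attn)
  dh_assert(length(dims) == 3, "dothisto_geometry", "attn must be 3-D")
  dh_assert(is.logical(seed_hint) && identical(dim(seed_hint), dims),
            "dothisto_geometry", "seed_hint must be a congruent logical array")
  dh_assert(any(seed_hint), "dothisto_geometry", "seed_hint is empty")
  hint_vals <- attn[seed_hint]
  if (diff(range(attn)) == 0 ||
      (diff(range(hint_vals)) == 0 && max(hint_vals) < max(attn))) {
    # a constant hint *at* the global maximum of a non-constant volume is a
    # flat tumor plateau and still seeds deterministically; a constant
    # volume, or a constant hint below the peak, carries no usable contrast
    dh_error("dothisto_no_contrast",
             "attenuation is constant within the seed hint: no tumor contrast")
  }
  masked <- attn
  masked[!seed_hint] <- -Inf
  seed_lin <- which.max(masked) # lowest linear index on ties
  seed_idx <- arrayInd(seed_lin, dims)[1, ]
  thr <- attn[seed_lin] * cutoff
  above <- attn >= thr

  # connected component containing the seed, by masked dilation restricted
  # to the bounding box of the above-threshold voxels
  idx_above <- which(above)
  ai <- arrayInd(idx_above, dims)
  lo <- pmax(apply(ai, 2, min) - 1L, 1L)
  hi <- pmin(apply(ai, 2, max) + 1L, dims)
  sub <- lapply(1:3, function(i) lo[i]:hi[i])
  above_c <- above[sub[[1]], sub[[2]], sub[[3]], drop = FALSE]
  dims_c <- dim(above_c)
  seed_c <- seed_idx - lo + 1L
  off <- neighbor_offsets(connectivity)
  comp_c <- array(FALSE, dims_c)
  comp_c[seed_c[1], seed_c[2], seed_c[3]] <- TRUE
  repeat {
    grown <- comp_c
    for (k in seq_len(nrow(off))) {
      grown <- grown | shift_array(comp_c, off[k, ])
    }
    grown <- grown & above_c
    if (identical(grown, comp_c)) break
    comp_c <- grown
  }
  comp <- array(FALSE, dims)
  comp[sub[[1]], sub[[2]], sub[[3]]] <- comp_c
  touches <- any(comp[1, , ]) || any(comp[dims[1], , ]) ||
    any(comp[, 1, ]) || any(comp[, dims[2], ]) ||
    any(comp[, , 1]) || any(comp[, , dims[3]])
  if (touches) {
    warning("tumor region touches the grid boundary; ",
            "normal-tissue complement may be truncated")
  }
  structure(list(mask = comp, seed_voxel = seed_idx, cutoff = cutoff,
                 connectivity = connectivity, touches_boundary = touches),
            class = "tumor_mask")
}

# shift a logical array by an integer offset, padding with FALSE
shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (i in 1:3) {
    o <- off[i]
    if (o >= 0) {
      src[[i]] <- seq_len(d[i] - o)
      dst[[i]] <- seq_len(d[i] - o) + o
    } else {
      src[[i]] <- seq_len(d[i] + o) - o
      dst[[i]] <- seq_len(d[i] + o)
    }
    if (length(src[[i]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Rectangular seed-hint region
#'
#' @param dims grid dimensions.
#' @param center voxel index triplet at the box center.
#' @param radius half-width in voxels (scalar or length 3).
#' @return Logical array marking the box, clipped to the grid.
#' @export
seed_box <- function(dims, center, radius = 3) {
  radius <- rep(radius, length.out = 3)
  hint <- array(FALSE, dims)
  rng <- lapply(1:3, function(i) {
    max(1, round(center[i] - radius[i])):min(dims[i], round(center[i] + radius[i]))
  })
  hint[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
  hint
}

#' Tumor-to-normal ratios of the optical parameters
#'
#' Averages each parameter over the tumor mask and over its complement
#' (all remaining "normal" tissue in the same volume), and forms the
#' tumor-to-normal ratio of each: rHbO2, rHb, rTHC, rStO2 and rmusp.
#'
#' Regional StO2 is computed from the masked-mean concentrations
#' (`mean(HbO2)/mean(THC)` per region), so that the algebraic identity
#' `rStO2 = rHbO2 / rTHC` holds to machine precision; the voxelwise
#' alternative (mean over the region of per-voxel StO2) is available with
#' `sto2_mode = "mean_of_voxels"`.
#'
#' @param map a `chromophore_map`.
#' @param musp 3-D reduced-scattering array (mm^-1).
#' @param mask a `tumor_mask` (or logical array).
#' @param sto2_mode `"ratio_of_means"` (default) or `"mean_of_voxels"`.
#' @return Object of class `relative_params`: data frame `params` with
#'   columns parameter, tumor_mean, normal_mean, ratio; plus named ratios
#'   `rHbO2`, `rHb`, `rTHC`, `rStO2`, `rmusp`.
#' @export
relative_params <- function(map, musp, mask,
                            sto2_mode = c("ratio_of_means", "mean_of_voxels")) {
  sto2_mode <- match.arg(sto2_mode)
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  dh_assert(is.logical(m) && identical(dim(m), dim(map$HbO2)),
            "dothisto_geometry", "mask must be congruent logical array")
  dh_assert(any(m), "dothisto_geometry", "tumor mask is empty")
  dh_assert(!all(m), "dothisto_geometry",
            "tumor mask covers the whole grid: empty normal complement")
  n <- !m
  tm <- c(HbO2 = mean(map$HbO2[m]), Hb = mean(map$Hb[m]),
          THC = mean(map$THC[m]), musp = mean(musp[m]))
  nm <- c(HbO2 = mean(map$HbO2[n]), Hb = mean(map$Hb[n]),
          THC = mean(map$THC[n]), musp = mean(musp[n]))
  if (sto2_mode == "ratio_of_means") {
    sto2_t <- tm[["HbO2"]] / tm[["THC"]]
    sto2_n <- nm[["HbO2"]] / nm[["THC"]]
  } else {
    sto2_t <- mean(map$StO2[m], na.rm = TRUE)
    sto2_n <- mean(map$StO2[n], na.rm = TRUE)
  }
  tumor_mean <- c(tm[c("HbO2", "Hb", "THC")], StO2 = sto2_t,
                  musp = tm[["musp"]])
  normal_mean <- c(nm[c("HbO2", "Hb", "THC")], StO2 = sto2_n,
                   musp = nm[["musp"]])
  params <- data.frame(parameter = c("HbO2", "Hb", "THC", "StO2", "musp"),
                       tumor_mean = as.numeric(tumor_mean),
                       normal_mean = as.numeric(normal_mean))
  params$ratio <- params$tumor_mean / params$normal_mean
  r <- setNames(params$ratio, params$parameter)
  structure(list(params = params,
                 rHbO2 = r[["HbO2"]], rHb = r[["Hb"]], rTHC = r[["THC"]],
                 rStO2 = r[["StO2"]], rmusp = r[["musp"]],
                 sto2_mode = sto2_mode, n_tumor_voxels = sum(m)),
            class = "relative_params")
}

#' @export
print.relative_params <- function(x, digits = 4, ...) {
  cat("tumor-to-normal optical parameter ratios (",
      x$n_tumor_voxels, " tumor voxels):\n", sep = "")
  print(cbind(`tumor mean` = round(x$params$tumor_mean, digits),
              `normal mean` = round(x$params$normal_mean, digits),
              ratio = round(x$params$ratio, digits)) |>
          `rownames<-`(paste0("r", x$params$parameter)))
  invisible(x)
}
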