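# Quantification of IHC slides: stains, nuclei, vessels, morphometry ----------

#' Construct a slide image object
#'
#' @param rgb numeric H x W x 3 array of 8-bit intensities (0-255), indexed
#'   `[y + 1, x + 1, channel]` with y increasing downwards.
#' @param scale microns per pixel.
#' @param white_ref per-channel white reference intensity I0.
#' @return Object of class `slide_image`.
#' @export
slide_image <- function(rgb, scale, white_ref = c(255, 255, 255)) {
  dh_assert(length(dim(rgb)) == 3 && dim(rgb)[3] == 3, "dothisto_config",
            "rgb must be an H x W x 3 array")
  dh_assert(is_number(scale) && scale > 0, "dothisto_config",
            "scale (um/pixel) must be positive")
  white_ref <- rep(white_ref, length.out = 3)
  dh_assert(all(white_ref > 0), "dothisto_config", "white_ref must be > 0")
  structure(list(rgb = rgb, scale = scale, white_ref = white_ref),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("slide_image: %d x %d px at %.3g um/px (%.0f x %.0f um)\n",
              d[2], d[1], x$scale, d[2] * x$scale, d[1] * x$scale))
  invisible(x)
}

#' Hematoxylin / DAB optical-density stain vectors
#'
#' Published RGB optical-density triplets for hematoxylin and
#' diaminobenzidine (normalized to unit length); brightfield stains mix
#' additively in OD space, so two vectors span the slide's color space.
#'
#' @param hematoxylin,dab length-3 OD triplets.
#' @return 3 x 2 matrix of unit column vectors.
#' @export
stain_vectors <- function(hematoxylin = c(0.650, 0.704, 0.286),
                          dab = c(0.268, 0.570, 0.776)) {
  v <- cbind(hematoxylin = hematoxylin / sqrt(sum(hematoxylin^2)),
             dab = dab / sqrt(sum(dab^2)))
  dh_assert(qr(v)$rank == 2, "dothisto_config", "stain vectors are collinear")
  v
}

#' RGB image to per-channel optical density
#'
#' `OD_c = -log10(max(I_c, 1) / I0_c)` per pixel and channel; OD is
#' non-negative (a blank pixel at the white reference has OD 0) and stains
#' add linearly in it (Beer-Lambert).
#'
#' @param img a [slide_image()].
#' @return H x W x 3 array of optical densities.
#' @export
rgb_to_od <- function(img) {
  od <- img$rgb
  for (c in 1:3) {
    od[, , c] <- -log10(pmax(img$rgb[, , c], 1) / img$white_ref[c])
  }
  od[od < 0] <- 0
  od
}

#' Unmix an OD stack into stain concentration maps
#'
#' Per-pixel least squares projection of the 3-channel OD vector onto the
#' two stain vectors, clamped to non-negative amounts.
#'
#' @param od H x W x 3 OD array from [rgb_to_od()].
#' @param stains 3 x 2 matrix from [stain_vectors()].
#' @return List with matrices `hematoxylin` and `dab` (OD amounts).
#' @export
stain_deconvolve <- function(od, stains = stain_vectors()) {
  d <- dim(od)
  Y <- t(matrix(od, ncol = 3)) # 3 x npix
  C <- solve(crossprod(stains), crossprod(stains, Y))
  C[C < 0] <- 0
  list(hematoxylin = matrix(C[1, ], d[1], d[2]),
       dab = matrix(C[2, ], d[1], d[2]))
}

# Undefined-result signalling --------------------------------------------------

undefined_value <- function(reason) {
  structure(NA_real_, undefined = TRUE, reason = reason)
}

#' Is a value the pipeline's undefined-result signal?
#' @param x value returned by a quantification function.
#' @export
is_undefined <- function(x) isTRUE(attr(x, "undefined")) ||
  (is.atomic(x) && length(x) == 1 && is.na(x))

# ROI annotations ---------------------------------------------------------------

#' Region-of-interest annotation
#'
#' @param polygon N x 2 matrix of vertex coordinates (columns x, y; 0-based
#'   pixel coordinates, y increasing downwards; closed implicitly).
#' @param tissue_class `"tumor"` or `"normal"`.
#' @param exclusions list of polygons (same convention) cut out of the ROI.
#' @return Object of class `roi_annotation`.
#' @export
roi_annotation <- function(polygon, tissue_class = c("tumor", "normal"),
                           exclusions = list()) {
  tissue_class <- match.arg(tissue_class)
  polygon <- as.matrix(polygon)
  dh_assert(ncol(polygon) == 2 && nrow(polygon) >= 3, "dothisto_config",
            "polygon must be an N x 2 matrix with N >= 3")
  structure(list(polygon = polygon, tissue_class = tissue_class,
                 exclusions = lapply(exclusions, as.matrix)),
            class = "roi_annotation")
}

polygon_pixel_mask <- function(polygon, dims) {
  # dims = c(H, W); pixel (row, col) has coordinates (x, y) = (col-1, row-1)
  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  cols <- max(1, floor(xr[1]) + 1):min(dims[2], ceiling(xr[2]) + 1)
  rows <- max(1, floor(yr[1]) + 1):min(dims[1], ceiling(yr[2]) + 1)
  mask <- matrix(FALSE, dims[1], dims[2])
  if (!length(cols) || !length(rows)) return(mask)
  pts <- cbind(x = rep(cols - 1, each = length(rows)),
               y = rep(rows - 1, times = length(cols)))
  bnd <- rbind(polygon, polygon[1, ])
  inside <- mgcv::in.out(bnd, pts)
  mask[cbind(rep(rows, times = length(cols)) ,
             rep(cols, each = length(rows)))] <- inside
  mask
}

#' Rasterize an ROI annotation to a pixel mask
#'
#' @param roi an [roi_annotation()].
#' @param dims image dimensions `c(H, W)`.
#' @return Logical H x W matrix (exclusion polygons removed).
#' @export
roi_mask <- function(roi, dims) {
  mask <- polygon_pixel_mask(roi$polygon, dims)
  for (ex in roi$exclusions) {
    mask <- mask & !polygon_pixel_mask(ex, dims)
  }
  mask
}

# Dark-artifact exclusion -------------------------------------------------------

#' Flag near-black staining artifacts
#'
#' Clusters of precipitated dye are far darker than any genuine stain and
#' would otherwise be mistaken for strongly positive nuclei.  Connected
#' regions whose minimum RGB channel falls below `intensity_floor` and whose
#' area reaches `min_area_um2` are masked out (an automated surrogate for
#' manual exclusion during slide review).
#'
#' @param img a [slide_image()].
#' @param intensity_floor 8-bit intensity below which a pixel counts as
#'   near-black (default 30).
#' @param min_area_um2 minimum component area (um^2) to mask (default 200).
#' @return Logical H x W artifact mask.
#' @export
flag_dark_artifacts <- function(img, intensity_floor = 30,
                                min_area_um2 = 200) {
  dh_assert(intensity_floor > 0 && min_area_um2 > 0, "dothisto_config",
            "thresholds must be positive")
  minch <- pmin(img$rgb[, , 1], img$rgb[, , 2], img$rgb[, , 3])
  dark <- minch < intensity_floor
  if (!any(dark)) return(dark)
  lab <- EBImage::bwlabel(dark)
  sizes <- tabulate(lab[lab > 0])
  min_px <- min_area_um2 / img$scale^2
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(dark), ncol(dark))
}

# Nuclei ------------------------------------------------------------------------

#' Default nucleus detection thresholds
#'
#' Stain-amount thresholds are in OD units of the deconvolved channels;
#' areas in um^2.  Defaults were tuned on the package's slide renderer.
#' @param hema_thresh hematoxylin amount above which a pixel is nuclear.
#' @param dab_cutoff mean DAB amount above which a nucleus is Ki67-positive.
#' @param min_area_um2,max_area_um2 retained nucleus area range.
#' @param split_touching apply one watershed pass on the hematoxylin channel
#'   to split touching nuclei (off by default; the renderer keeps nuclei
#'   separated).
#' @export
nucleus_thresholds <- function(hema_thresh = 0.3, dab_cutoff = 0.2,
                               min_area_um2 = 8, max_area_um2 = 200,
                               split_touching = FALSE) {
  list(hema_thresh = hema_thresh, dab_cutoff = dab_cutoff,
       min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
       split_touching = split_touching)
}

#' Detect and classify nuclei within an ROI
#'
#' Thresholds the deconvolved hematoxylin channel inside the ROI (minus
#' exclusions and dark artifacts), labels connected components, keeps those
#' within the plausible nuclear area range, and classifies each nucleus as
#' Ki67-positive when its mean DAB amount exceeds `dab_cutoff`.  Areas are
#' pixel counts scaled to um^2; perimeters use the corner-corrected
#' chain-code estimator (see the methods vignette).
#'
#' @param od H x W x 3 OD array from [rgb_to_od()].
#' @param roi an [roi_annotation()].
#' @param scale microns per pixel.
#' @param artifact_mask optional logical mask from [flag_dark_artifacts()].
#' @param stains stain vector matrix.
#' @param thresholds list from [nucleus_thresholds()].
#' @param conc,rmask precomputed [stain_deconvolve()] output and ROI pixel
#'   mask (recomputed from `od`/`roi` when `NULL`; passing them avoids
#'   redundant work when several detectors run on one slide).
#' @return `data.frame` with one row per nucleus: `centroid_x`, `centroid_y`
#'   (pixels), `area_um2`, `perimeter_um`, `compactness`, `mean_dab_od`,
#'   `positive`.  An empty ROI yields zero rows, not an error.
#' @export
detect_nuclei <- function(od, roi, scale, artifact_mask = NULL,
                          stains = stain_vectors(),
                          thresholds = nucleus_thresholds(),
                          conc = NULL, rmask = NULL) {
  dims <- dim(od)[1:2]
  if (is.null(rmask)) rmask <- roi_mask(roi, dims)
  empty <- data.frame(centroid_x = numeric(0), centroid_y = numeric(0),
                      area_um2 = numeric(0), perimeter_um = numeric(0),
                      compactness = numeric(0), mean_dab_od = numeric(0),
                      positive = logical(0))
  if (!any(rmask)) return(empty)
  if (is.null(conc)) conc <- stain_deconvolve(od, stains)
  nuc <- conc$hematoxylin > thresholds$hema_thresh & rmask
  if (!is.null(artifact_mask)) nuc <- nuc & !artifact_mask
  if (!any(nuc)) return(empty)
  if (isTRUE(thresholds$split_touching)) {
    dm <- EBImage::distmap(nuc)
    lab <- EBImage::watershed(dm)
  } else {
    lab <- EBImage::bwlabel(nuc)
  }
  lab <- matrix(as.integer(lab), dims[1], dims[2])
  sizes <- tabulate(lab[lab > 0])
  area_um2 <- sizes * scale^2
  keep <- which(area_um2 >= thresholds$min_area_um2 &
                  area_um2 <= thresholds$max_area_um2)
  if (!length(keep)) return(empty)
  contours <- EBImage::ocontour(EBImage::Image(lab))
  idx <- which(lab > 0)
  labv <- lab[idx]
  rc <- arrayInd(idx, dims)
  dabv <- conc$dab[idx]
  out <- lapply(keep, function(k) {
    sel <- labv == k
    per_px <- contour_perimeter(contours[[k]])
    a <- area_um2[k]; p <- per_px * scale
    data.frame(centroid_x = mean(rc[sel, 2]) - 1,
               centroid_y = mean(rc[sel, 1]) - 1,
               area_um2 = a, perimeter_um = p,
               compactness = compactness(a, p),
               mean_dab_od = mean(dabv[sel]),
               positive = mean(dabv[sel]) > thresholds$dab_cutoff)
  })
  do.call(rbind, out)
}

#' Area-weighted Ki67-positive percentage over multiple ROIs
#'
#' Per ROI the Ki67 percent is `100 * positives / total nuclei`; the subject
#' value is the ROI-area-weighted average, which accounts for tumor
#' heterogeneity across the sampled regions.  ROIs without nuclei carry no
#' information about the fraction and are excluded from the weighting.
#'
#' @param rois list of `list(area_um2 =, nuclei =)` entries, `nuclei` being
#'   a [detect_nuclei()] data frame.
#' @return Percent in `[0, 100]`, or the undefined-result signal when every
#'   ROI is empty.
#' @export
ki67_percent <- function(rois) {
  areas <- pct <- numeric(0)
  for (r in rois) {
    n <- nrow(r$nuclei)
    if (is.null(n) || n == 0) next
    areas <- c(areas, r$area_um2)
    pct <- c(pct, 100 * sum(r$nuclei$positive) / n)
  }
  if (!length(areas)) return(undefined_value("all ROIs empty"))
  sum(areas * pct) / sum(areas)
}

#' Tumor-to-normal Ki67 ratio
#'
#' @param pct_t,pct_n tumor and normal Ki67 percentages.
#' @return `pct_t / pct_n`, or the undefined-ratio signal when the normal
#'   tissue shows no Ki67 expression (such subjects enter the cancer-only
#'   analysis but are dropped from relative-Ki67 analyses).
#' @export
relative_ki67 <- function(pct_t, pct_n) {
  if (is_undefined(pct_t) || is_undefined(pct_n)) {
    return(undefined_value("Ki67 percent undefined"))
  }
  if (pct_n <= 0) {
    return(undefined_value("no Ki67 expression in normal tissue"))
  }
  pct_t / pct_n
}

# Vessels -----------------------------------------------------------------------

#' Default vessel detection thresholds
#' @param dab_thresh DAB amount above which a pixel is stained endothelium.
#' @param hema_max hematoxylin amount above which a pixel is rejected
#'   (separates DAB-stained vessel walls from doubly stained nuclei).
#' @param min_area_um2 minimum stained-wall component area retained.
#' @param min_lumen_px minimum enclosed background area (pixels) for a
#'   cross-section to count as closed.
#' @param gap_close_px radius (pixels) of the binary closing applied before
#'   the topological closedness test; tolerates 1-pixel staining gaps by
#'   default.
#' @export
vessel_thresholds <- function(dab_thresh = 0.3, hema_max = 0.25,
                              min_area_um2 = 30, min_lumen_px = 5,
                              gap_close_px = 1) {
  list(dab_thresh = dab_thresh, hema_max = hema_max,
       min_area_um2 = min_area_um2, min_lumen_px = min_lumen_px,
       gap_close_px = gap_close_px)
}

#' Detect vessels and compute vascular metrics in an ROI
#'
#' DAB-stained, hematoxylin-free connected structures are traced; a
#' structure is a closed cross-section if its stained wall topologically
#' encloses a lumen (filling the component's holes adds at least
#' `min_lumen_px` pixels after a small binary closing that bridges staining
#' gaps).  Only closed cross-sections enter the vessel metrics: micro-vessel
#' density (closed vessels per um^2 of ROI), mean vessel area (lumen plus
#' wall), mean vascular area (stained wall only), and the stained-area
#' ratio.
#'
#' @param od OD array; @param roi an [roi_annotation()]; @param scale um/px.
#' @param stains stain vectors; @param thresholds [vessel_thresholds()].
#' @param conc,rmask precomputed deconvolution / ROI mask (optional).
#' @return List of class `vessel_result`: `detections` data frame (one row
#'   per candidate structure: `closed`, `vessel_area_um2`,
#'   `vascular_area_um2`), `mvd` (um^-2), `mva` (um^2), `mean_vascular_area`
#'   (um^2, undefined-signal when no closed vessel), `stained_area_ratio`,
#'   `roi_area_um2`.
#' @export
detect_vessels <- function(od, roi, scale, stains = stain_vectors(),
                           thresholds = vessel_thresholds(),
                           conc = NULL, rmask = NULL) {
  dims <- dim(od)[1:2]
  if (is.null(rmask)) rmask <- roi_mask(roi, dims)
  roi_area_um2 <- sum(rmask) * scale^2
  if (is.null(conc)) conc <- stain_deconvolve(od, stains)
  wall <- conc$dab > thresholds$dab_thresh &
    conc$hematoxylin < thresholds$hema_max & rmask
  det <- data.frame(closed = logical(0), vessel_area_um2 = numeric(0),
                    vascular_area_um2 = numeric(0))
  if (any(wall)) {
    # label the raw wall mask; gap-closing happens per component so that a
    # staining gap inside one vessel can be bridged without fusing
    # neighboring structures
    lab <- matrix(as.integer(EBImage::bwlabel(wall)), dims[1], dims[2])
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes * scale^2 >= thresholds$min_area_um2)
    pad <- thresholds$gap_close_px + 1
    brush <- if (thresholds$gap_close_px > 0) {
      EBImage::makeBrush(2 * thresholds$gap_close_px + 1, "box")
    } else {
      NULL
    }
    rows <- lapply(keep, function(k) {
      idx <- which(lab == k)
      rc <- arrayInd(idx, dims)
      r0 <- max(1, min(rc[, 1]) - pad); r1 <- min(dims[1], max(rc[, 1]) + pad)
      c0 <- max(1, min(rc[, 2]) - pad); c1 <- min(dims[2], max(rc[, 2]) + pad)
      comp <- matrix(FALSE, r1 - r0 + 1, c1 - c0 + 1)
      comp[cbind(rc[, 1] - r0 + 1, rc[, 2] - c0 + 1)] <- TRUE
      compc <- if (is.null(brush)) comp else EBImage::closing(comp, brush) > 0
      filled <- EBImage::fillHull(compc) > 0
      lumen_px <- sum(filled) - sum(compc)
      data.frame(closed = lumen_px >= thresholds$min_lumen_px,
                 vessel_area_um2 = sum(filled) * scale^2,
                 vascular_area_um2 = sum(comp) * scale^2)
    })
    if (length(rows)) det <- do.call(rbind, rows)
  }
  closed <- det[det$closed, , drop = FALSE]
  structure(list(
    detections = det,
    n_closed = nrow(closed),
    mvd = if (roi_area_um2 > 0) nrow(closed) / roi_area_um2 else
      undefined_value("empty ROI"),
    mva = if (nrow(closed)) mean(closed$vessel_area_um2) else
      undefined_value("no closed vessels"),
    mean_vascular_area = if (nrow(closed)) mean(closed$vascular_area_um2) else
      undefined_value("no closed vessels"),
    stained_area_ratio = if (roi_area_um2 > 0)
      sum(det$vascular_area_um2) / roi_area_um2 else
        undefined_value("empty ROI"),
    roi_area_um2 = roi_area_um2), class = "vessel_result")
}

#' Area-weighted aggregation of per-ROI vessel metrics
#'
#' @param results list of `vessel_result` objects.
#' @return List with subject-level `mvd`, `mva`, `mean_vascular_area`,
#'   `stained_area_ratio` (ROI-area-weighted; vessel areas weighted over
#'   ROIs that contain closed vessels).
#' @export
aggregate_vessel_metrics <- function(results) {
  areas <- vapply(results, function(r) r$roi_area_um2, numeric(1))
  w_all <- areas / sum(areas)
  mvd <- sum(w_all * vapply(results, function(r) as.numeric(r$mvd), numeric(1)))
  sar <- sum(w_all * vapply(results, function(r)
    as.numeric(r$stained_area_ratio), numeric(1)))
  has <- vapply(results, function(r) r$n_closed > 0, logical(1))
  if (any(has)) {
    w <- areas[has] / sum(areas[has])
    mva <- sum(w * vapply(results[has], function(r) as.numeric(r$mva),
                          numeric(1)))
    mvsa <- sum(w * vapply(results[has], function(r)
      as.numeric(r$mean_vascular_area), numeric(1)))
  } else {
    mva <- undefined_value("no closed vessels in any ROI")
    mvsa <- undefined_value("no closed vessels in any ROI")
  }
  list(mvd = mvd, mva = mva, mean_vascular_area = mvsa,
       stained_area_ratio = sar)
}

# Nuclear compactness ------------------------------------------------------------

#' Aggregate nuclear compactness
#'
#' Per-nucleus isoperimetric compactness `4 pi A / P^2`, averaged over the
#' detected nuclei of a tissue class; the tumor-to-normal ratio of these
#' means quantifies relative nuclear elongation.
#'
#' @param nuclei a [detect_nuclei()] data frame (needs `area_um2`,
#'   `perimeter_um`; a precomputed `compactness` column is reused).
#' @return List with `per_nucleus` vector and `mean`.
#' @export
nuclear_compactness <- function(nuclei) {
  if (is.null(nuclei) || nrow(nuclei) == 0) {
    return(list(per_nucleus = numeric(0),
                mean = undefined_value("no nuclei")))
  }
  c_i <- if ("compactness" %in% names(nuclei)) nuclei$compactness else
    compactness(nuclei$area_um2, nuclei$perimeter_um)
  list(per_nucleus = c_i, mean = mean(c_i))
}
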