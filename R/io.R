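# File formats: NIfTI volumes, curve CSVs, TIFF slides, JSON annotations ------

#' Write an absorption volume set as NIfTI files
#'
#' One file per wavelength (`mua_<nm>nm.nii.gz`) plus `musp.nii.gz`, RAS
#' orientation with the voxel size (mm) carried in the header.
#'
#' @param vols an [absorption_volumes()]; @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_volumes_nifti <- function(vols, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  as_img <- function(arr) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- vols$voxel_size
    img
  }
  paths <- character(0)
  for (i in seq_along(vols$wavelengths)) {
    p <- file.path(dir, sprintf("mua_%dnm.nii.gz",
                                round(vols$wavelengths[i])))
    RNifti::writeNifti(as_img(vols$mua[[i]]), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "musp.nii.gz")
  RNifti::writeNifti(as_img(vols$musp), p)
  invisible(c(paths, p))
}

#' Read an absorption volume set from a directory of NIfTI files
#'
#' Expects the layout written by [write_volumes_nifti()]; voxel sizes come
#' from the NIfTI headers.
#'
#' @param dir directory containing `mua_<nm>nm.nii.gz` files and
#'   `musp.nii.gz`.
#' @return An [absorption_volumes()] object.
#' @export
read_volumes_nifti <- function(dir) {
  files <- list.files(dir, pattern = "^mua_[0-9]+nm\\.nii", full.names = TRUE)
  dh_assert(length(files) >= 2, "dothisto_geometry",
            "need at least two wavelength volumes")
  wl <- as.numeric(sub("^mua_([0-9]+)nm\\..*$", "\\1", basename(files)))
  ord <- order(wl)
  mua <- lapply(files[ord], function(f) {
    v <- RNifti::readNifti(f)
    array(as.numeric(v), dim(v))
  })
  hdr <- RNifti::niftiHeader(RNifti::readNifti(files[1]))
  voxel <- hdr$pixdim[2:4]
  musp_f <- file.path(dir, c("musp.nii.gz", "musp.nii"))
  musp_f <- musp_f[file.exists(musp_f)][1]
  musp <- RNifti::readNifti(musp_f)
  absorption_volumes(mua, array(as.numeric(musp), dim(musp)),
                     wl[ord], voxel)
}

#' Write a tumor mask as NIfTI (uint8)
#' @param mask a `tumor_mask` or logical array; @param path output file;
#' @param voxel_size mm voxel sizes for the header.
#' @export
write_mask_nifti <- function(mask, path, voxel_size = c(1, 1, 1)) {
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  img <- RNifti::asNifti(array(as.integer(m), dim(m)),
                         pixdim = voxel_size, datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a DCS scan as CSV
#'
#' Long format with columns `position_index`, `label`, `tau_s`, `g2`.
#' @param scan a `g2_scan` data frame; @param path CSV path.
#' @export
write_g2_csv <- function(scan, path) {
  write.csv(as.data.frame(scan)[, c("position_index", "label", "tau_s", "g2")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_g2_csv
#' @export
read_g2_csv <- function(path) {
  d <- read.csv(path)
  dh_assert(all(c("position_index", "label", "tau_s", "g2") %in% names(d)),
            "dothisto_config", "curve CSV lacks required columns")
  class(d) <- c("g2_scan", "data.frame")
  d
}

#' Write a rendered slide as TIFF plus JSON ground truth / ROI annotations
#'
#' The raster goes to an RGB TIFF; ROI polygons (0-based pixel coordinates,
#' y-down, implicitly closed) and the per-object ground truth go to a JSON
#' sidecar.
#'
#' @param slide an `ihc_slide`; @param tiff_path,json_path output files.
#' @export
write_slide <- function(slide, tiff_path, json_path) {
  img <- slide$image$rgb / 255
  tiff::writeTIFF(img, tiff_path, bits.per.sample = 8L)
  ann <- list(
    scale_um_px = slide$image$scale,
    white_ref = slide$image$white_ref,
    rois = lapply(slide$rois, function(r) {
      list(tissue_class = r$tissue_class,
           polygon = unname(apply(r$polygon, 1, as.numeric, simplify = FALSE)),
           exclusions = lapply(r$exclusions, function(e)
             unname(apply(e, 1, as.numeric, simplify = FALSE))))
    }),
    truth = slide$truth,
    objects = slide$objects
  )
  jsonlite::write_json(ann, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(tiff_path, json_path))
}

#' Read a slide TIFF and its JSON annotations
#' @param tiff_path,json_path files written by [write_slide()].
#' @return An `ihc_slide`-like list with `image`, `rois`, `truth`, `objects`.
#' @export
read_slide <- function(tiff_path, json_path) {
  raster <- tiff::readTIFF(tiff_path)
  ann <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  rgb <- round(raster * 255)
  rois <- lapply(seq_len(length(ann$rois$tissue_class)), function(i) {
    p <- ann$rois$polygon[[i]]
    poly <- if (is.matrix(p)) p else do.call(rbind, p)
    roi_annotation(poly, ann$rois$tissue_class[i])
  })
  structure(list(image = slide_image(rgb, ann$scale_um_px,
                                     unlist(ann$white_ref)),
                 rois = rois, truth = ann$truth,
                 objects = as.data.frame(ann$objects)),
            class = "ihc_slide")
}

#' Write the per-subject cohort table as CSV
#' @param cohort a `subject_cohort` or assembled results data frame.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
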