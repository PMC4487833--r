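# End-to-end orchestration: synth -> DOT -> DCS -> metabolism -> histology ----

#' Quantify a rendered (or loaded) IHC slide
#'
#' Runs the full histology chain on one slide: optical density conversion,
#' dark-artifact exclusion, per-ROI nucleus detection and Ki67 scoring with
#' area weighting, closed-cross-section vessel metrics on the tumor ROIs,
#' and mean nuclear compactness per tissue class.
#'
#' @param slide an `ihc_slide` (from [render_slide()] or [read_slide()]).
#' @param stains stain vectors; @param nucleus_thr,vessel_thr threshold
#'   lists; @param artifact_floor,artifact_min_area dark-artifact settings.
#' @return List: `ki67_t_pct`, `ki67_n_pct`, `rki67`, `mvd`, `mva`,
#'   `mean_vascular_area`, `stained_area_ratio`, `compact_t`, `compact_n`,
#'   `r_compact`, `n_nuclei`, `n_vessels_closed`.
#' @export
quantify_slide <- function(slide, stains = stain_vectors(),
                           nucleus_thr = nucleus_thresholds(),
                           vessel_thr = vessel_thresholds(),
                           artifact_floor = 30, artifact_min_area = 200) {
  img <- slide$image
  od <- rgb_to_od(img)
  art <- flag_dark_artifacts(img, artifact_floor, artifact_min_area)
  dims <- dim(od)[1:2]
  conc <- stain_deconvolve(od, stains)
  rmasks <- lapply(slide$rois, roi_mask, dims = dims)
  per_roi <- lapply(seq_along(slide$rois), function(i) {
    roi <- slide$rois[[i]]
    nuc <- detect_nuclei(od, roi, img$scale, artifact_mask = art,
                         stains = stains, thresholds = nucleus_thr,
                         conc = conc, rmask = rmasks[[i]])
    area <- sum(rmasks[[i]] & !art) * img$scale^2
    list(roi = roi, area_um2 = area, nuclei = nuc)
  })
  cls <- vapply(per_roi, function(p) p$roi$tissue_class, character(1))
  ki67_t <- ki67_percent(per_roi[cls == "tumor"])
  ki67_n <- ki67_percent(per_roi[cls == "normal"])
  vres <- lapply(which(cls == "tumor"), function(i) {
    detect_vessels(od, slide$rois[[i]], img$scale, stains = stains,
                   thresholds = vessel_thr, conc = conc,
                   rmask = rmasks[[i]])
  })
  vm <- aggregate_vessel_metrics(vres)
  nuc_t <- do.call(rbind, lapply(per_roi[cls == "tumor"], `[[`, "nuclei"))
  nuc_n <- do.call(rbind, lapply(per_roi[cls == "normal"], `[[`, "nuclei"))
  ct <- nuclear_compactness(nuc_t)$mean
  cn <- nuclear_compactness(nuc_n)$mean
  list(ki67_t_pct = as.numeric(ki67_t), ki67_n_pct = as.numeric(ki67_n),
       rki67 = as.numeric(relative_ki67(ki67_t, ki67_n)),
       mvd = as.numeric(vm$mvd), mva = as.numeric(vm$mva),
       mean_vascular_area = as.numeric(vm$mean_vascular_area),
       stained_area_ratio = as.numeric(vm$stained_area_ratio),
       compact_t = as.numeric(ct), compact_n = as.numeric(cn),
       r_compact = as.numeric(ct) / as.numeric(cn),
       n_nuclei = sum(vapply(per_roi, function(p) as.numeric(nrow(p$nuclei)),
                             numeric(1))),
       n_vessels_closed = sum(vapply(vres, function(v) as.numeric(v$n_closed),
                                     numeric(1))))
}

#' Pipeline run configuration
#'
#' @param cohort a [cohort_config()]; its `n_subjects` and `seed` drive the
#'   whole run.
#' @param grid a [phantom_grid()]; @param ext an [extinction_table()].
#' @param optics a [tissue_optics()] for the DCS stage.
#' @param layout a [slide_layout()].
#' @param dcs_subjects how many subjects (from subject 1) have DCS scans —
#'   blood flow is measured in a subset of any real cohort; the default
#'   reproduces a 6-of-21 availability ratio.  `0` disables the DCS and
#'   metabolism stages.
#' @param sao2,svo2 arterial/venous saturations for the venous-fraction
#'   model.  The venous default sits below the lowest tissue StO2 the
#'   normal-reference model can produce (0.67 at the default 2:1
#'   oxy:deoxyhemoglobin reference), keeping every derived venous fraction
#'   physical.
#' @param out_dir optional directory for CSV/report artifacts.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       grid = phantom_grid(),
                       ext = default_extinction(),
                       optics = tissue_optics(),
                       layout = slide_layout(),
                       dcs_subjects = NULL,
                       sao2 = 0.98, svo2 = 0.55,
                       out_dir = NULL) {
  if (is.null(dcs_subjects)) {
    dcs_subjects <- round(cohort$n_subjects * 6 / 21)
  }
  dh_assert(dcs_subjects >= 0 && dcs_subjects <= cohort$n_subjects,
            "dothisto_config", "dcs_subjects out of range")
  structure(list(cohort = cohort, grid = grid, ext = ext, optics = optics,
                 layout = layout, dcs_subjects = dcs_subjects,
                 sao2 = sao2, svo2 = svo2, out_dir = out_dir),
            class = "run_config")
}

#' Analysis-membership flags for one subject record
#'
#' Deterministic mapping from data availability to analysis membership:
#' relative-Ki67 analyses need normal-tissue Ki67 expression, metabolism
#' needs a blood-flow measurement, vessel and compactness analyses need a
#' slide.
#'
#' @param record one-row data frame (or list) with `ki67_n_pct`, `rbf`,
#'   `has_slide` fields (NA = missing).
#' @return Named logical vector: `rki67`, `cancer_ki67`, `rmmro2`, `cd34`,
#'   `compactness`.
#' @export
subject_availability <- function(record) {
  has_slide <- isTRUE(record$has_slide)
  has_rbf <- !is.null(record$rbf) && is.finite(record$rbf)
  pct_n <- record$ki67_n_pct
  c(rki67 = has_slide && is.finite(pct_n) && pct_n > 0,
    cancer_ki67 = has_slide,
    rmmro2 = has_rbf,
    cd34 = has_slide,
    compactness = has_slide)
}

process_subject_optics <- function(subject, config, seed) {
  ph <- render_phantom(subject, config$grid, config$ext,
                       config$cohort$normal_ref,
                       mua_sigma = config$cohort$noise$mua_sigma,
                       seed = seed)
  cm <- fit_chromophores(ph$vols, config$ext)
  # segment on the tumor *contrast* of total hemoglobin: the half-of-peak
  # cutoff is meaningful relative to background-free excess signal (the
  # volume median is a robust background estimate for a small tumor), and
  # THC is the one parameter whose tumor contrast is sign-definite --
  # oxy/deoxy absorption contrast can cancel near the isosbestic point
  attn <- pmax(cm$THC - median(cm$THC), 0)
  center_vox <- round(ph$center_mm / config$grid$voxel_mm)
  hint <- seed_box(config$grid$dims, center_vox, radius = 4)
  mask <- grow_tumor_region(attn, hint)
  relative_params(cm, ph$vols$musp, mask)
}

process_subject_dcs <- function(subject, config, seed) {
  scan <- simulate_g2_scan(subject, config$optics,
                           bfi_n = config$cohort$normal_ref$BFI_N,
                           g2_sigma = config$cohort$noise$g2_sigma,
                           seed = seed)
  fits <- lapply(g2_scan_curves(scan), fit_bfi, optics = config$optics)
  compute_rbf(fits)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates the cohort, renders and analyzes every subject's modalities
#' (absorption phantom -> chromophore unmixing -> half-maximum segmentation
#' -> tumor-to-normal ratios; autocorrelation scan -> blood-flow fits ->
#' relative blood flow -> relative metabolic rate; slide -> histology
#' metrics), assembles the per-subject table with availability flags, and
#' computes the optical-histology association table.  Identical
#' configuration and seed give identical outputs.
#'
#' @param config a [run_config()].
#' @param progress print a line per subject.
#' @param resume with an `out_dir` configured, reuse the per-subject table
#'   of a previous identical run (matching configuration signature) and
#'   recompute only the association layer.
#' @return List of class `pipeline_result`: `subjects` (per-subject data
#'   frame of recovered parameters, with ground truth in `truth_*`
#'   columns), `associations` (the [build_association_table()] output),
#'   `availability` (logical matrix), `config`.
#' @export
run_pipeline <- function(config = run_config(), progress = FALSE,
                         resume = FALSE) {
  sig <- config_signature(config)
  if (isTRUE(resume) && !is.null(config$out_dir)) {
    meta_path <- file.path(config$out_dir, "run_meta.txt")
    subj_path <- file.path(config$out_dir, "subjects.csv")
    if (file.exists(meta_path) && file.exists(subj_path) &&
        identical(paste(readLines(meta_path), collapse = "\n"), sig)) {
      subjects <- read.csv(subj_path)
      return(finish_pipeline(subjects, config, sig))
    }
  }
  cohort <- generate_cohort(config$cohort)
  n <- nrow(cohort)
  rows <- vector("list", n)
  stage <- function(name, subject_id, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "dothisto_stage")) stop(e)
      dh_error("dothisto_stage",
               sprintf("stage '%s' failed for subject %s: %s", name,
                       subject_id, conditionMessage(e)),
               stage = name, subject_id = subject_id, parent = e)
    })
  }
  for (i in seq_len(n)) {
    subject <- cohort[i, ]
    sid <- subject$subject_id
    seed_i <- substream_seed(config$cohort$seed, i, 0L)
    rp <- stage("dot", sid, process_subject_optics(subject, config, seed_i))
    rbf <- NA_real_
    if (i <= config$dcs_subjects) {
      rbf <- stage("dcs", sid, process_subject_dcs(
        subject, config, substream_seed(config$cohort$seed, i, 1L))$rbf)
    }
    slide <- stage("render_slide", sid, render_slide(
      subject, config$layout,
      slide_jitter = config$cohort$noise$slide_jitter,
      seed = substream_seed(config$cohort$seed, i, 2L)))
    hq <- stage("histology", sid, quantify_slide(slide))
    rmmro2 <- NA_real_
    if (is.finite(rbf)) {
      sto2_n_abs <- config$cohort$normal_ref$HbO2_N /
        (config$cohort$normal_ref$HbO2_N + config$cohort$normal_ref$Hb_N)
      clamp_sat <- function(s) min(max(s, config$svo2 + 1e-3),
                                   config$sao2 - 1e-3)
      sto2_n_abs <- clamp_sat(sto2_n_abs)
      sto2_t_abs <- clamp_sat(rp$rStO2 * sto2_n_abs)
      rmmro2 <- compute_rmmro2(rp$rHb, rp$rTHC, rbf,
                               sto2_t = sto2_t_abs, sto2_n = sto2_n_abs,
                               sao2 = config$sao2,
                               svo2 = config$svo2)$rmmro2
    }
    rows[[i]] <- data.frame(
      subject_id = subject$subject_id,
      rStO2 = rp$rStO2, rTHC = rp$rTHC, rHbO2 = rp$rHbO2, rHb = rp$rHb,
      rmusp = rp$rmusp, rbf = rbf, rmmro2 = rmmro2,
      Ki67_T_pct = hq$ki67_t_pct, ki67_n_pct = hq$ki67_n_pct,
      rKi67 = hq$rki67, MVA = hq$mva, MVD = hq$mvd,
      stained_area_ratio = hq$stained_area_ratio,
      compact_t = hq$compact_t, compact_n = hq$compact_n,
      r_compact = hq$r_compact,
      has_slide = TRUE,
      truth_rStO2 = subject$rStO2, truth_rTHC = subject$rTHC,
      truth_rHbO2 = subject$rHbO2, truth_rHb = subject$rHb,
      truth_rmusp = subject$rmusp, truth_rBF = subject$rBF,
      truth_Ki67_T = subject$Ki67_T, truth_Ki67_N = subject$Ki67_N,
      truth_MVA = subject$MVA_true,
      truth_compact_T = subject$compact_T,
      truth_compact_N = subject$compact_N
    )
    if (progress) {
      message(sprintf("[%s] rStO2 %.3f (true %.3f), Ki67 %.1f%% (true %.1f%%)",
                      subject$subject_id, rp$rStO2, subject$rStO2,
                      hq$ki67_t_pct, subject$Ki67_T))
    }
  }
  subjects <- do.call(rbind, rows)
  if (config$dcs_subjects == 0) {
    subjects$rbf <- NULL
    subjects$rmmro2 <- NULL
  }
  finish_pipeline(subjects, config, sig)
}

config_signature <- function(config) {
  c2 <- config
  c2$out_dir <- NULL
  paste(deparse(c2, control = "exact"), collapse = "\n")
}

finish_pipeline <- function(subjects, config, sig) {
  n <- nrow(subjects)
  avail <- t(vapply(seq_len(n), function(i)
    subject_availability(subjects[i, ]), logical(5)))
  rownames(avail) <- subjects$subject_id
  assoc <- build_association_table(subjects)
  out <- structure(list(subjects = subjects, associations = assoc,
                        availability = avail, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, sig)
  out
}

write_pipeline_outputs <- function(result, sig) {
  dir <- result$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$subjects, file.path(dir, "subjects.csv"),
            row.names = FALSE)
  writeLines(sig, file.path(dir, "run_meta.txt"))
  write.csv(as.data.frame(result$associations),
            file.path(dir, "associations.csv"), row.names = FALSE)
  md <- c("# Optical-histology association report", "",
          sprintf("Subjects: %d; DCS-measured: %d", nrow(result$subjects),
                  result$config$dcs_subjects),
          sprintf("Per-analysis n: %s",
                  paste(colnames(result$availability),
                        colSums(result$availability),
                        sep = "=", collapse = ", ")),
          "", "## Correlations", "")
  a <- result$associations
  for (i in seq_len(nrow(a))) {
    md <- c(md, sprintf("- %s vs %s (n=%d): Pearson r=%.3f (p=%.3g), Spearman rho=%.3f (p=%.3g)",
                        a$optical[i], a$marker[i], a$n[i], a$pearson_r[i],
                        a$p_pearson[i], a$spearman_rho[i], a$p_spearman[i]))
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result:", nrow(x$subjects), "subjects\n")
  cat("per-analysis n:",
      paste(colnames(x$availability), colSums(x$availability),
            sep = "=", collapse = ", "), "\n\n")
  print(x$associations)
  invisible(x)
}

#' Small end-to-end demonstration run
#'
#' A 12-subject cohort on reduced grids, suitable for a quick smoke check.
#' @param seed master seed.
#' @param n_subjects cohort size.
#' @param out_dir optional artifact directory.
#' @export
demo_pipeline <- function(seed = 1L, n_subjects = 12, out_dir = NULL) {
  cfg <- run_config(
    cohort = cohort_config(n_subjects = n_subjects, seed = seed),
    grid = phantom_grid(c(40, 40, 40), 1),
    layout = slide_layout(width_px = 768, height_px = 512,
                          n_nuclei_tumor = 80, n_nuclei_normal = 60),
    out_dir = out_dir)
  run_pipeline(cfg)
}
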