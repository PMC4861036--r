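#' Process one baseline/follow-up pair end to end
#'
#' Registers the follow-up onto the baseline (rigid block matching),
#' resamples it, segments every catalogued lesion at both time points,
#' computes the six metabolic metrics, runs the two-frame factor
#' analysis, and classifies each lesion from the parametric change
#' image.
#'
#' When a lesion shows no focal uptake at follow-up (complete metabolic
#' response: the adaptive threshold finds nothing to delineate), its
#' follow-up metrics are measured inside the baseline mask transferred
#' to the registered follow-up volume, so the evolution is quantified
#' as a deep decrease instead of failing.
#'
#' @param baseline,followup [pet_volume]s of the same patient.
#' @param lesion_catalog Data frame with columns `lesion_id`, `organ`,
#'   `seed_x`, `seed_y`, `seed_z` (0-based voxel seeds on the baseline
#'   grid).
#' @param seg_config A [segmentation_config].
#' @param reg_config A [block_match_config].
#' @param fads_cfg A [fads_config].
#' @param sultan_threshold Significance cut of the parametric image.
#' @param register Set `FALSE` to skip registration (frames already
#'   aligned).
#' @return List with `transform`, `metrics_t1`, `metrics_t2` (one row
#'   per measurable lesion), `sultan_lesion` (named classification
#'   vector), `sultan_direction`, and `resolved_lesions`.
#' @export
process_pair <- function(baseline, followup, lesion_catalog,
                         seg_config = segmentation_config(),
                         reg_config = block_match_config(),
                         fads_cfg = fads_config(),
                         sultan_threshold = 1,
                         register = TRUE) {
  transform <- if (register) {
    tryCatch(register_rigid(baseline, followup, reg_config),
             error = function(e) {
               # a pair whose focal structure resolved completely has
               # nothing to match; proceed unaligned rather than fail
               warning("registration failed (", conditionMessage(e),
                       "); using the identity transform", call. = FALSE)
               rigid_transform()
             })
  } else rigid_transform()
  aligned <- if (register || !identical(dim(followup$values),
                                        dim(baseline$values)))
    resample_through(followup, transform, baseline) else followup

  m1 <- list(); m2 <- list(); vois <- list()
  resolved <- character(0)
  for (i in seq_len(nrow(lesion_catalog))) {
    row <- lesion_catalog[i, ]
    seed <- c(row$seed_x, row$seed_y, row$seed_z)
    voi1 <- tryCatch(
      segment_lesion(baseline, seed, seg_config,
                     lesion_id = row$lesion_id, organ = row$organ),
      error = function(e) NULL)
    if (is.null(voi1)) {
      warning("baseline segmentation failed for lesion ", row$lesion_id,
              "; lesion skipped", call. = FALSE)
      next
    }
    voi2 <- tryCatch(
      segment_lesion(aligned, seed, seg_config,
                     lesion_id = row$lesion_id, organ = row$organ),
      error = function(e) NULL)
    m1[[length(m1) + 1]] <- compute_all_metrics(baseline, voi1)
    if (is.null(voi2)) {
      # resolved lesion: measure SUV statistics inside the baseline mask
      # transferred to the registered follow-up; no metabolically active
      # volume is measurable, so MV (and with it TLG) is 0
      met2 <- compute_all_metrics(aligned, voi1)
      met2$mv <- 0; met2$tlg <- 0
      m2[[length(m2) + 1]] <- met2
      resolved <- c(resolved, row$lesion_id)
    } else {
      m2[[length(m2) + 1]] <- compute_all_metrics(aligned, voi2)
    }
    vois[[row$lesion_id]] <- voi1
  }
  if (length(m1) == 0)
    stop("no measurable lesion in the pair", call. = FALSE)
  metrics_t1 <- do.call(rbind, m1)
  metrics_t2 <- do.call(rbind, m2)

  model <- fads_two_frame(baseline, aligned, config = fads_cfg)
  simg <- sultan_image(model, sultan_threshold)
  sultan_lesion <- vapply(vois, function(v)
    classify_lesion_sultan(simg, v), character(1))

  list(transform = transform, metrics_t1 = metrics_t1,
       metrics_t2 = metrics_t2, sultan_lesion = sultan_lesion,
       sultan_direction = simg$direction, resolved_lesions = resolved)
}

#' Run the full phantom cohort through the pipeline
#'
#' Generates (or reuses) each patient's paired scans, processes them
#' with [process_pair], applies PERCIST target selection, and collects
#' the per-lesion and per-patient observations every downstream study
#' needs. Deterministic for a fixed cohort (the per-pair seeds live in
#' the cohort specification).
#'
#' @param cohort A [generate_cohort] result.
#' @param seg_config,reg_config,fads_cfg,sultan_threshold,register
#'   Passed to [process_pair].
#' @param verbose Print one line per pair.
#' @return An object of class `cohort_results` with data frames
#'   `lesion_results` (per-lesion percent changes of all six metrics,
#'   the parametric call, and the ground-truth label) and
#'   `patient_results` (hottest-lesion changes, patient-level
#'   parametric call, and label), plus `registration` (true vs
#'   recovered misalignment summary).
#' @export
run_cohort_study <- function(cohort,
                             seg_config = segmentation_config(),
                             reg_config = block_match_config(),
                             fads_cfg = fads_config(),
                             sultan_threshold = 1,
                             register = TRUE, verbose = FALSE) {
  lesion_rows <- list(); patient_rows <- list(); reg_rows <- list()
  for (pt in cohort$patients) {
    if (!is.null(pt$baseline)) {
      pair <- list(baseline = pt$baseline, followup = pt$followup,
                   truth = pt$truth)
    } else {
      pair <- generate_pair(pt$spec, pt$truth$response_threshold)
    }
    catalog <- cohort$lesion_catalog[
      cohort$lesion_catalog$pair_id == pt$pair_id, , drop = FALSE]
    res <- process_pair(pair$baseline, pair$followup, catalog,
                        seg_config, reg_config, fads_cfg,
                        sultan_threshold, register)

    targets <- select_targets(res$metrics_t1)
    ids <- targets$lesion_id
    t1 <- res$metrics_t1[match(ids, res$metrics_t1$lesion_id), ]
    t2 <- res$metrics_t2[match(ids, res$metrics_t2$lesion_id), ]
    truth <- pt$truth$lesions[match(ids, pt$truth$lesions$lesion_id), ]

    ch <- lapply(metric_names(), function(m)
      percent_change(t1[[m]], t2[[m]]))
    names(ch) <- paste0("change_", metric_names())
    lesion_rows[[pt$pair_id]] <- data.frame(
      patient_id = pt$patient_id, pair_id = pt$pair_id,
      lesion_id = ids, organ = t1$organ,
      as.data.frame(ch),
      sultan = unname(res$sultan_lesion[ids]),
      gold = truth$label, true_change_pct = truth$true_change_pct,
      stringsAsFactors = FALSE)

    rp <- response_pair(pt$pair_id, pt$patient_id, t1, t2,
                        gold_label = pt$truth$patient_label)
    pch <- vapply(metric_names(), function(m)
      patient_change_percist(rp, m), numeric(1))
    patient_rows[[pt$pair_id]] <- data.frame(
      pair_id = pt$pair_id, patient_id = pt$patient_id,
      as.data.frame(as.list(setNames(pch,
                                     paste0("change_", metric_names())))),
      sultan = classify_patient_sultan(res$sultan_lesion[ids]),
      gold = pt$truth$patient_label, stringsAsFactors = FALSE)

    err <- registration_error(pt$truth$misalignment, res$transform,
                              pair$baseline)
    reg_rows[[pt$pair_id]] <- data.frame(pair_id = pt$pair_id,
                                         trans_err_mm = err$translation,
                                         rot_err_deg = err$rotation,
                                         stringsAsFactors = FALSE)
    if (verbose)
      cat(sprintf("%s: %d lesions, reg err %.2f mm, sultan %s (gold %s)\n",
                  pt$pair_id, length(ids), err$translation,
                  patient_rows[[pt$pair_id]]$sultan,
                  pt$truth$patient_label))
  }
  structure(list(lesion_results = do.call(rbind, lesion_rows),
                 patient_results = do.call(rbind, patient_rows),
                 registration = do.call(rbind, reg_rows)),
            class = "cohort_results")
}

# Worst-case point discrepancy between two transforms over the volume,
# split into a translation-like magnitude (mm, at the volume center) and
# a rotation discrepancy (deg).
registration_error <- function(true_tf, est_tf, volume) {
  d <- dim(volume$values)
  ctr <- voxel_to_world(volume, matrix((d - 1) / 2, 1))
  trans <- sqrt(sum((transform_points(true_tf, ctr) -
                       transform_points(est_tf, ctr))^2))
  Rrel <- t(est_tf$matrix) %*% true_tf$matrix
  ang <- acos(max(-1, min(1, (sum(diag(Rrel)) - 1) / 2))) * 180 / pi
  list(translation = trans, rotation = ang)
}

# Responder call at an ROC cut. Unlike a clinical threshold policy
# (always a positive required decrease), a data-driven optimal cut may
# be non-positive on a cohort whose classes separate above zero change.
call_at_cut <- function(change, cut) {
  ifelse(change < -cut, "responder", "non_responder")
}

study_row <- function(level, metric, source, threshold, auc, cells) {
  st <- confusion_stats(sum(cells == "TP"), sum(cells == "TN"),
                        sum(cells == "FP"), sum(cells == "FN"))
  data.frame(level = level, metric = metric, threshold_source = source,
             threshold = threshold, auc = auc,
             tp = st$tp, tn = st$tn, fp = st$fp, fn = st$fn,
             sensitivity = st$sensitivity, specificity = st$specificity,
             ppv = st$ppv, npv = st$npv, accuracy = st$accuracy,
             youden_j = st$youden_j, chi2_p = st$chi2_p,
             significant = st$significant, stringsAsFactors = FALSE)
}

#' Write a study report as CSV and/or JSON
#'
#' @param report A report data frame from [run_per_lesion_study] or
#'   [run_per_patient_study].
#' @param csv,json Optional output paths.
#' @return Invisibly, the report.
#' @export
write_study_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) write.csv(report, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  invisible(report)
}

#' Per-lesion diagnostic study
#'
#' For each of the six metrics: per-lesion percent changes, ROC against
#' the gold standard, Youden-optimal threshold, responder calls at that
#' threshold, and confusion statistics; plus one row for the parametric
#' (factor-analysis) classification. Requires both gold classes.
#'
#' @param results A [run_cohort_study] result.
#' @return List with `report` (one row per metric + one SULTAN row) and
#'   `rocs` (named list of [roc_analysis] results).
#' @export
run_per_lesion_study <- function(results) {
  lr <- results$lesion_results
  if (length(unique(lr$gold)) < 2)
    stop("per-lesion study needs both gold classes", call. = FALSE)
  rows <- list(); rocs <- list()
  for (m in metric_names()) {
    ch <- lr[[paste0("change_", m)]]
    roc <- roc_analysis(ch, lr$gold)
    rocs[[m]] <- roc
    calls <- call_at_cut(ch, roc$optimal_threshold)
    cells <- mapply(confusion_cell, calls, lr$gold)
    rows[[m]] <- study_row("lesion", m, "optimal",
                           roc$optimal_threshold, roc$auc, cells)
  }
  cells <- mapply(confusion_cell, lr$sultan, lr$gold)
  rows$sultan <- study_row("lesion", "sultan", "parametric", NA_real_,
                           NA_real_, cells)
  list(report = do.call(rbind, rows), rocs = rocs)
}

#' Per-patient diagnostic study
#'
#' Evaluates the hottest-lesion percent change of each metric under the
#' PERCIST policy (30% decrease, 45% for TLG) and under
#' cohort-optimal Youden thresholds, plus the patient-level parametric
#' classification; mirrors the per-lesion report layout.
#'
#' @param results A [run_cohort_study] result.
#' @param policy A [threshold_policy] used as the fixed-threshold
#'   criterion (default [percist_policy]).
#' @return List with `report` (two rows per metric: fixed-policy and
#'   optimal, plus one SULTAN row) and `rocs`.
#' @export
run_per_patient_study <- function(results, policy = percist_policy()) {
  pr <- results$patient_results
  if (length(unique(pr$gold)) < 2)
    stop("per-patient study needs both gold classes", call. = FALSE)
  rows <- list(); rocs <- list()
  for (m in metric_names()) {
    ch <- pr[[paste0("change_", m)]]
    roc <- roc_analysis(ch, pr$gold)
    rocs[[m]] <- roc
    cells_fix <- mapply(confusion_cell,
                        classify_change(ch, policy[[m]]), pr$gold)
    rows[[paste0(m, "_percist")]] <-
      study_row("patient", m, "percist", policy[[m]], roc$auc, cells_fix)
    cells_opt <- mapply(confusion_cell,
                        call_at_cut(ch, roc$optimal_threshold),
                        pr$gold)
    rows[[paste0(m, "_optimal")]] <-
      study_row("patient", m, "optimal", roc$optimal_threshold, roc$auc,
                cells_opt)
  }
  cells <- mapply(confusion_cell, pr$sultan, pr$gold)
  rows$sultan <- study_row("patient", "sultan", "parametric", NA_real_,
                           NA_real_, cells)
  list(report = do.call(rbind, rows), rocs = rocs)
}
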