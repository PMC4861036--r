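#' Percent change of a metric between two time points
#'
#' `100 * (m2 - m1) / m1`; negative values are decreases.
#'
#' @param m1 Baseline value (> 0).
#' @param m2 Follow-up value.
#' @return Percent change (vectorized).
#' @export
percent_change <- function(m1, m2) {
  if (any(m1 <= 0)) stop("baseline metric must be positive", call. = FALSE)
  100 * (m2 - m1) / m1
}

#' Threshold policy for responder calls
#'
#' A named vector of required percent decreases per metric. The PERCIST
#' preset requires a 30% decrease for every metric except TLG (45%).
#'
#' @param ... Named thresholds (positive percent decreases), e.g.
#'   `suv_max = 21`.
#' @return Named numeric vector of class `threshold_policy`.
#' @export
threshold_policy <- function(...) {
  x <- c(...)
  stopifnot(length(x) > 0, all(x > 0), !is.null(names(x)),
            all(names(x) %in% metric_names()))
  structure(x, class = "threshold_policy")
}

#' @rdname threshold_policy
#' @export
percist_policy <- function() {
  threshold_policy(suv_max = 30, suv_peak = 30, suv_mean = 30,
                   mv = 30, tlg = 45, sam = 30)
}

#' Classify a percent change against a decrease threshold
#'
#' A responder is a decrease strictly greater than the threshold; a
#' decrease exactly at the threshold, a smaller decrease, or any
#' increase is a non-responder.
#'
#' @param change Percent change (negative = decrease; vectorized).
#' @param threshold Required percent decrease (positive number).
#' @return `"responder"` / `"non_responder"`.
#' @export
classify_change <- function(change, threshold) {
  stopifnot(threshold > 0)
  ifelse(change < -threshold, "responder", "non_responder")
}

#' Select PERCIST target lesions
#'
#' Ranks lesions by baseline SUVmax (descending, ties broken by
#' lesion id) and keeps at most `max_total` lesions with at most
#' `max_per_organ` per organ.
#'
#' @param lesions Data frame with columns `lesion_id`, `organ`,
#'   `suv_max` (one row per lesion at baseline).
#' @param max_total,max_per_organ Selection caps.
#' @return The selected subset, in ranking order.
#' @export
select_targets <- function(lesions, max_total = 5, max_per_organ = 2) {
  stopifnot(nrow(lesions) >= 1)
  ord <- order(-lesions$suv_max, lesions$lesion_id)
  lesions <- lesions[ord, , drop = FALSE]
  kept <- integer(0)
  count <- setNames(rep(0L, length(unique(lesions$organ))),
                    unique(lesions$organ))
  for (i in seq_len(nrow(lesions))) {
    if (length(kept) >= max_total) break
    o <- lesions$organ[i]
    if (count[[o]] < max_per_organ) {
      kept <- c(kept, i)
      count[[o]] <- count[[o]] + 1L
    }
  }
  lesions[kept, , drop = FALSE]
}

#' Paired-scan response record
#'
#' Bundles the per-lesion metrics of a baseline/follow-up pair with the
#' gold-standard label used for evaluation.
#'
#' @param pair_id,patient_id Identifiers.
#' @param baseline,followup `lesion_metrics` data frames (one row per
#'   lesion; see [compute_all_metrics]).
#' @param gold_label `"responder"`, `"non_responder"`, or `NA`.
#' @param interval_months Optional time between scans.
#' @return An object of class `response_pair`.
#' @export
response_pair <- function(pair_id, patient_id, baseline, followup,
                          gold_label = NA_character_,
                          interval_months = NA_real_) {
  stopifnot(nrow(baseline) >= 1, nrow(followup) >= 1)
  if (!is.na(gold_label))
    stopifnot(gold_label %in% c("responder", "non_responder"))
  structure(list(pair_id = pair_id, patient_id = patient_id,
                 baseline = baseline, followup = followup,
                 gold_label = gold_label,
                 interval_months = interval_months),
            class = "response_pair")
}

#' Per-patient percent change under the hottest-lesion rule
#'
#' The patient-level change of a metric is the percent change between
#' the metric value of the most intense target lesion at baseline and
#' the most intense target lesion at follow-up - the two lesions may
#' differ. By default "most intense" is judged by the metric being
#' evaluated; set `rank_by_suv_max = TRUE` to always pick the hottest
#' lesion by SUVmax instead.
#'
#' @param pair A [response_pair].
#' @param metric One of `"suv_max"`, `"suv_peak"`, `"suv_mean"`, `"mv"`,
#'   `"tlg"`, `"sam"`.
#' @param rank_by_suv_max Ranking variant flag.
#' @return Percent change of the hottest-lesion value.
#' @export
patient_change_percist <- function(pair, metric,
                                   rank_by_suv_max = FALSE) {
  metric <- match.arg(metric, metric_names())
  pick <- function(frame) {
    rank_col <- if (rank_by_suv_max) frame$suv_max else frame[[metric]]
    frame[[metric]][which.max(rank_col)]
  }
  m1 <- pick(pair$baseline)
  m2 <- pick(pair$followup)
  if (length(m1) == 0 || length(m2) == 0)
    stop("no measurable lesion at one of the time points", call. = FALSE)
  percent_change(m1, m2)
}

#' Score one evolution against the gold standard
#'
#' Crosses the PET responder call with the gold label: TP = responder by
#' both, TN = non-responder by both, FP = PET responder but gold
#' non-responder, FN = PET non-responder but gold responder.
#'
#' @param pet_call,gold `"responder"` / `"non_responder"`.
#' @return One of `"TP"`, `"TN"`, `"FP"`, `"FN"`.
#' @export
confusion_cell <- function(pet_call, gold) {
  stopifnot(pet_call %in% c("responder", "non_responder"))
  if (is.na(gold)) stop("gold label missing", call. = FALSE)
  stopifnot(gold %in% c("responder", "non_responder"))
  if (pet_call == "responder") {
    if (gold == "responder") "TP" else "FP"
  } else {
    if (gold == "responder") "FN" else "TN"
  }
}

#' @rdname confusion_cell
#' @param pair A [response_pair] with a gold label.
#' @param policy A [threshold_policy].
#' @param metric Metric to evaluate.
#' @export
evaluate_pair <- function(pair, policy, metric) {
  metric <- match.arg(metric, metric_names())
  change <- patient_change_percist(pair, metric)
  call <- classify_change(change, policy[[metric]])
  confusion_cell(call, pair$gold_label)
}
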