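#' Triage policy
#'
#' How the image call and the questionnaire are fused. The default `"OR"`
#' mode is sensitivity-first: any single trigger — positive image, a hard
#' clinical flag (wound opening, secretion, fever), a high symptom count, or
#' severe pain — sends the patient to in-person review. `symptom_count_cutoff`
#' and `vas_cutoff` are calibration constants of this implementation, not
#' study-reported values.
#'
#' @param mode `"OR"`, `"image_only"` or `"questionnaire_only"`.
#' @param hard_flags subset of `c("opening", "secretion", "fever")` that
#'   individually force review.
#' @param symptom_count_cutoff review when at least this many of the six
#'   binary symptoms are present (0-6).
#' @param vas_cutoff review when pain VAS is at least this (0-10).
#' @return A `triage_policy` list.
#' @export
triage_policy <- function(mode = c("OR", "image_only", "questionnaire_only"),
                          hard_flags = c("opening", "secretion", "fever"),
                          symptom_count_cutoff = 3, vas_cutoff = 7) {
  mode <- match.arg(mode)
  stopifnot(all(hard_flags %in% c("opening", "secretion", "fever")),
            symptom_count_cutoff >= 0, symptom_count_cutoff <= 6,
            vas_cutoff >= 0, vas_cutoff <= 10)
  structure(list(mode = mode, hard_flags = hard_flags,
                 symptom_count_cutoff = symptom_count_cutoff,
                 vas_cutoff = vas_cutoff),
            class = "triage_policy")
}

#' Fuse image and questionnaire into the patient-facing decision
#'
#' @param redness a `redness_result` that has been classified (see
#'   [classify_redness()]).
#' @param qscore a `questionnaire_score` from [score_questionnaire()].
#' @param policy a [triage_policy()].
#' @return A `triage_decision`: `review_needed`, `reasons` (one string per
#'   trigger; empty when evolution is satisfactory) and `inputs_summary`.
#' @export
triage_decide <- function(redness, qscore, policy = triage_policy()) {
  stopifnot(inherits(redness, "redness_result"),
            inherits(qscore, "questionnaire_score"),
            inherits(policy, "triage_policy"))
  if (is.na(redness$positive))
    stop("redness result has no classification; run classify_redness() first")
  reasons <- character(0)
  use_img <- policy$mode %in% c("OR", "image_only")
  use_q <- policy$mode %in% c("OR", "questionnaire_only")
  if (use_img && redness$positive)
    reasons <- c(reasons, sprintf("redness %.3f >= threshold %.2f",
                                  redness$proportion, redness$threshold))
  if (use_q) {
    for (fl in policy$hard_flags)
      if (qscore$items[[fl]] == 1) reasons <- c(reasons, paste0("hard flag: ", fl))
    if (qscore$symptom_count >= policy$symptom_count_cutoff)
      reasons <- c(reasons, sprintf("symptom count %d >= %d",
                                    qscore$symptom_count,
                                    policy$symptom_count_cutoff))
    if (qscore$vas >= policy$vas_cutoff)
      reasons <- c(reasons, sprintf("VAS %d >= %d", qscore$vas, policy$vas_cutoff))
  }
  structure(list(review_needed = length(reasons) > 0,
                 reasons = reasons,
                 inputs_summary = list(redness_proportion = redness$proportion,
                                       redness_threshold = redness$threshold,
                                       symptom_count = qscore$symptom_count,
                                       vas = qscore$vas,
                                       fever_flag = qscore$fever_flag),
                 policy = policy),
            class = "triage_decision")
}

#' @export
print.triage_decision <- function(x, ...) {
  cat(sprintf("<triage_decision> %s\n",
              if (x$review_needed) "NEEDS IN-PERSON REVIEW" else
                "satisfactory evolution"))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}
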