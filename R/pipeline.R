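#' Resolved run configuration
#'
#' One object holding every tunable of the screening pipeline, so a run can
#' be reproduced from its emitted configuration. Defaults are the package
#' defaults of the individual modules; the redness cutoff 0.63 is the study
#' calibration constant.
#'
#' @param threshold redness-proportion infection cutoff.
#' @param method `"crisp"` or `"weighted"` redness proportion.
#' @param inpaint_first reconstruct under the staple mask before scoring
#'   (default); when `FALSE`, staple pixels are excluded from the ROI
#'   instead.
#' @param roi_mode `"band"` (peri-wound band around the staple axis, falling
#'   back to whole-image when no axis is found) or `"whole_image"`.
#' @param detect a [staple_detect_params()].
#' @param red a [red_membership_params()].
#' @param policy a [triage_policy()].
#' @param inpaint_iterations,inpaint_tol diffusion inpainting controls.
#' @param seed top-level seed recorded for provenance.
#' @return A `run_config` list.
#' @export
run_config <- function(threshold = 0.63,
                       method = c("crisp", "weighted"),
                       inpaint_first = TRUE,
                       roi_mode = c("band", "whole_image"),
                       detect = staple_detect_params(),
                       red = red_membership_params(),
                       policy = triage_policy(),
                       inpaint_iterations = 500, inpaint_tol = 1e-5,
                       seed = 1L) {
  structure(list(threshold = threshold, method = match.arg(method),
                 inpaint_first = inpaint_first,
                 roi_mode = match.arg(roi_mode),
                 detect = detect, red = red, policy = policy,
                 inpaint_iterations = inpaint_iterations,
                 inpaint_tol = inpaint_tol, seed = as.integer(seed)),
            class = "run_config")
}

config_as_list <- function(config) {
  list(threshold = config$threshold, method = config$method,
       inpaint_first = config$inpaint_first, roi_mode = config$roi_mode,
       detect = list(se_size = config$detect$se_size,
                     brightness_threshold = config$detect$brightness_threshold,
                     min_area = config$detect$min_area,
                     max_area = config$detect$max_area,
                     min_elongation = config$detect$min_elongation,
                     max_saturation = config$detect$max_saturation,
                     roi_halfwidth = config$detect$roi_halfwidth,
                     logic = config$detect$logic$name),
       red = unclass(config$red),
       policy = unclass(config$policy),
       inpaint_iterations = config$inpaint_iterations,
       inpaint_tol = config$inpaint_tol,
       seed = config$seed)
}

#' Load a run configuration from a YAML file
#'
#' Only keys present in the file override the defaults; nested blocks
#' (`detect`, `red`, `policy`) merge the same way.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A [run_config()].
#' @export
read_run_config <- function(path = NULL) {
  if (is.null(path)) return(run_config())
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("threshold", "method", "inpaint_first", "roi_mode",
              "inpaint_iterations", "inpaint_tol", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$detect)) args$detect <- do.call(staple_detect_params, y$detect)
  if (!is.null(y$red)) args$red <- do.call(red_membership_params, y$red)
  if (!is.null(y$policy)) args$policy <- do.call(triage_policy, y$policy)
  do.call(run_config, args)
}

#' Screen a single wound photograph end to end
#'
#' Runs the full image pipeline — staple detection, optional inpainting,
#' peri-wound ROI, redness proportion, classification — and, when a
#' questionnaire record is supplied, fuses image and questionnaire into the
#' triage decision.
#'
#' @param image a [wound_image()].
#' @param record optional `questionnaire_record` (see [validate_record()]).
#' @param config a [run_config()].
#' @return A `wound_screen` list: `detection`, `redness`,
#'   `axis_undeterminable`, `decision` (`NULL` without a questionnaire),
#'   `config`.
#' @export
screen_wound <- function(image, record = NULL, config = run_config()) {
  stopifnot(inherits(image, "wound_image"))
  det <- detect_staples(image, config$detect)
  scored_img <- image
  if (config$inpaint_first && any(det$staple_mask))
    scored_img <- inpaint_staples(image, det$staple_mask,
                                  iterations = config$inpaint_iterations,
                                  tol = config$inpaint_tol)
  axis_undeterminable <- is.null(det$wound_axis)
  roi <- if (config$roi_mode == "band" && !axis_undeterminable)
    det$roi_mask else matrix(TRUE, dim(image)[1], dim(image)[2])
  if (!config$inpaint_first) roi <- roi & !det$staple_mask
  if (!any(roi)) roi <- matrix(TRUE, dim(image)[1], dim(image)[2])
  red <- redness_proportion(scored_img, roi, config$red, config$method)
  red <- classify_redness(red, config$threshold)
  decision <- NULL
  if (!is.null(record)) {
    qs <- score_questionnaire(record)
    decision <- triage_decide(red, qs, config$policy)
  }
  structure(list(detection = det, redness = red,
                 axis_undeterminable = axis_undeterminable,
                 decision = decision, config = config),
            class = "wound_screen")
}

#' @export
print.wound_screen <- function(x, ...) {
  cat("<wound_screen>\n")
  cat(sprintf("  staples: %d%s\n", nrow(x$detection$components),
              if (x$axis_undeterminable) " (axis undeterminable; whole-image ROI)" else ""))
  cat(sprintf("  redness: %.4f (threshold %.2f) -> %s\n",
              x$redness$proportion, x$redness$threshold,
              if (x$redness$positive) "POSITIVE" else "negative"))
  if (!is.null(x$decision))
    cat(sprintf("  triage: %s\n", if (x$decision$review_needed)
      "needs in-person review" else "satisfactory evolution"))
  invisible(x)
}

#' Screen every image of a synthetic cohort and evaluate the screen
#'
#' Renders each cohort image, runs [screen_wound()], and compares the
#' image-level calls with the cohort's ground-truth labels. Patient-level
#' aggregation (a patient is positive when any of their images is) is also
#' reported.
#'
#' @param cohort a `wound_cohort` from [generate_cohort()].
#' @param config a [run_config()].
#' @param use_questionnaire fuse the paired questionnaires via the triage
#'   policy; otherwise the image-only call is evaluated.
#' @param progress print a dot per image.
#' @return A `cohort_screen` list: `results` data frame (per image:
#'   proportion, prediction, truth, decision), `eval`
#'   (see [evaluate_predictions()]), `patient_eval`, `config`.
#' @export
screen_cohort <- function(cohort, config = run_config(),
                          use_questionnaire = FALSE, progress = FALSE) {
  stopifnot(inherits(cohort, "wound_cohort"))
  n <- nrow(cohort$manifest)
  prop <- numeric(n); pred <- integer(n); review <- logical(n)
  n_staples <- integer(n)
  for (i in seq_len(n)) {
    sc <- cohort_image(cohort, i)
    rec <- if (use_questionnaire) cohort$questionnaires[[i]] else NULL
    out <- screen_wound(sc$image, rec, config)
    prop[i] <- out$redness$proportion
    pred[i] <- as.integer(out$redness$positive)
    review[i] <- if (is.null(out$decision)) NA else out$decision$review_needed
    n_staples[i] <- nrow(out$detection$components)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  res <- cbind(cohort$manifest,
               data.frame(proportion = prop, prediction = pred,
                          n_staples_found = n_staples,
                          review_needed = review))
  final_pred <- if (use_questionnaire) as.integer(review) else pred
  ev <- evaluate_predictions(final_pred, res$truth, scores = prop)
  pat <- stats::aggregate(cbind(pred = final_pred, truth = res$truth),
                          by = list(patient_code = res$patient_code),
                          FUN = max)
  pat_ev <- if (length(unique(pat$truth)) == 2)
    evaluate_predictions(pat$pred, pat$truth) else NULL
  structure(list(results = res, eval = ev, patient_eval = pat_ev,
                 config = config),
            class = "cohort_screen")
}

#' @export
print.cohort_screen <- function(x, ...) {
  cat(sprintf("<cohort_screen> %d images\n", nrow(x$results)))
  print(x$eval$metrics)
  if (!is.null(x$eval$roc))
    cat(sprintf("  AUC %.4f, Youden-optimal threshold %.4f\n",
                x$eval$roc$auc, x$eval$roc$optimal_threshold))
  invisible(x)
}
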