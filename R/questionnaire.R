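#' Validate a raw symptom-questionnaire record
#'
#' The per-visit questionnaire has seven items: pain on a 0-10 visual analog
#' scale (VAS) and six binary signs — redness around the wound, burning
#' sensation, wound opening, swelling, liquid secretion, and fever. All seven
#' must be answered: the screen has a hard completeness gate, with no
#' imputation. Fever may be supplied as a 0/1 answer or as a raw body
#' temperature in degrees Celsius (coded 1 when strictly above 37.7);
#' when both a binary answer and a temperature are given and disagree, the
#' temperature wins and a warning is raised.
#'
#' @param raw named list or one-row data frame with keys `vas`, `redness`,
#'   `burning`, `opening`, `swelling`, `secretion`, `fever` and optionally
#'   `temperature_c`, `timestamp`, `patient_code`.
#' @return A `questionnaire_record` list with all items coded 0/1 (fever
#'   resolved), `vas` integer, and any supplied metadata.
#' @export
#' @examples
#' validate_record(list(vas = 2, redness = 0, burning = 0, opening = 0,
#'                      swelling = 0, secretion = 0, fever = 0))
validate_record <- function(raw) {
  if (is.data.frame(raw)) {
    stopifnot(nrow(raw) == 1)
    raw <- as.list(raw)
  }
  binaries <- c("redness", "burning", "opening", "swelling", "secretion")
  required <- c("vas", binaries, "fever")
  optional <- c("temperature_c", "timestamp", "patient_code")
  unknown <- setdiff(names(raw), c(required, optional))
  if (length(unknown))
    stop("unknown questionnaire keys: ", paste(unknown, collapse = ", "))
  missing_keys <- required[!required %in% names(raw) |
                           vapply(required, function(k) is.null(raw[[k]]) ||
                                    (length(raw[[k]]) == 1 && is.na(raw[[k]])),
                                  logical(1))]
  if (length(missing_keys))
    stop("incomplete questionnaire: missing ",
         paste(missing_keys, collapse = ", "))

  coerce_int <- function(x, what) {
    if (is.character(x)) {
      if (!grepl("^\\s*-?[0-9]+\\s*$", x))
        stop("coding error: ", what, " must be an integer, got \"", x, "\"")
      x <- as.numeric(x)
    }
    if (!is.numeric(x) || length(x) != 1 || x != round(x))
      stop("coding error: ", what, " must be a single integer")
    as.integer(x)
  }
  vas <- coerce_int(raw$vas, "vas")
  if (vas < 0 || vas > 10) stop("vas out of range: must be in 0..10")
  rec <- list(vas = vas)
  for (b in binaries) {
    v <- coerce_int(raw[[b]], b)
    if (!v %in% c(0L, 1L)) stop("coding error: ", b, " must be 0 or 1")
    rec[[b]] <- v
  }

  fever_raw <- raw$fever
  temp <- raw$temperature_c
  # a fever "answer" that looks like a temperature is treated as one
  if (is.null(temp) && is.numeric(fever_raw) && length(fever_raw) == 1 &&
      !fever_raw %in% c(0, 1)) {
    temp <- fever_raw; fever_raw <- NULL
  }
  fever_bin <- if (!is.null(fever_raw)) {
    v <- coerce_int(fever_raw, "fever")
    if (!v %in% c(0L, 1L)) stop("coding error: fever must be 0, 1 or a temperature")
    v
  } else NULL
  if (!is.null(temp)) {
    fever_t <- fever_from_temperature(temp)
    if (!is.null(fever_bin) && fever_bin != fever_t)
      warning(sprintf("fever answer %d disagrees with temperature %.1f C; using the temperature",
                      fever_bin, temp), call. = FALSE)
    rec$fever <- fever_t
    rec$temperature_c <- as.numeric(temp)
  } else {
    rec$fever <- fever_bin
  }
  rec$timestamp <- raw$timestamp
  rec$patient_code <- if (is.null(raw$patient_code)) NA_character_ else
    as.character(raw$patient_code)
  structure(rec, class = "questionnaire_record")
}

#' Code fever from a body temperature
#'
#' Fever is coded 1 when the temperature is strictly above 37.7 degrees C.
#' Temperatures outside a 30-45 degree sanity window are rejected as
#' recording errors.
#'
#' @param temp_c body temperature in degrees Celsius.
#' @return Integer 0 or 1 (vectorised).
#' @export
#' @examples
#' fever_from_temperature(c(36, 37.7, 38))  # 0 0 1
fever_from_temperature <- function(temp_c) {
  if (!is.numeric(temp_c) || anyNA(temp_c))
    stop("temperature must be numeric")
  if (any(temp_c < 30 | temp_c > 45))
    stop("temperature outside the 30-45 C sanity window")
  as.integer(temp_c > 37.7)
}

#' Score a validated questionnaire record
#'
#' @param record a `questionnaire_record` from [validate_record()].
#' @return A `questionnaire_score` list: `symptom_count` (0-6, the sum of
#'   the six binary items), `vas`, `fever_flag`.
#' @export
score_questionnaire <- function(record) {
  stopifnot(inherits(record, "questionnaire_record"))
  items <- c("redness", "burning", "opening", "swelling", "secretion", "fever")
  cnt <- sum(vapply(items, function(k) record[[k]], integer(1)))
  structure(list(symptom_count = as.integer(cnt),
                 vas = record$vas,
                 fever_flag = record$fever,
                 items = lapply(stats::setNames(items, items),
                                function(k) record[[k]])),
            class = "questionnaire_score")
}

#' @export
print.questionnaire_score <- function(x, ...) {
  cat(sprintf("<questionnaire_score> %d/6 symptoms, VAS %d, fever %d\n",
              x$symptom_count, x$vas, x$fever_flag))
  invisible(x)
}

#' Read one questionnaire record per visit from JSON or CSV
#'
#' @param path a `.json` file (one object, or an array of objects) or a
#'   `.csv` file (one row per visit).
#' @return A list of validated `questionnaire_record`s.
#' @export
read_questionnaires <- function(path) {
  if (!file.exists(path)) stop("incomplete questionnaire: file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!is.null(names(x))) x <- list(x)
    lapply(x, validate_record)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(df)), function(i) validate_record(df[i, , drop = FALSE]))
  }
}
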