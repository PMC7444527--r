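#' Read a long-format response table
#'
#' Reads a CSV with one row per volunteer x face pair and validates it into
#' the canonical response table. Required columns: `volunteer_id`, `variant`,
#' `version`, `item_id`, `truth`, `prior_label`, `rating`, `is_catch`.
#' Ratings are integers on the 7-point certainty scale from -3 ("absolutely
#' certain these are different people") through 0 ("not sure") to +3
#' ("absolutely certain this is the same person").
#'
#' Validation failures are reported with the 1-based file line number of the
#' offending row (the header is line 1). A missing column is a schema error;
#' an out-of-range or non-integer rating, or an unknown enum value, is a
#' validation error listing every bad line.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble of validated rating records in canonical column order,
#'   with `rating` integer and `is_catch` logical.
#' @seealso [write_response_table()], [validate_records()]
#' @export
read_response_table <- function(path) {
  if (!file.exists(path)) {
    stop("response table not found: ", path, call. = FALSE)
  }
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  missing <- setdiff(RESPONSE_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[RESPONSE_COLUMNS]
  lines <- seq_len(nrow(raw)) + 1L  # header occupies line 1

  problems <- character(0)
  note <- function(bad, what) {
    if (any(bad)) {
      problems <<- c(problems, paste0(
        what, " on line(s) ", paste(lines[bad], collapse = ", ")))
    }
  }

  rating_num <- suppressWarnings(as.numeric(raw$rating))
  note(is.na(rating_num) | rating_num != round(rating_num),
       "non-integer rating")
  ok_num <- !is.na(rating_num) & rating_num == round(rating_num)
  note(ok_num & (rating_num < -3 | rating_num > 3),
       "rating outside [-3, 3]")
  note(!(raw$variant %in% VARIANT_LEVELS), "unknown variant")
  note(!(raw$version %in% VERSION_LEVELS), "unknown version")
  note(!(raw$truth %in% TRUTH_LEVELS), "unknown truth")
  note(!(raw$prior_label %in% PRIOR_LEVELS), "unknown prior_label")
  note(!(toupper(raw$is_catch) %in% c("TRUE", "FALSE")), "unknown is_catch")

  if (length(problems) > 0) {
    stop("validation error:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }

  records <- tibble::tibble(
    volunteer_id = raw$volunteer_id,
    variant = raw$variant,
    version = raw$version,
    item_id = raw$item_id,
    truth = raw$truth,
    prior_label = raw$prior_label,
    rating = as.integer(rating_num),
    is_catch = toupper(raw$is_catch) == "TRUE"
  )
  validate_records(records)
}

#' Validate a response table against the survey-design invariants
#'
#' Checks, beyond per-field types and enums: control responses carry no prior
#' label (and only control responses may), and no volunteer responds to the
#' same item twice within a (variant, version) cell. Duplicate rows are a
#' hard error because the nested design makes them ambiguous.
#'
#' @param records A response tibble (see [read_response_table()]).
#' @return The records, invisibly reordered to canonical column order.
#' @export
validate_records <- function(records) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(RESPONSE_COLUMNS, names(records))
  if (length(missing) > 0) {
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  records <- records[RESPONSE_COLUMNS]
  stopifnot(
    is.numeric(records$rating),
    all(records$rating == round(records$rating)),
    all(records$rating >= -3 & records$rating <= 3),
    is.logical(records$is_catch)
  )
  if (!all(records$variant %in% VARIANT_LEVELS) ||
      !all(records$truth %in% TRUTH_LEVELS) ||
      !all(records$prior_label %in% PRIOR_LEVELS) ||
      !all(records$version %in% VERSION_LEVELS)) {
    stop("validation error: unknown enum value in variant/truth/prior_label/version",
         call. = FALSE)
  }
  is_control <- records$variant == "control"
  if (any(is_control & records$prior_label != "none")) {
    stop("validation error: control responses must have prior_label 'none'",
         call. = FALSE)
  }
  if (any(!is_control & !records$is_catch & records$prior_label == "none")) {
    stop("validation error: sourced experimental responses must carry a prior label",
         call. = FALSE)
  }
  key <- paste(records$variant, records$version, records$volunteer_id,
               records$item_id, sep = "\r")
  if (anyDuplicated(key) > 0) {
    dup <- records[duplicated(key), , drop = FALSE]
    stop("validation error: duplicate volunteer x item row(s), e.g. volunteer ",
         dup$volunteer_id[1], " item ", dup$item_id[1], call. = FALSE)
  }
  records$rating <- as.integer(records$rating)
  invisible(records)
}

#' Write the canonical response CSV
#'
#' Writes records in canonical column order as plain UTF-8 comma-separated
#' text with a header and no quoting, so that write -> read -> write is
#' byte-identical. Identifiers must therefore not contain commas or quotes.
#'
#' @param records A validated response tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(records, path) {
  records <- validate_records(records)
  chr <- c(records$volunteer_id, records$item_id)
  if (any(grepl('[,"\n]', chr))) {
    stop("identifiers must not contain commas, quotes, or newlines", call. = FALSE)
  }
  out <- as.data.frame(records)
  out$is_catch <- ifelse(out$is_catch, "TRUE", "FALSE")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a volunteer profile table
#'
#' Optional demographics and trust responses: columns `volunteer_id`,
#' `gender`, `age_bin`, `race`, `trust_response`. Age bins follow the study's
#' six brackets; empty cells become `"missing"` for `trust_response` and `NA`
#' for demographics (volunteers with missing demographics are retained for
#' signal-detection analysis and dropped only from demographic tables).
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per volunteer.
#' @export
read_volunteer_table <- function(path) {
  if (!file.exists(path)) {
    stop("volunteer table not found: ", path, call. = FALSE)
  }
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  required <- c("volunteer_id", "gender", "age_bin", "race", "trust_response")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$volunteer_id) > 0) {
    stop("validation error: duplicate volunteer_id in profile table",
         call. = FALSE)
  }
  bad_bin <- !(raw$age_bin %in% c(AGE_BINS, "", NA))
  if (any(bad_bin)) {
    stop("validation error: unknown age_bin on line(s) ",
         paste(which(bad_bin) + 1L, collapse = ", "), call. = FALSE)
  }
  trust <- tolower(raw$trust_response)
  trust[trust == "" | is.na(trust)] <- "missing"
  if (!all(trust %in% TRUST_LEVELS)) {
    stop("validation error: trust_response must be yes/no/not_sure/missing",
         call. = FALSE)
  }
  tibble::tibble(
    volunteer_id = raw$volunteer_id,
    gender = ifelse(raw$gender == "", NA_character_, raw$gender),
    age_bin = ifelse(raw$age_bin == "", NA_character_, raw$age_bin),
    race = ifelse(raw$race == "", NA_character_, raw$race),
    trust_response = trust
  )
}

#' Catch-trial screening rule
#'
#' The celebrity face pairs are screening controls: one mated, one obviously
#' non-mated, both easy for a compliant observer. The default rule counts a
#' response correct only when its sign matches the ground truth with at least
#' "somewhat certain" confidence, so "not sure" (0) fails. Set
#' `unsure_fails = FALSE` to accept a 0 response.
#'
#' @param unsure_fails Should a "not sure" (0) rating on a catch pair count
#'   as a failure? Default `TRUE`.
#' @return A screening-rule object for [screen_catch_trials()].
#' @export
catch_rule <- function(unsure_fails = TRUE) {
  structure(list(unsure_fails = isTRUE(unsure_fails)), class = "catch_rule")
}

#' Screen volunteers by their catch-trial responses
#'
#' A volunteer is excluded when any celebrity catch-pair response violates
#' the rule: for a mated pair the rating must be >= +1, for a non-mated pair
#' <= -1 (under the default strict rule). Exclusion is volunteer-level: all
#' of an excluded volunteer's records are dropped. Catch-trial records are
#' removed from the kept set as well, since they are screening controls and
#' take no part in the analysis.
#'
#' Volunteers with no catch trials at all cannot be screened; they are
#' retained and reported in `$unscreenable` with a warning.
#'
#' @param records A validated response tibble.
#' @param rule A [catch_rule()].
#' @return A list with `kept` (experimental records of retained volunteers),
#'   `excluded` (tibble of `volunteer_id`, `reason`), and `unscreenable`
#'   (character vector of volunteer ids lacking catch trials).
#' @export
screen_catch_trials <- function(records, rule = catch_rule()) {
  records <- validate_records(records)
  if (nrow(records) == 0) {
    stop("cannot screen an empty response table", call. = FALSE)
  }
  stopifnot(inherits(rule, "catch_rule"))
  catch <- records[records$is_catch, , drop = FALSE]

  all_ids <- unique(records$volunteer_id)
  unscreenable <- setdiff(all_ids, unique(catch$volunteer_id))
  if (length(unscreenable) > 0) {
    warning(length(unscreenable),
            " volunteer(s) have no catch trials and cannot be screened; retained",
            call. = FALSE)
  }

  lo <- if (rule$unsure_fails) 1L else 0L
  correct <- ifelse(catch$truth == "same",
                    catch$rating >= lo,
                    catch$rating <= -lo)
  failed <- unique(catch$volunteer_id[!correct])

  kept <- records[!records$is_catch &
                    !(records$volunteer_id %in% failed), , drop = FALSE]
  list(
    kept = kept,
    excluded = tibble::tibble(
      volunteer_id = failed,
      reason = rep("incorrect catch-trial response", length(failed))
    ),
    unscreenable = unscreenable
  )
}

#' Summarize the survey design of a response table
#'
#' Reports per-variant volunteer counts, per-item prior-label coverage, and
#' balance checks of the nested design: equal numbers of mated and non-mated
#' experimental pairs, and (within each sourced variant) every experimental
#' item presented under both the "same" and the "different" label across the
#' two survey versions. Imbalances are reported, never raised as errors.
#'
#' @param records A validated response tibble.
#' @return A list of class `design_summary` with elements
#'   `volunteers_by_variant`, `items`, `item_label_coverage`, and `balance`
#'   (named logical flags `truth_balanced` and `labels_counterbalanced`).
#' @export
summarize_design <- function(records) {
  records <- validate_records(records)
  expt <- records[!records$is_catch, , drop = FALSE]

  volunteers_by_variant <- expt |>
    dplyr::distinct(.data$variant, .data$volunteer_id) |>
    dplyr::count(.data$variant, name = "n_volunteers")

  items <- expt |>
    dplyr::distinct(.data$item_id, .data$truth) |>
    dplyr::arrange(.data$item_id)
  truth_balanced <- sum(items$truth == "same") == sum(items$truth == "different")

  coverage <- expt |>
    dplyr::filter(.data$variant != "control") |>
    dplyr::distinct(.data$variant, .data$item_id, .data$prior_label) |>
    dplyr::count(.data$variant, .data$item_id, name = "n_labels")
  labels_counterbalanced <- nrow(coverage) > 0 && all(coverage$n_labels == 2L)

  structure(list(
    volunteers_by_variant = volunteers_by_variant,
    items = items,
    item_label_coverage = coverage,
    balance = c(truth_balanced = truth_balanced,
                labels_counterbalanced = labels_counterbalanced)
  ), class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  cat("Survey design summary\n")
  cat("  volunteers:",
      paste(sprintf("%s=%d", x$volunteers_by_variant$variant,
                    x$volunteers_by_variant$n_volunteers), collapse = ", "),
      "\n")
  cat("  experimental items:", nrow(x$items),
      sprintf("(%d same / %d different)", sum(x$items$truth == "same"),
              sum(x$items$truth == "different")), "\n")
  cat("  truth balanced:", x$balance[["truth_balanced"]],
      "| labels counterbalanced:", x$balance[["labels_counterbalanced"]], "\n")
  invisible(x)
}
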