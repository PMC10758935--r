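#' Assemble a coaching cohort
#'
#' A cohort bundles three tidy tables keyed by `member_id`:
#' \describe{
#'   \item{members}{demographics at enrollment: `member_id`, `age_years`,
#'     `age_band` (`"child"` 6-12 / `"adolescent"` 13-17), `sex`,
#'     `gender_conformity`, `ethnicity`, `enrollment_date`,
#'     `symptom_group` (`"anxiety"` / `"depression"`), `instrument_id`.}
#'   \item{sessions}{one row per attended coaching session: `member_id`,
#'     `date`; strictly increasing within member.}
#'   \item{assessments}{scored observations as returned by
#'     [score_assessments()]; [align_assessments()] adds `session_index`.}
#' }
#'
#' @param members,sessions,assessments tibbles as described above.
#' @return object of class `coach_cohort`.
#' @export
coach_cohort <- function(members, sessions, assessments) {
  members <- tibble::as_tibble(members)
  sessions <- tibble::as_tibble(sessions)
  assessments <- tibble::as_tibble(assessments)
  abort_if(!all(c("member_id", "age_years", "age_band", "enrollment_date",
                  "symptom_group", "instrument_id") %in% names(members)),
           "members table is missing required columns")
  abort_if(anyNA(members$enrollment_date),
           "every member needs an enrollment date")
  abort_if(!all(members$age_years >= 6 & members$age_years <= 17),
           "age_years must lie in [6, 17]")
  band <- ifelse(members$age_years < 13, "child", "adolescent")
  abort_if(!all(band == members$age_band),
           "age_band inconsistent with age_years")
  sessions$date <- as.Date(sessions$date)
  assessments$date <- as.Date(assessments$date)
  bad <- sessions |>
    dplyr::group_by(.data$member_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$date, strictly = TRUE)) |>
    dplyr::filter(!.data$ok)
  abort_if(nrow(bad) > 0,
           sprintf("session dates not strictly increasing for member %s",
                   bad$member_id[1]))
  if (!"session_index" %in% names(assessments)) {
    assessments$session_index <- NA_integer_
  }
  structure(
    list(members = members, sessions = sessions, assessments = assessments),
    class = "coach_cohort"
  )
}

#' @export
print.coach_cohort <- function(x, ...) {
  cat("<coach_cohort> ", nrow(x$members), " members, ",
      nrow(x$sessions), " sessions, ", nrow(x$assessments),
      " assessment observations\n", sep = "")
  grp <- table(x$members$symptom_group)
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# per-member session counts
session_counts <- function(cohort) {
  cohort$members |>
    dplyr::select("member_id") |>
    dplyr::left_join(
      dplyr::count(cohort$sessions, .data$member_id, name = "n_sessions"),
      by = "member_id"
    ) |>
    dplyr::mutate(n_sessions = dplyr::coalesce(.data$n_sessions, 0L))
}

#' Align assessments to session counts
#'
#' Assigns each assessment its session index — the number of coaching
#' sessions on or before the assessment date — and thins the timeline so
#' that each inter-session interval keeps only its first assessment.
#' Assessments dated before the first session share index 0; the latest of
#' them is retained as the baseline (the last pre-coaching measurement).
#' For every index of 1 or more (including the interval after the last
#' session) the earliest assessment is kept and later duplicates dropped.
#' The operation is idempotent.
#'
#' @param cohort a [coach_cohort()].
#' @return the cohort with `assessments$session_index` populated and
#'   duplicate assessments removed.
#' @export
align_assessments <- function(cohort) {
  stopifnot(inherits(cohort, "coach_cohort"))
  sess <- split(cohort$sessions$date, cohort$sessions$member_id)
  a <- cohort$assessments
  idx <- vapply(seq_len(nrow(a)), function(i) {
    s <- sess[[a$member_id[i]]]
    if (is.null(s)) 0L else sum(s <= a$date[i])
  }, 1L)
  a$session_index <- idx
  a <- a |>
    dplyr::arrange(.data$member_id, .data$date) |>
    dplyr::group_by(.data$member_id, .data$session_index) |>
    dplyr::filter(
      if (.data$session_index[1] == 0L) {
        # baseline: the latest pre-coaching completed full assessment;
        # screen-outs cannot displace a scored baseline
        if (any(!.data$screened_out)) {
          dplyr::row_number() == max(which(!.data$screened_out))
        } else {
          dplyr::row_number() == dplyr::n()
        }
      } else {
        dplyr::row_number() == 1L           # otherwise: first in interval
      }
    ) |>
    dplyr::ungroup()
  cohort$assessments <- a
  cohort
}

#' Per-member care statistics
#'
#' Duration in coaching is measured first-to-last session and expressed in
#' 30.44-day months; the session rate divides attended sessions by that
#' duration; the between-session statistic is the mean successive gap in
#' weeks.
#'
#' @param cohort a [coach_cohort()].
#' @return tibble with one row per member: `member_id`, `n_sessions`,
#'   `n_assessments`, `duration_months`, `sessions_per_month`,
#'   `mean_between_session_weeks`. Members with fewer than 2 sessions get
#'   `NA` statistics (rates are undefined without a gap).
#' @export
compute_care_statistics <- function(cohort) {
  stopifnot(inherits(cohort, "coach_cohort"))
  st <- cohort$sessions |>
    dplyr::group_by(.data$member_id) |>
    dplyr::summarise(
      n_sessions = dplyr::n(),
      duration_months = as.numeric(max(.data$date) - min(.data$date)) / DAYS_PER_MONTH,
      mean_between_session_weeks = mean(diff(as.numeric(.data$date))) / 7
    ) |>
    dplyr::mutate(
      sessions_per_month = ifelse(.data$duration_months > 0,
                                  .data$n_sessions / .data$duration_months,
                                  NA_real_),
      duration_months = ifelse(.data$n_sessions < 2L, NA_real_, .data$duration_months),
      sessions_per_month = ifelse(.data$n_sessions < 2L, NA_real_, .data$sessions_per_month)
    )
  n_assess <- dplyr::count(cohort$assessments, .data$member_id, name = "n_assessments")
  cohort$members |>
    dplyr::select("member_id") |>
    dplyr::left_join(st, by = "member_id") |>
    dplyr::left_join(n_assess, by = "member_id") |>
    dplyr::mutate(
      n_sessions = dplyr::coalesce(.data$n_sessions, 0L),
      n_assessments = dplyr::coalesce(.data$n_assessments, 0L)
    )
}

#' Apply cohort inclusion criteria with an exclusion ledger
#'
#' Criteria are applied sequentially, in the order the study protocol
#' lists them, and each excluded member is counted under the first
#' criterion that removes them:
#' \enumerate{
#'   \item 2 completed assessments (a full baseline assessment dated before
#'     the first session, plus at least one assessment observation during
#'     coaching);
#'   \item 1.5-2.5 sessions per month;
#'   \item 1-3 weeks mean between-session gap;
#'   \item 3 or more sessions attended;
#'   \item moderate or moderately severe baseline severity (per the
#'     instrument's `eligible_severities`).
#' }
#' Members below the session-count floor have no meaningful session rate
#' or gap (the two windows are jointly unsatisfiable for very short
#' schedules); they fall through criteria 2-3 and are excluded under
#' criterion 4. Assessments must already be aligned (see
#' [align_assessments()]).
#'
#' @param cohort an aligned [coach_cohort()].
#' @param configs named list of instrument configurations.
#' @param sessions_per_month_range,between_session_weeks_range,min_sessions
#'   criterion windows; defaults match the study protocol.
#' @return list with `cohort` (retained members only) and `ledger`, a
#'   tibble of per-criterion exclusion counts satisfying
#'   `sum(excluded) + retained = input size`.
#' @export
apply_inclusion_criteria <- function(cohort,
                                     configs = default_instrument_configs(),
                                     sessions_per_month_range = c(1.5, 2.5),
                                     between_session_weeks_range = c(1, 3),
                                     min_sessions = 3L) {
  stopifnot(inherits(cohort, "coach_cohort"))
  abort_if(nrow(cohort$assessments) > 0 && anyNA(cohort$assessments$session_index),
           "assessments must be aligned first (align_assessments)")
  stats <- compute_care_statistics(cohort)
  a <- cohort$assessments

  baseline_ok <- a |>
    dplyr::filter(.data$session_index == 0L, !.data$screened_out) |>
    dplyr::distinct(.data$member_id) |>
    dplyr::mutate(has_baseline = TRUE)
  followup_ok <- a |>
    dplyr::filter(.data$session_index >= 1L) |>
    dplyr::distinct(.data$member_id) |>
    dplyr::mutate(has_followup = TRUE)
  base_sev <- a |>
    dplyr::filter(.data$session_index == 0L, !.data$screened_out) |>
    dplyr::group_by(.data$member_id) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup() |>
    dplyr::select("member_id", baseline_severity = "severity")

  eligible <- vapply(cohort$members$instrument_id, function(id) {
    cfg <- configs[[id]]
    abort_if(is.null(cfg), sprintf("no configuration for instrument %s", id))
    TRUE
  }, TRUE)

  m <- cohort$members |>
    dplyr::left_join(stats, by = "member_id") |>
    dplyr::left_join(baseline_ok, by = "member_id") |>
    dplyr::left_join(followup_ok, by = "member_id") |>
    dplyr::left_join(base_sev, by = "member_id") |>
    dplyr::mutate(
      has_baseline = dplyr::coalesce(.data$has_baseline, FALSE),
      has_followup = dplyr::coalesce(.data$has_followup, FALSE),
      sev_ok = mapply(function(sev, id) {
        !is.na(sev) && sev %in% configs[[id]]$eligible_severities
      }, .data$baseline_severity, .data$instrument_id)
    )

  rate_ok <- function(x) !is.na(x) &
    x >= sessions_per_month_range[1] & x <= sessions_per_month_range[2]
  gap_ok <- function(x) !is.na(x) &
    x >= between_session_weeks_range[1] & x <= between_session_weeks_range[2]

  # first failing criterion per member. Session rate and gap windows are
  # only evaluable once the session-count floor is met: with fewer than 3
  # sessions the two windows are jointly unsatisfiable, so such members
  # are counted under the session-count criterion.
  enough <- m$n_sessions >= min_sessions
  reason <- dplyr::case_when(
    !(m$has_baseline & m$has_followup) ~ "2 completed assessments (baseline and during coaching)",
    enough & !rate_ok(m$sessions_per_month) ~ "1.5-2.5 sessions per month",
    enough & !gap_ok(m$mean_between_session_weeks) ~ "1-3 weeks between-sessions",
    m$n_sessions < min_sessions ~ "3 or more sessions attended",
    !m$sev_ok ~ "moderate or moderately severe baseline severity",
    TRUE ~ NA_character_
  )

  criteria <- c("2 completed assessments (baseline and during coaching)",
                "1.5-2.5 sessions per month",
                "1-3 weeks between-sessions",
                "3 or more sessions attended",
                "moderate or moderately severe baseline severity")
  ledger <- tibble::tibble(
    criterion = criteria,
    n_excluded = vapply(criteria, function(cr) sum(reason == cr, na.rm = TRUE), 1L,
                        USE.NAMES = FALSE)
  )
  keep <- cohort$members$member_id[is.na(reason)]
  retained <- coach_cohort(
    members = dplyr::filter(cohort$members, .data$member_id %in% keep),
    sessions = dplyr::filter(cohort$sessions, .data$member_id %in% keep),
    assessments = dplyr::filter(cohort$assessments, .data$member_id %in% keep)
  )
  ledger <- dplyr::bind_rows(
    ledger,
    tibble::tibble(criterion = "retained", n_excluded = length(keep))
  )
  list(cohort = retained, ledger = ledger,
       exclusion_reason = tibble::tibble(member_id = cohort$members$member_id,
                                         reason = reason))
}

#' Write a cohort to plain-text CSV files
#'
#' Emits the three tables the pipeline ingests: `members.csv`,
#' `sessions.csv` and, when item-level responses are attached (as produced
#' by [generate_cohort()]), `assessment_items.csv` in the long format
#' [score_assessments()] reads. Dates are ISO-8601.
#'
#' @param cohort a [coach_cohort()].
#' @param dir output directory (created if missing).
#' @param items optional long-format item tibble to write alongside.
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir, items = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$members, file.path(dir, "members.csv"))
  readr::write_csv(cohort$sessions, file.path(dir, "sessions.csv"))
  items <- items %||% attr(cohort, "items")
  if (!is.null(items)) {
    readr::write_csv(items, file.path(dir, "assessment_items.csv"))
  }
  invisible(dir)
}

#' Read a cohort from CSV files
#'
#' Counterpart of [write_cohort_csv()]: reads `members.csv`,
#' `sessions.csv` and `assessment_items.csv` from `dir`, scores the items
#' with [score_assessments()] and assembles a [coach_cohort()].
#'
#' @param dir directory holding the three CSV files.
#' @param configs named list of instrument configurations.
#' @return a `coach_cohort` (not yet aligned).
#' @export
read_cohort_csv <- function(dir, configs = default_instrument_configs()) {
  members <- readr::read_csv(file.path(dir, "members.csv"),
                             show_col_types = FALSE, progress = FALSE)
  members$enrollment_date <- as.Date(members$enrollment_date)
  sessions <- readr::read_csv(file.path(dir, "sessions.csv"),
                              show_col_types = FALSE, progress = FALSE)
  items <- readr::read_csv(file.path(dir, "assessment_items.csv"),
                           show_col_types = FALSE, progress = FALSE)
  coach_cohort(members, sessions, score_assessments(items, configs))
}
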