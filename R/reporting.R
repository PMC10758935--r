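#' Demographic summary table
#'
#' Counts and integer percentages by symptom group for age band, sex,
#' gender conformity and ethnicity, in the layout of a clinical Table 1.
#' Percentages are rounded half-up.
#'
#' @param members a members table (see [coach_cohort()]).
#' @return tidy tibble: `symptom_group`, `variable`, `level`, `n`, `pct`.
#' @export
summarize_demographics <- function(members) {
  members <- tibble::as_tibble(members)
  one_var <- function(var) {
    members |>
      dplyr::count(.data$symptom_group, level = .data[[var]]) |>
      dplyr::group_by(.data$symptom_group) |>
      dplyr::mutate(variable = var, pct = plain_pct(.data$n, sum(.data$n))) |>
      dplyr::ungroup()
  }
  dplyr::bind_rows(lapply(
    c("age_band", "sex", "gender_conformity", "ethnicity"), one_var
  )) |>
    dplyr::select("symptom_group", "variable", "level", "n", "pct") |>
    dplyr::arrange(.data$symptom_group, .data$variable, dplyr::desc(.data$n))
}

#' Session attendance retention table
#'
#' For each session number from `min_session` upward, the count and
#' percentage of members (per symptom group) who attended at least that
#' many sessions. Counts are non-increasing down the table.
#'
#' @param cohort a retained [coach_cohort()].
#' @param min_session first row of the table (default 3, the inclusion
#'   floor).
#' @return tibble: `symptom_group`, `session`, `n`, `pct`.
#' @export
attendance_table <- function(cohort, min_session = 3L) {
  stopifnot(inherits(cohort, "coach_cohort"))
  counts <- session_counts(cohort) |>
    dplyr::left_join(dplyr::select(cohort$members, "member_id", "symptom_group"),
                     by = "member_id")
  max_s <- max(counts$n_sessions)
  counts |>
    dplyr::group_by(.data$symptom_group) |>
    dplyr::reframe(
      session = seq(min_session, max_s),
      n = vapply(seq(min_session, max_s),
                 function(s) sum(.data$n_sessions >= s), 1L),
      pct = plain_pct(.data$n, dplyr::n())
    ) |>
    dplyr::filter(.data$n > 0 | .data$session == min_session)
}

#' Assessment completion table
#'
#' For each assessment number (1 = baseline), the count and percentage of
#' members (per symptom group) with at least that many retained
#' assessments.
#'
#' @param cohort an aligned, retained [coach_cohort()].
#' @return tibble: `symptom_group`, `assessment`, `n`, `pct`.
#' @export
assessment_completion_table <- function(cohort) {
  stopifnot(inherits(cohort, "coach_cohort"))
  counts <- cohort$assessments |>
    dplyr::count(.data$member_id, name = "n_assessments") |>
    dplyr::right_join(dplyr::select(cohort$members, "member_id", "symptom_group"),
                      by = "member_id") |>
    dplyr::mutate(n_assessments = dplyr::coalesce(.data$n_assessments, 0L))
  max_a <- max(counts$n_assessments)
  counts |>
    dplyr::group_by(.data$symptom_group) |>
    dplyr::reframe(
      assessment = seq_len(max_a),
      n = vapply(seq_len(max_a),
                 function(a) sum(.data$n_assessments >= a), 1L),
      pct = plain_pct(.data$n, dplyr::n())
    ) |>
    dplyr::filter(.data$n > 0)
}

#' Headline results summary
#'
#' Per symptom group and endpoint: the number and percentage of members
#' with an observed event, and the median sessions-to-event with its 95%
#' confidence interval. Percentages are integer-rounded via a one-decimal
#' intermediate, the convention of the reference report tables (so 63/66
#' prints as 96, not 95).
#'
#' @param event_tables named list of event tibbles (one per
#'   group/endpoint combination) as built by [build_event_table()]; names
#'   like `"anxiety.first_reliable"`.
#' @param curves named list of matching [km_fit()] objects.
#' @return tibble: `group`, `endpoint`, `n`, `n_events`, `pct_events`,
#'   `median_sessions`, `ci_lower`, `ci_upper`.
#' @export
results_summary <- function(event_tables, curves) {
  rows <- lapply(names(event_tables), function(nm) {
    ev <- event_tables[[nm]]
    cv <- curves[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    tibble::tibble(
      group = parts[1],
      endpoint = parts[length(parts)],
      n = nrow(ev),
      n_events = sum(ev$event_observed),
      pct_events = if (nrow(ev) > 0) report_pct(sum(ev$event_observed), nrow(ev)) else NA_integer_,
      median_sessions = if (!is.null(cv)) cv$median else NA_real_,
      ci_lower = if (!is.null(cv)) cv$median_ci[1] else NA_real_,
      ci_upper = if (!is.null(cv)) cv$median_ci[2] else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Run the full session-to-improvement pipeline
#'
#' Orchestrates every stage on a cohort: alignment, inclusion filtering
#' with the exclusion ledger, per-instrument RCC derivation from the
#' unfiltered enrollment sample, event-table construction for the first
#' and stable reliable-change endpoints per symptom group, product-limit
#' fits with age-band subgroup curves, and the report tables.
#'
#' @param cohort a [coach_cohort()] (e.g. from [generate_cohort()] or
#'   [read_cohort_csv()]).
#' @param configs named list of instrument configurations.
#' @param reliabilities per-instrument reliabilities for the RCC.
#' @param z_quantile RCC confidence quantile (default 1.96).
#' @param stable_assign which assessment of a stable pair carries the
#'   event (`"second"`, default).
#' @return list with `cohort` (retained, aligned), `ledger`, `rcc`,
#'   `care_statistics`, `events`, `curves`, `subgroups`, `demographics`,
#'   `attendance`, `assessment_completion`, `summary`.
#' @export
run_pipeline <- function(cohort,
                         configs = default_instrument_configs(),
                         reliabilities = default_reliabilities(),
                         z_quantile = 1.96,
                         stable_assign = "second") {
  aligned <- align_assessments(cohort)
  rcc <- rcc_from_cohort(aligned, reliabilities, z_quantile)
  filt <- apply_inclusion_criteria(aligned, configs)
  retained <- filt$cohort

  groups <- sort(unique(retained$members$symptom_group))
  endpoints <- c("first_reliable", "stable_reliable")
  events <- list()
  curves <- list()
  subgroups <- list()
  for (g in groups) {
    ids <- retained$members$member_id[retained$members$symptom_group == g]
    sub <- coach_cohort(
      members = dplyr::filter(retained$members, .data$member_id %in% ids),
      sessions = dplyr::filter(retained$sessions, .data$member_id %in% ids),
      assessments = dplyr::filter(retained$assessments, .data$member_id %in% ids)
    )
    for (ep in endpoints) {
      nm <- paste(g, ep, sep = ".")
      events[[nm]] <- build_event_table(sub, rcc, ep,
                                        stable_assign = stable_assign)
      if (nrow(events[[nm]]) > 0) {
        curves[[nm]] <- km_fit(events[[nm]])
        subgroups[[nm]] <- suppressWarnings(
          subgroup_analysis(events[[nm]], sub$members)
        )
      }
    }
  }
  list(
    cohort = retained,
    ledger = filt$ledger,
    rcc = rcc,
    care_statistics = compute_care_statistics(retained),
    events = events,
    curves = curves,
    subgroups = subgroups,
    demographics = summarize_demographics(retained$members),
    attendance = attendance_table(retained),
    assessment_completion = assessment_completion_table(retained),
    summary = results_summary(events, curves)
  )
}

#' Write pipeline outputs to CSV
#'
#' Emits the exclusion ledger, care statistics, event tables, tidy curve
#' tables, and report tables as plain CSV files under `dir`, so every
#' number in a rendered report traces back to a CSV cell.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$ledger, file.path(dir, "exclusion_ledger.csv"))
  readr::write_csv(result$care_statistics, file.path(dir, "care_statistics.csv"))
  readr::write_csv(dplyr::bind_rows(result$events), file.path(dir, "events.csv"))
  curves <- dplyr::bind_rows(lapply(names(result$curves), function(nm) {
    dplyr::mutate(km_table(result$curves[[nm]]), analysis = nm, .before = 1)
  }))
  readr::write_csv(curves, file.path(dir, "curves.csv"))
  readr::write_csv(result$demographics, file.path(dir, "demographics.csv"))
  readr::write_csv(result$attendance, file.path(dir, "attendance.csv"))
  readr::write_csv(result$assessment_completion,
                   file.path(dir, "assessment_completion.csv"))
  readr::write_csv(result$summary, file.path(dir, "results_summary.csv"))
  rcc <- lapply(result$rcc, function(r) r[c("baseline_sd", "reliability",
                                            "z_quantile", "rcc_value")])
  jsonlite::write_json(rcc, file.path(dir, "rcc.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
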