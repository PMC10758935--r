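#' Jacobson-Truax reliable change criterion
#'
#' The reliable change criterion (RCC) is the smallest score decrease that
#' is unlikely, at confidence level `z_quantile`, to be measurement noise:
#' \deqn{RCC = z \cdot SD_{baseline} \cdot \sqrt{2} \cdot \sqrt{1 - r}}
#' where `r` is the instrument's reliability and `SD` the dispersion of
#' scores in the reference population at enrollment. Perfect reliability
#' forces a zero threshold; the RCC is linear in the baseline SD and
#' strictly decreasing in reliability.
#'
#' @param baseline_sd positive dispersion of enrollment scores on the
#'   instrument's reporting scale.
#' @param reliability published reliability in `(0, 1]` (internal
#'   consistency or test-retest).
#' @param z_quantile normal quantile for the confidence level
#'   (default 1.96, the two-sided 95% criterion).
#' @param instrument_id optional label carried through to output.
#' @return object of class `rcc_spec`: a list with the inputs and the
#'   derived `rcc_value`.
#' @examples
#' compute_rcc(5, 0.90)$rcc_value  # approx 4.383
#' @export
compute_rcc <- function(baseline_sd, reliability, z_quantile = 1.96,
                        instrument_id = NA_character_) {
  abort_if(!is.numeric(baseline_sd) || baseline_sd <= 0,
           "baseline_sd must be positive")
  abort_if(!is.numeric(reliability) || reliability <= 0 || reliability > 1,
           "reliability must lie in (0, 1]")
  structure(
    list(
      instrument_id = instrument_id,
      baseline_sd = baseline_sd,
      reliability = reliability,
      z_quantile = z_quantile,
      rcc_value = z_quantile * baseline_sd * sqrt(2) * sqrt(1 - reliability)
    ),
    class = "rcc_spec"
  )
}

#' @export
print.rcc_spec <- function(x, ...) {
  cat(sprintf("<rcc_spec> %s: RCC = %.3f (SD %.3f, r %.3f, z %.2f)\n",
              x$instrument_id, x$rcc_value, x$baseline_sd, x$reliability,
              x$z_quantile))
  invisible(x)
}

#' Default instrument reliabilities
#'
#' Conventional published values used when a configuration supplies none:
#' GAD-7 0.92, PHQ-9A 0.89, PROMIS pediatric measures 0.90. These are
#' configuration inputs, not estimates from data.
#' @return named numeric vector.
#' @export
default_reliabilities <- function() {
  c(GAD7 = 0.92, PHQ9A_8ITEM = 0.89,
    PROMIS_ANX_PED = 0.90, PROMIS_DEP_PED = 0.90)
}

#' Derive per-instrument RCC specifications from a reference cohort
#'
#' The baseline dispersion for each instrument is the standard deviation
#' of the converted scores of all enrollment (pre-coaching) assessments in
#' the supplied reference cohort — mirroring the practice of estimating
#' measure variance from all members at enrollment, before any inclusion
#' filtering. Supply `baseline_sd` directly to override.
#'
#' @param cohort an aligned [coach_cohort()] used as reference sample.
#' @param reliabilities named numeric vector of per-instrument
#'   reliabilities (default [default_reliabilities()]).
#' @param z_quantile normal quantile, default 1.96.
#' @param baseline_sd optional named numeric vector overriding the
#'   estimated dispersions.
#' @return named list of [compute_rcc()] specs, one per instrument present.
#' @export
rcc_from_cohort <- function(cohort, reliabilities = default_reliabilities(),
                            z_quantile = 1.96, baseline_sd = NULL) {
  stopifnot(inherits(cohort, "coach_cohort"))
  base <- cohort$assessments |>
    dplyr::filter(.data$session_index == 0L, !.data$screened_out)
  sds <- tapply(base$converted_score, base$instrument_id, stats::sd)
  ids <- names(sds)
  out <- lapply(ids, function(id) {
    sd_i <- if (!is.null(baseline_sd) && id %in% names(baseline_sd)) {
      baseline_sd[[id]]
    } else {
      sds[[id]]
    }
    abort_if(is.na(sd_i) || sd_i <= 0,
             sprintf("cannot estimate a positive baseline SD for %s", id))
    abort_if(!id %in% names(reliabilities),
             sprintf("no reliability supplied for %s", id))
    compute_rcc(sd_i, reliabilities[[id]], z_quantile, instrument_id = id)
  })
  names(out) <- ids
  out
}

#' Flag reliable change along one assessment trajectory
#'
#' A post-baseline assessment shows reliable change when the score has
#' decreased from baseline by strictly more than the RCC, or when the
#' member screened out of the full assessment (symptoms no longer reach
#' the screener threshold).
#'
#' @param baseline_score converted score of the pre-coaching baseline
#'   (must be present: a screened-out baseline is ineligible).
#' @param scores numeric vector of post-baseline converted scores (`NA`
#'   where screened out).
#' @param screened_out logical vector, same length as `scores`.
#' @param rcc an [compute_rcc()] spec or a bare numeric threshold.
#' @return logical vector of reliable-change flags.
#' @export
detect_reliable_change <- function(baseline_score, scores, screened_out, rcc) {
  abort_if(is.na(baseline_score),
           "baseline is screened out or unscored; member is ineligible")
  thr <- if (inherits(rcc, "rcc_spec")) rcc$rcc_value else rcc
  abort_if(length(scores) != length(screened_out),
           "scores and screened_out lengths differ")
  screened_out | (!is.na(scores) & (baseline_score - scores) > thr)
}

#' Locate stable reliable change in a flag sequence
#'
#' Stable reliable change requires two successive assessments with
#' reliable change; the event is assigned to the confirming (second)
#' assessment of the first such pair, or optionally to the first.
#'
#' @param flags logical vector ordered by assessment time.
#' @param assign which assessment of the pair carries the event
#'   (`"second"`, the default, or `"first"`).
#' @return 1-based index into `flags`, or `NA_integer_` when no
#'   consecutive pair exists.
#' @examples
#' detect_stable_reliable_change(c(FALSE, TRUE, TRUE))  # 3
#' @export
detect_stable_reliable_change <- function(flags, assign = c("second", "first")) {
  assign <- match.arg(assign)
  if (length(flags) < 2L) return(NA_integer_)
  pair <- which(flags[-length(flags)] & flags[-1])
  if (length(pair) == 0L) return(NA_integer_)
  if (assign == "second") pair[1] + 1L else pair[1]
}

#' Build per-member time-to-event records
#'
#' Converts each member's aligned assessment trajectory into a
#' time-to-event record in session units. For the `first_reliable`
#' endpoint the event time is the session index of the first flagged
#' assessment; for `stable_reliable` it is the session index of the
#' confirming assessment of the first consecutive flagged pair. Members
#' without the event are right-censored at their total number of attended
#' sessions. An event whose triggering assessment carries session index 0
#' is floored to 1 so all event times are positive.
#'
#' @param cohort an aligned, filtered [coach_cohort()].
#' @param rcc_specs named list of RCC specs per instrument
#'   (see [rcc_from_cohort()]).
#' @param endpoint `"first_reliable"` or `"stable_reliable"`.
#' @param stable_assign passed to [detect_stable_reliable_change()].
#' @return tibble of event records: `member_id`, `endpoint`,
#'   `time_sessions`, `event_observed`.
#' @export
build_event_table <- function(cohort, rcc_specs,
                              endpoint = c("first_reliable", "stable_reliable"),
                              stable_assign = "second") {
  endpoint <- match.arg(endpoint)
  stopifnot(inherits(cohort, "coach_cohort"))
  if (nrow(cohort$members) == 0L) {
    return(tibble::tibble(member_id = character(), endpoint = character(),
                          time_sessions = integer(), event_observed = logical()))
  }
  abort_if(anyNA(cohort$assessments$session_index),
           "assessments must be aligned first (align_assessments)")
  nsess <- session_counts(cohort)
  a <- cohort$assessments |>
    dplyr::arrange(.data$member_id, .data$date)
  by_member <- split(a, a$member_id)
  recs <- lapply(cohort$members$member_id, function(id) {
    traj <- by_member[[id]]
    total <- nsess$n_sessions[nsess$member_id == id]
    base <- traj[traj$session_index == 0L & !traj$screened_out, ]
    abort_if(nrow(base) == 0L,
             sprintf("member %s has no scored baseline assessment", id))
    base <- base[nrow(base), ]
    post <- traj[traj$date > base$date, ]
    flags <- detect_reliable_change(
      base$converted_score, post$converted_score, post$screened_out,
      rcc_specs[[base$instrument_id]]
    )
    hit <- if (endpoint == "first_reliable") {
      if (any(flags)) which(flags)[1] else NA_integer_
    } else {
      detect_stable_reliable_change(flags, assign = stable_assign)
    }
    if (is.na(hit)) {
      tibble::tibble(member_id = id, endpoint = endpoint,
                     time_sessions = as.integer(total), event_observed = FALSE)
    } else {
      tibble::tibble(member_id = id, endpoint = endpoint,
                     time_sessions = max(1L, post$session_index[hit]),
                     event_observed = TRUE)
    }
  })
  dplyr::bind_rows(recs)
}
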