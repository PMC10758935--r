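# Shared fixture builders. Everything is generated in code; no data files.

# random right-censored event table on a discrete time grid
random_event_table <- function(n, max_time = 10, event_prob = 0.7) {
  tibble::tibble(
    time_sessions = sample(seq_len(max_time), n, replace = TRUE),
    event_observed = stats::runif(n) < event_prob
  )
}

# minimal members table for hand-built cohorts
make_members <- function(ids, age_years = 10, symptom_group = "anxiety",
                         instrument_id = "GAD7") {
  n <- length(ids)
  tibble::tibble(
    member_id = ids,
    age_years = rep_len(age_years, n),
    age_band = ifelse(rep_len(age_years, n) < 13, "child", "adolescent"),
    sex = "Female", gender_conformity = "Conforming", ethnicity = "White",
    enrollment_date = as.Date("2023-01-01"),
    symptom_group = rep_len(symptom_group, n),
    instrument_id = rep_len(instrument_id, n)
  )
}

# cohort for one member given session day offsets and assessment
# (day, score, screened_out) rows; days are offsets from enrollment
make_single_member_cohort <- function(session_days,
                                      assess_days,
                                      scores,
                                      screened_out = rep(FALSE, length(assess_days)),
                                      instrument_id = "GAD7") {
  d0 <- as.Date("2023-01-01")
  coach_cohort(
    members = make_members("M1", age_years = 14, instrument_id = instrument_id),
    sessions = tibble::tibble(member_id = "M1", date = d0 + session_days),
    assessments = tibble::tibble(
      member_id = "M1", date = d0 + assess_days,
      instrument_id = instrument_id,
      screened_out = screened_out,
      raw_sum = ifelse(screened_out, NA_integer_, as.integer(scores)),
      converted_score = ifelse(screened_out, NA_real_, as.numeric(scores)),
      severity = ifelse(screened_out, NA_character_,
                        classify_severity(
                          pmin(pmax(ifelse(is.na(scores), 0, scores), 0), 21),
                          default_instrument_configs()$GAD7))
    )
  )
}

# event table -> survival::survfit reference fit (log-log bands)
survfit_oracle <- function(events) {
  survival::survfit(
    survival::Surv(events$time_sessions, events$event_observed) ~ 1,
    conf.type = "log-log"
  )
}
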