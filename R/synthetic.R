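#' Synthetic cohort generator parameters
#'
#' Controls the simulator that emulates the structure of a coaching
#' cohort: enrollment screening, roughly fortnightly sessions over a 3-7
#' month stay, approximately monthly assessments, baseline severity
#' confined to the eligible (moderate / moderately severe) bands, a
#' geometric first-improvement process on the assessment grid, and
#' configurable relapse, screen-out and planted inclusion-violation
#' rates. Identical seeds reproduce identical cohorts bit for bit; each
#' member draws from its own pseudo-random stream derived from
#' `(seed, member index)`, so cohorts are stable under reordering.
#'
#' @param n_members cohort size before inclusion filtering.
#' @param seed integer seed.
#' @param prop_anxiety proportion of members in the anxiety symptom group
#'   (the remainder are the depression group).
#' @param prop_child named proportions of children (ages 6-12) per group;
#'   remaining members are adolescents (13-17).
#' @param session_gap_mean_days,session_gap_sd_days normal between-session
#'   gap, truncated to `session_gap_range_days`. The default mean of 16.5
#'   days reproduces the reference care statistics (about 2.2-week gaps
#'   and 2 sessions per month) once duration is measured first-to-last
#'   session.
#' @param session_gap_range_days truncation bounds for gaps, in days.
#' @param duration_months_range attainable coaching duration
#'   (first-to-last session) range, in 30.44-day months.
#' @param duration_beta_shape shape parameters of the beta draw scaled
#'   onto `duration_months_range`; the default `c(0.9, 2)` gives the
#'   right-skewed stay lengths of the reference cohort (mean about 4.3
#'   months, SD about 1).
#' @param enrollment_lead_days_range days between enrollment (baseline
#'   assessment) and the first session, drawn uniformly.
#' @param assessment_gap_days,assessment_jitter_sd_days target
#'   inter-assessment gap and its normal jitter.
#' @param improvement_prob per-assessment probability `q` that a member
#'   first crosses the reliable-change threshold (geometric first-event
#'   index).
#' @param relapse_prob probability that a post-improvement assessment
#'   regresses to within the RCC of baseline.
#' @param screenout_prob probability that an improved member screens out
#'   of a given full assessment.
#' @param violation_rates named rates of members planted to fail each
#'   inclusion criterion: `missing_followup` (no post-baseline
#'   assessments), `session_rate` (sessions far too frequent),
#'   `session_gap` (mean gap above 3 weeks at an in-range session rate),
#'   `few_sessions` (a single session), `baseline_severity` (baseline in
#'   the mild band). Members not planted with a violation are guaranteed
#'   to satisfy the care-pattern criteria.
#' @param reliabilities per-instrument reliabilities used to size the
#'   planted score drops (and downstream RCCs).
#' @param start_date calendar anchor for enrollment dates.
#' @return a `generator_params` list.
#' @seealso [paper_like_params()] for the calibrated preset.
#' @export
generator_params <- function(n_members = 100L,
                             seed = 1L,
                             prop_anxiety = 66 / 125,
                             prop_child = c(anxiety = 43 / 66, depression = 26 / 59),
                             session_gap_mean_days = 16.5,
                             session_gap_sd_days = 2.6,
                             session_gap_range_days = c(4, 35),
                             duration_months_range = c(3.0, 7.23),
                             duration_beta_shape = c(0.9, 2),
                             enrollment_lead_days_range = c(7, 21),
                             assessment_gap_days = 30,
                             assessment_jitter_sd_days = 3,
                             improvement_prob = 0.55,
                             relapse_prob = 0.35,
                             screenout_prob = 0.25,
                             violation_rates = c(missing_followup = 0,
                                                 session_rate = 0,
                                                 session_gap = 0,
                                                 few_sessions = 0,
                                                 baseline_severity = 0),
                             reliabilities = default_reliabilities(),
                             start_date = as.Date("2023-01-01")) {
  probs <- c(improvement_prob, relapse_prob, screenout_prob, violation_rates)
  abort_if(any(probs < 0 | probs > 1), "all probabilities must lie in [0,1]")
  abort_if(sum(violation_rates) > 1, "violation rates must sum to at most 1")
  abort_if(n_members < 0, "n_members must be non-negative")
  structure(as.list(environment()), class = "generator_params")
}

#' Calibrated cohort preset
#'
#' The study-condition preset: an eligible pool of 392 members with
#' per-criterion violation rates matching the protocol's exclusion counts
#' (24 missing a follow-up assessment, 101 with out-of-range session
#' rates, 77 with out-of-range between-session gaps, 37 with too few
#' sessions) plus 28 planted below the severity threshold, leaving an
#' expected 125 analyzable members split roughly 66/59 between the
#' anxiety and depression groups.
#'
#' @param seed integer seed.
#' @param n_members pool size, default 392.
#' @return a [generator_params()] object.
#' @export
paper_like_params <- function(seed = 1L, n_members = 392L) {
  generator_params(
    n_members = n_members,
    seed = seed,
    violation_rates = c(missing_followup = 24, session_rate = 101,
                        session_gap = 77, few_sessions = 37,
                        baseline_severity = 28) / 392
  )
}

# conservative design threshold: an upper bound on any RCC the pipeline
# could derive from baselines confined to the eligible band, so planted
# improvements always clear the realized criterion and planted
# fluctuations never do.
design_rcc_upper <- function(config, reliability, z = 1.96) {
  conv <- convert_score(0:(config$item_count * config$item_scale_max), config)
  elig <- eligible_converted(config)
  width <- max(elig) - min(elig)
  z * (0.6 * width) * sqrt(2) * sqrt(1 - reliability)
}

# converted scores attainable within the eligible severity bands
eligible_converted <- function(config) {
  conv <- convert_score(0:(config$item_count * config$item_scale_max), config)
  sev <- classify_severity(conv, config)
  conv[sev %in% config$eligible_severities]
}

# raw sums whose converted score falls in the given band labels
raws_in_bands <- function(config, labels) {
  raw <- 0:(config$item_count * config$item_scale_max)
  conv <- convert_score(raw, config)
  raw[classify_severity(conv, config) %in% labels]
}

#' Distribute a target raw sum across items
#'
#' Greedy even spread: every item receives `floor(sum/n)` and the first
#' `sum %% n` items one more, so scoring the items reproduces the target
#' sum exactly and the fill is deterministic.
#'
#' @param target_sum non-negative integer raw sum.
#' @param n_items number of items.
#' @param max_level per-item maximum.
#' @return integer vector of length `n_items` summing to `target_sum`.
#' @export
backfill_items <- function(target_sum, n_items, max_level) {
  abort_if(target_sum < 0 || target_sum > n_items * max_level,
           sprintf("target sum %d outside attainable range [0, %d]",
                   target_sum, n_items * max_level))
  base <- target_sum %/% n_items
  rem <- target_sum %% n_items
  as.integer(base + (seq_len(n_items) <= rem))
}

# truncated-normal gap draws (simple rejection, vectorised retry)
draw_gaps <- function(n, mean, sd, range) {
  g <- stats::rnorm(n, mean, sd)
  bad <- g < range[1] | g > range[2]
  while (any(bad)) {
    g[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- g < range[1] | g > range[2]
  }
  g
}

# session schedule (gap vector in days) for a clean member: redrawn until
# the realized care statistics sit inside the inclusion windows.
clean_schedule <- function(params) {
  b <- stats::rbeta(1, params$duration_beta_shape[1], params$duration_beta_shape[2])
  target <- (params$duration_months_range[1] +
               b * diff(params$duration_months_range)) * DAYS_PER_MONTH
  for (attempt in 1:100) {
    n_gaps <- max(2L, ceiling(target / params$session_gap_mean_days))
    gaps <- draw_gaps(n_gaps, params$session_gap_mean_days,
                      params$session_gap_sd_days, params$session_gap_range_days)
    n <- n_gaps + 1L
    dur <- sum(gaps)
    rate <- n / (dur / DAYS_PER_MONTH)
    mg <- mean(gaps)
    if (rate >= 1.52 && rate <= 2.48 && mg >= 7.2 && mg <= 20.8) return(gaps)
  }
  stop("could not draw an in-window session schedule", call. = FALSE)
}

# planted-violation schedules; each is caught by exactly the intended
# criterion when criteria run in protocol order.
violation_schedule <- function(kind, params) {
  switch(kind,
    session_rate = draw_gaps(9L, 5.5, 0.8, c(4, 8)),
    session_gap = draw_gaps(5L, 23, 0.6, c(21.8, 24)),
    few_sessions = numeric(0), # single session
    clean_schedule(params)
  )
}

#' Simulate one assessment trajectory
#'
#' Draws the post-baseline trajectory for a member on the raw-sum scale:
#' the index of first reliable improvement is geometric with success
#' `improvement_prob`; pre-improvement assessments fluctuate at or above
#' baseline (never crossing the reliable-change threshold); improved
#' assessments drop by more than the design RCC, may relapse with
#' probability `relapse_prob`, and may screen out with probability
#' `screenout_prob`.
#'
#' @param baseline_raw baseline raw sum.
#' @param config an [instrument_config()].
#' @param params a [generator_params()].
#' @param n_assessments number of post-baseline assessments to draw.
#' @return list with integer vector `raw` (`NA` where screened out),
#'   logical `screened_out`, and `first_improve_k`, the 1-based
#'   assessment index of first improvement (may exceed `n_assessments`).
#' @export
generate_trajectory <- function(baseline_raw, config, params, n_assessments) {
  raw_max <- config$item_count * config$item_scale_max
  conv_all <- convert_score(0:raw_max, config)
  base_conv <- conv_all[baseline_raw + 1L]
  rcc_up <- design_rcc_upper(config, params$reliabilities[[config$instrument_id]])
  # clamp at the scale floor: a low (e.g. sub-threshold) baseline improves
  # to the minimum attainable score rather than erroring out
  target <- max(base_conv - rcc_up - 0.5, min(conv_all))
  improved_raw_max <- max(which(conv_all <= target) - 1L)

  k1 <- if (params$improvement_prob >= 1) 1L
        else if (params$improvement_prob <= 0) .Machine$integer.max
        else stats::rgeom(1, params$improvement_prob) + 1L

  raw <- integer(n_assessments)
  so <- logical(n_assessments)
  stable_raw <- function() { # fluctuation at/above baseline, never reliable
    min(baseline_raw + sample(0:2, 1, prob = c(0.6, 0.3, 0.1)), raw_max)
  }
  for (k in seq_len(n_assessments)) {
    if (k < k1) {
      raw[k] <- stable_raw()
    } else if (k > k1 && stats::runif(1) < params$relapse_prob) {
      raw[k] <- stable_raw()
    } else if (stats::runif(1) < params$screenout_prob) {
      so[k] <- TRUE
      raw[k] <- NA_integer_
    } else {
      raw[k] <- improved_raw_max - sample(0:min(2L, improved_raw_max), 1)
    }
  }
  list(raw = raw, screened_out = so, first_improve_k = k1)
}

#' Generate a synthetic coaching cohort
#'
#' Produces a [coach_cohort()] with dated sessions, screener and
#' item-level assessment responses consistent with the sampled trajectory
#' scores (items are back-filled to sum exactly to the target raw score),
#' and planted inclusion violations at the configured rates. The returned
#' cohort carries two attributes: `items`, the long-format item table the
#' pipeline can re-score (see [score_assessments()]), and `truth`, a
#' per-member tibble of the planted violation and first-improvement index
#' for test assertions.
#'
#' @param params a [generator_params()].
#' @return a `coach_cohort` (unaligned) with `items` and `truth`
#'   attributes.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  configs <- default_instrument_configs()
  n <- params$n_members
  if (n == 0L) {
    empty <- coach_cohort(
      members = tibble::tibble(member_id = character(), age_years = numeric(),
                               age_band = character(), sex = character(),
                               gender_conformity = character(),
                               ethnicity = character(),
                               enrollment_date = as.Date(character()),
                               symptom_group = character(),
                               instrument_id = character()),
      sessions = tibble::tibble(member_id = character(), date = as.Date(character())),
      assessments = tibble::tibble(member_id = character(), date = as.Date(character()),
                                   instrument_id = character(), screened_out = logical(),
                                   raw_sum = integer(), converted_score = numeric(),
                                   severity = character())
    )
    attr(empty, "items") <- tibble::tibble()
    attr(empty, "truth") <- tibble::tibble()
    return(empty)
  }
  viol_kinds <- names(params$violation_rates)
  cum <- cumsum(params$violation_rates)

  members <- vector("list", n)
  sessions <- vector("list", n)
  assess <- vector("list", n)
  items <- vector("list", n)
  truth <- vector("list", n)

  for (i in seq_len(n)) {
    id <- sprintf("M%04d", i)
    set.seed((params$seed * 1000003L + i * 7919L) %% 2147483629L)

    u <- stats::runif(1)
    violation <- if (any(u < cum)) viol_kinds[which(u < cum)[1]] else NA_character_

    group <- if (stats::runif(1) < params$prop_anxiety) "anxiety" else "depression"
    child <- stats::runif(1) < params$prop_child[[group]]
    age <- if (child) stats::runif(1, 6, 12.9) else stats::runif(1, 13, 16.9)
    instrument <- if (group == "anxiety") {
      if (child) "PROMIS_ANX_PED" else "GAD7"
    } else {
      if (child) "PROMIS_DEP_PED" else "PHQ9A_8ITEM"
    }
    cfg <- configs[[instrument]]
    sex <- sample(c("Female", "Male", "Other"), 1, prob = c(0.52, 0.46, 0.02))
    conf <- sample(c("Conforming", "Nonconforming"), 1, prob = c(0.965, 0.035))
    eth <- sample(c("Asian", "Black or African American", "Hispanic or Latino",
                    "White", "Other or multiracial"), 1,
                  prob = c(0.05, 0.01, 0.05, 0.50, 0.39))
    enrollment <- params$start_date + sample(0:120, 1)

    gaps <- if (!is.na(violation)) violation_schedule(violation, params)
            else clean_schedule(params)
    lead <- stats::runif(1, params$enrollment_lead_days_range[1],
                         params$enrollment_lead_days_range[2])
    sess_dates <- enrollment + round(lead + c(0, cumsum(gaps)))

    baseline_bands <- if (!is.na(violation) && violation == "baseline_severity") {
      "mild"
    } else {
      cfg$eligible_severities
    }
    baseline_raw <- sample(rep(raws_in_bands(cfg, baseline_bands), 2), 1)

    # monthly assessment dates after baseline, within the coaching window
    k_max <- max(1L, floor((as.numeric(max(sess_dates) - enrollment) + 21) /
                             params$assessment_gap_days))
    offs <- round(params$assessment_gap_days * seq_len(k_max) +
                    stats::rnorm(k_max, 0, params$assessment_jitter_sd_days))
    offs <- offs[offs > 0]
    a_dates <- enrollment + cummax(offs)
    a_dates <- a_dates[a_dates <= max(sess_dates) + 21]
    a_dates <- a_dates[!duplicated(a_dates)]
    if (!is.na(violation) && violation == "missing_followup") {
      a_dates <- a_dates[0]
    }

    traj <- generate_trajectory(baseline_raw, cfg, params, length(a_dates))

    all_dates <- c(enrollment, a_dates)
    all_raw <- c(baseline_raw, traj$raw)
    all_so <- c(FALSE, traj$screened_out)
    conv <- ifelse(is.na(all_raw), NA_real_,
                   convert_score(ifelse(is.na(all_raw), 0L, all_raw), cfg))
    sev <- ifelse(is.na(conv), NA_character_, classify_severity(
      ifelse(is.na(conv), converted_range(cfg)[1], conv), cfg))

    members[[i]] <- tibble::tibble(
      member_id = id, age_years = round(age, 1),
      age_band = if (child) "child" else "adolescent",
      sex = sex, gender_conformity = conf, ethnicity = eth,
      enrollment_date = enrollment, symptom_group = group,
      instrument_id = instrument
    )
    sessions[[i]] <- tibble::tibble(member_id = id, date = sess_dates)
    assess[[i]] <- tibble::tibble(
      member_id = id, date = all_dates, instrument_id = instrument,
      screened_out = all_so, raw_sum = all_raw, converted_score = conv,
      severity = sev
    )
    items[[i]] <- make_item_rows(id, all_dates, all_raw, all_so, cfg)
    truth[[i]] <- tibble::tibble(
      member_id = id, violation = violation,
      first_improve_k = traj$first_improve_k,
      n_assessments = length(a_dates), baseline_raw = baseline_raw
    )
  }
  cohort <- coach_cohort(
    members = dplyr::bind_rows(members),
    sessions = dplyr::bind_rows(sessions),
    assessments = dplyr::bind_rows(assess)
  )
  attr(cohort, "items") <- dplyr::bind_rows(items)
  attr(cohort, "truth") <- dplyr::bind_rows(truth)
  cohort
}

# long-format screener + full item rows for one member's assessments
make_item_rows <- function(id, dates, raws, screened_out, cfg) {
  rows <- lapply(seq_along(dates), function(j) {
    scr <- if (screened_out[j]) c(1L, 0L, 1L) else c(3L, 1L, 0L)
    scr <- scr[seq_len(cfg$screener_item_count)]
    out <- tibble::tibble(
      member_id = id, date = dates[j], instrument_id = cfg$instrument_id,
      phase = "screener", item_index = seq_along(scr), response = scr
    )
    if (!screened_out[j]) {
      full <- backfill_items(raws[j], cfg$item_count, cfg$item_scale_max)
      out <- dplyr::bind_rows(out, tibble::tibble(
        member_id = id, date = dates[j], instrument_id = cfg$instrument_id,
        phase = "full", item_index = seq_along(full), response = full
      ))
    }
    out
  })
  dplyr::bind_rows(rows)
}
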