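#' Instrument configuration
#'
#' Describes one symptom instrument: its item structure, how raw item sums
#' are converted to the reporting scale, the severity bands on that scale,
#' and the screener rule that gates administration of the full assessment.
#'
#' Severity band boundaries are inclusive lower bounds: a converted score is
#' assigned to the band with the largest lower bound not exceeding it.
#'
#' @param instrument_id one of `"GAD7"`, `"PHQ9A_8ITEM"`, `"PROMIS_ANX_PED"`,
#'   `"PROMIS_DEP_PED"`, or a custom identifier.
#' @param item_count number of items in the full assessment.
#' @param item_scale_max maximum response level per item (items run
#'   `0:item_scale_max`).
#' @param conversion how the raw sum maps to the reporting scale: `"none"`
#'   (GAD-7 totals are reported as-is), `"prorate_9_8"` (8-item PHQ-9A
#'   prorated onto the 0-27 nine-item scale), or `"tscore"` (lookup in
#'   `tscore_table`).
#' @param severity_bands data frame with columns `label` and `lower`
#'   (inclusive lower bound on the converted scale), ordered by `lower`.
#' @param eligible_severities character vector of band labels counting as
#'   "moderate or moderately severe" for cohort eligibility.
#' @param tscore_table data frame with columns `raw_sum`, `t_score`
#'   (required when `conversion = "tscore"`); must be monotone
#'   non-decreasing and defined for every attainable raw sum.
#' @param screener_item_count number of screener items for the domain.
#' @param screener_trigger_threshold item response level at or above which
#'   the domain's full assessment is triggered (default 2, i.e. "mild" or
#'   greater on the 0-4 DSM-5 Level 1 frequency scale).
#' @return an object of class `instrument_config`.
#' @export
instrument_config <- function(instrument_id,
                              item_count,
                              item_scale_max,
                              conversion = c("none", "prorate_9_8", "tscore"),
                              severity_bands,
                              eligible_severities,
                              tscore_table = NULL,
                              screener_item_count = 3L,
                              screener_trigger_threshold = 2L) {
  conversion <- match.arg(conversion)
  item_count <- check_integerish(item_count, "item_count")
  item_scale_max <- check_integerish(item_scale_max, "item_scale_max")
  abort_if(item_count < 1L, "item_count must be positive")
  severity_bands <- tibble::as_tibble(severity_bands)
  abort_if(!all(c("label", "lower") %in% names(severity_bands)),
           "severity_bands needs columns 'label' and 'lower'")
  abort_if(is.unsorted(severity_bands$lower, strictly = TRUE),
           "severity band lower bounds must be strictly increasing")
  if (conversion == "tscore") {
    abort_if(is.null(tscore_table), "tscore conversion requires a tscore_table")
    tscore_table <- tibble::as_tibble(tscore_table)
    abort_if(!all(c("raw_sum", "t_score") %in% names(tscore_table)),
             "tscore_table needs columns 'raw_sum' and 'raw_sum'/'t_score'")
    tscore_table <- dplyr::arrange(tscore_table, .data$raw_sum)
    attainable <- 0:(item_count * item_scale_max)
    abort_if(!all(attainable %in% tscore_table$raw_sum),
             "tscore_table must cover every attainable raw sum")
    abort_if(is.unsorted(tscore_table$t_score),
             "tscore_table must be monotone non-decreasing")
  }
  structure(
    list(
      instrument_id = instrument_id,
      item_count = item_count,
      item_scale_max = item_scale_max,
      conversion = conversion,
      severity_bands = severity_bands,
      eligible_severities = eligible_severities,
      tscore_table = tscore_table,
      screener_item_count = as.integer(screener_item_count),
      screener_trigger_threshold = as.integer(screener_trigger_threshold)
    ),
    class = "instrument_config"
  )
}

#' @export
print.instrument_config <- function(x, ...) {
  cat("<instrument_config>", x$instrument_id, "\n")
  cat("  items:", x$item_count, " (0-", x$item_scale_max, "), conversion: ",
      x$conversion, "\n", sep = "")
  cat("  bands:", paste(x$severity_bands$label, "≥", x$severity_bands$lower,
                        collapse = "; "), "\n")
  invisible(x)
}

# range of the converted reporting scale for a config
converted_range <- function(config) {
  raw_max <- config$item_count * config$item_scale_max
  switch(config$conversion,
    none = c(0, raw_max),
    prorate_9_8 = c(0, prorate_phq8_sum(raw_max)),
    tscore = range(config$tscore_table$t_score)
  )
}

# synthetic monotone raw->T calibration used for the shipped PROMIS configs.
# The official scoring tables are licensed publications, so these are
# package-generated stand-ins with a realistic shape (T approx. 33 at the
# raw floor rising to approx. 88 at the ceiling).
synthetic_tscore_table <- function(item_count, item_scale_max) {
  raw <- 0:(item_count * item_scale_max)
  t <- 33 + 55 * (raw / max(raw))^0.85
  tibble::tibble(raw_sum = raw, t_score = round(t, 1))
}

#' Default instrument configurations
#'
#' Ships the four instruments the pipeline analyses: self-report GAD-7
#' (adolescent anxiety, raw 0-21 scale), the 8-item PHQ-9A (adolescent
#' depression, prorated to the 0-27 scale), and caregiver-report PROMIS
#' pediatric anxiety (10 items) and depressive symptoms (11 items), both
#' reported as T-scores. Severity bands follow the published GAD-7 / PHQ-9
#' cutoffs and the conventional PROMIS pediatric T-score bands
#' (55 mild, 60 moderate, 70 severe). The PROMIS raw-to-T tables shipped
#' here are synthetic monotone calibrations (the official tables are
#' licensed); supply real tables via [instrument_config()] or
#' [read_instrument_config()] for production use.
#'
#' "Moderate or moderately severe" eligibility maps to `moderate` for
#' GAD-7 and PROMIS (which have no moderately-severe band) and to
#' `moderate` + `moderately severe` for the PHQ-9A.
#'
#' @return named list of `instrument_config` objects.
#' @export
default_instrument_configs <- function() {
  gad7_bands <- tibble::tibble(
    label = c("minimal", "mild", "moderate", "severe"),
    lower = c(0, 5, 10, 15)
  )
  phq_bands <- tibble::tibble(
    label = c("minimal", "mild", "moderate", "moderately severe", "severe"),
    lower = c(0, 5, 10, 15, 20)
  )
  promis_bands <- function(floor_t) tibble::tibble(
    label = c("within normal limits", "mild", "moderate", "severe"),
    lower = c(floor_t, 55, 60, 70)
  )
  anx_tab <- synthetic_tscore_table(10L, 4L)
  dep_tab <- synthetic_tscore_table(11L, 4L)
  list(
    GAD7 = instrument_config(
      "GAD7", 7L, 3L, "none", gad7_bands, "moderate"
    ),
    PHQ9A_8ITEM = instrument_config(
      "PHQ9A_8ITEM", 8L, 3L, "prorate_9_8", phq_bands,
      c("moderate", "moderately severe")
    ),
    PROMIS_ANX_PED = instrument_config(
      "PROMIS_ANX_PED", 10L, 4L, "tscore",
      promis_bands(min(anx_tab$t_score)), "moderate", tscore_table = anx_tab
    ),
    PROMIS_DEP_PED = instrument_config(
      "PROMIS_DEP_PED", 11L, 4L, "tscore",
      promis_bands(min(dep_tab$t_score)), "moderate", tscore_table = dep_tab
    )
  )
}

#' Score a symptom-domain screener
#'
#' DSM-5 Level 1 cross-cutting screener items ask about symptom frequency
#' over the past two weeks on a 0-4 scale. The domain's full assessment is
#' triggered when any item response reaches the configured threshold.
#'
#' @param responses integer vector of item responses in `[0, 4]`.
#' @param config an [instrument_config()] (supplies the trigger threshold).
#' @return list with `triggered` (logical) and `responses`.
#' @examples
#' cfg <- default_instrument_configs()$GAD7
#' score_screener(c(0, 1, 2), cfg)$triggered
#' @export
score_screener <- function(responses, config) {
  responses <- check_integerish(responses, "screener responses")
  bad <- which(responses < 0L | responses > 4L)
  abort_if(length(bad) > 0,
           sprintf("screener response out of [0,4] at item %d", bad[1]))
  list(
    triggered = any(responses >= config$screener_trigger_threshold),
    responses = responses
  )
}

#' Score the GAD-7
#'
#' Sum of the seven 0-3 items; totals are reported on the raw 0-21 scale
#' (no conversion).
#'
#' @param items integer vector of exactly 7 responses in `[0, 3]`.
#' @return integer total in `[0, 21]`.
#' @examples
#' score_gad7(c(1, 2, 0, 3, 1, 1, 2))
#' @export
score_gad7 <- function(items) {
  items <- check_integerish(items, "GAD-7 items")
  abort_if(length(items) != 7L, "GAD-7 requires exactly 7 items")
  bad <- which(items < 0L | items > 3L)
  abort_if(length(bad) > 0, sprintf("GAD-7 item %d out of [0,3]", bad[1]))
  sum(items)
}

prorate_phq8_sum <- function(raw_sum) {
  as.integer(round_half_up(raw_sum * 9 / 8))
}

#' Prorate the 8-item PHQ-9A onto the 0-27 scale
#'
#' The suicide item is omitted from the administered PHQ-9A, leaving 8
#' items (raw 0-24). The total is adjusted for the removed item by
#' multiplying by 9/8 and rounding half-up to an integer, so scores live on
#' the published 0-27 PHQ-9 scale.
#'
#' @param items integer vector of exactly 8 responses in `[0, 3]`.
#' @return integer adjusted score in `[0, 27]`.
#' @examples
#' prorate_phq8(c(2, 2, 2, 2, 2, 2, 2, 2))  # raw 16 -> 18
#' @export
prorate_phq8 <- function(items) {
  items <- check_integerish(items, "PHQ-9A items")
  abort_if(length(items) != 8L, "8-item PHQ-9A requires exactly 8 items")
  bad <- which(items < 0L | items > 3L)
  abort_if(length(bad) > 0, sprintf("PHQ-9A item %d out of [0,3]", bad[1]))
  prorate_phq8_sum(sum(items))
}

#' Convert a PROMIS raw sum to a T-score
#'
#' Looks the raw sum up in the instrument's raw-to-T calibration table
#' (population mean 50, SD 10 on the reporting scale).
#'
#' @param raw_sum integer raw item-sum.
#' @param config an [instrument_config()] with `conversion = "tscore"`.
#' @return numeric T-score.
#' @export
convert_promis_tscore <- function(raw_sum, config) {
  abort_if(is.null(config$tscore_table),
           sprintf("instrument %s has no T-score table", config$instrument_id))
  i <- match(raw_sum, config$tscore_table$raw_sum)
  abort_if(anyNA(i),
           sprintf("T-score table for %s has no entry for raw sum %s",
                   config$instrument_id,
                   paste(raw_sum[is.na(i)], collapse = ", ")))
  config$tscore_table$t_score[i]
}

# raw sum -> converted reporting-scale score (vectorised over raw_sum)
convert_score <- function(raw_sum, config) {
  switch(config$conversion,
    none = as.numeric(raw_sum),
    prorate_9_8 = as.numeric(prorate_phq8_sum(raw_sum)),
    tscore = convert_promis_tscore(raw_sum, config)
  )
}

#' Classify a converted score into a severity band
#'
#' Bands are contiguous with inclusive lower bounds; a score on a boundary
#' belongs to the higher band.
#'
#' @param converted_score numeric score(s) on the instrument's reporting
#'   scale.
#' @param config an [instrument_config()].
#' @return character vector of band labels.
#' @examples
#' classify_severity(12, default_instrument_configs()$GAD7)  # "moderate"
#' @export
classify_severity <- function(converted_score, config) {
  rng <- converted_range(config)
  abort_if(any(converted_score < rng[1] - 1e-9 | converted_score > rng[2] + 1e-9),
           sprintf("score outside the %s range [%s, %s]",
                   config$instrument_id, rng[1], rng[2]))
  idx <- findInterval(converted_score + 1e-9, config$severity_bands$lower)
  abort_if(any(idx < 1L),
           sprintf("score below the lowest %s severity band", config$instrument_id))
  config$severity_bands$label[idx]
}

#' Read an instrument configuration from YAML
#'
#' The YAML file carries the [instrument_config()] fields; a
#' `tscore_table` entry may be either an inline mapping or a path
#' (relative to the YAML file) to a two-column CSV `raw_sum,t_score`.
#'
#' @param path path to a YAML file.
#' @return an `instrument_config`.
#' @export
read_instrument_config <- function(path) {
  y <- yaml::read_yaml(path)
  tab <- NULL
  if (!is.null(y$tscore_table)) {
    if (is.character(y$tscore_table) && length(y$tscore_table) == 1L) {
      csv <- file.path(dirname(path), y$tscore_table)
      tab <- readr::read_csv(csv, col_types = "id", progress = FALSE)
    } else {
      tab <- tibble::tibble(
        raw_sum = vapply(y$tscore_table, function(r) as.integer(r$raw_sum), 1L),
        t_score = vapply(y$tscore_table, function(r) as.numeric(r$t_score), 1)
      )
    }
  }
  instrument_config(
    instrument_id = y$instrument_id,
    item_count = y$item_count,
    item_scale_max = y$item_scale_max,
    conversion = y$conversion %||% "none",
    severity_bands = tibble::tibble(
      label = vapply(y$severity_bands, function(b) as.character(b$label), ""),
      lower = vapply(y$severity_bands, function(b) as.numeric(b$lower), 1)
    ),
    eligible_severities = unlist(y$eligible_severities),
    tscore_table = tab,
    screener_item_count = y$screener_item_count %||% 3L,
    screener_trigger_threshold = y$screener_trigger_threshold %||% 2L
  )
}

# score one member-date worth of item rows; internal workhorse for
# score_assessments(). Screener rows gate the full assessment: a
# non-triggered screener yields a screened-out observation.
score_one_assessment <- function(screener_responses, full_items, config) {
  scr <- score_screener(screener_responses, config)
  if (!scr$triggered) {
    return(list(screened_out = TRUE, raw_sum = NA_integer_,
                converted_score = NA_real_, severity = NA_character_))
  }
  if (is.null(full_items) || length(full_items) == 0L) {
    return(NULL) # triggered but full assessment not completed -> no observation
  }
  abort_if(length(full_items) != config$item_count,
           sprintf("%s expects %d items, got %d", config$instrument_id,
                   config$item_count, length(full_items)))
  full_items <- check_integerish(full_items, "assessment items")
  bad <- which(full_items < 0L | full_items > config$item_scale_max)
  abort_if(length(bad) > 0,
           sprintf("%s item %d out of [0,%d]", config$instrument_id, bad[1],
                   config$item_scale_max))
  raw <- sum(full_items)
  conv <- convert_score(raw, config)
  list(screened_out = FALSE, raw_sum = raw, converted_score = conv,
       severity = classify_severity(conv, config))
}

#' Score long-format item responses into assessment observations
#'
#' Takes item-level responses in long format (one row per item response)
#' and produces one scored observation per member-date. Screener rows
#' (`phase == "screener"`) gate the full assessment: if no screener item
#' reaches the trigger threshold the observation is recorded as screened
#' out, with no converted score. Member-dates whose screener triggered but
#' whose full assessment is absent are dropped (incomplete assessments).
#'
#' @param items tibble/data frame with columns `member_id`, `date`,
#'   `instrument_id`, `phase` (`"screener"` or `"full"`), `item_index`,
#'   `response`.
#' @param configs named list of [instrument_config()] objects (defaults to
#'   [default_instrument_configs()]).
#' @return tibble with one row per scored observation: `member_id`, `date`,
#'   `instrument_id`, `screened_out`, `raw_sum`, `converted_score`,
#'   `severity`.
#' @export
score_assessments <- function(items, configs = default_instrument_configs()) {
  items <- tibble::as_tibble(items)
  need <- c("member_id", "date", "instrument_id", "phase", "item_index", "response")
  abort_if(!all(need %in% names(items)),
           paste("items must have columns", paste(need, collapse = ", ")))
  items$date <- as.Date(items$date)
  out <- items |>
    dplyr::group_by(.data$member_id, .data$date, .data$instrument_id) |>
    dplyr::group_modify(function(g, key) {
      cfg <- configs[[key$instrument_id]]
      abort_if(is.null(cfg),
               sprintf("no configuration for instrument %s", key$instrument_id))
      scr <- dplyr::arrange(g[g$phase == "screener", ], .data$item_index)
      ful <- dplyr::arrange(g[g$phase == "full", ], .data$item_index)
      res <- score_one_assessment(scr$response, ful$response, cfg)
      if (is.null(res)) return(tibble::tibble())
      tibble::as_tibble(res)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$member_id, .data$date)
  out
}
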