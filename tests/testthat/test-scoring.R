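cfgs <- default_instrument_configs()

test_that("screener gating follows the any-item-at-threshold rule", {
  gad <- cfgs$GAD7
  expect_false(score_screener(c(0, 0, 0), gad)$triggered)
  expect_true(score_screener(c(0, 2, 0), gad)$triggered)   # boundary item
  expect_false(score_screener(c(1, 1, 1), gad)$triggered)  # all sub-threshold
  expect_error(score_screener(c(0, 5, 0), gad), "item 2")
  # rule depends only on the vector and threshold, exhaustively checked
  set.seed(11)
  for (i in 1:50) {
    r <- sample(0:4, 3, replace = TRUE)
    expect_identical(score_screener(r, gad)$triggered, any(r >= 2))
  }
})

test_that("GAD-7 totals are plain sums on the 0-21 scale", {
  expect_identical(score_gad7(rep(0L, 7)), 0L)
  expect_identical(score_gad7(rep(3L, 7)), 21L)
  expect_identical(score_gad7(c(1, 2, 0, 3, 1, 1, 2)), 10L)
  expect_error(score_gad7(rep(1, 6)), "exactly 7")
  expect_error(score_gad7(c(rep(1, 6), 4)), "out of \\[0,3\\]")
})

test_that("PHQ-9A proration maps the 8-item sum onto the 0-27 scale", {
  expect_identical(prorate_phq8(rep(0L, 8)), 0L)
  expect_identical(prorate_phq8(rep(2L, 8)), 18L)  # raw 16 * 9/8
  expect_identical(prorate_phq8(rep(3L, 8)), 27L)  # maximum maps to maximum
  # half-up rounding: raw 4 -> 4.5 -> 5
  expect_identical(prorate_phq8(c(rep(1L, 4), rep(0L, 4))), 5L)
  # monotone over the full attainable range
  prorated <- vapply(0:24, function(s) {
    prorate_phq8(backfill_items(s, 8, 3))
  }, 1L)
  expect_true(all(diff(prorated) >= 0))
  expect_error(prorate_phq8(rep(1, 7)), "exactly 8")
})

test_that("PROMIS T-score lookup is a monotone table map", {
  idcfg <- instrument_config(
    "PROMIS_ANX_PED", 3L, 4L, "tscore",
    severity_bands = tibble::tibble(label = c("low", "high"), lower = c(0, 6)),
    eligible_severities = "high",
    tscore_table = tibble::tibble(raw_sum = 0:12, t_score = as.numeric(0:12))
  )
  expect_identical(convert_promis_tscore(12L, idcfg), 12)
  two <- instrument_config(
    "PROMIS_ANX_PED", 1L, 1L, "tscore",
    severity_bands = tibble::tibble(label = "all", lower = 0),
    eligible_severities = "all",
    tscore_table = tibble::tibble(raw_sum = 0:1, t_score = c(38.1, 42.0))
  )
  expect_identical(convert_promis_tscore(1L, two), 42.0)
  expect_error(convert_promis_tscore(7L, two), "no entry for raw sum 7")
  # monotone over the full shipped synthetic tables
  for (cfg in cfgs[c("PROMIS_ANX_PED", "PROMIS_DEP_PED")]) {
    raws <- 0:(cfg$item_count * cfg$item_scale_max)
    expect_true(all(diff(convert_promis_tscore(raws, cfg)) >= 0))
  }
})

test_that("severity bands partition every attainable converted score", {
  expect_identical(classify_severity(12, cfgs$GAD7), "moderate")
  expect_identical(classify_severity(17, cfgs$PHQ9A_8ITEM), "moderately severe")
  # boundaries are inclusive lower bounds of the higher band
  expect_identical(classify_severity(15, cfgs$GAD7), "severe")
  expect_identical(classify_severity(10, cfgs$PHQ9A_8ITEM), "moderate")
  expect_error(classify_severity(25, cfgs$GAD7), "outside")
  for (cfg in cfgs) {
    raws <- 0:(cfg$item_count * cfg$item_scale_max)
    conv <- vapply(raws, function(r) {
      switch(cfg$conversion,
             none = as.numeric(r),
             prorate_9_8 = as.numeric(prorate_phq8(backfill_items(r, 8, 3))),
             tscore = convert_promis_tscore(r, cfg))
    }, 1)
    sev <- classify_severity(conv, cfg)
    expect_true(all(sev %in% cfg$severity_bands$label))
    expect_false(anyNA(sev))
  }
})

test_that("long-format item responses score into gated observations", {
  d <- as.Date("2023-03-01")
  items <- dplyr::bind_rows(
    # triggered screener + full assessment
    tibble::tibble(member_id = "A", date = d, instrument_id = "GAD7",
                   phase = "screener", item_index = 1:3, response = c(3L, 0L, 0L)),
    tibble::tibble(member_id = "A", date = d, instrument_id = "GAD7",
                   phase = "full", item_index = 1:7,
                   response = c(2L, 2L, 2L, 2L, 2L, 1L, 1L)),
    # screened out: no full assessment administered
    tibble::tibble(member_id = "A", date = d + 30, instrument_id = "GAD7",
                   phase = "screener", item_index = 1:3, response = c(1L, 0L, 1L)),
    # triggered but full assessment missing -> dropped as incomplete
    tibble::tibble(member_id = "A", date = d + 60, instrument_id = "GAD7",
                   phase = "screener", item_index = 1:3, response = c(3L, 0L, 0L))
  )
  out <- score_assessments(items)
  expect_identical(nrow(out), 2L)
  expect_identical(out$raw_sum[1], 12L)
  expect_identical(out$severity[1], "moderate")
  expect_true(out$screened_out[2])
  expect_true(is.na(out$converted_score[2]))
})

test_that("instrument configs round-trip through YAML with a CSV T-table", {
  dir <- withr::local_tempdir()
  readr::write_csv(tibble::tibble(raw_sum = 0:8, t_score = 30 + 2 * (0:8)),
                   file.path(dir, "ttab.csv"))
  yaml::write_yaml(list(
    instrument_id = "PROMIS_ANX_PED", item_count = 2L, item_scale_max = 4L,
    conversion = "tscore",
    severity_bands = list(list(label = "normal", lower = 30),
                          list(label = "moderate", lower = 40)),
    eligible_severities = list("moderate"),
    tscore_table = "ttab.csv"
  ), file.path(dir, "cfg.yaml"))
  cfg <- read_instrument_config(file.path(dir, "cfg.yaml"))
  expect_s3_class(cfg, "instrument_config")
  expect_identical(convert_promis_tscore(4L, cfg), 38)
  expect_identical(classify_severity(41, cfg), "moderate")
})
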