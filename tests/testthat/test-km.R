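test_that("the product-limit estimate matches hand computation", {
  # three events at distinct times
  f <- km_fit(time = c(1, 2, 3), event = c(TRUE, TRUE, TRUE))
  expect_equal(f$table$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(f$table$at_risk, c(3L, 2L, 1L))
  # all censored: flat at 1, no median
  f2 <- km_fit(time = c(2, 5, 7), event = c(FALSE, FALSE, FALSE))
  expect_true(all(f2$table$survival == 1))
  expect_true(is.na(f2$median))
  # censoring shrinks the risk set after its time: risk sets {3, 1}
  f3 <- km_fit(time = c(1, 2, 3), event = c(TRUE, FALSE, TRUE))
  expect_equal(f3$table$survival[f3$table$time == 1], 2 / 3)
  expect_equal(f3$table$survival[f3$table$time == 3], 0)
  expect_identical(f3$median, 3)
  expect_error(km_fit(time = numeric(0), event = logical(0)), "no event")
  expect_error(km_fit(time = c(0, 1), event = c(TRUE, TRUE)), "positive")
})

test_that("the median is the first time survival reaches one half", {
  expect_identical(km_fit(time = 4, event = TRUE)$median, 4)
  # S(2) = 0.5 exactly: default takes the first time at 0.5 or below
  ev <- tibble::tibble(time_sessions = rep(c(2, 7), each = 50),
                       event_observed = TRUE)
  f <- km_fit(ev)
  expect_identical(f$median, 2)
  # the interpolating variant reports the midpoint of the flat region
  expect_identical(km_median(f, interpolate = TRUE)$median, 4.5)
})

test_that("log-log bands are degenerate at S=1 and tighten with confidence", {
  f <- km_fit(time = c(3, 5, 5, 8, 9), event = c(FALSE, TRUE, TRUE, FALSE, TRUE))
  tab <- f$table
  expect_equal(tab$ci_lower[tab$survival == 1], 1)
  expect_equal(tab$ci_upper[tab$survival == 1], 1)
  inner <- tab$survival > 0 & tab$survival < 1
  expect_true(all(tab$ci_lower[inner] <= tab$survival[inner]))
  expect_true(all(tab$ci_upper[inner] >= tab$survival[inner]))
  # a lower confidence level gives a narrower band at every time
  set.seed(8)
  for (i in 1:20) {
    ev <- random_event_table(30)
    f95 <- km_fit(ev, conf_level = 0.95)$table
    f80 <- km_fit(ev, conf_level = 0.80)$table
    ok <- !is.na(f95$ci_lower) & f95$survival > 0 & f95$survival < 1
    expect_true(all(f80$ci_lower[ok] >= f95$ci_lower[ok] - 1e-12))
    expect_true(all(f80$ci_upper[ok] <= f95$ci_upper[ok] + 1e-12))
  }
  # the plain (untransformed Greenwood) variant stays within [0, 1]
  fp <- km_fit(time = c(1, 1, 2, 3), event = rep(TRUE, 4), conf_type = "plain")
  ok <- !is.na(fp$table$ci_lower)
  expect_true(all(fp$table$ci_lower[ok] >= 0 & fp$table$ci_upper[ok] <= 1))
})

test_that("median confidence bounds come from band crossings of one half", {
  # hand-checkable: heavy late events push the upper bound out
  ev <- tibble::tibble(
    time_sessions = c(rep(2, 6), rep(5, 3), rep(9, 3)),
    event_observed = c(rep(TRUE, 6), rep(TRUE, 3), rep(FALSE, 3))
  )
  f <- km_fit(ev)
  tab <- f$table
  lcl <- tab$time[which(tab$ci_lower <= 0.5 + 1e-9)[1]]
  ucl_idx <- which(!is.na(tab$ci_upper) & tab$ci_upper <= 0.5 + 1e-9)
  ucl <- if (length(ucl_idx) == 0) NA_real_ else tab$time[ucl_idx[1]]
  expect_identical(f$median_ci[1], lcl)
  expect_identical(f$median_ci[2], ucl)
  # an upper bound can be genuinely unavailable
  ev2 <- tibble::tibble(time_sessions = c(1, 2, 3, 4),
                        event_observed = c(TRUE, TRUE, FALSE, FALSE))
  expect_true(is.na(km_fit(ev2)$median_ci[2]))
})

test_that("age-band subgroup curves partition the pooled analysis", {
  set.seed(21)
  members <- make_members(sprintf("M%02d", 1:40),
                          age_years = c(rep(8, 22), rep(15, 18)))
  ev <- random_event_table(40)
  ev$member_id <- members$member_id
  sub <- subgroup_analysis(ev, members)
  expect_named(sub, c("child", "adolescent"))
  expect_identical(sub$child$n, 22L)
  # pooled fit equals the fit of the union of the band tables
  pooled <- km_fit(ev)
  union_fit <- km_fit(dplyr::bind_rows(
    ev[ev$member_id %in% members$member_id[members$age_band == "child"], ],
    ev[ev$member_id %in% members$member_id[members$age_band == "adolescent"], ]
  ))
  expect_equal(union_fit$table, pooled$table)
  # an empty band is omitted with a warning
  kids <- make_members(sprintf("K%02d", 1:10), age_years = 9)
  evk <- random_event_table(10)
  evk$member_id <- kids$member_id
  expect_warning(subk <- subgroup_analysis(evk, kids), "adolescent")
  expect_named(subk, "child")
})

test_that("higher child hazard yields child medians at or below adolescent medians", {
  # planted stochastic ordering: children improve faster
  set.seed(33)
  worse <- 0
  for (i in 1:20) {
    members <- make_members(sprintf("M%03d", 1:120),
                            age_years = c(rep(8, 60), rep(15, 60)))
    t_child <- pmin(stats::rgeom(60, 0.5) + 1L, 12L)
    t_adol <- pmin(stats::rgeom(60, 0.25) + 1L, 12L)
    ev <- tibble::tibble(
      member_id = members$member_id,
      time_sessions = c(t_child, t_adol),
      event_observed = c(t_child, t_adol) < 12L
    )
    sub <- subgroup_analysis(ev, members)
    if (sub$child$median > sub$adolescent$median) worse <- worse + 1
  }
  expect_lte(worse, 1)
})
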