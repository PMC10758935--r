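#' Product-limit (Kaplan-Meier) estimate over discrete session counts
#'
#' From-scratch product-limit estimator for right-censored event times on
#' a discrete time axis (coaching sessions). At each distinct time
#' \eqn{t_i} with \eqn{d_i} events among \eqn{n_i} at risk,
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i/n_i)}. Members censored at an
#' event time are kept in the risk set for that time (events are processed
#' before censorings, the standard tie convention). Pointwise 95%
#' confidence bands use the Greenwood variance on the log(-log S) scale;
#' the median is the first time S drops to 0.5 or below, with its
#' confidence interval read off the times at which the pointwise bands
#' cross 0.5 (the band-crossing construction used by mainstream survival
#' software).
#'
#' @param events tibble with columns `time_sessions` (positive times) and
#'   `event_observed` (logical; `FALSE` = right-censored), as produced by
#'   [build_event_table()]. Alternatively pass numeric `time` and logical
#'   `event` vectors via `time`/`event`.
#' @param time,event optional bare vectors instead of `events`.
#' @param conf_level confidence level for the bands (default 0.95).
#' @param conf_type `"loglog"` (default) or `"plain"` (untransformed
#'   Greenwood interval).
#' @return object of class `km_curve`: a list with a per-time tibble
#'   (`time`, `at_risk`, `events`, `censored`, `survival`, `variance`,
#'   `ci_lower`, `ci_upper`), the sample size `n`, and `median`,
#'   `median_ci` as computed by [km_median()].
#' @examples
#' km_fit(time = c(1, 2, 3), event = c(TRUE, TRUE, TRUE))
#' @export
km_fit <- function(events = NULL, time = NULL, event = NULL,
                   conf_level = 0.95, conf_type = c("loglog", "plain")) {
  conf_type <- match.arg(conf_type)
  if (!is.null(events)) {
    time <- events$time_sessions
    event <- events$event_observed
  }
  abort_if(length(time) == 0L, "no event records supplied")
  abort_if(any(is.na(time)) || any(time <= 0),
           "event times must be positive and non-missing")
  event <- as.logical(event)

  ut <- sort(unique(as.numeric(time)))
  n_risk <- vapply(ut, function(t) sum(time >= t), 1L)
  d <- vapply(ut, function(t) sum(time == t & event), 1L)
  cns <- vapply(ut, function(t) sum(time == t & !event), 1L)
  s <- cumprod(1 - d / n_risk)
  # Greenwood: Var(S) = S^2 * sum d/(n(n-d)); term undefined once S hits 0
  gterm <- ifelse(n_risk > d, d / (n_risk * (n_risk - d)), NA_real_)
  g <- cumsum(gterm)
  vr <- s^2 * g
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- hi <- rep(NA_real_, length(s))
  inner <- s > 0 & s < 1 & !is.na(g)
  if (conf_type == "loglog") {
    se_ll <- sqrt(g[inner]) / abs(log(s[inner]))
    lo[inner] <- s[inner]^exp(z * se_ll)
    hi[inner] <- s[inner]^exp(-z * se_ll)
  } else {
    se <- sqrt(vr[inner])
    lo[inner] <- pmax(0, s[inner] - z * se)
    hi[inner] <- pmin(1, s[inner] + z * se)
  }
  # degenerate band where no uncertainty has accrued yet
  lo[s == 1] <- 1
  hi[s == 1] <- 1
  tab <- tibble::tibble(
    time = ut, at_risk = n_risk, events = d, censored = cns,
    survival = s, variance = vr, ci_lower = lo, ci_upper = hi
  )
  curve <- structure(
    list(table = tab, n = length(time), conf_level = conf_level,
         conf_type = conf_type),
    class = "km_curve"
  )
  med <- km_median(curve)
  curve$median <- med$median
  curve$median_ci <- c(med$ci_lower, med$ci_upper)
  curve
}

#' Median survival time with confidence interval
#'
#' The median is the smallest observed time at which the survival estimate
#' is 0.5 or less (`NA` when the curve never reaches 0.5). When
#' `interpolate = TRUE` and the curve sits exactly at 0.5 over a flat
#' region, the median is instead reported as the midpoint of that region —
#' the convention of common survival software, which can yield
#' half-integer medians on an integer time grid. The confidence bounds are
#' the first times at which the pointwise lower (resp. upper) confidence
#' band drops to 0.5 or below; the upper bound is "not available" (`NA`)
#' when the upper band never reaches 0.5.
#'
#' @param curve a [km_fit()] object.
#' @param interpolate midpoint rule for curves hitting 0.5 exactly
#'   (default `FALSE`).
#' @return list with `median`, `ci_lower`, `ci_upper`.
#' @export
km_median <- function(curve, interpolate = FALSE) {
  stopifnot(inherits(curve, "km_curve"))
  tab <- curve$table
  # ties with 0.5 at square-root machine precision, the convention of
  # mainstream survival software
  eps <- sqrt(.Machine$double.eps)
  first_at_or_below <- function(v, x) {
    i <- which(!is.na(v) & v <= x + eps)
    if (length(i) == 0L) NA_real_ else tab$time[i[1]]
  }
  med <- first_at_or_below(tab$survival, 0.5)
  if (interpolate && !is.na(med)) {
    # exact tie at 0.5: midpoint of the flat region, taken to the time the
    # curve first drops below one half, or to the end of follow-up if it
    # never does
    i <- which(!is.na(tab$survival) & tab$survival <= 0.5 + eps)[1]
    if (abs(tab$survival[i] - 0.5) < eps) {
      j <- which(tab$time > tab$time[i] & tab$survival < 0.5 - eps)
      upper <- if (length(j) > 0L) tab$time[j[1]] else max(tab$time)
      med <- (tab$time[i] + upper) / 2
    }
  }
  list(
    median = med,
    ci_lower = first_at_or_below(tab$ci_lower, 0.5),
    ci_upper = first_at_or_below(tab$ci_upper, 0.5)
  )
}

#' @export
print.km_curve <- function(x, ...) {
  ci <- x$median_ci
  fmt <- function(v) ifelse(is.na(v), "not available", format(v))
  cat(sprintf(
    "<km_curve> n=%d, events=%d; median %s (%.0f%% CI %s-%s)\n",
    x$n, sum(x$table$events), fmt(x$median), 100 * x$conf_level,
    fmt(ci[1]), fmt(ci[2])
  ))
  invisible(x)
}

#' Tidy a fitted curve
#'
#' @param curve a [km_fit()] object.
#' @return the per-time tibble of the estimate.
#' @export
km_table <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  curve$table
}

#' Age-band subgroup survival analysis
#'
#' Refits the product-limit estimator within each age band (children 6-12,
#' adolescents 13-17), mirroring the pooled analysis. Empty bands are
#' omitted with a warning.
#'
#' @param events event tibble from [build_event_table()].
#' @param members members table carrying `member_id` and `age_band`.
#' @param conf_level,conf_type passed to [km_fit()].
#' @return named list of `km_curve` objects, one per non-empty band.
#' @export
subgroup_analysis <- function(events, members, conf_level = 0.95,
                              conf_type = "loglog") {
  ev <- dplyr::inner_join(events,
                          dplyr::select(members, "member_id", "age_band"),
                          by = "member_id")
  bands <- c("child", "adolescent")
  out <- list()
  for (b in bands) {
    sub <- dplyr::filter(ev, .data$age_band == b)
    if (nrow(sub) == 0L) {
      warning(sprintf("no members in the %s band; curve omitted", b),
              call. = FALSE)
      next
    }
    out[[b]] <- km_fit(sub, conf_level = conf_level, conf_type = conf_type)
  }
  out
}

#' Plot a survival curve
#'
#' Step plot of the product-limit estimate with dotted pointwise
#' confidence bands and a horizontal reference line at 0.5, the style of
#' time-to-improvement survival figures.
#'
#' @param curve a [km_fit()] object.
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_km <- function(curve, title = NULL) {
  tab <- km_table(curve)
  # prepend time 0 at S = 1 so the step starts at the origin
  tab0 <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1, ci_lower = 1, ci_upper = 1),
    dplyr::select(tab, "time", "survival", "ci_lower", "ci_upper")
  )
  ggplot2::ggplot(tab0, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_step(ggplot2::aes(y = .data$ci_lower), linetype = "dotted",
                       na.rm = TRUE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$ci_upper), linetype = "dotted",
                       na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0.5, colour = "blue", linewidth = 0.3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Coaching sessions", y = "Proportion without reliable change",
                  title = title) +
    ggplot2::theme_minimal()
}
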