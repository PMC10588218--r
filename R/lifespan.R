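#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate of the survival function with Greenwood
#' standard errors and log-log transformed pointwise 95% confidence
#' intervals (the transform respects the \[0, 1\] bounds). Deaths precede
#' censorings at tied times, the standard convention — relevant here
#' because every-other-day census data make ties common.
#'
#' @param time_days event or censoring times (> 0).
#' @param event 1 = died, 0 = censored.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `km_curve`: list with `time`, `n_risk`,
#'   `n_event`, `surv`, `std_err` (Greenwood SE of S), `lower`, `upper`,
#'   `n`, and the underlying [survival::survfit] object in `fit`.
#' @examples
#' km <- km_estimate(c(2, 4, 5, 6, 8), c(1, 1, 0, 1, 1))
#' km$surv  # 0.8 0.6 0.3 0.0
#' @export
km_estimate <- function(time_days, event, conf_level = 0.95) {
  stopifnot(length(time_days) == length(event), all(time_days > 0),
            all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time_days, event) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, surv = fit$surv,
                 std_err = fit$std.err * fit$surv,  # Greenwood SE of S
                 lower = fit$lower, upper = fit$upper,
                 n = length(time_days), conf_level = conf_level,
                 fit = fit),
            class = "km_curve")
}

#' Median survival with confidence interval
#'
#' Median = smallest time at which the estimated survival falls to 0.5 or
#' below; the interval comes from intersecting the pointwise log-log
#' confidence band with 0.5 (Brookmeyer-Crowley style, as implemented by
#' the survival package). All three are `NA` when the curve never
#' reaches 0.5.
#'
#' @param curve a [km_estimate()] object.
#' @return data.frame with `median`, `lower`, `upper` (days).
#' @export
median_with_ci <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  tab <- summary(curve$fit)$table
  lcl <- grep("LCL", names(tab)); ucl <- grep("UCL", names(tab))
  data.frame(median = unname(tab["median"]),
             lower = unname(tab[lcl]), upper = unname(tab[ucl]))
}

#' Log-rank comparison of survival across groups
#'
#' Two-group log-rank test, extended to k groups via the usual chi-square
#' statistic.
#'
#' @param time_days,event as in [km_estimate()].
#' @param group group labels; at least two distinct groups.
#' @return data.frame with `statistic` (chi-square), `df`, `p_value`.
#' @export
logrank_test <- function(time_days, event, group) {
  group <- as.character(group)
  if (length(unique(group)) < 2L) {
    stop("log-rank test requires at least two groups")
  }
  sd <- survival::survdiff(survival::Surv(time_days, event) ~ group)
  df <- length(sd$n) - 1L
  data.frame(statistic = unname(sd$chisq), df = df,
             p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' @export
print.km_curve <- function(x, ...) {
  med <- median_with_ci(x)
  cat("Kaplan-Meier curve: n =", x$n, ", events =", sum(x$n_event), "\n")
  cat(sprintf("median survival %s days (%d%% CI %s-%s)\n",
              format(med$median), round(100 * x$conf_level),
              format(med$lower), format(med$upper)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "days", ylab = "survival", ...) {
  plot(x$fit, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
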