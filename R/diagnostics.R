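#' Kaplan-Meier product-limit estimator
#'
#' Nonparametric survival estimate feeding the Weibull-adequacy
#' diagnostic. At each distinct event time the survival drops by the
#' factor (1 - d/r); subjects censored exactly at an event time are still
#' counted in the risk set at that time (deaths before censorings at
#' ties, the standard convention).
#'
#' @param data a [cohort()].
#' @param event_definition `"cause1"` (competing deaths censored, the
#'   default, since the diagnostic targets the cause-specific Weibull
#'   form) or `"any-death"`.
#' @return object of class `"step_survival"`: data frame with one row per
#'   distinct event time (`time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`), survival nonincreasing, equal to 1 before the first event.
#' @export
kaplan_meier <- function(data, event_definition = c("cause1", "any-death")) {
  event_definition <- match.arg(event_definition)
  if (!nrow(data)) stop("empty dataset")
  status <- if (event_definition == "cause1") data$event == 1
            else data$event > 0
  if (!any(status)) stop("no events under definition '", event_definition,
                         "'")
  ord <- order(data$time)
  tt <- data$time[ord]
  st <- status[ord]
  ut <- sort(unique(tt[st]))
  n <- length(tt)
  rows <- lapply(ut, function(u) {
    data.frame(time = u,
               n_risk = sum(tt >= u),
               n_event = sum(tt == u & st),
               n_censor = sum(tt == u & !st))
  })
  out <- do.call(rbind, rows)
  out$surv <- cumprod(1 - out$n_event / out$n_risk)
  attr(out, "n") <- n
  attr(out, "event_definition") <- event_definition
  class(out) <- c("step_survival", "data.frame")
  out
}

#' Complementary log-log transform of a survival step function
#'
#' The Weibull diagnostic coordinates: if S(t) = exp(-lambda t^p) then
#' log(-log S(t)) = log lambda + p log t, a straight line in log t with
#' slope p. Points where S = 1 or S = 0 are dropped (the transform is
#' undefined there).
#'
#' @param surv a `"step_survival"` from [kaplan_meier()], or any data
#'   frame with columns `time` and `surv`.
#' @return data frame with columns `log_time` and `cloglog`.
#' @export
cloglog_points <- function(surv) {
  keep <- surv$surv > 0 & surv$surv < 1
  if (sum(keep) < 2) stop("fewer than 2 usable points (0 < S < 1)")
  data.frame(log_time = log(surv$time[keep]),
             cloglog = log(-log(surv$surv[keep])))
}

#' Weibull linearity diagnostic
#'
#' Ordinary least squares of log(-log S) on log t. Under a Weibull law the
#' points lie on a line whose slope estimates the shape p and whose
#' intercept estimates log lambda; R^2 close to 1 supports the Weibull
#' form.
#'
#' @param points data frame from [cloglog_points()].
#' @return list with `slope`, `intercept`, `r2`.
#' @export
weibull_linearity <- function(points) {
  if (nrow(points) < 3) stop("need at least 3 points")
  if (stats::var(points$log_time) < 1e-14)
    stop("degenerate x-variance: all log times equal")
  fit <- stats::lm(cloglog ~ log_time, data = points)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((points$cloglog - mean(points$cloglog))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = 1 - ss_res / ss_tot)
}
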