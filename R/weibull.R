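#' Model parameters for the cause-specific Weibull model
#'
#' The model gives cause j the Weibull survival function
#' S_j(t; x) = exp(-lambda_j(x) t^{p_j}) with a log-linear scale link
#' lambda_j(x) = exp(x . beta_j). Under this link every coefficient is a
#' time-constant log cause-specific hazard ratio, since
#' h_j(t; x) = lambda_j(x) p_j t^{p_j - 1} is proportional in x.
#'
#' @param betas list of per-cause coefficient vectors (first entry the
#'   intercept, on the log-scale contribution to lambda_j).
#' @param shapes per-cause shapes p_j (> 0).
#' @return object of class `"model_params"`.
#' @export
model_params <- function(betas, shapes) {
  if (!is.list(betas)) betas <- list(betas)
  if (length(shapes) != length(betas))
    stop("one shape per cause required")
  if (any(shapes <= 0)) stop("shapes must be strictly positive")
  w <- unique(vapply(betas, length, integer(1)))
  if (length(w) != 1) stop("all beta vectors must share one design width")
  structure(list(betas = betas, shapes = as.numeric(shapes),
                 n_causes = length(betas), width = w),
            class = "model_params")
}

scale_lambda <- function(x, beta) {
  x <- rbind(x)  # single profile or matrix of profiles
  unname(exp(drop(x %*% beta)))
}

#' Cause-specific hazard
#'
#' h_j(t; x) = lambda_j(x) p_j t^{p_j - 1}, the instantaneous rate of
#' failure from cause j among subjects still free of every cause.
#'
#' @param t time in months, strictly positive.
#' @param x covariate design row (or matrix of rows).
#' @param j cause index.
#' @param params a [model_params()].
#' @return hazard per month.
#' @export
cause_specific_hazard <- function(t, x, j, params) {
  if (any(t <= 0)) stop("t must be strictly positive")
  lam <- scale_lambda(x, params$betas[[j]])
  p <- params$shapes[j]
  lam * p * t^(p - 1)
}

#' Cause-specific survival function
#'
#' S_j(t; x) = exp(-lambda_j(x) t^{p_j}).
#'
#' @inheritParams cause_specific_hazard
#' @return probability in (0, 1].
#' @export
cause_specific_survival <- function(t, x, j, params) {
  if (any(t < 0)) stop("t must be nonnegative")
  lam <- scale_lambda(x, params$betas[[j]])
  p <- params$shapes[j]
  exp(-lam * t^p)
}

#' Overall (event-free) survival
#'
#' Probability of surviving all causes: the cause-specific cumulative
#' hazards add, so S(t; x) = exp(-sum_j lambda_j(x) t^{p_j}) =
#' prod_j S_j(t; x).
#'
#' @inheritParams cause_specific_hazard
#' @return probability in (0, 1].
#' @export
overall_survival <- function(t, x, params) {
  if (any(t < 0)) stop("t must be nonnegative")
  H <- 0
  for (j in seq_len(params$n_causes)) {
    lam <- scale_lambda(x, params$betas[[j]])
    H <- H + lam * t^params$shapes[j]
  }
  exp(-H)
}

#' Competing-risks log-likelihood
#'
#' The cause-specific likelihood: each subject contributes the log hazard
#' of their failure cause (if any) and minus the total cumulative hazard
#' over all causes,
#' ell = sum_i [ sum_j 1(event_i = j) log h_j(t_i; x_i)
#'               - sum_j lambda_j(x_i) t_i^{p_j} ].
#' It is additively separable across causes: the joint value equals the sum
#' of single-cause log-likelihoods in which other-cause failures are
#' treated as censored.
#'
#' @param data a [cohort()].
#' @param params a [model_params()] with one beta vector per cause.
#' @param covariates covariate set passed to [encode_design()]; must match
#'   the width of `params`.
#' @return log-likelihood value.
#' @export
log_likelihood <- function(data, params,
                           covariates = c("bmi", "age", "sex", "stage")) {
  if (any(data$time <= 0)) stop("all times must be strictly positive")
  X <- encode_design(data, covariates)
  if (ncol(X) != params$width)
    stop("design width ", ncol(X), " does not match params width ",
         params$width)
  ll <- 0
  for (j in seq_len(params$n_causes)) {
    ll <- ll + single_cause_loglik(
      c(params$betas[[j]], log(params$shapes[j])),
      time = data$time, status = as.numeric(data$event == j), X = X,
      fix_shape = NULL)
  }
  ll
}

# theta = (beta, log p) -- or just beta when fix_shape is given
single_cause_loglik <- function(theta, time, status, X, fix_shape = NULL) {
  q <- ncol(X)
  beta <- theta[1:q]
  p <- if (is.null(fix_shape)) exp(theta[q + 1]) else fix_shape
  lt <- log(time)
  eta <- drop(X %*% beta)
  mu <- exp(eta + p * lt)            # lambda_i * t_i^p
  sum(status * (eta + log(p) + (p - 1) * lt)) - sum(mu)
}

single_cause_grad <- function(theta, time, status, X, fix_shape = NULL) {
  q <- ncol(X)
  beta <- theta[1:q]
  p <- if (is.null(fix_shape)) exp(theta[q + 1]) else fix_shape
  lt <- log(time)
  mu <- exp(drop(X %*% beta) + p * lt)
  gb <- drop(crossprod(X, status - mu))
  if (is.null(fix_shape)) {
    gs <- sum(status * (1 + p * lt)) - p * sum(mu * lt)
    c(gb, gs)
  } else gb
}

# Central finite differences of the analytic gradient -> observed information
numeric_hessian <- function(theta, time, status, X, fix_shape = NULL) {
  k <- length(theta)
  H <- matrix(NA_real_, k, k)
  for (j in 1:k) {
    h <- 1e-5 * max(1, abs(theta[j]))
    tp <- tm <- theta
    tp[j] <- theta[j] + h
    tm[j] <- theta[j] - h
    H[, j] <- (single_cause_grad(tp, time, status, X, fix_shape) -
               single_cause_grad(tm, time, status, X, fix_shape)) / (2 * h)
  }
  (H + t(H)) / 2
}

# Maximum likelihood for one cause: events of that cause vs everything else
# censored. Optimizes (beta, log p) by BFGS with the analytic gradient;
# restarts from jittered starts if the scaled gradient does not vanish.
fit_single_cause <- function(time, status, X, fix_shape = NULL,
                             max_restarts = 4L, grad_tol = 1e-5) {
  q <- ncol(X)
  d <- sum(status)
  out <- list(n = length(time), n_events = as.integer(d),
              design = colnames(X), fixed_shape = fix_shape)

  if (d == 0) {
    out$estimable <- FALSE
    out$converged <- FALSE
    out$divergent <- FALSE
    out$beta <- rep(NA_real_, q)
    out$shape <- NA_real_
    class(out) <- "cause_fit"
    return(out)
  }

  # start: intercept at the closed-form exponential MLE, rest at 0
  start <- c(log(d / sum(time)), rep(0, q - 1))
  if (is.null(fix_shape)) start <- c(start, 0)

  nll <- function(th) {
    v <- single_cause_loglik(th, time, status, X, fix_shape)
    if (!is.finite(v)) 1e10 else -v
  }
  ngr <- function(th) {
    g <- single_cause_grad(th, time, status, X, fix_shape)
    g[!is.finite(g)] <- 0
    -g
  }

  best <- NULL
  restarts <- 0L
  th0 <- start
  repeat {
    opt <- stats::optim(th0, nll, ngr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    g <- single_cause_grad(opt$par, time, status, X, fix_shape)
    scaled <- max(abs(g)) / (1 + abs(opt$value))
    ok <- is.finite(scaled) && scaled < grad_tol
    if (is.null(best) || opt$value < best$opt$value)
      best <- list(opt = opt, scaled_grad = scaled, ok = ok)
    if (best$ok || restarts >= max_restarts) break
    restarts <- restarts + 1L
    th0 <- start + stats::rnorm(length(start), 0, 0.25 * restarts)
  }

  theta <- best$opt$par
  H <- numeric_hessian(theta, time, status, X, fix_shape)
  vcov <- tryCatch(solve(-H), error = function(e) NULL)
  se <- if (!is.null(vcov) && all(diag(vcov) > 0)) sqrt(diag(vcov))
        else rep(NA_real_, length(theta))
  if (is.null(vcov)) vcov <- matrix(NA_real_, length(theta), length(theta))

  beta <- theta[1:q]
  names(beta) <- colnames(X)
  pn <- c(colnames(X), if (is.null(fix_shape)) "log_shape")
  dimnames(vcov) <- list(pn, pn)
  names(se) <- pn

  out$estimable <- TRUE
  out$beta <- beta
  out$shape <- if (is.null(fix_shape)) exp(theta[q + 1]) else fix_shape
  out$vcov <- vcov
  out$se <- se
  out$loglik <- -best$opt$value
  out$converged <- best$ok
  out$scaled_grad <- best$scaled_grad
  out$iterations <- best$opt$counts[["function"]]
  out$restarts <- restarts
  # monotone-likelihood / separation flag, e.g. a covariate level with no
  # events drives its coefficient to -infinity with an enormous SE
  out$divergent <- any(abs(beta[-1]) > 10) ||
    any(se[seq_len(q)][-1] > 20, na.rm = TRUE)
  class(out) <- "cause_fit"
  out
}

#' Fit the competing-risks Weibull model
#'
#' Maximizes the cause-specific likelihood. Because the likelihood is
#' additively separable across causes, each cause j is fitted as its own
#' Weibull regression in which failures from other causes are treated as
#' censored; the joint log-likelihood is the sum over causes. A cause with
#' zero observed events is flagged non-estimable and the other causes are
#' unaffected.
#'
#' @param data a [cohort()].
#' @param covariates covariate set for [encode_design()].
#' @param fix_shape optional numeric: fix every cause's shape p_j at this
#'   value instead of estimating it (e.g. 1 for the exponential model).
#' @return object of class `"cr_weibull"`: a list with per-cause
#'   `"cause_fit"` elements in `$fits`, the summed `$loglik`, and metadata.
#' @export
fit_competing <- function(data, covariates = c("bmi", "age", "sex", "stage"),
                          fix_shape = NULL) {
  if (!nrow(data)) stop("empty dataset")
  if (any(data$time <= 0)) stop("all times must be strictly positive")
  X <- encode_design(data, covariates)
  check_full_rank(X)
  K <- n_causes(data)
  fits <- vector("list", K)
  for (j in 1:K) {
    fits[[j]] <- fit_single_cause(data$time, as.numeric(data$event == j), X,
                                  fix_shape = fix_shape)
    fits[[j]]$cause <- j
  }
  structure(list(fits = fits, n_causes = K,
                 loglik = sum(vapply(fits, function(f)
                   if (f$estimable) f$loglik else 0, numeric(1))),
                 covariates = covariates, design = colnames(X),
                 n = nrow(data)),
            class = "cr_weibull")
}

#' Naive single-event Weibull fit ignoring competing risks
#'
#' The comparator analysis that does not model competing events: a single
#' Weibull regression in which either only cause-1 failures count as
#' events (competing deaths censored, the standard "ignore competing
#' risks" analysis) or any death counts as the event.
#'
#' @param data a [cohort()].
#' @param covariates covariate set for [encode_design()].
#' @param event_definition `"cause1"` or `"any-death"`.
#' @param fix_shape optional fixed shape, as in [fit_competing()].
#' @return a `"cause_fit"` with an `event_definition` field. Fits whose
#'   likelihood diverges (e.g. a category with no events) carry
#'   `divergent = TRUE`.
#' @export
fit_naive <- function(data, covariates = c("bmi", "age", "sex", "stage"),
                      event_definition = c("cause1", "any-death"),
                      fix_shape = NULL) {
  event_definition <- match.arg(event_definition)
  if (!nrow(data)) stop("empty dataset")
  if (any(data$time <= 0)) stop("all times must be strictly positive")
  X <- encode_design(data, covariates)
  check_full_rank(X)
  status <- if (event_definition == "cause1") as.numeric(data$event == 1)
            else as.numeric(data$event > 0)
  fit <- fit_single_cause(data$time, status, X, fix_shape = fix_shape)
  fit$cause <- 1L
  fit$event_definition <- event_definition
  fit
}

check_full_rank <- function(X) {
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient; drop collinear covariates")
  invisible(TRUE)
}

#' Extract fitted model parameters
#'
#' Collects the per-cause estimates of a converged [fit_competing()] result
#' into a [model_params()] for curve evaluation.
#'
#' @param fit a `"cr_weibull"`.
#' @return a [model_params()].
#' @export
fitted_params <- function(fit) {
  stopifnot(inherits(fit, "cr_weibull"))
  est <- vapply(fit$fits, function(f) f$estimable, logical(1))
  if (!all(est)) stop("non-estimable cause(s): ",
                      paste(which(!est), collapse = ", "))
  model_params(lapply(fit$fits, function(f) unname(f$beta)),
               vapply(fit$fits, function(f) f$shape, numeric(1)))
}

#' Wald hazard ratio, confidence interval and p-value from (coef, SE)
#'
#' The inference chain applied to every coefficient: HR = exp(coef),
#' 95% CI = exp(coef +/- 1.959964 SE), two-sided p-value from coef/SE
#' against the standard normal. Exposed directly so printed
#' coefficient/SE pairs can be pushed through the same machinery.
#'
#' @param coef log hazard-ratio estimate.
#' @param se its standard error.
#' @param conf_level confidence level, default 0.95.
#' @return data frame with columns `coef`, `se`, `hr`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
hr_from_estimate <- function(coef, se, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(coef = coef, se = se, hr = exp(coef),
             ci_low = exp(coef - z * se), ci_high = exp(coef + z * se),
             p_value = 2 * stats::pnorm(-abs(coef / se)))
}

#' Hazard ratio for one covariate of a fitted cause
#'
#' @param fit a `"cause_fit"` (one element of a [fit_competing()] result,
#'   or a [fit_naive()] result).
#' @param covariate design column name, e.g. `"stage_IV"`.
#' @param conf_level confidence level, default 0.95.
#' @return one-row data frame from [hr_from_estimate()].
#' @export
hazard_ratio <- function(fit, covariate, conf_level = 0.95) {
  stopifnot(inherits(fit, "cause_fit"))
  if (!fit$estimable) stop("fit is non-estimable (no events)")
  if (!covariate %in% names(fit$beta))
    stop("unknown covariate: ", covariate, "; design has: ",
         paste(names(fit$beta), collapse = ", "))
  out <- hr_from_estimate(unname(fit$beta[covariate]),
                          unname(fit$se[covariate]), conf_level)
  out$covariate <- covariate
  out[, c("covariate", "coef", "se", "hr", "ci_low", "ci_high", "p_value")]
}

#' Hazard-ratio table for all covariates of a fitted cause
#'
#' @inheritParams hazard_ratio
#' @return data frame with one row per non-intercept covariate.
#' @export
hr_table <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "cause_fit"))
  covs <- setdiff(names(fit$beta), "intercept")
  do.call(rbind, lapply(covs, hazard_ratio, fit = fit,
                        conf_level = conf_level))
}

#' @export
print.cause_fit <- function(x, ...) {
  lbl <- if (!is.null(x$event_definition))
    paste0("naive Weibull fit (", x$event_definition, ")")
  else paste0("cause-", x$cause, " Weibull fit")
  cat(lbl, ": ", x$n_events, " events / ", x$n, " subjects\n", sep = "")
  if (!x$estimable) {
    cat("  non-estimable: no events of this cause\n")
    return(invisible(x))
  }
  cat(sprintf("  loglik %.4f, shape %.4f, converged: %s%s\n",
              x$loglik, x$shape, x$converged,
              if (isTRUE(x$divergent)) " [DIVERGENT]" else ""))
  tab <- cbind(coef = x$beta, se = x$se[seq_along(x$beta)])
  print(round(tab, 4))
  invisible(x)
}

#' @export
print.cr_weibull <- function(x, ...) {
  cat("Competing-risks Weibull model:", x$n_causes, "causes,",
      x$n, "subjects, joint loglik", sprintf("%.4f", x$loglik), "\n")
  for (f in x$fits) print(f)
  invisible(x)
}
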