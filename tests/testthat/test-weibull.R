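test_that("hazard and survival evaluate their closed forms", {
  x0 <- c(1, rep(0, 6))
  unit <- model_params(list(rep(0, 7)), 1)
  expect_equal(cause_specific_hazard(c(0.5, 1, 7), x0, 1, unit),
               c(1, 1, 1))
  # lambda = 1, p = 2: h(3) = 1 * 2 * 3
  par2 <- model_params(list(rep(0, 7)), 2)
  expect_equal(cause_specific_hazard(3, x0, 1, par2), 6)
  expect_error(cause_specific_hazard(0, x0, 1, unit), "positive")

  expect_equal(overall_survival(0, x0, random_params(2)), 1)
  expect_equal(overall_survival(1, x0, unit), exp(-1))
  two <- model_params(list(rep(0, 7), rep(0, 7)), c(1, 1))
  expect_equal(overall_survival(1, x0, two), exp(-2))
  expect_equal(overall_survival(1, x0, two),
               cause_specific_survival(1, x0, 1, two) *
                 cause_specific_survival(1, x0, 2, two))
})

test_that("hazard equals minus the derivative of log survival", {
  set.seed(77)
  for (i in 1:100) {
    params <- random_params(sample(1:3, 1))
    j <- sample(params$n_causes, 1)
    x <- c(1, runif(1, 18, 32), runif(1, 30, 80), rbinom(4, 1, 0.3))
    t <- runif(1, 0.5, 90)
    h <- cause_specific_hazard(t, x, j, params)
    eps <- 1e-5 * t
    fd <- -(log(cause_specific_survival(t + eps, x, j, params)) -
              log(cause_specific_survival(t - eps, x, j, params))) /
      (2 * eps)
    expect_equal(fd, h, tolerance = 1e-6)
  }
})

test_that("log-likelihood matches hand-computed values", {
  # one censored subject, single cause, lambda = 1, p = 1, t = 2: ell = -2
  d <- cohort(time = 2, event = 0L, sex = "man", age = 50, bmi = 24,
              stage = "I", n_causes = 1)
  expect_equal(log_likelihood(d, model_params(list(rep(0, 7)), 1)), -2)
  # one cause-1 event at t = 1, two unit-exponential causes:
  # log h1(1) - 2 * 1 = 0 - 2
  d <- cohort(time = 1, event = 1L, sex = "man", age = 50, bmi = 24,
              stage = "I", n_causes = 2)
  expect_equal(
    log_likelihood(d, model_params(list(rep(0, 7), rep(0, 7)), c(1, 1))),
    -2)
  expect_error(log_likelihood(tiny_cohort(),
                              model_params(list(1, 1), c(1, 1))),
               "width")
})

test_that("the joint likelihood separates into per-cause censored fits", {
  set.seed(12)
  for (i in 1:20) {
    d <- random_cohort(n = 60, seed = 1000 + i)
    params <- random_params(2)
    parts <- vapply(1:2, function(j) {
      log_likelihood(recode_single_cause(d, j),
                     model_params(params$betas[j], params$shapes[j]))
    }, numeric(1))
    expect_equal(log_likelihood(d, params), sum(parts), tolerance = 1e-12)
  }
})

test_that("analytic gradient matches central finite differences", {
  set.seed(31)
  d <- random_cohort(n = 120, seed = 4)
  X <- encode_design(d)
  status <- as.numeric(d$event == 1)
  for (i in 1:20) {
    theta <- c(runif(1, -6, -4), runif(6, -0.3, 0.3), runif(1, -0.3, 0.3))
    theta[2] <- runif(1, -0.05, 0.05)  # bmi scale
    theta[3] <- runif(1, -0.02, 0.02)  # age scale
    g <- unname(crweibull:::single_cause_grad(theta, d$time, status, X))
    fd <- vapply(seq_along(theta), function(k) {
      h <- 1e-6 * max(1, abs(theta[k]))
      tp <- tm <- theta; tp[k] <- theta[k] + h; tm[k] <- theta[k] - h
      (crweibull:::single_cause_loglik(tp, d$time, status, X) -
         crweibull:::single_cause_loglik(tm, d$time, status, X)) / (2 * h)
    }, numeric(1))
    expect_equal(fd, g, tolerance = 1e-6)
  }
})

test_that("intercept-only MLE recovers simulated truth within 3 SEs", {
  lam <- 0.05; p <- 1.2
  cfg <- generator_config(
    n = 5000, seed = 6,
    betas = list(c(log(lam), 0, 0, 0, 0, 0, 0)), shapes = p,
    censoring = list(type = "uniform", max = 132))
  d <- generate_cohort(cfg)
  fit <- fit_competing(d, covariates = character(0))$fits[[1]]
  expect_true(fit$converged)
  expect_lt(abs(fit$beta[["intercept"]] - log(lam)),
            3 * fit$se[["intercept"]])
  expect_lt(abs(log(fit$shape) - log(p)), 3 * fit$se[["log_shape"]])
})

test_that("MLE agrees with flexsurv's Weibull PH regression", {
  library(flexsurv)
  d <- random_cohort(n = 600, seed = 3)
  ours <- fit_competing(d)$fits[[1]]
  df <- as.data.frame(d)
  df$status1 <- as.numeric(df$event == 1)
  df$woman <- as.numeric(df$sex == "woman")
  df$stII <- as.numeric(df$stage == "II")
  df$stIII <- as.numeric(df$stage == "III")
  df$stIV <- as.numeric(df$stage == "IV")
  fs <- flexsurvreg(
    survival::Surv(time, status1) ~ bmi + age + woman + stII + stIII + stIV,
    data = df, dist = "weibullPH")
  expect_equal(ours$shape, fs$res["shape", "est"], tolerance = 1e-5)
  expect_equal(ours$beta[["intercept"]], log(fs$res["scale", "est"]),
               tolerance = 1e-5)
  expect_equal(unname(ours$beta[-1]),
               unname(fs$res[c("bmi", "age", "woman", "stII", "stIII",
                               "stIV"), "est"]),
               tolerance = 1e-5)
  expect_equal(unname(ours$se[2:7]),
               unname(fs$res[c("bmi", "age", "woman", "stII", "stIII",
                               "stIV"), "se"]),
               tolerance = 1e-4)
})

test_that("a cause with zero events is flagged and others are unaffected", {
  d <- random_cohort(n = 150, seed = 14)
  d1 <- cohort(time = d$time, event = ifelse(d$event == 2L, 0L, d$event),
               sex = d$sex, age = d$age, bmi = d$bmi, stage = d$stage,
               n_causes = 2)
  fit <- fit_competing(d1)
  expect_false(fit$fits[[2]]$estimable)
  expect_true(fit$fits[[1]]$estimable)
  # cause-1 fit identical to the naive cause-1 fit on the same records
  naive <- fit_naive(d1)
  expect_equal(fit$fits[[1]]$beta, naive$beta, tolerance = 1e-6)
  expect_equal(fit$fits[[1]]$shape, naive$shape, tolerance = 1e-6)
})

test_that("competing cause-1 fit equals the naive censored-recode fit", {
  d <- random_cohort(n = 200, seed = 23)
  comp <- fit_competing(d)$fits[[1]]
  naive <- fit_naive(d, event_definition = "cause1")
  expect_equal(comp$beta, naive$beta, tolerance = 1e-6)
  expect_equal(comp$shape, naive$shape, tolerance = 1e-6)
  expect_equal(comp$loglik, naive$loglik, tolerance = 1e-9)
})

test_that("the any-death definition counts every death as an event", {
  d <- random_cohort(n = 200, seed = 29)
  naive <- fit_naive(d, event_definition = "any-death")
  expect_equal(naive$n_events, sum(d$event > 0))
  expect_true(naive$converged)
})

test_that("with shape fixed at 1 the intercept-only fit is the exponential MLE", {
  d <- random_cohort(n = 400, seed = 37)
  fit <- fit_competing(d, covariates = character(0),
                       fix_shape = 1)$fits[[1]]
  closed_form <- sum(d$event == 1) / sum(d$time)
  expect_equal(exp(fit$beta[["intercept"]]), closed_form,
               tolerance = 1e-6)
})

test_that("rescaling time shifts only the intercept, by -p log c", {
  d <- random_cohort(n = 300, seed = 41)
  f1 <- fit_competing(d)$fits[[1]]
  cc <- 12  # months -> years
  d2 <- cohort(time = d$time / cc, event = d$event, sex = d$sex,
               age = d$age, bmi = d$bmi, stage = d$stage, n_causes = 2)
  f2 <- fit_competing(d2)$fits[[1]]
  expect_equal(f2$shape, f1$shape, tolerance = 1e-4)
  expect_equal(unname(f2$beta[-1]), unname(f1$beta[-1]), tolerance = 1e-4)
  # lambda -> lambda * c^p when t -> t / c
  expect_equal(f2$beta[["intercept"]],
               f1$beta[["intercept"]] + f1$shape * log(cc),
               tolerance = 1e-3)
})

test_that("monotone-likelihood divergence is detected and flagged", {
  # stage II subjects never die: the stage II coefficient runs to -Inf
  set.seed(55)
  n <- 120
  stage <- rep(c("I", "II", "III", "IV"), each = n / 4)
  time <- rexp(n, 0.05)
  event <- rep(1L, n)
  ii <- stage == "II"
  time[ii] <- 100
  event[ii] <- 0L
  d <- cohort(time = time, event = event, sex = rep("man", n),
              age = rep(50, n), bmi = rep(24, n), stage = stage,
              n_causes = 1)
  fit <- fit_naive(d, covariates = "stage")
  expect_true(fit$divergent)
})

test_that("rank-deficient designs are rejected", {
  d <- cohort(time = c(2, 3, 4, 9), event = c(1L, 0L, 1L, 0L),
              sex = rep("man", 4), age = rep(50, 4), bmi = rep(24, 4),
              stage = rep("I", 4))
  expect_error(fit_competing(d), "rank deficient")
})

test_that("Wald machinery: HR, CI and p-value from coefficient and SE", {
  r <- hr_from_estimate(0, 0.2)
  expect_equal(r$hr, 1)
  expect_equal(r$p_value, 1)
  # CI symmetric about 1 on the log scale
  expect_equal(log(r$ci_high), -log(r$ci_low))
  r <- hr_from_estimate(1.507, 0.224)
  expect_equal(r$hr, 4.511, tolerance = 0.01)
  expect_equal(r$ci_low, 2.911, tolerance = 0.01)
  expect_equal(r$ci_high, 6.992, tolerance = 0.01)
})

test_that("hazard_ratio extracts covariate rows from a fit", {
  d <- random_cohort(n = 300, seed = 61)
  fit <- fit_competing(d)$fits[[1]]
  hr <- hazard_ratio(fit, "stage_IV")
  expect_equal(hr$hr, exp(fit$beta[["stage_IV"]]))
  expect_equal(hr$ci_low,
               exp(fit$beta[["stage_IV"]] -
                     stats::qnorm(0.975) * fit$se[["stage_IV"]]))
  expect_error(hazard_ratio(fit, "tumour_grade"), "unknown covariate")
  tab <- hr_table(fit)
  expect_equal(nrow(tab), 6)
  expect_false("intercept" %in% tab$covariate)
})

test_that("coefficient estimates recover the generating truth (n = 5000)", {
  tr <- recovery_truth()
  cfg <- generator_config(n = 5000, seed = 71, betas = tr$betas,
                          shapes = tr$shapes)
  fit <- fit_competing(generate_cohort(cfg))
  for (j in 1:2) {
    f <- fit$fits[[j]]
    expect_true(f$converged)
    th <- c(f$beta, log(f$shape))
    truth <- c(tr$betas[[j]], log(tr$shapes[j]))
    expect_true(all(abs(th - truth) < 3.5 * f$se))
  }
})
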