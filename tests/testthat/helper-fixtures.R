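# Small fixtures built in code.

tiny_cohort <- function() {
  cohort(time = c(5, 10, 20), event = c(1L, 2L, 0L),
         sex = c("man", "woman", "man"), age = c(50, 60, 70),
         bmi = c(24, 22, 28), stage = c("I", "II", "IV"))
}

# a random cohort from the generator, small by default
random_cohort <- function(n = 80, seed = 1, ...) {
  generate_cohort(generator_config(n = n, seed = seed, ...))
}

# random but valid model parameters for K causes on the full 7-wide design
random_params <- function(K = 2) {
  model_params(
    betas = lapply(seq_len(K), function(j)
      c(stats::runif(1, -6, -4), stats::runif(1, -0.05, 0.05),
        stats::runif(1, -0.02, 0.02), stats::runif(4, -0.5, 0.5))),
    shapes = stats::runif(K, 0.7, 1.6))
}

# recode a K-cause cohort as single-cause: cause j kept, others censored
recode_single_cause <- function(data, j) {
  cohort(time = data$time, event = as.integer(data$event == j),
         sex = data$sex, age = data$age, bmi = data$bmi,
         stage = data$stage, n_causes = 1L)
}

# truth used by the recovery simulation study: moderate effects on every
# covariate so relative bias is well defined, stage-IV log-HR 1.5
recovery_truth <- function() {
  list(betas = list(c(-4.6, -0.08, 0.03, -0.5, 0.7, 1.0, 1.5),
                    c(-3.9, -0.06, 0.02, -0.4, 0.6, 0.9, 1.2)),
       shapes = c(1.2, 0.9))
}
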