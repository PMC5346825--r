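#' Render a fitted model as a publication-style table
#'
#' One row per covariate with "Coefficient (SE)", HR, "(low-high)" 95% CI
#' and P value, grouped by cause, with reference rows (man, stage I)
#' rendered with HR 1 and a blank coefficient -- the layout of a typical
#' prognostic-factors table. Numbers are rounded to 3 decimals for
#' display; use [fit_to_json()] to keep full precision.
#'
#' @param fit a `"cr_weibull"` from [fit_competing()] or a `"cause_fit"`
#'   from [fit_naive()].
#' @param cause_labels labels per cause; defaults to
#'   "Death from colorectal cancer" / "Death from other causes" for K = 2,
#'   generic "Cause j" otherwise.
#' @param digits display digits, default 3.
#' @return data frame with character columns `event`, `covariate`,
#'   `coefficient_se`, `hr`, `ci95`, `p_value`.
#' @export
render_fit_table <- function(fit, cause_labels = NULL, digits = 3) {
  fits <- if (inherits(fit, "cr_weibull")) fit$fits else list(fit)
  K <- length(fits)
  if (is.null(cause_labels)) {
    cause_labels <- if (K == 2 && inherits(fit, "cr_weibull"))
      c("Death from colorectal cancer", "Death from other causes")
    else if (!is.null(fits[[1]]$event_definition))
      paste0("Naive (", fits[[1]]$event_definition, ")")
    else paste("Cause", seq_len(K))
  }
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  blocks <- list()
  for (k in seq_len(K)) {
    f <- fits[[k]]
    if (!f$estimable) {
      blocks[[k]] <- data.frame(event = cause_labels[k],
                                covariate = "(non-estimable)",
                                coefficient_se = "", hr = "", ci95 = "",
                                p_value = "")
      next
    }
    tab <- hr_table(f)
    ref_rows <- function(covariate) data.frame(
      event = "", covariate = covariate, coefficient_se = "", hr = "1",
      ci95 = "", p_value = "")
    rows <- list()
    for (i in seq_len(nrow(tab))) {
      cv <- tab$covariate[i]
      if (cv == "sex_woman") rows[[length(rows) + 1]] <- ref_rows("Man")
      if (cv == "stage_II") rows[[length(rows) + 1]] <- ref_rows("Stage I")
      rows[[length(rows) + 1]] <- data.frame(
        event = "",
        covariate = pretty_covariate(cv),
        coefficient_se = paste0(fmt(tab$coef[i]), "(", fmt(tab$se[i]), ")"),
        hr = fmt(tab$hr[i]),
        ci95 = paste0("(", fmt(tab$ci_low[i]), "-", fmt(tab$ci_high[i]), ")"),
        p_value = ifelse(tab$p_value[i] < 10^-digits,
                         paste0("<", format(10^-digits)),
                         fmt(tab$p_value[i])))
    }
    block <- do.call(rbind, rows)
    block$event[1] <- cause_labels[k]
    blocks[[k]] <- block
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

pretty_covariate <- function(x) {
  switch(x,
         bmi = "BMI (kg/m2)", age = "Age at diagnosis",
         sex_woman = "Woman", stage_II = "Stage II",
         stage_III = "Stage III", stage_IV = "Stage IV", x)
}

#' Write a rendered fit table as TSV
#'
#' @param table output of [render_fit_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a TSV written by [write_fit_tsv()]
#'
#' @param path TSV path.
#' @return data frame with the same character columns.
#' @export
read_fit_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8",
                    na.strings = NULL)
}

#' Serialize a fit to JSON at full precision
#'
#' Stores per-cause estimates, standard errors, the covariance matrix,
#' log-likelihood and convergence metadata.
#'
#' @param fit a `"cr_weibull"` or `"cause_fit"`.
#' @param path optional path; when given the JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
fit_to_json <- function(fit, path = NULL) {
  fits <- if (inherits(fit, "cr_weibull")) fit$fits else list(fit)
  payload <- lapply(fits, function(f) {
    if (!f$estimable)
      return(list(cause = f$cause, estimable = FALSE,
                  n = f$n, n_events = f$n_events))
    list(cause = f$cause, estimable = TRUE,
         event_definition = f$event_definition,
         beta = as.list(f$beta), shape = f$shape,
         se = as.list(f$se), vcov = f$vcov,
         loglik = f$loglik, converged = f$converged,
         divergent = f$divergent, iterations = unname(f$iterations),
         n = f$n, n_events = f$n_events)
  })
  js <- jsonlite::toJSON(list(model = class(fit)[1], causes = payload),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Write a cohort summary as TSV and JSON
#'
#' @param summary a `"cr_summary"` from [summarize_cohort()].
#' @param tsv_path,json_path optional output paths.
#' @return the summary, invisibly.
#' @export
write_summary <- function(summary, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    by <- rbind(cbind(partition = "sex", summary$by_sex),
                cbind(partition = "stage", summary$by_stage))
    by$percent <- round(by$percent, 1)
    utils::write.table(by, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
  }
  if (!is.null(json_path)) {
    writeLines(jsonlite::toJSON(unclass(summary), auto_unbox = TRUE,
                                digits = NA, pretty = TRUE,
                                dataframe = "rows"),
               json_path)
  }
  invisible(summary)
}
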