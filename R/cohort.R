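#' Subject-level survival cohort
#'
#' A cohort is a data frame with one row per subject carrying follow-up time
#' in months, an integer event code (0 = right-censored, `1..K` = cause of
#' death), and the prognostic covariates sex, age at diagnosis (years),
#' body-mass index (kg/m^2) and AJCC tumour stage (I-IV). The number of
#' competing causes `K` is stored as the `n_causes` attribute.
#'
#' @param time numeric vector of strictly positive follow-up times (months).
#' @param event integer vector of cause codes in `0..n_causes`.
#' @param sex character or factor with levels `"man"`, `"woman"`.
#' @param age numeric, age at diagnosis in years.
#' @param bmi numeric, strictly positive body-mass index (kg/m^2).
#' @param stage character or factor with levels `"I".."IV"`.
#' @param n_causes number of competing causes `K`; defaults to the largest
#'   event code observed (at least 1).
#' @return A data frame of class `"cr_cohort"` with attribute `n_causes`.
#' @export
cohort <- function(time, event, sex, age, bmi, stage, n_causes = NULL) {
  n <- length(time)
  stopifnot(n >= 1)
  lens <- c(length(event), length(sex), length(age), length(bmi), length(stage))
  if (any(lens != n)) stop("all columns must have the same length")

  time <- as.numeric(time)
  event <- as.integer(event)
  age <- as.numeric(age)
  bmi <- as.numeric(bmi)
  sex <- factor(as.character(sex), levels = sex_levels())
  stage <- factor(as.character(stage), levels = stage_levels(), ordered = TRUE)

  bad <- which(!is.finite(time) | time <= 0)
  if (length(bad)) stop("nonpositive or non-finite time in row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(is.na(event) | event < 0)
  if (length(bad)) stop("invalid event code in row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(is.na(sex))
  if (length(bad)) stop("unknown sex label in row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(is.na(stage))
  if (length(bad)) stop("unknown stage label in row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.finite(age))
  if (length(bad)) stop("missing age in row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.finite(bmi) | bmi <= 0)
  if (length(bad)) stop("nonpositive or missing bmi in row(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))

  if (is.null(n_causes)) n_causes <- max(1L, max(event))
  n_causes <- as.integer(n_causes)
  if (n_causes < 1L) stop("n_causes must be >= 1")
  if (any(event > n_causes))
    stop("event code exceeds n_causes = ", n_causes)

  out <- data.frame(time = time, event = event, sex = sex, age = age,
                    bmi = bmi, stage = stage)
  attr(out, "n_causes") <- n_causes
  class(out) <- c("cr_cohort", "data.frame")
  out
}

sex_levels <- function() c("man", "woman")
stage_levels <- function() c("I", "II", "III", "IV")

#' Number of competing causes in a cohort
#' @param data a `cr_cohort`.
#' @return integer `K`.
#' @export
n_causes <- function(data) {
  k <- attr(data, "n_causes")
  if (is.null(k)) max(1L, max(data$event)) else k
}

#' Read a cohort from a delimited text file
#'
#' Expects a header row. Columns may be renamed through `column_map`, a
#' named character vector mapping the canonical roles (`time`, `event`,
#' `sex`, `age`, `bmi`, `stage`) to the names used in the file.
#'
#' @param path path to the CSV file.
#' @param column_map named character vector role -> file column name;
#'   `NULL` means the file already uses the canonical names.
#' @param delim field delimiter, default `","`.
#' @param n_causes override for `K` (default: inferred as the maximum
#'   event code).
#' @return a [cohort()].
#' @export
read_cohort <- function(path, column_map = NULL, delim = ",", n_causes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           fileEncoding = "UTF-8")
  if (nrow(raw) == 0) stop("empty dataset: ", path)
  roles <- c("time", "event", "sex", "age", "bmi", "stage")
  cols <- stats::setNames(roles, roles)
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || !all(names(column_map) %in% roles))
      stop("column_map names must be among: ", paste(roles, collapse = ", "))
    cols[names(column_map)] <- column_map
  }
  missing <- cols[!cols %in% names(raw)]
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))

  ev_raw <- raw[[cols["event"]]]
  ev_num <- suppressWarnings(as.numeric(ev_raw))
  bad <- which(is.na(ev_num) | ev_num != round(ev_num))
  if (length(bad))
    stop("non-integer event code in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))

  cohort(time = raw[[cols["time"]]], event = as.integer(ev_num),
         sex = raw[[cols["sex"]]], age = raw[[cols["age"]]],
         bmi = raw[[cols["bmi"]]], stage = raw[[cols["stage"]]],
         n_causes = n_causes)
}

#' Write a cohort to a delimited text file
#'
#' Inverse of [read_cohort()]: writes canonical column names so that a
#' read/write/read round trip reproduces the records exactly (up to numeric
#' printing precision, 15 significant digits).
#'
#' @param data a `cr_cohort`.
#' @param path output path.
#' @param delim field delimiter, default `","`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, delim = ",") {
  df <- as.data.frame(data)
  df$time <- format(df$time, digits = 15, trim = TRUE, scientific = FALSE)
  df$age <- format(df$age, digits = 15, trim = TRUE, scientific = FALSE)
  df$bmi <- format(df$bmi, digits = 15, trim = TRUE, scientific = FALSE)
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Design-matrix encoding of the covariates
#'
#' Encodes sex, age, BMI and stage as the regression design used by the
#' cause-specific scale link: an intercept, untransformed BMI and age, a
#' woman indicator and stage II/III/IV indicators. Reference subject: man,
#' stage I. Age and BMI enter on their natural scales so fitted
#' coefficients are per-year and per-kg/m^2 log hazard ratios.
#'
#' @param data a `cr_cohort` (or any data frame with columns `sex`, `age`,
#'   `bmi`, `stage`).
#' @param covariates which covariates to include; subset of
#'   `c("bmi", "age", "sex", "stage")`. `character(0)` gives an
#'   intercept-only design.
#' @return numeric matrix with one row per subject; first column is the
#'   intercept.
#' @export
encode_design <- function(data, covariates = c("bmi", "age", "sex", "stage")) {
  stopifnot(all(covariates %in% c("bmi", "age", "sex", "stage")))
  n <- nrow(data)
  out <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if ("bmi" %in% covariates)
    out <- cbind(out, bmi = as.numeric(data$bmi))
  if ("age" %in% covariates)
    out <- cbind(out, age = as.numeric(data$age))
  if ("sex" %in% covariates)
    out <- cbind(out, sex_woman = as.numeric(data$sex == "woman"))
  if ("stage" %in% covariates) {
    st <- as.character(data$stage)
    out <- cbind(out,
                 stage_II = as.numeric(st == "II"),
                 stage_III = as.numeric(st == "III"),
                 stage_IV = as.numeric(st == "IV"))
  }
  out
}

#' Descriptive cohort summary
#'
#' Tabulates the cohort the way registry studies report baseline tables:
#' counts and percentages by sex and stage with cause-specific death counts
#' within each category, overall event-mix percentages, mean/sd of age and
#' BMI, and mean/sd/median/quartiles of the observed follow-up time. The
#' follow-up mean is the naive mean of observed (possibly censored) times.
#'
#' @param data a `cr_cohort`.
#' @return a list of class `"cr_summary"` with elements `n`, `events`
#'   (count and percentage per cause plus censored), `by_sex` and
#'   `by_stage` (count, percentage, per-cause death counts, mean and se of
#'   observed time), `age`, `bmi` and `time` summaries.
#' @export
summarize_cohort <- function(data) {
  if (!nrow(data)) stop("empty dataset")
  n <- nrow(data)
  K <- n_causes(data)

  ev_count <- vapply(0:K, function(j) sum(data$event == j), integer(1))
  names(ev_count) <- c("censored", paste0("cause", 1:K))
  events <- data.frame(group = names(ev_count), count = as.integer(ev_count),
                       percent = 100 * as.integer(ev_count) / n)

  by_cat <- function(f) {
    lv <- levels(f)
    do.call(rbind, lapply(lv, function(l) {
      idx <- f == l
      row <- data.frame(level = l, count = sum(idx),
                        percent = 100 * sum(idx) / n)
      for (j in 1:K)
        row[[paste0("deaths_cause", j)]] <- sum(data$event[idx] == j)
      row$mean_time <- mean(data$time[idx])
      row$se_time <- stats::sd(data$time[idx]) / sqrt(sum(idx))
      row
    }))
  }

  qs <- stats::quantile(data$time, c(0.25, 0.5, 0.75), names = FALSE)
  out <- list(
    n = n, n_causes = K, events = events,
    by_sex = by_cat(data$sex), by_stage = by_cat(data$stage),
    age = c(mean = mean(data$age), sd = stats::sd(data$age)),
    bmi = c(mean = mean(data$bmi), sd = stats::sd(data$bmi)),
    time = c(mean = mean(data$time), sd = stats::sd(data$time),
             q25 = qs[1], median = qs[2], q75 = qs[3])
  )
  class(out) <- "cr_summary"
  out
}

#' @export
print.cr_summary <- function(x, ...) {
  cat("Cohort of", x$n, "subjects,", x$n_causes, "competing cause(s)\n")
  ev <- x$events
  for (i in seq_len(nrow(ev)))
    cat(sprintf("  %-10s %4d (%.1f%%)\n", ev$group[i], ev$count[i],
                ev$percent[i]))
  cat(sprintf("  age  mean %.2f sd %.2f\n", x$age["mean"], x$age["sd"]))
  cat(sprintf("  bmi  mean %.2f sd %.2f\n", x$bmi["mean"], x$bmi["sd"]))
  cat(sprintf("  time mean %.2f sd %.2f median %.1f (P25 %.1f, P75 %.1f)\n",
              x$time["mean"], x$time["sd"], x$time["median"],
              x$time["q25"], x$time["q75"]))
  invisible(x)
}
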