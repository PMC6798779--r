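#' Read life tables from CSV
#'
#' Expects a UTF-8, comma-separated file with header columns `age`, `sex`,
#' `deaths_per_1000`. A file may hold one or both sexes.
#'
#' @param path CSV path.
#' @param sex optional: return only this sex's table.
#' @return A single [life_table()] when the file holds one sex (or `sex`
#'   is given), otherwise a named list of life tables.
#' @export
read_life_table <- function(path, sex = NULL) {
  df <- read_checked_csv(path, c("age", "sex", "deaths_per_1000"))
  bad <- which(is.na(df$age) | is.na(df$deaths_per_1000) |
                 df$deaths_per_1000 < 0 | df$deaths_per_1000 > 1000)
  if (length(bad) > 0L) {
    stop("invalid life-table row at line ", bad[1L] + 1L, " of ", path,
         call. = FALSE)
  }
  tables <- lapply(split(df, df$sex), function(d) {
    life_table(d$age, d$deaths_per_1000, unique(d$sex))
  })
  if (!is.null(sex)) {
    if (!sex %in% names(tables)) {
      stop("no rows for sex ", sex, " in ", path, call. = FALSE)
    }
    return(tables[[sex]])
  }
  if (length(tables) == 1L) tables[[1L]] else tables
}

#' Write life tables to CSV
#'
#' @param lt a [life_table()] or named list of them.
#' @param path output CSV path.
#' @export
write_life_table <- function(lt, path) {
  if (inherits(lt, "life_table")) lt <- list(lt)
  df <- do.call(rbind, lapply(lt, function(t) {
    data.frame(age = t$age, sex = attr(t, "sex"),
               deaths_per_1000 = t$deaths_per_1000)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a patient cohort from CSV
#'
#' Expects columns `id`, `age`, `sex`, `arm`, `died_1yr`. The death flag
#' accepts `true`/`false` (any case) and `1`/`0`.
#'
#' @param path CSV path.
#' @param enrollment_days enrolment window, days.
#' @return A [cohort()].
#' @export
read_cohort <- function(path, enrollment_days) {
  df <- read_checked_csv(path, c("id", "age", "sex", "arm", "died_1yr"))
  df$died_1yr <- parse_bool(df$died_1yr, path)
  cohort(df, enrollment_days)
}

#' Write a cohort to CSV
#'
#' @param x a [cohort()].
#' @param path output CSV path.
#' @export
write_cohort <- function(x, path) {
  df <- as.data.frame(x)
  df$died_1yr <- tolower(as.character(df$died_1yr))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read binned employment and population CSVs into labour inputs
#'
#' The bins file has columns `age_lo`, `age_hi`, `employed_per_1000` and
#' optionally `sex`; the population file has `age`, `sex`, `population`.
#'
#' @param bins_path,population_path CSV paths.
#' @param total_labour_force scalar or named per-sex counts.
#' @param lfpr_per_1000 optional overall LFPR metadata.
#' @return A [labor_inputs()] object.
#' @export
read_labor_inputs <- function(bins_path, population_path, total_labour_force,
                              lfpr_per_1000 = NULL) {
  bins <- read_checked_csv(bins_path, c("age_lo", "age_hi", "employed_per_1000"))
  pop <- read_checked_csv(population_path, c("age", "sex", "population"))
  labor_inputs(bins, pop, total_labour_force, lfpr_per_1000)
}

#' Load a run configuration (YAML or JSON)
#'
#' Parses the economic parameters, macro inputs, cost breakdown, labour
#' scalars and optional sensitivity-grid axes from one file. Format is
#' chosen by extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param path config file path.
#' @return A list of class `"run_config"` with elements `params`
#'   ([economic_params()]), `macro` ([macro_inputs()] or `NULL`), `cost`
#'   ([cost_breakdown()] or `NULL`), `enrollment_days`,
#'   `total_labour_force`, `lfpr_per_1000`, `growth_rates`,
#'   `discount_rates`, `annualized_n`, `exchange_rate`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pget <- function(block, key, default) {
    v <- raw[[block]][[key]]
    if (is.null(v)) default else v
  }
  le_default <- c(female = 72.7, male = 68.6)
  le <- raw$params$life_expectancy
  le <- if (is.null(le)) le_default else unlist(le)[c("female", "male")]
  params <- economic_params(
    income_now = pget("params", "income_now", NA_real_),
    growth_rate = pget("params", "growth_rate", 0.03),
    discount_rate = pget("params", "discount_rate", 0.06),
    retirement_age = pget("params", "retirement_age", 70L),
    life_expectancy = le,
    days_per_year = pget("params", "days_per_year", 365.25))
  macro <- NULL
  if (!is.null(raw$macro)) {
    macro <- macro_inputs(raw$macro$gdp, raw$macro$labour_share,
                          raw$macro$employed_workers)
  }
  cost <- NULL
  if (!is.null(raw$cost)) {
    cost <- cost_breakdown(unlist(raw$cost$setting_up),
                           unlist(raw$cost$implementing),
                           unlist(raw$cost$monitoring),
                           raw$cost$period_days)
  }
  tlf <- raw$total_labour_force
  if (is.list(tlf)) tlf <- unlist(tlf)
  structure(list(
    params = params, macro = macro, cost = cost,
    enrollment_days = raw$enrollment_days,
    total_labour_force = tlf,
    lfpr_per_1000 = raw$lfpr_per_1000,
    growth_rates = raw$growth_rates,
    discount_rates = raw$discount_rates,
    annualized_n = raw$annualized_n,
    exchange_rate = if (is.null(raw$exchange_rate)) 58.51 else raw$exchange_rate
  ), class = "run_config")
}

#' Render an evaluation report
#'
#' `"json"` produces a schema-stable machine-readable document (undefined
#' metrics appear as `null`); `"markdown"` produces headline and
#' sensitivity tables for human readers, with undefined metrics shown as
#' `n/a`, never as 0.
#'
#' @param report an [evaluate_cohort()] result.
#' @param format `"json"` or `"markdown"`.
#' @return A character scalar (the document).
#' @export
render_report <- function(report, format = c("json", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "evaluation_report"))
  if (format == "json") {
    x <- unclass(report)
    x$work_years <- NULL
    x$effect <- unclass(x$effect)
    if (!is.null(x$sensitivity)) {
      s <- x$sensitivity
      x$sensitivity <- list(growth_rates = attr(s, "growth_rates"),
                            discount_rates = attr(s, "discount_rates"),
                            ratio = unclass_matrix(s))
    }
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                            na = "null"))
  }
  fmt <- function(v, digits = 2) {
    if (is.null(v) || length(v) == 0L || is.na(v)) "n/a"
    else formatC(v, format = "f", digits = digits, big.mark = ",")
  }
  e <- report$effect
  lines <- c(
    "## Headline metrics", "",
    "| Metric | Value |", "| --- | --- |",
    sprintf("| 1-year mortality pre | %s |", fmt(e$mortality_pre * 100)),
    sprintf("| 1-year mortality post | %s |", fmt(e$mortality_post * 100)),
    sprintf("| Absolute risk reduction (%%) | %s |", fmt(e$arr * 100)),
    sprintf("| Number needed to treat | %s |", fmt(e$nnt, 0)),
    sprintf("| Deaths averted (annualized) | %s |",
            fmt(e$deaths_averted_annualized, 1)),
    sprintf("| Life-years saved (annualized) | %s |",
            fmt(report$life_years_saved, 0)),
    sprintf("| Annualized cost | %s |", fmt(report$annualized_cost, 0)),
    sprintf("| Cost per life saved | %s |", fmt(report$cost_per_life_saved, 0)),
    sprintf("| Cost per life-year saved | %s |",
            fmt(report$cost_per_life_year, 0)),
    sprintf("| Net economic gain (annualized) | %s |",
            fmt(report$economic_gain, 0)),
    sprintf("| Benefit-cost ratio | %s |", fmt(report$benefit_cost_ratio)),
    sprintf("| Years added per death averted | %s |",
            fmt(report$years_per_death_averted, 0)))
  if (!is.null(report$sensitivity)) {
    s <- report$sensitivity
    header <- paste0("| Growth \\ Discount | ",
                     paste(colnames(s), collapse = " | "), " |")
    sep <- paste0("| --- |", paste(rep(" --- |", ncol(s)), collapse = ""))
    rows <- vapply(seq_len(nrow(s)), function(i) {
      paste0("| ", rownames(s)[i], " | ",
             paste(formatC(s[i, ], format = "f", digits = 2),
                   collapse = " | "), " |")
    }, character(1))
    lines <- c(lines, "", "## Sensitivity of benefit-cost ratio", "",
               header, sep, rows)
  }
  paste(lines, collapse = "\n")
}

unclass_matrix <- function(m) {
  m <- unclass(m)
  attributes(m) <- list(dim = dim(m))
  m
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(render_report(x, "markdown"), "\n")
  invisible(x)
}

#' @export
print.fixture_report <- function(x, ...) {
  fmt <- function(v, d = 2) formatC(v, format = "f", digits = d, big.mark = ",")
  cat("Aggregate evaluation (printed-aggregates fixture)\n",
      "  Absolute risk reduction:      ", fmt(x$arr * 100, 1), " %\n",
      "  Number needed to treat:       ", x$nnt, "\n",
      "  Annualized cost (INR):        ", fmt(x$annualized_cost, 0), "\n",
      "  Cost per life saved (INR):    ", fmt(x$cost_per_life_saved, 0), "\n",
      "  Life-years saved:             ", fmt(x$life_years_saved, 0), "\n",
      "  Years per death averted:      ", fmt(x$years_per_death_averted, 0), "\n",
      "  Cost per life-year (INR):     ", fmt(x$cost_per_life_year, 0), "\n",
      "  Net economic gain (INR):      ", fmt(x$economic_gain, 0), "\n",
      "  Benefit per rupee spent:      ", fmt(x$benefit_cost_ratio, 2), "\n",
      "  Average labour income (INR):  ", fmt(x$average_labor_income, 2), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat("Benefit-cost ratio by growth (rows) and discount (columns) rate:\n")
  m <- unclass_matrix(x)
  dimnames(m) <- dimnames(x)
  print(round(m, 2))
  invisible(x)
}

# -- internal helpers ---------------------------------------------------------

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

parse_bool <- function(x, path) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "1", "t", "yes")] <- TRUE
  out[v %in% c("false", "0", "f", "no")] <- FALSE
  if (anyNA(out) && length(out) > 0L) {
    stop("unparseable boolean at line ", which(is.na(out))[1L] + 1L,
         " of ", path, "; allowed: true/false, 1/0", call. = FALSE)
  }
  as.logical(out)
}
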