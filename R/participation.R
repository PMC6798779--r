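#' Labour force participation rate per 1,000
#'
#' The LFPR counts employed plus unemployed (i.e. job-seeking) persons per
#' 1,000 of the total population.
#'
#' @param employed,unemployed,population non-negative counts; `population`
#'   must be positive and at least `employed + unemployed`.
#' @return The rate per 1,000, a number in \[0, 1000\].
#' @examples
#' lfpr_from_counts(500, 0, 1000)  # 500 per 1,000
#' @export
lfpr_from_counts <- function(employed, unemployed, population) {
  if (any(population <= 0)) {
    stop("LFPR undefined: population must be positive", call. = FALSE)
  }
  if (any(employed < 0) || any(unemployed < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(employed + unemployed > population)) {
    stop("employed + unemployed exceeds population", call. = FALSE)
  }
  (employed + unemployed) / population * 1000
}

#' Bundle binned employment data with population counts
#'
#' Official employment tables typically report the age-wise distribution of
#' the employed per 1,000 in 5-year bins. This container couples those bins
#' with single-age population counts and the total labour force size, the
#' three ingredients needed to derive age-specific participation rates.
#'
#' @param bins `data.frame` with columns `age_lo`, `age_hi` (half-open bins
#'   `[age_lo, age_hi)`), `employed_per_1000`, and optionally `sex` for
#'   sex-specific bin tables.
#' @param population `data.frame` with columns `age`, `sex`, `population`.
#' @param total_labour_force total persons in the labour force: a single
#'   count applied to every sex, or a named vector such as
#'   `c(male = 21827337, female = 11090789)`.
#' @param lfpr_per_1000 optional overall LFPR per 1,000 (carried as
#'   metadata; not used in disaggregation).
#' @return An object of class `"labor_inputs"`.
#' @export
labor_inputs <- function(bins, population, total_labour_force,
                         lfpr_per_1000 = NULL) {
  need <- c("age_lo", "age_hi", "employed_per_1000")
  if (!all(need %in% names(bins))) {
    stop("`bins` must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("age", "sex", "population") %in% names(population))) {
    stop("`population` must have columns: age, sex, population", call. = FALSE)
  }
  if (any(bins$employed_per_1000 < 0)) {
    stop("employed_per_1000 must be non-negative", call. = FALSE)
  }
  if (any(bins$age_hi <= bins$age_lo)) {
    stop("bins must satisfy age_lo < age_hi", call. = FALSE)
  }
  if (any(population$population < 0)) {
    stop("population counts must be non-negative", call. = FALSE)
  }
  check_bins <- function(b) {
    b <- b[order(b$age_lo), , drop = FALSE]
    if (nrow(b) > 1L && any(b$age_lo[-1L] < b$age_hi[-nrow(b)])) {
      stop("employment bins overlap", call. = FALSE)
    }
    if (sum(b$employed_per_1000) > 1000 + 1e-8) {
      stop("employed_per_1000 sums above 1000 across bins", call. = FALSE)
    }
    b
  }
  if ("sex" %in% names(bins)) {
    bins <- do.call(rbind, lapply(split(bins, bins$sex), check_bins))
    rownames(bins) <- NULL
  } else {
    bins <- check_bins(bins)
  }
  out <- list(bins = bins, population = population,
              total_labour_force = total_labour_force,
              lfpr_per_1000 = lfpr_per_1000)
  class(out) <- "labor_inputs"
  out
}

#' Disaggregate binned employment into single-age participation rates
#'
#' Each bin's employed-per-1,000 mass is split uniformly across its single
#' years of age. The employed count at age `t` is then the per-age per-1,000
#' share scaled by the total labour force, and the participation rate `l[t]`
#' is that count divided by the population at age `t`, clamped into
#' \[0, 1\]. Participation is forced to zero at and beyond the retirement
#' age, reflecting the assumption that no one works from that age on.
#'
#' @param labor a [labor_inputs()] object.
#' @param sex which sex's schedule to build.
#' @param retirement_age first age at which participation is zero (default 70).
#' @return A named numeric vector of class `"participation_schedule"`:
#'   `l[t]` for every age covered by the population table, with attributes
#'   `sex` and `retirement_age`.
#' @export
disaggregate_participation <- function(labor, sex = c("male", "female"),
                                       retirement_age = 70L) {
  sex <- match.arg(sex)
  stopifnot(inherits(labor, "labor_inputs"))
  bins <- labor$bins
  if ("sex" %in% names(bins)) bins <- bins[bins$sex == sex, , drop = FALSE]
  pop <- labor$population
  pop <- pop[pop$sex == sex, , drop = FALSE]
  if (nrow(pop) == 0L) stop("no population rows for sex ", sex, call. = FALSE)
  tlf <- labor$total_labour_force
  if (!is.null(names(tlf))) {
    if (!sex %in% names(tlf)) {
      stop("total_labour_force has no entry for sex ", sex, call. = FALSE)
    }
    tlf <- tlf[[sex]]
  }
  ages <- seq(min(pop$age), max(pop$age))
  pop_at <- rep(0, length(ages))
  pop_at[match(pop$age, ages)] <- pop$population
  employed_at <- rep(0, length(ages))
  if (nrow(bins) > 0L) for (k in seq_len(nrow(bins))) {
    yrs <- seq(bins$age_lo[k], bins$age_hi[k] - 1L)
    share <- bins$employed_per_1000[k] / length(yrs)  # uniform within bin
    idx <- match(yrs, ages)
    if (anyNA(idx)) {
      stop("population table does not cover bin [", bins$age_lo[k], ", ",
           bins$age_hi[k], ")", call. = FALSE)
    }
    employed_at[idx] <- employed_at[idx] + share * tlf / 1000
  }
  bad <- employed_at > 0 & pop_at == 0
  if (any(bad)) {
    stop("zero population at age ", ages[which(bad)[1L]],
         " with nonzero employment", call. = FALSE)
  }
  l <- ifelse(pop_at > 0, employed_at / pop_at, 0)
  clamped <- l > 1
  if (any(clamped)) {
    warning("participation rate clamped to 1 at ", sum(clamped), " age(s)",
            call. = FALSE)
    l[clamped] <- 1
  }
  l[ages >= retirement_age] <- 0
  names(l) <- ages
  class(l) <- "participation_schedule"
  attr(l, "sex") <- sex
  attr(l, "retirement_age") <- as.integer(retirement_age)
  l
}

#' Expected remaining working years at a given age
#'
#' Sums, over each year from the current age up to retirement, the joint
#' probability of surviving to that age and being in the labour force:
#' `T_j = sum_{t=j}^{R} s[j, t] * l[t]`, where `l[t] = 0` for `t >=
#' retirement_age`, so the sum effectively stops at `R - 1`. Persons at or
#' beyond the retirement age, or older than the life table's maximum age,
#' have zero expected working years.
#'
#' @param surv a [build_survival_matrix()] result.
#' @param sched a [disaggregate_participation()] schedule of the same sex.
#' @param j current age (integer years).
#' @return Expected working years, a non-negative number bounded by
#'   `retirement_age - j`.
#' @export
expected_working_years <- function(surv, sched, j) {
  stopifnot(inherits(surv, "survival_matrix"),
            inherits(sched, "participation_schedule"))
  retirement <- attr(sched, "retirement_age")
  ages <- as.integer(rownames(surv))
  if (j >= retirement || j > max(ages)) return(0)
  if (j < min(ages)) {
    stop("age ", j, " below life-table coverage (min ", min(ages), ")",
         call. = FALSE)
  }
  ts <- seq(j, min(retirement - 1L, max(ages)))
  l <- sched[as.character(ts)]
  l[is.na(l)] <- 0
  sum(surv[as.character(j), as.character(ts)] * l)
}

#' Table of expected working years at every age
#'
#' Applies [expected_working_years()] across all ages covered by the
#' survival matrix.
#'
#' @inheritParams expected_working_years
#' @return Named numeric vector `T[j]` of class `"working_years_table"`,
#'   with attributes `sex` and `retirement_age`.
#' @export
working_years_table <- function(surv, sched) {
  ages <- as.integer(rownames(surv))
  tj <- vapply(ages, function(j) expected_working_years(surv, sched, j),
               numeric(1))
  names(tj) <- ages
  class(tj) <- "working_years_table"
  attr(tj, "sex") <- attr(surv, "sex")
  attr(tj, "retirement_age") <- attr(sched, "retirement_age")
  tj
}

#' Look up expected working years for given ages
#'
#' Ages above the table's coverage (or at/after retirement) map to zero
#' working years; ages below coverage are an error.
#'
#' @param wy a [working_years_table()].
#' @param age integer vector of ages.
#' @return Numeric vector of `T` values.
#' @export
working_years_at <- function(wy, age) {
  stopifnot(inherits(wy, "working_years_table"))
  ages <- as.integer(names(wy))
  if (any(age < min(ages))) {
    stop("age below working-years table coverage", call. = FALSE)
  }
  out <- unclass(wy)[match(age, ages)]
  out[is.na(out)] <- 0  # above max tabulated age: no expected working years
  unname(out)
}
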