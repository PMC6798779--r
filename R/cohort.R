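#' Construct a pre/post evaluation cohort
#'
#' @param patients `data.frame` with columns `id`, `age` (integer years at
#'   the index event), `sex` (`male`/`female`), `arm` (`pre`/`post`), and
#'   `died_1yr` (logical: died within 1-year follow-up).
#' @param enrollment_days number of days over which the cohort was enrolled
#'   (> 0); used to annualize cohort-level quantities.
#' @return The patient `data.frame` with class `"cohort"` and attribute
#'   `enrollment_days`.
#' @export
cohort <- function(patients, enrollment_days) {
  need <- c("id", "age", "sex", "arm", "died_1yr")
  if (!all(need %in% names(patients))) {
    stop("cohort needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (enrollment_days <= 0) {
    stop("enrollment_days must be positive", call. = FALSE)
  }
  if (nrow(patients) > 0L) {
    if (anyNA(patients[need])) stop("cohort contains missing values", call. = FALSE)
    if (any(patients$age < 0)) stop("ages must be non-negative", call. = FALSE)
    if (!all(patients$sex %in% c("male", "female"))) {
      bad <- setdiff(unique(patients$sex), c("male", "female"))
      stop("unknown sex value(s): ", paste(bad, collapse = ", "),
           "; allowed: male, female", call. = FALSE)
    }
    if (!all(patients$arm %in% c("pre", "post"))) {
      bad <- setdiff(unique(patients$arm), c("pre", "post"))
      stop("unknown arm value(s): ", paste(bad, collapse = ", "),
           "; allowed: pre, post", call. = FALSE)
    }
    if (!is.logical(patients$died_1yr)) {
      stop("died_1yr must be logical", call. = FALSE)
    }
  }
  out <- as.data.frame(patients)
  class(out) <- c("cohort", "data.frame")
  attr(out, "enrollment_days") <- as.integer(enrollment_days)
  out
}

#' Mortality effect of the intervention
#'
#' Per-arm 1-year mortality proportions, absolute risk reduction
#' (pre minus post), number needed to treat (`ceiling(1 / arr)`, the
#' standard clinical convention), and the annualized number of deaths
#' averted. The annualization base defaults to the total enrolled cohort
#' scaled to a full year (`n_total * days_per_year / enrollment_days`); an
#' explicit `annualized_n` may be supplied instead when an official
#' annualized enrolment figure is to be used.
#'
#' When the post arm does no better than the pre arm (`arr <= 0`) the NNT
#' is undefined (`NA`) and the estimate is flagged `no_benefit`; downstream
#' cost-per-life metrics refuse to divide by a non-positive effect.
#'
#' @param x a [cohort()].
#' @param days_per_year annualization convention (default 365.25).
#' @param annualized_n optional externally supplied annualized cohort size.
#' @return A list of class `"effect_estimate"`.
#' @export
effect_estimate <- function(x, days_per_year = 365.25, annualized_n = NULL) {
  stopifnot(inherits(x, "cohort"))
  n_pre <- sum(x$arm == "pre")
  n_post <- sum(x$arm == "post")
  if (n_pre == 0L || n_post == 0L) {
    stop("both arms must be non-empty", call. = FALSE)
  }
  d_pre <- sum(x$died_1yr[x$arm == "pre"])
  d_post <- sum(x$died_1yr[x$arm == "post"])
  if (d_pre + d_post == 0L) {
    stop("no deaths in either arm; effect undefined", call. = FALSE)
  }
  m_pre <- d_pre / n_pre
  m_post <- d_post / n_post
  arr <- m_pre - m_post
  if (is.null(annualized_n)) {
    annualized_n <- (n_pre + n_post) * days_per_year /
      attr(x, "enrollment_days")
  }
  structure(list(
    n_pre = n_pre, n_post = n_post,
    deaths_pre = d_pre, deaths_post = d_post,
    mortality_pre = m_pre, mortality_post = m_post,
    arr = arr,
    nnt = if (arr > 0) as.integer(ceiling(1 / arr)) else NA_integer_,
    annualized_n = annualized_n,
    deaths_averted_annualized = if (arr > 0) arr * annualized_n else 0,
    no_benefit = arr <= 0
  ), class = "effect_estimate")
}

#' Life-years saved if one patient's death is averted
#'
#' Sex-specific life expectancy minus age at the index event, floored at
#' zero (a patient already older than the life expectancy contributes no
#' life-years), and zero for survivors.
#'
#' @param patient one-row `data.frame` (or list) with `age`, `sex`,
#'   `died_1yr`.
#' @param params an [economic_params()].
#' @return Years, non-negative.
#' @export
life_years_saved_patient <- function(patient, params) {
  life_years_lost(patient$age, patient$sex, patient$died_1yr, params)
}

# Vectorized core used by both the per-patient op and the cohort sum.
life_years_lost <- function(age, sex, died, params) {
  stopifnot(inherits(params, "economic_params"))
  if (!all(sex %in% names(params$life_expectancy))) {
    stop("unknown sex category; expected one of: ",
         paste(names(params$life_expectancy), collapse = ", "), call. = FALSE)
  }
  le <- params$life_expectancy[sex]
  ifelse(died, pmax(le - age, 0), 0)
}

#' Annualized life-years lost per arm and life-years saved
#'
#' Sums life-years lost over deceased patients within each arm, then puts
#' both arms on a common annualized patient base: each arm's total is
#' scaled by `annualized_n / n_arm`, where `annualized_n` defaults to the
#' total enrolled cohort scaled to a full year. Scaling both arms to the
#' same base is what makes the pre-minus-post difference attributable to
#' the intervention rather than to unequal arm sizes. The difference pre
#' minus post is the life-years saved.
#'
#' @param x a [cohort()].
#' @param params an [economic_params()].
#' @param annualized_n common annualized patient base; default
#'   `n_total * days_per_year / enrollment_days`.
#' @return List with elements `pre`, `post`, `saved` (years/yr).
#' @export
cohort_life_years <- function(x, params, annualized_n = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(annualized_n)) {
    annualized_n <- nrow(x) * params$days_per_year / attr(x, "enrollment_days")
  }
  lyl <- life_years_lost(x$age, x$sex, x$died_1yr, params)
  arm_total <- function(a) {
    n <- sum(x$arm == a)
    if (n == 0L) return(0)
    sum(lyl[x$arm == a]) * annualized_n / n
  }
  pre <- arm_total("pre")
  post <- arm_total("post")
  list(pre = pre, post = post, saved = pre - post)
}

#' Annualized present value of income lost to 1-year mortality, per arm
#'
#' Each deceased patient contributes the present value of the income they
#' would have earned over their expected remaining working years
#' (see [present_value_income()]); survivors contribute nothing. As in
#' [cohort_life_years()], both arm totals are scaled to a common annualized
#' patient base (`annualized_n / n_arm`) so the pre/post comparison is not
#' confounded by arm size. Patients older than the working-years table's
#' coverage contribute with `T = 0` (a single undiscounted income term),
#' consistent with zero expected working years beyond the tabulated ages.
#'
#' @param x a [cohort()].
#' @param work_years named list with a [working_years_table()] for `male`
#'   and `female`.
#' @param params an [economic_params()] with `income_now` set.
#' @param annualized_n common annualized patient base; default
#'   `n_total * days_per_year / enrollment_days`.
#' @return List with elements `pre` and `post` (currency/yr).
#' @export
pv_lost_income <- function(x, work_years, params, annualized_n = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (!all(c("male", "female") %in% names(work_years))) {
    stop("work_years must be a named list with male and female tables",
         call. = FALSE)
  }
  if (is.null(annualized_n)) {
    annualized_n <- nrow(x) * params$days_per_year / attr(x, "enrollment_days")
  }
  dead <- x[x$died_1yr, , drop = FALSE]
  if (nrow(dead) == 0L) return(list(pre = 0, post = 0))
  tvals <- numeric(nrow(dead))
  for (s in c("male", "female")) {
    idx <- dead$sex == s
    if (any(idx)) tvals[idx] <- working_years_at(work_years[[s]], dead$age[idx])
  }
  pv <- present_value_income(params, tvals)
  arm_total <- function(a) {
    n <- sum(x$arm == a)
    if (n == 0L) return(0)
    sum(pv[dead$arm == a]) * annualized_n / n
  }
  list(pre = arm_total("pre"), post = arm_total("post"))
}

#' Net economic gain of the intervention
#'
#' The decrease in the annualized present value of lost income from the
#' pre- to the post-implementation period. A negative value (a net loss)
#' is reported as-is, with an attribute flag.
#'
#' @param pv_pre,pv_post annualized PV of lost income per arm.
#' @return Currency/yr, with attribute `net_loss` set when negative.
#' @export
economic_gain <- function(pv_pre, pv_post) {
  gain <- pv_pre - pv_post
  attr(gain, "net_loss") <- gain < 0
  gain
}

#' Headline cost-effectiveness metrics
#'
#' Cost per life saved, cost per life-year saved, benefit-cost ratio
#' (gain per unit of annualized programme cost) and the average life-years
#' added per death averted (rounded to the nearest integer, half to even).
#' Metrics whose denominator is non-positive are reported as `NA`
#' ("undefined"), never forced to a number.
#'
#' @param effect an [effect_estimate()].
#' @param life_years_saved annualized life-years saved.
#' @param gain annualized net economic gain.
#' @param annualized_cost annualized programme cost (> 0).
#' @return List of class `"headline_metrics"`.
#' @export
headline_metrics <- function(effect, life_years_saved, gain, annualized_cost) {
  if (annualized_cost <= 0) {
    stop("annualized_cost must be positive", call. = FALSE)
  }
  da <- effect$deaths_averted_annualized
  list_out <- list(
    deaths_averted_annualized = da,
    life_years_saved = life_years_saved,
    cost_per_life_saved = if (da > 0) annualized_cost / da else NA_real_,
    cost_per_life_year = if (life_years_saved > 0)
      annualized_cost / life_years_saved else NA_real_,
    benefit_cost_ratio = as.numeric(gain) / annualized_cost,
    years_per_death_averted = if (da > 0 && life_years_saved > 0)
      round(life_years_saved / da) else NA_real_,
    annualized_cost = annualized_cost
  )
  structure(list_out, class = "headline_metrics")
}

#' Benefit-cost ratio sensitivity to growth and discount rates
#'
#' Recomputes the annualized PV of lost income in both arms, the net gain,
#' and the benefit-cost ratio at every combination of the supplied growth
#' and discount rates. For a cohort with positive gain the grid is
#' non-decreasing down the growth axis and non-increasing across the
#' discount axis.
#'
#' @param x a [cohort()].
#' @param work_years named list of [working_years_table()]s (`male`,
#'   `female`).
#' @param params baseline [economic_params()]; only `growth_rate` and
#'   `discount_rate` vary across the grid.
#' @param growth_rates,discount_rates strictly increasing numeric vectors.
#' @param annualized_cost annualized programme cost (> 0).
#' @param annualized_n common annualized patient base passed to
#'   [pv_lost_income()].
#' @return Matrix of class `"sensitivity_grid"` with growth rates as rows
#'   and discount rates as columns; attribute `gain` holds the gain matrix.
#' @export
sensitivity_analysis <- function(x, work_years, params, growth_rates,
                                 discount_rates, annualized_cost,
                                 annualized_n = NULL) {
  if (length(growth_rates) == 0L || length(discount_rates) == 0L) {
    stop("rate lists must be non-empty", call. = FALSE)
  }
  if (is.unsorted(growth_rates, strictly = TRUE) ||
      is.unsorted(discount_rates, strictly = TRUE)) {
    stop("rate lists must be strictly increasing", call. = FALSE)
  }
  if (annualized_cost <= 0) stop("annualized_cost must be positive", call. = FALSE)
  ratio <- matrix(NA_real_, length(growth_rates), length(discount_rates),
                  dimnames = list(growth = paste0(growth_rates * 100, "%"),
                                  discount = paste0(discount_rates * 100, "%")))
  gain <- ratio
  for (gi in seq_along(growth_rates)) {
    for (ri in seq_along(discount_rates)) {
      p <- params
      p$growth_rate <- growth_rates[gi]
      p$discount_rate <- discount_rates[ri]
      pv <- pv_lost_income(x, work_years, p, annualized_n)
      g <- pv$pre - pv$post
      gain[gi, ri] <- g
      ratio[gi, ri] <- g / annualized_cost
    }
  }
  structure(ratio, gain = gain, growth_rates = growth_rates,
            discount_rates = discount_rates,
            class = c("sensitivity_grid", "matrix", "array"))
}

#' End-to-end cohort evaluation
#'
#' Runs the full pipeline: survival matrices and participation schedules
#' per sex, working-years tables, average labour income (unless
#' `params$income_now` is already set), the mortality effect, annualized
#' life-years, PV of lost income, net gain, headline metrics, and (when
#' rate grids are given) the sensitivity grid.
#'
#' @param x a [cohort()].
#' @param life_tables named list with a [life_table()] for `male` and
#'   `female`.
#' @param labor a [labor_inputs()] object.
#' @param params an [economic_params()].
#' @param macro optional [macro_inputs()]; used to derive `income_now` when
#'   it is not set in `params`.
#' @param cost a [cost_breakdown()]; its total over `period_days` is
#'   annualized. Alternatively pass `annualized_cost` directly.
#' @param annualized_cost annualized programme cost, overriding `cost`.
#' @param growth_rates,discount_rates optional rate vectors for the
#'   sensitivity grid.
#' @param annualized_n optional externally supplied annualized cohort size
#'   for the deaths-averted computation.
#' @param survival_method passed to [build_survival_matrix()].
#' @return A list of class `"evaluation_report"`.
#' @export
evaluate_cohort <- function(x, life_tables, labor, params,
                            macro = NULL, cost = NULL,
                            annualized_cost = NULL,
                            growth_rates = NULL, discount_rates = NULL,
                            annualized_n = NULL,
                            survival_method = "cumulative") {
  stopifnot(inherits(x, "cohort"))
  if (!all(c("male", "female") %in% names(life_tables))) {
    stop("life_tables must be a named list with male and female entries",
         call. = FALSE)
  }
  if (is.na(params$income_now)) {
    if (is.null(macro)) {
      stop("either params$income_now or `macro` must be supplied", call. = FALSE)
    }
    params$income_now <- average_labor_income(macro)
  }
  if (is.null(annualized_cost)) {
    if (is.null(cost)) stop("supply `cost` or `annualized_cost`", call. = FALSE)
    annualized_cost <- annualize(cost$total, cost$period_days,
                                 params$days_per_year)
  }
  work_years <- lapply(stats::setNames(c("male", "female"),
                                       c("male", "female")), function(s) {
    surv <- build_survival_matrix(life_tables[[s]], method = survival_method)
    sched <- disaggregate_participation(labor, s, params$retirement_age)
    working_years_table(surv, sched)
  })
  effect <- effect_estimate(x, params$days_per_year, annualized_n)
  ly <- cohort_life_years(x, params, annualized_n)
  pv <- pv_lost_income(x, work_years, params, annualized_n)
  gain <- economic_gain(pv$pre, pv$post)
  metrics <- headline_metrics(effect, ly$saved, gain, annualized_cost)
  sens <- NULL
  if (!is.null(growth_rates) && !is.null(discount_rates)) {
    sens <- sensitivity_analysis(x, work_years, params, growth_rates,
                                 discount_rates, annualized_cost, annualized_n)
  }
  structure(list(
    effect = effect,
    life_years_lost_pre = ly$pre, life_years_lost_post = ly$post,
    life_years_saved = ly$saved,
    pv_lost_pre = pv$pre, pv_lost_post = pv$post,
    economic_gain = as.numeric(gain),
    net_loss = isTRUE(attr(gain, "net_loss")),
    annualized_cost = annualized_cost,
    cost_per_life_saved = metrics$cost_per_life_saved,
    cost_per_life_year = metrics$cost_per_life_year,
    benefit_cost_ratio = metrics$benefit_cost_ratio,
    years_per_death_averted = metrics$years_per_death_averted,
    income_now = params$income_now,
    work_years = work_years,
    sensitivity = sens
  ), class = "evaluation_report")
}
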