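#' Macro-economic inputs for average labour income
#'
#' @param gdp gross domestic product, INR per year.
#' @param labour_share share of GDP accruing to labour, in \[0, 1\].
#' @param employed_workers total number of employed workers (> 0).
#' @return A list of class `"macro_inputs"`.
#' @export
macro_inputs <- function(gdp, labour_share, employed_workers) {
  if (gdp < 0) stop("gdp must be non-negative", call. = FALSE)
  if (labour_share < 0 || labour_share > 1) {
    stop("labour_share must lie in [0, 1]", call. = FALSE)
  }
  if (employed_workers <= 0) {
    stop("employed_workers must be positive", call. = FALSE)
  }
  structure(list(gdp = gdp, labour_share = labour_share,
                 employed_workers = employed_workers),
            class = "macro_inputs")
}

#' Economic evaluation parameters
#'
#' Default growth and discount rates follow World Bank guidance for low-
#' and middle-income countries (real income growth 3\%/yr, social discount
#' rate 6\%/yr). Default life expectancies are the Tamil Nadu 2010-14
#' figures (72.7 years female, 68.6 male). The retirement age caps the
#' working-years horizon. `days_per_year = 365.25` is the annualization
#' convention.
#'
#' @param income_now average labour income in the present year, INR/yr
#'   (typically from [average_labor_income()]).
#' @param growth_rate annual real income growth rate `g` (> -1).
#' @param discount_rate social discount rate `r` (> -1).
#' @param retirement_age first non-working age.
#' @param life_expectancy named vector, years, for `male` and `female`.
#' @param days_per_year annualization denominator.
#' @return A list of class `"economic_params"`.
#' @export
economic_params <- function(income_now = NA_real_,
                            growth_rate = 0.03,
                            discount_rate = 0.06,
                            retirement_age = 70L,
                            life_expectancy = c(female = 72.7, male = 68.6),
                            days_per_year = 365.25) {
  if (!is.na(income_now) && income_now < 0) {
    stop("income_now must be non-negative", call. = FALSE)
  }
  if (growth_rate <= -1 || discount_rate <= -1) {
    stop("growth_rate and discount_rate must exceed -1", call. = FALSE)
  }
  if (!all(c("male", "female") %in% names(life_expectancy))) {
    stop("life_expectancy needs named entries for male and female",
         call. = FALSE)
  }
  structure(list(income_now = income_now, growth_rate = growth_rate,
                 discount_rate = discount_rate,
                 retirement_age = as.integer(retirement_age),
                 life_expectancy = life_expectancy,
                 days_per_year = days_per_year),
            class = "economic_params")
}

#' Programme cost breakdown
#'
#' Direct implementation costs split into three phases with two components
#' each, incurred over `period_days`. The total is always computed as the
#' sum of the six leaf components.
#'
#' @param setting_up named vector: `devices`, `software_servers` (INR).
#' @param implementing named vector: `telecom_it`, `operations` (INR).
#' @param monitoring named vector: `logistics`, `overheads` (INR).
#' @param period_days days over which the costs were incurred.
#' @return A list of class `"cost_breakdown"` with a `total` element.
#' @export
cost_breakdown <- function(setting_up, implementing, monitoring, period_days) {
  chk <- function(x, nm) {
    if (!all(nm %in% names(x))) {
      stop("expected components: ", paste(nm, collapse = ", "), call. = FALSE)
    }
    if (any(x < 0)) stop("cost components must be non-negative", call. = FALSE)
    x[nm]
  }
  setting_up <- chk(setting_up, c("devices", "software_servers"))
  implementing <- chk(implementing, c("telecom_it", "operations"))
  monitoring <- chk(monitoring, c("logistics", "overheads"))
  if (period_days <= 0) stop("period_days must be positive", call. = FALSE)
  structure(list(setting_up = setting_up, implementing = implementing,
                 monitoring = monitoring,
                 period_days = as.integer(period_days),
                 total = sum(setting_up) + sum(implementing) + sum(monitoring)),
            class = "cost_breakdown")
}

#' Average labour income from national accounts
#'
#' The labour share of GDP divided by the number of employed workers:
#' `I = GDP * s / w`.
#'
#' @param macro a [macro_inputs()] object.
#' @return Average labour income, currency per year.
#' @examples
#' average_labor_income(macro_inputs(1000, 0.5, 10))  # 50
#' @export
average_labor_income <- function(macro) {
  stopifnot(inherits(macro, "macro_inputs"))
  if (macro$employed_workers <= 0) {
    stop("cannot divide by zero employed workers", call. = FALSE)
  }
  macro$gdp * macro$labour_share / macro$employed_workers
}

#' Present value of expected future labour income
#'
#' Discounted sum of income growing at rate `g` and discounted at rate `r`
#' over `T` working years: `PV = sum_{i=0}^{T} I_0 (1+g)^i / (1+r)^i`.
#' Income is credited at the start of each year, so the `i = 0` term is
#' undiscounted and `T = 0` returns exactly `income_now`. A fractional `T`
#' (working years are expectations, generally non-integer) contributes its
#' fractional part as a pro-rated share of the next year's term.
#'
#' @param params an [economic_params()] with `income_now` set.
#' @param working_years `T`, non-negative; may be a vector.
#' @return Present value(s), same length as `working_years`.
#' @examples
#' p <- economic_params(income_now = 100)
#' present_value_income(p, 2)  # 100 + 100*(1.03/1.06) + 100*(1.03/1.06)^2
#' @export
present_value_income <- function(params, working_years) {
  stopifnot(inherits(params, "economic_params"))
  if (is.na(params$income_now)) {
    stop("income_now is not set in params", call. = FALSE)
  }
  if (any(working_years < 0)) {
    stop("working_years must be non-negative", call. = FALSE)
  }
  x <- (1 + params$growth_rate) / (1 + params$discount_rate)
  vapply(working_years, function(T) {
    k <- floor(T)
    f <- T - k
    terms <- x^(0:k)
    pv <- sum(terms)
    if (f > 0) pv <- pv + f * x^(k + 1)
    params$income_now * pv
  }, numeric(1))
}

#' Annualize an amount incurred over a shorter or longer period
#'
#' Scales linearly to a full year: `amount * days_per_year / period_days`.
#'
#' @param amount currency amount incurred over `period_days`.
#' @param period_days length of the incurrence period, days (> 0).
#' @param days_per_year annualization denominator (default 365.25).
#' @return Currency per year.
#' @examples
#' annualize(13.2e6, 319)  # ~15.11e6
#' @export
annualize <- function(amount, period_days, days_per_year = 365.25) {
  if (any(period_days <= 0)) {
    stop("period_days must be positive", call. = FALSE)
  }
  amount * days_per_year / period_days
}
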