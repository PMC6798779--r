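params0 <- economic_params(income_now = 85669)

test_that("effect estimate recovers ARR, NNT and annualized deaths averted", {
  co <- counted_cohort(898, 158, 1522, 216)
  e <- effect_estimate(co, annualized_n = 2265)
  expect_equal(e$mortality_pre, 158 / 898)
  expect_equal(e$mortality_post, 216 / 1522)
  expect_equal(e$arr, 158 / 898 - 216 / 1522)
  expect_equal(e$nnt, 30L)
  expect_equal(e$deaths_averted_annualized, e$arr * 2265)
  expect_false(e$no_benefit)
  # default annualization base: total cohort scaled to a full year
  e2 <- effect_estimate(co)
  expect_equal(e2$annualized_n, 2420 * 365.25 / 319)
})

test_that("a no-benefit cohort flags an undefined NNT without erroring", {
  co <- counted_cohort(100, 10, 100, 10)
  e <- effect_estimate(co)
  expect_equal(e$arr, 0)
  expect_true(is.na(e$nnt))
  expect_true(e$no_benefit)
  expect_equal(e$deaths_averted_annualized, 0)
  expect_error(effect_estimate(counted_cohort(100, 0, 100, 0)), "no deaths")
  expect_error(effect_estimate(cohort(data.frame(
    id = "a", age = 60L, sex = "male", arm = "pre", died_1yr = TRUE), 319)),
    "non-empty")
})

test_that("life-years saved follow the life-expectancy rule", {
  p <- economic_params()
  # deceased man aged 70 exceeds the male life expectancy of 68.6
  expect_equal(life_years_saved_patient(
    list(age = 70, sex = "male", died_1yr = TRUE), p), 0)
  # survivors never contribute
  expect_equal(life_years_saved_patient(
    list(age = 40, sex = "female", died_1yr = FALSE), p), 0)
  # deceased woman aged 62: 72.7 - 62
  expect_equal(life_years_saved_patient(
    list(age = 62, sex = "female", died_1yr = TRUE), p), 10.7)
  expect_error(life_years_saved_patient(
    list(age = 62, sex = "other", died_1yr = TRUE), p), "unknown sex")
})

test_that("cohort life-years are scaled to a common annualized base", {
  p <- economic_params()
  toy <- cohort(data.frame(
    id = c("a", "b"), age = c(60L, 50L), sex = c("female", "male"),
    arm = c("pre", "post"), died_1yr = c(TRUE, FALSE)),
    enrollment_days = 365L)
  p365 <- economic_params(days_per_year = 365)
  # per-arm mean life-years times the shared base (here 1 per arm-year)
  ly1 <- cohort_life_years(toy, p365, annualized_n = 1)
  expect_equal(ly1$pre, 12.7)
  expect_equal(ly1$post, 0)
  expect_equal(ly1$saved, 12.7)
  # default base is the whole cohort annualized: 2 patients over one year
  ly2 <- cohort_life_years(toy, p365)
  expect_equal(ly2$pre, 25.4)
  # no deaths anywhere: all zeros
  none <- cohort(data.frame(id = "a", age = 60L, sex = "male", arm = "pre",
                            died_1yr = FALSE), 100)
  expect_equal(cohort_life_years(none, p), list(pre = 0, post = 0, saved = 0))
})

test_that("PV of lost income equals a per-patient brute-force loop", {
  wy <- flat_work_years(rate = 100, l = 0.5)
  toy <- cohort(data.frame(
    id = c("a", "b", "c", "d"),
    age = c(55L, 64L, 72L, 40L),
    sex = c("male", "female", "male", "female"),
    arm = c("pre", "pre", "post", "post"),
    died_1yr = c(TRUE, TRUE, TRUE, FALSE)),
    enrollment_days = 200L)
  got <- pv_lost_income(toy, wy, params0)

  base <- 4 * 365.25 / 200
  oracle_arm <- function(arm) {
    dead <- toy[toy$died_1yr & toy$arm == arm, ]
    n_arm <- sum(toy$arm == arm)
    tot <- 0
    for (i in seq_len(nrow(dead))) {
      T <- working_years_at(wy[[dead$sex[i]]], dead$age[i])
      tot <- tot + pv_oracle_patient(85669, 0.03, 0.06, T)
    }
    tot * base / n_arm
  }
  expect_equal(got$pre, oracle_arm("pre"), tolerance = 1e-9)
  expect_equal(got$post, oracle_arm("post"), tolerance = 1e-9)

  # a deceased patient past working age still costs one undiscounted term
  old <- cohort(data.frame(id = c("x", "y"), age = c(85L, 30L),
                           sex = "male", arm = c("pre", "post"),
                           died_1yr = c(TRUE, FALSE)),
                enrollment_days = 365L)
  p365 <- economic_params(income_now = 85669, days_per_year = 365)
  expect_equal(pv_lost_income(old, wy, p365, annualized_n = 1)$pre, 85669)

  # all survivors: nothing lost
  alive <- cohort(data.frame(id = "a", age = 50L, sex = "male", arm = "pre",
                             died_1yr = FALSE), 100)
  expect_equal(pv_lost_income(alive, wy, params0), list(pre = 0, post = 0))
})

test_that("economic gain is the drop in lost income, conserving totals", {
  expect_equal(as.numeric(economic_gain(228.7e6, 175.6e6)), 53.1e6)
  expect_equal(as.numeric(economic_gain(5, 5)), 0)
  loss <- economic_gain(10, 25)
  expect_equal(as.numeric(loss), -15)
  expect_true(attr(loss, "net_loss"))
  # conservation: gain + pv_post = pv_pre exactly
  set.seed(33)
  a <- runif(1, 0, 1e8); b <- runif(1, 0, 1e8)
  expect_identical(as.numeric(economic_gain(a, b)) + b, a)
})

test_that("headline metrics divide cost by effect, refusing zero effects", {
  co <- counted_cohort(898, 158, 1522, 216)
  e <- effect_estimate(co, annualized_n = 78 / (158 / 898 - 216 / 1522))
  m <- headline_metrics(e, life_years_saved = 1108, gain = 53.1e6,
                        annualized_cost = 15.11e6)
  expect_equal(m$cost_per_life_saved, 15.11e6 / 78, tolerance = 1e-9)
  expect_equal(m$cost_per_life_year, 15.11e6 / 1108, tolerance = 1e-9)
  expect_equal(m$benefit_cost_ratio, 53.1 / 15.11, tolerance = 1e-9)
  expect_equal(m$years_per_death_averted, 14)
  # exact inverse relation
  expect_equal(m$cost_per_life_saved * e$deaths_averted_annualized, 15.11e6)
  # zero gain gives a zero ratio; zero effect gives undefined metrics
  expect_equal(headline_metrics(e, 1108, 0, 15.11e6)$benefit_cost_ratio, 0)
  e0 <- effect_estimate(counted_cohort(100, 10, 100, 10))
  m0 <- headline_metrics(e0, 0, 0, 15.11e6)
  expect_true(is.na(m0$cost_per_life_saved))
  expect_true(is.na(m0$cost_per_life_year))
  expect_true(is.na(m0$years_per_death_averted))
  expect_error(headline_metrics(e, 1108, 1, 0), "positive")
})

test_that("doubling income doubles every monetary output exactly", {
  wy <- flat_work_years(rate = 50, l = 0.7)
  co <- generate_cohort(n_pre = 200, n_post = 300, seed = 5)
  p1 <- economic_params(income_now = 50000)
  p2 <- economic_params(income_now = 100000)
  pv1 <- pv_lost_income(co, wy, p1)
  pv2 <- pv_lost_income(co, wy, p2)
  expect_equal(pv2$pre, 2 * pv1$pre)
  expect_equal(pv2$post, 2 * pv1$post)
  g1 <- economic_gain(pv1$pre, pv1$post)
  g2 <- economic_gain(pv2$pre, pv2$post)
  expect_equal(as.numeric(g2), 2 * as.numeric(g1))
})

test_that("sensitivity grid cells equal independent single-rate runs", {
  wy <- flat_work_years(rate = 80, l = 0.6)
  co <- generate_cohort(n_pre = 400, n_post = 600, seed = 9)
  cost <- 2e6
  gr <- c(0.02, 0.08)
  dr <- c(0.03, 0.09)
  grid <- sensitivity_analysis(co, wy, params0, gr, dr, cost)
  for (gi in 1:2) for (ri in 1:2) {
    p <- params0
    p$growth_rate <- gr[gi]
    p$discount_rate <- dr[ri]
    pv <- pv_lost_income(co, wy, p)
    expect_equal(grid[gi, ri], (pv$pre - pv$post) / cost, tolerance = 1e-12)
  }
  # single-cell grid is the headline ratio at the same rates
  one <- sensitivity_analysis(co, wy, params0, 0.03, 0.06, cost)
  pv <- pv_lost_income(co, wy, params0)
  expect_equal(one[1, 1], (pv$pre - pv$post) / cost, tolerance = 1e-12)
  expect_error(sensitivity_analysis(co, wy, params0, c(0.08, 0.02), dr, cost),
               "increasing")
  expect_error(sensitivity_analysis(co, wy, params0, numeric(0), dr, cost),
               "non-empty")
})

test_that("grid ratios rise with growth and fall with discounting", {
  wy <- flat_work_years(rate = 80, l = 0.6)
  # deaths only in the pre arm guarantee a positive gain
  co <- counted_cohort(200, 40, 200, 10, age = 50L)
  grid <- sensitivity_analysis(co, wy, params0,
                               c(0.01, 0.04, 0.08), c(0.02, 0.05, 0.1), 1e6)
  expect_true(all(diff(grid) > 0))          # down the growth axis
  expect_true(all(t(diff(t(grid))) < 0))    # across the discount axis
})
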