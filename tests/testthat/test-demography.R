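test_that("life table construction enforces contiguity and rate bounds", {
  expect_error(life_table(c(60, 62), c(1, 1), "male"), "missing age")
  expect_error(life_table(c(60, 61), c(1, 1001), "male"), "\\[0, 1000\\]")
  expect_error(life_table(c(60, 60), c(1, 1), "male"), "unique")
  lt <- life_table(60:62, c(5, 6, 7), "female")
  expect_s3_class(lt, "life_table")
  expect_identical(attr(lt, "max_age"), 62L)
})

test_that("survival matrix follows the cumulative-deaths construction", {
  # zero mortality: certain survival everywhere
  s0 <- build_survival_matrix(flat_life_table(0, ages = 50:60))
  expect_true(all(s0[upper.tri(s0, diag = TRUE)] == 1))

  # flat 10 per 1,000: s[60, 62] = 1 - 30/1000
  s10 <- build_survival_matrix(flat_life_table(10, ages = 50:70))
  expect_equal(s10["60", "62"], 0.970)

  # accumulated deaths beyond 1,000 clamp survival at zero
  s400 <- build_survival_matrix(flat_life_table(400, ages = 45:60))
  expect_equal(s400["50", "53"], 0)
})

test_that("survival matrices are valid probabilities, non-increasing in t", {
  set.seed(101)
  for (rep in 1:20) {
    ages <- 0:sample(60:100, 1)
    lt <- life_table(ages, runif(length(ages), 0, 60), "male")
    for (m in c("cumulative", "product")) {
      s <- build_survival_matrix(lt, method = m)
      vals <- s[upper.tri(s, diag = TRUE)]
      expect_true(all(vals >= 0 & vals <= 1))
      for (j in sample(seq_along(ages), 5)) {
        row <- s[j, j:length(ages)]
        expect_true(all(diff(row) <= 1e-12))
      }
    }
    # cumulative-sum survival is a lower bound on the product form
    sc <- build_survival_matrix(lt, "cumulative")
    sp <- build_survival_matrix(lt, "product")
    ut <- upper.tri(sc, diag = TRUE)
    expect_true(all(sc[ut] <= sp[ut] + 1e-12))
  }
})

test_that("LFPR is employed plus unemployed per 1,000 population", {
  expect_equal(lfpr_from_counts(500, 0, 1000), 500)
  expect_equal(lfpr_from_counts(0, 0, 1000), 0)
  # state-level counts: formula gives ~456 per 1,000, near the official 454
  got <- lfpr_from_counts(32918126, 0, 72147030)
  expect_equal(got, 32918126 / 72147030 * 1000)
  expect_lt(abs(got - 454) / 454, 0.01)
  expect_error(lfpr_from_counts(1, 0, 0), "population")
  expect_error(lfpr_from_counts(900, 200, 1000), "exceeds")
})

test_that("binned employment disaggregates uniformly and conserves totals", {
  pop <- rbind(data.frame(age = 0:80, sex = "male", population = 20000),
               data.frame(age = 0:80, sex = "female", population = 20000))
  # single bin [60, 65) with 5 per 1,000 and a 1M labour force:
  # 1 per 1,000 per single year -> 1000 employed / 20000 pop = 0.05
  bins <- data.frame(age_lo = 60L, age_hi = 65L, employed_per_1000 = 5)
  l <- disaggregate_participation(labor_inputs(bins, pop, 1e6), "male")
  expect_equal(unname(l["60"]), 0.05)
  expect_equal(unname(l["64"]), 0.05)
  expect_equal(unname(l["65"]), 0)   # outside the bin
  expect_equal(unname(l["70"]), 0)   # at retirement

  # conservation: per-age employed counts recover the bin total
  employed_back <- sum(unclass(l)[as.character(60:64)] * 20000)
  expect_equal(employed_back, 5 * 1e6 / 1000, tolerance = 1e-12)

  # all-zero employment gives zero participation everywhere
  bins0 <- data.frame(age_lo = 60L, age_hi = 65L, employed_per_1000 = 0)
  l0 <- disaggregate_participation(labor_inputs(bins0, pop, 1e6), "male")
  expect_true(all(unclass(l0) == 0))
})

test_that("disaggregation validates populations, bins, and clamps rates", {
  pop0 <- rbind(data.frame(age = 0:80, sex = "male",
                           population = c(rep(20000, 60), 0, rep(20000, 20))),
                data.frame(age = 0:80, sex = "female", population = 20000))
  bins <- data.frame(age_lo = 60L, age_hi = 65L, employed_per_1000 = 5)
  expect_error(disaggregate_participation(labor_inputs(bins, pop0, 1e6),
                                          "male"),
               "zero population")
  overlapping <- data.frame(age_lo = c(60L, 62L), age_hi = c(65L, 67L),
                            employed_per_1000 = c(5, 5))
  pop <- data.frame(age = 0:80, sex = "male", population = 20000)
  expect_error(labor_inputs(overlapping, pop, 1e6), "overlap")
  expect_error(labor_inputs(data.frame(age_lo = 0L, age_hi = 5L,
                                       employed_per_1000 = 1500),
                            pop, 1e6), "1000")
  # a sparse population forces a rate above 1, which is clamped with warning
  tiny <- data.frame(age = 0:80, sex = "male", population = 10)
  expect_warning(
    lc <- disaggregate_participation(labor_inputs(bins, tiny, 1e6), "male"),
    "clamped")
  expect_true(all(unclass(lc) <= 1))
})

test_that("expected working years match hand and oracle computations", {
  # at or beyond retirement: zero
  wy <- flat_work_years(rate = 0, l = 1)
  expect_equal(unname(unclass(wy$male)["70"]), 0)
  expect_equal(working_years_at(wy$male, 95), 0)

  # zero mortality, full participation below 70: count of remaining ages
  expect_equal(unname(unclass(wy$male)["60"]), 10)

  # flat 100 per 1,000, l = 0.5, j = 68: 0.9*0.5 + 0.8*0.5
  surv <- build_survival_matrix(flat_life_table(100))
  sched <- flat_schedule(0.5)
  expect_equal(expected_working_years(surv, sched, 68), 0.85)

  # oracle equivalence: with zero mortality T is the plain sum of l
  set.seed(7)
  lvals <- runif(1)
  sched_r <- flat_schedule(lvals)
  surv0 <- build_survival_matrix(flat_life_table(0))
  for (j in c(25, 40, 55, 69)) {
    expect_equal(expected_working_years(surv0, sched_r, j),
                 sum(rep(lvals, 70 - j)), tolerance = 1e-9)
  }
})

test_that("working-years tables satisfy their bounds at every age", {
  set.seed(11)
  lt <- life_table(0:100, runif(101, 0, 50), "male")
  sched <- flat_schedule(0.8)
  wy <- working_years_table(build_survival_matrix(lt), sched)
  ages <- as.integer(names(wy))
  expect_true(all(unclass(wy) >= 0))
  expect_true(all(unclass(wy) <= pmax(70 - ages, 0)))
  expect_true(all(unclass(wy)[ages >= 70] == 0))
})
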