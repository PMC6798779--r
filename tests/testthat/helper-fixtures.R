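# Shared builders for small, fully hand-checkable inputs.

flat_life_table <- function(rate, sex = "male", ages = 0:100) {
  life_table(ages, rep(rate, length(ages)), sex)
}

# A participation schedule with a constant rate below retirement, built
# through the public disaggregation path so invariants are exercised.
flat_schedule <- function(l, sex = "male", max_age = 100L,
                          retirement_age = 70L) {
  pop <- 10000
  tlf <- 1e6
  # one 5-year bin per block covering 0..retirement_age, each delivering
  # employed = l * pop at every single age
  lo <- seq(0L, retirement_age - 5L, by = 5L)
  per_bin <- l * pop / tlf * 1000 * 5
  bins <- data.frame(age_lo = lo, age_hi = lo + 5L,
                     employed_per_1000 = per_bin)
  population <- rbind(
    data.frame(age = 0:max_age, sex = "male", population = pop),
    data.frame(age = 0:max_age, sex = "female", population = pop))
  disaggregate_participation(labor_inputs(bins, population, tlf), sex,
                             retirement_age)
}

# Working-years tables for both sexes from flat mortality/participation.
flat_work_years <- function(rate = 0, l = 1, max_age = 100L) {
  lapply(stats::setNames(c("male", "female"), c("male", "female")),
         function(s) {
    working_years_table(build_survival_matrix(flat_life_table(rate, s,
                                                              0:max_age)),
                        flat_schedule(l, s, max_age))
  })
}

# Cohort with exact per-arm death counts (deaths assigned to the first
# rows of each arm).
counted_cohort <- function(n_pre, d_pre, n_post, d_post,
                           age = 60L, sex = "male",
                           enrollment_days = 319L) {
  mk <- function(n, d, arm) {
    if (n == 0L) return(NULL)
    data.frame(id = paste0(arm, seq_len(n)), age = age, sex = sex,
               arm = arm, died_1yr = seq_len(n) <= d)
  }
  cohort(rbind(mk(n_pre, d_pre, "pre"), mk(n_post, d_post, "post")),
         enrollment_days)
}

# Brute-force oracle: per-patient, per-year discounted income sum,
# independent of the package's vectorized path.
pv_oracle_patient <- function(income, g, r, T) {
  k <- floor(T)
  total <- 0
  for (i in 0:k) total <- total + income * (1 + g)^i / (1 + r)^i
  f <- T - k
  if (f > 0) total <- total + f * income * (1 + g)^(k + 1) / (1 + r)^(k + 1)
  total
}
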