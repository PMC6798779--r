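#' Construct a sex-specific life table
#'
#' A life table records deaths per 1,000 persons at each single year of age
#' for one sex. Ages must be unique, contiguous integers; rates must lie in
#' \[0, 1000\]. The table is the input from which survival probability
#' matrices are built.
#'
#' @param age integer vector of completed years, contiguous and unique.
#' @param deaths_per_1000 numeric vector of death rates per 1,000 at each age.
#' @param sex `"male"` or `"female"`.
#' @return A `data.frame` of class `"life_table"` with columns `age` and
#'   `deaths_per_1000`, and attributes `sex` and `max_age`.
#' @examples
#' lt <- life_table(0:100, rep(10, 101), "male")
#' attr(lt, "max_age")
#' @export
life_table <- function(age, deaths_per_1000, sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (length(age) != length(deaths_per_1000)) {
    stop("`age` and `deaths_per_1000` must have equal length", call. = FALSE)
  }
  if (length(age) == 0L) stop("life table must have at least one age", call. = FALSE)
  age <- as.integer(age)
  if (anyNA(age) || anyNA(deaths_per_1000)) {
    stop("life table contains missing values", call. = FALSE)
  }
  if (any(age < 0L)) stop("ages must be non-negative", call. = FALSE)
  if (anyDuplicated(age)) stop("ages must be unique", call. = FALSE)
  o <- order(age)
  age <- age[o]
  deaths_per_1000 <- as.numeric(deaths_per_1000)[o]
  gaps <- setdiff(seq(min(age), max(age)), age)
  if (length(gaps) > 0L) {
    stop("life table ages are not contiguous; missing age(s): ",
         paste(utils::head(gaps, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(deaths_per_1000 < 0 | deaths_per_1000 > 1000)) {
    bad <- age[deaths_per_1000 < 0 | deaths_per_1000 > 1000][1L]
    stop("deaths_per_1000 outside [0, 1000] at age ", bad, call. = FALSE)
  }
  out <- data.frame(age = age, deaths_per_1000 = deaths_per_1000)
  class(out) <- c("life_table", "data.frame")
  attr(out, "sex") <- sex
  attr(out, "max_age") <- max(age)
  out
}

#' Build a survival probability matrix from a life table
#'
#' Entry `s[j, t]` is the probability that a person of age `j` survives to
#' the end of age `t` (for `j <= t`). The default `"cumulative"` method
#' follows the convention of accumulating deaths per 1,000 from age `j`
#' through age `t` and taking the complement, clamped into \[0, 1\]:
#' `s[j, t] = 1 - min(1, sum(d[j:t]) / 1000)`. Over long horizons the
#' accumulated death probability can exceed 1, in which case survival is
#' clamped at 0. The `"product"` method instead multiplies conditional
#' annual survival probabilities `prod(1 - d[j:t]/1000)`, the standard
#' actuarial construction, and is provided for methodological comparison.
#'
#' @param lt a [life_table()].
#' @param method `"cumulative"` (default) or `"product"`.
#' @return A square matrix of class `"survival_matrix"` with rows and
#'   columns named by age; entries below the diagonal (`t < j`) are `NA`.
#'   Attributes: `sex`, `method`.
#' @examples
#' lt <- life_table(60:70, rep(10, 11), "male")
#' s <- build_survival_matrix(lt)
#' s["60", "62"]  # 1 - 30/1000 = 0.97
#' @export
build_survival_matrix <- function(lt, method = c("cumulative", "product")) {
  method <- match.arg(method)
  stopifnot(inherits(lt, "life_table"))
  ages <- lt$age
  n <- length(ages)
  d <- lt$deaths_per_1000 / 1000
  if (method == "cumulative") {
    cum <- cumsum(d)
    # cumulative deaths from j through t = cum[t] - cum[j - 1]
    block <- outer(c(0, cum[-n]), cum, function(prev, tot) tot - prev)
    block[block > 1] <- 1  # accumulated death probability capped at 1
    s <- 1 - block
    s[s < 0] <- 0
    s[s > 1] <- 1
  } else {
    lp <- cumsum(log(pmax(1 - d, 0)))
    block <- outer(c(0, lp[-n]), lp, function(prev, tot) tot - prev)
    s <- exp(block)
    s[!is.finite(s)] <- 0
  }
  s[lower.tri(s)] <- NA_real_
  dimnames(s) <- list(j = ages, t = ages)
  class(s) <- c("survival_matrix", class(s))
  attr(s, "sex") <- attr(lt, "sex")
  attr(s, "method") <- method
  s
}
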