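#' Default smoking-history distribution parameters
#'
#' Parametric stand-in for a smoking history generator: per sex and
#' birth-year band it gives the ever-smoker probability, truncated-normal
#' start/quit age parameters, the probability of quitting within a lifetime,
#' and a categorical distribution over smoking-intensity classes
#' (cigarettes/day). Values are round numbers loosely matching 20th-century
#' US birth cohorts (male prevalence peaking around 60% for mid-century
#' cohorts, female prevalence lower and peaking later); they are
#' configuration, not estimates.
#'
#' @return A tibble with one row per sex x birth-band, consumed by
#'   [cohort_config()].
#' @export
smoking_defaults <- function() {
  bands <- tibble(
    year_from = c(1880, 1920, 1950),
    year_to   = c(1919, 1949, 1990)
  )
  m <- bands %>% mutate(
    sex = "M",
    p_smoker = c(0.55, 0.60, 0.45),
    start_mean = 17, start_sd = 4,
    p_quit = c(0.45, 0.55, 0.60),
    quit_mean = 47, quit_sd = 12
  )
  f <- bands %>% mutate(
    sex = "F",
    p_smoker = c(0.25, 0.40, 0.35),
    start_mean = 19, start_sd = 5,
    p_quit = c(0.45, 0.55, 0.60),
    quit_mean = 47, quit_sd = 12
  )
  out <- bind_rows(m, f)
  # intensity classes (cig/day) and their probabilities among ever-smokers
  out$int_levels <- list(c(10, 20, 30, 40))
  out$int_probs <- list(c(0.30, 0.40, 0.20, 0.10))
  out
}

#' Cohort configuration
#'
#' Describes the simulated birth cohorts: which birth years, how many
#' simulated persons per year (a count vector scaled by `scale` so that
#' desk-scale runs preserve cohort composition), and the smoking-history
#' distribution parameters per sex and birth band.
#'
#' @param birth_years Integer vector of birth years (consecutive or not).
#' @param births_per_year Scalar or vector (recycled/matched to
#'   `birth_years`) of per-year person counts before scaling.
#' @param scale Single positive scaling factor applied to the counts.
#' @param p_male Probability that a simulated person is male.
#' @param smoking Tibble of smoking parameters, see [smoking_defaults()].
#' @param seed Optional integer; when non-`NULL`, [generate_cohort()] seeds
#'   the RNG with it so the cohort is reproducible in isolation.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(birth_years = 1890:1984,
                          births_per_year = 1000,
                          scale = 1,
                          p_male = 0.5,
                          smoking = smoking_defaults(),
                          seed = NULL) {
  if (length(birth_years) == 0) abort("empty birth-year range")
  if (length(births_per_year) == 1) {
    births_per_year <- rep(births_per_year, length(birth_years))
  }
  if (length(births_per_year) != length(birth_years)) {
    abort("births_per_year must be scalar or match birth_years")
  }
  if (any(births_per_year < 0)) abort("negative birth counts")
  if (scale <= 0) abort("scale must be positive")
  structure(
    list(
      birth_years = as.integer(birth_years),
      births_per_year = births_per_year,
      scale = scale,
      p_male = p_male,
      smoking = smoking,
      seed = seed
    ),
    class = "cohort_config"
  )
}

# draw from a normal truncated to [lo, hi] by quantile inversion
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Generate a birth cohort with smoking histories
#'
#' Samples one row per simulated person: sex, age at smoking initiation
#' (`NA` for never-smokers), age at cessation (`NA` for current or never
#' smokers) and intensity in cigarettes/day (0 for never-smokers).
#' Reproducible given the RNG state (or `config$seed`).
#'
#' @param config A [cohort_config()].
#' @return Tibble with columns `id`, `birth_year`, `sex`, `start_age`,
#'   `quit_age`, `intensity`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  counts <- as.integer(round(config$births_per_year * config$scale))
  n <- sum(counts)
  if (n == 0) {
    return(tibble(
      id = integer(), birth_year = integer(), sex = character(),
      start_age = double(), quit_age = double(), intensity = double()
    ))
  }
  birth_year <- rep(config$birth_years, counts)
  sex <- ifelse(runif(n) < config$p_male, "M", "F")

  sm <- config$smoking
  # match each person to a (sex, band) parameter row
  row_of <- integer(n)
  for (i in seq_len(nrow(sm))) {
    hit <- sex == sm$sex[i] &
      birth_year >= sm$year_from[i] & birth_year <= sm$year_to[i]
    row_of[hit] <- i
  }
  if (any(row_of == 0)) abort("smoking parameter table does not cover cohort")

  p_smoker <- sm$p_smoker[row_of]
  smoker <- runif(n) < p_smoker
  start_age <- rep(NA_real_, n)
  quit_age <- rep(NA_real_, n)
  intensity <- rep(0, n)

  if (any(smoker)) {
    k <- which(smoker)
    r <- row_of[k]
    start_age[k] <- rtruncnorm(length(k), sm$start_mean[r], sm$start_sd[r], 10, 40)
    quits <- runif(length(k)) < sm$p_quit[r]
    kq <- k[quits]
    if (length(kq)) {
      rq <- row_of[kq]
      quit_age[kq] <- rtruncnorm(
        length(kq), sm$quit_mean[rq], sm$quit_sd[rq],
        start_age[kq] + 1, 90
      )
    }
    # intensity class; parameter rows share the class levels
    lev <- sm$int_levels[[1]]
    pr <- do.call(rbind, sm$int_probs)[r, , drop = FALSE]
    u <- runif(length(k))
    cum <- t(apply(pr, 1, cumsum))
    cls <- rowSums(u > cum) + 1L
    intensity[k] <- lev[cls]
  }

  tibble(
    id = seq_len(n), birth_year = birth_year, sex = sex,
    start_age = start_age, quit_age = quit_age, intensity = intensity
  )
}

#' Cumulative pack-years at a given age
#'
#' A pack-year is one pack (20 cigarettes) per day for one year, so
#' pack-years accrue at `intensity/20` per year between the start and quit
#' ages and are constant elsewhere: zero before initiation, frozen after
#' cessation.
#'
#' @param history Data frame with columns `start_age`, `quit_age`,
#'   `intensity` (a cohort tibble or any subset of rows).
#' @param age Age(s) in years, recycled against the rows of `history`.
#' @return Numeric vector of pack-years.
#' @export
pack_years_at <- function(history, age) {
  if (any(age < 0)) abort("age must be non-negative")
  start <- history$start_age
  quit <- ifelse(is.na(history$quit_age), Inf, history$quit_age)
  dur <- pmax(0, pmin(age, quit) - ifelse(is.na(start), Inf, start))
  dur * history$intensity / 20
}

#' Screening eligibility policy
#'
#' Age window, minimum pack-years, maximum years since quitting, screening
#' frequency, and the CT detectability threshold. The default reproduces a
#' "Group 1" policy: ages 55-77, at least 30 pack-years, current smokers or
#' quit within 15 years, one scan a year.
#'
#' @param start_age,end_age Screening age window (years).
#' @param min_pack_years Minimum cumulative pack-years.
#' @param max_quit_years Maximum years since cessation (10 or 15 in common
#'   guidelines).
#' @param screens_per_year Screens per year: 0.5 = biennial, 1 = annual,
#'   2 = biannual, 4 = quarterly.
#' @param v_detect_min Volume (cm^3) above which a compartment is visible on
#'   CT.
#' @return Object of class `screening_policy`.
#' @export
screening_policy <- function(start_age = 55, end_age = 77,
                             min_pack_years = 30, max_quit_years = 15,
                             screens_per_year = 1,
                             v_detect_min = .v_detect_default) {
  if (start_age >= end_age) abort("start_age must be below end_age")
  if (screens_per_year <= 0) abort("screens_per_year must be positive")
  structure(
    list(
      start_age = start_age, end_age = end_age,
      min_pack_years = min_pack_years, max_quit_years = max_quit_years,
      screens_per_year = screens_per_year, v_detect_min = v_detect_min
    ),
    class = "screening_policy"
  )
}

#' Is a person screening-eligible at a given age?
#'
#' Eligible iff the age lies in the policy window, cumulative pack-years
#' meet the minimum, and the person is a current smoker or quit no more than
#' `max_quit_years` ago.
#'
#' @inheritParams pack_years_at
#' @param policy A [screening_policy()].
#' @return Logical vector.
#' @export
is_eligible <- function(history, age, policy) {
  py <- pack_years_at(history, age)
  quit <- ifelse(is.na(history$quit_age), Inf, history$quit_age)
  age >= policy$start_age & age <= policy$end_age &
    py >= policy$min_pack_years &
    (age - quit) <= policy$max_quit_years
}

# eligibility interval [lo, hi] per person (NA if never eligible); used to
# lay out screening schedules without re-testing every age
eligibility_window <- function(history, policy) {
  start <- history$start_age
  quit <- ifelse(is.na(history$quit_age), Inf, history$quit_age)
  int <- history$intensity
  # age at which pack-years reach the minimum (Inf if never)
  need <- policy$min_pack_years * 20 / ifelse(int > 0, int, NA_real_)
  age_py <- start + need
  age_py[is.na(age_py)] <- Inf
  max_py <- (quit - start) * int / 20
  age_py[!is.na(max_py) & max_py < policy$min_pack_years] <- Inf
  lo <- pmax(policy$start_age, age_py)
  hi <- pmin(policy$end_age, quit + policy$max_quit_years)
  bad <- !is.finite(lo) | lo > hi
  lo[bad] <- NA_real_
  hi[bad] <- NA_real_
  tibble(elig_lo = lo, elig_hi = hi)
}
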