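#' Stage-group mapping rules
#'
#' Maps (detected primary size, detectable nodal disease, detectable distant
#' disease) to a stage group. The default is an AJCC-6-consistent mapping on
#' the three modelled extent states: without detectable nodal or distant
#' disease, `<= 3 cm` is IA and `> 3 cm` IB; with detectable nodal disease
#' IIA / IIB by the same 3 cm cut; detectable distant disease is IV. IIIA
#' and IIIB exist in the stage vocabulary and survival configuration but are
#' only reachable by supplying replacement rules (the modelled N0/N1/M1
#' extent states cannot express N2/N3 or T4 disease).
#'
#' Only detectable nodal disease upstages: occult deposits are invisible to
#' the staging workup by construction.
#'
#' @param rules Optional replacement tibble with columns `n_detectable`,
#'   `m_detectable`, `size_min`, `size_max`, `stage`.
#' @return Object of class `stage_rules`.
#' @export
stage_rules <- function(rules = NULL) {
  if (is.null(rules)) {
    rules <- tibble(
      n_detectable = c(FALSE, FALSE, TRUE, TRUE, NA),
      m_detectable = c(FALSE, FALSE, FALSE, FALSE, TRUE),
      size_min = c(0, 3, 0, 3, 0),
      size_max = c(3, Inf, 3, Inf, Inf),
      stage = c("IA", "IB", "IIA", "IIB", "IV")
    )
  }
  structure(list(table = rules, levels = stage_levels()), class = "stage_rules")
}

#' @rdname stage_rules
#' @export
stage_levels <- function() c("IA", "IB", "IIA", "IIB", "IIIA", "IIIB", "IV")

#' Observed (clinical) stage group at diagnosis
#'
#' Deterministic lookup in the staging rules; distant detectable disease
#' always maps to IV.
#'
#' @param pts_cm Detected primary tumor size, cm (diameter).
#' @param nms_detectable,dmp_detectable Logical: nodal / distant compartment
#'   at or above the CT threshold at diagnosis.
#' @param rules A [stage_rules()].
#' @return Character vector of stage groups.
#' @export
observed_stage <- function(pts_cm, nms_detectable, dmp_detectable,
                           rules = stage_rules()) {
  if (any(pts_cm < 0)) abort("pts_cm must be non-negative")
  tb <- rules$table
  out <- rep(NA_character_, length(pts_cm))
  # metastatic rows take precedence: distant detectable disease is IV
  m_row <- which(!is.na(tb$m_detectable) & tb$m_detectable)[1]
  out[dmp_detectable] <- tb$stage[m_row]
  for (i in seq_len(nrow(tb))) {
    hit <- is.na(out) &
      (is.na(tb$n_detectable[i]) | nms_detectable == tb$n_detectable[i]) &
      !dmp_detectable &
      (pts_cm > tb$size_min[i] | tb$size_min[i] == 0) & pts_cm <= tb$size_max[i]
    out[hit] <- tb$stage[i]
  }
  if (any(is.na(out))) abort("stage rules do not cover some (PTS, N, M) input")
  out
}

#' Mixture-cure survival curve set
#'
#' Per-stage (and, for stage I, per primary-size-bin) post-diagnosis
#' lung-cancer survival as mixture-cure exponentials
#' `S(t) = c + (1 - c) * exp(-r t)`: a fraction `c` is cured (never dies of
#' lung cancer), the rest die at constant rate `r`. The analytic inverse
#' `S^{-1}(u) = -log((u - c)/(1 - c)) / r` on `(c, 1]` makes inversion
#' sampling exact. These are cause-specific curves — death *from lung
#' cancer* — since other-cause mortality competes separately through the
#' life table. Defaults approximate published cause-specific stage-specific
#' five-year survival of US lung-cancer patients diagnosed in the
#' mid-2000s, with stage I additionally stratified by tumor size (bins
#' <=1, 1-2, 2-3, 3-5, >5 cm).
#'
#' @param curves Optional replacement tibble with columns `stage`,
#'   `size_min`, `size_max`, `cure`, `rate`.
#' @return Object of class `survival_curves`.
#' @export
survival_curves <- function(curves = NULL) {
  if (is.null(curves)) {
    five_year <- c(0.93, 0.88, 0.80, 0.70, 0.60, 0.52, 0.42, 0.28, 0.14, 0.05)
    cure <- c(0.90, 0.82, 0.72, 0.60, 0.50, 0.40, 0.32, 0.18, 0.07, 0.02)
    curves <- tibble(
      stage = c("IA", "IA", "IA", "IB", "IB", "IIA", "IIB", "IIIA", "IIIB", "IV"),
      size_min = c(0, 1, 2, 3, 5, rep(0, 5)),
      size_max = c(1, 2, 3, 5, Inf, rep(Inf, 5)),
      cure = cure,
      rate = -log((five_year - cure) / (1 - cure)) / 5
    )
  }
  stopifnot(all(curves$cure >= 0 & curves$cure < 1), all(curves$rate > 0))
  structure(list(table = curves), class = "survival_curves")
}

# curve row index per record; errors when a stage has no curve
match_curve <- function(stage, pts_cm, curves) {
  tb <- curves$table
  idx <- rep(NA_integer_, length(stage))
  for (i in seq_len(nrow(tb))) {
    hit <- is.na(idx) & stage == tb$stage[i] &
      pts_cm > tb$size_min[i] & pts_cm <= tb$size_max[i]
    idx[hit] <- i
  }
  # size 0 edge: fall into the first bin of the stage
  zero <- is.na(idx) & pts_cm == 0
  if (any(zero)) {
    first_bin <- match(stage[zero], tb$stage)
    idx[zero] <- first_bin
  }
  if (any(is.na(idx))) {
    abort(paste(
      "no survival curve for stage(s):",
      paste(unique(stage[is.na(idx)]), collapse = ", ")
    ))
  }
  idx
}

#' Evaluate a configured survival curve
#'
#' @param curves A [survival_curves()].
#' @param stage Stage group (scalar).
#' @param pts_cm Primary size in cm (scalar; picks the size bin for stage I).
#' @param t Times since diagnosis, years.
#' @return `S(t)` values.
#' @export
lc_survival_at <- function(curves, stage, pts_cm, t) {
  i <- match_curve(stage, pts_cm, curves)[1]
  tb <- curves$table
  tb$cure[i] + (1 - tb$cure[i]) * exp(-tb$rate[i] * t)
}

#' Sample years from diagnosis to lung-cancer death
#'
#' Inversion sampling from the stage/size-specific mixture-cure curve:
#' a uniform deviate `u` below the cure fraction means no lung-cancer death
#' (`Inf`); otherwise the survival time is `S^{-1}(u)`.
#'
#' @param records Tibble with `observed_stage` and `pts_cm`.
#' @param curves A [survival_curves()].
#' @param u Optional uniforms (one per record), e.g. shared across paired
#'   scenario arms; drawn from the RNG when `NULL`.
#' @return Numeric vector of years to LC death (`Inf` = cured).
#' @export
sample_lc_survival <- function(records, curves = survival_curves(), u = NULL) {
  n <- nrow(records)
  if (is.null(u)) u <- runif(n)
  idx <- match_curve(records$observed_stage, records$pts_cm, curves)
  tb <- curves$table
  cure <- tb$cure[idx]
  rate <- tb$rate[idx]
  # u at or below the cure fraction lands on log(0) = -Inf, i.e. no LC death
  -log(pmax(u - cure, 0) / (1 - cure)) / rate
}

#' Gompertz-Makeham life table for other-cause mortality
#'
#' All-cause (non-lung-cancer) mortality hazard
#' `h(x) = a + b * exp(g * x)` by sex, multiplied by a smoking-status rate
#' ratio (current and former smokers die of other causes — cardiovascular
#' disease, COPD, other cancers — substantially earlier than never-smokers).
#' Defaults give never-smoker life expectancies around 80, female above
#' male, and roughly an 8-year deficit for lifelong smokers. A
#' piecewise-constant hazard table (columns `age`, `sex`, `hazard`) can be
#' supplied instead of the parametric form; the rate ratios still apply.
#'
#' @param a Makeham constant (/year).
#' @param b,g Gompertz level and slope; `b` is sex-specific.
#' @param smoker_rr Named hazard multipliers for `current` and `former`
#'   smokers (never-smokers are the reference).
#' @param table Optional hazard table overriding the parametric form.
#' @return Object of class `life_table`.
#' @export
life_table <- function(a = 8e-4, b = c(M = 3.4e-5, F = 1.9e-5), g = 0.095,
                       smoker_rr = c(current = 2.2, former = 1.5),
                       table = NULL) {
  structure(list(a = a, b = b, g = g, smoker_rr = smoker_rr, table = table),
    class = "life_table"
  )
}

#' Sample ages at death from other causes
#'
#' Exact inversion of the Gompertz-Makeham cumulative hazard
#' `H(x) = a x + (b/g)(exp(g x) - 1)` via safeguarded Newton (or of the
#' step-function hazard when a table is supplied).
#'
#' @param sex Character vector (`"M"`/`"F"`).
#' @param lt A [life_table()].
#' @param smoking Optional smoking status per person (`"never"`,
#'   `"former"`, `"current"`); scales the hazard by `lt$smoker_rr`.
#' @return Ages at other-cause death, years.
#' @export
sample_other_cause_death <- function(sex, lt = life_table(), smoking = NULL) {
  n <- length(sex)
  E <- rexp(n)
  if (!is.null(smoking)) {
    rr <- c(never = 1, lt$smoker_rr)[smoking]
    E <- E / unname(rr)
  }
  if (!is.null(lt$table)) {
    return(sample_death_from_table(sex, E, lt$table))
  }
  b <- unname(lt$b[sex])
  a <- lt$a
  g <- lt$g
  H <- function(x) a * x + b / g * expm1(g * x)
  x <- rep(75, n)
  lo <- rep(0, n)
  hi <- rep(130, n)
  for (i in 1:60) {
    fx <- H(x) - E
    hi <- ifelse(fx > 0, pmin(hi, x), hi)
    lo <- ifelse(fx <= 0, pmax(lo, x), lo)
    xn <- x - fx / (a + b * exp(g * x))
    bad <- !is.finite(xn) | xn <= lo | xn >= hi
    x <- ifelse(bad, (lo + hi) / 2, xn)
  }
  x
}

# inversion under a piecewise-constant hazard table
sample_death_from_table <- function(sex, E, tab) {
  out <- numeric(length(sex))
  for (s in unique(sex)) {
    tb <- tab[tab$sex == s, ]
    tb <- tb[order(tb$age), ]
    width <- diff(c(tb$age, 130))
    cumH <- c(0, cumsum(tb$hazard * width))
    k <- sex == s
    j <- findInterval(E[k], cumH, rightmost.closed = TRUE)
    j <- pmin(j, nrow(tb))
    out[k] <- tb$age[j] + (E[k] - cumH[j]) / tb$hazard[j]
  }
  pmin(out, 130)
}

#' Resolve competing lung-cancer and other-cause death
#'
#' The earlier event wins; exact ties are attributed to lung cancer (a fixed
#' convention so the cause label is deterministic).
#'
#' @param lc_death_age Age at LC death (`Inf` when cured / never detected).
#' @param other_cause_age Age at other-cause death (finite).
#' @return Tibble `death_age`, `cause` (`"LC"` / `"other"`).
#' @export
resolve_death <- function(lc_death_age, other_cause_age) {
  if (any(!is.finite(lc_death_age) & !is.finite(other_cause_age))) {
    abort("life table must be proper: both death ages infinite")
  }
  lc_first <- lc_death_age <= other_cause_age
  tibble(
    death_age = pmin(lc_death_age, other_cause_age),
    cause = ifelse(lc_first, "LC", "other")
  )
}
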