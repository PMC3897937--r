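# Trial cohort simulator: masked 1:1:1:1 letter allocation, HIV strata,
# correlated morphometric measures via a Gaussian copula, pre/post biopsies
# and orientation-failure attrition. Treatment identity stays sealed behind
# the letter code until the database is locked and explicitly unblinded.

MEASURE_VARS <- c("VH", "CD", "VP", "VW", "VA")
LOGNORMAL_VARS <- c("VP", "VW")   # the rank-test-routed, skewed measures

#' Masked 1:1:1:1 randomisation
#'
#' Allocates participants to four letter codes balanced within one, with two
#' letters standing for active supplementation (MM) and two for placebo. The
#' letter-to-arm map is returned sealed; it can only be applied through
#' [unblind()] after the cohort database is locked.
#'
#' @param n number of participants (>= 1; >= 4 for every letter to appear).
#' @param seed integer seed for the allocation sequence.
#' @param letters the four allocation codes.
#' @return list with `allocation` (tibble: `id`, `letter`) and `code_map`
#'   (a `sealed_code_map`).
#' @export
randomize <- function(n, seed = NULL, letters = c("A", "B", "C", "D")) {
  if (!is.numeric(n) || n < 1) abort("n must be >= 1")
  stopifnot(length(letters) == 4)
  if (!is.null(seed)) set.seed(seed)
  base <- rep(letters, floor(n / 4))
  extra <- if (n %% 4 > 0) sample(letters, n %% 4) else character(0)
  alloc <- sample(c(base, extra))
  mm <- sample(letters, 2)
  map <- setNames(ifelse(letters %in% mm, "MM", "placebo"), letters)
  allocation <- tibble::tibble(id = sprintf("P%03d", seq_len(n)), letter = alloc)
  list(allocation = allocation, code_map = seal_code_map(map))
}

seal_code_map <- function(map) {
  env <- new.env(parent = emptyenv())
  env$map <- map
  structure(list(letters = names(map)), class = "sealed_code_map", env = env)
}

#' @export
print.sealed_code_map <- function(x, ...) {
  cat("<sealed code map>", length(x$letters),
      "letters; arm identities withheld until unblinding\n")
  invisible(x)
}

# only unblind() and the simulator (acting as the manufacturer) call this
reveal_arm <- function(code_map, letter) {
  stopifnot(inherits(code_map, "sealed_code_map"))
  map <- attr(code_map, "env")$map
  missing <- setdiff(unique(letter), names(map))
  if (length(missing)) {
    abort(sprintf("code map is missing letter(s): %s", paste(missing, collapse = ", ")))
  }
  unname(map[letter])
}

#' Effect specification for the cohort simulator
#'
#' Defines, per treatment arm and HIV stratum, the location of the five
#' morphometric measures, their spreads, and the Spearman correlation
#' structure among them. VH, CD and VA are simulated Gaussian; VP and VW
#' log-normal (their supplied locations are read as medians), so a
#' Shapiro-Wilk screen routes them to rank-based tests just as in the trial
#' being emulated. The default `"paper"` scenario reproduces the printed
#' HIV-negative contrasts and a null HIV-positive stratum; `"null"` removes
#' all arm effects.
#'
#' @param scenario `"paper"` or `"null"`.
#' @param n_per_letter participants per allocation letter (default 13, i.e.
#'   26 per arm).
#' @param attrition_rate probability a biopsy fails the orientation screen
#'   (default 14/52, the trial-level loss).
#' @param p_hiv probability a participant is HIV positive (default 15/38).
#' @param p_post probability a post-vaccination biopsy is also available
#'   (default 14/38).
#' @param vaccination_effect additive shift applied to post-vaccination
#'   records (single number or named per-variable vector; default 0 — the
#'   vaccine had no measurable morphometric effect).
#' @param subject_rho within-subject correlation of the latent Gaussian
#'   between pre and post records.
#' @param means,sds,spearman optional overrides: `means` a named list
#'   `[[hiv]][[arm]]` of 5-vectors (VH, CD, VP, VW, VA), `sds` a 5-vector,
#'   `spearman` a named list `[[hiv]]` of 5x5 Spearman target matrices.
#' @param seed default master seed carried in the spec.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(scenario = c("paper", "null"),
                        n_per_letter = 13,
                        attrition_rate = 14 / 52,
                        p_hiv = 15 / 38,
                        p_post = 14 / 38,
                        vaccination_effect = 0,
                        subject_rho = 0.5,
                        means = NULL, sds = NULL, spearman = NULL,
                        seed = 1L) {
  scenario <- match.arg(scenario)
  # placebo-arm locations: printed placebo means/medians; CD set so that the
  # printed V:C ratios are reproduced (236.6/1.56 and 293.3/1.83)
  placebo <- c(VH = 236.6, CD = 151.7, VP = 273.7, VW = 110, VA = 21650)
  mm <- c(VH = 293.3, CD = 160.3, VP = 355.0, VW = 110, VA = 27623)
  if (is.null(means)) {
    means <- if (scenario == "paper") {
      list(negative = list(MM = mm, placebo = placebo),
           positive = list(MM = placebo, placebo = placebo))
    } else {
      list(negative = list(MM = placebo, placebo = placebo),
           positive = list(MM = placebo, placebo = placebo))
    }
  }
  # only the VH SD (36.3) is printed; the rest are calibrated once to the
  # printed confidence intervals and exposed here
  if (is.null(sds)) sds <- c(VH = 36.3, CD = 30, VP = 80, VW = 25, VA = 6000)
  if (is.null(spearman)) {
    spearman <- list(
      negative = spearman_target_matrix(c(
        0.18, 0.715, 0.424, 0.732, 0.18, -0.11, 0.17, 0.14, 0.796, 0.426)),
      positive = spearman_target_matrix(c(
        0.254, 0.514, 0.182, 0.511, -0.236, 0.182, -0.154, -0.268, 0.882, 0.093))
    )
  }
  spec <- structure(list(
    scenario = scenario, n_per_letter = as.integer(n_per_letter),
    attrition_rate = attrition_rate, p_hiv = p_hiv, p_post = p_post,
    vaccination_effect = vaccination_effect, subject_rho = subject_rho,
    means = means, sds = sds, spearman = spearman, seed = as.integer(seed)
  ), class = "effect_spec")
  validate_effect_spec(spec)
  spec
}

# build a symmetric unit-diagonal matrix from the 10 lower-triangle values
# in the order (CD,VH) (VP,VH) (VW,VH) (VA,VH) (VP,CD) (VW,CD) (VA,CD)
# (VW,VP) (VA,VP) (VA,VW)
spearman_target_matrix <- function(lower) {
  stopifnot(length(lower) == 10)
  m <- diag(5)
  m[lower.tri(m)] <- lower
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  dimnames(m) <- list(MEASURE_VARS, MEASURE_VARS)
  m
}

validate_effect_spec <- function(spec) {
  if (spec$attrition_rate < 0 || spec$attrition_rate >= 1) {
    abort("attrition_rate must be in [0, 1)")
  }
  if (any(spec$sds <= 0)) abort("all SDs must be positive")
  for (hiv in names(spec$spearman)) {
    m <- spec$spearman[[hiv]]
    if (!isSymmetric(unname(m)) || any(diag(m) != 1)) {
      abort(sprintf("spearman matrix '%s' must be symmetric with unit diagonal", hiv))
    }
    ev <- eigen(spearman_to_pearson(m), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      abort(sprintf("spearman matrix '%s' maps to a non-positive-definite copula correlation", hiv))
    }
  }
  invisible(spec)
}

# Gaussian-copula conversion: Pearson correlation of the latent normals that
# induces the requested Spearman rank correlation
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

# draw n correlated 5-vectors for one (hiv, arm) stratum; returns a list of
# the latent z matrix and the measure tibble, so pre/post pairs can share z
draw_stratum <- function(spec, hiv, arm, n, z = NULL) {
  R <- spearman_to_pearson(spec$spearman[[hiv]])
  if (is.null(z)) {
    z <- matrix(rnorm(n * 5), nrow = n) %*% chol(R)
  }
  mu <- spec$means[[hiv]][[arm]][MEASURE_VARS]
  sdv <- spec$sds[MEASURE_VARS]
  vals <- sapply(MEASURE_VARS, function(v) {
    j <- match(v, MEASURE_VARS)
    if (v %in% LOGNORMAL_VARS) {
      sdlog <- sqrt(log1p((sdv[v] / mu[v])^2))
      exp(log(mu[v]) + sdlog * z[, j])
    } else {
      mu[v] + sdv[v] * z[, j]
    }
  })
  vals <- matrix(vals, nrow = n, dimnames = list(NULL, MEASURE_VARS))
  list(z = z, values = tibble::as_tibble(vals))
}

#' Simulate a masked randomised cohort
#'
#' Draws a full cohort under an [effect_spec()]: masked letter allocation,
#' HIV status assigned after randomisation, one pre-vaccination morphometry
#' record per participant (plus a correlated post-vaccination record for a
#' subset), and orientation-failure attrition. Treatment arm is never a
#' column of the returned table; it is recoverable only through
#' [unblind()] with the sealed code map after [lock_cohort()].
#'
#' @param spec an [effect_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return list with `cohort` (tibble: `id`, `letter`, `hiv`, `age`, `sex`,
#'   `bmi`, `timepoint`, the five measures, `adequate`), `code_map`
#'   (sealed), and `truth` (the generating spec).
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  validate_effect_spec(spec)
  seed <- if (is.null(seed)) spec$seed else as.integer(seed)
  n <- 4L * spec$n_per_letter
  rz <- randomize(n, seed = seed)
  alloc <- rz$allocation
  arm <- reveal_arm(rz$code_map, alloc$letter)  # manufacturer-side knowledge

  hiv <- ifelse(rbinom(n, 1, spec$p_hiv) == 1, "positive", "negative")
  age <- round(pmin(60, pmax(18, rnorm(n, 39, 11))))
  sex <- ifelse(rbinom(n, 1, 0.7) == 1, "male", "female")
  bmi <- round(pmax(15, rnorm(n, 23.8, 5)), 1)
  has_post <- runif(n) < spec$p_post

  shift <- vaccination_shift(spec$vaccination_effect)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pre <- draw_stratum(spec, hiv[i], arm[i], 1)
    rec_pre <- pre$values
    rec <- dplyr::bind_cols(
      tibble::tibble(id = alloc$id[i], letter = alloc$letter[i], hiv = hiv[i],
                     age = age[i], sex = sex[i], bmi = bmi[i],
                     timepoint = "pre"),
      rec_pre,
      tibble::tibble(adequate = runif(1) >= spec$attrition_rate)
    )
    if (has_post[i]) {
      eps <- matrix(rnorm(5), nrow = 1) %*% chol(spearman_to_pearson(spec$spearman[[hiv[i]]]))
      z_post <- spec$subject_rho * pre$z + sqrt(1 - spec$subject_rho^2) * eps
      rec_post_vals <- draw_stratum(spec, hiv[i], arm[i], 1, z = z_post)$values
      rec_post_vals <- rec_post_vals + shift[rep(1, 1), , drop = FALSE]
      rec_post <- dplyr::bind_cols(
        tibble::tibble(id = alloc$id[i], letter = alloc$letter[i], hiv = hiv[i],
                       age = age[i], sex = sex[i], bmi = bmi[i],
                       timepoint = "post"),
        rec_post_vals,
        tibble::tibble(adequate = runif(1) >= spec$attrition_rate)
      )
      rec <- dplyr::bind_rows(rec, rec_post)
    }
    rows[[i]] <- rec
  }
  cohort <- dplyr::bind_rows(rows)
  attr(cohort, "locked") <- FALSE
  attr(cohort, "audit") <- sprintf("simulated cohort: n=%d, seed=%d", n, seed)
  class(cohort) <- c("villi_cohort", class(cohort))
  list(cohort = cohort, code_map = rz$code_map, truth = spec)
}

#' Draw one stratum of correlated morphometric measures
#'
#' Samples `n` participants' measure vectors from the multivariate model of
#' a single (HIV status, arm) stratum — the building block of
#' [simulate_cohort()], exposed for calibration and power studies.
#'
#' @inheritParams simulate_cohort
#' @param hiv `"negative"` or `"positive"`.
#' @param arm `"MM"` or `"placebo"`.
#' @param n number of draws.
#' @param seed optional seed.
#' @return tibble with columns `VH`, `CD`, `VP`, `VW`, `VA`.
#' @export
simulate_stratum <- function(spec, hiv, arm, n, seed = NULL) {
  validate_effect_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  draw_stratum(spec, hiv, arm, n)$values
}

vaccination_shift <- function(effect) {
  shift <- setNames(rep(0, 5), MEASURE_VARS)
  if (length(effect) == 1 && is.null(names(effect))) {
    shift[] <- effect
  } else {
    shift[names(effect)] <- effect
  }
  matrix(shift, nrow = 1, dimnames = list(NULL, MEASURE_VARS))
}

#' Lock the cohort database
#'
#' Marks morphometry as complete; unblinding is refused before this step.
#' @param cohort a `villi_cohort`.
#' @export
lock_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "villi_cohort"))
  attr(cohort, "locked") <- TRUE
  attr(cohort, "audit") <- c(attr(cohort, "audit"), "database locked")
  cohort
}

#' Unblind a locked cohort
#'
#' Applies the sealed letter-to-arm map, attaching an `arm` column. Refused
#' with an explicit error if the database has not been locked.
#'
#' @param cohort a locked `villi_cohort`.
#' @param code_map the `sealed_code_map` from [randomize()].
#' @export
unblind <- function(cohort, code_map) {
  stopifnot(inherits(cohort, "villi_cohort"))
  if (!isTRUE(attr(cohort, "locked"))) {
    abort("refusing to unblind: cohort database is not locked (run lock_cohort() once morphometry is complete)")
  }
  out <- dplyr::mutate(cohort, arm = reveal_arm(code_map, .data$letter))
  attr(out, "locked") <- TRUE
  attr(out, "audit") <- c(attr(cohort, "audit"), "unblinded with sealed code map")
  class(out) <- unique(c("villi_cohort", class(out)))
  out
}
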