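# Trial statistics: Shapiro-Wilk-routed group comparisons with confidence
# intervals, paired pre/post tests, Spearman matrices, Fisher's exact 2x2,
# percent differences, villous:crypt ratios, intention-to-treat routing and
# conservative pre/post dataset selection. Standard tests are delegated to
# base stats; this module owns the routing, estimates and presentation.

#' Shapiro-Wilk normality screen
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @param alpha routing level (default 0.05).
#' @return one-row tibble: `W`, `p_value`, `is_normal`.
#' @export
shapiro_wilk <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000) {
    abort("shapiro_wilk needs 3 <= n <= 5000 non-missing values")
  }
  if (sd(values) == 0) {
    abort("shapiro_wilk: all values identical; W undefined")
  }
  ht <- shapiro.test(values)
  tibble::tibble(W = unname(ht$statistic), p_value = ht$p.value,
                 is_normal = ht$p.value >= alpha)
}

#' Two-sample t test with CI of the mean difference
#'
#' Pooled-variance Student's t by default (Welch switchable). Accepts raw
#' vectors or `c(mean=, sd=, n=)` summaries, so printed group summaries can
#' be re-analysed directly.
#'
#' @param x,y numeric vectors, or named vectors/lists with `mean`, `sd`, `n`.
#' @param welch use the Welch unequal-variance form.
#' @param conf confidence level (default 0.95).
#' @return one-row tibble: `estimate` (mean of `x` minus mean of `y`),
#'   `ci_low`, `ci_high`, `statistic`, `df`, `p_value`, `n1`, `n2`, `method`.
#' @export
two_sample_t <- function(x, y, welch = FALSE, conf = 0.95) {
  sx <- summarize_group(x); sy <- summarize_group(y)
  if (sx$n < 2 || sy$n < 2) abort("each group needs n >= 2")
  if (welch) {
    se2x <- sx$sd^2 / sx$n; se2y <- sy$sd^2 / sy$n
    se <- sqrt(se2x + se2y)
    if (se == 0) abort("zero variance in both groups; t undefined")
    df <- (se2x + se2y)^2 / (se2x^2 / (sx$n - 1) + se2y^2 / (sy$n - 1))
    method <- "Welch two-sample t"
  } else {
    sp2 <- ((sx$n - 1) * sx$sd^2 + (sy$n - 1) * sy$sd^2) / (sx$n + sy$n - 2)
    if (sp2 == 0) abort("zero pooled variance; t undefined")
    se <- sqrt(sp2 * (1 / sx$n + 1 / sy$n))
    df <- sx$n + sy$n - 2
    method <- "pooled two-sample t"
  }
  est <- sx$mean - sy$mean
  tstat <- est / se
  tcrit <- qt(1 - (1 - conf) / 2, df)
  tibble::tibble(
    estimate = est, ci_low = est - tcrit * se, ci_high = est + tcrit * se,
    statistic = tstat, df = df, p_value = 2 * pt(-abs(tstat), df),
    n1 = sx$n, n2 = sy$n, method = method
  )
}

summarize_group <- function(g) {
  if (!is.null(names(g)) && all(c("mean", "sd", "n") %in% names(g))) {
    list(mean = unname(g[["mean"]]), sd = unname(g[["sd"]]), n = unname(g[["n"]]))
  } else {
    g <- as.numeric(g[!is.na(g)])
    list(mean = mean(g), sd = sd(g), n = length(g))
  }
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with a chi-square p on k - 1 degrees of freedom. When
#' every value is tied across all groups the test carries no information and
#' H = 0, p = 1 is reported rather than an error.
#'
#' @param groups list of numeric vectors (>= 2 groups, total n >= 3).
#' @return one-row tibble: `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (any(lengths(groups) < 1) || sum(lengths(groups)) < 3) {
    abort("kruskal_wallis needs each group nonempty and total n >= 3")
  }
  values <- unlist(groups)
  if (length(unique(values)) == 1) {
    return(tibble::tibble(statistic = 0, df = length(groups) - 1, p_value = 1))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- kruskal.test(values, g)
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Hodges-Lehmann median difference with a rank-based CI
#'
#' Point estimate: the median of all pairwise differences `a_i - b_j`. The
#' confidence interval inverts the Mann-Whitney test at the requested level
#' (the standard interval to accompany a printed "median difference").
#'
#' @param a,b numeric vectors (nonempty).
#' @param conf confidence level.
#' @return one-row tibble: `estimate`, `ci_low`, `ci_high`, `n1`, `n2`.
#' @export
median_difference <- function(a, b, conf = 0.95) {
  a <- as.numeric(a[!is.na(a)]); b <- as.numeric(b[!is.na(b)])
  if (!length(a) || !length(b)) abort("both groups must be nonempty")
  est <- median(as.vector(outer(a, b, "-")))
  ci <- c(NA_real_, NA_real_)
  if (length(a) >= 2 && length(b) >= 2) {
    wt <- suppressWarnings(wilcox.test(a, b, conf.int = TRUE, conf.level = conf))
    ci <- as.numeric(wt$conf.int)
  }
  tibble::tibble(estimate = est, ci_low = ci[1], ci_high = ci[2],
                 n1 = length(a), n2 = length(b))
}

#' Paired pre/post comparisons: paired t and Wilcoxon signed rank
#'
#' Returns both tests on the same pairs. Zero differences are dropped for
#' the signed-rank test by default (`zero_method = "wilcoxon"`); `"pratt"`
#' keeps them in the ranking. A constant difference of zero yields p = 1
#' for both tests rather than an error.
#'
#' @param pre,post equal-length paired vectors.
#' @param zero_method `"wilcoxon"` (drop zeros) or `"pratt"`.
#' @return tibble with one row per test: `test`, `estimate`
#'   (post minus pre: mean difference / pseudomedian), `statistic`,
#'   `p_value`, `n`.
#' @export
paired_tests <- function(pre, post, zero_method = c("wilcoxon", "pratt")) {
  zero_method <- match.arg(zero_method)
  stopifnot(length(pre) == length(post))
  ok <- complete.cases(pre, post)
  d <- post[ok] - pre[ok]
  if (length(d) < 2) abort("paired_tests needs at least 2 complete pairs")

  if (sd(d) == 0) {
    t_row <- tibble::tibble(test = "paired t", estimate = mean(d),
                            statistic = NA_real_, p_value = 1, n = length(d))
  } else {
    ht <- t.test(d)
    t_row <- tibble::tibble(test = "paired t", estimate = mean(d),
                            statistic = unname(ht$statistic),
                            p_value = ht$p.value, n = length(d))
  }

  dz <- if (zero_method == "wilcoxon") d[d != 0] else d
  if (!length(dz) || all(dz == 0)) {
    w_row <- tibble::tibble(test = "Wilcoxon signed rank", estimate = 0,
                            statistic = NA_real_, p_value = 1, n = length(d))
  } else {
    wt <- suppressWarnings(wilcox.test(dz, conf.int = TRUE))
    w_row <- tibble::tibble(test = "Wilcoxon signed rank",
                            estimate = unname(wt$estimate),
                            statistic = unname(wt$statistic),
                            p_value = wt$p.value, n = length(d))
  }
  dplyr::bind_rows(t_row, w_row)
}

#' Spearman correlation matrix with significance flags
#'
#' Pairwise Spearman rho over the five morphometric measures with two-sided
#' significance flags (`*` p < 0.05, `**` p < 0.01). Constant variables get
#' `NA` correlations flagged `"na"`.
#'
#' @param records data frame containing the measure columns.
#' @param vars measure columns to correlate.
#' @return object of class `villi_corr`: list with `rho`, `p`, `flags`, `n`;
#'   `tidy()` gives the long lower-triangular form.
#' @export
spearman_matrix <- function(records, vars = MEASURE_VARS) {
  dat <- as.data.frame(records)[, vars, drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 4) abort("spearman_matrix needs >= 4 complete records")
  k <- length(vars)
  rho <- diag(k); pmat <- matrix(NA_real_, k, k)
  dimnames(rho) <- dimnames(pmat) <- list(vars, vars)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      xi <- dat[[vars[i]]]; xj <- dat[[vars[j]]]
      if (sd(xi) == 0 || sd(xj) == 0) {
        rho[i, j] <- rho[j, i] <- NA_real_
        next
      }
      ct <- suppressWarnings(cor.test(xi, xj, method = "spearman"))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pmat[i, j] <- pmat[j, i] <- ct$p.value
    }
  }
  flags <- matrix("", k, k, dimnames = dimnames(rho))
  flags[!is.na(pmat) & pmat < 0.05] <- "*"
  flags[!is.na(pmat) & pmat < 0.01] <- "**"
  flags[is.na(rho) & row(rho) != col(rho)] <- "na"
  structure(list(rho = rho, p = pmat, flags = flags, n = nrow(dat)),
            class = "villi_corr")
}

#' @export
print.villi_corr <- function(x, digits = 3, ...) {
  k <- ncol(x$rho)
  out <- matrix("", k, k, dimnames = dimnames(x$rho))
  for (i in seq_len(k)) for (j in seq_len(i)) {
    out[i, j] <- paste0(formatC(x$rho[i, j], format = "f", digits = digits),
                        x$flags[i, j])
  }
  cat("Spearman correlations (n =", x$n, "); * p<0.05, ** p<0.01\n")
  print(out, quote = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @exportS3Method generics::tidy
tidy.villi_corr <- function(x, ...) {
  k <- ncol(x$rho); vars <- colnames(x$rho)
  idx <- which(lower.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(
    var1 = vars[idx[, 2]], var2 = vars[idx[, 1]],
    rho = x$rho[idx], p_value = x$p[idx], flag = x$flags[idx]
  )
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by summing hypergeometric probabilities no larger than the
#' observed table's. An empty margin makes every table certain, so p = 1.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return one-row tibble: `p_value`, `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    abort("fisher_exact_2x2 needs a 2x2 table of nonnegative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(tibble::tibble(p_value = 1, odds_ratio = NA_real_))
  }
  ht <- fisher.test(tab)
  tibble::tibble(p_value = ht$p.value, odds_ratio = unname(ht$estimate))
}

#' Percent difference of a treated value over a control value
#'
#' `(treated - control) / control * 100`. Note the asymmetry: swapping the
#' roles does not negate the result except at zero difference.
#'
#' @param treated,control single numeric values; `control` must be nonzero.
#' @return percent difference (full precision; round at presentation).
#' @export
percent_difference <- function(treated, control) {
  if (!is.numeric(control) || any(control == 0)) {
    abort("percent_difference: control must be nonzero")
  }
  (treated - control) / control * 100
}

#' Villous:crypt ratios with a group comparison
#'
#' Computes the per-patient VH/CD ratio and compares arms with the
#' two-sample t test. Patients with zero crypt depth are excluded with a
#' warning.
#'
#' @param data data frame with columns `VH`, `CD` and `arm` (MM / placebo).
#' @param welch passed to [two_sample_t()].
#' @return list with `ratios` (tibble: `arm`, `vc_ratio`) and `comparison`
#'   (the [two_sample_t()] row for MM minus placebo).
#' @export
vc_ratio <- function(data, welch = FALSE) {
  stopifnot(all(c("VH", "CD", "arm") %in% names(data)))
  bad <- !is.na(data$CD) & data$CD == 0
  if (any(bad)) {
    warn(sprintf("excluding %d patient(s) with zero crypt depth", sum(bad)))
    data <- data[!bad, , drop = FALSE]
  }
  ratios <- tibble::tibble(arm = data$arm, vc_ratio = data$VH / data$CD)
  cmp <- two_sample_t(ratios$vc_ratio[ratios$arm == "MM"],
                      ratios$vc_ratio[ratios$arm == "placebo"], welch = welch)
  list(ratios = ratios, comparison = cmp)
}

#' Normality-routed intention-to-treat comparisons
#'
#' For each HIV stratum and measure, screens normality with Shapiro-Wilk on
#' arm-centred residuals and routes to the pooled t test (normal) or to
#' Kruskal-Wallis with a Hodges-Lehmann median-difference interval
#' (non-normal). All randomised participants with adequate sections are
#' analysed in their assigned arm; no multiplicity adjustment is applied by
#' default (a Holm option exists).
#'
#' @param cohort an unblinded `villi_cohort` (must carry an `arm` column).
#' @param vars measures to compare.
#' @param timepoint which records to analyse (`"pre"` or `"post"`).
#' @param alpha routing level for the normality screen.
#' @param welch use Welch instead of pooled t on the parametric route.
#' @param holm apply a Holm correction across the comparisons of a stratum.
#' @return object of class `villi_analysis`: a tibble of comparisons
#'   (`stratum`, `variable`, `test`, `estimate`, `ci_low`, `ci_high`,
#'   `statistic`, `p_value`, `group1_stat`, `group2_stat`, `n_mm`,
#'   `n_placebo`, `note`) with routing metadata; see [tidy.villi_analysis()].
#' @export
route_and_compare <- function(cohort, vars = MEASURE_VARS, timepoint = "pre",
                              alpha = 0.05, welch = FALSE, holm = FALSE) {
  if (!"arm" %in% names(cohort)) {
    abort("cohort carries no 'arm' column; unblind() it first")
  }
  dat <- dplyr::filter(as.data.frame(cohort),
                       .data$timepoint == !!timepoint, .data$adequate)
  rows <- list()
  for (stratum in c("negative", "positive")) {
    sdat <- dat[dat$hiv == stratum, , drop = FALSE]
    mm <- sdat[sdat$arm == "MM", , drop = FALSE]
    pl <- sdat[sdat$arm == "placebo", , drop = FALSE]
    if (nrow(mm) < 2 || nrow(pl) < 2) {
      inform(sprintf("stratum '%s': fewer than 2 per arm; comparisons skipped", stratum))
      next
    }
    for (v in vars) {
      a <- mm[[v]]; b <- pl[[v]]
      resid <- c(a - mean(a), b - mean(b))
      normal <- tryCatch(shapiro_wilk(resid, alpha = alpha)$is_normal,
                         error = function(e) FALSE)
      if (normal) {
        tt <- two_sample_t(a, b, welch = welch)
        rows[[length(rows) + 1]] <- tibble::tibble(
          stratum = stratum, variable = v,
          test = if (welch) "Welch t" else "2-tailed t",
          routed_normal = TRUE,
          estimate = tt$estimate, ci_low = tt$ci_low, ci_high = tt$ci_high,
          statistic = tt$statistic, p_value = tt$p_value,
          group1_stat = mean(a), group2_stat = mean(b),
          n_mm = length(a), n_placebo = length(b), note = ""
        )
      } else {
        kw <- kruskal_wallis(list(a, b))
        md <- median_difference(a, b)
        rows[[length(rows) + 1]] <- tibble::tibble(
          stratum = stratum, variable = v, test = "Kruskal-Wallis",
          routed_normal = FALSE,
          estimate = md$estimate, ci_low = md$ci_low, ci_high = md$ci_high,
          statistic = kw$statistic, p_value = kw$p_value,
          group1_stat = median(a), group2_stat = median(b),
          n_mm = length(a), n_placebo = length(b), note = ""
        )
      }
    }
  }
  res <- dplyr::bind_rows(rows)
  if (holm && nrow(res)) {
    res <- res |>
      dplyr::group_by(.data$stratum) |>
      dplyr::mutate(p_adjusted = stats::p.adjust(.data$p_value, "holm")) |>
      dplyr::ungroup()
  }
  structure(res, class = c("villi_analysis", class(res)),
            timepoint = timepoint, alpha = alpha, welch = welch, holm = holm)
}

#' @exportS3Method generics::tidy
tidy.villi_analysis <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @importFrom generics glance
#' @exportS3Method generics::glance
glance.villi_analysis <- function(x, ...) {
  tibble::tibble(
    timepoint = attr(x, "timepoint"),
    n_comparisons = nrow(x),
    n_significant = sum(x$p_value < attr(x, "alpha"), na.rm = TRUE),
    n_parametric = sum(x$routed_normal),
    alpha = attr(x, "alpha")
  )
}

#' Conservative pre/post dataset selection
#'
#' When both pre- and post-vaccination result sets exist, selects the whole
#' dataset whose effect on the pre-registered primary variable (villous
#' height) has the larger p-value — en bloc, never per variable. Ties (or
#' identical sets) resolve to the pre-vaccination dataset.
#'
#' @param results_pre,results_post `villi_analysis` objects over identical
#'   (stratum, variable) comparison sets.
#' @param primary primary variable (default `"VH"`).
#' @param primary_stratum stratum carrying the primary comparison (default
#'   `"negative"`, falling back to the first available).
#' @return the chosen `villi_analysis`, with attribute `dataset` set to
#'   `"pre"` or `"post"`.
#' @export
select_conservative <- function(results_pre, results_post, primary = "VH",
                                primary_stratum = "negative") {
  key <- function(r) paste(r$stratum, r$variable)
  if (!setequal(key(results_pre), key(results_post))) {
    abort("pre and post result sets cover different comparisons")
  }
  pick <- function(r) {
    hit <- r[r$variable == primary & r$stratum == primary_stratum, ]
    if (!nrow(hit)) hit <- r[r$variable == primary, ][1, ]
    if (!nrow(hit) || is.na(hit$p_value[1])) abort(sprintf("no '%s' comparison found", primary))
    hit$p_value[1]
  }
  chosen <- if (pick(results_post) > pick(results_pre)) "post" else "pre"
  out <- if (chosen == "pre") results_pre else results_post
  attr(out, "dataset") <- chosen
  out
}
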