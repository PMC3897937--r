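test_that("Shapiro-Wilk screen is calibrated and detects log-normal skew", {
  normal_ok <- vapply(1:100, function(s) {
    set.seed(s); shapiro_wilk(rnorm(500))$is_normal
  }, logical(1))
  expect_gte(mean(normal_ok), 0.90)
  lognormal_flagged <- vapply(1:100, function(s) {
    set.seed(s); !shapiro_wilk(rlnorm(500, 0, 1))$is_normal
  }, logical(1))
  expect_gte(mean(lognormal_flagged), 0.99)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(1, 10)), "identical")
})

test_that("pooled t from printed summaries reproduces the baseline-table p", {
  # age: mean (SD) 41.8 (10.5) n=20 vs 35.8 (11.0) n=18 prints as P = 0.1
  tt <- two_sample_t(c(mean = 41.8, sd = 10.5, n = 20),
                     c(mean = 35.8, sd = 11.0, n = 18))
  expect_equal(round(tt$p_value, 1), 0.1)
  expect_equal(tt$estimate, 6, tolerance = 1e-9)
})

test_that("two-sample t matches the hand-computed CI and degenerates sanely", {
  a <- c(1, 4, 6); b <- c(2, 3, 9)
  tt <- two_sample_t(a, b)
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  se <- sp * sqrt(2 / 3)
  expect_equal(tt$ci_low, mean(a) - mean(b) - qt(0.975, 4) * se)
  expect_equal(tt$ci_high, mean(a) - mean(b) + qt(0.975, 4) * se)
  expect_equal(tt$p_value, t.test(a, b, var.equal = TRUE)$p.value)
  # identical groups: zero estimate, p = 1
  tt0 <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt0$estimate, 0)
  expect_equal(tt0$p_value, 1)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "pooled variance")
  # the 95% CI excludes 0 exactly when p < 0.05
  set.seed(20)
  for (i in 1:25) {
    x <- rnorm(8); y <- rnorm(7, mean = runif(1, 0, 2))
    r <- two_sample_t(x, y)
    expect_identical(r$ci_low > 0 || r$ci_high < 0, r$p_value < 0.05)
  }
})

test_that("Kruskal-Wallis H matches the exhaustive rank computation", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # closed form on ranks 1..6 with group rank-sums 6 and 15
  expect_equal(kw$statistic, 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7)
  expect_equal(kw$df, 1)
  # identical groups: H = 0; all values tied: p = 1 not an error
  expect_equal(kruskal_wallis(list(c(1, 2), c(1, 2)))$statistic, 0,
               tolerance = 1e-12)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$p_value, 1)
  # k = 2 agrees with the Mann-Whitney normal approximation
  set.seed(4)
  a <- rnorm(12); b <- rnorm(10, 1)
  kw2 <- kruskal_wallis(list(a, b))
  mw <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(kw2$p_value, mw$p.value, tolerance = 1e-9)
})

test_that("Hodges-Lehmann equals the brute-force pairwise median", {
  md <- median_difference(c(1, 2, 3), c(0))
  expect_equal(md$estimate, 2)
  # shift equivariance
  b <- c(1.2, 5.7, 9.1, 3.3)
  md2 <- median_difference(b + 4.5, b)
  expect_equal(md2$estimate, 4.5)
  # random small inputs against a double-loop oracle
  set.seed(8)
  for (i in 1:20) {
    n <- sample(2:20, 1); m <- sample(2:20, 1)
    a <- sample(-50:50, n, replace = TRUE)
    bb <- sample(-50:50, m, replace = TRUE)
    diffs <- numeric(0)
    for (x in a) for (y in bb) diffs <- c(diffs, x - y)
    expect_equal(median_difference(a, bb)$estimate, median(diffs))
  }
  expect_error(median_difference(numeric(0), 1), "nonempty")
})

test_that("Wilcoxon signed rank p matches exhaustive sign-flip enumeration", {
  d <- c(3, -1, 6, 2, -4, 5)
  pt <- paired_tests(rep(0, 6), d)
  r <- rank(abs(d)); v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  venum <- as.vector(signs %*% r)
  p_enum <- min(1, 2 * min(mean(venum <= v_obs), mean(venum >= v_obs)))
  expect_equal(pt$p_value[pt$test == "Wilcoxon signed rank"], p_enum)
  # identical pre/post: both tests report p = 1, no error
  pt0 <- paired_tests(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pt0$p_value, c(1, 1))
})

test_that("Spearman matrix matches the closed-form rank formula and flags ties", {
  rec <- data.frame(VH = c(1, 2, 3, 4, 5), CD = c(2, 1, 4, 3, 5),
                    VP = c(1, 2, 3, 4, 5)^3, VW = c(5, 4, 3, 2, 1),
                    VA = c(2, 3, 4, 5, 6))
  sm <- spearman_matrix(rec)
  # no ties: rho = 1 - 6 sum(d^2) / (n(n^2-1)); d^2 sums to 4 for VH vs CD
  expect_equal(sm$rho["VH", "CD"], 1 - 6 * 4 / (5 * 24))
  # strictly monotone transform: perfect rank correlation
  expect_equal(sm$rho["VH", "VP"], 1)
  expect_equal(sm$rho["VH", "VW"], -1)
  expect_equal(sm$rho["VH", "VA"], 1)
  # constant variable flagged, not an error
  rec$VW <- 1
  sm2 <- spearman_matrix(rec)
  expect_true(is.na(sm2$rho["VH", "VW"]))
  expect_equal(sm2$flags["VH", "VW"], "na")
  expect_error(spearman_matrix(rec[1:3, ]), ">= 4")
  td <- generics::tidy(sm)
  expect_equal(nrow(td), 10)
})

test_that("simulator correlation targets are recovered through spearman_matrix", {
  spec <- effect_spec()
  x <- simulate_stratum(spec, "negative", "placebo", 10000, seed = 12)
  sm <- spearman_matrix(x)
  expect_equal(sm$rho["VP", "VA"], 0.796, tolerance = 0.05)
  expect_equal(sm$rho["VH", "VP"], 0.715, tolerance = 0.07)
})

test_that("Fisher's exact test reproduces printed 2x2 results and symmetries", {
  # HIV prevalence 9/20 v. 6/18 and sex split 16:4 v. 11:7
  expect_equal(round(fisher_exact_2x2(rbind(c(9, 11), c(6, 12)))$p_value, 2), 0.52)
  # exhaustive hypergeometric enumeration oracle for the sex table; the
  # two-sided exact p is 0.2877 (printed as 0.28, a truncation)
  tab <- rbind(c(16, 4), c(11, 7))
  enum_p <- local({
    n1 <- 20; n2 <- 18; k <- 27   # margins: row sums and first-column sum
    a_all <- max(0, k - n2):min(n1, k)
    probs <- dhyper(a_all, n1, n2, k)
    sum(probs[probs <= dhyper(16, n1, n2, k) * (1 + 1e-7)])
  })
  p_sex <- fisher_exact_2x2(tab)$p_value
  expect_equal(p_sex, enum_p, tolerance = 1e-9)
  expect_lt(abs(p_sex - 0.28), 0.01)
  expect_equal(fisher_exact_2x2(rbind(c(1, 0), c(0, 1)))$p_value, 1)
  # invariances: transpose and row/column swaps
  tab <- rbind(c(7, 3), c(2, 9))
  p <- fisher_exact_2x2(tab)$p_value
  expect_equal(fisher_exact_2x2(t(tab))$p_value, p)
  expect_equal(fisher_exact_2x2(tab[2:1, ])$p_value, p)
  expect_equal(fisher_exact_2x2(tab[, 2:1])$p_value, p)
  # empty margin: every table is certain
  expect_equal(fisher_exact_2x2(rbind(c(0, 0), c(3, 4)))$p_value, 1)
  expect_error(fisher_exact_2x2(rbind(c(1.5, 2), c(3, 4))), "integer")
})

test_that("percent difference reproduces the printed contrasts and asymmetry", {
  expect_equal(round(percent_difference(293.3, 236.6), 1), 24.0)
  expect_equal(round(percent_difference(27623, 21650), 1), 27.6)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(1, 0), "nonzero")
  # asymmetry: the reverse direction is not the negation except at zero
  p1 <- percent_difference(120, 100); p2 <- percent_difference(100, 120)
  expect_false(isTRUE(all.equal(p1, -p2)))
  expect_equal(percent_difference(7, 7), -percent_difference(7, 7))
})

test_that("V:C ratios reproduce the printed magnitudes and compare arms", {
  expect_equal(round(293.3 / 160.3, 2), 1.83)
  dat <- data.frame(VH = c(293, 300, 280, 237, 230, 240),
                    CD = c(160, 158, 162, 152, 150, 154),
                    arm = rep(c("MM", "placebo"), each = 3))
  vc <- vc_ratio(dat)
  expect_equal(nrow(vc$ratios), 6)
  expect_gt(mean(vc$ratios$vc_ratio[vc$ratios$arm == "MM"]),
            mean(vc$ratios$vc_ratio[vc$ratios$arm == "placebo"]))
  dat$CD[1] <- 0
  expect_warning(vc_ratio(dat), "zero crypt depth")
})

test_that("MM raises the V:C ratio in most simulated paper-scenario trials", {
  spec <- effect_spec()
  wins <- vapply(1:40, function(s) {
    set.seed(s)
    mm <- simulate_stratum(spec, "negative", "MM", 100)
    pl <- simulate_stratum(spec, "negative", "placebo", 100)
    mean(mm$VH / mm$CD) > mean(pl$VH / pl$CD)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("normality routing sends skewed measures to rank tests", {
  # at a few hundred records per stratum the screen is decisive for the
  # log-normal measures while the Gaussian ones stay parametric
  routes <- lapply(1:5, function(s) {
    sim <- simulate_cohort(effect_spec(n_per_letter = 100), seed = s)
    ub <- unblind(lock_cohort(sim$cohort), sim$code_map)
    res <- route_and_compare(ub)
    res[res$stratum == "negative", c("variable", "routed_normal")]
  })
  routed <- do.call(rbind, routes)
  agg <- tapply(routed$routed_normal, routed$variable, mean)
  expect_lte(agg[["VP"]], 0.2)   # log-normal: almost always non-parametric
  expect_lte(agg[["VW"]], 0.2)
  expect_gte(agg[["VH"]], 0.8)   # Gaussian: almost always parametric
  expect_gte(agg[["VA"]], 0.8)
})

test_that("routing skips degenerate strata and needs an unblinded cohort", {
  sim <- simulate_cohort(small_effect_spec(p_hiv = 0.02), seed = 3)
  expect_error(route_and_compare(sim$cohort), "unblind")
  ub <- unblind(lock_cohort(sim$cohort), sim$code_map)
  expect_message(res <- route_and_compare(ub), "skipped")
  expect_true(all(res$stratum == "negative"))
  gl <- generics::glance(res)
  expect_equal(gl$n_comparisons, nrow(res))
})

test_that("conservative selection picks the dataset with the larger primary p", {
  mk <- function(p_vh) {
    structure(tibble::tibble(
      stratum = "negative", variable = c("VH", "CD"),
      test = "2-tailed t", routed_normal = TRUE,
      estimate = c(50, 5), ci_low = NA_real_, ci_high = NA_real_,
      statistic = 1, p_value = c(p_vh, 0.5),
      group1_stat = 1, group2_stat = 1, n_mm = 10, n_placebo = 10, note = ""
    ), class = c("villi_analysis", "tbl_df", "tbl", "data.frame"))
  }
  sel <- select_conservative(mk(0.006), mk(0.001))
  expect_equal(attr(sel, "dataset"), "pre")
  expect_equal(sel$p_value[1], 0.006)
  sel2 <- select_conservative(mk(0.01), mk(0.04))
  expect_equal(attr(sel2, "dataset"), "post")
  # identical sets: deterministic tie-break to pre
  sel3 <- select_conservative(mk(0.02), mk(0.02))
  expect_equal(attr(sel3, "dataset"), "pre")
  # mismatched comparison sets refuse
  other <- mk(0.01); other$variable <- c("VH", "VW")
  expect_error(select_conservative(mk(0.01), other), "different comparisons")
})
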