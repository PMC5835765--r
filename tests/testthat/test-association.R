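test_that("exact test reproduces the published subgroup table and handles degeneracy", {
  # IIa subgroup: 7/8 small vs 1/6 large with SRE
  p <- fisher_exact_2x2(crosstab_counts(7, 1, 1, 5))$p_value
  expect_equal(round(p, 3), 0.026)
  expect_warning(res <- fisher_exact_2x2(crosstab_counts(0, 0, 3, 5)),
                 "degenerate")
  expect_equal(res$p_value, 1)
})

test_that("exact test equals the full hypergeometric enumeration oracle", {
  set.seed(41)
  for (i in 1:200) {
    m <- random_table_2x2(40)
    expect_equal(fisher_exact_2x2(m)$p_value, oracle_fisher_p(m),
                 tolerance = 1e-9)
  }
})

test_that("Pearson chi-square matches manual expected counts and warns when sparse", {
  # manual Pearson statistic from expected counts for the 25/16/9/25 table
  m <- matrix(c(25, 9, 16, 25), 2)
  exp_counts <- outer(rowSums(m), colSums(m)) / sum(m)
  stat_manual <- sum((m - exp_counts)^2 / exp_counts)
  res <- chi_square_2x2(crosstab_counts(25, 16, 9, 25))
  expect_equal(res$statistic, stat_manual)
  expect_equal(round(res$statistic, 1), 8.9)
  expect_equal(res$df, 1)
  # statistic 0, p 1 when observed equals expected
  res0 <- chi_square_2x2(crosstab_counts(10, 10, 10, 10))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_warning(sparse <- chi_square_2x2(crosstab_counts(3, 1, 1, 3)),
                 "expected")
  expect_match(sparse$note, "expected")
  expect_error(chi_square_2x2(crosstab_counts(0, 0, 3, 5)),
               class = "fcdsre_domain_error")
})

test_that("Yates-corrected statistic never exceeds the uncorrected one", {
  set.seed(42)
  for (i in 1:100) {
    m <- random_table_2x2(60)
    s1 <- suppressWarnings(chi_square_2x2(m, yates = FALSE)$statistic)
    s2 <- suppressWarnings(chi_square_2x2(m, yates = TRUE)$statistic)
    expect_lte(s2, s1 + 1e-12)
  }
})

test_that("odds ratio, Woolf interval and transposition behave", {
  or <- odds_ratio_2x2(crosstab_counts(25, 16, 9, 25))
  expect_equal(round(or$estimate, 2), 4.34)
  expect_true(or$conf.low < or$estimate && or$estimate < or$conf.high)
  flat <- odds_ratio_2x2(crosstab_counts(1, 1, 1, 1))
  expect_equal(flat$estimate, 1)
  expect_true(flat$conf.low < 1 && 1 < flat$conf.high)
  # transposing rows and columns inverts the ratio
  or_t <- odds_ratio_2x2(crosstab_counts(16, 25, 25, 9))
  expect_equal(or_t$estimate, 1 / or$estimate)
  expect_error(odds_ratio_2x2(crosstab_counts(0, 5, 3, 2)),
               class = "fcdsre_domain_error")
  corr <- odds_ratio_2x2(crosstab_counts(0, 5, 3, 2), correct = TRUE)
  expect_match(corr$note, "continuity")
})

test_that("Wilcoxon rank-sum: exactness, symmetry and ties dialect", {
  # completely separated samples, n = m = 4: two-sided exact p = 2/70
  res <- wilcoxon_rank_sum(1:4, 11:14)
  expect_equal(res$p_value, 2 / choose(8, 4), tolerance = 1e-9)
  expect_equal(res$method, "wilcoxon_exact")
  # swapping samples leaves p unchanged
  expect_equal(wilcoxon_rank_sum(11:14, 1:4)$p_value, res$p_value)
  # identical multisets give p = 1
  x <- c(1.5, 2.5, 9)
  expect_equal(wilcoxon_rank_sum(x, x)$p_value, 1, tolerance = 1e-9)
  # ties switch to the normal approximation and record it
  res_t <- wilcoxon_rank_sum(c(1, 1, 2, 3), c(1, 2, 2, 4))
  expect_equal(res_t$method, "wilcoxon_normal_ties")
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3),
               class = "fcdsre_domain_error")
})

test_that("auto dialect routes sparse tables to the exact test", {
  sparse <- crosstab_counts(3, 1, 1, 5)
  expect_equal(assoc_test_2x2(sparse)$method, "fisher_exact")
  dense <- crosstab_counts(25, 16, 9, 25)
  expect_equal(assoc_test_2x2(dense)$method, "chi_square_pearson")
  all3 <- assoc_test_2x2(dense, verbose = TRUE)
  expect_equal(all3$method,
               c("chi_square_pearson", "chi_square_yates", "fisher_exact"))
})

test_that("logistic fit recovers a known odds ratio without bias and with Wald coverage", {
  set.seed(43)
  or_true <- 3.67
  reps <- 200
  stats <- t(replicate(reps, {
    n <- 1000
    d <- tibble::tibble(x = factor(ifelse(runif(n) < 0.55, "small", "large"),
                                   levels = c("small", "large")))
    d$y <- runif(n) < plogis(-0.9 + log(or_true) * (d$x == "small"))
    td <- tidy(logistic_fit(d, y, "x", reference = c(x = "large")))
    c(log(td$estimate), td$conf.low <= or_true & or_true <= td$conf.high)
  }))
  bias <- mean(stats[, 1]) - log(or_true)
  expect_lt(abs(bias), 0.05 * log(or_true))
  expect_gte(mean(stats[, 2]), 0.92)
  expect_lte(mean(stats[, 2]), 0.98)
})

test_that("a null predictor gives an odds ratio near 1 with a covering interval", {
  set.seed(44)
  n <- 2000
  d <- tibble::tibble(x = runif(n) < 0.5, y = runif(n) < 0.4)
  td <- tidy(logistic_fit(d, y, "x"))
  expect_equal(td$estimate, 1, tolerance = 0.25)
  expect_true(td$conf.low <= 1 && 1 <= td$conf.high)
})

test_that("quasi-complete separation is flagged as a diagnostic", {
  d <- tibble::tibble(
    loc = rep(c("frontal", "temporal"), c(40, 6)),
    y = c(runif(40) < 0.5, rep(TRUE, 6)))
  d$y[1] <- TRUE; d$y[2] <- FALSE # ensure both classes in frontal
  fit <- suppressWarnings(logistic_fit(d, y, "loc",
                                       reference = c(loc = "frontal")))
  td <- tidy(fit)
  expect_true(td$separated[td$term == "loctemporal"])
  expect_true(glance(fit)$any_separated)
})

test_that("ANCOVA reduces to the pooled two-sample comparison without covariates", {
  set.seed(45)
  d <- tibble::tibble(g = rep(c(TRUE, FALSE), each = 25),
                      y = rnorm(50) + 0.5 * rep(c(1, 0), each = 25))
  res <- ancova_group_test(d, y, g, covariates = character(0),
                           alpha_family = 1)
  oracle <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-12)
  # Bonferroni family of 3 gives the 0.0167 threshold
  res3 <- ancova_group_test(d, y, g, covariates = character(0),
                            alpha_family = 3)
  expect_equal(res3$alpha_adjusted, 0.05 / 3, tolerance = 1e-12)
})

test_that("ANCOVA type-I error stays near nominal under the null", {
  set.seed(46)
  reps <- 400
  rej <- mean(replicate(reps, {
    n <- 60
    d <- tibble::tibble(g = rep(c(TRUE, FALSE), each = n / 2),
                        age_at_mri = runif(n, 5, 58),
                        sex = sample(c("M", "F"), n, TRUE),
                        icv_mm3 = rnorm(n, 1.45e6, 1.2e5))
    d$y <- rnorm(n) + 0.01 * scale(d$age_at_mri)[, 1]
    ancova_group_test(d, y, g, alpha_family = 1)$p_value < 0.05
  }))
  se <- sqrt(0.05 * 0.95 / reps)
  expect_gt(rej, 0.05 - 3 * se)
  expect_lt(rej, 0.05 + 3 * se)
})

test_that("ANCOVA reports rank deficiency by naming the collinear term", {
  d <- tibble::tibble(g = rep(c(TRUE, FALSE), each = 10),
                      y = rnorm(20), age_at_mri = rnorm(20),
                      dup = NA_real_)
  d$dup <- d$age_at_mri
  expect_error(ancova_group_test(d, y, g, covariates = c("age_at_mri", "dup")),
               "dup", class = "fcdsre_domain_error")
})

test_that("partial correlation matches the residual-regression oracle", {
  set.seed(47)
  n <- 80
  z1 <- rnorm(n); z2 <- runif(n)
  x <- 2 * z1 - z2 + rnorm(n)
  y <- -z1 + 0.5 * z2 + rnorm(n)
  res <- partial_correlation(x, y, controls = data.frame(z1, z2))
  # oracle: residuals from explicit lm fits, plain cor + t transform
  rx <- resid(lm(x ~ z1 + z2)); ry <- resid(lm(y ~ z1 + z2))
  r <- cor(rx, ry)
  tval <- r * sqrt((n - 4) / (1 - r^2))
  expect_equal(res$estimate, r, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(-abs(tval), n - 4), tolerance = 1e-10)
  # empty control set reduces to ordinary Pearson
  res0 <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(res0$estimate, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(res0$p_value, ct$p.value, tolerance = 1e-10)
  # controlling for x itself leaves zero residual variance: undefined
  expect_error(partial_correlation(x, y, controls = data.frame(x)),
               "constant residuals", class = "fcdsre_domain_error")
  expect_error(partial_correlation(c(1, 2), c(3, 4)),
               class = "fcdsre_domain_error")
})

test_that("univariate screening applies the 0.1 entry rule", {
  fx <- paper_fixture()
  fx$size <- classify_size(fx$lesion_volume_mm3, 3217)
  meas <- fx[!is.na(fx$size), ]
  sel <- suppressWarnings(
    select_univariate(meas, sre, c("size", "sex", "age_at_mri", "location")))
  expect_true(sel$selected[sel$candidate == "size"])
  expect_false(sel$selected[sel$candidate == "sex"])
  # a constant candidate is skipped with a warning
  meas$const <- "x"
  expect_warning(sel2 <- select_univariate(meas, sre, c("const", "size")),
                 "untestable")
  expect_false("const" %in% sel2$candidate)
  expect_true("size" %in% sel2$candidate)
})
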