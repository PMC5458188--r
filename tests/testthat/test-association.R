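test_that("pearson_chi2 reproduces published statistics without continuity correction", {
  cv <- hcc_covariate_counts()
  expect_equal(pearson_chi2(cv$smoking)$statistic, 17.49, tolerance = 0.005)
  expect_equal(pearson_chi2(cv$gender)$statistic, 0.15, tolerance = 0.005)
  # a corrected gender statistic would be ~0.10, so this pins the decision
  expect_gt(pearson_chi2(cv$gender)$statistic, 0.13)
  gc <- hcc_genotype_counts()
  r <- pearson_chi2(unclass(gc$rs73013281))
  expect_equal(r$statistic, 5.14, tolerance = 0.005)
  expect_equal(r$df, 2L)
})

test_that("pearson_chi2 is invariant to permutation/transposition and zero on proportional rows", {
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(sample(1:50, 6L, TRUE), 2L, 3L)
    s0 <- pearson_chi2(m)$statistic
    expect_equal(pearson_chi2(m[, c(3, 1, 2)])$statistic, s0)
    expect_equal(pearson_chi2(m[c(2, 1), ])$statistic, s0)
    expect_equal(pearson_chi2(t(m))$statistic, s0)
  }
  prop <- rbind(c(10, 20, 30), c(5, 10, 15))
  expect_equal(pearson_chi2(prop)$statistic, 0)
  expect_error(pearson_chi2(rbind(c(0, 0), c(3, 4))), "degenerate")
  expect_error(pearson_chi2(rbind(c(1, 0), c(3, 0))), "degenerate")
})

test_that("crude_or matches hand cross-products, Woolf CI and reciprocal identity", {
  r <- crude_or(two_by_two(240, 44, 236, 67))
  expect_equal(r$or, (240 * 67) / (44 * 236), tolerance = 1e-12)
  expect_equal(round(c(r$or, r$ci_low, r$ci_high), 2L), c(1.55, 1.02, 2.36))
  # symmetric null table
  r0 <- crude_or(two_by_two(10, 10, 10, 10))
  expect_equal(r0$or, 1)
  expect_equal(log(r0$ci_low), -log(r0$ci_high), tolerance = 1e-12)
  # swapping exposure labels inverts the OR exactly
  set.seed(11)
  for (i in 1:20) {
    cells <- sample(1:80, 4L, TRUE)
    t1 <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    t2 <- two_by_two(cells[2], cells[1], cells[4], cells[3])
    expect_equal(crude_or(t1)$or * crude_or(t2)$or, 1, tolerance = 1e-12)
  }
})

test_that("a zero cell triggers the flagged Haldane correction, an empty table errors", {
  r <- crude_or(two_by_two(5, 0, 3, 7))
  expect_true(r$haldane)
  expect_equal(r$or, (5.5 * 7.5) / (0.5 * 3.5), tolerance = 1e-12)
  expect_false(crude_or(two_by_two(5, 1, 3, 7))$haldane)
  expect_error(two_by_two(0, 0, 0, 0), "empty")
})

test_that("Woolf CI coverage of the generating OR is ~95% at study-like n", {
  set.seed(91)
  n_sim <- 2000L
  true_or <- 1.7
  p0 <- 0.35
  p1 <- plogis(qlogis(p0) + log(true_or))
  covered <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    a <- rbinom(1L, 600L, p1); b <- 600L - a
    c <- rbinom(1L, 600L, p0); d <- 600L - c
    r <- crude_or(two_by_two(a, b, c, d))
    covered[i] <- r$ci_low <= true_or && true_or <= r$ci_high
  }
  expect_gt(mean(covered), 0.95 - 0.015)
  expect_lt(mean(covered), 0.95 + 0.015)
})

test_that("hwe_test matches the closed form, exact proportions, and monomorphic flag", {
  expect_equal(hwe_test(c(25, 50, 25))$statistic, 0, tolerance = 1e-12)
  r <- hwe_test(c(67, 236, 310))
  expect_equal(r$allele_freq, 856 / 1226, tolerance = 1e-12)
  # frozen hand evaluation of sum((O-E)^2/E) at p = 856/1226
  expect_equal(r$statistic, 4.5829, tolerance = 1e-4)
  expect_equal(sum(r$expected), 613, tolerance = 1e-9)
  m <- hwe_test(c(0, 0, 100))
  expect_true(m$monomorphic)
  expect_equal(m$statistic, 0)
  # statistic is zero iff observed equals expectation
  r2 <- hwe_test(c(36, 48, 16))    # exact HWE at p = 0.4
  expect_equal(r2$statistic, 0, tolerance = 1e-12)
  expect_gt(hwe_test(c(40, 40, 20))$statistic, 0)
})

test_that("exact HWE option agrees with the chi-square in large balanced samples", {
  r <- hwe_test(c(240, 500, 260), exact = TRUE)
  expect_equal(r$method, "exact")
  expect_gt(r$p_value, 0.5)
  # strong disequilibrium is detected by both routes
  expect_lt(hwe_test(c(100, 20, 100), exact = TRUE)$p_value, 1e-6)
  expect_lt(hwe_test(c(100, 20, 100))$p_value, 1e-6)
})

test_that("fit_logistic agrees with glm to 1e-6 and reproduces the 2x2 OR exactly", {
  # saturated single-binary-predictor identity on the published cells
  tabs <- fix_study_or_tables()
  for (tt in tabs) {
    y <- rep(c(1L, 1L, 0L, 0L), c(tt$a, tt$b, tt$c, tt$d))
    e <- rep(c(1, 0, 1, 0), c(tt$a, tt$b, tt$c, tt$d))
    f <- fit_logistic(y, cbind(exposed = e))
    expect_true(f$converged)
    expect_equal(exp(f$beta[["exposed"]]), crude_or(tt)$or, tolerance = 1e-6)
  }
  # cross-implementation oracle with two covariates
  x <- fix_cohort(100L, 100L, or_dom = 1.5, seed = 9L)
  d <- cbind(dom = as.numeric(x$subjects$rs0001 >= 1L),
             smoke = x$subjects$smoke, age = x$subjects$age)
  f <- fit_logistic(x$subjects$phenotype, d)
  g <- glm(x$subjects$phenotype ~ d, family = binomial())
  expect_equal(unname(f$beta), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(f$vcov))),
               unname(sqrt(diag(vcov(g)))), tolerance = 1e-5)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
})

test_that("fit_logistic flags separation and rejects degenerate designs", {
  y <- rep(c(0L, 1L), each = 20L)
  x_sep <- as.numeric(y == 1L)          # perfect separation
  set.seed(5)
  f <- fit_logistic(y, cbind(s = x_sep, n = rnorm(40)))
  expect_false(f$converged)
  expect_true(f$separated)
  expect_error(fit_logistic(y, cbind(k = rep(1, 40))), "constant")
  expect_error(fit_logistic(y[1:3], cbind(a = rnorm(3), b = rnorm(3), c = rnorm(3))),
               "more observations")
  # independence: coefficient near zero
  f0 <- fit_logistic(y, cbind(z = rep(c(0, 1), 20L)))
  expect_lt(abs(f0$beta[["z"]]), 0.7)
})

test_that("adjusted_or with no covariates equals the crude OR; codominant matches published", {
  x <- hcc_cohort()
  ors <- adjusted_or(x, "rs73013281", "codominant")
  expect_equal(round(ors[["CT"]]$or, 2L), 1.55)
  expect_equal(round(ors[["TT"]]$or, 2L), 1.60)
  dom <- adjusted_or(x, "rs73013281", "dominant")
  expect_equal(dom[[1L]]$or, crude_or(collapse_counts(
    genotype_counts(x, "rs73013281"), "dominant"))$or, tolerance = 1e-6)
  expect_false(dom[[1L]]$adjusted)
})

test_that("adjusted_or recovers a generating dominant OR through confounding", {
  set.seed(77)
  n <- 4000L
  g <- rbinom(n, 2L, 0.4)
  conf <- rbinom(n, 1L, plogis(-0.5 + 0.8 * (g >= 1L)))  # correlated with G
  y <- rbinom(n, 1L, plogis(-1 + log(1.7) * (g >= 1L) + 0.9 * conf))
  x <- cohort(data.frame(id = as.character(seq_len(n)), phenotype = y,
                         rs0001 = g, conf = conf),
              list(rs0001 = fix_variant()))
  r <- adjusted_or(x, "rs0001", "dominant", covariates = "conf")[[1L]]
  expect_true(r$adjusted)
  expect_true(r$ci_low <= 1.7 && 1.7 <= r$ci_high)
  # and the crude OR is confounded upward
  expect_gt(crude_or(collapse_counts(genotype_counts(x, "rs0001"), "dominant"))$or,
            r$or)
})

test_that("select_genetic_model ranks a simulated pure dominant model first", {
  set.seed(123)
  n <- 6000L
  g <- rbinom(n, 2L, 0.35)
  y <- rbinom(n, 1L, plogis(-0.8 + log(2.2) * (g >= 1L)))
  x <- cohort(data.frame(id = as.character(seq_len(n)), phenotype = y, rs0001 = g),
              list(rs0001 = fix_variant()))
  sel <- select_genetic_model(x, "rs0001")
  expect_equal(sel$best, "dominant")
  expect_equal(nrow(sel$ranking), 4L)
  expect_true(all(sel$ranking$converged))
  # the study cohort reports the dominant contrast among its fits
  sel2 <- select_genetic_model(hcc_cohort(), "rs73013281")
  expect_equal(round(sel2$ors$dominant[[1L]]$or, 2L), 1.58)
})
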