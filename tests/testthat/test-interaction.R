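# Cohort whose joint-exposure cells reproduce the published physical-activity
# stratification of the dominant rs73013281 contrast.
pa_cohort <- function() {
  cells <- list(  # (G, E, n_case, n_control); E = 1 is inactive
    c(0, 0, 20, 28), c(1, 0, 200, 262), c(0, 1, 24, 39), c(1, 1, 365, 284))
  rows <- do.call(rbind, lapply(cells, function(z) {
    rbind(
      data.frame(phenotype = rep(1L, z[3]), G = z[1], E = z[2]),
      data.frame(phenotype = rep(0L, z[4]), G = z[1], E = z[2]))
  }))
  rows$rs0001 <- rows$G   # carrier coded as one alt copy
  rows$id <- as.character(seq_len(nrow(rows)))
  cohort(rows[c("id", "phenotype", "rs0001", "E")],
         list(rs0001 = fix_variant()))
}

test_that("stratified crude ORs match the published cross-products", {
  x <- pa_cohort()
  s <- stratified_ors(x, "rs0001", "dominant", "E")
  expect_equal(s[["1"]]$or, (365 * 39) / (24 * 284), tolerance = 1e-12) # 2.09
  expect_equal(s[["0"]]$or, (200 * 28) / (20 * 262), tolerance = 1e-12) # 1.07
  expect_equal(round(s[["1"]]$or, 2L), 2.09)
  expect_equal(round(s[["0"]]$or, 2L), 1.07)
  # constant stratifier: single stratum equal to the unstratified analysis
  x0 <- x; x0$subjects$E <- 1
  s0 <- stratified_ors(x0, "rs0001", "dominant", "E")
  expect_length(s0, 1L)
  expect_equal(s0[["1"]]$or,
               crude_or(collapse_counts(genotype_counts(x, "rs0001"),
                                        "dominant"))$or)
})

test_that("saturated product-term OR equals the ratio of stratum cross-product ORs", {
  x <- pa_cohort()
  m <- multiplicative_interaction(x, "rs0001", "dominant", "E")
  s <- stratified_ors(x, "rs0001", "dominant", "E")
  expect_equal(m$or_interaction$or, s[["1"]]$or / s[["0"]]$or, tolerance = 1e-6)
  expect_equal(round(m$or_interaction$or, 2L), 1.95)
  # property on random 2x2x2 tables
  set.seed(19)
  for (i in 1:10) {
    cells <- matrix(sample(5:60, 8L, TRUE), 2L)
    s2 <- data.frame(
      phenotype = rep(rep(c(1L, 0L), 4L), as.vector(cells)),
      G = rep(c(0, 0, 1, 1, 0, 0, 1, 1), as.vector(cells)),
      E = rep(c(0, 0, 0, 0, 1, 1, 1, 1), as.vector(cells)))
    s2$rs0001 <- s2$G; s2$id <- as.character(seq_len(nrow(s2)))
    xi <- cohort(s2[c("id", "phenotype", "rs0001", "E")],
                 list(rs0001 = fix_variant()))
    mi <- multiplicative_interaction(xi, "rs0001", "dominant", "E")
    si <- stratified_ors(xi, "rs0001", "dominant", "E")
    expect_equal(mi$or_interaction$or, si[["1"]]$or / si[["0"]]$or,
                 tolerance = 1e-6)
  }
})

test_that("RERI from the joint fit matches the cell cross-products and additivity", {
  x <- pa_cohort()
  fit <- snpgxe:::joint_fit(x, "rs0001", "dominant", "E")
  r <- reri(fit)
  or11 <- (365 * 28) / (20 * 284)
  or10 <- (200 * 28) / (20 * 262)
  or01 <- (24 * 28) / (20 * 39)
  expect_equal(r, or11 - or10 - or01 + 1, tolerance = 1e-6)
  expect_equal(round(r, 2L), 0.87)
  expect_error(reri(fit, terms = c("nope", "G0E1", "G1E1")), "not in fit")
  # RERI is exactly 0 under OR11 = OR10 + OR01 - 1
  fake <- fit
  fake$beta[c("G1E0", "G0E1", "G1E1")] <- log(c(1.5, 1.5, 2.0))
  expect_equal(reri(fake), 0, tolerance = 1e-12)
  # multiplicativity of two harmful factors implies super-additivity
  fake$beta[c("G1E0", "G0E1", "G1E1")] <- log(c(1.4, 1.8, 1.4 * 1.8))
  expect_gt(reri(fake), 0)
})

test_that("joint exposure indicators are exclusive and respect exposure_ref", {
  x <- pa_cohort()
  je <- joint_exposure(x, "rs0001", "dominant", "E")
  expect_true(all(rowSums(je$X_joint) <= 1))
  expect_equal(sum(je$X_joint[, "G1E1"]), 365 + 284)
  # flipping the reference level relabels the cells
  je2 <- joint_exposure(x, "rs0001", "dominant", "E", exposure_ref = 1)
  expect_equal(sum(je2$X_joint[, "G1E1"]), 200 + 262)
})

test_that("additive bootstrap is reproducible, covers the point estimate, and p behaves", {
  x <- pa_cohort()
  b1 <- additive_interaction_bootstrap(x, "rs0001", "dominant", "E",
                                       n_boot = 500L, seed = 7L)
  b2 <- additive_interaction_bootstrap(x, "rs0001", "dominant", "E",
                                       n_boot = 500L, seed = 7L)
  expect_identical(b1$p_additive, b2$p_additive)
  expect_identical(b1$reri_boot, b2$reri_boot)
  expect_equal(round(b1$reri_point, 2L), 0.87)
  expect_true(b1$reri_ci[1L] <= b1$reri_point &&
              b1$reri_point <= b1$reri_ci[2L])
  expect_gte(b1$p_additive, 2 / 500)
  expect_lte(b1$p_additive, 1)
  expect_error(additive_interaction_bootstrap(x, "rs0001", "dominant", "E",
                                              n_boot = 100L), "seed")
})

test_that("covariate-adjusted bootstrap route agrees with the closed form when the covariate is noise", {
  set.seed(55)
  x <- pa_cohort()
  x$subjects$noise <- rbinom(nrow(x$subjects), 1L, 0.5)
  b_adj <- additive_interaction_bootstrap(x, "rs0001", "dominant", "E",
                                          covariates = "noise",
                                          n_boot = 60L, seed = 9L)
  b_fast <- additive_interaction_bootstrap(x, "rs0001", "dominant", "E",
                                           n_boot = 2000L, seed = 9L)
  expect_equal(b_adj$reri_point, b_fast$reri_point, tolerance = 0.05)
  expect_equal(stats::median(b_adj$reri_boot),
               stats::median(b_fast$reri_boot), tolerance = 0.35)
})

test_that("full interaction analysis bundles strata, multiplicative and additive tests", {
  x <- pa_cohort()
  ir <- interaction_analysis(x, "rs0001", "dominant", "E",
                             n_boot = 400L, seed = 13L)
  expect_named(ir$stratum_ors, c("0", "1"))
  expect_equal(ir$p_multiplicative,
               multiplicative_interaction(x, "rs0001", "dominant", "E")$p_value)
  expect_true(is.finite(ir$reri_point))
  expect_gte(ir$p_additive, 2 / 400)
})
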