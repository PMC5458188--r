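test_that("phase-unambiguous data reduce EM to direct haplotype counting", {
  G <- rbind(c(0, 0), c(0, 0), c(2, 2), c(2, 0), c(0, 2), c(2, 2))
  em <- em_haplotypes(G)
  expect_true(em$converged)
  # 12 chromosomes counted directly: 00 x4, 10 x2, 01 x2, 11 x4
  want <- c(`00` = 4 / 12, `01` = 2 / 12, `10` = 2 / 12, `11` = 4 / 12)
  got <- setNames(em$freq, em$haplotype)
  for (h in names(want)) expect_equal(unname(got[h]), unname(want[h]),
                                      tolerance = 1e-7)
})

test_that("a lone double heterozygote settles at the symmetric fixed point", {
  em <- em_haplotypes(rbind(c(1, 1)), n_start = 1L)
  expect_equal(sort(em$freq), rep(0.25, 4L), tolerance = 1e-9)
})

test_that("frequencies stay on the simplex and the likelihood beats the grid oracle", {
  set.seed(202)
  hf <- c(0.45, 0.2, 0.05, 0.3)  # (00, 10, 01, 11)
  hapmat <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  for (rep in 1:3) {
    n <- sample(12:20, 1L)
    h1 <- sample(1:4, n, TRUE, hf); h2 <- sample(1:4, n, TRUE, hf)
    G <- hapmat[h1, ] + hapmat[h2, ]
    em <- em_haplotypes(G, seed = rep)
    expect_equal(sum(em$freq), 1, tolerance = 1e-9)
    expect_true(all(em$freq >= -1e-12))
    expect_gte(em$loglik, oracle_loglik(G) - 1e-6)
  }
})

test_that("EM recovers generating 3-locus haplotype frequencies within sampling error", {
  set.seed(404)
  haps <- c("000", "100", "110", "111")
  hf <- c(0.35, 0.15, 0.2, 0.3)
  n <- 400L
  draw <- function() sample(haps, n, TRUE, hf)
  h1 <- draw(); h2 <- draw()
  G <- sapply(1:3, function(l) {
    as.integer(substr(h1, l, l) == "1") + as.integer(substr(h2, l, l) == "1")
  })
  em <- em_haplotypes(G, seed = 2L)
  got <- setNames(em$freq, em$haplotype)
  for (i in seq_along(haps)) {
    expect_equal(unname(got[haps[i]]), hf[i], tolerance = 0.06)
  }
  # haplotypes never drawn get (near) zero mass
  expect_lt(sum(got[setdiff(names(got), haps)]), 0.02)
})

test_that("monomorphic loci yield the single-haplotype degenerate solution", {
  G <- matrix(0L, 5L, 2L)
  em <- em_haplotypes(G)
  expect_true(em$converged)
  expect_equal(em$freq, 1)
  expect_equal(em$haplotype, "00")
})

test_that("pairwise LD matches the hand-evaluated frequencies and edge cases", {
  ld <- pairwise_ld(c(0.4, 0.1, 0.1, 0.4))
  expect_equal(ld$D, 0.15, tolerance = 1e-12)
  expect_equal(ld$D_prime, 0.6, tolerance = 1e-12)
  expect_equal(ld$r2, 0.36, tolerance = 1e-12)
  # independence
  p <- c(0.35 * 0.6, 0.35 * 0.4, 0.65 * 0.6, 0.65 * 0.4)
  ld0 <- pairwise_ld(p)
  expect_equal(ld0$D, 0, tolerance = 1e-12)
  expect_equal(ld0$D_prime, 0)
  expect_equal(ld0$r2, 0, tolerance = 1e-12)
  # complete association at equal frequencies
  ld1 <- pairwise_ld(c(0.5, 0, 0, 0.5))
  expect_equal(ld1$D_prime, 1)
  expect_equal(ld1$r2, 1)
  # negative D uses the other Dmax branch and reports |D'|
  ld2 <- pairwise_ld(c(0.1, 0.4, 0.4, 0.1))
  expect_lt(ld2$D, 0)
  expect_equal(ld2$D_prime, 0.6, tolerance = 1e-12)
  expect_error(pairwise_ld(c(0.5, 0.5, 0, 0)), "monomorphic")
})

test_that("pairwise LD from a fitted haplotype_set marginalises correctly", {
  set.seed(77)
  # strong coupling between loci 1 and 2
  haps <- c("00", "11")
  h1 <- sample(haps, 300L, TRUE, c(0.4, 0.6))
  h2 <- sample(haps, 300L, TRUE, c(0.4, 0.6))
  G <- sapply(1:2, function(l)
    as.integer(substr(h1, l, l) == "1") + as.integer(substr(h2, l, l) == "1"))
  em <- em_haplotypes(G)
  ld <- pairwise_ld(em, c(1L, 2L))
  expect_gt(ld$D_prime, 0.95)
  expect_gt(ld$r2, 0.9)
})

test_that("haplotype association flags enrichment and pools rare haplotypes", {
  set.seed(99)
  v2 <- list(l1 = variant_def("l1", "A", "C"), l2 = variant_def("l2", "A", "C"))
  draw_geno <- function(n, hf) {
    haps <- c("00", "10", "01", "11")
    h1 <- sample(haps, n, TRUE, hf); h2 <- sample(haps, n, TRUE, hf)
    sapply(1:2, function(l)
      as.integer(substr(h1, l, l) == "1") + as.integer(substr(h2, l, l) == "1"))
  }
  # "11" (= allele string "CC") enriched ~2-fold in cases
  Gc <- draw_geno(500L, c(0.40, 0.25, 0.15, 0.20))
  Gk <- draw_geno(500L, c(0.50, 0.28, 0.12, 0.10))
  s <- data.frame(id = as.character(1:1000),
                  phenotype = rep(c(1L, 0L), each = 500L),
                  l1 = c(Gc[, 1L], Gk[, 1L]), l2 = c(Gc[, 2L], Gk[, 2L]))
  ha <- haplotype_association(cohort(s, v2), min_freq = 0.05)
  tab <- ha$table
  expect_true(ha$em_based)
  enr <- tab[tab$haplotype == "CC", ]
  expect_gt(enr$or, 1.5)
  expect_lt(enr$or, 3.0)
  # identical distributions: ORs all near 1
  Gk2 <- draw_geno(500L, c(0.40, 0.25, 0.15, 0.20))
  s2 <- s; s2$l1 <- c(Gc[, 1L], Gk2[, 1L]); s2$l2 <- c(Gc[, 2L], Gk2[, 2L])
  tab2 <- haplotype_association(cohort(s2, v2), min_freq = 0.05)$table
  expect_true(all(abs(log(tab2$or)) < log(1.5)))
})

test_that("min_freq threshold pools sub-threshold haplotypes into 'other'", {
  set.seed(123)
  v2 <- list(l1 = variant_def("l1", "A", "C"), l2 = variant_def("l2", "A", "C"))
  haps <- c("00", "10", "01", "11")
  hf <- c(0.55, 0.27, 0.15, 0.03)
  n <- 800L
  h1 <- sample(haps, n, TRUE, hf); h2 <- sample(haps, n, TRUE, hf)
  G <- sapply(1:2, function(l)
    as.integer(substr(h1, l, l) == "1") + as.integer(substr(h2, l, l) == "1"))
  s <- data.frame(id = as.character(1:n), phenotype = rep(c(1L, 0L), n / 2),
                  l1 = G[, 1L], l2 = G[, 2L])
  tab <- haplotype_association(cohort(s, v2), min_freq = 0.05)$table
  expect_equal(sum(tab$haplotype == "other"), 1L)
  expect_equal(nrow(tab), 4L)  # three common + pooled remainder
})
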