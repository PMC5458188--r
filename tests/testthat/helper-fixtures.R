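# Shared fixtures: all built in code, no files.

fix_variant <- function(id = "rs0001", ref = "C", alt = "T",
                        reference_genotype = "ref_hom") {
  variant_def(id, ref, alt, reference_genotype)
}

# Small random cohort with one variant and two binary covariates, no
# genotype-phenotype association unless or_dom != 1.
fix_cohort <- function(n_case = 50L, n_ctrl = 50L, p_alt = 0.4, or_dom = 1,
                       seed = 42L, missing = 0L) {
  set.seed(seed)
  v <- fix_variant()
  N <- 50L * (n_case + n_ctrl)
  g <- rbinom(N, 2L, p_alt)
  y <- rbinom(N, 1L, plogis(qlogis(0.3) + log(or_dom) * (g >= 1L)))
  keep <- c(which(y == 1L)[seq_len(n_case)], which(y == 0L)[seq_len(n_ctrl)])
  g <- g[keep]; y <- y[keep]
  if (missing > 0L) g[sample.int(length(g), missing)] <- NA_integer_
  subjects <- data.frame(
    id = sprintf("P%04d", seq_along(y)), phenotype = y, rs0001 = g,
    smoke = rbinom(length(y), 1L, 0.5), act = rbinom(length(y), 1L, 0.5),
    age = rnorm(length(y), 55, 10))
  cohort(subjects, list(rs0001 = v))
}

# The published study tables wired into TwoByTwo fixtures used across tests.
fix_study_or_tables <- function() {
  gc <- hcc_genotype_counts()
  m <- unclass(gc$rs73013281)
  list(
    ct_vs_cc = two_by_two(m[1, 2], m[1, 1], m[2, 2], m[2, 1],
                          exposed = "CT", unexposed = "CC"),
    tt_vs_cc = two_by_two(m[1, 3], m[1, 1], m[2, 3], m[2, 1],
                          exposed = "TT", unexposed = "CC"),
    dom = collapse_counts(gc$rs73013281, "dominant"),
    rs167007_rec = collapse_counts(gc$rs167007, "recessive"),
    rs9397984_rec = collapse_counts(gc$rs9397984, "recessive")
  )
}
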