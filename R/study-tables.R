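#' Published summary tables from the motivating HCC case-control study
#'
#' The package was built around a hospital-based case-control study of
#' hepatocellular carcinoma (611 cases, 614 cancer-free controls, Southern
#' Chinese Han population) that genotyped three candidate regulatory variants
#' of the chromatin-remodelling gene ARID1B. Individual-level data were never
#' deposited; these functions return the published summary counts, which are
#' sufficient for every crude (unadjusted) statistic and serve as worked
#' examples and regression fixtures throughout the package.
#'
#' `hcc_variants()` returns the three variant definitions with the study's
#' baseline genotypes (CC for rs73013281 — deliberately the *minor*
#' homozygote — AA+AG baseline for rs167007, CC+CT baseline for rs9397984).
#'
#' @return `hcc_variants()`: named list of [variant_def()].
#' @name hcc_study
NULL

#' @rdname hcc_study
#' @export
hcc_variants <- function() {
  list(
    rs73013281 = variant_def("rs73013281", "C", "T", "ref_hom"),
    rs167007   = variant_def("rs167007", "A", "G", "ref_hom"),
    rs9397984  = variant_def("rs9397984", "C", "T", "ref_hom")
  )
}

#' @rdname hcc_study
#' @return `hcc_genotype_counts()`: named list of `genotype_count_table`s
#'   (case/control genotype counts per variant; totals fall short of 611/614
#'   where calls failed).
#' @export
hcc_genotype_counts <- function() {
  v <- hcc_variants()
  list(
    rs73013281 = genotype_count_table(v$rs73013281,
                                      cases = c(44, 240, 325),
                                      controls = c(67, 236, 310)),
    rs167007   = genotype_count_table(v$rs167007,
                                      cases = c(6, 83, 522),
                                      controls = c(3, 87, 520)),
    rs9397984  = genotype_count_table(v$rs9397984,
                                      cases = c(4, 70, 536),
                                      controls = c(2, 79, 530))
  )
}

#' @rdname hcc_study
#' @return `hcc_covariate_counts()`: named list of [two_by_two()] tables for
#'   the binary subject characteristics (exposed level listed first).
#' @export
hcc_covariate_counts <- function() {
  list(
    gender = two_by_two(532, 79, 530, 84,
                        exposed = "male", unexposed = "female"),
    smoking = two_by_two(417, 194, 348, 266,
                         exposed = "ever", unexposed = "never"),
    drinking = two_by_two(343, 268, 275, 339,
                          exposed = "ever", unexposed = "never"),
    physical_activity = two_by_two(391, 220, 323, 291,
                                   exposed = "inactive", unexposed = "active"),
    hbsag = two_by_two(454, 157, 107, 507,
                       exposed = "positive", unexposed = "negative"),
    family_history = two_by_two(85, 526, 23, 591,
                                exposed = "yes", unexposed = "no")
  )
}

#' @rdname hcc_study
#' @return `hcc_interaction_counts()`: for each stratifying risk factor, a
#'   list of per-stratum [two_by_two()] tables of the dominant rs73013281
#'   contrast (TT+TC exposed vs CC), in (unfavourable, favourable) stratum
#'   order used by the stratified interaction analysis.
#' @export
hcc_interaction_counts <- function() {
  list(
    smoking = list(
      ever = two_by_two(388, 27, 306, 42, exposed = "TT+TC", unexposed = "CC"),
      never = two_by_two(177, 17, 240, 25, exposed = "TT+TC", unexposed = "CC")
    ),
    drinking = list(
      ever = two_by_two(316, 25, 244, 30, exposed = "TT+TC", unexposed = "CC"),
      never = two_by_two(249, 19, 302, 37, exposed = "TT+TC", unexposed = "CC")
    ),
    physical_activity = list(
      inactive = two_by_two(365, 24, 284, 39, exposed = "TT+TC", unexposed = "CC"),
      active = two_by_two(200, 20, 262, 28, exposed = "TT+TC", unexposed = "CC")
    ),
    hbsag = list(
      positive = two_by_two(416, 36, 96, 11, exposed = "TT+TC", unexposed = "CC"),
      negative = two_by_two(149, 8, 450, 56, exposed = "TT+TC", unexposed = "CC")
    ),
    family_history = list(
      yes = two_by_two(79, 6, 20, 3, exposed = "TT+TC", unexposed = "CC"),
      no = two_by_two(486, 38, 526, 64, exposed = "TT+TC", unexposed = "CC")
    )
  )
}

#' @rdname hcc_study
#' @param ... Passed to [cohort_from_genotype_counts()].
#' @return `hcc_cohort()`: a subject-level [cohort()] whose genotype counts
#'   reproduce the published tables (covariates are not recoverable and are
#'   absent).
#' @export
hcc_cohort <- function(...) {
  cohort_from_genotype_counts(hcc_genotype_counts(),
                              n_cases = 611, n_controls = 614, ...)
}
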