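format_or_ci <- function(or, lo, hi) sprintf("%.2f (%.2f-%.2f)", or, lo, hi)

#' Configuration for the end-to-end analysis
#'
#' @param cohort A [cohort()], or a path + `schema` for [read_cohort()].
#' @param schema Column schema when `cohort` is a file path.
#' @param variants Variant definitions (required when reading from file).
#' @param covariates Adjustment covariates for the adjusted OR / interaction
#'   stages (empty = crude analysis only).
#' @param codings Genetic codings fitted per variant.
#' @param exposures Covariates to test for gene-environment interaction with
#'   each variant (empty = skip the interaction stage).
#' @param n_perm,n_boot Permutation and bootstrap sizes.
#' @param haplotype_loci Variant ids for the haplotype stage (`NULL` = all
#'   declared variants; fewer than 2 skips the stage).
#' @param seed Mandatory seed (used by permutation and bootstrap stages).
#' @param out_dir Optional output directory for CSV/JSON/log files.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(cohort, schema = list(), variants = NULL,
                            covariates = character(0L),
                            codings = c("codominant", "dominant"),
                            exposures = character(0L),
                            n_perm = 10000L, n_boot = 10000L,
                            haplotype_loci = NULL, seed, out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  structure(list(cohort = cohort, schema = schema, variants = variants,
                 covariates = covariates, codings = codings,
                 exposures = exposures, n_perm = n_perm, n_boot = n_boot,
                 haplotype_loci = haplotype_loci, seed = seed,
                 out_dir = out_dir),
            class = "analysis_config")
}

#' Run the full case-control analysis pipeline
#'
#' Executes, in order: covariate comparison (chi-square per binary
#' covariate), genotype distribution with chi-square and permutation
#' empirical p-values, HWE in controls, crude (and, when covariates are
#' configured, adjusted) ORs under the configured genetic codings,
#' stratified gene-environment interaction (multiplicative product-term p
#' and additive RERI bootstrap p) for each configured exposure, and the
#' haplotype EM stage with pairwise LD. A stage that fails is recorded in
#' `$failed` and the remaining stages still run.
#'
#' Rendered tables round ORs and chi-squares to 2 decimals and p-values to 3
#' (printing `<0.001` below that); the returned object keeps full precision,
#' and `write_analysis_bundle()` serialises it to CSVs plus one JSON.
#'
#' @param config An [analysis_config()].
#' @return An `analysis_bundle` list of per-stage results and rendered
#'   data.frames; written to `config$out_dir` when set.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  x <- config$cohort
  if (is.character(x)) {
    x <- read_cohort(x, config$variants, config$schema)
  }
  stopifnot(inherits(x, "cohort"))
  bundle <- list(config = config, failed = character(0L),
                 log = character(0L))
  note <- function(...) {
    bundle$log <<- c(bundle$log, sprintf(...))
  }
  note("seed = %d, n_perm = %d, n_boot = %d", config$seed, config$n_perm,
       config$n_boot)
  stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e) {
      bundle$failed <<- c(bundle$failed, name)
      note("stage %s FAILED: %s", name, conditionMessage(e))
      NULL
    })
    r
  }
  covs <- intersect(names(x$subjects),
                    setdiff(names(x$subjects),
                            c("id", "phenotype", "age", names(x$variants))))
  # Stage 1: covariate comparison
  bundle$covariate_table <- stage("covariates", {
    if (!length(covs)) NULL else {
      do.call(rbind, lapply(covs, function(cv) {
        tt <- crosstab_covariate(x, cv)
        cs <- pearson_chi2(tt)
        data.frame(covariate = cv, cases_1 = tt$a, cases_0 = tt$b,
                   controls_1 = tt$c, controls_0 = tt$d,
                   chi2 = cs$statistic, p = cs$p_value)
      }))
    }
  })
  # Stage 2: genotype distribution + HWE + permutation correction
  vids <- names(x$variants)
  bundle$genotype_tables <- stage("genotype_counts",
                                  lapply(stats::setNames(vids, vids),
                                         function(v) genotype_counts(x, v)))
  bundle$genotype_chi2 <- stage("genotype_chi2", {
    do.call(rbind, lapply(vids, function(v) {
      cs <- pearson_chi2(unclass(bundle$genotype_tables[[v]]))
      data.frame(variant = v, chi2 = cs$statistic, df = cs$df, p = cs$p_value)
    }))
  })
  bundle$hwe <- stage("hwe", {
    do.call(rbind, lapply(vids, function(v) {
      h <- hwe_test(unclass(bundle$genotype_tables[[v]])["control", ])
      data.frame(variant = v, allele_freq = h$allele_freq,
                 chi2 = h$statistic, p = h$p_value,
                 monomorphic = h$monomorphic)
    }))
  })
  # Stage 3: crude/adjusted ORs per coding, with shared permutation stream
  bundle$or_table <- stage("odds_ratios", {
    rows <- list()
    for (v in vids) {
      for (cd in config$codings) {
        ors <- adjusted_or(x, v, cd, character(0L))
        for (nm in names(ors)) {
          r <- ors[[nm]]
          rows[[length(rows) + 1L]] <- data.frame(
            variant = v, coding = cd, term = nm,
            crude_or = r$or, crude_low = r$ci_low, crude_high = r$ci_high,
            crude_p = r$p_value)
        }
        if (length(config$covariates)) {
          adj <- adjusted_or(x, v, cd, config$covariates)
          k <- length(rows) - length(adj)
          for (j in seq_along(adj)) {
            rows[[k + j]]$adj_or <- adj[[j]]$or
            rows[[k + j]]$adj_low <- adj[[j]]$ci_low
            rows[[k + j]]$adj_high <- adj[[j]]$ci_high
            rows[[k + j]]$adj_p <- adj[[j]]$p_value
          }
        }
      }
    }
    do.call(rbind, rows)
  })
  bundle$permutation <- stage("permutation", {
    if (!length(vids)) NULL else {
      tests <- list()
      for (v in vids) for (cd in config$codings) {
        tests[[length(tests) + 1L]] <- perm_test(v, cd)
      }
      permutation_pvalues(x, tests, n_perm = config$n_perm,
                          seed = config$seed)
    }
  })
  # Stage 4: gene-environment interaction
  bundle$interaction <- stage("interaction", {
    if (!length(config$exposures) || !length(vids)) NULL else {
      out <- list()
      for (ex in config$exposures) {
        note("interaction exposure %s: exposed level = 1", ex)
        out[[ex]] <- interaction_analysis(
          x, vids[1L], "dominant", ex, config$covariates,
          n_boot = config$n_boot, seed = config$seed)
      }
      out
    }
  })
  # Stage 5: haplotypes
  loci <- config$haplotype_loci %||% vids
  bundle$haplotypes <- stage("haplotypes", {
    if (length(loci) < 2L) NULL else {
      ha <- haplotype_association(x, loci, seed = config$seed)
      ld <- list()
      for (i in seq_len(length(loci) - 1L)) for (j in seq((i + 1L), length(loci))) {
        ld[[paste(loci[i], loci[j], sep = "-")]] <-
          pairwise_ld(ha$em_pooled, c(loci[i], loci[j]))
      }
      list(association = ha, ld = ld)
    }
  })
  bundle$rendered <- render_tables(bundle)
  class(bundle) <- "analysis_bundle"
  if (!is.null(config$out_dir)) write_analysis_bundle(bundle, config$out_dir)
  bundle
}

render_tables <- function(bundle) {
  out <- list()
  fmt2 <- function(v) formatC(v, format = "f", digits = 2L)
  if (!is.null(bundle$covariate_table)) {
    ct <- bundle$covariate_table
    out$covariates <- data.frame(covariate = ct$covariate,
                                 cases = paste0(ct$cases_1, "/", ct$cases_0),
                                 controls = paste0(ct$controls_1, "/", ct$controls_0),
                                 chi2 = fmt2(ct$chi2), p = format_p(ct$p))
  }
  if (!is.null(bundle$or_table)) {
    ot <- bundle$or_table
    out$odds_ratios <- data.frame(
      variant = ot$variant, coding = ot$coding, term = ot$term,
      crude_or = format_or_ci(ot$crude_or, ot$crude_low, ot$crude_high),
      p = format_p(ot$crude_p))
    if ("adj_or" %in% names(ot)) {
      out$odds_ratios$adjusted_or <-
        format_or_ci(ot$adj_or, ot$adj_low, ot$adj_high)
      out$odds_ratios$adj_p <- format_p(ot$adj_p)
    }
    if (!is.null(bundle$permutation)) {
      ep <- vapply(bundle$permutation, `[[`, numeric(1L), "empirical_p")
      ids <- names(bundle$permutation)
      key <- paste(ot$variant, ot$coding, ot$term, sep = ":")
      out$odds_ratios$p_perm <- format_p(ep[match(key, ids)])
    }
  }
  if (!is.null(bundle$interaction)) {
    rows <- lapply(names(bundle$interaction), function(ex) {
      ir <- bundle$interaction[[ex]]
      s <- ir$stratum_ors
      data.frame(exposure = ex, stratum = names(s),
                 or = vapply(s, function(r) format_or_ci(r$or, r$ci_low, r$ci_high),
                             character(1L)),
                 p_mult = format_p(ir$p_multiplicative),
                 p_add = format_p(ir$p_additive))
    })
    out$interaction <- do.call(rbind, rows)
  }
  out
}

#' Write an analysis bundle to disk
#'
#' One CSV per rendered table, a `results.json` with full-precision numeric
#' results, and a `run.log` recording seeds, simulation sizes and any failed
#' stage.
#'
#' @param bundle An `analysis_bundle` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle$rendered)) {
    utils::write.csv(bundle$rendered[[nm]],
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  json <- list(
    covariates = bundle$covariate_table,
    genotype_chi2 = bundle$genotype_chi2,
    hwe = bundle$hwe,
    odds_ratios = bundle$or_table,
    permutation = lapply(unclass(bundle$permutation), function(r)
      r[c("test_id", "observed_p", "empirical_p", "n_perm", "seed",
          "n_as_extreme")]),
    interaction = lapply(bundle$interaction, function(ir)
      list(p_multiplicative = ir$p_multiplicative,
           reri = ir$reri_point, reri_ci = ir$reri_ci,
           p_additive = ir$p_additive)),
    haplotypes = if (!is.null(bundle$haplotypes))
      list(table = bundle$haplotypes$association$table,
           ld = lapply(bundle$haplotypes$ld, function(l)
             l[c("D", "D_prime", "r2")])),
    failed = bundle$failed
  )
  jsonlite::write_json(json, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  writeLines(bundle$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("== Case-control association analysis ==\n")
  for (nm in names(x$rendered)) {
    cat("\n--", nm, "--\n")
    print(x$rendered[[nm]], row.names = FALSE)
  }
  if (!is.null(x$hwe)) {
    cat("\n-- HWE in controls --\n")
    print(transform(x$hwe, allele_freq = round(allele_freq, 3L),
                    chi2 = round(chi2, 2L), p = round(p, 3L)),
          row.names = FALSE)
  }
  if (length(x$failed)) cat("\nFAILED stages:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}
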