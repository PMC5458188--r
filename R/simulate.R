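#' Configuration for the synthetic case-control cohort generator
#'
#' The generator emulates a frequency-matched case-control study: a
#' prospective population with HWE genotypes (or diplotypes drawn from
#' multi-locus haplotype frequencies, which induces LD), independent
#' Bernoulli covariates (optionally coupled in pairs on the odds-ratio
#' scale), Gaussian age, and disease from a logistic model with configurable
#' genetic, covariate and gene-environment interaction effects; individuals
#' are then rejection-sampled until exactly `n_cases` cases and `n_controls`
#' controls are collected.
#'
#' Defaults reproduce the study conditions the package was built around:
#' 611 cases / 614 controls, three candidate variants at their control-group
#' alternate-allele frequencies, covariate prevalences from the published
#' control column, age ~ Normal(55.9, 12.1) years.
#'
#' @param n_cases,n_controls Target sample sizes.
#' @param variants Named list of [variant_def()].
#' @param alt_freqs Named vector: population frequency of each variant's
#'   alternate allele (used under independent HWE sampling).
#' @param haplotype_freqs Optional named vector of multi-locus haplotype
#'   frequencies (names are allele strings over the variants in list order,
#'   e.g. `"TGC"`); overrides `alt_freqs` and induces LD.
#' @param covariate_prevalences Named vector of control-population Bernoulli
#'   prevalences for the binary covariates.
#' @param covariate_coupling Optional list of `list(pair = c("a", "b"),
#'   odds_ratio = )` entries inducing pairwise dependence between two binary
#'   covariates at the given odds ratio (each covariate in at most one pair);
#'   default independence.
#' @param gene_effects Named list (by variant id) of
#'   `list(coding = , log_or = )`: per-term log odds ratios on the disease
#'   scale (two values for codominant).
#' @param covariate_effects Named vector of covariate log odds ratios.
#' @param age_mean,age_sd,age_effect Age distribution (years) and its
#'   per-year log-OR (age enters centred at `age_mean`).
#' @param interaction Optional `list(variant = , exposure = ,
#'   scale = "multiplicative"|"additive", magnitude = )`. On the
#'   multiplicative scale `magnitude` is the product-term log-OR; on the
#'   additive scale it is the target RERI, and the joint-cell log-odds is
#'   solved so that OR11 - OR10 - OR01 + 1 equals it (the genetic main
#'   effect must be specified under the dominant or recessive coding).
#' @param baseline_risk Disease probability at the reference level of every
#'   term (in (0,1)).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cases = 611L, n_controls = 614L,
                       variants = hcc_variants(),
                       alt_freqs = c(rs73013281 = 0.698, rs167007 = 0.919,
                                     rs9397984 = 0.932),
                       haplotype_freqs = NULL,
                       covariate_prevalences = c(
                         gender = 0.863, smoking = 0.567, drinking = 0.448,
                         physical_activity = 0.526, hbsag = 0.174,
                         family_history = 0.037),
                       covariate_coupling = NULL,
                       gene_effects = list(),
                       covariate_effects = numeric(0L),
                       age_mean = 55.9, age_sd = 12.1, age_effect = 0,
                       interaction = NULL,
                       baseline_risk = 0.2) {
  stopifnot(n_cases > 0L, n_controls > 0L,
            baseline_risk > 0, baseline_risk < 1)
  if (is.null(names(variants))) {
    names(variants) <- vapply(variants, `[[`, character(1L), "id")
  }
  if (is.null(haplotype_freqs)) {
    stopifnot(all(names(variants) %in% names(alt_freqs)))
    stopifnot(all(alt_freqs > 0 & alt_freqs < 1))
  } else {
    stopifnot(abs(sum(haplotype_freqs) - 1) < 1e-9, all(haplotype_freqs >= 0),
              all(nchar(names(haplotype_freqs)) == length(variants)))
  }
  stopifnot(all(covariate_prevalences > 0 & covariate_prevalences < 1))
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 variants = variants, alt_freqs = alt_freqs,
                 haplotype_freqs = haplotype_freqs,
                 covariate_prevalences = covariate_prevalences,
                 covariate_coupling = covariate_coupling,
                 gene_effects = gene_effects,
                 covariate_effects = covariate_effects,
                 age_mean = age_mean, age_sd = age_sd, age_effect = age_effect,
                 interaction = interaction, baseline_risk = baseline_risk),
            class = "sim_config")
}

# Joint cell probability P(X1=1, X2=1) for two Bernoulli margins coupled at
# a given odds ratio (Plackett construction).
coupled_p11 <- function(p1, p2, or) {
  if (abs(or - 1) < 1e-12) return(p1 * p2)
  s <- 1 + (p1 + p2) * (or - 1)
  (s - sqrt(s^2 - 4 * or * (or - 1) * p1 * p2)) / (2 * (or - 1))
}

draw_covariates <- function(cfg, n) {
  prev <- cfg$covariate_prevalences
  out <- matrix(NA_real_, n, length(prev), dimnames = list(NULL, names(prev)))
  paired <- character(0L)
  for (cp in cfg$covariate_coupling %||% list()) {
    p1 <- prev[[cp$pair[1L]]]; p2 <- prev[[cp$pair[2L]]]
    p11 <- coupled_p11(p1, p2, cp$odds_ratio)
    probs <- c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11)
    cell <- sample.int(4L, n, replace = TRUE, prob = probs)
    out[, cp$pair[1L]] <- as.numeric(cell %in% c(1L, 2L))
    out[, cp$pair[2L]] <- as.numeric(cell %in% c(1L, 3L))
    paired <- c(paired, cp$pair)
  }
  for (nm in setdiff(names(prev), paired)) {
    out[, nm] <- stats::rbinom(n, 1L, prev[[nm]])
  }
  out
}

draw_genotypes <- function(cfg, n) {
  vids <- names(cfg$variants)
  if (is.null(cfg$haplotype_freqs)) {
    G <- vapply(vids, function(v) stats::rbinom(n, 2L, cfg$alt_freqs[[v]]),
                integer(n))
  } else {
    hf <- cfg$haplotype_freqs
    h1 <- sample(names(hf), n, replace = TRUE, prob = hf)
    h2 <- sample(names(hf), n, replace = TRUE, prob = hf)
    G <- vapply(seq_along(vids), function(l) {
      alt <- cfg$variants[[l]]$allele_alt
      as.integer(substr(h1, l, l) == alt) + as.integer(substr(h2, l, l) == alt)
    }, integer(n))
    colnames(G) <- vids
  }
  G
}

# Interaction product-term log-OR implied by the configured scale.
interaction_beta <- function(cfg, beta_g, beta_e) {
  it <- cfg$interaction
  if (is.null(it)) return(0)
  if (it$scale == "multiplicative") return(it$magnitude)
  # additive: RERI target; solve exp(bg+be+bge) = RERI + exp(bg) + exp(be) - 1
  joint <- it$magnitude + exp(beta_g) + exp(beta_e) - 1
  if (joint <= 0) stop("additive interaction target implies non-positive joint OR")
  log(joint) - beta_g - beta_e
}

#' Simulate a case-control cohort
#'
#' Draws individuals from the configured prospective population and keeps
#' them as cases or controls according to the logistic disease model until
#' both quotas are filled. Deterministic given `seed`.
#'
#' @param cfg A [sim_config()].
#' @param seed Mandatory RNG seed.
#' @param draw_cap Maximum number of population draws before giving up
#'   (default `2000 * (n_cases + n_controls)`).
#' @return A [cohort()] with genotype, covariate and `age` columns.
#' @export
simulate_cohort <- function(cfg, seed, draw_cap = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (missing(seed)) stop("seed is mandatory")
  n_total <- cfg$n_cases + cfg$n_controls
  draw_cap <- draw_cap %||% (2000L * n_total)
  set.seed(seed, kind = "Mersenne-Twister")
  got_case <- list(); got_ctrl <- list()
  n_case <- 0L; n_ctrl <- 0L; drawn <- 0L
  it <- cfg$interaction
  while (n_case < cfg$n_cases || n_ctrl < cfg$n_controls) {
    if (drawn >= draw_cap) {
      stop("draw cap (", draw_cap, ") exceeded before filling quotas; ",
           "baseline_risk = ", cfg$baseline_risk,
           " is too extreme for the requested sample sizes")
    }
    m <- min(max(2L * n_total, 1000L), draw_cap - drawn)
    drawn <- drawn + m
    G <- draw_genotypes(cfg, m)
    C <- draw_covariates(cfg, m)
    age <- stats::rnorm(m, cfg$age_mean, cfg$age_sd)
    eta <- rep(stats::qlogis(cfg$baseline_risk), m)
    for (vid in names(cfg$gene_effects)) {
      ge <- cfg$gene_effects[[vid]]
      cols <- genetic_coding(ge$coding)$build(G[, vid], cfg$variants[[vid]])
      eta <- eta + drop(cols %*% ge$log_or)
    }
    for (nm in names(cfg$covariate_effects)) {
      eta <- eta + cfg$covariate_effects[[nm]] * C[, nm]
    }
    eta <- eta + cfg$age_effect * (age - cfg$age_mean)
    if (!is.null(it)) {
      ge <- cfg$gene_effects[[it$variant]]
      beta_g <- if (is.null(ge)) 0 else ge$log_or[1L]
      beta_e <- if (it$exposure %in% names(cfg$covariate_effects))
        cfg$covariate_effects[[it$exposure]] else 0
      bge <- interaction_beta(cfg, beta_g, beta_e)
      gbin <- drop(genetic_coding(if (is.null(ge)) "dominant" else ge$coding)$build(
        G[, it$variant], cfg$variants[[it$variant]]))
      eta <- eta + bge * gbin * C[, it$exposure]
    }
    y <- stats::rbinom(m, 1L, stats::plogis(eta))
    block <- data.frame(phenotype = y, G, C, age = age, check.names = FALSE)
    need_case <- cfg$n_cases - n_case
    need_ctrl <- cfg$n_controls - n_ctrl
    cases <- block[block$phenotype == 1L, , drop = FALSE]
    ctrls <- block[block$phenotype == 0L, , drop = FALSE]
    if (need_case > 0L && nrow(cases)) {
      got_case[[length(got_case) + 1L]] <- utils::head(cases, need_case)
      n_case <- n_case + min(nrow(cases), need_case)
    }
    if (need_ctrl > 0L && nrow(ctrls)) {
      got_ctrl[[length(got_ctrl) + 1L]] <- utils::head(ctrls, need_ctrl)
      n_ctrl <- n_ctrl + min(nrow(ctrls), need_ctrl)
    }
  }
  subjects <- rbind(do.call(rbind, got_case), do.call(rbind, got_ctrl))
  subjects <- cbind(id = sprintf("S%05d", seq_len(nrow(subjects))), subjects,
                    stringsAsFactors = FALSE)
  rownames(subjects) <- NULL
  cohort(subjects, cfg$variants)
}

#' Simulation-based power estimate
#'
#' Simulates cohorts with the target variant's effect set to
#' `log(detect_or)` under `coding`, tests the (crude) genetic contrast on
#' each, and reports the fraction of two-sided Wald p-values below `alpha`.
#'
#' @param cfg A [sim_config()] (its effect for `variant` is overridden).
#' @param detect_or Odds ratio to detect.
#' @param variant Variant id (default first configured variant).
#' @param coding Genetic coding of both the generating effect and the test.
#' @param alpha Significance level (default 0.05).
#' @param n_sims Number of simulated cohorts (>= 100).
#' @param seed Mandatory RNG seed.
#' @return A `power_estimate` list: `power`, `mc_se`, `n_sims`, `alpha`,
#'   `detect_or`, `config`.
#' @export
estimate_power <- function(cfg, detect_or, variant = names(cfg$variants)[1L],
                           coding = "dominant", alpha = 0.05,
                           n_sims = 200L, seed) {
  stopifnot(inherits(cfg, "sim_config"), n_sims >= 100L)
  if (missing(seed)) stop("seed is mandatory")
  cfg$gene_effects[[variant]] <- list(
    coding = coding,
    log_or = if (coding == "codominant") c(log(detect_or) / 2, log(detect_or))
             else log(detect_or))
  hits <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    x <- simulate_cohort(cfg, seed = seed + i - 1L)
    d <- build_design(x, variant, coding)
    if (length(d$genetic_terms) == 1L && all(d$X[, 1L] %in% c(0, 1))) {
      p <- wald_p_2x2(d$y == 1L, d$X[, 1L] == 1)
    } else {
      f <- fit_logistic(d$y, d$X)
      z <- f$beta[d$genetic_terms] / sqrt(diag(f$vcov)[d$genetic_terms])
      p <- min(2 * stats::pnorm(-abs(z)))
    }
    hits[i] <- p < alpha
  }
  pw <- mean(hits)
  structure(list(power = pw, mc_se = sqrt(pw * (1 - pw) / n_sims),
                 n_sims = n_sims, alpha = alpha, detect_or = detect_or,
                 variant = variant, coding = coding, config = cfg),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Power to detect OR %.2f (%s, %s) at alpha %.3f: %.3f (MC SE %.3f, %d sims)\n",
              x$detect_or, x$variant, x$coding, x$alpha, x$power, x$mc_se,
              x$n_sims))
  invisible(x)
}
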