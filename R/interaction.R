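#' Joint gene-environment exposure indicators
#'
#' Builds the three indicator columns (G=1,E=0), (G=0,E=1), (G=1,E=1)
#' against the reference cell (G=0, E=0), where G is the collapsed genetic
#' contrast (carrier vs baseline homozygote under the dominant model) and E a
#' binary covariate. Exactly one indicator is 1 for every non-reference
#' subject. The reference level of E is configurable (`exposure_ref`), so the
#' reference cell can always be the favourable exposure level.
#'
#' @param x A [cohort()].
#' @param variant Variant id or [variant_def()].
#' @param model Collapsing model for G, `"dominant"` (default) or
#'   `"recessive"`.
#' @param exposure Name of the binary environment covariate.
#' @param exposure_ref Value of `exposure` treated as unexposed (default 0).
#' @return List: `G`, `E` (0/1 vectors with NA), indicator matrix `X_joint`
#'   with columns `G1E0`, `G0E1`, `G1E1`, and the variant.
#' @export
joint_exposure <- function(x, variant, model = "dominant", exposure,
                           exposure_ref = 0) {
  stopifnot(inherits(x, "cohort"))
  v <- if (inherits(variant, "variant_def")) variant else x$variants[[variant]]
  if (is.null(v)) stop("unknown variant")
  coding <- genetic_coding(match.arg(model, c("dominant", "recessive")))
  G <- drop(coding$build(x$subjects[[v$id]], v))
  if (!exposure %in% names(x$subjects)) stop("exposure '", exposure, "' not found")
  ev <- x$subjects[[exposure]]
  if (!all(ev[!is.na(ev)] %in% c(0, 1))) stop("exposure must be binary 0/1")
  E <- as.numeric(ev != exposure_ref)
  X <- cbind(G1E0 = as.numeric(G == 1 & E == 0),
             G0E1 = as.numeric(G == 0 & E == 1),
             G1E1 = as.numeric(G == 1 & E == 1))
  list(G = G, E = E, X_joint = X, variant = v, model = model)
}

#' Stratified odds ratios of a genetic contrast
#'
#' Within each level of a binary stratifier, the OR of the collapsed genetic
#' contrast — crude if `covariates` is empty, otherwise adjusted by logistic
#' regression. A stratum whose 2x2 table has a zero cell falls back to the
#' Haldane-corrected crude OR with a warning (the adjusted fit is skipped).
#'
#' @inheritParams joint_exposure
#' @param stratifier Name of the binary stratifying covariate.
#' @param covariates Adjustment covariates for the within-stratum fits.
#' @return Named list (stratum level -> `or_result`).
#' @export
stratified_ors <- function(x, variant, model = "dominant", stratifier,
                           covariates = character(0L)) {
  stopifnot(inherits(x, "cohort"))
  sv <- x$subjects[[stratifier]]
  if (is.null(sv)) stop("stratifier '", stratifier, "' not found")
  covariates <- setdiff(covariates, stratifier)  # constant within stratum
  levs <- sort(unique(sv[!is.na(sv)]))
  out <- list()
  for (lv in levs) {
    sub <- x$subjects[!is.na(sv) & sv == lv, , drop = FALSE]
    xs <- cohort(sub, x$variants)
    gc <- genotype_counts(xs, if (inherits(variant, "variant_def")) variant$id else variant)
    tt <- collapse_counts(gc, model)
    zero_cell <- any(c(tt$a, tt$b, tt$c, tt$d) == 0)
    if (length(covariates) == 0L || zero_cell) {
      if (zero_cell && length(covariates) > 0L) {
        warning("stratum ", stratifier, "=", lv,
                ": zero cell, reporting Haldane-corrected crude OR")
      }
      out[[as.character(lv)]] <- crude_or(tt)
    } else {
      ors <- adjusted_or(xs, variant, model, covariates)
      out[[as.character(lv)]] <- ors[[1L]]
    }
  }
  out
}

#' Multiplicative gene-environment interaction test
#'
#' Fits phenotype ~ G + E + G:E (+ covariates) and reports the two-sided
#' Wald p-value and OR of the product term. With no covariates this is the
#' saturated model on the 2x2x2 table, whose product-term OR equals the
#' ratio of the two stratum cross-product ORs exactly.
#'
#' @inheritParams joint_exposure
#' @param covariates Adjustment covariates.
#' @return List: `p_value`, `or_interaction` (an `or_result` for the product
#'   term), `fit`.
#' @export
multiplicative_interaction <- function(x, variant, model = "dominant",
                                       exposure, covariates = character(0L),
                                       exposure_ref = 0) {
  covariates <- setdiff(covariates, exposure)  # E already a main effect
  je <- joint_exposure(x, variant, model, exposure, exposure_ref)
  X <- cbind(G = je$G, E = je$E, GxE = je$G * je$E)
  if (length(covariates)) {
    X <- cbind(X, as.matrix(x$subjects[, covariates, drop = FALSE]))
  }
  keep <- stats::complete.cases(X)
  fit <- fit_logistic(x$subjects$phenotype[keep], X[keep, , drop = FALSE])
  if (!fit$converged) stop("interaction model did not converge")
  orr <- term_or(fit, "GxE", paste0(je$variant$id, " x ", exposure), covariates)
  list(p_value = orr$p_value, or_interaction = orr, fit = fit)
}

#' Relative excess risk due to interaction
#'
#' RERI = OR11 - OR10 - OR01 + 1 from a logistic fit on the joint-exposure
#' indicator coding; zero under exact additivity of the OR-scale excess
#' risks, positive for super-additive joint effects.
#'
#' @param fit A converged `logistic_fit` containing the three joint-exposure
#'   terms.
#' @param terms Names of the (G-only, E-only, joint) coefficients.
#' @return RERI point estimate (numeric scalar).
#' @export
reri <- function(fit, terms = c("G1E0", "G0E1", "G1E1")) {
  stopifnot(inherits(fit, "logistic_fit"), length(terms) == 3L)
  if (!fit$converged) stop("fit has not converged")
  miss <- setdiff(terms, fit$terms)
  if (length(miss)) stop("terms not in fit: ", paste(miss, collapse = ", "))
  ors <- exp(fit$beta[terms])
  unname(ors[3L] - ors[1L] - ors[2L] + 1)
}

# Fit the joint-exposure model on a cohort; returns the logistic_fit.
joint_fit <- function(x, variant, model, exposure, covariates = character(0L),
                      exposure_ref = 0) {
  covariates <- setdiff(covariates, exposure)  # absorbed by the joint terms
  je <- joint_exposure(x, variant, model, exposure, exposure_ref)
  X <- je$X_joint
  if (length(covariates)) {
    X <- cbind(X, as.matrix(x$subjects[, covariates, drop = FALSE]))
  }
  keep <- stats::complete.cases(X)
  fit_logistic(x$subjects$phenotype[keep], X[keep, , drop = FALSE])
}

# Closed-form RERI from the 2 (phenotype) x 4 (joint-exposure cell) counts,
# cells ordered (G0E0, G1E0, G0E1, G1E1); Haldane +0.5 everywhere when any
# cell is zero. Vectorised over columns when given matrices.
reri_from_cells <- function(n_case, n_ctrl) {
  if (is.null(dim(n_case))) { n_case <- cbind(n_case); n_ctrl <- cbind(n_ctrl) }
  zero <- colSums(n_case == 0) + colSums(n_ctrl == 0) > 0
  n_case <- n_case + rep(0.5 * zero, each = 4L)
  n_ctrl <- n_ctrl + rep(0.5 * zero, each = 4L)
  or_ <- function(k) (n_case[k, ] * n_ctrl[1L, ]) / (n_case[1L, ] * n_ctrl[k, ])
  drop(or_(4L) - or_(2L) - or_(3L) + 1)
}

#' Bootstrap test of additive gene-environment interaction
#'
#' Tests departure from OR-scale additivity (RERI = 0) by nonparametric
#' bootstrap: subjects are resampled with replacement *within* phenotype
#' groups — respecting the fixed case/control margins of the retrospective
#' design — RERI is recomputed on every resample, and the percentile CI and
#' a two-sided p-value `2 * min(fraction <= 0, fraction > 0)` (clipped to
#' `[2/n_boot, 1]`) are reported.
#'
#' With no adjustment covariates, per-resample RERI is computed in closed
#' form from the 2x4 joint-exposure cell counts (exactly the saturated
#' logistic fit); with covariates every resample is refit, and more than 1%
#' non-converging resamples aborts with a diagnostic.
#'
#' @inheritParams multiplicative_interaction
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Mandatory RNG seed.
#' @param conf_level Level of the percentile interval (default 0.95).
#' @return An `additive_interaction` list: `reri_point`, `reri_ci`,
#'   `p_additive`, `n_boot`, `seed`, plus AP (attributable proportion
#'   RERI/OR11) and synergy index S at the point estimate.
#' @export
additive_interaction_bootstrap <- function(x, variant, model = "dominant",
                                           exposure,
                                           covariates = character(0L),
                                           n_boot = 10000L, seed,
                                           exposure_ref = 0,
                                           conf_level = 0.95) {
  if (missing(seed)) stop("seed is mandatory for the bootstrap")
  covariates <- setdiff(covariates, exposure)
  je <- joint_exposure(x, variant, model, exposure, exposure_ref)
  cell <- 1L + je$G + 2L * je$E            # 1..4 = G0E0, G1E0, G0E1, G1E1
  keep <- !is.na(cell)
  if (length(covariates)) {
    keep <- keep & stats::complete.cases(
      as.matrix(x$subjects[, covariates, drop = FALSE]))
  }
  ph <- x$subjects$phenotype[keep]
  cell <- cell[keep]
  obs_case <- tabulate(cell[ph == 1L], 4L)
  obs_ctrl <- tabulate(cell[ph == 0L], 4L)
  fit <- joint_fit(x, variant, model, exposure, covariates, exposure_ref)
  if (!fit$converged) stop("joint-exposure model did not converge on observed data")
  point <- reri(fit)
  ors <- exp(fit$beta[c("G1E0", "G0E1", "G1E1")])
  set.seed(seed, kind = "Mersenne-Twister")
  if (length(covariates) == 0L) {
    bc <- stats::rmultinom(n_boot, sum(obs_case), obs_case)
    bk <- stats::rmultinom(n_boot, sum(obs_ctrl), obs_ctrl)
    reri_b <- reri_from_cells(bc, bk)
  } else {
    idx_case <- which(keep)[ph == 1L]
    idx_ctrl <- which(keep)[ph == 0L]
    reri_b <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      take <- c(sample(idx_case, length(idx_case), replace = TRUE),
                sample(idx_ctrl, length(idx_ctrl), replace = TRUE))
      sub <- x$subjects[take, , drop = FALSE]
      sub$id <- sprintf("B%06d", seq_along(take))
      fb <- tryCatch(joint_fit(cohort(sub, x$variants), variant, model,
                               exposure, covariates, exposure_ref),
                     error = function(e) NULL)
      if (!is.null(fb) && fb$converged) reri_b[b] <- reri(fb)
    }
    fail <- mean(is.na(reri_b))
    if (fail > 0.01) {
      stop(sprintf("%.1f%% of bootstrap resamples failed to converge (limit 1%%)",
                   100 * fail))
    }
    reri_b <- reri_b[!is.na(reri_b)]
  }
  alpha <- 1 - conf_level
  ci <- unname(stats::quantile(reri_b, c(alpha / 2, 1 - alpha / 2)))
  p_add <- 2 * min(mean(reri_b <= 0), mean(reri_b > 0))
  p_add <- min(max(p_add, 2 / n_boot), 1)
  structure(list(reri_point = point, reri_ci = ci, p_additive = p_add,
                 n_boot = n_boot, seed = seed,
                 ap = point / unname(ors[3L]),
                 synergy_index = (unname(ors[3L]) - 1) /
                   (unname(ors[1L]) + unname(ors[2L]) - 2),
                 reri_boot = reri_b),
            class = "additive_interaction")
}

#' @export
print.additive_interaction <- function(x, ...) {
  cat(sprintf("Additive interaction: RERI = %.3f (95%% CI %.3f to %.3f), p = %s\n",
              x$reri_point, x$reri_ci[1L], x$reri_ci[2L], format_p(x$p_additive)))
  cat(sprintf("  AP = %.3f, S = %.3f; %d bootstrap resamples, seed %d\n",
              x$ap, x$synergy_index, x$n_boot, x$seed))
  invisible(x)
}

#' Full pairwise gene-environment interaction analysis
#'
#' Stratified ORs, the multiplicative product-term test and the additive
#' RERI bootstrap for one variant/exposure pair, mirroring a stratified
#' interaction table.
#'
#' @inheritParams additive_interaction_bootstrap
#' @return An `interaction_result` list: `stratum_ors`, `p_multiplicative`,
#'   `or_interaction`, `reri_point`, `reri_ci`, `p_additive`, `n_boot`,
#'   `seed`.
#' @export
interaction_analysis <- function(x, variant, model = "dominant", exposure,
                                 covariates = character(0L),
                                 n_boot = 10000L, seed, exposure_ref = 0) {
  strat <- stratified_ors(x, variant, model, exposure, covariates)
  mult <- multiplicative_interaction(x, variant, model, exposure, covariates,
                                     exposure_ref)
  add <- additive_interaction_bootstrap(x, variant, model, exposure,
                                        covariates, n_boot, seed,
                                        exposure_ref)
  structure(list(stratum_ors = strat, p_multiplicative = mult$p_value,
                 or_interaction = mult$or_interaction,
                 reri_point = add$reri_point, reri_ci = add$reri_ci,
                 p_additive = add$p_additive, n_boot = n_boot, seed = seed),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat("Stratified ORs:\n")
  for (nm in names(x$stratum_ors)) {
    r <- x$stratum_ors[[nm]]
    cat(sprintf("  stratum %s: OR %.2f (%.2f-%.2f)\n", nm, r$or, r$ci_low, r$ci_high))
  }
  cat(sprintf("P_mult = %s; RERI = %.3f (%.3f to %.3f), P_add = %s\n",
              format_p(x$p_multiplicative), x$reri_point,
              x$reri_ci[1L], x$reri_ci[2L], format_p(x$p_additive)))
  invisible(x)
}
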