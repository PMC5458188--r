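#' Specify one association test for permutation correction
#'
#' @param variant Variant id (or [variant_def()]).
#' @param coding Genetic coding name or [genetic_coding()].
#' @param covariates Adjustment covariates (default none: crude test).
#' @return A `perm_test` specification.
#' @export
perm_test <- function(variant, coding = "dominant", covariates = character(0L)) {
  structure(list(variant = variant, coding = as_genetic_coding(coding),
                 covariates = covariates), class = "perm_test")
}

# Two-sided Wald p from a 2x2 split of binary exposure by phenotype,
# Haldane-corrected when a cell is zero. Identical to the logistic Wald p by
# the saturated-model identity, but closed-form.
wald_p_2x2 <- function(ph, e) {
  a <- sum(ph & e); b <- sum(ph & !e)
  c <- sum(!ph & e); d <- sum(!ph & !e)
  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5
  lor <- log(cells[1L]) + log(cells[4L]) - log(cells[2L]) - log(cells[3L])
  se <- sqrt(sum(1 / cells))
  2 * stats::pnorm(-abs(lor / se))
}

#' Permutation empirical p-values for a family of genetic-model tests
#'
#' Corrects the observed Wald p-values of a set of single-variant tests for
#' multiple testing by permuting case/control labels. Labels are shuffled
#' uniformly; genotypes and covariates travel with the subject, so the
#' genotype-covariate joint distribution is preserved and exchangeability
#' holds under the global null of no phenotype association. All tests share
#' one permutation stream, so the correction respects the correlation among
#' linked variants. The empirical p uses the add-one rule
#' (r + 1)/(B + 1), bounded away from zero.
#'
#' A test on the codominant coding contributes one result per genotype term.
#' Crude single-indicator tests (dominant/recessive, no covariates) use a
#' closed-form 2x2 Wald statistic — equal to the logistic Wald p by the
#' saturated-model identity — all other tests refit the logistic model per
#' permutation.
#'
#' @param x A [cohort()].
#' @param tests List of [perm_test()] specifications.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Mandatory RNG seed.
#' @param max_nonconverge Abort if the fraction of permutations in which any
#'   test fails to converge exceeds this (default 0.01).
#' @param return_indices Keep the permutation index matrix for audit.
#' @return A `permutation_result_set`: list of results, each with `test_id`,
#'   `observed_p`, `empirical_p`, `n_perm`, `seed`, `n_as_extreme`.
#' @export
permutation_pvalues <- function(x, tests, n_perm = 10000L, seed,
                                max_nonconverge = 0.01,
                                return_indices = FALSE) {
  stopifnot(inherits(x, "cohort"), length(tests) >= 1L)
  if (missing(seed)) stop("seed is mandatory for permutation analysis")
  # Expand each spec into unit tests (one per genetic term) with
  # precomputed complete-case design material.
  units <- list()
  for (spec in tests) {
    d <- build_design(x, spec$variant, spec$coding, spec$covariates)
    if (length(d$y) < 2L) stop("no usable subjects for test on ", d$variant$id)
    for (tm in d$genetic_terms) {
      units[[length(units) + 1L]] <- list(
        id = paste(d$variant$id, d$coding$name, tm, sep = ":"),
        X = d$X, keep = d$keep, term = tm,
        fast = length(spec$covariates) == 0L && length(d$genetic_terms) == 1L &&
          all(d$X[, tm] %in% c(0, 1)),
        exposure = d$X[, tm] == 1
      )
    }
  }
  ph_full <- x$subjects$phenotype
  p_of <- function(u, ph_sub) {
    if (u$fast) return(wald_p_2x2(ph_sub == 1L, u$exposure))
    f <- tryCatch(fit_logistic(ph_sub, u$X), error = function(e) NULL)
    if (is.null(f) || !f$converged) return(NA_real_)
    b <- f$beta[[u$term]]
    2 * stats::pnorm(-abs(b / sqrt(f$vcov[u$term, u$term])))
  }
  observed <- vapply(units, function(u) p_of(u, ph_full[u$keep]), numeric(1L))
  if (anyNA(observed)) stop("a test does not converge on the observed data")
  n <- length(ph_full)
  set.seed(seed, kind = "Mersenne-Twister")
  idx <- if (return_indices) matrix(NA_integer_, n, n_perm) else NULL
  n_extreme <- numeric(length(units))
  n_fail <- numeric(length(units))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    if (return_indices) idx[, b] <- perm
    ph_perm <- ph_full[perm]
    for (j in seq_along(units)) {
      u <- units[[j]]
      pj <- p_of(u, ph_perm[u$keep])
      # "as extreme" with a relative tolerance: label-swapped tables give the
      # same |z| up to the last ulp, and an exact <= would miss those ties
      if (is.na(pj)) n_fail[j] <- n_fail[j] + 1 else
        n_extreme[j] <- n_extreme[j] + (pj <= observed[j] * (1 + 1e-9) + 1e-300)
    }
  }
  if (any(n_fail / n_perm > max_nonconverge)) {
    bad <- which.max(n_fail)
    stop(sprintf("test '%s' failed to converge in %.1f%% of permutations (limit %.1f%%)",
                 units[[bad]]$id, 100 * n_fail[bad] / n_perm,
                 100 * max_nonconverge))
  }
  res <- lapply(seq_along(units), function(j) {
    structure(list(test_id = units[[j]]$id, observed_p = observed[j],
                   empirical_p = (n_extreme[j] + 1) / (n_perm + 1),
                   n_perm = n_perm, seed = seed,
                   n_as_extreme = as.integer(n_extreme[j])),
              class = "permutation_result")
  })
  names(res) <- vapply(units, `[[`, character(1L), "id")
  structure(res, indices = idx, class = "permutation_result_set")
}

#' @export
print.permutation_result_set <- function(x, ...) {
  cat(sprintf("Permutation empirical p-values (%d permutations, seed %d):\n",
              x[[1L]]$n_perm, x[[1L]]$seed))
  for (r in x) {
    cat(sprintf("  %-40s p = %s  p_perm = %s\n", r$test_id,
                format_p(r$observed_p), format_p(r$empirical_p)))
  }
  invisible(x)
}
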