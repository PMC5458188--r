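#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson statistic, sum (O-E)^2/E with expected counts from the
#' product of the margins, on (r-1)(c-1) degrees of freedom. No continuity
#' correction is ever applied, for 2x2 tables included: the package's
#' reference fixtures (e.g. a gender table whose published statistic is 0.15)
#' are uncorrected values, and mixing corrected and uncorrected statistics
#' across table sizes would make permutation reference distributions
#' inconsistent.
#'
#' @param x A non-negative count matrix, or a [two_by_two()].
#' @return A `chisq_result` list: `statistic`, `df`, `p_value`, `expected`.
#' @export
pearson_chi2 <- function(x) {
  if (inherits(x, "two_by_two")) x <- as.matrix(x)
  x <- as.matrix(x)
  if (any(x < 0)) stop("counts must be non-negative")
  rs <- rowSums(x); cs <- colSums(x)
  if (any(rs == 0)) stop("degenerate table: row '", rownames(x)[which(rs == 0)[1L]] %||%
                           which(rs == 0)[1L], "' has zero total")
  if (any(cs == 0)) stop("degenerate table: column '", colnames(x)[which(cs == 0)[1L]] %||%
                           which(cs == 0)[1L], "' has zero total")
  ct <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value), expected = ct$expected),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.4f, df = %d, p = %s\n",
              x$statistic, x$df, format_p(x$p_value)))
  invisible(x)
}

Z95 <- 1.959964

#' Crude odds ratio with Woolf confidence interval
#'
#' OR = ad/bc from a 2x2 table, with the log-scale Woolf standard error
#' sqrt(1/a + 1/b + 1/c + 1/d) and a two-sided Wald p-value. If any cell is
#' zero the Haldane-Anscombe correction (+0.5 to all four cells) is applied
#' and the result flagged via `haldane = TRUE`.
#'
#' @param t A [two_by_two()].
#' @param z Normal quantile for the CI (default `1.959964`, a 95% interval).
#' @return An `or_result` list: `or`, `ci_low`, `ci_high`, `p_value`,
#'   `contrast_label`, `adjusted = FALSE`, `haldane`, and the cells used.
#' @export
crude_or <- function(t, z = Z95) {
  stopifnot(inherits(t, "two_by_two"))
  cells <- c(t$a, t$b, t$c, t$d)
  haldane <- any(cells == 0)
  if (haldane) cells <- cells + 0.5
  lor <- log(cells[1L]) + log(cells[4L]) - log(cells[2L]) - log(cells[3L])
  se <- sqrt(sum(1 / cells))
  p <- 2 * stats::pnorm(-abs(lor / se))
  structure(list(or = exp(lor), ci_low = exp(lor - z * se),
                 ci_high = exp(lor + z * se), p_value = p,
                 se_log = se,
                 contrast_label = paste(t$labels["exposed"], "vs", t$labels["unexposed"]),
                 adjusted = FALSE, covariates = character(0L),
                 haldane = haldane, cells = c(a = t$a, b = t$b, c = t$c, d = t$d)),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("%s OR %s: %.2f (95%% CI %.2f-%.2f), p = %s%s\n",
              if (x$adjusted) "Adjusted" else "Crude",
              x$contrast_label, x$or, x$ci_low, x$ci_high,
              format_p(x$p_value),
              if (isTRUE(x$haldane)) " [Haldane-corrected]" else ""))
  if (x$adjusted && length(x$covariates)) {
    cat("  adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' Compares observed genotype counts (n0, n1, n2 copies of one allele) with
#' the q^2, 2pq, p^2 expectation at the sample allele frequency, by the
#' asymptotic chi-square on 1 df (the frequency is estimated, leaving one
#' free dimension). An exact test (conditional on allele counts, summing
#' heterozygote probabilities as or less likely than observed) is available
#' via `exact = TRUE` for sparse genotype classes.
#'
#' @param counts Length-3 non-negative integer vector `(n0, n1, n2)`, counts
#'   of genotypes carrying 0, 1, 2 copies of the allele whose frequency is
#'   reported.
#' @param exact Use the exact conditional test instead of the chi-square.
#' @return An `hwe_result` list: `allele_freq` (of the counted allele),
#'   `expected`, `statistic`, `df`, `p_value`, `monomorphic`, `method`.
#' @export
hwe_test <- function(counts, exact = FALSE) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n0 <- counts[1L]; n1 <- counts[2L]; n2 <- counts[3L]
  N <- n0 + n1 + n2
  if (N == 0) stop("empty genotype counts")
  p <- (2 * n2 + n1) / (2 * N)
  q <- 1 - p
  expected <- c(q^2, 2 * p * q, p^2) * N
  if (p == 0 || p == 1) {
    return(structure(list(allele_freq = p, expected = expected, statistic = 0,
                          df = 1L, p_value = 1, monomorphic = TRUE,
                          method = "chisq"), class = "hwe_result"))
  }
  if (exact) {
    p_value <- hwe_exact_p(n0, n1, n2)
    stat <- NA_real_
    method <- "exact"
  } else {
    stat <- sum((counts - expected)^2 / expected)
    p_value <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
    method <- "chisq"
  }
  structure(list(allele_freq = p, expected = expected, statistic = stat,
                 df = 1L, p_value = p_value, monomorphic = FALSE,
                 method = method), class = "hwe_result")
}

# Exact HWE p: conditional distribution of heterozygote count given allele
# counts; p = sum of probabilities <= observed probability.
hwe_exact_p <- function(n0, n1, n2) {
  N <- n0 + n1 + n2
  nA <- 2 * n2 + n1           # copies of counted allele
  na <- 2 * N - nA
  nh <- seq(nA %% 2L, min(nA, na), by = 2L)
  n2v <- (nA - nh) / 2
  n0v <- (na - nh) / 2
  logp <- lgamma(N + 1) - lgamma(n0v + 1) - lgamma(nh + 1) - lgamma(n2v + 1) +
    nh * log(2) + lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * N + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n1, nh)]
  sum(pr[pr <= obs + 1e-12])
}

#' @export
print.hwe_result <- function(x, ...) {
  if (x$method == "exact") {
    cat(sprintf("HWE exact test: allele freq %.3f, p = %s\n",
                x$allele_freq, format_p(x$p_value)))
  } else {
    cat(sprintf("HWE chi-square: allele freq %.3f, X2 = %.3f (df 1), p = %s%s\n",
                x$allele_freq, x$statistic, format_p(x$p_value),
                if (x$monomorphic) " [monomorphic]" else ""))
  }
  invisible(x)
}

#' Maximum-likelihood logistic regression
#'
#' Newton-Raphson / iteratively reweighted least squares fit of a binary
#' outcome on a design matrix. Convergence is declared when the largest
#' coefficient update falls below `tol_beta` or the log-likelihood change
#' below `tol_loglik`, within `max_iter` iterations. If the iteration cap is
#' hit with any coefficient exceeding 15 on the standardised (unit predictor
#' SD) scale, the fit is flagged as non-converged — the classic footprint of
#' separated data — and is never silently returned as converged.
#'
#' @param y Binary 0/1 outcome vector.
#' @param X Numeric design matrix (without intercept unless
#'   `intercept = FALSE`); column names become term names.
#' @param intercept Prepend an intercept column (default `TRUE`).
#' @param tol_beta,tol_loglik,max_iter Convergence controls.
#' @return A `logistic_fit` list: `terms`, `beta`, `vcov` (inverse observed
#'   information), `loglik`, `converged`, `n_used`, `n_iter`.
#' @export
fit_logistic <- function(y, X, intercept = TRUE,
                         tol_beta = 1e-8, tol_loglik = 1e-10, max_iter = 100L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- stats::complete.cases(y, X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  n <- length(y); k <- ncol(X)
  if (n <= k) stop("need more observations (", n, ") than terms (", k, ")")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds[-1L] == 0) && intercept) {
    stop("constant non-intercept column: ",
         paste(colnames(X)[-1L][sds[-1L] == 0], collapse = ", "))
  }
  beta <- numeric(k)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-12)
    info <- crossprod(X, X * w)
    score <- crossprod(X, y - mu)
    delta <- tryCatch(solve(info, score),
                      error = function(e) stop("information matrix singular: ", conditionMessage(e)))
    beta <- beta + drop(delta)
    eta <- drop(X %*% beta)
    ll <- sum(stats::dbinom(y, 1L, stats::plogis(eta), log = TRUE))
    if (max(abs(delta)) < tol_beta || abs(ll - ll_old) < tol_loglik) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    if (iter >= max_iter) break
  }
  std_beta <- beta * c(1, sds[-1L])[seq_len(k)]
  if (intercept) std_beta[1L] <- 0
  # a fit whose likelihood has stalled but whose standardized coefficients
  # have run off to +/-15 is separated, whichever exit fired
  separated <- any(abs(std_beta) > 15)
  if (separated) converged <- FALSE
  mu <- stats::plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-12)
  vc <- solve(crossprod(X, X * w))
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(terms = colnames(X), beta = stats::setNames(beta, colnames(X)),
                 vcov = vc,
                 loglik = sum(stats::dbinom(y, 1L, mu, log = TRUE)),
                 converged = converged, separated = separated,
                 n_used = n, n_iter = iter),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, loglik = %.3f, %s (%d iterations)\n",
              x$n_used, x$loglik,
              if (x$converged) "converged" else if (x$separated)
                "NOT converged (separation suspected)" else "NOT converged",
              x$n_iter))
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(beta = x$beta, se = se, z = x$beta / se,
                    p = 2 * stats::pnorm(-abs(x$beta / se)))
  print(round(tab, 4L))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$beta

#' @export
vcov.logistic_fit <- function(object, ...) object$vcov

#' @export
logLik.logistic_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta), class = "logLik")
}

# Wald OR for one term of a logistic fit.
term_or <- function(fit, term, contrast_label, covariates, z = Z95) {
  if (!term %in% fit$terms) stop("term '", term, "' not in fit")
  b <- fit$beta[[term]]
  se <- sqrt(fit$vcov[term, term])
  structure(list(or = exp(b), ci_low = exp(b - z * se), ci_high = exp(b + z * se),
                 p_value = 2 * stats::pnorm(-abs(b / se)), se_log = se,
                 contrast_label = contrast_label,
                 adjusted = length(covariates) > 0L, covariates = covariates,
                 haldane = FALSE, cells = NULL),
            class = "or_result")
}

# Assemble outcome + design for a variant under a coding, plus covariate
# columns (complete-case across everything used).
build_design <- function(x, variant, coding, covariates = character(0L)) {
  stopifnot(inherits(x, "cohort"))
  v <- if (inherits(variant, "variant_def")) variant else x$variants[[variant]]
  if (is.null(v)) stop("unknown variant")
  coding <- as_genetic_coding(coding)
  calls <- x$subjects[[v$id]]
  G <- coding$build(calls, v)
  C <- NULL
  if (length(covariates)) {
    miss <- setdiff(covariates, names(x$subjects))
    if (length(miss)) stop("covariates not found: ", paste(miss, collapse = ", "))
    C <- as.matrix(x$subjects[, covariates, drop = FALSE])
  }
  X <- if (is.null(C)) G else cbind(G, C)
  keep <- stats::complete.cases(X)
  list(y = x$subjects$phenotype[keep], X = X[keep, , drop = FALSE],
       keep = which(keep), genetic_terms = colnames(G), variant = v,
       coding = coding)
}

#' Adjusted odds ratios under a genetic coding
#'
#' Fits phenotype ~ genetic term(s) + covariates by maximum-likelihood
#' logistic regression and returns one OR per genetic term
#' (two for the codominant coding, one otherwise), each with a Wald CI and
#' two-sided p. With `covariates = character(0)` this reproduces the crude
#' cross-product OR on the same complete-case subject set.
#'
#' @param x A [cohort()].
#' @param variant A [variant_def()] or the id of a declared variant.
#' @param coding A [genetic_coding()] or its name.
#' @param covariates Character vector of adjustment columns (binary 0/1, or
#'   continuous such as `age`).
#' @return List of `or_result`, one per genetic term; the `logistic_fit` is
#'   attached as attribute `fit`.
#' @export
adjusted_or <- function(x, variant, coding = "codominant",
                        covariates = character(0L)) {
  d <- build_design(x, variant, coding, covariates)
  fit <- fit_logistic(d$y, d$X)
  if (!fit$converged) stop("logistic fit did not converge",
                           if (fit$separated) " (separation suspected)" else "")
  base <- reference_genotype_label(d$variant)
  res <- lapply(d$genetic_terms, function(tm) {
    term_or(fit, tm, paste(tm, "vs", base), covariates)
  })
  names(res) <- d$genetic_terms
  attr(res, "fit") <- fit
  res
}

#' Fit and rank the four genetic models
#'
#' Fits the codominant, dominant, recessive and additive codings (with any
#' adjustment covariates) and ranks the converged fits by AIC. All fits are
#' returned, converged or not, so the ranking is auditable; non-converged
#' fits are excluded from the ranking with a warning.
#'
#' @inheritParams adjusted_or
#' @return A `genetic_model_selection` list: `fits` (named `logistic_fit`s),
#'   `ranking` (data.frame with model, AIC, loglik, df, converged, ordered by
#'   AIC), `ors` (per-model OR results), `best` (name of the top-ranked
#'   model).
#' @export
select_genetic_model <- function(x, variant, covariates = character(0L)) {
  models <- c("codominant", "dominant", "recessive", "additive")
  fits <- list(); ors <- list()
  for (m in models) {
    d <- build_design(x, variant, m, covariates)
    fits[[m]] <- fit_logistic(d$y, d$X)
    ors[[m]] <- tryCatch(adjusted_or(x, variant, m, covariates),
                         error = function(e) NULL)
  }
  aic <- vapply(fits, function(f) 2 * length(f$beta) - 2 * f$loglik, numeric(1L))
  conv <- vapply(fits, `[[`, logical(1L), "converged")
  if (any(!conv)) {
    warning("excluded from ranking (non-converged): ",
            paste(models[!conv], collapse = ", "))
  }
  rk <- data.frame(model = models, aic = aic,
                   loglik = vapply(fits, `[[`, numeric(1L), "loglik"),
                   df = vapply(fits, function(f) length(f$beta), integer(1L)),
                   converged = conv, row.names = NULL)
  rk <- rk[order(!rk$converged, rk$aic), ]
  structure(list(fits = fits, ranking = rk, ors = ors,
                 best = rk$model[rk$converged][1L]),
            class = "genetic_model_selection")
}

#' @export
print.genetic_model_selection <- function(x, ...) {
  cat("Genetic model ranking (by AIC):\n")
  print(transform(x$ranking, aic = round(aic, 2L), loglik = round(loglik, 2L)),
        row.names = FALSE)
  cat("best:", x$best, "\n")
  invisible(x)
}

format_p <- function(p, digits = 3L) {
  ifelse(p < 10^-digits, paste0("<", format(10^-digits)),
         formatC(p, format = "f", digits = digits))
}
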