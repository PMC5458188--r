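# Enumerate the unordered compatible haplotype pairs for one multilocus
# genotype (vector over L loci of alt-allele copies). Haplotypes are encoded
# as integers 0..2^L-1, bit l set = alt allele at locus l (locus 1 = least
# significant bit). k heterozygous loci yield 2^(k-1) pairs.
compatible_pairs <- function(g) {
  L <- length(g)
  het <- which(g == 1L)
  base <- sum(as.integer(g == 2L) * 2L^(seq_len(L) - 1L))
  if (length(het) == 0L) return(matrix(c(base, base), 1L, 2L))
  k <- length(het)
  bits <- 2L^(het - 1L)
  full <- sum(bits)
  # fix the first het locus on haplotype 1 to the ref allele: unordered pairs
  combos <- if (k == 1L) matrix(0L, 1L, 1L) else
    as.matrix(expand.grid(rep(list(0:1), k - 1L)))
  h1 <- base + if (k == 1L) rep(0L, nrow(combos)) else
    as.integer(combos %*% bits[-1L])
  h2 <- base + full - (h1 - base)
  cbind(h1, h2)
}

hap_string <- function(code, L, alleles) {
  vapply(code, function(h) {
    bits <- bitwAnd(h %/% 2L^(seq_len(L) - 1L), 1L)
    paste(vapply(seq_len(L), function(l) alleles[[l]][bits[l] + 1L], character(1L)),
          collapse = "")
  }, character(1L))
}

#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Standard expectation-maximisation over diplotypes: the E-step distributes
#' each subject's genotype over its compatible haplotype pairs in proportion
#' to the current frequency products (2 f_i f_j for heterozygous pairs), the
#' M-step re-estimates frequencies from the expected haplotype counts.
#' Iteration stops when the largest frequency change drops below `tol`. The
#' observed-data log-likelihood is asserted to be non-decreasing at every
#' iteration. Because the likelihood can be multi-modal for three or more
#' loci, the first start is uniform over the compatible haplotypes and the
#' remaining `n_start - 1` are random (seeded); the best final
#' log-likelihood wins.
#'
#' Subjects with a missing call at any of the loci are excluded
#' (complete-case over the haplotype block).
#'
#' @param x A [cohort()] (with `loci` naming declared variants) or an
#'   n-by-L matrix of 0/1/2 alt-allele counts.
#' @param loci Variant ids / column names, in haplotype order.
#' @param tol Convergence threshold on max absolute frequency change
#'   (default 1e-8).
#' @param max_iter Iteration cap (default 10000).
#' @param n_start Number of EM starts (default 5).
#' @param seed Seed for the random restarts (default 1).
#' @return A `haplotype_set`: `loci`, `haplotype` (allele strings),
#'   `freq`, `loglik`, `n_iter`, `converged`, `n_subjects`.
#' @export
em_haplotypes <- function(x, loci = NULL, tol = 1e-8, max_iter = 10000L,
                          n_start = 5L, seed = 1L) {
  if (inherits(x, "cohort")) {
    loci <- loci %||% names(x$variants)
    alleles <- lapply(x$variants[loci], function(v) c(v$allele_ref, v$allele_alt))
    G <- as.matrix(x$subjects[, loci, drop = FALSE])
  } else {
    G <- as.matrix(x)
    loci <- loci %||% colnames(G) %||% paste0("locus", seq_len(ncol(G)))
    alleles <- rep(list(c("0", "1")), ncol(G))
  }
  L <- ncol(G)
  if (L < 2L) stop("need at least 2 loci")
  G <- G[stats::complete.cases(G), , drop = FALSE]
  n <- nrow(G)
  if (n == 0L) stop("no subjects with complete calls at the requested loci")
  # unique genotype classes
  key <- apply(G, 1L, paste, collapse = "/")
  cls <- !duplicated(key)
  counts <- as.vector(table(key)[key[cls]])
  pairs <- lapply(which(cls), function(i) compatible_pairs(G[i, ]))
  haps <- sort(unique(unlist(pairs)))
  H <- length(haps)
  idx <- function(h) match(h, haps)
  pairs <- lapply(pairs, function(p) cbind(idx(p[, 1L]), idx(p[, 2L])))
  run_em <- function(f0) {
    f <- f0
    ll_old <- -Inf
    iter <- 0L
    converged <- FALSE
    repeat {
      iter <- iter + 1L
      expected <- numeric(H)
      ll <- 0
      for (j in seq_along(pairs)) {
        p <- pairs[[j]]
        pr <- f[p[, 1L]] * f[p[, 2L]] * ifelse(p[, 1L] == p[, 2L], 1, 2)
        tot <- sum(pr)
        if (tot <= 0) { ll <- -Inf; break }
        w <- counts[j] * pr / tot
        for (r in seq_len(nrow(p))) {
          expected[p[r, 1L]] <- expected[p[r, 1L]] + w[r]
          expected[p[r, 2L]] <- expected[p[r, 2L]] + w[r]
        }
        ll <- ll + counts[j] * log(tot)
      }
      if (is.finite(ll_old) && ll < ll_old - 1e-9) {
        stop("internal error: EM log-likelihood decreased")
      }
      f_new <- expected / (2 * n)
      delta <- max(abs(f_new - f))
      f <- f_new
      if (delta < tol) { converged <- TRUE; ll_old <- ll; break }
      ll_old <- ll
      if (iter >= max_iter) break
    }
    list(f = f, loglik = ll_old, n_iter = iter, converged = converged)
  }
  best <- NULL
  set.seed(seed, kind = "Mersenne-Twister")
  for (s in seq_len(max(1L, n_start))) {
    f0 <- if (s == 1L) rep(1 / H, H) else {
      d <- stats::rgamma(H, 1); d / sum(d)
    }
    fit <- run_em(f0)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  structure(list(loci = loci,
                 haplotype = hap_string(haps, L, alleles),
                 hap_code = haps, freq = best$f, loglik = best$loglik,
                 n_iter = best$n_iter, converged = best$converged,
                 n_subjects = n, alleles = alleles),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, digits = 4L, ...) {
  cat(sprintf("<haplotype_set> %d loci (%s), %d subjects, loglik %.4f%s\n",
              length(x$loci), paste(x$loci, collapse = ", "), x$n_subjects,
              x$loglik, if (x$converged) "" else " [NOT converged]"))
  ord <- order(-x$freq)
  print(data.frame(haplotype = x$haplotype[ord],
                   freq = round(x$freq[ord], digits)), row.names = FALSE)
  invisible(x)
}

# Two-locus haplotype frequencies (AB, Ab, aB, ab) with A/B = alt alleles.
marginal_pair_freqs <- function(hapset, pair) {
  L <- length(hapset$loci)
  pos <- if (is.character(pair)) match(pair, hapset$loci) else pair
  if (anyNA(pos)) stop("unknown loci in pair")
  b1 <- bitwAnd(hapset$hap_code %/% 2L^(pos[1L] - 1L), 1L)
  b2 <- bitwAnd(hapset$hap_code %/% 2L^(pos[2L] - 1L), 1L)
  c(AB = sum(hapset$freq[b1 == 1L & b2 == 1L]),
    Ab = sum(hapset$freq[b1 == 1L & b2 == 0L]),
    aB = sum(hapset$freq[b1 == 0L & b2 == 1L]),
    ab = sum(hapset$freq[b1 == 0L & b2 == 0L]))
}

#' Pairwise linkage disequilibrium
#'
#' D = p(AB) - p(A)p(B); D' = |D| / Dmax where Dmax is
#' min(p(A)p(b), p(a)p(B)) for positive D and min(p(A)p(B), p(a)p(b))
#' otherwise; r^2 = D^2 / (p(A)p(a)p(B)p(b)). D' is reported as an absolute
#' value in [0, 1].
#'
#' @param x A `haplotype_set` (LD computed from the fitted frequencies), or
#'   a length-4 numeric vector of two-locus haplotype frequencies in order
#'   (AB, Ab, aB, ab).
#' @param pair For a `haplotype_set`: the two loci (ids or positions).
#' @return An `ld_stats` list: `pair`, `D`, `D_prime`, `r2`, and the allele
#'   frequencies used.
#' @export
pairwise_ld <- function(x, pair = c(1L, 2L)) {
  if (inherits(x, "haplotype_set")) {
    p4 <- marginal_pair_freqs(x, pair)
    lab <- if (is.character(pair)) pair else x$loci[pair]
  } else {
    p4 <- as.numeric(x)
    if (length(p4) != 4L || abs(sum(p4) - 1) > 1e-6) {
      stop("expected 4 haplotype frequencies (AB, Ab, aB, ab) summing to 1")
    }
    names(p4) <- c("AB", "Ab", "aB", "ab")
    lab <- c("locus1", "locus2")
  }
  pA <- unname(p4["AB"] + p4["Ab"]); pB <- unname(p4["AB"] + p4["aB"])
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    stop("LD undefined: a locus is monomorphic")
  }
  D <- unname(p4["AB"] - pA * pB)
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  structure(list(pair = lab, D = D,
                 D_prime = if (D == 0) 0 else abs(D) / dmax,
                 r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
                 p_A = unname(pA), p_B = unname(pB)),
            class = "ld_stats")
}

#' @export
print.ld_stats <- function(x, ...) {
  cat(sprintf("LD %s-%s: D = %.4f, D' = %.3f, r2 = %.3f\n",
              x$pair[1L], x$pair[2L], x$D, x$D_prime, x$r2))
  invisible(x)
}

#' Haplotype-level case-control association
#'
#' Runs the EM separately on cases, controls and the pooled sample, reports
#' haplotypes whose pooled frequency exceeds `min_freq` (rarer ones pooled
#' into `"other"`), and for each common haplotype an odds ratio (that
#' haplotype vs all others) from the *expected* haplotype counts with a
#' Woolf CI. Because the counts are EM expectations rather than observed
#' chromosomes, the CIs understate uncertainty; every result is flagged
#' `em_based`.
#'
#' @param x A [cohort()].
#' @param loci Variant ids in haplotype order (default: all declared).
#' @param min_freq Pooled-frequency threshold for reporting (default 0.05).
#' @param ... Passed to [em_haplotypes()].
#' @return A `haplotype_association` object: a data.frame `table` with
#'   haplotype, case/control frequencies and expected counts, OR, CI, p; and
#'   the three `haplotype_set`s.
#' @export
haplotype_association <- function(x, loci = NULL, min_freq = 0.05, ...) {
  stopifnot(inherits(x, "cohort"))
  loci <- loci %||% names(x$variants)
  ph <- x$subjects$phenotype
  sub <- function(rows) cohort(x$subjects[rows, , drop = FALSE], x$variants)
  em_case <- em_haplotypes(sub(ph == 1L), loci, ...)
  em_ctrl <- em_haplotypes(sub(ph == 0L), loci, ...)
  em_pool <- em_haplotypes(x, loci, ...)
  freq_of <- function(em, hap) {
    i <- match(hap, em$haplotype)
    ifelse(is.na(i), 0, em$freq[i])
  }
  common <- em_pool$haplotype[em_pool$freq > min_freq]
  rare <- setdiff(em_pool$haplotype, common)
  n_case <- 2 * em_case$n_subjects
  n_ctrl <- 2 * em_ctrl$n_subjects
  rows <- lapply(common, function(h) {
    fc <- freq_of(em_case, h); fk <- freq_of(em_ctrl, h)
    data.frame(haplotype = h, freq_case = fc, freq_control = fk,
               freq_pooled = freq_of(em_pool, h),
               count_case = fc * n_case, count_control = fk * n_ctrl)
  })
  tab <- do.call(rbind, rows)
  if (length(rare)) {
    fc <- sum(vapply(rare, freq_of, numeric(1L), em = em_case))
    fk <- sum(vapply(rare, freq_of, numeric(1L), em = em_ctrl))
    tab <- rbind(tab, data.frame(
      haplotype = "other", freq_case = fc, freq_control = fk,
      freq_pooled = sum(em_pool$freq[match(rare, em_pool$haplotype)]),
      count_case = fc * n_case, count_control = fk * n_ctrl))
  }
  if (length(common) >= 2L) {
    ors <- lapply(seq_len(nrow(tab)), function(i) {
      tt <- two_by_two(tab$count_case[i], n_case - tab$count_case[i],
                       tab$count_control[i], n_ctrl - tab$count_control[i],
                       exposed = tab$haplotype[i], unexposed = "all others")
      crude_or(tt)
    })
    tab$or <- vapply(ors, `[[`, numeric(1L), "or")
    tab$ci_low <- vapply(ors, `[[`, numeric(1L), "ci_low")
    tab$ci_high <- vapply(ors, `[[`, numeric(1L), "ci_high")
    tab$p_value <- vapply(ors, `[[`, numeric(1L), "p_value")
  }
  structure(list(table = tab, em_case = em_case, em_control = em_ctrl,
                 em_pooled = em_pool, min_freq = min_freq, em_based = TRUE),
            class = "haplotype_association")
}

#' @export
print.haplotype_association <- function(x, ...) {
  cat(sprintf("Haplotype association (%s; pooled frequency > %g reported; EM-based counts)\n",
              paste(x$em_pooled$loci, collapse = "-"), x$min_freq))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1L))
  tab[num] <- lapply(tab[num], round, 3L)
  print(tab, row.names = FALSE)
  invisible(x)
}
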