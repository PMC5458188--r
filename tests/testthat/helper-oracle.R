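# Brute-force maximised log-likelihood for 2-locus unphased genotypes,
# independent of the EM implementation: an exhaustive grid over the
# 4-haplotype simplex (step `res`), refined by a softmax-parameterised
# Nelder-Mead fit started from the best grid point.
oracle_loglik <- function(G, res = 0.01) {
  stopifnot(ncol(G) == 2L)
  key <- paste(G[, 1L], G[, 2L])
  counts <- table(key)
  gclasses <- do.call(rbind, lapply(strsplit(names(counts), " "), as.integer))
  nc <- as.vector(counts)
  # haplotypes indexed 1..4 = (00, 10, 01, 11); per class, its compatible
  # unordered pairs with multiplicity 2 for heterozygous pairs
  hapmat <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  class_pairs <- lapply(seq_len(nrow(gclasses)), function(i) {
    g <- gclasses[i, ]
    out <- NULL
    for (h1 in 1:4) for (h2 in h1:4) {
      if (all(hapmat[h1, ] + hapmat[h2, ] == g)) {
        out <- rbind(out, c(h1, h2, if (h1 == h2) 1 else 2))
      }
    }
    out
  })
  # log-likelihood for each column of a 4 x m frequency matrix
  ll_of <- function(F4) {
    ll <- 0
    for (j in seq_along(class_pairs)) {
      cp <- class_pairs[[j]]
      pr <- 0
      for (r in seq_len(nrow(cp))) {
        pr <- pr + cp[r, 3L] * F4[cp[r, 1L], ] * F4[cp[r, 2L], ]
      }
      ll <- ll + nc[j] * log(pr)
    }
    ll
  }
  k <- round(1 / res)
  grid <- as.matrix(expand.grid(i = 0:k, j = 0:k, l = 0:k))
  grid <- grid[rowSums(grid) <= k, , drop = FALSE]
  F4 <- t(cbind(grid, k - rowSums(grid))) / k
  ll <- ll_of(F4)
  best <- max(ll, na.rm = TRUE)
  fbest <- F4[, which.max(ll)]
  obj <- function(theta) {
    e <- exp(c(theta, 0))
    -ll_of(matrix(e / sum(e), 4L, 1L))
  }
  th0 <- log(pmax(fbest[1:3], 1e-6) / max(fbest[4L], 1e-6))
  opt <- stats::optim(th0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-13))
  max(best, -opt$value)
}
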