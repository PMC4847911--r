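# Independent oracles used by the tests.  These share no code with the
# implementation paths they check.

# Full enumeration of genotype-count tables conditional on allele counts
# (Levene distribution), for <= 3 alleles and small n.  Returns one row per
# table: the conditional probability, heterozygote count H, homozygote
# count U, and the table-ordering statistic used by the exact test.
hweEnumTables <- function(alleleCounts) {
  K <- length(alleleCounts)
  stopifnot(K <= 3, sum(alleleCounts) %% 2 == 0)
  n <- sum(alleleCounts) / 2
  cats <- list()
  for (i in seq_len(K)) for (j in i:K)
    cats[[length(cats) + 1]] <- c(i, j)
  recurse <- function(idx, remaining, used, counts) {
    if (idx > length(cats)) {
      if (remaining != 0 || any(used != alleleCounts)) return(NULL)
      return(matrix(counts, nrow = 1))
    }
    out <- list()
    g <- cats[[idx]]
    for (k in 0:remaining) {
      u2 <- used
      u2[g[1]] <- u2[g[1]] + k
      u2[g[2]] <- u2[g[2]] + k
      if (any(u2 > alleleCounts)) break
      sub <- recurse(idx + 1, remaining - k, u2, c(counts, k))
      if (!is.null(sub)) out[[length(out) + 1]] <- sub
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }
  tabs <- recurse(1, n, rep(0, K), integer(0))
  het <- vapply(cats, function(g) g[1] != g[2], TRUE)
  H <- as.vector(tabs %*% het)
  U <- n - H
  logP <- lgamma(n + 1) + sum(lgamma(alleleCounts + 1)) -
    lgamma(2 * n + 1) + H * log(2) -
    rowSums(lgamma(tabs + 1))
  data.frame(prob = exp(logP), H = H, U = U, logP = logP)
}

# Exact lower-tail p of the conditional exact test: total probability of
# tables no more probable than the observed one.
hweEnumExactP <- function(alleleCounts, obsLogP) {
  tabs <- hweEnumTables(alleleCounts)
  sum(tabs$prob[tabs$logP <= obsLogP + 1e-9])
}

# Exact upper-tail p of the homozygote-count test.
hweEnumUP <- function(alleleCounts, obsU) {
  tabs <- hweEnumTables(alleleCounts)
  sum(tabs$prob[tabs$U >= obsU])
}

# Observed-table statistics for a 2-column allele matrix.
obsTableStats <- function(g) {
  n <- nrow(g)
  key <- paste(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2]))
  ng <- table(key)
  cA <- table(c(g))
  H <- sum(g[, 1] != g[, 2])
  logP <- lgamma(n + 1) + sum(lgamma(as.numeric(cA) + 1)) -
    lgamma(2 * n + 1) + H * log(2) - sum(lgamma(as.numeric(ng) + 1))
  list(logP = logP, U = n - H, alleleCounts = as.numeric(cA))
}

# Exclusion probability by full enumeration over genotype trios under HWE
# (small allele counts only).
exclusionEnum <- function(f) {
  al <- as.integer(names(f))
  gp <- list(); pr <- c()
  for (i in seq_along(al)) for (j in i:length(al)) {
    gp[[length(gp) + 1]] <- c(al[i], al[j])
    pr <- c(pr, if (i == j) f[i]^2 else 2 * f[i] * f[j])
  }
  tot <- 0
  for (i in seq_along(gp)) for (j in seq_along(gp)) for (k in seq_along(gp)) {
    g <- cbind(gp[[i]], gp[[j]], gp[[k]])
    if (!kinpatch:::groupCompatible(g)) tot <- tot + pr[i] * pr[j] * pr[k]
  }
  unname(tot)
}

# Mean local transitivity of an adjacency matrix (degree-<2 nodes count 0);
# independent of igraph.
meanLocalTransAdj <- function(A) {
  d <- rowSums(A)
  closed <- diag(A %*% A %*% A) / 2
  pairs <- d * (d - 1) / 2
  mean(ifelse(pairs > 0, closed / pairs, 0))
}
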