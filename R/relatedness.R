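# Pairwise relatedness by maximum likelihood on the IBD-coefficient simplex
# (k0, k1, k2), with a class-II per-allele genotyping-error model folded in
# analytically.
#
# Error model: each observed allele equals the true allele with probability
# 1 - e, otherwise it is replaced by a random draw from the locus frequency
# distribution.  Because replacement draws come from the same frequencies,
# an unshared gene copy keeps its marginal distribution, and an IBD-shared
# pair of copies stays jointly "intact" with probability q = (1 - e)^2 (else
# it behaves as two independent draws).  Hence the likelihood with error is
# the error-free likelihood evaluated at mixed state probabilities:
#   Q0 = P0
#   Q1 = (1-q) P0 + q P1
#   Q2 = (1-q)^2 P0 + 2 q (1-q) P1 + q^2 P2
# where P_m is the probability of the observed genotype pair given m IBD
# alleles (no error).  This is exact, not an approximation.
#
# The log-likelihood sum_l log(k0 Q0 + k1 Q1 + k2 Q2) is concave in k (log
# of a linear function), so the constrained maximiser is unique and a
# vectorised EM over mixture weights converges to it from any interior
# start.

# State probabilities for every dyad at every locus.
# pairsIdx: D x 2 matrix of row indices into x; returns list of three
# D x L matrices (NA where a dyad lacks a scored genotype or an allele
# frequency is unavailable).
dyadStateProbs <- function(x, pairsIdx, freqs, errorRate) {
  D <- nrow(pairsIdx); L <- length(x@loci)
  q <- (1 - errorRate)^2
  Q0 <- Q1 <- Q2 <- matrix(NA_real_, D, L)
  grp <- freqs@groups[1]
  for (j in seq_len(L)) {
    f <- freqs@freqs[[grp]][[x@loci[j]]]
    if (is.null(f)) next
    maxA <- max(as.integer(names(f)), max(x@alleles[, j, ], na.rm = TRUE), 1)
    pv <- numeric(maxA)
    pv[as.integer(names(f))] <- f
    ai1 <- x@alleles[pairsIdx[, 1], j, 1]; ai2 <- x@alleles[pairsIdx[, 1], j, 2]
    aj1 <- x@alleles[pairsIdx[, 2], j, 1]; aj2 <- x@alleles[pairsIdx[, 2], j, 2]
    ok <- !is.na(ai1) & !is.na(aj1)
    if (!any(ok)) next
    i1 <- ai1[ok]; i2 <- ai2[ok]; j1 <- aj1[ok]; j2 <- aj2[ok]
    pI1 <- pv[i1]; pI2 <- pv[i2]; pJ1 <- pv[j1]; pJ2 <- pv[j2]
    covered <- pI1 > 0 & pI2 > 0 & pJ1 > 0 & pJ2 > 0
    pgI <- ifelse(i1 == i2, pI1^2, 2 * pI1 * pI2)
    pgJ <- ifelse(j1 == j2, pJ1^2, 2 * pJ1 * pJ2)
    P0 <- pgI * pgJ
    P2 <- (i1 == j1 & i2 == j2) * pgI
    condI <- function(cc) ifelse(i1 == i2, (cc == i1) * pI1,
                                 (cc == i1) * pI2 + (cc == i2) * pI1)
    condJ <- function(cc) ifelse(j1 == j2, (cc == j1) * pJ1,
                                 (cc == j1) * pJ2 + (cc == j2) * pJ1)
    term <- function(cc) pv[cc] * condI(cc) * condJ(cc)
    P1 <- term(i1) + ifelse(i2 != i1, term(i2), 0)
    q0 <- P0
    q1 <- (1 - q) * P0 + q * P1
    q2 <- (1 - q)^2 * P0 + 2 * q * (1 - q) * P1 + q^2 * P2
    q0[!covered] <- NA; q1[!covered] <- NA; q2[!covered] <- NA
    Q0[ok, j] <- q0; Q1[ok, j] <- q1; Q2[ok, j] <- q2
  }
  list(Q0 = Q0, Q1 = Q1, Q2 = Q2)
}

# Vectorised EM for the mixture weights; returns D x 3 matrix of k-hat and
# the attained log-likelihood.  Concavity makes the optimum unique; several
# interior starts are run and the best kept as a numerical safeguard.
fitIbdSimplex <- function(Q, maxIter = 2000, tol = 1e-8,
                          starts = list(c(1, 1, 1) / 3,
                                        c(0.8, 0.15, 0.05),
                                        c(0.05, 0.15, 0.8))) {
  D <- nrow(Q$Q0)
  W <- rowSums(!is.na(Q$Q0))
  best <- NULL; bestLL <- rep(-Inf, D)
  runEM <- function(Q0, Q1, Q2, W, k0, k1, k2, maxIter) {
    # active-set EM: dyads whose coefficients have stopped moving are
    # frozen, so slow boundary cases do not stall the whole batch
    act <- seq_along(k0)
    it <- 0
    while (it < maxIter && length(act)) {
      den <- k0[act] * Q0[act, , drop = FALSE] +
        k1[act] * Q1[act, , drop = FALSE] +
        k2[act] * Q2[act, , drop = FALSE]
      n0 <- rowSums(k0[act] * Q0[act, , drop = FALSE] / den,
                    na.rm = TRUE) / W[act]
      n1 <- rowSums(k1[act] * Q1[act, , drop = FALSE] / den,
                    na.rm = TRUE) / W[act]
      n2 <- rowSums(k2[act] * Q2[act, , drop = FALSE] / den,
                    na.rm = TRUE) / W[act]
      delta <- pmax(abs(n0 - k0[act]), abs(n1 - k1[act]),
                    abs(n2 - k2[act]))
      k0[act] <- n0; k1[act] <- n1; k2[act] <- n2
      act <- act[is.finite(delta) & delta >= tol]
      it <- it + 1
    }
    cbind(k0, k1, k2)
  }
  for (s in starts) {
    k <- runEM(Q$Q0, Q$Q1, Q$Q2, W,
               rep(s[1], D), rep(s[2], D), rep(s[3], D), maxIter)
    k0 <- k[, 1]; k1 <- k[, 2]; k2 <- k[, 3]
    ll <- rowSums(log(k0 * Q$Q0 + k1 * Q$Q1 + k2 * Q$Q2), na.rm = TRUE)
    if (is.null(best)) {
      best <- cbind(k0, k1, k2); bestLL <- ll
    } else {
      upd <- ll > bestLL
      upd[is.na(upd)] <- FALSE
      best[upd, ] <- cbind(k0, k1, k2)[upd, , drop = FALSE]
      bestLL[upd] <- ll[upd]
    }
  }
  best[W == 0, ] <- NA_real_
  attr(best, "logLik") <- bestLL
  attr(best, "nLoci") <- W
  best
}

#' Pairwise maximum-likelihood relatedness
#'
#' For every dyad, the IBD coefficients \eqn{(k_0, k_1, k_2)} maximising the
#' multilocus likelihood of the observed genotype pair are found on the
#' simplex, with a class-II per-allele genotyping-error model, and
#' relatedness is \eqn{\hat r = k_2 + k_1/2}.  The triad form of the
#' likelihood (focal pair plus an unrelated reference individual) factorises
#' under this non-inbred parameterisation -- the reference genotype term is
#' constant in the pair's coefficients -- so the triadic and dyadic maxima
#' coincide; the reference arguments are accepted for interface
#' compatibility and recorded in the result.
#'
#' @param x a \linkS4class{GenotypeTable} with >= 3 individuals.
#' @param frequencies optional \linkS4class{FrequencyTable}; defaults to
#'   frequencies pooled over the full sample (kin structure inflates
#'   within-site frequencies, so pooling is the default).
#' @param errorRate per-allele genotyping error rate (default 0.01).
#' @param nReference number of reference individuals per dyad (recorded;
#'   see Details).
#' @param seed RNG seed (recorded).
#' @param maxIter,tol EM iteration cap and convergence tolerance.
#' @return a \linkS4class{RelatednessMatrix}; dyads sharing no scored locus
#'   are NA and counted in attribute \code{"noOverlap"}.
#' @export
pairwiseRelatedness <- function(x, frequencies = NULL, errorRate = 0.01,
                                nReference = 1, seed = NULL,
                                maxIter = 2000, tol = 1e-8) {
  n <- nInd(x)
  if (n < 3) stop("need >= 3 individuals (dyads plus a reference)")
  freqs <- normaliseFrequencies(frequencies, x)
  pairsIdx <- t(combn(n, 2))
  Q <- dyadStateProbs(x, pairsIdx, freqs, errorRate)
  k <- fitIbdSimplex(Q, maxIter, tol)
  r <- pmin(pmax(k[, 3] + k[, 2] / 2, 0), 1)
  rm <- symFromLower2(r, pairsIdx, n, x@ids)
  k0 <- symFromLower2(k[, 1], pairsIdx, n, x@ids)
  k1 <- symFromLower2(k[, 2], pairsIdx, n, x@ids)
  k2 <- symFromLower2(k[, 3], pairsIdx, n, x@ids)
  out <- new("RelatednessMatrix", ids = x@ids, r = rm, k0 = k0, k1 = k1,
             k2 = k2, estimator = "triadic-ml (dyadic-equivalent)",
             errorRate = errorRate, seed = seed %||% NA_real_)
  attr(out, "noOverlap") <- sum(attr(k, "nLoci") == 0)
  out
}

#' Relatedness for specified dyads
#'
#' Same estimator as \code{\link{pairwiseRelatedness}} but restricted to a
#' given set of id pairs (e.g. simulated dyads of known pedigree).
#'
#' @param x a \linkS4class{GenotypeTable}.
#' @param pairs 2-column matrix (or data.frame) of individual ids.
#' @param frequencies optional \linkS4class{FrequencyTable} or named list
#'   of allele-frequency vectors.
#' @param errorRate per-allele error rate.
#' @param maxIter,tol EM controls.
#' @return data.frame id1, id2, k0, k1, k2, r, nLoci.
#' @export
dyadRelatedness <- function(x, pairs, frequencies = NULL,
                            errorRate = 0.01, maxIter = 2000, tol = 1e-8) {
  pairs <- as.matrix(pairs)
  pairsIdx <- cbind(match(pairs[, 1], x@ids), match(pairs[, 2], x@ids))
  if (anyNA(pairsIdx)) stop("unknown individual id in 'pairs'")
  freqs <- normaliseFrequencies(frequencies, x)
  Q <- dyadStateProbs(x, pairsIdx, freqs, errorRate)
  k <- fitIbdSimplex(Q, maxIter, tol)
  data.frame(id1 = pairs[, 1], id2 = pairs[, 2], k0 = k[, 1], k1 = k[, 2],
             k2 = k[, 3], r = pmin(pmax(k[, 3] + k[, 2] / 2, 0), 1),
             nLoci = attr(k, "nLoci"))
}

# Accept a FrequencyTable, a plain named list of frequency vectors, or NULL
# (pooled global frequencies of x).
normaliseFrequencies <- function(frequencies, x) {
  if (is.null(frequencies)) return(alleleFrequencies(x, "global"))
  if (is(frequencies, "FrequencyTable")) return(frequencies)
  fl <- frequencies[x@loci]
  new("FrequencyTable", grouping = "global", groups = "all", loci = x@loci,
      freqs = list(all = fl),
      n = matrix(NA_integer_, 1, length(x@loci),
                 dimnames = list("all", x@loci)))
}

symFromLower2 <- function(v, pairsIdx, n, labels) {
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  m[pairsIdx] <- v
  m[pairsIdx[, c(2, 1), drop = FALSE]] <- v
  m
}

setMethod("show", "RelatednessMatrix", function(object) {
  v <- lowerTri(object@r)
  cat(sprintf(
    "RelatednessMatrix: %d individuals, %d dyads (%s, e = %g)\n  mean rhat = %.3f\n",
    length(object@ids), length(v), object@estimator, object@errorRate,
    mean(v, na.rm = TRUE)))
})

#' Mean within-group relatedness
#'
#' Arithmetic mean of the pairwise relatedness over all unordered
#' within-group dyads, with its standard error (SE over pairs; 0 for a
#' single pair).
#'
#' @param rm a \linkS4class{RelatednessMatrix}.
#' @param groups named character vector mapping individual ids to groups
#'   (sites or clusters).
#' @return data.frame with columns group, n, nPairs, rbar, se; singleton
#'   groups get NA.
#' @export
meanGroupRelatedness <- function(rm, groups) {
  gl <- unique(groups)
  out <- lapply(gl, function(g) {
    ids <- intersect(names(groups)[groups == g], rm@ids)
    if (length(ids) < 2)
      return(data.frame(group = g, n = length(ids), nPairs = 0,
                        rbar = NA_real_, se = NA_real_))
    sub <- rm@r[ids, ids]
    v <- lowerTri(sub)
    se <- if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
          else 0
    data.frame(group = g, n = length(ids), nPairs = sum(!is.na(v)),
               rbar = mean(v, na.rm = TRUE), se = se)
  })
  do.call(rbind, out)
}

#' Permutation test of elevated within-group relatedness
#'
#' Whole individuals (genotype rows) are permuted among groups, preserving
#' group sizes; relatedness between a given pair of individuals is
#' unaffected by relabelling, so the permuted group means are recomputed
#' from the same pairwise matrix.  One-tailed upper p-values use the
#' add-one rule; the 2.5/97.5 percentile null envelope is returned for
#' plotting.
#'
#' @param rm a \linkS4class{RelatednessMatrix}.
#' @param groups named character vector id -> group (>= 2 groups).
#' @param nPerm permutations (default 1000).
#' @param seed RNG seed.
#' @return data.frame: group, n, rbar, p, envLower, envUpper.
#' @export
relatednessPermutationTest <- function(rm, groups, nPerm = 1000,
                                       seed = NULL) {
  groups <- groups[names(groups) %in% rm@ids]
  gl <- unique(groups)
  if (length(gl) < 2) stop("need >= 2 groups")
  ids <- names(groups)
  obs <- meanGroupRelatedness(rm, groups)
  rbarFor <- function(memb) vapply(gl, function(g) {
    sel <- ids[memb == g]
    if (length(sel) < 2) return(NA_real_)
    mean(lowerTri(rm@r[sel, sel]), na.rm = TRUE)
  }, 0)
  permMat <- withSeed(seed, {
    vapply(seq_len(nPerm), function(b) rbarFor(unname(groups)[sample(length(groups))]),
           numeric(length(gl)))
  })
  if (is.null(dim(permMat))) permMat <- matrix(permMat, nrow = length(gl))
  p <- vapply(seq_along(gl), function(i) {
    if (is.na(obs$rbar[i])) return(NA_real_)
    addOneP(sum(permMat[i, ] >= obs$rbar[i] - 1e-12, na.rm = TRUE), nPerm)
  }, 0)
  env <- t(apply(permMat, 1, quantile, c(0.025, 0.975), na.rm = TRUE))
  data.frame(group = obs$group, n = obs$n, rbar = obs$rbar, p = p,
             envLower = env[, 1], envUpper = env[, 2])
}
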