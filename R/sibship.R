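# Pairwise-likelihood sibship classification (full-sib / half-sib /
# unrelated), permutation tests of within-cluster sib counts, and the
# exclusion-probability power analysis of the marker panel.
#
# This is an explicit pairwise-likelihood dyad classifier: each dyad is
# scored under the three fixed IBD hypotheses FS = (1/4, 1/2, 1/4),
# HS = (1/2, 1/2, 0), U = (1, 0, 0), with the same class-II error model as
# the relatedness module, and assigned by posterior probability.  Full
# full multi-generation pedigree reconstruction is out of scope;
# note that avuncular and grandparent-grandchild dyads share the HS
# k-vector and are indistinguishable from half-sibs here.

kVectors <- list(FS = c(0.25, 0.5, 0.25), HS = c(0.5, 0.5, 0),
                 U = c(1, 0, 0))

#' Classify dyads as full-sib, half-sib or unrelated
#'
#' Per dyad, the multilocus likelihood of the observed genotype pair is
#' computed under the FS, HS and U IBD hypotheses (error model as in
#' \code{\link{pairwiseRelatedness}}); the posterior is proportional to
#' prior x likelihood and a label is assigned only when the maximum
#' posterior reaches the confidence threshold.
#'
#' @param x a \linkS4class{GenotypeTable}.
#' @param frequencies optional \linkS4class{FrequencyTable} (default:
#'   pooled global frequencies); must cover all observed alleles.
#' @param errorRate genotyping error rate (default 0.01).
#' @param prior prior over (FS, HS, U); default uniform.
#' @param threshold posterior confidence threshold (default 0.95).
#' @param minLoci dyads with fewer overlapping scored loci are UNASSIGNED
#'   and flagged (default 3).
#' @param pairs optional 2-column id matrix restricting the dyads scored
#'   (default: all pairs).
#' @return a \linkS4class{DyadClassification}.
#' @export
classifyDyads <- function(x, frequencies = NULL, errorRate = 0.01,
                          prior = c(FS = 1, HS = 1, U = 1) / 3,
                          threshold = 0.95, minLoci = 3, pairs = NULL) {
  n <- nInd(x)
  if (n < 2) stop("need >= 2 individuals")
  freqs <- normaliseFrequencies(frequencies, x)
  pairsIdx <- if (is.null(pairs)) t(combn(n, 2)) else
    cbind(match(as.matrix(pairs)[, 1], x@ids),
          match(as.matrix(pairs)[, 2], x@ids))
  if (anyNA(pairsIdx)) stop("unknown individual id in 'pairs'")
  Q <- dyadStateProbs(x, pairsIdx, freqs, errorRate)
  ll <- vapply(names(kVectors), function(h) {
    k <- kVectors[[h]]
    rowSums(log(k[1] * Q$Q0 + k[2] * Q$Q1 + k[3] * Q$Q2), na.rm = TRUE)
  }, numeric(nrow(pairsIdx)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1,
                                     dimnames = list(NULL, names(kVectors)))
  lp <- sweep(ll, 2, log(prior), "+")
  m <- apply(lp, 1, max)
  post <- exp(lp - m)
  post <- post / rowSums(post)
  nLoci <- rowSums(!is.na(Q$Q0))
  lab <- colnames(post)[max.col(post)]
  pmax3 <- apply(post, 1, max)
  lab[pmax3 < threshold] <- "UNASSIGNED"
  lab[nLoci < minLoci] <- "UNASSIGNED"
  dy <- data.frame(id1 = x@ids[pairsIdx[, 1]], id2 = x@ids[pairsIdx[, 2]],
                   pFS = post[, "FS"], pHS = post[, "HS"], pU = post[, "U"],
                   nLoci = nLoci, label = lab, stringsAsFactors = FALSE)
  out <- new("DyadClassification", dyads = dy, errorRate = errorRate,
             prior = prior, threshold = threshold)
  attr(out, "lowOverlap") <- sum(nLoci < minLoci)
  out
}

setMethod("show", "DyadClassification", function(object) {
  cat(sprintf("DyadClassification: %d dyads (threshold %.2f, e = %g)\n",
              nrow(object@dyads), object@threshold, object@errorRate))
  print(table(object@dyads$label))
})

#' Permutation test of within-cluster sib-dyad counts
#'
#' The statistic per cluster is the number of FS + HS dyads with both
#' members inside the cluster.  The null permutes individuals among
#' clusters preserving cluster sizes; the two-tailed p doubles the smaller
#' add-one tail (capped at 1).
#'
#' @param dyads a \linkS4class{DyadClassification}.
#' @param clusters named character vector id -> cluster (>= 2 clusters).
#' @param nPerm permutations (default 10000).
#' @param seed RNG seed.
#' @return data.frame: cluster, n, sibDyads, fsDyads, hsDyads, p.
#' @export
sibCountPermutation <- function(dyads, clusters, nPerm = 10000,
                                seed = NULL) {
  cl <- unique(clusters)
  if (length(cl) < 2) stop("need >= 2 clusters")
  d <- dyads@dyads
  sib <- d[d$label %in% c("FS", "HS"), c("id1", "id2", "label")]
  ids <- names(clusters)
  countsFor <- function(memb) {
    m1 <- memb[match(sib$id1, ids)]
    m2 <- memb[match(sib$id2, ids)]
    inside <- !is.na(m1) & !is.na(m2) & m1 == m2
    vapply(cl, function(g) sum(inside & m1 == g), 0L)
  }
  obs <- countsFor(unname(clusters))
  perm <- withSeed(seed, vapply(seq_len(nPerm), function(b)
    countsFor(unname(clusters)[sample(length(clusters))]),
    integer(length(cl))))
  if (is.null(dim(perm))) perm <- matrix(perm, nrow = length(cl))
  p <- vapply(seq_along(cl), function(i) {
    up <- addOneP(sum(perm[i, ] >= obs[i]), nPerm)
    lo <- addOneP(sum(perm[i, ] <= obs[i]), nPerm)
    min(1, 2 * min(up, lo))
  }, 0)
  fs <- vapply(cl, function(g) {
    m1 <- clusters[d$id1]; m2 <- clusters[d$id2]
    sum(d$label == "FS" & !is.na(m1) & !is.na(m2) & m1 == g & m2 == g)
  }, 0L)
  hs <- vapply(cl, function(g) {
    m1 <- clusters[d$id1]; m2 <- clusters[d$id2]
    sum(d$label == "HS" & !is.na(m1) & !is.na(m2) & m1 == g & m2 == g)
  }, 0L)
  data.frame(cluster = cl, n = as.integer(table(factor(clusters, cl))),
             sibDyads = obs, fsDyads = fs, hsDyads = hs, p = p)
}

# Can any ordered pair of parental genotypes (built from the alleles seen in
# the group) produce every group member as an offspring?  Restricting
# candidate parents to observed alleles is sufficient: a parental allele
# never transmitted to any group member can be replaced by any observed
# allele without invalidating a compatible configuration, and an allele
# transmitted to someone is observed by definition.
groupCompatible <- function(g) {
  # g: 2 x m matrix of alleles (columns = individuals)
  U <- unique(as.vector(g))
  np <- length(U)
  pg <- cbind(rep(seq_len(np), each = np), rep(seq_len(np), times = np))
  pg <- pg[pg[, 1] <= pg[, 2], , drop = FALSE] # unordered parent genotypes
  nG <- nrow(pg)
  ok <- matrix(TRUE, nG, nG)
  for (i in seq_len(ncol(g))) {
    a <- g[1, i]; b <- g[2, i]
    inA1 <- U[pg[, 1]] == a | U[pg[, 2]] == a
    inB1 <- U[pg[, 1]] == b | U[pg[, 2]] == b
    # parent pair (P, Q) works for child (a,b) if a from P and b from Q or
    # vice versa
    okChild <- outer(inA1, inB1, "&") | outer(inB1, inA1, "&")
    ok <- ok & okChild
    if (!any(ok)) return(FALSE)
  }
  TRUE
}

# Canonical relabelling of a group's genotype multiset so exclusion
# checks can be memoised across Monte Carlo draws.
canonicalGroupKey <- function(g) {
  # g: 2 x m matrix, each column sorted
  ord <- order(g[1, ], g[2, ])
  g <- g[, ord, drop = FALSE]
  v <- as.vector(g)
  relab <- match(v, unique(v))
  g2 <- matrix(relab, nrow = 2)
  g2 <- apply(g2, 2, sort)
  ord2 <- order(g2[1, ], g2[2, ])
  paste(g2[, ord2, drop = FALSE], collapse = ",")
}

#' Exclusion probability of a marker panel for sibship groups
#'
#' Monte Carlo estimate of the probability that a group of
#' \code{groupSize} unrelated individuals (genotypes drawn error-free from
#' the given allele frequencies under HWE) is excluded from a joint full
#' sibship: a locus excludes the group when no ordered pair of parental
#' genotypes can produce every member as offspring; per-locus exclusion
#' probabilities combine as \eqn{1 - \prod_l (1 - E_l)}.
#'
#' @param frequencies a \linkS4class{FrequencyTable} (first group used) or
#'   a named list of allele-frequency vectors.
#' @param loci locus subset (default all).
#' @param groupSize number of unrelated individuals (default 3).
#' @param nMC Monte Carlo replicates per locus (default 100000).
#' @param seed RNG seed.
#' @param subsetSize if non-NULL, additionally evaluate \code{nSubsets}
#'   random locus subsets of this size and report their mean and
#'   2.5/97.5 percentiles.
#' @param nSubsets number of random subsets (default 1000).
#' @return an \linkS4class{ExclusionResult}.
#' @export
exclusionProbability <- function(frequencies, loci = NULL, groupSize = 3,
                                 nMC = 100000, seed = NULL,
                                 subsetSize = NULL, nSubsets = 1000) {
  fl <- if (is(frequencies, "FrequencyTable"))
    frequencies@freqs[[frequencies@groups[1]]] else frequencies
  loci <- loci %||% names(fl)
  if (!length(loci)) stop("empty locus subset")
  fl <- fl[loci]
  if (any(vapply(fl, is.null, TRUE))) stop("missing frequencies for a locus")
  if (all(vapply(fl, length, 0L) < 2))
    warning("no polymorphic locus in subset")
  perLocus <- withSeed(seed, vapply(fl, function(f) {
    if (length(f) < 2) return(0)
    alleles <- as.integer(names(f))
    draws <- matrix(sample(alleles, 2 * groupSize * nMC, replace = TRUE,
                           prob = f), nrow = 2 * groupSize)
    # sort within each genotype pair
    for (i in seq_len(groupSize)) {
      r1 <- 2 * i - 1; r2 <- 2 * i
      lo <- pmin(draws[r1, ], draws[r2, ])
      hi <- pmax(draws[r1, ], draws[r2, ])
      draws[r1, ] <- lo; draws[r2, ] <- hi
    }
    keys <- apply(draws, 2, function(col)
      canonicalGroupKey(matrix(col, nrow = 2)))
    tab <- table(keys)
    uniqKeys <- names(tab)
    excl <- vapply(uniqKeys, function(kk) {
      col <- draws[, match(kk, keys)]
      !groupCompatible(matrix(col, nrow = 2))
    }, TRUE)
    sum(as.numeric(tab)[excl]) / nMC
  }, 0))
  res <- new("ExclusionResult", probability = 1 - prod(1 - perLocus),
             perLocus = perLocus, loci = loci, groupSize = groupSize,
             nMC = nMC, subsets = data.frame())
  if (!is.null(subsetSize)) {
    if (subsetSize > length(loci)) stop("subsetSize exceeds locus count")
    combos <- withSeed(if (is.null(seed)) NULL else seed + 1,
      matrix(replicate(nSubsets, sample(length(loci), subsetSize)),
             nrow = subsetSize))
    vals <- apply(combos, 2, function(idx) 1 - prod(1 - perLocus[idx]))
    res@subsets <- data.frame(mean = mean(vals),
                              lower = unname(quantile(vals, 0.025)),
                              upper = unname(quantile(vals, 0.975)),
                              subsetSize = subsetSize, nSubsets = nSubsets)
  }
  res
}

setMethod("show", "ExclusionResult", function(object) {
  cat(sprintf(
    "ExclusionResult: P(exclude %d unrelated) = %.4f over %d loci (%g MC reps/locus)\n",
    object@groupSize, object@probability, length(object@loci), object@nMC))
  if (nrow(object@subsets))
    cat(sprintf("  random %d-locus subsets: mean %.3f (95%% CI %.3f-%.3f)\n",
                object@subsets$subsetSize, object@subsets$mean,
                object@subsets$lower, object@subsets$upper))
})
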