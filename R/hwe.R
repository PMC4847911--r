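# Hardy-Weinberg diagnostics: exact tests, homozygote-excess (U-score)
# tests, inbreeding coefficients, and the null-allele missingness
# regression.  All Monte Carlo tests share one conditional null: genotype
# tables drawn by shuffling the observed multiset of gene copies and
# re-pairing, which fixes the allele counts.

# Extract the n x 2 matrix of scored allele pairs for a test.
extractPairs <- function(x, locus = NULL, site = NULL) {
  if (is(x, "GenotypeTable")) {
    if (is.null(locus)) stop("'locus' required with a GenotypeTable")
    rows <- if (is.null(site)) seq_len(nInd(x)) else which(x@sites == site)
    if (!is.null(site) && !length(rows)) stop("unknown site: ", site)
    g <- genotypes(x, locus)[rows, , drop = FALSE]
  } else {
    g <- as.matrix(x)
    if (ncol(g) != 2) stop("genotype input must be an n x 2 allele matrix")
  }
  g[!is.na(g[, 1]) & !is.na(g[, 2]), , drop = FALSE]
}

# Shared driver for the two conditional Monte Carlo tests.
hweMonteCarlo <- function(g, nMC, seed, weights = NULL) {
  alleles <- sort(unique(c(g)))
  codes <- matrix(match(g, alleles), ncol = 2)
  copies <- as.integer(c(t(codes)))
  A <- length(alleles)
  w <- weights %||% rep(1, A)
  sims <- withSeed(seed, hweNullSim(copies, as.integer(nMC), w))
  n <- nrow(codes)
  hom <- codes[, 1] == codes[, 2]
  H <- sum(!hom)
  key <- pmin(codes[, 1], codes[, 2]) * 1e6 + pmax(codes[, 1], codes[, 2])
  ng <- table(key)
  vObs <- H * log(2) - sum(lgamma(as.numeric(ng) + 1))
  uObs <- sum(w[codes[hom, 1]])
  list(sims = sims, vObs = vObs, uObs = uObs, n = n, A = A,
       alleles = alleles, copies = copies, H = H)
}

#' Exact test for Hardy-Weinberg equilibrium (Monte Carlo)
#'
#' Conditional exact test: the p-value is the probability, over genotype
#' tables with the observed allele counts (generated by random re-pairing of
#' the observed gene copies), that a table's conditional probability is less
#' than or equal to that of the observed table.  Uses the add-one Monte
#' Carlo correction \eqn{(x+1)/(n_{mc}+1)}.
#'
#' @param x a \linkS4class{GenotypeTable} or an n x 2 allele matrix.
#' @param locus,site locus and optional site when \code{x} is a table.
#' @param nMC Monte Carlo replicates (>= 1000; default 100000).
#' @param seed RNG seed.
#' @return a \linkS4class{TestResult}; the statistic is the conditional
#'   probability of the observed table.
#' @export
hweExactTest <- function(x, locus = NULL, site = NULL, nMC = 100000,
                         seed = NULL) {
  g <- extractPairs(x, locus, site)
  if (nrow(g) < 2) stop("need >= 2 non-missing genotypes")
  if (nMC < 1000) stop("nMC must be >= 1000")
  if (length(unique(c(g))) == 1)
    return(new("TestResult", statistic = 1, p = 1, nRep = 0,
               tail = "lower", seed = seed %||% NA_real_,
               method = "hwe-exact", flags = "degenerate"))
  mc <- hweMonteCarlo(g, nMC, seed)
  # full conditional probability of the observed table (reporting only)
  n <- mc$n
  cA <- table(mc$copies)
  logP <- lgamma(n + 1) + sum(lgamma(as.numeric(cA) + 1)) - lgamma(2 * n + 1) +
    mc$vObs
  p <- addOneP(sum(mc$sims[, 1] <= mc$vObs + 1e-9), nMC)
  new("TestResult", statistic = exp(logP), p = p, nRep = nMC,
      tail = "lower", seed = seed %||% NA_real_, method = "hwe-exact",
      flags = character())
}

#' Monte Carlo test for homozygote excess (U-score)
#'
#' One-tailed (upper) test against the same conditional null as
#' \code{\link{hweExactTest}}.  The default statistic U is the number of
#' homozygous individuals; \code{weighted = TRUE} uses the per-allele
#' weighted score \eqn{\sum_a (O_{aa} - E_{aa})/p_a} instead (monotone in
#' \eqn{\sum_a O_{aa}/p_a} given the allele counts, which is what is
#' simulated).
#'
#' @inheritParams hweExactTest
#' @param weighted use the per-allele weighted U-score.
#' @return a \linkS4class{TestResult} with the observed U statistic.
#' @export
homozygoteExcessTest <- function(x, locus = NULL, site = NULL, nMC = 100000,
                                 seed = NULL, weighted = FALSE) {
  g <- extractPairs(x, locus, site)
  if (nrow(g) < 2) stop("need >= 2 non-missing genotypes")
  if (nMC < 1000) stop("nMC must be >= 1000")
  alleles <- sort(unique(c(g)))
  if (length(alleles) == 1)
    return(new("TestResult", statistic = nrow(g), p = 1, nRep = 0,
               tail = "upper", seed = seed %||% NA_real_,
               method = "homozygote-excess", flags = "degenerate"))
  weights <- NULL
  if (weighted) {
    cnt <- table(factor(c(g), levels = alleles))
    pA <- as.numeric(cnt) / (2 * nrow(g))
    weights <- 1 / pA
  }
  mc <- hweMonteCarlo(g, nMC, seed, weights)
  p <- addOneP(sum(mc$sims[, 2] >= mc$uObs - 1e-9), nMC)
  stat <- mc$uObs
  if (weighted) {
    # report the centred form; the constant shift does not affect p
    cnt <- as.numeric(table(factor(c(g), levels = alleles)))
    n <- mc$n
    eAA <- n * cnt * (cnt - 1) / ((2 * n) * (2 * n - 1))
    stat <- mc$uObs - sum(eAA / (cnt / (2 * n)))
  }
  new("TestResult", statistic = stat, p = p, nRep = nMC, tail = "upper",
      seed = seed %||% NA_real_,
      method = if (weighted) "homozygote-excess-weighted"
               else "homozygote-excess", flags = character())
}

#' Within-site inbreeding coefficient with permutation significance
#'
#' \eqn{F_{IS} = 1 - H_o/H_e} from within-site allele frequencies.
#' Significance is a one-tailed allele-permutation test: gene copies are
#' shuffled within the site x locus sample and re-paired; because the
#' allele counts (hence He) are fixed under this null, \eqn{F_{IS}} is
#' monotone in the homozygote count and the test is computed through the
#' same conditional simulator as the U-score test.
#'
#' @param x a \linkS4class{GenotypeTable}.
#' @param site site label.
#' @param locus locus name.
#' @param nPerm permutation replicates (default 10000).
#' @param seed RNG seed.
#' @return a \linkS4class{TestResult}; statistic = \eqn{F_{IS}} (NA when He
#'   is 0 or no genotype is scored).
#' @export
inbreedingCoefficient <- function(x, site, locus, nPerm = 10000,
                                  seed = NULL) {
  g <- extractPairs(x, locus, site)
  if (nrow(g) < 1) stop("no non-missing genotype at ", site, "/", locus)
  a <- c(g)
  f <- as.numeric(table(a)) / length(a)
  he <- 1 - sum(f^2)
  if (he == 0)
    return(new("TestResult", statistic = NA_real_, p = NA_real_, nRep = 0,
               tail = "upper", seed = seed %||% NA_real_,
               method = "fis-permutation", flags = "degenerate"))
  ho <- mean(g[, 1] != g[, 2])
  fis <- 1 - ho / he
  if (nrow(g) < 2 || nPerm < 1)
    return(new("TestResult", statistic = fis, p = NA_real_, nRep = 0,
               tail = "upper", seed = seed %||% NA_real_,
               method = "fis-permutation", flags = "untested"))
  mc <- hweMonteCarlo(g, nPerm, seed)
  p <- addOneP(sum(mc$sims[, 2] >= mc$uObs - 1e-9), nPerm)
  new("TestResult", statistic = fis, p = p, nRep = nPerm, tail = "upper",
      seed = seed %||% NA_real_, method = "fis-permutation",
      flags = character())
}

#' Site-by-locus grids of HWE diagnostics
#'
#' Runs \code{\link{hweExactTest}}, \code{\link{homozygoteExcessTest}} or
#' \code{\link{inbreedingCoefficient}} for every site x locus combination,
#' returning matrices shaped like the published significance grids.
#'
#' @param x a \linkS4class{GenotypeTable}.
#' @param test \code{"exact"}, \code{"uscore"} or \code{"fis"}.
#' @param nMC replicates per test.
#' @param seed base seed; each combination uses an offset sub-seed.
#' @return list with matrices \code{p} (sites x loci) and \code{statistic};
#'   cells with < 2 scored genotypes are NA.
#' @export
hweGrid <- function(x, test = c("exact", "uscore", "fis"), nMC = 10000,
                    seed = NULL) {
  test <- match.arg(test)
  sites <- unique(x@sites)
  p <- stat <- matrix(NA_real_, length(sites), length(x@loci),
                      dimnames = list(sites, x@loci))
  k <- 0
  for (s in sites) for (l in x@loci) {
    k <- k + 1
    g <- extractPairs(x, l, s)
    if (nrow(g) < 2) next
    sub <- if (is.null(seed)) NULL else stageSeed(seed, k %% 100) + k
    res <- switch(test,
      exact = hweExactTest(g, nMC = nMC, seed = sub),
      uscore = homozygoteExcessTest(g, nMC = nMC, seed = sub),
      fis = inbreedingCoefficient(x, s, l, nPerm = nMC, seed = sub))
    p[s, l] <- res@p
    stat[s, l] <- res@statistic
  }
  list(p = p, statistic = stat, test = test)
}

#' Null-allele diagnostic regression
#'
#' Ordinary least squares of \eqn{|H_e - H_o|} on the proportion of
#' individuals failing to amplify, over all site x locus combinations.
#' Null alleles produce apparent homozygotes and missing genotypes
#' simultaneously, so a positive slope is consistent with null alleles while
#' a flat regression points to inbreeding/kin structure instead.
#'
#' @param x a \linkS4class{GenotypeTable}.
#' @return a \linkS4class{RegressionResult}; \code{points} holds the
#'   site x locus scatter for plotting.
#' @export
missingnessHeterozygosityRegression <- function(x) {
  ls <- locusSummary(x, grouping = "site")
  pts <- ls[!is.na(ls$He) & !is.na(ls$Ho), ]
  if (nrow(pts) < 3) stop("need >= 3 site x locus points with defined He")
  pts$absDiff <- abs(pts$He - pts$Ho)
  if (var(pts$missing) == 0)
    stop("no variance in missingness across site x locus points")
  fit <- lm(absDiff ~ missing, data = pts)
  an <- anova(fit)
  new("RegressionResult",
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      fstat = an$`F value`[1], df = c(an$Df[1], an$Df[2]),
      p = an$`Pr(>F)`[1], n = nrow(pts),
      points = pts[, c("group", "locus", "missing", "absDiff")])
}

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult [%s, %s-tail]: statistic = %.4g, p = %.4g (%g reps)",
              object@method, object@tail, object@statistic, object@p,
              object@nRep))
  if (length(object@flags)) cat(" [", paste(object@flags, collapse = ","),
                                "]", sep = "")
  cat("\n")
})

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf("RegressionResult: slope = %.4g, F(%d,%d) = %.4g, p = %.3g, n = %d\n",
              object@slope, object@df[1], object@df[2], object@fstat,
              object@p, object@n))
})
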