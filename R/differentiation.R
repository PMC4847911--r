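# Pairwise between-site differentiation (P_D, F_ST), permutation
# significance with Holm (sequential Bonferroni) correction, great-circle
# distances and Mantel isolation-by-distance tests.

#' Pairwise proportion of different alleles (P_D)
#'
#' Population-frequency definition: for sites A and B,
#' \deqn{P_D(A,B) = 1 - \frac{1}{L}\sum_{l}\sum_{a}\min(p_a^A, p_a^B)}
#' averaged over the loci scored in both sites.  Identical frequency
#' distributions give 0; fully disjoint allele sets give 1.
#'
#' @param x a \linkS4class{GenotypeTable} with >= 2 sites.
#' @return symmetric matrix of P_D values; NA (flagged via attribute
#'   \code{"noSharedLocus"}) for pairs with no shared scored locus.
#' @export
pairwisePd <- function(x) {
  ft <- alleleFrequencies(x, "site")
  sites <- ft@groups
  if (length(sites) < 2) stop("need >= 2 sites")
  m <- matrix(0, length(sites), length(sites),
              dimnames = list(sites, sites))
  flagged <- character()
  for (i in seq_along(sites)[-1]) for (j in seq_len(i - 1)) {
    v <- pdPair(ft, sites[i], sites[j])
    if (is.na(v)) flagged <- c(flagged, paste(sites[i], sites[j], sep = "-"))
    m[i, j] <- m[j, i] <- v
  }
  attr(m, "noSharedLocus") <- flagged
  m
}

pdPair <- function(ft, s1, s2) {
  shares <- numeric()
  for (l in ft@loci) {
    f1 <- ft@freqs[[s1]][[l]]; f2 <- ft@freqs[[s2]][[l]]
    if (is.null(f1) || is.null(f2)) next
    al <- union(names(f1), names(f2))
    shares <- c(shares,
                sum(pmin(f1[al], f2[al], na.rm = FALSE) *
                      !(is.na(f1[al]) | is.na(f2[al])), na.rm = TRUE))
  }
  if (!length(shares)) return(NA_real_)
  1 - mean(shares)
}

# Weir-Cockerham variance components for one locus, two samples.
# g1, g2: scored n x 2 allele matrices. Returns c(a, a + b + c) summed over
# alleles.
wcComponentsLocus <- function(g1, g2) {
  n1 <- nrow(g1); n2 <- nrow(g2)
  if (n1 == 0 || n2 == 0) return(c(0, 0))
  alleles <- sort(unique(c(g1, g2)))
  if (length(alleles) < 2) return(c(0, 0))
  r <- 2
  nbar <- (n1 + n2) / 2
  if (nbar <= 1) return(c(0, 0))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  aSum <- dSum <- 0
  for (al in alleles) {
    p1 <- sum(g1 == al) / (2 * n1)
    p2 <- sum(g2 == al) / (2 * n2)
    h1 <- sum((g1[, 1] == al) != (g1[, 2] == al)) / n1
    h2 <- sum((g2[, 1] == al) != (g2[, 2] == al)) / n2
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    aSum <- aSum + a
    dSum <- dSum + a + b + cc
  }
  c(aSum, dSum)
}

fstPairValue <- function(al1, al2, estimator) {
  # al1/al2: n x L x 2 arrays for the two samples
  L <- dim(al1)[2]
  if (estimator == "wc") {
    num <- den <- 0
    for (j in seq_len(L)) {
      g1 <- matrix(al1[, j, ], ncol = 2); g1 <- g1[!is.na(g1[, 1]), , drop = FALSE]
      g2 <- matrix(al2[, j, ], ncol = 2); g2 <- g2[!is.na(g2[, 1]), , drop = FALSE]
      comp <- wcComponentsLocus(g1, g2)
      num <- num + comp[1]; den <- den + comp[2]
    }
    if (den == 0) return(NA_real_)
    num / den
  } else { # Nei G_ST-style, ratio of sums across loci
    num <- den <- 0
    for (j in seq_len(L)) {
      g1 <- matrix(al1[, j, ], ncol = 2); g1 <- g1[!is.na(g1[, 1]), , drop = FALSE]
      g2 <- matrix(al2[, j, ], ncol = 2); g2 <- g2[!is.na(g2[, 1]), , drop = FALSE]
      if (!nrow(g1) || !nrow(g2)) next
      alleles <- sort(unique(c(g1, g2)))
      p1 <- vapply(alleles, function(a) sum(g1 == a) / (2 * nrow(g1)), 0)
      p2 <- vapply(alleles, function(a) sum(g2 == a) / (2 * nrow(g2)), 0)
      hs <- ((1 - sum(p1^2)) + (1 - sum(p2^2))) / 2
      pb <- (p1 + p2) / 2
      ht <- 1 - sum(pb^2)
      if (ht == 0) next
      num <- num + (ht - hs); den <- den + ht
    }
    if (den == 0) return(NA_real_)
    num / den
  }
}

#' Pairwise multilocus F_ST between sites
#'
#' Weir-Cockerham theta (ratio of variance-component sums across loci and
#' alleles; default) or a Nei G_ST-style estimator.  Negative estimates are
#' reported as computed.  Loci monomorphic across a pair contribute nothing
#' (0/0 terms are skipped).
#'
#' @param x a \linkS4class{GenotypeTable} with >= 2 sites.
#' @param estimator \code{"wc"} or \code{"nei"}.
#' @return symmetric matrix of F_ST estimates.
#' @export
pairwiseFst <- function(x, estimator = c("wc", "nei")) {
  estimator <- match.arg(estimator)
  sites <- unique(x@sites)
  if (length(sites) < 2) stop("need >= 2 sites")
  m <- matrix(0, length(sites), length(sites), dimnames = list(sites, sites))
  for (i in seq_along(sites)[-1]) for (j in seq_len(i - 1)) {
    al1 <- x@alleles[x@sites == sites[i], , , drop = FALSE]
    al2 <- x@alleles[x@sites == sites[j], , , drop = FALSE]
    m[i, j] <- m[j, i] <- fstPairValue(al1, al2, estimator)
  }
  m
}

#' Permutation significance of pairwise differentiation
#'
#' For each pair of sites, individuals are permuted between the two sites
#' (preserving sample sizes) and the statistic recomputed; the p-value is
#' the add-one upper-tail probability.  Holm's step-down ("sequential
#' Bonferroni") is applied across all pairs.
#'
#' @param x a \linkS4class{GenotypeTable}.
#' @param statistic \code{"fst"} or \code{"pd"}.
#' @param estimator F_ST estimator (when \code{statistic = "fst"}).
#' @param nPerm permutations per pair (>= 100; default 10000).
#' @param seed RNG seed.
#' @param correction p.adjust method across pairs (default \code{"holm"}).
#' @return list with matrices \code{stat}, \code{p} (raw), \code{pAdj}.
#' @export
differentiationSignificance <- function(x, statistic = c("fst", "pd"),
                                        estimator = "wc", nPerm = 10000,
                                        seed = NULL, correction = "holm") {
  statistic <- match.arg(statistic)
  if (nPerm < 100) stop("nPerm must be >= 100")
  sites <- unique(x@sites)
  ns <- length(sites)
  if (ns < 2) stop("need >= 2 sites")
  stat <- p <- matrix(NA_real_, ns, ns, dimnames = list(sites, sites))
  diag(stat) <- diag(p) <- 0
  withSeed(seed, {
    for (i in seq_len(ns)[-1]) for (j in seq_len(i - 1)) {
      rows <- c(which(x@sites == sites[i]), which(x@sites == sites[j]))
      n1 <- sum(x@sites == sites[i])
      al <- x@alleles[rows, , , drop = FALSE]
      obs <- pairStatistic(al, seq_len(n1), statistic, estimator)
      hits <- 0
      for (b in seq_len(nPerm)) {
        idx <- sample(length(rows))
        v <- pairStatistic(al, idx[seq_len(n1)], statistic, estimator)
        if (!is.na(v) && v >= obs - 1e-12) hits <- hits + 1
      }
      stat[i, j] <- stat[j, i] <- obs
      p[i, j] <- p[j, i] <- addOneP(hits, nPerm)
    }
  })
  raw <- p[lower.tri(p)]
  adj <- p.adjust(raw, method = correction)
  pAdj <- symFromLower(adj, ns, sites, diagVal = 0)
  diag(pAdj) <- NA_real_
  diag(p) <- NA_real_
  list(stat = stat, p = p, pAdj = pAdj, statistic = statistic,
       correction = correction)
}

pairStatistic <- function(al, idx1, statistic, estimator) {
  idx2 <- setdiff(seq_len(dim(al)[1]), idx1)
  a1 <- al[idx1, , , drop = FALSE]; a2 <- al[idx2, , , drop = FALSE]
  if (statistic == "fst") return(fstPairValue(a1, a2, estimator))
  # frequency-based P_D for a pair of index sets
  L <- dim(al)[2]
  shares <- numeric()
  for (j in seq_len(L)) {
    g1 <- matrix(a1[, j, ], ncol = 2); g1 <- g1[!is.na(g1[, 1]), , drop = FALSE]
    g2 <- matrix(a2[, j, ], ncol = 2); g2 <- g2[!is.na(g2[, 1]), , drop = FALSE]
    if (!nrow(g1) || !nrow(g2)) next
    alleles <- sort(unique(c(g1, g2)))
    p1 <- vapply(alleles, function(a) sum(g1 == a) / (2 * nrow(g1)), 0)
    p2 <- vapply(alleles, function(a) sum(g2 == a) / (2 * nrow(g2)), 0)
    shares <- c(shares, sum(pmin(p1, p2)))
  }
  if (!length(shares)) return(NA_real_)
  1 - mean(shares)
}

#' Great-circle distances between sites
#'
#' Haversine distances with Earth radius 6371.0088 km.
#'
#' @param coords data.frame with columns \code{site}, \code{lat},
#'   \code{lon} (decimal degrees).
#' @return symmetric matrix of distances in km.
#' @export
greatCircleDistances <- function(coords) {
  need <- c("site", "lat", "lon")
  if (!all(need %in% names(coords))) stop("coords needs site, lat, lon")
  bad <- coords$site[!complete.cases(coords[, c("lat", "lon")])]
  if (length(bad)) stop("missing coordinates for site(s): ",
                        paste(bad, collapse = ", "))
  if (any(coords$lat < -90 | coords$lat > 90))
    stop("latitude outside [-90, 90]")
  if (any(coords$lon < -180 | coords$lon > 180))
    stop("longitude outside [-180, 180]")
  xy <- as.matrix(coords[, c("lon", "lat")])
  m <- geosphere::distm(xy, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371.0088 * 1000)) / 1000
  dimnames(m) <- list(coords$site, coords$site)
  m
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation of the lower triangles of two distance matrices;
#' significance by simultaneous row/column permutation of one matrix,
#' add-one upper-tail p-value.
#'
#' @param dGen,dGeo conformable symmetric matrices.
#' @param nPerm permutations (default 10000).
#' @param seed RNG seed.
#' @return a \linkS4class{TestResult} with statistic = Mantel r.
#' @export
mantelTest <- function(dGen, dGeo, nPerm = 10000, seed = NULL) {
  if (!all(dim(dGen) == dim(dGeo))) stop("matrices not conformable")
  if (nrow(dGen) < 3) stop("need >= 3 sites for a Mantel test")
  v1 <- lowerTri(dGen); v2 <- lowerTri(dGeo)
  ok <- !is.na(v1) & !is.na(v2)
  if (sum(ok) < 3 || sd(v1[ok]) == 0 || sd(v2[ok]) == 0)
    stop("constant distance matrix: Mantel r undefined")
  robs <- cor(v1[ok], v2[ok])
  n <- nrow(dGen)
  hits <- withSeed(seed, {
    h <- 0
    for (b in seq_len(nPerm)) {
      idx <- sample(n)
      vp <- lowerTri(dGeo[idx, idx])
      rp <- suppressWarnings(cor(v1[ok], vp[ok]))
      if (!is.na(rp) && rp >= robs - 1e-12) h <- h + 1
    }
    h
  })
  new("TestResult", statistic = robs, p = addOneP(hits, nPerm), nRep = nPerm,
      tail = "upper", seed = seed %||% NA_real_, method = "mantel",
      flags = character())
}

#' Assemble the full differentiation bundle
#'
#' Computes P_D, F_ST, geographic distances and permutation significance and
#' returns them as a \linkS4class{DistanceMatrices} object shaped like the
#' published pairwise table (P_D above the diagonal, F_ST below).
#'
#' @param x a \linkS4class{GenotypeTable} (coordinates required for the
#'   geographic matrix; otherwise it is left empty).
#' @param estimator F_ST estimator.
#' @param nPerm permutations per pair.
#' @param seed RNG seed.
#' @return a \linkS4class{DistanceMatrices}.
#' @export
distanceMatrices <- function(x, estimator = "wc", nPerm = 1000,
                             seed = NULL) {
  sigF <- differentiationSignificance(x, "fst", estimator, nPerm,
                                      seed = if (is.null(seed)) NULL else seed)
  sigP <- differentiationSignificance(x, "pd", estimator, nPerm,
                                      seed = if (is.null(seed)) NULL else seed + 1)
  geo <- if (nrow(x@coords)) {
    co <- x@coords[match(unique(x@sites), x@coords$site), ]
    greatCircleDistances(co)
  } else matrix(numeric(), 0, 0)
  pClean <- function(m) { m2 <- m; diag(m2) <- 0; m2 }
  new("DistanceMatrices", sites = unique(x@sites), pd = sigP$stat,
      fst = sigF$stat, geo = geo, pPd = pClean(sigP$p),
      pFst = pClean(sigF$p), pPdAdj = pClean(sigP$pAdj),
      pFstAdj = pClean(sigF$pAdj), correction = "holm")
}

setMethod("show", "DistanceMatrices", function(object) {
  cat("DistanceMatrices:", length(object@sites), "sites;",
      "P_D above diagonal, F_ST below\n")
  m <- object@pd
  m[lower.tri(m)] <- object@fst[lower.tri(object@fst)]
  diag(m) <- NA
  print(round(m, 3))
})
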