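# Pedigree-structured genotype simulator emulating the study design:
# several reef sites, each composed of a few clusters of full-sib families
# optionally linked by shared fathers (half-sibs), genotyped at
# microsatellite-like loci with configurable error, missingness and null
# alleles.  Every individual's pedigree is recorded, so truth is available
# for relatedness, sibship, clustering and network stages.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 9 sites of 34-85 individuals,
#' 2-5 clusters per site of 8-36 individuals built from full-sib families
#' (consecutive families within a cluster share a father with probability
#' \code{halfSibProb}, producing a predominance of half-sib over full-sib
#' dyads), 10 loci whose allele counts match the reported richness profile
#' (7-50), per-locus missingness drawn from 0.06-0.26, and a 1\% per-allele
#' genotyping error rate.  Between-site differentiation is induced by
#' drawing per-site allele frequencies from a Dirichlet centred on the
#' global frequencies with concentration \code{siteTheta} (expected F_ST
#' roughly \eqn{1/(siteTheta + 1)}; \code{Inf} gives identical, panmictic
#' baselines).
#'
#' @param nSites number of sites.
#' @param siteSizeRange admissible per-site individual counts.
#' @param clustersPerSite range of clusters per site.
#' @param clusterSizeRange range of cluster sizes.
#' @param familySizeRange range of full-sib family sizes.
#' @param halfSibProb probability a family shares the previous family's
#'   father.
#' @param nLoci number of loci.
#' @param allelesPerLocus integer vector (recycled) of allele counts.
#' @param concentration symmetric Dirichlet concentration for global
#'   frequencies.
#' @param siteTheta concentration of per-site frequencies around the global
#'   ones (Inf = no site differentiation).
#' @param clusterTheta concentration of per-cluster parental-pool
#'   frequencies around the site pool (Inf = none, the default).  Finite
#'   values give each cluster a differentiated source cohort (a
#'   within-site Wahlund effect), at the cost of inflating between-site
#'   differentiation.
#' @param inbreedingF autozygosity probability of each offspring gene
#'   pair: with this probability the paternal copy is identical by
#'   descent to the transmitted maternal copy.  Produces the site-level
#'   homozygote excess (expected F_IS = inbreedingF) that kin-aggregated
#'   samples display without touching between-site differentiation;
#'   default 0.33, the median of the study-scale inbreeding coefficients
#'   this generator emulates.
#' @param errorRate per-allele class-II genotyping error rate.
#' @param missingnessRange per-locus missingness rates drawn uniformly from
#'   this range (use c(0, 0) for complete data).
#' @param nullAlleleFreq per-locus null-allele frequency (0 disables).
#' @return a list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nSites = 9, siteSizeRange = c(34, 85),
                             clustersPerSite = c(2, 5),
                             clusterSizeRange = c(8, 36),
                             familySizeRange = c(2, 10),
                             halfSibProb = 0.5, nLoci = 10,
                             allelesPerLocus = c(13, 9, 14, 24, 10, 7, 33,
                                                 19, 50, 24),
                             concentration = 1, siteTheta = 30,
                             clusterTheta = Inf,
                             inbreedingF = 0.33, errorRate = 0.01,
                             missingnessRange = c(0.06, 0.26),
                             nullAlleleFreq = 0) {
  cfg <- list(nSites = nSites, siteSizeRange = siteSizeRange,
              clustersPerSite = clustersPerSite,
              clusterSizeRange = clusterSizeRange,
              familySizeRange = familySizeRange, halfSibProb = halfSibProb,
              nLoci = nLoci,
              allelesPerLocus = rep_len(allelesPerLocus, nLoci),
              concentration = concentration, siteTheta = siteTheta,
              clusterTheta = clusterTheta, inbreedingF = inbreedingF,
              errorRate = errorRate, missingnessRange = missingnessRange,
              nullAlleleFreq = nullAlleleFreq)
  ranges <- list(cfg$siteSizeRange, cfg$clustersPerSite,
                 cfg$clusterSizeRange, cfg$familySizeRange)
  if (any(vapply(ranges, function(r) length(r) != 2 || r[1] > r[2] ||
                   r[1] < 1, TRUE)))
    stop("invalid range in configuration")
  if (cfg$halfSibProb < 0 || cfg$halfSibProb > 1 ||
      cfg$inbreedingF < 0 || cfg$inbreedingF > 1 ||
      cfg$errorRate < 0 || cfg$errorRate > 1 ||
      cfg$nullAlleleFreq < 0 || cfg$nullAlleleFreq > 1)
    stop("probabilities must lie in [0, 1]")
  if (cfg$clustersPerSite[1] * cfg$clusterSizeRange[1] >
        cfg$siteSizeRange[2] ||
      cfg$clustersPerSite[2] * cfg$clusterSizeRange[2] <
        cfg$siteSizeRange[1])
    stop("infeasible ranges: cluster sizes cannot sum into the site size range")
  class(cfg) <- "SimulationConfig"
  cfg
}

# length-safe uniform draw from an integer range
sampleRange <- function(r, n = 1) {
  if (r[1] == r[2]) rep(r[1], n) else sample(r[1]:r[2], n, replace = TRUE)
}

# length-safe weighted sampling of allele codes
sampleAlleles <- function(a, n, prob) a[sample.int(length(a), n, replace = TRUE, prob = prob)]

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = pmax(alpha, 1e-8))
  g / sum(g)
}

#' Random allele-frequency profile
#'
#' Draws one symmetric-Dirichlet frequency vector per locus; allele "sizes"
#' are distinct even integers so tables can round-trip through both file
#' dialects.
#'
#' @param nLoci number of loci.
#' @param allelesPerLocus allele counts (recycled).
#' @param concentration symmetric Dirichlet concentration.
#' @param seed RNG seed.
#' @return named list of named frequency vectors.
#' @export
randomFrequencies <- function(nLoci, allelesPerLocus = 10,
                              concentration = 1, seed = NULL) {
  allelesPerLocus <- rep_len(allelesPerLocus, nLoci)
  withSeed(seed, {
    out <- lapply(seq_len(nLoci), function(j) {
      A <- allelesPerLocus[j]
      f <- rdirichlet1(rep(concentration, A))
      # avoid exact zeros from underflow
      f <- pmax(f, 1e-12); f <- f / sum(f)
      names(f) <- 100 + 2 * (seq_len(A) - 1)
      f
    })
    names(out) <- paste0("L", seq_len(nLoci))
    out
  })
}

drawGenotype <- function(f) sort(sampleAlleles(as.integer(names(f)), 2, f))

#' Simulate a full kin-structured study
#'
#' Generates the genotype table and pedigree truth for one study: per site,
#' baseline allele frequencies are drawn around the global pool, clusters
#' are filled with full-sib families (fathers shared between consecutive
#' families with probability \code{halfSibProb}), offspring genotypes
#' follow Mendelian segregation from their recorded parents, and
#' genotyping error, per-locus missingness and optional null-allele
#' masking are applied in that order.  Deterministic given \code{seed}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed RNG seed (mandatory).
#' @return list with elements \code{table} (a
#'   \linkS4class{GenotypeTable} with coordinates attached), \code{truth}
#'   (data.frame id, site, cluster, mother, father),
#'   \code{parentGenotypes} (named list of L x 2 allele matrices),
#'   \code{globalFrequencies} and \code{siteFrequencies}.
#' @export
simulateStudy <- function(config = simulationConfig(), seed) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  withSeed(seed, {
    L <- config$nLoci
    lociNames <- paste0("L", seq_len(L))
    globalF <- randomFrequencies(L, config$allelesPerLocus,
                                 config$concentration)
    names(globalF) <- lociNames
    sites <- paste0("S", seq_len(config$nSites))
    siteF <- lapply(sites, function(s) {
      if (is.infinite(config$siteTheta)) return(globalF)
      lapply(globalF, function(f) {
        g <- rdirichlet1(config$siteTheta * f)
        g <- pmax(g, 1e-12); g <- g / sum(g)
        names(g) <- names(f)
        g
      })
    })
    names(siteF) <- sites
    ids <- character(); siteOf <- character(); clusterOf <- character()
    mother <- character(); father <- character()
    rows <- list()
    parentGenos <- list()
    parentCounter <- 0
    newParent <- function(fl) {
      parentCounter <<- parentCounter + 1
      pid <- paste0("P", parentCounter)
      parentGenos[[pid]] <<- t(vapply(fl, drawGenotype, integer(2)))
      pid
    }
    for (s in sites) {
      fl <- siteF[[s]]
      # cluster sizes: rejection-sample into the site size range
      sizes <- NULL
      for (try in seq_len(1000)) {
        k <- sampleRange(config$clustersPerSite)
        cand <- sampleRange(config$clusterSizeRange, k)
        if (sum(cand) >= config$siteSizeRange[1] &&
            sum(cand) <= config$siteSizeRange[2]) { sizes <- cand; break }
      }
      if (is.null(sizes))
        stop("could not draw cluster sizes inside the site size range")
      for (ci in seq_along(sizes)) {
        clusterId <- paste0(s, ".C", ci)
        clF <- if (is.infinite(config$clusterTheta)) fl else
          lapply(fl, function(f) {
            g <- rdirichlet1(config$clusterTheta * f)
            g <- pmax(g, 1e-12); g <- g / sum(g)
            names(g) <- names(f)
            g
          })
        remaining <- sizes[ci]
        prevFather <- NULL
        while (remaining > 0) {
          fs <- sampleRange(config$familySizeRange)
          fs <- min(fs, remaining)
          mom <- newParent(clF)
          dad <- if (!is.null(prevFather) && runif(1) < config$halfSibProb)
            prevFather else newParent(clF)
          for (o in seq_len(fs)) {
            iid <- paste0(s, "_i", length(ids) + 1)
            ids <- c(ids, iid)
            siteOf <- c(siteOf, s); clusterOf <- c(clusterOf, clusterId)
            mother <- c(mother, mom); father <- c(father, dad)
            gm <- parentGenos[[mom]]; gf <- parentGenos[[dad]]
            off <- matrix(NA_integer_, L, 2)
            pick <- function(g) g[cbind(seq_len(L),
                                        sample(1:2, L, replace = TRUE))]
            a <- pick(gm); b <- pick(gf)
            if (config$inbreedingF > 0) {
              ibd <- runif(L) < config$inbreedingF
              b[ibd] <- a[ibd]
            }
            off[, 1] <- pmin(a, b); off[, 2] <- pmax(a, b)
            rows[[length(rows) + 1]] <- off
          }
          prevFather <- dad
          remaining <- remaining - fs
        }
      }
    }
    n <- length(ids)
    al <- array(NA_integer_, c(n, L, 2))
    for (i in seq_len(n)) al[i, , ] <- rows[[i]]
    # class-II genotyping error using site frequencies
    if (config$errorRate > 0) {
      for (i in seq_len(n)) {
        fl <- siteF[[siteOf[i]]]
        for (j in seq_len(L)) {
          for (cpy in 1:2) {
            if (runif(1) < config$errorRate) {
              f <- fl[[j]]
              al[i, j, cpy] <- sampleAlleles(as.integer(names(f)), 1, f)
            }
          }
          al[i, j, ] <- sort(al[i, j, ])
        }
      }
    }
    # per-locus missingness (one global rate per locus)
    missRates <- runif(L, config$missingnessRange[1],
                       config$missingnessRange[2])
    if (any(missRates > 0)) {
      for (j in seq_len(L)) {
        hit <- runif(n) < missRates[j]
        al[hit, j, ] <- NA_integer_
      }
      # keep every individual scored somewhere: restore one locus if wiped
      wiped <- which(rowSums(matrix(!is.na(al[, , 1]), nrow = n)) == 0)
      for (i in wiped) {
        j <- sample(L, 1)
        al[i, j, ] <- rows[[i]][j, ]
      }
    }
    coords <- data.frame(
      site = sites,
      lat = 16.5 + cumsum(c(0, runif(config$nSites - 1, 0.03, 0.22))),
      lon = -87.8 + runif(config$nSites, -0.08, 0.08))
    gt <- genotypeTable(ids, siteOf, lociNames, al, coords = coords,
                        siteLevels = sites)
    if (config$nullAlleleFreq > 0)
      for (l in lociNames)
        gt <- injectNullAlleles(gt, l, config$nullAlleleFreq)
    truth <- data.frame(id = ids, site = siteOf, cluster = clusterOf,
                        mother = mother, father = father,
                        stringsAsFactors = FALSE)
    list(table = gt, truth = truth, parentGenotypes = parentGenos,
         globalFrequencies = globalF, siteFrequencies = siteF,
         config = config, seed = seed)
  })
}

#' Pedigree dyad labels from simulation truth
#'
#' @param truth the \code{truth} data.frame of \code{\link{simulateStudy}}.
#' @param within restrict pairs to the same cluster, same site, or all
#'   pairs.
#' @return data.frame id1, id2, label (FS/HS/U), r (0.5/0.25/0).
#' @export
truthDyads <- function(truth, within = c("cluster", "site", "all")) {
  within <- match.arg(within)
  idx <- t(combn(nrow(truth), 2))
  if (within == "cluster") {
    keep <- truth$cluster[idx[, 1]] == truth$cluster[idx[, 2]]
  } else if (within == "site") {
    keep <- truth$site[idx[, 1]] == truth$site[idx[, 2]]
  } else keep <- rep(TRUE, nrow(idx))
  idx <- idx[keep, , drop = FALSE]
  shared <- (truth$mother[idx[, 1]] == truth$mother[idx[, 2]]) +
    (truth$father[idx[, 1]] == truth$father[idx[, 2]])
  label <- c("U", "HS", "FS")[shared + 1]
  data.frame(id1 = truth$id[idx[, 1]], id2 = truth$id[idx[, 2]],
             label = label, r = c(0, 0.25, 0.5)[shared + 1],
             stringsAsFactors = FALSE)
}

#' Inject null alleles at a locus
#'
#' Each gene copy independently becomes null with probability
#' \code{nullFrequency}; a null/null genotype presents as missing data and
#' a null/visible genotype as an apparent homozygote for the visible
#' allele.
#'
#' @param x a \linkS4class{GenotypeTable}.
#' @param locus locus name.
#' @param nullFrequency per-copy null probability in [0, 1].
#' @param seed RNG seed.
#' @return a \linkS4class{GenotypeTable}; individuals left with no scored
#'   locus are dropped with a warning.
#' @export
injectNullAlleles <- function(x, locus, nullFrequency, seed = NULL) {
  if (!locus %in% x@loci) stop("unknown locus: ", locus)
  if (nullFrequency < 0 || nullFrequency > 1)
    stop("nullFrequency must lie in [0, 1]")
  if (nullFrequency == 0) return(x)
  j <- match(locus, x@loci)
  al <- x@alleles
  n <- nInd(x)
  withSeed(seed, {
    null1 <- runif(n) < nullFrequency
    null2 <- runif(n) < nullFrequency
    scored <- !is.na(al[, j, 1])
    both <- scored & null1 & null2
    one1 <- scored & null1 & !null2
    one2 <- scored & !null1 & null2
    al[both, j, ] <- NA_integer_
    al[one1, j, 1] <- al[one1, j, 2] # visible copy is allele 2
    al[one2, j, 2] <- al[one2, j, 1]
  })
  alive <- rowSums(matrix(!is.na(al[, , 1]), nrow = n)) > 0
  if (!all(alive))
    warning(sum(!alive), " individual(s) lost their last scored locus and ",
            "were dropped")
  genotypeTable(x@ids[alive], x@sites[alive], x@loci,
                al[alive, , , drop = FALSE], coords = x@coords,
                siteLevels = x@siteLevels)
}

#' Simulate unrelated individuals under HWE
#'
#' @param n number of individuals.
#' @param frequencies named list of allele-frequency vectors (see
#'   \code{\link{randomFrequencies}}).
#' @param site site label for all individuals.
#' @param idPrefix id prefix.
#' @param errorRate per-allele class-II error rate (default 0).
#' @param seed RNG seed.
#' @return a \linkS4class{GenotypeTable}.
#' @export
simulateUnrelated <- function(n, frequencies, site = "S1", idPrefix = "i",
                              errorRate = 0, seed = NULL) {
  L <- length(frequencies)
  withSeed(seed, {
    al <- array(NA_integer_, c(n, L, 2))
    for (j in seq_len(L)) {
      a <- sampleAlleles(as.integer(names(frequencies[[j]])), 2 * n,
                         frequencies[[j]])
      a <- matrix(a, n, 2)
      if (errorRate > 0) {
        err <- matrix(runif(2 * n) < errorRate, n, 2)
        ne <- sum(err)
        if (ne) a[err] <- sampleAlleles(as.integer(names(frequencies[[j]])), ne,
                                        frequencies[[j]])
      }
      al[, j, 1] <- pmin(a[, 1], a[, 2])
      al[, j, 2] <- pmax(a[, 1], a[, 2])
    }
    genotypeTable(paste0(idPrefix, seq_len(n)), rep(site, n),
                  names(frequencies) %||% paste0("L", seq_len(L)), al)
  })
}

#' Simulate dyads of known relationship
#'
#' Generates \code{nDyads} independent pairs with pedigree relationship
#' FS, HS or U by explicit parent construction and Mendelian segregation,
#' then applies the class-II error model.
#'
#' @param relationship \code{"FS"}, \code{"HS"} or \code{"U"}.
#' @param nDyads number of pairs.
#' @param frequencies named list of allele-frequency vectors.
#' @param errorRate per-allele error rate (default 0).
#' @param seed RNG seed.
#' @return list: \code{table} (a \linkS4class{GenotypeTable}; ids
#'   \code{d<i>a} / \code{d<i>b}) and \code{pairs} (2-column id matrix).
#' @export
simulateDyads <- function(relationship = c("FS", "HS", "U"), nDyads,
                          frequencies, errorRate = 0, seed = NULL) {
  relationship <- match.arg(relationship)
  L <- length(frequencies)
  lnames <- names(frequencies) %||% paste0("L", seq_len(L))
  withSeed(seed, {
    n <- 2 * nDyads
    al <- array(NA_integer_, c(n, L, 2))
    alInt <- lapply(frequencies, function(f) as.integer(names(f)))
    for (d in seq_len(nDyads)) {
      for (j in seq_len(L)) {
        f <- frequencies[[j]]; a <- alInt[[j]]
        draw <- function() sampleAlleles(a, 2, f)
        mendel <- function(p1, p2) sort(c(sample(p1, 1), sample(p2, 1)))
        g <- switch(relationship,
          U = list(sort(draw()), sort(draw())),
          FS = { m <- draw(); p <- draw()
                 list(mendel(m, p), mendel(m, p)) },
          HS = { p <- draw(); m1 <- draw(); m2 <- draw()
                 list(mendel(m1, p), mendel(m2, p)) })
        al[2 * d - 1, j, ] <- g[[1]]
        al[2 * d, j, ] <- g[[2]]
      }
    }
    if (errorRate > 0) {
      for (j in seq_len(L)) {
        f <- frequencies[[j]]; a <- alInt[[j]]
        for (cpy in 1:2) {
          err <- runif(n) < errorRate
          ne <- sum(err)
          if (ne) al[err, j, cpy] <- sampleAlleles(a, ne, f)
        }
        al[, j, ] <- cbind(pmin(al[, j, 1], al[, j, 2]),
                           pmax(al[, j, 1], al[, j, 2]))
      }
    }
    ids <- paste0("d", rep(seq_len(nDyads), each = 2), c("a", "b"))
    gt <- genotypeTable(ids, rep("D", n), lnames, al)
    list(table = gt,
         pairs = matrix(ids, ncol = 2, byrow = TRUE,
                        dimnames = list(NULL, c("id1", "id2"))))
  })
}
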