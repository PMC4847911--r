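setOldClass("igraph")

#' GenotypeTable: multilocus codominant genotypes with site labels
#'
#' Central data container of the package: one row per individual, one pair of
#' positive-integer allele sizes per locus (canonically sorted), with missing
#' genotypes stored as a pair of \code{NA}s.  Site labels are drawn from a
#' declared set and optional site coordinates (decimal degrees, WGS84) can be
#' attached.
#'
#' @slot ids character vector of unique individual identifiers.
#' @slot sites character vector (same length) of site labels.
#' @slot siteLevels declared set of site labels.
#' @slot loci ordered character vector of locus names.
#' @slot alleles integer array \code{n x L x 2}; \code{NA} pairs mark missing
#'   genotypes; each non-missing pair is sorted ascending.
#' @slot coords data.frame with columns \code{site}, \code{lat}, \code{lon}
#'   (possibly zero rows).
#' @export
setClass("GenotypeTable",
  representation(ids = "character", sites = "character",
                 siteLevels = "character", loci = "character",
                 alleles = "array", coords = "data.frame"))

setValidity("GenotypeTable", function(object) {
  n <- length(object@ids)
  L <- length(object@loci)
  msg <- character()
  if (anyDuplicated(object@ids)) msg <- c(msg, "duplicate individual ids")
  if (length(object@sites) != n) msg <- c(msg, "sites/ids length mismatch")
  if (!all(object@sites %in% object@siteLevels))
    msg <- c(msg, "site label outside the declared site set")
  d <- dim(object@alleles)
  if (length(d) != 3L || d[1] != n || d[2] != L || d[3] != 2L)
    msg <- c(msg, "allele array must be n x L x 2")
  a1 <- object@alleles[, , 1, drop = FALSE]
  a2 <- object@alleles[, , 2, drop = FALSE]
  if (any(xor(is.na(a1), is.na(a2))))
    msg <- c(msg, "half-missing genotype found (one NA allele)")
  ok <- !is.na(a1)
  if (any(a1[ok] <= 0) || any(a2[!is.na(a2)] <= 0))
    msg <- c(msg, "allele sizes must be positive integers")
  if (any(a1[ok] > a2[ok]))
    msg <- c(msg, "allele pairs must be stored sorted ascending")
  if (n > 0 && L > 0) {
    nonMiss <- rowSums(matrix(!is.na(object@alleles[, , 1]), nrow = n))
    if (any(nonMiss < 1))
      msg <- c(msg, "every individual needs >= 1 non-missing locus")
  }
  if (nrow(object@coords) &&
      !all(c("site", "lat", "lon") %in% names(object@coords)))
    msg <- c(msg, "coords needs columns site, lat, lon")
  if (length(msg)) msg else TRUE
})

#' FrequencyTable: per-group, per-locus allele frequencies
#'
#' @slot grouping one of \code{"global"}, \code{"site"}, \code{"cluster"}.
#' @slot groups group labels.
#' @slot loci locus names.
#' @slot freqs nested list \code{freqs[[group]][[locus]]}: named numeric
#'   vector of allele frequencies (alleles with frequency 0 absent), or
#'   \code{NULL} when the group has no scored genotypes at that locus.
#' @slot n matrix (groups x loci) of non-missing genotype counts.
#' @export
setClass("FrequencyTable",
  representation(grouping = "character", groups = "character",
                 loci = "character", freqs = "list", n = "matrix"))

setValidity("FrequencyTable", function(object) {
  msg <- character()
  for (g in object@groups) for (l in object@loci) {
    f <- object@freqs[[g]][[l]]
    if (is.null(f)) next
    if (any(f < 0)) msg <- c(msg, sprintf("negative frequency in %s/%s", g, l))
    if (abs(sum(f) - 1) > 1e-9)
      msg <- c(msg, sprintf("frequencies do not sum to 1 in %s/%s", g, l))
    if (any(f == 0)) msg <- c(msg, sprintf("zero-frequency allele kept in %s/%s", g, l))
  }
  if (length(msg)) head(msg, 5) else TRUE
})

#' TestResult: outcome of a Monte Carlo / permutation test
#'
#' @slot statistic observed test statistic (semantics depend on the test).
#' @slot p p-value in (0, 1]; Monte Carlo p-values use the add-one rule.
#' @slot nRep number of Monte Carlo / permutation replicates.
#' @slot tail \code{"lower"}, \code{"upper"} or \code{"two-sided"}.
#' @slot seed RNG seed used (NA if none supplied).
#' @slot method short label of the test.
#' @slot flags character vector, e.g. \code{"degenerate"}.
#' @export
setClass("TestResult",
  representation(statistic = "numeric", p = "numeric", nRep = "numeric",
                 tail = "character", seed = "numeric", method = "character",
                 flags = "character"))

setValidity("TestResult", function(object) {
  if (length(object@p) == 1 && !is.na(object@p) &&
      (object@p <= 0 || object@p > 1)) "p must lie in (0, 1]" else TRUE
})

#' RegressionResult: OLS fit of |He - Ho| on missingness
#'
#' @slot slope,intercept fitted coefficients.
#' @slot fstat F statistic of the slope.
#' @slot df numerator and denominator degrees of freedom.
#' @slot p p-value of the F test.
#' @slot n number of site-by-locus points.
#' @slot points data.frame (site, locus, missing, absDiff) for plotting.
#' @export
setClass("RegressionResult",
  representation(slope = "numeric", intercept = "numeric", fstat = "numeric",
                 df = "numeric", p = "numeric", n = "numeric",
                 points = "data.frame"))

setValidity("RegressionResult", function(object) {
  msg <- character()
  if (object@fstat < 0) msg <- c(msg, "F must be >= 0")
  if (object@df[2] != object@n - 2) msg <- c(msg, "df_den must equal n - 2")
  if (length(msg)) msg else TRUE
})

#' DistanceMatrices: pairwise site differentiation and geography
#'
#' Table-shaped bundle of pairwise between-site matrices: proportion of
#' different alleles (P_D), F_ST, great-circle distances (km), raw and
#' Holm-adjusted permutation p-values.
#'
#' @slot sites site labels.
#' @slot pd,fst,geo symmetric matrices (possibly 0 x 0 when not computed).
#' @slot pPd,pFst raw permutation p-value matrices.
#' @slot pPdAdj,pFstAdj Holm-adjusted p-value matrices.
#' @slot correction multiple-testing correction label.
#' @export
setClass("DistanceMatrices",
  representation(sites = "character", pd = "matrix", fst = "matrix",
                 geo = "matrix", pPd = "matrix", pFst = "matrix",
                 pPdAdj = "matrix", pFstAdj = "matrix",
                 correction = "character"))

setValidity("DistanceMatrices", function(object) {
  msg <- character()
  chk <- function(m, name, unit = FALSE) {
    if (!length(m)) return(character())
    out <- character()
    if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
      out <- c(out, paste(name, "not symmetric"))
    if (any(abs(diag(m)) > 1e-12, na.rm = TRUE))
      out <- c(out, paste(name, "diagonal not zero"))
    v <- m[lower.tri(m)]
    if (unit && any(v < -1e-12 | v > 1 + 1e-12, na.rm = TRUE))
      out <- c(out, paste(name, "outside [0,1]"))
    out
  }
  msg <- c(chk(object@pd, "pd", TRUE), chk(object@geo, "geo"),
           chk(object@fst, "fst"))
  if (length(object@geo) && any(object@geo < 0, na.rm = TRUE))
    msg <- c(msg, "geographic distances must be >= 0")
  if (length(msg)) msg else TRUE
})

#' RelatednessMatrix: pairwise maximum-likelihood relatedness
#'
#' @slot ids individual identifiers.
#' @slot r symmetric matrix of rhat in [0,1]; diagonal NA; NA where a dyad
#'   shares no scored locus.
#' @slot k0,k1,k2 matrices of the fitted IBD coefficients.
#' @slot estimator estimator label.
#' @slot errorRate per-allele class-II genotyping error rate used.
#' @slot seed RNG seed (reference-individual sampling).
#' @export
setClass("RelatednessMatrix",
  representation(ids = "character", r = "matrix", k0 = "matrix",
                 k1 = "matrix", k2 = "matrix", estimator = "character",
                 errorRate = "numeric", seed = "numeric"))

setValidity("RelatednessMatrix", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@r, t(object@r), check.attributes = FALSE)))
    msg <- c(msg, "r must be symmetric")
  v <- object@r[lower.tri(object@r)]
  if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "relatedness outside [0,1]")
  if (length(msg)) msg else TRUE
})

#' ClusterAssignment: within-site k-means/BIC genetic clusters
#'
#' @slot site site label.
#' @slot ids individual identifiers.
#' @slot cluster integer cluster id per individual (1..k).
#' @slot bic numeric vector of BIC values, names = candidate k.
#' @slot k selected number of clusters (argmin BIC).
#' @slot nPcs number of principal components retained.
#' @slot pcs matrix of retained PC scores (for discriminant projection).
#' @export
setClass("ClusterAssignment",
  representation(site = "character", ids = "character", cluster = "integer",
                 bic = "numeric", k = "integer", nPcs = "integer",
                 pcs = "matrix"))

setValidity("ClusterAssignment", function(object) {
  msg <- character()
  if (length(object@cluster) != length(object@ids))
    msg <- c(msg, "cluster/ids length mismatch")
  if (length(object@bic) &&
      object@k != as.integer(names(object@bic)[which.min(object@bic)]))
    msg <- c(msg, "selected k must be the argmin of BIC")
  if (length(object@cluster) && !all(tabulate(object@cluster) >= 0))
    msg <- c(msg, "invalid cluster ids")
  if (length(msg)) msg else TRUE
})

#' DyadClassification: full-sib / half-sib / unrelated dyad calls
#'
#' @slot dyads data.frame with columns id1, id2, pFS, pHS, pU, nLoci, label
#'   (one of FS, HS, U, UNASSIGNED).
#' @slot errorRate genotyping error rate used in the likelihood.
#' @slot prior prior over (FS, HS, U).
#' @slot threshold posterior confidence threshold for assignment.
#' @export
setClass("DyadClassification",
  representation(dyads = "data.frame", errorRate = "numeric",
                 prior = "numeric", threshold = "numeric"))

setValidity("DyadClassification", function(object) {
  d <- object@dyads
  need <- c("id1", "id2", "pFS", "pHS", "pU", "nLoci", "label")
  if (!all(need %in% names(d))) return("dyads missing required columns")
  s <- d$pFS + d$pHS + d$pU
  ok <- is.na(s) | abs(s - 1) < 1e-9
  if (!all(ok)) return("posteriors must sum to 1")
  pmax3 <- pmax(d$pFS, d$pHS, d$pU)
  bad <- !is.na(pmax3) & d$label != "UNASSIGNED" &
    pmax3 < object@threshold - 1e-12
  if (any(bad)) return("label assigned below the confidence threshold")
  TRUE
})

#' ExclusionResult: sibship exclusion probability of a marker panel
#'
#' @slot probability combined exclusion probability in [0,1].
#' @slot perLocus per-locus exclusion probabilities.
#' @slot loci locus subset used.
#' @slot groupSize number of unrelated individuals in the tested group.
#' @slot nMC Monte Carlo replicates per locus.
#' @slot subsets data.frame summarising random locus subsets (possibly 0-row):
#'   columns mean, lower, upper, subsetSize, nSubsets.
#' @export
setClass("ExclusionResult",
  representation(probability = "numeric", perLocus = "numeric",
                 loci = "character", groupSize = "numeric", nMC = "numeric",
                 subsets = "data.frame"))

setValidity("ExclusionResult", function(object) {
  if (object@probability < 0 || object@probability > 1)
    "exclusion probability must lie in [0,1]" else TRUE
})

#' SibGraph: sibship network of one genetic cluster
#'
#' Undirected simple graph whose nodes are the cluster's individuals and whose
#' edges are full- or half-sib dyads (edge attribute \code{kind} retains the
#' category; topology does not distinguish them).
#'
#' @slot cluster cluster identifier.
#' @slot graph igraph object.
#' @slot transitivity mean local transitivity (degree-<2 nodes contribute 0).
#' @slot transitivitySD standard deviation across nodes.
#' @export
setClass("SibGraph",
  representation(cluster = "character", graph = "igraph",
                 transitivity = "numeric", transitivitySD = "numeric"))

setValidity("SibGraph", function(object) {
  g <- object@graph
  msg <- character()
  if (igraph::any_loop(g) || igraph::any_multiple(g))
    msg <- c(msg, "sib graph must be simple")
  if (!is.na(object@transitivity) &&
      (object@transitivity < 0 || object@transitivity > 1))
    msg <- c(msg, "transitivity must lie in [0,1]")
  if (length(msg)) msg else TRUE
})
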