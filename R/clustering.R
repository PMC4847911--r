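# Within-site genetic clustering in the DAPC framework: allele-dosage
# encoding, PCA, k-means over candidate k, minimum-BIC model choice, and
# linear discriminant projections for plotting.

# One-hot allele dosage matrix (individuals x alleles, entries 0/1/2);
# missing genotypes imputed by the per-column (locus-allele) mean.
alleleDosage <- function(x, rows = seq_len(nInd(x))) {
  cols <- list()
  for (j in seq_along(x@loci)) {
    a1 <- x@alleles[rows, j, 1]; a2 <- x@alleles[rows, j, 2]
    alleles <- sort(unique(c(a1, a2)))
    alleles <- alleles[!is.na(alleles)]
    for (al in alleles) {
      v <- (a1 == al) + (a2 == al)
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      cols[[paste0(x@loci[j], ".", al)]] <- v
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- x@ids[rows]
  m
}

#' Find genetic clusters within a site (k-means / BIC)
#'
#' Individuals are encoded as allele-dosage counts, centred (optionally
#' scaled), projected onto principal components, and clustered by k-means
#' for every candidate k.  Model choice uses
#' \deqn{BIC(k) = n \ln(W_k/n) + k \ln(n)}
#' where \eqn{W_k} is the total within-cluster sum of squares of the
#' best-of-restarts solution; the selected k minimises BIC.
#'
#' @param x a \linkS4class{GenotypeTable}.
#' @param site site label (NULL = use all individuals).
#' @param maxK largest k evaluated (lowered to n - 1 when the site is
#'   small; default 10).
#' @param nPcs number of PCs retained (default: all with positive
#'   variance; the k-means step is not overfitting-sensitive).
#' @param nStarts k-means restarts (default 50).
#' @param seed RNG seed.
#' @param scale scale dosage columns to unit variance (default FALSE).
#' @return a \linkS4class{ClusterAssignment}.
#' @export
findClusters <- function(x, site = NULL, maxK = 10, nPcs = NULL,
                         nStarts = 50, seed = NULL, scale = FALSE) {
  rows <- if (is.null(site)) seq_len(nInd(x)) else which(x@sites == site)
  n <- length(rows)
  if (n < 2) stop("need >= 2 individuals to cluster")
  maxK <- min(maxK, n - 1)
  dos <- alleleDosage(x, rows)
  keep <- apply(dos, 2, function(v) var(v) > 0)
  dos <- dos[, keep, drop = FALSE]
  pc <- prcomp(dos, center = TRUE, scale. = scale)
  pos <- which(pc$sdev^2 > 1e-12)
  nPcs <- min(nPcs %||% length(pos), length(pos))
  scores <- pc$x[, seq_len(nPcs), drop = FALSE]
  withSeed(seed, {
    bic <- numeric(maxK)
    assignments <- vector("list", maxK)
    for (k in seq_len(maxK)) {
      if (k == 1) {
        W <- sum(scale(scores, scale = FALSE)^2)
        assignments[[1]] <- rep(1L, n)
      } else {
        km <- kmeans(scores, centers = k, nstart = nStarts, iter.max = 100)
        W <- km$tot.withinss
        assignments[[k]] <- km$cluster
      }
      bic[k] <- n * log(W / n) + k * log(n)
    }
    names(bic) <- seq_len(maxK)
    kSel <- which.min(bic)
    new("ClusterAssignment", site = site %||% "all", ids = x@ids[rows],
        cluster = as.integer(assignments[[kSel]]), bic = bic,
        k = as.integer(kSel), nPcs = as.integer(nPcs), pcs = scores)
  })
}

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment [site %s]: k = %d (BIC %.1f), n = %d, %d PCs\n",
              object@site, object@k, min(object@bic), length(object@ids),
              object@nPcs))
  print(table(cluster = object@cluster))
})

#' Discriminant projection of genetic clusters
#'
#' Linear discriminant analysis of the retained principal components on the
#' cluster labels, giving up to k - 1 discriminant axes per individual, plus
#' 67\% inertia-ellipse parameters per cluster for plotting.  With k = 2
#' there is a single axis and the coordinates are suited to a density plot.
#'
#' @param assignment a \linkS4class{ClusterAssignment} with k >= 2.
#' @param nAxes number of discriminant axes to return (default all,
#'   <= k - 1).
#' @return list: \code{coords} (individuals x axes), \code{ellipses}
#'   (data.frame cluster, cx, cy, sdx, sdy, cor, radius scale for 67\%
#'   coverage), \code{k}.
#' @export
discriminantProjection <- function(assignment, nAxes = NULL) {
  k <- assignment@k
  if (k < 2) stop("k = 1: no discriminant axes")
  scores <- assignment@pcs
  cl <- factor(assignment@cluster)
  fit <- MASS::lda(scores, grouping = cl)
  coords <- predict(fit, scores)$x
  nAxes <- min(nAxes %||% ncol(coords), ncol(coords))
  coords <- coords[, seq_len(nAxes), drop = FALSE]
  rownames(coords) <- assignment@ids
  scaleR <- sqrt(qchisq(0.67, df = min(2, ncol(coords))))
  ell <- do.call(rbind, lapply(levels(cl), function(g) {
    sub <- coords[cl == g, , drop = FALSE]
    cx <- mean(sub[, 1])
    cy <- if (ncol(sub) >= 2) mean(sub[, 2]) else 0
    sdx <- sd(sub[, 1]); if (is.na(sdx)) sdx <- 0
    sdy <- if (ncol(sub) >= 2) sd(sub[, 2]) else 0
    if (is.na(sdy)) sdy <- 0
    rho <- if (ncol(sub) >= 2 && nrow(sub) > 2 && sdx > 0 && sdy > 0)
      cor(sub[, 1], sub[, 2]) else 0
    data.frame(cluster = g, cx = cx, cy = cy, sdx = sdx, sdy = sdy,
               cor = rho, radiusScale = scaleR)
  }))
  list(coords = coords, ellipses = ell, k = k)
}
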