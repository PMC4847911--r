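#' Allele frequencies per group and locus
#'
#' Frequencies are computed from non-missing genotypes only; the number of
#' gene copies behind each entry is twice the non-missing genotype count.
#' Groups with zero scored genotypes at a locus get a \code{NULL} entry and
#' are flagged in attribute \code{"empty"}.
#'
#' @param x a \linkS4class{GenotypeTable}.
#' @param grouping \code{"global"}, \code{"site"}, or a named character
#'   vector mapping individual ids to cluster labels.
#' @return a \linkS4class{FrequencyTable}.
#' @export
alleleFrequencies <- function(x, grouping = "global") {
  if (nInd(x) == 0) stop("empty genotype table")
  if (is.character(grouping) && length(grouping) == 1 &&
      grouping %in% c("global", "site")) {
    lab <- grouping
    memb <- if (lab == "global") rep("all", nInd(x)) else x@sites
  } else {
    lab <- "cluster"
    memb <- as.character(grouping[x@ids])
    if (anyNA(memb)) stop("grouping vector must cover all individual ids")
  }
  groups <- unique(memb)
  L <- length(x@loci)
  freqs <- vector("list", length(groups)); names(freqs) <- groups
  n <- matrix(0L, length(groups), L, dimnames = list(groups, x@loci))
  empty <- character()
  for (g in groups) {
    rows <- which(memb == g)
    fg <- vector("list", L); names(fg) <- x@loci
    for (j in seq_len(L)) {
      a <- c(x@alleles[rows, j, 1], x@alleles[rows, j, 2])
      a <- a[!is.na(a)]
      n[g, j] <- length(a) / 2
      if (!length(a)) {
        empty <- c(empty, paste0(g, "/", x@loci[j]))
        fg[j] <- list(NULL)
      } else {
        tab <- table(a)
        f <- as.numeric(tab) / length(a)
        names(f) <- names(tab)
        fg[[j]] <- f
      }
    }
    freqs[[g]] <- fg
  }
  out <- new("FrequencyTable", grouping = lab, groups = groups,
             loci = x@loci, freqs = freqs, n = n)
  attr(out, "empty") <- empty
  out
}

#' @describeIn alleleFrequencies extract one group/locus frequency vector
#' @param ft a FrequencyTable.
#' @param group group label (default the first group).
#' @param locus locus name.
#' @export
getFrequencies <- function(ft, locus, group = ft@groups[1]) {
  ft@freqs[[group]][[locus]]
}

setMethod("show", "FrequencyTable", function(object) {
  cat("FrequencyTable (", object@grouping, "): ",
      length(object@groups), " group(s) x ", length(object@loci),
      " loci\n", sep = "")
})

#' Per-locus summary statistics
#'
#' Allelic richness, observed heterozygosity (Ho), expected heterozygosity
#' (He, plain gene diversity \eqn{1 - \sum_a p_a^2}), and the proportion of
#' individuals failing to amplify.  By default statistics pool all
#' individuals (one row per locus); \code{grouping = "site"} gives per-site
#' rows.
#'
#' @param x a \linkS4class{GenotypeTable}.
#' @param loci loci to summarise (default all).
#' @param grouping \code{"global"} or \code{"site"}.
#' @param unbiased apply the small-sample correction
#'   \eqn{2n/(2n-1)} to He (off by default).
#' @return data.frame with columns group, locus, n, richness, Ho, He,
#'   missing.
#' @export
locusSummary <- function(x, loci = lociNames(x), grouping = "global",
                         unbiased = FALSE) {
  bad <- setdiff(loci, x@loci)
  if (length(bad)) stop("unknown locus: ", paste(bad, collapse = ", "))
  ft <- alleleFrequencies(x, grouping)
  memb <- if (grouping == "global") rep("all", nInd(x)) else x@sites
  out <- list()
  for (g in ft@groups) {
    rows <- which(memb == g)
    for (l in loci) {
      j <- match(l, x@loci)
      a1 <- x@alleles[rows, j, 1]; a2 <- x@alleles[rows, j, 2]
      scored <- !is.na(a1)
      ng <- sum(scored)
      f <- ft@freqs[[g]][[l]]
      if (is.null(f)) {
        out[[length(out) + 1]] <- data.frame(group = g, locus = l, n = 0,
          richness = NA_integer_, Ho = NA_real_, He = NA_real_,
          missing = mean(!scored))
        next
      }
      ho <- sum(a1[scored] != a2[scored]) / ng
      he <- 1 - sum(f^2)
      if (unbiased && ng > 0) he <- he * 2 * ng / (2 * ng - 1)
      out[[length(out) + 1]] <- data.frame(group = g, locus = l, n = ng,
        richness = length(f), Ho = ho, He = he, missing = mean(!scored))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
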