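# End-to-end orchestration in the study's order: summary -> HWE ->
# differentiation -> clustering -> relatedness -> sibship -> networks.
# Per-stage sub-seeds are derived from the global seed by the documented
# counter scheme (seed * 100 + stage index), so any stage can be rerun
# independently and deterministically.

#' Pipeline configuration
#'
#' @param input a \linkS4class{GenotypeTable}, or a path to a genotype CSV.
#' @param coordsPath optional coordinates CSV (when \code{input} is a path).
#' @param outDir output directory (NULL = return the bundle only).
#' @param seed global RNG seed (mandatory).
#' @param nMCHwe Monte Carlo replicates per HWE/U test cell.
#' @param nPermDiff permutations per site pair.
#' @param estimator F_ST estimator.
#' @param errorRate genotyping error rate for relatedness/sibship.
#' @param nPermRel relatedness permutations.
#' @param maxK largest k for clustering.
#' @param threshold sibship posterior confidence threshold.
#' @param nPermSib sib-count permutations.
#' @param nSimNet Erdos-Renyi simulations per cluster.
#' @param exclusionMC Monte Carlo replicates per locus for exclusion.
#' @param stages character vector of stages to run (dependency order is
#'   enforced: clusters are required by cluster-level relatedness, sibship
#'   and networks).
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(input, coordsPath = NULL, outDir = NULL, seed,
                           nMCHwe = 5000, nPermDiff = 1000,
                           estimator = "wc", errorRate = 0.01,
                           nPermRel = 1000, maxK = 10, threshold = 0.95,
                           nPermSib = 1000, nSimNet = 1000,
                           exclusionMC = 20000,
                           stages = c("summary", "hwe", "differentiation",
                                      "clustering", "relatedness",
                                      "sibship", "networks")) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  need <- c(relatedness = "clustering", sibship = "clustering",
            networks = "sibship")
  for (st in names(need))
    if (st %in% stages && !need[[st]] %in% stages)
      stop("stage '", st, "' requires stage '", need[[st]], "'")
  structure(list(input = input, coordsPath = coordsPath, outDir = outDir,
                 seed = seed, nMCHwe = nMCHwe, nPermDiff = nPermDiff,
                 estimator = estimator, errorRate = errorRate,
                 nPermRel = nPermRel, maxK = maxK, threshold = threshold,
                 nPermSib = nPermSib, nSimNet = nSimNet,
                 exclusionMC = exclusionMC, stages = stages),
            class = "PipelineConfig")
}

writeStageCsv <- function(df, outDir, name) {
  if (is.null(outDir)) return(invisible(NULL))
  path <- file.path(outDir, paste0(name, ".csv"))
  con <- file(path, "w")
  writeLines("# kinpatch output schema 1", con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

matrixToDf <- function(m) {
  data.frame(row = rownames(m) %||% seq_len(nrow(m)), as.data.frame(m),
             check.names = FALSE)
}

#' Run the full kin-aggregation analysis
#'
#' Executes the configured stages in order and returns (and optionally
#' writes) a report bundle: locus summaries, HWE/homozygote-excess and
#' inbreeding grids, the missingness regression, pairwise differentiation
#' with Mantel tests, per-site cluster assignments and BIC curves,
#' site- and cluster-level mean relatedness with permutation envelopes,
#' sibship dyad calls with per-cluster permutation tests and the
#' exclusion-probability power analysis, and per-cluster network
#' transitivity with Erdos-Renyi significance.  A stage failure aborts with
#' the stage name; outputs of completed stages are kept alongside an
#' \code{INCOMPLETE} marker when writing to disk.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return the report bundle (named list), invisibly including the run log.
#' @export
runFullAnalysis <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  x <- config$input
  if (is.character(x))
    x <- readGenotypeTable(x, coordsPath = config$coordsPath)
  outDir <- config$outDir
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  if (!is.null(outDir))
    file.create(file.path(outDir, "INCOMPLETE"))
  bundle <- list(seed = config$seed, params = config[
    setdiff(names(config), c("input", "outDir"))])
  log <- c(sprintf("kinpatch pipeline, seed %d", config$seed),
           sprintf("individuals: %d, loci: %d, sites: %d", nInd(x),
                   length(lociNames(x)), length(unique(siteLabels(x)))))
  runStage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log <<- c(log, sprintf("stage %s: done in %.1fs (sub-seed %d)", name,
                           as.numeric(difftime(Sys.time(), t0, units = "secs")),
                           stageSeed(config$seed, stageIndex(name))))
    bundle[[name]] <<- res
    invisible(NULL)
  }
  stageIndex <- function(name) match(name, c("summary", "hwe",
    "differentiation", "clustering", "relatedness", "sibship", "networks"))

  runStage("summary", function() {
    tab <- locusSummary(x)
    writeStageCsv(tab, outDir, "locus_summary")
    tab
  })

  runStage("hwe", function() {
    sd1 <- stageSeed(config$seed, 2)
    exact <- hweGrid(x, "exact", nMC = config$nMCHwe, seed = sd1)
    usc <- hweGrid(x, "uscore", nMC = config$nMCHwe, seed = sd1 + 1)
    fis <- hweGrid(x, "fis", nMC = config$nMCHwe, seed = sd1 + 2)
    reg <- missingnessHeterozygosityRegression(x)
    writeStageCsv(matrixToDf(exact$p), outDir, "hwe_exact_p_grid")
    writeStageCsv(matrixToDf(usc$p), outDir, "homozygote_excess_p_grid")
    writeStageCsv(matrixToDf(fis$statistic), outDir, "fis_matrix")
    writeStageCsv(matrixToDf(fis$p), outDir, "fis_p_matrix")
    writeStageCsv(reg@points, outDir, "missingness_regression_points")
    list(exact = exact, uscore = usc, fis = fis, regression = reg)
  })

  runStage("differentiation", function() {
    sd3 <- stageSeed(config$seed, 3)
    dm <- distanceMatrices(x, estimator = config$estimator,
                           nPerm = config$nPermDiff, seed = sd3)
    mant <- NULL
    if (length(dm@geo) && length(dm@sites) >= 4) {
      mant <- list(
        pd = mantelTest(dm@pd, dm@geo, nPerm = config$nPermDiff,
                        seed = sd3 + 2),
        fst = mantelTest(dm@fst, dm@geo, nPerm = config$nPermDiff,
                         seed = sd3 + 3))
    }
    tbl <- dm@pd; tbl[lower.tri(tbl)] <- dm@fst[lower.tri(dm@fst)]
    writeStageCsv(matrixToDf(tbl), outDir, "pd_fst_matrix")
    writeStageCsv(matrixToDf(dm@pFstAdj), outDir, "fst_p_holm")
    writeStageCsv(matrixToDf(dm@pPdAdj), outDir, "pd_p_holm")
    list(matrices = dm, mantel = mant)
  })

  runStage("clustering", function() {
    sd4 <- stageSeed(config$seed, 4)
    sites <- unique(siteLabels(x))
    assignments <- lapply(seq_along(sites), function(i)
      findClusters(x, sites[i], maxK = config$maxK, seed = sd4 + i))
    names(assignments) <- sites
    clusterMap <- unlist(lapply(assignments, function(a)
      setNames(paste0(a@site, ".G", a@cluster), a@ids)))
    names(clusterMap) <- unlist(lapply(assignments, function(a) a@ids))
    bic <- do.call(rbind, lapply(assignments, function(a)
      data.frame(site = a@site, k = as.integer(names(a@bic)), bic = a@bic)))
    writeStageCsv(bic, outDir, "bic_curves")
    writeStageCsv(data.frame(id = names(clusterMap),
                             cluster = unname(clusterMap)),
                  outDir, "cluster_assignments")
    list(assignments = assignments, clusterMap = clusterMap, bic = bic)
  })

  runStage("relatedness", function() {
    sd5 <- stageSeed(config$seed, 5)
    rm <- pairwiseRelatedness(x, errorRate = config$errorRate, seed = sd5)
    siteGroups <- setNames(siteLabels(x), indIds(x))
    siteTest <- relatednessPermutationTest(rm, siteGroups,
                                           nPerm = config$nPermRel,
                                           seed = sd5 + 1)
    clusterMap <- bundle$clustering$clusterMap
    clTest <- relatednessPermutationTest(rm, clusterMap,
                                         nPerm = config$nPermRel,
                                         seed = sd5 + 2)
    writeStageCsv(siteTest, outDir, "site_relatedness")
    writeStageCsv(clTest, outDir, "cluster_relatedness")
    long <- which(lower.tri(rm@r), arr.ind = TRUE)
    writeStageCsv(data.frame(id1 = rm@ids[long[, 2]],
                             id2 = rm@ids[long[, 1]],
                             r = rm@r[long]),
                  outDir, "relatedness_pairs")
    list(matrix = rm, site = siteTest, cluster = clTest)
  })

  runStage("sibship", function() {
    sd6 <- stageSeed(config$seed, 6)
    dy <- classifyDyads(x, errorRate = config$errorRate,
                        threshold = config$threshold)
    clusterMap <- bundle$clustering$clusterMap
    perm <- sibCountPermutation(dy, clusterMap, nPerm = config$nPermSib,
                                seed = sd6)
    freqs <- alleleFrequencies(x, "global")
    minLoci <- min(rowSums(matrix(!is.na(x@alleles[, , 1]),
                                  nrow = nInd(x))))
    excl <- exclusionProbability(freqs, nMC = config$exclusionMC,
                                 seed = sd6 + 1,
                                 subsetSize = min(minLoci,
                                                  length(lociNames(x))))
    writeStageCsv(dy@dyads, outDir, "sib_dyads")
    writeStageCsv(perm, outDir, "sib_cluster_counts")
    list(dyads = dy, clusterTest = perm, exclusion = excl)
  })

  runStage("networks", function() {
    sd7 <- stageSeed(config$seed, 7)
    clusterMap <- bundle$clustering$clusterMap
    dy <- bundle$sibship$dyads
    cls <- unique(clusterMap)
    out <- lapply(seq_along(cls), function(i) {
      members <- names(clusterMap)[clusterMap == cls[i]]
      sg <- buildSibGraph(members, dy, cluster = cls[i])
      tt <- if (length(members) >= 3)
        erTransitivityTest(sg, nSim = config$nSimNet, seed = sd7 + i)
      else NULL
      list(graph = sg, test = tt)
    })
    names(out) <- cls
    tab <- do.call(rbind, lapply(out, function(o)
      data.frame(cluster = o$graph@cluster,
                 n = igraph::vcount(o$graph@graph),
                 sibEdges = igraph::ecount(o$graph@graph),
                 transitivity = o$graph@transitivity,
                 transitivitySD = o$graph@transitivitySD,
                 p = if (is.null(o$test)) NA_real_ else o$test@p)))
    writeStageCsv(tab, outDir, "cluster_transitivity")
    list(graphs = out, table = tab)
  })

  bundle$log <- log
  if (!is.null(outDir)) {
    writeLines(log, file.path(outDir, "run_log.txt"))
    jsonlite::write_json(bundleSummary(bundle),
                         file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    unlink(file.path(outDir, "INCOMPLETE"))
  }
  invisible(bundle)
}

# Machine-readable summary of the main quantities of a bundle.
bundleSummary <- function(bundle) {
  out <- list(schema = "kinpatch-summary-1", seed = bundle$seed)
  if (!is.null(bundle$hwe)) {
    out$hweRejectionRate <- mean(bundle$hwe$exact$p < 0.05, na.rm = TRUE)
    out$homozygoteExcessRate <- mean(bundle$hwe$uscore$p < 0.05,
                                     na.rm = TRUE)
    out$missingnessRegressionF <- bundle$hwe$regression@fstat
    out$missingnessRegressionP <- bundle$hwe$regression@p
  }
  if (!is.null(bundle$differentiation)) {
    dm <- bundle$differentiation$matrices
    out$fstSignificantFraction <- mean(lowerTri(dm@pFstAdj) < 0.05,
                                       na.rm = TRUE)
    out$pdSignificantFraction <- mean(lowerTri(dm@pPdAdj) < 0.05,
                                      na.rm = TRUE)
    out$meanFst <- mean(lowerTri(dm@fst), na.rm = TRUE)
    mant <- bundle$differentiation$mantel
    if (!is.null(mant)) {
      out$mantelRPd <- mant$pd@statistic
      out$mantelPPd <- mant$pd@p
      out$mantelRFst <- mant$fst@statistic
      out$mantelPFst <- mant$fst@p
    }
  }
  if (!is.null(bundle$clustering)) {
    ks <- vapply(bundle$clustering$assignments, function(a) a@k, 0L)
    out$clustersPerSiteMin <- min(ks)
    out$clustersPerSiteMax <- max(ks)
  }
  if (!is.null(bundle$relatedness)) {
    out$siteRelatednessSignificantFraction <-
      mean(bundle$relatedness$site$p < 0.05, na.rm = TRUE)
    out$clusterRelatednessSignificantFraction <-
      mean(bundle$relatedness$cluster$p < 0.05, na.rm = TRUE)
    out$meanClusterRelatedness <-
      mean(bundle$relatedness$cluster$rbar, na.rm = TRUE)
  }
  if (!is.null(bundle$sibship)) {
    ct <- bundle$sibship$clusterTest
    nPairs <- choose(ct$n, 2)
    out$sibProportionMean <- mean(ct$sibDyads[nPairs > 0] /
                                    nPairs[nPairs > 0]) * 100
    out$exclusionAllLoci <- bundle$sibship$exclusion@probability
    if (nrow(bundle$sibship$exclusion@subsets))
      out$exclusionSubsetMean <- bundle$sibship$exclusion@subsets$mean
  }
  if (!is.null(bundle$networks)) {
    tab <- bundle$networks$table
    out$meanTransitivity <- mean(tab$transitivity, na.rm = TRUE)
    out$transitivitySignificantFraction <- mean(tab$p < 0.05, na.rm = TRUE)
  }
  out
}

#' Render a human-readable report from a bundle
#'
#' One section per stage; stages absent from the bundle are flagged rather
#' than failing.
#'
#' @param bundle result of \code{\link{runFullAnalysis}}.
#' @param path optional output file (markdown).
#' @return character vector of report lines, invisibly when written.
#' @export
makeReport <- function(bundle, path = NULL) {
  sec <- function(title, body) c(paste("##", title), "", body, "")
  lines <- c("# kinpatch analysis report", "",
             sprintf("Seed: %d", bundle$seed), "")
  fmt <- function(x) formatC(x, digits = 3, format = "g")
  lines <- c(lines, if (is.null(bundle$summary))
    sec("Locus summary", "*stage absent*")
    else sec("Locus summary", c("```",
      capture.output(print(bundle$summary, digits = 3)), "```")))
  lines <- c(lines, if (is.null(bundle$hwe)) sec("HWE", "*stage absent*")
    else sec("HWE", c(
      sprintf("Exact-test rejections (alpha 0.05): %s",
              fmt(mean(bundle$hwe$exact$p < 0.05, na.rm = TRUE))),
      sprintf("Homozygote-excess rejections: %s",
              fmt(mean(bundle$hwe$uscore$p < 0.05, na.rm = TRUE))),
      sprintf("Missingness regression: F(%d,%d) = %s, p = %s",
              bundle$hwe$regression@df[1], bundle$hwe$regression@df[2],
              fmt(bundle$hwe$regression@fstat),
              fmt(bundle$hwe$regression@p)))))
  lines <- c(lines, if (is.null(bundle$differentiation))
    sec("Differentiation", "*stage absent*")
    else sec("Differentiation", c("```",
      capture.output(show(bundle$differentiation$matrices)), "```",
      if (!is.null(bundle$differentiation$mantel))
        sprintf("Mantel (P_D): r = %s, p = %s; Mantel (F_ST): r = %s, p = %s",
                fmt(bundle$differentiation$mantel$pd@statistic),
                fmt(bundle$differentiation$mantel$pd@p),
                fmt(bundle$differentiation$mantel$fst@statistic),
                fmt(bundle$differentiation$mantel$fst@p)))))
  lines <- c(lines, if (is.null(bundle$clustering))
    sec("Clustering", "*stage absent*")
    else sec("Clustering", vapply(bundle$clustering$assignments,
      function(a) sprintf("site %s: k = %d (n = %d)%s", a@site, a@k,
        length(a@ids), if (a@k == 2)
          " [density-plot data: single discriminant axis]" else ""), "")))
  lines <- c(lines, if (is.null(bundle$relatedness))
    sec("Relatedness", "*stage absent*")
    else sec("Relatedness", c("```",
      capture.output(print(bundle$relatedness$cluster, digits = 3)), "```")))
  lines <- c(lines, if (is.null(bundle$sibship))
    sec("Sibship", "*stage absent*")
    else sec("Sibship", c("```",
      capture.output(print(bundle$sibship$clusterTest, digits = 3)), "```",
      sprintf("Exclusion probability (all loci): %s",
              fmt(bundle$sibship$exclusion@probability)))))
  lines <- c(lines, if (is.null(bundle$networks))
    sec("Networks", "*stage absent*")
    else sec("Networks", c("```",
      capture.output(print(bundle$networks$table, digits = 3)), "```")))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
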