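test_that("construction canonicalises allele pairs and enforces invariants", {
  al <- array(c(5L, 1L, 3L, 2L), dim = c(2, 1, 2)) # pairs (5,3) and (1,2)
  gt <- genotypeTable(c("a", "b"), c("S", "S"), "L1", al)
  g <- genotypes(gt, "L1")
  expect_equal(unname(g["a", ]), c(3, 5))
  expect_equal(unname(g["b", ]), c(1, 2))
  # genotype equality independent of input order
  al2 <- array(c(3L, 1L, 5L, 2L), dim = c(2, 1, 2))
  gt2 <- genotypeTable(c("a", "b"), c("S", "S"), "L1", al2)
  expect_identical(gt@alleles, gt2@alleles)
  # duplicate ids rejected
  expect_error(genotypeTable(c("a", "a"), c("S", "S"), "L1", al),
               "duplicate")
  # half-missing genotypes become missing, with a warning
  al3 <- array(c(5L, NA, 3L, 2L), dim = c(2, 1, 2))
  expect_error(
    expect_warning(genotypeTable(c("a", "b"), c("S", "S"), "L1", al3),
                   "half-missing"),
    "non-missing") # individual a then has no scored locus
})

test_that("csv and genepop writers round-trip canonical tables", {
  st <- simulateStudy(simulationConfig(
    nSites = 2, siteSizeRange = c(16, 24), clustersPerSite = c(2, 2),
    clusterSizeRange = c(8, 12), nLoci = 4,
    allelesPerLocus = c(5, 8, 3, 6)), seed = 71)
  gt <- st$table
  for (dialect in c("csv", "genepop")) {
    path <- tempfile(fileext = paste0(".", dialect))
    writeGenotypeTable(gt, path, dialect)
    back <- readGenotypeTable(path, dialect)
    expect_identical(indIds(back), indIds(gt))
    expect_identical(siteLabels(back), siteLabels(gt))
    expect_identical(lociNames(back), lociNames(gt))
    expect_identical(unname(back@alleles), unname(gt@alleles))
  }
})

test_that("reader rejects malformed input with informative errors", {
  empty <- tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(readGenotypeTable(empty), "empty|header")
  odd <- tempfile(fileext = ".csv")
  writeLines(c("id,site,L1_1,L1_2,L2_1", "a,S,1,2,3"), odd)
  expect_error(readGenotypeTable(odd), "odd|mismatched")
  bad <- tempfile(fileext = ".csv")
  writeLines(c("id,site,L1_1,L1_2", "a,S,x,2", "b,S,1,2"), bad)
  expect_error(readGenotypeTable(bad), "unparseable")
  expect_error(readGenotypeTable(tempfile()), "not found")
})

test_that("missing codes map to MISSING and minLoci filters individuals", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("id,site,L1_1,L1_2,L2_1,L2_2",
               "a,S,0,0,101,103",
               "b,S,101,101,0,0",
               "c,S,0,0,0,0"), path)
  expect_error(readGenotypeTable(path), NA) # c dropped, not fatal
  gt <- readGenotypeTable(path)
  expect_identical(attr(gt, "rejected"), "c")
  expect_true(all(is.na(genotypes(gt, "L1")["a", ])))
  expect_equal(unname(genotypes(gt, "L1")["b", ]), c(101, 101))
})

test_that("allele frequencies match a brute-force gene-copy count", {
  gt <- tinyTable()
  ft <- alleleFrequencies(gt, "global")
  f1 <- getFrequencies(ft, "L1")
  # direct count: copies 101,103, 101,101, 103,105, 101,105
  expect_equal(f1[["101"]], 4 / 8)
  expect_equal(f1[["103"]], 2 / 8)
  expect_equal(f1[["105"]], 2 / 8)
  expect_equal(unname(ft@n[1, "L1"]), 4)
  # missing genotypes excluded; sample size reflects scored only
  f2 <- getFrequencies(ft, "L2")
  expect_equal(unname(ft@n[1, "L2"]), 3)
  expect_equal(sum(f2), 1)
  # per-site grouping equals per-site recount on a simulated table
  st <- simulateStudy(simulationConfig(
    nSites = 2, siteSizeRange = c(16, 24), clustersPerSite = c(2, 2),
    clusterSizeRange = c(8, 12), nLoci = 3, allelesPerLocus = 6),
    seed = 72)
  fs <- alleleFrequencies(st$table, "site")
  for (s in unique(siteLabels(st$table))) {
    rows <- siteLabels(st$table) == s
    for (l in lociNames(st$table)) {
      a <- c(genotypes(st$table, l)[rows, ])
      a <- a[!is.na(a)]
      expected <- as.numeric(table(a)) / length(a)
      got <- fs@freqs[[s]][[l]]
      expect_equal(unname(got[order(as.integer(names(got)))]),
                   expected, tolerance = 1e-12)
    }
  }
})

test_that("locus summaries reproduce hand-computable statistics", {
  # all-heterozygous A/B sample: richness 2, Ho 1, He 0.5
  al <- array(rep(c(101L, 103L), each = 4), dim = c(4, 1, 2))
  gt <- genotypeTable(paste0("i", 1:4), rep("S", 4), "L1", al)
  ls <- locusSummary(gt)
  expect_equal(ls$richness, 2)
  expect_equal(ls$Ho, 1)
  expect_equal(ls$He, 0.5)
  # monomorphic locus: richness 1, Ho = He = 0
  alm <- array(101L, dim = c(4, 1, 2))
  gm <- genotypeTable(paste0("i", 1:4), rep("S", 4), "L1", alm)
  lm2 <- locusSummary(gm)
  expect_equal(lm2$richness, 1)
  expect_equal(lm2$Ho, 0)
  expect_equal(lm2$He, 0)
  # He recomputation from the FrequencyTable matches, and the unbiased
  # option applies 2n/(2n-1)
  gt2 <- tinyTable()
  ls2 <- locusSummary(gt2)
  f1 <- getFrequencies(alleleFrequencies(gt2), "L1")
  expect_equal(ls2$He[ls2$locus == "L1"], 1 - sum(f1^2))
  lsu <- locusSummary(gt2, unbiased = TRUE)
  expect_equal(lsu$He[lsu$locus == "L1"],
               (1 - sum(f1^2)) * 8 / 7)
  expect_equal(ls2$missing[ls2$locus == "L2"], 0.25)
  expect_error(locusSummary(gt2, loci = "nope"), "unknown locus")
})
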