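test_that("Monte Carlo p-values agree with the Levene enumeration oracle", {
  # a spread of 2- and 3-allele samples, n <= 8, including the classic
  # all-homozygote case {AA:3, BB:3}
  cases <- list(
    cbind(c(1, 1, 1, 2, 2, 2), c(1, 1, 1, 2, 2, 2)),
    cbind(c(1, 1, 2, 2), c(1, 2, 2, 2)),
    cbind(c(1, 1, 1, 1, 2, 2, 2, 2), c(1, 2, 1, 2, 2, 2, 1, 1)),
    cbind(c(1, 1, 2, 3, 3, 2), c(1, 2, 2, 3, 3, 3)),
    cbind(c(1, 2, 3, 1, 2, 3, 1, 2), c(1, 2, 3, 2, 3, 1, 3, 2)))
  set.seed(10)
  for (sim in 1:5) { # plus random draws widen coverage
    K <- sample(2:3, 1); n <- sample(4:8, 1)
    cases[[length(cases) + 1]] <-
      matrix(sample(seq_len(K), 2 * n, replace = TRUE), ncol = 2)
  }
  for (ci in seq_along(cases)) {
    g <- cases[[ci]]
    if (length(unique(c(g))) < 2) next
    st <- obsTableStats(g)
    pEnumExact <- hweEnumExactP(st$alleleCounts, st$logP)
    pEnumU <- hweEnumUP(st$alleleCounts, st$U)
    mcExact <- hweExactTest(g, nMC = 20000, seed = 100 + ci)
    mcU <- homozygoteExcessTest(g, nMC = 20000, seed = 200 + ci)
    expect_lt(abs(mcExact@p - pEnumExact), 0.02)
    expect_lt(abs(mcU@p - pEnumU), 0.02)
  }
})

test_that("degenerate and extreme inputs are handled as documented", {
  mono <- cbind(rep(1, 5), rep(1, 5))
  r <- hweExactTest(mono, nMC = 1000, seed = 1)
  expect_equal(r@p, 1)
  expect_true("degenerate" %in% r@flags)
  ru <- homozygoteExcessTest(mono, nMC = 1000, seed = 1)
  expect_equal(ru@p, 1)
  # all-heterozygous sample: minimal U, upper tail p = 1
  het <- cbind(rep(1, 6), rep(2, 6))
  expect_equal(homozygoteExcessTest(het, nMC = 1000, seed = 2)@p, 1)
  expect_error(hweExactTest(cbind(1, 2), nMC = 1000), ">= 2")
  expect_error(hweExactTest(het, nMC = 10), "nMC")
})

test_that("tests are invariant to allele relabeling", {
  g <- cbind(c(1, 1, 2, 2, 3, 1), c(1, 2, 2, 3, 3, 3))
  relab <- matrix(c(7, 5, 9)[g], ncol = 2)
  p1 <- hweExactTest(g, nMC = 5000, seed = 3)@p
  p2 <- hweExactTest(relab, nMC = 5000, seed = 3)@p
  expect_equal(p1, p2)
  u1 <- homozygoteExcessTest(g, nMC = 5000, seed = 4)@p
  u2 <- homozygoteExcessTest(relab, nMC = 5000, seed = 4)@p
  expect_equal(u1, u2)
})

test_that("weighted U-score variant runs and orders like the count version
           on homozygote-heavy samples", {
  g <- cbind(c(1, 1, 1, 2, 2, 2, 1, 2), c(1, 1, 1, 2, 2, 2, 2, 1))
  pc <- homozygoteExcessTest(g, nMC = 5000, seed = 5)
  pw <- homozygoteExcessTest(g, nMC = 5000, seed = 5, weighted = TRUE)
  expect_lt(pc@p, 0.2)
  expect_lt(pw@p, 0.2)
  expect_match(pw@method, "weighted")
})

test_that("F_IS matches its definition and bounds", {
  # Ho = He exactly: p = 0.5 with genotype counts AA:1 AB:2 BB:1
  al <- array(c(101L, 101L, 101L, 103L, 101L, 103L, 103L, 103L),
              dim = c(4, 1, 2))
  gt <- genotypeTable(paste0("i", 1:4), rep("S", 4), "L1", al)
  r <- inbreedingCoefficient(gt, "S", "L1", nPerm = 1000, seed = 6)
  expect_equal(r@statistic, 0)
  # polymorphic with zero heterozygotes: F_IS = 1
  al2 <- array(c(101L, 101L, 103L, 103L, 101L, 101L, 103L, 103L),
               dim = c(4, 1, 2))
  gt2 <- genotypeTable(paste0("i", 1:4), rep("S", 4), "L1", al2)
  r2 <- inbreedingCoefficient(gt2, "S", "L1", nPerm = 1000, seed = 7)
  expect_equal(r2@statistic, 1)
  expect_lt(r2@p, 0.2)
  # monomorphic: undefined
  al3 <- array(101L, dim = c(3, 1, 2))
  gt3 <- genotypeTable(paste0("i", 1:3), rep("S", 3), "L1", al3)
  expect_true(is.na(inbreedingCoefficient(gt3, "S", "L1")@statistic))
  # property: F_IS in [-1, 1] and sign tied to Ho < He
  f <- uniformFreqs(1, 6)
  set.seed(8)
  for (rep in 1:20) {
    gt4 <- simulateUnrelated(30, f)
    ls <- locusSummary(gt4)
    r4 <- inbreedingCoefficient(gt4, "S1", "L1", nPerm = 0)
    expect_gte(r4@statistic, -1)
    expect_lte(r4@statistic, 1)
    expect_equal(r4@statistic > 0, ls$Ho < ls$He)
  }
})

test_that("missingness regression has the documented shape and errors", {
  st <- simulateStudy(simulationConfig(
    nSites = 3, siteSizeRange = c(20, 30), clustersPerSite = c(2, 2),
    clusterSizeRange = c(10, 15), nLoci = 5, allelesPerLocus = 8),
    seed = 73)
  reg <- missingnessHeterozygosityRegression(st$table)
  expect_equal(reg@df[1], 1)
  expect_equal(reg@df[2], reg@n - 2)
  expect_gte(reg@fstat, 0)
  expect_equal(nrow(reg@points), reg@n)
  # constant predictor -> error
  cfg0 <- simulationConfig(nSites = 3, siteSizeRange = c(20, 30),
                           clustersPerSite = c(2, 2),
                           clusterSizeRange = c(10, 15), nLoci = 5,
                           allelesPerLocus = 8,
                           missingnessRange = c(0, 0))
  st0 <- simulateStudy(cfg0, seed = 74)
  expect_error(missingnessHeterozygosityRegression(st0$table),
               "no variance")
})

test_that("null alleles at a few loci produce a positive missingness slope", {
  # loci with injected null alleles show correlated missingness and
  # homozygote excess; the regression should detect a positive slope in
  # most replicates
  cfg <- simulationConfig(nSites = 9, siteSizeRange = c(40, 60),
                          clustersPerSite = c(2, 3),
                          clusterSizeRange = c(14, 25),
                          familySizeRange = c(1, 1), halfSibProb = 0,
                          siteTheta = Inf, clusterTheta = Inf,
                          inbreedingF = 0, nLoci = 10,
                          allelesPerLocus = 8, errorRate = 0,
                          missingnessRange = c(0, 0))
  hits <- 0
  nRep <- 100
  for (r in seq_len(nRep)) {
    st <- simulateStudy(cfg, seed = 9000 + r)
    gt <- st$table
    for (l in c("L1", "L2", "L3"))
      gt <- injectNullAlleles(gt, l, 0.25, seed = 9500 + r)
    reg <- missingnessHeterozygosityRegression(gt)
    if (reg@slope > 0 && reg@p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / nRep, 0.8)
})

test_that("hweGrid fills a site-by-locus matrix", {
  st <- simulateStudy(simulationConfig(
    nSites = 2, siteSizeRange = c(16, 24), clustersPerSite = c(2, 2),
    clusterSizeRange = c(8, 12), nLoci = 3, allelesPerLocus = 6),
    seed = 75)
  gr <- hweGrid(st$table, "uscore", nMC = 1000, seed = 11)
  expect_equal(dim(gr$p), c(2, 3))
  expect_true(all(gr$p > 0 & gr$p <= 1, na.rm = TRUE))
})
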