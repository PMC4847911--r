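twoSiteTable <- function(f1, f2, n = 20, seed = NULL) {
  withr_seed <- function(expr) if (is.null(seed)) expr else {
    set.seed(seed); expr }
  withr_seed({
    a <- simulateUnrelated(n, f1, site = "A")
    b <- simulateUnrelated(n, f2, site = "B", idPrefix = "j")
    L <- length(f1)
    al <- array(NA_integer_, c(2 * n, L, 2))
    al[seq_len(n), , ] <- a@alleles
    al[n + seq_len(n), , ] <- b@alleles
    genotypeTable(c(indIds(a), indIds(b)), c(rep("A", n), rep("B", n)),
                  names(f1), al)
  })
}

test_that("P_D hits its fixed points and the study-style definition", {
  f <- uniformFreqs(3, 4)
  gt <- twoSiteTable(f, f, seed = 1)
  # make the two sites literally identical in frequencies
  gt@alleles[21:40, , ] <- gt@alleles[1:20, , ]
  expect_equal(pairwisePd(gt)["A", "B"], 0)
  fDisj <- uniformFreqs(3, 4, base = 300)
  gt2 <- twoSiteTable(f, fDisj, seed = 2)
  expect_equal(pairwisePd(gt2)["A", "B"], 1)
  # definition check against a direct computation on one pair
  gt3 <- twoSiteTable(f, uniformFreqs(3, 6), seed = 3)
  ft <- alleleFrequencies(gt3, "site")
  direct <- 1 - mean(vapply(lociNames(gt3), function(l) {
    fa <- ft@freqs[["A"]][[l]]; fb <- ft@freqs[["B"]][[l]]
    al <- union(names(fa), names(fb))
    pa <- ifelse(al %in% names(fa), fa[al], 0)
    pb <- ifelse(al %in% names(fb), fb[al], 0)
    sum(pmin(pa, pb))
  }, 0))
  expect_equal(pairwisePd(gt3)["A", "B"], direct)
})

test_that("F_ST estimators behave at the fixed and panmictic ends", {
  f1 <- list(L1 = c("101" = 1), L2 = c("103" = 1))
  f2 <- list(L1 = c("201" = 1), L2 = c("203" = 1))
  gt <- twoSiteTable(f1, f2, seed = 4)
  expect_equal(pairwiseFst(gt, "nei")["A", "B"], 1)
  expect_gt(pairwiseFst(gt, "wc")["A", "B"], 0.97)
  # panmictic: mean estimate within +-0.01 of 0 over 200 replicates
  f <- randomFrequencies(10, 8, seed = 5)
  set.seed(6)
  vals <- replicate(200, pairwiseFst(twoSiteTable(f, f, n = 50))["A", "B"])
  expect_lt(abs(mean(vals)), 0.01)
  # negative estimates are reported, not truncated
  expect_true(any(vals < 0))
})

test_that("differentiation statistics are invariant to relabeling and order", {
  f <- randomFrequencies(4, 5, seed = 7)
  gt <- twoSiteTable(f, f, seed = 8)
  perm <- sample(nInd(gt))
  gtp <- subsetIndividuals(gt, perm)
  expect_equal(pairwiseFst(gt)["A", "B"], pairwiseFst(gtp)["A", "B"])
  expect_equal(pairwisePd(gt)["A", "B"], pairwisePd(gtp)["A", "B"])
  # allele relabeling (order-preserving shift)
  gt2 <- gt; gt2@alleles <- gt@alleles + 1000L
  expect_equal(pairwiseFst(gt)["A", "B"], pairwiseFst(gt2)["A", "B"])
})

test_that("permutation significance reaches its floor and Holm is monotone", {
  f1 <- list(L1 = c("101" = 1), L2 = c("103" = 1))
  f2 <- list(L1 = c("201" = 1), L2 = c("203" = 1))
  gt <- twoSiteTable(f1, f2, n = 10, seed = 9)
  sig <- differentiationSignificance(gt, "fst", nPerm = 199, seed = 10)
  expect_equal(sig$p["A", "B"], 1 / 200)
  # Holm adjusted never below raw, monotone in raw
  st <- simulateStudy(simulationConfig(
    nSites = 4, siteSizeRange = c(16, 24), clustersPerSite = c(2, 2),
    clusterSizeRange = c(8, 12), nLoci = 4, allelesPerLocus = 6),
    seed = 76)
  s2 <- differentiationSignificance(st$table, "fst", nPerm = 100,
                                    seed = 11)
  raw <- kinpatch:::lowerTri(s2$p)
  adj <- kinpatch:::lowerTri(s2$pAdj)
  expect_true(all(adj >= raw - 1e-12))
  expect_true(all(diff(adj[order(raw)]) >= -1e-12))
})

test_that("great-circle distances use the haversine closed form", {
  co <- data.frame(site = c("a", "b"), lat = c(0, 0), lon = c(0, 1))
  d <- greatCircleDistances(co)
  expect_equal(d["a", "b"], 111.195, tolerance = 1e-3 / 111.195)
  expect_equal(d["a", "a"], 0)
  expect_equal(d, t(d))
  expect_error(greatCircleDistances(
    data.frame(site = "x", lat = NA, lon = 2)), "x")
  expect_error(greatCircleDistances(
    data.frame(site = "x", lat = 95, lon = 2)), "latitude")
})

test_that("Mantel test matches vegan and is calibrated at the null", {
  set.seed(12)
  n <- 9
  m1 <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  m2 <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  r <- mantelTest(m1, m2, nPerm = 999, seed = 13)
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(m1, m2, permutations = 999)
  expect_equal(r@statistic, unname(vg$statistic), tolerance = 1e-10)
  expect_lt(abs(r@p - vg$signif), 0.06)
  # identity: r = 1
  expect_equal(mantelTest(m1, m1, nPerm = 99, seed = 14)@statistic, 1)
  # null: mean r near 0 over replicates
  set.seed(15)
  rs <- replicate(500, {
    a <- as.matrix(dist(rnorm(n))); b <- as.matrix(dist(rnorm(n)))
    cor(kinpatch:::lowerTri(a), kinpatch:::lowerTri(b))
  })
  expect_lt(abs(mean(rs)), 0.02)
  expect_error(mantelTest(matrix(0, 3, 3), m1[1:3, 1:3]), "constant")
})

test_that("distanceMatrices assembles a valid bundle", {
  st <- simulateStudy(simulationConfig(
    nSites = 3, siteSizeRange = c(16, 24), clustersPerSite = c(2, 2),
    clusterSizeRange = c(8, 12), nLoci = 4, allelesPerLocus = 6),
    seed = 77)
  dm <- distanceMatrices(st$table, nPerm = 100, seed = 16)
  expect_s4_class(dm, "DistanceMatrices")
  expect_equal(dim(dm@pd), c(3, 3))
  expect_true(all(dm@geo >= 0))
  expect_true(isSymmetric(unname(dm@fst)))
})
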