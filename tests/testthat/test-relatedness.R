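test_that("EM maximiser agrees with a dense grid search of the likelihood", {
  f <- randomFrequencies(10, 8, seed = 5)
  sim <- simulateDyads("FS", 6, f, errorRate = 0.02, seed = 9)
  d <- dyadRelatedness(sim$table, sim$pairs, f, errorRate = 0.02)
  ids <- indIds(sim$table)
  idx <- cbind(match(sim$pairs[, 1], ids), match(sim$pairs[, 2], ids))
  Q <- kinpatch:::dyadStateProbs(sim$table, idx,
    kinpatch:::normaliseFrequencies(f, sim$table), 0.02)
  grid <- expand.grid(k1 = seq(0, 1, 0.0025), k2 = seq(0, 1, 0.0025))
  grid <- grid[grid$k1 + grid$k2 <= 1, ]
  for (r in seq_len(nrow(sim$pairs))) {
    ll <- rowSums(log((1 - grid$k1 - grid$k2) %o% Q$Q0[r, ] +
                        grid$k1 %o% Q$Q1[r, ] + grid$k2 %o% Q$Q2[r, ]))
    best <- which.max(ll)
    expect_equal(d$r[r], grid$k2[best] + grid$k1[best] / 2,
                 tolerance = 0.005)
  }
})

test_that("identical multilocus genotypes give rhat near 1", {
  f <- uniformFreqs(20, 10)
  gt <- simulateUnrelated(3, f, seed = 17)
  al <- gt@alleles
  al[2, , ] <- al[1, , ] # clone individual 1
  gt2 <- genotypeTable(indIds(gt), siteLabels(gt), lociNames(gt), al)
  d <- dyadRelatedness(gt2, cbind("i1", "i2"), f, errorRate = 0)
  expect_gte(d$r, 0.9)
})

test_that("pedigree dyad classes are recovered with documented accuracy", {
  f <- randomFrequencies(10, c(13, 9, 14, 24, 10, 7, 33, 19, 50, 24),
                         seed = 11)
  means <- vapply(c(U = "U", HS = "HS", FS = "FS"), function(rel) {
    sim <- simulateDyads(rel, 200, f, errorRate = 0.01,
                         seed = 100 + nchar(rel))
    mean(dyadRelatedness(sim$table, sim$pairs, f, errorRate = 0.01)$r)
  }, 0)
  expect_lt(abs(means["FS"] - 0.5), 0.05)
  expect_lt(abs(means["HS"] - 0.25), 0.05)
  # constrained-ML truncation keeps unrelated dyads non-negative with a
  # small positive mean (see the methods vignette for the bias analysis)
  expect_gte(means["U"], 0)
  expect_lt(means["U"], 0.06)
})

test_that("RMSE decreases with locus count and k converges to pedigree
           values with many informative loci", {
  rmse <- vapply(c(10, 20, 40), function(L) {
    f <- uniformFreqs(L, 10)
    sim <- simulateDyads("FS", 100, f, errorRate = 0, seed = 300 + L)
    d <- dyadRelatedness(sim$table, sim$pairs, f, errorRate = 0)
    sqrt(mean((d$r - 0.5)^2))
  }, 0)
  expect_true(all(diff(rmse) < 0))
  f100 <- uniformFreqs(100, 20)
  for (rel in c("FS", "HS", "U")) {
    kTrue <- switch(rel, FS = c(0.25, 0.5, 0.25), HS = c(0.5, 0.5, 0),
                    U = c(1, 0, 0))
    sim <- simulateDyads(rel, 60, f100, errorRate = 0, seed = 400)
    d <- dyadRelatedness(sim$table, sim$pairs, f100, errorRate = 0)
    expect_lt(max(abs(colMeans(d[, c("k0", "k1", "k2")]) - kTrue)), 0.02)
  }
})

test_that("estimates are invariant to locus order and allele relabeling", {
  f <- randomFrequencies(6, 6, seed = 19)
  sim <- simulateDyads("HS", 20, f, errorRate = 0.01, seed = 20)
  d1 <- dyadRelatedness(sim$table, sim$pairs, f, errorRate = 0.01)
  # locus order
  perm <- c(4, 2, 6, 1, 3, 5)
  gt2 <- genotypeTable(indIds(sim$table), siteLabels(sim$table),
                       lociNames(sim$table)[perm],
                       sim$table@alleles[, perm, , drop = FALSE])
  d2 <- dyadRelatedness(gt2, sim$pairs, f[perm], errorRate = 0.01)
  expect_equal(d1$r, d2$r, tolerance = 1e-9)
  # allele relabeling (shift codes and frequency names together)
  gt3 <- sim$table; gt3@alleles <- gt3@alleles + 1000L
  f3 <- lapply(f, function(v) setNames(v, as.integer(names(v)) + 1000))
  d3 <- dyadRelatedness(gt3, sim$pairs, f3, errorRate = 0.01)
  expect_equal(d1$r, d3$r, tolerance = 1e-9)
})

test_that("pairwiseRelatedness returns a valid symmetric matrix", {
  st <- simulateStudy(simulationConfig(
    nSites = 2, siteSizeRange = c(16, 20), clustersPerSite = c(2, 2),
    clusterSizeRange = c(8, 10), nLoci = 6, allelesPerLocus = 8),
    seed = 78)
  rm <- pairwiseRelatedness(st$table, errorRate = 0.01, seed = 21)
  expect_s4_class(rm, "RelatednessMatrix")
  v <- kinpatch:::lowerTri(rm@r)
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  expect_true(all(is.na(diag(rm@r))))
  expect_error(pairwiseRelatedness(subsetIndividuals(st$table, 1:2)),
               ">= 3")
})

test_that("group means and their edge cases follow the definitions", {
  ids <- c("a", "b", "c")
  r <- matrix(NA_real_, 3, 3, dimnames = list(ids, ids))
  r["a", "b"] <- r["b", "a"] <- 0.1
  r["a", "c"] <- r["c", "a"] <- 0.2
  r["b", "c"] <- r["c", "b"] <- 0.3
  rm <- new("RelatednessMatrix", ids = ids, r = r, k0 = r, k1 = r, k2 = r,
            estimator = "manual", errorRate = 0, seed = NA_real_)
  g <- meanGroupRelatedness(rm, setNames(c("G", "G", "G"), ids))
  expect_equal(g$rbar, 0.2)
  # group of two: rbar is the single pairwise value, SE 0
  g2 <- meanGroupRelatedness(rm, setNames(c("G", "G", "H"), ids))
  expect_equal(g2$rbar[g2$group == "G"], 0.1)
  expect_equal(g2$se[g2$group == "G"], 0)
  expect_true(is.na(g2$rbar[g2$group == "H"])) # singleton
})

test_that("permutation test flags clonemate groups at the minimal p", {
  f <- uniformFreqs(10, 8)
  gt <- simulateUnrelated(20, f, seed = 22)
  al <- gt@alleles
  for (i in 2:4) al[i, , ] <- al[1, , ] # individuals 1-4 are clonemates
  gt2 <- genotypeTable(indIds(gt), siteLabels(gt), lociNames(gt), al)
  rm <- pairwiseRelatedness(gt2, frequencies =
    kinpatch:::normaliseFrequencies(f, gt2), errorRate = 0)
  groups <- setNames(rep(c("clones", "rest"), c(4, 16)), indIds(gt2))
  res <- relatednessPermutationTest(rm, groups, nPerm = 200, seed = 23)
  expect_equal(res$p[res$group == "clones"], 1 / 201)
  expect_true(all(c("envLower", "envUpper") %in% names(res)))
  expect_error(relatednessPermutationTest(rm,
    setNames(rep("one", 20), indIds(gt2))), ">= 2 groups")
})
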