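test_that("PCA response behaves as a deterministic first axis", {
  set.seed(2)
  base <- runif(10)
  f <- cbind(L1 = base, L2 = 0.2 + 0.6 * base)   # perfectly correlated
  rownames(f) <- sprintf("s%02d", 1:10)
  y <- pcaResponse(f)
  expect_equal(attr(y, "varExplained"), 1, tolerance = 1e-10)
  expect_gte(y[order(rownames(f))[1]], 0)        # sign convention
  # locus order leaves scores unchanged
  expect_equal(unname(pcaResponse(f[, 2:1])), unname(y), tolerance = 1e-12)
  expect_error(pcaResponse(matrix(0.5, 5, 3)), "variable loci")
})

test_that("PCA response recovers a planted driver direction", {
  ok <- 0
  for (seed in 1:6) {
    cfg <- syntheticConfig(nSites = 25, nLoci = 80, noiseSd = 0.02,
                           seed = seed, arcLengthKm = 2500)
    sites <- generateCoastlineSites(cfg)
    dbmem <- buildDbMEM(euclideanDistances(sites), sites = sites)
    cfg@drivers <- data.frame(label = "db-MEM 1", beta = 0.15)
    afs <- suppressWarnings(simulateAlleleFrequencies(sites, dbmem, cfg))
    r <- cor(pcaResponse(afs), basisVectors(dbmem)[, 1])
    ok <- ok + (abs(r) > 0.9)
  }
  expect_gte(ok, 5)
})

test_that("BIC selection finds exact and strong predictors", {
  set.seed(5)
  X <- qr.Q(qr(matrix(rnorm(30 * 6), 30, 6)))
  colnames(X) <- paste0("V", 1:6)
  ps <- predictorSet(X, rep("geography", 6))
  Xs <- predictorMatrix(ps)
  # y exactly a candidate: both directions pick exactly it
  sel <- selectVariablesBIC(Xs[, "V3"], ps)
  expect_equal(colnames(predictorMatrix(sel)), "V3")
  # two strong orthogonal drivers
  y <- Xs[, "V1"] * 0.5 + Xs[, "V5"] * 0.5 + rnorm(30, 0, 0.02)
  sel2 <- colnames(predictorMatrix(selectVariablesBIC(y, ps)))
  expect_true(all(c("V1", "V5") %in% sel2))
})

test_that("BIC selection on pure noise is empty or near-empty", {
  set.seed(8)
  X <- qr.Q(qr(matrix(rnorm(47 * 10), 47, 10)))
  colnames(X) <- paste0("V", 1:10)
  ps <- predictorSet(X, rep("geography", 10))
  sizes <- replicate(100, {
    y <- rnorm(47)
    suppressWarnings(ncol(predictorMatrix(selectVariablesBIC(y, ps))))
  })
  expect_gte(mean(sizes <= 1), 0.8)
})

test_that("correlation pruning follows the documented drop rules", {
  # identical columns: one dropped, deterministically the later name
  set.seed(1)
  a <- runif(20)
  m <- cbind(A = a, B = a, C = rnorm(20))
  pr <- pruneCorrelated(predictorSet(m, rep("environment", 3)))
  expect_false("B" %in% colnames(predictorMatrix(pr)))
  expect_true(all(c("A", "C") %in% colnames(predictorMatrix(pr))))
  # orthogonal columns: nothing dropped
  Q <- qr.Q(qr(matrix(rnorm(40 * 3), 40, 3)))
  colnames(Q) <- c("A", "B", "C")
  pr2 <- pruneCorrelated(predictorSet(Q, rep("geography", 3)))
  expect_equal(ncol(predictorMatrix(pr2)), 3)
  # hand-traced mean-|r| rule: r(A,B)=.9, r(A,C)=.6, r(B,C)=.25 -> drop A
  # (the hub), then the remaining pair is below the cutoff; r(B,C) must
  # stay above the 0.19 positive-definiteness floor implied by the other two
  R <- rbind(c(1, .9, .6), c(.9, 1, .25), c(.6, .25, 1))
  dimnames(R) <- list(c("A", "B", "C"), c("A", "B", "C"))
  set.seed(2)
  m3 <- exactCorMatrix(R)
  pr3 <- pruneCorrelated(predictorSet(m3, rep("geography", 3)))
  expect_equal(attr(pr3, "dropped"), "A")
  expect_equal(sort(colnames(predictorMatrix(pr3))), c("B", "C"))
  # response-guided rule keeps the supported member of a redundant pair
  y <- m3[, "A"]
  pr4 <- pruneCorrelated(predictorSet(m3, rep("geography", 3)), y = y)
  expect_true("A" %in% colnames(predictorMatrix(pr4)))
})

test_that("all-subsets importances match the brute-force oracle at p = 4", {
  set.seed(7)
  n <- 25
  X <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, paste0("V", 1:4)))
  X <- standardize01(X)
  y <- 0.4 * X[, 1] - 0.3 * X[, 3] + rnorm(n, 0, 0.2)
  fit <- allSubsetsRegression(y, X)
  oracle <- bruteForceImportance(y, X)
  expect_equal(fit$importance, oracle, tolerance = 1e-12)
  expect_equal(sum(fit$models$weight), 1, tolerance = 1e-12)
  # enumeration order must not matter
  fit2 <- allSubsetsRegression(y, X[, c(3, 1, 4, 2)])
  expect_equal(fit2$importance[names(fit$importance)], fit$importance,
               tolerance = 1e-12)
})

test_that("a perfect predictor takes all the importance", {
  set.seed(9)
  X <- standardize01(matrix(runif(20 * 3), 20, 3,
                            dimnames = list(NULL, paste0("V", 1:3))))
  fit <- allSubsetsRegression(X[, 1], X)
  expect_gt(fit$importance["V1"], 0.999)
  expect_match(fit$bestModel, "V1")
  expect_equal(fit$adjR2Best, 1, tolerance = 1e-6)
  expect_true(fit$significant)
})

test_that("rank-deficient subsets are flagged, not fatal", {
  set.seed(10)
  a <- runif(15)
  X <- cbind(V1 = a, V2 = a, V3 = runif(15))   # exact duplicate
  y <- a + rnorm(15, 0, 0.1)
  expect_warning(sc <- scanAllSubsets(cbind(y), X), "rank-deficient")
  expect_true(any(sc$rankDeficient))
  expect_equal(unname(sc$weightSums), 1, tolerance = 1e-12)
})

test_that("scan summaries are internally consistent", {
  sc <- smallSea
  cand <- makePredictorSet(env = sc$sites[, c("sss", "sst")],
                           dbmem = sc$dbmem, aem = sc$aem)
  y1 <- pcaResponse(sc$afs)
  pr <- pruneCorrelated(selectVariablesBIC(y1, cand), y = y1)
  scan <- scanAllSubsets(sc$afs, pr)
  expect_equal(max(abs(scan$weightSums - 1)), 0, tolerance = 1e-12)
  expect_true(all(scan$importance >= 0 & scan$importance <= 1))
  expect_true(all(scan$perLocus$adjR2Best <= 1))
  # AICc option shifts AIC but keeps weights normalised
  scanC <- scanAllSubsets(sc$afs, pr, aicc = TRUE)
  expect_true(all(scanC$aic >= scan$aic))
  expect_equal(max(abs(scanC$weightSums - 1)), 0, tolerance = 1e-12)
})

test_that("omega summary separates a planted driver via Dunn's test", {
  set.seed(13)
  n <- 47
  X <- qr.Q(qr(matrix(rnorm(n * 8), n, 8)))
  colnames(X) <- paste0("V", 1:8)
  Xs <- standardize01(X)
  Y <- 0.5 * Xs[, "V4"] + matrix(rnorm(n * 300, 0, 0.15), n, 300)
  scan <- scanAllSubsets(Y, predictorSet(Xs, rep("geography", 8),
                                         standardize = FALSE))
  s <- summarizeImportance(scan)
  expect_equal(names(s$omega)[1], "V4")
  expect_lt(s$kwP, 0.01)
  expect_gte(sum(s$dunnP["V4", setdiff(colnames(Xs), "V4")] < 0.05), 4)
  expect_equal(s$dunnP, t(s$dunnP))
  expect_equal(unname(s$selectionCounts["V4"]), max(s$selectionCounts))
  # identical loci: omega equals the single-locus importance vector
  Y1 <- matrix(Y[, 1], n, 3)
  colnames(Y1) <- paste0("l", 1:3)
  sc1 <- scanAllSubsets(Y1, predictorSet(Xs, rep("geography", 8),
                                         standardize = FALSE))
  s1 <- summarizeImportance(sc1)
  expect_equal(sort(unname(s1$omega)), sort(unname(sc1$importance[1, ])),
               tolerance = 1e-12)
})

test_that("null importances are flat across variables", {
  set.seed(14)
  n <- 30
  X <- standardize01(qr.Q(qr(matrix(rnorm(n * 4), n, 4))))
  colnames(X) <- paste0("V", 1:4)
  sc <- scanAllSubsets(matrix(rnorm(n * 500), n, 500),
                       predictorSet(X, rep("geography", 4),
                                    standardize = FALSE))
  mi <- colMeans(sc$importance)
  expect_lt(max(dist(mi)), 0.05)
})

test_that("nested LR tests follow the Gaussian likelihood-ratio form", {
  set.seed(15)
  n <- 40
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("V", 1:4)))
  y <- X[, 1] + rnorm(n)
  # nested = full -> LR 0, p 1
  full <- lrNestedTest(y, X, nested = colnames(X))
  expect_equal(full$lr, 0)
  expect_equal(full$p, 1)
  # direct evaluation of LR = n log(RSSn / RSSf)
  lr <- lrNestedTest(y, X, nested = c("V1", "V2"))
  rssF <- sum(resid(lm(y ~ X))^2)
  rssN <- sum(resid(lm(y ~ X[, 1:2]))^2)
  expect_equal(lr$lr, n * log(rssN / rssF), tolerance = 1e-12)
  expect_equal(lr$df, 2)
  expect_equal(lr$p, pchisq(lr$lr, 2, lower.tail = FALSE))
  expect_gte(lr$lr, 0)
  # invariant to predictor column scaling
  lr2 <- lrNestedTest(y, sweep(X, 2, c(10, 0.1, 3, 7), "*"),
                      nested = c("V1", "V2"))
  expect_equal(lr2$lr, lr$lr, tolerance = 1e-9)
  expect_error(lrNestedTest(y, X, nested = "V9"), "subset")
})

test_that("a planted dispersal driver dominates the geography-only LR", {
  cfg <- smallCfg
  sites <- smallSea$sites
  aemDrv <- smallSea$config@drivers$label[2]
  cfg@drivers <- data.frame(label = aemDrv, beta = 0.15)
  afs <- suppressWarnings(
    simulateAlleleFrequencies(sites, list(smallSea$dbmem, smallSea$aem),
                              cfg))
  m <- cbind(basisVectors(smallSea$dbmem)[, 1:3],
             basisVectors(smallSea$aem)[, c(1, 2)],
             basisVectors(smallSea$aem)[, aemDrv])
  colnames(m) <- c(paste0("g", 1:3), paste0("a", 1:3))
  ps <- predictorSet(m, c(rep("geography", 3), rep("dispersal", 3)))
  lr <- lrNestedTests(afs, ps)
  expect_gt(lr$meanLrGeography, lr$meanLrDispersal)
  expect_true(all(lr$perLocus$lrGeography >= 0))
})

test_that("family summaries partition variance sensibly", {
  set.seed(16)
  n <- 47
  Q <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  m <- standardize01(Q)
  colnames(m) <- c("g1", "g2", "a1", "a2")
  ps <- predictorSet(m, c("geography", "geography",
                          "dispersal", "dispersal"),
                     standardize = FALSE)
  mc <- predictorMatrix(ps)
  # equal-strength orthogonal geography and dispersal signals
  Y <- 0.5 * mc[, "g1"] + 0.5 * mc[, "a1"] +
    matrix(rnorm(n * 150, 0, 0.08), n, 150)
  fam <- familyModelSummary(Y, ps)
  expect_equal(rownames(fam),
               c("Null", "Geography", "Dispersal", "GeographyDispersal"))
  expect_equal(fam["Null", "meanAdjR2"], 0)
  r2 <- adjR2ByFamily(Y, ps)
  expect_lt(abs(r2["GeographyDispersal"] -
                (r2["Geography"] + r2["Dispersal"])), 0.05)
  # perfect single-driver fit: its family reaches adjusted R2 of 1
  Yp <- cbind(l1 = mc[, "g1"], l2 = mc[, "g1"])
  r2p <- adjR2ByFamily(Yp, ps)
  expect_equal(unname(r2p["Geography"]), 1, tolerance = 1e-6)
  # noise-only loci: means near 0 (adjusted R2 centres at 0 under the null)
  Yn <- matrix(rnorm(n * 200), n, 200)
  r2n <- adjR2ByFamily(Yn, ps)
  expect_lt(max(abs(r2n)), 0.15)
})

test_that("Dunn post hoc matches the z formula with tie correction", {
  set.seed(17)
  v <- c(rnorm(30), rnorm(30, 1))
  g <- rep(c("x", "z"), each = 30)
  d <- dunnPosthoc(v, g)
  # two groups: Dunn z^2 equals the (tie-corrected) Kruskal-Wallis statistic
  kw <- kruskal.test(v ~ factor(g))
  expect_equal(unname(d$z["x", "z"]^2), unname(kw$statistic),
               tolerance = 1e-9)
  expect_equal(d$p["x", "z"],
               2 * pnorm(abs(d$z["x", "z"]), lower.tail = FALSE))
  # adjustment is applied when requested
  d2 <- dunnPosthoc(rep(v, 2), rep(c("x", "z", "w", "u"), each = 30),
                    pAdjust = "bonferroni")
  expect_true(all(d2$p >= d$p["x", "z"] - 1))
})
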