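test_that("db-MEMs are centred, unit-norm, orthogonal on random clouds", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 10 + seed
    sites <- data.frame(site_id = sprintf("s%02d", 1:n), lon = 0, lat = 0,
                        x = runif(n, 0, 500), y = runif(n, 0, 500),
                        pool_size = 10L, sss = 0, sst = 0)
    b <- buildDbMEM(euclideanDistances(sites), sites = sites)
    V <- basisVectors(b)
    expect_lt(max(abs(colSums(V))), 1e-8)
    expect_equal(unname(sqrt(colSums(V^2))), rep(1, ncol(V)))
    G <- crossprod(V); diag(G) <- 0
    expect_lt(max(abs(G)), 1e-8)
    expect_true(all(diff(basisValues(b)) <= 1e-10))
    expect_lt(ncol(V), n)
  }
})

test_that("db-MEMs match the reference PCNM implementation", {
  skip_if_not_installed("vegan")
  d <- euclideanDistances(transect63)
  ours <- basisVectors(buildDbMEM(d, moranScreen = FALSE))
  ref <- vegan::pcnm(as.dist(d))$vectors
  k <- min(ncol(ours), ncol(ref))
  for (j in seq_len(k))
    expect_gt(abs(cor(ours[, j], ref[, j])), 1 - 1e-10)
})

test_that("three equidistant sites give two symmetric eigenvectors", {
  sites <- data.frame(site_id = c("a", "b", "c"), lon = 0, lat = 0,
                      x = c(0, 1, 0.5), y = c(0, 0, sqrt(3) / 2),
                      pool_size = 1L, sss = 0, sst = 0)
  b <- buildDbMEM(euclideanDistances(sites), moranScreen = FALSE)
  expect_equal(ncol(basisVectors(b)), 2)
  v <- basisValues(b)
  expect_equal(unname(v[1]), unname(v[2]), tolerance = 1e-9)
})

test_that("db-MEM construction validates input and truncation options", {
  d2 <- as.matrix(dist(c(0, 1)))
  expect_error(buildDbMEM(d2), "3 sites")
  d <- euclideanDistances(transect63[1:10, ])
  expect_s4_class(buildDbMEM(d, truncation = 100), "EigenvectorBasis")
  expect_s4_class(buildDbMEM(d, truncation = "none"), "EigenvectorBasis")
  expect_error(buildDbMEM(d, truncation = -5), "truncation")
  expect_error(buildDbMEM(d, truncation = "bogus"), "truncation")
  # disconnected neighbour graph under a too-small threshold warns
  expect_warning(buildDbMEM(d, truncation = 10), "disconnected")
})

test_that("site permutation permutes db-MEM rows identically", {
  set.seed(3)
  n <- 12
  sites <- data.frame(site_id = sprintf("s%02d", 1:n), lon = 0, lat = 0,
                      x = runif(n, 0, 300), y = runif(n, 0, 300),
                      pool_size = 5L, sss = 0, sst = 0)
  perm <- sample(n)
  b1 <- buildDbMEM(euclideanDistances(sites))
  b2 <- buildDbMEM(euclideanDistances(sites[perm, ]))
  V1 <- basisVectors(b1); V2 <- basisVectors(b2)
  expect_equal(ncol(V1), ncol(V2))
  for (j in seq_len(ncol(V1)))
    expect_equal(abs(cor(V1[perm, j], V2[, j])), 1, tolerance = 1e-8)
})

test_that("AEM worked example: root -> A -> B -> C chain", {
  p <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  p["B", "A"] <- 0.6; p["C", "B"] <- 0.6
  fit <- buildAEM(connectivityMatrix(p))
  E <- edgeMatrix(fit$edges)
  expect_equal(unname(E),
               rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)))
  expect_equal(rootSites(fit$edges), "A")   # largest net outflow
  # exactly 2 nonzero singular values, cross-checked by an eigen oracle
  expect_equal(length(basisValues(fit$basis)), 2)
  Ec <- scale(E, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Ec), symmetric = TRUE)$values
  expect_equal(unname(basisValues(fit$basis)), sqrt(ev[ev > 1e-12]),
               tolerance = 1e-10)
  # AEM 1 strictly monotone along the chain
  a1 <- basisVectors(fit$basis)[, 1]
  expect_true(all(diff(a1) > 0) || all(diff(a1) < 0))
})

test_that("SVD of the centred E matrix reconstructs it exactly", {
  sc <- smallSea
  E <- edgeMatrix(sc$edges)
  Ec <- scale(E, center = TRUE, scale = FALSE)
  sv <- svd(Ec)
  expect_lt(max(abs(sv$u %*% diag(sv$d) %*% t(sv$v) - Ec)), 1e-10)
  # retained basis is orthonormal, descending, fewer than n columns
  U <- basisVectors(sc$aem)
  expect_equal(unname(crossprod(U)), diag(ncol(U)), tolerance = 1e-8)
  expect_true(all(diff(basisValues(sc$aem)) <= 1e-10))
  expect_lte(ncol(U), min(nrow(E), ncol(E)) - 1)
})

test_that("degenerate and unreachable AEM inputs are handled", {
  one <- matrix(0.1, 1, 1, dimnames = list("a", "a"))
  fit <- buildAEM(connectivityMatrix(one), root = "a")
  expect_equal(dim(edgeMatrix(fit$edges)), c(1, 1))
  expect_equal(ncol(basisVectors(fit$basis)), 0)

  p <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  p["B", "A"] <- 0.5                       # C receives nothing
  expect_error(buildAEM(connectivityMatrix(p), root = "A"), "C")
  expect_error(buildAEM(connectivityMatrix(p), root = "Z"), "root")
})

test_that("scale estimation counts sinusoid cycles over the extent", {
  x <- transect63$x; L <- max(x)
  expect_equal(unname(estimateScale(cbind(cos(2 * pi * x / L)), transect63)),
               L)
  expect_equal(unname(estimateScale(cbind(cos(6 * pi * x / L)), transect63)),
               L / 3)
  # constant-sign vector: zero cycles -> full extent
  expect_equal(unname(estimateScale(cbind(rep(1, 63)), transect63)), L)
  # dead band ignores near-zero chatter
  v <- cos(2 * pi * x / L); v[10] <- 1e-6 * sign(-v[10])
  expect_equal(unname(estimateScale(cbind(v), transect63)), L)
  expect_error(estimateScale(cbind(1), transect63[1, , drop = FALSE]),
               "2 sites")
})

test_that("scale classes split at the configured breaks", {
  expect_equal(as.character(classifyScale(c(4500, 600, 100))),
               c("broad", "intermediate", "local"))
  expect_equal(as.character(classifyScale(1000)), "broad")
  expect_equal(as.character(classifyScale(250)), "local")
  expect_error(classifyScale(100, localBreak = 2000, broadBreak = 1000),
               "breaks")
  expect_error(classifyScale(-5), "scales")
})

test_that("transect db-MEM scales decrease monotonically with rank", {
  b <- buildDbMEM(euclideanDistances(transect63), sites = transect63)
  sc <- basisScales(b)
  expect_true(all(diff(sc) <= 1e-9))
})

test_that("symmetric connectivity is a negative control for dispersal", {
  # bias 0 kernel, geography-driven frequencies: the broad db-MEM driver
  # must out-rank every AEM in omega
  cfg <- syntheticConfig(seed = 6, downstreamBias = 0, nLoci = 200)
  sites <- generateCoastlineSites(cfg)
  d <- euclideanDistances(sites)
  dbmem <- buildDbMEM(d, sites = sites)
  conn <- generateDispersalMatrix(sites, cfg)
  aem <- buildAEM(conn, root = sites$site_id[1], sites = sites)$basis
  cfg@drivers <- data.frame(label = colnames(basisVectors(dbmem))[1],
                            beta = 0.12)
  afs <- suppressWarnings(simulateAlleleFrequencies(sites, list(dbmem, aem),
                                                    cfg))
  y1 <- pcaResponse(afs)
  cand <- makePredictorSet(dbmem = dbmem, aem = aem)
  pr <- pruneCorrelated(selectVariablesBIC(y1, cand), y = y1)
  om <- summarizeImportance(scanAllSubsets(afs, pr))$omega
  fam <- predictorFamily(pr)
  expect_equal(unname(fam[names(om)[1]]), "geography")
})
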