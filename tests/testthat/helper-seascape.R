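# shared fixtures, built once per test run

quietSeascape <- function(config, ...) {
  suppressWarnings(simulateSeascape(config, ...))
}

# small basin seascape reused across files
smallCfg <- syntheticConfig(nSites = 20, nLoci = 60, seed = 42,
                            arcLengthKm = 2000, basinWidthKm = 80)
smallSea <- quietSeascape(smallCfg)

# the regular calibration transect
transect63 <- makeRegularTransect(63, 47)

# a matrix with exactly the requested sample correlation structure
exactCorMatrix <- function(R, n = 120) {
  p <- ncol(R)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1, drop = FALSE]
  m <- Q %*% chol(R)
  colnames(m) <- colnames(R)
  m
}

# independent 8-neighbour shortest-path oracle (Dijkstra over sea cells)
gridOracle <- function(mask, cellKm, from, to) {
  nr <- nrow(mask); nc <- ncol(mask)
  dist <- matrix(Inf, nr, nc)
  done <- matrix(FALSE, nr, nc)
  dist[from[1], from[2]] <- 0
  steps <- expand.grid(dr = -1:1, dc = -1:1)
  steps <- steps[!(steps$dr == 0 & steps$dc == 0), ]
  repeat {
    d <- dist; d[done | !mask] <- Inf
    if (all(is.infinite(d))) break
    idx <- arrayInd(which.min(d), c(nr, nc))
    r <- idx[1]; c <- idx[2]
    done[r, c] <- TRUE
    for (k in seq_len(nrow(steps))) {
      r2 <- r + steps$dr[k]; c2 <- c + steps$dc[k]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || !mask[r2, c2]) next
      w <- cellKm * sqrt(steps$dr[k]^2 + steps$dc[k]^2)
      if (dist[r, c] + w < dist[r2, c2]) dist[r2, c2] <- dist[r, c] + w
    }
  }
  dist[to[1], to[2]]
}

# independent brute-force model-averaging oracle: lm() per subset,
# AIC = n log(RSS/n) + 2k, k = coefficients + 1
bruteForceImportance <- function(y, X) {
  n <- length(y); p <- ncol(X)
  subsets <- unlist(lapply(0:p, function(k)
    combn(p, k, simplify = FALSE)), recursive = FALSE)
  aic <- vapply(subsets, function(s) {
    df <- data.frame(y = y, X[, s, drop = FALSE])
    rss <- sum(resid(lm(y ~ ., data = df))^2)
    n * log(rss / n) + 2 * (length(s) + 2)
  }, numeric(1))
  w <- exp(-(aic - min(aic)) / 2); w <- w / sum(w)
  imp <- vapply(seq_len(p), function(j)
    sum(w[vapply(subsets, function(s) j %in% s, logical(1))]), numeric(1))
  setNames(imp, colnames(X))
}

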