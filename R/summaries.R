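#' Across-locus importance summary (omega, Kruskal-Wallis, Dunn)
#'
#' Averages per-locus Akaike-weight importances over loci to give each
#' variable's global contribution omega, tests for differences among the
#' variables' importance distributions with a Kruskal-Wallis test followed
#' by Dunn's pairwise post hoc z-tests, and tallies how often each variable
#' appears in the per-locus best models.
#'
#' @param scan a \code{"subsetScan"} (see [scanAllSubsets()]) or a loci x p
#'   importance matrix.
#' @param pAdjust p-value adjustment for the Dunn tests
#'   (\code{stats::p.adjust} method; default "none").
#' @return list with \code{omega} (named, sorted decreasing),
#'   \code{kwStatistic}, \code{kwP}, \code{dunnZ} and \code{dunnP}
#'   (symmetric p x p matrices), \code{selectionCounts}.
#' @export
summarizeImportance <- function(scan, pAdjust = "none") {
  imp <- if (inherits(scan, "subsetScan")) scan$importance else
    as.matrix(scan)
  if (nrow(imp) < 2) stop("at least 2 loci required")
  omega <- colMeans(imp)
  long <- data.frame(value = as.vector(imp),
                     variable = factor(rep(colnames(imp),
                                           each = nrow(imp)),
                                       levels = colnames(imp)))
  kw <- kruskal.test(value ~ variable, data = long)
  dunn <- dunnPosthoc(long$value, long$variable, pAdjust = pAdjust)
  counts <- if (inherits(scan, "subsetScan")) colSums(scan$bestMask)
            else rep(NA_integer_, ncol(imp))
  list(omega = sort(omega, decreasing = TRUE),
       kwStatistic = unname(kw$statistic), kwP = kw$p.value,
       dunnZ = dunn$z, dunnP = dunn$p,
       selectionCounts = counts)
}

#' Dunn's post hoc pairwise rank comparisons
#'
#' Pairwise z statistics on mean ranks after a Kruskal-Wallis test, with
#' the usual tie correction:
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))
#' where T = sum(t^3 - t) over tied groups.  Two-sided p-values, unadjusted
#' by default.
#'
#' @param values numeric observations.
#' @param groups factor of the same length.
#' @param pAdjust \code{stats::p.adjust} method (default "none").
#' @return list of symmetric matrices \code{z} and \code{p}.
#' @export
dunnPosthoc <- function(values, groups, pAdjust = "none") {
  groups <- droplevels(as.factor(groups))
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  ties <- table(values)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - Tcorr
  g <- levels(groups)
  z <- p <- matrix(NA_real_, length(g), length(g), dimnames = list(g, g))
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (i == j) { z[i, j] <- 0; p[i, j] <- 1; next }
    zz <- (rbar[i] - rbar[j]) / sqrt(s2 * (1 / ng[i] + 1 / ng[j]))
    z[i, j] <- zz
    p[i, j] <- 2 * stats::pnorm(abs(zz), lower.tail = FALSE)
  }
  if (pAdjust != "none") {
    lt <- lower.tri(p)
    p[lt] <- stats::p.adjust(p[lt], method = pAdjust)
    p[upper.tri(p)] <- t(p)[upper.tri(p)]
  }
  list(z = z, p = p)
}

#' Likelihood-ratio test of nested OLS models
#'
#' LR = 2 (l_full - l_nested) with Gaussian log-likelihoods
#' l = -n/2 (ln(2 pi RSS / n) + 1), which reduces to
#' LR = n ln(RSS_nested / RSS_full); the degrees of freedom are the
#' difference in coefficient counts and the p-value comes from the
#' chi-square upper tail.
#'
#' @param y response vector.
#' @param full a \linkS4class{PredictorSet} or matrix (the full model's
#'   predictors).
#' @param nested character vector naming the nested model's predictors;
#'   must be a subset of the full model's.
#' @return list with \code{lr}, \code{df}, \code{p}.
#' @examples
#' X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' lrNestedTest(X %*% c(1, 0, 0) + rnorm(20), X, nested = "a")
#' @export
lrNestedTest <- function(y, full, nested) {
  X <- if (is(full, "PredictorSet")) predictorMatrix(full) else
    as.matrix(full)
  if (!all(nested %in% colnames(X)))
    stop("nested variables must be a subset of the full model's")
  n <- length(y)
  rssOf <- function(cols) {
    Xl <- cbind(1, X[, cols, drop = FALSE])
    sum(stats::lm.fit(Xl, y)$residuals^2)
  }
  rssFull <- rssOf(colnames(X))
  rssNested <- rssOf(nested)
  lr <- max(0, n * log(rssNested / rssFull))
  df <- ncol(X) - length(nested)
  list(lr = lr, df = df,
       p = if (df > 0) pchisq(lr, df, lower.tail = FALSE) else 1)
}

#' Per-family nested LR tests across loci
#'
#' For each locus, compares the full spatial model (all geography + all
#' dispersal predictors) to the geography-only and dispersal-only nested
#' models; reports per-locus statistics and their means over the screened
#' loci (the convention for the across-SNP summary table).
#'
#' @param y sites x loci matrix or \linkS4class{AlleleFreqSet}.
#' @param predictors a \linkS4class{PredictorSet}; environment columns are
#'   excluded from these models.
#' @param screen optional logical per locus (e.g. best model beats null by
#'   delta AIC > 2 and has a significant coefficient); default all loci.
#' @return list with \code{perLocus} data.frame (lrGeography,
#'   lrDispersal, dfGeography, dfDispersal, pGeography, pDispersal) and
#'   \code{meanLrGeography}, \code{meanLrDispersal} over screened loci.
#' @export
lrNestedTests <- function(y, predictors, screen = NULL) {
  Y <- if (is(y, "AlleleFreqSet")) freqMatrix(y) else as.matrix(y)
  fam <- predictorFamily(predictors)
  geo <- names(fam)[fam == "geography"]
  dis <- names(fam)[fam == "dispersal"]
  if (!length(geo) || !length(dis))
    stop("need both geography and dispersal predictors")
  spatial <- predictors[match(c(geo, dis),
                              colnames(predictorMatrix(predictors)))]
  L <- ncol(Y)
  if (is.null(screen)) screen <- rep(TRUE, L)
  res <- lapply(seq_len(L), function(l) {
    g <- lrNestedTest(Y[, l], spatial, nested = geo)
    d <- lrNestedTest(Y[, l], spatial, nested = dis)
    c(lrGeography = g$lr, lrDispersal = d$lr, dfGeography = g$df,
      dfDispersal = d$df, pGeography = g$p, pDispersal = d$p)
  })
  perLocus <- as.data.frame(do.call(rbind, res))
  perLocus$locus <- colnames(Y)
  list(perLocus = perLocus,
       meanLrGeography = mean(perLocus$lrGeography[screen]),
       meanLrDispersal = mean(perLocus$lrDispersal[screen]),
       nScreened = sum(screen))
}

#' Family-wise model summary (geography / dispersal / combined)
#'
#' For each predictor family - geography-only (db-MEMs), dispersal-only
#' (AEMs) and combined - reruns the all-subsets scan restricted to that
#' family's predictors and reports, over the loci whose family best model
#' beats the intercept-only model by delta AIC > 2: the locus count and
#' percentage, the mean adjusted R-squared and mean AIC of the best models,
#' plus the mean LR statistic comparing the family-only nested model to the
#' combined model over the combined screen.  The Null row reports the mean
#' intercept-only AIC over all loci.
#'
#' @param y sites x loci matrix or \linkS4class{AlleleFreqSet}.
#' @param predictors a \linkS4class{PredictorSet} containing geography and
#'   dispersal columns (environment columns are ignored here).
#' @param aicc use AICc in the scans.
#' @return data.frame with rows Null, Geography, Dispersal,
#'   GeographyDispersal and columns nSnps, pctSnps, meanAdjR2, meanAic,
#'   meanLr.
#' @export
familyModelSummary <- function(y, predictors, aicc = FALSE) {
  Y <- if (is(y, "AlleleFreqSet")) freqMatrix(y) else as.matrix(y)
  fam <- predictorFamily(predictors)
  cols <- colnames(predictorMatrix(predictors))
  sets <- list(Geography = cols[fam == "geography"],
               Dispersal = cols[fam == "dispersal"],
               GeographyDispersal = cols[fam != "environment"])
  scans <- lapply(sets, function(v)
    scanAllSubsets(Y, predictors[match(v, cols)], aicc = aicc))
  combinedScreen <- scans$GeographyDispersal$perLocus$deltaAicNull > 2
  lr <- lrNestedTests(Y, predictors, screen = combinedScreen)
  L <- ncol(Y)
  nullAic <- scans$GeographyDispersal$aic[1, ]
  row <- function(scan, meanLr) {
    keep <- scan$perLocus$deltaAicNull > 2
    data.frame(nSnps = sum(keep), pctSnps = 100 * mean(keep),
               meanAdjR2 = mean(scan$perLocus$adjR2Best[keep]),
               meanAic = mean(scan$perLocus$aicBest[keep]),
               meanLr = meanLr)
  }
  out <- rbind(
    Null = data.frame(nSnps = L, pctSnps = 100, meanAdjR2 = 0,
                      meanAic = mean(nullAic), meanLr = NA_real_),
    Geography = row(scans$Geography, lr$meanLrGeography),
    Dispersal = row(scans$Dispersal, lr$meanLrDispersal),
    GeographyDispersal = row(scans$GeographyDispersal, NA_real_))
  out
}

#' Mean adjusted R-squared by predictor family
#'
#' Thin convenience over [familyModelSummary()]: the mean best-model
#' adjusted R-squared for the geography-only, dispersal-only and combined
#' model families across the loci passing each family's delta-AIC > 2
#' screen.
#'
#' @inheritParams familyModelSummary
#' @return named numeric vector (Geography, Dispersal,
#'   GeographyDispersal).
#' @export
adjR2ByFamily <- function(y, predictors, aicc = FALSE) {
  s <- familyModelSummary(y, predictors, aicc = aicc)
  setNames(s$meanAdjR2[-1], rownames(s)[-1])
}
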