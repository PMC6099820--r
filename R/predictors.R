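#' Rescale matrix columns to [0,1]
#'
#' @param m numeric matrix; every column must have positive range.
#' @return matrix with each column mapped linearly onto [0,1].
#' @export
standardize01 <- function(m) {
  m <- as.matrix(m)
  rng <- apply(m, 2, range)
  if (any(rng[2, ] - rng[1, ] <= 0))
    stop("cannot standardize a constant column to [0,1]")
  sweep(sweep(m, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], "/")
}

#' Assemble a PredictorSet from environment and eigenvector bases
#'
#' Combines environmental covariates, db-MEMs and AEMs into one predictor
#' matrix, tagging each column with its family and standardizing all
#' columns to [0,1] (the scale on which regressions are run).  Eigenvector
#' labels are sanitized to syntactic names ("db-MEM 1" becomes "dbMEM1").
#'
#' @param env data.frame or matrix of environmental covariates (e.g. sss,
#'   sst columns of a site table), or NULL.
#' @param dbmem an \linkS4class{EigenvectorBasis} of kind "dbMEM", or NULL.
#' @param aem an \linkS4class{EigenvectorBasis} of kind "AEM", or NULL.
#' @return a \linkS4class{PredictorSet}.
#' @examples
#' tr <- makeRegularTransect(20, 100)
#' mem <- buildDbMEM(euclideanDistances(tr), sites = tr)
#' ps <- makePredictorSet(env = tr[, c("sss", "sst")], dbmem = mem)
#' predictorFamily(ps)
#' @export
makePredictorSet <- function(env = NULL, dbmem = NULL, aem = NULL) {
  parts <- list(); fam <- character()
  if (!is.null(env)) {
    env <- as.matrix(env)
    colnames(env) <- toupper(colnames(env))
    parts <- c(parts, list(env))
    fam <- c(fam, rep("environment", ncol(env)))
  }
  addBasis <- function(b, family) {
    v <- basisVectors(b)
    colnames(v) <- gsub("[^A-Za-z0-9]", "", colnames(v))
    parts <<- c(parts, list(v))
    fam <<- c(fam, rep(family, ncol(v)))
  }
  if (!is.null(dbmem)) addBasis(dbmem, "geography")
  if (!is.null(aem)) addBasis(aem, "dispersal")
  if (!length(parts)) stop("no predictors supplied")
  predictorSet(do.call(cbind, parts), fam)
}

#' Drop predictors until all pairwise correlations are below a cutoff
#'
#' Iteratively finds the pair with the largest |Pearson r| above
#' \code{rMax} and drops one member, until every remaining pair satisfies
#' |r| <= rMax.  Which member is dropped: with a response \code{y} supplied
#' (as the pipeline does, using the PC1 selection response), the member
#' less correlated with \code{y} -- a redundant pair always loses its
#' weaker-supported half, never a true driver to its own proxy.  Without a
#' response, the member with the larger mean |r| to all other retained
#' predictors is dropped.  Ties break by dropping the lexicographically
#' later name.
#'
#' @param predictors a \linkS4class{PredictorSet} (or numeric matrix).
#' @param rMax correlation cutoff (default 0.5).
#' @param y optional response vector guiding which pair member to keep.
#' @return the pruned \linkS4class{PredictorSet}; the dropped names are in
#'   attribute \code{"dropped"}.
#' @export
pruneCorrelated <- function(predictors, rMax = 0.5, y = NULL) {
  ps <- if (is(predictors, "PredictorSet")) predictors
        else predictorSet(predictors, rep("environment", ncol(predictors)))
  keep <- colnames(predictorMatrix(ps))
  dropped <- character()
  repeat {
    m <- predictorMatrix(ps)[, keep, drop = FALSE]
    if (ncol(m) < 2) break
    r <- abs(cor(m)); diag(r) <- 0
    if (max(r) <= rMax) break
    ij <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- colnames(m)[ij]
    score <- if (is.null(y)) {
      vapply(pair, function(v) mean(r[v, setdiff(keep, v)]), numeric(1))
    } else {
      -abs(cor(y, m[, pair]))[1, ]   # drop the weaker-supported member
    }
    drop <- if (abs(diff(score)) > 1e-12) pair[which.max(score)]
            else sort(pair)[2]
    dropped <- c(dropped, drop)
    keep <- setdiff(keep, drop)
  }
  out <- ps[match(keep, colnames(predictorMatrix(ps)))]
  attr(out, "dropped") <- dropped
  out
}

#' First principal component of the allele-frequency matrix as response
#'
#' Site loading scores on the first axis of a PCA of the (column-centred)
#' sites x loci frequency matrix; used as the single response for BIC
#' variable pre-selection when loci are many.  The sign is fixed so the
#' first site (smallest site id) has a non-negative score.
#'
#' @param afm an \linkS4class{AlleleFreqSet} or sites x loci matrix.
#' @return named numeric vector of site scores; the proportion of variance
#'   explained by the axis is in attribute \code{"varExplained"}.
#' @export
pcaResponse <- function(afm) {
  p <- if (is(afm, "AlleleFreqSet")) freqMatrix(afm) else as.matrix(afm)
  vr <- apply(p, 2, var)
  p <- p[, vr > 0, drop = FALSE]
  if (ncol(p) < 2) stop("need at least 2 variable loci for a PCA response")
  pc <- prcomp(p, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1]
  first <- order(rownames(p))[1]
  if (scores[first] < 0) scores <- -scores
  attr(scores, "varExplained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  scores
}

#' BIC-based forward and backward pre-selection of spatial predictors
#'
#' Runs forward stepwise (add while BIC decreases) and backward stepwise
#' (drop while BIC decreases) regressions of \code{y} on each spatial
#' family separately (geography/db-MEMs and dispersal/AEMs) and keeps the
#' union of the two selections per family.  Environmental predictors are
#' not subjected to selection and pass through.  The greedy add/drop search
#' scores models with the Gaussian BIC n log(RSS/n) + k log(n).
#'
#' Forward additions are capped at \code{maxPerFamily} per family: this
#' stage exists to reduce each spatial family to the handful of vectors the
#' exhaustive all-subsets scan can enumerate, and an uncapped greedy search
#' over-selects whenever a family's eigenvectors approach a complete basis
#' of site space (n - 1 orthogonal AEMs always fit any response exactly).
#'
#' @param y response vector (typically [pcaResponse()]).
#' @param candidates a \linkS4class{PredictorSet}.
#' @param maxPerFamily cap on forward additions per spatial family
#'   (default 7).
#' @return the reduced \linkS4class{PredictorSet} (possibly with empty
#'   spatial families, with a warning).
#' @export
selectVariablesBIC <- function(y, candidates, maxPerFamily = 7) {
  stopifnot(is(candidates, "PredictorSet"))
  X <- predictorMatrix(candidates)
  fam <- predictorFamily(candidates)
  n <- length(y)
  selected <- names(fam)[fam == "environment"]
  for (f in c("geography", "dispersal")) {
    vars <- names(fam)[fam == f]
    if (!length(vars)) next
    fwd <- .stepBIC(y, X[, vars, drop = FALSE], "forward",
                    maxSteps = maxPerFamily)
    # the saturated backward start is only estimable when the family is
    # smaller than n - 2; otherwise backward prunes the forward solution
    bwdVars <- if (length(vars) < n - 2) vars else fwd
    bwd <- if (length(bwdVars)) {
      .stepBIC(y, X[, bwdVars, drop = FALSE], "backward")
    } else character()
    sel <- union(fwd, bwd)
    if (length(sel) > maxPerFamily)   # forward entries first, then backward
      sel <- sel[seq_len(maxPerFamily)]
    if (!length(sel))
      warning("BIC selection kept no ", f, " predictors")
    selected <- c(selected, sel)
  }
  candidates[match(intersect(colnames(X), selected), colnames(X))]
}

# greedy stepwise under BIC = n log(RSS/n) + k log(n); RSS floored so an
# exact fit (possible when a family spans the whole site space) stays finite
.stepBIC <- function(y, X, direction, maxSteps = Inf) {
  n <- length(y)
  Xa <- cbind(1, X)
  G <- crossprod(Xa)
  C <- crossprod(Xa, y)
  yty <- sum(y^2)
  bicOf <- function(cols) {            # cols: indices into X
    idx <- c(1L, cols + 1L)
    R <- tryCatch(chol(G[idx, idx, drop = FALSE]), error = function(e) NULL)
    if (!is.null(R) && min(diag(R)) < 1e-7 * max(diag(R))) R <- NULL
    rss <- if (is.null(R)) {
      Gi <- MASS::ginv(G[idx, idx, drop = FALSE])
      yty - sum(C[idx] * (Gi %*% C[idx]))
    } else {
      yty - sum(backsolve(R, C[idx], transpose = TRUE)^2)
    }
    n * log(max(rss, 1e-30) / n) + length(idx) * log(n)
  }
  p <- ncol(X)
  cur <- if (direction == "forward") integer(0) else seq_len(p)
  curBic <- bicOf(cur)
  repeat {
    if (direction == "forward" && length(cur) >= maxSteps) break
    cand <- if (direction == "forward") setdiff(seq_len(p), cur) else cur
    if (!length(cand)) break
    trials <- vapply(cand, function(j) {
      bicOf(if (direction == "forward") c(cur, j) else setdiff(cur, j))
    }, numeric(1))
    best <- which.min(trials)
    if (trials[best] >= curBic - 1e-10) break
    curBic <- trials[best]
    cur <- if (direction == "forward") c(cur, cand[best])
           else setdiff(cur, cand[best])
  }
  colnames(X)[sort(cur)]
}
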