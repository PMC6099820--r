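#' Distance-based Moran's eigenvector maps (db-MEMs)
#'
#' Classical PCNM/db-MEM construction: (1) choose a truncation threshold t
#' (default: the longest edge of the minimum spanning tree of the distance
#' matrix, the smallest t keeping all sites connected); (2) replace every
#' distance above t by 4t; (3) apply principal-coordinates double-centring
#' to -0.5 * D*^2; (4) eigen-decompose; (5) retain eigenvectors whose
#' eigenvalue exceeds \code{eps} times the largest and (optionally) whose
#' Moran's I on the t-neighbour graph exceeds its null expectation
#' -1/(n-1), i.e. positively autocorrelated broad-to-fine spatial patterns.
#' Columns are unit-norm, sum to zero, and are labelled "db-MEM 1", ... by
#' decreasing eigenvalue.
#'
#' On a regular transect the retained eigenvectors are sampled sinusoids of
#' decreasing period, which anchors the spatial-scale attribution (see
#' [estimateScale()]).
#'
#' @param d symmetric distance matrix (km).
#' @param truncation "mst" (default), "none" (threshold = the largest
#'   distance, i.e. a literal no-truncation reading), or a numeric t in km.
#' @param sites optional site table; when given, characteristic scales are
#'   estimated and stored in the basis.
#' @param eps relative eigenvalue cutoff (numerical rank; default 1e-9).
#' @param moranScreen keep only vectors with positive spatial
#'   autocorrelation (default TRUE).
#' @return an \linkS4class{EigenvectorBasis} of kind "dbMEM".
#' @examples
#' tr <- makeRegularTransect(20, 50)
#' mem <- buildDbMEM(euclideanDistances(tr), sites = tr)
#' basisScales(mem)[1:3]
#' @export
buildDbMEM <- function(d, truncation = "mst", sites = NULL, eps = 1e-9,
                       moranScreen = TRUE) {
  d <- as.matrix(d)
  .checkDistanceMatrix(d)
  n <- nrow(d)
  if (n < 3) stop("at least 3 sites required")
  t <- .truncationThreshold(d, truncation)
  tol <- t * (1 + 1e-12)                  # guard exact-tie distances
  W <- d <= tol & row(d) != col(d)
  if (!.graphConnected(W))
    warning("t-neighbour graph is disconnected; 4t padding keeps D* finite")
  Dstar <- ifelse(d > tol, 4 * t, d)
  diag(Dstar) <- 0
  B <- .gowerCenter(-0.5 * Dstar^2)
  e <- eigen(B, symmetric = TRUE)
  keep <- e$values > eps * max(e$values)
  V <- e$vectors[, keep, drop = FALSE]
  vals <- e$values[keep]
  if (moranScreen && ncol(V) && any(W)) {
    I <- apply(V, 2, .moranI, W = W)
    pos <- !is.na(I) & I > -1 / (n - 1)
    V <- V[, pos, drop = FALSE]
    vals <- vals[pos]
  }
  V <- .fixSigns(V)
  dimnames(V) <- list(rownames(d), sprintf("db-MEM %d", seq_len(ncol(V))))
  b <- new("EigenvectorBasis", vectors = V, values = vals, kind = "dbMEM",
           scaleKm = rep(NA_real_, ncol(V)))
  if (!is.null(sites)) b@scaleKm <- estimateScale(b, sites)
  b
}

.truncationThreshold <- function(d, truncation) {
  if (is.numeric(truncation)) {
    if (truncation <= 0) stop("numeric truncation must be > 0")
    return(truncation)
  }
  switch(truncation,
    none = max(d),
    mst = {
      g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                               weighted = TRUE)
      max(igraph::E(igraph::mst(g))$weight)
    },
    stop("truncation must be 'mst', 'none' or a numeric threshold"))
}

.graphConnected <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W * 1, mode = "undirected")
  igraph::components(g)$no == 1
}

.gowerCenter <- function(A) {
  rm <- rowMeans(A); gm <- mean(A)
  A - outer(rm, rep(1, ncol(A))) - outer(rep(1, nrow(A)), rm) + gm
}

# Moran's I of a (centred) vector under binary weights W
.moranI <- function(v, W) {
  v <- v - mean(v)
  n <- length(v)
  (n / sum(W)) * as.numeric(t(v) %*% (W %*% v)) / sum(v^2)
}

# deterministic sign convention: largest-|entry| element is positive
.fixSigns <- function(V) {
  if (!ncol(V)) return(V)
  sg <- apply(V, 2, function(v) if (v[which.max(abs(v))] < 0) -1 else 1)
  sweep(V, 2, sg, "*")
}
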