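#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with significance from
#' joint row/column permutations of the second matrix.  The p-value uses the
#' add-one convention p = (1 + #{r_perm >= r_obs}) / (nPerm + 1) for the
#' one-sided (positive association) alternative, matching the permutation
#' test used for isolation-by-distance.
#'
#' @param d1,d2 symmetric matrices of equal size (e.g. FST vs geographic
#'   distance).
#' @param nPerm number of permutations (default 10000).
#' @param seed seed for the permutation stream.
#' @return list with elements \code{r} (Mantel correlation), \code{p}
#'   (permutation p-value) and \code{nPerm}.
#' @examples
#' set.seed(1)
#' x <- as.matrix(dist(runif(8)))
#' mantelTest(x, 2 * x, nPerm = 99, seed = 1)$r  # exactly 1
#' @export
mantelTest <- function(d1, d2, nPerm = 10000, seed = 1) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) stop("matrices must have the same size")
  .checkDistanceMatrix(d1, "d1"); .checkDistanceMatrix(d2, "d2")
  n <- nrow(d1)
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  v2 <- d2[lt]
  if (sd(v1) == 0 || sd(v2) == 0)
    stop("constant distance matrix: Mantel correlation undefined")
  rObs <- cor(v1, v2)
  set.seed(seed)
  ge <- 0L
  for (i in seq_len(nPerm)) {
    perm <- sample.int(n)
    rp <- cor(v1, d2[perm, perm][lt])
    if (rp >= rObs) ge <- ge + 1L
  }
  list(r = rObs, p = (1 + ge) / (nPerm + 1), nPerm = nPerm)
}
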