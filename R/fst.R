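#' Pairwise FST from pool allele frequencies
#'
#' Frequency-only ratio-of-sums estimator for a pair of sites (a, b) over
#' loci l with frequencies p_a, p_b and mean p.bar = (p_a + p_b) / 2:
#'
#'   FST = sum_l (p_a - p_b)^2 / 2
#'         / sum_l ( p.bar (1 - p.bar) + (p_a - p_b)^2 / 4 )
#'
#' Loci monomorphic for the pair (p.bar in {0, 1}) are excluded from both
#' sums.  This is the natural estimator when only pool frequencies, not
#' individual genotypes, are available; it is exposed through the
#' \code{estimator} argument so a variance-components alternative can be
#' plugged in.  Values are in [0, 1]: identical pools give 0, a fixed
#' difference gives 1.
#'
#' @param afm an \linkS4class{AlleleFreqSet} or a sites x loci matrix of
#'   frequencies in [0,1].
#' @param estimator a function(pa, pb) returning the pairwise value;
#'   defaults to the ratio-of-sums estimator above.
#' @return symmetric sites x sites matrix with attribute
#'   \code{kind = "fst"}; negative estimates (possible only with a custom
#'   estimator) are truncated to 0 with a warning.
#' @examples
#' f <- rbind(A = c(0.2, 0.5), B = c(0.4, 0.5))
#' pairwiseFst(f)["A", "B"]  # 0.0909...
#' @export
pairwiseFst <- function(afm, estimator = NULL) {
  p <- if (is(afm, "AlleleFreqSet")) freqMatrix(afm) else as.matrix(afm)
  n <- nrow(p)
  if (n < 2) stop("at least 2 sites required")
  if (ncol(p) < 1) stop("at least 1 locus required")
  if (is.null(estimator)) estimator <- .fstRatioOfSums
  F <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    F[a, b] <- F[b, a] <- estimator(p[a, ], p[b, ])
  }
  if (any(F < 0)) {
    warning("negative FST estimates truncated to 0")
    F[F < 0] <- 0
  }
  attr(F, "kind") <- "fst"
  F
}

.fstRatioOfSums <- function(pa, pb) {
  pbar <- (pa + pb) / 2
  keep <- pbar > 0 & pbar < 1
  if (!any(keep))
    stop("all loci monomorphic for a site pair: FST undefined")
  pa <- pa[keep]; pb <- pb[keep]; pbar <- pbar[keep]
  num <- sum((pa - pb)^2 / 2)
  den <- sum(pbar * (1 - pbar) + (pa - pb)^2 / 4)
  num / den
}
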