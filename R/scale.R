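#' Characteristic spatial scale of eigenvectors
#'
#' On a regular transect the j-th db-MEM is a sampled sinusoid; its scale is
#' the spatial extent divided by the number of full cycles.  This
#' generalises to any site cloud by (1) projecting site coordinates onto
#' their first principal axis, (2) ordering sites along it, (3) counting
#' sign changes s of the eigenvector in that order (entries within a
#' dead-band |v| < deadBand * max|v| are skipped to avoid chatter on noisy
#' vectors), and (4) taking scale = extent / (s / 2).  A constant-sign
#' vector has zero cycles and is assigned the full extent.
#'
#' @param basis an \linkS4class{EigenvectorBasis} or a sites x k matrix.
#' @param sites site table sharing the basis' site ordering.
#' @param deadBand relative dead-band for sign-change counting
#'   (default 0.01).
#' @return numeric vector of scales in km, one per eigenvector.
#' @examples
#' tr <- makeRegularTransect(63, 47)
#' v <- cos(6 * pi * tr$x / max(tr$x))  # 3 cycles
#' estimateScale(cbind(v), tr)          # ~ extent / 3
#' @export
estimateScale <- function(basis, sites, deadBand = 0.01) {
  V <- if (is(basis, "EigenvectorBasis")) basisVectors(basis) else
    as.matrix(basis)
  if (nrow(sites) < 2) stop("at least 2 sites required")
  stopifnot(nrow(V) == nrow(sites))
  ax <- prcomp(as.matrix(sites[, c("x", "y")]))$x[, 1]
  extent <- diff(range(ax))
  ord <- order(ax)
  apply(V, 2, function(v) {
    v <- v[ord]
    v <- v[abs(v) >= deadBand * max(abs(v))]
    s <- sum(diff(sign(v)) != 0)
    if (s == 0) extent else extent / (s / 2)
  })
}

#' Classify a spatial scale as broad, intermediate or local
#'
#' Cutoffs follow the scale bands used to interpret seascape drivers:
#' geographic isolation dominates above ~1,000 km, larval dispersal below,
#' with local retention effects under ~250 km.
#'
#' @param scaleKm numeric vector of scales (> 0), km.
#' @param localBreak upper bound of the local class (default 250 km).
#' @param broadBreak lower bound of the broad class (default 1000 km).
#' @return factor with levels local, intermediate, broad.
#' @examples
#' classifyScale(c(4500, 600, 100))
#' @export
classifyScale <- function(scaleKm, localBreak = 250, broadBreak = 1000) {
  if (localBreak >= broadBreak)
    stop("breaks must satisfy localBreak < broadBreak")
  if (any(scaleKm <= 0, na.rm = TRUE)) stop("scales must be > 0")
  out <- ifelse(scaleKm >= broadBreak, "broad",
                ifelse(scaleKm <= localBreak, "local", "intermediate"))
  factor(out, levels = c("local", "intermediate", "broad"))
}
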