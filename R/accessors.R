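#' Construct an AlleleFreqSet from a sites x loci frequency matrix
#'
#' @param freq numeric matrix of allele frequencies, sites in rows (the
#'   orientation used by the delimited-text files), loci in columns, values
#'   in [0,1]; rownames are site ids.
#' @param poolSizes integer vector, one pooled-sample size per site.
#' @param siteData optional data.frame of per-site covariates (e.g. a site
#'   table) stored in \code{colData}.
#' @param metadata optional list stored in \code{metadata()}.
#' @return an \linkS4class{AlleleFreqSet}.
#' @examples
#' f <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("S", 1:3), c("L1", "L2")))
#' afs <- alleleFreqSet(f, poolSizes = c(9L, 12L, 18L))
#' freqMatrix(afs)
#' @export
alleleFreqSet <- function(freq, poolSizes, siteData = NULL, metadata = list()) {
  freq <- as.matrix(freq)
  if (is.null(rownames(freq)))
    rownames(freq) <- paste0("site", seq_len(nrow(freq)))
  if (is.null(colnames(freq)))
    colnames(freq) <- paste0("locus", seq_len(ncol(freq)))
  cd <- S4Vectors::DataFrame(pool_size = as.integer(poolSizes),
                             row.names = rownames(freq))
  if (!is.null(siteData)) {
    siteData <- siteData[, setdiff(colnames(siteData), "pool_size"),
                         drop = FALSE]
    cd <- cbind(cd, S4Vectors::DataFrame(siteData))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(freq = t(freq)), colData = cd, metadata = metadata)
  new("AlleleFreqSet", se)
}

#' @rdname AlleleFreqSet-class
#' @aliases freqMatrix,AlleleFreqSet-method
#' @return \code{freqMatrix} returns the sites x loci frequency matrix (the
#'   analysis orientation).
#' @export
setMethod("freqMatrix", "AlleleFreqSet",
          function(x) t(SummarizedExperiment::assay(x, "freq")))

#' @rdname AlleleFreqSet-class
#' @aliases poolSizes,AlleleFreqSet-method
#' @export
setMethod("poolSizes", "AlleleFreqSet",
          function(x) setNames(SummarizedExperiment::colData(x)$pool_size,
                               colnames(x)))

#' @rdname AlleleFreqSet-class
#' @aliases siteIds,AlleleFreqSet-method
#' @export
setMethod("siteIds", "AlleleFreqSet", function(x) colnames(x))

#' @rdname AlleleFreqSet-class
#' @aliases lociIds,AlleleFreqSet-method
#' @export
setMethod("lociIds", "AlleleFreqSet", function(x) rownames(x))

#' Construct a ConnectivityMatrix
#'
#' @param probs square numeric matrix; entry (i, j) is the probability that
#'   a larva released at source j settles at destination i.
#' @return a \linkS4class{ConnectivityMatrix}.
#' @export
connectivityMatrix <- function(probs) {
  probs <- as.matrix(probs)
  if (is.null(rownames(probs)))
    rownames(probs) <- paste0("site", seq_len(nrow(probs)))
  colnames(probs) <- rownames(probs)
  new("ConnectivityMatrix", probs = probs)
}

#' @rdname ConnectivityMatrix-class
#' @aliases probMatrix,ConnectivityMatrix-method
#' @export
setMethod("probMatrix", "ConnectivityMatrix", function(x) x@probs)

setMethod("show", "ConnectivityMatrix", function(object) {
  p <- object@probs
  cat("ConnectivityMatrix:", nrow(p), "sites,",
      sum(p[row(p) != col(p)] > 0), "directed links,",
      "mean self-retention", signif(mean(diag(p)), 3), "\n")
})

#' @rdname EigenvectorBasis-class
#' @aliases basisVectors,EigenvectorBasis-method
#' @export
setMethod("basisVectors", "EigenvectorBasis", function(x) x@vectors)

#' @rdname EigenvectorBasis-class
#' @aliases basisValues,EigenvectorBasis-method
#' @export
setMethod("basisValues", "EigenvectorBasis",
          function(x) setNames(x@values, colnames(x@vectors)))

#' @rdname EigenvectorBasis-class
#' @aliases basisKind,EigenvectorBasis-method
#' @export
setMethod("basisKind", "EigenvectorBasis", function(x) x@kind)

#' @rdname EigenvectorBasis-class
#' @aliases basisScales,EigenvectorBasis-method
#' @export
setMethod("basisScales", "EigenvectorBasis",
          function(x) setNames(x@scaleKm, colnames(x@vectors)))

setMethod("show", "EigenvectorBasis", function(object) {
  cat("EigenvectorBasis (", object@kind, "): ", ncol(object@vectors),
      " vectors over ", nrow(object@vectors), " sites\n", sep = "")
  if (ncol(object@vectors)) {
    sc <- if (all(is.na(object@scaleKm))) "unestimated"
          else paste(signif(range(object@scaleKm, na.rm = TRUE), 3),
                     collapse = " - ")
    cat("  values: ", paste(signif(head(object@values, 5), 3),
                            collapse = ", "),
        if (length(object@values) > 5) ", ...", "\n",
        "  scale range (km): ", sc, "\n", sep = "")
  }
})

#' @rdname SitesByEdges-class
#' @aliases edgeMatrix,SitesByEdges-method
#' @export
setMethod("edgeMatrix", "SitesByEdges", function(x) x@m)

#' @rdname SitesByEdges-class
#' @aliases edgeList,SitesByEdges-method
#' @export
setMethod("edgeList", "SitesByEdges", function(x) x@edges)

#' @rdname SitesByEdges-class
#' @aliases rootSites,SitesByEdges-method
#' @export
setMethod("rootSites", "SitesByEdges", function(x) x@root)

setMethod("show", "SitesByEdges", function(object) {
  cat("SitesByEdges:", nrow(object@m), "sites x", ncol(object@m),
      "edges; root attached at", paste(object@root, collapse = ", "), "\n")
})

#' Construct a PredictorSet
#'
#' Columns are rescaled to [0,1] unless already standardized.
#'
#' @param m sites x p numeric matrix with column names.
#' @param family character per column: "environment", "geography" or
#'   "dispersal".
#' @param standardize rescale each column to [0,1] (default TRUE).
#' @return a \linkS4class{PredictorSet}.
#' @export
predictorSet <- function(m, family, standardize = TRUE) {
  m <- as.matrix(m)
  if (standardize && ncol(m)) m <- standardize01(m)
  new("PredictorSet", m = m, family = as.character(family))
}

#' @rdname PredictorSet-class
#' @aliases predictorMatrix,PredictorSet-method
#' @export
setMethod("predictorMatrix", "PredictorSet", function(x) x@m)

#' @rdname PredictorSet-class
#' @aliases predictorFamily,PredictorSet-method
#' @export
setMethod("predictorFamily", "PredictorSet",
          function(x) setNames(x@family, colnames(x@m)))

setMethod("show", "PredictorSet", function(object) {
  cat("PredictorSet:", ncol(object@m), "predictors x", nrow(object@m),
      "sites\n")
  if (ncol(object@m))
    print(table(factor(object@family,
                       c("environment", "geography", "dispersal"))))
})

#' Subset the columns of a PredictorSet
#'
#' @param x a PredictorSet.
#' @param i column (predictor) selector.
#' @param j,drop,... unused.
#' @export
setMethod("[", "PredictorSet", function(x, i, j, ..., drop = FALSE) {
  new("PredictorSet", m = x@m[, i, drop = FALSE], family = x@family[i])
})

#' Construct a SeascapeGrid
#'
#' @param mask logical matrix, TRUE = sea; rows index northing (row 1 =
#'   southernmost), columns easting.
#' @param cellSizeKm cell edge length in km.
#' @param origin numeric (x, y) of the grid's lower-left corner in km.
#' @return a \linkS4class{SeascapeGrid}.
#' @export
seascapeGrid <- function(mask, cellSizeKm, origin = c(0, 0)) {
  new("SeascapeGrid", mask = mask, cellSizeKm = cellSizeKm,
      origin = as.numeric(origin))
}

setMethod("show", "SeascapeGrid", function(object) {
  cat("SeascapeGrid:", nrow(object@mask), "x", ncol(object@mask),
      "cells of", object@cellSizeKm, "km;",
      round(100 * mean(object@mask)), "% sea\n")
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@nSites, "sites on a", object@coastline,
      "coastline;", object@nLoci, "loci;",
      nrow(object@drivers), "planted driver(s); seed", object@seed, "\n")
})
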