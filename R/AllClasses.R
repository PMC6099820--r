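#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor prcomp rnorm rbinom runif sd pchisq pt var
#'   kruskal.test lm as.formula setNames quantile
#' @importFrom utils combn head read.csv write.csv packageVersion
NULL

#' Pool allele frequencies with site metadata
#'
#' \code{AlleleFreqSet} extends \linkS4class{SummarizedExperiment}: the
#' \code{"freq"} assay holds per-locus alternate-allele frequencies (loci in
#' rows, sites in columns, values in [0,1]) and \code{colData} carries, at
#' minimum, an integer \code{pool_size} per site (number of diploid
#' individuals pooled).  When built by the synthetic generator the latent
#' (pre-sampling) frequencies sit in \code{metadata()$latent} together with
#' the planted driver table and the clip count.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @seealso [alleleFreqSet()], [simulateAlleleFrequencies()], [pairwiseFst()]
#' @export
setClass("AlleleFreqSet", contains = "SummarizedExperiment")

setValidity("AlleleFreqSet", function(object) {
  msg <- character()
  if (!"freq" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'freq' is required")
  else {
    f <- SummarizedExperiment::assay(object, "freq")
    if (anyNA(f)) msg <- c(msg, "frequencies contain NA")
    else if (min(f) < 0 || max(f) > 1)
      msg <- c(msg, "frequencies must lie in [0,1]")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"pool_size" %in% colnames(cd))
    msg <- c(msg, "colData must contain 'pool_size'")
  else {
    ps <- cd$pool_size
    if (anyNA(ps) || any(ps < 1) || any(ps != round(ps)))
      msg <- c(msg, "pool_size must be integers >= 1")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "site (column) names must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Directed larval connectivity between sites
#'
#' Entry (i, j) is the probability that a larva released at source site j
#' settles at destination site i; the diagonal is self-retention.  Columns
#' (sources) must sum to at most 1.
#'
#' @slot probs square numeric matrix, destinations in rows, sources in
#'   columns, identical dimnames.
#' @seealso [connectivityMatrix()], [generateDispersalMatrix()], [buildAEM()]
#' @export
setClass("ConnectivityMatrix", representation(probs = "matrix"))

setValidity("ConnectivityMatrix", function(object) {
  p <- object@probs
  msg <- character()
  if (nrow(p) != ncol(p)) msg <- c(msg, "matrix must be square")
  if (anyNA(p) || min(p) < 0 || max(p) > 1)
    msg <- c(msg, "probabilities must lie in [0,1]")
  if (nrow(p) > 0 && any(colSums(p) > 1 + 1e-8))
    msg <- c(msg, "column sums must be <= 1")
  if (is.null(rownames(p)) || !identical(rownames(p), colnames(p)))
    msg <- c(msg, "row and column names must be identical site ids")
  if (length(msg)) msg else TRUE
})

#' Orthogonal spatial eigenvector basis (db-MEMs or AEMs)
#'
#' Site-indexed spatial predictors: unit-norm, mutually orthogonal columns
#' sorted by decreasing eigen/singular value.  db-MEM columns additionally
#' sum to zero (they arise from a double-centred matrix).  \code{scaleKm}
#' holds the characteristic spatial scale of each vector as estimated by
#' [estimateScale()] (NA until sites are supplied).
#'
#' @slot vectors sites x k numeric matrix, rownames = site ids, colnames =
#'   labels ("db-MEM 1", "AEM 1", ...).
#' @slot values eigenvalues (db-MEM) or singular values (AEM), descending.
#' @slot kind "dbMEM" or "AEM".
#' @slot scaleKm characteristic scale per vector in km (may be NA).
#' @seealso [buildDbMEM()], [buildAEM()], [estimateScale()], [classifyScale()]
#' @export
setClass("EigenvectorBasis",
  representation(vectors = "matrix", values = "numeric", kind = "character",
                 scaleKm = "numeric"))

setValidity("EigenvectorBasis", function(object) {
  v <- object@vectors
  msg <- character()
  k <- ncol(v)
  if (length(object@values) != k) msg <- c(msg, "one value per vector required")
  if (length(object@scaleKm) != k) msg <- c(msg, "one scaleKm per vector required")
  if (!object@kind %in% c("dbMEM", "AEM"))
    msg <- c(msg, "kind must be 'dbMEM' or 'AEM'")
  if (k > 0) {
    if (k >= nrow(v)) msg <- c(msg, "k must be < n_sites")
    nrm <- sqrt(colSums(v^2))
    if (any(abs(nrm - 1) > 1e-6)) msg <- c(msg, "columns must be unit norm")
    g <- crossprod(v)
    if (max(abs(g - diag(k))) > 1e-6)
      msg <- c(msg, "columns must be mutually orthogonal")
    if (is.unsorted(rev(object@values)) &&
        any(diff(object@values) > 1e-10))
      msg <- c(msg, "values must be sorted descending")
    if (object@kind == "dbMEM" && max(abs(colSums(v))) > 1e-6)
      msg <- c(msg, "db-MEM columns must sum to zero")
  }
  if (length(msg)) msg else TRUE
})

#' Binary sites-by-edges matrix for AEM construction
#'
#' Row i marks, with 1s, the edges lying on the directed path from a virtual
#' root node (placed upstream of the flow) to site i.
#'
#' @slot m sites x edges 0/1 matrix.
#' @slot edges data.frame with columns from, to, weight (dispersal
#'   probability; the root is site id "<root>").
#' @slot root character ids of the entry sites attached to the virtual root.
#' @seealso [buildAEM()]
#' @export
setClass("SitesByEdges",
  representation(m = "matrix", edges = "data.frame", root = "character"))

setValidity("SitesByEdges", function(object) {
  msg <- character()
  if (!all(object@m %in% c(0, 1))) msg <- c(msg, "entries must be 0/1")
  if (ncol(object@m) > 0 && any(colSums(object@m) == 0))
    msg <- c(msg, "no all-zero edge columns allowed")
  if (ncol(object@m) != nrow(object@edges))
    msg <- c(msg, "one edge row per matrix column required")
  if (length(msg)) msg else TRUE
})

#' Standardized regression predictors with family labels
#'
#' Columns are predictors standardized to [0,1]; each belongs to a family:
#' \code{environment}, \code{geography} (db-MEMs) or \code{dispersal} (AEMs).
#'
#' @slot m sites x p numeric matrix, columns in [0,1] with min 0 and max 1.
#' @slot family character per column.
#' @seealso [makePredictorSet()], [pruneCorrelated()], [selectVariablesBIC()]
#' @export
setClass("PredictorSet", representation(m = "matrix", family = "character"))

setValidity("PredictorSet", function(object) {
  m <- object@m
  msg <- character()
  if (ncol(m) != length(object@family))
    msg <- c(msg, "one family label per column required")
  if (!all(object@family %in% c("environment", "geography", "dispersal")))
    msg <- c(msg, "family must be environment/geography/dispersal")
  if (ncol(m) > 0) {
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
      msg <- c(msg, "unique column names required")
    rng <- apply(m, 2, range)
    if (any(abs(rng[1, ]) > 1e-8) || any(abs(rng[2, ] - 1) > 1e-8))
      msg <- c(msg, "columns must be standardized to [0,1] (min 0, max 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Land/sea raster for least-cost marine distances
#'
#' A boolean lattice (TRUE = sea) with a cell size in km and the (x, y)
#' coordinate of the lower-left corner of cell [1,1]; land cells carry
#' infinite movement resistance.
#'
#' @slot mask logical matrix, rows = northing, cols = easting; TRUE = sea.
#' @slot cellSizeKm edge length of a cell in km.
#' @slot origin numeric (x, y) of the lower-left corner, km.
#' @seealso [seascapeGrid()], [leastCostDistances()]
#' @export
setClass("SeascapeGrid",
  representation(mask = "matrix", cellSizeKm = "numeric", origin = "numeric"))

setValidity("SeascapeGrid", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (!any(object@mask)) msg <- c(msg, "at least one sea cell required")
  if (length(object@cellSizeKm) != 1 || object@cellSizeKm <= 0)
    msg <- c(msg, "cellSizeKm must be a single positive number")
  if (length(object@origin) != 2) msg <- c(msg, "origin must be (x, y)")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic seascape generator
#'
#' Defaults emulate the study conditions the package is validated against:
#' 47 coastal sites on a gently curved ~4,600 km coastline (mean spacing
#' ~100 km), pools of 9-18 diploid individuals, smooth basin-wide salinity
#' and temperature gradients, an exponential dispersal kernel (decay 100 km,
#' the reach of a ~30-day pelagic larval stage) with along-coast downstream
#' bias and self-retention, and allele frequencies built as linear
#' combinations of chosen spatial eigenvectors plus site-level Gaussian
#' noise and binomial pool-sampling noise.
#'
#' @slot nSites number of sites (>= 3).
#' @slot coastline "basin" (default: sites around the rim of an elongated
#'   basin traversed by a one-way boundary current, the configuration that
#'   decouples dispersal from straight-line geography), "arc", "line" or
#'   "lattice".
#' @slot nLoci number of simulated SNPs.
#' @slot drivers data.frame(label, beta): eigenvector labels (as produced by
#'   [buildDbMEM()]/[buildAEM()]) and their effect sizes on latent
#'   frequencies.
#' @slot noiseSd site-level Gaussian noise SD on the latent frequency scale.
#' @slot poolSizeRange integer (min, max) pool sizes.
#' @slot seed root seed; stage-labelled substreams are derived from it so
#'   stages can be rerun independently (see [stageSeed()]).
#' @slot dispersalDecayKm e-folding distance of the dispersal kernel (km).
#' @slot downstreamBias in [0,1]; 0 = symmetric kernel.
#' @slot entryFraction along-coast position (fraction of the coastline
#'   length) of the dispersal entry point; currents are biased away from it
#'   in both directions, so the connection diagram branches there like a
#'   basin fed through an inflow strait.
#' @slot selfRetention diagonal of the connectivity matrix, in [0,1].
#' @slot arcLengthKm total along-coast length (perimeter, for "basin") of
#'   the coastline (km).
#' @slot arcRadiusKm radius of curvature of the "arc" coastline (km).
#' @slot basinWidthKm across-basin width of the "basin" coastline (km).
#' @slot jitterSdKm SD of along-coast placement jitter (km).
#' @seealso [syntheticConfig()], [generateCoastlineSites()],
#'   [generateDispersalMatrix()], [simulateAlleleFrequencies()]
#' @export
setClass("SyntheticConfig",
  representation(nSites = "numeric", coastline = "character",
    nLoci = "numeric", drivers = "data.frame", noiseSd = "numeric",
    poolSizeRange = "numeric", seed = "numeric",
    dispersalDecayKm = "numeric", downstreamBias = "numeric",
    selfRetention = "numeric", entryFraction = "numeric",
    arcLengthKm = "numeric", arcRadiusKm = "numeric",
    basinWidthKm = "numeric", jitterSdKm = "numeric"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nSites < 3) msg <- c(msg, "nSites must be >= 3")
  if (!object@coastline %in% c("basin", "arc", "line", "lattice"))
    msg <- c(msg, "coastline must be basin/arc/line/lattice")
  if (object@nLoci < 1) msg <- c(msg, "nLoci must be >= 1")
  if (nrow(object@drivers) &&
      !all(c("label", "beta") %in% colnames(object@drivers)))
    msg <- c(msg, "drivers needs columns label, beta")
  if (nrow(object@drivers) && !all(is.finite(object@drivers$beta)))
    msg <- c(msg, "driver effect sizes must be finite")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  pr <- object@poolSizeRange
  if (length(pr) != 2 || any(pr < 1) || pr[1] > pr[2] || any(pr != round(pr)))
    msg <- c(msg, "poolSizeRange must be integer (min, max), min <= max, >= 1")
  if (object@dispersalDecayKm <= 0)
    msg <- c(msg, "dispersalDecayKm must be > 0")
  if (object@downstreamBias < 0 || object@downstreamBias > 1)
    msg <- c(msg, "downstreamBias must be in [0,1]")
  if (object@selfRetention < 0 || object@selfRetention > 1)
    msg <- c(msg, "selfRetention must be in [0,1]")
  if (object@entryFraction < 0 || object@entryFraction > 1)
    msg <- c(msg, "entryFraction must be in [0,1]")
  if (length(msg)) msg else TRUE
})
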