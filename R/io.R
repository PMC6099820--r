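#' Read and write site tables and labelled matrices as delimited text
#'
#' Site tables are comma-separated with a header row.  Matrices (distance,
#' connectivity, allele-frequency) are comma-separated with site ids as both
#' row index (first column) and column header; sites stay in fixed order.
#'
#' @param sites site table; \code{path} file path; \code{m} matrix.
#' @param path file path.
#' @return readers return the parsed object; writers return the path,
#'   invisibly.
#' @name seascape-io
NULL

#' @rdname seascape-io
#' @export
writeSiteTable <- function(sites, path) {
  write.csv(sites, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname seascape-io
#' @export
readSiteTable <- function(path) {
  sites <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% colnames(sites)) &&
      all(c("lon", "lat") %in% colnames(sites)))
    sites <- projectSites(sites)
  validateSiteTable(sites)
  sites
}

#' @rdname seascape-io
#' @param m matrix with dimnames.
#' @export
writeMatrixCsv <- function(m, path) {
  write.csv(as.data.frame(m), path, quote = FALSE)
  invisible(path)
}

#' @rdname seascape-io
#' @export
readMatrixCsv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write an eigenvector basis plus metadata sidecar
#'
#' The basis goes to \code{path} (site id column + one column per vector);
#' the sidecar \code{<path>.meta.csv} records each vector's eigen/singular
#' value, kind, estimated scale and scale class.
#'
#' @param basis an \linkS4class{EigenvectorBasis}.
#' @param path output csv path.
#' @param localBreak,broadBreak scale-class cutoffs (km).
#' @return the path, invisibly.
#' @export
writeBasis <- function(basis, path, localBreak = 250, broadBreak = 1000) {
  v <- basisVectors(basis)
  out <- data.frame(site_id = rownames(v), v, check.names = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  sc <- basisScales(basis)
  meta <- data.frame(
    label = colnames(v), value = basisValues(basis), kind = basisKind(basis),
    scale_km = sc,
    scale_class = if (all(is.na(sc))) NA else
      as.character(classifyScale(sc, localBreak, broadBreak)))
  write.csv(meta, paste0(path, ".meta.csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an allele-frequency matrix together with its site table
#'
#' @param freqPath csv of sites x loci frequencies (site ids as row index).
#' @param sites site table providing pool sizes (matched by site_id).
#' @return an \linkS4class{AlleleFreqSet}.
#' @export
readAlleleFrequencies <- function(freqPath, sites) {
  f <- readMatrixCsv(freqPath)
  idx <- match(rownames(f), sites$site_id)
  if (anyNA(idx))
    stop("frequency matrix contains site ids absent from the site table")
  alleleFreqSet(f, poolSizes = sites$pool_size[idx],
                siteData = sites[idx, ])
}
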