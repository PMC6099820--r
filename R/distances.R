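#' Euclidean distances between sites on the Cartesian plane
#'
#' @param sites site table with x, y in km.
#' @return symmetric sites x sites matrix in km with attribute
#'   \code{kind = "euclidean"}; duplicate coordinates are allowed but warned
#'   about.
#' @export
euclideanDistances <- function(sites) {
  validateSiteTable(sites, minSites = 2)
  d <- as.matrix(stats::dist(sites[, c("x", "y")]))
  dimnames(d) <- list(sites$site_id, sites$site_id)
  if (any(d[upper.tri(d)] == 0))
    warning("duplicate coordinates: some off-diagonal distances are 0")
  attr(d, "kind") <- "euclidean"
  d
}

.checkDistanceMatrix <- function(d, name = "distance matrix") {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop(name, " must be a square matrix")
  if (max(abs(d - t(d)), na.rm = TRUE) > 1e-8)
    stop(name, " must be symmetric")
  if (any(diag(d) != 0)) stop(name, " must have a zero diagonal")
  invisible(d)
}

# (row, col) of the sea cell a site snaps to; ties broken by smallest row,
# then smallest column, for determinism.
.snapToSea <- function(grid, x, y, snapRadius = 2) {
  cs <- grid@cellSizeKm
  col0 <- floor((x - grid@origin[1]) / cs) + 1
  row0 <- floor((y - grid@origin[2]) / cs) + 1
  nr <- nrow(grid@mask); nc <- ncol(grid@mask)
  best <- NULL; bestd <- Inf
  for (dr in -snapRadius:snapRadius) for (dc in -snapRadius:snapRadius) {
    r <- row0 + dr; c <- col0 + dc
    if (r < 1 || r > nr || c < 1 || c > nc || !grid@mask[r, c]) next
    dd <- dr^2 + dc^2
    if (dd < bestd ||
        (dd == bestd && (r < best[1] || (r == best[1] && c < best[2])))) {
      best <- c(r, c); bestd <- dd
    }
  }
  if (is.null(best))
    stop("site at (", x, ", ", y, ") has no sea cell within ",
         snapRadius, " cells")
  best
}

#' Least-cost marine distances over a land/sea raster
#'
#' Shortest over-water path between every pair of sites on the sea-cell
#' lattice, moving to 8 neighbours at cost cellSizeKm (orthogonal) or
#' cellSizeKm * sqrt(2) (diagonal); land cells are impassable (infinite
#' resistance).  Sites are snapped to the nearest sea cell within
#' \code{snapRadius} cells.  Pairs in disconnected sea regions get
#' \code{Inf} and a warning.
#'
#' @param grid a \linkS4class{SeascapeGrid}.
#' @param sites site table.
#' @param snapRadius snapping radius in cells (default 2).
#' @return symmetric matrix in km with attribute \code{kind = "least_cost"}.
#' @export
leastCostDistances <- function(grid, sites, snapRadius = 2) {
  stopifnot(is(grid, "SeascapeGrid"))
  validateSiteTable(sites, minSites = 2)
  mask <- grid@mask
  nr <- nrow(mask); nc <- ncol(mask)
  cellId <- matrix(NA_integer_, nr, nc)
  sea <- which(mask)
  cellId[sea] <- seq_along(sea)
  # 8-neighbour edges between sea cells
  from <- integer(0); to <- integer(0); w <- numeric(0)
  steps <- rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))
  rc <- arrayInd(sea, c(nr, nc))
  for (k in seq_len(nrow(steps))) {
    r2 <- rc[, 1] + steps[k, 1]; c2 <- rc[, 2] + steps[k, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    from <- c(from, cellId[sea[ok]])
    to <- c(to, cellId[cbind(r2[ok], c2[ok])])
    w <- c(w, rep(steps[k, 3] * grid@cellSizeKm, sum(ok)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to),
    directed = FALSE,
    vertices = data.frame(name = seq_along(sea)))
  siteCells <- vapply(seq_len(nrow(sites)), function(i) {
    rcs <- .snapToSea(grid, sites$x[i], sites$y[i], snapRadius)
    cellId[rcs[1], rcs[2]]
  }, integer(1))
  dm <- igraph::distances(g, v = as.character(siteCells),
                          to = as.character(siteCells), weights = w)
  dimnames(dm) <- list(sites$site_id, sites$site_id)
  diag(dm) <- 0
  if (any(is.infinite(dm)))
    warning("some site pairs are separated by land (distance Inf)")
  attr(dm, "kind") <- "least_cost"
  dm
}

#' Write / read a SeascapeGrid as plain text
#'
#' Format: four header lines (\code{ncols}, \code{nrows}, \code{cellsize},
#' \code{origin x y}) followed by nrows lines of space-separated 0/1
#' (1 = sea), northernmost row first.
#'
#' @param grid a \linkS4class{SeascapeGrid}.
#' @param path file path.
#' @return \code{readGridAsc} returns a \linkS4class{SeascapeGrid}.
#' @export
writeGridAsc <- function(grid, path) {
  mask <- grid@mask
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("ncols", ncol(mask)), paste("nrows", nrow(mask)),
               paste("cellsize", grid@cellSizeKm),
               paste("origin", grid@origin[1], grid@origin[2])), con)
  for (r in rev(seq_len(nrow(mask))))
    writeLines(paste(as.integer(mask[r, ]), collapse = " "), con)
  invisible(path)
}

#' @rdname writeGridAsc
#' @export
readGridAsc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:4], "\\s+")
  val <- function(i) as.numeric(hdr[[i]][-1])
  nc <- val(1); nr <- val(2); cs <- val(3); org <- val(4)
  body <- lapply(lines[4 + seq_len(nr)],
                 function(l) as.integer(strsplit(trimws(l), "\\s+")[[1]]))
  mask <- do.call(rbind, rev(body)) == 1
  seascapeGrid(mask, cs, org)
}
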