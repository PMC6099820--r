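#' Create a synthetic-seascape configuration
#'
#' Returns a validated \linkS4class{SyntheticConfig}.  Defaults reproduce
#' the conditions the package is validated under: 47 sites spaced ~100 km
#' around the 4,600 km rim of an elongated basin, pools of 9-18 diploid
#' individuals, a 50 km exponential along-coast dispersal kernel carried by
#' a one-way boundary current (bias 0.5, self-retention 0.2), and 300 loci
#' with site-level noise SD 0.05.  The basin shape puts opposite shores
#' within geographic-neighbour distance of each other while their
#' along-coast dispersal distance stays large, so geographic isolation and
#' dispersal are genuinely distinguishable -- the premise of the
#' scale-attribution analysis.
#'
#' @param nSites,coastline,nLoci,drivers,noiseSd,poolSizeRange,seed
#'   see \linkS4class{SyntheticConfig}.
#' @param dispersalDecayKm,downstreamBias,selfRetention,entryFraction
#'   dispersal kernel parameters (see \linkS4class{SyntheticConfig}).
#' @param arcLengthKm,arcRadiusKm,basinWidthKm,jitterSdKm coastline
#'   geometry.
#' @return a \linkS4class{SyntheticConfig}.
#' @examples
#' cfg <- syntheticConfig(nSites = 10, nLoci = 20, seed = 7)
#' sites <- generateCoastlineSites(cfg)
#' @export
syntheticConfig <- function(nSites = 47, coastline = "basin", nLoci = 300,
    drivers = data.frame(label = character(), beta = numeric()),
    noiseSd = 0.05, poolSizeRange = c(9, 18), seed = 1,
    dispersalDecayKm = 50, downstreamBias = 0.5, selfRetention = 0.2,
    entryFraction = 0, arcLengthKm = 4600, arcRadiusKm = 4000,
    basinWidthKm = 80, jitterSdKm = 10) {
  new("SyntheticConfig", nSites = nSites, coastline = coastline,
      nLoci = nLoci, drivers = drivers, noiseSd = noiseSd,
      poolSizeRange = poolSizeRange, seed = seed,
      dispersalDecayKm = dispersalDecayKm, downstreamBias = downstreamBias,
      selfRetention = selfRetention, entryFraction = entryFraction,
      arcLengthKm = arcLengthKm, arcRadiusKm = arcRadiusKm,
      basinWidthKm = basinWidthKm, jitterSdKm = jitterSdKm)
}

# Reference point of the local equirectangular projection used to back-fill
# lon/lat for synthetic sites generated directly in km (central Mediterranean).
.REF_LON <- 15
.REF_LAT <- 38
.EARTH_R <- 6371

.kmToLonLat <- function(x, y, lat0 = .REF_LAT, lon0 = .REF_LON) {
  rad <- pi / 180
  list(lon = lon0 + x / (.EARTH_R * cos(lat0 * rad)) / rad,
       lat = lat0 + y / .EARTH_R / rad)
}

.makeSiteTable <- function(s, x, y, poolSize, id = NULL) {
  n <- length(x)
  if (is.null(id))
    id <- sprintf("S%0*d", nchar(as.character(n)), seq_len(n))
  ll <- .kmToLonLat(x, y)
  u <- if (diff(range(s)) > 0) (s - min(s)) / diff(range(s)) else rep(0, n)
  # environmental fields: a mild basin-scale trend plus mesoscale anomalies
  # (patchiness keeps env distinguishable from the broadest spatial mode,
  # as in the real predictor set where env survives the r <= 0.5 pruning)
  sss <- 36.5 + 1.0 * u + 1.5 * sin(2.5 * pi * u)
  sst <- 18 + 1.0 * (1 - u) + 1.2 * sin(1.5 * pi * u + 1)
  data.frame(site_id = id, lon = ll$lon, lat = ll$lat, x = x, y = y,
             pool_size = as.integer(poolSize), sss = sss, sst = sst,
             along_km = s, stringsAsFactors = FALSE)
}

#' Validate a site table
#'
#' A site table is a data.frame with columns \code{site_id}, \code{lon},
#' \code{lat}, \code{x}, \code{y} (km, Cartesian), \code{pool_size},
#' \code{sss}, \code{sst}.  Stops with an informative error when a required
#' column is missing, ids are duplicated, pool sizes are < 1, or fewer than
#' 3 sites are present.
#'
#' @param sites data.frame to check.
#' @param minSites minimum number of sites (default 3).
#' @return the site table, invisibly.
#' @export
validateSiteTable <- function(sites, minSites = 3) {
  need <- c("site_id", "lon", "lat", "x", "y", "pool_size", "sss", "sst")
  miss <- setdiff(need, colnames(sites))
  if (length(miss))
    stop("site table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(sites$site_id)) stop("site_id values must be unique")
  if (any(sites$pool_size < 1)) stop("pool_size must be >= 1")
  if (nrow(sites) < minSites) stop("at least ", minSites, " sites required")
  invisible(sites)
}

#' Project longitude/latitude to local Cartesian km
#'
#' Local equirectangular projection about the mean latitude:
#' x = R * dlon * cos(mean lat), y = R * dlat, with R = 6371 km.  Used when
#' a real site table arrives with lon/lat only.
#'
#' @param sites site table with lon and lat columns (degrees).
#' @return the site table with x and y columns (km) filled in.
#' @export
projectSites <- function(sites) {
  rad <- pi / 180
  lat0 <- mean(sites$lat)
  sites$x <- .EARTH_R * (sites$lon - mean(sites$lon)) * rad * cos(lat0 * rad)
  sites$y <- .EARTH_R * (sites$lat - lat0) * rad
  sites
}

#' Place sites along a synthetic coastline
#'
#' Sites are spread evenly along the configured geometry ("arc", "line" or
#' "lattice"), given small along- and cross-shore Gaussian jitter, and
#' assigned pool sizes drawn uniformly from \code{poolSizeRange}.  Smooth
#' salinity and temperature gradients are attached.  Fully determined by
#' \code{config@seed} (stage label "sites").
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return a site table (see [validateSiteTable()]) with an extra
#'   \code{along_km} column giving the along-coast position used to orient
#'   the dispersal kernel.
#' @export
generateCoastlineSites <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  n <- config@nSites
  set.seed(stageSeed(config@seed, "sites"))
  L <- config@arcLengthKm
  base <- if (config@coastline == "basin")
    seq(0, L * (1 - 1 / n), length.out = n) else seq(0, L, length.out = n)
  s <- sort(base + rnorm(n, 0, config@jitterSdKm))
  off <- rnorm(n, 0, config@jitterSdKm / 2)
  if (config@coastline == "basin") {
    # rim of a stadium-shaped basin: two straight shores of length Lx
    # joined by semicircular ends; s runs once around the perimeter
    W <- config@basinWidthKm
    Lx <- (L - pi * W) / 2
    s <- sort(s %% L)
    xy <- vapply(seq_len(n), function(i) {
      si <- s[i]; r <- W / 2 + off[i]
      if (si < Lx) c(si, W / 2 - r)
      else if (si < Lx + pi * W / 2) {
        a <- (si - Lx) / (W / 2)
        c(Lx + r * sin(a), W / 2 - r * cos(a))
      } else if (si < 2 * Lx + pi * W / 2) {
        c(Lx - (si - Lx - pi * W / 2), W / 2 + r)
      } else {
        a <- (si - 2 * Lx - pi * W / 2) / (W / 2)
        c(-r * sin(a), W / 2 + r * cos(a))
      }
    }, numeric(2))
    x <- xy[1, ]; y <- xy[2, ]
  } else if (config@coastline == "arc") {
    Rc <- config@arcRadiusKm
    phi <- s / Rc - (L / Rc) / 2          # centred on the arc midpoint
    x <- (Rc + off) * sin(phi)
    y <- Rc - (Rc + off) * cos(phi)
  } else if (config@coastline == "line") {
    x <- s
    y <- off
  } else {                                 # lattice
    ncols <- ceiling(sqrt(n))
    spacing <- L / max(1, n - 1) * ncols   # keeps extents comparable
    ix <- (seq_len(n) - 1) %% ncols
    iy <- (seq_len(n) - 1) %/% ncols
    x <- ix * spacing + rnorm(n, 0, config@jitterSdKm)
    y <- iy * spacing + rnorm(n, 0, config@jitterSdKm)
  }
  pool <- sample(seq(config@poolSizeRange[1], config@poolSizeRange[2]),
                 n, replace = TRUE)
  validateSiteTable(.makeSiteTable(s, x, y, pool))
}

#' Regular one-dimensional transect of sampling points
#'
#' The calibration fixture for db-MEM construction and scale estimation: n
#' points on a line at x_i = (i-1) * spacing, y = 0.  The default arguments
#' give the 63-point, 47-km transect (extent 2,914 km) on which theoretical
#' db-MEMs are sampled sinusoids.
#'
#' @param nPoints number of points (>= 2).
#' @param spacingKm distance between adjacent points, km (> 0).
#' @param poolSize pool size recorded for every point (cosmetic).
#' @return a site table ordered by strictly increasing x.
#' @examples
#' tr <- makeRegularTransect(63, 47)
#' max(tr$x) - min(tr$x)  # 2914
#' @export
makeRegularTransect <- function(nPoints = 63, spacingKm = 47, poolSize = 12) {
  stopifnot(nPoints >= 2, spacingKm > 0)
  s <- (seq_len(nPoints) - 1) * spacingKm
  .makeSiteTable(s, x = s, y = rep(0, nPoints),
                 poolSize = rep(poolSize, nPoints))
}

#' Build a direction-biased dispersal kernel over synthetic sites
#'
#' P[i, j] = probability a larva released at j settles at i, built from an
#' exponential distance kernel exp(-d_ij / decay) multiplied by
#' (1 + downstreamBias) for down-current edges and (1 - downstreamBias)
#' against the current.  For the "basin" coastline the kernel distance is
#' the along-coast (marine) distance around the rim -- larvae travel with
#' the boundary current, not across land -- and the current runs one way
#' around the basin; for the other geometries the kernel is Euclidean and
#' the current flows away from the entry point at \code{entryFraction} of
#' the coastline.  The diagonal is
#' the self-retention; each column is rescaled, if needed, so that its sum
#' does not exceed 1.  Kernel values below 1e-10 are set to exact zero so
#' that the connection graph has finite reach.
#'
#' @param sites a site table (synthetic tables carry \code{along_km}; for
#'   other tables x is used as the coastline direction).
#' @param config a \linkS4class{SyntheticConfig}.
#' @return a \linkS4class{ConnectivityMatrix}.
#' @export
generateDispersalMatrix <- function(sites, config) {
  validateSiteTable(sites)
  validObject(config)
  if (config@dispersalDecayKm <= 0) stop("dispersal decay must be > 0")
  n <- nrow(sites)
  along <- if ("along_km" %in% colnames(sites)) sites$along_km else sites$x
  if (config@coastline == "basin") {
    P0 <- config@arcLengthKm
    ds <- abs(outer(along, along, "-"))
    d <- pmin(ds, P0 - ds)                 # marine distance around the rim
    down <- (outer(along, along, "-") %% P0) < P0 / 2  # one-way current
  } else {
    d <- as.matrix(stats::dist(sites[, c("x", "y")]))
    src <- min(along) + config@entryFraction * diff(range(along))
    away <- abs(along - src)
    down <- outer(away, away, ">")         # [i,j]: i is further down-current
  }
  K <- exp(-d / config@dispersalDecayKm)
  b <- config@downstreamBias
  P <- K * ifelse(down, 1 + b, 1 - b)
  P[K < 1e-10] <- 0
  diag(P) <- 0
  budget <- 1 - config@selfRetention
  cs <- colSums(P)
  scale <- ifelse(cs > budget, budget / cs, 1)
  P <- sweep(P, 2, scale, "*")
  diag(P) <- config@selfRetention
  dimnames(P) <- list(sites$site_id, sites$site_id)
  connectivityMatrix(P)
}

#' Simulate pool-sampled allele frequencies driven by spatial eigenvectors
#'
#' For every locus the latent frequency is
#' q = 0.5 + sum_k beta_k * V_k + eps, with eps ~ N(0, noiseSd) drawn per
#' site and locus, clipped to [0.01, 0.99] (clips counted and warned on).
#' The observed frequency is a binomial draw over the 2 * pool_size allele
#' copies of the site's pool, divided by 2 * pool_size.  Fully determined
#' by \code{config@seed} (stage label "freqs").
#'
#' Driver eigenvectors enter after rescaling to unit range and re-centring,
#' so an effect size beta is the latent allele-frequency change across the
#' full spatial range of the pattern -- the same [0,1] predictor scale on
#' which the downstream regressions are run.
#'
#' @param sites site table.
#' @param bases an \linkS4class{EigenvectorBasis} or list of them; driver
#'   labels in \code{config@drivers} are looked up across all of them.
#' @param config a \linkS4class{SyntheticConfig}; \code{config@drivers} is a
#'   data.frame(label, beta).
#' @return an \linkS4class{AlleleFreqSet}; \code{metadata()} holds the
#'   latent sites x loci matrix (\code{$latent}), the driver table
#'   (\code{$drivers}) and the clip count (\code{$clipCount}).
#' @export
simulateAlleleFrequencies <- function(sites, bases, config) {
  validateSiteTable(sites)
  validObject(config)
  if (is(bases, "EigenvectorBasis")) bases <- list(bases)
  V <- do.call(cbind, lapply(bases, basisVectors))
  drv <- config@drivers
  if (nrow(drv)) {
    missing <- setdiff(drv$label, colnames(V))
    if (length(missing))
      stop("driver(s) not found in supplied bases: ",
           paste(missing, collapse = ", "))
  }
  n <- nrow(sites)
  L <- config@nLoci
  set.seed(stageSeed(config@seed, "freqs"))
  mu <- rep(0.5, n)
  if (nrow(drv)) {
    Vd <- V[, drv$label, drop = FALSE]
    Vd <- apply(Vd, 2, function(v) {
      v <- (v - min(v)) / (max(v) - min(v))  # beta acts on the [0,1] scale
      v - mean(v)
    })
    mu <- mu + as.vector(Vd %*% drv$beta)
  }
  q <- matrix(mu, n, L) + matrix(rnorm(n * L, 0, config@noiseSd), n, L)
  nClip <- sum(q < 0.01 | q > 0.99)
  if (nClip > 0)
    warning(nClip, " latent frequencies clipped to [0.01, 0.99]")
  q <- pmin(pmax(q, 0.01), 0.99)
  copies <- 2L * sites$pool_size
  obs <- matrix(rbinom(n * L, size = rep(copies, L), prob = q),
                n, L) / rep(copies, L)
  dimnames(obs) <- list(sites$site_id,
                        sprintf("L%0*d", nchar(as.character(L)), seq_len(L)))
  dimnames(q) <- dimnames(obs)
  alleleFreqSet(obs, poolSizes = sites$pool_size, siteData = sites,
                metadata = list(latent = q, drivers = drv,
                                clipCount = nClip))
}

#' Pick default planted drivers: one broad db-MEM and one local AEM
#'
#' Chooses "db-MEM 1" (the broadest geographic eigenvector) and, among the
#' AEMs whose estimated scale is local (<= \code{localBreak} km), the one
#' with the smallest singular value -- a genuinely fine-grained route
#' contrast -- giving the two planted signals used in parameter-recovery
#' validation.
#'
#' @param dbmem,aem bases with estimated scales (see [estimateScale()]).
#' @param beta effect size assigned to both drivers.
#' @param localBreak local-scale threshold in km.
#' @return data.frame(label, beta).
#' @export
defaultDrivers <- function(dbmem, aem, beta = 0.12, localBreak = 250) {
  sc <- basisScales(aem)
  local <- names(sc)[which(sc <= localBreak)]
  if (!length(local))
    stop("no AEM with estimated scale <= ", localBreak, " km")
  data.frame(label = c(colnames(basisVectors(dbmem))[1],
                       local[length(local)]),
             beta = c(beta, beta), stringsAsFactors = FALSE)
}

#' Simulate a full seascape with planted spatial structure
#'
#' Convenience wrapper running the whole generator: sites, Euclidean
#' distances, db-MEMs, dispersal kernel, AEMs, then allele frequencies.
#' When \code{config@drivers} is empty, [defaultDrivers()] plants one broad
#' db-MEM and one local AEM driver at effect size \code{beta}.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param beta effect size used when drivers default.
#' @return list with elements sites, dist, dbmem, connectivity, edges, aem,
#'   afs (the \linkS4class{AlleleFreqSet}) and config (with the resolved
#'   driver table).
#' @examples
#' sc <- simulateSeascape(syntheticConfig(nSites = 15, nLoci = 30, seed = 2))
#' sc$config@drivers
#' @export
simulateSeascape <- function(config = syntheticConfig(), beta = 0.12) {
  sites <- generateCoastlineSites(config)
  d <- euclideanDistances(sites)
  dbmem <- buildDbMEM(d, sites = sites)
  conn <- generateDispersalMatrix(sites, config)
  src <- min(sites$along_km) +
    config@entryFraction * diff(range(sites$along_km))
  entry <- sites$site_id[which.min(abs(sites$along_km - src))]
  aemFit <- buildAEM(conn, root = entry, sites = sites)
  if (!nrow(config@drivers))
    config@drivers <- defaultDrivers(dbmem, aemFit$basis, beta = beta)
  afs <- simulateAlleleFrequencies(sites, list(dbmem, aemFit$basis), config)
  list(sites = sites, dist = d, dbmem = dbmem, connectivity = conn,
       edges = aemFit$edges, aem = aemFit$basis, afs = afs, config = config)
}
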