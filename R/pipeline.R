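#' Run the full seascape-genetics analysis from one configuration
#'
#' Orchestrates every stage: distances (Euclidean, plus least-cost marine
#' distances when a land/sea grid is supplied), pairwise FST and the Mantel
#' isolation-by-distance test, db-MEM and AEM construction with
#' scale attribution, BIC pre-selection and correlation pruning of
#' predictors, the per-locus all-subsets scan, the omega importance summary
#' with Kruskal-Wallis/Dunn comparisons, and the family-wise model summary
#' with nested LR tests.  All artifacts are written to
#' \code{config$out_dir} as delimited text together with a run-metadata
#' JSON recording the seed, options, package version and md5 checksums;
#' reruns with the same config are bit-identical.
#'
#' Configuration keys (YAML file or list): either \code{simulate: true}
#' (with optional \code{n_sites}, \code{n_loci}, \code{beta},
#' \code{noise_sd}) to analyse a synthetic seascape, or paths
#' \code{sites}, \code{freqs} and optionally \code{connectivity} and
#' \code{grid}; plus \code{out_dir}, \code{seed}, \code{n_perm},
#' \code{truncation} ("mst", "none" or km), \code{root}, \code{r_max},
#' \code{local_break}, \code{broad_break}, \code{aicc}.  Without a
#' connectivity matrix the AEM stages are skipped with a notice and the
#' analysis runs geography-only.
#'
#' @param config list or path to a YAML file.
#' @return invisibly, a run report list: sites, fst, mantel, dbmem, aem,
#'   predictors, scan, omega summary, family summary, and the paths of all
#'   written artifacts.
#' @examples
#' \donttest{
#' rep <- runPipeline(list(simulate = TRUE, n_sites = 15, n_loci = 40,
#'                         seed = 3, n_perm = 99, out_dir = tempdir()))
#' rep$omega$omega
#' }
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .pipelineDefaults(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = cfg)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inputs <- stage("inputs", .pipelineInputs(cfg))
  sites <- inputs$sites; afs <- inputs$afs; conn <- inputs$conn
  report$sites <- sites

  dEuc <- stage("distances", euclideanDistances(sites))
  dGeo <- dEuc
  if (!is.null(inputs$grid))
    dGeo <- stage("distances", leastCostDistances(inputs$grid, sites))
  report$distanceKind <- attr(dGeo, "kind")

  report$fst <- stage("fst", pairwiseFst(afs))
  report$mantel <- stage("mantel",
    mantelTest(report$fst, dGeo, nPerm = cfg$n_perm,
               seed = stageSeed(cfg$seed, "mantel")))

  dbmem <- stage("dbmem",
    buildDbMEM(dEuc, truncation = cfg$truncation, sites = sites))
  report$dbmem <- dbmem
  aem <- NULL
  if (!is.null(conn)) {
    fit <- stage("aem", buildAEM(conn, root = cfg$root, sites = sites))
    aem <- fit$basis
    report$aem <- aem
    report$edges <- fit$edges
  } else {
    message("no connectivity matrix supplied: AEM stages skipped, ",
            "running geography-only")
  }

  report$predictors <- stage("selection", {
    candidates <- makePredictorSet(env = sites[, c("sss", "sst")],
                                   dbmem = dbmem, aem = aem)
    y1 <- pcaResponse(afs)
    pruneCorrelated(selectVariablesBIC(y1, candidates), rMax = cfg$r_max,
                    y = y1)
  })

  report$scan <- stage("regression",
    scanAllSubsets(afs, report$predictors, aicc = cfg$aicc))
  report$omega <- stage("summary", summarizeImportance(report$scan))
  fam <- predictorFamily(report$predictors)
  if (any(fam == "geography") && any(fam == "dispersal"))
    report$familySummary <- stage("summary",
      familyModelSummary(afs, report$predictors, aicc = cfg$aicc))

  report$paths <- stage("write", .writeArtifacts(report, cfg))
  invisible(report)
}

.pipelineDefaults <- function(config) {
  defaults <- list(out_dir = "seascape-run", seed = 1, n_perm = 10000,
                   truncation = "mst", root = NULL, r_max = 0.5,
                   local_break = 250, broad_break = 1000, aicc = FALSE,
                   simulate = FALSE, n_sites = 47, n_loci = 300,
                   beta = 0.12, noise_sd = 0.05)
  defaults[names(config)] <- config
  defaults
}

.pipelineInputs <- function(cfg) {
  if (isTRUE(cfg$simulate) || is.list(cfg$simulate)) {
    sc <- simulateSeascape(
      syntheticConfig(nSites = cfg$n_sites, nLoci = cfg$n_loci,
                      noiseSd = cfg$noise_sd, seed = cfg$seed,
                      arcLengthKm = 100 * (cfg$n_sites - 1)),
      beta = cfg$beta)
    return(list(sites = sc$sites, afs = sc$afs, conn = sc$connectivity,
                grid = NULL))
  }
  for (key in c("sites", "freqs"))
    if (is.null(cfg[[key]]) || !file.exists(cfg[[key]]))
      stop("config must point at an existing '", key, "' file")
  sites <- readSiteTable(cfg$sites)
  afs <- readAlleleFrequencies(cfg$freqs, sites)
  conn <- NULL
  if (!is.null(cfg$connectivity)) {
    if (!file.exists(cfg$connectivity))
      stop("connectivity file not found: ", cfg$connectivity)
    conn <- connectivityMatrix(readMatrixCsv(cfg$connectivity))
  }
  grid <- if (!is.null(cfg$grid)) readGridAsc(cfg$grid) else NULL
  list(sites = sites, afs = afs, conn = conn, grid = grid)
}

.writeArtifacts <- function(report, cfg) {
  out <- cfg$out_dir
  paths <- c(
    sites = writeSiteTable(report$sites, file.path(out, "sites.csv")),
    fst = writeMatrixCsv(report$fst, file.path(out, "fst.csv")),
    dbmem = writeBasis(report$dbmem, file.path(out, "dbmem.csv"),
                       cfg$local_break, cfg$broad_break))
  if (!is.null(report$aem))
    paths["aem"] <- writeBasis(report$aem, file.path(out, "aem.csv"),
                               cfg$local_break, cfg$broad_break)
  paths["predictors"] <- writeMatrixCsv(
    predictorMatrix(report$predictors), file.path(out, "predictors.csv"))
  write.csv(report$scan$perLocus, file.path(out, "per_locus.csv"),
            row.names = FALSE, quote = FALSE)
  paths["per_locus"] <- file.path(out, "per_locus.csv")
  omega <- data.frame(variable = names(report$omega$omega),
                      omega = report$omega$omega,
                      family = predictorFamily(report$predictors)[
                        names(report$omega$omega)])
  write.csv(omega, file.path(out, "omega.csv"), row.names = FALSE,
            quote = FALSE)
  paths["omega"] <- file.path(out, "omega.csv")
  if (!is.null(report$familySummary)) {
    write.csv(cbind(model = rownames(report$familySummary),
                    report$familySummary),
              file.path(out, "family_summary.csv"), row.names = FALSE,
              quote = FALSE)
    paths["family_summary"] <- file.path(out, "family_summary.csv")
  }
  meta <- list(
    seed = cfg$seed, config = cfg,
    mantel = report$mantel,
    package = as.character(packageVersion("SeascapeScales")),
    checksums = as.list(tools::md5sum(unname(paths))))
  metaPath <- file.path(out, "run_metadata.json")
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  c(paths, metadata = metaPath)
}

#' Barplot of variable importances (omega)
#'
#' @param omega the \code{omega} element of [summarizeImportance()] output,
#'   or the whole summary list.
#' @param families optional named family vector for colouring.
#' @param ... passed to \code{barplot}.
#' @return the bar midpoints, invisibly.
#' @export
plotOmega <- function(omega, families = NULL, ...) {
  if (is.list(omega) && !is.null(omega$omega)) omega <- omega$omega
  cols <- "grey60"
  if (!is.null(families)) {
    pal <- c(environment = "seagreen", geography = "steelblue",
             dispersal = "firebrick")
    cols <- pal[families[names(omega)]]
  }
  mp <- graphics::barplot(omega, las = 2, col = cols,
                          ylab = expression(omega), ...)
  invisible(mp)
}
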