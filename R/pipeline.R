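#' Run a simulate-analyze-report study workflow
#'
#' Orchestrates the synthetic study end to end: \code{simulate} builds the
#' phantom atlas and all modality data; \code{dwi}, \code{bbb},
#' \code{connectivity} and \code{behavior} run the corresponding analyses;
#' \code{report} collates a summary table (regional DWI statistics,
#' permeability calls per group, network metrics per group, behavior
#' statistics). Stage outputs are CSV files under
#' \code{<outDir>/<stage>/}; a manifest records the seed, the
#' configuration fingerprint and the files written. Numeric CSV output is
#' written at fixed precision, so re-running with the same seed and
#' config reproduces files byte for byte.
#'
#' @param config a \code{\link{simConfig}} or path to a YAML file whose
#'   keys override \code{simConfig} defaults.
#' @param outDir output directory.
#' @param stages subset of simulate/dwi/bbb/connectivity/behavior/report.
#' @param q,pRaw,zthr,band analysis thresholds (study defaults: FDR 0.1,
#'   raw p 0.05, |Z| 2.3, 0.01-0.1 Hz).
#' @return invisible list of stage results (also serialized as CSVs).
#' @export
runStudy <- function(config = simConfig(), outDir,
                     stages = c("simulate", "dwi", "bbb", "connectivity",
                                "behavior", "report"),
                     q = 0.1, pRaw = 0.05, zthr = 2.3,
                     band = c(0.01, 0.1)) {
  known <- c("simulate", "dwi", "bbb", "connectivity", "behavior",
             "report")
  bad <- setdiff(stages, known)
  stopUnless(length(bad) == 0,
             paste("unknown stage(s):", paste(bad, collapse = ", ")))
  if (is.character(config)) {
    overrides <- yaml::read_yaml(config)
    config <- do.call(simConfig, overrides)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeCsv <- function(df, stage, name) {
    dir.create(file.path(outDir, stage), showWarnings = FALSE)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) signif(x, 10))
    utils::write.csv(df, file.path(outDir, stage, name),
                     row.names = FALSE)
  }
  results <- list()
  atlas <- makePhantomAtlas(config)
  if ("simulate" %in% stages) {
    writeLabeledVolume(atlas, file.path(outDir, "simulate", "atlas.nii.gz"))
    writeCsv(atlas@regions, "simulate", "regions.csv")
  }
  if ("dwi" %in% stages) {
    dwi <- simulateDwiStudy(config, atlas)
    scal <- do.call(rbind, lapply(dwi$subjects, function(s) {
      flat <- matrix(s$volume@data, ncol = dim(s$volume@data)[4])
      fit <- fitTensorLogLinear(flat, dwi$btable)
      aggregateRegionalScalars(scalarMaps(fit), atlas, s$id, s$group)
    }))
    rownames(scal) <- NULL
    results$dwi <- list(
      regional = scal,
      adcStats = compareRegionsNonparametric(scal, "mean_adc"),
      faStats = compareRegionsNonparametric(scal, "mean_fa"))
    if ("dwi" %in% stages) {
      writeCsv(scal, "dwi", "regional_scalars.csv")
      writeCsv(results$dwi$adcStats, "dwi", "adc_stats.csv")
      writeCsv(results$dwi$faStats, "dwi", "fa_stats.csv")
    }
  }
  if ("bbb" %in% stages) {
    qs <- simulateQuteceStudy(config, atlas)
    tc <- qcbvRegionalTimecourse(qs$regional, bloodLabel(atlas))
    screen <- subjectPermeabilityScreen(tc, q = q, pRaw = pRaw)
    results$bbb <- screen
    if ("bbb" %in% stages) {
      writeCsv(screen$calls, "bbb", "permeability_calls.csv")
      writeCsv(screen$summary, "bbb", "group_summary.csv")
    }
  }
  if ("connectivity" %in% stages) {
    bold <- simulateBoldStudy(config, atlas)
    cg <- connectivityByGroup(bold, band = band, zthr = zthr)
    degTbl <- do.call(rbind, lapply(c("sham", "impacted"), function(g)
      data.frame(group = g, label_id = names(cg[[g]]$metrics$degree),
                 degree = unname(cg[[g]]$metrics$degree))))
    cmp <- compareDegreeByRegion(cg$sham$metrics, cg$impacted$metrics,
                                 atlas@regions)
    gm <- do.call(rbind, lapply(c("sham", "impacted"), function(g) {
      m <- cg[[g]]$metrics
      data.frame(group = g, n_nodes = m$nNodes, n_edges = m$nEdges,
                 average_degree = m$averageDegree, density = m$density,
                 average_path_length = m$averagePathLength)
    }))
    results$connectivity <- list(groups = cg, degrees = degTbl,
                                 comparison = cmp, globalMetrics = gm)
    if ("connectivity" %in% stages) {
      writeCsv(degTbl, "connectivity", "degrees.csv")
      writeCsv(gm, "connectivity", "global_metrics.csv")
      writeCsv(cmp$byRegion, "connectivity", "region_comparison.csv")
      for (g in c("sham", "impacted"))
        writeEdgeList(cg[[g]]$groupZ,
                      file.path(outDir, "connectivity",
                                paste0("group_z_", g, ".csv")))
    }
  }
  if ("behavior" %in% stages) {
    beh <- simulateBehaviorTracks(config)
    of <- do.call(rbind, lapply(names(beh$tracks), function(id) {
      m <- openFieldMetrics(beh$tracks[[id]], beh$arena)
      data.frame(subject_id = id, group = attr(beh$tracks[[id]], "group"),
                 distance_cm = m$distanceCm, center_s = m$centerTimeS,
                 periphery_s = m$peripheryTimeS)
    }))
    nor <- norInvestigation(beh$nor)
    results$behavior <- list(openField = of, nor = nor)
    if ("behavior" %in% stages) {
      writeCsv(of, "behavior", "open_field.csv")
      writeCsv(nor$perSubject, "behavior", "nor_ir.csv")
      writeCsv(nor$byGroup, "behavior", "nor_group_tests.csv")
    }
  }
  if ("report" %in% stages) {
    # each report table comes from this run's results or a prior stage's CSV
    need <- list(
      dwi_adc_stats = list(results$dwi$adcStats,
                           file.path("dwi", "adc_stats.csv")),
      dwi_fa_stats = list(results$dwi$faStats,
                          file.path("dwi", "fa_stats.csv")),
      bbb_group_summary = list(results$bbb$summary,
                               file.path("bbb", "group_summary.csv")),
      network_metrics = list(results$connectivity$globalMetrics,
                             file.path("connectivity",
                                       "global_metrics.csv")),
      nor_tests = list(results$behavior$nor$byGroup,
                       file.path("behavior", "nor_group_tests.csv")))
    missing <- character()
    tables <- list()
    for (nm in names(need)) {
      inMem <- need[[nm]][[1]]
      onDisk <- file.path(outDir, need[[nm]][[2]])
      if (!is.null(inMem)) tables[[nm]] <- inMem
      else if (file.exists(onDisk)) tables[[nm]] <- utils::read.csv(onDisk)
      else missing <- c(missing, need[[nm]][[2]])
    }
    stopUnless(length(missing) == 0,
               paste("report inputs missing:",
                     paste(missing, collapse = ", ")))
    for (nm in names(tables))
      writeCsv(tables[[nm]], "report", paste0(nm, ".csv"))
    results$report <- tables
  }
  cfgTxt <- yaml::as.yaml(unclass(config))
  manifest <- list(seed = config$seed, config_hash = fnv1a32(cfgTxt),
                   stages = stages,
                   files = list.files(outDir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' Write a connectivity matrix as a source,target,weight edge list
#'
#' @param mat \linkS4class{ConnectivityMatrix}.
#' @param path output CSV path.
#' @return path, invisibly.
#' @export
writeEdgeList <- function(mat, path) {
  v <- cmValues(mat)
  labs <- nodeLabels(mat)
  ut <- which(upper.tri(v), arr.ind = TRUE)
  df <- data.frame(source = labs[ut[, 1]], target = labs[ut[, 2]],
                   weight = signif(v[ut], 10))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
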