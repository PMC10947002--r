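#' Pipeline run configuration
#'
#' All stage parameters with their documented defaults: Taubin smoothing
#' iterations (10), curvature neighbourhood rings (2), spectral mode count
#' (5), inter-layer coupling (0.1), multiple-comparison correction
#' ("holm"), global-period definition ("t1t3"), vertex summary statistic
#' ("median", signed). Round-trips losslessly through JSON.
#'
#' @param seed integer seed for the simulate stage.
#' @param outDir output directory (NULL keeps results in memory).
#' @param structures structures to process.
#' @param smoothingIters,rings,kModes,coupling geometry/spectral parameters.
#' @param correction,globalPeriod,summaryAbsolute statistics parameters.
#' @param doCurvature run the curvature stage (white matter only).
#' @param doSpectral run longitudinal joint spectral matching (expensive).
#' @param nOSB,nControl,effect simulate-stage cohort settings.
#' @param force overwrite existing results even when the provenance hash
#'   matches.
#' @return a list of class `fmRunConfig`.
#' @export
runConfig <- function(seed = 1L, outDir = NULL,
                      structures = c("wm", "ventricles", "cerebellum"),
                      smoothingIters = 10L, rings = 2L, kModes = 5L,
                      coupling = 0.1, correction = "holm",
                      globalPeriod = "t1t3", summaryAbsolute = FALSE,
                      doCurvature = TRUE, doSpectral = FALSE,
                      nOSB = 29L, nControl = 12L, effect = "paper",
                      force = FALSE) {
  cfg <- list(seed = as.integer(seed), outDir = outDir,
              structures = structures,
              smoothingIters = as.integer(smoothingIters),
              rings = as.integer(rings), kModes = as.integer(kModes),
              coupling = coupling, correction = correction,
              globalPeriod = globalPeriod,
              summaryAbsolute = summaryAbsolute,
              doCurvature = doCurvature, doSpectral = doSpectral,
              nOSB = as.integer(nOSB), nControl = as.integer(nControl),
              effect = effect, force = force)
  class(cfg) <- "fmRunConfig"
  cfg
}

.configHash <- function(cfg) {
  cfg$force <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                              digits = NA, null = "null"), f)
  unname(tools::md5sum(f))
}

.log <- function(..., verbose = TRUE) {
  if (verbose) message(sprintf("[fetalmorpho %s] ", format(Sys.time(),
                                                           "%H:%M:%S")), ...)
}

#' Per-timepoint structure measurements for a cohort
#'
#' Runs volume/area/shape measurement for every subject, timepoint and
#' structure. Subjects whose geometry fails an invariant (e.g. a clipped or
#' non-manifold structure) are excluded with a logged reason rather than
#' aborting the cohort, mirroring per-subject exclusion in clinical
#' pipelines; subjects lacking any timepoint are excluded likewise.
#'
#' @param cohort a cohort list from [generateCohort()], or a manifest
#'   data.frame with `path_t1..t3` columns pointing at NIfTI volumes.
#' @param structures structure names to measure.
#' @param smoothingIters Taubin iterations for mesh extraction.
#' @param volumeOnly skip mesh extraction and report voxel-count volumes
#'   only (area and shape columns NA); volume is defined by voxel counting,
#'   so this is exact for volume-rate studies and much faster on large
#'   replicate designs.
#' @param verbose log progress to stderr.
#' @return data.frame: subject_id, group, timepoint, ga_weeks, structure,
#'   volume_mm3, area_mm2, shape_mm.
#' @export
measureCohort <- function(cohort, structures = c("wm", "ventricles",
                                                 "cerebellum"),
                          smoothingIters = 10L, volumeOnly = FALSE,
                          verbose = FALSE) {
  manifest <- if (is.data.frame(cohort)) cohort else cohort$manifest
  inMemory <- !is.data.frame(cohort)
  codes <- .LABEL_CODES[structures]
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    gas <- as.numeric(manifest[i, c("ga_t1", "ga_t2", "ga_t3")])
    if (anyNA(gas)) {
      .log("excluding ", sid, ": missing timepoint", verbose = verbose)
      next
    }
    rows <- try({
      lapply(1:3, function(t) {
        vol <- if (inMemory) cohort$subjects[[sid]]$volumes[[t]] else
          readLabelVolume(manifest[[paste0("path_t", t)]][i])
        do.call(rbind, lapply(seq_along(codes), function(s) {
          m <- if (volumeOnly) {
            data.frame(structure = .structureName(codes[s]),
                       volume_mm3 = computeVolume(vol, codes[s]),
                       area_mm2 = NA_real_, shape_mm = NA_real_,
                       mesh_volume_mm3 = NA_real_,
                       volume_source = "voxel-count")
          } else {
            measureStructure(vol, codes[s], smoothingIters = smoothingIters)
          }
          cbind(subject_id = sid, group = manifest$group[i], timepoint = t,
                ga_weeks = gas[t], m)
        }))
      })
    }, silent = TRUE)
    if (inherits(rows, "try-error")) {
      .log("excluding ", sid, ": ", attr(rows, "condition")$message,
           verbose = verbose)
      next
    }
    out[[sid]] <- do.call(rbind, rows)
  }
  if (!length(out)) stop("no subject survived measurement")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Curvature-marker summaries for a cohort's white matter
#'
#' Computes the white-matter curvature field per timepoint and summarizes
#' median curvedness and median shape index over the whole surface, with
#' lobe parcellation against the canonical atlas surface at the matching GA.
#'
#' @inheritParams measureCohort
#' @param rings curvature neighbourhood rings.
#' @param byLobe include per-lobe rows.
#' @return data.frame: subject_id, group, timepoint, ga_weeks, region,
#'   parameter, value, n_vertices.
#' @export
curvatureCohort <- function(cohort, rings = 2L, smoothingIters = 10L,
                            byLobe = FALSE, verbose = FALSE) {
  manifest <- if (is.data.frame(cohort)) cohort else cohort$manifest
  inMemory <- !is.data.frame(cohort)
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    gas <- as.numeric(manifest[i, c("ga_t1", "ga_t2", "ga_t3")])
    rows <- try(lapply(1:3, function(t) {
      vol <- if (inMemory) cohort$subjects[[sid]]$volumes[[t]] else
        readLabelVolume(manifest[[paste0("path_t", t)]][i])
      mesh <- extractMesh(vol, .LABEL_CODES[["wm"]],
                          smoothingIters = smoothingIters)
      cf <- curvatureField(mesh, rings = rings)
      parc <- if (byLobe)
        parcellateLobes(mesh, atlasSurface(min(max(gas[t], 20), 37)))
      else NULL
      cs <- curvatureSummary(curvednessValues(cf), parc)
      ss <- curvatureSummary(shapeIndexValues(cf), parc)
      cs$parameter <- "curvedness"
      ss$parameter <- "shape_index"
      cbind(subject_id = sid, group = manifest$group[i], timepoint = t,
            ga_weeks = gas[t], rbind(cs, ss))
    }), silent = TRUE)
    if (inherits(rows, "try-error")) {
      .log("excluding ", sid, " from curvature stage: ",
           attr(rows, "condition")$message, verbose = verbose)
      next
    }
    out[[sid]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  names(res)[names(res) == "median"] <- "value"
  res
}

#' Three-period weekly rates from a measures table
#'
#' @param measures output of [measureCohort()] (or any table with
#'   subject_id, group, timepoint, ga_weeks, structure and parameter value
#'   columns).
#' @param parameters value columns to convert to rates.
#' @param globalPeriod `"t1t3"` or `"difference"`, see [periodRates()].
#' @return long data.frame: subject_id, group, structure, parameter, period,
#'   rate.
#' @export
cohortRates <- function(measures, parameters = c("volume_mm3", "area_mm2",
                                                 "shape_mm"),
                        globalPeriod = "t1t3") {
  out <- list()
  for (sid in unique(measures$subject_id)) {
    ms <- measures[measures$subject_id == sid, ]
    for (st in unique(ms$structure)) {
      mst <- ms[ms$structure == st, ]
      mst <- mst[order(mst$timepoint), ]
      if (nrow(mst) != 3L) next
      for (p in parameters) {
        r <- periodRates(mst[[p]], mst$ga_weeks, global = globalPeriod)
        out[[length(out) + 1L]] <- data.frame(
          subject_id = sid, group = mst$group[1], structure = st,
          parameter = p, period = names(r), rate = unname(r))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group statistics over all parameters and periods
#'
#' Runs [compareGroups()] for every structure x parameter x period cell of a
#' rates table.
#'
#' @param rates output of [cohortRates()].
#' @param correction p-adjustment method for the post-hoc tests.
#' @param alpha significance level.
#' @return data.frame with per-group medians/IQRs, H, p, adjusted p and the
#'   significance flag per cell.
#' @export
cohortStats <- function(rates, correction = "holm", alpha = 0.05) {
  out <- list()
  cells <- unique(rates[, c("structure", "parameter", "period")])
  for (i in seq_len(nrow(cells))) {
    sel <- rates$structure == cells$structure[i] &
      rates$parameter == cells$parameter[i] & rates$period == cells$period[i]
    cg <- compareGroups(rates[sel, ], value = "rate", group = "group",
                        correction = correction, alpha = alpha)
    g <- cg$groups
    wide <- stats::setNames(
      as.vector(t(g[, c("median", "q25", "q75", "n")])),
      as.vector(t(outer(g$group, c("median", "q25", "q75", "n"), paste,
                        sep = "_"))))
    out[[i]] <- cbind(cells[i, , drop = FALSE], as.data.frame(t(wide)),
                      H = if (is.null(cg$omnibus)) NA else cg$omnibus$H,
                      p = if (is.null(cg$omnibus)) NA else cg$omnibus$p.value,
                      p_adjusted = if (is.null(cg$posthoc)) NA else
                        min(cg$posthoc$p.adjusted),
                      significant = cg$significant)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full pipeline
#'
#' simulate -> extract -> measure -> (curvature) -> rates -> statistics,
#' with reproducible seeding and a machine-readable provenance record. When
#' `outDir` is set, result tables are written as CSV together with
#' `provenance.json` (config hash, seed, stage row counts); re-running with
#' an identical configuration is a no-op unless `force`.
#'
#' @param config an `fmRunConfig` from [runConfig()].
#' @param cohort optional pre-generated cohort (skips the simulate stage).
#' @param verbose log stage progress.
#' @return list with `measures`, `curvature`, `rates`, `stats`, `manifest`,
#'   `provenance`.
#' @export
runPipeline <- function(config = runConfig(), cohort = NULL, verbose = TRUE) {
  hash <- .configHash(config)
  if (!is.null(config$outDir)) {
    pv <- file.path(config$outDir, "provenance.json")
    if (!config$force && file.exists(pv)) {
      prev <- jsonlite::read_json(pv)
      if (identical(prev$config_hash, as.vector(hash))) {
        .log("identical config hash ", hash, " found: no-op (use force)",
             verbose = verbose)
        return(invisible(NULL))
      }
    }
  }
  if (is.null(cohort)) {
    .log("simulate: ", config$nOSB, " OSB + ", config$nControl, " controls",
         verbose = verbose)
    cc <- cohortConfig(nOSB = config$nOSB, nControl = config$nControl,
                       seed = config$seed, effect = config$effect,
                       structures = config$structures)
    cohort <- generateCohort(cc)
  }
  .log("measure", verbose = verbose)
  measures <- measureCohort(cohort, structures = config$structures,
                            smoothingIters = config$smoothingIters,
                            verbose = verbose)
  curv <- NULL
  if (config$doCurvature && "wm" %in% config$structures) {
    .log("curvature", verbose = verbose)
    curv <- curvatureCohort(cohort, rings = config$rings,
                            smoothingIters = config$smoothingIters,
                            verbose = verbose)
  }
  .log("rates", verbose = verbose)
  rates <- cohortRates(measures, globalPeriod = config$globalPeriod)
  if (!is.null(curv)) {
    whole <- curv[curv$region == "whole", ]
    wide <- stats::reshape(
      whole[, c("subject_id", "group", "timepoint", "ga_weeks", "parameter",
                "value")],
      direction = "wide", idvar = c("subject_id", "group", "timepoint",
                                    "ga_weeks"),
      timevar = "parameter")
    names(wide) <- sub("^value\\.", "", names(wide))
    wide$structure <- "wm_surface"
    cr <- cohortRates(wide, parameters = c("curvedness", "shape_index"),
                      globalPeriod = config$globalPeriod)
    rates <- rbind(rates, cr)
  }
  .log("statistics", verbose = verbose)
  stats <- cohortStats(rates, correction = config$correction)
  prov <- list(config_hash = as.vector(hash), seed = config$seed,
               generated = format(Sys.time()),
               n_subjects = length(unique(measures$subject_id)),
               stages = list(measures = nrow(measures),
                             rates = nrow(rates), stats = nrow(stats)))
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(measures, file.path(config$outDir, "measures.csv"),
                     row.names = FALSE)
    if (!is.null(curv))
      utils::write.csv(curv, file.path(config$outDir, "curvature.csv"),
                       row.names = FALSE)
    utils::write.csv(rates, file.path(config$outDir, "rates.csv"),
                     row.names = FALSE)
    utils::write.csv(stats, file.path(config$outDir, "stats.csv"),
                     row.names = FALSE)
    jsonlite::write_json(prov, file.path(config$outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(measures = measures, curvature = curv, rates = rates, stats = stats,
       manifest = if (is.data.frame(cohort)) cohort else cohort$manifest,
       provenance = prov)
}
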