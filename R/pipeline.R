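#' Build and validate a pipeline configuration
#'
#' Defaults reproduce the canonical study conditions: the 7-band, 5-contrast
#' design with repetition scheme (3, 9, 19, 23) over 15 runs, a 10-subject
#' cohort, 200 voxels per region, and the five ventral-stream region
#' presets of [regionPresets()]. The noise-response model is fit to
#' scene-normalized matrices.
#'
#' @param design an \linkS4class{ExperimentDesign}
#' @param regions named list of [groundTruth()] argument lists; per-region
#'   entries may include \code{r2Min} for the voxel-selection cut
#' @param nSubjects simulated cohort size
#' @param nVoxels voxels per region
#' @param nRuns runs per subject
#' @param eccRange voxel-selection eccentricity interval, degrees
#' @param normalize fit the noise-response model on the scene-normalized
#'   scale (the noise-threshold target is then the scene response, 1)
#' @return a validated configuration (class \code{"PipelineConfig"})
#' @export
pipelineConfig <- function(design = experimentDesign(),
                           regions = regionPresets(),
                           nSubjects = 10L, nVoxels = 200L, nRuns = 15L,
                           eccRange = c(0, 6), normalize = TRUE) {
  stopifnot(is(design, "ExperimentDesign"))
  validObject(design)
  if (is.null(names(regions)) || any(names(regions) == ""))
    stop("regions must be a named list")
  if (nSubjects < 1L) stop("nSubjects must be >= 1")
  if (nVoxels < 2L) stop("nVoxels must be >= 2")
  structure(list(design = design, regions = regions,
                 nSubjects = as.integer(nSubjects),
                 nVoxels = as.integer(nVoxels), nRuns = as.integer(nRuns),
                 eccRange = as.numeric(eccRange),
                 normalize = isTRUE(normalize)),
            class = "PipelineConfig")
}

# behavioral-budget condition table: scene-in-noise and scene-only rows
.behavior_conditions <- function(design) {
  cond <- enumerateConditions(design)
  cond <- cond[cond$kind %in% c("sceneNoise", "sceneOnly"), , drop = FALSE]
  reps <- ifelse(cond$kind == "sceneNoise",
                 design@reps[["sceneNoise"]], design@reps[["sceneOnly"]])
  list(conditions = cond[, c("sigma", "freq")], reps = reps)
}

.run_subject_region <- function(config, region, preset, trialTable,
                                voxels, seedBase) {
  design <- config$design
  gt_args <- preset[setdiff(names(preset), "r2Min")]
  truth <- do.call(groundTruth,
                   c(list(V = config$nVoxels,
                          nCategories = design@nCategories,
                          seed = seedBase), gt_args))
  se <- simulateTrialBetas(trialTable, truth, voxels, seed = seedBase + 1L)
  vox <- selectVoxels(se, eccRange = config$eccRange,
                      r2Min = preset$r2Min)
  Rraw <- noiseResponseMatrix(se, vox)
  Rfit <- if (config$normalize) normalizeByScene(Rraw, se, vox) else Rraw
  respFit <- fitNoiseResponse(Rfit)

  decoded <- decodeTrials(se, vox)
  acc <- accuracyMatrix(se, vox)
  mvpaFit <- fitDecodingModel(decoded)

  beh <- .behavior_conditions(design)
  outcomes <- simulateBehavior(beh$conditions, truth, beh$reps,
                               seed = seedBase + 2L)
  recFit <- fitDecodingModel(outcomes)

  summ <- bandSummary(respFit, recFit, region = region)
  summ$fw2mMvpa <- suppressWarnings(fw2m(mvpaFit))
  summ$baselineAccuracy <- acc@baseline
  list(summary = summ, responseMatrix = Rfit, rawMatrix = Rraw,
       accuracyMatrix = acc, respFit = respFit, recFit = recFit,
       mvpaFit = mvpaFit, outcomes = outcomes, decoded = decoded,
       nVoxelsSelected = length(vox))
}

.fit_to_list <- function(f) {
  if (is(f, "NoiseResponseFit")) {
    list(betaBase = f@betaBase, betaMax = f@betaMax, sigma50 = f@sigma50,
         mu = f@mu, w = f@w, sse = f@sse, r2 = f@r2,
         normalized = f@normalized, identifiable = f@identifiable)
  } else {
    list(mu = f@mu, w = f@w, kappa = f@kappa, m = f@m, b = f@b,
         nll = f@nll, nTrials = f@nTrials, identifiable = f@identifiable)
  }
}

#' Run the full simulation-and-analysis pipeline
#'
#' For each simulated subject and region: simulate voxel metadata and
#' trial-wise betas under the region's generating parameters, select
#' voxels, compute the (scene-normalized) noise-response matrix and the
#' MVPA decoding-accuracy matrix, fit the noise-response channel, fit the
#' recognition channel to classification outcomes simulated from the
#' region's recognition parameters (and, as a secondary output, to the
#' MVPA outcomes), and derive the band metrics. Group-level fits use the
#' subject-averaged response matrix and the pooled outcomes per region.
#' All randomness derives from \code{seed}; identical config and seed give
#' identical outputs (byte-identical files when \code{outDir} is set).
#'
#' @param config a \code{"PipelineConfig"} from [pipelineConfig()]
#' @param seed master integer seed
#' @param outDir optional output directory; per-subject and summary CSV /
#'   JSON artifacts are written beneath it
#' @param quiet suppress per-stage progress messages
#' @return list with \code{bandSummary} (one row per subject x region),
#'   \code{groupSummary} (one row per region, group-level fits),
#'   \code{cohortSummary} (mean and SEM of the band metrics across
#'   subjects), and \code{groupFits}
#' @export
runPipeline <- function(config, seed, outDir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  seed <- as.integer(seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  design <- config$design
  regions <- names(config$regions)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    cfg <- list(nSubjects = config$nSubjects, nVoxels = config$nVoxels,
                nRuns = config$nRuns, eccRange = config$eccRange,
                normalize = config$normalize, seed = seed,
                nCategories = design@nCategories,
                bandCenters = design@bandCenters,
                contrasts = design@contrasts,
                reps = as.list(design@reps), regions = config$regions)
    jsonlite::write_json(cfg, file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  rows <- list()
  norm_mats <- list()       # region -> list of subject matrices
  pooled <- list()          # region -> pooled recognition outcomes
  for (s in seq_len(config$nSubjects)) {
    seedS <- seed + 1000L * s
    voxels <- simulateVoxels(config$nVoxels, seedS)
    trialTable <- buildTrialTable(design, config$nRuns, seedS + 1L)
    sdir <- if (!is.null(outDir)) {
      d <- file.path(outDir, sprintf("subject-%02d", s))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      writeTrialTable(trialTable, file.path(d, "trials.csv"))
      utils::write.csv(voxels, file.path(d, "voxels.csv"),
                       row.names = FALSE)
      d
    }
    for (ri in seq_along(regions)) {
      rg <- regions[ri]
      res <- .run_subject_region(config, rg, config$regions[[ri]],
                                 trialTable, voxels,
                                 seedBase = seedS + 10L * ri)
      res$summary <- cbind(subject = s, res$summary,
                           nVoxelsSelected = res$nVoxelsSelected)
      rows[[length(rows) + 1L]] <- res$summary
      norm_mats[[rg]] <- c(norm_mats[[rg]], list(res$responseMatrix))
      pooled[[rg]] <- rbind(pooled[[rg]], res$outcomes)
      if (!is.null(outDir)) {
        rdir <- file.path(sdir, rg)
        dir.create(rdir, showWarnings = FALSE)
        writeConditionMatrix(res$responseMatrix,
                             file.path(rdir, "response_matrix.csv"))
        writeConditionMatrix(res$accuracyMatrix,
                             file.path(rdir, "accuracy_matrix.csv"))
        utils::write.csv(res$decoded,
                         file.path(rdir, "decoded_trials.csv"),
                         row.names = FALSE)
        jsonlite::write_json(
          list(response = .fit_to_list(res$respFit),
               recognition = .fit_to_list(res$recFit),
               mvpa = .fit_to_list(res$mvpaFit)),
          file.path(rdir, "fits.json"), auto_unbox = TRUE, digits = NA)
      }
    }
    say("subject %d/%d done (%.1f s elapsed)", s, config$nSubjects,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  band <- do.call(rbind, rows)

  # group-level: subject-averaged matrices and pooled outcomes per region
  grows <- list()
  gfits <- list()
  for (rg in regions) {
    mats <- norm_mats[[rg]]
    avg <- Reduce(`+`, lapply(mats, function(m) m@values)) / length(mats)
    Ravg <- new("ResponseMatrix", values = avg, sigmas = mats[[1]]@sigmas,
                freqs = mats[[1]]@freqs,
                nTrials = Reduce(`+`, lapply(mats, function(m) m@nTrials)),
                normalized = mats[[1]]@normalized, reference = NA_real_,
                nVoxels = mats[[1]]@nVoxels)
    respG <- fitNoiseResponse(Ravg)
    recG <- fitDecodingModel(pooled[[rg]])
    gfits[[rg]] <- list(response = respG, recognition = recG)
    grows[[rg]] <- bandSummary(respG, recG, region = rg)
  }
  group <- do.call(rbind, grows)
  rownames(group) <- NULL

  metr <- c("fwhmResponse", "fw2mRecognition", "noiseThreshold",
            "noiseTolerance")
  coh <- do.call(rbind, lapply(regions, function(rg) {
    sub <- band[band$region == rg, metr, drop = FALSE]
    means <- colMeans(sub)
    sems <- apply(sub, 2, function(v) sd(v) / sqrt(length(v)))
    data.frame(region = rg, metric = metr, mean = as.numeric(means),
               sem = as.numeric(sems))
  }))

  if (!is.null(outDir)) {
    utils::write.csv(band, file.path(outDir, "band_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(group, file.path(outDir, "group_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(coh, file.path(outDir, "cohort_summary.csv"),
                     row.names = FALSE)
  }
  say("pipeline finished in %.1f s",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(bandSummary = band, groupSummary = group,
                 cohortSummary = coh, groupFits = gfits))
}
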