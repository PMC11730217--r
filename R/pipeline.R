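## End-to-end orchestration: build -> sample (variants x conditions x
## replicas) -> geometry statistics -> thermodynamic report.

#' Pipeline run configuration
#'
#' @param variants tail variants to run (subset of E, D, K, S).
#' @param conditions iodination conditions to sample.
#' @param sampler a \code{\link{samplerConfig}}; its seed is replaced per
#'   replica.
#' @param replicaSeeds distinct integer seeds, one per replica (three by
#'   default, mirroring triplicate sampling).
#' @param binWidth histogram bin width for the distance distributions,
#'   Angstrom.
#' @param reactiveCutoff distance cutoff for the reactive-fraction
#'   statistic, Angstrom.
#' @param outDir optional directory for intermediate artifacts
#'   (multi-model PDB ensembles); NULL keeps everything in memory.
#' @return A list of class \code{RunConfig}.
#' @export
runConfig <- function(variants = c("E", "D", "K", "S"),
                      conditions = c("Y_distal", "DIT_distal",
                                     "DIT_proximal"),
                      sampler = samplerConfig(),
                      replicaSeeds = c(101L, 102L, 103L),
                      binWidth = 0.25, reactiveCutoff = 6.0,
                      outDir = NULL) {
  stopifnot(length(variants) >= 1L, length(conditions) >= 1L,
            all(variants %in% c("E", "D", "K", "S")),
            all(conditions %in% c("Y_distal", "DIT_distal", "DIT_proximal")),
            length(replicaSeeds) >= 1L,
            !anyDuplicated(replicaSeeds))
  structure(list(variants = variants, conditions = conditions,
                 sampler = sampler, replicaSeeds = as.integer(replicaSeeds),
                 binWidth = binWidth, reactiveCutoff = reactiveCutoff,
                 outDir = outDir),
            class = "RunConfig")
}

.configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[setdiff(names(cfg), "outDir")], tmp,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

.summarize <- function(d) {
  list(mode = d@mode, mean = d@mean, interdecile = d@interdecile,
       n_bins = length(d@probabilities))
}

## Build (and cache) the variant models used by a run.
.variantModels <- function(variant) {
  model <- appendExtendedTail(makeScaffold(), makeVariant(variant))
  iodinated <- iodinateTyrosine(iodinateTyrosine(model, 341L), 375L)
  list(plain = model, iodinated = iodinated)
}

.sampleCell <- function(models, condition, sampler, seed) {
  cfg <- sampler
  cfg$seed <- as.integer(seed)
  if (condition == "Y_distal") {
    sampleEnsemble(models$plain, "Y_distal", cfg)
  } else if (condition == "DIT_distal") {
    sampleEnsemble(models$iodinated, "DIT_distal", cfg)
  } else {
    yEns <- sampleEnsemble(models$plain, "Y_distal", cfg)
    sel <- selectProximalFrame(yEns)
    proximal <- iodinateTyrosine(iodinateTyrosine(sel$structure, 341L), 375L)
    sampleEnsemble(proximal, "DIT_proximal", cfg)
  }
}

#' Run the full analysis pipeline
#'
#' For every requested variant and iodination condition, builds the
#' precursor model, samples the configured replicas, pools their frames,
#' and reports distance distributions (donor-acceptor Cbeta-Cbeta and
#' Ozeta-Cbeta), per-frame stacking-label counts, reactive fractions and
#' (for the acidic variants) the carboxylate-proximity distribution,
#' together with a thermodynamic section (iodotyrosine pKa table,
#' synthetic concerted coupling free energies and the implied variant
#' ranking).  Deterministic given the replica seeds; any failing cell is
#' recorded as failed without aborting the run.
#'
#' @param cfg a \code{\link{runConfig}}.
#' @return A list of class \code{RunReport}.
#' @seealso \code{\link{writeRunReport}}, \code{\link{validateRunReport}}
#' @export
runPipeline <- function(cfg = runConfig()) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (!is.null(cfg$outDir) && !dir.exists(cfg$outDir))
    dir.create(cfg$outDir, recursive = TRUE)
  cells <- list()
  for (v in cfg$variants) {
    models <- .variantModels(v)
    for (cond in cfg$conditions) {
      key <- sprintf("%s_%s", v, cond)
      cells[[key]] <- tryCatch({
        replicas <- lapply(cfg$replicaSeeds, function(seed)
          .sampleCell(models, cond, cfg$sampler, seed))
        ozcb <- unlist(lapply(replicas, function(e)
          seriesValues(pairDistanceSeries(e, c(375L, "OH"), c(341L, "CB")))))
        cbcb <- unlist(lapply(replicas, function(e)
          seriesValues(pairDistanceSeries(e, c(375L, "CB"), c(341L, "CB")))))
        stack <- do.call(rbind, lapply(replicas, stackingLabels))
        labelCounts <- as.list(table(factor(
          stack$label, levels = c("parallel", "perpendicular", "none"))))
        carbox <- if (v %in% c("E", "D")) {
          pooled <- unlist(lapply(replicas, function(e) {
            carbon <- if (v == "E") "CD" else "CG"
            seriesValues(pairDistanceSeries(e, c(375L, "OH"),
                                            c(374L, carbon)))
          }))
          .summarize(distanceDistribution(pooled, cfg$binWidth))
        } else "not-applicable"
        if (!is.null(cfg$outDir))
          for (k in seq_along(replicas))
            writeEnsemble(replicas[[k]],
                          file.path(cfg$outDir,
                                    sprintf("%s_rep%d.pdb", key, k)))
        list(variant = v, condition = cond, status = "ok",
             n_frames = length(ozcb),
             distributions = list(
               oz_cb = .summarize(distanceDistribution(ozcb, cfg$binWidth)),
               cb_cb = .summarize(distanceDistribution(cbcb, cfg$binWidth))),
             reactive_fraction = reactiveFraction(ozcb, cfg$reactiveCutoff),
             stacking_counts = labelCounts,
             carboxylate_proximity = carbox,
             replicas = lapply(seq_along(replicas), function(k)
               list(seed = cfg$replicaSeeds[k],
                    n_frames = nFrames(replicas[[k]]),
                    acceptance = replicas[[k]]@acceptanceRate,
                    mean_energy = mean(frameEnergies(replicas[[k]])))))
      }, error = function(e)
        list(variant = v, condition = cond, status = "failed",
             message = conditionMessage(e)))
    }
  }
  pm <- pkaModel()
  dg2tab <- makeEnergyTable("variant-ranking")
  ledger <- couplingLedger("variant-ranking")
  dg2 <- vapply(c("E", "D", "K", "S"), function(v)
    reactionDeltaG(ledger, dg2tab, paste0("concerted-", v)), numeric(1L))
  thermo <- list(
    pka = list(Y = pm$referencePka,
               MIT = pkaFromCycle(pm, "MIT"),
               DIT = pkaFromCycle(pm, "DIT")),
    deprotonated_fraction_ph7.4 =
      deprotonatedFraction(pkaFromCycle(pm, "DIT"), 7.4),
    deprotonated_fraction_ph6.0 =
      deprotonatedFraction(pkaFromCycle(pm, "DIT"), 6.0),
    dg2_synthetic = as.list(dg2),
    variant_ranking = as.character(rankVariants(dg2)))
  report <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("iodosite")),
      config_hash = .configHash(cfg),
      replica_seeds = cfg$replicaSeeds,
      sampler_seed_base = cfg$sampler$seed,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    thermodynamics = thermo,
    cells = cells)
  class(report) <- "RunReport"
  report
}

#' Write a run report as JSON
#'
#' @param report a \code{\link{runPipeline}} result.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeRunReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}

#' Validate a run report against the packaged schema
#'
#' Checks the presence of the required top-level sections and per-cell
#' fields listed in the packaged schema document.
#'
#' @param report a \code{RunReport} (or a list parsed from its JSON).
#' @param schemaPath path to the schema JSON (defaults to the packaged
#'   document).
#' @return TRUE invisibly; errors describe any violation.
#' @export
validateRunReport <- function(report,
                              schemaPath = system.file("extdata",
                                                       "run_report_schema.json",
                                                       package = "iodosite")) {
  schema <- jsonlite::fromJSON(schemaPath)
  miss <- setdiff(schema$required, names(report))
  if (length(miss))
    stop(sprintf("report lacks required sections: %s",
                 paste(miss, collapse = ", ")))
  for (cell in report$cells) {
    need <- if (identical(cell$status, "ok")) schema$cell_required_ok
            else schema$cell_required
    miss <- setdiff(need, names(cell))
    if (length(miss))
      stop(sprintf("cell %s/%s lacks fields: %s", cell$variant,
                   cell$condition, paste(miss, collapse = ", ")))
  }
  miss <- setdiff(schema$provenance_required, names(report$provenance))
  if (length(miss))
    stop(sprintf("provenance lacks fields: %s", paste(miss, collapse = ", ")))
  invisible(TRUE)
}
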