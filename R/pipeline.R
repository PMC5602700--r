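#' Pipeline configuration
#'
#' Collects every knob of the end-to-end workflow: survey design, coupling,
#' analysis options and MCMC settings, plus optional paths to real input
#' CSVs (when given, the simulation stage is skipped and the files are
#' ingested instead).  `config` may also be loaded from a YAML file with
#' the same field names.
#'
#' @param seed Master seed recorded in all outputs.
#' @param design List of [study_design()] arguments.
#' @param coupling,activity_sd Generator coupling settings.
#' @param anova List: `nested`, `method`.
#' @param clustering List: `distance`, `linkage`.
#' @param logistic List: `predictor`.
#' @param mcmc List of [mcmc_config()] arguments (seed is supplied from the
#'   pipeline seed).
#' @param inputs Optional list of paths: `counts`, `detections`, `sites`.
#' @param out_dir Optional output directory; when given, every stage writes
#'   its tables there.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, design = list(), coupling = 1,
                            activity_sd = 1,
                            anova = list(nested = FALSE, method = "tukey"),
                            clustering = list(distance = "correlation",
                                              linkage = "average"),
                            logistic = list(predictor = "richness"),
                            mcmc = list(), inputs = NULL, out_dir = NULL) {
  if (!is.null(inputs)) {
    for (p in unlist(inputs))
      if (!file.exists(p))
        stop("pipeline_config: input path does not exist: ", p, call. = FALSE)
  }
  structure(list(seed = as.integer(seed), design = design,
                 coupling = coupling, activity_sd = activity_sd,
                 anova = anova, clustering = clustering, logistic = logistic,
                 mcmc = mcmc, inputs = inputs, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Validate pipeline input tables
#'
#' Schema checks with row-level error locations.  Accepts data frames or
#' CSV paths.  Checked: required columns; binary `y` in detections; known
#' stratum and period labels; nonnegative integer call counts.
#'
#' @param counts Call-count table (or path).
#' @param detections Long detection table `species,site,occasion,period,y`
#'   (or path).
#' @param sites Site table `site,stratum,...` (or path).
#' @param strata,periods Known labels.
#' @return Data frame of errors (`table`, `row`, `message`); zero rows means
#'   all inputs are valid.
#' @export
validate_inputs <- function(counts = NULL, detections = NULL, sites = NULL,
                            strata = c("agriculture", "mixed", "forest"),
                            periods = c("before_sunrise", "sunrise",
                                        "after_sunrise")) {
  errs <- list()
  add <- function(tab, row, msg)
    errs[[length(errs) + 1L]] <<- data.frame(table = tab, row = row,
                                             message = msg,
                                             stringsAsFactors = FALSE)
  load_tab <- function(x) if (is.character(x))
    utils::read.csv(x, stringsAsFactors = FALSE) else x

  if (!is.null(counts)) {
    counts <- load_tab(counts)
    need <- setdiff(c("survey_id", "site", "stratum", "period", "species",
                      "call_count"), names(counts))
    if (length(need))
      add("counts", NA, paste("missing columns:", paste(need, collapse = ", ")))
    else {
      for (r in which(!counts$stratum %in% strata))
        add("counts", r, paste0("unknown stratum '", counts$stratum[r], "'"))
      for (r in which(!counts$period %in% periods))
        add("counts", r, paste0("unknown period '", counts$period[r], "'"))
      bad <- which(!is.finite(counts$call_count) | counts$call_count < 0 |
                   counts$call_count != round(counts$call_count))
      for (r in bad)
        add("counts", r, paste0("call_count must be a nonnegative integer, ",
                                "got ", counts$call_count[r]))
    }
  }
  if (!is.null(detections)) {
    det <- load_tab(detections)
    need <- setdiff(c("species", "site", "occasion", "period", "y"),
                    names(det))
    if (length(need))
      add("detections", NA,
          paste("missing columns:", paste(need, collapse = ", ")))
    else {
      for (r in which(!det$y %in% c(0, 1)))
        add("detections", r, paste0("y must be 0/1, got ", det$y[r]))
      for (r in which(!det$period %in% periods))
        add("detections", r, paste0("unknown period '", det$period[r], "'"))
    }
  }
  if (!is.null(sites)) {
    sites <- load_tab(sites)
    need <- setdiff(c("site", "stratum"), names(sites))
    if (length(need))
      add("sites", NA, paste("missing columns:", paste(need, collapse = ", ")))
    else
      for (r in which(!sites$stratum %in% strata))
        add("sites", r, paste0("unknown stratum '", sites$stratum[r], "'"))
  }
  if (length(errs)) do.call(rbind, errs) else
    data.frame(table = character(), row = integer(), message = character(),
               stringsAsFactors = FALSE)
}

#' Run the full survey analysis pipeline
#'
#' Executes simulate (or ingest) -> segment -> habitats -> behavior ->
#' occupancy, collecting a manifest (seed, package version, per-stage row
#' counts and wall time) and a combined report.  Any stage failure halts
#' with the stage name.  The manifest embeds the full configuration, so
#' `run_pipeline(manifest$config)` reproduces the run bit-compatibly.
#'
#' @param config A [pipeline_config()], a list of its arguments, or a YAML
#'   path.
#' @return List of class `pipeline_result`: `counts`, `habitat`,
#'   `clustering`, `logistic` (one fit per native species), `occupancy`
#'   (fit + summary), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)

  manifest <- list(seed = config$seed,
                   version = as.character(utils::packageVersion("islandcall")),
                   config = unclass(config), stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    list(result = res, elapsed = proc.time()[["elapsed"]] - t0)
  }
  note_stage <- function(name, status, rows, elapsed, note = NULL) {
    manifest$stages[[name]] <<- list(status = status, rows = rows,
                                     elapsed = round(elapsed, 3),
                                     note = note)
  }

  profiles <- species_profiles()
  ingest <- !is.null(config$inputs)

  # -- stage 1: simulate or ingest ------------------------------------------
  if (!ingest) {
    st <- t_stage("simulate", {
      simulate_community(design = do.call(study_design, config$design),
                         profiles = profiles, seed = config$seed,
                         coupling = config$coupling,
                         activity_sd = config$activity_sd)
    })
    sim <- st$result
    note_stage("simulate", "complete", nrow(sim$streams), st$elapsed)
    schedule <- sim$frame
  } else {
    st <- t_stage("simulate", {
      v <- validate_inputs(counts = config$inputs$counts,
                           detections = config$inputs$detections,
                           sites = config$inputs$sites)
      if (nrow(v))
        stop("invalid inputs: ", v$table[1], " row ", v$row[1], ": ",
             v$message[1])
      list(counts = utils::read.csv(config$inputs$counts,
                                    stringsAsFactors = FALSE))
    })
    sim <- NULL
    note_stage("simulate", "ingested", nrow(st$result$counts), st$elapsed)
  }

  # -- stage 2: segment ------------------------------------------------------
  if (!ingest) {
    st <- t_stage("segment", counts_from_streams(sim$streams,
                                                 default_ruleset(), schedule))
    counts <- st$result
    note_stage("segment", "complete", nrow(counts), st$elapsed)
  } else {
    counts <- utils::read.csv(config$inputs$counts, stringsAsFactors = FALSE)
    note_stage("segment", "skipped", nrow(counts), 0,
               note = "counts ingested directly")
  }

  # -- stage 3: habitats -----------------------------------------------------
  st <- t_stage("habitats",
                habitat_table(counts, nested = isTRUE(config$anova$nested),
                              method = config$anova$method %||% "tukey"))
  habitat <- st$result
  note_stage("habitats", "complete", nrow(habitat), st$elapsed)

  # -- stage 4: behavior -----------------------------------------------------
  st <- t_stage("behavior", {
    dm <- detection_matrix(counts)
    dmr <- restrict_to_complete_sites(dm)
    note <- NULL
    clus <- tryCatch(
      hierarchical_cluster(dmr, distance = config$clustering$distance,
                           linkage = config$clustering$linkage),
      error = function(e) {
        note <<- paste("fell back to jaccard distance:", conditionMessage(e))
        hierarchical_cluster(dmr, distance = "jaccard",
                             linkage = config$clustering$linkage)
      })
    natives <- profiles$name[profiles$native]
    nonnatives <- profiles$name[!profiles$native]
    natives <- intersect(natives, colnames(dmr$x))
    fits <- lapply(natives, function(sp)
      logistic_native_vs_nonnative(dmr, sp, nonnatives,
                                   predictor =
                                     config$logistic$predictor %||% "richness",
                                   counts = counts))
    names(fits) <- natives
    list(matrix = dmr, clustering = clus, logistic = fits, note = note)
  })
  behavior <- st$result
  note_stage("behavior", "complete", nrow(behavior$matrix$x), st$elapsed,
             note = behavior$note)

  # -- stage 5: occupancy ----------------------------------------------------
  st <- t_stage("occupancy", {
    od <- if (!ingest) as_occupancy_data(sim) else
      occupancy_data_from_csv(config$inputs$detections, config$inputs$sites)
    cfg <- do.call(mcmc_config, c(config$mcmc, list(seed = config$seed)))
    fit <- run_mcmc(od, cfg)
    list(data = od, fit = fit, summary = summarize_posterior(fit))
  })
  occupancy <- st$result
  note_stage("occupancy", "complete",
             nrow(occupancy$summary$parameters), st$elapsed)

  out <- structure(list(counts = counts, habitat = habitat,
                        clustering = behavior$clustering,
                        logistic = behavior$logistic,
                        occupancy = occupancy, sim = sim,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                       row.names = FALSE)
  w(result$counts, "call_counts.csv")
  w(result$habitat, "habitat_table.csv")
  hc <- result$clustering$hclust
  w(data.frame(merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
               height = hc$height), "linkage.csv")
  w(data.frame(species = names(result$clustering$partition),
               group = unname(result$clustering$partition)),
    "cluster_partition.csv")
  jsonlite::write_json(
    lapply(result$logistic, function(f)
      list(target = f$target, slope = f$slope, se = f$se, p = f$p,
           converged = f$converged)),
    file.path(dir, "logistic_fits.json"), auto_unbox = TRUE, digits = NA)
  w(result$occupancy$summary$parameters, "posterior_summary.csv")
  w(result$occupancy$summary$species, "occupancy_species.csv")
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run (seed ", x$manifest$seed, ")\n", sep = "")
  for (nm in names(x$manifest$stages)) {
    s <- x$manifest$stages[[nm]]
    cat(sprintf("  %-9s %-9s rows=%-6s %.2fs\n", nm, s$status,
                s$rows, s$elapsed))
  }
  invisible(x)
}
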