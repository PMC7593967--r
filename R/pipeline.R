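# End-to-end pipeline driver: simulate (optional) -> metrics -> classify ->
# compete -> partition, with a single master seed spawning named sub-streams
# per stage so every stage is independently reproducible, and a manifest
# recording the configuration and per-stage seeds.

#' Run the full invasion-analysis pipeline
#'
#' Executes every analysis stage on either a synthetic scenario (which is
#' generated first) or a set of input tables, writing TSV/JSON artifacts to
#' `outdir`. Identical inputs, configuration and seed produce byte-identical
#' outputs.
#'
#' @param scenario An [invasion_scenario()] to simulate, or `NULL` when
#'   `inputs` is given.
#' @param inputs Named list of file paths (`otus`, `meta`, `taxonomy`,
#'   `functioning`) read with the package readers; ignored when `scenario`
#'   is given.
#' @param config Configuration list from [read_config()]; `config$seed`
#'   seeds every stochastic stage, `config$depths` gives the rarefaction
#'   depths (the first is the reporting depth).
#' @param outdir Output directory (created if needed). `NULL` skips writing.
#' @param organism Organism group label used for competitor reporting.
#' @return Invisibly, a list with `dataset`, `metrics`, `classification`
#'   (per depth), `aggregate`, `gtest` (when >= 2 depths), `competitors`,
#'   `partition` (per environment x response), `contrasts`
#'   (invaded-vs-control tests) and `manifest`.
#' @export
run_pipeline <- function(scenario = NULL, inputs = NULL,
                         config = read_config(), outdir = NULL,
                         organism = "bacteria") {
  stage <- "setup"
  on_fail <- function(e) {
    stop_invasim("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  }
  tryCatch({
    stage <- "simulate"
    dataset <- if (!is.null(scenario)) {
      generate_dataset(scenario)
    } else {
      if (is.null(inputs) || !all(c("otus", "meta") %in% names(inputs))) {
        stop("need a scenario or inputs with at least 'otus' and 'meta'")
      }
      list(otus = read_otu_table(inputs$otus),
           meta = read_metadata(inputs$meta),
           taxonomy = if (!is.null(inputs$taxonomy)) read_taxonomy(inputs$taxonomy),
           functioning = if (!is.null(inputs$functioning)) read_functioning(inputs$functioning),
           truth = NULL)
    }

    stage <- "validate"
    report <- validate_dataset(dataset$otus, dataset$meta, dataset$taxonomy)
    if (!report$pass) {
      stop("dataset validation failed: ", paste(report$errors, collapse = "; "))
    }

    depth0 <- config$depths[1]
    seed <- config$seed

    stage <- "metrics"
    rar <- suppressWarnings(rarefy(dataset$otus, depth0,
                                   seed = derive_seed(seed, "metrics")))
    metrics <- data.frame(sample_id = rownames(rar),
                          richness = richness(rar),
                          shannon = shannon(rar),
                          stringsAsFactors = FALSE, row.names = NULL)

    stage <- "classify"
    events <- build_events(dataset$meta)
    classification <- lapply(config$depths, function(dd) {
      classify_events(dataset$otus, events, depth = dd,
                      n_reps = config$n_rarefactions,
                      seed = derive_seed(seed, "classify", dd))
    })
    names(classification) <- as.character(config$depths)
    aggregate <- aggregate_events(classification[[1]])
    gtest <- if (length(config$depths) >= 2) {
      depth_robustness_gtest(classification)
    }

    stage <- "compete"
    competitors <- if (!is.null(dataset$taxonomy)) {
      scores_by_depth <- lapply(classification, function(res) {
        score_competitors(suppressWarnings(collect_instances(
          res, dataset$taxonomy,
          min_confidence = config$min_family_confidence)))
      })
      competitor_report(scores_by_depth, organism = organism,
                        threshold = config$competitor_threshold)
    }

    stage <- "partition"
    partition <- list()
    contrasts <- list()
    meta <- dataset$meta
    for (env in unique(meta$environment)) {
      inv <- meta[meta$environment == env & meta$role == "final_invaded", ]
      design <- data.frame(dose = factor(inv$dose),
                           frequency = factor(inv$frequency),
                           invader = factor(inv$invader_id),
                           resident = factor(inv$resident_id))
      full_terms <- c(DESIGN_FACTORS,
                      utils::combn(DESIGN_FACTORS, 2, paste, collapse = ":"))
      # univariate responses: functioning + richness
      responses <- list()
      if (!is.null(dataset$functioning)) {
        fun <- dataset$functioning[match(inv$sample_id, dataset$functioning$sample_id), ]
        responses$co2_total <- fun$co2_total
        responses$doc <- fun$doc
      }
      rich_all <- metrics$richness[match(inv$sample_id, metrics$sample_id)]
      if (!anyNA(rich_all)) responses$richness <- as.numeric(rich_all)
      for (resp in names(responses)) {
        full <- anova_factorial(responses[[resp]], design, terms = full_terms)
        red <- reduce_model(full, alpha = config$alpha)
        partition[[paste(env, resp, sep = ".")]] <-
          list(environment = env, response = resp, model_type = "ANOVA",
               full = full$table, retained = red$retained %||% character(0),
               reduced = red$table,
               percent = as.data.frame(variance_components_anova(red)))
      }
      # multivariate composition on the rarefied final invaded communities
      inv_rar_ids <- intersect(inv$sample_id, rownames(rar))
      if (length(inv_rar_ids) >= 8) {
        idx <- match(inv_rar_ids, inv$sample_id)
        bc <- bray_curtis(rar[inv_rar_ids, , drop = FALSE])
        full <- permanova(bc, design[idx, , drop = FALSE], terms = full_terms,
                          n_perm = config$n_permutations,
                          seed = derive_seed(seed, "permanova", env))
        red <- reduce_model(full, alpha = config$alpha)
        partition[[paste(env, "composition", sep = ".")]] <-
          list(environment = env, response = "composition",
               model_type = "PERMANOVA",
               full = full$table, retained = red$retained %||% character(0),
               reduced = red$table,
               percent = as.data.frame(variance_components_permanova(red)))
      }
      # invaded-vs-control contrasts
      finals <- meta[meta$environment == env & meta$role %in% MICROCOSM_ROLES, ]
      grp <- ifelse(finals$role == "final_invaded", "invaded", finals$role)
      if (!is.null(dataset$functioning)) {
        fun <- dataset$functioning[match(finals$sample_id,
                                         dataset$functioning$sample_id), ]
        for (resp in c("co2_total", "doc")) {
          contrasts[[paste(env, resp, sep = ".")]] <-
            c(list(environment = env, response = resp),
              one_way_anova(fun[[resp]], grp))
        }
      }
      fin_rar_ids <- intersect(finals$sample_id, rownames(rar))
      if (length(fin_rar_ids) >= 8) {
        bc <- bray_curtis(rar[fin_rar_ids, , drop = FALSE])
        contrasts[[paste(env, "composition", sep = ".")]] <- list(
          environment = env, response = "composition",
          pairwise = suppressWarnings(pairwise_permanova(
            bc, grp[match(fin_rar_ids, finals$sample_id)],
            n_perm = config$n_permutations,
            seed = derive_seed(seed, "pairwise", env))))
      }
    }

    stage <- "report"
    manifest <- list(package = "invasim",
                     version = as.character(utils::packageVersion("invasim")),
                     config = config,
                     stage_seeds = list(
                       metrics = derive_seed(seed, "metrics"),
                       classify = lapply(stats::setNames(nm = as.character(config$depths)),
                                         function(dd) derive_seed(seed, "classify", dd)),
                       permanova = lapply(stats::setNames(nm = unique(meta$environment)),
                                          function(e) derive_seed(seed, "permanova", e))),
                     n_samples = nrow(dataset$otus), n_otus = ncol(dataset$otus),
                     n_events = length(events))

    out <- list(dataset = dataset, metrics = metrics,
                classification = classification, aggregate = aggregate,
                gtest = gtest, competitors = competitors,
                partition = partition, contrasts = contrasts,
                manifest = manifest)
    if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
    invisible(out)
  }, error = on_fail)
}

# Flatten per-event classification results into TSV-friendly tables.
event_summary_table <- function(results) {
  do.call(rbind, lapply(results, function(s) {
    data.frame(event_id = s$event_id, depth = s$depth,
               n_rarefactions = s$n_rarefactions,
               category = names(s$percent),
               percent_mean = as.numeric(s$percent),
               percent_sd = as.numeric(s$percent_sd),
               relabund_mean = as.numeric(s$relabund[names(s$percent)]),
               relabund_sd = as.numeric(s$relabund_sd[names(s$percent)]),
               n_otus_universe = s$n_otus_universe,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

assignment_table <- function(results) {
  do.call(rbind, lapply(results, function(s) {
    data.frame(event_id = s$event_id, otu_id = s$otu$otu_id,
               category = s$otu$modal_category,
               mean_final_relabund = s$otu$mean_relabund_final,
               fraction_of_rarefactions_in_category = s$otu$fraction_modal,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(out$dataset, "invasion_dataset")) {
    write_dataset(out$dataset, file.path(outdir, "data"))
  }
  write_tsv(out$metrics, file.path(outdir, "metrics.tsv"))
  for (dd in names(out$classification)) {
    write_tsv(event_summary_table(out$classification[[dd]]),
              file.path(outdir, paste0("event_summaries_", dd, ".tsv")))
  }
  write_tsv(assignment_table(out$classification[[1]]),
            file.path(outdir, "assignments.tsv"))
  write_tsv(out$aggregate, file.path(outdir, "aggregate.tsv"))
  if (!is.null(out$competitors)) {
    write_tsv(out$competitors, file.path(outdir, "competitors.tsv"))
  }
  strip <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  jsonlite::write_json(strip(out$partition), file.path(outdir, "partition.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(strip(out$contrasts), file.path(outdir, "contrasts.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(out$gtest)) {
    g <- out$gtest
    jsonlite::write_json(list(statistic = g$statistic, df = g$df,
                              p_value = g$p_value),
                         file.path(outdir, "gtest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(out$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
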