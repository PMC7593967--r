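# Synthetic factorial invasion-experiment generator.
#
# Emulates the post-OTU-clustering state of a two-environment microcosm
# coalescence experiment: four source communities (MC1-MC4) per environment,
# invasions of two resident communities by the four inocula at two doses and
# two introduction frequencies, with resident-resident and killed-inoculum
# controls, inoculum and initial-resident sequencing samples, planted
# ground-truth invasion outcomes per OTU, and scalar functioning responses
# (CO2, DOC) whose per-factor variance shares are planted exactly.

#' Construct a synthetic-scenario definition
#'
#' All downstream generator behaviour is controlled by this object; the
#' defaults describe the standard study design (two environments, four
#' invader communities, two residents, two doses, two frequencies, three
#' replicates; 240 microcosms in total, 144 of them invaded finals).
#'
#' @param n_otus_per_pool Number of OTUs in each source community (pool).
#' @param pool_overlap Fraction of each pool shared among MC1-MC4.
#' @param abund_sdlog Log-normal sdlog for within-pool relative abundances
#'   (heavy tail, so near-detection-limit taxa occur naturally).
#' @param establishment_prob Per-introduction probability that an
#'   inoculum-only OTU establishes in the final community (low dose).
#' @param dose_effect Multiplier on `establishment_prob` for a high dose.
#' @param displacement_prob Probability that a resident OTU is lost from the
#'   final community of an invasion event.
#' @param invader_boost Relative growth factor applied to an established
#'   invader's inoculum abundance when it joins the final community.
#' @param depth_mean Expected library size; realised sizes are uniform on
#'   `[0.8, 1.2] * depth_mean`.
#' @param n_replicates Replicate microcosms per treatment cell.
#' @param n_inoculum_samples Sequencing replicates per invader inoculum.
#' @param n_initial_resident_samples Initial (pre-invasion) resident
#'   sequencing samples per resident community.
#' @param environments Environments to generate (`"litter"`, `"agar"`).
#' @param variance_shares Named fractions summing to 1 over
#'   `dose, frequency, invader, resident`, optional interaction terms such
#'   as `"invader:resident"`, and `residual`; planted exactly (sequential
#'   sums of squares) into the functioning responses.
#' @param noise_sd Residual standard deviation of the functioning model.
#' @param co2_mean,doc_mean Grand means of the two functioning responses
#'   (arbitrary units).
#' @param control_offset Fractional shift of control-microcosm functioning
#'   relative to the invaded grand mean.
#' @param seed Master seed; every stream the generator uses is derived from
#'   it, so identical scenarios reproduce byte-identical datasets.
#' @return A validated list of class `invasion_scenario`.
#' @export
invasion_scenario <- function(n_otus_per_pool = 250,
                              pool_overlap = 0.4,
                              abund_sdlog = 1.5,
                              establishment_prob = 0.015,
                              dose_effect = 2,
                              displacement_prob = 0.45,
                              invader_boost = 3,
                              depth_mean = 15000,
                              n_replicates = 3,
                              n_inoculum_samples = 7,
                              n_initial_resident_samples = 3,
                              environments = c("litter", "agar"),
                              variance_shares = c(dose = 0.1, frequency = 0,
                                                  invader = 0.6, resident = 0.2,
                                                  residual = 0.1),
                              noise_sd = 1,
                              co2_mean = 100,
                              doc_mean = 50,
                              control_offset = -0.15,
                              seed = 1L) {
  sc <- list(n_otus_per_pool = as.integer(n_otus_per_pool),
             pool_overlap = pool_overlap, abund_sdlog = abund_sdlog,
             establishment_prob = establishment_prob, dose_effect = dose_effect,
             displacement_prob = displacement_prob, invader_boost = invader_boost,
             depth_mean = depth_mean, n_replicates = as.integer(n_replicates),
             n_inoculum_samples = as.integer(n_inoculum_samples),
             n_initial_resident_samples = as.integer(n_initial_resident_samples),
             environments = match.arg(environments, ENVIRONMENTS, several.ok = TRUE),
             variance_shares = variance_shares, noise_sd = noise_sd,
             co2_mean = co2_mean, doc_mean = doc_mean,
             control_offset = control_offset, seed = as.integer(seed))
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  assert_that(sc$n_otus_per_pool >= 2, "n_otus_per_pool must be >= 2")
  for (p in c("pool_overlap", "establishment_prob", "displacement_prob")) {
    assert_that(sc[[p]] >= 0 && sc[[p]] <= 1,
                paste0(p, " must be a probability in [0, 1]"))
  }
  assert_that(sc$establishment_prob * sc$dose_effect <= 1,
              "establishment_prob * dose_effect must not exceed 1")
  assert_that(sc$noise_sd > 0, "noise_sd must be positive")
  assert_that(sc$depth_mean > 0, "depth_mean must be positive")
  vs <- sc$variance_shares
  assert_that(!is.null(names(vs)) && "residual" %in% names(vs),
              "variance_shares must be named and include 'residual'")
  assert_that(all(vs >= 0), "variance_shares must be non-negative")
  assert_that(abs(sum(vs) - 1) < 1e-9, "variance_shares must sum to 1")
  structure(sc, class = "invasion_scenario")
}

#' Generate source-community relative-abundance profiles
#'
#' For each environment, builds MC1-MC4 as log-normal relative-abundance
#' profiles over a pool of OTUs of which a fraction `pool_overlap` is shared
#' by all four communities (so the pairwise shared-taxon fraction equals
#' `pool_overlap` by construction) and the rest is community-specific.
#'
#' @param scenario An [invasion_scenario()].
#' @return Named list (one element per environment) of 4 x n_OTUs matrices
#'   of relative abundances; rows `MC1..MC4` each sum to 1, zero outside the
#'   community's support.
#' @export
generate_pools <- function(scenario) {
  scenario <- validate_scenario(scenario)
  n <- scenario$n_otus_per_pool
  n_shared <- round(scenario$pool_overlap * n)
  n_unique <- n - n_shared
  pools <- list()
  for (env in scenario$environments) {
    n_total <- n_shared + 4L * n_unique
    otu_ids <- sprintf("OTU_%s_%05d", env, seq_len(n_total))
    prof <- matrix(0, nrow = 4, ncol = n_total,
                   dimnames = list(COMMUNITIES, otu_ids))
    shared_idx <- seq_len(n_shared)
    pools[[env]] <- with_seed(derive_seed(scenario$seed, "pools", env), {
      for (i in seq_along(COMMUNITIES)) {
        own_idx <- if (n_unique > 0) {
          n_shared + (i - 1L) * n_unique + seq_len(n_unique)
        } else integer()
        support <- c(shared_idx, own_idx)
        ab <- stats::rlnorm(length(support), meanlog = 0,
                            sdlog = scenario$abund_sdlog)
        prof[i, support] <- ab / sum(ab)
      }
      prof
    })
  }
  pools
}

dose_establishment_prob <- function(scenario, dose, frequency) {
  p1 <- scenario$establishment_prob *
    if (identical(dose, "high")) scenario$dose_effect else 1
  p1 <- min(1, p1)
  1 - (1 - p1)^as.integer(as.character(frequency))
}

#' Simulate one invasion treatment
#'
#' Inoculum-only OTUs establish with probability
#' `establishment_prob * dose_effect(dose)` per introduction (so a 4x
#' frequency gives four establishment opportunities); resident OTUs are
#' displaced with probability `displacement_prob`; OTUs present in both
#' source communities become `common` when retained. The final profile mixes
#' retained resident abundances with `invader_boost`-scaled inoculum
#' abundances of established invaders, renormalised to the simplex.
#'
#' @param scenario An [invasion_scenario()].
#' @param resident_profile,invader_profile Named relative-abundance vectors
#'   (simplex) of the resident community and the invader inoculum.
#' @param dose `"high"` or `"low"`.
#' @param frequency Number of introductions (1 or 4).
#' @param displaced Optional character vector of resident OTUs to displace
#'   (drawn internally when `NULL`); lets several treatments of one event
#'   share a single event-level displacement draw.
#' @param seed Optional seed for the stochastic draws.
#' @return List with `final_profile` (named simplex vector over the union of
#'   supports), `labels` (named category per source OTU: invader,
#'   noninvasive, resilient, nonresilient or common), `established`,
#'   `displaced`.
#' @export
simulate_event <- function(scenario, resident_profile, invader_profile,
                           dose = "high", frequency = 1, displaced = NULL,
                           seed = NULL) {
  scenario <- validate_scenario(scenario)
  for (prof in list(resident_profile, invader_profile)) {
    assert_that(!is.null(names(prof)) && all(prof >= 0) &&
                  abs(sum(prof) - 1) < 1e-8,
                "profiles must be named non-negative vectors summing to 1")
  }
  r_support <- names(resident_profile)[resident_profile > 0]
  i_support <- names(invader_profile)[invader_profile > 0]
  invader_only <- setdiff(i_support, r_support)
  shared <- intersect(i_support, r_support)
  resident_only <- setdiff(r_support, i_support)

  p_est <- dose_establishment_prob(scenario, dose, frequency)
  draws <- with_seed(seed, {
    est <- invader_only[stats::runif(length(invader_only)) < p_est]
    disp <- if (is.null(displaced)) {
      r_support[stats::runif(length(r_support)) < scenario$displacement_prob]
    } else intersect(displaced, r_support)
    list(established = est, displaced = disp)
  })
  established <- draws$established
  displaced <- draws$displaced
  kept <- setdiff(r_support, displaced)

  labels <- c(
    stats::setNames(ifelse(invader_only %in% established, "invader", "noninvasive"),
                    invader_only),
    stats::setNames(ifelse(resident_only %in% kept, "resilient", "nonresilient"),
                    resident_only),
    stats::setNames(ifelse(shared %in% kept, "common", "nonresilient"), shared)
  )

  universe <- union(names(resident_profile), names(invader_profile))
  final <- stats::setNames(numeric(length(universe)), universe)
  final[kept] <- resident_profile[kept]
  final[established] <- final[established] +
    scenario$invader_boost * invader_profile[established]
  if (sum(final) > 0) final <- final / sum(final)

  list(final_profile = final, labels = labels,
       established = established, displaced = displaced)
}

#' Draw sequencing counts from a community profile
#'
#' Multinomial read sampling: `depth` reads distributed over taxa with
#' probabilities given by the relative-abundance profile.
#'
#' @param profile Named simplex vector.
#' @param depth Positive integer library size.
#' @param seed Optional seed.
#' @return Named integer count vector summing to `depth`.
#' @export
sample_counts <- function(profile, depth, seed = NULL) {
  assert_that(length(depth) == 1 && depth > 0 && depth == round(depth),
              "depth must be a positive integer")
  assert_that(all(profile >= 0) && abs(sum(profile) - 1) < 1e-8,
              "profile must be non-negative and sum to 1")
  counts <- with_seed(seed, stats::rmultinom(1, size = depth, prob = profile))
  stats::setNames(as.integer(counts), names(profile))
}

# Library size for one sample: uniform within +/-20% of depth_mean.
draw_depth <- function(scenario, seed) {
  with_seed(seed, as.integer(round(stats::runif(1, 0.8, 1.2) * scenario$depth_mean)))
}

# Synthetic taxonomy for a set of OTU ids: ~40 families, each mapped to a
# fixed synthetic higher-rank lineage; family confidence mostly >= 70 with a
# low-confidence tail exercising the competitor-scoring filter.
generate_taxonomy <- function(otu_ids, seed, n_families = 40) {
  with_seed(seed, {
    fam_pool <- sprintf("Family_%02d", seq_len(n_families))
    fam <- sample(fam_pool, length(otu_ids), replace = TRUE)
    fam_idx <- match(fam, fam_pool)
    low_conf <- stats::runif(length(otu_ids)) < 0.12
    conf <- ifelse(low_conf, stats::runif(length(otu_ids), 30, 70),
                   stats::runif(length(otu_ids), 70, 100))
    data.frame(
      otu_id = otu_ids,
      domain = "Bacteria",
      phylum = sprintf("Phylum_%02d", (fam_idx - 1L) %/% 8L + 1L),
      class = sprintf("Class_%02d", (fam_idx - 1L) %/% 4L + 1L),
      order = sprintf("Order_%02d", (fam_idx - 1L) %/% 2L + 1L),
      family = fam,
      genus = sprintf("Genus_%03d", match(otu_ids, otu_ids)),
      family_confidence = round(conf, 1),
      stringsAsFactors = FALSE
    )
  })
}

# Plant factor effects into a response so that the sequential (Type I) sum
# of squares of each named term equals exactly its share of the total SS.
# Terms are entered in the canonical order (dose, frequency, invader,
# resident, then interactions); the residual vector is orthogonalised
# against the full four-way model space so unplanted terms get SS exactly 0.
plant_functioning_response <- function(design, shares, grand_mean, noise_sd, seed) {
  n <- nrow(design)
  canonical <- c("dose", "frequency", "invader", "resident")
  extra <- setdiff(names(shares), c(canonical, "residual"))
  term_labels <- c(canonical, extra)
  residual_share <- shares[["residual"]]
  total_var <- if (residual_share > 0) noise_sd^2 / residual_share else 1
  ss_total <- (n - 1) * total_var

  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(term_labels, collapse = "+"))), design)
  asgn <- attr(mm, "assign")
  Q <- qr.Q(qr(mm))
  mm_full <- stats::model.matrix(~ dose * frequency * invader * resident, design)
  Qf <- qr.Q(qr(mm_full))

  with_seed(seed, {
    y <- rep(grand_mean, n)
    for (j in seq_along(term_labels)) {
      s <- shares[term_labels[j]]
      if (is.na(s) || s == 0) next
      idx <- which(asgn == j)
      v <- Q[, idx, drop = FALSE] %*% stats::rnorm(length(idx))
      y <- y + drop(v) / sqrt(sum(v^2)) * sqrt(s * ss_total)
    }
    e <- stats::rnorm(n)
    e <- e - drop(Qf %*% crossprod(Qf, e))
    if (residual_share > 0) {
      y <- y + e / sqrt(sum(e^2)) * sqrt(residual_share * ss_total)
    }
    y
  })
}

# Merge treatment-level labels into one event-level truth label per OTU:
# presence in ANY treatment's final community wins (matching the pooled
# any-sample presence rule used by the classifier).
merge_truth_labels <- function(label_list) {
  otus <- unique(unlist(lapply(label_list, names)))
  out <- character(length(otus))
  names(out) <- otus
  lab_mat <- vapply(label_list, function(l) l[otus], character(length(otus)))
  for (k in seq_along(otus)) {
    labs <- lab_mat[k, ]
    out[k] <- if ("invader" %in% labs) "invader"
    else if ("common" %in% labs) "common"
    else if ("resilient" %in% labs) "resilient"
    else if (all(labs == "noninvasive")) "noninvasive"
    else "nonresilient"
  }
  out
}

#' Generate a complete synthetic invasion-experiment dataset
#'
#' Produces everything the analysis pipeline consumes: an OTU count table
#' covering invader-inoculum, initial-resident, final invaded,
#' resident-resident and killed-inoculum samples across the factorial
#' design; sample metadata; a taxonomy table; per-microcosm functioning
#' (CO2, DOC) with exactly planted variance shares; and per-event
#' ground-truth invasion categories.
#'
#' @param scenario An [invasion_scenario()].
#' @return List of class `invasion_dataset` with elements `otus` (integer
#'   matrix, samples x OTUs), `meta`, `taxonomy`, `functioning`, `truth`
#'   (data frame: event_id, otu_id, category), `pools`, and `scenario`.
#' @export
generate_dataset <- function(scenario) {
  scenario <- validate_scenario(scenario)
  pools <- generate_pools(scenario)
  all_otus <- unlist(lapply(pools, colnames), use.names = FALSE)
  taxonomy <- generate_taxonomy(all_otus, derive_seed(scenario$seed, "taxonomy"))

  meta_rows <- list()
  count_rows <- list()
  truth_rows <- list()

  add_samples <- function(ids, env, role, resident, invader, dose, freq,
                          profile) {
    for (r in seq_along(ids)) {
      meta_rows[[length(meta_rows) + 1]] <<- data.frame(
        sample_id = ids[r], environment = env, role = role,
        resident_id = resident, invader_id = invader, dose = dose,
        frequency = freq, replicate = r, stringsAsFactors = FALSE)
      depth <- draw_depth(scenario, derive_seed(scenario$seed, "depth", ids[r]))
      count_rows[[ids[r]]] <<- sample_counts(
        profile, depth, seed = derive_seed(scenario$seed, "counts", ids[r]))
    }
  }

  for (env in scenario$environments) {
    prof <- pools[[env]]
    residents <- COMMUNITIES[1:2]
    # invader inoculum sequencing replicates (all four communities)
    for (mc in COMMUNITIES) {
      ids <- sprintf("%s_inoc_%s_r%d", env, mc, seq_len(scenario$n_inoculum_samples))
      add_samples(ids, env, "invader_inoculum", "none", mc, "none", "none",
                  prof[mc, ])
    }
    for (res in residents) {
      # initial (pre-invasion) resident samples
      ids <- sprintf("%s_init_%s_r%d", env, res,
                     seq_len(scenario$n_initial_resident_samples))
      add_samples(ids, env, "resident_initial", res, "none", "none", "none",
                  prof[res, ])
      for (inv in COMMUNITIES) {
        if (inv == res) {
          # resident-resident controls across the dose x frequency grid
          for (dose in c("high", "low")) for (freq in c("1", "4")) {
            ids <- sprintf("%s_rr_%s_%s_f%s_r%d", env, res, dose, freq,
                           seq_len(scenario$n_replicates))
            add_samples(ids, env, "final_resident_resident", res, inv, dose,
                        freq, prof[res, ])
          }
          # killed-inoculum control (high dose, 4x frequency)
          ids <- sprintf("%s_kill_%sin%s_r%d", env, inv, res,
                         seq_len(scenario$n_replicates))
          add_samples(ids, env, "final_killed_resident", res, inv, "killed",
                      "4", prof[res, ])
        } else {
          # one invasion event: shared displacement draw, per-treatment
          # establishment, pooled event-level truth
          event_id <- sprintf("%s_%s-%s", env, inv, res)
          r_support <- colnames(prof)[prof[res, ] > 0]
          displaced <- with_seed(
            derive_seed(scenario$seed, "displace", event_id),
            r_support[stats::runif(length(r_support)) < scenario$displacement_prob])
          treatment_labels <- list()
          for (dose in c("high", "low")) for (freq in c("1", "4")) {
            ev <- simulate_event(scenario, prof[res, ], prof[inv, ],
                                 dose = dose, frequency = freq,
                                 displaced = displaced,
                                 seed = derive_seed(scenario$seed, "establish",
                                                    event_id, dose, freq))
            treatment_labels[[paste(dose, freq)]] <- ev$labels
            ids <- sprintf("%s_inv_%sin%s_%s_f%s_r%d", env, inv, res, dose,
                           freq, seq_len(scenario$n_replicates))
            add_samples(ids, env, "final_invaded", res, inv, dose, freq,
                        ev$final_profile)
          }
          labels <- merge_truth_labels(treatment_labels)
          truth_rows[[event_id]] <- data.frame(
            event_id = event_id, otu_id = names(labels), category = labels,
            stringsAsFactors = FALSE, row.names = NULL)
          # killed-inoculum control for this invader into this resident
          ids <- sprintf("%s_kill_%sin%s_r%d", env, inv, res,
                         seq_len(scenario$n_replicates))
          add_samples(ids, env, "final_killed_resident", res, inv, "killed",
                      "4", prof[res, ])
        }
      }
    }
  }

  meta <- validate_metadata(do.call(rbind, meta_rows))
  otus <- matrix(0L, nrow = length(count_rows), ncol = length(all_otus),
                 dimnames = list(names(count_rows), all_otus))
  for (sid in names(count_rows)) {
    cc <- count_rows[[sid]]
    otus[sid, names(cc)] <- cc
  }
  otus <- validate_otu_table(otus)

  # functioning: exact variance shares on invaded finals, offset controls
  inv_meta <- meta[meta$role == "final_invaded", ]
  design <- data.frame(dose = factor(inv_meta$dose),
                       frequency = factor(inv_meta$frequency),
                       invader = factor(inv_meta$invader_id),
                       resident = factor(inv_meta$resident_id))
  ctrl_meta <- meta[meta$role %in% c("final_resident_resident",
                                     "final_killed_resident"), ]
  functioning <- data.frame(sample_id = c(inv_meta$sample_id, ctrl_meta$sample_id),
                            stringsAsFactors = FALSE)
  for (resp in c("co2_total", "doc")) {
    grand <- if (resp == "co2_total") scenario$co2_mean else scenario$doc_mean
    y_inv <- plant_functioning_response(
      design, scenario$variance_shares, grand, scenario$noise_sd,
      derive_seed(scenario$seed, "functioning", resp))
    y_ctrl <- with_seed(derive_seed(scenario$seed, "functioning_ctrl", resp),
                        grand * (1 + scenario$control_offset) +
                          stats::rnorm(nrow(ctrl_meta), sd = scenario$noise_sd))
    functioning[[resp]] <- pmax(c(y_inv, y_ctrl), 0)
  }
  functioning <- validate_functioning(functioning)

  structure(list(otus = otus, meta = meta, taxonomy = taxonomy,
                 functioning = functioning,
                 truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
                 pools = pools, scenario = scenario),
            class = "invasion_dataset")
}

#' @export
print.invasion_dataset <- function(x, ...) {
  cat(sprintf("synthetic invasion dataset: %d samples x %d OTUs, %d events\n",
              nrow(x$otus), ncol(x$otus), length(unique(x$truth$event_id))))
  print(table(x$meta$role))
  invisible(x)
}

#' Write a synthetic dataset to a directory of TSV files
#'
#' @param dataset An `invasion_dataset` from [generate_dataset()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    otus = file.path(outdir, "otu_table.tsv"),
    meta = file.path(outdir, "metadata.tsv"),
    taxonomy = file.path(outdir, "taxonomy.tsv"),
    functioning = file.path(outdir, "functioning.tsv"),
    truth = file.path(outdir, "truth_labels.tsv"))
  write_otu_table(dataset$otus, paths["otus"])
  write_metadata(dataset$meta, paths["meta"])
  write_taxonomy(dataset$taxonomy, paths["taxonomy"])
  write_functioning(dataset$functioning, paths["functioning"])
  utils::write.table(dataset$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
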