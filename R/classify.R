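# Six-category OTU invasion classification with repeated-rarefaction
# averaging.
#
# For each invasion event (environment x resident x invader), every OTU
# detected in at least one of three pooled presence groups -- invader
# inoculum (I), composite resident control (R: initial resident +
# resident-resident finals + killed-inoculum finals), final invaded
# communities (F) -- is assigned one of six categories by its presence
# pattern across the groups:
#
#   R only          -> nonresilient     (resident lost)
#   I only          -> noninvasive      (inoculum taxon that failed)
#   F only          -> undetermined     (detection-limit artifact)
#   R & F (not I)   -> resilient        (resident that persisted)
#   I & F (not R)   -> invader          (inoculum taxon that established)
#   R & I (not F)   -> nonresilient
#   R & I & F       -> common

CATEGORIES <- c("invader", "noninvasive", "resilient", "nonresilient",
                "common", "undetermined")
FINAL_CATEGORIES <- c("common", "resilient", "invader", "undetermined")

#' Build the invasion events encoded in sample metadata
#'
#' One event per (environment, resident, invader != resident) combination
#' with final invaded samples, following the composite-control rule: the
#' resident control pools initial-resident, resident-resident final and
#' killed-inoculum final samples of that resident. The standard full design
#' yields 12 events, 6 per environment.
#'
#' @param meta Validated sample metadata (see [validate_metadata()]).
#' @return List of `invasion_event` objects, each holding `event_id`,
#'   `environment`, `resident_id`, `invader_id` and the three disjoint
#'   sample-id sets `invader_samples`, `control_samples`, `final_samples`.
#' @export
build_events <- function(meta) {
  meta <- validate_metadata(meta)
  finals <- meta[meta$role == "final_invaded", ]
  combos <- unique(finals[, c("environment", "resident_id", "invader_id")])
  combos <- combos[order(combos$environment, combos$resident_id,
                         combos$invader_id), ]
  events <- list()
  for (k in seq_len(nrow(combos))) {
    env <- combos$environment[k]
    res <- combos$resident_id[k]
    inv <- combos$invader_id[k]
    ev <- structure(list(
      event_id = sprintf("%s_%s-%s", env, inv, res),
      environment = env, resident_id = res, invader_id = inv,
      invader_samples = meta$sample_id[meta$environment == env &
                                         meta$role == "invader_inoculum" &
                                         meta$invader_id == inv],
      control_samples = meta$sample_id[meta$environment == env &
                                         meta$resident_id == res &
                                         meta$role %in% c("resident_initial",
                                                          "final_resident_resident",
                                                          "final_killed_resident")],
      final_samples = meta$sample_id[meta$environment == env &
                                       meta$role == "final_invaded" &
                                       meta$resident_id == res &
                                       meta$invader_id == inv]),
      class = "invasion_event")
    for (grp in c("invader_samples", "control_samples", "final_samples")) {
      if (length(ev[[grp]]) == 0) {
        stop_invasim("event ", ev$event_id, " has no ", grp)
      }
    }
    events[[ev$event_id]] <- ev
  }
  events
}

event_group_rows <- function(counts, event, group) {
  present <- intersect(event[[group]], rownames(counts))
  if (length(present) == 0) {
    stop_invasim("event ", event$event_id, ": no ", group,
                 " remain in the table (all dropped at rarefaction?)")
  }
  present
}

#' Presence sets of an event
#'
#' An OTU belongs to a group's presence set iff its count is >= 1 in at
#' least one sample of that group (the any-sample rule: controls are pooled
#' precisely to strengthen detection).
#'
#' @param counts (Rarefied) OTU matrix.
#' @param event An `invasion_event` from [build_events()].
#' @return List with character vectors `I` (inoculum), `R` (resident
#'   control), `F` (final invaded).
#' @export
presence_sets <- function(counts, event) {
  grp_set <- function(group) {
    rows <- event_group_rows(counts, event, group)
    colnames(counts)[colSums(counts[rows, , drop = FALSE] > 0) > 0]
  }
  list(I = grp_set("invader_samples"),
       R = grp_set("control_samples"),
       F = grp_set("final_samples"))
}

#' Classify OTUs by presence pattern
#'
#' Maps each OTU in `I`, `R` or `F` onto one of the six invasion-outcome
#' categories (see the region table at the top of this file's help index).
#'
#' @param I,R,F Character vectors: OTUs present in the invader inoculum,
#'   resident control, and final invaded communities.
#' @return Named character vector: one category per OTU in the union.
#' @export
classify_otus <- function(I, R, F) {
  universe <- union(union(I, R), F)
  in_i <- universe %in% I
  in_r <- universe %in% R
  in_f <- universe %in% F
  cat <- ifelse(in_f,
                ifelse(in_i & in_r, "common",
                       ifelse(in_i, "invader",
                              ifelse(in_r, "resilient", "undetermined"))),
                ifelse(in_i & !in_r, "noninvasive", "nonresilient"))
  stats::setNames(cat, universe)
}

#' Summarise one classified event on one rarefied table
#'
#' Category percentages use the event's OTU universe |I u R u F| as the
#' denominator (the six categories partition it, so percentages sum to
#' 100). Relative abundances are reported for the four categories that can
#' occur in final communities: each final sample's counts are divided by
#' its depth, summed over the category's member OTUs, then averaged across
#' final samples.
#'
#' @param counts Rarefied OTU matrix the assignment was derived from.
#' @param event An `invasion_event`.
#' @param assignment Named category vector from [classify_otus()].
#' @return List of class `event_summary`: `percent` (named over the six
#'   categories, sums to 100), `relabund` (named over common, resilient,
#'   invader, undetermined; sums to 1), `n_otus_universe`.
#' @export
summarize_event <- function(counts, event, assignment) {
  if (length(assignment) == 0) stop_invasim("empty OTU universe for event ",
                                            event$event_id)
  percent <- 100 * vapply(CATEGORIES, function(cc) mean(assignment == cc),
                          numeric(1))
  finals <- event_group_rows(counts, event, "final_samples")
  fin <- counts[finals, , drop = FALSE]
  rel <- fin / rowSums(fin)
  relabund <- vapply(FINAL_CATEGORIES, function(cc) {
    members <- names(assignment)[assignment == cc]
    if (length(members) == 0) return(0)
    mean(rowSums(rel[, members, drop = FALSE]))
  }, numeric(1))
  structure(list(event_id = event$event_id, percent = percent,
                 relabund = relabund, n_otus_universe = length(assignment)),
            class = "event_summary")
}

# One rarefied pass for one event; returns the summary plus the raw
# assignment and per-OTU group-mean relative abundances.
classify_event_once <- function(rarefied, event) {
  sets <- presence_sets(rarefied, event)
  assignment <- classify_otus(sets$I, sets$R, sets$F)
  summ <- summarize_event(rarefied, event, assignment)
  group_means <- lapply(c(I = "invader_samples", R = "control_samples",
                          F = "final_samples"), function(group) {
    rows <- event_group_rows(rarefied, event, group)
    sub <- rarefied[rows, , drop = FALSE]
    colMeans(sub / rowSums(sub))
  })
  list(summary = summ, assignment = assignment, group_means = group_means)
}

#' Classify an event averaged over repeated rarefactions
#'
#' Repeats rarefy -> presence -> classify -> summarise `n_reps` times with
#' independent sub-seeds and averages. Because category membership can
#' flicker across rarefactions near the detection limit, the per-OTU output
#' records the modal category together with the fraction of rarefactions
#' supporting it.
#'
#' @param counts Full-depth OTU matrix (only the event's samples are used).
#' @param event An `invasion_event`.
#' @param depth Rarefaction depth.
#' @param n_reps Number of rarefaction repetitions (the standard analysis
#'   uses 100).
#' @param seed Master seed; repetition `r` uses an independently derived
#'   sub-seed so it is reproducible in isolation.
#' @return List of class `event_rarefaction_summary`: `percent` and
#'   `percent_sd` (named over the six categories), `relabund` and
#'   `relabund_sd`, `n_otus_universe` (mean), `n_rarefactions`, and `otu` -- a
#'   data frame with per-OTU `modal_category`, `fraction_modal` (of the
#'   rarefactions in which the OTU was in the universe), `n_reps_present`,
#'   and mean relative abundances in the inoculum, control and final groups.
#' @export
average_over_rarefactions <- function(counts, event, depth, n_reps = 100,
                                      seed = NULL) {
  assert_that(n_reps >= 1, "n_reps must be >= 1")
  rows <- unique(c(event$invader_samples, event$control_samples,
                   event$final_samples))
  rows <- intersect(rownames(counts), rows)
  sub <- counts[rows, , drop = FALSE]
  accumulate_event_reps(sub, event, depth, n_reps, seed)
}

# Shared accumulator: runs n_reps rarefactions of `sub` (already restricted
# to the relevant samples) and averages one event's results.
accumulate_event_reps <- function(sub, event, depth, n_reps, seed) {
  n_otu <- ncol(sub)
  percent_mat <- matrix(NA_real_, n_reps, length(CATEGORIES),
                        dimnames = list(NULL, CATEGORIES))
  relabund_mat <- matrix(NA_real_, n_reps, length(FINAL_CATEGORIES),
                         dimnames = list(NULL, FINAL_CATEGORIES))
  universe_n <- numeric(n_reps)
  cat_counts <- matrix(0L, n_otu, length(CATEGORIES),
                       dimnames = list(colnames(sub), CATEGORIES))
  gm <- list(I = numeric(n_otu), R = numeric(n_otu), F = numeric(n_otu))
  for (r in seq_len(n_reps)) {
    rar <- suppressWarnings(
      rarefy(sub, depth, seed = derive_seed(seed, "rarefaction", r)))
    one <- classify_event_once(rar, event)
    percent_mat[r, ] <- one$summary$percent
    relabund_mat[r, ] <- one$summary$relabund
    universe_n[r] <- one$summary$n_otus_universe
    idx <- cbind(match(names(one$assignment), colnames(sub)),
                 match(one$assignment, CATEGORIES))
    cat_counts[idx] <- cat_counts[idx] + 1L
    for (g in names(gm)) gm[[g]] <- gm[[g]] + one$group_means[[g]]
  }
  present <- rowSums(cat_counts) > 0
  modal_idx <- apply(cat_counts[present, , drop = FALSE], 1, which.max)
  n_present <- rowSums(cat_counts)[present]
  otu <- data.frame(
    otu_id = colnames(sub)[present],
    modal_category = CATEGORIES[modal_idx],
    fraction_modal = cat_counts[present, , drop = FALSE][
      cbind(seq_along(modal_idx), modal_idx)] / n_present,
    n_reps_present = as.integer(n_present),
    mean_relabund_inoculum = (gm$I / n_reps)[present],
    mean_relabund_control = (gm$R / n_reps)[present],
    mean_relabund_final = (gm$F / n_reps)[present],
    stringsAsFactors = FALSE, row.names = NULL)
  sd0 <- function(m) {
    if (n_reps == 1) return(stats::setNames(rep(0, ncol(m)), colnames(m)))
    apply(m, 2, stats::sd)
  }
  structure(list(event_id = event$event_id,
                 environment = event$environment,
                 depth = depth, n_rarefactions = n_reps,
                 percent = colMeans(percent_mat), percent_sd = sd0(percent_mat),
                 relabund = colMeans(relabund_mat), relabund_sd = sd0(relabund_mat),
                 n_otus_universe = mean(universe_n), otu = otu),
            class = "event_rarefaction_summary")
}

#' Classify every event of a dataset with shared rarefactions
#'
#' Convenience driver equivalent to calling [average_over_rarefactions()]
#' for each event of [build_events()], subsetting the table to each event's
#' samples.
#'
#' @param counts Full-depth OTU matrix.
#' @param meta Sample metadata (or a pre-built event list).
#' @param depth Rarefaction depth.
#' @param n_reps Rarefaction repetitions.
#' @param seed Master seed; event streams are derived per event id.
#' @return Named list of `event_rarefaction_summary`, one per event.
#' @export
classify_events <- function(counts, meta, depth, n_reps = 100, seed = NULL) {
  events <- if (is.data.frame(meta)) build_events(meta) else meta
  out <- lapply(events, function(ev) {
    average_over_rarefactions(counts, ev, depth, n_reps,
                              seed = derive_seed(seed, "classify", ev$event_id))
  })
  names(out) <- vapply(events, `[[`, character(1), "event_id")
  out
}

#' Aggregate event summaries across the invasion events
#'
#' Per-category mean, sample standard deviation (n-1 denominator), minimum
#' and maximum across events, for both the OTU percentages and (where
#' defined) the final-community relative abundances.
#'
#' @param summaries List of event summaries from [classify_events()] or
#'   [average_over_rarefactions()].
#' @return Data frame, one row per category.
#' @export
aggregate_events <- function(summaries) {
  assert_that(length(summaries) >= 1, "need at least one event summary")
  pc <- t(vapply(summaries, `[[`, numeric(length(CATEGORIES)), "percent"))
  ra <- t(vapply(summaries, `[[`, numeric(length(FINAL_CATEGORIES)), "relabund"))
  sd0 <- function(x) if (length(x) == 1) 0 else stats::sd(x)
  out <- data.frame(
    category = CATEGORIES,
    percent_mean = colMeans(pc), percent_sd = apply(pc, 2, sd0),
    percent_min = apply(pc, 2, min), percent_max = apply(pc, 2, max),
    relabund_mean = NA_real_, relabund_sd = NA_real_,
    relabund_min = NA_real_, relabund_max = NA_real_,
    n_events = length(summaries),
    stringsAsFactors = FALSE, row.names = NULL)
  fi <- match(FINAL_CATEGORIES, out$category)
  out$relabund_mean[fi] <- colMeans(ra)
  out$relabund_sd[fi] <- apply(ra, 2, sd0)
  out$relabund_min[fi] <- apply(ra, 2, min)
  out$relabund_max[fi] <- apply(ra, 2, max)
  out
}

#' G-test of independence
#'
#' Log-likelihood-ratio test on a contingency table:
#' G = 2 sum O log(O/E) with independence expectations, compared to a
#' chi-square distribution on (r-1)(c-1) degrees of freedom.
#'
#' @param x Matrix of non-negative counts with positive row and column
#'   totals.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
g_test <- function(x) {
  x <- as.matrix(x)
  assert_that(all(x >= 0), "counts must be non-negative")
  assert_that(nrow(x) >= 2 && ncol(x) >= 2, "need at least a 2x2 table")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop_invasim("zero marginal total in contingency table")
  }
  expected <- outer(rowSums(x), colSums(x)) / sum(x)
  nz <- x > 0
  g <- 2 * sum(x[nz] * log(x[nz] / expected[nz]))
  df <- (nrow(x) - 1) * (ncol(x) - 1)
  list(statistic = g, df = df,
       p_value = stats::pchisq(g, df, lower.tail = FALSE),
       expected = expected)
}

#' Depth-robustness G-test of the category distribution
#'
#' Tests whether the OTU category distribution is independent of the
#' rarefaction depth. The counts entering the test are the rounded mean
#' per-category OTU counts (percentage x universe size), summed across
#' events, per depth; categories absent at every depth are dropped.
#'
#' @param summaries_by_depth Named list: depth -> list of event summaries.
#' @return As [g_test()], plus the category-by-depth `counts` table.
#' @export
depth_robustness_gtest <- function(summaries_by_depth) {
  assert_that(length(summaries_by_depth) >= 2, "need summaries for >= 2 depths")
  counts <- vapply(summaries_by_depth, function(summaries) {
    per_event <- vapply(summaries, function(s) {
      s$percent / 100 * s$n_otus_universe
    }, numeric(length(CATEGORIES)))
    round(rowSums(per_event))
  }, numeric(length(CATEGORIES)))
  rownames(counts) <- CATEGORIES
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  res <- g_test(counts)
  res$counts <- counts
  res
}
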