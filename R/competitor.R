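# Family-level competitor scoring.
#
# OTU-level invasion outcomes are aggregated to taxonomic families: OTUs
# that succeeded as invaders and/or persisted as residents (resilient)
# contribute to a strong competitor score
#   ( sum_{i=1..k} N_iFinal / N_iInitial ) * k,
# and OTUs that failed (noninvasive) or were lost (nonresilient) contribute
# to a weak competitor score
#   ( sum_{i=1..k} N_iInitial ) * k,
# where k is the number of qualifying (OTU, event) instances in the family
# and N is the mean relative abundance of the OTU in the relevant initial
# (inoculum or resident-control) and final communities. An OTU contributes
# one instance per event, so a taxon resilient in one event and invasive in
# another counts twice -- both outcomes are successful competition.

STRONG_CATEGORIES <- c("invader", "resilient")
WEAK_CATEGORIES <- c("noninvasive", "nonresilient")

#' Collect per-family scoring instances from classified events
#'
#' One instance per (OTU, event) whose modal category across rarefactions is
#' invader/resilient (strong) or noninvasive/nonresilient (weak). The
#' initial abundance of an invader-side instance is its mean relative
#' abundance across the event's inoculum samples; for a resident-side
#' instance, across the composite resident-control samples. OTUs without a
#' family assignment, or with family confidence below `min_confidence`
#' percent, are excluded.
#'
#' Abundances are expressed on the percent scale (0-100): strong scores are
#' abundance-ratio based and therefore scale-free, while weak scores sum
#' initial abundances directly, and on the percent scale the conventional
#' `> 50` reporting threshold is attainable for them.
#'
#' @param results Named list of event summaries from [classify_events()].
#' @param taxonomy Taxonomy data frame (see [validate_taxonomy()]).
#' @param min_confidence Minimum family-level taxonomic confidence
#'   (percent, default 70; an OTU at 69.9 is excluded).
#' @return Data frame with columns `family, environment, event_id, otu_id,
#'   category, n_initial, n_final` (abundances in percent).
#' @export
collect_instances <- function(results, taxonomy, min_confidence = 70) {
  taxonomy <- validate_taxonomy(taxonomy)
  keep_tax <- !is.na(taxonomy$family) & nzchar(taxonomy$family) &
    !is.na(taxonomy$family_confidence) &
    taxonomy$family_confidence >= min_confidence
  fam_of <- stats::setNames(taxonomy$family[keep_tax], taxonomy$otu_id[keep_tax])

  rows <- lapply(results, function(res) {
    otu <- res$otu
    sel <- otu$modal_category %in% c(STRONG_CATEGORIES, WEAK_CATEGORIES)
    otu <- otu[sel, , drop = FALSE]
    fam <- fam_of[otu$otu_id]
    known <- !is.na(fam)
    if (any(!known)) {
      warning(sum(!known), " OTU instance(s) in event ", res$event_id,
              " excluded (no family at >= ", min_confidence, "% confidence)",
              call. = FALSE)
    }
    otu <- otu[known, , drop = FALSE]
    invader_side <- otu$modal_category %in% c("invader", "noninvasive")
    data.frame(
      family = fam[known],
      environment = res$environment,
      event_id = res$event_id,
      otu_id = otu$otu_id,
      category = otu$modal_category,
      n_initial = 100 * ifelse(invader_side, otu$mean_relabund_inoculum,
                               otu$mean_relabund_control),
      n_final = 100 * otu$mean_relabund_final,
      stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Strong competitor score of one family in one environment
#'
#' `(sum_i N_final,i / N_initial,i) * k` over the family's invader and
#' resilient instances.
#'
#' @param instances Data frame of instances (rows for one family in one
#'   environment); only invader/resilient rows are used.
#' @return List with `score`, `k`, and the contributing `categories`.
#' @export
strong_score <- function(instances) {
  inst <- instances[instances$category %in% STRONG_CATEGORIES, , drop = FALSE]
  k <- nrow(inst)
  if (k == 0) return(list(score = NA_real_, k = 0L, categories = character()))
  if (any(inst$n_initial <= 0)) {
    stop_invasim("strong-score instance with zero initial abundance; ",
                 "invader/resilient OTUs must be detected in their initial pool")
  }
  list(score = sum(inst$n_final / inst$n_initial) * k, k = as.integer(k),
       categories = unique(inst$category))
}

#' Weak competitor score of one family in one environment
#'
#' `(sum_i N_initial,i) * k` over the family's noninvasive and nonresilient
#' instances (final abundances are irrelevant: these taxa are absent from
#' the final community).
#'
#' @inheritParams strong_score
#' @return List with `score`, `k`, and the contributing `categories`.
#' @export
weak_score <- function(instances) {
  inst <- instances[instances$category %in% WEAK_CATEGORIES, , drop = FALSE]
  k <- nrow(inst)
  if (k == 0) return(list(score = NA_real_, k = 0L, categories = character()))
  list(score = sum(inst$n_initial) * k, k = as.integer(k),
       categories = unique(inst$category))
}

#' Score every family in every environment
#'
#' @param instances Instance data frame from [collect_instances()].
#' @return Data frame with one row per (family, environment): strong and
#'   weak scores, instance counts `k`, and logical flags for which outcome
#'   categories occurred.
#' @export
score_competitors <- function(instances) {
  assert_that(is.data.frame(instances) && nrow(instances) > 0,
              "no scoring instances")
  out <- do.call(rbind, lapply(
    split(instances, list(instances$family, instances$environment), drop = TRUE),
    function(inst) {
      s <- strong_score(inst)
      w <- weak_score(inst)
      data.frame(family = inst$family[1], environment = inst$environment[1],
                 strong_score = s$score, strong_k = s$k,
                 weak_score = w$score, weak_k = w$k,
                 has_invader = "invader" %in% inst$category,
                 has_resilient = "resilient" %in% inst$category,
                 has_noninvasive = "noninvasive" %in% inst$category,
                 has_nonresilient = "nonresilient" %in% inst$category,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  rownames(out) <- NULL
  out[order(out$family, out$environment), ]
}

#' Strength class of a family
#'
#' Strong competitors are labelled by which successful outcomes occurred
#' (`invader`, `resilient`, `invader_and_resilient`), weak competitors
#' analogously (`noninvasive`, `nonresilient`,
#' `nonresilient_and_noninvasive`); a family qualifying on both the strong
#' and the weak side is `mixed`.
#'
#' @param categories Character vector of instance categories observed for
#'   the family (across its qualifying environments).
#' @param strong_qualifies,weak_qualifies Did the family pass the score
#'   threshold filter on the strong / weak side?
#' @return A single strength-class string.
#' @export
classify_strength <- function(categories, strong_qualifies = TRUE,
                              weak_qualifies = FALSE) {
  if (strong_qualifies && weak_qualifies) return("mixed")
  if (strong_qualifies) {
    has_inv <- "invader" %in% categories
    has_res <- "resilient" %in% categories
    if (has_inv && has_res) return("invader_and_resilient")
    if (has_inv) return("invader")
    if (has_res) return("resilient")
  }
  if (weak_qualifies) {
    has_ni <- "noninvasive" %in% categories
    has_nr <- "nonresilient" %in% categories
    if (has_ni && has_nr) return("nonresilient_and_noninvasive")
    if (has_nr) return("nonresilient")
    if (has_ni) return("noninvasive")
  }
  "mixed"
}

qualifying_families <- function(scores, score_col, envs_required, threshold) {
  ok_by_fam <- tapply(seq_len(nrow(scores)), scores$family, function(idx) {
    sub <- scores[idx, ]
    all(vapply(envs_required, function(e) {
      any(sub$environment == e & !is.na(sub[[score_col]]) &
            sub[[score_col]] > threshold)
    }, logical(1)))
  })
  names(ok_by_fam)[ok_by_fam]
}

#' Filter and report competitor families
#'
#' Applies the reporting rules: a bacterial family is retained when its
#' score exceeds `threshold` in BOTH environments (fungi: in litter only,
#' since fungal data exist only there); retained scores are averaged across
#' the qualifying environments; the reported value is the square root of
#' the averaged raw score (the threshold applies to the raw score, not its
#' root); and a family must qualify at every supplied rarefaction depth --
#' families not found at all cutoffs are excluded.
#'
#' @param scores_by_depth Named list: depth -> family score table from
#'   [score_competitors()]. The first element is the reporting depth.
#' @param organism `"bacteria"` (both environments required) or `"fungi"`
#'   (litter only).
#' @param threshold Raw-score threshold (default 50).
#' @return Data frame with one row per retained family and score type:
#'   `family, organism, type, strength_class, k_total, score_agar,
#'   score_litter, score_mean, score_sqrt, environments_passing,
#'   depths_passing`.
#' @export
competitor_report <- function(scores_by_depth, organism = c("bacteria", "fungi"),
                              threshold = 50) {
  organism <- match.arg(organism)
  if (is.data.frame(scores_by_depth)) scores_by_depth <- list(scores_by_depth)
  envs_required <- if (organism == "bacteria") c("litter", "agar") else "litter"
  primary <- scores_by_depth[[1]]

  retained <- lapply(c(strong = "strong_score", weak = "weak_score"),
                     function(col) {
    per_depth <- lapply(scores_by_depth, qualifying_families, score_col = col,
                        envs_required = envs_required, threshold = threshold)
    Reduce(intersect, per_depth)
  })

  build_rows <- function(type) {
    fams <- retained[[type]]
    score_col <- paste0(type, "_score")
    k_col <- paste0(type, "_k")
    cat_cols <- if (type == "strong") c("has_invader", "has_resilient")
                else c("has_noninvasive", "has_nonresilient")
    cat_names <- if (type == "strong") STRONG_CATEGORIES else WEAK_CATEGORIES
    do.call(rbind, lapply(fams, function(fam) {
      sub <- primary[primary$family == fam &
                       primary$environment %in% envs_required, ]
      get_env <- function(e) {
        v <- sub[[score_col]][sub$environment == e]
        if (length(v) == 0) NA_real_ else v
      }
      cats <- cat_names[vapply(cat_cols, function(cc) any(sub[[cc]]), logical(1))]
      data.frame(
        family = fam, organism = organism, type = type,
        strength_class = classify_strength(
          cats, strong_qualifies = fam %in% retained$strong,
          weak_qualifies = fam %in% retained$weak),
        k_total = sum(sub[[k_col]]),
        score_agar = get_env("agar"), score_litter = get_env("litter"),
        score_mean = mean(sub[[score_col]]),
        score_sqrt = sqrt(mean(sub[[score_col]])),
        environments_passing = paste(sort(unique(sub$environment)), collapse = ","),
        depths_passing = length(scores_by_depth),
        stringsAsFactors = FALSE, row.names = NULL)
    }))
  }
  out <- rbind(build_rows("strong"), build_rows("weak"))
  if (is.null(out)) {
    out <- data.frame(family = character(), organism = character(),
                      type = character(), strength_class = character(),
                      k_total = integer(), score_agar = numeric(),
                      score_litter = numeric(), score_mean = numeric(),
                      score_sqrt = numeric(), environments_passing = character(),
                      depths_passing = integer(), stringsAsFactors = FALSE)
  }
  out[order(out$type, -rank(out$score_mean, ties.method = "first")), ]
}
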