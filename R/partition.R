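# Multifactorial ANOVA and PERMANOVA with model reduction and estimated
# percent-variance components, for partitioning propagule pressure (dose,
# frequency) versus biotic interactions (invader, resident composition).
#
# Both engines use sequential (Type I) sums of squares with terms entered
# in the stated order; on the balanced parts of the design Type I/II/III
# coincide for main effects. PERMANOVA follows the McArdle-Anderson
# Gower-centred inner-product formulation with free permutation of sample
# labels and the +1 p-value convention.

DESIGN_FACTORS <- c("dose", "frequency", "invader", "resident")

check_design <- function(design, terms) {
  assert_that(is.data.frame(design) && nrow(design) > 1,
              "design must be a data frame with > 1 row")
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  missing_vars <- setdiff(vars, names(design))
  assert_that(length(missing_vars) == 0,
              paste("design lacks factor(s):", paste(missing_vars, collapse = ", ")))
  for (v in vars) {
    design[[v]] <- factor(design[[v]])
    assert_that(nlevels(design[[v]]) >= 2,
                paste0("factor '", v, "' needs >= 2 levels"))
  }
  design[, vars, drop = FALSE]
}

#' Sequential multifactorial ANOVA
#'
#' Fits a fixed-effects linear model with the given terms in order and
#' returns the sequential (Type I) analysis-of-variance decomposition.
#' A term that is completely aliased by earlier terms (zero residual
#' degrees of freedom for it) is an error.
#'
#' @param response Numeric vector.
#' @param design Data frame of factors (one row per observation).
#' @param terms Character vector of model terms in entry order, e.g.
#'   `c("dose", "frequency", "invader", "resident", "invader:resident")`.
#' @return Object of class `invasim_anova`: `table` (term, df, sum_sq,
#'   mean_sq, f_value, p_value, with a Residuals row), `terms`, `ss_total`,
#'   and the inputs for refitting.
#' @export
anova_factorial <- function(response, design,
                            terms = DESIGN_FACTORS) {
  assert_that(is.numeric(response) && length(response) == nrow(design),
              "response length must match the design")
  design <- check_design(design, terms)
  df <- data.frame(.y = response, design)
  fit <- stats::lm(stats::as.formula(
    paste(".y ~", paste(terms, collapse = "+"))), data = df)
  # degenerate (perfect-fit) data is handled explicitly below
  an <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tab <- data.frame(term = rownames(an), df = an$Df, sum_sq = an$`Sum Sq`,
                    mean_sq = an$`Mean Sq`, f_value = an$`F value`,
                    p_value = an$`Pr(>F)`, stringsAsFactors = FALSE,
                    row.names = NULL)
  # anova() silently drops completely aliased terms; surface them instead
  aliased <- union(setdiff(terms, tab$term),
                   tab$term[tab$term != "Residuals" & tab$df == 0])
  if (length(aliased) > 0) {
    stop_invasim("aliased term(s): ", paste(aliased, collapse = ", "))
  }
  if (tab$df[tab$term == "Residuals"] == 0) {
    stop_invasim("no residual degrees of freedom")
  }
  # degenerate data (constant response up to rounding): F undefined -> 0, p = 1
  constant <- sum(tab$sum_sq) <= 1e-20 * max(1, sum(response^2))
  bad <- tab$term != "Residuals" & (constant | !is.finite(tab$f_value))
  tab$f_value[bad] <- 0
  tab$p_value[bad] <- 1
  structure(list(table = tab, terms = terms, ss_total = sum(tab$sum_sq),
                 response = response, design = design,
                 reduced = FALSE, no_significant_terms = FALSE),
            class = "invasim_anova")
}

#' One-way ANOVA
#'
#' Classical between/within decomposition for a single grouping factor.
#' A constant response gives F = 0, p = 1.
#'
#' @param response Numeric vector.
#' @param groups Grouping vector (>= 2 groups required).
#' @return List with `statistic`, `df_between`, `df_within`, `p_value`.
#' @export
one_way_anova <- function(response, groups) {
  groups <- factor(groups)
  assert_that(nlevels(groups) >= 2, "need at least two groups")
  assert_that(length(response) == length(groups), "length mismatch")
  assert_that(length(response) - nlevels(groups) > 0,
              "no residual degrees of freedom")
  fit <- anova_factorial(response, data.frame(g = groups), terms = "g")
  tab <- fit$table
  list(statistic = tab$f_value[1], df_between = tab$df[1],
       df_within = tab$df[2], p_value = tab$p_value[1])
}

# Orthonormal bases of the sequential term spaces of a design.
# Gram-Schmidt over the model-matrix columns in term order, robust to rank
# deficiency (e.g. interactions over incomplete factorial cells): columns
# already spanned by earlier ones contribute no basis vector, so term
# degrees of freedom are sequential rank increments.
sequential_basis <- function(design, terms, tol = 1e-9) {
  mm <- stats::model.matrix(stats::as.formula(
    paste("~", paste(terms, collapse = "+"))), design)
  asgn <- attr(mm, "assign")
  n <- nrow(mm)
  B <- matrix(1 / sqrt(n), n, 1)  # intercept
  term_of <- integer(0)
  for (j in seq_len(ncol(mm))[asgn > 0]) {
    v <- mm[, j]
    nrm0 <- sqrt(sum(v^2))
    for (pass in 1:2) v <- v - B %*% crossprod(B, v)
    nrm <- sqrt(sum(v^2))
    if (nrm > tol * max(nrm0, 1)) {
      B <- cbind(B, v / nrm)
      term_of <- c(term_of, asgn[j])
    }
  }
  list(B = B[, -1, drop = FALSE], term_of = term_of,
       df = vapply(seq_along(terms), function(t) sum(term_of == t), integer(1)))
}

gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(a)
  rm <- rowMeans(a)
  sweep(sweep(a, 1, rm), 2, rm) + mean(a)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions a distance matrix by the McArdle-Anderson method: the
#' Gower-centred inner-product matrix of the (squared) distances is
#' decomposed over the sequential term spaces of the design, giving
#' sequential sums of squares, pseudo-F statistics
#' `(SS_term/df_term) / (SS_res/df_res)`, and p-values from free
#' permutation of sample labels with the +1 convention
#' `p = (1 + #{F* >= F}) / (1 + n_perm)`.
#'
#' @param d Symmetric distance matrix with zero diagonal (sample ids as
#'   dimnames; row order must match `design`).
#' @param design Data frame of factors.
#' @param terms Model terms in entry order.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional seed for the permutation stream.
#' @return Object of class `invasim_permanova`: `table` (term, df, sum_sq,
#'   pseudo_f, p_value, plus a Residuals row), `ss_total`, `n_perm`, and
#'   the inputs for refitting.
#' @export
permanova <- function(d, design, terms = DESIGN_FACTORS, n_perm = 999,
                      seed = NULL) {
  d <- as.matrix(d)
  validate_distance_matrix(d, unit_range = FALSE)
  assert_that(all(d >= 0), "distances must be non-negative")
  assert_that(n_perm >= 99, "n_perm must be >= 99")
  design <- check_design(design, terms)
  assert_that(nrow(design) == nrow(d), "design rows must match distance matrix")
  n <- nrow(d)

  G <- gower_center(d)
  sb <- sequential_basis(design, terms)
  if (any(sb$df == 0)) {
    stop_invasim("aliased term(s): ", paste(terms[sb$df == 0], collapse = ", "))
  }
  ss_total <- sum(diag(G))
  df_res <- n - 1L - length(sb$term_of)
  assert_that(df_res > 0, "no residual degrees of freedom")

  term_ss <- function(Gmat) {
    comp <- colSums(sb$B * (Gmat %*% sb$B))
    vapply(seq_along(terms), function(t) sum(comp[sb$term_of == t]), numeric(1))
  }
  ss <- term_ss(G)
  ss_res <- ss_total - sum(ss)
  ms_res <- ss_res / df_res
  f_obs <- if (ms_res > 0) (ss / sb$df) / ms_res else rep(0, length(ss))

  exceed <- rep(0L, length(terms))
  perms <- with_seed(seed, replicate(n_perm, sample.int(n), simplify = FALSE))
  for (p in perms) {
    Gp <- G[p, p]
    ssp <- term_ss(Gp)
    msp <- (ss_total - sum(ssp)) / df_res
    fp <- if (msp > 0) (ssp / sb$df) / msp else rep(0, length(ssp))
    exceed <- exceed + (fp >= f_obs)
  }
  pvals <- (1 + exceed) / (1 + n_perm)
  if (ms_res == 0) pvals[] <- 1

  tab <- data.frame(
    term = c(terms, "Residuals"),
    df = c(sb$df, df_res),
    sum_sq = c(ss, ss_res),
    pseudo_f = c(f_obs, NA_real_),
    p_value = c(pvals, NA_real_),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, terms = terms, ss_total = ss_total,
                 n_perm = n_perm, d = d, design = design, seed = seed,
                 reduced = FALSE, no_significant_terms = FALSE),
            class = "invasim_permanova")
}

# hierarchy closure: a retained interaction forces its constituent main
# effects; preserve the original entry order
close_hierarchy <- function(retained, terms) {
  mains <- unique(unlist(strsplit(retained, ":", fixed = TRUE)))
  terms[terms %in% union(retained, mains)]
}

#' Reduce a fitted model to its significant terms
#'
#' Retains terms with p < `alpha`, closes the retained set under the model
#' hierarchy (an interaction forces its main effects), and refits on the
#' retained terms only. With no significant term the result is an
#' intercept-only fit flagged `no_significant_terms`, whose variance
#' partition is 100% residual.
#'
#' @param fit An `invasim_anova` or `invasim_permanova` object.
#' @param alpha Significance level (default 0.05).
#' @return A refitted object of the same class, with `reduced = TRUE` and a
#'   `retained` element.
#' @export
reduce_model <- function(fit, alpha = 0.05) {
  tab <- fit$table
  term_rows <- tab$term != "Residuals"
  signif_terms <- tab$term[term_rows & tab$p_value < alpha]
  retained <- close_hierarchy(signif_terms, fit$terms)
  if (length(retained) == 0) {
    out <- fit
    out$table <- tab[tab$term == "Residuals", , drop = FALSE]
    out$table$df <- length(fit$response %||% fit$d[, 1]) - 1L
    out$table$sum_sq <- fit$ss_total
    out$terms <- character(0)
    out$retained <- character(0)
    out$reduced <- TRUE
    out$no_significant_terms <- TRUE
    return(out)
  }
  out <- if (inherits(fit, "invasim_anova")) {
    anova_factorial(fit$response, fit$design, terms = retained)
  } else {
    permanova(fit$d, fit$design, terms = retained, n_perm = fit$n_perm,
              seed = fit$seed)
  }
  out$retained <- retained
  out$reduced <- TRUE
  out
}

#' Percent-variance components from a reduced ANOVA
#'
#' Omega-squared-style components:
#' `w2_t = (SS_t - df_t * MS_res) / (SS_total + MS_res)`, negative values
#' truncated to zero, with the residual component computed the same way and
#' the whole set rescaled to sum to 100%.
#'
#' @param fit A (reduced) `invasim_anova`.
#' @return Object of class `variance_partition`: data frame `term, percent`
#'   including a Residuals row, with attribute `model_type = "ANOVA"`.
#' @export
variance_components_anova <- function(fit) {
  assert_that(inherits(fit, "invasim_anova"), "need an invasim_anova fit")
  tab <- fit$table
  if (fit$no_significant_terms || all(tab$term == "Residuals")) {
    return(new_variance_partition(data.frame(term = "Residuals", percent = 100),
                                  "ANOVA"))
  }
  res <- tab[tab$term == "Residuals", ]
  trm <- tab[tab$term != "Residuals", ]
  ss_total <- sum(tab$sum_sq)
  denom <- ss_total + res$mean_sq
  comp <- pmax(0, (trm$sum_sq - trm$df * res$mean_sq) / denom)
  comp_res <- (res$sum_sq + res$mean_sq * sum(trm$df)) / denom
  scale <- 100 / (sum(comp) + comp_res)
  new_variance_partition(
    data.frame(term = c(trm$term, "Residuals"),
               percent = c(comp, comp_res) * scale,
               stringsAsFactors = FALSE),
    "ANOVA")
}

#' Percent-variance components from a reduced PERMANOVA
#'
#' Each retained term's percent is `100 * SS_term / SS_total` from the
#' reduced sequential decomposition; the residual takes the remainder, so
#' the components sum to 100 exactly.
#'
#' @param fit A (reduced) `invasim_permanova`.
#' @return A `variance_partition` with attribute `model_type = "PERMANOVA"`.
#' @export
variance_components_permanova <- function(fit) {
  assert_that(inherits(fit, "invasim_permanova"), "need an invasim_permanova fit")
  tab <- fit$table
  if (fit$no_significant_terms || all(tab$term == "Residuals")) {
    return(new_variance_partition(data.frame(term = "Residuals", percent = 100),
                                  "PERMANOVA"))
  }
  trm <- tab[tab$term != "Residuals", ]
  pct <- 100 * trm$sum_sq / fit$ss_total
  new_variance_partition(
    data.frame(term = c(trm$term, "Residuals"),
               percent = c(pct, 100 - sum(pct)),
               stringsAsFactors = FALSE),
    "PERMANOVA")
}

new_variance_partition <- function(df, model_type) {
  structure(df, class = c("variance_partition", "data.frame"),
            model_type = model_type)
}

#' Pairwise PERMANOVA over group pairs
#'
#' One-factor PERMANOVA restricted to each pair of groups, with p-values
#' adjusted across pairs (Benjamini-Hochberg by default). Pairs involving a
#' group with fewer than two samples are skipped with a warning.
#'
#' @param d Distance matrix.
#' @param groups Grouping vector aligned with the rows of `d`.
#' @param n_perm Permutations per pair.
#' @param seed Optional seed (sub-seeds are derived per pair).
#' @param p_adjust Adjustment method (see [stats::p.adjust()]).
#' @return Data frame: `group1, group2, n1, n2, pseudo_f, p_value,
#'   p_adjusted`, one row per usable pair (`choose(g, 2)` rows when no
#'   group is degenerate).
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999, seed = NULL,
                               p_adjust = "BH") {
  d <- as.matrix(d)
  groups <- factor(groups)
  assert_that(nlevels(groups) >= 2, "need at least two groups")
  assert_that(length(groups) == nrow(d), "groups must match distance matrix")
  lv <- levels(groups)
  rows <- list()
  for (i in seq_len(length(lv) - 1)) for (j in seq(i + 1, length(lv))) {
    idx <- which(groups %in% c(lv[i], lv[j]))
    n1 <- sum(groups == lv[i])
    n2 <- sum(groups == lv[j])
    if (n1 < 2 || n2 < 2) {
      warning("pair ", lv[i], " vs ", lv[j], " skipped (group with < 2 samples)",
              call. = FALSE)
      next
    }
    fit <- permanova(d[idx, idx], data.frame(g = droplevels(groups[idx])),
                     terms = "g", n_perm = n_perm,
                     seed = derive_seed(seed, "pair", lv[i], lv[j]))
    rows[[length(rows) + 1]] <- data.frame(
      group1 = lv[i], group2 = lv[j], n1 = n1, n2 = n2,
      pseudo_f = fit$table$pseudo_f[1], p_value = fit$table$p_value[1],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_invasim("no testable group pair")
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}
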