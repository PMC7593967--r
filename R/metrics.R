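# Rarefaction, alpha diversity and Bray-Curtis distances.

#' Rarefy an OTU table to a common depth
#'
#' Classic rarefying: per-sample subsampling WITHOUT replacement down to
#' `depth` reads (so each output row sums exactly to `depth` and no count
#' can exceed its input). Samples whose library is smaller than `depth` are
#' dropped with a warning; rarefying to the minimum library size (the usual
#' choice) therefore keeps every sample, while higher user-chosen cutoffs
#' discard shallow libraries.
#'
#' @param counts OTU matrix (samples x OTUs, non-negative integers).
#' @param depth Target depth (positive integer).
#' @param seed Optional seed for the subsampling stream.
#' @return Rarefied integer matrix; dropped samples are recorded in the
#'   `"dropped_samples"` attribute.
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  counts <- validate_otu_table(counts, allow_empty_samples = TRUE)
  assert_that(length(depth) == 1 && depth > 0 && depth == round(depth),
              "depth must be a positive integer")
  keep <- rowSums(counts) >= depth
  if (!any(keep)) stop_invasim("no sample reaches depth ", depth)
  if (any(!keep)) {
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(utils::head(rownames(counts)[!keep], 5), collapse = ", "),
            call. = FALSE)
  }
  sub <- counts[keep, , drop = FALSE]
  # vegan heuristically warns when the smallest nonzero count exceeds 1;
  # that is routine for simulated tables, so muffle only that warning
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(sub, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  storage.mode(out) <- "integer"
  attr(out, "dropped_samples") <- rownames(counts)[!keep]
  out
}

#' Per-sample OTU richness
#'
#' Number of OTUs observed (count > 0) in each sample.
#'
#' @param counts OTU matrix (samples x OTUs).
#' @return Named integer vector.
#' @export
richness <- function(counts) {
  counts <- validate_otu_table(counts, allow_empty_samples = TRUE)
  stats::setNames(as.integer(vegan::specnumber(counts)), rownames(counts))
}

#' Per-sample Shannon diversity
#'
#' H = -sum p_i log(p_i) over OTUs with nonzero relative abundance. The
#' natural logarithm is the default; any base accepted by
#' [vegan::diversity()] can be supplied.
#'
#' @param counts OTU matrix (samples x OTUs).
#' @param base Logarithm base (default `exp(1)`).
#' @param empty How to treat all-zero samples: `"error"` (default) or
#'   `"na"` to flag them as missing.
#' @return Named numeric vector.
#' @export
shannon <- function(counts, base = exp(1), empty = c("error", "na")) {
  empty <- match.arg(empty)
  counts <- validate_otu_table(counts, allow_empty_samples = TRUE)
  zero <- rowSums(counts) == 0
  if (any(zero) && empty == "error") {
    stop_invasim("all-zero sample(s): ",
                 paste(rownames(counts)[zero], collapse = ", "))
  }
  h <- vegan::diversity(counts, index = "shannon", base = base)
  h[zero] <- NA_real_
  stats::setNames(as.numeric(h), rownames(counts))
}

#' Bray-Curtis distance matrix
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i). Computed on counts; with
#' equal row sums (rarefied tables) this equals the relative-abundance form.
#'
#' @param counts OTU matrix (samples x OTUs) with at least two samples and
#'   positive row sums.
#' @return Symmetric numeric matrix with zero diagonal, values in [0, 1],
#'   sample ids on both dimnames.
#' @export
bray_curtis <- function(counts) {
  counts <- validate_otu_table(counts, allow_empty_samples = TRUE)
  assert_that(nrow(counts) >= 2, "need at least two samples")
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    stop_invasim("zero-sum sample(s): ",
                 paste(rownames(counts)[zero], collapse = ", "))
  }
  d <- as.matrix(vegan::vegdist(counts, method = "bray"))
  diag(d) <- 0
  d
}

#' Validate a distance matrix
#'
#' @param d Square numeric matrix: symmetric (1e-12), zero diagonal, values
#'   in [0, 1] unless `unit_range = FALSE`.
#' @param unit_range Require values within [0, 1]?
#' @return The matrix, invisibly validated.
#' @export
validate_distance_matrix <- function(d, unit_range = TRUE) {
  assert_that(is.matrix(d) && nrow(d) == ncol(d), "distance matrix must be square")
  assert_that(max(abs(d - t(d))) <= 1e-12, "distance matrix must be symmetric")
  assert_that(all(abs(diag(d)) <= 1e-12), "distance matrix diagonal must be zero")
  if (unit_range) assert_that(all(d >= 0 & d <= 1 + 1e-12),
                              "distances must lie in [0, 1]")
  d
}
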