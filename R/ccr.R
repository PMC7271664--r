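# Correct Classification Ratio (CCR) framework: per-subregion CCR, the
# CCR-Rank Matrix, the Array of Importance and key-region detection.

#' Per-subject, per-subregion correct classification ratio
#'
#' For every disease-class subject and sub-region r, CCR is the fraction
#' of that subject's ROIs in r that the leave-one-subject-out classifier
#' predicted with the true label. Sub-regions with no ROIs are `NA`
#' (flagged missing with a warning).
#'
#' @param preds A [loso_classify()] result.
#' @param disease_label The disease class whose subjects are scored.
#' @return An object of class `"ccr_matrix"`: list with `subjects`
#'   (ordered ids), `ccr` (subjects x 5 matrix in `[0, 1]`, `NA` where
#'   missing), `counts` (ROI counts) and `disease_label`.
#' @export
compute_ccr <- function(preds, disease_label) {
  d <- preds[preds$true_label == disease_label, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no predictions for class ", disease_label)
  subjects <- unique(d$subject_id)
  n <- length(subjects)
  ccr <- matrix(NA_real_, n, 5L,
                dimnames = list(subjects, paste0("R", 1:5)))
  counts <- matrix(0L, n, 5L,
                   dimnames = list(subjects, paste0("R", 1:5)))
  for (i in seq_len(n)) {
    rows <- d[d$subject_id == subjects[i], , drop = FALSE]
    for (r in 1:5) {
      in_r <- rows$region_index == r
      counts[i, r] <- sum(in_r)
      if (counts[i, r] > 0L)
        ccr[i, r] <- sum(in_r & rows$predicted_label == rows$true_label) /
          counts[i, r]
    }
  }
  if (anyNA(ccr))
    warning("missing CCR entries (sub-regions with zero ROIs): ",
            sum(is.na(ccr)))
  structure(list(subjects = subjects, ccr = ccr, counts = counts,
                 disease_label = disease_label),
            class = "ccr_matrix")
}

#' CCR-Rank Matrix
#'
#' Each subject's five sub-region indices sorted by descending CCR; ties
#' are broken by ascending anatomical region index. Missing CCR entries
#' are treated as `missing_value` (default -1, i.e. ranked last).
#'
#' @param ccr A [compute_ccr()] result.
#' @param missing_value Stand-in CCR for missing entries.
#' @return Integer matrix (subjects x 5) of class `"ccr_rank_matrix"`;
#'   every row is a permutation of 1..5.
#' @export
rank_matrix <- function(ccr, missing_value = -1) {
  v <- ccr$ccr
  v[is.na(v)] <- missing_value
  rk <- t(apply(v, 1L, function(row) order(-row)))  # stable: ties by index
  dimnames(rk) <- list(ccr$subjects, paste0("rank", 1:5))
  class(rk) <- c("ccr_rank_matrix", class(rk))
  rk
}

#' Array of Importance
#'
#' The first column of the CCR-Rank Matrix: each subject's best-classified
#' (most texture-altered) sub-region, together with its CCR value (the
#' maximum of that subject's CCR vector), which downstream group
#' discrimination consumes.
#'
#' @param rank A [rank_matrix()] result.
#' @param ccr The matching [compute_ccr()] result.
#' @return Data frame with columns `subject_id`, `top_region`, `top_ccr`.
#' @export
array_of_importance <- function(rank, ccr) {
  stopifnot(nrow(rank) == length(ccr$subjects))
  top <- rank[, 1L]
  data.frame(subject_id = ccr$subjects,
             top_region = as.integer(top),
             top_ccr = ccr$ccr[cbind(seq_along(top), top)],
             stringsAsFactors = FALSE)
}

#' Key sub-regions from the Array of Importance
#'
#' `f_k` is the fraction of subjects whose top region is k; the key set
#' holds the most frequent region(s), with all ties included.
#'
#' @param ai An [array_of_importance()] data frame, or an integer vector
#'   of top regions.
#' @return List with `frequencies` (length-5 vector summing to 1) and
#'   `key_regions` (integer vector).
#' @export
key_regions <- function(ai) {
  top <- if (is.data.frame(ai)) ai$top_region else as.integer(ai)
  if (length(top) == 0L) stop("need at least one subject")
  f <- tabulate(top, nbins = 5L) / length(top)
  names(f) <- paste0("R", 1:5)
  list(frequencies = f, key_regions = which(f == max(f)))
}

#' Combined occurrence fraction of the top-k sub-regions
#'
#' Selects the `k` most frequent sub-regions of an occurrence-fraction
#' vector (ties broken by ascending region index) and sums their
#' fractions — the "percentage of subjects in the key sub-regions"
#' summary (e.g. the mid-body pair R3+R4).
#'
#' @param f Numeric occurrence-fraction (or count) vector, one entry per
#'   sub-region.
#' @param k Number of regions to combine (default 2).
#' @return List with `regions` (ascending indices) and `fraction`.
#' @export
combined_top_fraction <- function(f, k = 2L) {
  stopifnot(k >= 1L, k <= length(f))
  regions <- sort(order(-f)[seq_len(k)])
  list(regions = regions, fraction = sum(f[regions]))
}
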