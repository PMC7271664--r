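# Per-ROI feature extraction and leave-one-subject-out SVM evaluation.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the per-ROI texture feature table for a cohort
#'
#' For each subject: parcel the mask, tile it with the class's ROI size,
#' compute the LBP map once over the whole image (or per ROI under
#' `border_policy = "roi_interior"`), then record energy and entropy per
#' ROI together with the ROI's sub-region. Subjects whose mask admits no
#' ROI are excluded with a warning (their ids are attached as the
#' `"excluded_subjects"` attribute).
#'
#' @param cohort List of [subject_image()] objects.
#' @param scheme A [parcellation_scheme()] or name.
#' @param lbp_cfg An [lbp_config()].
#' @param roi_sizes Named integer vector mapping class labels to ROI side
#'   lengths (default `c(HC = 5)`); classes not named fall back to
#'   `roi_size_default`.
#' @param roi_size_default ROI size for classes absent from `roi_sizes`
#'   (default 4, the patient-group window).
#' @param stride ROI lattice stride (default 1 = all possible ROIs).
#' @param anterior_side Passed to [parcellate()].
#' @param energy_convention Passed to [lbp_energy()].
#' @return Data frame with columns `subject_id`, `class_label`,
#'   `roi_index`, `region_index`, `top`, `left`, `energy`, `entropy`;
#'   one row per ROI, deterministic order.
#' @export
build_feature_table <- function(cohort,
                                scheme = parcellation_scheme("hofer"),
                                lbp_cfg = lbp_config(),
                                roi_sizes = c(HC = 5L),
                                roi_size_default = 4L,
                                stride = 1L,
                                anterior_side = "left",
                                energy_convention = "label_moment") {
  if (length(cohort) == 0L) stop("cohort is empty")
  if (is.character(scheme)) scheme <- parcellation_scheme(scheme)
  out <- vector("list", length(cohort))
  excluded <- character(0)
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    stopifnot(inherits(s, "subject_image"))
    size <- as.integer(roi_sizes[s$class_label] %||% roi_size_default)
    if (is.na(size)) size <- as.integer(roi_size_default)
    rmap <- parcellate(s$mask, scheme, anterior_side)
    grid <- tile_rois(s$mask, size, stride)
    a <- grid$anchors
    if (nrow(a) == 0L) {
      warning("subject ", s$subject_id, " admits no ", size, "x", size,
              " ROI; excluded")
      excluded <- c(excluded, s$subject_id)
      next
    }
    feats <- .roi_features(s$image, a, size, lbp_cfg, energy_convention)
    keep <- !is.na(feats$entropy)
    if (!all(keep))
      warning("subject ", s$subject_id, ": ", sum(!keep),
              " ROI(s) without valid LBP codes dropped")
    region <- vapply(a$center_col, assign_roi_region, integer(1),
                     region_map = rmap)
    out[[i]] <- data.frame(
      subject_id = s$subject_id,
      class_label = s$class_label,
      roi_index = seq_len(nrow(a)),
      region_index = region,
      top = a$top, left = a$left,
      energy = feats$energy, entropy = feats$entropy,
      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L)
    stop("no subject produced any ROI")
  rownames(res) <- NULL
  attr(res, "excluded_subjects") <- excluded
  res
}

# fast per-ROI energy/entropy from tabulated codes; NA where an ROI has
# no valid codes
.roi_features <- function(image, anchors, size, cfg, energy_convention) {
  n <- nrow(anchors)
  energy <- numeric(n); entropy <- numeric(n)
  if (cfg$border_policy == "image_interior") {
    map <- compute_lbp_map(image, cfg)
    codes <- map$codes
    get_codes <- function(i) {
      v <- codes[anchors$top[i]:(anchors$top[i] + size - 1L),
                 anchors$left[i]:(anchors$left[i] + size - 1L)]
      v[!is.na(v)]
    }
  } else {
    get_codes <- function(i) {
      sub <- image[anchors$top[i]:(anchors$top[i] + size - 1L),
                   anchors$left[i]:(anchors$left[i] + size - 1L),
                   drop = FALSE]
      m <- compute_lbp_map(sub, cfg)
      v <- m$codes
      v[!is.na(v)]
    }
  }
  nbins <- if (cfg$mapping == "u2_uniform")
    max(build_u2_mapping(cfg$num_neighbors)) + 1L else 2L^cfg$num_neighbors
  for (i in seq_len(n)) {
    v <- get_codes(i)
    if (length(v) == 0L) {
      energy[i] <- NA_real_; entropy[i] <- NA_real_
      next
    }
    cnt <- tabulate(v + 1L, nbins = nbins)
    nz <- cnt > 0L
    f <- cnt[nz] / length(v)
    x <- which(nz) - 1L
    entropy[i] <- -sum(f * log2(f))
    energy[i] <- if (energy_convention == "label_moment")
      sum(as.numeric(x)^2 * f) else sum(f^2)
  }
  list(energy = energy, entropy = entropy)
}

#' Leave-one-subject-out per-ROI SVM classification
#'
#' For each held-out subject a two-class SVM (polynomial kernel) is
#' trained on all ROIs of all remaining subjects of both classes and
#' applied to every ROI of the held-out subject, so no subject's ROIs
#' ever inform their own predictions. Features are standardized with
#' training-fold statistics only.
#'
#' @param table A [build_feature_table()] data frame.
#' @param class_a,class_b The two class labels to evaluate (each needs
#'   >= 2 subjects).
#' @param feature `"energy"`, `"entropy"` or `"both"` (2-D feature).
#' @param kernel_degree Polynomial kernel degree (default 3).
#' @param cost SVM regularization constant C (default 1).
#' @param coef0 Polynomial kernel offset (default 1).
#' @param scale_features Standardize by training-fold mean/sd
#'   (default TRUE).
#' @param class_weights `"balanced"` (default) weights each class
#'   inversely to its training-fold ROI count, so the unequal ROI
#'   totals of 5x5 control vs 4x4 patient windows (and the held-out
#'   subject's absence from its own class) do not bias the classifier
#'   toward the majority class; `NULL` for unweighted, or a named
#'   numeric vector passed to [e1071::svm()] as is.
#' @param seed Optional integer seed fixed before each fold's fit.
#' @return Data frame of class `"roi_predictions"` with columns
#'   `subject_id`, `roi_index`, `region_index`, `true_label`,
#'   `predicted_label`; attribute `feature_used`.
#' @export
loso_classify <- function(table, class_a, class_b,
                          feature = c("energy", "entropy", "both"),
                          kernel_degree = 3L, cost = 1, coef0 = 1,
                          scale_features = TRUE,
                          class_weights = "balanced",
                          seed = NULL) {
  feature <- match.arg(feature)
  cols <- switch(feature, energy = "energy", entropy = "entropy",
                 both = c("energy", "entropy"))
  df <- table[table$class_label %in% c(class_a, class_b), , drop = FALSE]
  if (nrow(df) == 0L) stop("no rows for the requested classes")
  for (cl in c(class_a, class_b)) {
    if (length(unique(df$subject_id[df$class_label == cl])) < 2L)
      stop("class ", cl, " needs >= 2 subjects")
  }
  X <- as.matrix(df[, cols, drop = FALSE])
  y <- factor(df$class_label, levels = c(class_a, class_b))
  subjects <- unique(df$subject_id)
  pred <- character(nrow(df))
  for (s in subjects) {
    te <- df$subject_id == s
    tr <- !te
    ytr <- y[tr]
    if (length(unique(ytr)) < 2L)
      stop("training fold for held-out subject ", s,
           " contains a single class")
    Xtr <- X[tr, , drop = FALSE]
    if (scale_features) {
      mu <- colMeans(Xtr)
      sd_ <- apply(Xtr, 2L, stats::sd)
      sd_[sd_ == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sd_, "/")
      Xte <- sweep(sweep(X[te, , drop = FALSE], 2L, mu), 2L, sd_, "/")
    } else {
      Xte <- X[te, , drop = FALSE]
    }
    if (!is.null(seed)) set.seed(seed)
    cw <- class_weights
    if (identical(cw, "balanced")) {
      tabw <- table(ytr)
      cw <- as.numeric(sum(tabw) / (length(tabw) * tabw))
      names(cw) <- names(tabw)
    }
    fit <- e1071::svm(x = Xtr, y = ytr, kernel = "polynomial",
                      degree = kernel_degree, cost = cost, coef0 = coef0,
                      gamma = 1 / ncol(Xtr), scale = FALSE,
                      class.weights = cw)
    pred[te] <- as.character(stats::predict(fit, Xte))
  }
  res <- data.frame(subject_id = df$subject_id,
                    roi_index = df$roi_index,
                    region_index = df$region_index,
                    true_label = as.character(df$class_label),
                    predicted_label = pred,
                    stringsAsFactors = FALSE)
  attr(res, "feature_used") <- feature
  class(res) <- c("roi_predictions", "data.frame")
  res
}
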