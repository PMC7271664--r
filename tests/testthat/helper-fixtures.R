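# Shared fixtures: all inputs are generated in code at test time.

# random 8-bit integer image
rand_image <- function(nr, nc, seed = 1) {
  withr::with_seed(seed, matrix(sample(0:255, nr * nc, replace = TRUE),
                                nr, nc))
}

# independent scalar-path LBP oracle: per-pixel composition of
# sample_circular_neighbors and lbp_code
brute_lbp_map <- function(image, cfg) {
  b <- ceiling(cfg$radius)
  H <- nrow(image); W <- ncol(image)
  out <- matrix(NA_integer_, H, W)
  for (y in (b + 1):(H - b)) {
    for (x in (b + 1):(W - b)) {
      nb <- sample_circular_neighbors(image, x, y, cfg)
      out[y, x] <- lbp_code(image[y, x], nb)
    }
  }
  if (cfg$mapping == "u2_uniform") {
    map <- build_u2_mapping(cfg$num_neighbors)
    idx <- !is.na(out)
    out[idx] <- map[out[idx] + 1L]
  }
  out
}

# random connected-ish blob mask: union of filled discs
blob_mask <- function(nr, nc, n_discs = 4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, nr, nc)
    row <- matrix(seq_len(nr), nr, nc)
    col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (i in seq_len(n_discs)) {
      cy <- sample(3:(nr - 2), 1); cx <- sample(3:(nc - 2), 1)
      r <- sample(2:5, 1)
      m <- m | ((row - cy)^2 + (col - cx)^2 <= r^2)
    }
    m
  })
}

# synthetic per-ROI feature table (no images involved): n_roi ROIs per
# subject, energies drawn from the given sampler per class
synth_feature_table <- function(classes, n_subj, n_roi, sampler, seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (cl in classes) {
      for (s in seq_len(n_subj)) {
        e <- sampler(cl, n_roi)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("%s_%02d", cl, s), class_label = cl,
          roi_index = seq_len(n_roi),
          region_index = rep_len(1:5, n_roi),
          top = 1L, left = 1L, energy = e, entropy = e,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

# end-to-end localization on a phantom cohort: control class + one
# disease class with localization vector p; returns the recovered
# key-region frequency vector and its Scatter Index
run_localization <- function(p, seed, n_per_class = 20, effect = 3,
                             image_size = c(48, 96), stride = 3,
                             feature = "energy") {
  spec <- cohort_spec(n_per_class = n_per_class, image_size = image_size,
                      effect = effect, localization = p,
                      classes = c("HC", "PD"), seed = seed)
  coh <- generate_cohort(spec)
  ft <- build_feature_table(coh$subjects, stride = stride)
  pr <- loso_classify(ft, "PD", "HC", feature = feature, seed = 1)
  ccr <- compute_ccr(pr, "PD")
  ai <- array_of_importance(rank_matrix(ccr), ccr)
  f <- key_regions(ai)$frequencies
  list(fhat = f, si = scatter_index(f)$si,
       truth = coh$truth[coh$truth$class_label == "PD", ], ai = ai)
}

# published Array-of-Importance occurrence fractions shipped with the
# package (rows: group x scheme)
published_fractions <- function() {
  utils::read.csv(system.file("extdata", "ai_region_fractions.csv",
                              package = "callotex"),
                  stringsAsFactors = FALSE)
}

fraction_row <- function(frac, group, scheme) {
  as.numeric(frac[frac$group == group & frac$scheme == scheme,
                  paste0("f", 1:5)])
}
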