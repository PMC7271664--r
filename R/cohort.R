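# Synthetic callosum phantom cohorts: CC-like masks, smooth Gaussian
# noise textures, and sub-region-localized texture alteration, so the
# full pipeline (features -> LOSO SVM -> CCR -> AI -> SI) can be
# exercised and its parameter recovery validated without MRI data.

#' Specification of a synthetic phantom cohort
#'
#' Defaults mirror the structure of the clinical study the framework
#' targets: one healthy-control class plus three Parkinsonian disease
#' classes of 20 subjects each, 5x5 control / 4x4 patient ROI windows,
#' and per-class localization vectors equal to the published Hofer-scheme
#' Array-of-Importance occurrence fractions, so each disease subject's
#' truly altered sub-region is drawn from a realistic distribution.
#'
#' @param n_per_class Subjects per class (default 20).
#' @param image_size `c(rows, cols)` in pixels (default `c(72, 144)`;
#'   the arch mask needs at least `c(40, 80)`).
#' @param mask_shape `"arch"` (region between two offset ellipses, open
#'   at the bottom like a mid-sagittal CC) or `"band"` (thick horizontal
#'   sinusoid).
#' @param base_mean,base_sd Mean gray level and noise standard deviation
#'   of the base texture (defaults 128 and 30 on the 8-bit scale).
#' @param smooth_sigma Gaussian smoothing scale of the noise field in
#'   pixels (default 1.2; the texture correlation length).
#' @param effect Texture alteration strength inside the altered
#'   sub-region, per `effect_type`: the factor by which the texture
#'   correlation length is divided (`"roughness"`, default 3: altered
#'   tissue looks finer-grained), a noise-sd multiplier
#'   (`"sd_multiplier"`), or an additive gray shift
#'   (`"contrast_shift"`). LBP codes are invariant to local gray scaling
#'   and shifts away from saturation, so `"roughness"` is the effect the
#'   texture operator actually sees; the other two are kept as
#'   first-order contrast variants.
#' @param effect_type `"roughness"`, `"sd_multiplier"` or
#'   `"contrast_shift"`.
#' @param localization Either a single 5-vector of probabilities summing
#'   to 1 (used for every disease class) or a named list of such vectors
#'   keyed by class label; per disease subject the altered sub-region is
#'   drawn from this distribution.
#' @param classes Class labels; the first is the unaltered control class.
#' @param scheme Parcellation scheme used to plant the alteration.
#' @param roi_size_hc,roi_size_patient ROI window sizes recorded in the
#'   spec for downstream feature extraction.
#' @param seed Master seed; per-subject sub-streams are derived from it
#'   by stable hashing of (seed, class, index).
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_class = 20L,
                        image_size = c(72L, 144L),
                        mask_shape = c("arch", "band"),
                        base_mean = 128, base_sd = 30,
                        smooth_sigma = 1.2,
                        effect = 3,
                        effect_type = c("roughness", "sd_multiplier",
                                        "contrast_shift"),
                        localization = list(
                          PD_NC = c(0.1, 0.2, 0.3, 0.3, 0.1),
                          MSA   = c(0, 0.25, 0.4, 0.35, 0),
                          PSP   = c(0, 0.05, 0.45, 0.5, 0)),
                        classes = c("HC", "PD_NC", "MSA", "PSP"),
                        scheme = "hofer",
                        roi_size_hc = 5L, roi_size_patient = 4L,
                        seed = 1L) {
  mask_shape <- match.arg(mask_shape)
  effect_type <- match.arg(effect_type)
  stopifnot(n_per_class >= 1L, effect > 0, length(image_size) == 2L)
  if (mask_shape == "arch" &&
      (image_size[1L] < 40L || image_size[2L] < 80L))
    stop("arch mask needs image_size >= c(40, 80)")
  disease <- classes[-1L]
  if (!is.list(localization)) {
    localization <- stats::setNames(
      rep(list(localization), length(disease)), disease)
  }
  for (cl in disease) {
    p <- localization[[cl]]
    if (is.null(p) || length(p) != 5L || any(p < 0) ||
        abs(sum(p) - 1) > 1e-9)
      stop("localization for class ", cl,
           " must be a 5-vector of probabilities summing to 1")
  }
  structure(
    list(n_per_class = as.integer(n_per_class),
         image_size = as.integer(image_size),
         mask_shape = mask_shape,
         base_mean = base_mean, base_sd = base_sd,
         smooth_sigma = smooth_sigma,
         effect = effect, effect_type = effect_type,
         localization = localization, classes = classes,
         scheme = scheme,
         roi_size_hc = as.integer(roi_size_hc),
         roi_size_patient = as.integer(roi_size_patient),
         seed = as.integer(seed)),
    class = "cohort_spec")
}

# stable sub-seed from (seed, class, index); kept below 2^31
subject_seed <- function(seed, class_label, index) {
  h <- sum(utf8ToInt(class_label) * seq_along(utf8ToInt(class_label)))
  as.integer((as.numeric(seed) * 2654435 + h * 977 + index * 7919) %%
               2147483629 + 1)
}

# separable Gaussian blur with replicate padding
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(m) {  # along rows (filter each column)
    p <- rbind(m[rep(1L, r), , drop = FALSE], m,
               m[rep(nrow(m), r), , drop = FALSE])
    f <- apply(p, 2L, function(col)
      stats::filter(col, k, sides = 2L))
    f[(r + 1L):(r + nrow(m)), , drop = FALSE]
  }
  t(smooth1(t(smooth1(mat))))
}

#' Generate a CC-like binary mask
#'
#' `"arch"`: pixels inside an outer ellipse but outside an inner ellipse
#' offset downward, producing an arch open at the bottom with two legs
#' (genu/splenium analogues); `"band"`: a thick horizontal sinusoid.
#' Both are connected, keep a margin from the image border (so every
#' mask pixel has a full radius-1 LBP neighborhood) and span a
#' horizontal extent of at least 60 px so both parcellation schemes cut
#' cleanly. Thickness and curvature are jittered per subject from the
#' supplied RNG stream; the same seed reproduces the same mask.
#'
#' @param spec A [cohort_spec()].
#' @return Logical matrix.
#' @export
generate_mask <- function(spec) {
  H <- spec$image_size[1L]; W <- spec$image_size[2L]
  jit <- function(lo, hi) stats::runif(1L, lo, hi)
  row <- matrix(seq_len(H), H, W)
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  if (spec$mask_shape == "arch") {
    cx <- W / 2
    a_o <- (W / 2 - 4) * jit(0.97, 1.0)
    b_o <- 0.52 * H * jit(0.95, 1.05)
    cy_o <- 0.58 * H
    thick <- 0.24 * H * jit(0.92, 1.08)     # top thickness
    leg <- 0.13 * W * jit(0.9, 1.1)         # leg thickness
    a_i <- a_o - leg
    b_i <- b_o - thick
    cy_i <- cy_o + 0.10 * H                 # inner pokes out the bottom
    inside <- function(cy, aa, bb)
      ((col - cx) / aa)^2 + ((row - cy) / bb)^2 <= 1
    mask <- inside(cy_o, a_o, b_o) & !inside(cy_i, a_i, b_i)
  } else {
    t0 <- 0.22 * H * jit(0.93, 1.07)
    amp <- 0.10 * H * jit(0.9, 1.1)
    yc <- 0.5 * H + amp * sin(2 * pi * (seq_len(W) - 1) / (W - 1))
    mask <- abs(row - matrix(yc, H, W, byrow = TRUE)) <= t0 / 2
  }
  # border margin of 2 px: full LBP neighborhoods, no image-edge ROIs
  mask[c(1:2, (H - 1):H), ] <- FALSE
  mask[, c(1:2, (W - 1):W)] <- FALSE
  if (!any(mask)) stop("mask parameters produced an empty mask")
  ext <- range(which(colSums(mask) > 0))
  if (diff(ext) + 1 < 60)
    stop("mask horizontal extent below 60 px; enlarge image_size")
  mask
}

#' Generate one phantom subject
#'
#' The base texture is a smoothed Gaussian noise field (rescaled to unit
#' variance after smoothing) on the configured mean/sd. Disease subjects
#' additionally have the effect applied inside one sub-region drawn from
#' the class's localization vector (region geometry from [parcellate()]
#' under the spec's scheme): the same underlying noise smoothed at
#' `smooth_sigma / effect` (`"roughness"`, a shorter correlation
#' length), the local noise amplitude multiplied (`"sd_multiplier"`),
#' or a gray shift added (`"contrast_shift"`). With `effect = 1` all
#' three reduce to the control texture. Gray levels are quantized to
#' 8 bits. The truly altered region index is recorded as the
#' `"altered_region"` attribute (`NA` for controls).
#'
#' @param spec A [cohort_spec()].
#' @param class_label Class of the subject (first spec class = control).
#' @param index Subject index within the class (drives the sub-stream).
#' @return A [subject_image()] with attribute `"altered_region"`.
#' @export
generate_subject <- function(spec, class_label, index = 1L) {
  sseed <- subject_seed(spec$seed, class_label, index)
  withr::with_seed(sseed, {
    mask <- generate_mask(spec)
    H <- spec$image_size[1L]; W <- spec$image_size[2L]
    z <- matrix(stats::rnorm(H * W), H, W)
    field <- gaussian_blur(z, spec$smooth_sigma)
    field <- field / stats::sd(field)
    altered <- NA_integer_
    is_control <- class_label == spec$classes[1L]
    if (!is_control) {
      p <- spec$localization[[class_label]]
      if (is.null(p))
        stop("no localization vector for class ", class_label)
      altered <- sample.int(5L, 1L, prob = p)
      rmap <- parcellate(mask, spec$scheme)
      in_region <- rmap$labels == altered
      if (spec$effect_type == "roughness") {
        rough <- gaussian_blur(z, spec$smooth_sigma / spec$effect)
        rough <- rough / stats::sd(rough)
        field[in_region] <- rough[in_region]
      } else if (spec$effect_type == "sd_multiplier") {
        field[in_region] <- field[in_region] * spec$effect
      }
    }
    img <- spec$base_mean + spec$base_sd * field
    if (!is_control && spec$effect_type == "contrast_shift")
      img[in_region] <- img[in_region] + spec$effect
    img <- matrix(pmin(pmax(round(img), 0), 255), H, W)
    s <- subject_image(sprintf("%s_%02d", class_label, index),
                       class_label, img, mask)
    attr(s, "altered_region") <- altered
    s
  })
}

#' Generate a full phantom cohort
#'
#' `n_per_class` subjects for every class in the spec, each from an
#' independent sub-stream of the master seed, plus a ground-truth table
#' recording each disease subject's truly altered sub-region.
#'
#' @param spec A [cohort_spec()].
#' @return List with `subjects` (list of [subject_image()]) and `truth`
#'   (data frame: `subject_id`, `class_label`, `altered_region`,
#'   `sub_seed`).
#' @export
generate_cohort <- function(spec) {
  subjects <- list()
  truth <- list()
  for (cl in spec$classes) {
    for (i in seq_len(spec$n_per_class)) {
      s <- generate_subject(spec, cl, i)
      subjects[[length(subjects) + 1L]] <- s
      truth[[length(truth) + 1L]] <- data.frame(
        subject_id = s$subject_id, class_label = cl,
        altered_region = attr(s, "altered_region"),
        sub_seed = subject_seed(spec$seed, cl, i),
        stringsAsFactors = FALSE)
    }
  }
  list(subjects = subjects, truth = do.call(rbind, truth))
}
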