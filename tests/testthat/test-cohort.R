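# 4-connectivity flood fill for connectivity checks
n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      comp <- comp + 1L
      queue <- list(c(i, j)); lab[i, j] <- comp
      while (length(queue)) {
        q <- queue[[1L]]; queue <- queue[-1L]
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          y <- q[1L] + d[1L]; x <- q[2L] + d[2L]
          if (y >= 1 && y <= nrow(mask) && x >= 1 && x <= ncol(mask) &&
              mask[y, x] && lab[y, x] == 0L) {
            lab[y, x] <- comp
            queue[[length(queue) + 1L]] <- c(y, x)
          }
        }
      }
    }
  }
  comp
}

test_that("cohort generation is deterministic and correctly sized", {
  spec <- cohort_spec(n_per_class = 3, image_size = c(48, 96),
                      classes = c("HC", "PD"),
                      localization = c(0, 0, 1, 0, 0), seed = 5)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$truth, c2$truth)
  expect_length(c1$subjects, 6L)
  ids <- vapply(c1$subjects, `[[`, character(1), "subject_id")
  expect_false(any(duplicated(ids)))
  expect_identical(sort(unique(c1$truth$class_label)), c("HC", "PD"))

  # different master seeds give different textures
  c3 <- generate_cohort(cohort_spec(n_per_class = 3,
                                    image_size = c(48, 96),
                                    classes = c("HC", "PD"),
                                    localization = c(0, 0, 1, 0, 0),
                                    seed = 6))
  expect_false(identical(c1$subjects[[1]]$image, c3$subjects[[1]]$image))
})

test_that("altered regions follow the localization distribution", {
  # one-hot: every disease subject altered in region 4, controls NA
  spec <- cohort_spec(n_per_class = 4, image_size = c(48, 96),
                      classes = c("HC", "PD"),
                      localization = c(0, 0, 0, 1, 0), seed = 2)
  tr <- generate_cohort(spec)$truth
  expect_true(all(is.na(tr$altered_region[tr$class_label == "HC"])))
  expect_true(all(tr$altered_region[tr$class_label == "PD"] == 4L))

  # law of large numbers on a non-degenerate vector
  p <- c(0.1, 0.2, 0.3, 0.3, 0.1)
  spec2 <- cohort_spec(n_per_class = 80, image_size = c(48, 96),
                       classes = c("HC", "PD"), localization = p,
                       seed = 3)
  reg <- generate_cohort(spec2)$truth
  reg <- reg$altered_region[reg$class_label == "PD"]
  counts <- tabulate(reg, 5L)
  expect_gt(stats::chisq.test(counts, p = p)$p.value, 1e-3)
})

test_that("localization vectors are validated", {
  expect_error(cohort_spec(localization = c(0.5, 0.5, 0, 0),
                           classes = c("HC", "PD")), "5-vector")
  expect_error(cohort_spec(localization = c(0.5, 0.6, 0, 0, 0),
                           classes = c("HC", "PD")), "summing to 1")
  expect_error(cohort_spec(
    localization = list(PD = c(1, 0, 0, 0, 0)),
    classes = c("HC", "PD", "MSA")), "class MSA")
})

test_that("masks are connected, bordered, and parcellable into 5 regions", {
  for (shape in c("arch", "band")) {
    spec <- cohort_spec(image_size = c(72, 144), mask_shape = shape,
                        seed = 4)
    m <- withr::with_seed(11, generate_mask(spec))
    expect_gt(sum(m), 900)
    expect_identical(n_components(m), 1L)
    # 2-px clear border: every mask pixel has a full LBP neighborhood
    expect_false(any(m[c(1, 2, 71, 72), ]))
    expect_false(any(m[, c(1, 2, 143, 144)]))
    # every Hofer sub-region admits at least one 5x5 ROI at stride 1
    pc <- parcellate(m, "hofer")
    g <- tile_rois(m, 5, 1)
    regs <- vapply(seq_len(nrow(g$anchors)), function(i)
      assign_roi_region(g$anchors$center_col[i], pc), integer(1))
    expect_identical(sort(unique(regs)), 1:5)
  }
})

test_that("effect = 1 reduces to the control texture", {
  mk <- function(eff) cohort_spec(
    n_per_class = 1, image_size = c(48, 96), classes = c("HC", "PD"),
    localization = c(0, 0, 1, 0, 0), effect = eff, seed = 9)
  # the altered-region pixels are the only ones the effect may touch
  s1 <- generate_subject(mk(1), "PD", 1)
  s3 <- generate_subject(mk(3), "PD", 1)
  pc <- parcellate(s1$mask, "hofer")
  outside <- pc$labels != 3L
  expect_identical(s1$image[outside], s3$image[outside])
  expect_false(identical(s1$image[!outside], s3$image[!outside]))
  # at effect = 1 the subject is pixel-identical to the same sub-stream
  # run through the control branch (class first in the spec)
  ctrl <- generate_subject(
    cohort_spec(n_per_class = 1, image_size = c(48, 96),
                classes = c("PD"), seed = 9), "PD", 1)
  expect_identical(s1$image, ctrl$image)
  expect_identical(s1$mask, ctrl$mask)
})

test_that("effect = 3 roughens the altered sub-region measurably", {
  spec <- cohort_spec(n_per_class = 2, image_size = c(48, 96),
                      classes = c("HC", "PD"),
                      localization = c(0, 0, 1, 0, 0), effect = 3,
                      seed = 10)
  s <- generate_subject(spec, "PD", 1)
  expect_identical(attr(s, "altered_region"), 3L)
  ft <- build_feature_table(list(s), stride = 1)
  a <- ft$entropy[ft$region_index == 3]
  b <- ft$entropy[ft$region_index != 3]
  expect_gte(length(a), 30)
  tt <- stats::t.test(a, b)
  expect_lt(tt$p.value, 0.01)
  # roughening concentrates LBP mass in the pooled non-uniform label,
  # lowering label entropy inside the altered sub-region
  expect_lt(mean(a), mean(b))
})

test_that("subject images are valid 8-bit rasters", {
  spec <- cohort_spec(n_per_class = 1, image_size = c(48, 96),
                      classes = c("HC", "PD"),
                      localization = c(0.2, 0.2, 0.2, 0.2, 0.2),
                      seed = 12)
  for (cl in c("HC", "PD")) {
    s <- generate_subject(spec, cl, 1)
    expect_true(all(s$image >= 0 & s$image <= 255))
    expect_true(all(s$image == round(s$image)))
    expect_identical(dim(s$image), dim(s$mask))
  }
})
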