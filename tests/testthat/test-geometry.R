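test_that("scheme fractions are exact rational partitions of 1", {
  w <- parcellation_scheme("witelson")$fractions
  h <- parcellation_scheme("hofer")$fractions
  # common denominators: 30ths and 12ths
  expect_identical(round(w * 30), c(10, 5, 5, 4, 6))
  expect_equal(w * 30, c(10, 5, 5, 4, 6), tolerance = 1e-15)
  expect_identical(round(h * 12), c(2, 4, 2, 1, 3))
  expect_equal(h * 12, c(2, 4, 2, 1, 3), tolerance = 1e-15)
  expect_equal(sum(w), 1, tolerance = 1e-15)
  expect_equal(sum(h), 1, tolerance = 1e-15)
})

test_that("parcellation cuts at rounded cumulative fractions", {
  m30 <- matrix(TRUE, 10, 30)
  pw <- parcellate(m30, "witelson")
  # width 30: cut offsets 10, 15, 20, 24 -> region starts 1,11,16,21,25
  expect_identical(unname(pw$boundaries[, "start"]),
                   c(1L, 11L, 16L, 21L, 25L))
  expect_identical(unname(pw$boundaries[, "end"]),
                   c(11L, 16L, 21L, 25L, 31L))

  m12 <- matrix(TRUE, 8, 12)
  ph <- parcellate(m12, "hofer")
  # width 12: cut offsets 2, 6, 8, 9
  expect_identical(unname(ph$boundaries[, "start"]),
                   c(1L, 3L, 7L, 9L, 10L))

  # partition: region pixel counts sum to the mask pixel count
  blob <- blob_mask(20, 40, n_discs = 6, seed = 3)
  pb <- parcellate(blob, "hofer")
  expect_identical(sum(pb$labels > 0), sum(blob))
  expect_true(all(sort(unique(pb$labels[blob])) %in% 1:5))
  expect_true(all(pb$labels[!blob] == 0L))
  # labels monotone non-decreasing along the anterior-posterior axis
  colreg <- pb$column_region[pb$column_region > 0]
  expect_true(all(diff(colreg) >= 0))
})

test_that("width-60 masks give exact region pixel widths", {
  for (mult in c(1L, 2L)) {
    w <- 60L * mult
    m <- matrix(TRUE, 6, w)
    widths <- function(rm) unname(rm$boundaries[, "end"] -
                                    rm$boundaries[, "start"])
    expect_identical(widths(parcellate(m, "witelson")),
                     c(20L, 10L, 10L, 8L, 12L) * mult)
    expect_identical(widths(parcellate(m, "hofer")),
                     c(10L, 20L, 10L, 5L, 15L) * mult)
  }
})

test_that("parcellation rejects degenerate masks", {
  expect_error(parcellate(matrix(FALSE, 5, 5)), "empty")
  expect_error(parcellate(matrix(TRUE, 5, 4)), "cannot host")
})

test_that("mirrored parcellation equals flip-parcellate-flip", {
  blob <- blob_mask(18, 70, n_discs = 8, seed = 11)
  for (sch in c("witelson", "hofer")) {
    left <- parcellate(blob, sch, "left")
    right <- parcellate(blob, sch, "right")
    flipped <- parcellate(blob[, ncol(blob):1], sch, "left")
    expect_identical(right$labels,
                     flipped$labels[, ncol(blob):1])
    # region order is reversed along x
    colreg <- right$column_region[right$column_region > 0]
    expect_true(all(diff(colreg) <= 0))
    expect_identical(sum(right$labels > 0), sum(left$labels > 0))
  }
})

test_that("ROI tiling: combinatorics, containment and exhaustive oracle", {
  g <- tile_rois(matrix(TRUE, 6, 6), 5, 1)
  expect_identical(g$anchors$top, c(1L, 1L, 2L, 2L))
  expect_identical(g$anchors$left, c(1L, 2L, 1L, 2L))

  # a hole in the center of the only candidate window kills it
  m <- matrix(TRUE, 5, 5)
  m[3, 3] <- FALSE
  expect_identical(nrow(tile_rois(m, 5, 1)$anchors), 0L)

  # brute-force oracle: scan all anchors, check all roi_size^2 pixels
  blob <- blob_mask(22, 30, n_discs = 7, seed = 5)
  for (rs in c(4L, 5L)) {
    g <- tile_rois(blob, rs, 1)
    oracle <- list()
    for (t in 1:(22 - rs + 1)) {
      for (l in 1:(30 - rs + 1)) {
        if (all(blob[t:(t + rs - 1), l:(l + rs - 1)]))
          oracle[[length(oracle) + 1L]] <- c(t, l)
      }
    }
    om <- do.call(rbind, oracle)
    expect_identical(nrow(g$anchors), if (is.null(om)) 0L else nrow(om))
    if (!is.null(om)) {
      expect_identical(g$anchors$top, om[, 1])
      expect_identical(g$anchors$left, om[, 2])
    }
    # containment re-check
    for (i in seq_len(nrow(g$anchors))) {
      expect_true(all(blob[g$anchors$top[i]:(g$anchors$top[i] + rs - 1),
                           g$anchors$left[i]:(g$anchors$left[i] + rs - 1)]))
    }
  }

  # stride lattice and even-size center convention
  g2 <- tile_rois(matrix(TRUE, 10, 10), 4, 2)
  expect_true(all((g2$anchors$top - 1L) %% 2L == 0L))
  expect_identical(g2$anchors$center_row, g2$anchors$top + 1L)

  expect_error(tile_rois(matrix(TRUE, 5, 5), 1), "roi_size")
})

test_that("ROI-to-region assignment by center column", {
  m <- matrix(TRUE, 10, 30)
  pw <- parcellate(m, "witelson")
  expect_identical(assign_roi_region(1L, pw), 1L)
  # a center exactly on a cut belongs to the region beginning there
  expect_identical(assign_roi_region(11L, pw), 2L)
  expect_identical(assign_roi_region(10L, pw), 1L)

  # interval-membership oracle on random centers
  edges <- unname(pw$boundaries[, "start"])
  for (col in withr::with_seed(2, sample(1:30, 100, replace = TRUE))) {
    expect_identical(assign_roi_region(col, pw),
                     max(which(edges <= col)))
  }
  expect_error(assign_roi_region(0L, pw), "outside")
})
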