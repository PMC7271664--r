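test_that("circular sampling: constants, axis points and a hand-coded bilinear check", {
  cfg <- lbp_config()

  const <- matrix(7, 9, 9)
  expect_equal(sample_circular_neighbors(const, 4, 4, cfg), rep(7, 8))

  img <- rand_image(9, 9, seed = 42)
  nb <- sample_circular_neighbors(img, 4, 4, cfg)
  # p = 0 is the exact pixel at (x + R, y): no interpolation
  expect_identical(nb[1], as.numeric(img[4, 5]))
  # p = 2, 4, 6 are the exact pixels above, left, below
  expect_identical(nb[3], as.numeric(img[3, 4]))
  expect_identical(nb[5], as.numeric(img[4, 3]))
  expect_identical(nb[7], as.numeric(img[5, 4]))

  # diagonal samples vs an independent hand-coded bilinear evaluation
  hand_bilinear <- function(im, yy, xx) {
    y0 <- floor(yy); x0 <- floor(xx); fy <- yy - y0; fx <- xx - x0
    (1 - fy) * (1 - fx) * im[y0, x0] + (1 - fy) * fx * im[y0, x0 + 1] +
      fy * (1 - fx) * im[y0 + 1, x0] + fy * fx * im[y0 + 1, x0 + 1]
  }
  h <- 1 / sqrt(2)
  for (p in c(1, 3, 5, 7)) {  # the four diagonal sampling points
    ang <- 2 * pi * p / 8
    expect_equal(nb[p + 1],
                 hand_bilinear(img, 4 - sin(ang), 4 + cos(ang)),
                 tolerance = 1e-6)
  }
  # diagonal offsets really are +-1/sqrt(2)
  expect_equal(abs(cos(2 * pi * 1 / 8)), h)

  expect_error(sample_circular_neighbors(img, 1, 1, cfg), "outside")
})

test_that("LBP code follows the >= sign rule", {
  expect_identical(lbp_code(5, rep(5, 8)), 255L)   # s(0) = 1
  expect_identical(lbp_code(10, rep(5, 8)), 0L)
  expect_identical(lbp_code(5, c(6, 4, 4, 4, 4, 4, 4, 4)), 1L)
  expect_error(lbp_code(5, numeric(0)), "non-empty")
})

test_that("uniformity counts circular bit transitions", {
  expect_identical(uniformity(0L, 8L), 0L)
  expect_identical(uniformity(0x0F, 8L), 2L)       # one block of ones
  expect_identical(uniformity(0x55, 8L), 8L)       # alternating
  expect_identical(uniformity(255L, 8L), 0L)
})

test_that("u2 mapping: 58 uniform labels plus one pooled label, total", {
  map <- build_u2_mapping(8L)
  expect_length(map, 256L)
  u <- vapply(0:255, uniformity, integer(1), P = 8L)
  expect_identical(sum(u <= 2), 58L)
  # uniform codes get distinct labels 0..57 in ascending raw-code order
  expect_identical(map[which(u <= 2)], 0:57)
  # all non-uniform codes share the pooled label 58
  expect_true(all(map[which(u > 2)] == 58L))
  expect_identical(map[0x55 + 1L], 58L)
  expect_identical(map[1L], 0L)  # code 0 has U = 0
})

test_that("LBP map: constant image, border band, oracle equivalence", {
  cfg_raw <- lbp_config(mapping = "raw")
  const <- matrix(3, 8, 10)
  m <- compute_lbp_map(const, cfg_raw)
  expect_identical(unique(m$codes[m$valid_mask]), 255L)
  # valid mask excludes exactly the 1-pixel border for R = 1
  expect_identical(m$valid_mask,
                   {v <- matrix(FALSE, 8, 10); v[2:7, 2:9] <- TRUE; v})
  expect_true(all(is.na(m$codes[!m$valid_mask])))

  mu <- compute_lbp_map(const, lbp_config())
  expect_identical(unique(mu$codes[mu$valid_mask]),
                   build_u2_mapping(8L)[255L + 1L])

  for (seed in 1:3) {
    img <- rand_image(12, 12, seed = seed)
    expect_identical(compute_lbp_map(img, cfg_raw)$codes,
                     brute_lbp_map(img, cfg_raw))
  }
  # square-8 variant matches its own brute force too
  cfg_sq <- lbp_config(neighborhood_mode = "square8", mapping = "raw")
  img <- rand_image(10, 10, seed = 9)
  expect_identical(compute_lbp_map(img, cfg_sq)$codes,
                   brute_lbp_map(img, cfg_sq))

  expect_error(compute_lbp_map(matrix(0, 2, 2), cfg_raw), "smaller")
})

test_that("gray-shift invariance on integer images", {
  cfg <- lbp_config(mapping = "raw")
  for (seed in 1:4) {
    img <- rand_image(14, 14, seed = seed)
    for (shift in c(1, 37, -12)) {
      expect_identical(compute_lbp_map(img + shift, cfg)$codes,
                       compute_lbp_map(img, cfg)$codes)
    }
  }
})

test_that("ROI histogram: degenerate, counted and normalized", {
  const <- matrix(5, 9, 9)
  m <- compute_lbp_map(const, lbp_config())
  h <- roi_histogram(m, 3, 3, 5)
  expect_identical(h$n, 1L)
  expect_equal(h$freq, 1.0)

  # hand-built map with labels {3: 2 px, 7: 2 px}
  fake <- structure(list(
    codes = matrix(c(3L, 3L, 7L, 7L), 2, 2),
    valid_mask = matrix(TRUE, 2, 2)), class = "lbp_map")
  h2 <- roi_histogram(fake, 1, 1, 2)
  expect_identical(h2$values, c(3L, 7L))
  expect_equal(h2$freq, c(0.5, 0.5))

  # dictionary-count oracle + normalization on random ROIs
  img <- rand_image(20, 20, seed = 7)
  m <- compute_lbp_map(img, lbp_config())
  for (i in 1:5) {
    top <- 2 + i; left <- 3 + i
    h <- roi_histogram(m, top, left, 5)
    v <- m$codes[top:(top + 4), left:(left + 4)]
    v <- v[!is.na(v)]
    oracle <- table(v)
    expect_equal(sum(h$freq), 1, tolerance = 1e-12)
    expect_identical(h$values, as.integer(names(oracle)))
    expect_equal(h$freq, as.numeric(oracle) / length(v))
    expect_true(all(diff(h$values) > 0))
  }

  # ROI with zero valid pixels errors
  allna <- structure(list(codes = matrix(NA_integer_, 4, 4),
                          valid_mask = matrix(FALSE, 4, 4)),
                     class = "lbp_map")
  expect_error(roi_histogram(allna, 1, 1, 3), "unusable")
})

test_that("entropy: closed forms and bounds", {
  h1 <- list(values = 0L, freq = 1, n = 1L)
  expect_identical(lbp_entropy(h1), 0)
  h2 <- list(values = c(1L, 2L), freq = c(0.5, 0.5), n = 2L)
  expect_equal(lbp_entropy(h2), 1.0)
  h25 <- list(values = 0:24, freq = rep(1 / 25, 25), n = 25L)
  expect_equal(lbp_entropy(h25), log2(25), tolerance = 1e-12)

  # 0 <= H <= log2(n) on random histograms
  for (seed in 1:10) {
    f <- withr::with_seed(seed, {x <- runif(sample(2:30, 1)); x / sum(x)})
    H <- lbp_entropy(list(freq = f))
    expect_gte(H, 0)
    expect_lte(H, log2(length(f)) + 1e-12)
  }
})

test_that("energy: label-moment and classic conventions", {
  h <- list(values = 255L, freq = 1, n = 1L)
  expect_equal(lbp_energy(h), 65025)
  expect_equal(lbp_energy(h, "classic"), 1)
  h2 <- list(values = c(3L, 7L), freq = c(0.5, 0.5), n = 2L)
  expect_equal(lbp_energy(h2), 29.0)
})
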