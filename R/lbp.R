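# Uniform local binary pattern (LBP) texture operators.
#
# Images are numeric matrices indexed image[row, col]; x refers to the
# column coordinate and y to the row coordinate, with y increasing
# downward (standard raster convention), so the sampling circle
# (x + R cos t, y - R sin t) runs counter-clockwise on screen.

#' LBP configuration
#'
#' Bundle of the parameters controlling LBP code computation: the number of
#' sampling points `P` on a circle of radius `R`, how the neighborhood is
#' sampled, how raw codes are mapped to histogram labels, and where codes
#' are considered valid.
#'
#' @param num_neighbors Integer `P >= 4`, number of sampling points
#'   (default 8; with `mapping = "u2_uniform"` and `P = 8` the label
#'   alphabet has 59 symbols: 58 uniform patterns plus one pooled
#'   non-uniform label).
#' @param radius Sampling radius `R` in pixels (default 1).
#' @param neighborhood_mode `"circular_bilinear"` samples the exact circle
#'   with bilinear interpolation at non-integer coordinates;
#'   `"square8"` uses the 8 axis/diagonal neighbors directly (`P` must
#'   be 8).
#' @param mapping `"u2_uniform"` relabels codes through the uniform-pattern
#'   (U <= 2) mapping; `"raw"` keeps raw codes `0..2^P - 1`.
#' @param border_policy `"image_interior"` computes LBP once over the whole
#'   image (an ROI's histogram may use codes whose neighborhoods extend
#'   outside the ROI but never outside the image); `"roi_interior"`
#'   restricts the neighborhood to the ROI itself.
#' @return An object of class `"lbp_config"`.
#' @export
lbp_config <- function(num_neighbors = 8L, radius = 1,
                       neighborhood_mode = c("circular_bilinear", "square8"),
                       mapping = c("u2_uniform", "raw"),
                       border_policy = c("image_interior", "roi_interior")) {
  neighborhood_mode <- match.arg(neighborhood_mode)
  mapping <- match.arg(mapping)
  border_policy <- match.arg(border_policy)
  num_neighbors <- as.integer(num_neighbors)
  if (num_neighbors < 4L)
    stop("num_neighbors must be >= 4")
  if (radius <= 0)
    stop("radius must be > 0")
  if (neighborhood_mode == "square8" && num_neighbors != 8L)
    stop("neighborhood_mode 'square8' requires num_neighbors = 8")
  structure(
    list(num_neighbors = num_neighbors, radius = radius,
         neighborhood_mode = neighborhood_mode, mapping = mapping,
         border_policy = border_policy),
    class = "lbp_config")
}

# Neighbor offsets (dy, dx) for sampling point p = 0..P-1; near-integer
# offsets are snapped so that axis-aligned samples need no interpolation.
.lbp_offsets <- function(cfg) {
  P <- cfg$num_neighbors
  p <- seq_len(P) - 1L
  ang <- 2 * pi * p / P
  dx <- cfg$radius * cos(ang)
  dy <- -cfg$radius * sin(ang)
  if (cfg$neighborhood_mode == "square8") {
    dx <- round(dx)
    dy <- round(dy)
  }
  snap <- function(v) ifelse(abs(v - round(v)) < 1e-9, round(v), v)
  cbind(dy = snap(dy), dx = snap(dx))
}

# Bilinear interpolation at (yy, xx); interpolated values are rounded to
# 6 decimals so the >= threshold in the sign rule is stable on integer
# images (constant-image and gray-shift invariances hold exactly).
.bilinear_at <- function(image, yy, xx) {
  y0 <- floor(yy); x0 <- floor(xx)
  fy <- yy - y0;   fx <- xx - x0
  y1 <- if (fy > 0) y0 + 1 else y0
  x1 <- if (fx > 0) x0 + 1 else x0
  v <- (1 - fy) * (1 - fx) * image[y0, x0] +
       (1 - fy) * fx       * image[y0, x1] +
       fy       * (1 - fx) * image[y1, x0] +
       fy       * fx       * image[y1, x1]
  round(v, 6)
}

#' Sample the circular neighborhood around one pixel
#'
#' Returns the `P` gray values `g_p = I(x + R cos(2 pi p / P),
#' y - R sin(2 pi p / P))`, `p = 0..P-1`, using bilinear interpolation at
#' non-integer coordinates (or the 8 direct neighbors for
#' `neighborhood_mode = "square8"`). The whole circle must lie within the
#' image.
#'
#' @param image Numeric matrix, `image[row, col]`.
#' @param x Column coordinate of the center pixel.
#' @param y Row coordinate of the center pixel.
#' @param cfg An [lbp_config()].
#' @return Numeric vector of length `P`.
#' @export
sample_circular_neighbors <- function(image, x, y, cfg = lbp_config()) {
  off <- .lbp_offsets(cfg)
  yy <- y + off[, "dy"]
  xx <- x + off[, "dx"]
  if (any(yy < 1 | yy > nrow(image) | xx < 1 | xx > ncol(image)))
    stop("neighborhood of radius ", cfg$radius, " around (", x, ", ", y,
         ") extends outside the image")
  vapply(seq_len(nrow(off)),
         function(i) .bilinear_at(image, yy[i], xx[i]),
         numeric(1))
}

#' Raw LBP code of one pixel
#'
#' `code = sum_p s(g_p - g_c) 2^p` with the sign rule `s(d) = 1` iff
#' `d >= 0` (equality counts as 1, so a constant patch yields the
#' all-ones code).
#'
#' @param center_value Gray value of the center pixel.
#' @param neighbor_values Numeric vector of `P` neighbor gray values.
#' @return Integer raw code in `[0, 2^P - 1]`.
#' @export
lbp_code <- function(center_value, neighbor_values) {
  P <- length(neighbor_values)
  if (P == 0L)
    stop("neighbor_values must be non-empty")
  bits <- as.numeric(neighbor_values >= center_value)
  as.integer(sum(bits * 2^(seq_len(P) - 1L)))
}

#' Circular bitwise transition count (uniformity) of an LBP code
#'
#' @param code Integer raw code in `[0, 2^P - 1]`.
#' @param P Number of bits in the pattern.
#' @return Integer number of 0/1 transitions in the circular bit string.
#' @export
uniformity <- function(code, P = 8L) {
  if (code < 0 || code > 2^P - 1)
    stop("code out of range for P = ", P)
  bits <- as.integer(intToBits(code))[seq_len(P)]
  sum(bits != c(bits[-1L], bits[1L]))
}

#' Uniform-pattern (u2) label mapping
#'
#' Codes with uniformity `U <= 2` each receive a distinct label, assigned
#' in ascending raw-code order starting at 0; all non-uniform codes share
#' a single pooled label. For `P = 8` there are exactly 58 uniform codes,
#' labeled `0..57`, and the pooled label is 58.
#'
#' @param P Number of sampling points.
#' @return Integer vector of length `2^P`; entry `code + 1` is the label.
#' @export
build_u2_mapping <- function(P = 8L) {
  codes <- 0:(2^P - 1)
  u <- vapply(codes, uniformity, integer(1), P = P)
  is_unif <- u <= 2L
  map <- integer(length(codes))
  map[is_unif] <- seq_len(sum(is_unif)) - 1L
  map[!is_unif] <- sum(is_unif)
  map
}

#' Compute the LBP label map of an image
#'
#' Computes a code for every pixel whose full neighborhood lies inside the
#' image; the border band of width `ceiling(R)` is marked invalid and its
#' codes are the `NA` sentinel.
#'
#' @param image Numeric matrix.
#' @param cfg An [lbp_config()]; with `mapping = "u2_uniform"` codes are
#'   u2 labels, with `"raw"` they are raw codes.
#' @return An object of class `"lbp_map"`: list with `codes` (integer
#'   matrix, `NA` where invalid), `valid_mask` (logical matrix) and `cfg`.
#' @export
compute_lbp_map <- function(image, cfg = lbp_config()) {
  if (!is.matrix(image)) image <- as.matrix(image)
  P <- cfg$num_neighbors
  b <- as.integer(ceiling(cfg$radius))
  H <- nrow(image); W <- ncol(image)
  if (H < 2L * b + 1L || W < 2L * b + 1L)
    stop("image (", H, "x", W, ") smaller than the LBP neighborhood")
  rows <- (b + 1L):(H - b)
  cols <- (b + 1L):(W - b)
  ctr <- image[rows, cols, drop = FALSE]
  acc <- matrix(0, length(rows), length(cols))
  off <- .lbp_offsets(cfg)
  for (p in seq_len(P)) {
    dy <- off[p, "dy"]; dx <- off[p, "dx"]
    y0 <- floor(dy); x0 <- floor(dx)
    fy <- dy - y0;   fx <- dx - x0
    r0 <- rows + y0; c0 <- cols + x0
    if (fy == 0 && fx == 0) {
      nv <- image[r0, c0, drop = FALSE]
    } else {
      r1 <- if (fy > 0) r0 + 1L else r0
      c1 <- if (fx > 0) c0 + 1L else c0
      nv <- (1 - fy) * (1 - fx) * image[r0, c0, drop = FALSE] +
            (1 - fy) * fx       * image[r0, c1, drop = FALSE] +
            fy       * (1 - fx) * image[r1, c0, drop = FALSE] +
            fy       * fx       * image[r1, c1, drop = FALSE]
      nv <- round(nv, 6)
    }
    acc <- acc + (nv >= ctr) * 2^(p - 1L)
  }
  codes_in <- matrix(as.integer(acc), length(rows), length(cols))
  if (cfg$mapping == "u2_uniform") {
    map <- build_u2_mapping(P)
    codes_in <- matrix(map[codes_in + 1L], length(rows), length(cols))
  }
  codes <- matrix(NA_integer_, H, W)
  codes[rows, cols] <- codes_in
  valid <- matrix(FALSE, H, W)
  valid[rows, cols] <- TRUE
  structure(list(codes = codes, valid_mask = valid, cfg = cfg),
            class = "lbp_map")
}

#' LBP histogram of a rectangular ROI
#'
#' Bins over the distinct label values occurring among the ROI's valid
#' pixels (sparse support: ROIs hold at most a few dozen pixels, so only
#' values actually present are binned). Frequencies are normalized to
#' sum 1.
#'
#' @param lbp_map An object from [compute_lbp_map()].
#' @param top,left 1-based row/column of the ROI's upper-left pixel.
#' @param height,width ROI extent in pixels (`width` defaults to `height`).
#' @return An object of class `"lbp_histogram"`: list with `values`
#'   (strictly increasing distinct labels), `freq` (matching normalized
#'   frequencies, all > 0) and `n` (number of distinct bins).
#' @export
roi_histogram <- function(lbp_map, top, left, height, width = height) {
  rows <- top:(top + height - 1L)
  cols <- left:(left + width - 1L)
  if (min(rows) < 1L || max(rows) > nrow(lbp_map$codes) ||
      min(cols) < 1L || max(cols) > ncol(lbp_map$codes))
    stop("ROI extends outside the image")
  v <- lbp_map$codes[rows, cols]
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    stop("ROI contains no valid LBP codes (unusable ROI)")
  cnt <- table(v)
  values <- as.integer(names(cnt))
  freq <- as.numeric(cnt) / length(v)
  structure(list(values = values, freq = freq, n = length(values)),
            class = "lbp_histogram")
}

#' Shannon entropy of an LBP histogram (bits)
#'
#' `H = -sum_i f_i log2(f_i)` over non-zero bins; 0 for a single-bin
#' histogram and at most `log2(n)` for `n` bins.
#'
#' @param h An `"lbp_histogram"` (or any list with a `freq` field).
#' @return Non-negative entropy in bits.
#' @export
lbp_entropy <- function(h) {
  f <- h$freq[h$freq > 0]
  -sum(f * log2(f))
}

#' Energy of an LBP histogram
#'
#' The default convention is the second moment of the label values,
#' `E = sum_i x_i^2 f_i`, with `x_i` the bin's label value and `f_i` its
#' normalized frequency. `"classic"` gives the common LBP-literature
#' alternative `sum_i f_i^2`, provided for comparison.
#'
#' @param h An `"lbp_histogram"`.
#' @param convention `"label_moment"` (default) or `"classic"`.
#' @return Non-negative energy.
#' @export
lbp_energy <- function(h, convention = c("label_moment", "classic")) {
  convention <- match.arg(convention)
  if (convention == "label_moment") {
    sum(as.numeric(h$values)^2 * h$freq)
  } else {
    sum(h$freq^2)
  }
}
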