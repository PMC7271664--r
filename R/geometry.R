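# Corpus-callosum mask geometry: subject container, vertical parcellation
# into the five Witelson / Hofer-Frahm sub-regions, and exhaustive ROI
# tiling inside the mask.

#' Subject container: mid-sagittal image, CC mask and class label
#'
#' @param subject_id Character identifier.
#' @param class_label Group label (e.g. `"HC"`, `"PD_NC"`, `"MSA"`,
#'   `"PSP"`, or any user-defined label).
#' @param image Numeric matrix of gray values.
#' @param mask Logical (or 0/1 numeric) matrix of the same shape; `TRUE`
#'   marks corpus-callosum pixels. Must contain at least one `TRUE` pixel.
#' @return An object of class `"subject_image"`.
#' @export
subject_image <- function(subject_id, class_label, image, mask) {
  if (!is.matrix(image)) image <- as.matrix(image)
  if (!is.matrix(mask)) mask <- as.matrix(mask)
  mask <- mask > 0
  if (!all(dim(image) == dim(mask)))
    stop("image and mask shapes differ for subject ", subject_id)
  if (!any(mask))
    stop("mask has no foreground pixels for subject ", subject_id)
  structure(
    list(subject_id = as.character(subject_id),
         class_label = as.character(class_label),
         image = image, mask = mask),
    class = "subject_image")
}

#' Vertical CC parcellation schemes
#'
#' The two standard five-part vertical subdivisions of the mid-sagittal
#' corpus callosum, anterior to posterior:
#' * `"witelson"`: 1/3, 1/6, 1/6, 2/15, 1/5 (anterior third, anterior
#'   mid-body, posterior mid-body, posterior third/isthmus, posterior
#'   one-fifth/splenium);
#' * `"hofer"`: 1/6, 1/3, 1/6, 1/12, 1/4 (the Hofer-Frahm
#'   tractography-based scheme).
#'
#' Both fraction sets sum to 1 exactly.
#'
#' @param name `"witelson"` or `"hofer"`.
#' @return An object of class `"parcellation_scheme"` with fields `name`
#'   and `fractions` (length 5).
#' @export
parcellation_scheme <- function(name = c("hofer", "witelson")) {
  name <- match.arg(name)
  fractions <- switch(name,
    witelson = c(1 / 3, 1 / 6, 1 / 6, 2 / 15, 1 / 5),
    hofer    = c(1 / 6, 1 / 3, 1 / 6, 1 / 12, 1 / 4))
  structure(list(name = name, fractions = fractions),
            class = "parcellation_scheme")
}

# round-half-up, platform-stable (base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Parcel a CC mask into five vertical sub-regions
#'
#' The mask's horizontal bounding interval is cut at the cumulative
#' fractions of the chosen scheme: cut offsets are
#' `round(width * cumfrac)` (half-up), giving half-open column intervals
#' `[cut_k, cut_{k+1})`. Each mask pixel is labeled 1-5 by the interval
#' containing its column. With `anterior_side = "right"` the region order
#' is mirrored (identical to parcellating the horizontally flipped mask
#' and flipping the labels back).
#'
#' @param mask Logical matrix; `TRUE` = CC.
#' @param scheme A [parcellation_scheme()] or scheme name.
#' @param anterior_side Which image side is anterior, `"left"` (default)
#'   or `"right"`.
#' @return An object of class `"region_label_map"`: list with `labels`
#'   (integer matrix, 0 outside the mask), `column_region` (region of
#'   every image column, 0 outside the bounding interval), `boundaries`
#'   (5 x 2 matrix of half-open column intervals `[start, end)`), the
#'   scheme and `anterior_side`.
#' @export
parcellate <- function(mask, scheme = parcellation_scheme("hofer"),
                       anterior_side = c("left", "right")) {
  anterior_side <- match.arg(anterior_side)
  if (is.character(scheme)) scheme <- parcellation_scheme(scheme)
  if (!is.matrix(mask)) mask <- as.matrix(mask)
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  W <- ncol(mask)

  if (anterior_side == "right") {
    flipped <- parcellate(mask[, W:1, drop = FALSE], scheme, "left")
    labels <- flipped$labels[, W:1, drop = FALSE]
    column_region <- rev(flipped$column_region)
    boundaries <- .region_boundaries(column_region)
    return(structure(
      list(labels = labels, column_region = column_region,
           boundaries = boundaries, scheme = scheme,
           anterior_side = "right"),
      class = "region_label_map"))
  }

  cols_on <- which(colSums(mask) > 0)
  x_min <- min(cols_on); x_max <- max(cols_on)
  width <- x_max - x_min + 1L
  if (width < 5L)
    stop("mask bounding width ", width, " cannot host 5 sub-regions")
  cum <- cumsum(scheme$fractions)
  edges <- c(0, round_half_up(width * cum[1:4]), width)  # 0-based offsets
  column_region <- integer(W)
  inside <- x_min:x_max
  column_region[inside] <- findInterval(inside - x_min, edges[1:5])
  labels <- matrix(0L, nrow(mask), W)
  idx <- which(mask, arr.ind = TRUE)
  labels[idx] <- column_region[idx[, 2L]]
  structure(
    list(labels = labels, column_region = column_region,
         boundaries = .region_boundaries(column_region),
         scheme = scheme, anterior_side = "left"),
    class = "region_label_map")
}

# half-open [start, end) column interval per region, from a per-column
# region lookup; NA rows for regions with no columns
.region_boundaries <- function(column_region) {
  b <- matrix(NA_integer_, 5L, 2L,
              dimnames = list(paste0("R", 1:5), c("start", "end")))
  for (k in 1:5) {
    cols <- which(column_region == k)
    if (length(cols)) b[k, ] <- c(min(cols), max(cols) + 1L)
  }
  b
}

#' Tile a mask exhaustively with square ROIs
#'
#' Returns every anchor on the stride lattice whose
#' `roi_size x roi_size` window is entirely mask-true, in deterministic
#' row-major order (top varies slowest). The center pixel of each ROI is
#' recorded; for even `roi_size` the center is the upper-left of the two
#' central pixels.
#'
#' @param mask Logical matrix.
#' @param roi_size Window side length in pixels (>= 2).
#' @param stride Lattice step in pixels (>= 1; 1 = all possible ROIs).
#' @return An object of class `"roi_grid"`: list with `roi_size`,
#'   `stride` and `anchors`, a data.frame of `top`, `left`,
#'   `center_row`, `center_col` (possibly zero rows).
#' @export
tile_rois <- function(mask, roi_size, stride = 1L) {
  roi_size <- as.integer(roi_size); stride <- as.integer(stride)
  if (roi_size < 2L) stop("roi_size must be >= 2")
  if (stride < 1L) stop("stride must be >= 1")
  if (!is.matrix(mask)) mask <- as.matrix(mask)
  mask <- mask > 0
  H <- nrow(mask); W <- ncol(mask)
  empty <- data.frame(top = integer(0), left = integer(0),
                      center_row = integer(0), center_col = integer(0))
  if (H < roi_size || W < roi_size)
    return(structure(list(roi_size = roi_size, stride = stride,
                          anchors = empty), class = "roi_grid"))
  # integral image for O(1) window sums
  S <- matrix(0L, H + 1L, W + 1L)
  S[-1L, -1L] <- t(apply(apply(mask + 0L, 2L, cumsum), 1L, cumsum))
  tops <- seq(1L, H - roi_size + 1L, by = stride)
  lefts <- seq(1L, W - roi_size + 1L, by = stride)
  wsum <- S[tops + roi_size, lefts + roi_size, drop = FALSE] -
          S[tops, lefts + roi_size, drop = FALSE] -
          S[tops + roi_size, lefts, drop = FALSE] +
          S[tops, lefts, drop = FALSE]
  ok <- wsum == roi_size^2
  # row-major: iterate tops in the outer loop
  hit <- which(t(ok), arr.ind = TRUE)
  top <- tops[hit[, 2L]]
  left <- lefts[hit[, 1L]]
  coff <- (roi_size - 1L) %/% 2L
  anchors <- data.frame(top = top, left = left,
                        center_row = top + coff, center_col = left + coff)
  structure(list(roi_size = roi_size, stride = stride, anchors = anchors),
            class = "roi_grid")
}

#' Sub-region of an ROI by its center pixel
#'
#' An ROI (which may straddle a sub-region boundary) is assigned to the
#' region of its center pixel's column under the half-open interval rule;
#' a center exactly on a cut belongs to the region beginning there.
#'
#' @param center_col Column coordinate of the ROI center pixel.
#' @param region_map A [parcellate()] result.
#' @return Integer region index 1-5.
#' @export
assign_roi_region <- function(center_col, region_map) {
  if (center_col < 1L || center_col > length(region_map$column_region))
    stop("center column ", center_col, " outside the image")
  r <- region_map$column_region[center_col]
  if (r == 0L)
    stop("center column ", center_col, " outside the mask bounding box")
  r
}
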