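# File I/O: PNG / NIfTI images, cohort manifests, tabular round-trips.

#' Read a 2-D grayscale image
#'
#' PNG (8-bit grayscale; RGB(A) inputs use the first channel) or a
#' single-slice NIfTI volume (requires the RNifti package). PNG values
#' are returned on the 0-255 scale.
#'
#' @param path File path ending in `.png`, `.nii` or `.nii.gz`.
#' @return Numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(round(img * 255))
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI requires the RNifti package")
    v <- RNifti::readNifti(path)
    d <- dim(v)
    if (length(d) > 2L) {
      if (prod(d[-(1:2)]) != 1L)
        stop("NIfTI input must be a single 2-D slice: ", path)
      v <- array(v, dim = d[1:2])
    }
    return(matrix(as.numeric(v), nrow = dim(v)[1L]))
  }
  stop("unsupported image format: ", path)
}

#' Read a binary mask (nonzero = foreground)
#'
#' @param path PNG or NIfTI path, as in [read_image()].
#' @return Logical matrix.
#' @export
read_mask <- function(path) read_image(path) > 0

#' Read a cohort manifest
#'
#' CSV with columns `subject_id`, `class`, `image`, `mask` (paths,
#' resolved relative to the manifest's directory unless absolute). All
#' image/mask pairs are validated up front; problems are reported in one
#' itemized error.
#'
#' @param path Manifest CSV path.
#' @return List of [subject_image()] objects.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "class", "image", "mask")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(path)
  resolve <- function(p)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  man$image <- resolve(man$image)
  man$mask <- resolve(man$mask)
  problems <- character(0)
  subjects <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    res <- tryCatch(
      subject_image(man$subject_id[i], man$class[i],
                    read_image(man$image[i]), read_mask(man$mask[i])),
      error = function(e)
        paste0(man$subject_id[i], ": ", conditionMessage(e)))
    if (is.character(res)) problems <- c(problems, res)
    else subjects[[i]] <- res
  }
  if (length(problems))
    stop("manifest errors:\n  ", paste(problems, collapse = "\n  "))
  subjects
}

#' Write a phantom cohort to disk
#'
#' One grayscale image PNG and one mask PNG per subject, plus a manifest
#' CSV (`subject_id`, `class`, `image`, `mask`, `altered_region`)
#' readable by [read_manifest()].
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(s) {
    img_file <- paste0(s$subject_id, ".png")
    mask_file <- paste0(s$subject_id, "_mask.png")
    png::writePNG(s$image / 255, file.path(dir, img_file))
    png::writePNG(s$mask * 1, file.path(dir, mask_file))
    data.frame(subject_id = s$subject_id, class = s$class_label,
               image = img_file, mask = mask_file,
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  man$altered_region <- cohort$truth$altered_region
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  invisible(man_path)
}

#' Write / read a feature table as CSV (lossless round-trip)
#'
#' @param table A [build_feature_table()] data frame.
#' @param path CSV path.
#' @return `write_feature_table`: the path, invisibly;
#'   `read_feature_table`: the data frame.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read sub-region frequency vectors from CSV or JSON
#'
#' CSV needs columns `f1..f5` plus optional identifier columns; JSON is
#' either one object or an array of objects with an `f` array field and
#' optional identifiers. Published occurrence-fraction tables can be
#' typed in directly in either form.
#'
#' @param path CSV or JSON path.
#' @return Data frame with columns `f1..f5` (plus identifiers).
#' @export
read_frequencies <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.data.frame(x)) x <- as.data.frame(x)
    if ("f" %in% names(x)) {
      fm <- do.call(rbind, x$f)
      colnames(fm) <- paste0("f", seq_len(ncol(fm)))
      x <- cbind(x[setdiff(names(x), "f")], fm)
    }
  } else {
    x <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!all(paste0("f", 1:5) %in% names(x)))
    stop("frequency input needs columns f1..f5: ", path)
  x
}
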