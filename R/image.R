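# Per-cell astaxanthin quantification from bright-field RGB micrographs:
# invert -> split channels -> (green - red) -> integrated density per cell.
# In the inverted image the green channel carries the astaxanthin signal
# and the red channel the chlorophyll signal, so the subtraction corrects
# astaxanthin against chlorophyll.

#' Construct an RGB micrograph
#'
#' Container for an 8-bit RGB micrograph stored as three intensity
#' matrices (rows = image rows). Intensities must lie in \[0, 255\].
#'
#' @param r,g,b numeric matrices of identical dimension with values in
#'   \[0, 255\].
#' @param pixel_size_um optional pixel size, micrometres per pixel.
#' @return Object of class `micrograph` with elements `r`, `g`, `b` and
#'   attribute `pixel_size_um`.
#' @export
micrograph <- function(r, g, b, pixel_size_um = NA_real_) {
  if (!is.matrix(r) || !is.matrix(g) || !is.matrix(b)) {
    abort_validation("channels must be matrices")
  }
  if (!identical(dim(r), dim(g)) || !identical(dim(r), dim(b))) {
    abort_validation("channels must share the same dimensions")
  }
  rng <- range(r, g, b)
  if (rng[1] < 0 || rng[2] > 255) {
    abort_validation("8-bit image expected: intensities must lie in [0, 255]")
  }
  structure(list(r = r, g = g, b = b),
            pixel_size_um = pixel_size_um, class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("micrograph: %d x %d px", nrow(x$r), ncol(x$r)))
  ps <- attr(x, "pixel_size_um")
  if (is.finite(ps)) cat(sprintf(" (%g um/px)", ps))
  cat("\n")
  invisible(x)
}

#' Invert an 8-bit micrograph
#'
#' Maps every channel value `v` to `255 - v`, the first step of the
#' channel-arithmetic pigment quantification: in the inverted image, dense
#' (dark) pigment becomes a bright signal. Involution: inverting twice
#' restores the input.
#'
#' @param img a [micrograph()].
#' @return The inverted [micrograph()].
#' @export
invert_image <- function(img) {
  stopifnot(inherits(img, "micrograph"))
  micrograph(255 - img$r, 255 - img$g, 255 - img$b,
             pixel_size_um = attr(img, "pixel_size_um"))
}

#' Per-pixel astaxanthin signal map
#'
#' On the *inverted* image, the green channel represents the astaxanthin
#' signal and the red channel the chlorophyll signal; subtracting red from
#' green corrects astaxanthin against chlorophyll:
#' `A = G_inv - R_inv`, computed as signed values without clipping by
#' default so that region sums stay additive. Set `clip_negative = TRUE`
#' for the 8-bit-clamped dialect (`pmax(A, 0)`).
#'
#' @param img_inverted an inverted [micrograph()] (see [invert_image()]).
#' @param clip_negative clamp negative differences to zero? Default FALSE.
#' @return A numeric matrix of signed per-pixel astaxanthin values.
#' @export
astaxanthin_signal <- function(img_inverted, clip_negative = FALSE) {
  stopifnot(inherits(img_inverted, "micrograph"))
  a <- img_inverted$g - img_inverted$r
  if (clip_negative) a <- pmax(a, 0)
  a
}

#' Segment cells in a micrograph
#'
#' Cells appear dark on a bright background; segmentation runs on the
#' inverted luminance (mean of the inverted channels): Otsu threshold,
#' hole filling, connected-component labelling, then drops regions below
#' `min_area` and (optionally) regions touching the image border. The
#' procedure is an artifact choice; it is not prescribed by the assay.
#'
#' @param img a [micrograph()] (original, not inverted).
#' @param min_area minimum region area in pixels (default 50).
#' @param discard_border drop regions touching the border? Default TRUE.
#' @return Object of class `cell_segmentation`: integer `labels` matrix
#'   (0 = background) and tibble `regions` with `label`, `area`,
#'   `centroid_row`, `centroid_col` (0-based pixel coordinates).
#' @export
segment_cells <- function(img, min_area = 50, discard_border = TRUE) {
  stopifnot(inherits(img, "micrograph"))
  inv_lum <- (3 * 255 - img$r - img$g - img$b) / 3 / 255  # in [0, 1]
  eb <- EBImage::Image(inv_lum)
  thr <- EBImage::otsu(eb, range = c(0, 1))
  mask <- EBImage::fillHull(eb > thr)
  labels <- EBImage::imageData(EBImage::bwlabel(mask))
  storage.mode(labels) <- "integer"
  if (max(labels) > 0L) {
    areas <- tabulate(labels, nbins = max(labels))
    drop <- which(areas < min_area)
    if (discard_border) {
      border <- unique(c(labels[1, ], labels[nrow(labels), ],
                         labels[, 1], labels[, ncol(labels)]))
      drop <- union(drop, setdiff(border, 0L))
    }
    if (length(drop)) labels[labels %in% drop] <- 0L
  }
  keep <- sort(unique(labels[labels > 0L]))
  # relabel compactly, preserving order
  relab <- integer(max(labels, 1L))
  relab[keep] <- seq_along(keep)
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  regions <- .region_table(labels)
  structure(list(labels = labels, regions = regions),
            class = "cell_segmentation")
}

.region_table <- function(labels) {
  n <- max(labels)
  if (n == 0L) {
    return(tibble(label = integer(), area = integer(),
                  centroid_row = numeric(), centroid_col = numeric()))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels)       # 0-based
  cols <- (idx - 1L) %/% nrow(labels)
  area <- tabulate(lab, nbins = n)
  tibble(
    label = seq_len(n),
    area = area,
    centroid_row = as.numeric(rowsum(rows, lab)) / area,
    centroid_col = as.numeric(rowsum(cols, lab)) / area
  )
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat(sprintf("cell segmentation: %d regions\n", nrow(x$regions)))
  invisible(x)
}

#' Integrated pigment density per cell
#'
#' Sums the signed astaxanthin signal over the pixels of each segmented
#' cell region (the "integrated density" of the region).
#'
#' @param signal per-pixel signal matrix from [astaxanthin_signal()].
#' @param segmentation a [segment_cells()] result (its `labels` matrix
#'   must match the signal dimensions).
#' @return Tibble with `cell` (label id), `area` (px) and `density`
#'   (signed, arbitrary units).
#' @export
integrated_density <- function(signal, segmentation) {
  stopifnot(inherits(segmentation, "cell_segmentation"))
  labels <- segmentation$labels
  if (!identical(dim(signal), dim(labels))) {
    abort_validation("signal and segmentation dimensions differ")
  }
  regions <- segmentation$regions
  if (nrow(regions) == 0L) {
    return(tibble(cell = integer(), area = integer(), density = numeric()))
  }
  idx <- which(labels > 0L)
  dens <- as.numeric(rowsum(signal[idx], labels[idx]))
  tibble(cell = regions$label, area = regions$area, density = dens)
}

#' Population summary of per-cell pigment scores
#'
#' Aggregates per-cell integrated densities the way replicated imaging
#' experiments are reported: within each independent experiment the cell
#' scores are averaged, then the cross-experiment mean and standard error
#' (sd of the experiment means / sqrt(#experiments)) are computed per
#' group. A warning (not an error) is raised when fewer than `min_cells`
#' cells back a data point.
#'
#' @param scores data frame with a `density` column, an `experiment`
#'   column, and any grouping columns.
#' @param grouping character vector of grouping column names (may be
#'   empty for a single overall summary).
#' @param min_cells per-data-point cell-count target (default 500).
#' @return Tibble with the grouping columns plus `n_cells`,
#'   `n_experiments`, `mean_density`, `se_density` (NA with a single
#'   experiment).
#' @export
population_summary <- function(scores, grouping = character(), min_cells = 500) {
  if (!is.data.frame(scores) || nrow(scores) == 0L) {
    abort_validation("`scores` must be a non-empty data frame")
  }
  if (!"density" %in% names(scores)) abort_validation("`scores` needs a `density` column")
  if (!"experiment" %in% names(scores)) abort_validation("`scores` needs an `experiment` column")
  per_exp <- scores |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grouping, "experiment")))) |>
    dplyr::summarise(n = dplyr::n(), m = mean(.data$density), .groups = "drop")
  out <- per_exp |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      n_cells = sum(.data$n),
      n_experiments = dplyr::n(),
      mean_density = mean(.data$m),
      se_density = if (dplyr::n() > 1) sd(.data$m) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop"
    )
  if (any(out$n_cells < min_cells)) {
    warning(sprintf("some data points are backed by fewer than %d cells", min_cells))
  }
  out
}

#' Read a micrograph from a TIFF or PNG file
#'
#' @param path path to an RGB TIFF or PNG image (8- or 16-bit; 16-bit
#'   inputs are rescaled to 8-bit).
#' @param pixel_size_um optional pixel size to attach.
#' @return A [micrograph()].
#' @export
read_micrograph <- function(path, pixel_size_um = NA_real_) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    abort_validation(sprintf("unsupported image format: .%s", ext))
  )
  if (length(dim(arr)) != 3L || dim(arr)[3] < 3L) {
    abort_validation("an RGB image is required")
  }
  to8 <- function(ch) round(ch * 255)
  micrograph(to8(arr[, , 1]), to8(arr[, , 2]), to8(arr[, , 3]),
             pixel_size_um = pixel_size_um)
}

#' Write a micrograph to a TIFF or PNG file
#'
#' @param img a [micrograph()].
#' @param path destination path; format chosen by extension (.tif/.png).
#' @return The path, invisibly.
#' @export
write_micrograph <- function(img, path) {
  stopifnot(inherits(img, "micrograph"))
  arr <- array(0, dim = c(dim(img$r), 3L))
  arr[, , 1] <- img$r / 255
  arr[, , 2] <- img$g / 255
  arr[, , 3] <- img$b / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    png = png::writePNG(arr, path),
    abort_validation(sprintf("unsupported image format: .%s", ext))
  )
  invisible(path)
}

#' Score a batch of micrographs
#'
#' Convenience wrapper running invert -> signal -> segment -> integrated
#' density over a set of images.
#'
#' @param images named list of [micrograph()] objects (names become the
#'   `image` column), or a character vector of file paths.
#' @param clip_negative passed to [astaxanthin_signal()].
#' @param min_area passed to [segment_cells()].
#' @return Tibble with `image`, `cell`, `area`, `density`.
#' @export
score_images <- function(images, clip_negative = FALSE, min_area = 50) {
  if (is.character(images)) {
    paths <- images
    images <- lapply(paths, read_micrograph)
    names(images) <- basename(paths)
  }
  if (is.null(names(images))) names(images) <- as.character(seq_along(images))
  res <- lapply(names(images), function(nm) {
    img <- images[[nm]]
    seg <- segment_cells(img, min_area = min_area)
    a <- astaxanthin_signal(invert_image(img), clip_negative = clip_negative)
    sc <- integrated_density(a, seg)
    if (nrow(sc)) sc$image <- nm else sc$image <- character()
    sc
  })
  empty <- tibble(image = character(), cell = integer(),
                  area = integer(), density = numeric())
  dplyr::bind_rows(c(list(empty), res))[, c("image", "cell", "area", "density")]
}
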