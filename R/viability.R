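# Evans-Blue dye-exclusion mortality: stained (blue) cells are dead.
# Works either from tabular hemocytometer counts or from segmented
# micrographs via a colour-dominance classifier.

#' Mortality fraction of a count record
#'
#' `100 * stained / total`, vectorised over records.
#'
#' @param stained number of stained (blue, dead) cells.
#' @param total total cells counted (> 0).
#' @return Mortality percentage(s).
#' @export
#' @examples
#' mortality_fraction(3, 20)   # 15
mortality_fraction <- function(stained, total) {
  if (any(!is.finite(total)) || any(total <= 0)) {
    abort_validation("`total` must be positive")
  }
  if (any(!is.finite(stained)) || any(stained < 0) || any(stained > total)) {
    abort_validation("`stained` must lie in [0, total]")
  }
  100 * stained / total
}

#' Aggregate mortality across experimental series
#'
#' Computes the per-record mortality percentage, then the mean and
#' standard error across the independent experimental series within each
#' group (condition x timepoint by default). A warning is raised when a
#' group pools fewer than `min_cells` cells.
#'
#' @param records data frame with columns `total`, `stained`, a series
#'   identifier (`sample`), and grouping columns.
#' @param grouping character vector of grouping column names
#'   (default `c("condition", "timepoint_h")`, intersected with what is
#'   present).
#' @param min_cells pooled-count target per group (default 1500).
#' @return Tibble with the grouping columns plus `n_series`, `n_cells`,
#'   `mortality_pct`, `se_pct`.
#' @export
aggregate_mortality <- function(records,
                                grouping = c("condition", "timepoint_h"),
                                min_cells = 1500) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    abort_validation("`records` must be a non-empty data frame")
  }
  if (!all(c("total", "stained") %in% names(records))) {
    abort_validation("`records` needs `total` and `stained` columns")
  }
  grouping <- intersect(grouping, names(records))
  records$mortality <- mortality_fraction(records$stained, records$total)
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      n_series = dplyr::n(),
      n_cells = sum(.data$total),
      mortality_pct = mean(.data$mortality),
      se_pct = if (dplyr::n() > 1) sd(.data$mortality) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop"
    )
  if (any(out$n_cells < min_cells)) {
    warning(sprintf("some groups pool fewer than %d cells", min_cells))
  }
  out
}

#' Classify segmented cells as stained (dead) or unstained (alive)
#'
#' A cell that has taken up Evans Blue transmits blue light: its red and
#' green channels are strongly attenuated while blue is not. On the
#' inverted channels the rule is a blue-dominance margin
#' `d = ((mean R_inv + mean G_inv)/2 - mean B_inv) / 255`; the cell is
#' called dead when `d > margin`. The visual scoring of the original
#' assay has no published colour threshold, so both the rule and the
#' default margin are artifact choices (configurable).
#'
#' @param img a [micrograph()] (original, not inverted).
#' @param segmentation a [segment_cells()] result.
#' @param margin dominance threshold in \[0, 1\] (default 0.4).
#' @return Tibble with `cell`, `blue_dominance`, `dead` (logical).
#' @export
classify_stained <- function(img, segmentation, margin = 0.4) {
  stopifnot(inherits(img, "micrograph"), inherits(segmentation, "cell_segmentation"))
  labels <- segmentation$labels
  regions <- segmentation$regions
  if (nrow(regions) == 0L) {
    return(tibble(cell = integer(), blue_dominance = numeric(), dead = logical()))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  mr <- as.numeric(rowsum(img$r[idx], lab)) / regions$area
  mg <- as.numeric(rowsum(img$g[idx], lab)) / regions$area
  mb <- as.numeric(rowsum(img$b[idx], lab)) / regions$area
  # inverted-channel formulation; algebraically ((255-mr)+(255-mg))/2-(255-mb)
  dom <- (mb - (mr + mg) / 2) / 255
  tibble(cell = regions$label, blue_dominance = dom, dead = dom > margin)
}

#' Read a count table CSV
#'
#' Expects columns `sample`, `condition`, `timepoint_h`, `total`,
#' `stained` (validated).
#'
#' @param path CSV file path.
#' @return Tibble of count records.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  x <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("sample", "condition", "timepoint_h", "total", "stained")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort_validation(paste("count table missing columns:", paste(missing, collapse = ", ")))
  }
  mortality_fraction(x$stained, x$total)  # validates ranges
  x
}
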