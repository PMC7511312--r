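# Relative transcript quantification by the 2^(-ddCt) method with actin
# as housekeeping reference and the untreated control at 18 h as
# baseline, over a 3 biological x 3 technical replicate design.

#' Reference specification for relative quantification
#'
#' @param housekeeping housekeeping gene name (default `"actin"`).
#' @param baseline_condition baseline condition label (default `"control"`).
#' @param baseline_timepoint_h baseline timepoint in hours (default 18).
#' @return Object of class `reference_spec`.
#' @export
reference_spec <- function(housekeeping = "actin",
                           baseline_condition = "control",
                           baseline_timepoint_h = 18) {
  structure(
    list(housekeeping = housekeeping,
         baseline_condition = baseline_condition,
         baseline_timepoint_h = baseline_timepoint_h),
    class = "reference_spec"
  )
}

.check_ct_records <- function(records) {
  need <- c("gene", "condition", "timepoint_h", "bio_rep", "tech_rep", "ct")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    abort_validation(paste("Ct table missing columns:", paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(records$ct)) || any(records$ct <= 0) || any(records$ct >= 45)) {
    abort_validation("Ct values must lie in (0, 45)")
  }
  design <- records |>
    dplyr::count(.data$gene, .data$condition, .data$timepoint_h,
                 name = "n_measurements")
  if (any(design$n_measurements != 9L)) {
    warning("replicate design is not a complete 3 biological x 3 technical grid")
  }
  invisible(records)
}

#' Collapse technical replicates
#'
#' Arithmetic mean Ct of the technical replicates within each
#' (gene, condition, timepoint, biological replicate) group — the first
#' collapse step of the standard ddCt workflow.
#'
#' @param records tidy Ct table with columns `gene`, `condition`,
#'   `timepoint_h`, `bio_rep`, `tech_rep`, `ct`.
#' @return Tibble with one row per biological replicate (`ct` = mean of
#'   its technical replicates).
#' @export
collapse_technical <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    abort_validation("`records` must be a non-empty data frame")
  }
  records |>
    dplyr::group_by(.data$gene, .data$condition, .data$timepoint_h, .data$bio_rep) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
}

#' Delta-Ct normalisation against the housekeeping gene
#'
#' `dCt = Ct_target - Ct_housekeeping`, paired within each
#' (condition, timepoint, biological replicate) sample.
#'
#' @param collapsed output of [collapse_technical()].
#' @param housekeeping housekeeping gene name.
#' @return Tibble of target-gene rows with a `delta_ct` column.
#' @export
delta_ct <- function(collapsed, housekeeping = "actin") {
  if (!housekeeping %in% collapsed$gene) {
    abort_config(sprintf("housekeeping gene '%s' absent from the Ct table", housekeeping))
  }
  hk <- collapsed |>
    dplyr::filter(.data$gene == housekeeping) |>
    dplyr::select("condition", "timepoint_h", "bio_rep", hk_ct = "ct")
  out <- collapsed |>
    dplyr::filter(.data$gene != housekeeping) |>
    dplyr::inner_join(hk, by = c("condition", "timepoint_h", "bio_rep")) |>
    dplyr::mutate(delta_ct = .data$ct - .data$hk_ct)
  n_target <- sum(collapsed$gene != housekeeping)
  if (nrow(out) != n_target) {
    abort_validation("some samples lack a paired housekeeping measurement")
  }
  out
}

#' Fold change from ddCt
#'
#' `ddCt = dCt_sample - dCt_reference`; fold = `efficiency^(-ddCt)`
#' (efficiency 2 for the plain 2^(-ddCt) method).
#'
#' @param delta_ct_sample sample delta-Ct value(s).
#' @param delta_ct_reference reference delta-Ct.
#' @param efficiency amplification efficiency (default 2).
#' @return Fold change(s), strictly positive.
#' @export
#' @examples
#' fold_change(5, 5)   # 1
#' fold_change(4, 5)   # 2
fold_change <- function(delta_ct_sample, delta_ct_reference, efficiency = 2) {
  check_positive(efficiency, "efficiency")
  efficiency^(-(delta_ct_sample - delta_ct_reference))
}

#' Relative expression table by the 2^(-ddCt) method
#'
#' Full pipeline: technical replicates are averaged per biological
#' replicate, each target Ct is normalised to the housekeeping gene
#' within its sample (dCt), ddCt is computed per biological replicate
#' against the *mean* reference dCt (baseline condition and timepoint of
#' `refspec`), and per (gene, condition, timepoint) the summary fold is
#' `efficiency^(-mean ddCt)` — so the reference cell is exactly 1 by
#' construction — with the standard error taken across the per-replicate
#' folds. `se_scope = "all"` instead spreads the s.e. over all technical
#' measurements (no technical collapse before the s.e.).
#'
#' @param records tidy Ct table (see [collapse_technical()]).
#' @param refspec a [reference_spec()].
#' @param efficiency amplification efficiency (default 2).
#' @param se_scope `"biological"` (default) or `"all"`.
#' @return Tibble with `gene`, `condition`, `timepoint_h`, `n_bio`,
#'   `mean_ddct`, `fold` (= efficiency^-mean_ddct), `se_fold`.
#' @export
expression_table <- function(records, refspec = reference_spec(),
                             efficiency = 2,
                             se_scope = c("biological", "all")) {
  se_scope <- match.arg(se_scope)
  stopifnot(inherits(refspec, "reference_spec"))
  .check_ct_records(records)
  collapsed <- if (se_scope == "biological") {
    collapse_technical(records)
  } else {
    # keep technical replicates as pseudo-replicates for the s.e.
    records |>
      dplyr::mutate(bio_rep = paste(.data$bio_rep, .data$tech_rep, sep = ".")) |>
      dplyr::select("gene", "condition", "timepoint_h", "bio_rep", "ct")
  }
  dct <- delta_ct(collapsed, refspec$housekeeping)
  ref <- dct |>
    dplyr::filter(.data$condition == refspec$baseline_condition,
                  .data$timepoint_h == refspec$baseline_timepoint_h) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(ref_dct = mean(.data$delta_ct), .groups = "drop")
  if (nrow(ref) == 0L) {
    abort_config(sprintf(
      "reference cell (%s, %g h) absent from the Ct table",
      refspec$baseline_condition, refspec$baseline_timepoint_h
    ))
  }
  dct |>
    dplyr::inner_join(ref, by = "gene") |>
    dplyr::mutate(ddct = .data$delta_ct - .data$ref_dct,
                  rep_fold = efficiency^(-.data$ddct)) |>
    dplyr::group_by(.data$gene, .data$condition, .data$timepoint_h) |>
    dplyr::summarise(
      n_bio = dplyr::n(),
      mean_ddct = mean(.data$ddct),
      fold = efficiency^(-mean(.data$ddct)),
      se_fold = if (dplyr::n() > 1) sd(.data$rep_fold) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop"
    )
}

#' Wide gene x condition/timepoint fold-change matrix
#'
#' @param expr output of [expression_table()].
#' @return Tibble with one row per gene and one `condition_timepoint`
#'   column per cell of the design.
#' @export
expression_wide <- function(expr) {
  expr |>
    dplyr::mutate(cell = paste(.data$condition, .data$timepoint_h, sep = "_")) |>
    dplyr::select("gene", "cell", "fold") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "fold")
}

#' Read a tidy Ct table CSV
#'
#' @param path CSV with columns `gene`, `condition`, `timepoint_h`,
#'   `bio_rep`, `tech_rep`, `ct`.
#' @return Tibble of Ct records (validated).
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  x <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  suppressWarnings(.check_ct_records(x))
  x
}

#' qPCR primer metadata
#'
#' The primer pairs used for the four assayed genes (phytoene synthase
#' *psy*, beta-carotene hydroxylase *crtR-b*, beta-carotene ketolase
#' *bkt 1*, and the *actin* housekeeping reference), shipped as reference
#' data only — the package performs no sequence analysis.
#'
#' @return Tibble with `gene`, `accession`, `forward`, `reverse`.
#' @export
primer_table <- function() {
  path <- system.file("extdata", "primers.csv", package = "pefastax")
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
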