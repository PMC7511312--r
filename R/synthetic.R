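# Seeded generators for every input the pipeline consumes — bright-field
# RGB micrographs, tidy Ct tables, hemocytometer count tables — with
# planted ground truth, so each downstream stage can be validated by
# parameter recovery. Presets encode the reported effect structure of the
# wet-lab study conditions (pulse stringency x inhibitor x timepoint) as
# point parameters.

#' Synthetic-scenario configuration
#'
#' Bundles the planted truth for one experimental condition: the
#' mortality trajectory, the per-gene log2 fold-change profile of each
#' experimental arm (relative to the baseline cell), the astaxanthin
#' attenuation level driving the image generator, and the noise and
#' replicate design parameters.
#'
#' @param label condition label (e.g. `"50ns"`, `"25ns+DPI"`).
#' @param pulse pulse condition: `"control"`, `"25ns"` or `"50ns"`.
#' @param inhibitor inhibitor state: `"none"`, `"DPI"`, `"A23187"` or
#'   `"GdCl3"`.
#' @param timepoints_h measurement timepoints, hours.
#' @param mortality data frame `condition`, `timepoint_h`,
#'   `mortality_pct` (true stained fraction, percent) for every arm.
#' @param log2fc data frame `condition`, `gene`, `timepoint_h`, `log2fc`
#'   (planted log2 fold change vs the baseline cell) for every arm.
#' @param attenuation astaxanthin attenuation level in \[0, 1\] scaling
#'   the per-cell pigment planted in micrographs of the labelled
#'   condition.
#' @param ct_sd additive Gaussian Ct noise, cycles (default 0.2).
#' @param image_noise_sd additive Gaussian pixel noise, intensity units
#'   (default 8).
#' @param n_bio,n_tech replicate design (default 3 x 3).
#' @param n_series independent experimental series for counts (default 3).
#' @param n_total_counts cells counted per series (default 1500).
#' @param baseline_condition,baseline_timepoint_h the reference cell of
#'   the ddCt normalisation (default control at the first timepoint).
#' @param base_ct named numeric vector of baseline Ct values per gene
#'   (must include `actin`).
#' @param radius_px_range cell radius range in pixels (default 8--50,
#'   i.e. 8--50 um diameter at the 0.5 um/px default).
#' @param pixel_size_um pixel size, um/px (default 0.5).
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(label, pulse = "control", inhibitor = "none",
                            timepoints_h = c(18, 24, 48, 72, 96),
                            mortality, log2fc,
                            attenuation = 0.5,
                            ct_sd = 0.2, image_noise_sd = 8,
                            n_bio = 3, n_tech = 3, n_series = 3,
                            n_total_counts = 1500,
                            baseline_condition = "control",
                            baseline_timepoint_h = timepoints_h[1],
                            base_ct = c(actin = 18, psy = 24,
                                        `crtR-b` = 26, `bkt 1` = 25),
                            radius_px_range = c(8, 50),
                            pixel_size_um = 0.5) {
  if (any(mortality$mortality_pct < 0) || any(mortality$mortality_pct > 100)) {
    abort_validation("mortalities must lie in [0, 100]")
  }
  if (attenuation < 0 || attenuation > 1) {
    abort_validation("`attenuation` must lie in [0, 1]")
  }
  if (ct_sd < 0 || image_noise_sd < 0) {
    abort_validation("noise standard deviations must be non-negative")
  }
  if (!"actin" %in% names(base_ct)) {
    abort_config("`base_ct` must include the housekeeping gene `actin`")
  }
  structure(
    list(label = label, pulse = pulse, inhibitor = inhibitor,
         timepoints_h = timepoints_h,
         mortality = as_tibble(mortality), log2fc = as_tibble(log2fc),
         attenuation = attenuation, ct_sd = ct_sd,
         image_noise_sd = image_noise_sd,
         n_bio = n_bio, n_tech = n_tech, n_series = n_series,
         n_total_counts = n_total_counts,
         baseline_condition = baseline_condition,
         baseline_timepoint_h = baseline_timepoint_h,
         base_ct = base_ct,
         radius_px_range = radius_px_range,
         pixel_size_um = pixel_size_um),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario '%s' (%s pulse, inhibitor %s): %d arm(s), timepoints %s h\n",
              x$label, x$pulse, x$inhibitor,
              length(unique(x$log2fc$condition)),
              paste(x$timepoints_h, collapse = "/")))
  invisible(x)
}

# counter-based child seeds so each artefact is independently reproducible
child_seed <- function(seed, offset) {
  as.integer(((as.double(seed) %% 2147483647) * 48271 + offset) %% 2147483647)
}

.genes <- c("psy", "crtR-b", "bkt 1")

# fold profiles along c(18, 24, 48, 72, 96) h
.tc_profiles <- list(
  control = list(psy = c(1, 1, 1, 1, 1),
                 `crtR-b` = c(1, 1, 1, 1, 1),
                 `bkt 1` = c(1, 1, 1, 1, 1)),
  `25ns` = list(psy = c(1, 1, 1, 0.6, 0.5),
                `crtR-b` = c(1, 1, 1, 0.45, 1 / 3),
                `bkt 1` = c(1, 1, 1, 1, 1)),
  `50ns` = list(psy = c(1, 1, 1.3, 2, 1.1),
                `crtR-b` = c(1, 1, 1.3, 2, 1.1),
                `bkt 1` = c(1, 1, 1.4, 2, 1.1))
)

.tc_mortality <- list(
  control = c(2, 2.2, 2.4, 2.6, 2.8),
  `25ns` = c(7, 6.5, 6, 12, 17),
  `50ns` = c(14, 15, 16.5, 18, 19)
)

.arm_log2fc <- function(condition, folds, timepoints) {
  dplyr::bind_rows(lapply(names(folds), function(g) {
    tibble(condition = condition, gene = g, timepoint_h = timepoints,
           log2fc = log2(folds[[g]]))
  }))
}

#' Preset scenario bundle for the study conditions
#'
#' Returns the 12 preset configurations of the 3 pulse x 4 inhibitor
#' grid. Time-course presets (`"control"`, `"25ns"`, `"50ns"`) plant the
#' reported mortality trajectories (control below 3%; 50 ns from 14% at
#' 18 h to 19% at 96 h; 25 ns at ~6% until 48 h then up to 17%) and fold
#' profiles (50 ns: ~2x peak at 72 h; 25 ns: *crtR-b* down to 1/3,
#' *bkt 1* unchanged) relative to the untreated control at 18 h.
#' Inhibitor presets are single-timepoint (72 h) designs normalised to
#' the untreated control at 72 h, each carrying the matching pulse-alone
#' companion arm in the same normalisation (e.g. the GdCl3 set plants
#' *crtR-b* 4x for the 50 ns pulse alone vs 2x with GdCl3; the DPI set
#' plants the ~2x doubling of all transcripts in unpulsed cells).
#' These presets are emulation targets distilled from reported summary
#' narratives, not measured raw data.
#'
#' @return Named list of [scenario_config()] objects.
#' @export
preset_scenarios <- function() {
  tp <- c(18, 24, 48, 72, 96)
  att <- c(control = 0.5, `25ns` = 0.55, `50ns` = 0.52)

  time_course <- function(pulse) {
    arms <- .arm_log2fc("control", .tc_profiles$control, tp)
    mort <- tibble(condition = "control", timepoint_h = tp,
                   mortality_pct = .tc_mortality$control)
    if (pulse != "control") {
      arms <- dplyr::bind_rows(arms, .arm_log2fc(pulse, .tc_profiles[[pulse]], tp))
      mort <- dplyr::bind_rows(mort, tibble(
        condition = pulse, timepoint_h = tp,
        mortality_pct = .tc_mortality[[pulse]]
      ))
    }
    scenario_config(label = pulse, pulse = pulse, inhibitor = "none",
                    timepoints_h = tp, mortality = mort, log2fc = arms,
                    attenuation = att[[pulse]])
  }

  # inhibitor sets: 72 h only, normalised to untreated control at 72 h;
  # fold vectors are (psy, crtR-b, bkt 1)
  inhibitor_cfg <- function(pulse, inhibitor, pulse_alone, with_inhibitor,
                            attenuation) {
    label <- if (pulse == "control") paste0("control+", inhibitor) else
      paste0(pulse, "+", inhibitor)
    arms <- .arm_log2fc("control",
                        stats::setNames(as.list(rep(1, 3)), .genes), 72)
    mort <- tibble(condition = "control", timepoint_h = 72,
                   mortality_pct = 2.6)
    if (pulse != "control") {
      arms <- dplyr::bind_rows(arms, .arm_log2fc(
        pulse, stats::setNames(as.list(pulse_alone), .genes), 72))
      mort <- dplyr::bind_rows(mort, tibble(
        condition = pulse, timepoint_h = 72,
        mortality_pct = .tc_mortality[[pulse]][4]
      ))
    }
    arms <- dplyr::bind_rows(arms, .arm_log2fc(
      label, stats::setNames(as.list(with_inhibitor), .genes), 72))
    mort <- dplyr::bind_rows(mort, tibble(
      condition = label, timepoint_h = 72,
      mortality_pct = if (pulse == "control") 2.6 else .tc_mortality[[pulse]][4]
    ))
    scenario_config(label = label, pulse = pulse, inhibitor = inhibitor,
                    timepoints_h = 72, mortality = mort, log2fc = arms,
                    attenuation = attenuation,
                    baseline_timepoint_h = 72)
  }

  presets <- list(
    control = time_course("control"),
    `25ns` = time_course("25ns"),
    `50ns` = time_course("50ns"),
    # DPI roughly doubles all transcripts in unpulsed cells; with pulses
    # the enhancement saturates around 2.5x
    `control+DPI` = inhibitor_cfg("control", "DPI", NULL, c(2, 2, 2), 0.65),
    `25ns+DPI` = inhibitor_cfg("25ns", "DPI", c(1.5, 1.5, 1.5),
                               c(2.5, 2.5, 2.5), 0.90),
    `50ns+DPI` = inhibitor_cfg("50ns", "DPI", c(2, 2, 2),
                               c(2.5, 2.5, 2.5), 0.65),
    # calcium ionophore: sufficient for psy alone; at 25 ns lifts psy and
    # crtR-b to 50 ns-like levels; at 50 ns reduces bkt 1
    `control+A23187` = inhibitor_cfg("control", "A23187", NULL,
                                     c(2, 1, 1), 0.55),
    `25ns+A23187` = inhibitor_cfg("25ns", "A23187", c(1.2, 1.2, 1),
                                  c(2, 2, 1), 0.60),
    `50ns+A23187` = inhibitor_cfg("50ns", "A23187", c(2, 2, 2),
                                  c(2, 2, 1.3), 0.52),
    # calcium-influx block: eliminates most of the pulse stimulation
    # (crtR-b 50 ns: 4x alone vs 2x with GdCl3); stimulates crtR-b at 25 ns
    `control+GdCl3` = inhibitor_cfg("control", "GdCl3", NULL,
                                    c(1, 1, 1), 0.40),
    `25ns+GdCl3` = inhibitor_cfg("25ns", "GdCl3", c(1.5, 1, 1.5),
                                 c(1, 2, 1), 0.45),
    `50ns+GdCl3` = inhibitor_cfg("50ns", "GdCl3", c(3, 4, 3),
                                 c(1.5, 2, 1.5), 0.45)
  )
  presets
}

#' Generate a synthetic Ct table
#'
#' Emits the full replicate design (n_bio biological x n_tech technical)
#' for every arm of the scenario: target-gene Ct values are
#' `baseCt(gene) - log2fc + N(0, ct_sd)` and the housekeeping actin Ct is
#' constant across conditions up to the same noise, so the ddCt pipeline
#' recovers the planted folds exactly at `ct_sd = 0`.
#'
#' @param cfg a [scenario_config()].
#' @param seed integer seed (deterministic output for fixed cfg + seed).
#' @return Tibble of Ct records (`gene`, `condition`, `timepoint_h`,
#'   `bio_rep`, `tech_rep`, `ct`) with the planted `log2fc` attached as
#'   attribute `truth`.
#' @export
generate_ct_table <- function(cfg, seed) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(child_seed(seed, 1L))
  design <- tidyr::expand_grid(
    cfg$log2fc,
    bio_rep = seq_len(cfg$n_bio),
    tech_rep = seq_len(cfg$n_tech)
  )
  design$ct <- cfg$base_ct[design$gene] - design$log2fc +
    rnorm(nrow(design), sd = cfg$ct_sd)
  actin <- design |>
    dplyr::distinct(.data$condition, .data$timepoint_h, .data$bio_rep,
                    .data$tech_rep)
  actin$gene <- "actin"
  actin$ct <- cfg$base_ct[["actin"]] + rnorm(nrow(actin), sd = cfg$ct_sd)
  out <- dplyr::bind_rows(
    design[, c("gene", "condition", "timepoint_h", "bio_rep", "tech_rep", "ct")],
    actin[, c("gene", "condition", "timepoint_h", "bio_rep", "tech_rep", "ct")]
  )
  attr(out, "truth") <- cfg$log2fc
  out
}

#' Generate a synthetic count table
#'
#' For every (condition, timepoint) of the scenario and each independent
#' series, the stained count is drawn as
#' `Binomial(n_total_counts, mortality_pct / 100)`.
#'
#' @inheritParams generate_ct_table
#' @return Tibble of count records (`sample`, `condition`, `timepoint_h`,
#'   `total`, `stained`) with the planted mortality attached as attribute
#'   `truth`.
#' @export
generate_counts <- function(cfg, seed) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(child_seed(seed, 2L))
  design <- tidyr::expand_grid(cfg$mortality, series = seq_len(cfg$n_series))
  design$total <- cfg$n_total_counts
  design$stained <- rbinom(nrow(design), design$total,
                           design$mortality_pct / 100)
  out <- tibble(
    sample = paste(design$condition, design$timepoint_h, design$series,
                   sep = "_"),
    condition = design$condition,
    timepoint_h = design$timepoint_h,
    total = design$total,
    stained = design$stained
  )
  attr(out, "truth") <- cfg$mortality
  out
}

#' Generate a synthetic bright-field micrograph
#'
#' Draws roughly circular cells (anti-aliased disks with sub-pixel edge
#' coverage) on a bright background. Inside each cell, the planted
#' chlorophyll amount attenuates the red channel and the planted
#' astaxanthin amount (scaled by the scenario's attenuation level)
#' attenuates the green channel, so that after invert-and-subtract the
#' per-cell signal equals `(astaxanthin - chlorophyll) x area`. Dead
#' cells are blue-stained: red and green are additionally attenuated by
#' the stain while blue is not, leaving the astaxanthin score unchanged.
#' Gaussian pixel noise is added and the image quantised to 8 bit.
#'
#' Cell positions are drawn by dart-throwing with overlap rejection
#' (up to `max_attempts` draws); fewer than `n_cells` cells may be placed
#' on crowded canvases.
#'
#' @inheritParams generate_ct_table
#' @param width,height image size in pixels.
#' @param n_cells target number of cells.
#' @param dead_fraction probability that a cell is dead (default: the
#'   scenario condition's mortality at its last timepoint / 100).
#' @param max_attempts dart-throwing budget (default 10000).
#' @return List with `image` (a [micrograph()]) and `truth` (tibble:
#'   `cell`, `row`, `col`, `radius_px`, `dead`, `asta_px`, `chl_px`,
#'   `area_px`, `net_total` — the planted integrated astaxanthin-minus-
#'   chlorophyll density the scoring pipeline should recover).
#' @export
generate_micrograph <- function(cfg, seed, width = 512, height = 512,
                                n_cells = 12, dead_fraction = NULL,
                                max_attempts = 10000) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(child_seed(seed, 3L))
  if (is.null(dead_fraction)) {
    own <- cfg$mortality[cfg$mortality$condition == cfg$label, ]
    dead_fraction <- if (nrow(own)) own$mortality_pct[nrow(own)] / 100 else 0
  }
  bg <- 230
  r_ch <- matrix(bg, height, width)
  g_ch <- matrix(bg, height, width)
  b_ch <- matrix(bg, height, width)

  # dart-throwing placement with overlap rejection
  centres <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  attempts <- 0L
  # largest radius that still fits the canvas with a margin
  r_max <- min(cfg$radius_px_range[2], (min(width, height) - 6) / 2)
  r_min <- min(cfg$radius_px_range[1], r_max)
  while (length(radii) < n_cells && attempts < max_attempts) {
    attempts <- attempts + 1L
    r <- runif(1, r_min, r_max)
    cy <- runif(1, r + 2, height - r - 1)
    cx <- runif(1, r + 2, width - r - 1)
    if (length(radii) == 0 ||
        all(sqrt((centres[, 1] - cy)^2 + (centres[, 2] - cx)^2) >
            radii + r + 4)) {
      centres <- rbind(centres, c(cy, cx))
      radii <- c(radii, r)
    }
  }
  n <- length(radii)
  truth <- tibble(
    cell = seq_len(n),
    row = if (n) centres[, 1] - 1 else numeric(),  # 0-based
    col = if (n) centres[, 2] - 1 else numeric(),
    radius_px = radii,
    dead = if (n) runif(n) < dead_fraction else logical(),
    asta_px = if (n) cfg$attenuation * runif(n, 60, 100) else numeric(),
    chl_px = if (n) runif(n, 60, 110) else numeric(),
    area_px = numeric(n)
  )
  stain <- 160
  for (i in seq_len(n)) {
    r <- radii[i]; cy <- centres[i, 1]; cx <- centres[i, 2]
    rows <- max(1, floor(cy - r - 1)):min(height, ceiling(cy + r + 1))
    cols <- max(1, floor(cx - r - 1)):min(width, ceiling(cx + r + 1))
    d <- sqrt(outer((rows - cy)^2, (cols - cx)^2, `+`))
    cov <- pmin(pmax(r + 0.5 - d, 0), 1)
    truth$area_px[i] <- sum(cov)
    extra <- if (truth$dead[i]) stain else 0
    r_ch[rows, cols] <- r_ch[rows, cols] - cov * (truth$chl_px[i] + extra)
    g_ch[rows, cols] <- g_ch[rows, cols] - cov * (truth$asta_px[i] + extra)
    b_ch[rows, cols] <- b_ch[rows, cols] -
      cov * (if (truth$dead[i]) 0 else 0.5 * truth$chl_px[i])
  }
  clamp8 <- function(m) {
    if (cfg$image_noise_sd > 0) m <- m + rnorm(length(m), sd = cfg$image_noise_sd)
    matrix(pmin(pmax(round(m), 0), 255), nrow(m), ncol(m))
  }
  truth$net_total <- (truth$asta_px - truth$chl_px) * truth$area_px
  list(
    image = micrograph(clamp8(r_ch), clamp8(g_ch), clamp8(b_ch),
                       pixel_size_um = cfg$pixel_size_um),
    truth = truth
  )
}

#' Generate a batch of micrographs totalling at least `n_cells_total` cells
#'
#' @inheritParams generate_micrograph
#' @param n_cells_total minimum number of cells across the batch.
#' @param ... passed to [generate_micrograph()].
#' @return List with `images` (named list of [micrograph()]) and `truth`
#'   (tibble with an `image` column).
#' @export
generate_micrograph_batch <- function(cfg, seed, n_cells_total = 100, ...) {
  images <- list()
  truths <- list()
  placed <- 0L
  i <- 0L
  while (placed < n_cells_total) {
    i <- i + 1L
    out <- generate_micrograph(cfg, child_seed(seed, 100L + i), ...)
    nm <- sprintf("img%03d", i)
    images[[nm]] <- out$image
    out$truth$image <- nm
    truths[[nm]] <- out$truth
    placed <- placed + nrow(out$truth)
  }
  list(images = images, truth = dplyr::bind_rows(truths))
}
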