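# End-to-end orchestration: the membrane-charging modelling report, and
# full synthetic-scenario runs (generate -> score -> count -> qPCR ->
# stats) with deterministic seeds and a run manifest.

#' Membrane-charging modelling report
#'
#' Computes the charging curve over an azimuth x time grid, the
#' permeabilisation-geometry summary for each pulse duration, and the
#' specific-energy dose report, optionally writing CSVs and a
#' voltage-vs-time figure (one line per azimuth, threshold line, with
#' the above-threshold band dashed as hypothetical).
#'
#' @param out_dir output directory for CSVs (created if missing); `NULL`
#'   to skip writing.
#' @param config optional path to a YAML configuration (see
#'   [read_electro_config()]); overrides `cell`/`durations_ns`/`v_th`.
#' @param cell a [cell_model()].
#' @param field_kV_cm field strength, kV/cm.
#' @param durations_ns pulse durations to summarise, ns.
#' @param v_th electroporation threshold, V.
#' @param theta_grid,t_grid grids for the charging curve (degrees, ns).
#' @param plot write a charging-curve figure (PDF)? Default FALSE so
#'   headless runs stay file-only.
#' @return List with `curve` ([charging_curve()]), `permeabilisation`
#'   (tibble over `durations_ns`) and `dose` (tibble, one row per
#'   duration), invisibly when writing.
#' @export
run_modelling_report <- function(out_dir = NULL, config = NULL,
                                 cell = cell_model(), field_kV_cm = 40,
                                 durations_ns = c(25, 50), v_th = 1,
                                 theta_grid = seq(0, 90, by = 10),
                                 t_grid = seq(0, 100, by = 1),
                                 plot = FALSE) {
  if (!is.null(config)) {
    cfg <- read_electro_config(config)
    cell <- cfg$cell
    v_th <- cfg$v_th
    field_kV_cm <- cfg$protocols[[1]]$field_kV_cm
    durations_ns <- vapply(cfg$protocols, function(p) p$duration_ns, numeric(1))
  }
  curve <- charging_curve(cell, field_kV_cm, theta_grid, t_grid, v_th = v_th)
  perm <- permeabilisation_summary(cell, field_kV_cm, durations_ns, v_th = v_th)
  dose <- dplyr::bind_rows(lapply(durations_ns, function(d) {
    rep <- specific_energy(pulse_protocol(
      field_kV_cm = field_kV_cm, duration_ns = d,
      sigma_e_mS_cm = cell$sigma_e_mS_cm
    ))
    rep$duration_ns <- d
    rep
  }))
  out <- list(curve = curve, permeabilisation = perm, dose = dose)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(format(as.data.frame(curve), digits = 6),
              file.path(out_dir, "charging_curve.csv"), row.names = FALSE)
    write.csv(format(as.data.frame(perm), digits = 6),
              file.path(out_dir, "permeabilisation.csv"), row.names = FALSE)
    write.csv(format(as.data.frame(dose), digits = 6),
              file.path(out_dir, "dose.csv"), row.names = FALSE)
    if (plot) {
      grDevices::pdf(file.path(out_dir, "charging_curve.pdf"), width = 7,
                     height = 5)
      on.exit(grDevices::dev.off(), add = TRUE)
      plot_charging_curve(curve)
    }
    return(invisible(out))
  }
  out
}

#' Plot a charging curve
#'
#' Voltage vs time, one line per azimuth, with the electroporation
#' threshold drawn as a horizontal line; segments above threshold are
#' hypothetical (the membrane is expected to break down there) and are
#' drawn dashed.
#'
#' @param curve a [charging_curve()].
#' @export
plot_charging_curve <- function(curve) {
  stopifnot(inherits(curve, "charging_curve"))
  vm <- curve$v_m
  graphics::matplot(curve$t_ns, t(pmin(vm, curve$v_th)), type = "l",
                    lty = 1, col = seq_len(nrow(vm)),
                    xlab = "time (ns)", ylab = "V_m (V)",
                    ylim = range(vm),
                    main = "Membrane charging by azimuth")
  hyp <- vm
  hyp[vm <= curve$v_th] <- NA
  graphics::matlines(curve$t_ns, t(hyp), lty = 2, col = seq_len(nrow(vm)))
  graphics::abline(h = curve$v_th, col = "grey40")
  graphics::legend("topleft", legend = paste0(curve$theta_deg, "°"),
                   col = seq_along(curve$theta_deg), lty = 1, cex = 0.7)
  invisible(curve)
}

#' Run a full synthetic scenario end to end
#'
#' Generates count tables, Ct tables and micrographs for a named preset
#' scenario, runs them through the mortality, expression and pigment
#' pipelines, annotates t-test significance against the control arm, and
#' writes all tables plus a run manifest (file inventory with MD5
#' checksums, seed, configuration snapshot) to `out_dir`. Deterministic:
#' a fixed (scenario, seed) reproduces identical outputs (the manifest
#' timestamp aside).
#'
#' @param name preset scenario name (see [preset_scenarios()]).
#' @param seed integer seed.
#' @param out_dir output directory; `NULL` returns results without
#'   writing.
#' @param n_images micrographs to generate (default 2).
#' @param cells_per_image target cells per micrograph (default 12).
#' @param write_images also write the micrographs as TIFF? Default FALSE.
#' @return List with `scenario`, `counts`, `mortality`, `ct`,
#'   `expression`, `scores`, `pigment_summary`, `image_truth`,
#'   `mortality_tests` and (when writing) `manifest`.
#' @export
run_scenario <- function(name, seed = 1, out_dir = NULL, n_images = 2,
                         cells_per_image = 12, write_images = FALSE) {
  presets <- preset_scenarios()
  if (!name %in% names(presets)) {
    abort_config(sprintf("unknown scenario '%s'; available: %s",
                         name, paste(names(presets), collapse = ", ")))
  }
  cfg <- presets[[name]]

  counts <- generate_counts(cfg, seed)
  mortality <- aggregate_mortality(counts)

  ct <- generate_ct_table(cfg, seed)
  refspec <- reference_spec(baseline_condition = cfg$baseline_condition,
                            baseline_timepoint_h = cfg$baseline_timepoint_h)
  expr <- expression_table(ct, refspec)

  images <- lapply(seq_len(n_images), function(i) {
    generate_micrograph(cfg, child_seed(seed, 500L + i),
                        n_cells = cells_per_image)
  })
  names(images) <- sprintf("img%03d", seq_len(n_images))
  truth <- dplyr::bind_rows(lapply(names(images), function(nm) {
    tr <- images[[nm]]$truth
    tr$image <- nm
    tr
  }))
  scores <- score_images(lapply(images, `[[`, "image"))
  scores$experiment <- scores$image
  pigment <- if (nrow(scores)) {
    population_summary(scores, min_cells = 0)
  } else {
    NULL
  }

  # per-timepoint t-tests of treated vs control mortality across series
  tests <- NULL
  if (length(unique(counts$condition)) > 1) {
    per_series <- counts
    per_series$value <- mortality_fraction(counts$stained, counts$total)
    per_series$group <- per_series$condition
    tests <- dplyr::bind_rows(lapply(
      unique(per_series$timepoint_h),
      function(tp) {
        sub <- per_series[per_series$timepoint_h == tp, ]
        res <- compare_to_reference(sub, "control")
        res$timepoint_h <- tp
        res
      }
    ))
  }

  out <- list(scenario = name, seed = seed, counts = counts,
              mortality = mortality, ct = ct, expression = expr,
              scores = scores, pigment_summary = pigment,
              image_truth = truth, mortality_tests = tests)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, file) {
      write.csv(format(as.data.frame(x), digits = 6),
                file.path(out_dir, file), row.names = FALSE)
      file
    }
    files <- c(
      wr(counts, "counts.csv"),
      wr(mortality, "mortality.csv"),
      wr(ct, "ct.csv"),
      wr(expr, "expression.csv"),
      wr(scores, "scores.csv")
    )
    if (!is.null(tests)) files <- c(files, wr(tests, "mortality_tests.csv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         digits = 6, dataframe = "rows")
    files <- c(files, "truth.json")
    if (write_images) {
      for (nm in names(images)) {
        f <- paste0(nm, ".tif")
        write_micrograph(images[[nm]]$image, file.path(out_dir, f))
        files <- c(files, f)
      }
    }
    manifest <- list(
      package = "pefastax",
      version = as.character(utils::packageVersion("pefastax")),
      scenario = name,
      seed = seed,
      config = list(label = cfg$label, pulse = cfg$pulse,
                    inhibitor = cfg$inhibitor, ct_sd = cfg$ct_sd,
                    image_noise_sd = cfg$image_noise_sd,
                    attenuation = cfg$attenuation),
      files = data.frame(
        file = files,
        md5 = unname(tools::md5sum(file.path(out_dir, files))),
        stringsAsFactors = FALSE
      ),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    out$manifest <- manifest
  }
  out
}
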