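# shared fixtures: hand-built segmentations, disk images drawn
# independently of the package generator, and a minimal scenario builder

# wrap a label matrix as a segmentation object
make_seg <- function(labels) {
  structure(list(labels = labels, regions = pefastax:::.region_table(labels)),
            class = "cell_segmentation")
}

# draw hard-edged disks on a bright background (independent of the
# package's anti-aliased generator)
disk_image <- function(height, width, centres, radii, bg = 230, dark = 80) {
  m <- matrix(bg, height, width)
  for (i in seq_len(nrow(centres))) {
    for (rr in seq_len(height)) {
      d2 <- (rr - centres[i, 1])^2 + (seq_len(width) - centres[i, 2])^2
      m[rr, d2 <= radii[i]^2] <- dark
    }
  }
  micrograph(m, m, m)
}

# nearest-centroid matching of segmented regions to generator truth
match_truth <- function(seg, truth) {
  vapply(seq_len(nrow(seg$regions)), function(i) {
    which.min((truth$row - seg$regions$centroid_row[i])^2 +
              (truth$col - seg$regions$centroid_col[i])^2)
  }, integer(1))
}

# minimal single-condition scenario for generator edge cases
tiny_scenario <- function(mortality_pct = 10, log2fc = 0, gene = "psy",
                          timepoint = 18, ct_sd = 0.2, image_noise_sd = 8,
                          attenuation = 0.5, n_total_counts = 1500,
                          label = "test") {
  scenario_config(
    label = label, pulse = "control", inhibitor = "none",
    timepoints_h = timepoint,
    mortality = data.frame(condition = label, timepoint_h = timepoint,
                           mortality_pct = mortality_pct),
    log2fc = data.frame(condition = label, gene = gene,
                        timepoint_h = timepoint, log2fc = log2fc),
    attenuation = attenuation, ct_sd = ct_sd,
    image_noise_sd = image_noise_sd,
    n_total_counts = n_total_counts,
    baseline_condition = label, baseline_timepoint_h = timepoint
  )
}

hp_cell <- function() cell_model()  # study defaults
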