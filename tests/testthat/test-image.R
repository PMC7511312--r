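# channel-arithmetic astaxanthin scoring

test_that("inversion maps v to 255 - v and is an involution", {
  z <- matrix(0, 4, 4)
  img <- micrograph(z, z, z)
  inv <- invert_image(img)
  expect_true(all(inv$r == 255) && all(inv$g == 255) && all(inv$b == 255))

  px <- micrograph(matrix(10, 1, 1), matrix(200, 1, 1), matrix(255, 1, 1))
  ipx <- invert_image(px)
  expect_equal(c(ipx$r, ipx$g, ipx$b), c(245, 55, 0))

  set.seed(11)
  rnd <- micrograph(matrix(sample(0:255, 64, TRUE), 8),
                    matrix(sample(0:255, 64, TRUE), 8),
                    matrix(sample(0:255, 64, TRUE), 8))
  expect_equal(invert_image(invert_image(rnd)), rnd, ignore_attr = TRUE)
  expect_error(micrograph(matrix(-1, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2)),
               "8-bit")
})

test_that("astaxanthin signal is the signed green-minus-red difference", {
  g <- matrix(100, 3, 3); r <- matrix(30, 3, 3)
  img <- micrograph(r, g, matrix(0, 3, 3))
  expect_true(all(astaxanthin_signal(img) == 70))
  same <- micrograph(g, g, matrix(7, 3, 3))
  expect_true(all(astaxanthin_signal(same) == 0))
  neg <- micrograph(g, r, matrix(0, 3, 3))
  expect_true(all(astaxanthin_signal(neg) == -70))
  expect_true(all(astaxanthin_signal(neg, clip_negative = TRUE) == 0))
})

test_that("region sums equal the brute-force per-pixel accumulation", {
  set.seed(21)
  for (k in 1:5) {
    r <- matrix(sample(0:255, 400, TRUE), 20)
    g <- matrix(sample(0:255, 400, TRUE), 20)
    inv <- invert_image(micrograph(r, g, matrix(0, 20, 20)))
    a <- astaxanthin_signal(inv)
    labels <- matrix(sample(0:3, 400, TRUE), 20)
    seg <- make_seg(labels)
    sc <- integrated_density(a, seg)
    # brute-force pixel loop oracle
    acc <- numeric(max(labels))
    for (i in 1:20) for (j in 1:20) {
      l <- labels[i, j]
      if (l > 0) acc[l] <- acc[l] + (inv$g[i, j] - inv$r[i, j])
    }
    expect_equal(sc$density, acc[sc$cell])
    # linearity: region sum of the difference = difference of region sums
    for (l in sc$cell) {
      expect_equal(sc$density[sc$cell == l],
                   sum(inv$g[labels == l]) - sum(inv$r[labels == l]))
    }
  }
})

test_that("scores ignore the blue channel and cancel shared offsets", {
  set.seed(22)
  r <- matrix(sample(30:160, 400, TRUE), 20)
  g <- matrix(sample(30:160, 400, TRUE), 20)
  labels <- matrix(sample(0:2, 400, TRUE), 20)
  seg <- make_seg(labels)
  score <- function(img) {
    integrated_density(astaxanthin_signal(invert_image(img)), seg)$density
  }
  b1 <- matrix(0, 20, 20); b2 <- matrix(sample(0:255, 400, TRUE), 20)
  expect_equal(score(micrograph(r, g, b1)), score(micrograph(r, g, b2)))
  # adding the same constant to R and G of the original leaves scores unchanged
  expect_equal(score(micrograph(r + 40, g + 40, b1)),
               score(micrograph(r, g, b1)))
})

test_that("integrated density handles trivial and invalid inputs", {
  labels <- matrix(0L, 10, 10); labels[3:7, 3:7] <- 1L
  seg <- make_seg(labels)
  expect_equal(integrated_density(matrix(0, 10, 10), seg)$density, 0)
  # uniform signal 70 over a 25-px region
  expect_equal(integrated_density(matrix(70, 10, 10), seg)$density, 70 * 25)
  expect_error(integrated_density(matrix(0, 5, 5), seg), "dimensions")
})

test_that("segmentation recovers planted disks", {
  blank <- micrograph(matrix(230, 64, 64), matrix(230, 64, 64),
                      matrix(230, 64, 64))
  expect_equal(nrow(segment_cells(blank)$regions), 0)

  centres <- rbind(c(25, 25), c(25, 75), c(75, 25), c(75, 75), c(50, 50))
  img <- disk_image(100, 100, centres, radii = rep(9, 5))
  seg <- segment_cells(img, min_area = 50)
  expect_equal(nrow(seg$regions), 5)
  ord <- match_truth(seg, data.frame(row = centres[, 1] - 1,
                                     col = centres[, 2] - 1))
  expect_true(all(abs(seg$regions$centroid_row - (centres[ord, 1] - 1)) <= 1))
  expect_true(all(abs(seg$regions$centroid_col - (centres[ord, 2] - 1)) <= 1))
  # sub-threshold regions are dropped
  small <- disk_image(50, 50, rbind(c(25, 25)), radii = 3)
  expect_equal(nrow(segment_cells(small, min_area = 50)$regions), 0)
  # touching disks merge into a single region (documented behaviour)
  touching <- disk_image(60, 60, rbind(c(30, 24), c(30, 38)), radii = c(8, 8))
  expect_equal(nrow(segment_cells(touching)$regions), 1)
  # border-touching regions are discarded by default
  border <- disk_image(60, 60, rbind(c(5, 30)), radii = 8)
  expect_equal(nrow(segment_cells(border)$regions), 0)
  expect_equal(nrow(segment_cells(border, discard_border = FALSE)$regions), 1)
})

test_that("population summary aggregates per experiment then across", {
  one <- data.frame(experiment = "a", density = 5)
  s1 <- suppressWarnings(population_summary(one))
  expect_equal(s1$mean_density, 5)
  expect_true(is.na(s1$se_density))

  three <- data.frame(experiment = rep(c("a", "b", "c"), each = 4),
                      density = rep(c(1, 3), 6))
  s3 <- suppressWarnings(population_summary(three))
  expect_equal(s3$mean_density, 2)
  expect_equal(s3$se_density, 0)
  expect_warning(population_summary(three), "fewer than")

  # sampling-theory recovery: known mean, 600 cells x 3 experiments
  set.seed(31)
  mu <- 40
  big <- data.frame(experiment = rep(c("a", "b", "c"), each = 600),
                    density = rnorm(1800, mu, 15))
  sb <- population_summary(big)
  expect_lt(abs(sb$mean_density - mu), 3 * 15 / sqrt(1800))
  expect_error(population_summary(data.frame()), "non-empty")
})

test_that("mean score per condition is monotone in the attenuation level", {
  levels <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  means <- vapply(levels, function(att) {
    cfg <- tiny_scenario(attenuation = att, image_noise_sd = 4)
    out <- generate_micrograph(cfg, 99, width = 384, height = 384,
                               n_cells = 8, dead_fraction = 0)
    seg <- segment_cells(out$image)
    sc <- integrated_density(astaxanthin_signal(invert_image(out$image)), seg)
    mean(sc$density / sc$area)  # per-pixel mean is area-robust
  }, numeric(1))
  expect_equal(cor(means, levels, method = "spearman"), 1)
})

test_that("raising the dead fraction leaves the mean pigment score stable", {
  # per-cell scoring: mortality must not inflate the astaxanthin estimate
  score_mean <- function(dead_fraction, seed) {
    cfg <- tiny_scenario(attenuation = 0.5, image_noise_sd = 4)
    b <- generate_micrograph_batch(cfg, seed, n_cells_total = 40,
                                   width = 384, height = 384, n_cells = 8,
                                   dead_fraction = dead_fraction)
    sc <- score_images(b$images)
    mean(sc$density / sc$area)
  }
  alive <- score_mean(0, 41)
  half_dead <- score_mean(0.5, 42)
  # planted per-pixel net is (asta - chl): mean ~ -45, spread ~ 25
  expect_lt(abs(alive - half_dead), 15)
})

test_that("micrograph files round-trip through TIFF and PNG", {
  cfg <- tiny_scenario(image_noise_sd = 0)
  out <- generate_micrograph(cfg, 5, width = 96, height = 96, n_cells = 2)
  for (ext in c("tif", "png")) {
    path <- file.path(tempdir(), paste0("roundtrip.", ext))
    write_micrograph(out$image, path)
    back <- read_micrograph(path)
    expect_equal(back$r, out$image$r, ignore_attr = TRUE)
    expect_equal(back$g, out$image$g, ignore_attr = TRUE)
    unlink(path)
  }
})
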