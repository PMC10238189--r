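test_that("partitioning conserves molecules and respects trivial inputs", {
  layout <- small_layout()
  cfg <- sim_config(retention_fraction = 1, exact_copies = TRUE)
  withr::with_seed(1, {
    expect_equal(partition_molecules(0, layout, 1, cfg), rep(0L, 500))
    one <- partition_molecules(1, layout, 1, cfg)
    expect_equal(sum(one), 1L)
    expect_equal(sum(one > 0), 1L)
    many <- partition_molecules(137, layout, 1, cfg)
    expect_equal(sum(many), 137L)
  })
  expect_error(partition_molecules(-1, layout, 1, cfg),
               class = "dmspr_domain_error")
  expect_error(partition_molecules(5, layout, 3, cfg),
               class = "dmspr_domain_error")
})

test_that("mean retained fraction matches the retention probability", {
  layout <- small_layout()
  cfg <- sim_config(retention_fraction = 0.5, exact_copies = TRUE)
  m <- 200
  withr::with_seed(2, {
    retained <- replicate(4000, sum(partition_molecules(m, layout, 1, cfg)))
  })
  # retained ~ Binomial(200, 0.5) per replicate
  se <- sqrt(0.5 * 0.5 / (m * 4000))
  expect_lt(abs(mean(retained) / m - 0.5), 3 * se)
  expect_equal(sd(retained), sqrt(m * 0.25), tolerance = 0.1)
})

test_that("occupied-well count matches the Poisson occupancy closed form", {
  layout <- small_layout(1000, 25, 40)
  cfg <- sim_config(retention_fraction = 1)
  n_copies <- 100; N <- 1000; reps <- 4000
  withr::with_seed(3, {
    occ <- replicate(reps, sum(partition_molecules(n_copies, layout, 1, cfg) > 0))
  })
  # E[occupied] = N (1 - exp(-c/N)) for M ~ Poisson(c) thrown uniformly
  expected <- N * (1 - exp(-n_copies / N))
  expect_lt(abs(mean(occ) - expected), 3 * sd(occ) / sqrt(reps))
})

test_that("positive wells never exceed molecules, with equality absent collisions", {
  layout <- small_layout()
  cfg <- sim_config(retention_fraction = 1, amplification_probability = 1,
                    exact_copies = TRUE)
  withr::with_seed(4, {
    for (i in 1:50) {
      counts <- partition_molecules(sample(0:30, 1), layout, 1, cfg)
      amp <- amplify_wells(counts, cfg)
      expect_lte(sum(amp), sum(counts))
      if (all(counts <= 1)) expect_equal(sum(amp), sum(counts))
      expect_true(all(counts[amp] >= 1))
    }
  })
})

test_that("ideal rendering is exact: well interiors at background + negative mean", {
  layout <- small_layout(12, 3, 4)
  cfg <- quiet_config(background_level = 500, negative_mean = 1000)
  map <- default_geometry_map(layout, 1, cfg)
  img <- render_image(layout, map, matrix(FALSE, 12, 1,
                                          dimnames = list(NULL, "FAM")), cfg)
  wells <- extract_well_intensities(img, map, layout, aperture_radius = 1.5)
  expect_equal(wells$FAM, rep(1500, 12))
  # off-well background is exactly background_level
  expect_equal(img$FAM[1, 1], 500L)
  # a single positive well puts the image maximum inside that well's disk
  state <- matrix(FALSE, 12, 1, dimnames = list(NULL, "FAM")); state[7] <- TRUE
  img2 <- render_image(layout, map, state, cfg)
  peak <- which(img2$FAM == max(img2$FAM), arr.ind = TRUE)
  centers <- well_centers(map, layout)
  d <- sqrt((peak[, 2] - 1 - centers$x_px[7])^2 + (peak[, 1] - 1 - centers$y_px[7])^2)
  expect_true(all(d <= 2.5))
})

test_that("wells mapped outside the image raise an out-of-frame error", {
  layout <- small_layout(12, 3, 4)
  cfg <- quiet_config()
  map <- default_geometry_map(layout, 1, cfg)
  expect_error(render_image(layout, map, matrix(FALSE, 12, 1), cfg,
                            image_dim = c(10, 10)),
               class = "dmspr_out_of_frame_error")
})

test_that("render-extract-call round trip recovers every well state", {
  layout <- small_layout()
  cfg <- sim_config(seed = 5, retention_fraction = 1)
  map <- default_geometry_map(layout, 1, cfg)
  withr::with_seed(5, {
    state <- matrix(runif(500 * 4) < 0.04, 500, 4,
                    dimnames = list(NULL, cfg$channels))
  })
  img <- render_image(layout, map, state, cfg)
  wells <- extract_well_intensities(img, map, layout)
  res <- call_wells(wells, fit_channel_mixtures(wells))
  for (ch in cfg$channels) {
    expect_equal(res$calls[[ch]], unname(state[, ch]))
  }
})

test_that("the simulated standard curve has the expected shape and determinism", {
  layout <- small_layout()
  cfg <- sim_config(seed = 6)
  curve <- simulate_standard_curve(c(0, 6.25, 25), replicates = 2,
                                   background_copies = 1000,
                                   layout = layout, config = cfg)
  expect_equal(nrow(curve), 6)
  expect_equal(nrow(curve$wells[[1]]), 500)
  # zero-copy replicates are all-negative in truth
  zero <- dplyr::bind_rows(curve$truth[curve$nominal_copies == 0])
  expect_true(all(zero$amplified_wells == 0))
  # same seed, bit-identical output
  curve2 <- simulate_standard_curve(c(0, 6.25, 25), replicates = 2,
                                    background_copies = 1000,
                                    layout = layout, config = cfg)
  expect_identical(curve$wells, curve2$wells)
  expect_identical(curve$truth, curve2$truth)
  expect_error(simulate_standard_curve(numeric(0)), class = "dmspr_domain_error")
})

test_that("detected counts at a fixed load match the occupancy expectation", {
  layout <- small_layout(1000, 25, 40)
  cfg <- sim_config(retention_fraction = 1, amplification_probability = 1)
  N <- 1000; copies <- 10; reps <- 800
  withr::with_seed(8, {
    det <- replicate(reps, {
      counts <- partition_molecules(copies, layout, 1, cfg)
      sum(amplify_wells(counts, cfg))
    })
  })
  expected <- N * (1 - exp(-copies / N))
  expect_lt(abs(mean(det) - expected), 3 * sd(det) / sqrt(reps))
})

test_that("cohort generator reproduces the study shape and honours seeds", {
  cohort <- simulate_cohort(39, 33, seed = 9)
  expect_equal(nrow(cohort), 72)
  expect_equal(sum(cohort$label == "case"), 39)
  expect_equal(sum(cohort$label == "control"), 33)
  expect_true(all(c("SOX17", "CDO1", "TAC1", "HOXA7", "age", "pack_years")
                  %in% names(cohort)))
  # concentrations are whole molecules per digitized volume
  expect_true(all(cohort$SOX17 %% 10 == 0))
  expect_identical(cohort, simulate_cohort(39, 33, seed = 9))
  # degenerate separation: a huge case rate separates perfectly
  sep <- simulate_cohort(20, 20, tibble::tibble(marker = "M1", case_rate = 500,
                                                control_rate = 0), seed = 10)
  met <- sensitivity_specificity(sep$M1 > 0, sep$label)
  expect_equal(met$sensitivity, 100)
  expect_equal(met$specificity, 100)
})
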