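test_that("zero-noise trajectories realise their phenotype exactly", {
  pa <- generate_behaviour_trajectory("PainAlone", 100, 0, seed = 1)
  expect_equal(c(pa$pre$dominance_s, pa$post$dominance_s), rep(100, 12))

  pt <- generate_behaviour_trajectory("PainTransientDisability", 100, 0,
                                      seed = 1)
  expect_true(all(pt$post$dominance_s[1:3] <= 60))
  expect_equal(pt$post$dominance_s[5:6], c(100, 100))

  pd <- generate_behaviour_trajectory("PainDisability", 100, 0, seed = 1)
  expect_true(all(pd$post$dominance_s <= 60))
  for (lab in cci_levels()) {
    tr <- generate_behaviour_trajectory(lab, 100, 0, seed = 1)
    expect_identical(classify_phenotype(tr), lab)
  }
  expect_error(generate_behaviour_trajectory("PainAlone", 0, 0, seed = 1),
               "baseline_dominance")
  expect_error(generate_behaviour_trajectory("NotALabel", 100, 0, seed = 1),
               "invalid phenotype")
})

test_that("dominance lost to injury moves into non-social behaviour", {
  pd <- generate_behaviour_trajectory("PainDisability", 100, 0, seed = 1)
  pa <- generate_behaviour_trajectory("PainAlone", 100, 0, seed = 1)
  expect_equal(pd$post$nonsocial_s - pa$post$nonsocial_s,
               pa$post$dominance_s - pd$post$dominance_s)
  expect_equal(rowSums(pd$post), rowSums(pa$post))
})

test_that("noisy trajectories respect duration bounds", {
  for (seed in 1:10) {
    tr <- generate_behaviour_trajectory("PainDisability", 200, 60, seed = seed)
    m <- as.matrix(rbind(tr$pre, tr$post))
    expect_true(all(m >= 0))
    expect_true(all(rowSums(m) <= 360 + 1e-9))
  }
})

test_that("withdrawal generator applies the sham override and is seeded", {
  sham <- generate_withdrawal_series("Sham", 30, 10, seed = 1, trial_sd = 0)
  expect_equal(sham$post_g, c(30, 30))
  pa <- generate_withdrawal_series("PainAlone", 30, 10, seed = 1,
                                   trial_sd = 0)
  expect_equal(pa$post_g, c(20, 20))
  expect_equal(pa$baseline_g, rep(30, 3))

  a <- generate_withdrawal_series("PainAlone", 40, 15, seed = 8)
  b <- generate_withdrawal_series("PainAlone", 40, 15, seed = 8)
  expect_identical(a, b)
  expect_error(generate_withdrawal_series("PainAlone", 30, 30, seed = 1),
               "smaller than baseline")
  expect_error(generate_withdrawal_series("PainAlone", -5, 1, seed = 1),
               "positive")
})

test_that("cytokine panels honour censoring and degenerate parameters", {
  cfg <- cohort_config(seed = 2)
  panel <- generate_cytokine_panel("nerve", "PainDisability", cfg, seed = 3)
  il1b <- panel[panel$analyte == "IL1b", ]
  expect_true(all(il1b$censor == "high"))
  expect_true(all(il1b$conc_pg_ml == 3860))

  sham <- generate_cytokine_panel("nerve", "Sham", cfg, seed = 3)
  ifng <- sham[sham$analyte == "IFNg", ]
  expect_true(all(ifng$censor == "low"))
  expect_true(all(ifng$conc_pg_ml == 5))

  # every emitted value lies inside the assay range unless flagged
  for (tissue in c("nerve", "drg", "spinal")) {
    p <- generate_cytokine_panel(tissue, "PainAlone", cfg, seed = 11)
    rng <- merge(p, cfg$assay_range, by = "analyte")
    free <- rng[rng$censor == "none", ]
    expect_true(all(free$conc_pg_ml >= free$lower &
                      free$conc_pg_ml <= free$upper))
  }

  # SEM = 0 collapses the distribution onto the configured mean
  params0 <- cfg$group_cytokine_params
  params0$sem[params0$censor == "none"] <- 0
  cfg0 <- cohort_config(seed = 2, group_cytokine_params = params0)
  p0 <- generate_cytokine_panel("drg", "PainAlone", cfg0, seed = 5)
  ref <- params0[params0$tissue == "drg" & params0$group == "PainAlone", ]
  expect_equal(p0$conc_pg_ml,
               ref$mean[match(p0$analyte, ref$analyte)])

  expect_error(generate_cytokine_panel("liver", "PainAlone", cfg, seed = 1),
               "missing cytokine parameters")
})

test_that("simulated analyte distributions recover configured parameters", {
  # drg IL-6, PainDisability: mean 90.2, per-animal SD = 9.9 * sqrt(5)
  cfg <- cohort_config(seed = 2,
                       n_per_group = c(Sham = 2L, PainDisability = 10000L,
                                       PainTransientDisability = 2L,
                                       PainAlone = 2L))
  p <- generate_cytokine_panel("drg", "PainDisability", cfg, seed = 13)
  x <- p$conc_pg_ml[p$analyte == "IL6"]
  expect_length(x, 10000L)
  expect_lt(abs(mean(x) - 90.2) / 90.2, 0.02)
  expect_lt(abs(sd(x) - 9.9 * sqrt(5)) / (9.9 * sqrt(5)), 0.02)
})

test_that("ground-truth fields keep their bookkeeping promises", {
  empty <- generate_field_image(0, seed = 1)
  expect_equal(empty$true_count, 0)
  expect_equal(nrow(empty$true_positions), 0)
  expect_false(any(empty$true_mask))

  f <- generate_field_image(25, seed = 2)
  expect_equal(f$true_count, 25)
  expect_equal(nrow(f$true_positions), 25)
  p <- default_image_params()
  expect_true(all(f$true_positions[, 1] >= 1 &
                    f$true_positions[, 1] <= p$width_px))
  expect_true(all(f$true_positions[, 2] >= 1 &
                    f$true_positions[, 2] <= p$height_px))
  # pairwise centre separation of at least one cell diameter
  r_px <- p$cell_radius_um / p$pixel_size_um
  d <- as.matrix(dist(f$true_positions))
  expect_true(all(d[upper.tri(d)] >= 2 * r_px))
  expect_true(all(f$image$pixels >= 0 & f$image$pixels <= 65535))

  expect_error(generate_field_image(10000, seed = 1), "cannot be placed")
})

test_that("cohort generation is deterministic and correctly sized", {
  cfg <- small_config(seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  flat <- cohort_config(n_per_group = 5L, seed = 1)
  co <- generate_cohort(flat, include_images = FALSE)
  expect_equal(nrow(co$animals), 20L)
  expect_equal(nrow(co$behaviour), 20L * 12L)
  expect_equal(nrow(co$cytokines), 20L * 8L * 3L)

  # zero-noise closure through the classifier
  cfg0 <- cohort_config(seed = 5, behaviour_noise_sd = 0)
  co0 <- generate_cohort(cfg0, include_images = FALSE)
  labels <- classify_cohort(co0$behaviour)
  expect_equal(mean(labels$label ==
                      co0$animals$group_truth[match(labels$animal_id,
                                                    co0$animals$animal_id)]),
               1)
})

test_that("label recovery does not improve as behaviour noise grows", {
  recovery <- vapply(c(0, 15, 60), function(sd_noise) {
    cfg <- cohort_config(seed = 31, behaviour_noise_sd = sd_noise,
                         n_per_group = 8L)
    co <- generate_cohort(cfg, include_images = FALSE)
    labels <- classify_cohort(co$behaviour)
    mean(labels$label == co$animals$group_truth[match(labels$animal_id,
                                                      co$animals$animal_id)])
  }, numeric(1))
  expect_true(all(diff(recovery) <= 0))
  expect_equal(recovery[1], 1)
})

test_that("written cohorts round-trip through the documented formats", {
  cfg <- small_config(seed = 12, n_per_group = c(Sham = 1L,
                                                 PainDisability = 1L,
                                                 PainTransientDisability = 1L,
                                                 PainAlone = 1L))
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("behaviour.csv",
                                               "withdrawal.csv",
                                               "cytokines.csv",
                                               "config.json")))))
  beh <- read.csv(file.path(dir, "behaviour.csv"))
  expect_equal(nrow(beh), nrow(co$behaviour))

  tifs <- list.files(file.path(dir, "images"), pattern = "\\.tif$",
                     full.names = TRUE)
  expect_length(tifs, 4L * cfg$n_fields)
  img <- read_field_tiff(file.path(dir, "images", "SH_01_field01.tif"),
                         cfg$image_params$pixel_size_um)
  orig <- co$fields[["SH_01"]][[1]]$image
  expect_equal(img$pixels, orig$pixels)
  truth <- jsonlite::read_json(file.path(dir, "images", "truth.json"))
  expect_length(truth, 4L * cfg$n_fields)
})
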