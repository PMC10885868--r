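test_that("generation is a deterministic function of the config", {
  cfg <- synth_config(n_patients = 8L, images_per_patient = 2L,
                      image_size = 16L, seed = 99L)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$latent, b$latent)
  expect_identical(lapply(a$dataset$records, `[[`, "pixels"),
                   lapply(b$dataset$records, `[[`, "pixels"))
  expect_identical(label_table(a$dataset), label_table(b$dataset))
})

test_that("generated structure obeys the panel contracts", {
  cfg <- synth_config(n_patients = 25L, seed = 3L)
  g <- generate_dataset(cfg)
  for (r in g$dataset$records) {
    expect_true(all(r$annotations$score %in% 1:8))
    expect_true(r$annotations$k %in% 2:4)
    expect_false(anyDuplicated(r$annotations$reviewer_id) > 0)
    expect_true(all(r$pixels >= 0 & r$pixels <= 1))
  }
  expect_true(all(g$latent$u >= 0 & g$latent$u <= 10))
  expect_identical(g$latent$true_class, as.integer(g$latent$u > 5))
})

test_that("written datasets round-trip through the annotation reader", {
  cfg <- synth_config(n_patients = 6L, images_per_patient = 2L,
                      image_size = 16L, seed = 12L)
  g <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(g$dataset, dir, latent = g$latent)
  back <- read_annotation_table(file.path(dir, "annotations.csv"), dir,
                                panel_size = 14L)
  expect_equal(length(back), length(g$dataset))
  for (i in seq_along(back$records)) {
    orig <- g$dataset$records[[i]]
    got <- back$records[[i]]
    expect_identical(got$image_id, orig$image_id)
    expect_identical(got$patient_id, orig$patient_id)
    expect_identical(got$annotations$score, orig$annotations$score)
    expect_identical(got$annotations$reviewer_id, orig$annotations$reviewer_id)
    # pixels survive up to 8-bit PNG quantization
    expect_lt(max(abs(got$pixels - orig$pixels)), 1 / 255)
  }
  expect_identical(label_table(back), label_table(g$dataset))
})

test_that("severity drives the scores monotonically", {
  for (seed in 1:3) {
    g <- generate_dataset(synth_config(n_patients = 80L, seed = seed))
    m <- merge(label_table(g$dataset), g$latent, by = "image_id")
    expect_gt(cor(m$u, m$mu_S, method = "spearman"), 0.85)
    lo <- m$mu_S[m$u < 3]
    hi <- m$mu_S[m$u > 7]
    expect_gt(mean(hi), mean(lo))
  }
})

test_that("disagreement concentrates near the class boundary", {
  for (seed in 1:3) {
    g <- generate_dataset(synth_config(n_patients = 80L, seed = seed + 10L))
    m <- merge(label_table(g$dataset), g$latent, by = "image_id")
    mid <- m$D[m$u >= 4 & m$u <= 6]
    ext <- m$D[m$u < 3 | m$u > 7]
    expect_gt(mean(mid), mean(ext))
  }
})

test_that("the noise-free limit gives unanimous panels", {
  cfg <- synth_config(n_patients = 20L, annotator_bias_sd = 0,
                      annotator_noise_sd = 0, seed = 4L)
  g <- generate_dataset(cfg)
  for (r in g$dataset$records)
    expect_equal(length(unique(r$annotations$score)), 1L)  # sigma term 0
  lab <- label_table(g$dataset)
  zeroD <- lab$D == 0
  expect_identical(zeroD, lab$mu_S %in% c(1, 8))
  expect_equal(label_noise_rate(g$dataset, g$latent)$overall, 0,
               tolerance = 0.02)
})

test_that("label noise is concentrated in the equivocal stratum", {
  for (seed in 1:3) {
    g <- generate_dataset(synth_config(n_patients = 100L, seed = seed + 20L))
    nr <- label_noise_rate(g$dataset, g$latent)
    expect_gt(nr$by_stratum$rate[2], nr$by_stratum$rate[1])
  }
})

test_that("benchmark pairs share the panel but not the patients", {
  b <- quick_benchmark()
  tr_p <- vapply(b$train$dataset$records, `[[`, "", "patient_id")
  ho_p <- vapply(b$holdout$dataset$records, `[[`, "", "patient_id")
  expect_length(intersect(tr_p, ho_p), 0L)
  expect_identical(b$train$panel_bias, b$panel_bias)
})

test_that("binary panels corrupt labels at the configured rates", {
  set.seed(61)
  latent <- data.frame(image_id = sprintf("i%04d", 1:4000),
                       patient_id = sprintf("p%04d", 1:4000),
                       true_class = rep(0:1, 2000))
  anns <- simulate_binary_panel(latent, flip_pos = c(0, 0.3),
                                flip_neg = c(0.1, 0), seed = 8L)
  labs <- t(vapply(anns, function(a)
    binarize_review(a$score)[order(a$reviewer_id)], integer(2)))
  pos <- latent$true_class == 1
  expect_equal(mean(labs[pos, 1] == 0), 0, tolerance = 0.02)     # faithful
  expect_equal(mean(labs[pos, 2] == 0), 0.3, tolerance = 0.03)   # flipper
  expect_equal(mean(labs[!pos, 1] == 1), 0.1, tolerance = 0.03)
  expect_equal(mean(labs[!pos, 2] == 1), 0, tolerance = 0.02)
})
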