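test_that("annotation tables round-trip images and reject invalid rows", {
  dir <- withr::local_tempdir()
  img_dir <- file.path(dir, "img")
  dir.create(img_dir)
  tab <- data.frame(image_id = "img1", patient_id = "p1",
                    reviewer_id = c(8L, 6L, 12L), score = c(6L, 2L, 2L))
  write.csv(tab, file.path(dir, "ann.csv"), row.names = FALSE)
  png::writePNG(matrix(runif(64), 8, 8), file.path(img_dir, "img1.png"))

  ds <- read_annotation_table(file.path(dir, "ann.csv"), img_dir)
  expect_length(ds, 1L)
  expect_equal(ds$records[[1]]$annotations$k, 3L)
  expect_equal(ds$records[[1]]$annotations$score, c(6L, 2L, 2L))
  expect_equal(dim(ds$records[[1]]$pixels), c(8L, 8L))

  # csv numeric-grid images are accepted too
  write.table(matrix(1:16 / 16, 4, 4), file.path(img_dir, "img2.csv"),
              sep = ",", row.names = FALSE, col.names = FALSE)
  tab2 <- rbind(tab, data.frame(image_id = "img2", patient_id = "p1",
                                reviewer_id = 1L, score = 5L))
  write.csv(tab2, file.path(dir, "ann2.csv"), row.names = FALSE)
  ds2 <- read_annotation_table(file.path(dir, "ann2.csv"), img_dir)
  expect_equal(unname(ds2$records[[2]]$pixels[2, 3]), 10 / 16)

  # empty table -> empty dataset, no error
  write.csv(tab[0, ], file.path(dir, "empty.csv"), row.names = FALSE)
  expect_length(read_annotation_table(file.path(dir, "empty.csv"), img_dir), 0L)

  # duplicate (image, reviewer) pair is named in the error
  dup <- rbind(tab, tab[1, ])
  write.csv(dup, file.path(dir, "dup.csv"), row.names = FALSE)
  expect_error(read_annotation_table(file.path(dir, "dup.csv"), img_dir),
               "img1.*8|8.*img1")

  bad <- tab; bad$score[1] <- 9L
  write.csv(bad, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_annotation_table(file.path(dir, "bad.csv"), img_dir),
               "1\\.\\.8")

  missing <- tab; missing$image_id <- "ghost"
  write.csv(missing, file.path(dir, "missing.csv"), row.names = FALSE)
  expect_error(read_annotation_table(file.path(dir, "missing.csv"), img_dir),
               "ghost")
})

test_that("mean aggregation thresholds at 4.5 with the boundary positive", {
  expect_equal(aggregate_label(example_set()),
               list(mu_S = 10 / 3, y = 0L))
  expect_equal(aggregate_label(annotation_set("a", c(8, 8), 1:2)),
               list(mu_S = 8, y = 1L))
  # mean exactly 4.5 falls on the positive side
  expect_equal(aggregate_label(annotation_set("a", c(4, 5), 1:2)),
               list(mu_S = 4.5, y = 1L))
  expect_error(annotation_set("a", integer(0), integer(0)), "empty")
})

test_that("label rule matches an enumeration oracle and ignores order", {
  for (k in 1:3) {
    grid <- as.matrix(expand.grid(rep(list(1:8), k)))
    for (i in seq_len(nrow(grid))) {
      s <- grid[i, ]
      a <- annotation_set("x", s, seq_len(k))
      expect_identical(aggregate_label(a)$y,
                       as.integer(sum(s) / k >= 4.5))
    }
  }
  set.seed(1)
  for (rep in 1:20) {
    s <- sample(1:8, 4, replace = TRUE)
    p <- sample(4)
    expect_identical(aggregate_label(annotation_set("x", s, 1:4)),
                     aggregate_label(annotation_set("x", s[p], (1:4)[p])))
  }
})

test_that("ordinal target rounds half-up and clamps to the scale", {
  expect_identical(ordinal_target(example_set()), 3L)           # mean 3.33
  expect_identical(ordinal_target(annotation_set("a", c(4, 5), 1:2)), 5L)
  expect_identical(ordinal_target(annotation_set("a", c(1, 1), 1:2)), 1L)
  # banker's rounding switch
  expect_identical(ordinal_target(annotation_set("a", c(4, 5), 1:2),
                                  half = "even"), 4L)
})

test_that("review binarization thresholds the score scale at 4.5", {
  expect_identical(binarize_review(4L), 0L)
  expect_identical(binarize_review(5L), 1L)
  expect_identical(binarize_review(8L), 1L)
  expect_identical(binarize_review(1:8), c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))
  expect_error(binarize_review(0L), "1\\.\\.8")
  expect_error(binarize_review(9L), "1\\.\\.8")
})

test_that("pairwise kappa matches the closed form and flags missing pairs", {
  # reviewers 1 and 2 share 50 images: 20 both-positive, 5+5 discordant,
  # 20 both-negative -> kappa = (0.8 - 0.5)/(1 - 0.5) = 0.6
  recs <- list()
  lab_pairs <- rbind(matrix(c(8, 8), 20, 2, byrow = TRUE),
                     matrix(c(8, 1), 5, 2, byrow = TRUE),
                     matrix(c(1, 8), 5, 2, byrow = TRUE),
                     matrix(c(1, 1), 20, 2, byrow = TRUE))
  for (i in seq_len(nrow(lab_pairs))) {
    id <- sprintf("s%02d", i)
    recs[[i]] <- list(image_id = id, patient_id = id, pixels = NULL,
                      annotations = annotation_set(id, lab_pairs[i, ], 1:2))
  }
  # reviewer 3 reviews a disjoint image alone (no shared pairs), with both
  # classes so its diagonal is defined
  recs[[51]] <- list(image_id = "solo", patient_id = "solo", pixels = NULL,
                     annotations = annotation_set("solo", 7L, 3L))
  ds <- new_dataset(recs, panel_size = 3L)
  K <- pairwise_kappa(ds)
  expect_equal(K[1, 2], 0.6)
  expect_equal(K, t(K))
  expect_true(is.na(K[1, 3]) && is.na(K[2, 3]))
  expect_equal(diag(K), c("1" = 1, "2" = 1, "3" = 1))
  fin <- K[is.finite(K)]
  expect_true(all(fin >= -1 & fin <= 1))

  # perfect agreement with both classes present
  K2 <- pairwise_kappa(new_dataset(recs[c(1:20, 41:50)], panel_size = 2L))
  expect_equal(unname(K2[1, 2]), 1)

  # writer: missing entries become empty cells
  f <- withr::local_tempfile(fileext = ".csv")
  write_kappa_csv(K, f)
  expect_true(any(grepl(",,", readLines(f))))
})

test_that("label table collects mean scores, targets and uncertainty", {
  lab <- label_table(tiny_dataset())
  expect_equal(nrow(lab), 6L)
  expect_equal(lab$D[lab$image_id == "i1"], 0)
  expect_equal(lab$D[lab$image_id == "i3"], 3.5)
  expect_equal(lab$y[lab$image_id == "i3"], 1L)
  expect_equal(lab$ordinal_target[lab$image_id == "i4"], 3L)
})

test_that("preprocessing resizes and rescales to the pretrained range", {
  px <- matrix(runif(100), 10, 10)
  out <- preprocess_cxr(px, 64L)
  expect_equal(dim(out), c(64L, 64L))
  expect_equal(range(out), c(-1024, 1024))
})
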