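#' Synthetic multi-annotator dataset configuration
#'
#' The generator emulates the statistical structure the method assumes:
#' grayscale images carrying a latent severity signal, grouped by patient;
#' a panel of M reviewers of whom 2--4 score each image on the ordinal
#' 1..8 scale; per-reviewer bias and per-review noise so that disagreement
#' (hence uncertainty D) concentrates on images whose severity sits near
#' the class boundary.
#'
#' The severity-to-score map is `s = 4.5 + a*(u - u0) + b_t + eps`,
#' rounded half-up and clamped to 1..8, with slope `a = 7 / width` so the
#' severity range spans the whole score scale and the class threshold
#' `u0` lands on the scale midpoint 4.5 — the equivocal scores 4/5 then
#' mark ambiguous images, mirroring the premise of the uncertainty
#' measure. Reviewer bias `b_t ~ N(0, annotator_bias_sd)` is drawn once
#' per panel; `eps ~ N(0, annotator_noise_sd)` per review.
#'
#' Images are `image_size^2` grayscale fields: Gaussian background noise
#' plus two lateral elliptical "lung" regions receiving Gaussian opacity
#' blobs whose total intensity grows with severity; below `u0` the blobs
#' are mostly unilateral, above it bilateral — a learnable visual
#' correlate of the bilateral-opacity criterion, with no claim of
#' radiological realism.
#'
#' @param n_patients number of patients.
#' @param images_per_patient integer range of images per patient.
#' @param image_size image side length (32 keeps a full cross-validated
#'   benchmark to minutes on one CPU; configurable up to 512).
#' @param panel_size panel size M.
#' @param k_range number of reviewers per image.
#' @param severity_range latent severity interval.
#' @param class_threshold u0; true class is `u > u0`.
#' @param annotator_bias_sd per-reviewer score bias (scale units).
#' @param annotator_noise_sd per-review score noise (scale units).
#' @param blob_intensity_scale opacity amplitude at maximal severity.
#' @param background_noise_sd pixel noise.
#' @param seed RNG seed; the whole dataset is a deterministic function of
#'   the config.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_patients = 120L,
                         images_per_patient = 3:7,
                         image_size = 32L,
                         panel_size = 14L,
                         k_range = 2:4,
                         severity_range = c(0, 10),
                         class_threshold = 5,
                         annotator_bias_sd = 0.5,
                         annotator_noise_sd = 0.9,
                         blob_intensity_scale = 0.6,
                         background_noise_sd = 0.08,
                         seed = 1L) {
  stopifnot(image_size >= 16L, panel_size >= max(k_range),
            annotator_bias_sd >= 0, annotator_noise_sd >= 0,
            background_noise_sd >= 0,
            diff(severity_range) > 0)
  structure(as.list(environment()), class = "synth_config")
}

round_half_up <- function(x) floor(x + 0.5)

# sample() treats a scalar n as 1:n; pick_one never does
pick_one <- function(v) if (length(v) == 1L) v else sample(v, 1L)

#' Generate a synthetic multi-annotator image dataset
#'
#' @param config a [synth_config].
#' @param patient_prefix string prepended to patient ids (lets a train and
#'   a holdout set be generated with provably disjoint patients).
#' @param panel_bias optional vector of M reviewer biases, to share one
#'   panel across several generated sets; drawn from the config otherwise.
#' @return list with `dataset` (an `uncertram_dataset`), `latent`
#'   (data.frame `image_id, patient_id, u, true_class`) and `panel_bias`.
#' @export
generate_dataset <- function(config, patient_prefix = "P", panel_bias = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  lo <- config$severity_range[1L]
  hi <- config$severity_range[2L]
  a <- 7 / (hi - lo)
  if (is.null(panel_bias))
    panel_bias <- stats::rnorm(config$panel_size, 0, config$annotator_bias_sd)
  records <- list()
  latent <- list()
  img_n <- 0L
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("%s%04d", patient_prefix, p)
    # U-shaped severity: most patients are clearly positive or negative,
    # fewer sit near the class boundary (where annotators then disagree)
    center <- lo + (hi - lo) * stats::rbeta(1L, 0.55, 0.55)
    n_img <- pick_one(config$images_per_patient)
    for (im in seq_len(n_img)) {
      img_n <- img_n + 1L
      iid <- sprintf("%s_img%05d", patient_prefix, img_n)
      u <- min(max(center + stats::rnorm(1L, 0, (hi - lo) / 10), lo), hi)
      k <- pick_one(config$k_range)
      revs <- sample.int(config$panel_size, k)
      s_base <- 4.5 + a * (u - config$class_threshold)
      scores <- round_half_up(s_base + panel_bias[revs] +
                                stats::rnorm(k, 0, config$annotator_noise_sd))
      scores <- pmin(pmax(scores, 1L), 8L)
      px <- synth_image(u, config)
      records[[img_n]] <- list(
        image_id = iid, patient_id = pid, pixels = px,
        annotations = annotation_set(iid, scores, revs))
      latent[[img_n]] <- data.frame(
        image_id = iid, patient_id = pid, u = u,
        true_class = as.integer(u > config$class_threshold),
        stringsAsFactors = FALSE)
    }
  }
  list(dataset = new_dataset(records, panel_size = config$panel_size),
       latent = do.call(rbind, latent), panel_bias = panel_bias)
}

synth_image <- function(u, config) {
  s <- config$image_size
  lo <- config$severity_range[1L]
  hi <- config$severity_range[2L]
  v <- (u - lo) / (hi - lo)
  rr <- matrix(seq(0, 1, length.out = s), s, s)
  cc <- t(rr)
  img <- 0.15 + matrix(stats::rnorm(s * s, 0, config$background_noise_sd), s, s)
  lungs <- list(c(0.45, 0.30), c(0.45, 0.70))
  bilateral <- u > config$class_threshold
  for (li in 1:2) {
    ctr <- lungs[[li]]
    inside <- ((rr - ctr[1L]) / 0.32)^2 + ((cc - ctr[2L]) / 0.16)^2 <= 1
    img[inside] <- img[inside] + 0.1
    amp <- config$blob_intensity_scale * v *
      (if (li == 2L && !bilateral) 0.25 else 1)
    if (amp <= 0) next
    for (bl in 1:2) {
      bc <- ctr + c(stats::runif(1L, -0.2, 0.2), stats::runif(1L, -0.1, 0.1))
      sg <- stats::runif(1L, 0.06, 0.12)
      img <- img + (amp / 2) * exp(-(((rr - bc[1L])^2 + (cc - bc[2L])^2) /
                                       (2 * sg^2)))
    }
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a patient-disjoint train/holdout benchmark pair
#'
#' Both sets share one reviewer panel (biases drawn once); patient ids are
#' prefixed `Tr`/`Ho` so the protocol checks can prove disjointness.
#'
#' @param config a [synth_config] for the training set.
#' @param holdout_patients patients in the holdout set (default half the
#'   training count).
#' @return list with `train`, `holdout` (each as in [generate_dataset])
#'   and `panel_bias`.
#' @export
generate_benchmark <- function(config, holdout_patients = NULL) {
  if (is.null(holdout_patients))
    holdout_patients <- max(2L, config$n_patients %/% 2L)
  train <- generate_dataset(config, patient_prefix = "Tr")
  hconf <- config
  hconf$n_patients <- as.integer(holdout_patients)
  hconf$seed <- config$seed + 77003L
  holdout <- generate_dataset(hconf, patient_prefix = "Ho",
                              panel_bias = train$panel_bias)
  list(train = train, holdout = holdout, panel_bias = train$panel_bias)
}

#' Fraction of images whose aggregated label contradicts the latent truth
#'
#' Quantifies the label noise the method is designed to resist: the rate
#' at which the mean-aggregated binary label differs from the latent true
#' class, overall and per uncertainty stratum.
#'
#' @param dataset generated `uncertram_dataset`.
#' @param latent the matching latent table.
#' @param bins uncertainty strata (see [default_strata]).
#' @return list with `overall` rate and `by_stratum` data.frame.
#' @export
label_noise_rate <- function(dataset, latent, bins = default_strata()) {
  lab <- label_table(dataset)
  m <- merge(lab, latent, by = "image_id")
  wrong <- m$y != m$true_class
  idx <- vapply(m$D, assign_stratum, integer(1), bins = bins)
  by_stratum <- data.frame(
    label = bins$label,
    n = as.integer(tabulate(idx, nrow(bins))),
    rate = vapply(seq_len(nrow(bins)), function(b) {
      sel <- idx == b
      if (!any(sel)) NA_real_ else mean(wrong[sel])
    }, numeric(1)))
  list(overall = mean(wrong), by_stratum = by_stratum)
}

#' Simulate a panel of binary annotators with known confusion
#'
#' Each annotator reviews every record and reports a binarized score (1
#' for negative, 8 for positive on the ordinal scale) corrupted by known
#' flip probabilities — the ground truth against which the
#' confusion-estimation baseline's learned matrices can be validated.
#'
#' @param latent latent table (`image_id, patient_id, true_class`).
#' @param flip_pos per-annotator probability of flipping a positive.
#' @param flip_neg per-annotator probability of flipping a negative.
#' @param seed RNG seed.
#' @return list of [annotation_set]s aligned with `latent` rows.
#' @export
simulate_binary_panel <- function(latent, flip_pos, flip_neg = rep(0, length(flip_pos)),
                                  seed = 1L) {
  stopifnot(length(flip_pos) == length(flip_neg))
  M <- length(flip_pos)
  set.seed(seed)
  lapply(seq_len(nrow(latent)), function(i) {
    truth <- latent$true_class[i]
    lab <- vapply(seq_len(M), function(t) {
      flip <- stats::runif(1L) < (if (truth == 1L) flip_pos[t] else flip_neg[t])
      if (flip) 1L - truth else truth
    }, integer(1))
    annotation_set(latent$image_id[i], ifelse(lab == 1L, 8L, 1L), seq_len(M))
  })
}

#' Benchmark dataset for confusion-matrix recovery
#'
#' Generates n separable images (severity drawn from the extremes of the
#' range so the true class is visually unambiguous) and annotates each
#' with a small binary panel of known corruption, e.g. one annotator who
#' flips positives 30% of the time.
#'
#' @param n number of images (one patient per image).
#' @param flip_pos per-annotator positive-flip probabilities; the panel
#'   size is their length.
#' @param image_size image side length.
#' @param seed RNG seed.
#' @return list with `dataset` and `latent`.
#' @export
generate_confusion_benchmark <- function(n = 2000L,
                                         flip_pos = c(0, 0.3, 0),
                                         image_size = 16L, seed = 1L) {
  cfg <- synth_config(n_patients = n, images_per_patient = 1L,
                      image_size = image_size, seed = seed)
  set.seed(seed)
  latent <- data.frame(
    image_id = sprintf("cf_img%05d", seq_len(n)),
    patient_id = sprintf("CF%05d", seq_len(n)),
    u = ifelse(stats::runif(n) < 0.5, stats::runif(n, 0, 1.5),
               stats::runif(n, 8.5, 10)),
    stringsAsFactors = FALSE)
  latent$true_class <- as.integer(latent$u > cfg$class_threshold)
  anns <- simulate_binary_panel(latent, flip_pos, seed = seed + 1L)
  records <- lapply(seq_len(n), function(i)
    list(image_id = latent$image_id[i], patient_id = latent$patient_id[i],
         pixels = synth_image(latent$u[i], cfg), annotations = anns[[i]]))
  list(dataset = new_dataset(records, panel_size = length(flip_pos)),
       latent = latent)
}

#' Write a generated dataset to disk
#'
#' Emits `<image_id>.png` files (8-bit grayscale), `annotations.csv`
#' (`image_id,patient_id,reviewer_id,score`) and, when a latent table is
#' given, `latent_truth.csv`.
#'
#' @param dataset an `uncertram_dataset` with pixels in `[0, 1]`.
#' @param dir output directory (created if missing).
#' @param latent optional latent table.
#' @return invisibly, the annotation table.
#' @export
write_dataset <- function(dataset, dir, latent = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset$records, function(r) {
    png::writePNG(pmin(pmax(r$pixels, 0), 1),
                  file.path(dir, paste0(r$image_id, ".png")))
    data.frame(image_id = r$image_id, patient_id = r$patient_id,
               reviewer_id = r$annotations$reviewer_id,
               score = r$annotations$score, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(dir, "annotations.csv"), row.names = FALSE)
  if (!is.null(latent))
    utils::write.csv(latent, file.path(dir, "latent_truth.csv"),
                     row.names = FALSE)
  invisible(tab)
}
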