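#' Construct an annotation set
#'
#' An annotation set holds the k scored reviews attached to one image: the
#' ordinal scores (1--8 scale, 1 = confident negative, 8 = confident
#' positive, 4/5 equivocal) and the ids of the panel reviewers who gave
#' them. No reviewer may score the same image twice.
#'
#' @param image_id character scalar identifying the image.
#' @param scores integer vector of annotation scores in 1..8.
#' @param reviewers integer vector of reviewer ids (same length as
#'   `scores`), each in 1..M where M is the panel size.
#' @return An object of class `annotation_set` with fields `image_id`,
#'   `score`, `reviewer_id` and `k`.
#' @export
annotation_set <- function(image_id, scores, reviewers) {
  scores <- as.integer(scores)
  reviewers <- as.integer(reviewers)
  if (length(scores) < 1L)
    stop("annotation set for image '", image_id, "' is empty")
  if (length(scores) != length(reviewers))
    stop("scores and reviewers must have equal length")
  check_scores(scores)
  if (any(reviewers < 1L))
    stop("reviewer ids must be positive integers")
  dup <- reviewers[duplicated(reviewers)]
  if (length(dup))
    stop("duplicate review by reviewer ", dup[1L], " on image '", image_id, "'")
  structure(
    list(image_id = as.character(image_id), score = scores,
         reviewer_id = reviewers, k = length(scores)),
    class = "annotation_set")
}

check_scores <- function(scores) {
  if (any(!is.finite(scores)) || any(scores < 1L | scores > 8L))
    stop("annotation scores must lie in 1..8")
  invisible(scores)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> image '%s': %s\n", x$image_id,
              paste(sprintf("(%d,%d)", x$score, x$reviewer_id), collapse = " ")))
  invisible(x)
}

#' Construct a multi-annotator image dataset
#'
#' @param records list of image records, each a list with fields
#'   `image_id`, `patient_id`, `pixels` (numeric matrix or `NULL`) and
#'   `annotations` (an [annotation_set]).
#' @param panel_size integer M, the number of reviewers on the panel. All
#'   reviewer ids must be `<= panel_size`.
#' @param score_levels number of ordinal score levels (8).
#' @return An object of class `uncertram_dataset`.
#' @export
new_dataset <- function(records, panel_size, score_levels = 8L) {
  ids <- vapply(records, function(r) r$image_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate image_id in dataset: ", ids[duplicated(ids)][1L])
  for (r in records) {
    if (is.null(r$patient_id) || is.na(r$patient_id) || !nzchar(r$patient_id))
      stop("record '", r$image_id, "' has no patient_id")
    if (any(r$annotations$reviewer_id > panel_size))
      stop("record '", r$image_id, "' has reviewer id above panel size ",
           panel_size)
    if (!is.null(r$pixels) && any(!is.finite(r$pixels)))
      stop("record '", r$image_id, "' has non-finite pixels")
  }
  structure(
    list(records = records, panel_size = as.integer(panel_size),
         score_levels = as.integer(score_levels),
         access = new.env(parent = emptyenv())),
    class = "uncertram_dataset")
}

#' @export
print.uncertram_dataset <- function(x, ...) {
  cat(sprintf("<uncertram_dataset> %d images, %d patients, panel size %d\n",
              length(x$records),
              length(unique(vapply(x$records, `[[`, "", "patient_id"))),
              x$panel_size))
  invisible(x)
}

#' @export
length.uncertram_dataset <- function(x) length(x$records)

#' Read the pixel array of one record (access-tracked)
#'
#' All training and evaluation code reads pixels through this accessor,
#' which counts reads in the dataset's access log. The log is what lets
#' the cross-validation driver assert that the holdout set is never
#' touched before final evaluation.
#'
#' @param dataset an `uncertram_dataset`.
#' @param i record index.
#' @return the pixel matrix.
#' @export
record_pixels <- function(dataset, i) {
  acc <- dataset$access
  acc$n_reads <- (acc$n_reads %||% 0L) + 1L
  px <- dataset$records[[i]]$pixels
  if (is.null(px))
    stop("record '", dataset$records[[i]]$image_id, "' has no pixel data")
  px
}

#' Number of pixel reads recorded against a dataset
#' @param dataset an `uncertram_dataset`.
#' @return integer count of [record_pixels] calls.
#' @export
access_count <- function(dataset) dataset$access$n_reads %||% 0L

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an annotation table and its images into a dataset
#'
#' The table is a CSV with header `image_id,patient_id,reviewer_id,score`,
#' two-to-four rows per image in typical panel data. Images are resolved in
#' `image_dir` as `<image_id>.png` (8- or 16-bit grayscale) or
#' `<image_id>.csv` (plain numeric grid, no header).
#'
#' @param path path to the annotation CSV.
#' @param image_dir directory holding the image files, or `NULL` to build a
#'   label-only dataset without pixel data.
#' @param panel_size panel size M; defaults to the largest reviewer id seen
#'   (14 on the scale the encodings were designed for).
#' @return an `uncertram_dataset`.
#' @export
read_annotation_table <- function(path, image_dir = NULL, panel_size = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "patient_id", "reviewer_id", "score")
  if (!all(need %in% names(tab)))
    stop("annotation table must have columns ", paste(need, collapse = ", "))
  if (nrow(tab) == 0L)
    return(new_dataset(list(), panel_size = panel_size %||% 0L))
  tab$image_id <- as.character(tab$image_id)
  tab$patient_id <- as.character(tab$patient_id)
  check_scores(as.integer(tab$score))
  dup <- duplicated(tab[c("image_id", "reviewer_id")])
  if (any(dup))
    stop(sprintf("duplicate (image_id, reviewer_id) pair: (%s, %s)",
                 tab$image_id[dup][1L], tab$reviewer_id[dup][1L]))
  if (is.null(panel_size)) panel_size <- max(tab$reviewer_id)
  pieces <- split(tab, factor(tab$image_id, levels = unique(tab$image_id)))
  records <- lapply(pieces, function(p) {
    if (length(unique(p$patient_id)) != 1L)
      stop("image '", p$image_id[1L], "' maps to multiple patients")
    px <- if (!is.null(image_dir)) read_image(image_dir, p$image_id[1L])
    list(image_id = p$image_id[1L], patient_id = p$patient_id[1L],
         pixels = px,
         annotations = annotation_set(p$image_id[1L], p$score, p$reviewer_id))
  })
  names(records) <- NULL
  new_dataset(records, panel_size = panel_size)
}

read_image <- function(image_dir, image_id) {
  png_path <- file.path(image_dir, paste0(image_id, ".png"))
  csv_path <- file.path(image_dir, paste0(image_id, ".csv"))
  if (file.exists(png_path)) {
    px <- png::readPNG(png_path)
    if (length(dim(px)) == 3L) px <- px[, , 1L]  # collapse grayscale channels
    px
  } else if (file.exists(csv_path)) {
    as.matrix(utils::read.csv(csv_path, header = FALSE))
  } else {
    stop("no image file for id '", image_id, "' in ", image_dir)
  }
}

#' Aggregate a panel of scores into a mean label
#'
#' The binary class is obtained by averaging the annotation scores and
#' thresholding the mean at 4.5: below 4.5 the image is labeled negative
#' (non-ARDS), otherwise positive. A mean of exactly 4.5 is positive.
#'
#' @param annotation_set an [annotation_set].
#' @return list with `mu_S` (the mean score) and `y` (0/1 class).
#' @export
aggregate_label <- function(annotation_set) {
  mu <- mean(annotation_set$score)
  list(mu_S = mu, y = if (mu < 4.5) 0L else 1L)
}

#' Ordinal training target from a panel of scores
#'
#' The privileged branch is trained against the mean score rounded to the
#' nearest integer on the 1..8 scale. Half-values round toward the higher
#' rank by default (`half = "up"`); `half = "even"` gives banker's
#' rounding.
#'
#' @param annotation_set an [annotation_set].
#' @param half tie-break for means ending in .5.
#' @return integer rank in 1..8.
#' @export
ordinal_target <- function(annotation_set, half = c("up", "even")) {
  half <- match.arg(half)
  mu <- mean(annotation_set$score)
  r <- if (half == "up") floor(mu + 0.5) else round(mu)
  as.integer(min(max(r, 1), 8))
}

#' Binarize one ordinal review at the 4.5 midpoint
#'
#' @param score integer score(s) in 1..8.
#' @return 0 for scores 1..4, 1 for scores 5..8.
#' @export
binarize_review <- function(score) {
  check_scores(as.integer(score))
  as.integer(score >= 4.5)
}

#' Pairwise Cohen's kappa between panel reviewers
#'
#' Each reviewer's scores are binarized at 4.5 and, for every pair of
#' reviewers, Cohen's kappa is computed over the images both reviewed.
#' Pairs with no shared images get `NA`. The diagonal is 1 for reviewers
#' with at least one review (self-agreement, presentational only) and `NA`
#' otherwise. Pairs whose expected agreement is 1 (both raters constant
#' and identical on the shared images) are undefined and reported `NA`.
#'
#' @param dataset an `uncertram_dataset`.
#' @return symmetric `M x M` matrix with reviewer ids as dimnames.
#' @export
pairwise_kappa <- function(dataset) {
  if (length(dataset$records) == 0L) stop("dataset is empty")
  M <- dataset$panel_size
  # reviews[[t]]: named binary vector over image ids reviewed by t
  reviews <- vector("list", M)
  for (r in dataset$records) {
    a <- r$annotations
    b <- binarize_review(a$score)
    for (j in seq_len(a$k)) {
      t <- a$reviewer_id[j]
      reviews[[t]][r$image_id] <- b[j]
    }
  }
  K <- matrix(NA_real_, M, M, dimnames = list(seq_len(M), seq_len(M)))
  for (i in seq_len(M)) {
    if (!is.null(reviews[[i]]) && length(reviews[[i]])) K[i, i] <- 1
    for (j in seq_len(M)) {
      if (j <= i) next
      shared <- intersect(names(reviews[[i]]), names(reviews[[j]]))
      if (!length(shared)) next
      K[i, j] <- K[j, i] <- cohen_kappa(reviews[[i]][shared], reviews[[j]][shared])
    }
  }
  K
}

cohen_kappa <- function(a, b) {
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a == 1) * mean(b == 1) + mean(a == 0) * mean(b == 0)
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Write a pairwise kappa matrix as CSV
#'
#' Reviewer ids label rows and columns; undefined entries are written as
#' empty cells.
#'
#' @param kappa matrix from [pairwise_kappa].
#' @param path output file.
#' @export
write_kappa_csv <- function(kappa, path) {
  utils::write.csv(as.data.frame(kappa), path, na = "", row.names = TRUE)
}

#' Per-image derived label table
#'
#' Computes, for every record, the mean score, binary label, ordinal
#' target and uncertainty D.
#'
#' @param dataset an `uncertram_dataset`.
#' @param sd_type standard-deviation convention for D (see [uncertainty]).
#' @return data.frame with columns `image_id, patient_id, k, mu_S, y,
#'   ordinal_target, D`.
#' @export
label_table <- function(dataset, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  rows <- lapply(dataset$records, function(r) {
    agg <- aggregate_label(r$annotations)
    data.frame(image_id = r$image_id, patient_id = r$patient_id,
               k = r$annotations$k, mu_S = agg$mu_S, y = agg$y,
               ordinal_target = ordinal_target(r$annotations),
               D = uncertainty(r$annotations, sd_type = sd_type),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Resize and rescale a grayscale image for a pretrained encoder
#'
#' Bilinear resize to `size x size` followed by an affine rescale of the
#' pixel range to `[-1024, 1024]`, the input contract of chest-X-ray
#' pretrained encoders. Synthetic desk-scale images bypass this step.
#'
#' @param pixels numeric matrix.
#' @param size output side length (512 for the pretrained path).
#' @return `size x size` matrix with values in `[-1024, 1024]`.
#' @export
preprocess_cxr <- function(pixels, size = 512L) {
  px <- bilinear_resize(pixels, size, size)
  rng <- range(px)
  if (diff(rng) == 0) return(matrix(0, size, size))
  (px - rng[1L]) / diff(rng) * 2048 - 1024
}

bilinear_resize <- function(x, nr, nc) {
  h <- nrow(x); w <- ncol(x)
  if (h == nr && w == nc) return(x)
  # sample positions in source coordinates (align corners)
  ri <- if (nr == 1L) rep(1, nr) else seq(1, h, length.out = nr)
  ci <- if (nc == 1L) rep(1, nc) else seq(1, w, length.out = nc)
  r0 <- pmax(pmin(floor(ri), h - 1L), 1L); r1 <- pmin(r0 + 1L, h); fr <- ri - r0
  c0 <- pmax(pmin(floor(ci), w - 1L), 1L); c1 <- pmin(c0 + 1L, w); fc <- ci - c0
  a <- x[r0, c0, drop = FALSE] * (1 - fr) + x[r1, c0, drop = FALSE] * fr
  b <- x[r0, c1, drop = FALSE] * (1 - fr) + x[r1, c1, drop = FALSE] * fr
  sweep(a, 2, 1 - fc, "*") + sweep(b, 2, fc, "*")
}
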