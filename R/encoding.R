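#' Privileged annotation encodings
#'
#' Three protocols turn the (score, reviewer) pairs attached to an image
#' into the fixed-length vector supplied to the privileged branch during
#' training:
#'
#' * **Score encoding** (length 8): entry s counts how many reviewers gave
#'   score s; the entries sum to k.
#' * **Separate encoding** (length 8 + M): the score histogram concatenated
#'   with a binary indicator of which panel reviewers participated. With a
#'   14-reviewer panel the vector lives in R^22.
#' * **Combine encoding** (length M): entry t carries the score reviewer t
#'   gave, 0 if reviewer t did not review (unambiguous since scores >= 1).
#'
#' @param annotation_set an [annotation_set].
#' @param M panel size (number of reviewers); required for the separate and
#'   combine protocols.
#' @return A `privileged_vector`: numeric vector with attributes `method`
#'   and `length`.
#' @examples
#' a <- annotation_set("img", scores = c(6, 2, 2), reviewers = c(8, 6, 12))
#' encode_score(a)              # c(0,2,0,0,0,1,0,0)
#' length(encode_separate(a, M = 14))  # 22
#' @export
encode_score <- function(annotation_set) {
  check_scores(annotation_set$score)
  v <- tabulate(annotation_set$score, nbins = 8L)
  privileged_vector(as.numeric(v), "score")
}

#' @rdname encode_score
#' @export
encode_separate <- function(annotation_set, M) {
  if (any(annotation_set$reviewer_id > M))
    stop("reviewer id exceeds panel size ", M)
  ind <- numeric(M)
  ind[annotation_set$reviewer_id] <- 1
  privileged_vector(c(as.numeric(encode_score(annotation_set)), ind), "separate")
}

#' @rdname encode_score
#' @export
encode_combine <- function(annotation_set, M) {
  if (any(annotation_set$reviewer_id > M))
    stop("reviewer id exceeds panel size ", M)
  check_scores(annotation_set$score)
  v <- numeric(M)
  v[annotation_set$reviewer_id] <- annotation_set$score
  privileged_vector(v, "combine")
}

privileged_vector <- function(values, method) {
  structure(values, method = method, class = "privileged_vector")
}

#' Encode an annotation set under a named protocol
#'
#' @param annotation_set an [annotation_set].
#' @param method one of `"score"`, `"separate"`, `"combine"`.
#' @param M panel size.
#' @return a `privileged_vector`.
#' @export
encode_annotations <- function(annotation_set,
                               method = c("score", "separate", "combine"),
                               M = 14L) {
  switch(match.arg(method),
         score = encode_score(annotation_set),
         separate = encode_separate(annotation_set, M),
         combine = encode_combine(annotation_set, M))
}

#' Length of an encoding under a protocol and panel size
#' @inheritParams encode_annotations
#' @return integer vector length.
#' @export
encoding_length <- function(method = c("score", "separate", "combine"),
                            M = 14L) {
  switch(match.arg(method), score = 8L, separate = 8L + as.integer(M),
         combine = as.integer(M))
}

#' Per-score uncertainty g(s)
#'
#' `g(s) = -|s - 4.5| + 3.5` on the 1..8 scale: 0 at the confident
#' extremes (1 and 8), maximal (3) at the equivocal ratings 4 and 5.
#'
#' @param score integer score(s) in 1..8.
#' @return numeric value(s) in `[0, 3]`.
#' @export
g_score <- function(score) {
  check_scores(as.integer(score))
  -abs(score - 4.5) + 3.5
}

#' Image-level uncertainty measure D
#'
#' `D = mean(g(S_i)) + sd(S_1..S_k)`: the average per-score equivocality of
#' the panel plus the spread of the scores. D = 0 exactly when all
#' reviewers agree on a confident extreme (all 1s or all 8s). The standard
#' deviation uses the population convention (divisor k) by default, which
#' bounds D by about 4 for panels of up to four reviewers; the sample
#' convention (divisor k-1) is available as a switch.
#'
#' @param annotation_set an [annotation_set] (scores are what matter;
#'   reviewer ids are ignored).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return non-negative scalar D.
#' @examples
#' uncertainty(annotation_set("a", c(1, 1), c(1, 2)))   # 0
#' uncertainty(annotation_set("b", c(4, 5), c(1, 2)))   # 3.5
#' @export
uncertainty <- function(annotation_set, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  s <- annotation_set$score
  k <- length(s)
  sigma <- if (k == 1L) 0
  else if (sd_type == "population") sqrt(mean((s - mean(s))^2))
  else stats::sd(s)
  mean(g_score(s)) + sigma
}

#' Uncertainty-threshold gate for privileged information
#'
#' The privileged vector is supplied to the network only for records whose
#' uncertainty exceeds the threshold tau; otherwise an all-zero vector of
#' the same length is substituted, so the privileged branch carries no
#' annotation information for confidently-labeled images. D equal to tau
#' does not exceed it and is zeroed.
#'
#' @param privileged a `privileged_vector` (or plain numeric vector).
#' @param D uncertainty of the record.
#' @param tau threshold (>= 0); the reference choice is 2, the training-set
#'   median of D in the motivating cohort.
#' @return the vector, passed through or zeroed.
#' @export
gate <- function(privileged, D, tau = 2) {
  stopifnot(D >= 0, tau >= 0)
  if (D > tau) privileged
  else privileged_vector(numeric(length(privileged)),
                         attr(privileged, "method") %||% "score")
}

#' Enumerate D over all small annotation configurations
#'
#' Exhaustively evaluates the uncertainty measure over every multiset of
#' integer scores for panel sizes `k_values` (4,672 configurations for k in
#' 2..4), e.g. to establish its attainable minimum and maximum.
#'
#' @param k_values panel sizes to enumerate.
#' @param sd_type passed to [uncertainty].
#' @return data.frame with columns `k`, `scores` (slash-separated), `D`.
#' @export
enumerate_uncertainty <- function(k_values = 2:4,
                                  sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  out <- lapply(k_values, function(k) {
    grid <- as.matrix(expand.grid(rep(list(1:8), k)))
    D <- apply(grid, 1L, function(s) {
      a <- list(score = as.integer(s), k = k)
      class(a) <- "annotation_set"
      uncertainty(a, sd_type = sd_type)
    })
    data.frame(k = k, scores = apply(grid, 1L, paste, collapse = "/"), D = D,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Encode a whole dataset into a per-image feature table
#'
#' Convenience/inspection surface (used by the `encode` CLI subcommand):
#' one row per image with the encoded privileged vector and the derived
#' label quantities.
#'
#' @param dataset an `uncertram_dataset`.
#' @param method encoding protocol.
#' @param tau optional gate threshold; if supplied, vectors are gated on D.
#' @return data.frame with `image_id, patient_id, mu_S, y, ordinal_target,
#'   D` and columns `x1..xL` for the encoding.
#' @export
encode_dataset <- function(dataset, method = c("score", "separate", "combine"),
                           tau = NULL) {
  method <- match.arg(method)
  lab <- label_table(dataset)
  enc <- t(vapply(seq_along(dataset$records), function(i) {
    a <- dataset$records[[i]]$annotations
    v <- encode_annotations(a, method, M = dataset$panel_size)
    if (!is.null(tau)) v <- gate(v, lab$D[i], tau)
    as.numeric(v)
  }, numeric(encoding_length(method, dataset$panel_size))))
  colnames(enc) <- paste0("x", seq_len(ncol(enc)))
  cbind(lab, as.data.frame(enc))
}
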