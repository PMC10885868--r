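#' Confusion-estimation settings
#'
#' The confusion baseline learns, jointly with the class predictor, one
#' 2x2 column-stochastic confusion matrix per panel annotator: column c of
#' `P^(t)` is the distribution of annotator t's binarized label given true
#' class c, so the predicted annotation distribution for an image with
#' estimated class distribution p is `P^(t) %*% p`. Matrices are
#' parameterized by per-column softmax logits, which keeps them
#' column-stochastic after every optimization step. The training loss is
#' the mean cross-entropy of each observing annotator's binarized score
#' against `P^(t) %*% p` plus `trace_weight` times the summed traces of
#' all matrices (minimizing the trace makes the decomposition into true
#' label and annotator confusion identifiable).
#'
#' @param trace_weight lambda, weight of the trace regularizer (0.01).
#' @param init_diag initial diagonal mass of each confusion matrix, in
#'   (0.5, 1); 0.9 biases matrices toward the identity at the start.
#' @param trainable_encoder train the image encoder too (default `FALSE`:
#'   frozen encoder, the linear-probing architecture).
#' @return a list of settings for [build_model].
#' @export
confusion_config <- function(trace_weight = 0.01, init_diag = 0.9,
                             trainable_encoder = FALSE) {
  stopifnot(trace_weight >= 0, init_diag > 0.5, init_diag < 1)
  list(trace_weight = trace_weight, init_diag = init_diag,
       trainable_encoder = isTRUE(trainable_encoder))
}

#' Learned confusion matrices of a trained confusion model
#'
#' @param model a `tram_net` with variant `"confusion"`.
#' @return `2 x 2 x M` array; `[, , t]` is annotator t's column-stochastic
#'   confusion matrix (rows: annotated label 0/1; columns: true class 0/1).
#' @export
confusion_matrices <- function(model) {
  if (is.null(model$theta)) stop("model has no confusion matrices")
  P <- model$theta
  for (t in seq_len(dim(P)[3L]))
    for (cc in 1:2) P[, cc, t] <- softmax_vec(model$theta[, cc, t])
  P
}

softmax_vec <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

# Loss and gradients of the confusion variant for one batch.
# z: embedding (E x B); ann: list of annotation_sets, one per column of z.
# Returns the loss, the gradient wrt the xi logits (normalized like a
# batch-mean loss), the xi forward cache, and the gradient wrt theta.
confusion_loss_grad <- function(model, z, ann) {
  base <- seq_forward(model$xi, z, train = TRUE)
  logits <- base$out
  B <- ncol(logits)
  p <- softmax_cols(logits)
  M <- model$panel_size
  lambda <- model$confusion$trace_weight
  P <- confusion_matrices(model)
  n_terms <- sum(vapply(ann, function(a) a$k, integer(1)))
  loss <- 0
  dp <- matrix(0, 2L, B)
  dP <- array(0, dim(P))
  for (b in seq_len(B)) {
    a <- ann[[b]]
    labs <- binarize_review(a$score)
    for (j in seq_len(a$k)) {
      t <- a$reviewer_id[j]
      if (t > M) stop("annotation by unknown annotator id ", t)
      q <- P[, , t] %*% p[, b, drop = FALSE]
      li <- labs[j] + 1L
      loss <- loss - log(max(q[li], 1e-300)) / n_terms
      dq <- c(0, 0)
      dq[li] <- -1 / max(q[li], 1e-300) / n_terms
      dp[, b] <- dp[, b] + crossprod(P[, , t], dq)
      dP[, , t] <- dP[, , t] + dq %*% t(p[, b, drop = FALSE])
    }
  }
  # trace regularizer over all M annotators
  loss <- loss + lambda * sum(P[1L, 1L, ] + P[2L, 2L, ])
  dP[1L, 1L, ] <- dP[1L, 1L, ] + lambda
  dP[2L, 2L, ] <- dP[2L, 2L, ] + lambda
  # softmax jacobians: logits of xi ...
  dlogits <- p * sweep(dp, 2L, colSums(dp * p), "-")
  # ... and the per-column theta parameterization
  dtheta <- array(0, dim(P))
  for (t in seq_len(M))
    for (cc in 1:2) {
      pc <- P[, cc, t]
      dtheta[, cc, t] <- pc * (dP[, cc, t] - sum(dP[, cc, t] * pc))
    }
  list(loss = loss, dlogits_xi = dlogits, base = base, dtheta = dtheta)
}

#' Export learned confusion matrices as CSV
#'
#' One row per annotator with the four entries of its column-stochastic
#' confusion matrix, for inspection of annotator reliability (the mean of
#' the diagonal is a simple skill estimate).
#'
#' @param model a trained confusion-variant `tram_net`.
#' @param path output CSV path.
#' @return invisibly, the exported data.frame.
#' @export
write_confusion_csv <- function(model, path) {
  P <- confusion_matrices(model)
  df <- data.frame(
    annotator = seq_len(dim(P)[3L]),
    p_label0_true0 = P[1L, 1L, ], p_label1_true0 = P[2L, 1L, ],
    p_label0_true1 = P[1L, 2L, ], p_label1_true1 = P[2L, 2L, ],
    skill = (P[1L, 1L, ] + P[2L, 2L, ]) / 2)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Evaluate the confusion loss without updating (diagnostics/tests)
#'
#' @param model a confusion-variant `tram_net`.
#' @param x image array.
#' @param ann list of annotation sets matching the batch.
#' @return scalar loss.
#' @export
confusion_forward <- function(model, x, ann) {
  enc <- seq_forward(model$encoder, x, train = FALSE)
  confusion_loss_grad(model, enc$out, ann)$loss
}
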