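#' Network configuration
#'
#' Describes the two-branch architecture: the base branch is an image
#' encoder `phi` followed by a linear class predictor `xi`; the privileged
#' branch embeds the encoded annotation vector through `varphi` (linear 64
#' -> batch norm -> ReLU) and predicts from the concatenation `(z*, z)`
#' through `delta` (two 128-unit layers with batch norm + ReLU, then a
#' final head). The privileged head is a rank-consistent CORN head with
#' `num_ranks - 1` logits for the ordinal variants, or a 2-logit
#' cross-entropy head for plain TRAM.
#'
#' @param encoder_kind `"small_cnn"` (3-block strided convolutional test
#'   encoder, trainable) or `"resnet50"` (2048-dim untrained deep encoder;
#'   frozen-path use, see [resnet50_encoder]).
#' @param embedding_dim width of the image embedding z (small CNN path;
#'   the ResNet-50 path is fixed at 2048).
#' @param privileged_hidden units in the privileged encoder (64).
#' @param predictor_hidden units per privileged-predictor layer (128).
#' @param num_classes base-branch classes (2).
#' @param num_ranks K, ordinal levels of the score scale (8).
#' @param beta weight of the privileged-branch loss in
#'   `L = L1 + beta * L2` (0.5).
#' @param encoding_method privileged encoding protocol.
#' @param tau uncertainty-gate threshold (privileged information passes
#'   only when D > tau); 2 is the reference value.
#' @param zero_privileged diagnostic/ablation switch: feed an all-zero
#'   privileged vector to every record regardless of the gate.
#' @param cnn_channels channel widths of the three convolutional blocks.
#' @param confusion settings for the confusion-estimation variant (a
#'   [confusion_config]).
#' @return a `network_config` list.
#' @export
network_config <- function(encoder_kind = c("small_cnn", "resnet50"),
                           embedding_dim = 64L,
                           privileged_hidden = 64L,
                           predictor_hidden = 128L,
                           num_classes = 2L,
                           num_ranks = 8L,
                           beta = 0.5,
                           encoding_method = c("score", "separate", "combine"),
                           tau = 2,
                           zero_privileged = FALSE,
                           cnn_channels = c(8L, 16L, 32L),
                           confusion = confusion_config()) {
  stopifnot(num_ranks >= 2L, beta >= 0, embedding_dim > 0, tau >= 0)
  structure(list(encoder_kind = match.arg(encoder_kind),
                 embedding_dim = as.integer(embedding_dim),
                 privileged_hidden = as.integer(privileged_hidden),
                 predictor_hidden = as.integer(predictor_hidden),
                 num_classes = as.integer(num_classes),
                 num_ranks = as.integer(num_ranks),
                 beta = beta,
                 encoding_method = match.arg(encoding_method),
                 tau = tau,
                 zero_privileged = isTRUE(zero_privileged),
                 cnn_channels = as.integer(cnn_channels),
                 confusion = confusion),
            class = "network_config")
}

#' Model variants
#'
#' `linear_probe` trains only the linear class head on a frozen encoder;
#' `fine_tune` trains encoder and head with cross-entropy on the mean
#' label; `confusion` adds per-annotator 2x2 confusion matrices trained
#' against each reviewer's binarized score; `tram` is the two-branch
#' network with a 2-logit privileged head, no gate; `tram_thresh` adds the
#' uncertainty gate; `tram_ord` replaces the privileged head with the CORN
#' ordinal head, no gate; `proposed` combines gate and ordinal head.
#'
#' @export
model_variants <- function() {
  c("linear_probe", "fine_tune", "confusion",
    "tram", "tram_thresh", "tram_ord", "proposed")
}

variant_uses_gate <- function(variant) variant %in% c("tram_thresh", "proposed")
variant_uses_corn <- function(variant) variant %in% c("tram_ord", "proposed")
variant_has_priv <- function(variant)
  variant %in% c("tram", "tram_thresh", "tram_ord", "proposed")
variant_encoder_trainable <- function(variant, confusion_trainable = FALSE) {
  switch(variant,
         linear_probe = FALSE,
         confusion = confusion_trainable,
         TRUE)
}

#' Build a two-branch model
#'
#' @param config a [network_config].
#' @param variant one of [model_variants()].
#' @param panel_size panel size M (for the encoding length and confusion
#'   matrices).
#' @param image_size input image side length (small CNN path).
#' @param confusion a list of confusion-model settings (see
#'   [confusion_config]); used when `variant = "confusion"`.
#' @param seed integer seed for weight initialization.
#' @return a `tram_net` model object.
#' @export
build_model <- function(config, variant = "proposed", panel_size = 14L,
                        image_size = 32L, confusion = config$confusion,
                        seed = NULL) {
  if (is.null(confusion)) confusion <- confusion_config()
  variant <- match.arg(variant, model_variants())
  if (!is.null(seed)) set.seed(seed)
  if (config$encoder_kind != "small_cnn")
    stop("trainable models use the small_cnn encoder; the resnet50 ",
         "contract is exposed via resnet50_encoder()")
  ch <- config$cnn_channels
  encoder <- list(
    nn_conv(1L, ch[1L], 3L, stride = 2L, pad = 1L), nn_bn(ch[1L], "2d"), nn_relu(),
    nn_conv(ch[1L], ch[2L], 3L, stride = 2L, pad = 1L), nn_bn(ch[2L], "2d"), nn_relu(),
    nn_conv(ch[2L], ch[3L], 3L, stride = 2L, pad = 1L), nn_bn(ch[3L], "2d"), nn_relu(),
    nn_gap(),
    nn_linear(ch[3L], config$embedding_dim))
  xi <- list(nn_linear(config$embedding_dim, config$num_classes))
  phi <- delta <- NULL
  if (variant_has_priv(variant)) {
    enc_len <- encoding_length(config$encoding_method, panel_size)
    head_dim <- if (variant_uses_corn(variant)) config$num_ranks - 1L
                else config$num_classes
    phi <- list(nn_linear(enc_len, config$privileged_hidden),
                nn_bn(config$privileged_hidden, "1d"), nn_relu())
    delta <- list(
      nn_linear(config$privileged_hidden + config$embedding_dim,
                config$predictor_hidden),
      nn_bn(config$predictor_hidden, "1d"), nn_relu(),
      nn_linear(config$predictor_hidden, config$predictor_hidden),
      nn_bn(config$predictor_hidden, "1d"), nn_relu(),
      nn_linear(config$predictor_hidden, head_dim))
  }
  theta <- NULL
  if (variant == "confusion") {
    # per-annotator 2x2 confusion logits; softmax over rows of each column
    # gives a column-stochastic matrix, identity-biased at init
    d0 <- log(confusion$init_diag / (1 - confusion$init_diag))
    theta <- array(0, c(2L, 2L, panel_size))
    theta[1L, 1L, ] <- d0 / 2
    theta[2L, 1L, ] <- -d0 / 2
    theta[1L, 2L, ] <- -d0 / 2
    theta[2L, 2L, ] <- d0 / 2
  }
  structure(list(config = config, variant = variant,
                 panel_size = as.integer(panel_size),
                 image_size = as.integer(image_size),
                 encoder = encoder, xi = xi, phi = phi, delta = delta,
                 theta = theta, confusion = confusion),
            class = "tram_net")
}

#' @export
print.tram_net <- function(x, ...) {
  cat(sprintf("<tram_net> variant '%s', encoder %s (embed %d), encoding %s%s\n",
              x$variant, x$config$encoder_kind, x$config$embedding_dim,
              x$config$encoding_method,
              if (variant_uses_gate(x$variant))
                sprintf(", gate tau=%g", x$config$tau) else ""))
  invisible(x)
}

clone_model <- function(model) {
  for (part in c("encoder", "xi", "phi", "delta"))
    if (!is.null(model[[part]])) model[[part]] <- clone_layers(model[[part]])
  model
}

#' Forward pass of the two-branch network
#'
#' In training mode both branches run: `z = phi(x)`, `base_logits =
#' xi(z)`, `z* = varphi(x*)` and `rank_logits = delta(concat(z*, z))`. At
#' inference only the base branch is retained; `x_star` is ignored and no
#' privileged outputs are produced, so inference is independent of the
#' privileged branch by construction.
#'
#' @param model a `tram_net`.
#' @param x `(H, W, 1, B)` image array (a single `(H, W)` matrix is
#'   promoted).
#' @param x_star `(enc_len, B)` privileged matrix (train mode, TRAM-family
#'   variants).
#' @param mode `"train"` or `"infer"`.
#' @return list with `base_logits` (`num_classes x B`), `embedding z`, and
#'   in train mode `rank_logits` and `privileged_embedding`.
#' @export
forward <- function(model, x, x_star = NULL, mode = c("infer", "train")) {
  mode <- match.arg(mode)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  train <- mode == "train"
  enc <- seq_forward(model$encoder, x, train = train)
  z <- enc$out
  base <- seq_forward(model$xi, z, train = train)
  out <- list(base_logits = base$out, z = z)
  if (train && variant_has_priv(model$variant)) {
    if (is.null(x_star)) stop("train mode requires x_star for this variant")
    enc_len <- encoding_length(model$config$encoding_method, model$panel_size)
    if (nrow(x_star) != enc_len)
      stop("x_star has length ", nrow(x_star), ", expected ", enc_len)
    pe <- seq_forward(model$phi, x_star, train = TRUE)
    pr <- seq_forward(model$delta, rbind(pe$out, z), train = TRUE)
    out$privileged_embedding <- pe$out
    out$rank_logits <- pr$out
  }
  out
}

# ---- losses ----------------------------------------------------------------

softmax_cols <- function(l) {
  e <- exp(sweep(l, 2L, apply(l, 2L, max), "-"))
  sweep(e, 2L, colSums(e), "/")
}

# Mean cross-entropy over a batch; y in 0..(C-1). Returns loss and the
# gradient wrt the logits (already divided by batch size).
ce_loss <- function(logits, y) {
  B <- ncol(logits)
  p <- softmax_cols(logits)
  idx <- cbind(y + 1L, seq_len(B))
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / B)
}

#' CORN loss for rank-consistent ordinal regression
#'
#' The K-class ordinal problem is decomposed into K-1 conditional binary
#' tasks: task j is trained on the examples whose target exceeds j-1, with
#' binary label 1 when the target exceeds j, and probability
#' `sigmoid(rank_logits[j])`. The loss is the negative log-likelihood
#' summed over all contributing (task, example) terms and divided by the
#' number of such terms; tasks whose conditional subset is empty contribute
#' nothing.
#'
#' @param rank_logits `(K-1) x B` matrix of conditional logits.
#' @param targets integer vector in 1..K.
#' @param return_grad also return the gradient wrt the logits.
#' @return the scalar loss, or a list `(loss, dlogits)`.
#' @export
corn_loss <- function(rank_logits, targets, return_grad = FALSE) {
  Km1 <- nrow(rank_logits)
  B <- ncol(rank_logits)
  if (B < 1L) stop("empty batch")
  if (length(targets) != B) stop("targets must match the batch size")
  if (any(targets < 1L | targets > Km1 + 1L))
    stop("ordinal targets must lie in 1..K")
  j <- seq_len(Km1)
  mask <- outer(j, targets, function(a, b) b > a - 1L)
  lab <- outer(j, targets, function(a, b) as.numeric(b > a))
  n <- sum(mask)
  log_sig <- stats::plogis(rank_logits, log.p = TRUE)
  log_1msig <- stats::plogis(-rank_logits, log.p = TRUE)
  loss <- -sum((lab * log_sig + (1 - lab) * log_1msig)[mask]) / n
  if (!return_grad) return(loss)
  dl <- (stats::plogis(rank_logits) - lab) * mask / n
  list(loss = loss, dlogits = dl)
}

#' Rank prediction from CORN logits
#'
#' Unconditional exceedance probabilities are the running products of the
#' conditional sigmoids, `P(target > j) = prod_{i<=j} sigmoid(f_i)`, which
#' are non-increasing in j by construction; the predicted rank is 1 plus
#' the number of exceedance probabilities above 0.5.
#'
#' @param rank_logits `(K-1) x B` matrix (a vector is one example).
#' @return list with `rank` (integers in 1..K) and `exceed_probs`
#'   (`(K-1) x B`).
#' @export
corn_predict <- function(rank_logits) {
  if (is.null(dim(rank_logits))) rank_logits <- matrix(rank_logits, ncol = 1L)
  probs <- apply(stats::plogis(rank_logits), 2L, cumprod)
  if (is.null(dim(probs))) probs <- matrix(probs, ncol = ncol(rank_logits))
  list(rank = as.integer(1L + colSums(probs > 0.5)), exceed_probs = probs)
}

#' Combined two-branch training loss
#'
#' `L = CE(base_logits, y) + beta * L2(rank_logits, target)` where L2 is
#' the CORN loss for ordinal variants or cross-entropy for plain TRAM.
#'
#' @param base_logits `num_classes x B`.
#' @param y binary labels (0/1).
#' @param rank_logits privileged-head logits, or `NULL`.
#' @param ordinal_targets integer targets in 1..K (ordinal head) or 0/1
#'   labels (2-logit head).
#' @param beta privileged-loss weight.
#' @param priv_loss `"corn"` or `"ce"`.
#' @return list with `loss`, `L1`, `L2`.
#' @export
total_loss <- function(base_logits, y, rank_logits = NULL,
                       ordinal_targets = NULL, beta = 0.5,
                       priv_loss = c("corn", "ce")) {
  priv_loss <- match.arg(priv_loss)
  L1 <- ce_loss(base_logits, y)$loss
  L2 <- 0
  if (!is.null(rank_logits) && beta > 0) {
    L2 <- if (priv_loss == "corn") corn_loss(rank_logits, ordinal_targets)
          else ce_loss(rank_logits, ordinal_targets)$loss
  }
  list(loss = L1 + beta * L2, L1 = L1, L2 = L2)
}

# ---- optimizer wiring ------------------------------------------------------

optimizer_init <- function(model) {
  st <- list(t = 0L)
  for (part in c("encoder", "xi", "phi", "delta"))
    if (!is.null(model[[part]])) st[[part]] <- adam_init(model[[part]])
  if (!is.null(model$theta))
    st$theta <- list(m = model$theta * 0, v = model$theta * 0)
  st
}

adam_update_array <- function(p, g, st, lr, t,
                              beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  p <- p - lr * (st$m / (1 - beta1^t)) / (sqrt(st$v / (1 - beta2^t)) + eps)
  list(p = p, st = st)
}

#' One optimization step of a model variant
#'
#' Runs the forward pass in training mode, evaluates the variant's loss,
#' backpropagates, and applies one Adam update with two parameter groups
#' (encoder at `lr_encoder`, everything else at `lr_rest`).
#'
#' The stop-gradient contract is realized structurally: the base-branch
#' cross-entropy gradient is propagated into the class head `xi` only and
#' never past the embedding `z`, while the privileged-branch gradient
#' reaches `delta`, `varphi`, and (scaled by beta) the encoder.
#'
#' @param model a `tram_net`.
#' @param batch list with `x` (image array `(H,W,1,B)`), `y` (0/1),
#'   `x_star` (`enc_len x B`, TRAM variants), `ord` (ordinal targets, CORN
#'   variants), `ann` (list of per-record annotation sets, confusion
#'   variant).
#' @param opt optimizer state from a previous step, or `NULL` to start.
#' @param lr_encoder,lr_rest learning rates of the two parameter groups.
#' @param l1_weight multiplier on the base-branch loss; 0 disables L1
#'   (diagnostic use, e.g. verifying the gradient routing).
#' @return list `(model, opt, loss, L1, L2)`.
#' @export
train_step <- function(model, batch, opt = NULL, lr_encoder = 1e-3,
                       lr_rest = 1e-3, l1_weight = 1) {
  if (is.null(opt)) opt <- optimizer_init(model)
  opt$t <- opt$t + 1L
  variant <- model$variant
  trainable_enc <- variant_encoder_trainable(
    variant, model$confusion$trainable_encoder %||% FALSE)

  enc <- seq_forward(model$encoder, batch$x, train = trainable_enc)
  z <- enc$out
  B <- ncol(z)

  if (variant == "confusion") {
    res <- confusion_loss_grad(model, z, batch$ann)
    L1 <- res$loss; L2 <- 0
    dlb <- res$dlogits_xi
    base <- res$base  # forward cache of xi
    theta_grad <- res$dtheta
  } else {
    base <- seq_forward(model$xi, z, train = TRUE)
    l1 <- ce_loss(base$out, batch$y)
    L1 <- l1$loss
    dlb <- l1$dlogits * l1_weight
    theta_grad <- NULL
  }

  # base head gradient; stop-gradient: dz from this path is discarded for
  # TRAM variants, used for fine_tune, dropped for frozen encoders
  bb <- seq_backward(model$xi, base$caches, dlb, need_input_grad = TRUE)
  xi_grads <- bb$grads
  dz_base <- bb$dx

  L2 <- 0
  phi_grads <- delta_grads <- NULL
  dz_priv <- NULL
  if (variant_has_priv(variant)) {
    pe <- seq_forward(model$phi, batch$x_star, train = TRUE)
    h <- rbind(pe$out, z)
    pr <- seq_forward(model$delta, h, train = TRUE)
    if (variant_uses_corn(variant)) {
      l2 <- corn_loss(pr$out, batch$ord, return_grad = TRUE)
    } else {
      l2 <- ce_loss(pr$out, batch$y)
    }
    L2 <- l2$loss
    beta <- model$config$beta
    if (beta > 0) {
      db <- seq_backward(model$delta, pr$caches, l2$dlogits * beta,
                         need_input_grad = TRUE)
      delta_grads <- db$grads
      ph <- model$config$privileged_hidden
      dzs <- db$dx[seq_len(ph), , drop = FALSE]
      dz_priv <- db$dx[-seq_len(ph), , drop = FALSE]
      pb <- seq_backward(model$phi, pe$caches, dzs, need_input_grad = FALSE)
      phi_grads <- pb$grads
    }
  }

  # encoder gradient routing
  dz_enc <- switch(variant,
    fine_tune = dz_base,
    confusion = if (trainable_enc) dz_base,
    linear_probe = NULL,
    dz_priv)  # TRAM family: only the privileged branch reaches the encoder
  enc_grads <- NULL
  if (trainable_enc && !is.null(dz_enc)) {
    eb <- seq_backward(model$encoder, enc$caches, dz_enc,
                       need_input_grad = FALSE)
    enc_grads <- eb$grads
  }

  # Adam updates (shared step count, per-group learning rates)
  if (!is.null(enc_grads)) {
    r <- adam_step(model$encoder, enc_grads, opt$encoder, lr_encoder, opt$t)
    model$encoder <- r$layers; opt$encoder <- r$state
  }
  r <- adam_step(model$xi, xi_grads, opt$xi, lr_rest, opt$t)
  model$xi <- r$layers; opt$xi <- r$state
  if (!is.null(delta_grads)) {
    r <- adam_step(model$delta, delta_grads, opt$delta, lr_rest, opt$t)
    model$delta <- r$layers; opt$delta <- r$state
    r <- adam_step(model$phi, phi_grads, opt$phi, lr_rest, opt$t)
    model$phi <- r$layers; opt$phi <- r$state
  }
  if (!is.null(theta_grad)) {
    r <- adam_update_array(model$theta, theta_grad, opt$theta, lr_rest, opt$t)
    model$theta <- r$p; opt$theta <- r$st
  }

  loss <- L1 + (model$config$beta %||% 0) * L2
  if (!is.finite(loss)) stop("training loss diverged (non-finite)")
  list(model = model, opt = opt, loss = loss, L1 = L1, L2 = L2)
}

#' Class probabilities and predictions from the base branch
#'
#' @param model a `tram_net`.
#' @param x image array `(H, W, 1, B)`.
#' @return list with `prob` (positive-class softmax probability), `pred`
#'   (argmax class 0/1), `logits`.
#' @export
predict_base <- function(model, x) {
  out <- forward(model, x, mode = "infer")
  p <- softmax_cols(out$base_logits)
  list(prob = p[2L, ], pred = as.integer(apply(out$base_logits, 2L, which.max) - 1L),
       logits = out$base_logits)
}
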