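make_batch <- function(model, n = 8L, image_size = 16L, seed = 21L) {
  set.seed(seed)
  enc_len <- encoding_length(model$config$encoding_method, model$panel_size)
  list(x = array(rnorm(image_size^2 * n), c(image_size, image_size, 1L, n)),
       y = sample(0:1, n, replace = TRUE),
       ord = sample(1:8, n, replace = TRUE),
       x_star = matrix(abs(rnorm(enc_len * n)), enc_len, n))
}

test_that("forward produces the contracted shapes in both modes", {
  model <- build_model(network_config(), "proposed", seed = 1L)
  b <- make_batch(model)
  inf <- forward(model, b$x, mode = "infer")
  expect_equal(dim(inf$base_logits), c(2L, 8L))
  expect_null(inf$rank_logits)
  # identical weights and inputs give identical outputs (eval-mode norm)
  inf2 <- forward(model, b$x, mode = "infer")
  expect_identical(inf$base_logits, inf2$base_logits)
  tr <- forward(model, b$x, b$x_star, mode = "train")
  expect_equal(dim(tr$rank_logits), c(7L, 8L))  # K - 1
  expect_equal(dim(tr$privileged_embedding), c(64L, 8L))
  # mismatched privileged length is rejected
  expect_error(forward(model, b$x, b$x_star[1:3, ], mode = "train"),
               "expected")
})

test_that("inference is independent of the privileged branch", {
  model <- build_model(network_config(), "proposed", seed = 2L)
  b <- make_batch(model)
  before <- predict_base(model, b$x)
  scrambled <- model
  for (part in c("phi", "delta"))
    for (i in seq_along(scrambled[[part]]))
      if (!is.null(scrambled[[part]][[i]]$params))
        scrambled[[part]][[i]]$params <- lapply(
          scrambled[[part]][[i]]$params, function(p) p + 100)
  after <- predict_base(scrambled, b$x)
  expect_identical(before, after)
})

test_that("CORN loss matches hand evaluations of the conditional subsets", {
  K <- 8L
  f <- rnorm(K - 1)
  rl <- matrix(f, K - 1, 1)
  # target 1: only task 1's subset contains it, with label 0
  expect_equal(corn_loss(rl, 1L), -log(1 - plogis(f[1])))
  # target K: member of every subset with label 1
  expect_equal(corn_loss(rl, K), -mean(log(plogis(f))))
  expect_error(corn_loss(rl, 9L), "1\\.\\.K")
  # perfectly confident correct logits drive the loss to zero
  conf <- matrix(50, K - 1, 3)
  expect_lt(corn_loss(conf, rep(K, 3L)), 1e-6)
})

test_that("CORN loss equals the looped oracle on random batches", {
  set.seed(31)
  for (rep in 1:40) {
    K <- sample(3:8, 1)
    B <- sample(1:32, 1)
    rl <- matrix(rnorm((K - 1) * B, sd = 2), K - 1, B)
    tg <- sample(1:K, B, replace = TRUE)
    expect_equal(corn_loss(rl, tg), oracle_corn_loss(rl, tg),
                 tolerance = 1e-9)
  }
})

test_that("CORN predictions are rank-consistent with monotone exceedance", {
  set.seed(32)
  rl <- matrix(rnorm(7 * 500, sd = 3), 7, 500)
  cp <- corn_predict(rl)
  expect_true(all(diff(cp$exceed_probs) <= 1e-12))
  expect_true(all(cp$rank >= 1L & cp$rank <= 8L))
  expect_equal(corn_predict(rep(-10, 7))$rank, 1L)
  expect_equal(corn_predict(rep(10, 7))$rank, 8L)
  expect_equal(corn_predict(c(2, 0, -2))$exceed_probs[, 1],
               c(0.881, 0.440, 0.052), tolerance = 1e-3)
  expect_equal(corn_predict(c(2, 0, -2))$rank, 2L)
})

test_that("the combined loss is L1 + beta * L2", {
  model <- build_model(network_config(), "proposed", seed = 3L)
  b <- make_batch(model)
  out <- forward(model, b$x, b$x_star, mode = "train")
  tl <- total_loss(out$base_logits, b$y, out$rank_logits, b$ord, beta = 0.5)
  expect_equal(tl$loss, tl$L1 + 0.5 * tl$L2)
  tl0 <- total_loss(out$base_logits, b$y, out$rank_logits, b$ord, beta = 0)
  expect_equal(tl0$loss, tl0$L1)
  expect_equal(total_loss(out$base_logits, b$y, NULL, NULL, 0.5)$L2, 0)
})

test_that("stop-gradient routes updates exactly as wired", {
  cfg0 <- network_config(beta = 0)
  model <- build_model(cfg0, "proposed", seed = 4L)
  b <- make_batch(model)
  st <- train_step(model, b)
  # privileged loss disabled: encoder, phi, delta bitwise untouched
  expect_identical(param_vector(st$model$encoder), param_vector(model$encoder))
  expect_identical(param_vector(st$model$phi), param_vector(model$phi))
  expect_identical(param_vector(st$model$delta), param_vector(model$delta))
  expect_false(identical(param_vector(st$model$xi), param_vector(model$xi)))

  model <- build_model(network_config(), "proposed", seed = 4L)
  st2 <- train_step(model, b, l1_weight = 0)
  # base loss disabled: xi untouched; encoder, phi, delta all move
  expect_identical(param_vector(st2$model$xi), param_vector(model$xi))
  expect_false(identical(param_vector(st2$model$encoder),
                         param_vector(model$encoder)))
  expect_false(identical(param_vector(st2$model$phi), param_vector(model$phi)))
  expect_false(identical(param_vector(st2$model$delta),
                         param_vector(model$delta)))

  st3 <- train_step(model, b)  # full loss: every module may move
  expect_false(identical(param_vector(st3$model$encoder),
                         param_vector(model$encoder)))
  expect_false(identical(param_vector(st3$model$xi), param_vector(model$xi)))
})

test_that("the ordinal head alone recovers ranks on separable 1-D bands", {
  ns <- asNamespace("uncertram")
  set.seed(33)
  n <- 400L
  u <- runif(n, 0, 8)
  target <- pmin(pmax(ceiling(u), 1L), 8L)
  x <- matrix(u, 1L, n)
  layers <- list(ns$nn_linear(1L, 16L), ns$nn_relu(), ns$nn_linear(16L, 7L))
  opt <- ns$adam_init(layers)
  for (t in 1:600) {
    f <- ns$seq_forward(layers, x, train = TRUE)
    l <- corn_loss(f$out, target, return_grad = TRUE)
    bk <- ns$seq_backward(layers, f$caches, l$dlogits,
                          need_input_grad = FALSE)
    r <- ns$adam_step(layers, bk$grads, opt, lr = 5e-2, t = t)
    layers <- r$layers; opt <- r$state
  }
  pred <- corn_predict(ns$seq_forward(layers, x, train = TRUE)$out)$rank
  expect_gte(mean(pred == target), 0.95)
})

test_that("resnet50 emits finite embeddings of the contracted width", {
  enc <- resnet50_encoder(seed = 5L)
  z <- resnet50_embed(enc, matrix(rnorm(64 * 64), 64, 64))
  expect_equal(dim(z), c(2048L, 1L))
  expect_true(all(is.finite(z)))
})
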