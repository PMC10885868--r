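# Shared fixtures and independent oracles for the test suite. The oracles
# deliberately re-derive quantities from first principles (explicit loops,
# closed forms) rather than calling the package's vectorized paths.

# the worked three-reviewer example used throughout the documentation
example_set <- function() annotation_set("img", c(6L, 2L, 2L), c(8L, 6L, 12L))

# brute-force uncertainty: mean per-score equivocality + population sd,
# written straight from the definitions
oracle_D <- function(scores) {
  g <- numeric(length(scores))
  for (i in seq_along(scores)) g[i] <- -abs(scores[i] - 4.5) + 3.5
  mu <- sum(scores) / length(scores)
  sigma <- sqrt(sum((scores - mu)^2) / length(scores))
  sum(g) / length(g) + sigma
}

# looped CORN loss: iterate tasks and conditional subsets explicitly
oracle_corn_loss <- function(rank_logits, targets) {
  Km1 <- nrow(rank_logits)
  total <- 0
  n_terms <- 0L
  for (j in seq_len(Km1)) {
    for (b in seq_along(targets)) {
      if (targets[b] > j - 1) {            # conditional subset of task j
        lab <- as.numeric(targets[b] > j)
        p <- 1 / (1 + exp(-rank_logits[j, b]))
        total <- total - (lab * log(p) + (1 - lab) * log(1 - p))
        n_terms <- n_terms + 1L
      }
    }
  }
  total / n_terms
}

# AUROC by explicit pairwise comparison with half-credit ties
oracle_auroc <- function(y_true, y_score) {
  pos <- which(y_true == 1); neg <- which(y_true == 0)
  total <- 0
  for (i in pos) for (j in neg)
    total <- total + (y_score[i] > y_score[j]) + 0.5 * (y_score[i] == y_score[j])
  total / (length(pos) * length(neg))
}

# AUPRC by enumerating every distinct-threshold operating point
oracle_auprc <- function(y_true, y_score) {
  th <- sort(unique(y_score), decreasing = TRUE)
  np <- sum(y_true == 1)
  prev_rec <- 0; ap <- 0
  for (t in th) {
    pred <- y_score >= t
    tp <- sum(pred & y_true == 1)
    prec <- tp / sum(pred)
    rec <- tp / np
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# a small labeled dataset built in code: scores chosen to pin down D
tiny_dataset <- function(image_size = 16L) {
  mk <- function(id, pid, scores, reviewers, fill) {
    list(image_id = id, patient_id = pid,
         pixels = matrix(fill, image_size, image_size),
         annotations = annotation_set(id, scores, reviewers))
  }
  new_dataset(list(
    mk("i1", "pA", c(1L, 1L), c(1L, 2L), 0.1),   # D = 0
    mk("i2", "pA", c(8L, 8L), c(3L, 4L), 0.9),   # D = 0
    mk("i3", "pB", c(4L, 5L), c(1L, 3L), 0.5),   # D = 3.5
    mk("i4", "pC", c(6L, 2L, 2L), c(8L, 6L, 12L), 0.4),  # D ~ 3.219
    mk("i5", "pD", c(2L, 2L), c(5L, 7L), 0.2),   # D = 1
    mk("i6", "pE", c(7L, 7L), c(9L, 10L), 0.8)), # D = 1
    panel_size = 14L)
}

# a quick synthetic train/holdout pair for protocol tests
quick_benchmark <- function(seed = 7L, n_patients = 12L) {
  cfg <- synth_config(n_patients = n_patients, images_per_patient = 2L,
                      image_size = 16L, seed = seed)
  generate_benchmark(cfg, holdout_patients = 6L)
}

quick_tc <- function(max_epochs = 3L, patience = max_epochs, ...) {
  train_config(lr_encoder = 1e-3, lr_rest = 1e-3, max_epochs = max_epochs,
               patience = patience, ...)
}

# flatten every weight of a model into one numeric vector (for bitwise
# parameter-change checks)
param_vector <- function(layers) {
  unlist(lapply(layers, function(l) l$params), use.names = FALSE)
}
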