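#' Training configuration
#'
#' @param lr_encoder learning rate of the encoder parameter group (the
#'   grid-searched alpha).
#' @param lr_rest learning rate of every other parameter group.
#' @param batch_size minibatch size (64 in the reference protocol; a
#'   trailing batch of size 1 is dropped because batch-norm statistics are
#'   undefined on it).
#' @param max_epochs cap on training epochs (40).
#' @param patience early stopping fires when the validation loss has not
#'   improved on its best value for this many consecutive epochs (10).
#' @param n_folds cross-validation folds (3).
#' @param tau_val validation filter: only records with `D <= tau_val`
#'   enter the validation set (2).
#' @param seed_search seed of the hyperparameter-search CV.
#' @param seed_final seed of the final CV whose fold models are evaluated.
#' @return a `train_config` list.
#' @export
train_config <- function(lr_encoder = 1e-4, lr_rest = 1e-3,
                         batch_size = 64L, max_epochs = 40L, patience = 10L,
                         n_folds = 3L, tau_val = 2,
                         seed_search = 1L, seed_final = 2L) {
  stopifnot(patience <= max_epochs, n_folds >= 2L, batch_size >= 2L)
  structure(list(lr_encoder = lr_encoder, lr_rest = lr_rest,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 n_folds = as.integer(n_folds), tau_val = tau_val,
                 seed_search = as.integer(seed_search),
                 seed_final = as.integer(seed_final)),
            class = "train_config")
}

#' Patient-wise fold assignment
#'
#' All images of one patient land in the same fold; patients are shuffled
#' with the given seed and dealt round-robin, so fold patient counts
#' differ by at most one and the assignment is a deterministic function of
#' the patient ids and the seed.
#'
#' @param dataset an `uncertram_dataset`.
#' @param n_folds number of folds.
#' @param seed shuffle seed.
#' @return integer fold index (1..n_folds) per record.
#' @export
patient_wise_folds <- function(dataset, n_folds, seed = 1L) {
  pids <- vapply(dataset$records, `[[`, "", "patient_id")
  patients <- sort(unique(pids))
  if (length(patients) < n_folds)
    stop("fewer patients (", length(patients), ") than folds (", n_folds, ")")
  set.seed(seed)
  shuffled <- sample(patients)
  fold_of <- stats::setNames(rep_len(seq_len(n_folds), length(shuffled)),
                             shuffled)
  as.integer(fold_of[pids])
}

#' Subset a dataset by record index
#'
#' The subset shares the parent's access log, so pixel reads on either
#' count against the same ledger.
#'
#' @param dataset an `uncertram_dataset`.
#' @param idx record indices to keep.
#' @return an `uncertram_dataset`.
#' @export
dataset_subset <- function(dataset, idx) {
  out <- dataset
  out$records <- dataset$records[idx]
  out
}

#' Filter a validation set by uncertainty
#'
#' Keeps only records with `D <= tau_val`; the paired training portion is
#' never filtered. Uncertain validation cases carry unreliable mean
#' labels, so including them would make checkpoint selection noisy.
#'
#' @param dataset an `uncertram_dataset` (the candidate validation set).
#' @param tau_val threshold on D (2 in the reference protocol).
#' @return the filtered `uncertram_dataset` (warns when empty).
#' @export
filter_validation <- function(dataset, tau_val = 2) {
  D <- label_table(dataset)$D
  keep <- which(D <= tau_val)
  if (!length(keep))
    warning("validation filter left no records (tau_val = ", tau_val, ")")
  dataset_subset(dataset, keep)
}

# Materialize everything the trainer needs for a set of records: images,
# labels, ordinal targets, and the (gated) privileged matrix.
prep_training_data <- function(dataset, model) {
  lab <- label_table(dataset)
  n <- length(dataset$records)
  x <- assemble_images(dataset, seq_len(n))
  xstar <- NULL
  if (variant_has_priv(model$variant)) {
    enc_len <- encoding_length(model$config$encoding_method, model$panel_size)
    xstar <- matrix(0, enc_len, n)
    if (!model$config$zero_privileged) {
      for (i in seq_len(n)) {
        v <- encode_annotations(dataset$records[[i]]$annotations,
                                model$config$encoding_method,
                                M = model$panel_size)
        if (variant_uses_gate(model$variant))
          v <- gate(v, lab$D[i], model$config$tau)
        xstar[, i] <- as.numeric(v)
      }
    }
  }
  ann <- if (model$variant == "confusion")
    lapply(dataset$records, `[[`, "annotations")
  list(x = x, y = lab$y, ord = lab$ordinal_target, D = lab$D,
       xstar = xstar, ann = ann, n = n)
}

validation_loss <- function(model, val_data) {
  out <- forward(model, val_data$x, mode = "infer")
  ce_loss(out$base_logits, val_data$y)$loss
}

#' Train one cross-validation fold
#'
#' Optimizes the variant's loss on the training records (privileged
#' gating applied per record), computes the validation loss after every
#' epoch as the cross-entropy of the base branch against the
#' mean-aggregated labels on the (already filtered) validation set, stops
#' early when the loss has not improved for `patience` epochs, and returns
#' the checkpoint with the lowest validation loss.
#'
#' @param train an `uncertram_dataset` of training records.
#' @param val the filtered validation `uncertram_dataset` (non-empty).
#' @param net_config a [network_config].
#' @param tc a [train_config].
#' @param variant one of [model_variants()].
#' @param fold_index identifier carried into the result.
#' @param seed seed for weight init and epoch shuffles.
#' @return a `fold_result`: `fold_index`, `best_epoch`,
#'   `best_validation_loss`, `model` (best checkpoint), `history`
#'   (per-epoch train/validation losses).
#' @export
train_fold <- function(train, val, net_config, tc, variant = "proposed",
                       fold_index = 1L, seed = 1L) {
  if (length(val$records) == 0L)
    stop("validation set is empty; cannot select a checkpoint")
  set.seed(seed)
  model <- build_model(net_config, variant,
                       panel_size = train$panel_size,
                       image_size = nrow(train$records[[1L]]$pixels))
  td <- prep_training_data(train, model)
  vd <- prep_training_data(dataset_subset(val, seq_along(val$records)), model)
  opt <- NULL
  best <- list(loss = Inf, epoch = 0L, model = NULL)
  since_best <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  for (epoch in seq_len(tc$max_epochs)) {
    ord <- sample.int(td$n)
    ep_loss <- 0; n_batches <- 0L
    for (start in seq(1L, td$n, by = tc$batch_size)) {
      ix <- ord[start:min(start + tc$batch_size - 1L, td$n)]
      if (length(ix) < 2L) next  # batch norm needs >= 2 samples
      batch <- list(x = td$x[, , , ix, drop = FALSE], y = td$y[ix],
                    ord = td$ord[ix],
                    x_star = if (!is.null(td$xstar))
                      td$xstar[, ix, drop = FALSE],
                    ann = if (!is.null(td$ann)) td$ann[ix])
      st <- train_step(model, batch, opt, lr_encoder = tc$lr_encoder,
                       lr_rest = tc$lr_rest)
      model <- st$model; opt <- st$opt
      ep_loss <- ep_loss + st$loss; n_batches <- n_batches + 1L
    }
    vloss <- validation_loss(model, vd)
    if (!is.finite(vloss)) stop("validation loss diverged (non-finite)")
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n_batches,
                                         val_loss = vloss))
    if (vloss < best$loss) {
      best <- list(loss = vloss, epoch = epoch, model = clone_model(model))
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= tc$patience) break
    }
  }
  structure(list(fold_index = fold_index, best_epoch = best$epoch,
                 best_validation_loss = best$loss, model = best$model,
                 history = history),
            class = "fold_result")
}

#' Patient-wise cross-validation of one variant
#'
#' @param dataset training `uncertram_dataset`.
#' @param net_config a [network_config].
#' @param tc a [train_config].
#' @param variant model variant.
#' @param seed CV seed (drives the fold split, weight inits and shuffles).
#' @return list of `fold_result`s.
#' @export
crossval <- function(dataset, net_config, tc, variant = "proposed",
                     seed = 1L) {
  folds <- patient_wise_folds(dataset, tc$n_folds, seed)
  lapply(seq_len(tc$n_folds), function(f) {
    train <- dataset_subset(dataset, which(folds != f))
    val <- filter_validation(dataset_subset(dataset, which(folds == f)),
                             tc$tau_val)
    train_fold(train, val, net_config, tc, variant,
               fold_index = f, seed = seed + f)
  })
}

#' Grid search over the two learning rates
#'
#' Every (lr_encoder, lr_rest) pair is cross-validated under
#' `seed_search`; the pair minimizing the mean best validation loss across
#' folds wins, with ties broken toward the smaller lr_encoder, then the
#' smaller lr_rest. Pairs whose training diverges are skipped; if all
#' diverge, an error is raised.
#'
#' @param dataset training `uncertram_dataset`.
#' @param net_config a [network_config].
#' @param tc a [train_config]; its learning rates are overridden by the
#'   grid.
#' @param variant model variant.
#' @param lr_encoder_grid,lr_rest_grid candidate values (defaults are the
#'   reference 5 x 5 grids).
#' @return list with `lr_encoder`, `lr_rest`, `mean_val_loss`, and the
#'   full `table` of grid results.
#' @export
grid_search <- function(dataset, net_config, tc, variant = "proposed",
                        lr_encoder_grid = c(1e-4, 4e-4, 1e-5, 5e-5, 1e-6),
                        lr_rest_grid = c(1e-3, 5e-3, 1e-4, 5e-4, 1e-5)) {
  stopifnot(length(lr_encoder_grid) > 0, length(lr_rest_grid) > 0)
  tab <- expand.grid(lr_encoder = sort(lr_encoder_grid),
                     lr_rest = sort(lr_rest_grid))
  tab <- tab[order(tab$lr_encoder, tab$lr_rest), ]
  tab$mean_val_loss <- NA_real_
  best <- NULL
  for (i in seq_len(nrow(tab))) {
    tci <- tc
    tci$lr_encoder <- tab$lr_encoder[i]
    tci$lr_rest <- tab$lr_rest[i]
    res <- tryCatch(crossval(dataset, net_config, tci, variant,
                             seed = tc$seed_search),
                    error = function(e) NULL)
    if (is.null(res)) next
    m <- mean(vapply(res, `[[`, numeric(1), "best_validation_loss"))
    tab$mean_val_loss[i] <- m
    if (is.null(best) || m < best$mean_val_loss)
      best <- list(lr_encoder = tab$lr_encoder[i], lr_rest = tab$lr_rest[i],
                   mean_val_loss = m)
  }
  if (is.null(best)) stop("every learning-rate pair diverged")
  best$table <- tab
  best
}

#' Final cross-validated experiment with holdout evaluation
#'
#' Re-runs the cross-validation at the chosen hyperparameters under
#' `seed_final`, then applies each fold's best checkpoint (base branch
#' only) to the holdout set and reports per-fold metrics with their mean
#' and standard deviation, overall and per uncertainty stratum. Holdout
#' patients must be disjoint from training patients, and the holdout
#' pixels are provably untouched before evaluation (tracked through the
#' dataset access log).
#'
#' @param dataset training `uncertram_dataset`.
#' @param holdout holdout `uncertram_dataset`.
#' @param net_config a [network_config].
#' @param tc a [train_config].
#' @param variant model variant.
#' @param bins uncertainty strata for the stratified report.
#' @return list with `folds` (fold results), `results` (per-fold
#'   prediction tables), `metrics` (per-fold `metrics_record`s), `mean`
#'   and `sd` (named metric vectors), `stratified` (per-fold reports) and
#'   `holdout_untouched_during_training`.
#' @export
run_experiment <- function(dataset, holdout, net_config, tc,
                           variant = "proposed", bins = default_strata()) {
  tr_p <- unique(vapply(dataset$records, `[[`, "", "patient_id"))
  ho_p <- unique(vapply(holdout$records, `[[`, "", "patient_id"))
  overlap <- intersect(tr_p, ho_p)
  if (length(overlap))
    stop("patient overlap between training and holdout: ", overlap[1L])
  before <- access_count(holdout)
  folds <- crossval(dataset, net_config, tc, variant, seed = tc$seed_final)
  untouched <- access_count(holdout) == before
  results <- lapply(folds, function(f) evaluate_model(f$model, holdout))
  metrics <- lapply(results, function(r)
    compute_metrics(r$y_true, r$y_pred, r$y_score))
  stratified <- lapply(results, stratified_evaluate, bins = bins)
  keys <- c("precision", "accuracy", "auprc", "auroc", "sensitivity",
            "specificity", "f1", "mcc")
  vals <- sapply(metrics, function(m) unlist(m[keys]))
  list(folds = folds, results = results, metrics = metrics,
       mean = rowMeans(vals), sd = apply(vals, 1L, stats::sd),
       stratified = stratified,
       holdout_untouched_during_training = untouched)
}

#' Scaled-down synthetic benchmark across model variants
#'
#' Generates a patient-disjoint train/holdout pair, trains each requested
#' variant on a single patient-wise train/validation split, evaluates on
#' the holdout set, and reports stratified accuracies — repeated over
#' several seeds. This is the package's qualitative reproduction of the
#' full protocol at desk scale: clean-stratum accuracy should exceed
#' equivocal-stratum accuracy for every variant, and the uncertainty-gated
#' ordinal variant should match or beat plain TRAM on the clean stratum.
#'
#' The learning rate is selected per variant from `lr_grid` by the
#' validation loss of the best checkpoint — the reduced desk-scale form of
#' the full protocol's learning-rate grid search.
#'
#' @param variants variants to train.
#' @param seeds one run per seed.
#' @param config base [synth_config]; its seed is replaced per run.
#' @param tc a [train_config] (defaults here are the reduced desk-scale
#'   settings: 10 epochs, patience 5).
#' @param net_config a [network_config].
#' @param lr_grid candidate learning rates (applied to both parameter
#'   groups), selected by validation loss.
#' @return data.frame with one row per (seed, variant): chosen learning
#'   rate, overall, clean and equivocal accuracy and stratum sizes.
#' @export
run_synthetic_benchmark <- function(variants = model_variants(),
                                    seeds = 1:3,
                                    config = synth_config(),
                                    tc = train_config(lr_encoder = 1e-3,
                                                      lr_rest = 1e-3,
                                                      max_epochs = 10L,
                                                      patience = 5L),
                                    net_config = network_config(),
                                    lr_grid = c(1e-3, 1e-2)) {
  rows <- list()
  for (seed in seeds) {
    cfg <- config
    cfg$seed <- as.integer(seed * 1000L + 17L)
    bench <- generate_benchmark(cfg)
    trainset <- bench$train$dataset
    holdout <- bench$holdout$dataset
    split <- patient_wise_folds(trainset, 5L, seed = seed)
    tr <- dataset_subset(trainset, which(split != 1L))
    va <- filter_validation(dataset_subset(trainset, which(split == 1L)),
                            tc$tau_val)
    for (variant in variants) {
      nci <- net_config
      if (variant == "confusion") {
        # there is no pretrained encoder to freeze at desk scale, so the
        # confusion baseline runs its trainable-encoder switch here
        nci$confusion <- confusion_config(
          trace_weight = nci$confusion$trace_weight,
          init_diag = nci$confusion$init_diag,
          trainable_encoder = TRUE)
      }
      fr <- NULL
      for (lr in lr_grid) {
        tci <- tc
        tci$lr_encoder <- lr
        tci$lr_rest <- lr
        cand <- train_fold(tr, va, nci, tci, variant,
                           fold_index = 1L, seed = seed)
        cand$lr <- lr
        if (is.null(fr) || cand$best_validation_loss < fr$best_validation_loss)
          fr <- cand
      }
      res <- evaluate_model(fr$model, holdout)
      strat <- stratified_evaluate(res)
      acc <- function(b) if (is.null(strat$metrics[[b]])) NA_real_
                         else strat$metrics[[b]]$accuracy
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, variant = variant, lr = fr$lr,
        accuracy = compute_metrics(res$y_true, res$y_pred,
                                   res$y_score)$accuracy,
        clean_accuracy = acc(1L), equivocal_accuracy = acc(2L),
        n_clean = strat$n[1L], n_equivocal = strat$n[2L],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
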