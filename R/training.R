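# Stage-1 multi-task training (SGD with momentum), stratified k-fold
# cross-validation with grid search, and stage-2 transfer learning with a
# from-scratch control.

# Elementwise walk over two parameter trees; `b` is indexed by the names of
# `a` so tree order never matters.
map_params <- function(a, b, f) {
  purrr::imap(a, function(la, nm) {
    lb <- b[[nm]]
    purrr::imap(la, function(w, wn) f(w, lb[[wn]]))
  })
}

zero_like <- function(params) {
  purrr::map(params, function(layer) purrr::map(layer, function(w) w * 0))
}

sgd_update <- function(params, velocity, grads, lr, momentum) {
  velocity <- map_params(velocity, grads, function(v, g) momentum * v - lr * g)
  params <- map_params(params, velocity, `+`)
  list(params = params, velocity = velocity)
}

#' Train a model with SGD and momentum
#'
#' Runs mini-batch SGD over a dataset split, shuffling deterministically
#' each epoch; the per-epoch loss components are kept in `model$log`.
#' Zero epochs returns the initial weights unchanged.  A non-finite loss
#' aborts with a diagnostic.
#'
#' @param model An `m6a_model` (freshly built or partially trained).
#' @param train Dataset split: windows tibble with `label` and (for
#'   multitask/regression modes) `support_target`.
#' @param epochs Number of passes over the data.
#' @param lr Learning rate (default 0.01).
#' @param momentum SGD momentum (default 0.9).
#' @param batch_size Mini-batch size (default 64).
#' @param seed Integer seed governing shuffling and dropout.
#' @return The trained `m6a_model` with an updated `log` tibble
#'   (`epoch`, `loss`, `ce`, `logcosh`).
#' @export
train_model <- function(model, train, epochs, lr = 0.01, momentum = 0.9,
                        batch_size = 64, seed = 1) {
  epochs <- check_count(epochs, "epochs", min = 0)
  cfg <- model$config
  if (epochs == 0) return(model)
  use_class <- model$mode != "regress_only"
  use_reg <- model$mode != "classify_only"

  x_enc <- encode_windows(train)
  velocity <- zero_like(model$params)
  log_rows <- vector("list", epochs)

  with_seed(seed + 104729L, {
    for (e in seq_len(epochs)) {
      batches <- make_batches(train, batch_size, seed = seed, epoch = e, x = x_enc)
      tot <- ce <- lc <- 0
      for (b in batches) {
        out <- forward_model(model, b$x, training = TRUE)
        lg <- loss_and_grads(
          y = if (use_class) b$y else NULL,
          p = out$p %||% NULL,
          yr = if (use_reg) b$yr else NULL,
          yhat = out$yhat %||% NULL,
          w_class = cfg$loss_weight_class, w_reg = cfg$loss_weight_reg,
          ce_form = cfg$ce_form)
        if (!is.finite(lg$total)) {
          abort(sprintf(
            "Training diverged at epoch %d (loss = %s); reduce the learning rate.",
            e, format(lg$total)))
        }
        grads <- backward_model(model, out,
                                dz_class = if (use_class) lg$dz else NULL,
                                dyhat = if (use_reg) lg$dyhat else NULL)
        upd <- sgd_update(model$params, velocity, grads, lr, momentum)
        model$params <- upd$params
        velocity <- upd$velocity
        w <- nrow(b$y)
        tot <- tot + lg$total * w; ce <- ce + lg$ce * w; lc <- lc + lg$lc * w
      }
      n <- nrow(train)
      log_rows[[e]] <- tibble(epoch = e, loss = tot / n, ce = ce / n,
                              logcosh = lc / n)
    }
  })
  new_log <- dplyr::bind_rows(log_rows)
  if (!is.null(model$log)) {
    new_log$epoch <- new_log$epoch + max(model$log$epoch)
    new_log <- dplyr::bind_rows(model$log, new_log)
  }
  model$log <- new_log
  model
}

#' Build and train the stage-1 multi-task model
#'
#' @param train Balanced training split with `support_target` attached.
#' @param config An `m6a_config`.
#' @param mode Task mode; `"multitask"` trains both heads jointly.
#' @param epochs Training epochs (the reference design uses 60).
#' @inheritParams train_model
#' @param normalizer Optional fitted `support_normalizer` carried on the
#'   model for later prediction-time use.
#' @return A trained `m6a_model` tagged `stage1`.
#' @export
train_stage1 <- function(train, config, mode = "multitask", epochs = 60,
                         lr = 0.01, momentum = 0.9, batch_size = 64,
                         seed = 1, normalizer = NULL) {
  model <- build_model(config, mode = mode)
  model <- train_model(model, train, epochs = epochs, lr = lr,
                       momentum = momentum, batch_size = batch_size,
                       seed = seed)
  model$stage <- "stage1"
  model$normalizer <- normalizer
  model
}

#' Stratified cross-validation fold assignment
#'
#' @param labels Label vector.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer fold id per sample; within each class the fold sizes
#'   differ by at most one.
#' @export
make_cv_folds <- function(labels, folds = 5, seed = 1) {
  folds <- check_count(folds, "folds", min = 2)
  fold_id <- integer(length(labels))
  with_seed(seed, {
    for (lb in unique(labels)) {
      idx <- which(labels == lb)
      if (length(idx) < folds) {
        abort(sprintf("Class '%s' has fewer samples than folds.", lb))
      }
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold_id
}

cv_eval_one <- function(config, mode, train, fold_id, epochs, lr, momentum,
                        batch_size, seed, init_model = NULL) {
  purrr::map_dfr(sort(unique(fold_id)), function(j) {
    model <- init_model %||% build_model(config, mode = mode)
    model <- train_model(model, train[fold_id != j, , drop = FALSE],
                         epochs = epochs, lr = lr, momentum = momentum,
                         batch_size = batch_size, seed = seed + j)
    ev <- evaluate_model(model, train[fold_id == j, , drop = FALSE])
    tibble(fold = j, auroc = ev$auroc,
           pearson = ev$pearson_reg %||% NA_real_)
  })
}

#' Exhaustive grid search with stratified k-fold cross-validation
#'
#' Every combination of the supplied hyperparameter values is trained and
#' scored by mean cross-validated AUROC of the classification task (Pearson
#' r of the regression head is reported alongside).  Ties are broken by
#' smaller model, then grid order.  A combination that fails to build is
#' recorded as failed rather than aborting the search.
#'
#' @param train Dataset split with `label` (and `support_target` for
#'   multitask grids).
#' @param grid Named list of hyperparameter values to cross; names may be
#'   any [backbone_config()] argument plus `epochs`, `lr`, `batch_size`.
#' @param config Base configuration that the grid overrides.
#' @param folds Number of CV folds (default 5).
#' @param mode Task mode.
#' @param epochs,lr,momentum,batch_size Training settings used where the
#'   grid does not override them.
#' @param seed Integer seed (folds and training).
#' @return An object of class `m6a_cv`: `table` (per-fold results),
#'   `summary` (per-combination means), `best` (selected row), and
#'   `best_config`.
#' @export
grid_search_cv <- function(train, grid, config = backbone_config(),
                           folds = 5, mode = "multitask", epochs = 10,
                           lr = 0.01, momentum = 0.9, batch_size = 64,
                           seed = 1) {
  if (length(grid) == 0) abort("`grid` must name at least one hyperparameter.")
  combos <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  fold_id <- make_cv_folds(train$label, folds = folds, seed = seed)
  train_keys <- c("epochs", "lr", "batch_size")

  results <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    combo <- as.list(combos[i, , drop = FALSE])
    cfg_args <- combo[setdiff(names(combo), train_keys)]
    cfg <- tryCatch(
      do.call(backbone_config, modifyList(unclass(config), cfg_args)),
      error = function(e) e)
    if (inherits(cfg, "error")) {
      return(tibble(combo = i, fold = NA_integer_, auroc = NA_real_,
                    pearson = NA_real_, failed = TRUE,
                    message = conditionMessage(cfg)))
    }
    res <- cv_eval_one(cfg, mode, train, fold_id,
                       epochs = combo$epochs %||% epochs,
                       lr = combo$lr %||% lr, momentum = momentum,
                       batch_size = combo$batch_size %||% batch_size,
                       seed = seed)
    dplyr::mutate(res, combo = i, failed = FALSE, message = NA_character_,
                  .before = 1)
  })

  summary <- results |>
    dplyr::filter(!.data$failed) |>
    dplyr::group_by(.data$combo) |>
    dplyr::summarise(mean_auroc = mean(.data$auroc),
                     sd_auroc = stats::sd(.data$auroc),
                     mean_pearson = mean(.data$pearson),
                     .groups = "drop") |>
    dplyr::left_join(
      dplyr::mutate(as_tibble(combos), combo = dplyr::row_number()),
      by = "combo")

  size_of <- function(i) {
    combo <- as.list(combos[i, , drop = FALSE])
    cfg <- do.call(backbone_config,
                   modifyList(unclass(config),
                              combo[setdiff(names(combo), train_keys)]))
    n_params(build_model(cfg, mode = mode))
  }
  ranked <- summary |>
    dplyr::mutate(model_size = vapply(.data$combo, size_of, numeric(1))) |>
    dplyr::arrange(dplyr::desc(.data$mean_auroc), .data$model_size, .data$combo)
  best <- ranked[1, , drop = FALSE]
  best_combo <- as.list(combos[best$combo, , drop = FALSE])
  best_config <- do.call(backbone_config,
                         modifyList(unclass(config),
                                    best_combo[setdiff(names(best_combo),
                                                       train_keys)]))

  structure(list(table = results, summary = ranked, best = best,
                 best_config = best_config, folds = folds, seed = seed),
            class = "m6a_cv")
}

#' @export
print.m6a_cv <- function(x, ...) {
  cat(sprintf("<m6a_cv> %d combination(s), %d folds; best mean AUROC %.4f\n",
              nrow(x$summary), x$folds, x$best$mean_auroc))
  invisible(x)
}

#' @export
tidy.m6a_cv <- function(x, ...) x$summary

#' @export
glance.m6a_cv <- function(x, ...) {
  dplyr::select(x$best, "combo", "mean_auroc", "sd_auroc", "mean_pearson")
}

#' Initialise a stage-2 model from a stage-1 model
#'
#' All layers except the output heads are copied verbatim from the source
#' model; the remaining head(s) are freshly initialised from `seed`.  No
#' layer is frozen: every weight remains trainable.
#'
#' @param source Trained stage-1 `m6a_model`.
#' @param mode Stage-2 task mode; the default drops the regression head.
#' @param seed Seed for the head initialisation.
#' @return An untrained `m6a_model` tagged `stage2`.
#' @export
transfer_init <- function(source, mode = "classify_only", seed = 1) {
  cfg <- source$config
  cfg$seed <- as.integer(seed)
  target <- build_model(cfg, mode = mode)
  feature_layers <- setdiff(names(target$params),
                            c("head_class", "head_reg"))
  missing_layers <- setdiff(feature_layers, names(source$params))
  if (length(missing_layers) > 0) {
    abort(sprintf("Source model lacks layer(s): %s.",
                  paste(missing_layers, collapse = ", ")))
  }
  for (nm in feature_layers) {
    src <- source$params[[nm]]
    tgt <- target$params[[nm]]
    bad <- names(tgt)[!vapply(names(tgt), function(w) {
      identical(dim(src[[w]]) %||% length(src[[w]]),
                dim(tgt[[w]]) %||% length(tgt[[w]]))
    }, logical(1))]
    if (length(bad) > 0) {
      abort(sprintf("Shape mismatch transferring layer '%s' (%s).",
                    nm, paste(bad, collapse = ", ")))
    }
    target$params[[nm]] <- src
  }
  target$stage <- "stage2"
  target
}

#' Transfer learning for the stage-2 model, with a from-scratch control
#'
#' Cross-validates the number of training epochs for (a) the transfer
#' model, initialised from the stage-1 feature-extraction layers, and (b)
#' scratch controls with random initialisation over one or more epoch
#' grids.  The final stage-2 model is retrained on the full training split
#' at the best transfer epoch count.
#'
#' @param source Trained stage-1 `m6a_model`.
#' @param stage2_train Stage-2 training split (windows tibble with `label`).
#' @param epochs_grid Epoch counts cross-validated for the transfer model.
#' @param scratch_grids List of epoch grids for the scratch controls (the
#'   reference design uses one grid matching the transfer grid and one
#'   shifted upwards by the stage-1 epoch budget).
#' @param folds CV folds.
#' @param seed Integer seed (head init, folds, training).
#' @inheritParams train_model
#' @param mode Stage-2 task mode.
#' @return A list with the final `model`, `cv` (per-strategy per-fold
#'   AUROCs), and `best` (per-strategy best mean AUROC and epochs).
#' @export
transfer_stage2 <- function(source, stage2_train,
                            epochs_grid = c(16, 32, 64, 128, 256),
                            scratch_grids = list(c(16, 32, 64, 128, 256),
                                                 c(76, 92, 124, 188, 316)),
                            folds = 5, seed = 1, lr = 0.01, momentum = 0.9,
                            batch_size = 64, mode = "classify_only") {
  fold_id <- make_cv_folds(stage2_train$label, folds = folds, seed = seed)
  cfg <- source$config

  run_strategy <- function(strategy, grid, init_model) {
    purrr::map_dfr(grid, function(ep) {
      res <- cv_eval_one(cfg, mode, stage2_train, fold_id, epochs = ep,
                         lr = lr, momentum = momentum,
                         batch_size = batch_size, seed = seed,
                         init_model = init_model)
      dplyr::mutate(res, strategy = strategy, epochs = ep, .before = 1)
    })
  }

  transfer0 <- transfer_init(source, mode = mode, seed = seed)
  cv <- run_strategy("transfer", epochs_grid, transfer0)
  for (i in seq_along(scratch_grids)) {
    scratch0 <- build_model(`class<-`(modifyList(unclass(cfg),
                                                 list(seed = as.integer(seed))),
                            "m6a_config"), mode = mode)
    cv <- dplyr::bind_rows(
      cv, run_strategy(paste0("scratch", i), scratch_grids[[i]], scratch0))
  }

  best <- cv |>
    dplyr::group_by(.data$strategy, .data$epochs) |>
    dplyr::summarise(mean_auroc = mean(.data$auroc), .groups = "drop_last") |>
    dplyr::slice_max(.data$mean_auroc, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  best_ep <- best$epochs[best$strategy == "transfer"]
  final <- train_model(transfer_init(source, mode = mode, seed = seed),
                       stage2_train, epochs = best_ep, lr = lr,
                       momentum = momentum, batch_size = batch_size,
                       seed = seed)
  final$stage <- "stage2"
  list(model = final, cv = cv, best = best)
}
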