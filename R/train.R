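# Masked multi-task training with Adam, early stopping on validation
# mean balanced accuracy (the selection criterion), the multi-seed
# evaluation protocol, sequential model-based hyperparameter search over
# the published grids, and Y-randomization.

#' Training configuration
#'
#' @param epochs Maximum epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param patience Early-stopping patience on validation mean balanced
#'   accuracy.
#' @param seeds Seeds for the multi-seed protocol (default 0-9, i.e. 10
#'   independent runs).
#' @param search_budget Default number of hyperparameter-search trials.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 40L, batch_size = 64L,
                         learning_rate = 1e-3, patience = 10L,
                         seeds = 0:9, search_budget = 10L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, patience >= 1,
            length(seeds) >= 1, !anyDuplicated(seeds), search_budget >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience), seeds = as.integer(seeds),
                 search_budget = as.integer(search_budget)),
            class = "train_config")
}

#' Masked binary cross-entropy
#'
#' Mean binary cross-entropy over observed cells only (`mask == 1`), so
#' compounds without a label for a task contribute nothing to that task.
#' An all-zero mask yields 0 with a warning.
#'
#' @param probs N x T matrix of probabilities in `(0, 1)`.
#' @param labels N x T matrix in `{0, 1}`.
#' @param mask N x T matrix in `{0, 1}`.
#' @return Scalar loss.
#' @export
masked_loss <- function(probs, labels, mask) {
  stopifnot(all(dim(probs) == dim(labels)), all(dim(probs) == dim(mask)))
  n_obs <- sum(mask)
  if (n_obs == 0) {
    warning("mask is all zero; loss defined as 0", call. = FALSE)
    return(0)
  }
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  -sum(mask * (labels * log(p) + (1 - labels) * log(1 - p))) / n_obs
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

predict_rows <- function(features, rows, params, config, chunk = 256L) {
  out <- matrix(0, length(rows), config$n_tasks)
  for (start in seq(1, length(rows), by = chunk)) {
    idx <- rows[start:min(start + chunk - 1, length(rows))]
    batch <- list(graph = batch_graphs(features$graphs[idx]),
                  fp = features$fp[idx, , drop = FALSE])
    out[start:(start + length(idx) - 1), ] <-
      fpgnn_forward(batch, params, config)$probs
  }
  out
}

mean_ba <- function(probs, labels, mask) {
  bas <- vapply(seq_len(ncol(labels)), function(t) {
    obs <- mask[, t] == 1
    if (!any(obs)) return(NA_real_)
    compute_metrics(confusion_from_predictions(probs[obs, t],
                                               labels[obs, t]))$ba
  }, numeric(1))
  mean(bas, na.rm = TRUE)
}

#' Train the multi-task model
#'
#' Masked binary cross-entropy minimized with Adam; after each epoch the
#' validation mean balanced accuracy across tasks is computed and the
#' best-scoring parameters are kept (early stopping after `patience`
#' epochs without improvement). Fully deterministic given the seed.
#'
#' @param dataset An `mt_dataset` with train and valid splits.
#' @param mconfig A [model_config()]; its `n_tasks` must match the
#'   dataset.
#' @param tconfig A [train_config()].
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @param features Optional precomputed [featurize_dataset()] result
#'   (saves repeated featurization across seeds).
#' @return An object of class `fpgnn_model`: `params`, `config`,
#'   `task_ids`, `history` (per-epoch loss and validation mean BA),
#'   `best_epoch`.
#' @export
train_model <- function(dataset, mconfig, tconfig = train_config(),
                        seed = 0L, features = NULL) {
  stopifnot(inherits(dataset, "mt_dataset"),
            mconfig$n_tasks == length(dataset$task_ids),
            all(c("train", "valid") %in% dataset$split))
  if (is.null(features)) features <- featurize_dataset(dataset)
  train_idx <- which(dataset$split == "train")
  valid_idx <- which(dataset$split == "valid")

  with_local_seed(seed, {
    params <- init_model(mconfig, seed = seed)
    state <- adam_init(params)
    best <- list(ba = -Inf, params = params, epoch = 0L)
    history <- vector("list", tconfig$epochs)
    stall <- 0L
    for (epoch in seq_len(tconfig$epochs)) {
      ord <- sample(train_idx)
      losses <- c()
      for (start in seq(1, length(ord), by = tconfig$batch_size)) {
        idx <- ord[start:min(start + tconfig$batch_size - 1, length(ord))]
        batch <- list(graph = batch_graphs(features$graphs[idx]),
                      fp = features$fp[idx, , drop = FALSE])
        lab <- dataset$labels[idx, , drop = FALSE]
        msk <- dataset$mask[idx, , drop = FALSE]
        fwd <- fpgnn_forward(batch, params, mconfig, training = TRUE,
                             keep_cache = TRUE)
        loss <- masked_loss(fwd$probs, lab, msk)
        if (!is.finite(loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        }
        losses <- c(losses, loss)
        n_obs <- max(sum(msk), 1)
        dlogits <- (fwd$probs - lab) * msk / n_obs
        bk <- fpgnn_backward(dlogits, fwd, batch, params, mconfig)
        upd <- adam_step(params, bk$grads, state, tconfig$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      val_probs <- predict_rows(features, valid_idx, params, mconfig)
      vba <- mean_ba(val_probs,
                     dataset$labels[valid_idx, , drop = FALSE],
                     dataset$mask[valid_idx, , drop = FALSE])
      history[[epoch]] <- tibble::tibble(epoch = epoch,
                                         loss = mean(losses),
                                         val_mean_ba = vba)
      if (vba > best$ba + 1e-9) {
        best <- list(ba = vba, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tconfig$patience) break
      }
    }
    structure(list(params = best$params, config = mconfig,
                   task_ids = dataset$task_ids,
                   history = dplyr::bind_rows(history),
                   best_epoch = best$epoch, best_val_ba = best$ba,
                   seed = as.integer(seed)),
              class = "fpgnn_model")
  })
}

#' @export
print.fpgnn_model <- function(x, ...) {
  cat("<fpgnn_model> ", x$config$n_tasks, " task(s): ",
      paste(x$task_ids, collapse = ", "), "\n", sep = "")
  if (!is.null(x$best_epoch)) {
    cat("  best epoch ", x$best_epoch, " (validation mean BA ",
        sprintf("%.3f", x$best_val_ba), ")\n", sep = "")
  }
  invisible(x)
}

#' Predict per-task activity probabilities
#'
#' @param object An `fpgnn_model`.
#' @param newdata Character vector of SMILES, an `mt_dataset`, or a
#'   precomputed [featurize_dataset()] result.
#' @param ... Unused.
#' @return Tibble with `smiles` and one probability column per task.
#' @export
predict.fpgnn_model <- function(object, newdata, ...) {
  features <- if (is.character(newdata) || inherits(newdata, "mt_dataset")) {
    featurize_dataset(newdata)
  } else {
    newdata
  }
  probs <- predict_rows(features, seq_along(features$smiles),
                        object$params, object$config)
  colnames(probs) <- object$task_ids
  dplyr::bind_cols(tibble::tibble(smiles = features$smiles),
                   tibble::as_tibble(as.data.frame(probs)))
}

#' Per-task metrics of a model on one split of a dataset
#'
#' @param model An `fpgnn_model`.
#' @param dataset The `mt_dataset` to evaluate on.
#' @param split One of `"train"`, `"valid"`, `"test"`.
#' @param features Optional precomputed features.
#' @param rows Optional explicit row indices (overrides `split`).
#' @return Tibble with one row per task: the seven evaluation metrics.
#' @export
evaluate_model <- function(model, dataset, split = "test", features = NULL,
                           rows = NULL) {
  if (is.null(features)) features <- featurize_dataset(dataset)
  idx <- rows %||% which(dataset$split == split)
  probs <- predict_rows(features, idx, model$params, model$config)
  purrr::map_dfr(seq_along(dataset$task_ids), function(t) {
    obs <- dataset$mask[idx, t] == 1
    if (!any(obs)) {
      return(tibble::tibble(task_id = dataset$task_ids[t], n = 0L))
    }
    dplyr::bind_cols(
      tibble::tibble(task_id = dataset$task_ids[t]),
      metrics_report(probs[obs, t], dataset$labels[idx, t][obs]))
  })
}

fmt_pm <- function(m, s) sprintf("%.3f ± %.3f", m, s)

#' Multi-seed training and evaluation protocol
#'
#' Trains one model per seed and reports per-metric mean and standard
#' deviation over seeds (formatted `"m ± s"` to three decimals), per
#' task and for the task average, on validation and test splits.
#'
#' @inheritParams train_model
#' @param seeds Seeds to run (default from `tconfig`, 10 runs).
#' @return An object of class `fpgnn_run_result`: `per_seed` (tibble),
#'   `summary` (tibble with `mean`, `sd`, `formatted`), `models` (list).
#' @export
multi_seed_protocol <- function(dataset, mconfig, tconfig = train_config(),
                                seeds = tconfig$seeds, features = NULL) {
  stopifnot(length(seeds) >= 2)
  if (is.null(features)) features <- featurize_dataset(dataset)
  runs <- lapply(seeds, function(s) {
    model <- train_model(dataset, mconfig, tconfig, seed = s,
                         features = features)
    per_split <- dplyr::bind_rows(
      dplyr::mutate(evaluate_model(model, dataset, "valid", features),
                    split = "valid"),
      dplyr::mutate(evaluate_model(model, dataset, "test", features),
                    split = "test"))
    list(model = model, metrics = dplyr::mutate(per_split, seed = s))
  })
  per_seed <- dplyr::bind_rows(lapply(runs, `[[`, "metrics"))
  long <- tidyr::pivot_longer(per_seed,
                              cols = c("acc", "f1", "ba", "se", "sp",
                                       "mcc", "auc"),
                              names_to = "metric", values_to = "value")
  task_avg <- long |>
    dplyr::group_by(.data$seed, .data$split, .data$metric) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(task_id = ".average")
  summary <- dplyr::bind_rows(long[c("seed", "split", "metric", "value",
                                     "task_id")], task_avg) |>
    dplyr::group_by(.data$split, .data$task_id, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(formatted = fmt_pm(.data$mean, .data$sd))
  structure(list(per_seed = per_seed, summary = summary,
                 models = lapply(runs, `[[`, "model"), seeds = seeds),
            class = "fpgnn_run_result")
}

#' @export
print.fpgnn_run_result <- function(x, ...) {
  cat("<fpgnn_run_result> ", length(x$seeds), " seeds\n", sep = "")
  avg <- dplyr::filter(x$summary, .data$task_id == ".average",
                       .data$split == "test")
  for (i in seq_len(nrow(avg))) {
    cat("  test ", avg$metric[i], ": ", avg$formatted[i], "\n", sep = "")
  }
  invisible(x)
}

#' The hyperparameter search grids
#'
#' The six tunable hyperparameters and their candidate values: dropout
#' and dropout_gat 0-0.6 by 0.05, dim 300-600 by 50, gat_scale 0.2-0.8
#' by 0.1, nheads 2-8, nhid 40-80 by 5.
#'
#' @return Named list of numeric vectors.
#' @export
hyperparameter_grids <- function() {
  list(dropout = seq(0, 0.6, by = 0.05),
       dropout_gat = seq(0, 0.6, by = 0.05),
       dim = seq(300, 600, by = 50),
       gat_scale = seq(0.2, 0.8, by = 0.1),
       nheads = 2:8,
       nhid = seq(40, 80, by = 5))
}

tpe_sample_dim <- function(grid, good_vals, rng_n = 1) {
  # categorical density of the good trials with Laplace smoothing,
  # sampled against the uniform prior (TPE-style ratio maximisation)
  counts <- table(factor(good_vals, levels = as.character(grid)))
  prob <- (as.numeric(counts) + 1) / (length(good_vals) + length(grid))
  sample(grid, rng_n, replace = TRUE, prob = prob)
}

#' Sequential model-based hyperparameter search
#'
#' Tree-structured-Parzen-style search over the published grids
#' maximizing validation mean balanced accuracy: an initial random
#' stage, then candidates sampled from the per-dimension density of the
#' top quartile of trials. Every proposed configuration lies on the
#' grids; the argmax over evaluated trials is returned.
#'
#' @inheritParams train_model
#' @param space Named list of candidate values per hyperparameter
#'   (subset of [hyperparameter_grids()]).
#' @param budget Number of configurations to evaluate.
#' @param n_startup Random trials before the density model kicks in.
#' @return List with `best_config` (a [model_config()]), `best_ba` and
#'   `trials` (tibble of all evaluated configurations).
#' @export
hyperparameter_search <- function(dataset, space = hyperparameter_grids(),
                                  budget = 10L, tconfig = train_config(),
                                  seed = 0L, features = NULL,
                                  n_startup = max(3L, budget %/% 3L)) {
  if (budget < 1) stop("budget must be at least 1", call. = FALSE)
  grids <- hyperparameter_grids()
  for (nm in names(space)) {
    on_grid <- vapply(space[[nm]], function(v) {
      any(abs(v - grids[[nm]]) < 1e-9)
    }, logical(1))
    if (!all(on_grid)) {
      stop("values of '", nm, "' outside the search grid", call. = FALSE)
    }
  }
  if (is.null(features)) features <- featurize_dataset(dataset)
  n_tasks <- length(dataset$task_ids)
  trials <- list()
  with_local_seed(seed, {
    for (i in seq_len(budget)) {
      if (i <= n_startup || length(trials) < 2) {
        cand <- lapply(space, sample, size = 1)
      } else {
        done <- dplyr::bind_rows(lapply(trials, `[[`, "row"))
        cut <- stats::quantile(done$val_ba, 0.75, names = FALSE)
        good <- done[done$val_ba >= cut, , drop = FALSE]
        cand <- lapply(names(space), function(nm) {
          tpe_sample_dim(space[[nm]], as.character(good[[nm]]))
        })
        names(cand) <- names(space)
      }
      cfg <- model_config(n_tasks = n_tasks, dropout = cand$dropout,
                          dropout_gat = cand$dropout_gat, dim = cand$dim,
                          gat_scale = cand$gat_scale, nheads = cand$nheads,
                          nhid = cand$nhid,
                          fp_dim = ncol(features$fp),
                          atom_fdim = ncol(features$graphs[[1]]$atom_features))
      model <- train_model(dataset, cfg, tconfig, seed = seed,
                           features = features)
      trials[[i]] <- list(cfg = cfg,
                          row = tibble::tibble(trial = i,
                                               dropout = cand$dropout,
                                               dropout_gat = cand$dropout_gat,
                                               dim = cand$dim,
                                               gat_scale = cand$gat_scale,
                                               nheads = cand$nheads,
                                               nhid = cand$nhid,
                                               val_ba = model$best_val_ba))
    }
  })
  rows <- dplyr::bind_rows(lapply(trials, `[[`, "row"))
  best <- which.max(rows$val_ba)
  list(best_config = trials[[best]]$cfg, best_ba = rows$val_ba[best],
       trials = rows)
}

#' Y-randomization (label scrambling) test
#'
#' Permutes labels within each task among observed cells (mask and
#' per-task class counts unchanged), retrains, and evaluates on the test
#' split. Performance near chance confirms the unscrambled model is not
#' a chance correlation.
#'
#' @inheritParams train_model
#' @param n_repeats Number of scrambled retrainings (default 3).
#' @return Tibble of per-repeat, per-task test metrics.
#' @export
y_scramble <- function(dataset, mconfig, tconfig = train_config(),
                       n_repeats = 3L, seed = 0L, features = NULL) {
  stopifnot(n_repeats >= 1)
  if (is.null(features)) features <- featurize_dataset(dataset)
  purrr::map_dfr(seq_len(n_repeats), function(r) {
    scrambled <- dataset
    with_local_seed(seed * 1000L + r, {
      for (t in seq_along(dataset$task_ids)) {
        obs <- which(dataset$mask[, t] == 1)
        scrambled$labels[obs, t] <- sample(dataset$labels[obs, t])
      }
    })
    model <- train_model(scrambled, mconfig, tconfig, seed = seed + r,
                         features = features)
    dplyr::mutate(evaluate_model(model, scrambled, "test", features),
                  repeat_id = r)
  })
}

#' Reduce a multi-task dataset to one single-task dataset
#'
#' Keeps the compounds observed for the chosen task; used for the
#' multi-task vs single-task comparison.
#'
#' @param dataset An `mt_dataset`.
#' @param task_id The task to extract.
#' @return An `mt_dataset` with one task.
#' @export
single_task_dataset <- function(dataset, task_id) {
  stopifnot(task_id %in% dataset$task_ids)
  keep <- dataset$mask[, task_id] == 1
  labels <- dataset$labels[keep, task_id, drop = FALSE]
  mask <- dataset$mask[keep, task_id, drop = FALSE]
  mt_dataset(dataset$smiles[keep], labels, mask, dataset$split[keep])
}
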