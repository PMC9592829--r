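# Interpretability: map graph-attention coefficients to atoms and bonds,
# rank fingerprint bits by gradient-times-input attribution, and render
# highlighted depictions.

#' Atom and bond relevance map of the graph-attention branch
#'
#' Scores every atom of a molecule by its contribution to the model's
#' task logits through the graph branch, min-max normalized over the
#' molecule to `[0, 1]`; bond scores are the mean of the two endpoint
#' atom scores.
#'
#' Two aggregations are available. The default, `"grad_input"`,
#' backpropagates the mean task logit through the fused trunk and both
#' attention layers down to the atom input features and scores each atom
#' by gradient-times-input; because the gradient path runs through the
#' attention coefficients, highly attended atoms with informative
#' features score high, and the sign of the map is anchored to the
#' prediction (this is the stable choice; see the methods vignette).
#' `"attention"` is the direct aggregation - the mean attention an atom
#' receives over layers, heads and non-self edges - which reflects the
#' raw coefficients but can latch onto the complement of the informative
#' substructure in some trained models. A constant raw map (e.g. a fully
#' symmetric molecule under a symmetric model) normalizes to all ones.
#'
#' @param model An `fpgnn_model`.
#' @param smiles A single SMILES string.
#' @param method `"grad_input"` (default) or `"attention"`.
#' @param task Optional task id to attribute; default averages the
#'   logits of all tasks.
#' @return An object of class `attention_map`: tibbles `atoms`
#'   (`atom`, `score`) and `bonds` (`from`, `to`, `score`), plus the
#'   provenance of the aggregation.
#' @export
atom_bond_attention <- function(model, smiles,
                                method = c("grad_input", "attention"),
                                task = NULL) {
  stopifnot(inherits(model, "fpgnn_model"), length(smiles) == 1)
  method <- match.arg(method)
  feats <- featurize_dataset(smiles)
  batch <- list(graph = batch_graphs(feats$graphs), fp = feats$fp)
  cfg <- model$config
  fwd <- fpgnn_forward(batch, model$params, cfg, keep_cache = TRUE)
  g <- batch$graph
  n <- length(g$mol)
  if (method == "grad_input") {
    dlogits <- matrix(0, 1, cfg$n_tasks)
    if (is.null(task)) {
      dlogits[] <- 1 / cfg$n_tasks
    } else {
      dlogits[1, match(task, model$task_ids)] <- 1
    }
    bk <- fpgnn_backward(dlogits, fwd, batch, model$params, cfg)
    raw <- rowSums(bk$dX0 * fwd$cache$X0d)
    provenance <- "gradient x input of the task logit at the atom features, through both attention layers"
  } else {
    raw <- numeric(n)
    count <- numeric(n)
    for (layer in fwd$attention) {
      for (head in layer) {
        keep <- head$src != head$dst
        src <- head$src[keep]
        acc <- rowsum(matrix(head$alpha[keep], ncol = 1), group = src)
        idx <- as.integer(rownames(acc))
        raw[idx] <- raw[idx] + acc[, 1]
        cnt <- table(src)
        count[as.integer(names(cnt))] <- count[as.integer(names(cnt))] +
          as.integer(cnt)
      }
    }
    raw <- ifelse(count > 0, raw / count, 0)
    provenance <- "mean over 2 layers x nheads of non-self incoming attention, min-max normalized"
  }
  raw <- unname(raw)
  rng <- range(raw)
  score <- if (diff(rng) < 1e-12) rep(1, n) else (raw - rng[1]) / diff(rng)
  graph <- feats$graphs[[1]]
  und <- graph$edges[graph$edges[, 1] < graph$edges[, 2], , drop = FALSE]
  bonds <- tibble::tibble(from = und[, 1], to = und[, 2],
                          score = (score[und[, 1]] + score[und[, 2]]) / 2)
  structure(list(smiles = smiles,
                 atoms = tibble::tibble(atom = seq_len(n), score = score),
                 bonds = bonds, method = method, provenance = provenance),
            class = "attention_map")
}

#' Consensus relevance map over several models
#'
#' Averages the min-max-normalized atom maps of independently trained
#' models (e.g. the models of a [multi_seed_protocol()] run), the same
#' seed-averaging principle the evaluation protocol uses to remove run-
#' to-run variability.
#'
#' @param models List of `fpgnn_model`s.
#' @inheritParams atom_bond_attention
#' @return An `attention_map` whose scores are the across-model mean.
#' @export
consensus_attention_map <- function(models, smiles,
                                    method = c("grad_input", "attention"),
                                    task = NULL) {
  stopifnot(length(models) >= 1)
  method <- match.arg(method)
  maps <- lapply(models, atom_bond_attention, smiles = smiles,
                 method = method, task = task)
  score <- rowMeans(vapply(maps, function(m) m$atoms$score,
                           numeric(nrow(maps[[1]]$atoms))))
  out <- maps[[1]]
  out$atoms$score <- score
  out$bonds$score <- (score[out$bonds$from] + score[out$bonds$to]) / 2
  out$provenance <- paste0("mean over ", length(models), " models of: ",
                           out$provenance)
  out
}

#' @export
print.attention_map <- function(x, ...) {
  cat("<attention_map> ", x$smiles, ": ", nrow(x$atoms), " atoms, top atom ",
      which.max(x$atoms$score), "\n", sep = "")
  invisible(x)
}

#' Fingerprint bit importance
#'
#' Gradient-times-input attribution of each task logit with respect to
#' the fingerprint-branch input, averaged over the active molecules of
#' that task and then over tasks; bits are ranked by absolute mean
#' attribution. A bit that is zero for every molecule has importance 0.
#'
#' @param model An `fpgnn_model`.
#' @param dataset An `mt_dataset` (or character vector of SMILES, in
#'   which case every molecule is used for every task).
#' @param n_top Number of top bits to return (default 20).
#' @param features Optional precomputed features.
#' @return An object of class `bit_importance`: a tibble with `rank`,
#'   `family` (maccs/pubchem/erg), `bit` (index within the family),
#'   `column` (index in the concatenated block) and `score`, sorted
#'   descending.
#' @export
fingerprint_bit_importance <- function(model, dataset, n_top = 20L,
                                       features = NULL) {
  if (is.null(features)) features <- featurize_dataset(dataset)
  fp <- features$fp
  n <- nrow(fp)
  cfg <- model$config
  batch <- list(graph = batch_graphs(features$graphs), fp = fp)
  fwd <- fpgnn_forward(batch, model$params, cfg, training = FALSE,
                       keep_cache = TRUE)
  per_task <- matrix(0, cfg$n_tasks, ncol(fp))
  for (t in seq_len(cfg$n_tasks)) {
    rows <- if (inherits(dataset, "mt_dataset")) {
      which(dataset$mask[, t] == 1 & dataset$labels[, t] == 1)
    } else {
      seq_len(n)
    }
    if (length(rows) == 0) next
    dlogits <- matrix(0, n, cfg$n_tasks)
    dlogits[rows, t] <- 1
    bk <- fpgnn_backward(dlogits, fwd, batch, model$params, cfg)
    per_task[t, ] <- colMeans((bk$dfp * fp)[rows, , drop = FALSE])
  }
  score <- colMeans(per_task)
  family <- attr(fp, "family") %||%
    rep(c("maccs", "pubchem", "erg"), times = FP_LENGTHS[c("maccs",
                                                           "pubchem", "erg")])
  within <- stats::ave(seq_along(family), family, FUN = seq_along)
  ranked <- tibble::tibble(family = family, bit = within,
                           column = seq_along(score),
                           score = abs(score),
                           signed = score) |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::relocate("rank")
  structure(utils::head(ranked, n_top), class = c("bit_importance",
                                                  class(ranked)))
}

#' Render an attention-highlighted depiction
#'
#' Writes a 2D depiction as SVG with atoms and bonds coloured by their
#' attention score (colour intensity monotone in score).
#'
#' @param smiles A single SMILES string.
#' @param map An `attention_map` from [atom_bond_attention()].
#' @param path Output SVG path.
#' @return `path`, invisibly.
#' @export
render_highlights <- function(smiles, map, path) {
  stopifnot(inherits(map, "attention_map"))
  chem_call("depict", smiles = smiles,
            atom_scores = as.list(unname(map$atoms$score)), path = path)
  invisible(path)
}
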