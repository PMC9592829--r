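# The dual-branch multi-task network.
#
# Graph branch: two multi-head graph-attention layers over the heavy-atom
# graph (self-loops added so single-atom molecules are well defined),
# head outputs concatenated after layer 1 and averaged after layer 2,
# molecule embedding by mean pooling. Fingerprint branch: one hidden
# layer over the 1362-bit concatenated fingerprint block. Fusion:
# weighted concatenation (gat_scale vs 1 - gat_scale) into a shared
# 2-layer fully-connected trunk with one sigmoid output per task
# (pure parameter sharing).
#
# Forward and backward passes are hand-written matrix code; gradients are
# verified against finite differences in the test suite.

#' Model configuration
#'
#' The six tunable hyperparameters searched by the training protocol plus
#' structural settings.
#'
#' @param n_tasks Number of prediction tasks (sigmoid outputs).
#' @param dropout Fingerprint-branch dropout rate in `[0, 0.6]`.
#' @param dropout_gat Graph-branch dropout rate in `[0, 0.6]`.
#' @param dim Fingerprint-branch hidden width (search grid 300-600).
#' @param gat_scale Fusion weight of the graph branch in `[0, 1]`; the
#'   search grid is 0.2-0.8, the extremes 0/1 are allowed for branch
#'   ablation.
#' @param nheads Number of attention heads (grid 2-8).
#' @param nhid Attention hidden width per head (grid 40-80).
#' @param trunk_layers Widths of the two shared trunk layers; default
#'   `c(dim, ceiling(dim / 2))`.
#' @param fp_dim Width of the fingerprint input block (1362).
#' @param atom_fdim Atom feature width of the graph schema (28).
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_tasks, dropout = 0, dropout_gat = 0, dim = 300L,
                         gat_scale = 0.5, nheads = 2L, nhid = 40L,
                         trunk_layers = NULL, fp_dim = 1362L,
                         atom_fdim = 28L) {
  stopifnot(n_tasks >= 1, dropout >= 0, dropout <= 0.6,
            dropout_gat >= 0, dropout_gat <= 0.6, dim >= 1,
            gat_scale >= 0, gat_scale <= 1, nheads >= 1, nhid >= 1)
  if (is.null(trunk_layers)) trunk_layers <- c(dim, ceiling(dim / 2))
  stopifnot(length(trunk_layers) == 2, all(trunk_layers >= 1))
  structure(list(n_tasks = as.integer(n_tasks), dropout = dropout,
                 dropout_gat = dropout_gat, dim = as.integer(dim),
                 gat_scale = gat_scale, nheads = as.integer(nheads),
                 nhid = as.integer(nhid),
                 trunk_layers = as.integer(trunk_layers),
                 fp_dim = as.integer(fp_dim),
                 atom_fdim = as.integer(atom_fdim)),
            class = "model_config")
}

xavier <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

#' Initialize model parameters
#'
#' Xavier-uniform weights, zero biases; reproducible given the seed.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return Named list of parameter matrices/vectors of class
#'   `fpgnn_params`.
#' @export
init_model <- function(config, seed = 0L) {
  stopifnot(inherits(config, "model_config"))
  with_local_seed(seed, {
    p <- list()
    for (h in seq_len(config$nheads)) {
      p[[paste0("gat1_W_", h)]] <- xavier(config$atom_fdim, config$nhid)
      p[[paste0("gat1_as_", h)]] <- stats::runif(config$nhid, -0.1, 0.1)
      p[[paste0("gat1_ad_", h)]] <- stats::runif(config$nhid, -0.1, 0.1)
      p[[paste0("gat2_W_", h)]] <- xavier(config$nheads * config$nhid,
                                          config$nhid)
      p[[paste0("gat2_as_", h)]] <- stats::runif(config$nhid, -0.1, 0.1)
      p[[paste0("gat2_ad_", h)]] <- stats::runif(config$nhid, -0.1, 0.1)
    }
    p$fpn_W <- xavier(config$fp_dim, config$dim)
    p$fpn_b <- numeric(config$dim)
    fuse_in <- config$nhid + config$dim
    p$trunk_W1 <- xavier(fuse_in, config$trunk_layers[1])
    p$trunk_b1 <- numeric(config$trunk_layers[1])
    p$trunk_W2 <- xavier(config$trunk_layers[1], config$trunk_layers[2])
    p$trunk_b2 <- numeric(config$trunk_layers[2])
    p$head_W <- xavier(config$trunk_layers[2], config$n_tasks)
    p$head_b <- numeric(config$n_tasks)
    structure(p, class = "fpgnn_params")
  })
}

# ---- graph batching -------------------------------------------------------

#' Combine molecular graphs into one disjoint-union batch graph
#'
#' @param graphs List of `mol_graph` objects.
#' @return List with node matrix `X`, directed edge endpoints `src`/`dst`
#'   (self-loops appended), `mol` (molecule index per node) and `n_atoms`.
#' @export
batch_graphs <- function(graphs) {
  n_atoms <- vapply(graphs, function(g) g$n_atoms, integer(1))
  stopifnot(all(n_atoms >= 1))
  offset <- c(0L, cumsum(n_atoms))
  X <- do.call(rbind, lapply(graphs, function(g) g$atom_features))
  src <- dst <- integer(0)
  for (i in seq_along(graphs)) {
    e <- graphs[[i]]$edges
    if (nrow(e) > 0) {
      src <- c(src, e[, 1] + offset[i])
      dst <- c(dst, e[, 2] + offset[i])
    }
  }
  n <- sum(n_atoms)
  list(X = X, src = c(src, seq_len(n)), dst = c(dst, seq_len(n)),
       n_bond_edges = length(src),
       mol = rep(seq_along(graphs), times = n_atoms), n_atoms = n_atoms)
}

# ---- activations ----------------------------------------------------------

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(y) ifelse(y > 0, 1, y + 1)  # from the output
relu <- function(x) pmax(x, 0)
lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
sigmoid <- function(x) 1 / (1 + exp(-x))

dropout_mask <- function(dim1, dim2, rate) {
  matrix(stats::rbinom(dim1 * dim2, 1, 1 - rate) / (1 - rate), dim1, dim2)
}

# ---- graph attention layer ------------------------------------------------

gat_head_forward <- function(X, src, dst, W, as_, ad_) {
  Wh <- X %*% W
  u <- lrelu(Wh[src, , drop = FALSE] %*% as_ +
               Wh[dst, , drop = FALSE] %*% ad_)[, 1]
  mx <- stats::ave(u, dst, FUN = max)
  ex <- exp(u - mx)
  denom <- stats::ave(ex, dst, FUN = sum)
  alpha <- ex / denom
  out <- rowsum(Wh[src, , drop = FALSE] * alpha, group = dst)
  list(out = out, Wh = Wh, u = u, alpha = alpha)
}

gat_head_backward <- function(dOut, cache, X, src, dst, W, as_, ad_) {
  Wh <- cache$Wh; alpha <- cache$alpha; u <- cache$u
  dOut_dst <- dOut[dst, , drop = FALSE]
  # dalpha is also the per-edge relevance used by the interpretability
  # module: how much this attention coefficient moves the objective
  dalpha <- rowSums(dOut_dst * Wh[src, , drop = FALSE])
  dWh <- rowsum(dOut_dst * alpha, group = src)
  # rowsum orders groups 1..n; with self-loops every node appears
  s <- stats::ave(alpha * dalpha, dst, FUN = sum)
  de <- alpha * (dalpha - s)
  du <- de * ifelse(u > 0, 1, 0.2)
  dp <- rowsum(matrix(du, ncol = 1), group = src)[, 1]
  dq <- rowsum(matrix(du, ncol = 1), group = dst)[, 1]
  dWh <- dWh + outer(dp, as_) + outer(dq, ad_)
  list(dX = dWh %*% t(W),
       dW = t(X) %*% dWh,
       das = t(Wh) %*% dp,
       dad = t(Wh) %*% dq,
       edge_relevance = alpha * dalpha)
}

# ---- full forward ---------------------------------------------------------

#' Forward pass over a featurized batch
#'
#' Low-level entry point; most users call [predict.fpgnn_model()] or
#' [forward_smiles()]. In training mode dropout masks are sampled from
#' the current RNG stream; evaluation mode is deterministic.
#'
#' @param batch List with `graph` (from [batch_graphs()]) and `fp`
#'   (fingerprint matrix, one row per molecule).
#' @param params `fpgnn_params`.
#' @param config `model_config`.
#' @param training Sample dropout masks?
#' @param keep_cache Keep intermediates for [fpgnn_backward()]?
#' @return List with `probs` (M x T), `logits`, `attention` (per layer /
#'   head edge coefficients) and optionally `cache`.
#' @export
fpgnn_forward <- function(batch, params, config, training = FALSE,
                          keep_cache = FALSE) {
  g <- batch$graph
  stopifnot(nrow(batch$fp) == length(g$n_atoms),
            ncol(batch$fp) == config$fp_dim)
  H <- config$nheads
  cache <- list()

  X0 <- g$X
  m1 <- if (training && config$dropout_gat > 0) {
    dropout_mask(nrow(X0), ncol(X0), config$dropout_gat)
  }
  X0d <- if (is.null(m1)) X0 else X0 * m1
  heads1 <- lapply(seq_len(H), function(h) {
    gat_head_forward(X0d, g$src, g$dst, params[[paste0("gat1_W_", h)]],
                     params[[paste0("gat1_as_", h)]],
                     params[[paste0("gat1_ad_", h)]])
  })
  Z1 <- do.call(cbind, lapply(heads1, `[[`, "out"))
  A1 <- elu(Z1)

  m2 <- if (training && config$dropout_gat > 0) {
    dropout_mask(nrow(A1), ncol(A1), config$dropout_gat)
  }
  A1d <- if (is.null(m2)) A1 else A1 * m2
  heads2 <- lapply(seq_len(H), function(h) {
    gat_head_forward(A1d, g$src, g$dst, params[[paste0("gat2_W_", h)]],
                     params[[paste0("gat2_as_", h)]],
                     params[[paste0("gat2_ad_", h)]])
  })
  Z2 <- Reduce(`+`, lapply(heads2, `[[`, "out")) / H
  A2 <- elu(Z2)
  G <- rowsum(A2, group = g$mol) / g$n_atoms  # mean pool per molecule

  FPin <- batch$fp
  mf0 <- if (training && config$dropout > 0) {
    dropout_mask(nrow(FPin), ncol(FPin), config$dropout)
  }
  FPd <- if (is.null(mf0)) FPin else FPin * mf0
  Fpre <- sweep(FPd %*% params$fpn_W, 2, params$fpn_b, `+`)
  Fact <- relu(Fpre)
  mf1 <- if (training && config$dropout > 0) {
    dropout_mask(nrow(Fact), ncol(Fact), config$dropout)
  }
  Fout <- if (is.null(mf1)) Fact else Fact * mf1

  Z <- cbind(config$gat_scale * G, (1 - config$gat_scale) * Fout)
  T1pre <- sweep(Z %*% params$trunk_W1, 2, params$trunk_b1, `+`)
  T1 <- relu(T1pre)
  T2pre <- sweep(T1 %*% params$trunk_W2, 2, params$trunk_b2, `+`)
  T2 <- relu(T2pre)
  logits <- sweep(T2 %*% params$head_W, 2, params$head_b, `+`)
  probs <- sigmoid(logits)

  attention <- list(
    layer1 = lapply(heads1, function(hh) {
      list(src = g$src, dst = g$dst, alpha = hh$alpha)
    }),
    layer2 = lapply(heads2, function(hh) {
      list(src = g$src, dst = g$dst, alpha = hh$alpha)
    })
  )
  out <- list(probs = probs, logits = logits, attention = attention)
  if (keep_cache) {
    out$cache <- list(X0d = X0d, m1 = m1, heads1 = heads1, A1 = A1,
                      A1d = A1d, m2 = m2, heads2 = heads2, A2 = A2, G = G,
                      FPd = FPd, mf0 = mf0, Fpre = Fpre, Fact = Fact,
                      mf1 = mf1, Fout = Fout, Z = Z, T1pre = T1pre, T1 = T1,
                      T2pre = T2pre, T2 = T2)
  }
  out
}

#' Backward pass: gradients of a scalar loss w.r.t. all parameters
#'
#' @param dlogits Gradient of the loss at the logits (M x T).
#' @param fwd Result of [fpgnn_forward()] with `keep_cache = TRUE`.
#' @inheritParams fpgnn_forward
#' @return List with `grads` (named like `params`) and `dfp` (gradient at
#'   the fingerprint input, used for bit attribution).
#' @export
fpgnn_backward <- function(dlogits, fwd, batch, params, config) {
  cc <- fwd$cache
  g <- batch$graph
  H <- config$nheads
  grads <- list()

  grads$head_W <- t(cc$T2) %*% dlogits
  grads$head_b <- colSums(dlogits)
  dT2 <- (dlogits %*% t(params$head_W)) * (cc$T2pre > 0)
  grads$trunk_W2 <- t(cc$T1) %*% dT2
  grads$trunk_b2 <- colSums(dT2)
  dT1 <- (dT2 %*% t(params$trunk_W2)) * (cc$T1pre > 0)
  grads$trunk_W1 <- t(cc$Z) %*% dT1
  grads$trunk_b1 <- colSums(dT1)
  dZ <- dT1 %*% t(params$trunk_W1)

  nh <- config$nhid
  dG <- config$gat_scale * dZ[, seq_len(nh), drop = FALSE]
  dFout <- (1 - config$gat_scale) * dZ[, -seq_len(nh), drop = FALSE]

  dFact <- if (is.null(cc$mf1)) dFout else dFout * cc$mf1
  dFpre <- dFact * (cc$Fpre > 0)
  grads$fpn_W <- t(cc$FPd) %*% dFpre
  grads$fpn_b <- colSums(dFpre)
  dFPd <- dFpre %*% t(params$fpn_W)
  dfp <- if (is.null(cc$mf0)) dFPd else dFPd * cc$mf0

  # mean pool backward: spread molecule gradient over its atoms
  dA2 <- (dG / g$n_atoms)[g$mol, , drop = FALSE]
  dZ2 <- dA2 * elu_grad(cc$A2)
  dA1d <- matrix(0, nrow(cc$A1d), ncol(cc$A1d))
  edge_rel <- list(layer1 = vector("list", H), layer2 = vector("list", H))
  for (h in seq_len(H)) {
    bk <- gat_head_backward(dZ2 / H, cc$heads2[[h]], cc$A1d, g$src, g$dst,
                            params[[paste0("gat2_W_", h)]],
                            params[[paste0("gat2_as_", h)]],
                            params[[paste0("gat2_ad_", h)]])
    grads[[paste0("gat2_W_", h)]] <- bk$dW
    grads[[paste0("gat2_as_", h)]] <- bk$das[, 1]
    grads[[paste0("gat2_ad_", h)]] <- bk$dad[, 1]
    edge_rel$layer2[[h]] <- bk$edge_relevance
    dA1d <- dA1d + bk$dX
  }
  dA1 <- if (is.null(cc$m2)) dA1d else dA1d * cc$m2
  dZ1 <- dA1 * elu_grad(cc$A1)
  dX0 <- matrix(0, nrow(cc$X0d), ncol(cc$X0d))
  for (h in seq_len(H)) {
    cols <- ((h - 1) * nh + 1):(h * nh)
    bk <- gat_head_backward(dZ1[, cols, drop = FALSE], cc$heads1[[h]],
                            cc$X0d, g$src, g$dst,
                            params[[paste0("gat1_W_", h)]],
                            params[[paste0("gat1_as_", h)]],
                            params[[paste0("gat1_ad_", h)]])
    grads[[paste0("gat1_W_", h)]] <- bk$dW
    grads[[paste0("gat1_as_", h)]] <- bk$das[, 1]
    grads[[paste0("gat1_ad_", h)]] <- bk$dad[, 1]
    edge_rel$layer1[[h]] <- bk$edge_relevance
    dX0 <- dX0 + bk$dX
  }
  list(grads = grads, dfp = dfp, edge_relevance = edge_rel, dX0 = dX0)
}

#' Predict per-task probabilities for SMILES with explicit parameters
#'
#' Composes featurization, both branch encoders and the fused trunk.
#' Output is invariant to SMILES respelling of the same molecule because
#' featurization canonicalizes internally.
#'
#' @param smiles Character vector of SMILES.
#' @param params `fpgnn_params`.
#' @param config `model_config`.
#' @param task_ids Optional column names for the output.
#' @return List with `probs` tibble (`smiles` + one column per task) and
#'   `attention`.
#' @export
forward_smiles <- function(smiles, params, config, task_ids = NULL) {
  feats <- featurize_dataset(smiles)
  batch <- list(graph = batch_graphs(feats$graphs), fp = feats$fp)
  fwd <- fpgnn_forward(batch, params, config, training = FALSE)
  probs <- tibble::as_tibble(as.data.frame(fwd$probs))
  names(probs) <- task_ids %||% paste0("task_", seq_len(config$n_tasks))
  list(probs = dplyr::bind_cols(tibble::tibble(smiles = smiles), probs),
       attention = fwd$attention, batch = batch)
}

# ---- checkpointing --------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Single JSON archive holding the config, parameters and task ids, with
#' a schema version field.
#'
#' @param model An `fpgnn_model` (from [train_model()]).
#' @param path Checkpoint path (`.json`).
#' @return `path` invisibly; `load_checkpoint()` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "fpgnn_model"))
  payload <- list(schema = 1L,
                  config = unclass(model$config),
                  task_ids = model$task_ids,
                  params = lapply(model$params, function(p) {
                    if (is.matrix(p)) {
                      list(dim = dim(p), data = as.numeric(p))
                    } else {
                      list(dim = NULL, data = as.numeric(p))
                    }
                  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, payload$config[c(
    "n_tasks", "dropout", "dropout_gat", "dim", "gat_scale", "nheads",
    "nhid", "trunk_layers", "fp_dim", "atom_fdim")])
  params <- lapply(payload$params, function(p) {
    if (!is.null(p$dim)) matrix(p$data, p$dim[1], p$dim[2]) else p$data
  })
  class(params) <- "fpgnn_params"
  structure(list(params = params, config = cfg,
                 task_ids = payload$task_ids, history = NULL),
            class = "fpgnn_model")
}
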