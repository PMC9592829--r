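tiny_config <- function(n_tasks = 4, ...) {
  model_config(n_tasks = n_tasks, dim = 16, nhid = 6, nheads = 2,
               trunk_layers = c(12, 6), ...)
}

tiny_batch <- function(smiles) {
  feats <- featurize_dataset(smiles)
  list(graph = batch_graphs(feats$graphs), fp = feats$fp)
}

test_that("initialization is reproducible and shapes follow the config", {
  cfg <- tiny_config()
  p1 <- init_model(cfg, seed = 5)
  p2 <- init_model(cfg, seed = 5)
  expect_identical(p1, p2)
  expect_false(identical(p1, init_model(cfg, seed = 6)))
  expect_equal(ncol(p1$head_W), 4L)
  expect_equal(dim(p1$fpn_W), c(cfg$fp_dim, cfg$dim))
  # one task degenerates to the single-task architecture
  p_single <- init_model(tiny_config(n_tasks = 1), seed = 0)
  expect_equal(ncol(p_single$head_W), 1L)
})

test_that("forward pass yields probabilities with normalized attention", {
  cfg <- tiny_config()
  params <- init_model(cfg, seed = 1)
  lib <- fixture_library(100, seed = 31)
  batch <- tiny_batch(lib)
  fwd <- fpgnn_forward(batch, params, cfg)
  expect_equal(dim(fwd$probs), c(100L, 4L))
  expect_true(all(fwd$probs > 0 & fwd$probs < 1))
  # attention over each atom's neighbourhood sums to 1, every layer/head
  for (layer in fwd$attention) {
    for (head in layer) {
      sums <- tapply(head$alpha, head$dst, sum)
      expect_true(all(abs(sums - 1) < 1e-9))
    }
  }
  # evaluation mode is deterministic
  expect_identical(fwd$probs, fpgnn_forward(batch, params, cfg)$probs)
})

test_that("single-atom molecules are handled via self-loops", {
  cfg <- tiny_config()
  params <- init_model(cfg, seed = 2)
  fwd <- fpgnn_forward(tiny_batch("C"), params, cfg)
  expect_equal(dim(fwd$probs), c(1L, 4L))
  expect_true(all(is.finite(fwd$probs)))
  # with only the self-loop, its attention coefficient is exactly 1
  expect_equal(fwd$attention$layer1[[1]]$alpha, 1)
})

test_that("branch ablation at the fusion extremes is exact", {
  lib <- fixture_library(10, seed = 41)[1:5]
  feats <- featurize_dataset(lib)
  graph <- batch_graphs(feats$graphs)

  cfg1 <- tiny_config(gat_scale = 1)
  p1 <- init_model(cfg1, seed = 3)
  base <- fpgnn_forward(list(graph = graph, fp = feats$fp), p1, cfg1)$probs
  fp_perturbed <- feats$fp
  fp_perturbed[] <- 1L - fp_perturbed
  pert <- fpgnn_forward(list(graph = graph, fp = fp_perturbed), p1, cfg1)$probs
  expect_identical(base, pert)  # fingerprint branch fully silenced

  cfg0 <- tiny_config(gat_scale = 0)
  p0 <- init_model(cfg0, seed = 3)
  other_graph <- batch_graphs(featurize_dataset(fixture_library(10, 43)[6:10])$graphs)
  b0 <- fpgnn_forward(list(graph = graph, fp = feats$fp), p0, cfg0)$probs
  b1 <- fpgnn_forward(list(graph = other_graph, fp = feats$fp), p0, cfg0)$probs
  expect_identical(b0, b1)      # graph branch fully silenced
})

test_that("output is invariant to SMILES respelling of the same molecule", {
  cfg <- tiny_config()
  params <- init_model(cfg, seed = 4)
  out1 <- forward_smiles("c1ccccc1CCO", params, cfg)$probs
  out2 <- forward_smiles("OCCc1ccccc1", params, cfg)$probs
  expect_equal(out1[, -1], out2[, -1], tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  spec <- synthetic_spec(n_compounds = 12, seed = 51)
  lib <- generate_library(spec)
  ds <- assign_labels(lib, spec)
  feats <- featurize_dataset(ds)
  cfg <- model_config(n_tasks = 4, dim = 6, nhid = 4, nheads = 2,
                      trunk_layers = c(6, 4), fp_dim = ncol(feats$fp))
  params <- init_model(cfg, seed = 1)
  batch <- list(graph = batch_graphs(feats$graphs[1:6]),
                fp = feats$fp[1:6, , drop = FALSE])
  lab <- ds$labels[1:6, ]
  msk <- ds$mask[1:6, ]
  loss_fn <- function(p) {
    masked_loss(fpgnn_forward(batch, p, cfg)$probs, lab, msk)
  }
  fwd <- fpgnn_forward(batch, params, cfg, keep_cache = TRUE)
  dlog <- (fwd$probs - lab) * msk / sum(msk)
  bk <- fpgnn_backward(dlog, fwd, batch, params, cfg)
  set.seed(8)
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (i in idx) {
      eps <- 1e-5
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
      expect_equal(bk$grads[[nm]][i], num, tolerance = 1e-3)
    }
  }
  expect_true(all(vapply(bk$grads, function(g) all(is.finite(g)),
                         logical(1))))
})

test_that("checkpoints round-trip through JSON", {
  model <- fixture_tiny_model()
  tmp <- tempfile(fileext = ".json")
  save_checkpoint(model, tmp)
  back <- load_checkpoint(tmp)
  expect_equal(back$task_ids, model$task_ids)
  lib <- fixture_library(10, seed = 61)[1:5]
  expect_equal(predict(model, lib), predict(back, lib), tolerance = 1e-12)
})
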