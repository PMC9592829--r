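# Shared fixtures, computed lazily and memoized for the whole test run.
# Everything is generated in code from the synthetic grammar; nothing is
# read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# a small library of valid, standardized molecules
fixture_library <- function(n = 60, seed = 11) {
  memo(paste0("lib_", n, "_", seed),
       generate_library(synthetic_spec(n_compounds = n, seed = seed)))
}

# tiny multi-task dataset for fast structural tests
fixture_tiny_dataset <- function() {
  memo("tiny_ds", {
    spec <- synthetic_spec(n_compounds = 60, seed = 7)
    assign_labels(generate_library(spec), spec)
  })
}

# the full planted-SAR benchmark used by the acceptance suite
fixture_benchmark <- function() {
  memo("bench", make_benchmark("small-correlated", seed = 0))
}

fixture_benchmark_features <- function() {
  memo("bench_feats", featurize_dataset(fixture_benchmark()$dataset))
}

fixture_model_config <- function() {
  feats <- fixture_benchmark_features()
  model_config(n_tasks = 4, dim = 300, nhid = 40, nheads = 2,
               gat_scale = 0.5, fp_dim = ncol(feats$fp))
}

# the 5-seed protocol run on the benchmark (shared by several
# acceptance checks: held-out BA, multi-vs-single-task, interpretability)
fixture_protocol <- function() {
  memo("protocol", {
    multi_seed_protocol(fixture_benchmark()$dataset, fixture_model_config(),
                        train_config(epochs = 40, patience = 10),
                        seeds = 0:4,
                        features = fixture_benchmark_features())
  })
}

# one quick model on the tiny dataset for structural tests
fixture_tiny_model <- function() {
  memo("tiny_model", {
    ds <- fixture_tiny_dataset()
    feats <- featurize_dataset(ds)
    cfg <- model_config(n_tasks = 4, dim = 32, nhid = 8, nheads = 2,
                        fp_dim = ncol(feats$fp), trunk_layers = c(16, 8))
    train_model(ds, cfg, train_config(epochs = 3, patience = 3),
                seed = 0, features = feats)
  })
}

reference_csv <- function(name) {
  path <- system.file("extdata", name, package = "fpgnn")
  if (!nzchar(path)) path <- file.path("..", "..", "inst", "extdata", name)
  readr::read_csv(path, show_col_types = FALSE)
}

# brute-force oracles, deliberately independent of the implementation ---

oracle_confusion <- function(probs, labels, threshold = 0.5) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(probs)) {
    pred <- if (probs[i] >= threshold) 1 else 0
    if (pred == 1 && labels[i] == 1) tp <- tp + 1
    if (pred == 0 && labels[i] == 0) tn <- tn + 1
    if (pred == 1 && labels[i] == 0) fp <- fp + 1
    if (pred == 0 && labels[i] == 1) fn <- fn + 1
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

oracle_metrics <- function(cc) {
  sp <- if (cc["tn"] + cc["fp"] > 0) cc["tn"] / (cc["tn"] + cc["fp"]) else 0
  se <- if (cc["tp"] + cc["fn"] > 0) cc["tp"] / (cc["tp"] + cc["fn"]) else 0
  den <- sqrt(cc["tp"] + cc["fn"]) * sqrt(cc["tp"] + cc["fp"]) *
    sqrt(cc["tn"] + cc["fn"]) * sqrt(cc["tn"] + cc["fp"])
  c(acc = unname((cc["tp"] + cc["tn"]) / sum(cc)),
    f1 = unname(if (2 * cc["tp"] + cc["fn"] + cc["fp"] > 0) {
      2 * cc["tp"] / (2 * cc["tp"] + cc["fn"] + cc["fp"])
    } else 0),
    ba = unname((se + sp) / 2), se = unname(se), sp = unname(sp),
    mcc = unname(if (den > 0) {
      (cc["tp"] * cc["tn"] - cc["fn"] * cc["fp"]) / den
    } else 0))
}

# pairwise-comparison AUC: P(score_pos > score_neg) + 0.5 P(tie)
oracle_auc <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# exhaustive all-pairs k-NN applicability-domain oracle
oracle_ad <- function(fps, k, Z) {
  n <- nrow(fps)
  per <- numeric(n)
  for (i in seq_len(n)) {
    d <- numeric(0)
    for (j in seq_len(n)) {
      if (i != j) d <- c(d, sqrt(sum((fps[i, ] - fps[j, ])^2)))
    }
    per[i] <- mean(sort(d)[seq_len(k)])
  }
  list(d_ave = mean(per), theta = stats::sd(per),
       D_T = mean(per) + Z * stats::sd(per))
}
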