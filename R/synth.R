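# Synthetic structure-activity generator.
#
# Molecules are assembled from a scaffold + substituent grammar (ring
# cores decorated with amide, nitrile, halogen, alkyl and ether groups)
# rather than by random SMILES mutation, so planted substructure rules
# are guaranteed realizable and the ground-truth atoms of each
# pharmacophore are known. Emitted SMILES are already standardized, so
# they round-trip through standardize_molecule() unchanged.
#
# The default specification emulates the statistical structure of the
# PARP benchmark corpus: four correlated binary tasks over one shared
# library (two tasks share the amide rule), sparse observation (label
# density 5770 / (4539 * 4) ~ 0.318) and active fractions inside the
# published 65.78-85.79% range.

# four substitution slots per core so the grammar's support is much
# larger than any library drawn from it (canonical-SMILES deduplication
# would otherwise bias the realized substructure rates downwards)
CORE_TEMPLATES <- c(
  "c1c(%s)c(%s)cc(%s)c1%s",                 # benzene
  "c1nc(%s)c(%s)c(%s)c1%s",                 # pyridine
  "C1C(%s)C(%s)CC(%s)C1%s",                 # cyclohexane
  "c1(%s)sc(%s)c(%s)c1%s",                  # thiophene
  "c1cc(%s)ccc1-c1cc(%s)cc(%s)c1%s"         # biphenyl
)

FILLER_BRANCHES <- c("C", "CC", "CCC", "CCCC", "C(C)C", "C(C)(C)C", "OC",
                     "OCC", "OCCC", "O", "CO", "CCO", "OC(C)C", "CC(C)O")

PHARMACOPHORE_BRANCHES <- list(
  "[CX3](=O)[NX3]" = c("C(=O)N", "C(=O)NC"),
  "C#N" = "C#N",
  "[Cl,Br]" = c("Cl", "Br")
)

#' A planted structure-activity rule
#'
#' @param task_id Task identifier.
#' @param smarts SMARTS pattern of the required substructure.
#' @param p_match Activity probability when the substructure is present.
#' @param p_nomatch Activity probability when it is absent (must be
#'   lower than `p_match` so the signal is planted).
#' @return A list of class `sar_rule`.
#' @export
sar_rule <- function(task_id, smarts, p_match = 0.98, p_nomatch = 0.10) {
  stopifnot(p_match >= 0, p_match <= 1, p_nomatch >= 0, p_nomatch <= 1,
            p_match > p_nomatch)
  structure(list(task_id = task_id, smarts = smarts, p_match = p_match,
                 p_nomatch = p_nomatch), class = "sar_rule")
}

default_sar_rules <- function() {
  list(sar_rule("task_a", "[CX3](=O)[NX3]"),
       sar_rule("task_b", "[CX3](=O)[NX3]"),
       sar_rule("task_c", "C#N"),
       sar_rule("task_d", "[Cl,Br]"))
}

#' Synthetic dataset specification
#'
#' @param n_compounds Library size (at least 10).
#' @param tasks List of [sar_rule()]s; the default four tasks share one
#'   pharmacophore between two of them (shared-core fraction 0.5).
#' @param substructure_rates Named inclusion probability per distinct
#'   SMARTS; the defaults put every rule-implied active fraction near
#'   80%, inside the 65.78-85.79% imbalance range of the benchmark
#'   corpus.
#' @param label_density Fraction of compound-task cells observed
#'   (default 5770/18156).
#' @param seed Generator seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 500L, tasks = default_sar_rules(),
                           substructure_rates = c(
                             "[CX3](=O)[NX3]" = 0.80,
                             "C#N" = 0.78,
                             "[Cl,Br]" = 0.80),
                           label_density = 5770 / 18156, seed = 0L) {
  stopifnot(n_compounds >= 10, length(tasks) >= 1,
            label_density > 0, label_density <= 1)
  structure(list(n_compounds = as.integer(n_compounds), tasks = tasks,
                 substructure_rates = substructure_rates,
                 label_density = label_density, seed = as.integer(seed)),
            class = "synthetic_spec")
}

assemble_molecule <- function(include, rates) {
  template <- sample(CORE_TEMPLATES, 1)
  smarts_ids <- names(rates)
  slots <- character(4)
  for (s in 1:3) {
    branches <- if (s <= length(smarts_ids) && include[s]) {
      PHARMACOPHORE_BRANCHES[[smarts_ids[s]]]
    }
    slots[s] <- if (is.null(branches)) {
      sample(FILLER_BRANCHES, 1)
    } else {
      sample(branches, 1)
    }
  }
  slots[4] <- sample(FILLER_BRANCHES, 1)  # diversity slot
  sprintf(template, slots[1], slots[2], slots[3], slots[4])
}

#' Generate the synthetic compound library
#'
#' Deterministic given the spec seed; every emitted SMILES is unique,
#' parses, and is already in standardized canonical form.
#'
#' @param spec A [synthetic_spec()].
#' @return Character vector of `n_compounds` canonical SMILES.
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rates <- spec$substructure_rates
  with_local_seed(spec$seed, {
    seen <- character(0)
    guard <- 0L
    while (length(seen) < spec$n_compounds && guard < 200L) {
      guard <- guard + 1L
      want <- spec$n_compounds - length(seen)
      raw <- vapply(seq_len(max(want * 2L, 20L)), function(i) {
        include <- stats::runif(length(rates)) < rates
        assemble_molecule(include, rates)
      }, character(1))
      std <- suppressWarnings(standardize_molecule(raw))
      std <- std[!is.na(std)]
      seen <- unique(c(seen, std))
    }
    if (length(seen) < spec$n_compounds) {
      stop("could not generate enough unique molecules", call. = FALSE)
    }
    seen[seq_len(spec$n_compounds)]
  })
}

#' Assign task labels, observation mask and split
#'
#' Per task, the label is Bernoulli with the rule's match-dependent
#' probability; the mask is Bernoulli(`label_density`) with at least one
#' observed task per compound. Per-task class counts concentrate around
#' the rule-implied expectation. Splits are compound-level 80/10/10.
#'
#' @param library Character vector of canonical SMILES.
#' @param spec A [synthetic_spec()].
#' @return An `mt_dataset`.
#' @export
assign_labels <- function(library, spec) {
  stopifnot(length(library) > 0)
  smarts <- unique(vapply(spec$tasks, `[[`, character(1), "smarts"))
  hits <- match_smarts(library, smarts)
  n <- length(library)
  task_ids <- vapply(spec$tasks, `[[`, character(1), "task_id")
  labels <- mask <- matrix(0L, n, length(spec$tasks),
                           dimnames = list(library, task_ids))
  with_local_seed(spec$seed + 1L, {
    for (t in seq_along(spec$tasks)) {
      rule <- spec$tasks[[t]]
      p <- ifelse(hits[, rule$smarts], rule$p_match, rule$p_nomatch)
      labels[, t] <- stats::rbinom(n, 1, p)
      mask[, t] <- stats::rbinom(n, 1, spec$label_density)
    }
    empty <- which(rowSums(mask) == 0)
    if (length(empty) > 0) {
      mask[cbind(empty, sample(ncol(mask), length(empty), replace = TRUE))] <- 1L
    }
  })
  split <- split_dataset(library,
                         curation_config(seed = spec$seed, min_task_size = 0L))
  mt_dataset(library, labels, mask, split)
}

# molecules from a deliberately disjoint grammar (acyclic polyol /
# alkane chains: no rings, no nitrogen, no halogens) used to plant
# out-of-domain test compounds
remote_library <- function(n, seed = 0L) {
  with_local_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      len <- sample(8:14, 1)
      chain <- strsplit(paste(rep("C", len), collapse = ""), "")[[1]]
      n_oh <- sample(2:4, 1)
      pos <- sample(seq_len(len), n_oh)
      chain[pos] <- "C(O)"
      smi <- paste(chain, collapse = "")
      std <- suppressWarnings(standardize_molecule(smi))
      out <- unique(c(out, std[!is.na(std)]))
    }
    out[seq_len(n)]
  })
}

#' Packaged synthetic benchmarks
#'
#' Three pinned benchmark datasets used throughout the test suite:
#' \describe{
#'   \item{`small-correlated`}{Four correlated tasks, 500 compounds,
#'     benchmark-like imbalance and label sparsity.}
#'   \item{`planted-bit`}{A single task whose labels are a deterministic
#'     function of one MACCS bit (a bit with moderate frequency and no
#'     duplicated column is chosen so the signal is identifiable).}
#'   \item{`remote-test-AD`}{The correlated benchmark plus 10 test-set
#'     molecules from a disjoint acyclic grammar, structurally remote
#'     from every training compound.}
#' }
#'
#' @param name One of the benchmark names above.
#' @param n_compounds Library size (default 500; `planted-bit` uses
#'   `min(n_compounds, 400)`).
#' @param seed Pinned seed (default 0).
#' @param dir Optional directory: if given, the curated CSV and a JSON
#'   manifest are written there.
#' @return List with `dataset` (an `mt_dataset`), `spec`/`meta`, and
#'   file paths when `dir` is given.
#' @export
make_benchmark <- function(name, n_compounds = 500L, seed = 0L,
                           dir = NULL) {
  if (name == "small-correlated") {
    spec <- synthetic_spec(n_compounds = n_compounds, seed = seed)
    lib <- generate_library(spec)
    ds <- assign_labels(lib, spec)
    meta <- list(name = name, seed = seed)
  } else if (name == "planted-bit") {
    spec <- synthetic_spec(n_compounds = min(n_compounds, 400L), seed = seed)
    lib <- generate_library(spec)
    maccs <- compute_maccs(lib)
    freq <- colMeans(maccs)
    ok <- which(freq >= 0.25 & freq <= 0.75)
    dup <- duplicated(t(maccs)) | duplicated(t(maccs), fromLast = TRUE)
    ok <- setdiff(ok, which(dup))
    if (length(ok) == 0) stop("no identifiable MACCS bit", call. = FALSE)
    # the identifiable bit with frequency closest to 1/2
    bit <- ok[which.min(abs(freq[ok] - 0.5))]
    labels <- matrix(maccs[, bit], ncol = 1,
                     dimnames = list(lib, "planted_bit_task"))
    mask <- matrix(1L, length(lib), 1,
                   dimnames = list(lib, "planted_bit_task"))
    split <- split_dataset(lib, curation_config(seed = seed,
                                                min_task_size = 0L))
    ds <- mt_dataset(lib, labels, mask, split)
    meta <- list(name = name, seed = seed, planted_maccs_bit = bit)
    spec <- NULL
  } else if (name == "remote-test-AD") {
    spec <- synthetic_spec(n_compounds = n_compounds, seed = seed)
    lib <- generate_library(spec)
    remote <- remote_library(10L, seed = seed + 99L)
    full <- c(lib, remote)
    ds0 <- assign_labels(full, spec)
    split <- ds0$split
    split[match(remote, full)] <- "test"
    ds <- mt_dataset(ds0$smiles, ds0$labels, ds0$mask, split)
    meta <- list(name = name, seed = seed, remote_smiles = remote)
  } else {
    stop("unknown benchmark: ", name, call. = FALSE)
  }
  out <- list(dataset = ds, spec = spec, meta = meta)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    csv <- file.path(dir, paste0(gsub("[^a-zA-Z0-9]+", "_", name), ".csv"))
    write_curated_csv(ds, csv)
    manifest <- file.path(dir, paste0(gsub("[^a-zA-Z0-9]+", "_", name),
                                      "_manifest.json"))
    jsonlite::write_json(meta, manifest, auto_unbox = TRUE, digits = NA)
    out$files <- c(csv = csv, manifest = manifest)
  }
  out
}
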