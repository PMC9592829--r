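# Featurization: the fingerprint block consumed by the fingerprint
# branch and the molecular graph consumed by the graph-attention branch.

FP_LENGTHS <- c(maccs = 166L, pubchem = 881L, erg = 315L, morgan = 1024L)

bitstring_matrix <- function(strings, width, smiles) {
  out <- matrix(0L, length(strings), width,
                dimnames = list(smiles, NULL))
  for (i in seq_along(strings)) {
    s <- strings[[i]]
    if (is.null(s)) stop("invalid molecule: ", smiles[[i]], call. = FALSE)
    out[i, ] <- as.integer(strsplit(s, "")[[1]])
  }
  out
}

fp_query <- function(smiles, kind) {
  res <- cached_query(paste0("fp_", kind), smiles, function(miss) {
    chem_call("fingerprints", smiles = as.list(miss),
              kinds = list(kind))$results[[kind]]
  })
  res
}

#' Molecular fingerprints
#'
#' `compute_maccs()` gives the 166 MACCS substructure keys,
#' `compute_pubchem()` an 881-bit PubChem-style substructure key set
#' (hierarchic element counts, ring-composition counts, and a
#' deterministic combinatorial SMARTS section), `compute_morgan()` the
#' hashed circular fingerprint of radius 2 folded to 1024 bits (ECFP4),
#' and `compute_erg()` the extended reduced-graph pharmacophore vector
#' (315 fuzzy pharmacophore-pair increments; `binarize = TRUE` thresholds
#' at > 0).
#'
#' @param smiles Character vector of SMILES.
#' @param binarize For `compute_erg()`, return 0/1 presence instead of
#'   the raw fuzzy counts.
#' @return Numeric/integer matrix, one row per molecule, SMILES as row
#'   names.
#' @export
compute_maccs <- function(smiles) {
  bitstring_matrix(fp_query(smiles, "maccs"), FP_LENGTHS[["maccs"]], smiles)
}

#' @rdname compute_maccs
#' @export
compute_pubchem <- function(smiles) {
  bitstring_matrix(fp_query(smiles, "pubchem"), FP_LENGTHS[["pubchem"]],
                   smiles)
}

#' @rdname compute_maccs
#' @export
compute_morgan <- function(smiles) {
  bitstring_matrix(fp_query(smiles, "morgan"), FP_LENGTHS[["morgan"]], smiles)
}

#' @rdname compute_maccs
#' @export
compute_erg <- function(smiles, binarize = FALSE) {
  res <- fp_query(smiles, "erg")
  out <- matrix(0, length(res), FP_LENGTHS[["erg"]],
                dimnames = list(smiles, NULL))
  for (i in seq_along(res)) {
    if (is.null(res[[i]])) stop("invalid molecule: ", smiles[[i]],
                                call. = FALSE)
    out[i, ] <- unlist(res[[i]])
  }
  if (binarize) out <- (out > 0) + 0L
  out
}

#' Concatenated fingerprint block for the fingerprint branch
#'
#' Column-binds MACCS (166), PubChem-style (881) and binarized ErG (315)
#' into the 1362-wide input of the fingerprint network. The `family`
#' attribute records which fingerprint each column came from.
#'
#' @param smiles Character vector of SMILES.
#' @return Integer matrix `length(smiles) x 1362` with a `family`
#'   attribute (`"maccs"`, `"pubchem"`, `"erg"` per column).
#' @export
fingerprint_block <- function(smiles) {
  parts <- list(maccs = compute_maccs(smiles),
                pubchem = compute_pubchem(smiles),
                erg = compute_erg(smiles, binarize = TRUE))
  out <- do.call(cbind, unname(parts))
  stopifnot(ncol(out) == sum(FP_LENGTHS[c("maccs", "pubchem", "erg")]))
  attr(out, "family") <- rep(names(parts), times = vapply(parts, ncol,
                                                          integer(1)))
  out
}

#' Molecular graph for the graph-attention branch
#'
#' Heavy-atom graph with a fixed feature schema: atoms carry a one-hot
#' element (C, N, O, S, F, Cl, Br, I, P, other), degree, formal charge,
#' aromaticity, total hydrogen count, hybridization and ring membership
#' (28 features); bonds carry bond-order one-hot, conjugation and ring
#' flags (6 features). Both directions of every bond are stored.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `mol_graph` with `n_atoms`,
#'   `atom_features` (n x 28), `edges` (m x 2, 1-based, both directions)
#'   and `bond_features` (m x 6).
#' @export
mol_to_graph <- function(smiles) {
  stopifnot(length(smiles) == 1)
  mol_to_graphs(smiles)[[1]]
}

#' @rdname mol_to_graph
#' @export
mol_to_graphs <- function(smiles) {
  res <- cached_query("graph", smiles, function(miss) {
    chem_call("graphs", smiles = as.list(miss))$results
  })
  purrr::map2(res, smiles, function(g, smi) {
    if (!isTRUE(g$ok)) {
      stop("cannot build graph for SMILES '", smi, "': ", g$error,
           call. = FALSE)
    }
    af <- do.call(rbind, lapply(g$atom_features, unlist))
    ed <- if (length(g$edges) > 0) {
      do.call(rbind, lapply(g$edges, unlist)) + 1L
    } else {
      matrix(integer(0), 0, 2)
    }
    bf <- if (length(g$bond_features) > 0) {
      do.call(rbind, lapply(g$bond_features, unlist))
    } else {
      matrix(numeric(0), 0, 6)
    }
    structure(list(smiles = smi, n_atoms = g$n_atoms, atom_features = af,
                   edges = ed, bond_features = bf),
              class = "mol_graph")
  })
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$smiles, ": ", x$n_atoms, " atoms, ",
      nrow(x$edges) / 2, " bonds\n", sep = "")
  invisible(x)
}

#' SMARTS substructure matching
#'
#' @param smiles Character vector of SMILES.
#' @param smarts Character vector of SMARTS patterns.
#' @return Logical matrix `length(smiles) x length(smarts)`.
#' @export
match_smarts <- function(smiles, smarts) {
  res <- chem_call("match", smiles = as.list(smiles),
                   smarts = as.list(smarts))$results
  out <- matrix(NA, length(smiles), length(smarts),
                dimnames = list(smiles, smarts))
  for (i in seq_along(res)) {
    if (!is.null(res[[i]])) {
      out[i, ] <- as.integer(strsplit(res[[i]], "")[[1]]) == 1L
    }
  }
  out
}

#' @rdname match_smarts
#' @details `match_smarts_atoms()` returns, per molecule, the 1-based
#'   indices of the atoms covered by any match of a single SMARTS
#'   pattern (empty integer vector when there is no match).
#' @export
match_smarts_atoms <- function(smiles, smarts) {
  stopifnot(length(smarts) == 1)
  res <- chem_call("match_atoms", smiles = as.list(smiles),
                   smarts = smarts)$results
  lapply(res, function(r) {
    if (is.null(r)) integer(0) else unlist(r) + 1L
  })
}

#' Featurize a curated dataset for model training
#'
#' Computes the fingerprint block and molecular graphs for every
#' compound once; the result feeds [train_model()] and [predict] calls.
#'
#' @param dataset An `mt_dataset` (or character vector of SMILES).
#' @return List with `smiles`, `fp` (N x 1362 matrix) and `graphs`
#'   (list of `mol_graph`).
#' @export
featurize_dataset <- function(dataset) {
  smiles <- if (inherits(dataset, "mt_dataset")) dataset$smiles else dataset
  list(smiles = smiles,
       fp = fingerprint_block(smiles),
       graphs = mol_to_graphs(smiles))
}
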