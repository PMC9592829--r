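# Curation: raw per-target activity records -> deduplicated, standardized,
# binary-labelled multi-task dataset with train/validation/test splits.

RECOGNIZED_UNITS <- c("g/mL", "M", "mM", "uM", "µM", "nM")

#' Curation configuration
#'
#' @param mw_max Molecular-weight cutoff in daltons; heavier compounds are
#'   removed (default 1000).
#' @param activity_threshold Activity threshold on the p-scale
#'   (`pActivity = -log10(molar)`); compounds at or above it are actives
#'   (default 6, i.e. 1 uM).
#' @param split_fractions Train/validation/test fractions, summing to 1
#'   (default 0.8/0.1/0.1).
#' @param seed Integer seed for the random compound-level split.
#' @param min_task_size Tasks with fewer curated compounds are dropped
#'   (default 300, set to 0 to keep everything).
#' @param relation_policy How to treat censored records (`relation` other
#'   than `"="`): `"equals_only"` (default) keeps only exact values.
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(mw_max = 1000, activity_threshold = 6,
                            split_fractions = c(0.8, 0.1, 0.1), seed = 0L,
                            min_task_size = 300L,
                            relation_policy = c("equals_only")) {
  stopifnot(mw_max > 0, length(split_fractions) == 3,
            all(split_fractions > 0), all(split_fractions < 1),
            abs(sum(split_fractions) - 1) < 1e-9)
  structure(list(mw_max = mw_max, activity_threshold = activity_threshold,
                 split_fractions = split_fractions, seed = as.integer(seed),
                 min_task_size = as.integer(min_task_size),
                 relation_policy = match.arg(relation_policy)),
            class = "curation_config")
}

#' Standardize SMILES strings
#'
#' Strips counter-ions, solvents and salts down to the largest organic
#' fragment, neutralizes charges where chemically valid, and returns the
#' canonical SMILES. The operation is idempotent. Unparseable inputs give
#' `NA` with a warning so batch runs can drop them.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical standardized SMILES (`NA` where
#'   the input could not be parsed).
#' @export
#' @examples
#' \dontrun{standardize_molecule("CCO.[Na+].[Cl-]")  # "CCO"}
standardize_molecule <- function(smiles) {
  res <- cached_query("standardize", smiles, function(miss) {
    chem_call("standardize", smiles = as.list(miss))$results
  })
  out <- vapply(res, function(r) if (isTRUE(r$ok)) r$smiles else NA_character_,
                character(1))
  if (anyNA(out)) {
    warning(sum(is.na(out)), " SMILES could not be parsed and were dropped",
            call. = FALSE)
  }
  out
}

#' Molecular weight and AlogP
#'
#' @param smiles Character vector of SMILES.
#' @return Tibble with `smiles`, `mw` (daltons) and `alogp`.
#' @export
molecule_properties <- function(smiles) {
  res <- cached_query("props", smiles, function(miss) {
    chem_call("props", smiles = as.list(miss))$results
  })
  tibble::tibble(
    smiles = smiles,
    mw = vapply(res, function(r) r$mw %||% NA_real_, numeric(1)),
    alogp = vapply(res, function(r) r$alogp %||% NA_real_, numeric(1))
  )
}

#' Convert assay values to micromolar and the p-scale
#'
#' Supported units: `g/mL` (requires `mw`), `M`, `mM`, `uM`/`µM`, `nM`.
#' `p_activity = 6 - log10(micromolar)`, i.e. `-log10(molar)`.
#'
#' @param value Positive assay values.
#' @param unit Character vector of units (recycled).
#' @param mw Molecular weights in daltons; only needed for mass/volume
#'   units.
#' @return Tibble with `micromolar` and `p_activity`.
#' @export
#' @examples
#' convert_activity(5, "nM")     # 0.005 uM, p = 8.3
#' convert_activity(1, "uM")     # p_activity = 6
convert_activity <- function(value, unit, mw = NULL) {
  stopifnot(all(value > 0))
  n <- length(value)
  unit <- rep_len(unit, n)
  unit[unit == "µM"] <- "uM"
  bad <- setdiff(unique(unit), c("g/mL", "M", "mM", "uM", "nM"))
  if (length(bad) > 0) {
    stop("unknown unit(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(mw)) mw <- rep(NA_real_, n) else mw <- rep_len(mw, n)
  if (any(unit == "g/mL" & is.na(mw))) {
    stop("unit g/mL requires a molecular weight", call. = FALSE)
  }
  micromolar <- dplyr::case_when(
    unit == "g/mL" ~ value / mw * 1e6 * 1e3,  # g/mL = 1000 g/L; mol/L * 1e6
    unit == "M" ~ value * 1e6,
    unit == "mM" ~ value * 1e3,
    unit == "uM" ~ value,
    unit == "nM" ~ value * 1e-3
  )
  tibble::tibble(micromolar = micromolar,
                 p_activity = 6 - log10(micromolar))
}

#' Aggregate replicate measurements and assign an activity label
#'
#' Replicates for one compound-target pair are averaged arithmetically in
#' micromolar, converted to the p-scale, and compared (inclusively) to the
#' activity threshold: `p >= threshold` is active (1).
#'
#' @param micromolar Positive values in micromolar for one compound-target
#'   pair.
#' @param config A [curation_config()].
#' @return Integer label, 0 or 1.
#' @export
#' @examples
#' aggregate_and_label(c(0.5, 1.5))  # mean 1 uM -> p = 6 -> active
aggregate_and_label <- function(micromolar, config = curation_config()) {
  if (length(micromolar) == 0) stop("no records to aggregate", call. = FALSE)
  stopifnot(all(micromolar > 0))
  p <- 6 - log10(mean(micromolar))
  as.integer(p >= config$activity_threshold)
}

#' Filter raw activity records
#'
#' Keeps binding-assay records (`assay_type == "B"`) with exact values
#' (`relation == "="`), parseable SMILES and molecular weight at most
#' `mw_max`. Standardization happens here so later deduplication works on
#' canonical SMILES. Counts of records dropped by each rule are returned.
#'
#' @param records Tibble with columns `smiles`, `target_id`, `assay_type`,
#'   `value`, `unit`, `relation`.
#' @param config A [curation_config()].
#' @return List with `records` (filtered tibble gaining
#'   `canonical_smiles`, `mw`, `micromolar`, `p_activity`) and `dropped`
#'   (named counts per filter).
#' @export
apply_filters <- function(records, config = curation_config()) {
  stopifnot(all(c("smiles", "target_id", "assay_type", "value", "unit",
                  "relation") %in% names(records)))
  records <- tibble::as_tibble(records)
  n0 <- nrow(records)
  records <- dplyr::filter(records, .data$assay_type == "B")
  n1 <- nrow(records)
  records <- dplyr::filter(records, .data$relation == "=")
  n2 <- nrow(records)
  records <- dplyr::filter(records, .data$value > 0)
  n3 <- nrow(records)
  if (nrow(records) > 0) {
    records$canonical_smiles <- suppressWarnings(
      standardize_molecule(records$smiles))
    records <- dplyr::filter(records, !is.na(.data$canonical_smiles))
  } else {
    records$canonical_smiles <- character(0)
  }
  n4 <- nrow(records)
  if (nrow(records) > 0) {
    props <- molecule_properties(records$canonical_smiles)
    records$mw <- props$mw
    records <- dplyr::filter(records, .data$mw <= config$mw_max)
  } else {
    records$mw <- numeric(0)
  }
  n5 <- nrow(records)
  if (nrow(records) > 0) {
    conv <- convert_activity(records$value, records$unit, records$mw)
    records$micromolar <- conv$micromolar
    records$p_activity <- conv$p_activity
  } else {
    records$micromolar <- records$p_activity <- numeric(0)
  }
  list(records = records,
       dropped = c(non_binding_assay = n0 - n1,
                   censored_relation = n1 - n2,
                   nonpositive_value = n2 - n3,
                   unparseable_smiles = n3 - n4,
                   over_mw_cutoff = n4 - n5))
}

# Largest-remainder assignment of N compounds to the three split sizes so
# each size differs from round(f * N) by at most 1 and sizes sum to N.
split_sizes <- function(n, fractions) {
  raw <- fractions * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  as.integer(sizes)
}

#' Random compound-level split
#'
#' Assigns each compound to train/valid/test so all of its task labels
#' stay in one split. Deterministic given the config seed.
#'
#' @param smiles Character vector of unique compound identifiers.
#' @param config A [curation_config()].
#' @return Character vector in `{"train", "valid", "test"}` parallel to
#'   `smiles`.
#' @export
split_dataset <- function(smiles, config = curation_config()) {
  n <- length(smiles)
  if (n < 3) stop("need at least 3 compounds to split", call. = FALSE)
  sizes <- split_sizes(n, config$split_fractions)
  assignment <- rep(c("train", "valid", "test"), times = sizes)
  perm <- with_local_seed(config$seed, sample.int(n))
  out <- character(n)
  out[perm] <- assignment
  out
}

# evaluate expr under a fixed seed without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Multi-task dataset container
#'
#' @param smiles Character vector of unique canonical SMILES (length N).
#' @param labels N x T matrix in `{0, 1}` with task ids as column names.
#' @param mask N x T matrix in `{0, 1}`; 1 marks an observed label. Every
#'   compound must have at least one observed task.
#' @param split Character vector in `{"train", "valid", "test"}`.
#' @return An object of class `mt_dataset`.
#' @export
mt_dataset <- function(smiles, labels, mask, split) {
  labels <- as.matrix(labels); mask <- as.matrix(mask)
  stopifnot(!anyDuplicated(smiles), nrow(labels) == length(smiles),
            all(dim(labels) == dim(mask)),
            all(labels %in% c(0, 1)), all(mask %in% c(0, 1)),
            all(rowSums(mask) >= 1), length(split) == length(smiles),
            all(split %in% c("train", "valid", "test")),
            !is.null(colnames(labels)))
  rownames(labels) <- rownames(mask) <- smiles
  colnames(mask) <- colnames(labels)
  structure(list(smiles = smiles, task_ids = colnames(labels),
                 labels = labels, mask = mask, split = split),
            class = "mt_dataset")
}

#' @export
print.mt_dataset <- function(x, ...) {
  cat("<mt_dataset> ", length(x$smiles), " compounds x ",
      length(x$task_ids), " tasks (",
      sum(x$mask), " observed labels; ",
      paste(names(table(x$split)), table(x$split),
            sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.mt_dataset <- function(x, ...) {
  wide <- tibble::tibble(canonical_smiles = x$smiles, split = x$split)
  for (t in x$task_ids) {
    wide[[paste0("label_", t)]] <- unname(x$labels[, t])
    wide[[paste0("mask_", t)]] <- unname(x$mask[, t])
  }
  wide
}

#' Curate raw activity records into a multi-task dataset
#'
#' The full pipeline: filter (binding assays, exact relations, parseable
#' SMILES, MW cutoff), standardize, convert units to micromolar, average
#' replicates per compound-target pair, threshold on the p-scale, drop
#' undersized tasks, and split at compound level.
#'
#' @param records Raw activity records (see [apply_filters()]).
#' @param config A [curation_config()].
#' @return List with the `mt_dataset` (`dataset`) and a curation `report`
#'   (dropped counts, per-task sizes).
#' @export
curate_dataset <- function(records, config = curation_config()) {
  filt <- apply_filters(records, config)
  rec <- filt$records
  if (nrow(rec) == 0) stop("no records survive filtering", call. = FALSE)
  pair <- rec |>
    dplyr::group_by(.data$canonical_smiles, .data$target_id) |>
    dplyr::summarise(label = aggregate_and_label(.data$micromolar, config),
                     .groups = "drop")
  task_sizes <- dplyr::count(pair, .data$target_id)
  keep_tasks <- task_sizes$target_id[task_sizes$n > config$min_task_size]
  dropped_tasks <- setdiff(task_sizes$target_id, keep_tasks)
  if (config$min_task_size > 0) {
    pair <- dplyr::filter(pair, .data$target_id %in% keep_tasks)
  }
  if (nrow(pair) == 0) {
    stop("no task passes min_task_size = ", config$min_task_size,
         call. = FALSE)
  }
  tasks <- sort(unique(pair$target_id))
  smiles <- sort(unique(pair$canonical_smiles))
  labels <- mask <- matrix(0L, length(smiles), length(tasks),
                           dimnames = list(smiles, tasks))
  idx <- cbind(match(pair$canonical_smiles, smiles),
               match(pair$target_id, tasks))
  labels[idx] <- pair$label
  mask[idx] <- 1L
  split <- split_dataset(smiles, config)
  ds <- mt_dataset(smiles, labels, mask, split)
  list(dataset = ds,
       report = list(n_input_records = nrow(records),
                     dropped = as.list(filt$dropped),
                     dropped_tasks = dropped_tasks,
                     n_compounds = length(smiles),
                     n_observed_labels = sum(mask),
                     per_task = dataset_summary(ds)$per_task))
}

#' Bemis-Murcko scaffold diversity
#'
#' Counts distinct Murcko scaffolds (ring systems plus linkers with
#' substituents removed). Acyclic molecules all map to one shared "empty
#' scaffold" class so the ratio stays well defined.
#'
#' @param smiles Character vector of SMILES (or an `mt_dataset`).
#' @return Tibble with `n_compounds`, `n_scaffolds` and `ratio_percent`
#'   (`100 * n_scaffolds / n_compounds`, two decimals).
#' @export
scaffold_statistics <- function(smiles) {
  if (inherits(smiles, "mt_dataset")) smiles <- smiles$smiles
  stopifnot(length(smiles) > 0)
  res <- cached_query("scaffold", smiles, function(miss) {
    chem_call("scaffold", smiles = as.list(miss))$results
  })
  sc <- vapply(res, function(r) r %||% NA_character_, character(1))
  sc <- sc[!is.na(sc)]
  tibble::tibble(
    n_compounds = length(sc),
    n_scaffolds = length(unique(sc)),
    ratio_percent = round(100 * length(unique(sc)) / length(sc), 2)
  )
}

#' Dataset summary statistics
#'
#' Per-task sizes, active fractions, molecular weight and AlogP ranges,
#' and the pairwise matrix of compounds observed in both tasks.
#'
#' @param dataset An `mt_dataset`.
#' @return List with `per_task` (tibble) and `overlap` (T x T matrix).
#' @export
dataset_summary <- function(dataset) {
  stopifnot(inherits(dataset, "mt_dataset"))
  props <- molecule_properties(dataset$smiles)
  per_task <- purrr::map_dfr(dataset$task_ids, function(t) {
    obs <- dataset$mask[, t] == 1
    tibble::tibble(
      task_id = t,
      n = sum(obs),
      n_active = sum(dataset$labels[obs, t]),
      pct_active = round(100 * mean(dataset$labels[obs, t]), 2),
      mw_min = min(props$mw[obs]), mw_max = max(props$mw[obs]),
      alogp_min = min(props$alogp[obs]), alogp_max = max(props$alogp[obs])
    )
  })
  overlap <- crossprod(dataset$mask)
  list(per_task = per_task, overlap = overlap)
}

#' Read raw activity records from CSV
#'
#' Expects a header with columns
#' `smiles,target_id,assay_type,value,unit,relation`.
#'
#' @param path CSV file path.
#' @return Tibble of activity records.
#' @export
read_activity_csv <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           smiles = readr::col_character(),
                           target_id = readr::col_character(),
                           assay_type = readr::col_character(),
                           value = readr::col_double(),
                           unit = readr::col_character(),
                           relation = readr::col_character()))
  rec
}

#' Write / read a curated dataset as CSV
#'
#' One row per compound: `canonical_smiles`, a `label_<task>` and
#' `mask_<task>` column per task, and `split`.
#'
#' @param dataset An `mt_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly (`write_curated_csv`); an `mt_dataset`
#'   (`read_curated_csv`).
#' @export
write_curated_csv <- function(dataset, path) {
  readr::write_csv(as_tibble.mt_dataset(dataset), path)
  invisible(path)
}

#' @rdname write_curated_csv
#' @export
read_curated_csv <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  tasks <- sub("^label_", "", grep("^label_", names(wide), value = TRUE))
  labels <- as.matrix(wide[paste0("label_", tasks)])
  mask <- as.matrix(wide[paste0("mask_", tasks)])
  storage.mode(labels) <- storage.mode(mask) <- "integer"
  colnames(labels) <- colnames(mask) <- tasks
  mt_dataset(wide$canonical_smiles, labels, mask, wide$split)
}
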