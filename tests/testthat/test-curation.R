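test_that("unit conversion to micromolar and the p-scale is exact", {
  expect_equal(convert_activity(5, "nM")$micromolar, 0.005)
  expect_equal(convert_activity(1, "uM")$p_activity, 6)
  expect_equal(convert_activity(1, "µM")$p_activity, 6)
  # 0.001 g/mL at MW 500: 1 g/L / 500 g/mol = 2 mM = 2000 uM
  expect_equal(convert_activity(0.001, "g/mL", mw = 500)$micromolar, 2000)
  expect_error(convert_activity(1, "furlongs"), "unknown unit")
  expect_error(convert_activity(1, "g/mL"), "molecular weight")
})

test_that("replicate aggregation averages in micromolar with an inclusive threshold", {
  expect_equal(aggregate_and_label(c(0.5, 1.5)), 1L)   # mean 1 uM, p = 6
  expect_equal(aggregate_and_label(10), 0L)            # p = 5
  expect_equal(aggregate_and_label(10^(6 - 5.999)), 0L)  # p just under 6
  expect_error(aggregate_and_label(numeric(0)))
  # order invariance
  set.seed(3)
  for (i in 1:20) {
    x <- runif(5, 0.01, 10)
    expect_identical(aggregate_and_label(x), aggregate_and_label(rev(x)))
  }
})

test_that("standardization strips salts, neutralizes and is idempotent", {
  expect_equal(standardize_molecule("CCO.[Na+].[Cl-]"), "CCO")
  expect_equal(standardize_molecule("CC(=O)[O-]"), "CC(=O)O")
  expect_warning(out <- standardize_molecule("not_a_smiles"))
  expect_true(is.na(out))
  # idempotence over a generated library
  lib <- fixture_library(100, seed = 5)
  expect_identical(standardize_molecule(lib), lib)
})

test_that("record filtering keeps exact binding assays under the MW cutoff", {
  records <- tibble::tibble(
    smiles = c("CCO", "CCO", "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC",
               "CCN", "CCOC"),
    target_id = "t1",
    assay_type = c("B", "B", "B", "F", "B"),
    value = c(1, 1, 1, 1, 2),
    unit = "uM",
    relation = c("=", "=", "=", "=", ">"))
  filt <- apply_filters(records)
  # duplicate CCO rows both survive (merged later); the C72 alkane
  # exceeds 1000 Da, the functional assay and censored record drop
  expect_equal(nrow(filt$records), 2)
  expect_equal(unname(filt$dropped["non_binding_assay"]), 1)
  expect_equal(unname(filt$dropped["censored_relation"]), 1)
  expect_equal(unname(filt$dropped["over_mw_cutoff"]), 1)
  # aggregation then merges the replicate pair into one compound
  expect_equal(length(unique(filt$records$canonical_smiles)), 1)
})

test_that("curation end-to-end builds a labelled multi-task dataset", {
  records <- tibble::tibble(
    smiles = c("CCO", "CCO", "CCN", "CCOC", "c1ccccc1O", "CCS",
               "CCN", "CCC", "CCCC", "CCCO"),
    target_id = rep(c("t1", "t2"), each = 5),
    assay_type = "B",
    value = c(0.5, 1.5, 0.1, 20, 0.2, 5, 0.01, 0.4, 30, 2),
    unit = "uM",
    relation = "=")
  cur <- curate_dataset(records, curation_config(seed = 1, min_task_size = 0))
  ds <- cur$dataset
  expect_s3_class(ds, "mt_dataset")
  expect_setequal(ds$task_ids, c("t1", "t2"))
  # CCO replicates average to 1 uM -> active
  expect_equal(unname(ds$labels["CCO", "t1"]), 1L)
  expect_equal(unname(ds$mask["CCO", "t2"]), 0L)
  expect_equal(cur$report$n_observed_labels, sum(ds$mask))
  # round-trip through CSV
  tmp <- tempfile(fileext = ".csv")
  write_curated_csv(ds, tmp)
  back <- read_curated_csv(tmp)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$split, ds$split)
})

test_that("split sizes follow rounded fractions and are deterministic", {
  cfg <- curation_config(seed = 4)
  s200 <- split_dataset(paste0("m", 1:200), cfg)
  expect_equal(as.integer(table(s200)[c("train", "valid", "test")]),
               c(160L, 20L, 20L))
  s10 <- split_dataset(paste0("m", 1:10), cfg)
  expect_equal(as.integer(table(s10)[c("train", "valid", "test")]), c(8L, 1L, 1L))
  expect_identical(s200, split_dataset(paste0("m", 1:200), cfg))
  expect_error(split_dataset(c("a", "b"), cfg), "at least 3")
  # property: each split within 1 of round(f * N), partition exact
  for (n in c(7, 23, 101, 473)) {
    s <- split_dataset(paste0("m", seq_len(n)), cfg)
    expect_equal(length(s), n)
    sizes <- table(factor(s, levels = c("train", "valid", "test")))
    expect_true(all(abs(sizes - round(c(0.8, 0.1, 0.1) * n)) <= 1))
    expect_equal(sum(sizes), n)
  }
})

test_that("scaffold statistics count Murcko scaffolds with an empty-scaffold class", {
  # benzene, toluene and phenol share the benzene scaffold
  st <- scaffold_statistics(c("c1ccccc1", "Cc1ccccc1", "Oc1ccccc1"))
  expect_equal(st$n_scaffolds, 1)
  expect_equal(st$ratio_percent, 33.33)
  # acyclic molecules all land in the shared empty-scaffold class
  st2 <- scaffold_statistics(c("CCO", "CCC", "c1ccccc1"))
  expect_equal(st2$n_scaffolds, 2)
  # brute-force check on a hand-checkable set: 3 distinct ring systems
  smiles <- c("c1ccccc1", "Cc1ccccc1", "c1ccncc1", "Cc1ccncc1",
              "C1CCCCC1", "CC1CCCCC1", "CCO")
  st3 <- scaffold_statistics(smiles)
  expect_equal(st3$n_scaffolds, 4)  # benzene, pyridine, cyclohexane, empty
  expect_true(st3$ratio_percent > 0 && st3$ratio_percent <= 100)
})

test_that("dataset summary reports sizes, imbalance, property ranges and overlap", {
  smiles <- fixture_library(10, seed = 13)
  labels <- cbind(a = rep(1L, 10), b = rep(0L, 10))
  mask <- cbind(a = rep(1L, 10), b = c(rep(1L, 5), rep(0L, 5)))
  rownames(labels) <- rownames(mask) <- smiles
  ds <- mt_dataset(smiles, labels, mask, rep(c("train", "valid", "test"),
                                             c(8, 1, 1)))
  sm <- dataset_summary(ds)
  expect_equal(sm$per_task$n, c(10, 5))
  expect_equal(sm$per_task$pct_active, c(100, 0))
  expect_equal(unname(sm$overlap["a", "b"]), 5)
  expect_true(all(sm$per_task$mw_min <= sm$per_task$mw_max))
  # single compound: degenerate range
  one <- mt_dataset(smiles[1], labels[1, , drop = FALSE],
                    matrix(1L, 1, 2, dimnames = list(smiles[1], c("a", "b"))),
                    "train")
  expect_equal(dataset_summary(one)$per_task$mw_min,
               dataset_summary(one)$per_task$mw_max)
})

test_that("molecule properties match known atomic masses", {
  expect_equal(molecule_properties("CCO")$mw, 46.069, tolerance = 1e-3)
})
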