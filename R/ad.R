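# Applicability domain: Euclidean distances over raw 0/1 Morgan
# fingerprints, k-nearest-neighbour statistics over the training set,
# and the distance threshold D_T = d_ave + Z * theta.

pairwise_euclidean <- function(A, B = NULL) {
  # on 0/1 vectors: d^2 = |a| + |b| - 2 a.b
  if (is.null(B)) B <- A
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, `+`) - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Fit the applicability-domain model
#'
#' For every training molecule, the mean Euclidean distance to its `k`
#' nearest other training molecules (self excluded; ties broken by a
#' stable sort on distance then index) is computed; `d_ave` and `theta`
#' are the mean and standard deviation of those per-molecule values, and
#' the threshold is `D_T = d_ave + Z * theta`.
#'
#' @param train_fps Matrix of training fingerprints (rows = molecules),
#'   typically [compute_morgan()] output.
#' @param k Number of nearest neighbours (`k < nrow(train_fps)`).
#' @param Z Significance multiplier, `Z >= 0`.
#' @return An object of class `ad_model` with `d_ave`, `theta`, `D_T`,
#'   `per_molecule` distances, `k`, `Z` and the training fingerprints.
#' @export
fit_ad <- function(train_fps, k, Z) {
  train_fps <- as.matrix(train_fps)
  n <- nrow(train_fps)
  if (k >= n) stop("k must be smaller than the number of training molecules",
                   call. = FALSE)
  stopifnot(k >= 1, Z >= 0)
  D <- pairwise_euclidean(train_fps)
  per_mol <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    idx <- order(d, seq_along(d))  # stable tie-break by (distance, index)
    mean(d[idx[seq_len(k)]])
  }, numeric(1))
  d_ave <- mean(per_mol)
  theta <- stats::sd(per_mol)
  if (is.na(theta)) theta <- 0
  structure(list(train_fps = train_fps, k = as.integer(k), Z = Z,
                 d_ave = d_ave, theta = theta, D_T = d_ave + Z * theta,
                 per_molecule = per_mol),
            class = "ad_model")
}

#' @export
print.ad_model <- function(x, ...) {
  cat(sprintf("<ad_model> k = %d, Z = %.2f: d_ave = %.3f, theta = %.3f, D_T = %.3f (n_train = %d)\n",
              x$k, x$Z, x$d_ave, x$theta, x$D_T, nrow(x$train_fps)))
  invisible(x)
}

#' Classify query molecules as inside/outside the domain
#'
#' A query's distance is the Euclidean distance to its nearest training
#' molecule; distances strictly greater than `D_T` are outside the
#' domain (OD), anything at or below the threshold is inside (ID).
#'
#' @param query_fps Matrix of query fingerprints (same width as the
#'   training fingerprints).
#' @param model An `ad_model` from [fit_ad()].
#' @return Tibble with `distance` and `domain` (`"ID"`/`"OD"`) per query.
#' @export
classify_ad <- function(query_fps, model) {
  stopifnot(inherits(model, "ad_model"))
  query_fps <- as.matrix(query_fps)
  D <- pairwise_euclidean(query_fps, model$train_fps)
  nn <- apply(D, 1, min)
  tibble::tibble(distance = nn,
                 domain = ifelse(nn > model$D_T, "OD", "ID"))
}

#' Grid search over the (k, Z) applicability-domain parameters
#'
#' For each pair, fits the domain on the training fingerprints,
#' classifies the test set, and evaluates the supplied prediction model
#' separately on the inside- and outside-domain subsets. Because
#' `theta >= 0`, the number of OD compounds is non-increasing in `Z` at
#' fixed `k`.
#'
#' @param train_fps,test_fps Fingerprint matrices.
#' @param k_values,Z_values Grids to scan (defaults cover k 1-5 and
#'   Z 0.1-0.6).
#' @param evaluator `function(test_rows)` returning a one-row data frame
#'   of metrics for that subset of test indices (or `NULL` to skip
#'   metric evaluation).
#' @return Tibble with one row per (k, Z): `D_T`, `n_ID`, `n_OD`, and
#'   (if an evaluator is given) prefixed `id_*` / `od_*` metric columns.
#' @export
ad_grid_search <- function(train_fps, test_fps, k_values = 1:5,
                           Z_values = seq(0.1, 0.6, by = 0.1),
                           evaluator = NULL) {
  stopifnot(length(k_values) > 0, length(Z_values) > 0)
  purrr::map_dfr(k_values, function(k) {
    purrr::map_dfr(Z_values, function(z) {
      model <- fit_ad(train_fps, k, z)
      cls <- classify_ad(test_fps, model)
      row <- tibble::tibble(k = k, Z = z, D_T = model$D_T,
                            n_ID = sum(cls$domain == "ID"),
                            n_OD = sum(cls$domain == "OD"))
      if (!is.null(evaluator)) {
        id_rows <- which(cls$domain == "ID")
        od_rows <- which(cls$domain == "OD")
        if (length(id_rows) > 0) {
          idm <- evaluator(id_rows)
          names(idm) <- paste0("id_", names(idm))
          row <- dplyr::bind_cols(row, idm)
        }
        if (length(od_rows) > 0) {
          odm <- evaluator(od_rows)
          names(odm) <- paste0("od_", names(odm))
          row <- dplyr::bind_cols(row, odm)
        }
      }
      row
    })
  })
}
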