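# The multiparametric weighting framework: control normalisation,
# conditional 1/x inversion with a re-check, PCA-derived feature weights at
# a cumulative explained-variance threshold, and the final composite
# response metric (a weighted sum of the processed features, 1 at control).

new_norm_features <- function(tbl, control_reference, inversion_log) {
  attr(tbl, "control_reference") <- control_reference
  attr(tbl, "inversion_log") <- inversion_log
  class(tbl) <- unique(c("norm_features", class(tbl)))
  tbl
}

#' Control reference attached to a normalised feature table
#' @param m A `norm_features` table.
#' @return Tibble: `cell_line`, `feature`, `control_mean`.
#' @export
control_reference <- function(m) {
  attr(m, "control_reference") %||% abort("not a normalised feature table")
}

#' Inversion log attached to a normalised feature table
#' @param m A `norm_features` table.
#' @return Tibble: `cell_line`, `feature`, `inverted`, `reverted`,
#'   `mean_before`, `mean_after`.
#' @export
inversion_log <- function(m) {
  attr(m, "inversion_log") %||% abort("not a normalised feature table")
}

#' Normalise features to the zero-dose control
#'
#' Each feature is divided by the mean of the control (concentration 0)
#' wells of the same cell line, so control columns average exactly 1.
#' (Percent-of-control is the same quantity times 100; the fraction scale
#' is used throughout because the inversion rule compares means to 1.)
#'
#' @param tbl Feature table with at least one control well per cell line
#'   and strictly positive feature values.
#' @param features Feature columns (default: all).
#' @return A `norm_features` tibble; the per-feature control means are
#'   available via [control_reference()].
#' @export
normalize_to_control <- function(tbl, features = NULL) {
  check_well_keys(tbl)
  features <- features %||% feature_columns(tbl)
  if (length(features) == 0) abort("no feature columns found")
  refs <- list()
  for (cl in unique(tbl$cell_line)) {
    ci <- tbl$cell_line == cl
    ctrl <- ci & tbl$concentration == 0
    if (!any(ctrl)) abort(paste0("no control (concentration 0) wells for cell line ", cl))
    for (f in features) {
      if (any(tbl[[f]][ci] <= 0)) {
        abort(paste0("feature ", f, " has non-positive values; normalisation needs > 0"))
      }
      cm <- mean(tbl[[f]][ctrl])
      if (cm <= 0) abort(paste0("zero control mean for feature ", f))
      tbl[[f]][ci] <- tbl[[f]][ci] / cm
      refs[[length(refs) + 1]] <- tibble(cell_line = cl, feature = f,
                                         control_mean = cm)
    }
  }
  inv <- tibble(cell_line = character(), feature = character(),
                inverted = logical(), reverted = logical(),
                mean_before = numeric(), mean_after = numeric())
  new_norm_features(tbl, list_rbind(refs), inv)
}

#' Conditionally invert features that rise with dose
#'
#' Per feature and cell line, over the treatment (non-control) wells: if
#' the mean normalised value exceeds 1 and the mean of its reciprocals is
#' smaller than that mean, the whole column is replaced by its reciprocal.
#' This aligns feature directionality (all features then fall with
#' increasing impairment) and does not alter relative contributions in the
#' PCA. Control columns, averaging 1, are excluded from the decision so
#' they cannot dilute the trend test.
#'
#' @param m A `norm_features` table from [normalize_to_control()].
#' @return The table with inverted columns and an updated
#'   [inversion_log()].
#' @export
conditional_invert <- function(m) {
  stopifnot(inherits(m, "norm_features"))
  log <- inversion_log(m)
  feats <- unique(control_reference(m)$feature)
  for (cl in unique(m$cell_line)) {
    ci <- m$cell_line == cl
    ti <- ci & m$concentration > 0
    for (f in feats) {
      mu <- mean(m[[f]][ti])
      mu_inv <- mean(1 / m[[f]][ti])
      if (mu > 1 && mu_inv < mu) {
        m[[f]][ci] <- 1 / m[[f]][ci]
        log <- bind_rows(log, tibble(cell_line = cl, feature = f,
                                     inverted = TRUE, reverted = FALSE,
                                     mean_before = mu, mean_after = mu_inv))
      }
    }
  }
  attr(m, "inversion_log") <- log
  m
}

#' Re-check inverted features and revert them if the inversion backfired
#'
#' For each feature flagged as inverted, the treatment-well mean is
#' recomputed on the current data; if it now exceeds the pre-inversion
#' mean (the original data were essentially flat, or edits between the
#' inversion and this re-check changed the picture), the column is
#' restored to its original values and flagged `reverted`.
#'
#' @param m A `norm_features` table with an inversion log.
#' @return The table, possibly with columns reverted.
#' @export
recheck_revert <- function(m) {
  stopifnot(inherits(m, "norm_features"))
  log <- inversion_log(m)
  if (nrow(log) == 0 || !any(log$inverted)) return(m)
  for (i in which(log$inverted)) {
    cl <- log$cell_line[i]; f <- log$feature[i]
    ci <- m$cell_line == cl
    ti <- ci & m$concentration > 0
    mu_now <- mean(m[[f]][ti])
    log$mean_after[i] <- mu_now
    if (mu_now > log$mean_before[i]) {
      m[[f]][ci] <- 1 / m[[f]][ci] # inversion is an involution
      log$inverted[i] <- FALSE
      log$reverted[i] <- TRUE
    }
  }
  attr(m, "inversion_log") <- log
  m
}

#' PCA-derived feature weights at a cumulative-variance threshold
#'
#' Columns are centred (and, by default, scaled to unit variance, since
#' raw morphometric features span orders of magnitude); principal
#' components are taken from the eigendecomposition of the resulting
#' covariance matrix. The smallest number of components `k` whose
#' cumulative explained-variance ratio reaches the threshold is kept, and
#' each feature's raw weight is the loading magnitude averaged over those
#' components, weighted by their explained-variance ratios:
#' `raw_j = sum_i a_i * |c_ij|` for `i = 1..k`. Weights are normalised to
#' sum to 1. The result is invariant to the sign of any component.
#'
#' @param m A `norm_features` table (one cell line; use
#'   [compute_composite_metric()] for multi-line tables), a plain tibble
#'   with feature columns, or a numeric matrix.
#' @param cum_var_threshold Cumulative explained-variance threshold in
#'   (0, 1\] (default 0.90).
#' @param scale Standardise columns to unit variance first (default TRUE).
#' @param include_control Include zero-dose wells as PCA rows (default
#'   FALSE: weights are driven by treatment response variance).
#' @return Object of class `pca_weighting`.
#' @export
pca_feature_weights <- function(m, cum_var_threshold = 0.90, scale = TRUE,
                                include_control = FALSE) {
  if (cum_var_threshold <= 0 || cum_var_threshold > 1) {
    abort("cum_var_threshold must lie in (0, 1]")
  }
  cell_line <- NA_character_
  if (is.matrix(m)) {
    X <- m
  } else {
    feats <- feature_columns(m)
    rows <- if (!include_control && "concentration" %in% names(m)) {
      m$concentration > 0
    } else rep(TRUE, nrow(m))
    if ("cell_line" %in% names(m)) {
      cls <- unique(m$cell_line)
      if (length(cls) > 1) {
        abort("multiple cell lines; compute weights per cell line")
      }
      cell_line <- cls
    }
    X <- as.matrix(m[rows, feats, drop = FALSE])
  }
  if (nrow(X) < 2) abort("need at least 2 rows for PCA")
  if (anyNA(X)) abort("missing values in the feature matrix")
  sds <- apply(X, 2, sd)
  if (all(sds == 0)) abort("zero-variance feature matrix")
  if (scale && any(sds == 0)) {
    abort("zero-variance feature column cannot be standardised")
  }

  if (ncol(X) == 1) {
    a <- 1; rot <- matrix(1, 1, 1, dimnames = list(colnames(X), "PC1"))
    k <- 1L
  } else {
    pc <- prcomp(X, center = TRUE, scale. = scale)
    a <- pc$sdev^2 / sum(pc$sdev^2)
    rot <- pc$rotation
    k <- which(cumsum(a) >= cum_var_threshold - 1e-12)[1]
  }
  raw <- as.numeric(abs(rot[, seq_len(k), drop = FALSE]) %*% a[seq_len(k)])
  names(raw) <- colnames(X) %||% paste0("feature_", seq_along(raw))
  w <- raw / sum(raw)

  structure(
    list(explained_variance_ratios = a,
         loadings = rot, k = as.integer(k),
         cum_var_threshold = cum_var_threshold,
         raw_weights = raw, weights = w,
         features = names(w), n_rows = nrow(X),
         scaled = scale, cell_line = cell_line),
    class = "pca_weighting")
}

#' @export
print.pca_weighting <- function(x, ...) {
  cat(sprintf("PCA feature weighting (%d wells, %d features, k = %d at %.0f%% cum. var.)\n",
              x$n_rows, length(x$weights), x$k, 100 * x$cum_var_threshold))
  print(round(x$weights, 4))
  invisible(x)
}

#' @export
tidy.pca_weighting <- function(x, ...) {
  tibble(cell_line = x$cell_line, feature = x$features,
         weight = unname(x$weights),
         rank = rank(-x$weights, ties.method = "min"))
}

#' @export
glance.pca_weighting <- function(x, ...) {
  tibble(cell_line = x$cell_line, n_features = length(x$weights),
         n_rows = x$n_rows, k = x$k,
         cum_var_threshold = x$cum_var_threshold,
         cum_var_explained = sum(x$explained_variance_ratios[seq_len(x$k)]))
}

#' Composite response metric per well
#'
#' The weighted sum of the processed (normalised, direction-aligned)
#' features: `sigma = sum_j w_j * x_j`. On clean data control wells score
#' exactly 1 because every normalised feature is 1 and the weights sum
#' to 1; increasing treatment impairment drives sigma down.
#'
#' @param m A `norm_features` table (or any tibble whose feature columns
#'   match the weighting).
#' @param w A `pca_weighting`.
#' @return Tibble of well metadata plus `sigma`.
#' @export
composite_metric <- function(m, w) {
  stopifnot(inherits(w, "pca_weighting"))
  if (!all(w$features %in% names(m))) {
    abort("feature sets of the table and the weighting differ")
  }
  extra <- setdiff(feature_columns(as_tibble(m)), w$features)
  if (length(extra) > 0) {
    abort(paste0("table has feature columns unknown to the weighting: ",
                 paste(extra, collapse = ", ")))
  }
  X <- as.matrix(as_tibble(m)[, w$features, drop = FALSE])
  meta <- as_tibble(m)[, intersect(WELL_KEYS, names(m)), drop = FALSE]
  dplyr::bind_cols(meta, tibble(sigma = as.numeric(X %*% w$weights)))
}

#' Full composite-metric pipeline over a raw feature table
#'
#' Per cell line: Dixon Q-test replacement (optional), normalisation to
#' control, conditional inversion with re-check, PCA feature weighting at
#' the requested threshold, and the weighted composite metric.
#'
#' @param tbl Raw feature table (metadata + positive feature columns).
#' @param cum_var_threshold Cumulative-variance threshold for
#'   [pca_feature_weights()].
#' @param qc Apply [dixon_replace()] first (default TRUE).
#' @param scale Standardise features before PCA (default TRUE).
#' @return Tibble of well metadata plus `sigma`; attribute `weighting`
#'   (named list of `pca_weighting` per cell line, see
#'   [metric_weighting()]) and attribute `qc_log`.
#' @export
compute_composite_metric <- function(tbl, cum_var_threshold = 0.90,
                                     qc = TRUE, scale = TRUE) {
  check_well_keys(tbl)
  if (qc) tbl <- dixon_replace(tbl)
  qlog <- attr(tbl, "qc_log")
  out <- list(); ws <- list()
  for (cl in unique(tbl$cell_line)) {
    sub <- tbl[tbl$cell_line == cl, ]
    m <- normalize_to_control(sub) |> conditional_invert() |> recheck_revert()
    w <- pca_feature_weights(m, cum_var_threshold, scale = scale)
    ws[[cl]] <- w
    out[[cl]] <- composite_metric(m, w)
  }
  res <- list_rbind(out)
  attr(res, "weighting") <- ws
  attr(res, "qc_log") <- qlog
  res
}

#' Per-cell-line weightings attached by [compute_composite_metric()]
#' @param metric_tbl Result of [compute_composite_metric()].
#' @return Named list of `pca_weighting` objects.
#' @export
metric_weighting <- function(metric_tbl) {
  attr(metric_tbl, "weighting") %||% abort("no weighting attribute present")
}
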