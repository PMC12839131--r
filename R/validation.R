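# Validation layer: concordance of IC50s across readouts, the
# cumulative-variance-threshold robustness scan, and per-feature weight
# reports. Censored ("greater than") and non-determinable entries never
# enter a correlation; the audit pair list makes that checkable.

parse_ic50_entry <- function(x) {
  x <- trimws(as.character(x))
  if (is.na(x) || x == "" || tolower(x) == "n/a") {
    return(list(kind = "not_determinable", value = NA_real_))
  }
  if (startsWith(x, ">")) {
    return(list(kind = "greater_than", value = as.numeric(sub(">", "", x))))
  }
  list(kind = "definite", value = as.numeric(x))
}

#' Published reference IC50 panel
#'
#' Summary IC50 values (mean and SD over three independent experiments)
#' for four colorectal/pancreatic cancer cell lines (HCT116, LoVo, PANC-1,
#' CFPAC-1) and six cytostatics, under three readouts: the fluorometric
#' proliferation assay, the spheroid area, and the multiparametric
#' composite metric. Entries of the form `">x"` are censored bounds;
#' `"n/a"` marks series for which no four-parameter curve could be fitted.
#' Used to validate readout concordance and ratio computations.
#'
#' @param path CSV path; defaults to the copy shipped with the package.
#' @return Tidy tibble: `cell_line`, `compound`, `readout`
#'   (`proliferative` / `metric` / `area`), `kind`, `value` (nM), `sd`.
#' @export
ic50_reference <- function(path = system.file("extdata", "ic50_reference.csv",
                                              package = "spheromet")) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  long <- list()
  for (ro in c("proliferative", "metric", "area")) {
    parsed <- map(raw[[ro]], parse_ic50_entry)
    long[[ro]] <- tibble(
      cell_line = raw$cell_line, compound = raw$compound, readout = ro,
      kind = vapply(parsed, `[[`, character(1), "kind"),
      value = vapply(parsed, `[[`, numeric(1), "value"),
      sd = suppressWarnings(as.numeric(raw[[paste0(ro, "_sd")]])))
  }
  list_rbind(long)
}

#' Concordance between two IC50 readouts
#'
#' Pearson and Spearman correlation restricted to (cell line, compound)
#' pairs where both readouts are definite; censored bounds are excluded by
#' construction. Requires at least 3 usable pairs.
#'
#' @param tbl Tidy IC50 table (`cell_line`, `compound`, `readout`,
#'   `kind`, `value`), e.g. from [ic50_reference()] or [screen_ic50()].
#' @param readout_a,readout_b Readout labels to compare.
#' @param scale `"linear"` (headline) or `"log10"`.
#' @return List of class `concordance`: `n_pairs`, `pearson_r`,
#'   `pearson_p`, `spearman_rho`, `spearman_p`, `scale`, `pairs` (audit
#'   tibble of the values used).
#' @export
concordance <- function(tbl, readout_a = "metric", readout_b = "proliferative",
                        scale = c("linear", "log10")) {
  scale <- match.arg(scale)
  if (identical(readout_a, readout_b)) abort("readouts must differ")
  wide <- tbl |>
    filter(.data$readout %in% c(readout_a, readout_b), .data$kind == "definite") |>
    select("cell_line", "compound", "readout", "value") |>
    pivot_wider(names_from = "readout", values_from = "value")
  if (!all(c(readout_a, readout_b) %in% names(wide))) {
    abort("fewer than 3 usable (definite/definite) pairs")
  }
  wide <- wide[stats::complete.cases(wide[c(readout_a, readout_b)]), ]
  if (nrow(wide) < 3) abort("fewer than 3 usable (definite/definite) pairs")

  a <- wide[[readout_a]]; b <- wide[[readout_b]]
  if (scale == "log10") { a <- log10(a); b <- log10(b) }
  pe <- cor.test(a, b, method = "pearson")
  sp <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))

  structure(
    list(n_pairs = nrow(wide),
         pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
         spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
         scale = scale, readouts = c(readout_a, readout_b), pairs = wide),
    class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Concordance %s vs %s (%s scale, %d pairs): r = %.3f (p = %.2g), rho = %.3f (p = %.2g)\n",
              x$readouts[1], x$readouts[2], x$scale, x$n_pairs,
              x$pearson_r, x$pearson_p, x$spearman_rho, x$spearman_p))
  invisible(x)
}

#' @export
tidy.concordance <- function(x, ...) {
  tibble(readout_a = x$readouts[1], readout_b = x$readouts[2],
         scale = x$scale, n_pairs = x$n_pairs,
         pearson_r = x$pearson_r, pearson_p = x$pearson_p,
         spearman_rho = x$spearman_rho, spearman_p = x$spearman_p)
}

#' Cumulative-variance-threshold robustness scan
#'
#' Reruns the weighting and dose-response stages at each threshold and
#' cross-correlates the resulting IC50 vectors (definite in every scan)
#' pairwise, and optionally against an external reference readout.
#'
#' @param tbl Raw feature table (as for [compute_composite_metric()]).
#' @param thresholds Cumulative-variance thresholds in (0, 1\].
#' @param reference Optional tidy IC50 table of an independent readout to
#'   correlate each scan against.
#' @param qc,scale Passed to [compute_composite_metric()].
#' @return List of class `robustness_scan`: `tables` (named list of
#'   [screen_ic50()] tables per threshold), `correlations` (tibble of
#'   pairwise Pearson/Spearman between thresholds), `vs_reference`
#'   (tibble or NULL).
#' @export
robustness_scan <- function(tbl, thresholds = c(0.80, 0.90, 0.95),
                            reference = NULL, qc = TRUE, scale = TRUE) {
  if (any(thresholds <= 0 | thresholds > 1)) {
    abort("thresholds must lie in (0, 1]")
  }
  thresholds <- sort(unique(thresholds))
  tables <- lapply(setNames(thresholds, sprintf("%.2f", thresholds)), function(th) {
    compute_composite_metric(tbl, cum_var_threshold = th, qc = qc, scale = scale) |>
      screen_ic50(response = "sigma", readout = sprintf("metric@%.2f", th))
  })

  cors <- list()
  if (length(thresholds) > 1) {
    combos <- utils::combn(names(tables), 2)
    for (j in seq_len(ncol(combos))) {
      na <- combos[1, j]; nb <- combos[2, j]
      a <- tables[[na]]; b <- tables[[nb]]
      m <- dplyr::inner_join(
        a |> filter(.data$kind == "definite") |> select("cell_line", "compound", a = "value"),
        b |> filter(.data$kind == "definite") |> select("cell_line", "compound", b = "value"),
        by = c("cell_line", "compound"))
      if (nrow(m) >= 3) {
        cors[[j]] <- tibble(
          threshold_a = na, threshold_b = nb, n_pairs = nrow(m),
          pearson_r = cor(m$a, m$b),
          spearman_rho = cor(m$a, m$b, method = "spearman"))
      }
    }
  }

  vs_ref <- NULL
  if (!is.null(reference)) {
    vs_ref <- list_rbind(imap(tables, function(t, nm) {
      joint <- bind_rows(
        t |> mutate(readout = "metric"),
        reference)
      cc <- tryCatch(concordance(joint, "metric", unique(reference$readout)),
                     error = function(e) NULL)
      if (is.null(cc)) return(tibble())
      tidy(cc) |> mutate(threshold = nm, .before = 1)
    }))
  }

  structure(list(tables = tables,
                 correlations = if (length(cors)) list_rbind(cors) else tibble(),
                 vs_reference = vs_ref),
            class = "robustness_scan")
}

#' @export
print.robustness_scan <- function(x, ...) {
  cat("Robustness scan over cumulative-variance thresholds:",
      paste(names(x$tables), collapse = ", "), "\n")
  if (nrow(x$correlations)) print(x$correlations)
  invisible(x)
}

#' Tidy report of per-cell-line feature weights
#'
#' @param weights A `pca_weighting`, or a (possibly named) list of them —
#'   e.g. [metric_weighting()] output.
#' @return Tibble: `cell_line`, `feature`, `weight`, `rank`; attribute
#'   `ranges` holds the cross-line min-max weight range per feature.
#' @export
weight_report <- function(weights) {
  if (inherits(weights, "pca_weighting")) weights <- list(weights)
  rows <- imap(weights, function(w, nm) {
    t <- tidy(w)
    if (is.na(t$cell_line[1]) && is.character(nm) && nzchar(nm)) t$cell_line <- nm
    t
  })
  out <- list_rbind(rows)
  ranges <- out |>
    group_by(.data$feature) |>
    summarise(min_weight = min(.data$weight), max_weight = max(.data$weight),
              .groups = "drop")
  attr(out, "ranges") <- ranges
  out
}

#' Compute the relation (ratio) column between two readouts of an IC50 table
#'
#' For every (cell line, compound) row, forms the [ic50_ratio()] of
#' `readout_a` over `readout_b`, reproducing the "relation" columns of a
#' screening summary table.
#'
#' @param tbl Tidy IC50 table.
#' @param readout_a,readout_b Numerator and denominator readouts.
#' @return Tibble: `cell_line`, `compound`, `kind`, `ratio`, `label`.
#' @export
ic50_relations <- function(tbl, readout_a = "metric", readout_b = "proliferative") {
  keys <- distinct(tbl, .data$cell_line, .data$compound)
  rows <- map(seq_len(nrow(keys)), function(i) {
    pick <- function(ro) {
      r <- tbl[tbl$cell_line == keys$cell_line[i] & tbl$compound == keys$compound[i] &
                 tbl$readout == ro, ]
      if (nrow(r) != 1) return(NULL)
      structure(list(kind = r$kind, value = r$value, reason = NA_character_),
                class = "censored_ic50")
    }
    a <- pick(readout_a); b <- pick(readout_b)
    if (is.null(a) || is.null(b)) return(NULL)
    rr <- ic50_ratio(a, b)
    tibble(cell_line = keys$cell_line[i], compound = keys$compound[i],
           kind = rr$kind, ratio = rr$value, label = format(rr))
  })
  list_rbind(rows)
}
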