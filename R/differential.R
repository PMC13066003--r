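#' Construct a phosphosite abundance matrix
#'
#' Container for site-by-sample log-abundances with a two-group design
#' (`altered` vs `wildtype`). Missing measurements are `NA`.
#'
#' @param values numeric matrix, sites in rows, samples in columns; row and
#'   column names are the site and sample identifiers.
#' @param group_labels character vector (one per column) with values
#'   `"altered"` or `"wildtype"`.
#' @return an object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, group_labels) {
  if (!is.matrix(values) || !is.numeric(values))
    abort("'values' must be a numeric matrix")
  if (length(group_labels) != ncol(values))
    abort("one group label per sample column is required")
  group_labels <- as.character(group_labels)
  bad <- setdiff(unique(group_labels), c("altered", "wildtype"))
  if (length(bad))
    abort("group labels must be 'altered' or 'wildtype'; found: ",
          paste(bad, collapse = ", "))
  if (length(unique(group_labels)) < 2L)
    abort("both groups ('altered' and 'wildtype') must be non-empty")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("site", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample", seq_len(ncol(values)))
  structure(list(values = values, group_labels = group_labels),
            class = "abundance_matrix")
}

#' Read an abundance matrix and its sample grouping from CSV
#'
#' @param matrix_csv CSV with the site identifier in the first column and
#'   one column per sample (header = sample ids); empty cells are missing.
#' @param groups_csv two-column CSV (`sample_id`, `group`) mapping each
#'   sample to `altered` or `wildtype`.
#' @return an `abundance_matrix`.
#' @export
read_abundance_matrix <- function(matrix_csv, groups_csv) {
  m <- utils::read.csv(matrix_csv, check.names = FALSE,
                       stringsAsFactors = FALSE)
  vals <- as.matrix(m[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(m[[1L]])
  g <- utils::read.csv(groups_csv, stringsAsFactors = FALSE)
  if (ncol(g) < 2L) abort("groups CSV must have two columns: sample_id, group")
  grp <- g[[2L]][match(colnames(vals), as.character(g[[1L]]))]
  if (anyNA(grp))
    abort("samples missing from groups CSV: ",
          paste(colnames(vals)[is.na(grp)], collapse = ", "))
  abundance_matrix(vals, grp)
}

# two-sided Wilcoxon rank-sum p-value: exact when the pooled sample is
# small and tie-free, tie-corrected normal approximation otherwise
wilcoxon_p <- function(a, w, exact_max_n = 25L) {
  n <- length(a) + length(w)
  has_ties <- anyDuplicated(c(a, w)) > 0L
  use_exact <- n <= exact_max_n && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, w, alternative = "two.sided",
                       exact = use_exact, correct = FALSE))
  min(1, wt$p.value)
}

#' Differential phosphosite analysis (Wilcoxon rank-sum + BH)
#'
#' For each site with at least `min_per_group` non-missing values in both
#' groups, computes a two-sided Wilcoxon rank-sum p-value (exact when the
#' pooled non-missing n is at most 25 and tie-free; tie-corrected normal
#' approximation otherwise), a median-based log fold change
#' (altered minus wildtype), and Benjamini-Hochberg q-values across the
#' tested sites only. Sites failing the minimum-observations rule are
#' returned untested (`tested = FALSE`, `NA` p/q) rather than given a
#' fabricated p-value.
#'
#' @param matrix an [abundance_matrix()].
#' @param min_per_group minimum non-missing observations required per group
#'   for a site to enter the test family (default 3).
#' @return a data frame of class `differential_results` with columns
#'   `site_id`, `log_fold_change`, `p_value`, `q_value`, `n_altered`,
#'   `n_wildtype`, `tested`.
#' @export
wilcoxon_differential <- function(matrix, min_per_group = 3L) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  vals <- matrix$values
  is_alt <- matrix$group_labels == "altered"
  if (!any(is_alt) || all(is_alt))
    abort("need both an 'altered' and a 'wildtype' group")

  n <- nrow(vals)
  lfc <- p <- rep(NA_real_, n)
  na_ <- nw_ <- integer(n)
  for (i in seq_len(n)) {
    a <- vals[i, is_alt]; a <- a[!is.na(a)]
    w <- vals[i, !is_alt]; w <- w[!is.na(w)]
    na_[i] <- length(a); nw_[i] <- length(w)
    if (length(a) >= 1L && length(w) >= 1L)
      lfc[i] <- stats::median(a) - stats::median(w)
    if (length(a) >= min_per_group && length(w) >= min_per_group)
      p[i] <- wilcoxon_p(a, w)
  }
  tested <- !is.na(p)
  q <- rep(NA_real_, n)
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  out <- data.frame(
    site_id = rownames(vals), log_fold_change = lfc,
    p_value = p, q_value = q,
    n_altered = na_, n_wildtype = nw_, tested = tested,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("differential_results", "data.frame")
  out
}

#' Volcano table of differential results
#'
#' Restricts to tested sites and annotates each with `-log10(p)` and a
#' significance flag (`q < fdr_threshold`). Rows are ordered by q-value
#' (ascending) then absolute log fold change (descending) then site id,
#' so the ordering is deterministic.
#'
#' @param results output of [wilcoxon_differential()].
#' @param fdr_threshold FDR cutoff for flagging (default 0.05).
#' @return a data frame with columns `site_id`, `log_fold_change`,
#'   `neg_log10_p`, `q_value`, `significant`.
#' @export
volcano_table <- function(results, fdr_threshold = 0.05) {
  stopifnot(inherits(results, "differential_results"))
  r <- results[results$tested, , drop = FALSE]
  out <- data.frame(
    site_id = r$site_id,
    log_fold_change = r$log_fold_change,
    neg_log10_p = -log10(r$p_value),
    q_value = r$q_value,
    significant = r$q_value < fdr_threshold,
    stringsAsFactors = FALSE)
  out <- out[order(out$q_value, -abs(out$log_fold_change), out$site_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
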