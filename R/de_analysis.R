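#' Construct a two-group expression matrix
#'
#' Container for a miRNA x sample expression matrix with a two-level group
#' labelling (treatment responders vs non-responders) and a scale tag.
#'
#' @param values Numeric matrix, miRNAs in rows (rownames = normalized
#'   miRNA IDs), samples in columns (colnames = sample IDs).
#' @param groups Named character vector or factor mapping every sample ID
#'   to `"responder"` or `"non_responder"`.
#' @param scale `"log2"` (default; normalized array convention) or
#'   `"linear"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, groups, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  groups <- vapply(groups, as.character, character(1))
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing) > 0L) {
    stop(sprintf("sample(s) without a group label: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  groups <- groups[colnames(values)]
  if (!all(groups %in% c("responder", "non_responder"))) {
    stop("group labels must be 'responder' or 'non_responder'", call. = FALSE)
  }
  n_per <- table(factor(groups, levels = c("responder", "non_responder")))
  if (any(n_per < 2L)) {
    stop("each group needs at least 2 samples (two-sample t undefined otherwise)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicated miRNA row IDs; collapse probes first (see read_expression)",
         call. = FALSE)
  }
  structure(list(values = values, groups = groups, scale = scale),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  n <- table(x$groups)
  cat(sprintf("Expression matrix (%s scale): %d miRNAs x %d samples (%d responders / %d non-responders)\n",
              x$scale, nrow(x$values), ncol(x$values),
              n[["responder"]], n[["non_responder"]]))
  invisible(x)
}

#' Read an expression matrix and its sample grouping from TSV files
#'
#' The matrix file is series-matrix-like: first column = row IDs, header =
#' sample IDs. The group file has two columns, sample ID and group
#' (`responder` / `non_responder`). Rows containing any missing value are
#' dropped with a counted warning; duplicate row IDs (multiple probes per
#' miRNA) are collapsed by the per-sample mean.
#'
#' @param path Path to the expression TSV.
#' @param group_file Path to the two-column group TSV.
#' @param scale `"log2"` or `"linear"`.
#' @param alias_table Optional miRNA alias table applied to row IDs.
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path, group_file, scale = c("log2", "linear"),
                            alias_table = NULL) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  ids <- normalize_mirna_id(as.character(df[[1L]]), alias_table)
  values <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids

  complete <- stats::complete.cases(values)
  if (any(!complete)) {
    warning(sprintf("dropped %d row(s) with missing values", sum(!complete)),
            call. = FALSE)
    values <- values[complete, , drop = FALSE]
  }
  if (anyDuplicated(rownames(values))) {
    values <- rowsum(values, group = rownames(values)) /
      as.vector(table(rownames(values))[sort(unique(rownames(values)))])
  }

  grp <- utils::read.delim(group_file, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  groups <- stats::setNames(as.character(grp[[2L]]), as.character(grp[[1L]]))
  expression_matrix(values, groups, scale)
}

#' Two-sample t-test p-value
#'
#' Two-sided p-value comparing two independent samples. The `student`
#' variant uses the classical pooled-variance statistic with
#' `nA + nB - 2` degrees of freedom; `welch` does not pool. Degenerate
#' inputs follow fixed conventions so a genome-wide scan never aborts:
#' both groups constant and equal gives p = 1 (zero effect), both
#' constant but different gives the p = 0 limit (flagged by callers in a
#' QC column).
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2, no NAs.
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return Two-sided p-value; symmetric in the group order.
#' @export
two_sample_t <- function(values_a, values_b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (anyNA(values_a) || anyNA(values_b)) {
    stop("NA values in t-test input", call. = FALSE)
  }
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  const_a <- stats::var(values_a) == 0
  const_b <- stats::var(values_b) == 0
  if (const_a && const_b) {
    return(if (values_a[1L] == values_b[1L]) 1 else 0)
  }
  stats::t.test(values_a, values_b,
                var.equal = (variant == "student"))$p.value
}

#' Fold change between two group means
#'
#' By convention group a = responders. On log2-scale input the log2 fold
#' change is the difference of means and the linear fold change is its
#' antilog; on linear input the fold change is the ratio of means (which
#' must be strictly positive).
#'
#' @param mean_a,mean_b Group mean expression values.
#' @param scale `"log2"` or `"linear"`.
#' @return List with `fold_change` (positive linear ratio) and `log2_fc`.
#' @export
fold_change <- function(mean_a, mean_b, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (scale == "log2") {
    lfc <- mean_a - mean_b
    list(fold_change = 2^lfc, log2_fc = lfc)
  } else {
    if (any(c(mean_a, mean_b) <= 0)) {
      stop("linear-scale fold change needs strictly positive means; supply log2 data instead",
           call. = FALSE)
    }
    fc <- mean_a / mean_b
    list(fold_change = fc, log2_fc = log2(fc))
  }
}

#' Differential-expression selection between responders and non-responders
#'
#' One two-sample t-test and fold change per miRNA. A miRNA is selected
#' when `p_value < p_threshold` AND `|log2_fc| > log2(fc_threshold)` — raw
#' p-values, as is conventional for this screen; Benjamini-Hochberg FDR is
#' reported alongside but not used for selection.
#'
#' @param expr An `expression_matrix`.
#' @param p_threshold Raw p-value cutoff (default 0.05).
#' @param fc_threshold Linear fold-change cutoff (default 2, i.e.
#'   |log2FC| > 1).
#' @param variant t-test variant, see [two_sample_t()].
#' @return Data frame (one row per miRNA, sorted p ascending then ID):
#'   `mirna_id`, `mean_responder`, `mean_nonresponder`, `fold_change`,
#'   `log2_fc`, `p_value`, `bh_fdr`, `selected`, `qc_degenerate` (TRUE
#'   where both groups were constant but unequal, the p = 0 limit).
#' @export
select_de <- function(expr, p_threshold = 0.05, fc_threshold = 2,
                      variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stopifnot(inherits(expr, "expression_matrix"))
  a_cols <- names(expr$groups)[expr$groups == "responder"]
  b_cols <- names(expr$groups)[expr$groups == "non_responder"]
  va <- expr$values[, a_cols, drop = FALSE]
  vb <- expr$values[, b_cols, drop = FALSE]
  mean_a <- rowMeans(va)
  mean_b <- rowMeans(vb)
  p <- vapply(seq_len(nrow(expr$values)), function(i) {
    two_sample_t(va[i, ], vb[i, ], variant)
  }, numeric(1))
  degenerate <- vapply(seq_len(nrow(expr$values)), function(i) {
    stats::var(va[i, ]) == 0 && stats::var(vb[i, ]) == 0 && mean_a[i] != mean_b[i]
  }, logical(1))
  fc <- fold_change(mean_a, mean_b, expr$scale)
  out <- data.frame(
    mirna_id = rownames(expr$values),
    mean_responder = unname(mean_a),
    mean_nonresponder = unname(mean_b),
    fold_change = unname(fc$fold_change),
    log2_fc = unname(fc$log2_fc),
    p_value = p,
    bh_fdr = stats::p.adjust(p, method = "BH"),
    qc_degenerate = degenerate,
    stringsAsFactors = FALSE
  )
  out$selected <- out$p_value < p_threshold & abs(out$log2_fc) > log2(fc_threshold)
  out <- out[order(out$p_value, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "thresholds") <- list(p_threshold = p_threshold,
                                  fc_threshold = fc_threshold,
                                  variant = variant)
  out
}
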