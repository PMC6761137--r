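#' Read a qPCR cycle-threshold table
#'
#' Expects a CSV with columns `sample_id`, `condition`, `gene`, `ct` (one row
#' per replicate well; an optional `replicate` column is ignored). Ct values
#' must be finite and positive.
#'
#' @param path CSV path.
#' @return A validated data frame of class `ct_table`.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop_tj("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ct_table(df)
}

#' Validate a Ct table
#'
#' @param df data frame with columns `sample_id`, `condition`, `gene`, `ct`.
#' @return `df` with class `c("ct_table", "data.frame")`.
#' @export
ct_table <- function(df) {
  need <- c("sample_id", "condition", "gene", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_tj("Ct table lacks column(s): %s", paste(miss, collapse = ", "))
  if (!is.numeric(df$ct) || any(!is.finite(df$ct)) || any(df$ct <= 0)) {
    stop_tj("Ct values must be finite and positive")
  }
  class(df) <- unique(c("ct_table", class(df)))
  df
}

#' Per-sample delta-Ct
#'
#' `delta Ct = mean Ct(target) - mean Ct(reference)` over the replicate wells
#' of one sample. Normalizing to the reference gene (actin) cancels loading
#' differences between samples.
#'
#' @param table a `ct_table` (or data frame with its columns).
#' @param sample_id sample to evaluate.
#' @param gene target gene.
#' @param reference_gene reference gene label (default `"Actin"`).
#' @return The delta-Ct value, with attributes `target_mean`, `target_sd`,
#'   `reference_mean`, `reference_sd` (replicate mean and SD).
#' @export
delta_ct <- function(table, sample_id, gene, reference_gene = "Actin") {
  table <- ct_table(as.data.frame(table))
  tgt <- table$ct[table$sample_id == sample_id & table$gene == gene]
  ref <- table$ct[table$sample_id == sample_id & table$gene == reference_gene]
  if (!length(tgt)) stop_tj("sample '%s' has no Ct for gene '%s'", sample_id, gene)
  if (!length(ref)) {
    stop_tj("sample '%s' has no Ct for reference gene '%s'", sample_id, reference_gene)
  }
  structure(mean(tgt) - mean(ref),
            target_mean = mean(tgt), target_sd = stats::sd(tgt),
            reference_mean = mean(ref), reference_sd = stats::sd(ref))
}

#' Relative expression from delta-Ct values
#'
#' The comparative method: `relative expression = 2^-(sample dCt - control dCt)`.
#'
#' @param sample_dct delta-Ct of the sample.
#' @param control_dct delta-Ct of the control.
#' @return The fold change, a positive number.
#' @export
relative_expression <- function(sample_dct, control_dct) {
  if (!is.finite(sample_dct) || !is.finite(control_dct)) stop_tj("inputs must be finite")
  2^-(sample_dct - control_dct)
}

#' Relative-expression report for a Ct table
#'
#' For every gene and sample, computes the per-sample delta-Ct (mean target Ct
#' minus mean reference Ct over replicate wells) and the fold change relative
#' to the control condition. The control delta-Ct of a gene is the mean of the
#' per-sample delta-Ct values over all samples of the control condition, so
#' results are expressed per treatment group. Genes are reported in their
#' input order; the reference gene itself is included and is exactly 1 for
#' control-condition samples by construction.
#'
#' @param table a `ct_table` (or data frame with its columns).
#' @param control_condition condition label of the untreated control.
#' @param reference_gene reference gene label (default `"Actin"`).
#' @return A data frame of class `tj_expression` with columns `gene`,
#'   `sample_id`, `condition`, `delta_ct`, `ct_sd` (replicate SD of the target
#'   gene) and `relative_expression`.
#' @export
expression_report <- function(table, control_condition = "control",
                              reference_gene = "Actin") {
  table <- ct_table(as.data.frame(table))
  if (!any(table$condition == control_condition)) {
    stop_tj("no rows with control condition '%s'", control_condition)
  }
  genes <- unique(table$gene)
  samples <- unique(table[, c("sample_id", "condition")])
  out <- list()
  for (g in genes) {
    dct <- vapply(samples$sample_id, function(s) {
      as.numeric(delta_ct(table, s, g, reference_gene))
    }, 0)
    sds <- vapply(samples$sample_id, function(s) {
      tgt <- table$ct[table$sample_id == s & table$gene == g]
      if (length(tgt) > 1L) stats::sd(tgt) else NA_real_
    }, 0)
    control_dct <- mean(dct[samples$condition == control_condition])
    out[[g]] <- data.frame(
      gene = g,
      sample_id = samples$sample_id,
      condition = samples$condition,
      delta_ct = dct,
      ct_sd = sds,
      relative_expression = 2^-(dct - control_dct)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("tj_expression", "data.frame")
  res
}

#' @export
print.tj_expression <- function(x, digits = 4, ...) {
  cat("Relative expression (comparative 2^-ddCt method)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
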