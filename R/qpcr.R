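#' Aggregate replicate Ct values
#'
#' Arithmetic mean of the finite replicates; rows with missing replicates
#' are usable but flagged through the `n_used` attribute.
#'
#' @param cts numeric vector of replicate Ct values (normally 3).
#' @return mean Ct with attribute `n_used` (finite replicates averaged).
#' @export
aggregate_replicates <- function(cts) {
  ok <- is.finite(cts)
  if (!any(ok)) stop("no finite Ct replicate")
  structure(mean(cts[ok]), n_used = sum(ok))
}

#' Delta-Ct: target minus reference Ct
#'
#' `dCt = Ct(target) - Ct(reference)`; a larger target Ct (later
#' amplification) gives a larger dCt and hence lower expression.
#'
#' @param target_ct,reference_ct finite Ct values (cycles).
#' @return dCt in cycles.
#' @export
delta_ct <- function(target_ct, reference_ct) {
  if (!all(is.finite(target_ct)) || !all(is.finite(reference_ct))) {
    stop("non-finite Ct value")
  }
  target_ct - reference_ct
}

#' Relative expression level 2^-dCt
#'
#' @param dct delta-Ct value(s).
#' @return expression on the `2^-dCt` scale (positive).
#' @export
expression_level <- function(dct) 2^(-dct)

#' Group fold change of mean expression
#'
#' `fold = mean(tumor) / mean(control)` on the `2^-dCt` expression scale,
#' with group means and standard errors.
#'
#' @param tumor_expressions,control_expressions positive expression vectors.
#' @return list: `fold`, `mean_tumor`, `mean_control`, `se_tumor`,
#'   `se_control`.
#' @export
group_fold <- function(tumor_expressions, control_expressions) {
  stopifnot(length(tumor_expressions) >= 1, length(control_expressions) >= 1)
  mc <- mean(control_expressions)
  if (mc == 0) stop("zero control mean expression")
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  list(fold = mean(tumor_expressions) / mc,
       mean_tumor = mean(tumor_expressions), mean_control = mc,
       se_tumor = se(tumor_expressions), se_control = se(control_expressions))
}

#' Independent-samples comparison of two expression groups
#'
#' Two-sided t-test on the expression values (Welch by default; set
#' `var.equal = TRUE` for the classical equal-variance test).
#'
#' @param tumor_expressions,control_expressions expression vectors, each of
#'   length >= 2.
#' @param var.equal assume equal variances?
#' @return list: `t` (statistic), `p` (two-sided p-value), `df`.
#' @export
group_compare <- function(tumor_expressions, control_expressions,
                          var.equal = FALSE) {
  if (length(tumor_expressions) < 2 || length(control_expressions) < 2) {
    stop("each group needs at least 2 samples")
  }
  if (sd(tumor_expressions) == 0 && sd(control_expressions) == 0) {
    # degenerate (noise-free) data: t is 0 when the means agree, infinite otherwise
    eq <- mean(tumor_expressions) == mean(control_expressions)
    return(list(t = if (eq) 0 else Inf * sign(mean(tumor_expressions) -
                                              mean(control_expressions)),
                p = if (eq) 1 else 0, df = NA_real_))
  }
  ht <- t.test(tumor_expressions, control_expressions, var.equal = var.equal)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Full relative-quantification analysis of a qPCR Ct table
#'
#' Per sample: replicate Cts are averaged for the target and the reference
#' gene, dCt and `2^-dCt` expression computed; per gene: tumor/control fold
#' change and the independent-samples test.
#'
#' @param table a [simulate_qpcr()]-style table (`sample_id`, `group`,
#'   `gene`, `ct_rep1..3`, `ref_ct_rep1..3`).
#' @param genes genes to analyse (default: all in the table).
#' @param var.equal see [group_compare()].
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return list: `samples` (per-sample `delta_ct` and `expression`) and
#'   `genes` (per-gene `fold`, group means/SEs, `t`, `p`, `significant`).
#' @export
qpcr_analyze <- function(table, genes = NULL, var.equal = FALSE, alpha = 0.05) {
  stopifnot(all(c("sample_id", "group", "gene") %in% names(table)))
  genes <- genes %||% unique(table$gene)
  ct_cols <- grep("^ct_rep", names(table), value = TRUE)
  ref_cols <- grep("^ref_ct_rep", names(table), value = TRUE)
  stopifnot(length(ct_cols) >= 1, length(ref_cols) >= 1)

  tab <- table[table$gene %in% genes, , drop = FALSE]
  tab$target_ct <- apply(tab[ct_cols], 1, function(r) aggregate_replicates(as.numeric(r)))
  tab$reference_ct <- apply(tab[ref_cols], 1, function(r) aggregate_replicates(as.numeric(r)))
  tab$delta_ct <- delta_ct(tab$target_ct, tab$reference_ct)
  tab$expression <- expression_level(tab$delta_ct)

  per_gene <- lapply(split(tab, tab$gene), function(g) {
    tu <- g$expression[g$group == "tumor"]
    co <- g$expression[g$group == "control"]
    f <- group_fold(tu, co)
    cmp <- if (length(tu) >= 2 && length(co) >= 2) {
      group_compare(tu, co, var.equal = var.equal)
    } else list(t = NA_real_, p = NA_real_, df = NA_real_)
    data.frame(gene = g$gene[1], n_tumor = length(tu), n_control = length(co),
               mean_tumor = f$mean_tumor, se_tumor = f$se_tumor,
               mean_control = f$mean_control, se_control = f$se_control,
               fold = f$fold, t = cmp$t, p = cmp$p,
               significant = is.finite(cmp$p) && cmp$p < alpha,
               stringsAsFactors = FALSE)
  })
  genes_df <- do.call(rbind, per_gene)
  rownames(genes_df) <- NULL
  list(samples = tab[, c("sample_id", "group", "gene", "target_ct",
                         "reference_ct", "delta_ct", "expression")],
       genes = genes_df)
}
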