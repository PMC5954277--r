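#' Select differentially expressed genes (DEGs) for a condition
#'
#' Genes with `p_value < alpha` (strict) and `|log2_fc| >= min_abs_log2fc`
#' (inclusive), i.e. both induced and repressed genes qualify.
#'
#' @param m An [expression_matrix()].
#' @param design A `condition_design`.
#' @param condition_id Condition to test.
#' @param alpha P-value threshold (default 0.01).
#' @param min_abs_log2fc Absolute log2 fold-change threshold
#'   (default `log2(1.5)`).
#' @param gene_ids Genes to consider (default: all rows of `m`).
#' @return Character vector of DEG gene ids.
#' @export
select_degs <- function(m, design, condition_id, alpha = 0.01,
                        min_abs_log2fc = log2(1.5), gene_ids = rownames(m)) {
  r <- suppressWarnings(test_differential(m, design, condition_id, gene_ids))
  r$gene_id[r$p_value < alpha & abs(r$log2_fc) >= min_abs_log2fc]
}

#' Pearson correlation with degenerate-input handling
#'
#' Standard product-moment correlation; a constant vector makes the
#' coefficient undefined and returns NA (callers treat NA as
#' non-correlated).
#'
#' @param u,v Equal-length numeric vectors (length >= 3).
#' @return Correlation in \[-1, 1\], or NA if either vector is constant.
#' @export
pearson_cor <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  if (length(u) < 3) stop("need >=3 paired observations")
  if (stats::sd(u) == 0 || stats::sd(v) == 0) return(NA_real_)
  stats::cor(u, v, method = "pearson")
}

#' Build the co-expressed gene group of a CsTF
#'
#' Members are the condition's DEGs whose Pearson correlation with the
#' CsTF, computed over ALL samples of the CsTF's dataset (not just the
#' condition's treatment/control arrays), is `>= min_pcc`. DEGs with
#' constant expression are excluded (undefined correlation). The CsTF
#' itself is excluded from its own member list unless `include_self`.
#' A group smaller than `min_size` is flagged `discarded` and skipped by
#' downstream enrichment.
#'
#' @param cstf_id TF gene id.
#' @param condition_id Condition in which the TF is condition-specific.
#' @param degs Character vector of DEG ids for the condition.
#' @param m An [expression_matrix()].
#' @param design A `condition_design`.
#' @param min_pcc Correlation threshold (default 0.8, inclusive).
#' @param include_self Keep the CsTF in its own group (default FALSE).
#' @param min_size Minimum member count to proceed (default 10).
#' @return A `coexpression_group` list: `cstf_id`, `condition_id`,
#'   `dataset`, `members`, `pcc` (named vector), `discarded`.
#' @export
build_group <- function(cstf_id, condition_id, degs, m, design,
                        min_pcc = 0.8, include_self = FALSE, min_size = 10) {
  if (!cstf_id %in% rownames(m)) stop("CsTF '", cstf_id, "' absent from matrix")
  cc <- design$conditions[[condition_id]]
  if (is.null(cc)) stop("unknown condition: ", condition_id)
  samples <- design$datasets[[cc$dataset]]
  if (!include_self) degs <- setdiff(degs, cstf_id)
  degs <- intersect(degs, rownames(m))
  if (length(degs) == 0) {
    warning("empty DEG list for CsTF '", cstf_id, "' in '", condition_id, "'")
    pcc <- stats::setNames(numeric(0), character(0))
    members <- character(0)
  } else {
    tf_row <- m[cstf_id, samples]
    if (stats::sd(tf_row) == 0) stop("CsTF '", cstf_id, "' has constant expression")
    sub <- m[degs, samples, drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    pcc <- rep(NA_real_, length(degs))
    names(pcc) <- degs
    ok <- sds > 0
    if (any(ok)) {
      pcc[ok] <- as.vector(stats::cor(t(sub[ok, , drop = FALSE]), tf_row))
    }
    members <- degs[!is.na(pcc) & pcc >= min_pcc]
    pcc <- pcc[members]
  }
  structure(list(cstf_id = cstf_id, condition_id = condition_id,
                 dataset = cc$dataset, members = members, pcc = pcc,
                 discarded = length(members) < min_size),
            class = "coexpression_group")
}
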