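#' Differential expression test for one condition
#'
#' Two-sided Welch (unequal-variance) t-test of treatment versus control
#' for each gene, with the log2 fold change taken as the difference of
#' group means on the log2 scale. If both groups have zero variance the
#' t-test is degenerate; the p-value is then set to 0 when the means
#' differ and 1 when they are equal, with a warning.
#'
#' @param m An [expression_matrix()].
#' @param design A `condition_design`.
#' @param condition_id Condition to test.
#' @param gene_ids Genes to test (default: all rows of `m`).
#' @return A data.frame with columns `gene_id`, `p_value`, `log2_fc`.
#' @export
test_differential <- function(m, design, condition_id, gene_ids = rownames(m)) {
  cc <- design$conditions[[condition_id]]
  if (is.null(cc)) stop("unknown condition: ", condition_id)
  if (length(cc$treatment) < 2) stop("treatment group of '", condition_id, "' has <2 replicates")
  if (length(cc$control) < 2) stop("control group of '", condition_id, "' has <2 replicates")
  missing <- setdiff(gene_ids, rownames(m))
  if (length(missing) > 0) {
    stop("genes absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  tr <- m[gene_ids, cc$treatment, drop = FALSE]
  ct <- m[gene_ids, cc$control, drop = FALSE]
  lfc <- rowMeans(tr) - rowMeans(ct)
  vt <- apply(tr, 1, stats::var)
  vc <- apply(ct, 1, stats::var)
  pv <- numeric(length(gene_ids))
  degenerate <- vt == 0 & vc == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " gene(s) constant within both groups; p set to 0/1 by mean equality")
    pv[degenerate] <- ifelse(lfc[degenerate] == 0, 1, 0)
  }
  for (i in which(!degenerate)) {
    pv[i] <- stats::t.test(tr[i, ], ct[i, ])$p.value
  }
  data.frame(gene_id = gene_ids, p_value = pv, log2_fc = unname(lfc),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select differentially expressed TFs (DETFs)
#'
#' Keeps genes with `p_value < alpha` and `log2_fc > min_log2fc` (strict
#' inequalities; induced TFs only). With `two_sided_fc = TRUE` the fold
#' change criterion becomes `|log2_fc| > min_log2fc`.
#'
#' @param results Output of [test_differential()].
#' @param alpha P-value threshold (default 0.01).
#' @param min_log2fc Log2 fold-change threshold (default 1).
#' @param two_sided_fc Admit repressed TFs as well (default FALSE).
#' @return The selected rows of `results`.
#' @export
select_detfs <- function(results, alpha = 0.01, min_log2fc = 1.0,
                         two_sided_fc = FALSE) {
  fc_ok <- if (two_sided_fc) abs(results$log2_fc) > min_log2fc else results$log2_fc > min_log2fc
  out <- results[results$p_value < alpha & fc_ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-condition z-score of fold change
#'
#' For one TF within one dataset: z = (x - mu) / sigma, where x is the
#' fold change in the target condition and mu, sigma are the mean and
#' sample (n-1) standard deviation of the TF's fold changes over all
#' conditions of that dataset. With sigma = 0 the z-score is undefined
#' and reported as NA.
#'
#' @param fold_changes Named numeric vector: condition id -> fold change,
#'   covering all conditions of one dataset.
#' @param target Condition id to score.
#' @return A list with `condition_id`, `x`, `mu`, `sigma`, `z` (NA when
#'   sigma is 0).
#' @export
condition_zscore <- function(fold_changes, target) {
  if (length(fold_changes) < 2) stop("need >=2 conditions in the dataset")
  if (!target %in% names(fold_changes)) stop("target condition not in fold_changes")
  x <- fold_changes[[target]]
  mu <- mean(fold_changes)
  sigma <- stats::sd(fold_changes)
  z <- if (sigma == 0) NA_real_ else (x - mu) / sigma
  list(condition_id = target, x = x, mu = mu, sigma = sigma, z = z)
}

#' Promote DETFs to condition-specific TFs (CsTFs)
#'
#' A DETF becomes a CsTF in its condition when the cross-condition
#' z-score of its fold change exceeds `z_threshold` (strictly). DETFs
#' with undefined (NA) z are excluded. A TF may be a CsTF in more than
#' one condition.
#'
#' @param detfs data.frame with columns `tf_id`, `condition_id`,
#'   `p_value`, `log2_fc`.
#' @param zscores data.frame with columns `tf_id`, `condition_id`, `z`.
#' @param z_threshold z-score cut-off (default 2, strict).
#' @return The CsTF records: `tf_id`, `condition_id`, `p_value`,
#'   `log2_fc`, `z`.
#' @export
select_cstfs <- function(detfs, zscores, z_threshold = 2.0) {
  key <- function(df) paste(df$tf_id, df$condition_id, sep = "\r")
  idx <- match(key(detfs), key(zscores))
  if (anyNA(idx)) {
    bad <- detfs[is.na(idx), , drop = FALSE]
    stop(sprintf("no z-score for DETF '%s' in condition '%s'",
                 bad$tf_id[1], bad$condition_id[1]))
  }
  detfs$z <- zscores$z[idx]
  out <- detfs[!is.na(detfs$z) & detfs$z > z_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan all conditions for condition-specific TFs
#'
#' Runs [test_differential()] for every condition, computes each TF's
#' cross-condition z-score within its condition's dataset, and applies
#' the DETF and CsTF thresholds. This is the per-TF, per-condition table
#' behind the pipeline's `cstf` stage.
#'
#' @param m An [expression_matrix()].
#' @param design A `condition_design`.
#' @param tf_ids TF gene identifiers (rows of `m`) to scan.
#' @param alpha DETF p-value threshold (default 0.01).
#' @param min_log2fc DETF log2 fold-change threshold (default 1).
#' @param min_z CsTF z-score threshold (default 2).
#' @param two_sided_fc Passed to [select_detfs()].
#' @return data.frame with one row per (TF, condition):
#'   `tf_id`, `condition_id`, `dataset`, `p_value`, `log2_fc`, `z`,
#'   `is_detf`, `is_cstf`.
#' @export
cstf_scan <- function(m, design, tf_ids, alpha = 0.01, min_log2fc = 1.0,
                      min_z = 2.0, two_sided_fc = FALSE) {
  validate_design(design, m)
  tf_ids <- intersect(tf_ids, rownames(m))
  if (length(tf_ids) == 0) stop("no TF ids present in the matrix")
  cond_ids <- names(design$conditions)
  res <- lapply(cond_ids, function(cid) {
    r <- suppressWarnings(test_differential(m, design, cid, tf_ids))
    data.frame(tf_id = r$gene_id, condition_id = cid,
               dataset = design$conditions[[cid]]$dataset,
               p_value = r$p_value, log2_fc = r$log2_fc,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)

  # z within each (TF, dataset) over that dataset's conditions
  tab$z <- NA_real_
  for (ds in unique(tab$dataset)) {
    sel <- tab$dataset == ds
    sub <- tab[sel, , drop = FALSE]
    fcs <- split(sub$log2_fc, sub$tf_id)
    mus <- vapply(fcs, mean, 0)
    sds <- vapply(fcs, stats::sd, 0)
    mu_i <- mus[sub$tf_id]
    sd_i <- sds[sub$tf_id]
    z <- ifelse(sd_i == 0, NA_real_, (sub$log2_fc - mu_i) / sd_i)
    tab$z[sel] <- z
  }

  fc_ok <- if (two_sided_fc) abs(tab$log2_fc) > min_log2fc else tab$log2_fc > min_log2fc
  tab$is_detf <- tab$p_value < alpha & fc_ok
  tab$is_cstf <- tab$is_detf & !is.na(tab$z) & tab$z > min_z
  rownames(tab) <- NULL
  tab
}
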