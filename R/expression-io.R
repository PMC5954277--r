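#' Construct a validated expression matrix
#'
#' An expression matrix holds log2-scale intensities with genes as rows and
#' samples as columns. Gene and sample identifiers must be unique and every
#' value finite.
#'
#' @param values Numeric matrix (genes x samples) with rownames (gene ids)
#'   and colnames (sample ids).
#' @param normalized Logical flag recording whether quantile normalization
#'   has been applied.
#' @return A numeric matrix of class `expression_matrix` with a
#'   `normalized` attribute.
#' @export
expression_matrix <- function(values, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix requires gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate gene ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids")
  }
  if (!all(is.finite(values))) {
    stop("expression matrix contains non-finite values")
  }
  structure(values,
            normalized = isTRUE(normalized),
            class = c("expression_matrix", class(values)))
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids;
#' the body must be numeric. Rows whose gene id appears more than once are
#' rejected outright (ambiguous identifier mapping).
#'
#' @param path Path to a tab-separated text file.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  if (ncol(df) < 2) stop("expression file needs a gene id column and >=1 sample column")
  gene_ids <- df[[1]]
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("ambiguous gene ids listed more than once: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(gene_ids, colnames(body))))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                 gene_ids[bad[1, 1]], colnames(num)[bad[1, 2]]))
  }
  if (anyNA(num)) {
    na <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 gene_ids[na[1, 1]], colnames(num)[na[1, 2]]))
  }
  expression_matrix(num)
}

#' Write an expression matrix to TSV
#'
#' @param m An [expression_matrix()] (or plain named numeric matrix).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column to share the identical value distribution:
#' each column's sorted values are replaced by the vector of row means of
#' the column-sorted matrix, preserving within-column rank order. Ties
#' receive the mean of the reference values at their rank positions.
#' Delegates to [limma::normalizeQuantiles()].
#'
#' @param m An [expression_matrix()].
#' @return A quantile-normalized [expression_matrix()] with
#'   `normalized = TRUE`.
#' @export
quantile_normalize <- function(m) {
  if (nrow(m) == 0 || ncol(m) == 0) stop("cannot normalize an empty matrix")
  out <- limma::normalizeQuantiles(unclass(m), ties = TRUE)
  dimnames(out) <- dimnames(m)
  expression_matrix(out, normalized = TRUE)
}

#' Read a condition design from YAML or JSON
#'
#' The design maps samples to treatment/control roles per condition and
#' records dataset membership. Expected structure:
#' \preformatted{
#' datasets:
#'   DS1: [s1, s2, s3, s4, ...]
#' conditions:
#'   - condition_id: heat_shoot
#'     dataset: DS1
#'     treatment: [s1, s2]
#'     control: [s3, s4]
#' }
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `condition_design` list with `conditions` and `datasets`.
#' @export
read_condition_design <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    stop("condition design must be .yaml/.yml or .json, got: ", ext)
  }
  conds <- lapply(raw$conditions, function(cc) {
    list(condition_id = as.character(cc$condition_id),
         dataset = as.character(cc$dataset),
         treatment = as.character(unlist(cc$treatment)),
         control = as.character(unlist(cc$control)))
  })
  names(conds) <- vapply(conds, `[[`, "", "condition_id")
  condition_design(conditions = conds,
                   datasets = lapply(raw$datasets, function(x) as.character(unlist(x))))
}

#' Construct and validate a condition design
#'
#' @param conditions Named list of conditions, each a list with
#'   `condition_id`, `dataset`, `treatment` (sample ids) and `control`
#'   (sample ids).
#' @param datasets Named list mapping dataset id to its full sample id
#'   vector.
#' @return A validated `condition_design` object.
#' @export
condition_design <- function(conditions, datasets) {
  if (is.null(names(conditions)) || anyDuplicated(names(conditions))) {
    stop("conditions must be uniquely named by condition_id")
  }
  for (cc in conditions) {
    if (length(cc$treatment) < 2 || length(cc$control) < 2) {
      stop(sprintf("condition '%s' needs >=2 treatment and >=2 control samples",
                   cc$condition_id))
    }
    if (length(intersect(cc$treatment, cc$control)) > 0) {
      stop(sprintf("condition '%s': treatment and control samples overlap",
                   cc$condition_id))
    }
    if (!cc$dataset %in% names(datasets)) {
      stop(sprintf("condition '%s' references unknown dataset '%s'",
                   cc$condition_id, cc$dataset))
    }
    missing <- setdiff(c(cc$treatment, cc$control), datasets[[cc$dataset]])
    if (length(missing) > 0) {
      stop(sprintf("condition '%s': samples not in dataset '%s': %s",
                   cc$condition_id, cc$dataset, paste(missing, collapse = ", ")))
    }
  }
  structure(list(conditions = conditions, datasets = datasets),
            class = "condition_design")
}

#' Write a condition design to YAML
#'
#' @param design A `condition_design`.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_condition_design <- function(design, path) {
  out <- list(
    datasets = design$datasets,
    conditions = lapply(unname(design$conditions), function(cc) {
      list(condition_id = cc$condition_id, dataset = cc$dataset,
           treatment = cc$treatment, control = cc$control)
    }))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Check a condition design against an expression matrix
#'
#' Verifies that every sample referenced by the design exists as a column
#' of the matrix.
#'
#' @param design A `condition_design`.
#' @param m An [expression_matrix()].
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
validate_design <- function(design, m) {
  samples <- unique(unlist(design$datasets))
  missing <- setdiff(samples, colnames(m))
  if (length(missing) > 0) {
    stop("design samples absent from the expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  invisible(TRUE)
}
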