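#' Enumerate all DNA k-mers in a length range
#'
#' All strings over {A,C,G,T}, lexicographic within each length, shorter
#' lengths first. The full 4-8-mer catalogue used for background
#' calibration contains 87,296 motifs.
#'
#' @param k_min,k_max Inclusive length range (default 4 and 8).
#' @return Character vector of motifs.
#' @export
enumerate_kmers <- function(k_min = 4L, k_max = 8L) {
  if (k_min < 1 || k_max < k_min) stop("invalid k range")
  unlist(lapply(k_min:k_max, function(k) {
    Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  }), use.names = FALSE)
}

#' Count exact motif occurrences in a sequence
#'
#' Forward-strand exact matching; overlapping matches are counted
#' (every valid start position is a potential match).
#'
#' @param sequence Character or [Biostrings::DNAString] subject.
#' @param motif Uppercase ACGT motif.
#' @return Integer match count.
#' @export
count_occurrences <- function(sequence, motif) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  if (nchar(motif) > length(sequence)) return(0L)
  Biostrings::countPattern(motif, sequence)
}

#' Build the genome-wide k-mer background index
#'
#' Scans every promoter for all k-mers of the requested lengths and
#' records, per motif, the number of genes whose promoter(s) contain it
#' at least once (`presence`) and its total occurrence count (`number`,
#' overlaps counted). Genes with several promoters contribute presence
#' once; occurrences are summed over their promoters. Per length k the
#' total number of valid match start positions, sum over promoters of
#' max(0, L-k+1), is stored as the trial count for number enrichment.
#'
#' @param ps A `promoter_set`, already filtered to pure-ACGT sequences.
#' @param k_min,k_max K-mer length range (defaults 4 and 8).
#' @param both_strands Also count matches on the reverse complement
#'   (default FALSE: forward strand only).
#' @param genes_per_chunk Genes processed per scan chunk (memory knob).
#' @return A `background_index` list: `n_genes`, `k_min`, `k_max`,
#'   `both_strands`, `positions` (named by k), `presence` and `number`
#'   (named integer vectors over all motifs).
#' @export
build_background <- function(ps, k_min = 4L, k_max = 8L, both_strands = FALSE,
                             genes_per_chunk = 100L) {
  if (nrow(ps) == 0) stop("empty promoter set")
  if (any(grepl("[^ACGT]", ps$sequence))) {
    stop("promoter set contains non-ACGT bases; run filter_ambiguous() first")
  }
  seqs <- Biostrings::DNAStringSet(ps$sequence)
  genes <- ps$gene_id
  gene_levels <- unique(genes)
  widths <- Biostrings::width(seqs)
  ks <- k_min:k_max
  positions <- vapply(ks, function(k) sum(pmax(0, widths - k + 1)), 0)
  if (both_strands) positions <- 2 * positions
  names(positions) <- as.character(ks)

  chunks <- split(gene_levels,
                  ceiling(seq_along(gene_levels) / genes_per_chunk))
  presence <- list(); number <- list()
  for (k in ks) {
    kk <- as.character(k)
    pres_acc <- NULL; num_acc <- NULL
    for (ch in chunks) {
      idx <- which(genes %in% ch)
      counts <- Biostrings::oligonucleotideFrequency(seqs[idx], width = k)
      if (both_strands) {
        counts <- counts + Biostrings::oligonucleotideFrequency(
          Biostrings::reverseComplement(seqs[idx]), width = k)
      }
      per_gene <- rowsum(counts, group = genes[idx])
      pres <- colSums(per_gene > 0)
      num <- colSums(counts)
      if (is.null(pres_acc)) { pres_acc <- pres; num_acc <- num }
      else { pres_acc <- pres_acc + pres; num_acc <- num_acc + num }
    }
    presence[[kk]] <- pres_acc
    number[[kk]] <- num_acc
  }
  structure(list(n_genes = length(gene_levels), k_min = k_min, k_max = k_max,
                 both_strands = both_strands, positions = positions,
                 presence = unlist(unname(presence)),
                 number = unlist(unname(number))),
            class = "background_index")
}

#' Serialize a background index to TSV
#'
#' Header comment lines carry the scalar fields; the body is one row per
#' motif with its presence and occurrence counts.
#'
#' @param bg A `background_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_background_index <- function(bg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("#n_genes=%d", bg$n_genes),
    sprintf("#k_min=%d", bg$k_min),
    sprintf("#k_max=%d", bg$k_max),
    sprintf("#both_strands=%s", bg$both_strands),
    sprintf("#positions=%s",
            paste(sprintf("%s:%.0f", names(bg$positions), bg$positions),
                  collapse = ","))), con)
  utils::write.table(
    data.frame(motif = names(bg$presence), presence = bg$presence,
               number = bg$number),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a background index written by [write_background_index()]
#'
#' @param path Input path.
#' @return A `background_index`.
#' @export
read_background_index <- function(path) {
  hdr <- readLines(path, n = 5)
  get <- function(key) sub(paste0("^#", key, "="), "", grep(paste0("^#", key, "="),
                                                            hdr, value = TRUE))
  pos_raw <- strsplit(strsplit(get("positions"), ",")[[1]], ":")
  positions <- vapply(pos_raw, function(x) as.numeric(x[2]), 0)
  names(positions) <- vapply(pos_raw, `[`, "", 1)
  body <- utils::read.delim(path, skip = 5, stringsAsFactors = FALSE)
  structure(list(n_genes = as.integer(get("n_genes")),
                 k_min = as.integer(get("k_min")),
                 k_max = as.integer(get("k_max")),
                 both_strands = as.logical(get("both_strands")),
                 positions = positions,
                 presence = stats::setNames(body$presence, body$motif),
                 number = stats::setNames(body$number, body$motif)),
            class = "background_index")
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= x) for X hypergeometric with population size N containing M
#' successes, drawing n without replacement: the over-representation
#' p-value sum_{i=x}^{min(n,M)} C(M,i) C(N-M,n-i) / C(N,n). Exactly 1
#' when x = 0. Delegates to [stats::phyper()] (upper tail), which
#' computes in a numerically stable way. Vectorized over `x`.
#'
#' @param x Observed success count(s) in the draw.
#' @param n Draw size.
#' @param M Successes in the population.
#' @param N Population size.
#' @return P(X >= x).
#' @export
hypergeom_upper_tail <- function(x, n, M, N) {
  if (any(c(x, n, M, N) < 0)) stop("counts must be non-negative")
  if (any(n > N) || any(M > N)) stop("n and M must not exceed N")
  if (any(x > n) || any(x > M)) stop("x must not exceed min(n, M)")
  stats::phyper(x - 1, m = M, n = N - M, k = n, lower.tail = FALSE)
}

group_promoter_rows <- function(ps, group_gene_ids) {
  has_prom <- group_gene_ids %in% ps$gene_id
  if (any(!has_prom)) {
    warning(sum(!has_prom), " group gene(s) lack promoters; excluded: ",
            paste(utils::head(group_gene_ids[!has_prom], 3), collapse = ", "))
  }
  list(genes = group_gene_ids[has_prom],
       rows = ps[ps$gene_id %in% group_gene_ids, , drop = FALSE])
}

#' Presence enrichment of one motif in a co-expressed group
#'
#' Hypergeometric over-representation of the number of group genes whose
#' promoter(s) contain the motif, against the genome-wide gene
#' background of the index.
#'
#' @param motif Uppercase ACGT motif.
#' @param group_gene_ids Gene ids of the co-expressed group.
#' @param ps The `promoter_set` covering (at least) the group genes.
#' @param bg A `background_index`.
#' @return Upper-tail p-value.
#' @export
presence_enrichment <- function(motif, group_gene_ids, ps, bg) {
  gp <- group_promoter_rows(ps, group_gene_ids)
  seqs <- Biostrings::DNAStringSet(gp$rows$sequence)
  hits <- Biostrings::vcountPattern(motif, seqs)
  if (bg$both_strands) {
    hits <- hits + Biostrings::vcountPattern(
      motif, Biostrings::reverseComplement(seqs))
  }
  x <- length(unique(gp$rows$gene_id[hits > 0]))
  M <- bg$presence[[motif]]
  if (is.null(M) || is.na(M)) M <- 0L
  hypergeom_upper_tail(x, n = length(gp$genes), M = M, N = bg$n_genes)
}

#' Number (occurrence-frequency) enrichment of one motif
#'
#' Hypergeometric over-representation of the motif's total occurrence
#' count in group promoters, where trials are the valid match start
#' positions sum(L-k+1) in the group versus the background total.
#'
#' @param motif Uppercase ACGT motif.
#' @param group_gene_ids Gene ids of the co-expressed group.
#' @param ps The `promoter_set`.
#' @param bg A `background_index`.
#' @return Upper-tail p-value.
#' @export
number_enrichment <- function(motif, group_gene_ids, ps, bg) {
  gp <- group_promoter_rows(ps, group_gene_ids)
  k <- nchar(motif)
  seqs <- Biostrings::DNAStringSet(gp$rows$sequence)
  hits <- Biostrings::vcountPattern(motif, seqs)
  if (bg$both_strands) {
    hits <- hits + Biostrings::vcountPattern(
      motif, Biostrings::reverseComplement(seqs))
  }
  x <- sum(hits)
  n <- sum(pmax(0, Biostrings::width(seqs) - k + 1))
  if (bg$both_strands) n <- 2 * n
  M <- bg$number[[motif]]
  if (is.null(M) || is.na(M)) M <- 0L
  N <- bg$positions[[as.character(k)]]
  hypergeom_upper_tail(x, n = n, M = M, N = N)
}

#' Enrichment scan of a co-expressed group's promoters
#'
#' Computes presence- and number-enrichment p-values for every k-mer
#' with at least one occurrence in the group's promoters. A motif is
#' `enriched` when both p-values fall below `alpha`; the quadrant
#' assignment follows the presence/number scatter convention
#' (1 = both significant, 2 = number only, 3 = neither, 4 = presence
#' only).
#'
#' @param group A `coexpression_group` or character vector of gene ids.
#' @param ps The `promoter_set` covering the group genes.
#' @param bg A `background_index`.
#' @param alpha Significance threshold (default 0.001).
#' @param k K-mer length(s) to scan (default 8; must lie within the
#'   index's range).
#' @return data.frame: `motif`, `k`, `x_presence`, `p_presence`,
#'   `x_number`, `p_number`, `enriched`, `quadrant`, sorted by
#'   `p_presence` then `p_number`.
#' @export
enrich_group <- function(group, ps, bg, alpha = 0.001, k = 8L) {
  group_gene_ids <- if (inherits(group, "coexpression_group")) group$members else group
  if (length(group_gene_ids) == 0) stop("empty group")
  if (any(k < bg$k_min | k > bg$k_max)) {
    stop("requested k outside background index range")
  }
  gp <- group_promoter_rows(ps, group_gene_ids)
  seqs <- Biostrings::DNAStringSet(gp$rows$sequence)
  n_genes_grp <- length(unique(gp$rows$gene_id))
  out <- list()
  for (kk in k) {
    counts <- Biostrings::oligonucleotideFrequency(seqs, width = kk)
    if (bg$both_strands) {
      counts <- counts + Biostrings::oligonucleotideFrequency(
        Biostrings::reverseComplement(seqs), width = kk)
    }
    per_gene <- rowsum(counts, group = gp$rows$gene_id)
    x_num <- colSums(counts)
    keep <- x_num > 0
    if (!any(keep)) next
    motifs <- colnames(counts)[keep]
    x_pres <- colSums(per_gene[, keep, drop = FALSE] > 0)
    x_num <- x_num[keep]
    M_pres <- bg$presence[motifs]
    M_num <- bg$number[motifs]
    n_pos <- sum(pmax(0, Biostrings::width(seqs) - kk + 1)) *
      (if (bg$both_strands) 2 else 1)
    p_pres <- hypergeom_upper_tail(x_pres, n = n_genes_grp, M = M_pres,
                                   N = bg$n_genes)
    p_num <- hypergeom_upper_tail(x_num, n = n_pos, M = M_num,
                                  N = bg$positions[[as.character(kk)]])
    pres_sig <- p_pres < alpha
    num_sig <- p_num < alpha
    quadrant <- ifelse(pres_sig & num_sig, 1L,
                       ifelse(num_sig, 2L, ifelse(pres_sig, 4L, 3L)))
    out[[as.character(kk)]] <- data.frame(
      motif = motifs, k = kk,
      x_presence = unname(x_pres), p_presence = unname(p_pres),
      x_number = unname(x_num), p_number = unname(p_num),
      enriched = unname(pres_sig & num_sig), quadrant = unname(quadrant),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out) == 0) {
    data.frame(motif = character(0), k = integer(0), x_presence = integer(0),
               p_presence = numeric(0), x_number = integer(0),
               p_number = numeric(0), enriched = logical(0),
               quadrant = integer(0))
  } else {
    do.call(rbind, out)
  }
  res <- res[order(res$p_presence, res$p_number, res$motif), , drop = FALSE]
  rownames(res) <- NULL
  res
}
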