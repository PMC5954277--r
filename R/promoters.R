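#' Construct a promoter set
#'
#' A promoter set is a data.frame of upstream regions, one row per
#' promoter, with 1-based inclusive genomic coordinates and the sequence
#' stored 5'->3' relative to the gene (i.e. minus-strand promoters are
#' reverse-complemented). Sequences are uppercased on construction.
#'
#' @param records data.frame with columns `promoter_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `sequence`.
#' @return A `promoter_set` data.frame.
#' @export
promoter_set <- function(records) {
  req <- c("promoter_id", "gene_id", "chrom", "start", "end", "strand", "sequence")
  missing <- setdiff(req, names(records))
  if (length(missing) > 0) stop("missing columns: ", paste(missing, collapse = ", "))
  records$sequence <- toupper(records$sequence)
  if (anyDuplicated(records$promoter_id)) stop("duplicate promoter_ids")
  if (!all(records$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  widths <- records$end - records$start + 1L
  if (!all(nchar(records$sequence) == widths)) {
    stop("sequence length must equal end - start + 1")
  }
  rownames(records) <- NULL
  class(records) <- c("promoter_set", "data.frame")
  records
}

#' Extract one promoter upstream of a TSS
#'
#' The promoter is the `length` bases immediately upstream of the
#' transcription start site, excluding the TSS base itself: genomic
#' `[tss-length, tss-1]` on the plus strand, `[tss+1, tss+length]`
#' reverse-complemented on the minus strand. Intervals are truncated at
#' chromosome boundaries; a TSS with no upstream sequence yields NULL
#' with a warning.
#'
#' @param tss A list/row with `transcript_id`, `gene_id`, `chrom`,
#'   `pos` (1-based TSS coordinate) and `strand`.
#' @param genome A [Biostrings::DNAStringSet] keyed by chromosome name.
#' @param length Promoter length in bp (default 1000).
#' @return A one-row data.frame (promoter record without `promoter_id`),
#'   or NULL if no upstream sequence exists.
#' @export
extract_promoter <- function(tss, genome, length = 1000) {
  chrom <- as.character(tss$chrom)
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  chrom_len <- Biostrings::width(genome[chrom])
  pos <- as.integer(tss$pos)
  if (tss$strand == "+") {
    start <- max(1L, pos - as.integer(length))
    end <- pos - 1L
  } else {
    start <- pos + 1L
    end <- min(chrom_len, pos + as.integer(length))
  }
  if (end < start || end < 1L || start > chrom_len) {
    warning("TSS of '", tss$transcript_id, "' has no upstream sequence; skipped")
    return(NULL)
  }
  seq <- Biostrings::subseq(genome[[chrom]], start, end)
  if (tss$strand == "-") seq <- Biostrings::reverseComplement(seq)
  data.frame(gene_id = as.character(tss$gene_id), chrom = chrom,
             start = start, end = end, strand = as.character(tss$strand),
             sequence = toupper(as.character(seq)), stringsAsFactors = FALSE)
}

#' Extract promoters for a table of TSSs
#'
#' Runs [extract_promoter()] per transcript and assigns deterministic
#' promoter ids (`<gene_id>_p<ordinal>` by genomic start within a gene).
#'
#' @param tss_table data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `pos`, `strand`.
#' @param genome A [Biostrings::DNAStringSet].
#' @param length Promoter length (default 1000).
#' @return A `promoter_set`.
#' @export
extract_promoters <- function(tss_table, genome, length = 1000) {
  recs <- lapply(seq_len(nrow(tss_table)), function(i) {
    extract_promoter(tss_table[i, ], genome, length)
  })
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (length(recs) == 0) stop("no promoters could be extracted")
  df <- do.call(rbind, recs)
  df <- df[order(df$gene_id, df$chrom, df$start, df$end), , drop = FALSE]
  ord <- stats::ave(seq_len(nrow(df)), df$gene_id, FUN = seq_along)
  df$promoter_id <- paste0(df$gene_id, "_p", ord)
  promoter_set(df[, c("promoter_id", "gene_id", "chrom", "start", "end",
                      "strand", "sequence")])
}

#' Drop promoters containing uncertain bases
#'
#' Removes any promoter whose (uppercased) sequence contains a character
#' outside A, C, G, T — e.g. the IUPAC ambiguity codes N, S, K, M, R, W.
#'
#' @param ps A `promoter_set`.
#' @return The filtered `promoter_set`; the number of removals is
#'   reported via `message()`.
#' @export
filter_ambiguous <- function(ps) {
  clean <- !grepl("[^ACGT]", ps$sequence)
  if (any(!clean)) {
    message("removed ", sum(!clean), " promoter(s) with uncertain bases")
  }
  promoter_set(ps[clean, , drop = FALSE])
}

#' Merge overlapping promoters of the same gene
#'
#' Within each gene, promoter intervals that overlap by at least one
#' base (or lie within `merge_gap` bases of each other; `merge_gap = 0`
#' also merges book-ended intervals) are replaced by their union, with
#' the sequence re-extracted from the genome. Disjoint intervals stay
#' separate, so one gene may keep several promoters. Output ids are
#' deterministic: `<gene_id>_p<ordinal>` by genomic start.
#'
#' @param ps A `promoter_set`.
#' @param genome A [Biostrings::DNAStringSet] for re-extraction.
#' @param merge_gap Maximum gap (bp) between intervals that still merges
#'   them (default 0: overlapping or book-ended).
#' @return A merged `promoter_set`.
#' @export
merge_promoters <- function(ps, genome, merge_gap = 0L) {
  out <- list()
  for (g in unique(ps$gene_id)) {
    sub <- ps[ps$gene_id == g, , drop = FALSE]
    if (length(unique(sub$strand)) > 1 || length(unique(sub$chrom)) > 1) {
      stop("gene '", g, "' has promoters on mixed strands/chromosomes")
    }
    ir <- IRanges::reduce(IRanges::IRanges(sub$start, sub$end),
                          min.gapwidth = merge_gap + 1L)
    chrom <- sub$chrom[1]; strand <- sub$strand[1]
    seqs <- vapply(seq_along(ir), function(i) {
      s <- Biostrings::subseq(genome[[chrom]], IRanges::start(ir)[i],
                              IRanges::end(ir)[i])
      if (strand == "-") s <- Biostrings::reverseComplement(s)
      toupper(as.character(s))
    }, "")
    out[[g]] <- data.frame(
      promoter_id = paste0(g, "_p", seq_along(ir)),
      gene_id = g, chrom = chrom,
      start = IRanges::start(ir), end = IRanges::end(ir),
      strand = strand, sequence = seqs, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df <- df[order(df$gene_id, df$start), , drop = FALSE]
  promoter_set(df)
}

#' Write a promoter set to FASTA (and optionally BED)
#'
#' FASTA headers encode the full record:
#' `promoter_id|gene_id|chrom:start-end(strand)`, so the FASTA alone
#' round-trips through [read_promoters()]. BED output is 0-based
#' half-open per the standard.
#'
#' @param ps A `promoter_set`.
#' @param fasta Output FASTA path.
#' @param bed Optional output BED6 path.
#' @return `fasta`, invisibly.
#' @export
write_promoters <- function(ps, fasta, bed = NULL) {
  seqs <- Biostrings::DNAStringSet(ps$sequence)
  names(seqs) <- sprintf("%s|%s|%s:%d-%d(%s)", ps$promoter_id, ps$gene_id,
                         ps$chrom, ps$start, ps$end, ps$strand)
  Biostrings::writeXStringSet(seqs, fasta)
  if (!is.null(bed)) {
    bed_df <- data.frame(ps$chrom, ps$start - 1L, ps$end, ps$promoter_id,
                         0L, ps$strand)
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta)
}

#' Read a promoter set from FASTA
#'
#' Expects the header convention of [write_promoters()].
#'
#' @param fasta FASTA path.
#' @return A `promoter_set`.
#' @export
read_promoters <- function(fasta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  hdr <- names(seqs)
  m <- regmatches(hdr, regexec(
    "^([^|]+)\\|([^|]+)\\|([^:]+):([0-9]+)-([0-9]+)\\(([+-])\\)", hdr))
  bad <- vapply(m, length, 0L) != 7L
  if (any(bad)) stop("unparseable promoter FASTA header: ", hdr[which(bad)[1]])
  promoter_set(data.frame(
    promoter_id = vapply(m, `[`, "", 2), gene_id = vapply(m, `[`, "", 3),
    chrom = vapply(m, `[`, "", 4),
    start = as.integer(vapply(m, `[`, "", 5)),
    end = as.integer(vapply(m, `[`, "", 6)),
    strand = vapply(m, `[`, "", 7),
    sequence = as.character(seqs), stringsAsFactors = FALSE))
}

#' Read a TSS table from TSV
#'
#' Columns: `transcript_id`, `gene_id`, `chrom`, `pos` (1-based TSS
#' coordinate), `strand`.
#'
#' @param path TSV path.
#' @return A validated data.frame.
#' @export
read_tss_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("transcript_id", "gene_id", "chrom", "pos", "strand")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) stop("TSS table missing columns: ",
                                paste(missing, collapse = ", "))
  df$pos <- as.integer(df$pos)
  if (any(df$pos < 1)) stop("TSS positions must be >= 1")
  if (!all(df$strand %in% c("+", "-"))) stop("invalid strand values")
  df
}
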