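#' Rank core k-mers within a set of enriched 8-mers
#'
#' Counts every substring window of every enriched 8-mer (6 windows for
#' 3-mers, 5 for 4-mers; a core occurring twice in one 8-mer counts
#' twice) and returns the top-ranked cores. Ties are broken
#' lexicographically; cores just below the cut-off that tie with the
#' last kept core are reported in the `tied_at_cutoff` attribute.
#'
#' @param enriched_8mers Character vector of enriched 8-mer motifs.
#' @param core_length Core length (3 or 4; any value < 8 accepted).
#' @param top Number of cores to keep (default 10).
#' @return data.frame `core`, `count`, `rank`, with attribute
#'   `tied_at_cutoff`.
#' @export
rank_core_kmers <- function(enriched_8mers, core_length, top = 10L) {
  if (core_length >= 8) stop("core_length must be < 8")
  if (length(enriched_8mers) == 0) {
    out <- data.frame(core = character(0), count = integer(0), rank = integer(0))
    attr(out, "tied_at_cutoff") <- character(0)
    return(out)
  }
  windows <- unlist(lapply(enriched_8mers, function(m) {
    vapply(seq_len(nchar(m) - core_length + 1),
           function(i) substr(m, i, i + core_length - 1), "")
  }))
  tab <- table(windows)
  df <- data.frame(core = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$core), , drop = FALSE]
  kept <- utils::head(df, top)
  kept$rank <- seq_len(nrow(kept))
  rownames(kept) <- NULL
  cutoff <- if (nrow(kept) > 0) kept$count[nrow(kept)] else NA_integer_
  dropped <- df$core[-seq_len(min(top, nrow(df)))]
  tied <- dropped[df$count[-seq_len(min(top, nrow(df)))] == cutoff]
  attr(kept, "tied_at_cutoff") <- tied
  kept
}

#' Select enriched 8-mers carrying top-ranked core k-mers
#'
#' Keeps the 8-mers that contain at least one top-10 3-mer or at least
#' one top-10 4-mer (`mode = "union"`, the default); with
#' `mode = "intersection"` both a top 3-mer and a top 4-mer are
#' required.
#'
#' @param enriched_8mers Character vector of enriched 8-mers.
#' @param ranking3 Output of [rank_core_kmers()] with `core_length = 3`.
#' @param ranking4 Output of [rank_core_kmers()] with `core_length = 4`.
#' @param mode `"union"` or `"intersection"`.
#' @return Character vector: the selected 8-mers.
#' @export
select_step1_motifs <- function(enriched_8mers, ranking3, ranking4,
                                mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (length(enriched_8mers) == 0) return(character(0))
  has_any <- function(motif, cores) {
    length(cores) > 0 && any(vapply(cores, function(cc)
      grepl(cc, motif, fixed = TRUE), TRUE))
  }
  h3 <- vapply(enriched_8mers, has_any, TRUE, cores = ranking3$core)
  h4 <- vapply(enriched_8mers, has_any, TRUE, cores = ranking4$core)
  keep <- if (mode == "union") h3 | h4 else h3 & h4
  unname(enriched_8mers[keep])
}

#' Map motifs onto promoters and merge overlapping occurrences
#'
#' Locates every exact forward-strand occurrence of the selected motifs
#' in each promoter and merges occurrences that share at least one base
#' (transitively) into maximal regions. Book-ended occurrences are not
#' merged; occurrences on different promoters never merge.
#'
#' @param motifs Character vector of (8-mer) motifs.
#' @param ps `promoter_set` restricted to the group's promoters.
#' @return data.frame of merged regions: `promoter_id`, `start`, `end`
#'   (0-based half-open within the promoter), `sequence`, and a
#'   list-column `contributing` of data.frames (`motif`, `offset`).
#' @export
map_and_merge <- function(motifs, ps) {
  out <- list()
  for (i in seq_len(nrow(ps))) {
    subject <- Biostrings::DNAString(ps$sequence[i])
    occ_start <- integer(0); occ_end <- integer(0); occ_motif <- character(0)
    for (m in motifs) {
      if (nchar(m) > length(subject)) next
      hits <- Biostrings::matchPattern(m, subject)
      if (length(hits) > 0) {
        occ_start <- c(occ_start, Biostrings::start(hits))
        occ_end <- c(occ_end, Biostrings::end(hits))
        occ_motif <- c(occ_motif, rep(m, length(hits)))
      }
    }
    if (length(occ_start) == 0) next
    ir <- IRanges::IRanges(occ_start, occ_end)
    merged <- IRanges::reduce(ir, min.gapwidth = 0L)
    # each occurrence falls in exactly one merged region (regions disjoint,
    # sorted); locate it by its start coordinate
    region_of <- findInterval(occ_start, IRanges::start(merged))
    for (j in seq_along(merged)) {
      rs <- IRanges::start(merged)[j]; re <- IRanges::end(merged)[j]
      members <- which(region_of == j)
      ord <- members[order(occ_start[members], occ_motif[members])]
      out[[length(out) + 1]] <- data.frame(
        promoter_id = ps$promoter_id[i],
        start = rs - 1L, end = re,
        sequence = as.character(Biostrings::subseq(subject, rs, re)),
        contributing = I(list(data.frame(motif = occ_motif[ord],
                                         offset = occ_start[ord] - 1L,
                                         stringsAsFactors = FALSE))),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(promoter_id = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      contributing = I(list())))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a position-specific scoring matrix from merged regions
#'
#' Region sequences are stacked deterministically: each region is
#' anchored at the start of its leftmost occurrence of `anchor_core`
#' (regions lacking the core anchor at offset 0), then padded so the
#' anchors line up. Per-column base frequencies are computed over the
#' sequences covering the column, with an optional pseudocount; columns
#' supported by fewer than `trim_support` of the regions are trimmed
#' from both ends. The logo matrix is the per-column information
#' content (bits) times the frequency.
#'
#' @param regions Output of [map_and_merge()] (or any data.frame with a
#'   `sequence` column).
#' @param anchor_core Anchor k-mer, typically the group's top-ranked
#'   core; NULL anchors everything at offset 0.
#' @param pseudocount Added to each base count per column (default 0).
#' @param trim_support Minimum fraction of regions that must cover a
#'   column for it to survive end-trimming (default 0.5).
#' @return A `pssm` list: `freq` (4 x W, columns sum to 1), `ic`
#'   (bits per column), `logo` (freq scaled by ic), `support`, `nseq`,
#'   `pseudocount`, `consensus`.
#' @export
build_pssm <- function(regions, anchor_core = NULL, pseudocount = 0,
                       trim_support = 0.5) {
  seqs <- regions$sequence
  if (length(seqs) == 0) stop("no regions to build a PSSM from")
  anchor <- rep(0L, length(seqs))
  if (!is.null(anchor_core)) {
    pos <- regexpr(anchor_core, seqs, fixed = TRUE)
    anchor[pos > 0] <- as.integer(pos[pos > 0]) - 1L
  }
  pad <- max(anchor) - anchor
  lens <- nchar(seqs)
  width <- max(pad + lens)
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0, nrow = 4, ncol = width, dimnames = list(bases, NULL))
  cover <- integer(width)
  for (i in seq_along(seqs)) {
    cols <- pad[i] + seq_len(lens[i])
    chars <- strsplit(seqs[i], "")[[1]]
    for (j in seq_along(cols)) {
      counts[chars[j], cols[j]] <- counts[chars[j], cols[j]] + 1
    }
    cover[cols] <- cover[cols] + 1L
  }
  keep <- cover >= trim_support * length(seqs)
  # trim from the ends only; interior low-support columns are retained
  first <- which(keep)[1]
  last <- utils::tail(which(keep), 1)
  if (is.na(first)) stop("no column reaches the support threshold")
  sel <- first:last
  counts <- counts[, sel, drop = FALSE]
  cover <- cover[sel]
  freq <- sweep(counts + pseudocount, 2, cover + 4 * pseudocount, "/")
  ent <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  ic <- 2 - ent
  structure(list(freq = freq, ic = ic,
                 logo = sweep(freq, 2, ic, "*"),
                 support = cover, nseq = length(seqs),
                 pseudocount = pseudocount,
                 consensus = paste(bases[apply(freq, 2, which.max)],
                                   collapse = "")),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM: %d columns, %d regions, consensus %s\n",
              ncol(x$freq), x$nseq, x$consensus))
  print(round(x$freq, 3))
  invisible(x)
}

#' Classify an 8-mer as a reverse-complement palindrome
#'
#' `full` when the motif equals its own reverse complement (e.g. the
#' heat-shock element GAATATTC); `flank_k` (k = 1..3, maximal) when the
#' outer k base pairs are reverse-complementary (position i pairs with
#' position 9-i) but some inner position breaks full palindromy, as in
#' GAAnnTTC-type elements with non-complementary spacers; `none`
#' otherwise.
#'
#' @param motif A length-8 ACGT string.
#' @return One of `"full"`, `"flank_3"`, `"flank_2"`, `"flank_1"`,
#'   `"none"`.
#' @export
classify_palindrome <- function(motif) {
  if (nchar(motif) != 8 || grepl("[^ACGT]", motif)) {
    stop("motif must be a length-8 ACGT string")
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  b <- strsplit(motif, "")[[1]]
  pair_ok <- vapply(1:4, function(i) b[i] == comp[[b[9 - i]]], TRUE)
  if (all(pair_ok)) return("full")
  k <- 0
  for (i in 1:3) {
    if (pair_ok[i]) k <- i else break
  }
  if (k > 0) paste0("flank_", k) else "none"
}

#' Palindrome report for a motif set
#'
#' @param motifs Character vector of 8-mers.
#' @return data.frame `motif`, `class`.
#' @export
palindrome_report <- function(motifs) {
  data.frame(motif = motifs,
             class = vapply(motifs, classify_palindrome, ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' TSS-distance histogram of merged regions
#'
#' Bins region midpoints by their distance upstream of the TSS. The
#' promoter sequence runs 5'->3' towards the TSS, so a region midpoint
#' at offset m within a promoter of length L lies L - m bases upstream.
#'
#' @param regions Output of [map_and_merge()].
#' @param ps The `promoter_set` the regions refer to.
#' @param bin Bin width in bp (default 100).
#' @return data.frame `bin_start`, `bin_end`, `count` covering
#'   `[0, max promoter length)`.
#' @export
tss_distance_profile <- function(regions, ps, bin = 100L) {
  max_len <- max(nchar(ps$sequence))
  breaks <- seq(0, ceiling(max_len / bin) * bin, by = bin)
  counts <- integer(length(breaks) - 1)
  if (nrow(regions) > 0) {
    lens <- nchar(ps$sequence)[match(regions$promoter_id, ps$promoter_id)]
    mid <- (regions$start + regions$end) / 2
    dist <- lens - mid
    idx <- findInterval(dist, breaks, rightmost.closed = TRUE,
                        left.open = TRUE)
    idx[dist == 0] <- 1L
    tab <- table(factor(idx, levels = seq_along(counts)))
    counts <- as.integer(tab)
  }
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             count = counts)
}

#' Write PSSMs in MEME minimal motif format
#'
#' @param pssms A named list of `pssm` objects (names become motif ids).
#' @param path Output path.
#' @param background Background base frequencies (default uniform).
#' @return `path`, invisibly.
#' @export
write_meme <- function(pssms, path, background = rep(0.25, 4)) {
  if (inherits(pssms, "pssm")) pssms <- list(motif_1 = pssms)
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: +", "",
             "Background letter frequencies",
             sprintf("A %.5f C %.5f G %.5f T %.5f", background[1],
                     background[2], background[3], background[4]), "")
  for (nm in names(pssms)) {
    p <- pssms[[nm]]
    lines <- c(lines, paste("MOTIF", nm),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       ncol(p$freq), p$nseq),
               apply(p$freq, 2, function(col)
                 sprintf(" %.6f %.6f %.6f %.6f", col[1], col[2], col[3], col[4])),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}
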