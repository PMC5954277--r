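# Small in-code fixtures shared across test files.

# 4-condition, one-dataset design over 16 samples named s01..s16
tiny_design <- function(n_cond = 4, reps = 2) {
  n <- n_cond * reps * 2
  samples <- sprintf("s%02d", seq_len(n))
  conds <- lapply(seq_len(n_cond), function(i) {
    base <- (i - 1) * reps * 2
    list(condition_id = sprintf("c%d", i), dataset = "DS1",
         treatment = samples[base + seq_len(reps)],
         control = samples[base + reps + seq_len(reps)])
  })
  names(conds) <- sprintf("c%d", seq_len(n_cond))
  condition_design(conds, list(DS1 = samples))
}

# deterministic matrix matching tiny_design
tiny_matrix <- function(n_genes = 6, n_cond = 4, reps = 2, seed = 99) {
  set.seed(seed)
  n <- n_cond * reps * 2
  m <- matrix(rnorm(n_genes * n, 8, 1), n_genes, n,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  expression_matrix(m)
}

# promoter set built directly from sequences, one gene per promoter
ps_from_seqs <- function(seqs, gene_ids = sprintf("g%02d", seq_along(seqs))) {
  ord <- stats::ave(seq_along(gene_ids), gene_ids, FUN = seq_along)
  promoter_set(data.frame(
    promoter_id = paste0(gene_ids, "_p", ord), gene_id = gene_ids,
    chrom = "chr1", start = 1000L + seq_along(seqs) * 5000L,
    end = 999L + seq_along(seqs) * 5000L + nchar(seqs),
    strand = "+", sequence = seqs, stringsAsFactors = FALSE))
}

# exhaustive-enumeration oracle for the hypergeometric upper tail:
# population of N items, M successes; count the n-subsets with >= x successes
hyper_tail_enum <- function(x, n, M, N) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= M)  # items 1..M are the successes
  mean(hits >= x)
}
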