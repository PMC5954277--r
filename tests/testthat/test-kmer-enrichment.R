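test_that("k-mer enumeration covers the full catalogue in order", {
  expect_length(enumerate_kmers(1, 1), 4)
  k2 <- enumerate_kmers(2, 2)
  expect_length(k2, 16)
  expect_equal(k2[1:4], c("AA", "AC", "AG", "AT"))  # lexicographic
  expect_length(enumerate_kmers(4, 8), 87296)
  expect_error(enumerate_kmers(3, 2), "invalid")
})

test_that("occurrence counting is exact, forward-strand, overlap-aware", {
  expect_equal(count_occurrences("GAAGAA", "GAA"), 2)
  expect_equal(count_occurrences("AAAA", "AA"), 3)
  expect_equal(count_occurrences("ACG", "ACGT"), 0)  # motif longer than subject
  expect_equal(count_occurrences("TTTT", "GAA"), 0)
})

test_that("background index counts gene-level presence and total occurrences", {
  ps <- ps_from_seqs("GAAGAA", "gX")
  bg <- build_background(ps, 3, 3)
  expect_equal(unname(bg$presence[["GAA"]]), 1)
  expect_equal(unname(bg$number[["GAA"]]), 2)
  expect_equal(unname(bg$positions[["3"]]), 4)  # 6 - 3 + 1
  expect_equal(unname(bg$number[["TTT"]]), 0)

  # two promoters of one gene, each with one occurrence
  ps2 <- promoter_set(data.frame(
    promoter_id = c("gX_p1", "gX_p2"), gene_id = "gX", chrom = "chr1",
    start = c(100, 900), end = c(105, 905), strand = "+",
    sequence = c("AGAAAT", "TGAACT")))
  bg2 <- build_background(ps2, 3, 3)
  expect_equal(unname(bg2$presence[["GAA"]]), 1)  # presence once per gene
  expect_equal(unname(bg2$number[["GAA"]]), 2)
  expect_equal(bg2$n_genes, 1)

  expect_error(build_background(ps_from_seqs("ACGN"), 3, 3), "non-ACGT")
  expect_error(build_background(ps_from_seqs("ACGT")[0, ], 3, 3), "empty")
})

test_that("background index agrees with brute-force scanning", {
  set.seed(61)
  seqs <- vapply(1:6, function(i) paste(
    sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = ""), "")
  ps <- ps_from_seqs(seqs, gene_ids = c("g1", "g1", "g2", "g3", "g3", "g4"))
  bg <- build_background(ps, 4, 5)
  for (motif in c("ACGT", "AAAA", "GGCA", "ACGTA", "TTTTT")) {
    per_seq <- vapply(seqs, function(s) count_occurrences(s, motif), 0L)
    expect_equal(unname(bg$number[[motif]]), sum(per_seq))
    genes_with <- unique(ps$gene_id[per_seq > 0])
    expect_equal(unname(bg$presence[[motif]]), length(genes_with))
  }
})

test_that("background index round-trips through its TSV serialization", {
  ps <- ps_from_seqs(c("GAAGAATTC", "ACGTACGTA"), c("g1", "g2"))
  bg <- build_background(ps, 3, 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_background_index(bg, path)
  bg2 <- read_background_index(path)
  expect_equal(bg2$n_genes, bg$n_genes)
  expect_equal(bg2$positions, bg$positions)
  expect_equal(bg2$presence, bg$presence)
  expect_equal(bg2$number, bg$number)
})

test_that("hypergeometric upper tail matches the exact tail sums", {
  expect_equal(hypergeom_upper_tail(0, 5, 4, 10), 1.0)
  expect_equal(hypergeom_upper_tail(3, 5, 4, 10), 66 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(4, 8, 5, 20), 7280 / 125970,
               tolerance = 1e-12)
  expect_error(hypergeom_upper_tail(5, 4, 5, 10), "x must not exceed")
  expect_error(hypergeom_upper_tail(1, 11, 5, 10), "exceed N")
})

test_that("hypergeometric tail equals exhaustive subset enumeration (small N)", {
  for (N in c(5, 7, 9)) {
    for (M in 0:N) {
      for (n in 1:N) {
        for (x in 0:min(n, M)) {
          expect_equal(hypergeom_upper_tail(x, n, M, N),
                       hyper_tail_enum(x, n, M, N), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("hypergeometric tail is monotone in x and satisfies the sum rule", {
  N <- 40; M <- 12; n <- 15
  xs <- 0:min(n, M)
  p <- hypergeom_upper_tail(xs, n, M, N)
  expect_true(all(diff(p) <= 1e-15))
  for (x in xs[-1]) {
    lower <- stats::phyper(x - 1, M, N - M, n)
    expect_equal(hypergeom_upper_tail(x, n, M, N) + lower, 1, tolerance = 1e-12)
  }
})

test_that("presence and number enrichment reproduce the toy hypergeometrics", {
  # background: 10 genes, 4 of which carry the motif once
  motif <- "GAAT"
  with_m <- paste0("CCCC", motif, "CCCC")
  without <- "CCCCCCCCCCCC"
  ps <- ps_from_seqs(c(rep(with_m, 4), rep(without, 6)),
                     gene_ids = sprintf("g%02d", 1:10))
  bg <- build_background(ps, 4, 4)
  # group of 5 genes, 3 carrying the motif -> 66/252
  grp <- c("g01", "g02", "g03", "g05", "g06")
  expect_equal(presence_enrichment(motif, grp, ps, bg), 66 / 252,
               tolerance = 1e-12)
  # motif absent from every group promoter -> p = 1
  expect_equal(presence_enrichment("TTTT", grp, ps, bg), 1.0)
  # motif in every group promoter with saturated background -> p = 1
  ps_all <- ps_from_seqs(rep(with_m, 4), sprintf("g%02d", 1:4))
  bg_all <- build_background(ps_all, 4, 4)
  expect_equal(presence_enrichment(motif, sprintf("g%02d", 1:4), ps_all, bg_all),
               1.0)
  # group = entire background in number mode -> point mass, p = 1
  expect_equal(number_enrichment(motif, sprintf("g%02d", 1:4), ps_all, bg_all),
               1.0)
  # a group gene without a promoter is dropped from n with a warning
  expect_warning(p <- presence_enrichment(motif, c(grp, "missing"), ps, bg),
                 "lack promoters")
  expect_equal(p, 66 / 252, tolerance = 1e-12)
})

test_that("number enrichment uses valid start positions as trials", {
  # background: 20 positions of which 5 are occurrences; group 8 positions,
  # 4 occurrences -> 7280/125970 (verified against the exact tail sum)
  motif <- "GG"
  bg <- structure(list(n_genes = 3, k_min = 2, k_max = 2, both_strands = FALSE,
                       positions = c("2" = 20), presence = c(GG = 3),
                       number = c(GG = 5)), class = "background_index")
  ps <- ps_from_seqs("GGCGGAGGG", "gA")  # 8 start positions; GG at 1,4,7,8
  expect_equal(count_occurrences(ps$sequence[1], "GG"), 4)
  expect_equal(number_enrichment(motif, "gA", ps, bg), 7280 / 125970,
               tolerance = 1e-12)
})

test_that("enrich_group flags quadrant-1 motifs and omits absent ones", {
  set.seed(71)
  rand <- function() paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  motif <- "GAATTCGA"
  group_seqs <- vapply(1:6, function(i) paste0(substr(rand(), 1, 30), motif,
                                               substr(rand(), 1, 22)), "")
  bg_seqs <- vapply(1:40, function(i) rand(), "")
  ps <- ps_from_seqs(c(group_seqs, bg_seqs), sprintf("g%02d", 1:46))
  bg <- build_background(ps, 8, 8)
  grp <- sprintf("g%02d", 1:6)
  er <- enrich_group(grp, ps, bg, alpha = 0.001, k = 8)
  row <- er[er$motif == motif, ]
  expect_equal(row$x_presence, 6)
  expect_true(row$enriched)
  expect_equal(row$quadrant, 1L)
  # p-values agree with the single-motif entry points
  expect_equal(row$p_presence, presence_enrichment(motif, grp, ps, bg),
               tolerance = 1e-12)
  expect_equal(row$p_number, number_enrichment(motif, grp, ps, bg),
               tolerance = 1e-12)
  # motifs never seen in the group are omitted
  expect_false(any(er$x_number == 0))
  # enriched = both significant; quadrants partition significance states
  expect_equal(er$enriched, er$p_presence < 0.001 & er$p_number < 0.001)
  expect_true(all(er$quadrant[er$enriched] == 1L))
  expect_error(enrich_group(character(0), ps, bg), "empty group")
  expect_error(enrich_group(grp, ps, bg, k = 9), "outside")
})
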