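#' Pipeline configuration
#'
#' Collects every stage threshold with the method's standard defaults:
#' DETF p < 0.01 and log2FC > 1, CsTF z > 2, DEG p < 0.01 and
#' |log2FC| >= log2(1.5), co-expression PCC >= 0.8, enrichment p < 0.001
#' on 4-8-mers with 8-mers carried into assembly, top-10 core 3-/4-mers,
#' 1000-bp promoters.
#'
#' @param alpha_detf,min_lfc,min_z DETF/CsTF thresholds.
#' @param alpha_deg,min_abs_lfc DEG thresholds.
#' @param min_pcc Co-expression threshold.
#' @param min_group_size Minimum group size to proceed to enrichment.
#' @param alpha_enrich Enrichment significance threshold.
#' @param k_min,k_max Background k-mer range.
#' @param enrich_k K-mer length(s) scanned per group.
#' @param top_cores Core-ranking depth.
#' @param promoter_length Promoter length (bp).
#' @param both_strands Scan both strands (default FALSE).
#' @param normalize Quantile-normalize the input matrix first.
#' @param two_sided_fc Admit repressed DETFs.
#' @param merge_gap Promoter merge gap (bp).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(alpha_detf = 0.01, min_lfc = 1.0, min_z = 2.0,
                            alpha_deg = 0.01, min_abs_lfc = log2(1.5),
                            min_pcc = 0.8, min_group_size = 10L,
                            alpha_enrich = 0.001, k_min = 4L, k_max = 8L,
                            enrich_k = 8L, top_cores = 10L,
                            promoter_length = 1000L, both_strands = FALSE,
                            normalize = TRUE, two_sided_fc = FALSE,
                            merge_gap = 0L) {
  cfg <- list(alpha_detf = alpha_detf, min_lfc = min_lfc, min_z = min_z,
              alpha_deg = alpha_deg, min_abs_lfc = min_abs_lfc,
              min_pcc = min_pcc, min_group_size = as.integer(min_group_size),
              alpha_enrich = alpha_enrich, k_min = as.integer(k_min),
              k_max = as.integer(k_max), enrich_k = as.integer(enrich_k),
              top_cores = as.integer(top_cores),
              promoter_length = as.integer(promoter_length),
              both_strands = isTRUE(both_strands),
              normalize = isTRUE(normalize),
              two_sided_fc = isTRUE(two_sided_fc),
              merge_gap = as.integer(merge_gap))
  probs <- c("alpha_detf", "alpha_deg", "alpha_enrich")
  for (p in probs) {
    if (cfg[[p]] <= 0 || cfg[[p]] > 1) stop(p, " must be in (0, 1]")
  }
  if (cfg$min_pcc < -1 || cfg$min_pcc > 1) stop("min_pcc must be in [-1, 1]")
  if (cfg$k_min < 1 || cfg$k_max < cfg$k_min) stop("invalid k range")
  if (any(cfg$enrich_k < cfg$k_min | cfg$enrich_k > cfg$k_max)) {
    stop("enrich_k must lie within [k_min, k_max]")
  }
  if (cfg$promoter_length < cfg$k_max) stop("promoter_length too small")
  structure(cfg, class = "pipeline_config")
}

fmt6 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full CsTF / cis-element discovery pipeline
#'
#' Executes normalize -> CsTF scan -> co-expression grouping ->
#' background indexing -> per-group k-mer enrichment -> motif assembly,
#' writing fixed-format TSV outputs per stage plus a machine-readable
#' `summary.json` and `run_manifest.json` under `out_dir`. Outputs are a
#' pure function of the inputs and configuration, so reruns are
#' byte-identical.
#'
#' @param m An [expression_matrix()] (raw or already normalized).
#' @param design A `condition_design`.
#' @param tf_ids TF gene identifiers.
#' @param ps A `promoter_set` (already ambiguity-filtered and merged).
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param bg Optional precomputed `background_index` (skips the
#'   background stage).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the stage results: `cstf_table`,
#'   `groups`, `background`, `enrichment` (per CsTF), `assembly`
#'   (per CsTF), `summary`.
#' @export
run_pipeline <- function(m, design, tf_ids, ps, out_dir,
                         config = pipeline_config(), bg = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  validate_design(design, m)

  if (config$normalize) {
    say("stage normalize: quantile normalization")
    m <- quantile_normalize(m)
  }

  say("stage cstf: scanning ", length(tf_ids), " TFs over ",
      length(design$conditions), " conditions")
  cstf_table <- cstf_scan(m, design, tf_ids, alpha = config$alpha_detf,
                          min_log2fc = config$min_lfc, min_z = config$min_z,
                          two_sided_fc = config$two_sided_fc)
  out_tab <- cstf_table
  out_tab$p_value <- fmt6(out_tab$p_value)
  out_tab$log2_fc <- fmt6(out_tab$log2_fc)
  out_tab$z <- fmt6(out_tab$z)
  write_tsv(out_tab, file.path(out_dir, "cstf_table.tsv"))
  cstfs <- cstf_table[cstf_table$is_cstf, , drop = FALSE]

  say("stage coexpress: ", nrow(cstfs), " CsTF(s)")
  groups <- list()
  group_rows <- list()
  for (i in seq_len(nrow(cstfs))) {
    cid <- cstfs$condition_id[i]
    degs <- select_degs(m, design, cid, alpha = config$alpha_deg,
                        min_abs_log2fc = config$min_abs_lfc)
    gr <- suppressWarnings(
      build_group(cstfs$tf_id[i], cid, degs, m, design,
                  min_pcc = config$min_pcc,
                  min_size = config$min_group_size))
    key <- paste(gr$cstf_id, gr$condition_id, sep = "@")
    groups[[key]] <- gr
    if (length(gr$members) > 0) {
      group_rows[[key]] <- data.frame(cstf_id = gr$cstf_id,
                                      condition_id = gr$condition_id,
                                      gene_id = gr$members,
                                      pcc = fmt6(unname(gr$pcc)),
                                      stringsAsFactors = FALSE)
    }
  }
  write_tsv(if (length(group_rows) > 0) do.call(rbind, c(group_rows, make.row.names = FALSE))
            else data.frame(cstf_id = character(0), condition_id = character(0),
                            gene_id = character(0), pcc = character(0)),
            file.path(out_dir, "coexpression_groups.tsv"))

  if (is.null(bg)) {
    say("stage background: indexing ", nrow(ps), " promoters, k ",
        config$k_min, "-", config$k_max)
    bg <- build_background(ps, k_min = config$k_min, k_max = config$k_max,
                           both_strands = config$both_strands)
  }

  say("stage enrich + assemble")
  enrichment <- list(); assembly <- list()
  enrich_rows <- list()
  for (key in names(groups)) {
    gr <- groups[[key]]
    if (gr$discarded) next
    er <- suppressWarnings(enrich_group(gr, ps, bg,
                                        alpha = config$alpha_enrich,
                                        k = config$enrich_k))
    enrichment[[key]] <- er
    if (nrow(er) > 0) {
      tab <- er
      tab$p_presence <- fmt6(tab$p_presence)
      tab$p_number <- fmt6(tab$p_number)
      enrich_rows[[key]] <- cbind(cstf_id = gr$cstf_id,
                                  condition_id = gr$condition_id, tab)
    }
    enriched8 <- er$motif[er$enriched & er$k == 8]
    if (length(enriched8) == 0) next
    r3 <- rank_core_kmers(enriched8, 3, top = config$top_cores)
    r4 <- rank_core_kmers(enriched8, 4, top = config$top_cores)
    sel <- select_step1_motifs(enriched8, r3, r4)
    grp_ps <- ps[ps$gene_id %in% gr$members, , drop = FALSE]
    regions <- map_and_merge(sel, grp_ps)
    if (nrow(regions) == 0) next
    pssm <- build_pssm(regions, anchor_core = r3$core[1])
    assembly[[key]] <- list(ranking3 = r3, ranking4 = r4,
                            selected_motifs = sel, regions = regions,
                            pssm = pssm,
                            palindromes = palindrome_report(enriched8),
                            tss_profile = tss_distance_profile(regions, grp_ps))
  }
  write_tsv(if (length(enrich_rows) > 0) do.call(rbind, c(enrich_rows, make.row.names = FALSE))
            else data.frame(), file.path(out_dir, "enrichment.tsv"))

  if (length(assembly) > 0) {
    write_meme(lapply(assembly, `[[`, "pssm"),
               file.path(out_dir, "pssms.meme"))
    pal <- do.call(rbind, c(lapply(names(assembly), function(key) {
      cbind(group = key, assembly[[key]]$palindromes)
    }), make.row.names = FALSE))
    write_tsv(pal, file.path(out_dir, "palindromes.tsv"))
    reg <- do.call(rbind, c(lapply(names(assembly), function(key) {
      r <- assembly[[key]]$regions
      data.frame(group = key, promoter_id = r$promoter_id, start = r$start,
                 end = r$end, sequence = r$sequence)
    }), make.row.names = FALSE))
    write_tsv(reg, file.path(out_dir, "regions.tsv"))
    prof <- do.call(rbind, c(lapply(names(assembly), function(key) {
      cbind(group = key, assembly[[key]]$tss_profile)
    }), make.row.names = FALSE))
    write_tsv(prof, file.path(out_dir, "tss_profile.tsv"))
  }

  summary <- list(
    n_conditions = length(design$conditions),
    n_tfs_scanned = length(intersect(tf_ids, rownames(m))),
    n_detf_records = sum(cstf_table$is_detf),
    n_cstf_records = sum(cstf_table$is_cstf),
    group_sizes = stats::setNames(
      lapply(groups, function(g) length(g$members)), names(groups)),
    n_groups_discarded = sum(vapply(groups, `[[`, TRUE, "discarded")),
    n_enriched_motifs = stats::setNames(
      lapply(enrichment, function(e) sum(e$enriched)), names(enrichment)),
    n_assembled = length(assembly))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest <- list(
    package = "cismotif",
    package_version = as.character(utils::packageVersion("cismotif")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    n_genes = nrow(m), n_samples = ncol(m), n_promoters = nrow(ps))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cstf_table = cstf_table, groups = groups, background = bg,
                 enrichment = enrichment, assembly = assembly,
                 summary = summary))
}
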