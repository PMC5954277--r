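#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generator. Defaults
#' emulate a two-replicate multi-condition microarray compendium: log2
#' baselines around 8 with gene-to-gene spread 1.5, within-condition
#' replicate noise 0.25 (log2 units), one TF strongly induced (+3 log2
#' units) in a single condition, and a block of target genes whose
#' profiles track the TF at correlation 0.95. Promoters are 1 kb of
#' i.i.d. background sequence at the configured GC content with an
#' 8-mer planted (by overwrite, preserving length) at rate 0.8 in
#' target-gene promoters and 0.05 elsewhere.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_genes Total genes (targets and background; TFs extra).
#' @param n_tfs TF genes prepended to the gene universe.
#' @param n_conditions Number of conditions.
#' @param n_datasets Datasets the conditions are split over.
#' @param replicates Treatment and control replicates per condition.
#' @param baseline_mean,baseline_sd Per-gene baseline log2 intensity.
#' @param cstf_effect Log2 shift of the planted TF in its condition.
#' @param target_fraction Fraction of genes made TF targets.
#' @param target_correlation Intended Pearson correlation of targets
#'   with the planted TF.
#' @param noise_sd Per-sample replicate noise (log2 units).
#' @param promoter_length Promoter length in bp.
#' @param gc_content Background GC fraction.
#' @param planted_motif 8-mer planted in promoters.
#' @param plant_rate_group,plant_rate_background Planting probability in
#'   target vs non-target promoters.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 1L, n_genes = 2000L, n_tfs = 20L,
                              n_conditions = 8L, n_datasets = 1L,
                              replicates = 2L, baseline_mean = 8,
                              baseline_sd = 1.5, cstf_effect = 3,
                              target_fraction = 0.03,
                              target_correlation = 0.95, noise_sd = 0.25,
                              promoter_length = 1000L, gc_content = 0.5,
                              planted_motif = "GAATATTC",
                              plant_rate_group = 0.8,
                              plant_rate_background = 0.05) {
  stopifnot(plant_rate_group >= 0, plant_rate_group <= 1,
            plant_rate_background >= 0, plant_rate_background <= 1,
            target_correlation > -1, target_correlation <= 1,
            promoter_length >= 8, replicates >= 2,
            n_conditions >= 2, gc_content >= 0, gc_content <= 1)
  if (grepl("[^ACGT]", planted_motif) || nchar(planted_motif) != 8) {
    stop("planted_motif must be a length-8 ACGT string")
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_tfs = as.integer(n_tfs),
                 n_conditions = as.integer(n_conditions),
                 n_datasets = as.integer(n_datasets),
                 replicates = as.integer(replicates),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 cstf_effect = cstf_effect,
                 target_fraction = target_fraction,
                 target_correlation = target_correlation,
                 noise_sd = noise_sd,
                 promoter_length = as.integer(promoter_length),
                 gc_content = gc_content, planted_motif = planted_motif,
                 plant_rate_group = plant_rate_group,
                 plant_rate_background = plant_rate_background),
            class = "sim_config")
}

# deterministic sub-seed per generator component, so e.g. adding genes to
# the expression draw does not perturb promoter sampling
sub_seed <- function(seed, component) {
  offsets <- c(expression = 11L, promoters = 23L)
  (as.integer(seed) * 48271L + offsets[[component]]) %% 2147483629L
}

#' Simulate an expression matrix with a planted condition-specific TF
#'
#' Gene baselines are i.i.d. normal; each sample adds i.i.d. replicate
#' noise. The planted TF (the first TF) is shifted by `cstf_effect` in
#' the treatment samples of the planted condition (the first
#' condition). Target genes are the TF's centered profile plus noise
#' scaled so the expected Pearson correlation equals
#' `target_correlation`. Deterministic given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return List with `matrix` ([expression_matrix()]), `design`
#'   (`condition_design`) and `truth` (planted TF/condition, target ids,
#'   planted motif).
#' @export
simulate_expression <- function(cfg) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(cfg$seed, "expression"))

  tf_ids <- sprintf("TF%03d", seq_len(cfg$n_tfs))
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  all_ids <- c(tf_ids, gene_ids)
  cond_ids <- sprintf("cond%02d", seq_len(cfg$n_conditions))
  ds_of <- rep(sprintf("DS%d", seq_len(cfg$n_datasets)),
               length.out = cfg$n_conditions)

  sample_ids <- unlist(lapply(seq_len(cfg$n_conditions), function(i) {
    c(sprintf("%s_T%d", cond_ids[i], seq_len(cfg$replicates)),
      sprintf("%s_C%d", cond_ids[i], seq_len(cfg$replicates)))
  }))
  conditions <- lapply(seq_len(cfg$n_conditions), function(i) {
    list(condition_id = cond_ids[i], dataset = ds_of[i],
         treatment = sprintf("%s_T%d", cond_ids[i], seq_len(cfg$replicates)),
         control = sprintf("%s_C%d", cond_ids[i], seq_len(cfg$replicates)))
  })
  names(conditions) <- cond_ids
  datasets <- lapply(split(cond_ids, ds_of), function(cids) {
    unlist(lapply(conditions[cids], function(cc) c(cc$treatment, cc$control)),
           use.names = FALSE)
  })
  design <- condition_design(conditions, datasets)

  n_row <- length(all_ids); n_col <- length(sample_ids)
  baseline <- stats::rnorm(n_row, cfg$baseline_mean, cfg$baseline_sd)
  vals <- baseline + matrix(stats::rnorm(n_row * n_col, 0, cfg$noise_sd),
                            n_row, n_col)
  dimnames(vals) <- list(all_ids, sample_ids)

  planted_tf <- tf_ids[1]
  planted_cond <- cond_ids[1]
  tr_samples <- conditions[[planted_cond]]$treatment
  vals[planted_tf, tr_samples] <- vals[planted_tf, tr_samples] + cfg$cstf_effect

  n_targets <- round(cfg$target_fraction * cfg$n_genes)
  target_ids <- gene_ids[seq_len(n_targets)]
  if (n_targets > 0) {
    # targets live in the planted TF's dataset; outside it they keep noise
    ds_samples <- datasets[[ds_of[1]]]
    tf_profile <- vals[planted_tf, ds_samples]
    signal <- tf_profile - mean(tf_profile)
    rho <- cfg$target_correlation
    sd_sig <- stats::sd(signal)
    if (sd_sig == 0) stop("planted TF profile is constant; cannot calibrate rho")
    eps_sd <- if (rho == 1) 0 else sd_sig * sqrt(1 / rho^2 - 1)
    for (g in target_ids) {
      vals[g, ds_samples] <- baseline[match(g, all_ids)] + signal +
        stats::rnorm(length(ds_samples), 0, eps_sd)
    }
  }

  list(matrix = expression_matrix(vals),
       design = design,
       truth = list(planted_tf_id = planted_tf,
                    planted_condition = planted_cond,
                    true_target_ids = target_ids,
                    planted_motif = cfg$planted_motif,
                    tf_ids = tf_ids))
}

#' Simulate a genome and TSS table with planted promoter motifs
#'
#' One contiguous chromosome per strand block: each gene gets a
#' `promoter_length` window of i.i.d. background sequence at the
#' configured GC content, separated by spacers, with alternating +/-
#' strand TSSs to exercise strand-aware extraction. The planted motif
#' overwrites the promoter at a uniform random position with probability
#' `plant_rate_group` in target-gene promoters and
#' `plant_rate_background` elsewhere; on minus-strand genes the genomic
#' sequence carries the reverse complement so the extracted 5'->3'
#' promoter contains the motif verbatim.
#'
#' @param cfg A [simulation_config()].
#' @param gene_ids Genes to give promoters.
#' @param true_target_ids Subset of `gene_ids` planted at the group rate.
#' @return List with `genome` ([Biostrings::DNAStringSet]), `tss`
#'   (data.frame for [extract_promoters()]) and `planted_at` (named
#'   vector of 0-based motif offsets within each planted promoter, NA if
#'   unplanted).
#' @export
simulate_promoters <- function(cfg, gene_ids, true_target_ids = character(0)) {
  if (cfg$promoter_length < nchar(cfg$planted_motif)) {
    stop("promoter shorter than the planted motif")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(cfg$seed, "promoters"))

  L <- cfg$promoter_length
  spacer <- 50L
  probs <- c(A = (1 - cfg$gc_content) / 2, C = cfg$gc_content / 2,
             G = cfg$gc_content / 2, T = (1 - cfg$gc_content) / 2)
  motif <- cfg$planted_motif
  k <- nchar(motif)
  n <- length(gene_ids)
  strands <- rep(c("+", "-"), length.out = n)
  is_target <- gene_ids %in% true_target_ids

  chrom_parts <- character(n)
  tss_pos <- integer(n)
  planted_at <- stats::setNames(rep(NA_integer_, n), gene_ids)
  offset <- 0L
  for (i in seq_len(n)) {
    prom <- paste(sample(names(probs), L, replace = TRUE, prob = probs),
                  collapse = "")
    rate <- if (is_target[i]) cfg$plant_rate_group else cfg$plant_rate_background
    if (stats::runif(1) < rate) {
      at <- sample.int(L - k + 1L, 1L)  # 1-based start within promoter
      substr(prom, at, at + k - 1L) <- motif
      planted_at[i] <- at - 1L
    }
    if (strands[i] == "+") {
      # layout: [spacer][promoter][TSS base]
      chrom_parts[i] <- paste0(strrep("A", spacer), prom, "G")
      tss_pos[i] <- offset + spacer + L + 1L
    } else {
      # layout: [TSS base][revcomp(promoter)][spacer]
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(prom)))
      chrom_parts[i] <- paste0("G", rc, strrep("A", spacer))
      tss_pos[i] <- offset + 1L
    }
    offset <- offset + nchar(chrom_parts[i])
  }
  genome <- Biostrings::DNAStringSet(paste(chrom_parts, collapse = ""))
  names(genome) <- "chrSim"
  tss <- data.frame(transcript_id = paste0(gene_ids, ".1"),
                    gene_id = gene_ids, chrom = "chrSim", pos = tss_pos,
                    strand = strands, stringsAsFactors = FALSE)
  list(genome = genome, tss = tss, planted_at = planted_at)
}

# preserve the caller's RNG state around seeded simulation
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
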