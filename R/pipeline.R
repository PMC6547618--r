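#' Pipeline configuration
#'
#' One flat configuration object drives [run_pipeline()]. Every analysis
#' threshold has a configuration key whose default equals the study value
#' (consensus FDR 1e-5, miRNA logCPM gate 3, mRNA |logFC| gate 0.5,
#' consistency fractions 0.80/0.70 relaxed to 0.70/0.60 for mRNA, MLR
#' threshold -0.3, merge support 3, scored-list threshold 0.2, survival
#' percentiles 0.10/0.10).
#'
#' @param outdir Output directory (created if missing).
#' @param seed Integer seed for demo-mode data generation.
#' @param demo If `TRUE`, all inputs are generated by the synthetic-data
#'   module (written under `outdir/inputs/` and then consumed through the
#'   regular file readers); if `FALSE` the paths below must point at
#'   existing files.
#' @param mirna_counts,mirna_manifest,mrna_counts,mrna_manifest Count
#'   matrix / manifest TSV paths.
#' @param mirna_fasta,utr_fasta FASTA paths for the target-prediction
#'   stage.
#' @param gmt_file Gene-set GMT path.
#' @param validated_tsv,predicted_tsv Character vectors of target-map TSV
#'   paths (knowledgebases; prediction programs).
#' @param scored_tsv Scored target-map TSV path (TargetScan-style), or
#'   `NULL`.
#' @param survival_tsv Survival table TSV (`subject_id`, `time`, `event`,
#'   `expression`).
#' @param mirna_de,mrna_de [de_config()]s for the two modes.
#' @param mlr An [mlr_model()].
#' @param flank Flank width for AU content.
#' @param min_support,ts_threshold,ts_keep_greater Merge parameters, see
#'   [merge_target_maps()].
#' @param low_pct,high_pct Survival percentile fractions.
#' @param demo_params Named list overriding [demo_inputs()] defaults.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, demo = TRUE,
                            mirna_counts = NULL, mirna_manifest = NULL,
                            mrna_counts = NULL, mrna_manifest = NULL,
                            mirna_fasta = NULL, utr_fasta = NULL,
                            gmt_file = NULL,
                            validated_tsv = character(0),
                            predicted_tsv = character(0),
                            scored_tsv = NULL,
                            survival_tsv = NULL,
                            mirna_de = de_config("mirna"),
                            mrna_de = de_config("mrna"),
                            mlr = default_mlr_model(),
                            flank = 30L,
                            min_support = 3, ts_threshold = 0.2,
                            ts_keep_greater = TRUE,
                            low_pct = 0.1, high_pct = 0.1,
                            demo_params = list()) {
  structure(list(outdir = outdir, seed = seed, demo = demo,
                 mirna_counts = mirna_counts,
                 mirna_manifest = mirna_manifest,
                 mrna_counts = mrna_counts, mrna_manifest = mrna_manifest,
                 mirna_fasta = mirna_fasta, utr_fasta = utr_fasta,
                 gmt_file = gmt_file, validated_tsv = validated_tsv,
                 predicted_tsv = predicted_tsv, scored_tsv = scored_tsv,
                 survival_tsv = survival_tsv,
                 mirna_de = mirna_de, mrna_de = mrna_de, mlr = mlr,
                 flank = flank, min_support = min_support,
                 ts_threshold = ts_threshold,
                 ts_keep_greater = ts_keep_greater,
                 low_pct = low_pct, high_pct = high_pct,
                 demo_params = demo_params),
            class = "pipeline_config")
}

#' Generate a coupled synthetic input bundle with planted truth
#'
#' Builds every input the pipeline consumes, with the miRNA and gene count
#' matrices sharing the matched 48-pair design, planted DE miRNAs linked to
#' planted DE genes of opposite direction through synthetic target lists
#' (so end-to-end pair recovery can be measured against truth), a small
#' sequence universe with planted seed sites, a hallmark-sized gene-set
#' collection, and a survival cohort. Planted |log2FC| defaults to the
#' \[2, 4\] range, matching the magnitude of reported candidate miRNAs
#' (|logFC| > 2) in matched-pair tumor studies.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_pairs Patient pairs (default 48).
#' @param n_mirnas,n_genes Feature counts of the two matrices.
#' @param frac_de Planted DE fraction for both matrices.
#' @param logfc_range Planted |log2FC| range.
#' @param targets_per_mirna Planted opposite-direction target genes per
#'   planted DE miRNA.
#' @param n_seq_mirnas,n_seq_utrs Size of the sequence universe.
#' @param n_decoys Decoy relations added per prediction list.
#' @param survival_n,survival_hr Survival cohort size and hazard ratio.
#' @return Named list of in-memory inputs plus a `truth` element
#'   (`mirna_truth`, `gene_truth`, `planted_pairs`, `planted_sites`).
#' @export
demo_inputs <- function(seed = 1L, n_pairs = 48, n_mirnas = 400,
                        n_genes = 2000, frac_de = 0.05,
                        logfc_range = c(2, 4), targets_per_mirna = 8,
                        n_seq_mirnas = 30, n_seq_utrs = 150,
                        n_decoys = 250, survival_n = 490,
                        survival_hr = 2.5) {
  with_seed(seed, {
    sub <- sample.int(2^31 - 10, 8)

    mir <- simulate_paired_counts(n_features = n_mirnas, n_pairs = n_pairs,
                                  frac_de = frac_de,
                                  logfc_range = logfc_range,
                                  seed = sub[1], feature_prefix = "mir")
    gene <- simulate_paired_counts(n_features = n_genes, n_pairs = n_pairs,
                                   frac_de = frac_de,
                                   logfc_range = logfc_range,
                                   seed = sub[2], feature_prefix = "gene")

    mir_up <- mir$truth$feature_id[mir$truth$log2fc > 0]
    mir_dn <- mir$truth$feature_id[mir$truth$log2fc < 0]
    gene_up <- gene$truth$feature_id[gene$truth$log2fc > 0]
    gene_dn <- gene$truth$feature_id[gene$truth$log2fc < 0]

    pick <- function(pool, k) sample(pool, min(k, length(pool)))
    pairs <- list()
    for (m in mir_up) {
      for (g in pick(gene_dn, targets_per_mirna)) {
        pairs[[length(pairs) + 1L]] <- c(m, g)
      }
    }
    for (m in mir_dn) {
      for (g in pick(gene_up, targets_per_mirna)) {
        pairs[[length(pairs) + 1L]] <- c(m, g)
      }
    }
    planted_pairs <- data.frame(
      mirna_id = vapply(pairs, `[`, "", 1L),
      gene_id = vapply(pairs, `[`, "", 2L), stringsAsFactors = FALSE)

    decoy_list <- function(prov) {
      dec <- data.frame(
        mirna_id = sample(mir$truth$feature_id, n_decoys, replace = TRUE),
        gene_id = sample(gene$truth$feature_id, n_decoys, replace = TRUE),
        stringsAsFactors = FALSE)
      rel <- rbind(planted_pairs, dec)
      rel$provenance <- prov
      rel$score <- NA_real_
      target_map(rel)
    }
    predicted <- list(decoy_list("predicted:progA"),
                      decoy_list("predicted:progB"),
                      decoy_list("predicted:progC"))

    val_idx <- sample.int(nrow(planted_pairs),
                          min(30L, nrow(planted_pairs)))
    validated <- target_map(data.frame(
      mirna_id = planted_pairs$mirna_id[val_idx],
      gene_id = planted_pairs$gene_id[val_idx],
      provenance = rep("validated", length(val_idx)),
      score = rep(NA_real_, length(val_idx)),
      stringsAsFactors = FALSE))

    scored_pass <- planted_pairs
    scored_pass$score <- runif(nrow(scored_pass), 0.3, 1)
    scored_fail <- data.frame(
      mirna_id = sample(mir$truth$feature_id, n_decoys, replace = TRUE),
      gene_id = sample(gene$truth$feature_id, n_decoys, replace = TRUE),
      score = runif(n_decoys, 0, 0.15), stringsAsFactors = FALSE)
    scored <- rbind(scored_pass, scored_fail)
    scored$provenance <- "predicted:targetscan"
    scored <- target_map(scored)

    seqs <- simulate_sequence_universe(n_mirnas = n_seq_mirnas,
                                       n_utrs = n_seq_utrs,
                                       sites_per_utr = 1, seed = sub[3])

    all_genes <- gene$truth$feature_id
    gmt <- lapply(seq_len(15), function(i) sample(all_genes, 100))
    names(gmt) <- sprintf("RANDOM_SET_%02d", seq_len(15))
    gmt$PLANTED_UP_PROGRAM <- unique(c(gene_up, sample(all_genes, 40)))
    gmt$PLANTED_DOWN_PROGRAM <- unique(c(gene_dn, sample(all_genes, 40)))

    cohort <- simulate_survival_cohort(n = survival_n,
                                       hazard_ratio = survival_hr,
                                       censor_rate = 0.3, seed = sub[4])

    list(mirna = mir$counts, mrna = gene$counts,
         mirnas_fasta = seqs$mirnas, utrs_fasta = seqs$utrs,
         gmt = gmt, validated = list(validated), predicted = predicted,
         scored = scored, cohort = cohort,
         truth = list(mirna_truth = mir$truth, gene_truth = gene$truth,
                      planted_pairs = planted_pairs,
                      planted_sites = seqs$planted_sites))
  })
}

.write_demo_inputs <- function(inputs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_matrix_tsv(inputs$mirna$counts, p("mirna_counts.tsv"))
  write_manifest_tsv(inputs$mirna$manifest, p("mirna_manifest.tsv"))
  write_matrix_tsv(inputs$mrna$counts, p("mrna_counts.tsv"))
  write_manifest_tsv(inputs$mrna$manifest, p("mrna_manifest.tsv"))
  write_fasta(inputs$mirnas_fasta, p("mirnas.fa"))
  write_fasta(inputs$utrs_fasta, p("utrs.fa"))
  write_gmt(inputs$gmt, p("gene_sets.gmt"))
  write_target_map_tsv(inputs$validated[[1]], p("targets_validated.tsv"))
  for (i in seq_along(inputs$predicted)) {
    write_target_map_tsv(inputs$predicted[[i]],
                         p(sprintf("targets_predicted_%d.tsv", i)))
  }
  write_target_map_tsv(inputs$scored, p("targets_scored.tsv"))
  utils::write.table(inputs$cohort, p("survival.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(inputs$truth$planted_pairs, p("truth_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(inputs$truth$mirna_truth, p("truth_mirna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(inputs$truth$gene_truth, p("truth_gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(mirna_counts = p("mirna_counts.tsv"),
       mirna_manifest = p("mirna_manifest.tsv"),
       mrna_counts = p("mrna_counts.tsv"),
       mrna_manifest = p("mrna_manifest.tsv"),
       mirna_fasta = p("mirnas.fa"), utr_fasta = p("utrs.fa"),
       gmt_file = p("gene_sets.gmt"),
       validated_tsv = p("targets_validated.tsv"),
       predicted_tsv = vapply(seq_along(inputs$predicted), function(i)
         p(sprintf("targets_predicted_%d.tsv", i)), character(1)),
       scored_tsv = p("targets_scored.tsv"),
       survival_tsv = p("survival.tsv"))
}

.stage_msg <- function(stage) {
  message(sprintf("[mirpair] stage: %s", stage))
}

#' Run the full integrative pipeline
#'
#' Executes normalize -> differential expression (miRNA and mRNA modes) ->
#' target prediction and merge -> anticorrelated pair integration ->
#' gene-set enrichment -> survival stratification, writing one TSV per
#' stage plus a machine-readable run manifest (`manifest.json` and
#' `manifest.tsv`: stage, output file, row count, md5 hash). With
#' `config$demo = TRUE` all inputs are first generated by [demo_inputs()]
#' under `outdir/inputs/` and then consumed through the regular file
#' readers, so a demo run exercises the external interfaces end to end.
#' Re-running with an identical configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list: `manifest` (data frame), `de_mirna`,
#'   `de_mrna`, `targets`, `pairs`, `enrichment`, `survival`, and in demo
#'   mode `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL

  if (isTRUE(config$demo)) {
    .stage_msg("simulate (demo inputs)")
    inputs <- do.call(demo_inputs,
                      c(list(seed = config$seed), config$demo_params))
    truth <- inputs$truth
    paths <- .write_demo_inputs(inputs, file.path(outdir, "inputs"))
    config[names(paths)] <- paths
  }

  manifest <- list()
  note <- function(stage, file, rows) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, output = basename(file), rows = rows,
      md5 = unname(tools::md5sum(file)), status = "ok",
      stringsAsFactors = FALSE)
  }

  .stage_msg("de (miRNA mode)")
  mirna_counts <- read_paired_counts(config$mirna_counts,
                                     config$mirna_manifest)
  de_mirna <- select_de_features(mirna_counts, config$mirna_de)
  f <- file.path(outdir, "de_mirna.tsv")
  utils::write.table(de_mirna, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("de_mirna", f, nrow(de_mirna))

  .stage_msg("de (mRNA mode)")
  mrna_counts <- read_paired_counts(config$mrna_counts,
                                    config$mrna_manifest)
  de_mrna <- select_de_features(mrna_counts, config$mrna_de)
  f <- file.path(outdir, "de_mrna.tsv")
  utils::write.table(de_mrna, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("de_mrna", f, nrow(de_mrna))

  .stage_msg("targets (MLR prediction + merge)")
  mlr_map <- predict_targets(read_fasta_rna(config$mirna_fasta),
                             read_fasta_rna(config$utr_fasta),
                             model = config$mlr, flank = config$flank)
  f <- file.path(outdir, "targets_mlr.tsv")
  write_target_map_tsv(mlr_map, f)
  note("targets_mlr", f, nrow(mlr_map))

  validated <- lapply(config$validated_tsv, read_target_map_tsv)
  predicted <- lapply(config$predicted_tsv, read_target_map_tsv)
  scored <- if (!is.null(config$scored_tsv)) {
    read_target_map_tsv(config$scored_tsv)
  }
  merged <- merge_target_maps(validated, predicted, scored,
                              min_support = config$min_support,
                              ts_threshold = config$ts_threshold,
                              ts_keep_greater = config$ts_keep_greater)
  merged <- target_map(rbind(as.data.frame(merged),
                             as.data.frame(mlr_map)))
  f <- file.path(outdir, "targets_merged.tsv")
  write_target_map_tsv(merged, f)
  note("targets_merged", f, nrow(merged))

  .stage_msg("integrate (anticorrelated pairs)")
  demirs <- de_mirna[de_mirna$called, c("feature_id", "direction")]
  degs <- de_mrna[de_mrna$called, c("feature_id", "direction")]
  pairs <- anticorrelated_pairs(demirs, degs, merged)
  f <- file.path(outdir, "pairs.tsv")
  utils::write.table(pairs, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("pairs", f, nrow(pairs))

  .stage_msg("enrich (gene sets)")
  gmt <- read_gmt(config$gmt_file)
  universe <- de_mrna$feature_id  # expressed genes (prefilter survivors)
  queries <- list(
    all_up = de_mrna$feature_id[de_mrna$called & de_mrna$direction == "up"],
    all_down = de_mrna$feature_id[de_mrna$called &
                                    de_mrna$direction == "down"],
    target_up = unique(pairs$gene_id[pairs$gene_dir == "up"]),
    target_down = unique(pairs$gene_id[pairs$gene_dir == "down"]))
  enr <- do.call(rbind, lapply(names(queries), function(nm) {
    if (!length(queries[[nm]])) return(NULL)
    e <- hypergeometric_enrich(queries[[nm]], gmt, universe,
                               query_direction = sub("^.*_", "", nm))
    e$query <- nm
    e
  }))
  if (is.null(enr)) {
    enr <- data.frame(set_name = character(0), k = integer(0),
                      K = integer(0), n = integer(0), N = integer(0),
                      p = numeric(0), q = numeric(0),
                      query_direction = character(0), query = character(0))
  }
  f <- file.path(outdir, "enrichment.tsv")
  utils::write.table(enr, f, sep = "\t", quote = FALSE, row.names = FALSE)
  note("enrichment", f, nrow(enr))

  .stage_msg("survive (percentile stratification)")
  cohort <- utils::read.delim(config$survival_tsv,
                              stringsAsFactors = FALSE)
  surv <- survival_stratify(cohort, config$low_pct, config$high_pct)
  km_tab <- do.call(rbind, lapply(names(surv$km), function(g) {
    k <- surv$km[[g]]; k$group <- g; k
  }))
  f <- file.path(outdir, "survival_km.tsv")
  utils::write.table(km_tab, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("survival_km", f, nrow(km_tab))
  lr_tab <- data.frame(chi_square = surv$logrank$chi_square,
                       p = surv$logrank$p,
                       n_low = surv$logrank$n[["low"]],
                       n_high = surv$logrank$n[["high"]])
  f <- file.path(outdir, "survival_logrank.tsv")
  utils::write.table(lr_tab, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("survival_logrank", f, 1L)

  manifest <- do.call(rbind, manifest)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(manifest = manifest, de_mirna = de_mirna,
                 de_mrna = de_mrna, targets = merged, pairs = pairs,
                 enrichment = enr, survival = surv, truth = truth))
}
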