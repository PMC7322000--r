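# One config drives simulate -> (chip | rna | screen); a single global seed
# is expanded into per-stage substreams so any stage can be re-run
# independently with identical randomness.

run_config_schema <- list(
  top = c("seed", "stages", "simulation", "chip", "rna", "screen"),
  chip = c("tau", "level", "mode", "condition", "control_assay",
           "metaprofile_subfamily", "n_bins", "write_bedgraph",
           "write_fragments"),
  rna = c("condition_a", "condition_b", "pseudocount_cpm", "lfc_threshold",
          "min_cpm", "background_mode"),
  screen = c("pseudocount", "min_shown", "hit_min_peptides", "hit_fold"))

#' Build and validate a pipeline run configuration
#'
#' @param seed global seed; expanded into per-stage substreams
#' @param stages subset of c("simulate", "chip", "rna", "screen"); the
#'   simulate stage always runs (it defines the shared genome)
#' @param simulation named list of [simulation_config()] overrides
#' @param chip named list: tau, level, mode, condition, control_assay,
#'   metaprofile_subfamily, n_bins, write_bedgraph, write_fragments
#' @param rna named list: condition_a, condition_b, pseudocount_cpm,
#'   lfc_threshold, min_cpm, background_mode
#' @param screen named list: pseudocount, min_shown, hit_min_peptides,
#'   hit_fold
#' @return a validated list of class `RunConfig`
#' @export
run_config <- function(seed = 1L,
                       stages = c("chip", "rna", "screen"),
                       simulation = list(), chip = list(), rna = list(),
                       screen = list(), ...) {
  extra <- list(...)
  if (length(extra) > 0L) {
    stop("unknown config key: ", paste(names(extra), collapse = ", "))
  }
  cfg <- list(seed = as.integer(seed), stages = stages,
              simulation = simulation,
              chip = utils::modifyList(
                list(tau = 1.5, level = "subfamily", mode = "midpoint",
                     condition = "WT", control_assay = "input",
                     metaprofile_subfamily = "IAPEz", n_bins = 20L,
                     write_bedgraph = FALSE, write_fragments = FALSE), chip),
              rna = utils::modifyList(
                list(condition_a = "dCas9-OGA", condition_b = "dCas9-OGA_D242A",
                     pseudocount_cpm = 0.5, lfc_threshold = 1, min_cpm = 1,
                     background_mode = "pooled"), rna),
              screen = utils::modifyList(
                list(pseudocount = 1, min_shown = 3L, hit_min_peptides = 6L,
                     hit_fold = 2), screen))
  validate_run_config_keys(list(seed = seed, stages = stages,
                                simulation = simulation, chip = chip,
                                rna = rna, screen = screen))
  bad <- setdiff(stages, c("simulate", "chip", "rna", "screen"))
  if (length(bad) > 0L) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  class(cfg) <- "RunConfig"
  cfg
}

validate_run_config_keys <- function(given) {
  unknown <- setdiff(names(given), run_config_schema$top)
  if (length(unknown) > 0L) {
    stop("unknown config key: ", paste(unknown, collapse = ", "))
  }
  for (stage in c("chip", "rna", "screen")) {
    unknown <- setdiff(names(given[[stage]]), run_config_schema[[stage]])
    if (length(unknown) > 0L) {
      stop("unknown config key: ", stage, ".",
           paste(unknown, collapse = paste0(", ", stage, ".")))
    }
  }
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror the [run_config()] arguments
#' @return a `RunConfig`
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  validate_run_config_keys(y)
  if (!is.null(y$simulation$families)) {
    y$simulation$families <- as.data.frame(
      lapply(y$simulation$families, unlist), stringsAsFactors = FALSE)
  }
  do.call(run_config, y)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline from one configuration
#'
#' Deterministic given (config, seed): simulates the genome, then runs the
#' selected stages (ChIP enrichment + ICR occupancy + LTR metaprofile;
#' RNA FPKM/background adjustment/log2FC/reactivation; interaction screen),
#' writing every result as TSV/BED/JSON under `outdir` together with the
#' serialized configuration and a checksum manifest of produced files.
#' Per-stage record counts are logged to stderr.
#'
#' @param config a `RunConfig`
#' @param outdir output directory (created if needed)
#' @return invisible list with the in-memory stage results and the file
#'   manifest
#' @export
run_pipeline <- function(config, outdir) {
  if (!inherits(config, "RunConfig")) stop("config must be a RunConfig")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  results <- list()

  sim_cfg <- do.call(simulation_config,
                     c(list(seed = config$seed), config$simulation))
  sim <- simulate_genome(sim_cfg)
  message("simulate: ", nrow(sim$annotation$intervals),
          " repeat intervals, ", nrow(sim$icrs), " ICRs")
  files <- c(files,
             write_repeat_bed(sim$annotation, file.path(outdir, "repeats.bed")),
             write_icr_bed(sim$icrs, file.path(outdir, "icrs.bed")),
             write_ground_truth(sim, file.path(outdir, "ground_truth.json")))
  cfg_for_yaml <- unclass(config)
  cfg_for_yaml$simulation <- rapply(config$simulation, as.vector, how = "replace")
  yaml::write_yaml(cfg_for_yaml, file.path(outdir, "config.yaml"))
  files <- c(files, file.path(outdir, "config.yaml"))
  results$sim <- sim

  if ("chip" %in% config$stages) {
    cc <- config$chip
    targets <- names(sim$config$chip$targets)
    all_frags <- list()
    manifests <- list()
    for (tgt in targets) {
      exp <- simulate_chip_experiment(sim, tgt, condition = cc$condition,
                                      control_assay = cc$control_assay,
                                      seed = substream_seed(config$seed,
                                                            10L + match(tgt, targets)))
      all_frags <- c(all_frags, exp$fragments)
      manifests[[tgt]] <- exp$manifest
    }
    manifest <- sample_manifest(do.call(rbind, lapply(manifests, as.data.frame)))
    all_frags <- lapply(all_frags, deduplicate)
    message("chip: ", length(all_frags), " samples of ",
            sim$config$chip$depth, " fragments (pre-deduplication)")
    counts <- count_by_unit(all_frags, sim$annotation, level = cc$level,
                            mode = cc$mode)
    enr <- list()
    for (tgt in targets) {
      e <- enrichment(counts, manifest,
                      treatment_key = list(assay = "chip", target = tgt,
                                           condition = cc$condition),
                      control_key = list(assay = cc$control_assay,
                                         target = tgt,
                                         condition = cc$condition),
                      tau = cc$tau)
      e$target <- tgt
      enr[[tgt]] <- e
    }
    enr_tab <- do.call(rbind, enr)
    rownames(enr_tab) <- NULL
    files <- c(files, write_tsv(enr_tab, file.path(outdir, "chip_enrichment.tsv")))
    occ <- icr_occupancy(all_frags, sim$icrs, manifest, targets,
                         condition = cc$condition, tau = cc$tau)
    files <- c(files,
               write_tsv(occ$table, file.path(outdir, "icr_occupancy.tsv")),
               write_tsv(as.data.frame(occ$summary),
                         file.path(outdir, "icr_summary.tsv")))
    chip1 <- all_frags[[manifest$sample_id[manifest$assay == "chip"][1]]]
    meta <- ltr_metaprofile(chip1, sim$annotation,
                            cc$metaprofile_subfamily, n_bins = cc$n_bins)
    meta$profile$contrast <- meta$contrast
    files <- c(files, write_tsv(meta$profile,
                                file.path(outdir, "ltr_metaprofile.tsv")))
    if (isTRUE(cc$write_bedgraph)) {
      cov <- per_contig_coverage(chip1)
      cov <- lapply(cov, as.numeric)
      files <- c(files, write_bedgraph(cov, file.path(outdir, "chip_rep1.bedgraph")))
    }
    if (isTRUE(cc$write_fragments)) {
      for (id in names(all_frags)) {
        files <- c(files, write_fragments_bed(
          all_frags[[id]], file.path(outdir, paste0("fragments_", id, ".bed"))))
      }
    }
    results$chip <- list(counts = counts, enrichment = enr_tab,
                         icr = occ, metaprofile = meta, manifest = manifest)
  }

  if ("rna" %in% config$stages) {
    rc <- config$rna
    rna <- simulate_rna_counts(sim, seed = substream_seed(config$seed, 20L))
    message("rna: ", ncol(rna$counts$counts), " samples, ",
            nrow(rna$counts$counts), " units")
    expr <- fpkm(rna$counts)
    expr <- background_adjust(expr, sim$annotation, rc$background_mode)
    fc <- log2fc(expr, rna$manifest, sim$annotation,
                 condition_a = rc$condition_a, condition_b = rc$condition_b,
                 pseudocount_cpm = rc$pseudocount_cpm)
    react <- reactivation_report(fc, sim$annotation,
                                 lfc_threshold = rc$lfc_threshold,
                                 min_cpm = rc$min_cpm)
    expr_long <- data.frame(
      unit = rep(rownames(expr$fpkm), ncol(expr$fpkm)),
      sample = rep(colnames(expr$fpkm), each = nrow(expr$fpkm)),
      count = as.numeric(expr$counts),
      fpkm = as.numeric(expr$fpkm),
      adjusted_fpkm = as.numeric(expr$adjusted_fpkm),
      adjusted_cpm = as.numeric(expr$adjusted_cpm),
      stringsAsFactors = FALSE)
    files <- c(files,
               write_tsv(expr_long, file.path(outdir, "rna_expression.tsv")),
               write_tsv(fc, file.path(outdir, "rna_log2fc.tsv")),
               write_tsv(react$calls, file.path(outdir, "rna_reactivation.tsv")))
    results$rna <- list(counts = rna$counts, expr = expr, fc = fc,
                        reactivation = react,
                        ground_truth = rna$ground_truth)
  }

  if ("screen" %in% config$stages) {
    sc <- config$screen
    conds <- sim$config$proteomics$conditions
    pep <- simulate_peptide_table(
      n_background = sim$config$proteomics$n_background,
      background_mean = sim$config$proteomics$background_mean,
      correlation = sim$config$proteomics$correlation,
      hits = sim$config$proteomics$hits,
      conditions = conds,
      seed = substream_seed(config$seed, 30L))
    message("screen: ", nrow(pep$table), " proteins")
    res <- screen(pep$table, ref = conds[1], cmp = conds[2],
                  pseudocount = sc$pseudocount, min_shown = sc$min_shown,
                  hit_min_peptides = sc$hit_min_peptides,
                  hit_fold = sc$hit_fold)
    files <- c(files,
               write_tsv(pep$table, file.path(outdir, "peptide_counts.tsv")),
               write_tsv(as.data.frame(res), file.path(outdir, "screen_result.tsv")),
               export_scatter(res, file.path(outdir, "screen_scatter.tsv")))
    results$screen <- list(table = pep$table, result = res,
                           ground_truth = pep$ground_truth)
  }

  checksums <- tools::md5sum(files)
  manifest_df <- data.frame(file = basename(names(checksums)),
                            md5 = as.character(checksums),
                            stringsAsFactors = FALSE)
  write_tsv(manifest_df, file.path(outdir, "manifest.tsv"))
  message("run_pipeline: wrote ", length(files) + 1L, " files to ", outdir)
  results$manifest <- manifest_df
  invisible(results)
}
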