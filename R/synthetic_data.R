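# Synthetic data with planted effects. The generator emulates the structure
# of the real assays -- a multi-family repeat landscape (an LTR
# retrotransposon family with 5'LTR/internal/3'LTR structure, a second LTR
# family, LINEs, SINEs and transcriptionally dead DNA transposons), ICR
# intervals, ChIP/input fragment sets with family- and region-specific
# enrichment, replicate RNA count tables with a condition-specific
# reactivation of one LTR subfamily, and two-condition peptide-count tables
# with one planted methylation-dependent interactor -- so every estimator
# can be checked by parameter recovery at desk scale.

default_families <- function() {
  data.frame(
    subfamily = c("IAPEz", "MERVL", "L1Md_T", "B1_Mus1", "Charlie1", "Tigger1"),
    family    = c("ERVK", "ERVL", "L1", "Alu", "hAT-Charlie", "TcMar-Tigger"),
    repclass  = c("LTR", "LTR", "LINE", "SINE", "DNA", "DNA"),
    n_copies  = c(12L, 8L, 10L, 40L, 20L, 15L),
    element_length = c(5000L, 3000L, 6000L, 150L, 800L, 600L),
    has_ltr_structure = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    ltr_length = c(400L, 0L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
}

default_icrs <- function() {
  data.frame(
    name = c("Kcnq1ot1", "Peg3", "Impact", "IG-DMR"),
    length = c(2000L, 2000L, 2000L, 2000L),
    methylated_allele = c("maternal", "maternal", "maternal", "paternal"),
    stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' Bundles every generator parameter with defaults chosen to mirror the
#' study conditions at desk scale: a 500 kb toy genome; an IAP-like
#' LTR-structured ERVK subfamily plus a second LTR family, a LINE, a SINE
#' and two DNA-transposon subfamilies (the inactive background); four ICRs;
#' ChIP enrichment of the LTR subfamilies and ICRs over a uniform input with
#' a 3x promoter boost on 5' LTRs; replicate RNA counts with the IAP-like
#' subfamily reactivated (+3 log2) in the deGlcNAcylation condition; and a
#' peptide-count screen with one planted methylation-dependent interactor
#' over correlated background proteins.
#'
#' @param seed integer; fixes every stochastic output bit-for-bit
#' @param genome list(n_contigs, contig_length)
#' @param families data.frame(subfamily, family, repclass, n_copies,
#'   element_length, has_ltr_structure, ltr_length)
#' @param icrs data.frame(name, length, methylated_allele)
#' @param chip list(targets = per-target named subfamily->enrichment vector,
#'   icr_enrichment = per-target scalar, promoter_boost, depth,
#'   fragment_length, n_chip_reps, n_control_reps)
#' @param rna list(baseline_expression = named per-subfamily per-kb rate,
#'   log2fc = list(condition -> named per-subfamily log2 effect),
#'   conditions, n_reps, depth, dispersion); dispersion is the extra-Poisson
#'   coefficient of variation among replicates (NB size = 1/dispersion^2)
#' @param proteomics list(n_background, background_mean, correlation,
#'   conditions, hits = data.frame(protein, mean_ref, mean_cmp))
#' @return a validated list of class `SimulationConfig`
#' @export
simulation_config <- function(seed = 1L,
                              genome = list(n_contigs = 1L,
                                            contig_length = 5e5),
                              families = default_families(),
                              icrs = default_icrs(),
                              chip = list(),
                              rna = list(),
                              proteomics = list()) {
  chip_default <- list(
    targets = list(
      "O-GlcNAc" = c(IAPEz = 4, MERVL = 3),
      "TRIM28"   = c(IAPEz = 4, MERVL = 3)),
    icr_enrichment = c("O-GlcNAc" = 3, "TRIM28" = 3),
    promoter_boost = 3,
    depth = 1e5,
    fragment_length = 50L,
    n_chip_reps = 3L,
    n_control_reps = 2L)
  rna_default <- list(
    baseline_expression = c(IAPEz = 2, MERVL = 1, L1Md_T = 2, B1_Mus1 = 8,
                            Charlie1 = 0.05, Tigger1 = 0.05),
    log2fc = list("dCas9-OGA" = c(IAPEz = 3)),
    conditions = c("dCas9-OGA_D242A", "dCas9-OGA"),
    n_reps = 3L,
    depth = 1e6,
    dispersion = 0.1)
  prot_default <- list(
    n_background = 300L,
    background_mean = 5,
    correlation = 0.9,
    conditions = c("WT", "Dnmt1KO"),
    hits = data.frame(protein = "OGT", mean_ref = 20, mean_cmp = 2,
                      stringsAsFactors = FALSE))
  cfg <- list(seed = as.integer(seed), genome = genome, families = families,
              icrs = icrs,
              chip = utils::modifyList(chip_default, chip),
              rna = utils::modifyList(rna_default, rna),
              proteomics = utils::modifyList(prot_default, proteomics))
  validate_simulation_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_simulation_config <- function(cfg) {
  if (cfg$genome$n_contigs < 1L || cfg$genome$contig_length <= 0) {
    stop("genome must have >= 1 contig of positive length")
  }
  fam <- cfg$families
  if (nrow(fam) > 0L) {
    if (any(fam$element_length <= 0) || any(fam$n_copies < 0)) {
      stop("family lengths/copy numbers must be positive")
    }
    if (any(fam$has_ltr_structure &
            (fam$ltr_length <= 0 | 2 * fam$ltr_length >= fam$element_length))) {
      stop("LTR-structured families need 0 < 2*ltr_length < element_length")
    }
    planted <- sum(fam$n_copies * fam$element_length)
    if (planted >= 0.8 * cfg$genome$n_contigs * cfg$genome$contig_length) {
      stop("planted repeat length exceeds 80% of the genome; lower the density")
    }
  }
  for (e in cfg$chip$targets) {
    if (any(!is.finite(e)) || any(e < 0)) stop("enrichment factors must be finite and >= 0")
  }
  if (cfg$chip$depth <= 0 || cfg$chip$fragment_length <= 0) {
    stop("chip depth and fragment length must be positive")
  }
  if (cfg$rna$dispersion < 0) stop("dispersion must be >= 0")
  invisible(cfg)
}

# deterministic per-stage substream so stages can be re-run independently
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)
}

#' Simulate the toy genome: repeat annotation, ICRs and ground truth
#'
#' Repeat copies are placed uniformly at random without overlap (bounded
#' rejection sampling); LTR-structured families emit a
#' five_prime_ltr/internal/three_prime_ltr interval triplet per copy with
#' identical LTR lengths, orientation-flipped on minus-strand copies; ICRs
#' are placed in repeat-free gaps. Sequence content is irrelevant to
#' counting and generated only on demand by [write_genome_fasta()].
#'
#' @param config a `SimulationConfig`
#' @return object of class `RepeatSimulation`: list with `contigs` (named
#'   length vector), `annotation`, `icrs`, `config`, `ground_truth`
#' @export
simulate_genome <- function(config) {
  validate_simulation_config(config)
  set.seed(substream_seed(config$seed, 1L))
  contigs <- stats::setNames(
    rep(config$genome$contig_length, config$genome$n_contigs),
    paste0("chr", seq_len(config$genome$n_contigs)))
  fam <- config$families
  elements <- if (nrow(fam) > 0L) {
    fam[rep(seq_len(nrow(fam)), fam$n_copies), , drop = FALSE]
  } else fam
  placed <- place_intervals(contigs,
                            if (nrow(elements) > 0L) elements$element_length
                            else integer(0))
  rows <- list()
  for (i in seq_len(nrow(elements))) {
    el <- elements[i, ]
    p <- placed[i, ]
    strand <- sample(c("+", "-"), 1L)
    if (el$has_ltr_structure) {
      b <- c(p$start, p$start + el$ltr_length,
             p$start + el$element_length - el$ltr_length,
             p$start + el$element_length)
      roles <- if (strand == "+") {
        c("five_prime_ltr", "internal", "three_prime_ltr")
      } else {
        c("three_prime_ltr", "internal", "five_prime_ltr")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contig = p$contig, start = b[1:3], end = b[2:4], strand = strand,
        subfamily = el$subfamily, family = el$family, repclass = el$repclass,
        role = roles, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = p$contig, start = p$start,
        end = p$start + el$element_length, strand = strand,
        subfamily = el$subfamily, family = el$family, repclass = el$repclass,
        role = "unassigned", stringsAsFactors = FALSE)
    }
  }
  intervals <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(contig = character(0), start = numeric(0), end = numeric(0),
               strand = character(0), subfamily = character(0),
               family = character(0), repclass = character(0),
               role = character(0), stringsAsFactors = FALSE)
  }
  annotation <- repeat_annotation(intervals)
  icr_cfg <- config$icrs
  icr_placed <- place_intervals(contigs, icr_cfg$length, avoid = placed)
  icrs <- data.frame(contig = icr_placed$contig, start = icr_placed$start,
                     end = icr_placed$start + icr_cfg$length,
                     name = icr_cfg$name,
                     methylated_allele = icr_cfg$methylated_allele,
                     stringsAsFactors = FALSE)
  ground_truth <- list(
    chip = list(targets = config$chip$targets,
                icr_enrichment = config$chip$icr_enrichment,
                promoter_boost = config$chip$promoter_boost),
    rna = list(baseline_expression = config$rna$baseline_expression,
               log2fc = config$rna$log2fc),
    proteomics = list(hits = config$proteomics$hits))
  structure(list(contigs = contigs, annotation = annotation, icrs = icrs,
                 config = config, ground_truth = ground_truth),
            class = "RepeatSimulation")
}

#' @export
print.RepeatSimulation <- function(x, ...) {
  cat("RepeatSimulation:", length(x$contigs), "contig(s),",
      sum(x$contigs), "bp;", nrow(x$annotation$intervals),
      "repeat intervals;", nrow(x$icrs), "ICRs\n")
  invisible(x)
}

# place lengths[] without overlap, uniformly at random; bounded retries
place_intervals <- function(contigs, lengths, avoid = NULL) {
  placed <- if (is.null(avoid)) {
    data.frame(contig = character(0), start = numeric(0), end = numeric(0),
               stringsAsFactors = FALSE)
  } else avoid
  out <- vector("list", length(lengths))
  for (i in seq_along(lengths)) {
    len <- lengths[i]
    ok <- FALSE
    for (try in seq_len(1000L)) {
      ct <- names(contigs)[sample.int(length(contigs), 1L,
                                      prob = as.numeric(contigs))]
      L <- contigs[[ct]]
      if (L < len) next
      s <- floor(stats::runif(1L, 0, L - len + 1))
      same <- placed$contig == ct
      if (!any(same & placed$start < s + len & placed$end > s)) {
        row <- data.frame(contig = ct, start = s, end = s + len,
                          stringsAsFactors = FALSE)
        placed <- rbind(placed, row)
        out[[i]] <- row
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place a ", len,
           " bp interval after 1000 tries; lower the repeat density")
    }
  }
  if (length(out) == 0L) {
    return(data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write a random-sequence FASTA for the simulated genome
#'
#' Counting consumes alignments, so sequence content is inert; uniform
#' random nucleotides are emitted purely to keep the dataset complete in
#' standard formats.
#'
#' @param sim a `RepeatSimulation`
#' @param path output FASTA
#' @return `path`, invisibly
#' @export
write_genome_fasta <- function(sim, path) {
  set.seed(substream_seed(sim$config$seed, 2L))
  con <- file(path, "w")
  on.exit(close(con))
  for (ct in names(sim$contigs)) {
    writeLines(paste0(">", ct), con)
    n <- sim$contigs[[ct]]
    seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    writeLines(substring(seq, seq(1, n, 70), pmin(seq(70, n + 69, 70), n)),
               con)
  }
  invisible(path)
}

# piecewise-constant fragment-start intensity over the genome for one target
chip_intensity_intervals <- function(sim, target) {
  iv <- sim$annotation$intervals
  cfg <- sim$config$chip
  rows <- list()
  for (ct in names(sim$contigs)) {
    feat <- rbind(
      if (nrow(iv) > 0L) {
        data.frame(start = iv$start, end = iv$end, kind = "repeat",
                   subfamily = iv$subfamily, role = iv$role,
                   stringsAsFactors = FALSE)[iv$contig == ct, , drop = FALSE]
      },
      if (nrow(sim$icrs) > 0L) {
        data.frame(start = sim$icrs$start, end = sim$icrs$end, kind = "icr",
                   subfamily = sim$icrs$name, role = "unassigned",
                   stringsAsFactors = FALSE)[sim$icrs$contig == ct, , drop = FALSE]
      })
    feat <- feat[order(feat$start), , drop = FALSE]
    e <- rep(1, nrow(feat))
    if (!is.null(target)) {
      tv <- cfg$targets[[target]]
      if (is.null(tv)) stop("no chip target spec for ", target)
      hit <- feat$kind == "repeat" & feat$subfamily %in% names(tv)
      e[hit] <- tv[feat$subfamily[hit]]
      boost <- hit & feat$role == "five_prime_ltr"
      e[boost] <- e[boost] * cfg$promoter_boost
      ie <- cfg$icr_enrichment[[target]]
      if (!is.null(ie) && !is.na(ie)) e[feat$kind == "icr"] <- ie
    }
    # fill gaps at e = 1
    bounds <- c(0, as.numeric(t(cbind(feat$start, feat$end))),
                sim$contigs[[ct]])
    seg_start <- bounds[-length(bounds)]
    seg_end <- bounds[-1]
    seg_e <- rep(1, length(seg_start))
    if (nrow(feat) > 0L) seg_e[seq(2, length(seg_e), by = 2)] <- e
    keep <- seg_end > seg_start
    rows[[ct]] <- data.frame(contig = ct, start = seg_start[keep],
                             end = seg_end[keep], e = seg_e[keep],
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate one ChIP (or input/IgG) fragment sample
#'
#' Fragment start positions are drawn from a piecewise-constant intensity
#' proportional to the planted enrichment e(x): 1 everywhere for
#' input/IgG (`target = NULL`), the per-subfamily factor over targeted
#' repeat intervals (times the promoter boost over 5' LTRs) and the per-ICR
#' factor over ICRs for a ChIP sample. Exactly `depth` fragments of fixed
#' length are emitted.
#'
#' @param sim a `RepeatSimulation`
#' @param target ChIP target name, or `NULL` for a control sample
#' @param depth number of fragments
#' @param fragment_length fragment length in bp
#' @param seed integer seed for this sample
#' @return an `AlignedFragmentSet`
#' @export
simulate_chip_sample <- function(sim, target = NULL,
                                 depth = sim$config$chip$depth,
                                 fragment_length = sim$config$chip$fragment_length,
                                 seed = sim$config$seed) {
  set.seed(seed)
  segs <- chip_intensity_intervals(sim, target)
  w <- (segs$end - segs$start) * segs$e
  idx <- sample.int(nrow(segs), depth, replace = TRUE, prob = w)
  offset <- floor(stats::runif(depth) * (segs$end[idx] - segs$start[idx]))
  start <- segs$start[idx] + offset
  L <- sim$contigs[segs$contig[idx]]
  start <- pmin(start, L - fragment_length)
  fragment_set(data.frame(
    contig = segs$contig[idx], start = start,
    end = start + fragment_length,
    strand = sample(c("+", "-"), depth, replace = TRUE),
    stringsAsFactors = FALSE))
}

#' Simulate a replicated ChIP experiment with matched controls
#'
#' @param sim a `RepeatSimulation`
#' @param target ChIP target name
#' @param condition condition label (default "WT")
#' @param control_assay `"input"` or `"igg"`
#' @param n_chip,n_control replicate counts (defaults from the config:
#'   ChIP triplicates over input duplicates)
#' @param depth,fragment_length per-sample fragment count and length
#' @param seed base seed; each sample uses an independent substream
#' @return list with `fragments` (named list of `AlignedFragmentSet`) and
#'   `manifest` (a `SampleManifest`)
#' @export
simulate_chip_experiment <- function(sim, target, condition = "WT",
                                     control_assay = "input",
                                     n_chip = sim$config$chip$n_chip_reps,
                                     n_control = sim$config$chip$n_control_reps,
                                     depth = sim$config$chip$depth,
                                     fragment_length = sim$config$chip$fragment_length,
                                     seed = sim$config$seed) {
  fragments <- list()
  rows <- list()
  k <- 0L
  for (r in seq_len(n_chip)) {
    k <- k + 1L
    id <- paste(target, condition, "chip", r, sep = "_")
    fragments[[id]] <- simulate_chip_sample(
      sim, target, depth, fragment_length, substream_seed(seed, 100L + k))
    rows[[k]] <- data.frame(sample_id = id, path = "", assay = "chip",
                            target = target, condition = condition,
                            replicate = r, stringsAsFactors = FALSE)
  }
  for (r in seq_len(n_control)) {
    k <- k + 1L
    id <- paste(target, condition, control_assay, r, sep = "_")
    fragments[[id]] <- simulate_chip_sample(
      sim, NULL, depth, fragment_length, substream_seed(seed, 100L + k))
    rows[[k]] <- data.frame(sample_id = id, path = "", assay = control_assay,
                            target = target, condition = condition,
                            replicate = r, stringsAsFactors = FALSE)
  }
  list(fragments = fragments, manifest = sample_manifest(do.call(rbind, rows)))
}

#' Simulate uniform (unenriched) fragments over the genome
#'
#' Per-read sampler used to exercise fragment-level operations such as the
#' rRNA/mRNA filter; equivalent to an input sample.
#'
#' @param sim a `RepeatSimulation`
#' @param depth,fragment_length fragment count and length
#' @param seed integer seed
#' @return an `AlignedFragmentSet`
#' @export
simulate_uniform_fragments <- function(sim, depth = 1e4,
                                       fragment_length = 50L, seed = 1L) {
  simulate_chip_sample(sim, NULL, depth, fragment_length, seed)
}

#' Simulate replicate RNA repeat count tables with planted fold changes
#'
#' Counts are drawn at the unit (subfamily) level: the expected count of a
#' unit is proportional to unit_length_kb x baseline expression x the
#' condition effect 2^log2fc, scaled to the target depth, with negative
#' binomial noise whose extra-Poisson coefficient of variation is
#' `dispersion`. The DNA-transposon units carry the configured low baseline
#' so background adjustment is exercised.
#'
#' @param sim a `RepeatSimulation`
#' @param conditions,n_reps,depth,dispersion study design (defaults from the
#'   config: two conditions, 3 replicates each, 1e6 fragments, 10%
#'   replicate CV)
#' @param seed base seed
#' @return list with `counts` (a `FamilyCountTable`), `manifest` and
#'   `ground_truth` (planted per-unit log2FC between the two conditions)
#' @export
simulate_rna_counts <- function(sim,
                                conditions = sim$config$rna$conditions,
                                n_reps = sim$config$rna$n_reps,
                                depth = sim$config$rna$depth,
                                dispersion = sim$config$rna$dispersion,
                                seed = sim$config$seed) {
  if (length(conditions) < 1L || n_reps < 1L) {
    stop("need >= 1 condition with >= 1 replicate")
  }
  set.seed(substream_seed(seed, 3L))
  lens <- unit_lengths(sim$annotation, "subfamily")
  units <- names(lens)
  base <- sim$config$rna$baseline_expression
  missing_expr <- setdiff(units, names(base))
  if (length(missing_expr) > 0L) {
    stop("no baseline expression for: ", paste(missing_expr, collapse = ", "))
  }
  if (any(base < 0)) stop("expected expression must be >= 0")
  samples <- character(0)
  mu_cols <- list()
  rows <- list()
  for (cond in conditions) {
    lfc <- stats::setNames(rep(0, length(units)), units)
    planted <- sim$config$rna$log2fc[[cond]]
    if (!is.null(planted)) lfc[names(planted)] <- planted
    w <- (lens / 1000) * base[units] * 2^lfc
    mu <- if (sum(w) > 0) depth * w / sum(w) else w * 0
    for (r in seq_len(n_reps)) {
      id <- paste(cond, "rna", r, sep = "_")
      samples <- c(samples, id)
      mu_cols[[id]] <- mu
      rows[[id]] <- data.frame(sample_id = id, path = "", assay = "rna",
                               target = "", condition = cond, replicate = r,
                               stringsAsFactors = FALSE)
    }
  }
  counts <- matrix(0, nrow = length(units), ncol = length(samples),
                   dimnames = list(units, samples))
  for (id in samples) {
    mu <- mu_cols[[id]]
    counts[, id] <- if (dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion^2)
    } else {
      stats::rpois(length(mu), lambda = mu)
    }
  }
  tab <- structure(list(counts = counts, unit_length = lens,
                        library_size = colSums(counts),
                        unassigned = stats::setNames(numeric(length(samples)),
                                                     samples),
                        level = "subfamily", mode = "simulated"),
                   class = "FamilyCountTable")
  gt <- stats::setNames(rep(0, length(units)), units)
  if (length(conditions) >= 2L) {
    for (cond in conditions[-1]) {
      planted <- sim$config$rna$log2fc[[cond]]
      if (!is.null(planted)) gt[names(planted)] <- planted
    }
  }
  list(counts = tab, manifest = sample_manifest(do.call(rbind, rows)),
       ground_truth = gt)
}

#' Simulate a two-condition unique-peptide-count table
#'
#' Background proteins receive correlated Poisson counts in the two
#' conditions: each protein's count is C + U where C ~ Pois(rho * mean) is
#' shared between conditions and U ~ Pois((1 - rho) * mean) is
#' condition-specific, so the marginal is Poisson(mean) with
#' between-condition correlation rho (replicate IP-MS peptide counts are
#' highly reproducible). Planted hits receive independent Poisson counts at
#' distinct per-condition means.
#'
#' @param n_background number of background proteins
#' @param background_mean marginal Poisson mean of background counts
#' @param correlation between-condition correlation rho in [0, 1]
#' @param hits data.frame(protein, mean_ref, mean_cmp); may have 0 rows
#' @param conditions the two condition column names (reference first)
#' @param seed integer seed
#' @return list with `table` (data.frame protein + two count columns) and
#'   `ground_truth` (character vector of planted hit proteins)
#' @export
simulate_peptide_table <- function(n_background = 300L, background_mean = 5,
                                   correlation = 0.9,
                                   hits = data.frame(protein = "OGT",
                                                     mean_ref = 20,
                                                     mean_cmp = 2),
                                   conditions = c("WT", "Dnmt1KO"),
                                   seed = 1L) {
  if (n_background < 1L) stop("need >= 1 background protein")
  if (correlation < 0 || correlation > 1) stop("correlation must be in [0, 1]")
  set.seed(seed)
  shared <- stats::rpois(n_background, correlation * background_mean)
  n_ref <- shared + stats::rpois(n_background,
                                 (1 - correlation) * background_mean)
  n_cmp <- shared + stats::rpois(n_background,
                                 (1 - correlation) * background_mean)
  proteins <- sprintf("bg_%04d", seq_len(n_background))
  if (nrow(hits) > 0L) {
    proteins <- c(hits$protein, proteins)
    n_ref <- c(stats::rpois(nrow(hits), hits$mean_ref), n_ref)
    n_cmp <- c(stats::rpois(nrow(hits), hits$mean_cmp), n_cmp)
  }
  tab <- data.frame(protein = proteins, stringsAsFactors = FALSE)
  tab[[conditions[1]]] <- n_ref
  tab[[conditions[2]]] <- n_cmp
  list(table = tab, ground_truth = if (nrow(hits) > 0L) hits$protein
       else character(0))
}

#' Serialize the planted ground truth as JSON
#' @param sim a `RepeatSimulation`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ground_truth <- function(sim, path) {
  jsonlite::write_json(sim$ground_truth, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
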