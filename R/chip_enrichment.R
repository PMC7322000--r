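#' Remove duplicate fragments
#'
#' Among fragments sharing (contig, start, strand) exactly one is retained
#' (the first in (contig, start, end) sort order), mirroring the standard
#' positional duplicate removal applied to ChIP-seq alignments. Idempotent.
#'
#' @param fragments an `AlignedFragmentSet`
#' @return the retained `AlignedFragmentSet`; the number removed is in the
#'   `n_duplicates_removed` attribute
#' @export
deduplicate <- function(fragments) {
  if (nrow(fragments) > 1L) {
    o <- order(fragments$contig, fragments$start, fragments$end)
    if (any(o != seq_len(nrow(fragments)))) {
      message("deduplicate: input was unsorted; sorting by (contig, start, end)")
      fragments <- fragments[o, , drop = FALSE]
    }
  }
  key <- paste(fragments$contig, fragments$start, fragments$strand, sep = "\r")
  dup <- duplicated(key)
  out <- fragments[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- attr(fragments, "n_skipped")
  attr(out, "n_duplicates_removed") <- sum(dup)
  class(out) <- c("AlignedFragmentSet", "data.frame")
  out
}

fragment_granges <- function(fragments) {
  GenomicRanges::GRanges(
    seqnames = fragments$contig,
    ranges = IRanges::IRanges(start = fragments$start + 1L,
                              end = fragments$end))
}

# fragment midpoint, 0-based: start + floor((end - start) / 2)
fragment_midpoints <- function(fragments) {
  fragments$start + floor((fragments$end - fragments$start) / 2)
}

# Assign each fragment of one sample to at most one annotation interval.
# Returns the row index of the assigned interval (NA = unassigned), or, in
# fractional mode, a (fragment, interval, weight) triple table.
assign_fragments <- function(fragments, iv, mode) {
  gr_iv <- GenomicRanges::GRanges(
    seqnames = iv$contig,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end))
  if (mode == "midpoint") {
    mid <- fragment_midpoints(fragments)
    gr_mid <- GenomicRanges::GRanges(
      seqnames = fragments$contig,
      ranges = IRanges::IRanges(start = mid + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(gr_mid, gr_iv)
    qh <- S4Vectors_from(hits)
    sh <- S4Vectors_to(hits)
    # ties (overlapping annotation intervals): smaller start, then instance_id
    pick <- pick_one_per_fragment(qh, sh, iv, rep(1, length(qh)))
    assigned <- rep(NA_integer_, nrow(fragments))
    assigned[pick$fragment] <- pick$interval
    return(assigned)
  }
  gr_fr <- fragment_granges(fragments)
  hits <- GenomicRanges::findOverlaps(gr_fr, gr_iv)
  qh <- S4Vectors_from(hits)
  sh <- S4Vectors_to(hits)
  ov <- pmin(fragments$end[qh], iv$end[sh]) -
    pmax(fragments$start[qh], iv$start[sh])
  if (mode == "any_overlap") {
    pick <- pick_one_per_fragment(qh, sh, iv, ov)
    assigned <- rep(NA_integer_, nrow(fragments))
    assigned[pick$fragment] <- pick$interval
    return(assigned)
  }
  if (mode == "fractional") {
    w <- ov / (fragments$end[qh] - fragments$start[qh])
    # overlapping annotation intervals can claim the same fragment bp twice;
    # renormalize so each fragment contributes at most one fragment of
    # evidence
    tot <- stats::ave(w, qh, FUN = sum)
    w <- ifelse(tot > 1, w / tot, w)
    return(data.frame(fragment = qh, interval = sh, weight = w))
  }
  stop("unknown counting mode: ", mode)
}

S4Vectors_from <- function(hits) as.integer(S4Vectors::queryHits(hits))
S4Vectors_to <- function(hits) as.integer(S4Vectors::subjectHits(hits))

# among candidate (fragment, interval) pairs keep, per fragment, the pair
# with maximal weight, ties by smaller interval start then instance_id
pick_one_per_fragment <- function(qh, sh, iv, weight) {
  if (length(qh) == 0L) {
    return(data.frame(fragment = integer(0), interval = integer(0)))
  }
  o <- order(qh, -weight, iv$start[sh],
             as.character(iv$instance_id[sh]))
  qh <- qh[o]; sh <- sh[o]
  keep <- !duplicated(qh)
  data.frame(fragment = qh[keep], interval = sh[keep])
}

#' Count fragments per repeat unit
#'
#' Builds the unit x sample count table that enrichment and expression
#' normalization consume. In `midpoint` mode (default) a fragment is
#' assigned to the unit containing its midpoint; in `any_overlap` mode to
#' the unit with maximal overlap (ties: smaller interval start, then
#' instance id); in `fractional` mode overlap-proportional weights are
#' spread across units (renormalized where self-overlapping annotation
#' would double-claim bp, so they sum to at most 1 per fragment). Fragments
#' assigned to no unit are tallied as unassigned; the library size is the
#' total number of (deduplicated, mapped) fragments per sample.
#'
#' @param fragments an `AlignedFragmentSet` or a named list of them (one per
#'   sample)
#' @param annotation a `RepeatAnnotation`
#' @param level `"subfamily"` (default), `"family"` or `"repclass"`
#' @param mode `"midpoint"`, `"any_overlap"` or `"fractional"`
#' @return a `FamilyCountTable`: list with `counts` (units x samples
#'   matrix), `unit_length`, `library_size`, `unassigned`, `level`, `mode`
#' @export
count_by_unit <- function(fragments, annotation,
                          level = c("subfamily", "family", "repclass"),
                          mode = c("midpoint", "any_overlap", "fractional")) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  iv <- annotation$intervals
  if (nrow(iv) == 0L) stop("annotation is empty")
  if (!is.list(fragments) || is.data.frame(fragments)) {
    fragments <- list(sample = fragments)
  }
  if (is.null(names(fragments))) {
    names(fragments) <- paste0("sample", seq_along(fragments))
  }
  lens <- unit_lengths(annotation, level)
  units <- names(lens)
  counts <- matrix(0, nrow = length(units), ncol = length(fragments),
                   dimnames = list(units, names(fragments)))
  unassigned <- stats::setNames(numeric(length(fragments)), names(fragments))
  library_size <- stats::setNames(numeric(length(fragments)), names(fragments))
  unit_of_interval <- iv[[level]]
  for (s in names(fragments)) {
    fr <- fragments[[s]]
    library_size[s] <- nrow(fr)
    if (nrow(fr) == 0L) next
    if (mode == "fractional") {
      triples <- assign_fragments(fr, iv, mode)
      if (nrow(triples) > 0L) {
        w <- tapply(triples$weight, unit_of_interval[triples$interval], sum)
        counts[names(w), s] <- as.numeric(w)
      }
      unassigned[s] <- nrow(fr) - sum(triples$weight)
    } else {
      assigned <- assign_fragments(fr, iv, mode)
      ok <- !is.na(assigned)
      if (any(ok)) {
        tab <- table(unit_of_interval[assigned[ok]])
        counts[names(tab), s] <- as.numeric(tab)
      }
      unassigned[s] <- sum(!ok)
    }
  }
  structure(list(counts = counts, unit_length = lens,
                 library_size = library_size, unassigned = unassigned,
                 level = level, mode = mode),
            class = "FamilyCountTable")
}

#' @export
print.FamilyCountTable <- function(x, ...) {
  cat("FamilyCountTable:", nrow(x$counts), "units (", x$level, ") x",
      ncol(x$counts), "samples; mode =", x$mode, "\n")
  invisible(x)
}

#' Count fragments in named intervals (e.g. ICRs)
#'
#' Midpoint-rule counting against an explicit interval set rather than a
#' repeat hierarchy; unit names are the interval names.
#'
#' @param fragments an `AlignedFragmentSet` or named list of them
#' @param intervals data.frame with `contig`, `start`, `end`, `name`
#' @return a `FamilyCountTable` with `level = "interval"`
#' @export
count_in_intervals <- function(fragments, intervals) {
  if (nrow(intervals) == 0L) stop("interval set is empty")
  iv <- data.frame(contig = intervals$contig, start = intervals$start,
                   end = intervals$end, strand = "+",
                   subfamily = intervals$name, family = intervals$name,
                   repclass = "interval", role = "unassigned",
                   instance_id = intervals$name, stringsAsFactors = FALSE)
  ann <- repeat_annotation(iv, background_classes = character(0))
  out <- count_by_unit(fragments, ann, level = "subfamily", mode = "midpoint")
  out$level <- "interval"
  out
}

counts_to_cpm <- function(counts) {
  if (any(counts$library_size <= 0)) stop("library size must be positive")
  sweep(counts$counts, 2, 1e6 / counts$library_size, `*`)
}

#' ChIP enrichment of repeat units: mean treatment cpm over mean control cpm
#'
#' The enrichment statistic is the ratio of the mean of the treatment
#' replicates to the mean of the control replicates, computed on cpm
#' (depth-normalized) values so a deep replicate cannot dominate the mean.
#' Rows whose control mean is zero are flagged `control_zero` and excluded
#' from enriched/not-enriched classification rather than reported as
#' infinite.
#'
#' @param counts a `FamilyCountTable` covering all involved samples
#' @param manifest a `SampleManifest`
#' @param treatment_key,control_key named lists matched against manifest
#'   columns, e.g. `list(assay = "chip", target = "O-GlcNAc",
#'   condition = "WT")` and `list(assay = "input", condition = "WT")`
#' @param tau enrichment threshold for the `enriched` flag (default 1.5)
#' @return data.frame with per-unit `mean_treatment_cpm`,
#'   `mean_control_cpm`, `ratio`, `n_treatment`, `n_control`,
#'   `control_zero`, `enriched`
#' @export
enrichment <- function(counts, manifest, treatment_key, control_key,
                       tau = 1.5) {
  cpm <- counts_to_cpm(counts)
  trt <- manifest_select(manifest, treatment_key)
  ctl <- manifest_select(manifest, control_key)
  trt <- intersect(trt, colnames(cpm))
  ctl <- intersect(ctl, colnames(cpm))
  if (length(trt) == 0L || length(ctl) == 0L) {
    stop("no samples match the treatment/control keys; available: ",
         paste(unique(paste(manifest$assay, manifest$target,
                            manifest$condition, sep = "/")), collapse = ", "))
  }
  mt <- rowMeans(cpm[, trt, drop = FALSE])
  mc <- rowMeans(cpm[, ctl, drop = FALSE])
  control_zero <- mc == 0
  ratio <- ifelse(control_zero, NA_real_, mt / mc)
  data.frame(unit = rownames(cpm),
             mean_treatment_cpm = mt, mean_control_cpm = mc,
             ratio = ratio,
             n_treatment = length(trt), n_control = length(ctl),
             control_zero = control_zero,
             enriched = !control_zero & !is.na(ratio) & ratio > tau,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' ICR occupancy by multiple ChIP targets
#'
#' Counts fragments falling in each imprinting control region (midpoint
#' rule), computes per-ICR enrichment for each target, and cross-classifies
#' ICRs as enriched in both targets, in exactly one, or in neither. ICRs
#' with a zero control mean for any target are flagged and excluded from the
#' summary denominators.
#'
#' @param fragments named list of `AlignedFragmentSet`s (all samples)
#' @param icrs data.frame from [read_icr_bed()]
#' @param manifest a `SampleManifest`
#' @param targets character vector of >= 2 ChIP targets
#' @param condition condition shared by the compared samples (default "WT")
#' @param tau enrichment threshold (default 1.5)
#' @return list with `table` (per ICR x target) and `summary`
#'   (n_icrs, n_classified, both, either, only_<target>, neither)
#' @export
icr_occupancy <- function(fragments, icrs, manifest, targets,
                          condition = "WT", tau = 1.5) {
  if (nrow(icrs) == 0L) stop("ICR set is empty")
  if (length(targets) < 2L) stop("need >= 2 targets to cross-classify")
  counts <- count_in_intervals(fragments, icrs)
  per_target <- lapply(targets, function(tgt) {
    ctl_assay <- intersect(c("input", "igg"),
                           manifest$assay[manifest$target %in% c(tgt, "") &
                                            manifest$condition == condition])
    if (length(ctl_assay) == 0L) {
      stop("no input/igg control for target ", tgt)
    }
    e <- enrichment(counts, manifest,
                    treatment_key = list(assay = "chip", target = tgt,
                                         condition = condition),
                    control_key = list(assay = ctl_assay[1], target = tgt,
                                       condition = condition),
                    tau = tau)
    e$target <- tgt
    e
  })
  tab <- do.call(rbind, per_target)
  enr <- sapply(per_target, function(e) e$enriched)
  cz <- sapply(per_target, function(e) e$control_zero)
  if (is.null(dim(enr))) { enr <- matrix(enr, nrow = 1); cz <- matrix(cz, nrow = 1) }
  usable <- rowSums(cz) == 0
  n_both <- sum(usable & rowSums(enr) == length(targets))
  n_neither <- sum(usable & rowSums(enr) == 0)
  n_either <- sum(usable & rowSums(enr) > 0)
  only <- vapply(seq_along(targets), function(k) {
    sum(usable & enr[, k] & rowSums(enr) == 1)
  }, numeric(1))
  summary <- c(list(n_icrs = nrow(icrs), n_classified = sum(usable),
                    both = n_both, either = n_either, neither = n_neither),
               stats::setNames(as.list(only), paste0("only_", targets)))
  list(table = tab, summary = summary)
}

#' LTR-anchored metaprofile of ChIP coverage
#'
#' For every complete element copy of a subfamily (a 5'LTR/internal/3'LTR
#' triplet of adjacent intervals), per-bp coverage over each segment is
#' rescaled to a fixed number of bins by mean pooling; minus-strand copies
#' are reversed so bin 0 is always the element's 5' end. The profile is the
#' mean across copies, and the scalar 5'/3' contrast
#' mean(5'LTR bins)/mean(3'LTR bins) quantifies the promoter-proximal
#' asymmetry of occupancy.
#'
#' @param fragments an `AlignedFragmentSet`
#' @param annotation a `RepeatAnnotation` with role-labelled LTR copies
#' @param subfamily subfamily name whose copies are profiled; copies are
#'   matched across the 5'LTR/3'LTR subfamily and the internal subfamily
#'   when they differ (e.g. an LTR subfamily flanking an -int subfamily)
#' @param n_bins bins per segment (default 20)
#' @return list with `profile` (data.frame segment/bin/mean_coverage),
#'   `contrast` (5'/3' ratio), `n_elements`
#' @export
ltr_metaprofile <- function(fragments, annotation, subfamily, n_bins = 20L) {
  iv <- annotation$intervals
  copies <- find_ltr_copies(iv, subfamily)
  if (length(copies) == 0L) {
    stop("no complete role-labelled copies for ", subfamily,
         "; assign five_prime_ltr/internal/three_prime_ltr roles")
  }
  cov <- per_contig_coverage(fragments)
  segs <- c("five_prime_ltr", "internal", "three_prime_ltr")
  acc <- matrix(0, nrow = 3L, ncol = n_bins,
                dimnames = list(segs, NULL))
  for (cp in copies) {
    for (k in seq_along(segs)) {
      row <- cp$segments[[segs[k]]]
      v <- coverage_slice(cov, row$contig, row$start, row$end)
      if (cp$strand == "-") v <- rev(v)
      acc[k, ] <- acc[k, ] + bin_means(v, n_bins)
    }
  }
  prof <- acc / length(copies)
  profile <- data.frame(
    segment = rep(segs, each = n_bins),
    bin = rep(seq_len(n_bins), times = 3L),
    mean_coverage = as.numeric(t(prof)),
    stringsAsFactors = FALSE)
  contrast <- mean(prof["five_prime_ltr", ]) / mean(prof["three_prime_ltr", ])
  list(profile = profile, contrast = contrast, n_elements = length(copies))
}

# group a subfamily's intervals into complete LTR-structured copies by
# adjacency: genomic order 5'LTR/internal/3'LTR on "+", reversed on "-"
find_ltr_copies <- function(iv, subfamily) {
  sub <- iv[iv$subfamily == subfamily & iv$role != "unassigned", , drop = FALSE]
  if (nrow(sub) == 0L) return(list())
  # include adjacent internal intervals of a partner subfamily if the named
  # subfamily only carries LTR roles (LTR/-int split annotations)
  if (!"internal" %in% sub$role) {
    flank <- iv[iv$role == "internal", , drop = FALSE]
    sub <- rbind(sub, flank)
  }
  sub <- sub[order(sub$contig, sub$start), , drop = FALSE]
  copies <- list()
  i <- 1L
  while (i <= nrow(sub) - 2L) {
    trio <- sub[i:(i + 2L), ]
    adjacent <- length(unique(trio$contig)) == 1L &&
      trio$end[1] == trio$start[2] && trio$end[2] == trio$start[3]
    roles_plus <- identical(trio$role,
                            c("five_prime_ltr", "internal", "three_prime_ltr"))
    roles_minus <- identical(trio$role,
                             c("three_prime_ltr", "internal", "five_prime_ltr"))
    if (adjacent && (roles_plus || roles_minus)) {
      strand <- if (roles_plus) "+" else "-"
      segments <- stats::setNames(
        lapply(1:3, function(k) trio[k, c("contig", "start", "end")]),
        trio$role)
      copies[[length(copies) + 1L]] <- list(strand = strand,
                                            segments = segments)
      i <- i + 3L
    } else {
      i <- i + 1L
    }
  }
  copies
}

per_contig_coverage <- function(fragments) {
  if (nrow(fragments) == 0L) return(list())
  gr <- fragment_granges(fragments)
  cov <- GenomicRanges::coverage(gr)
  lapply(stats::setNames(seq_along(cov), names(cov)),
         function(i) cov[[i]])
}

coverage_slice <- function(cov, contig, start, end) {
  n <- end - start
  if (!contig %in% names(cov)) return(numeric(n))
  v <- cov[[contig]]
  len <- length(v)
  out <- numeric(n)
  hi <- min(end, len)
  if (hi > start) {
    out[seq_len(hi - start)] <- as.numeric(v[(start + 1L):hi])
  }
  out
}

# mean-pool a length-L vector into n bins (contiguous, near-equal width)
bin_means <- function(v, n_bins) {
  L <- length(v)
  idx <- ceiling(seq_len(L) * n_bins / L)
  as.numeric(tapply(v, idx, mean))
}
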