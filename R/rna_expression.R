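#' Remove rRNA- and mRNA-mapping fragments before repeat counting
#'
#' A fragment overlapping any rRNA interval (by >= 1 bp) is removed and
#' attributed to rRNA; otherwise, if it overlaps any mRNA interval, it is
#' removed as mRNA; otherwise it is retained. The removal priority (rRNA
#' before mRNA) is fixed, and the report satisfies
#' input = removed_rrna + removed_mrna + retained.
#'
#' @param fragments an `AlignedFragmentSet`
#' @param rrna_intervals,mrna_intervals data.frames with `contig`, `start`,
#'   `end` (0-based half-open); may have zero rows
#' @return list with `fragments` (retained set) and `report` (one-row
#'   data.frame: input, removed_rrna, removed_mrna, retained)
#' @export
filter_reads <- function(fragments, rrna_intervals, mrna_intervals) {
  overlaps_any <- function(frags, iv) {
    if (is.null(iv) || nrow(iv) == 0L || nrow(frags) == 0L) {
      return(rep(FALSE, nrow(frags)))
    }
    gr_f <- fragment_granges(frags)
    gr_i <- GenomicRanges::GRanges(
      seqnames = iv$contig,
      ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end))
    IRanges::overlapsAny(gr_f, gr_i)
  }
  is_rrna <- overlaps_any(fragments, rrna_intervals)
  is_mrna <- rep(FALSE, nrow(fragments))
  rest <- !is_rrna
  is_mrna[rest] <- overlaps_any(fragments[rest, , drop = FALSE],
                                mrna_intervals)
  retained <- fragments[!is_rrna & !is_mrna, , drop = FALSE]
  rownames(retained) <- NULL
  attr(retained, "n_skipped") <- attr(fragments, "n_skipped")
  class(retained) <- c("AlignedFragmentSet", "data.frame")
  report <- data.frame(input = nrow(fragments),
                       removed_rrna = sum(is_rrna),
                       removed_mrna = sum(is_mrna),
                       retained = nrow(retained))
  list(fragments = retained, report = report)
}

#' FPKM normalization of a repeat count table
#'
#' FPKM = count x 10^9 / (unit_length_bp x library_size), i.e. fragments per
#' 1000 bp of repeat unit per million mapped fragments, where the library
#' size is the retained mapped fragment total per sample.
#'
#' @param counts a `FamilyCountTable`
#' @return an `ExpressionTable`: list with `counts`, `unit_length`,
#'   `library_size`, `fpkm`
#' @export
fpkm <- function(counts) {
  if (any(counts$library_size <= 0)) {
    stop("library size must be positive for FPKM; got a zero/negative library")
  }
  if (any(counts$unit_length <= 0)) stop("unit lengths must be positive")
  f <- sweep(counts$counts, 2, counts$library_size, `/`)
  f <- sweep(f, 1, counts$unit_length, `/`) * 1e9
  structure(list(counts = counts$counts, unit_length = counts$unit_length,
                 library_size = counts$library_size, level = counts$level,
                 fpkm = f),
            class = "ExpressionTable")
}

#' @export
print.ExpressionTable <- function(x, ...) {
  cat("ExpressionTable:", nrow(x$fpkm), "units x", ncol(x$fpkm), "samples",
      if (!is.null(x$adjusted_fpkm)) "(background-adjusted)" else "", "\n")
  invisible(x)
}

# row indices of background-class units at the table's level
background_units <- function(expr, annotation) {
  cls <- unit_class_map_level(annotation, expr$level)
  units <- rownames(expr$fpkm)
  bg <- units[cls[units] %in% annotation$background_classes]
  bg[!is.na(bg)]
}

unit_class_map_level <- function(annotation, level) {
  if (level == "repclass") {
    u <- unique(annotation$intervals$repclass)
    return(stats::setNames(u, u))
  }
  unit_class_map(annotation, level)
}

#' Background-adjust FPKM by the inactive DNA-transposon signal
#'
#' The background level B is the FPKM of the transcriptionally dead
#' background classes (DNA transposons by default): in `pooled` mode
#' (default) all background-class counts and bp are pooled into one unit,
#' B = total background count x 10^9 / (total background bp x library size);
#' in `mean_of_units` mode B is the mean of the per-unit background FPKMs.
#' Each unit's adjusted FPKM is max(FPKM - B, 0), and the adjusted value is
#' rescaled back to cpm by multiplying by unit length in kb (the exact
#' inverse of the per-kb step), so background removal is the only net
#' transformation.
#'
#' @param expr an `ExpressionTable` from [fpkm()]
#' @param annotation the `RepeatAnnotation` that produced the counts
#' @param background_mode `"pooled"` (default) or `"mean_of_units"`
#' @return the `ExpressionTable` with `adjusted_fpkm`, `adjusted_cpm` and
#'   per-sample `background_fpkm` added
#' @export
background_adjust <- function(expr, annotation,
                              background_mode = c("pooled", "mean_of_units")) {
  background_mode <- match.arg(background_mode)
  bg <- background_units(expr, annotation)
  if (length(bg) == 0L) {
    stop("no background-class unit (",
         paste(annotation$background_classes, collapse = ","),
         ") present in the count table")
  }
  if (background_mode == "pooled") {
    bg_count <- colSums(expr$counts[bg, , drop = FALSE])
    bg_len <- sum(expr$unit_length[bg])
    # same operation order as fpkm() so the pooled background unit adjusts
    # to exactly zero, not within rounding
    B <- ((bg_count / expr$library_size) / bg_len) * 1e9
  } else {
    B <- colMeans(expr$fpkm[bg, , drop = FALSE])
  }
  adj <- pmax(sweep(expr$fpkm, 2, B, `-`), 0)
  expr$adjusted_fpkm <- adj
  expr$adjusted_cpm <- sweep(adj, 1, expr$unit_length / 1000, `*`)
  expr$background_fpkm <- B
  expr$background_mode <- background_mode
  expr$background_units <- bg
  expr
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over units (restricted to
#' units with a nonzero geometric mean across samples) of
#' count / geometric mean(count across samples), rescaled to geometric
#' mean 1 across samples.
#'
#' @param counts units x samples count matrix
#' @return named numeric vector of size factors
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no unit has positive counts in every sample")
  lg <- log(counts[pos, , drop = FALSE])
  geo <- exp(rowMeans(lg))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(k) stats::median(k / geo))
  sf / exp(mean(log(sf)))
}

#' Per-unit log2 fold change between two conditions
#'
#' Counts are normalized with median-of-ratios size factors; the normalized
#' cpm of a unit is (count / sf) x 10^6 / G, where G is the geometric mean
#' over samples of library_size / sf (a fixed scale so cpm stays "per
#' million" while all cross-sample correction comes from the size factors).
#' Background adjustment is then recomputed on the normalized scale, and the
#' fold change is log2((mean_a + p) / (mean_b + p)) on replicate means of
#' normalized adjusted cpm, with pseudocount p in cpm units.
#'
#' @param expr a background-adjusted `ExpressionTable`
#' @param manifest a `SampleManifest` with the RNA samples
#' @param annotation the `RepeatAnnotation` behind the counts
#' @param condition_a,condition_b condition labels; the fold change is a
#'   over b (a = treatment, b = reference)
#' @param pseudocount_cpm pseudocount p (default 0.5 cpm)
#' @return data.frame(unit, mean_cpm_a, mean_cpm_b, log2fc) with the size
#'   factors and conditions as attributes
#' @export
log2fc <- function(expr, manifest, annotation, condition_a, condition_b,
                   pseudocount_cpm = 0.5) {
  if (pseudocount_cpm <= 0) stop("pseudocount must be positive")
  rna <- manifest[manifest$assay == "rna", , drop = FALSE]
  a_ids <- rna$sample_id[rna$condition == condition_a]
  b_ids <- rna$sample_id[rna$condition == condition_b]
  a_ids <- intersect(a_ids, colnames(expr$counts))
  b_ids <- intersect(b_ids, colnames(expr$counts))
  if (length(a_ids) < 1L || length(b_ids) < 1L) {
    stop("need >= 1 replicate per condition; available conditions: ",
         paste(unique(rna$condition), collapse = ", "))
  }
  ids <- c(a_ids, b_ids)
  K <- expr$counts[, ids, drop = FALSE]
  totals <- colSums(K)
  if (all(totals[a_ids] == 0) || all(totals[b_ids] == 0)) {
    stop("a condition has all-zero counts; cannot normalize")
  }
  sf <- size_factors(K)
  G <- exp(mean(log(expr$library_size[ids] / sf)))
  norm_counts <- sweep(K, 2, sf, `/`)
  norm_tab <- structure(list(counts = norm_counts,
                             unit_length = expr$unit_length,
                             library_size = stats::setNames(rep(G, length(ids)),
                                                            ids),
                             level = expr$level),
                        class = "FamilyCountTable")
  norm_expr <- fpkm(norm_tab)
  norm_expr <- background_adjust(norm_expr, annotation,
                                 if (is.null(expr$background_mode)) "pooled"
                                 else expr$background_mode)
  cpm <- norm_expr$adjusted_cpm
  mean_a <- rowMeans(cpm[, a_ids, drop = FALSE])
  mean_b <- rowMeans(cpm[, b_ids, drop = FALSE])
  out <- data.frame(unit = rownames(cpm),
                    mean_cpm_a = mean_a, mean_cpm_b = mean_b,
                    log2fc = log2((mean_a + pseudocount_cpm) /
                                    (mean_b + pseudocount_cpm)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "size_factors") <- sf
  attr(out, "conditions") <- c(a = condition_a, b = condition_b)
  out
}

#' Call reactivated repeat units
#'
#' A unit is called reactivated when its log2 fold change exceeds
#' `lfc_threshold` and its mean adjusted cpm in the treatment condition
#' exceeds `min_cpm`. Units of the background classes are not candidates:
#' their adjusted values are by construction the residual noise of the
#' subtraction that defines the baseline, so testing them would be circular
#' (set `exclude_background = FALSE` to override). Tallies are reported per
#' repeat class and family.
#'
#' @param fc data.frame from [log2fc()] (treatment is condition a)
#' @param annotation the `RepeatAnnotation` (for class/family tallies and
#'   background classes)
#' @param lfc_threshold log2FC call threshold (default 1.0)
#' @param min_cpm minimum treatment-condition mean adjusted cpm (default 1.0)
#' @param exclude_background drop background-class units from the candidate
#'   set (default TRUE)
#' @return list with `calls` (fc plus a `reactivated` flag), `by_class` and
#'   `by_family` tallies of reactivated units
#' @export
reactivation_report <- function(fc, annotation, lfc_threshold = 1,
                                min_cpm = 1, exclude_background = TRUE) {
  fc$reactivated <- fc$log2fc > lfc_threshold & fc$mean_cpm_a > min_cpm
  iv <- annotation$intervals
  key <- unique(iv[, c("subfamily", "family", "repclass")])
  m <- match(fc$unit, key$subfamily)
  fc$family <- key$family[m]
  fc$repclass <- key$repclass[m]
  if (exclude_background) {
    fc$reactivated <- fc$reactivated &
      !fc$repclass %in% annotation$background_classes
  }
  tally <- function(col) {
    x <- fc[[col]]
    x[is.na(x)] <- "unknown"
    t <- tapply(fc$reactivated, x, sum)
    data.frame(group = names(t), n_reactivated = as.integer(t),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(calls = fc, by_class = tally("repclass"), by_family = tally("family"))
}
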