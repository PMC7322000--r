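#' Rank proteins by methylation-dependent association
#'
#' The screen statistic is the pseudocounted peptide-count ratio
#' R = (n_ref + c) / (n_cmp + c), where n_ref and n_cmp are the unique
#' peptide counts of a protein in the reference (methylated, e.g. wild-type)
#' and comparison (demethylated) condition and c is the pseudocount that
#' keeps R positive and finite (default 1). A protein is `shown` (display
#' filter) when it is represented by at least `min_shown` peptides in either
#' condition (default 3), and is a `hit` when it is represented by more than
#' `hit_min_peptides` unique peptides (default 6) and depleted by more than
#' `hit_fold`-fold in the comparison condition (default 2, evaluated on the
#' pseudocounted ratio; set `raw_fold = TRUE` to filter on the raw ratio
#' instead). Ranking is by R descending with ties broken by n_ref descending
#' then protein id, so output order is byte-stable.
#'
#' @param table data.frame with a `protein` column and one non-negative
#'   integer count column per condition
#' @param ref,cmp reference and comparison condition column names
#' @param pseudocount c > 0
#' @param min_shown display-filter threshold on max(n_ref, n_cmp)
#' @param hit_min_peptides hit filter: max(n_ref, n_cmp) must exceed this
#' @param hit_fold hit filter: R must exceed this
#' @param raw_fold evaluate the fold filter on n_ref/n_cmp instead of R
#' @return data.frame of class `ScreenResult` (protein, n_ref, n_cmp, ratio,
#'   log2_ratio, shown, hit, rank), sorted by rank; the parameters are
#'   stored as attributes
#' @export
screen <- function(table, ref, cmp, pseudocount = 1, min_shown = 3L,
                   hit_min_peptides = 6L, hit_fold = 2, raw_fold = FALSE) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (min_shown < 0 || hit_min_peptides < 0 || hit_fold < 0) {
    stop("thresholds must be >= 0")
  }
  for (col in c(ref, cmp)) {
    if (!col %in% names(table)) stop("condition column not found: ", col)
    v <- table[[col]]
    if (any(v < 0) || any(v != floor(v))) {
      stop("peptide counts must be non-negative integers (column ", col, ")")
    }
  }
  n_ref <- as.numeric(table[[ref]])
  n_cmp <- as.numeric(table[[cmp]])
  ratio <- (n_ref + pseudocount) / (n_cmp + pseudocount)
  fold_stat <- if (raw_fold) ifelse(n_cmp > 0, n_ref / n_cmp, Inf) else ratio
  shown <- pmax(n_ref, n_cmp) >= min_shown
  hit <- pmax(n_ref, n_cmp) > hit_min_peptides & fold_stat > hit_fold
  out <- data.frame(protein = as.character(table$protein),
                    n_ref = n_ref, n_cmp = n_cmp,
                    ratio = ratio, log2_ratio = log2(ratio),
                    shown = shown, hit = hit, stringsAsFactors = FALSE)
  o <- order(-out$ratio, -out$n_ref, out$protein)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "pseudocount") <- pseudocount
  attr(out, "conditions") <- c(ref = ref, cmp = cmp)
  class(out) <- c("ScreenResult", "data.frame")
  out
}

#' Top methylation-dependent protein and its separation from the runner-up
#'
#' @param result a `ScreenResult`
#' @param margin separation R_top / R_second required to flag a clear top
#'   hit (default 2, the fold by which the strongest dependence exceeded any
#'   other protein in the motivating screen)
#' @return list(top, separation, clear_top) computed over shown proteins
#' @export
top_dependent <- function(result, margin = 2) {
  shown <- result[result$shown, , drop = FALSE]
  if (nrow(shown) < 2L) stop("need >= 2 shown proteins")
  list(top = shown$protein[1],
       separation = shown$ratio[1] / shown$ratio[2],
       clear_top = shown$ratio[1] / shown$ratio[2] >= margin)
}

#' Export the pseudocounted scatter table behind the screen plot
#'
#' Writes a TSV of (protein, ref + c, cmp + c, shown, hit) on the
#' pseudocounted scale so that a log-log scatter can represent zero counts;
#' the ratio statistic is exactly recomputable from the two exported
#' columns.
#'
#' @param result a `ScreenResult`
#' @param path output TSV
#' @return `path`, invisibly
#' @export
export_scatter <- function(result, path) {
  c0 <- attr(result, "pseudocount")
  out <- data.frame(protein = result$protein,
                    ref_plus_c = result$n_ref + c0,
                    cmp_plus_c = result$n_cmp + c0,
                    shown = result$shown, hit = result$hit,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a unique-peptide-count table (TSV: protein + one column per condition)
#' @param path TSV with a header
#' @return data.frame with `protein` and integer count columns
#' @export
read_peptide_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (!"protein" %in% names(df)) stop("peptide table needs a 'protein' column")
  df
}
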