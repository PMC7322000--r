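# Small in-code fixtures shared across test files.

mk_annotation <- function(df = NULL, background_classes = "DNA") {
  if (is.null(df)) {
    df <- data.frame(
      contig = c("chr1", "chr1", "chr1", "chr2", "chr2"),
      start = c(100, 500, 1200, 50, 900),
      end = c(400, 900, 2000, 650, 1500),
      strand = c("+", "-", "+", "+", "-"),
      subfamily = c("IAPEz", "IAPEz", "L1Md_T", "Charlie1", "Tigger1"),
      family = c("ERVK", "ERVK", "L1", "hAT-Charlie", "TcMar-Tigger"),
      repclass = c("LTR", "LTR", "LINE", "DNA", "DNA"),
      stringsAsFactors = FALSE)
  }
  repeat_annotation(df, background_classes)
}

random_fragments <- function(n, contigs = c(chr1 = 3000, chr2 = 2000),
                             max_len = 120, seed = 1) {
  set.seed(seed)
  ct <- sample(names(contigs), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (contigs[ct] - len))
  fragment_set(data.frame(contig = ct, start = start, end = start + len,
                          strand = sample(c("+", "-"), n, replace = TRUE),
                          stringsAsFactors = FALSE))
}

random_annotation <- function(n_int, contigs = c(chr1 = 3000, chr2 = 2000),
                              n_sub = 5, seed = 1,
                              background_classes = "DNA") {
  set.seed(seed)
  ct <- sample(names(contigs), n_int, replace = TRUE)
  len <- sample(20:200, n_int, replace = TRUE)
  start <- floor(runif(n_int) * (contigs[ct] - len))
  subs <- paste0("sub", seq_len(n_sub))
  cls <- rep(c("LTR", "LINE", "SINE", "DNA", "DNA"), length.out = n_sub)
  sub <- sample(subs, n_int, replace = TRUE)
  repeat_annotation(data.frame(
    contig = ct, start = start, end = start + len,
    strand = sample(c("+", "-"), n_int, replace = TRUE),
    subfamily = sub, family = sub,
    repclass = cls[match(sub, subs)],
    stringsAsFactors = FALSE), background_classes)
}

# hand-built count table with known cpm values
mk_count_table <- function(counts, unit_length, library_size) {
  structure(list(counts = counts, unit_length = unit_length,
                 library_size = library_size,
                 unassigned = stats::setNames(numeric(ncol(counts)),
                                              colnames(counts)),
                 level = "subfamily", mode = "midpoint"),
            class = "FamilyCountTable")
}

mk_rna_manifest <- function(conditions, n_reps) {
  rows <- do.call(rbind, lapply(conditions, function(cond) {
    data.frame(sample_id = paste(cond, "rna", seq_len(n_reps), sep = "_"),
               path = "", assay = "rna", target = "", condition = cond,
               replicate = seq_len(n_reps), stringsAsFactors = FALSE)
  }))
  sample_manifest(rows)
}
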