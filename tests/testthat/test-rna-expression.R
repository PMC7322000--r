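test_that("rRNA removal takes priority over mRNA and totals are conserved", {
  rrna <- data.frame(contig = "chr1", start = 100, end = 200)
  mrna <- data.frame(contig = "chr1", start = 150, end = 400)
  fr <- fragment_set(data.frame(
    contig = "chr1", start = c(120, 300, 900), end = c(170, 350, 950),
    strand = "+", stringsAsFactors = FALSE))
  res <- filter_reads(fr, rrna, mrna)
  expect_equal(res$report$removed_rrna, 1)   # 120-170 overlaps both -> rRNA
  expect_equal(res$report$removed_mrna, 1)
  expect_equal(res$report$retained, 1)
  expect_equal(res$report$input,
               res$report$removed_rrna + res$report$removed_mrna +
                 res$report$retained)
  # empty filter sets retain everything
  none <- filter_reads(fr, rrna[0, ], mrna[0, ])
  expect_equal(nrow(none$fragments), 3L)
  expect_equal(none$report$retained, 3)
})

test_that("read filtering matches the brute-force classifier on random input", {
  set.seed(33)
  fr <- random_fragments(2000, seed = 33)
  mk_iv <- function(n, seed) {
    set.seed(seed)
    ct <- sample(c("chr1", "chr2"), n, replace = TRUE)
    s <- floor(runif(n) * 1800)
    data.frame(contig = ct, start = s, end = s + sample(30:300, n, TRUE))
  }
  rrna <- mk_iv(15, 34)
  mrna <- mk_iv(40, 35)
  res <- filter_reads(fr, rrna, mrna)
  cls <- oracle_filter(fr, rrna, mrna)
  expect_equal(res$report$removed_rrna, sum(cls == "rrna"))
  expect_equal(res$report$removed_mrna, sum(cls == "mrna"))
  expect_equal(res$report$retained, sum(cls == "retained"))
})

test_that("FPKM follows its printed definition exactly", {
  tab <- mk_count_table(
    counts = matrix(c(10, 0), ncol = 1, dimnames = list(c("u1", "u2"), "s1")),
    unit_length = c(u1 = 2000, u2 = 500),
    library_size = c(s1 = 1e6))
  expr <- fpkm(tab)
  expect_identical(expr$fpkm["u1", "s1"], 5.0)   # 10*1e9/(2000*1e6)
  expect_identical(expr$fpkm["u2", "s1"], 0)
  bad <- tab; bad$library_size <- c(s1 = 0)
  expect_error(fpkm(bad), "library")
})

test_that("FPKM matches the one-line oracle to 1e-12 relative error", {
  set.seed(40)
  k <- matrix(rpois(60, 200), nrow = 10,
              dimnames = list(paste0("u", 1:10), paste0("s", 1:6)))
  lens <- setNames(sample(500:5000, 10), rownames(k))
  libs <- setNames(round(runif(6, 1e5, 1e6)), colnames(k))
  expr <- fpkm(mk_count_table(k, lens, libs))
  for (u in rownames(k)) for (s in colnames(k)) {
    expect_equal(expr$fpkm[u, s], oracle_fpkm(k[u, s], lens[[u]], libs[[s]]),
                 tolerance = 1e-12)
  }
})

test_that("background adjustment subtracts pooled DNA FPKM and rescales to cpm", {
  ann <- mk_annotation()   # Charlie1 + Tigger1 are DNA background
  # u = IAPEz with FPKM 7.5; background pooled FPKM 2.5
  # IAPEz length 700 in mk_annotation: use a custom table instead
  ann2 <- repeat_annotation(data.frame(
    contig = "chr1", start = c(0, 5000), end = c(4000, 9000), strand = "+",
    subfamily = c("IAPEz", "Charlie1"), family = c("ERVK", "hAT-Charlie"),
    repclass = c("LTR", "DNA"), stringsAsFactors = FALSE))
  # library 1e6: IAPEz count 30 -> FPKM 7.5; Charlie1 count 10, len 4000 -> B 2.5
  tab <- mk_count_table(
    counts = matrix(c(30, 10), ncol = 1,
                    dimnames = list(c("IAPEz", "Charlie1"), "s1")),
    unit_length = c(IAPEz = 4000, Charlie1 = 4000),
    library_size = c(s1 = 1e6))
  expr <- background_adjust(fpkm(tab), ann2)
  expect_equal(expr$background_fpkm[["s1"]], 2.5)
  expect_equal(expr$adjusted_fpkm["IAPEz", "s1"], 5.0)
  expect_equal(expr$adjusted_cpm["IAPEz", "s1"], 20.0)   # 5.0 * 4000/1000
  # self-cancellation: a unit at exactly the background level adjusts to 0
  expect_equal(expr$adjusted_fpkm["Charlie1", "s1"], 0)
  expect_error(background_adjust(fpkm(tab),
                                 repeat_annotation(ann2$intervals,
                                                   background_classes = "SINE")),
               "background")
})

test_that("pooled background self-cancels exactly in every sample", {
  sim <- simulate_genome(simulation_config(seed = 51))
  rna <- simulate_rna_counts(sim, seed = 51)
  expr <- background_adjust(fpkm(rna$counts), sim$annotation)
  bg <- expr$background_units
  k_bg <- colSums(expr$counts[bg, , drop = FALSE])
  l_bg <- sum(expr$unit_length[bg])
  pooled_fpkm <- k_bg * 1e9 / (l_bg * expr$library_size)
  expect_equal(unname(pooled_fpkm - expr$background_fpkm),
               rep(0, ncol(expr$counts)))
  # FPKM/cpm consistency: adjusted_cpm / adjusted_fpkm = unit_length / 1000
  pos <- expr$adjusted_fpkm > 0
  ratio <- (expr$adjusted_cpm / expr$adjusted_fpkm)[pos]
  lens <- matrix(expr$unit_length, nrow = nrow(pos), ncol = ncol(pos))[pos]
  expect_equal(ratio, lens / 1000, tolerance = 1e-12)
})

test_that("log2fc limit cases: identical tables, global scaling, single-unit fold", {
  ann <- random_annotation(80, seed = 61, n_sub = 6)
  lens <- unit_lengths(ann)
  set.seed(62)
  base <- matrix(rpois(length(lens) * 3, 5000), ncol = 3,
                 dimnames = list(names(lens), paste0("A_rna_", 1:3)))
  # keep the DNA background negligible so fold changes on expressed units
  # are not amplified by the subtraction
  bg_units <- intersect(rownames(base),
                        unique(ann$intervals$subfamily[
                          ann$intervals$repclass %in% ann$background_classes]))
  base[bg_units, ] <- 0
  manifest <- mk_rna_manifest(c("A", "B"), 3)
  # identical replicate tables in both conditions -> exactly 0 everywhere
  k <- cbind(base, base)
  colnames(k) <- manifest$sample_id
  tab <- mk_count_table(k, lens, setNames(colSums(k), colnames(k)))
  expr <- background_adjust(fpkm(tab), ann)
  fc0 <- log2fc(expr, manifest, ann, "A", "B")
  expect_equal(fc0$log2fc, rep(0, nrow(fc0)))
  # a global 4x on every unit is absorbed by median-of-ratios normalization
  # (composition correction, as in standard differential expression)
  k4 <- cbind(4 * base, base)
  colnames(k4) <- manifest$sample_id
  libs <- setNames(rep(sum(base[, 1]) * 4, 6), colnames(k4))
  expr4 <- background_adjust(fpkm(mk_count_table(k4, lens, libs)), ann)
  fc4 <- log2fc(expr4, manifest, ann, "A", "B")
  expect_equal(fc4$log2fc, rep(0, nrow(fc4)), tolerance = 1e-10)
  # a 4x fold on ONE unit against a stable majority approaches log2FC = 2
  k1 <- cbind(base, base)
  target <- setdiff(rownames(base), bg_units)[1]
  k1[target, 1:3] <- 4 * k1[target, 1:3]
  colnames(k1) <- manifest$sample_id
  expr1 <- background_adjust(fpkm(mk_count_table(
    k1, lens, setNames(colSums(k1), colnames(k1)))), ann)
  fc1 <- log2fc(expr1, manifest, ann, "A", "B")
  expect_equal(fc1$log2fc[fc1$unit == target], 2, tolerance = 0.02)
})

test_that("FPKM, adjusted cpm and log2fc are invariant to depth rescaling", {
  sim <- simulate_genome(simulation_config(seed = 52))
  rna <- simulate_rna_counts(sim, seed = 52)
  expr1 <- background_adjust(fpkm(rna$counts), sim$annotation)
  fc1 <- log2fc(expr1, rna$manifest, sim$annotation,
                "dCas9-OGA", "dCas9-OGA_D242A")
  scaled <- rna$counts
  scaled$counts <- scaled$counts * 9
  scaled$library_size <- scaled$library_size * 9
  expr9 <- background_adjust(fpkm(scaled), sim$annotation)
  fc9 <- log2fc(expr9, rna$manifest, sim$annotation,
                "dCas9-OGA", "dCas9-OGA_D242A")
  expect_equal(expr9$fpkm, expr1$fpkm, tolerance = 1e-12)
  expect_equal(expr9$adjusted_cpm, expr1$adjusted_cpm, tolerance = 1e-12)
  expect_equal(fc9$log2fc, fc1$log2fc, tolerance = 1e-12)
})

test_that("median-of-ratios size factors agree with the DESeq2 reference", {
  skip_if_not_installed("DESeq2")
  set.seed(71)
  # odd unit count: the sample median of ratios then equals DESeq2's
  # exp(median(log ratios)) exactly
  k <- matrix(rnbinom(8 * 61, mu = 500, size = 20), nrow = 61)
  k[1:5, 1:4] <- k[1:5, 1:4] * 8   # asymmetric composition
  colnames(k) <- paste0("s", 1:8); rownames(k) <- paste0("u", 1:61)
  mine <- size_factors(k)
  ref <- DESeq2::estimateSizeFactorsForMatrix(k)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
})

test_that("a planted reactivation is recovered and called specifically", {
  sim <- simulate_genome(simulation_config(seed = 53))
  rna <- simulate_rna_counts(sim, seed = 53)
  expr <- background_adjust(fpkm(rna$counts), sim$annotation)
  fc <- log2fc(expr, rna$manifest, sim$annotation,
               "dCas9-OGA", "dCas9-OGA_D242A")
  est <- setNames(fc$log2fc, fc$unit)
  expect_equal(est[["IAPEz"]], 3, tolerance = 0.3)
  other <- setdiff(c("MERVL", "L1Md_T", "B1_Mus1"), "IAPEz")
  expect_true(all(abs(est[other]) < 0.3))
  react <- reactivation_report(fc, sim$annotation)
  expect_equal(react$calls$unit[react$calls$reactivated], "IAPEz")
  expect_equal(react$by_class$n_reactivated[react$by_class$group == "LTR"], 1L)
  # threshold 0 calls every non-background unit with a positive estimate
  react0 <- reactivation_report(fc, sim$annotation, lfc_threshold = 0,
                                min_cpm = 0)
  nonbg <- !fc$unit %in% expr$background_units
  expect_equal(sum(react0$calls$reactivated), sum(fc$log2fc > 0 & nonbg))
})

test_that("log2fc validates its inputs", {
  ann <- random_annotation(40, seed = 81)
  lens <- unit_lengths(ann)
  manifest <- mk_rna_manifest(c("A", "B"), 2)
  k <- matrix(0, nrow = length(lens), ncol = 4,
              dimnames = list(names(lens), manifest$sample_id))
  k[, 1:2] <- rpois(2 * length(lens), 100)
  tab <- mk_count_table(k, lens, setNames(pmax(colSums(k), 1), colnames(k)))
  expr <- background_adjust(fpkm(tab), ann)
  expect_error(log2fc(expr, manifest, ann, "A", "B"), "all-zero")
  expect_error(log2fc(expr, manifest, ann, "A", "C"), "condition")
  expect_error(log2fc(expr, manifest, ann, "A", "B", pseudocount_cpm = 0),
               "pseudocount")
})
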