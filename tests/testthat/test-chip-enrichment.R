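test_that("deduplication keys on (contig, start, strand) and is idempotent", {
  fr <- fragment_set(data.frame(
    contig = "chr1", start = c(100, 100, 100, 100),
    end = c(150, 150, 150, 150), strand = c("+", "+", "+", "-"),
    stringsAsFactors = FALSE))
  dd <- deduplicate(fr)
  expect_equal(nrow(dd), 2L)
  expect_equal(attr(dd, "n_duplicates_removed"), 2L)
  expect_setequal(dd$strand, c("-", "+"))
  dd2 <- deduplicate(dd)
  expect_equal(as.data.frame(dd2), as.data.frame(dd), ignore_attr = TRUE)
  expect_equal(attr(dd2, "n_duplicates_removed"), 0L)
})

test_that("deduplication matches the set-based oracle on random fragments", {
  fr <- random_fragments(1000, max_len = 5, seed = 12)  # short => collisions
  dd <- deduplicate(fr)
  expect_equal(as.data.frame(dd)[, c("contig", "start", "strand")],
               oracle_dedup(fr)[, c("contig", "start", "strand")])
  expect_equal(nrow(dd) + attr(dd, "n_duplicates_removed"), nrow(fr))
})

test_that("midpoint assignment follows the floor convention at boundaries", {
  ann <- repeat_annotation(data.frame(
    contig = "chr1", start = c(50, 160), end = c(160, 300),
    strand = "+", subfamily = c("A", "B"), family = c("A", "B"),
    repclass = "LTR", stringsAsFactors = FALSE))
  fr <- fragment_set(data.frame(contig = "chr1", start = 100, end = 200,
                                strand = "+", stringsAsFactors = FALSE))
  # midpoint 150 < 160, so the fragment belongs to A
  counts <- count_by_unit(fr, ann, mode = "midpoint")
  expect_equal(counts$counts["A", 1], 1)
  expect_equal(counts$counts["B", 1], 0)
  # fragment entirely outside all units is unassigned
  out <- fragment_set(data.frame(contig = "chr1", start = 500, end = 600,
                                 strand = "+", stringsAsFactors = FALSE))
  c2 <- count_by_unit(out, ann)
  expect_equal(sum(c2$counts), 0)
  expect_equal(c2$unassigned[[1]], 1)
  expect_error(count_by_unit(fr, repeat_annotation(ann$intervals[0, ])),
               "empty")
})

test_that("all counting modes match the brute-force scan and conserve totals", {
  ann <- random_annotation(120, seed = 5)
  fr <- random_fragments(2000, seed = 6)
  for (mode in c("midpoint", "any_overlap", "fractional")) {
    got <- count_by_unit(fr, ann, mode = mode)
    want <- oracle_count(fr, ann, "subfamily", mode)
    expect_equal(got$counts[, 1], want$counts, tolerance = 1e-12)
    expect_equal(got$unassigned[[1]], want$unassigned, tolerance = 1e-9)
    # conservation: assigned + unassigned = total fragments
    expect_equal(sum(got$counts[, 1]) + got$unassigned[[1]], nrow(fr),
                 tolerance = 1e-9)
  }
})

test_that("fractional weights per fragment never exceed 1", {
  ann <- random_annotation(150, seed = 7)
  fr <- random_fragments(1500, seed = 8)
  tr <- repeatscreen:::assign_fragments(fr, ann$intervals, "fractional")
  per_frag <- tapply(tr$weight, tr$fragment, sum)
  expect_true(all(per_frag <= 1 + 1e-9))
})

test_that("counting levels aggregate the same assignments", {
  ann <- random_annotation(100, seed = 15)
  fr <- random_fragments(1000, seed = 16)
  by_sub <- count_by_unit(fr, ann, level = "subfamily")
  by_cls <- count_by_unit(fr, ann, level = "repclass")
  cls <- repeatscreen:::unit_class_map(ann)
  agg <- tapply(by_sub$counts[, 1], cls[rownames(by_sub$counts)], sum)
  expect_equal(by_cls$counts[names(agg), 1], as.numeric(agg),
               ignore_attr = TRUE)
})

test_that("enrichment is the ratio of mean treatment cpm to mean control cpm", {
  counts <- mk_count_table(
    counts = matrix(c(4, 6, 5, 2.5, 2.5), nrow = 1,
                    dimnames = list("IAPEz", c("t1", "t2", "t3", "c1", "c2"))),
    unit_length = c(IAPEz = 1000),
    library_size = c(t1 = 1e6, t2 = 1e6, t3 = 1e6, c1 = 1e6, c2 = 1e6))
  manifest <- sample_manifest(data.frame(
    sample_id = c("t1", "t2", "t3", "c1", "c2"), path = "",
    assay = c("chip", "chip", "chip", "input", "input"),
    target = c(rep("O-GlcNAc", 3), "", ""), condition = "WT",
    replicate = c(1:3, 1:2), stringsAsFactors = FALSE))
  e <- enrichment(counts, manifest,
                  list(assay = "chip", target = "O-GlcNAc", condition = "WT"),
                  list(assay = "input", condition = "WT"))
  expect_equal(e$ratio, 2.0)           # mean(4,6,5)/mean(2.5,2.5)
  expect_equal(e$n_treatment, 3L)
  expect_equal(e$n_control, 2L)
  expect_true(e$enriched)              # 2.0 > default tau 1.5
  # identical treatment and control samples give exactly 1
  same <- mk_count_table(
    counts = matrix(c(7, 7), nrow = 1, dimnames = list("u", c("t1", "c1"))),
    unit_length = c(u = 500), library_size = c(t1 = 1e5, c1 = 1e5))
  m2 <- sample_manifest(data.frame(
    sample_id = c("t1", "c1"), path = "", assay = c("chip", "input"),
    target = c("X", ""), condition = "WT", replicate = 1L,
    stringsAsFactors = FALSE))
  e2 <- enrichment(same, m2, list(assay = "chip"), list(assay = "input"))
  expect_equal(e2$ratio, 1.0)
  expect_error(enrichment(counts, manifest, list(assay = "chip",
                                                 target = "nope",
                                                 condition = "WT"),
                          list(assay = "input", condition = "WT")),
               "available")
})

test_that("enrichment ratios are invariant to global depth rescaling", {
  ann <- random_annotation(60, seed = 21)
  frs <- list(t1 = random_fragments(3000, seed = 22),
              c1 = random_fragments(3000, seed = 23))
  counts <- count_by_unit(frs, ann)
  manifest <- sample_manifest(data.frame(
    sample_id = c("t1", "c1"), path = "", assay = c("chip", "input"),
    target = c("X", ""), condition = "WT", replicate = 1L,
    stringsAsFactors = FALSE))
  e1 <- enrichment(counts, manifest, list(assay = "chip"), list(assay = "input"))
  scaled <- counts
  scaled$counts <- scaled$counts * 13
  scaled$library_size <- scaled$library_size * 13
  e2 <- enrichment(scaled, manifest, list(assay = "chip"), list(assay = "input"))
  expect_equal(e2$ratio, e1$ratio)
})

test_that("zero-control rows are flagged, not infinite", {
  counts <- mk_count_table(
    counts = matrix(c(5, 0), nrow = 1, dimnames = list("u", c("t1", "c1"))),
    unit_length = c(u = 500), library_size = c(t1 = 1e5, c1 = 1e5))
  m <- sample_manifest(data.frame(
    sample_id = c("t1", "c1"), path = "", assay = c("chip", "input"),
    target = c("X", ""), condition = "WT", replicate = 1L,
    stringsAsFactors = FALSE))
  e <- enrichment(counts, m, list(assay = "chip"), list(assay = "input"))
  expect_true(e$control_zero)
  expect_true(is.na(e$ratio))
  expect_false(e$enriched)
})

test_that("ICR occupancy cross-classifies planted co-enrichment as 'both'", {
  sim <- simulate_genome(simulation_config(seed = 14))
  frags <- list()
  manifests <- list()
  for (tgt in c("O-GlcNAc", "TRIM28")) {
    exp <- simulate_chip_experiment(sim, tgt, depth = 5e4,
                                    seed = 50 + match(tgt, c("O-GlcNAc", "TRIM28")))
    frags <- c(frags, exp$fragments)
    manifests[[tgt]] <- as.data.frame(exp$manifest)
  }
  manifest <- sample_manifest(do.call(rbind, manifests))
  occ <- icr_occupancy(frags, sim$icrs, manifest, c("O-GlcNAc", "TRIM28"))
  expect_equal(occ$summary$n_classified, 4L)
  expect_equal(occ$summary$both, 4L)     # all ICRs planted at e = 3
  expect_equal(occ$summary$neither, 0L)
  expect_equal(occ$summary$either, 4L)
  expect_error(icr_occupancy(frags, sim$icrs[0, ], manifest,
                             c("O-GlcNAc", "TRIM28")), "empty")
  expect_error(icr_occupancy(frags, sim$icrs, manifest, "O-GlcNAc"),
               ">= 2 targets")
})

test_that("metaprofile is flat with contrast 1 under uniform coverage", {
  ann <- repeat_annotation(data.frame(
    contig = "chr1", start = c(1000, 1400, 5600),
    end = c(1400, 5600, 6000), strand = "+",
    subfamily = "IAPEz", family = "ERVK", repclass = "LTR",
    role = c("five_prime_ltr", "internal", "three_prime_ltr"),
    stringsAsFactors = FALSE))
  # one fragment spanning the whole element: coverage exactly 1 everywhere
  fr <- fragment_set(data.frame(contig = "chr1", start = 500, end = 7000,
                                strand = "+", stringsAsFactors = FALSE))
  mp <- ltr_metaprofile(fr, ann, "IAPEz", n_bins = 10)
  expect_equal(mp$n_elements, 1L)
  expect_true(all(mp$profile$mean_coverage == 1))
  expect_equal(mp$contrast, 1)
})

test_that("minus-strand copies profile as the mirrored plus-strand coverage", {
  # same element geometry, annotated on the minus strand: genomic order is
  # 3'LTR, internal, 5'LTR
  ann_minus <- repeat_annotation(data.frame(
    contig = "chr1", start = c(1000, 1400, 5600),
    end = c(1400, 5600, 6000), strand = "-",
    subfamily = "IAPEz", family = "ERVK", repclass = "LTR",
    role = c("three_prime_ltr", "internal", "five_prime_ltr"),
    stringsAsFactors = FALSE))
  # asymmetric coverage: a block over the genomic-left LTR only
  fr <- fragment_set(data.frame(contig = "chr1", start = 1000, end = 1400,
                                strand = "+", stringsAsFactors = FALSE))
  mp <- ltr_metaprofile(fr, ann_minus, "IAPEz", n_bins = 4)
  prof <- mp$profile
  # on the element's own 5'->3' axis, the covered block is the 3' LTR
  expect_true(all(prof$mean_coverage[prof$segment == "three_prime_ltr"] == 1))
  expect_true(all(prof$mean_coverage[prof$segment == "five_prime_ltr"] == 0))
  expect_equal(mp$contrast, 0)
  expect_error(ltr_metaprofile(fr, ann_minus, "L1Md_T"), "role")
})

test_that("planted enrichment and estimated enrichment are monotone together", {
  cfg <- simulation_config(
    seed = 18,
    chip = list(targets = list("O-GlcNAc" = c(IAPEz = 4, MERVL = 2, L1Md_T = 1)),
                icr_enrichment = c("O-GlcNAc" = 1)))
  sim <- simulate_genome(cfg)
  exp <- simulate_chip_experiment(sim, "O-GlcNAc", seed = 18)
  counts <- count_by_unit(exp$fragments, sim$annotation)
  e <- enrichment(counts, exp$manifest,
                  list(assay = "chip", target = "O-GlcNAc", condition = "WT"),
                  list(assay = "input", condition = "WT"))
  est <- setNames(e$ratio, e$unit)
  expect_true(est[["IAPEz"]] > est[["MERVL"]])
  expect_true(est[["MERVL"]] > est[["L1Md_T"]])
})
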