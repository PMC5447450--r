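cfg <- threshold_config()

test_that("read-depth segment parsing keeps non-diploid, non-hypervariable, non-Y", {
  seg <- data.frame(case_id = "C1",
                    chrom = c("chr8", "chr8", "chrY", "chr1"),
                    start = c(0, 10000, 0, 5000),
                    end = c(5000, 20000, 4000, 9000),
                    copy_state = c(3L, 2L, 1L, 1L),
                    hypervariable = c(FALSE, FALSE, FALSE, TRUE),
                    stringsAsFactors = FALSE)
  out <- parse_read_depth_segments(seg, cfg)
  expect_equal(nrow(out), 1L)
  expect_equal(out$chrom, "chr8")
  expect_equal(out$state, "gain")
  bad <- seg; bad$start[1] <- 6000
  expect_error(parse_read_depth_segments(bad, cfg), "line")
  unk <- seg; unk$chrom[2] <- "scaffold_7"
  expect_error(parse_read_depth_segments(unk, cfg), "chromosome")
})

test_that("SV parsing enforces type, support and chromosome rules", {
  sv <- data.frame(case_id = "C1", chrom = "chr2",
                   start = c(0, 0, 0, 0), end = rep(500, 4),
                   type = c("deletion", "deletion", "inversion",
                            "tandem_duplication"),
                   support = c(20L, 19L, 100L, 35L), stringsAsFactors = FALSE)
  out <- parse_sv_events(sv, cfg)
  expect_equal(out$type, c("deletion", "tandem_duplication"))
  expect_equal(out$state, c("loss", "gain"))
})

test_that("reciprocal overlap matches forced values and the base-wise oracle", {
  expect_equal(reciprocal_overlap(0, 1000, 0, 1000), 1.0)
  expect_equal(reciprocal_overlap(0, 1000, 500, 1500), 0.5)
  expect_equal(reciprocal_overlap(0, 1000, 2000, 3000), 0)
  expect_equal(reciprocal_overlap(0, 1000, 0, 1000, same_chrom = FALSE), 0)
  # symmetry
  expect_equal(reciprocal_overlap(10, 800, 300, 1200),
               reciprocal_overlap(300, 1200, 10, 800))
  set.seed(101)
  for (i in 1:200) {
    a0 <- sample.int(5000, 1); a1 <- a0 + sample.int(3000, 1)
    b0 <- sample.int(5000, 1); b1 <- b0 + sample.int(3000, 1)
    expect_equal(reciprocal_overlap(a0, a1, b0, b1),
                 ro_bruteforce(a0, a1, b0, b1))
  }
})

test_that("fragment merging bridges small gaps, is idempotent, preserves bases", {
  r <- make_cnv(start = c(0, 6000, 30000), end = c(5000, 9000, 35000))
  m <- merge_fragmented_segments(r, gap_max = 10000)
  expect_equal(nrow(m), 2L)
  expect_equal(m$start[1], 0); expect_equal(m$end[1], 9000)
  expect_identical(merge_fragmented_segments(m, gap_max = 10000), m)
  # an 11 kb gap stays unmerged at the 10 kb default
  r2 <- make_cnv(start = c(0, 16001), end = c(5000, 20000))
  expect_equal(nrow(merge_fragmented_segments(r2, gap_max = 10000)), 2L)
  # covered bases only change by filling gaps <= gap_max
  cov <- function(x) sum(x$end - x$start)
  expect_lte(cov(m) - cov(r[1:2, ]) - 0, 10000)
  # different states never merge
  r3 <- make_cnv(start = c(0, 6000), end = c(5000, 9000),
                 state = c("loss", "gain"))
  expect_equal(nrow(merge_fragmented_segments(r3, gap_max = 10000)), 2L)
})

test_that("control frequency counts distinct qualifying samples", {
  ctrl <- do.call(rbind, lapply(1:3, function(s)
    data.frame(sample_id = paste0("S", s), chrom = "chr1", start = 0,
               end = 10000, state = "loss", stringsAsFactors = FALSE)))
  rec <- make_cnv(start = 0, end = 10000)
  out <- annotate_cnv_frequency(rec, ctrl, n_control = 100, cfg = cfg)
  expect_equal(out$control_freq, 0.03)
  # RO below 0.5 against every control does not count
  far <- make_cnv(start = 9000, end = 19000)
  out2 <- annotate_cnv_frequency(far, ctrl, n_control = 100, cfg = cfg)
  expect_equal(out2$control_freq, 0)
  # state mismatch does not count; empty control set warns
  gain <- make_cnv(start = 0, end = 10000, state = "gain")
  expect_equal(annotate_cnv_frequency(gain, ctrl, n_control = 100,
                                      cfg = cfg)$control_freq, 0)
  expect_warning(annotate_cnv_frequency(rec, ctrl[0, ], cfg = cfg), "empty")
})

test_that("gene and exon overlap annotation", {
  gm <- list(transcripts = data.frame(gene = c("G1", "G2"), chrom = "chr1",
                                      start = c(1000, 20000), end = c(11000, 30000),
                                      stringsAsFactors = FALSE),
             exons = data.frame(gene = c("G1", "G1", "G2"), chrom = "chr1",
                                start = c(1000, 10500, 20000),
                                end = c(1300, 10800, 20300),
                                stringsAsFactors = FALSE))
  intronic <- make_cnv(start = 2000, end = 9000)
  spanning <- make_cnv(start = 500, end = 25000)
  out <- annotate_gene_exon_overlap(rbind(intronic, spanning), gm)
  expect_equal(out$genes_hit, c("G1", "G1,G2"))
  expect_equal(out$exons_hit, c(FALSE, TRUE))
})

test_that("CNV classification rule table", {
  syn <- data.frame(chrom = "chr2", start = 1e6, end = 3e6, state = "loss",
                    name = "REGION_A", stringsAsFactors = FALSE)
  dg <- test_disease_genes()
  rec <- rbind(
    make_cnv(chrom = "chr2", start = 1.1e6, end = 2.9e6, state = "loss",
             control_freq = 0, dgv_overlap = FALSE, genes_hit = "",
             exons_hit = FALSE),
    make_cnv(start = 0, end = 10000, control_freq = 0, dgv_overlap = TRUE,
             genes_hit = "ADG", exons_hit = TRUE),
    make_cnv(start = 0, end = 10000, state = "gain", control_freq = 0.001,
             dgv_overlap = FALSE, genes_hit = "ZZZ", exons_hit = TRUE),
    make_cnv(start = 0, end = 10000, state = "loss", control_freq = 0.001,
             dgv_overlap = FALSE, genes_hit = "ADG", exons_hit = TRUE),
    make_cnv(start = 0, end = 10000, state = "loss", control_freq = 0.5,
             dgv_overlap = FALSE, genes_hit = "ADG", exons_hit = TRUE))
  out <- classify_cnv(rec, syn, dg, cfg)
  expect_equal(out$classification,
               c("pathogenic", "benign", "VUS", "likely_pathogenic", "benign"))
})

test_that("segdup coverage and the concordance exclusion filter", {
  segdup <- data.frame(chrom = "chr1", start = c(0, 5000), end = c(4000, 8000),
                       stringsAsFactors = FALSE)
  rec <- rbind(make_cnv(start = 0, end = 10000),     # 7000/10000 covered
               make_cnv(start = 0, end = 10145),     # just under 0.69
               make_cnv(start = 100000, end = 110000))
  expect_equal(segdup_coverage(rec, segdup), c(0.70, 7000 / 10145, 0))
  out <- filter_for_concordance(rec, segdup, freq_either = c(0, 0, 0), cfg = cfg)
  expect_equal(out$start, c(0, 100000))
  expect_equal(nrow(filter_for_concordance(rec, segdup,
                                           freq_either = c(0, 0, 0.03),
                                           cfg = cfg)), 1L)
  # idempotent
  again <- filter_for_concordance(out, segdup, freq_either = out$freq_either,
                                  cfg = cfg)
  expect_equal(again$start, out$start)
})

test_that("dataset frequency for the 3 percent rule never counts the query case", {
  wgs <- rbind(make_cnv(case_id = "A", start = 0, end = 10000),
               make_cnv(case_id = "B", start = 100, end = 10100),
               make_cnv(case_id = "C", start = 500000, end = 510000))
  f <- filter_for_concordance(wgs, data.frame(chrom = character(),
                                              start = numeric(), end = numeric()),
                              datasets = list(wgs), cfg = cfg)
  # A and B see each other (1/3 each >= 3% -> excluded); C is private (0)
  expect_equal(f$case_id, "C")
  expect_equal(f$freq_either, 0)
})

test_that("CMA matching picks the best same-state overlap per call", {
  cma <- data.frame(case_id = "C1", chrom = "chr1",
                    outer_start = c(0, 50000), inner_start = c(1000, 51000),
                    inner_end = c(19000, 69000), outer_end = c(20000, 70000),
                    state = c("loss", "loss"),
                    classification = "pathogenic", stringsAsFactors = FALSE)
  cma$start <- cma$outer_start; cma$end <- cma$outer_end
  wgs <- rbind(make_cnv(start = 0, end = 20000),
               make_cnv(start = 2000, end = 18000),
               make_cnv(start = 50000, end = 70000, state = "gain"))
  res <- match_cma_wgs(cma, wgs, cfg)
  expect_equal(res$n_detected, 1L)       # second call overlaps only a gain
  expect_equal(res$matched_pairs$wgs_start, 0)  # exact match beats partial
  expect_equal(res$detection_rate, 0.5)
  expect_equal(nrow(res$unmatched_cma), 1L)
})

test_that("breakpoint concordance windows", {
  mk_pair <- function(wgs_start, wgs_end) {
    cma <- data.frame(case_id = "C1", chrom = "chr1",
                      outer_start = 100000, inner_start = 110000,
                      inner_end = 190000, outer_end = 200000,
                      state = "loss", classification = "pathogenic",
                      stringsAsFactors = FALSE)
    cma$start <- cma$outer_start; cma$end <- cma$outer_end
    wgs <- make_cnv(start = wgs_start, end = wgs_end)
    breakpoint_concordance(match_cma_wgs(cma, wgs, cfg), cfg)
  }
  exact <- mk_pair(110000, 190000)   # exactly at the inner boundaries
  expect_equal(exact$within_boundary_count, 1L)
  expect_equal(exact$within_window_count, 1L)
  near <- mk_pair(100000 - 9999, 195000)   # 9,999 bp outside the outer start
  expect_equal(near$within_boundary_count, 0L)
  expect_equal(near$within_window_count, 1L)
  out <- mk_pair(100000 - 10001, 195000)
  expect_equal(out$within_window_count, 0L)
  # invariant: within_boundary implies within_window
  for (r in list(exact, near, out))
    expect_lte(r$within_boundary_count, r$within_window_count)
})

test_that("the printed pathogenic CNV table is fully detected with concordant breakpoints", {
  tc <- paper_table2_concordance()
  res <- match_cma_wgs(tc$cma_calls, tc$wgs_records, cfg)
  expect_equal(res$n_detected, 9L)
  expect_equal(res$n_cma, 9L)
  bp <- breakpoint_concordance(res, cfg)
  expect_equal(bp$n_pairs, 9L)
  expect_lte(bp$within_boundary_count, bp$within_window_count)
})
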