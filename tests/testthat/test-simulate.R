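small_cfg <- function(n = 4L, seed = 5L, scale = 0.02, ...)
  simulation_config(cohort_n = n, seed = seed, scale = scale, ...)

test_that("generation is deterministic under (config, seed)", {
  a <- simulate_cohort(small_cfg())
  b <- simulate_cohort(small_cfg())
  expect_identical(a$variants, b$variants)
  expect_identical(a$cnv_segments, b$cnv_segments)
  expect_identical(a$manifest, b$manifest)
  c <- simulate_cohort(small_cfg(seed = 6L))
  expect_false(identical(a$variants, c$variants))
})

test_that("resources respect their construction invariants", {
  res <- generate_resources(small_cfg())
  dg <- res$disease_genes
  expect_true(all(nzchar(dg$inheritance_modes)))
  # X-linked labels only on chrX genes
  tx <- res$gene_models$transcripts
  xl <- grepl("XL", dg$inheritance_modes)
  expect_true(all(tx$chrom[match(dg$gene[xl], tx$gene)] == "chrX"))
  expect_gte(nrow(tx), 500L)
  # segdup genome fraction via an independent interval-union measure
  cover <- sum(by(res$segdup, res$segdup$chrom, function(d) {
    x <- rep(FALSE, 30e6 / 1000)  # 1 kb resolution; track is 1 kb-aligned
    for (i in seq_len(nrow(d)))
      x[(d$start[i] / 1000 + 1):(d$end[i] / 1000)] <- TRUE
    sum(x) * 1000
  }))
  expect_equal(cover / (length(unique(res$segdup$chrom)) * 30e6), 0.05,
               tolerance = 0.02)
  # control CNVs only at the declared polymorphic loci
  expect_true(all(res$control_cnvs$start %in% res$common_cnv_loci$start))
})

test_that("planted scenarios are constructed as declared", {
  cfg <- small_cfg()
  res <- generate_resources(cfg)
  set.seed(99)
  cs <- generate_case(cfg, res, scenario = "AR_hom", case_id = "T1", sex = "F")
  man <- cs$manifest
  expect_equal(man$expected_category, "AR_hom")
  v <- cs$variants[variant_id(cs$variants) == man$variant_ids, ]
  expect_equal(v$zygosity, "hom")
  expect_true(v$effect_class %in% c("nonsense", "frameshift", "canonical_splice"))
  expect_true(is.na(v$freq_1kg) && is.na(v$freq_exac))
  expect_true(grepl("AR", res$disease_genes$inheritance_modes[
    res$disease_genes$gene == man$gene]))
  # planted gene's phenotype terms are in the case profile
  terms <- strsplit(res$disease_genes$phenotype_terms[
    res$disease_genes$gene == man$gene], ",")[[1]]
  expect_true(all(terms %in% strsplit(cs$case$hpo_terms, ",")[[1]]))
  expect_error(generate_case(cfg, res, scenario = "XL_hemizygous",
                             case_id = "T2", sex = "F"),
               "male")
})

test_that("a planted pathogenic CNV yields a CMA call at RO >= 0.5 with the WGS record", {
  cfg <- small_cfg()
  res <- generate_resources(cfg)
  thr <- threshold_config()
  for (s in 1:5) {
    set.seed(s)
    cs <- generate_case(cfg, res, scenario = "CNV_pathogenic",
                        case_id = "T1", sex = "F")
    cma <- cs$cma_calls[cs$cma_calls$classification == "pathogenic", ]
    expect_equal(nrow(cma), 1L)
    seg <- parse_read_depth_segments(cs$cnv_segments, thr)
    seg <- merge_fragmented_segments(seg, cfg = thr)
    hit <- seg[seg$chrom == cma$chrom & seg$state == cma$state, ]
    ro <- reciprocal_overlap(cma$outer_start, cma$outer_end, hit$start, hit$end)
    expect_true(any(ro >= 0.5))
  }
})

test_that("a planted AR_hom scenario ranks first in its own case", {
  cfg <- small_cfg(scale = 0.05)
  res <- generate_resources(cfg)
  set.seed(13)
  cs <- generate_case(cfg, res, scenario = "AR_hom", case_id = "T1", sex = "F")
  pr <- prioritize_case(cs$variants, res, case_sex = "F",
                        case_terms = strsplit(cs$case$hpo_terms, ",")[[1]])
  top <- pr$candidates[1, ]
  expect_equal(top$gene, cs$manifest$gene)
  expect_equal(top$moi_model, "AR_hom")
  expect_equal(top$acmg_class, "pathogenic")
})

test_that("per-genome counts scale linearly with the scale factor", {
  cfg <- small_cfg(n = 6L, seed = 21L, scale = 0.1)
  coh <- simulate_cohort(cfg)
  per_case <- table(coh$variants$case_id[coh$variants$effect_class %in%
    c("missense", "synonymous", "nonsense", "frameshift", "canonical_splice",
      "inframe_indel", "ncRNA_exonic", "splice_region", "UTR")])
  m <- mean(per_case)
  expect_gt(m, 0.7 * 2001.4)
  expect_lt(m, 1.3 * 2001.4)
  # rare damaging events scale the same way
  run <- suppressMessages(run_cohort_pipeline(coh, stages = "prioritize"))
  expect_gt(mean(run$rare_damaging$n), 0.7 * 49.8)
  expect_lt(mean(run$rare_damaging$n), 1.3 * 49.8)
})

test_that("event size medians track their calibration targets", {
  cfg <- small_cfg(n = 3L, seed = 31L, scale = 0.5)
  coh <- simulate_cohort(cfg)
  thr <- threshold_config()
  seg <- parse_read_depth_segments(coh$cnv_segments, thr)
  sv <- parse_sv_events(coh$sv_events, thr)
  expect_gt(median(seg$end - seg$start), 10000 * 0.5)
  expect_lt(median(seg$end - seg$start), 10000 * 2)
  expect_gt(median(sv$end - sv$start), 495 * 0.5)
  expect_lt(median(sv$end - sv$start), 495 * 2)
  expect_true(all(sv$end - sv$start <= 75000))
})

test_that("every manifest row corresponds to emitted records", {
  coh <- simulate_cohort(small_cfg(n = 12L, seed = 3L, scale = 0.03))
  man <- coh$manifest
  expect_gt(nrow(man), 0)
  for (i in seq_len(nrow(man))) {
    if (man$scenario[i] == "CNV_pathogenic") {
      segs <- coh$cnv_segments[coh$cnv_segments$case_id == man$case_id[i] &
                                 coh$cnv_segments$chrom == man$chrom[i], ]
      expect_gt(nrow(segs), 0)
    } else {
      ids <- strsplit(man$variant_ids[i], ",")[[1]]
      have <- variant_id(coh$variants[coh$variants$case_id == man$case_id[i], ])
      expect_true(all(ids %in% have))
    }
  }
})
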