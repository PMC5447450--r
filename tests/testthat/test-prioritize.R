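cfg <- threshold_config()

test_that("filter_rare_functional applies the rarity and region rules", {
  v <- make_variants(
    make_variant(pos = 1L, freq_1kg = 0.001),                        # rare missense
    make_variant(pos = 2L, freq_1kg = 0.06),                        # common missense
    make_variant(pos = 3L, effect_class = "intronic"),              # no splice delta
    make_variant(pos = 4L, effect_class = "intronic", splice_delta = 0.6),
    make_variant(pos = 5L, effect_class = "synonymous"),
    make_variant(pos = 6L, effect_class = "synonymous", splice_delta = -0.5),
    make_variant(pos = 7L, effect_class = "frameshift", freq_1kg = 0.049),
    make_variant(pos = 8L, freq_1kg = 0.03, freq_exac = 0.07))      # max freq rule
  out <- filter_rare_functional(v, cfg)
  expect_equal(out$pos, c(1L, 4L, 6L, 7L))
  # stable order, input untouched
  expect_equal(v$pos, 1:8)
  # idempotent
  expect_equal(filter_rare_functional(out, cfg)$pos, out$pos)
})

test_that("rarity threshold is monotone: raising it never removes variants", {
  set.seed(42)
  v <- do.call(rbind, lapply(1:60, function(i)
    make_variant(pos = i, freq_1kg = if (i %% 3 == 0) NA_real_ else runif(1, 0, 0.2))))
  kept <- lapply(c(0.01, 0.03, 0.05, 0.10, 0.25),
                 function(th) filter_rare_functional(v, threshold_config(rare_freq_max = th))$pos)
  for (i in seq_along(kept)[-1])
    expect_true(all(kept[[i - 1]] %in% kept[[i]]))
})

test_that("unannotated variants are rejected by name", {
  v <- make_variant(chrom = "chr5", pos = 123L)
  v$effect_class <- NA_character_
  expect_error(filter_rare_functional(v, cfg), "chr5:123")
  expect_error(filter_rare_functional(v[setdiff(names(v), "gene")], cfg), "gene")
})

test_that("tier assignment matches the documented cutoffs and is pure", {
  dg <- test_disease_genes()
  v <- make_variants(
    make_variant(pos = 1L, effect_class = "frameshift", gene = "ADG"),
    make_variant(pos = 2L, effect_class = "synonymous"),
    make_variant(pos = 3L, read_depth = 12L),
    make_variant(pos = 4L, read_depth = 5L),
    make_variant(pos = 5L, freq_1kg = 0.0005),
    make_variant(pos = 6L, freq_1kg = 0.004),
    make_variant(pos = 7L, freq_1kg = 0.04),
    make_variant(pos = 8L, mouse_phenotype_flag = TRUE))
  t1 <- assign_tiers(v, cfg, dg)
  # frameshift in a known disease gene, absent everywhere
  expect_equal(t1$impact_tier[1], 1L)
  expect_equal(t1$disease_tier[1], 1L)
  expect_equal(t1$frequency_tier[1], 1L)
  expect_equal(t1$impact_tier[2], 3L)   # synonymous, no splice prediction
  expect_equal(t1$quality_tier[1:4], c(1L, 1L, 2L, 3L))
  expect_equal(t1$frequency_tier[5:7], c(2L, 3L, 4L))
  expect_equal(t1$disease_tier[c(2, 8)], c(3L, 2L))
  # purity
  expect_identical(assign_tiers(v, cfg, dg), t1)
})

test_that("majority-vote impact tiering agrees with exhaustive enumeration", {
  # oracle: a missense variant (no conservation/splice support) is tier 2
  # iff damaging calls are at least half of the available predictors
  for (k in 1:6) {
    for (d in 0:k) {
      v <- make_variant(damaging_predictor_count = d, predictor_total = k,
                        cons_phylop = 0)
      got <- assign_tiers(v, cfg, NULL)$impact_tier
      expect_equal(got, if (d >= ceiling(k / 2)) 2L else 3L,
                   info = sprintf("k=%d d=%d", k, d))
    }
  }
  # high conservation rescues a split vote; zero predictors alone never tier 2
  v <- make_variant(damaging_predictor_count = 0L, predictor_total = 4L,
                    cons_phylop = 3)
  expect_equal(assign_tiers(v, cfg, NULL)$impact_tier, 2L)
  v0 <- make_variant(damaging_predictor_count = 0L, predictor_total = 0L)
  expect_equal(assign_tiers(v0, cfg, NULL)$impact_tier, 3L)
})

test_that("inheritance categories follow zygosity and gene mode", {
  dg <- test_disease_genes()
  v <- make_variants(
    make_variant(pos = 1L, gene = "ARG", zygosity = "hom"),
    make_variant(pos = 2L, gene = "ADG"),
    make_variant(pos = 3L, gene = "XLG", chrom = "chrX", zygosity = "hemizygous"),
    make_variant(pos = 4L, gene = "NOVELG"))
  out <- assign_inheritance_category(v, dg, "M")
  expect_equal(out$inheritance_category,
               c("AR_hom", "AD_het", "XL_hemizygous", "AD_het"))
  expect_equal(out$novel_gene, c(FALSE, FALSE, FALSE, TRUE))

  # compound het needs >= 2 distinct het positions; one lone het is a carrier
  two <- make_variants(make_variant(pos = 10L, gene = "ARG"),
                       make_variant(pos = 20L, gene = "ARG"))
  expect_equal(assign_inheritance_category(two, dg, "F")$inheritance_category,
               rep("AR_compound_het_candidate", 2))
  one <- make_variant(pos = 10L, gene = "ARG")
  expect_equal(assign_inheritance_category(one, dg, "F")$inheritance_category,
               "carrier_only")
  # duplicated position collapses the candidate pair
  dup <- make_variants(make_variant(pos = 10L, gene = "ARG"),
                       make_variant(pos = 10L, gene = "ARG", alt = "T"))
  expect_equal(unique(assign_inheritance_category(dup, dg, "F")$inheritance_category),
               "carrier_only")
  # hom in a dominant gene remains dominant-compatible
  adhom <- make_variant(gene = "ADG", zygosity = "hom")
  expect_equal(assign_inheritance_category(adhom, dg, "F")$inheritance_category,
               "AD_het")
  # X-linked het female is a carrier
  xf <- make_variant(gene = "XLG", chrom = "chrX")
  expect_equal(assign_inheritance_category(xf, dg, "F")$inheritance_category,
               "carrier_only")
})

test_that("reported pathogenicity combines the two assertion sources", {
  v <- make_variants(
    make_variant(pos = 1L, assertion_clinvar = "pathogenic"),
    make_variant(pos = 2L, assertion_hgmd = "likely_pathogenic"),
    make_variant(pos = 3L, assertion_clinvar = "pathogenic",
                 assertion_hgmd = "benign"),
    make_variant(pos = 4L),
    make_variant(pos = 5L, assertion_clinvar = "benign"))
  out <- classify_reported_pathogenicity(v)
  expect_equal(out$pathogenicity_category,
               c("asserted_pathogenic", "asserted_likely", "conflicting",
                 "novel", "novel"))
})

test_that("simplified ACMG classification follows the documented rule table", {
  dg <- test_disease_genes()
  run1 <- function(v, pm = 1) {
    v <- filter_rare_functional(v, cfg)
    v <- assign_tiers(v, cfg, dg)
    v <- assign_inheritance_category(v, dg, "F")
    v <- classify_reported_pathogenicity(v)
    acmg_classify_simplified(v, dg, pm)
  }
  # LoF, LoF-mechanism gene, absent -> pathogenic
  expect_equal(run1(make_variant(effect_class = "nonsense", gene = "ADG")),
               "pathogenic")
  # asserted pathogenic missense, MOI-compatible -> pathogenic
  expect_equal(run1(make_variant(gene = "ADG", assertion_clinvar = "pathogenic")),
               "pathogenic")
  # LoF in non-LoF-mechanism disease gene, rare but present -> likely
  expect_equal(run1(make_variant(effect_class = "frameshift", gene = "DUALG",
                                 freq_1kg = 0.001)),
               "likely_pathogenic")
  # novel damaging missense with phenotype overlap -> likely
  expect_equal(run1(make_variant(gene = "ADG")), "likely_pathogenic")
  # same without phenotype overlap -> VUS
  expect_equal(run1(make_variant(gene = "ADG"), pm = 0), "VUS")
  # predictors split -> VUS even with phenotype overlap
  expect_equal(run1(make_variant(gene = "ADG", damaging_predictor_count = 1L)),
               "VUS")
  # carrier-only het in recessive gene is never pathogenic on its own
  expect_equal(run1(make_variant(gene = "ARG", effect_class = "nonsense",
                                 freq_1kg = 0.001)),
               "VUS")
})

test_that("rank_candidates orders deterministically and excludes carriers", {
  res <- test_resources()
  dg <- res$disease_genes
  v <- make_variants(
    make_variant(pos = 100L, gene = "ADG", assertion_clinvar = "pathogenic",
                 effect_class = "missense"),
    make_variant(pos = 50L, chrom = "chr2", gene = "NOVELG",
                 effect_class = "missense"),
    make_variant(pos = 10L, gene = "ARG"))     # lone AR het: carrier only
  v <- filter_rare_functional(v, cfg)
  v <- assign_tiers(v, cfg, dg)
  v <- assign_inheritance_category(v, dg, "F")
  v <- classify_reported_pathogenicity(v)
  cand <- rank_candidates(v, dg, case_terms = c("HP:0001263"),
                          ontology = res$ontology, cfg = cfg)
  expect_equal(nrow(cand), 2L)  # carrier never becomes a candidate
  expect_equal(cand$gene[1], "ADG")  # asserted pathogenic outranks novel
  expect_equal(cand$rank, 1:2)

  # coordinate tie-break for identical keys
  tie <- make_variants(
    make_variant(pos = 500L, chrom = "chr2", gene = "NOVELG2"),
    make_variant(pos = 300L, chrom = "chr1", gene = "NOVELG1"))
  tie <- classify_reported_pathogenicity(
    assign_inheritance_category(assign_tiers(filter_rare_functional(tie, cfg),
                                             cfg, dg), dg, "F"))
  ct <- rank_candidates(tie, dg, cfg = cfg)
  expect_equal(ct$gene, c("NOVELG1", "NOVELG2"))
})

test_that("compound-het pairs use distinct positions and the weaker class", {
  res <- test_resources(); dg <- res$disease_genes
  v <- make_variants(
    make_variant(pos = 10L, gene = "ARG", effect_class = "nonsense"),
    make_variant(pos = 20L, gene = "ARG", assertion_clinvar = "pathogenic"),
    make_variant(pos = 30L, gene = "ARG", damaging_predictor_count = 0L))
  v <- filter_rare_functional(v, cfg)
  v <- assign_tiers(v, cfg, dg)
  v <- assign_inheritance_category(v, dg, "F")
  v <- classify_reported_pathogenicity(v)
  cand <- rank_candidates(v, dg, case_terms = "HP:0001250",
                          ontology = res$ontology, cfg = cfg)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$moi_model, "AR_compound_het")
  expect_equal(cand$n_variants, 2L)
  expect_true(cand$phase_unknown)
  expect_equal(cand$acmg_class, "pathogenic")  # both alleles qualify here
  ids <- strsplit(cand$variant_ids, ",")[[1]]
  expect_length(unique(sub(".*:(\\d+):.*:.*", "\\1", ids)), 2L)
})

test_that("phenotype match score behaves on the closure", {
  ont <- fixture_ontology()
  expect_equal(phenotype_match_score(c("HP:0001263"), c("HP:0001263"), ont), 1)
  # disjoint branches score zero (root excluded from closures)
  expect_equal(phenotype_match_score("HP:0001263", "HP:0000974", ont), 0)
  # child vs its own ancestor is positive: oracle by explicit traversal
  s <- phenotype_match_score("HP:0001263", "HP:0012758", ont)
  expect_gt(s, 0)
  walk_up <- function(term, edges) {  # independent closure traversal
    out <- term
    repeat {
      p <- edges$parent[edges$child %in% out & !edges$parent %in% out]
      if (!length(p)) break
      out <- union(out, p)
    }
    out
  }
  e <- ont$edges
  roots <- setdiff(unique(c(e$child, e$parent)), e$child)
  cc <- setdiff(walk_up("HP:0001263", e), roots)
  gc <- setdiff(walk_up("HP:0012758", e), roots)
  expect_equal(s, length(intersect(cc, gc)) / length(cc))
  expect_error(phenotype_match_score("HP:9999999", "HP:0012758", ont),
               "HP:9999999")
})

test_that("count_rare_damaging counts surviving tier<=2 variants", {
  dg <- test_disease_genes()
  v <- make_variants(
    make_variant(pos = 1L, effect_class = "nonsense"),
    make_variant(pos = 2L),
    make_variant(pos = 3L, damaging_predictor_count = 0L),
    make_variant(pos = 4L, effect_class = "synonymous"))
  t <- assign_tiers(filter_rare_functional(v, cfg), cfg, dg)
  expect_equal(count_rare_damaging(t), 2L)
  empty <- assign_tiers(filter_rare_functional(
    make_variant(freq_1kg = 0.5), cfg), cfg, dg)
  expect_equal(count_rare_damaging(empty), 0L)
})
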