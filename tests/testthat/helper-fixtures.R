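# Builders for small hand-made test objects. All defaults describe a clean
# rare damaging het missense call; override per test.

make_variant <- function(case_id = "C1", chrom = "chr1", pos = 1000L,
                         ref = "A", alt = "G", zygosity = "het",
                         read_depth = 40L, genotype_quality = 60L,
                         allele_fraction = 0.5, gene = "GENE1",
                         effect_class = "missense",
                         freq_1kg = NA_real_, freq_exac = NA_real_,
                         cons_phylop = 0,
                         damaging_predictor_count = 4L, predictor_total = 4L,
                         splice_delta = NA_real_,
                         assertion_clinvar = "none", assertion_hgmd = "none",
                         mouse_phenotype_flag = FALSE) {
  data.frame(case_id = case_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
             zygosity = zygosity, read_depth = read_depth,
             genotype_quality = genotype_quality,
             allele_fraction = allele_fraction, gene = gene,
             effect_class = effect_class, freq_1kg = freq_1kg,
             freq_exac = freq_exac, cons_phylop = cons_phylop,
             damaging_predictor_count = damaging_predictor_count,
             predictor_total = predictor_total, splice_delta = splice_delta,
             assertion_clinvar = assertion_clinvar,
             assertion_hgmd = assertion_hgmd,
             mouse_phenotype_flag = mouse_phenotype_flag,
             stringsAsFactors = FALSE)
}

make_variants <- function(...) do.call(rbind, list(...))

test_disease_genes <- function() {
  data.frame(
    gene = c("ADG", "ARG", "XLG", "DUALG"),
    inheritance_modes = c("AD", "AR", "XL", "AD,AR"),
    condition = paste("disorder", 1:4),
    phenotype_terms = c("HP:0001263,HP:0000750", "HP:0001250,HP:0001252",
                        "HP:0002652,HP:0002650", "HP:0004322,HP:0001508"),
    lof_mechanism = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

test_resources <- function() {
  list(disease_genes = test_disease_genes(), ontology = fixture_ontology())
}

make_cnv <- function(case_id = "C1", chrom = "chr1", start = 0, end = 10000,
                     state = "loss", source = "read_depth", ...) {
  data.frame(case_id = case_id, chrom = chrom, start = start, end = end,
             state = state, source = source, ..., stringsAsFactors = FALSE)
}

# brute-force reciprocal overlap by per-base membership (oracle; lengths <= 1e4)
ro_bruteforce <- function(a_start, a_end, b_start, b_end) {
  a <- seq(a_start, a_end - 1)
  b <- seq(b_start, b_end - 1)
  inter <- length(intersect(a, b))
  min(inter / length(a), inter / length(b))
}
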