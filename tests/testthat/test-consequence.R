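# The worked examples mirror the resistant/sensitive genotypes the
# platform recovered (single-residue deletion, 10-residue deletion,
# repeat-run deletion, substitution run, compound substitution+deletion).

sf_model <- synthetic_sf3b1_model()
sf_alleles <- worked_example_alleles(sf_model)

consequence_of <- function(id) {
  v <- genotype(sf_model, sf_alleles[[id]])
  protein_consequence(sf_model, v, allele_id = id)
}

test_that("frame classification is net-length mod 3 arithmetic", {
  del3 <- data.frame(kind = "deletion", cds_start = 10L, ref_allele = "AAA",
                     alt_allele = "", normalized = TRUE)
  del1 <- data.frame(kind = "deletion", cds_start = 10L, ref_allele = "A",
                     alt_allele = "", normalized = TRUE)
  expect_equal(classify_frame(del3), "in_frame")
  expect_equal(classify_frame(del1), "frameshift")
  expect_equal(classify_frame(del3[0, ]), "silent")
  # 1-nt del + 4-nt del + 2-nt ins: net -3 -> in frame
  mix <- data.frame(kind = c("deletion", "deletion", "insertion"),
                    cds_start = c(5L, 20L, 40L),
                    ref_allele = c("A", "ACGT", ""),
                    alt_allele = c("", "", "GG"), normalized = TRUE)
  expect_equal(classify_frame(mix), "in_frame")
  # synonymous substitution is silent when the model is supplied
  m <- build_gene_model(cds = "ATGCAACATTAA") # M Q H
  syn <- data.frame(kind = "substitution", cds_start = 5L,
                    ref_allele = "A", alt_allele = "G", normalized = TRUE)
  expect_equal(classify_frame(syn, m), "silent")   # CAA -> CAG, still Q
  expect_equal(classify_frame(syn), "in_frame")    # unknowable without model
  nonsyn <- data.frame(kind = "substitution", cds_start = 3L,
                       ref_allele = "C", alt_allele = "G", normalized = TRUE)
  expect_equal(classify_frame(nonsyn, m), "in_frame")
})

test_that("single-residue deletion reports Q157del", {
  r <- consequence_of("SGR1")
  expect_equal(r$frame, "in_frame")
  expect_equal(nrow(r$changes), 1L)
  expect_equal(r$changes$label, "Q157del")
  expect_equal(r$changes$start_res, 157L)
  expect_false(r$knockout_candidate)
})

test_that("codon-aligned 30-nt deletion reports ten residues 223-232", {
  r <- consequence_of("SGR2")
  ch <- r$changes
  expect_equal(ch$kind, "deletion")
  expect_equal(c(ch$start_res, ch$end_res), c(223L, 232L))
  expect_equal(ch$end_res - ch$start_res + 1L, 10L)
  expect_equal(ch$ref_aa, "DAPDATPGIG")
  expect_equal(ch$label, "D223_G232del")
})

test_that("K-run deletion 3'-normalizes to K1050", {
  r <- consequence_of("SGR3")
  expect_equal(r$changes$label, "K1050del")
})

test_that("9-nt replacement decomposes into three substitutions", {
  r <- consequence_of("SGR4")
  expect_equal(r$changes$kind, rep("substitution", 3))
  expect_equal(r$changes$label, c("K1049R", "K1050E", "G1051H"))
})

test_that("non-codon-aligned deletion decomposes into sub + deletion", {
  r <- consequence_of("SGR5")
  expect_equal(r$changes$label, c("H1048Q", "K1049del"))
  expect_equal(r$changes$kind, c("substitution", "deletion"))
})

test_that("compound PTG allele reports both cut regions", {
  r <- consequence_of("SGR6")
  expect_equal(r$changes$label, c("H1048Q", "K1049del", "A1064S"))
})

test_that("15-residue deletion allele (GEX1A-sensitive) reports 442-456", {
  r <- consequence_of("SGS1")
  expect_equal(c(r$changes$start_res, r$changes$end_res), c(442L, 456L))
  expect_equal(r$changes$end_res - r$changes$start_res + 1L, 15L)
  expect_equal(r$changes$ref_aa, "LPLMKPEDYQYFGTL")
})

test_that("frameshift reports first divergent residue and knockout flag", {
  r <- consequence_of("FS1")
  expect_equal(r$frame, "frameshift")
  expect_equal(nrow(r$changes), 1L)
  expect_match(r$changes$label, "^[A-Z]\\d+fs$")
  expect_true(r$knockout_candidate)
  expect_true(is.na(r$fs_new_stop) || r$fs_new_stop >= r$changes$start_res)
})

test_that("nonsense substitution sets the knockout flag", {
  m <- build_gene_model(cds = "ATGCAACATGGTTAA") # M Q H G
  v <- genotype(m, "ATGTAACATGGTTAA")            # Q2 -> stop
  r <- protein_consequence(m, v)
  expect_equal(r$frame, "in_frame")
  expect_true(r$knockout_candidate)
  expect_true(any(grepl("\\*", r$changes$alt_aa)))
})

test_that("silent alleles produce empty reports", {
  m <- build_gene_model(cds = "ATGCAACATTAA")
  r0 <- protein_consequence(m, genotype(m, m$cds))
  expect_equal(r0$frame, "silent")
  expect_equal(nrow(r0$changes), 0L)
  # synonymous edit CAA -> CAG
  rs <- protein_consequence(m, genotype(m, "ATGCAGCATTAA"))
  expect_equal(rs$frame, "silent")
})

test_that("in-frame changes re-apply onto the wild-type protein", {
  for (id in c("SGR1", "SGR2", "SGR3", "SGR4", "SGR5", "SGR6", "SGS1")) {
    v <- genotype(sf_model, sf_alleles[[id]])
    r <- protein_consequence(sf_model, v, allele_id = id)
    mut_prot <- sub("\\*$", "",
                    translate_cds(apply_variants(sf_model$cds, v)))
    # treat protein changes as string edits on the wild-type protein
    pv <- data.frame(kind = r$changes$kind,
                     cds_start = ifelse(r$changes$kind == "insertion",
                                        r$changes$start_res,
                                        r$changes$start_res - 1L),
                     ref_allele = r$changes$ref_aa,
                     alt_allele = r$changes$alt_aa,
                     stringsAsFactors = FALSE)
    expect_identical(oracle_apply_variants(sf_model$protein, pv), mut_prot,
                     label = id)
  }
})

test_that("reported change count equals residue-level edit distance", {
  for (id in c("SGR1", "SGR2", "SGR4", "SGR5", "SGR6", "SGS1")) {
    v <- genotype(sf_model, sf_alleles[[id]])
    r <- protein_consequence(sf_model, v, allele_id = id)
    mut_prot <- sub("\\*$", "",
                    translate_cds(apply_variants(sf_model$cds, v)))
    # confine the oracle to the affected window (edits are local)
    lo <- min(r$changes$start_res) - 1L
    hi <- max(r$changes$end_res) + 1L
    shift <- nchar(mut_prot) - nchar(sf_model$protein)
    wt_win <- substr(sf_model$protein, lo, hi)
    mut_win <- substr(mut_prot, lo, hi + shift)
    n_changed <- sum(ifelse(r$changes$kind == "substitution", 1L,
                            pmax(nchar(r$changes$ref_aa),
                                 nchar(r$changes$alt_aa))))
    expect_equal(n_changed, oracle_edit_distance(wt_win, mut_win),
                 label = id)
  }
})

test_that("domain annotation uses interval intersection", {
  doms <- domain_table(c("HR15-17", "Nterm"), c(1040L, 1L), c(1080L, 200L),
                       sf_model)
  r <- annotate_domains(consequence_of("SGR3"), doms)
  expect_equal(r$domains_hit, "HR15-17")
  r1 <- annotate_domains(consequence_of("SGR1"), doms)
  expect_equal(r1$domains_hit, "Nterm")
  r2 <- annotate_domains(consequence_of("SGR2"), doms)
  expect_equal(r2$domains_hit, character(0))
  # empty domain table -> no hits
  empty <- domain_table(character(0), integer(0), integer(0))
  expect_equal(annotate_domains(consequence_of("SGR3"), empty)$domains_hit,
               character(0))
  # frameshift flags every domain ending at/after the divergence point
  rfs <- annotate_domains(consequence_of("FS1"), doms)
  expect_equal(sort(rfs$domains_hit), c("HR15-17", "Nterm"))
})
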