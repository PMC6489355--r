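test_that("alignment of identical sequences is gapless with score 2n", {
  set.seed(31)
  s <- random_dna(40)
  a <- align_global(s, s)
  expect_equal(a$score, 2 * nchar(s))
  expect_identical(a$ref_aln, s)
  expect_identical(a$qry_aln, s)
  expect_error(align_global("", "ACGT"), "non-empty")
})

test_that("single-deletion example scores 7 matches + open + extend", {
  a <- align_global("ACGTACGT", "ACGACGT")
  expect_equal(a$score, 7 * 2 - 10 - 1)
  expect_equal(lengths(regmatches(a$qry_aln, gregexpr("-", a$qry_aln))), 1L)
  expect_false(grepl("-", a$ref_aln))
})

test_that("optimal score matches exhaustive alignment enumeration", {
  set.seed(32)
  for (k in 1:40) {
    a <- random_dna(sample(1:7, 1))
    b <- random_dna(sample(1:7, 1))
    expect_equal(align_global(a, b)$score, oracle_align_enum(a, b),
                 info = paste(a, b))
  }
})

test_that("optimal score matches the independent quadratic DP", {
  set.seed(33)
  for (k in 1:100) {
    a <- random_dna(sample(20:200, 1))
    b <- random_dna(sample(20:200, 1))
    expect_equal(align_global(a, b)$score, oracle_align_biostrings(a, b),
                 info = paste(nchar(a), nchar(b)))
  }
})

test_that("gapped rows reproduce the inputs and never share a gap column", {
  set.seed(34)
  for (k in 1:30) {
    a <- random_dna(sample(10:80, 1))
    b <- random_dna(sample(10:80, 1))
    al <- align_global(a, b)
    expect_equal(nchar(al$ref_aln), nchar(al$qry_aln))
    expect_identical(gsub("-", "", al$ref_aln), a)
    expect_identical(gsub("-", "", al$qry_aln), b)
    rr <- strsplit(al$ref_aln, "")[[1]]; qq <- strsplit(al$qry_aln, "")[[1]]
    expect_false(any(rr == "-" & qq == "-"))
  }
})

test_that("variant calling collapses non-match runs correctly", {
  ref <- "ATGCATAAGAAGGGTGAT"
  expect_equal(nrow(call_dna_variants(align_global(ref, ref))), 0L)

  # one codon removed -> a single 3-nt deletion
  v <- call_dna_variants(align_global(ref, "ATGCATAAGGGTGAT"))
  expect_equal(v$kind, "deletion")
  expect_equal(nchar(v$ref_allele), 3L)

  # 30-nt contiguous deletion stays one variant
  set.seed(35)
  m <- toy_model(seed = 35L)
  qry <- paste0(substr(m$cds, 1, 60), substr(m$cds, 91, nchar(m$cds)))
  v30 <- call_dna_variants(align_global(m$cds, qry))
  expect_equal(v30$kind, "deletion")
  expect_equal(nchar(v30$ref_allele), 30L)
  expect_equal(v30$alt_allele, "")

  # substitution / insertion / delins kinds
  sub1 <- call_dna_variants(align_global("AAAATTTT", "AAAGTTTT"))
  expect_equal(sub1$kind, "substitution")
  ins1 <- call_dna_variants(align_global("AAAATTTT", "AAAACCCTTTT"))
  expect_equal(ins1$kind, "insertion")
  expect_equal(ins1$alt_allele, "CCC")
})

test_that("runs separated by a single matching base stay separate", {
  ref <- "ATGCATCAGGGTTGGCCA"
  #       two mismatches around a matching base
  qry <- "ATGCATGATGGTTGGCCA" # C7->G and G9->T with A8 matching
  v <- call_dna_variants(align_global(ref, qry))
  expect_equal(nrow(v), 2L)
  expect_true(all(v$kind == "substitution"))
})

test_that("3'-normalization shifts indels to the repeat end", {
  # deleting any single A from CAAAT normalizes to the last A of the run
  ref <- "CAAAT"
  for (pos in 1:3) {
    v <- data.frame(kind = "deletion", cds_start = pos, ref_allele = "A",
                    alt_allele = "", normalized = FALSE)
    nv <- normalize_3prime(v, ref)
    expect_equal(nv$cds_start, 3L)
    expect_true(nv$normalized)
    # equivalence: same mutant sequence before and after
    expect_identical(oracle_apply_variants(ref, v),
                     oracle_apply_variants(ref, nv))
  }
  # deletion of AAG in a two-codon AAG AAG run shifts to the 3'-most copy
  ref2 <- "CATAAGAAGGGT"
  v2 <- data.frame(kind = "deletion", cds_start = 3L, ref_allele = "AAG",
                   alt_allele = "", normalized = FALSE)
  nv2 <- normalize_3prime(v2, ref2)
  expect_equal(nv2$cds_start, 6L)
  expect_identical(nv2$ref_allele, "AAG")
  # oracle: maximal equivalent placement
  equiv <- Filter(function(s) {
    identical(oracle_apply_variants(
      ref2, data.frame(kind = "deletion", cds_start = s,
                       ref_allele = substr(ref2, s + 1, s + 3),
                       alt_allele = "", normalized = FALSE)),
      oracle_apply_variants(ref2, v2))
  }, 0:(nchar(ref2) - 3))
  expect_equal(nv2$cds_start, max(unlist(equiv)))
  # idempotence
  expect_identical(normalize_3prime(nv2, ref2), nv2)

  # insertion into a homopolymer shifts right too
  vi <- data.frame(kind = "insertion", cds_start = 1L, ref_allele = "",
                   alt_allele = "A", normalized = FALSE)
  nvi <- normalize_3prime(vi, "CAAAT")
  expect_equal(nvi$cds_start, 4L)
  expect_identical(oracle_apply_variants("CAAAT", vi),
                   oracle_apply_variants("CAAAT", nvi))
})

test_that("genotype round-trips random edits and rejects foreign amplicons", {
  m <- toy_model(seed = 36L)
  expect_equal(nrow(genotype(m, m$cds)), 0L) # wild type

  set.seed(37)
  for (k in 1:25) {
    # random edit: deletion, insertion or substitution block
    pos <- sample(10:250, 1)
    type <- sample(c("del", "ins", "sub"), 1)
    qry <- switch(type,
      del = paste0(substr(m$cds, 1, pos),
                   substr(m$cds, pos + sample(1:12, 1) + 1, nchar(m$cds))),
      ins = paste0(substr(m$cds, 1, pos), random_dna(sample(1:8, 1)),
                   substr(m$cds, pos + 1, nchar(m$cds))),
      sub = paste0(substr(m$cds, 1, pos - 1), random_dna(3),
                   substr(m$cds, pos + 3, nchar(m$cds)))
    )
    v <- genotype(m, qry)
    expect_identical(oracle_apply_variants(m$cds, v), qry) # reconstruction
    expect_true(all(v$normalized))
  }
  expect_error(genotype(m, random_dna(nchar(m$cds))), "does not match locus")
})

test_that("sub-amplicon coordinates are lifted to CDS space", {
  m <- toy_model(seed = 38L)
  amp <- substr(m$cds, 101, 220) # CDS positions 100..219 (0-based)
  mut <- paste0(substr(amp, 1, 50), substr(amp, 54, nchar(amp))) # 3-nt del
  v <- genotype(m, mut, amplicon_range = c(101L, 220L))
  expect_equal(nrow(v), 1L)
  expect_true(v$cds_start >= 100L)
  full_mut <- paste0(substr(m$cds, 1, 100), mut,
                     substr(m$cds, 221, nchar(m$cds)))
  expect_identical(oracle_apply_variants(m$cds, v), full_mut)
})
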