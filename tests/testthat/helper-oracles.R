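# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks: the guide oracle is a literal per-offset scan, the
# alignment oracles are (a) exhaustive enumeration of all global
# alignments and (b) Biostrings::pairwiseAlignment, translation uses
# Biostrings::translate, and variant application has its own tiny
# re-implementation.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

oracle_translate <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

# literal per-offset scan for 20-nt protospacers with NGG PAM, both strands
oracle_scan_guides <- function(region, guide_len = 20L) {
  L <- nchar(region)
  hits <- list()
  for (p in seq_len(L)) { # p = 1-based PAM start, plus strand
    if (p + 2L <= L && p - guide_len >= 1L &&
        substr(region, p + 1L, p + 2L) == "GG") {
      hits[[length(hits) + 1L]] <- data.frame(
        protospacer = substr(region, p - guide_len, p - 1L),
        pam = substr(region, p, p + 2L), strand = "+",
        start = p - guide_len - 1L, stringsAsFactors = FALSE)
    }
  }
  rc <- oracle_revcomp(region)
  for (p in seq_len(nchar(rc))) { # same scan on the reverse complement
    if (p + 2L <= L && p - guide_len >= 1L &&
        substr(rc, p + 1L, p + 2L) == "GG") {
      # map the protospacer 5' end back to plus-strand coordinates
      start_plus <- L - (p - guide_len) # 0-based
      hits[[length(hits) + 1L]] <- data.frame(
        protospacer = substr(rc, p - guide_len, p - 1L),
        pam = substr(rc, p, p + 2L), strand = "-",
        start = start_plus, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(protospacer = character(0), pam = character(0),
                      strand = character(0), start = integer(0)))
  }
  h <- do.call(rbind, hits)
  h <- h[order(h$start, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# exhaustive enumeration of every global alignment (move strings over
# D/U/L), scored with gap runs charged open + len * extend; exponential,
# keep lengths <= 7
oracle_align_enum <- function(a, b, match = 2, mismatch = -3,
                              gap_open = -10, gap_extend = -1) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, prev) {
    if (i > length(ac) && j > length(bc)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(ac) && j <= length(bc)) {
      s <- if (ac[i] == bc[j]) match else mismatch
      rec(i + 1L, j + 1L, score + s, "D")
    }
    if (i <= length(ac)) {
      pen <- gap_extend + if (prev == "U") 0 else gap_open
      rec(i + 1L, j, score + pen, "U")
    }
    if (j <= length(bc)) {
      pen <- gap_extend + if (prev == "L") 0 else gap_open
      rec(i, j + 1L, score + pen, "L")
    }
  }
  rec(1L, 1L, 0, "start")
  best
}

# independent quadratic DP: Biostrings' C implementation with the same
# scoring convention (gap of length L costs opening + L * extension)
oracle_align_biostrings <- function(a, b, match = 2, mismatch = -3,
                                    gap_open = 10, gap_extend = 1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global"))
}

# independent variant application (string surgery right-to-left)
oracle_apply_variants <- function(ref, variants) {
  if (nrow(variants) == 0L) return(ref)
  v <- variants[order(variants$cds_start, decreasing = TRUE), , drop = FALSE]
  for (k in seq_len(nrow(v))) {
    pre <- substr(ref, 1, v$cds_start[k])
    post <- substr(ref, v$cds_start[k] + nchar(v$ref_allele[k]) + 1,
                   nchar(ref))
    ref <- paste0(pre, v$alt_allele[k], post)
  }
  ref
}

# residue-level Levenshtein distance (unit costs), for the decomposition
# minimality check
oracle_edit_distance <- function(a, b) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1, j + 1] <- min(d[i, j] + (ac[i] != bc[j]),
                           d[i, j + 1] + 1L, d[i + 1, j] + 1L)
  }
  d[n + 1, m + 1]
}

# shared toy reference used in several files: 100-codon CDS, no terminal
# stop shenanigans, deterministic
toy_model <- function(seed = 11L, n_codons = 100L) {
  set.seed(seed)
  aa <- c("M", sample(setdiff(names(crisprCDE:::AA_TO_CODON), c("*", "M")),
                      n_codons - 1L, replace = TRUE))
  build_gene_model(cds = paste(c(crisprCDE:::AA_TO_CODON[aa], "TAA"),
                               collapse = ""), gene_id = "toy")
}
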