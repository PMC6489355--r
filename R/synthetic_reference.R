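# Synthetic SF3B1-like reference. The platform's target gene is the rice
# splicing-factor locus LOC_Os02g05310, whose exact sequence is not
# bundled here; instead a clearly-synthetic stand-in protein is built that
# reproduces every residue context the worked examples depend on, with
# random non-repeating flanks. All coordinates then match the published
# residue numbering (Q157, 223-232, 442-456, 1048-1051, 1064).

#' Build a synthetic SF3B1-like gene model
#'
#' A deterministic ~1.1 kaa protein with fixed anchor contexts embedded at
#' the residue positions the worked examples use:
#' * `Q` at 157 (flanked by non-Q residues),
#' * `DAPDATPGIG` at 223-232,
#' * `LPLMKPEDYQYFGTL` at 442-456,
#' * `H K K G` at 1048-1051 with both lysines encoded `AAG`,
#' * `A` at 1064 (flanked by non-A residues).
#' Remaining residues are drawn uniformly from the 19 non-anchor-breaking
#' amino acids under `seed`; each amino acid reverse-translates through a
#' fixed codon so the CDS is reproducible. A terminal `TAA` stop is
#' appended (part of the CDS, excluded from residue numbering).
#'
#' @param seed Integer seed for the random flanks.
#' @param protein_length Total protein length (>= 1070).
#' @return A [gene_model] with `gene_id = "SF3B1-like-synthetic"`.
#' @export
synthetic_sf3b1_model <- function(seed = 101L, protein_length = 1100L) {
  stopifnot(protein_length >= 1070L)
  set.seed(as.integer(seed))
  aa_pool <- setdiff(names(AA_TO_CODON), c("*", "M"))
  prot <- sample(aa_pool, protein_length, replace = TRUE)
  prot[1] <- "M"

  put <- function(p, at, s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    p[at:(at + length(ch) - 1L)] <- ch
    p
  }
  # anchors, with flanks fixed to residues that cannot extend a repeat
  prot <- put(prot, 154L, "PWVQESR")          # Q at 157
  prot <- put(prot, 222L, "EDAPDATPGIGW")     # motif at 223-232
  prot <- put(prot, 441L, "SLPLMKPEDYQYFGTLR") # motif at 442-456
  prot <- put(prot, 1047L, "EHKKGD")          # H K K G at 1048-1051
  prot <- put(prot, 1063L, "TAV")             # A at 1064

  cds <- paste(c(AA_TO_CODON[prot], "TAA"), collapse = "")
  build_gene_model(cds = cds, gene_id = "SF3B1-like-synthetic")
}

#' Construct the worked-example mutant alleles
#'
#' Returns mutant CDS sequences for the published resistant/sensitive
#' genotypes, rebuilt on the synthetic reference:
#' * `SGR1` - 3-bp deletion removing the Q157 codon;
#' * `SGR2` - codon-aligned 30-nt deletion removing DAPDATPGIG (223-232);
#' * `SGR3` - one `AAG` deleted from the K1049/K1050 run (normalizes to
#'   K1050);
#' * `SGR4` - 9-nt replacement converting K1049 K1050 G1051 to R E H;
#' * `SGR5` - non-codon-aligned 3-nt deletion across codons 1048-1049
#'   (H1048Q + K1049del);
#' * `SGR6` - the SGR5 edit plus an A1064S substitution (dual-guide PTG
#'   outcome);
#' * `SGS1` - codon-aligned 45-nt deletion removing LPLMKPEDYQYFGTL
#'   (442-456), the GEX1A-sensitive in-frame allele;
#' * `FS1` - single-nucleotide deletion at the Q157 codon (frameshift
#'   knockout-candidate control).
#'
#' @param model The [synthetic_sf3b1_model()] (or a compatible model).
#' @return Named character vector of mutant CDS sequences.
#' @export
worked_example_alleles <- function(model = synthetic_sf3b1_model()) {
  cds <- model$cds
  del <- function(s, start0, len) { # 0-based half-open deletion
    paste0(substr(s, 1L, start0), substr(s, start0 + len + 1L, nchar(s)))
  }
  repl <- function(s, start0, len, alt) {
    paste0(substr(s, 1L, start0), alt, substr(s, start0 + len + 1L, nchar(s)))
  }
  c157 <- residue_to_cds(157L)[1, "start"]
  c223 <- residue_to_cds(223L)[1, "start"]
  c442 <- residue_to_cds(442L)[1, "start"]
  c1048 <- residue_to_cds(1048L)[1, "start"]
  c1049 <- residue_to_cds(1049L)[1, "start"]
  c1064 <- residue_to_cds(1064L)[1, "start"]

  # substitution first: its coordinate sits downstream of the deletion,
  # so applying the length-changing edit afterwards keeps both anchored
  sgr6 <- repl(cds, c1064, 1L, "T")           # GCT -> TCT = A1064S
  sgr6 <- del(sgr6, c1048 + 2L, 3L)           # H1048Q + K1049del

  c(
    SGR1 = del(cds, c157, 3L),
    SGR2 = del(cds, c223, 30L),
    SGR3 = del(cds, c1049, 3L),
    SGR4 = repl(cds, c1049, 9L, "AGGGAGCAT"), # K K G -> R E H
    SGR5 = del(cds, c1048 + 2L, 3L),
    SGR6 = sgr6,
    SGS1 = del(cds, c442, 45L),
    FS1 = del(cds, c157, 1L)
  )
}
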