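# Amplicon genotyping: affine-gap global alignment of a resolved mutant
# allele against the reference CDS, collapse of non-match runs into DNA
# variants, and HGVS-style 3'-normalization of indels. Each input allele
# is a single resolved haplotype (cloned-PCR Sanger reads); mixed-trace
# deconvolution is out of scope.

#' Global alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh alignment with the convention that a gap of
#' length L costs `gap_open + L * gap_extend` (the opening column is
#' charged both terms). Traceback is deterministic with tie-break
#' diagonal > up (gap in query) > left (gap in reference).
#'
#' @param ref,qry Non-empty sequences (DNA or protein; compared
#'   character-wise).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters; defaults
#'   favour one long gap over scattered mismatches, matching the
#'   contiguous-deletion alleles NHEJ produces.
#' @return List of class `alignment`: `ref_aln`, `qry_aln` (equal-length
#'   gapped strings), `score`.
#' @examples
#' align_global("ACGTACGT", "ACGACGT")$score # 7*2 - 10 - 1 = 3
#' @export
align_global <- function(ref, qry, match = 2, mismatch = -3,
                         gap_open = -10, gap_extend = -1) {
  if (nchar(ref) == 0L || nchar(qry) == 0L) {
    stop("alignment inputs must be non-empty", call. = FALSE)
  }
  res <- gotoh_align_cpp(ref, qry, match, mismatch, gap_open, gap_extend)
  structure(res, class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("global alignment, score", x$score, "\n")
  w <- 60L
  n <- nchar(x$ref_aln)
  for (s in seq(1L, n, w)) {
    e <- min(s + w - 1L, n)
    r <- substr(x$ref_aln, s, e); q <- substr(x$qry_aln, s, e)
    mk <- paste(ifelse(strsplit(r, "")[[1]] == strsplit(q, "")[[1]],
                       "|", " "), collapse = "")
    cat(r, "\n", mk, "\n", q, "\n\n", sep = "")
  }
  invisible(x)
}

.empty_variants <- function() {
  data.frame(kind = character(0), cds_start = integer(0),
             ref_allele = character(0), alt_allele = character(0),
             normalized = logical(0), stringsAsFactors = FALSE)
}

.variant_kind <- function(ref_allele, alt_allele) {
  rl <- nchar(ref_allele); al <- nchar(alt_allele)
  if (rl > 0L && al == 0L) "deletion"
  else if (rl == 0L && al > 0L) "insertion"
  else if (rl == al) "substitution"
  else "delins"
}

#' Collapse an alignment into DNA variants
#'
#' Maximal runs of non-match columns become single variants (gap runs as
#' deletion/insertion, equal-length mismatch runs as substitution, mixed
#' runs as delins). Runs separated by at least one matching column stay
#' separate. Coordinates are 0-based in reference space.
#'
#' @param aln An [align_global()] result.
#' @return Variant `data.frame`: `kind`, `cds_start`, `ref_allele`,
#'   `alt_allele`, `normalized` (FALSE until [normalize_3prime()]).
#' @export
call_dna_variants <- function(aln) {
  r <- strsplit(aln$ref_aln, "", fixed = TRUE)[[1]]
  q <- strsplit(aln$qry_aln, "", fixed = TRUE)[[1]]
  stopifnot(length(r) == length(q))
  is_match <- r == q & r != "-"
  out <- list()
  rpos <- 0L # reference characters consumed so far
  i <- 1L
  n <- length(r)
  while (i <= n) {
    if (is_match[i]) {
      rpos <- rpos + 1L
      i <- i + 1L
      next
    }
    j <- i
    start <- rpos
    while (j <= n && !is_match[j]) {
      if (r[j] != "-") rpos <- rpos + 1L
      j <- j + 1L
    }
    ref_allele <- paste(r[i:(j - 1L)][r[i:(j - 1L)] != "-"], collapse = "")
    alt_allele <- paste(q[i:(j - 1L)][q[i:(j - 1L)] != "-"], collapse = "")
    out[[length(out) + 1L]] <- data.frame(
      kind = .variant_kind(ref_allele, alt_allele), cds_start = start,
      ref_allele = ref_allele, alt_allele = alt_allele, normalized = FALSE,
      stringsAsFactors = FALSE
    )
    i <- j
  }
  if (length(out) == 0L) return(.empty_variants())
  v <- do.call(rbind, out)
  v[order(v$cds_start), , drop = FALSE]
}

#' Shift an indel to its 3'-most equivalent placement
#'
#' HGVS convention: a deletion or insertion inside a sequence repeat is
#' reported at the highest coordinate that yields the same mutant
#' sequence. Idempotent; substitutions and delins are returned unchanged
#' (flagged normalized). This is what makes a one-lysine deletion in a
#' K-K run report the higher-numbered lysine.
#'
#' @param variants Variant `data.frame` (one or more rows).
#' @param ref Reference sequence the coordinates refer to.
#' @return Variant `data.frame` with updated positions/alleles and
#'   `normalized = TRUE`.
#' @export
normalize_3prime <- function(variants, ref) {
  if (nrow(variants) == 0L) return(variants)
  rc <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(rc)
  for (k in seq_len(nrow(variants))) {
    kind <- variants$kind[k]
    if (kind == "deletion") {
      s <- variants$cds_start[k]
      L <- nchar(variants$ref_allele[k])
      # 0-based deletion [s, s+L); shift while the base after the run
      # equals the first deleted base
      while (s + L < n && rc[s + L + 1L] == rc[s + 1L]) s <- s + 1L
      variants$cds_start[k] <- s
      variants$ref_allele[k] <- paste(rc[(s + 1L):(s + L)], collapse = "")
    } else if (kind == "insertion") {
      s <- variants$cds_start[k] # insertion before 0-based index s
      a <- strsplit(variants$alt_allele[k], "", fixed = TRUE)[[1]]
      while (s < n && rc[s + 1L] == a[1L]) {
        a <- c(a[-1L], a[1L])
        s <- s + 1L
      }
      variants$cds_start[k] <- s
      variants$alt_allele[k] <- paste(a, collapse = "")
    }
    variants$normalized[k] <- TRUE
  }
  variants[order(variants$cds_start), , drop = FALSE]
}

#' Apply DNA variants to a reference sequence
#'
#' Reconstructs the mutant sequence implied by a variant set; the inverse
#' of variant calling (round-trip identity holds for every genotyped
#' allele).
#'
#' @param ref Reference sequence.
#' @param variants Variant `data.frame` with non-overlapping reference
#'   intervals.
#' @return Mutant sequence string.
#' @export
apply_variants <- function(ref, variants) {
  if (nrow(variants) == 0L) return(ref)
  v <- variants[order(variants$cds_start, decreasing = TRUE), , drop = FALSE]
  out <- ref
  for (k in seq_len(nrow(v))) {
    s <- v$cds_start[k]
    rl <- nchar(v$ref_allele[k])
    if (rl > 0L &&
        substr(out, s + 1L, s + rl) != v$ref_allele[k]) {
      stop("variant ref_allele does not match reference at position ",
           s + 1L, call. = FALSE)
    }
    out <- paste0(substr(out, 1L, s), v$alt_allele[k],
                  substr(out, s + rl + 1L, nchar(out)))
  }
  out
}

#' Genotype a mutant allele against a gene model
#'
#' Runs the align -> call -> 3'-normalize pipeline against the reference
#' CDS (or a sub-amplicon of it) and returns CDS-space DNA variants.
#'
#' @param model A [gene_model].
#' @param allele Allele sequence (string or single named element of
#'   [read_fasta()] output); `N` permitted.
#' @param amplicon_range Optional 1-based inclusive CDS interval
#'   `c(start, end)` when `allele` is a sub-amplicon rather than the full
#'   CDS; called coordinates are lifted to CDS space.
#' @param min_identity Reject alignments below this column identity with
#'   an "amplicon does not match locus" error (default 0.5).
#' @param ... Scoring parameters passed to [align_global()].
#' @return Normalized variant `data.frame` in CDS coordinates (zero rows
#'   for a wild-type allele).
#' @export
genotype <- function(model, allele, amplicon_range = NULL,
                     min_identity = 0.5, ...) {
  allele <- toupper(as.character(allele)[1])
  .check_alphabet(allele, "<allele>", allow_n = TRUE)
  ref <- model$cds
  offset <- 0L
  if (!is.null(amplicon_range)) {
    amplicon_range <- as.integer(amplicon_range)
    stopifnot(length(amplicon_range) == 2L,
              amplicon_range[1] >= 1L,
              amplicon_range[2] <= nchar(ref),
              amplicon_range[1] <= amplicon_range[2])
    ref <- substr(ref, amplicon_range[1], amplicon_range[2])
    offset <- amplicon_range[1] - 1L
  }
  aln <- align_global(ref, allele, ...)
  cols <- nchar(aln$ref_aln)
  ident <- sum(strsplit(aln$ref_aln, "")[[1]] ==
                 strsplit(aln$qry_aln, "")[[1]]) / cols
  if (ident < min_identity) {
    stop("amplicon does not match locus (identity ",
         sprintf("%.1f%%", 100 * ident), ")", call. = FALSE)
  }
  v <- call_dna_variants(aln)
  v <- normalize_3prime(v, ref)
  v$cds_start <- v$cds_start + offset
  v
}

#' Write a variant table
#'
#' TSV report with 1-based coordinates, one row per variant.
#'
#' @param variants Variant `data.frame`, optionally with an `allele_id`
#'   column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  tab <- data.frame(
    allele_id = if ("allele_id" %in% names(variants)) variants$allele_id
                else rep("allele", nrow(variants)),
    kind = variants$kind,
    cds_start_1based = variants$cds_start + 1L,
    ref = variants$ref_allele,
    alt = variants$alt_allele,
    normalized = variants$normalized,
    stringsAsFactors = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
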