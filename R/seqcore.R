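# Sequence and gene-model primitives shared by every other module.
# Internal coordinates are 0-based half-open; everything user-facing
# (library tables, variant labels) is 1-based inclusive.

.check_alphabet <- function(seq, id = "<sequence>", allow_n = FALSE) {
  allowed <- if (allow_n) DNA_ALPHABET_N else DNA_ALPHABET
  chars <- unique(strsplit(seq, "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, allowed)
  if (length(bad) > 0L) {
    stop(sprintf("record '%s' contains illegal character(s): %s",
                 id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a multi-record FASTA file into a strict DNA sequence set
#'
#' Sequences are uppercased on ingest. Characters outside `A,C,G,T`
#' (plus `N` when `allow_n = TRUE`, as genotyping queries permit) are
#' rejected with the offending record named, as are duplicate ids and
#' empty files.
#'
#' @param path Path to a FASTA file (any line wrapping).
#' @param allow_n Allow the ambiguity code `N` (default `FALSE`;
#'   reference CDS input must be unambiguous).
#' @return A named character vector of uppercase sequences, names are the
#'   FASTA ids (first whitespace-delimited token of each header).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, allow_n = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    if (nchar(seqs[[i]]) == 0L) {
      stop(sprintf("record '%s' is empty", ids[[i]]), call. = FALSE)
    }
    .check_alphabet(seqs[[i]], ids[[i]], allow_n = allow_n)
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' An involution over the alphabet `A,C,G,T,N`: `revcomp(revcomp(s))`
#' is `s`.
#'
#' @param seq DNA string (vectorized).
#' @return Reverse-complemented string(s).
#' @examples
#' revcomp("AAGG") # "CCTT"
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    .check_alphabet(s, allow_n = TRUE)
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a coding sequence with the standard genetic code
#'
#' Stops are rendered `*`. By default the full-length translation is
#' returned, embedded stops included; with `to_stop = TRUE` translation
#' ends at the first stop (which is not reported).
#'
#' @param cds DNA string, length divisible by 3.
#' @param to_stop Stop at the first stop codon.
#' @return Amino-acid string (one-letter codes).
#' @examples
#' translate_cds("ATGCAGTAA") # "MQ*"
#' translate_cds("ATGCAGTAA", to_stop = TRUE) # "MQ"
#' @export
translate_cds <- function(cds, to_stop = FALSE) {
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("CDS length (", n, ") not divisible by 3", call. = FALSE)
  }
  if (n == 0L) return("")
  .check_alphabet(cds, "<cds>")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(CODON_TABLE[codons])
  if (to_stop) {
    stop_at <- which(aa == "*")
    if (length(stop_at) > 0L) aa <- aa[seq_len(stop_at[1L] - 1L)]
  }
  paste(aa, collapse = "")
}

#' Map a 1-based residue index to its CDS codon interval
#'
#' @param res 1-based residue index (vectorized).
#' @param model Optional [gene_model]; when given, `res` is range-checked
#'   against the protein length.
#' @return Integer matrix with columns `start`, `end`: the 0-based
#'   half-open codon interval `[3(res-1), 3 res)`.
#' @examples
#' residue_to_cds(157) # [468, 471)
#' @export
residue_to_cds <- function(res, model = NULL) {
  res <- as.integer(res)
  if (any(res < 1L)) stop("residue index must be >= 1", call. = FALSE)
  if (!is.null(model) && any(res > nchar(model$protein))) {
    stop("residue index out of range (protein has ",
         nchar(model$protein), " residues)", call. = FALSE)
  }
  cbind(start = 3L * (res - 1L), end = 3L * res)
}

#' Build a validated gene model
#'
#' Either a spliced CDS is supplied directly, or a genomic sequence plus
#' exon intervals from which the CDS is extracted (plus-strand gene
#' assumed). All invariants are enforced at construction: exons sorted and
#' non-overlapping, CDS length divisible by 3, ATG start (demoted to a
#' warning under `permissive = TRUE`), no internal stop codon. A terminal
#' stop codon, when present, is kept in the CDS but excluded from the
#' protein and from residue numbering.
#'
#' @param cds Spliced coding sequence (optional if `genomic` + `exons`).
#' @param genomic Genomic sequence (optional).
#' @param exons Exon intervals: 2-column matrix/data.frame of 0-based
#'   half-open `[start,end)` intervals on `genomic`.
#' @param gene_id Identifier carried through reports.
#' @param permissive Demote the non-ATG-start error to a warning.
#' @return An object of class `gene_model` with elements `gene_id`,
#'   `genomic`, `exons`, `cds`, `protein`.
#' @examples
#' m <- build_gene_model(cds = "ATGCAGTAA", gene_id = "toy")
#' m$protein # "MQ"
#' @export
build_gene_model <- function(cds = NULL, genomic = NULL, exons = NULL,
                             gene_id = "gene", permissive = FALSE) {
  if (is.null(cds) && (is.null(genomic) || is.null(exons))) {
    stop("supply either `cds` or both `genomic` and `exons`", call. = FALSE)
  }
  if (!is.null(genomic)) {
    genomic <- toupper(genomic)
    .check_alphabet(genomic, "<genomic>")
  }
  if (!is.null(exons)) {
    exons <- as.matrix(exons)
    storage.mode(exons) <- "integer"
    colnames(exons) <- c("start", "end")
    if (is.null(genomic)) stop("exons given without genomic", call. = FALSE)
    if (any(exons[, 1] < 0L) || any(exons[, 2] > nchar(genomic)) ||
        any(exons[, 1] >= exons[, 2])) {
      stop("exon intervals out of bounds or empty", call. = FALSE)
    }
    if (is.unsorted(exons[, 1], strictly = TRUE) ||
        any(exons[-1, 1] < exons[-nrow(exons), 2])) {
      stop("exon intervals must be sorted and non-overlapping", call. = FALSE)
    }
    spliced <- paste(substring(genomic, exons[, 1] + 1L, exons[, 2]),
                     collapse = "")
    if (is.null(cds)) {
      cds <- spliced
    } else if (toupper(cds) != spliced) {
      stop("concatenated exon slices do not equal the supplied CDS",
           call. = FALSE)
    }
  }
  cds <- toupper(cds)
  .check_alphabet(cds, "<cds>")
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length not divisible by 3", call. = FALSE)
  }
  if (substr(cds, 1L, 3L) != "ATG") {
    msg <- "CDS does not begin with ATG"
    if (permissive) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  aa_full <- translate_cds(cds)
  protein <- sub("\\*$", "", aa_full)
  if (grepl("*", protein, fixed = TRUE)) {
    stop("CDS translation contains an internal stop codon", call. = FALSE)
  }
  structure(
    list(gene_id = gene_id, genomic = genomic, exons = exons,
         cds = cds, protein = protein),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", x$gene_id, "\n")
  cat("  CDS:", nchar(x$cds), "nt;  protein:", nchar(x$protein), "aa\n")
  if (!is.null(x$genomic)) {
    cat("  genomic:", nchar(x$genomic), "nt;  exons:", nrow(x$exons), "\n")
  }
  invisible(x)
}

#' Read exon intervals from GFF3 or a minimal TSV
#'
#' GFF3 input (via rtracklayer) uses rows of type `CDS`; TSV input has two
#' columns, start and end, 1-based inclusive. Both are converted to the
#' package-internal 0-based half-open convention.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or TSV file.
#' @return 2-column integer matrix of 0-based half-open intervals.
#' @export
read_exons <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("rtracklayer is required to read GFF3", call. = FALSE)
    }
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "CDS"]
    if (length(gr) == 0L) stop("no CDS features in ", path, call. = FALSE)
    m <- cbind(start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr))
  } else {
    tab <- read.delim(path, header = FALSE, comment.char = "#")
    m <- cbind(start = as.integer(tab[[1]]) - 1L,
               end = as.integer(tab[[2]]))
  }
  m[order(m[, 1]), , drop = FALSE]
}

#' Construct a residue-range domain table
#'
#' @param name Domain names.
#' @param start_res,end_res 1-based inclusive residue bounds.
#' @param model Optional [gene_model] for range validation.
#' @return `data.frame` of class `domain_table`.
#' @export
domain_table <- function(name, start_res, end_res, model = NULL) {
  start_res <- as.integer(start_res); end_res <- as.integer(end_res)
  if (any(start_res < 1L) || any(start_res > end_res)) {
    stop("require 1 <= start_res <= end_res", call. = FALSE)
  }
  if (!is.null(model) && any(end_res > nchar(model$protein))) {
    stop("domain extends beyond protein", call. = FALSE)
  }
  structure(
    data.frame(name = as.character(name), start_res = start_res,
               end_res = end_res, stringsAsFactors = FALSE),
    class = c("domain_table", "data.frame")
  )
}

# Map a 0-based plus-strand genomic coordinate into 0-based CDS space;
# NA_integer_ when the position falls outside every exon.
genomic_to_cds <- function(model, pos) {
  if (is.null(model$exons)) return(as.integer(pos))
  vapply(as.integer(pos), function(p) {
    off <- 0L
    for (k in seq_len(nrow(model$exons))) {
      s <- model$exons[k, 1]; e <- model$exons[k, 2]
      if (p >= s && p < e) return(off + (p - s))
      off <- off + (e - s)
    }
    NA_integer_
  }, integer(1))
}
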