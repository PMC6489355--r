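# Exhaustive PAM-adjacent protospacer enumeration on both strands.
#
# Coordinates: `start` is the 0-based plus-strand position of the
# protospacer 5' end (so for minus-strand guides it is the rightmost
# base of the plus-strand footprint); `cut_pos` is the 0-based plus-strand
# index such that the phosphodiester bond *after* that index is cleaved
# (SpCas9 blunt cut between protospacer positions 17|18, 3 nt from the
# PAM).

IUPAC_MATCH <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.pam_matches <- function(chars, at, pattern_chars) {
  # chars: region as character vector; at: 1-based start; TRUE if the
  # IUPAC pattern matches the slice.
  for (k in seq_along(pattern_chars)) {
    if (!(chars[at + k - 1L] %in% IUPAC_MATCH[[pattern_chars[k]]])) {
      return(FALSE)
    }
  }
  TRUE
}

#' Enumerate every PAM-adjacent protospacer on both strands
#'
#' All possible guides are reported: overlapping and nested hits included,
#' no GC-content, poly-T or efficiency filtering. A minus-strand hit is a
#' `CCN` (reverse-complement PAM) on the plus strand; its protospacer and
#' PAM are reported strand-oriented (5'->3' on the minus strand, PAM
#' printed as `NGG`). Output is sorted by `start` then `+` before `-`,
#' with deterministic ids `sg-001` onward.
#'
#' @param region A DNA string, a named length-1 character vector, or a
#'   [gene_model] (genomic sequence used when present, else the CDS).
#' @param guide_len Protospacer length (default 20, SpCas9).
#' @param pam PAM pattern in IUPAC code, default `"NGG"`.
#' @param model Optional [gene_model] used to annotate `cut_cds` (CDS-space
#'   cut coordinate), `cut_res` and `in_cds`. Implied when `region` is a
#'   gene_model.
#' @param require_5prime `"none"` (default), `"G"` or `"A"`: keep only
#'   guides whose strand-oriented protospacer starts with that base
#'   (pol III promoter preference; the platform default applies none).
#' @param include_noncds Keep guides whose cut falls outside exonic CDS
#'   when enumerating a genomic sequence (default `FALSE`).
#' @return `data.frame` with columns `guide_id`, `protospacer`, `pam`,
#'   `strand`, `start`, `cut_pos`, `cut_cds`, `cut_res`, `in_cds`.
#' @examples
#' enumerate_guides(strrep("AT", 25)) # no PAM possible -> 0 rows
#' @export
enumerate_guides <- function(region, guide_len = 20L, pam = "NGG",
                             model = NULL,
                             require_5prime = c("none", "G", "A"),
                             include_noncds = FALSE) {
  require_5prime <- match.arg(require_5prime)
  if (inherits(region, "gene_model")) {
    model <- region
    region <- if (!is.null(model$genomic)) model$genomic else model$cds
  }
  region <- toupper(as.character(region)[1])
  .check_alphabet(region, "<region>")
  guide_len <- as.integer(guide_len)
  pam_chars <- strsplit(toupper(pam), "", fixed = TRUE)[[1]]
  plen <- length(pam_chars)
  rc_pam_chars <- strsplit(revcomp(toupper(pam)), "", fixed = TRUE)[[1]]
  L <- nchar(region)

  empty <- data.frame(
    guide_id = character(0), protospacer = character(0), pam = character(0),
    strand = character(0), start = integer(0), cut_pos = integer(0),
    cut_cds = integer(0), cut_res = integer(0), in_cds = logical(0),
    stringsAsFactors = FALSE
  )
  if (L < guide_len + plen) {
    warning("region shorter than guide_len + PAM length; no guides",
            call. = FALSE)
    return(empty)
  }

  chars <- strsplit(region, "", fixed = TRUE)[[1]]
  rows <- list()
  # plus strand: PAM at 1-based q..q+plen-1, protospacer q-guide_len..q-1
  for (q in seq_len(L - plen + 1L)) {
    if (q > guide_len && .pam_matches(chars, q, pam_chars)) {
      start0 <- q - guide_len - 1L
      rows[[length(rows) + 1L]] <- list(
        protospacer = substr(region, q - guide_len, q - 1L),
        pam = substr(region, q, q + plen - 1L),
        strand = "+", start = start0,
        cut_pos = start0 + guide_len - 4L # bond after position 17 of 20
      )
    }
  }
  # minus strand: rc(PAM) at 1-based j..j+plen-1, protospacer plus-strand
  # slice j+plen .. j+plen+guide_len-1, reported strand-oriented
  for (j in seq_len(L - plen + 1L)) {
    if (j + plen + guide_len - 1L <= L && .pam_matches(chars, j, rc_pam_chars)) {
      proto_plus <- substr(region, j + plen, j + plen + guide_len - 1L)
      start0 <- j + plen + guide_len - 2L # 0-based rightmost base
      rows[[length(rows) + 1L]] <- list(
        protospacer = revcomp(proto_plus),
        pam = revcomp(substr(region, j, j + plen - 1L)),
        strand = "-", start = start0,
        cut_pos = start0 - (guide_len - 3L)
      )
    }
  }
  if (length(rows) == 0L) return(empty)

  g <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  g <- g[order(g$start, g$strand), , drop = FALSE]

  if (require_5prime != "none") {
    g <- g[substr(g$protospacer, 1L, 1L) == require_5prime, , drop = FALSE]
  }

  if (!is.null(model)) {
    g$cut_cds <- genomic_to_cds(model, g$cut_pos)
    g$in_cds <- !is.na(g$cut_cds)
    g$cut_res <- ifelse(g$in_cds, g$cut_cds %/% 3L + 1L, NA_integer_)
    if (!include_noncds && !is.null(model$genomic)) {
      g <- g[g$in_cds, , drop = FALSE]
    }
  } else {
    g$cut_cds <- NA_integer_
    g$cut_res <- NA_integer_
    g$in_cds <- NA
  }

  if (nrow(g) > 0L) {
    g$guide_id <- sprintf("sg-%03d", seq_len(nrow(g)))
  } else {
    g$guide_id <- character(0)
  }
  rownames(g) <- NULL
  g[, c("guide_id", "protospacer", "pam", "strand", "start", "cut_pos",
        "cut_cds", "cut_res", "in_cds")]
}

#' Plus-strand cut coordinate of a guide
#'
#' The bond after the returned 0-based index is the SpCas9 blunt cut,
#' 3 nt 5' of the PAM in strand orientation.
#'
#' @param guides One or more rows of an [enumerate_guides()] table.
#' @return Integer vector of 0-based plus-strand cut coordinates.
#' @export
cut_site <- function(guides) {
  guide_len <- nchar(guides$protospacer)
  ifelse(guides$strand == "+",
         guides$start + guide_len - 4L,
         guides$start - (guide_len - 3L))
}

#' Restrict a guide table to cuts within a residue range
#'
#' Retains guides whose CDS-space cut coordinate falls inside the codon
#' span of residues `start_res..end_res` (1-based inclusive), annotating
#' `cut_res` (residue whose codon contains the cut).
#'
#' @param guides Guide table from [enumerate_guides()].
#' @param model [gene_model] providing the residue frame.
#' @param start_res,end_res 1-based inclusive residue range.
#' @return Filtered guide table.
#' @export
filter_by_residue_range <- function(guides, model, start_res, end_res) {
  start_res <- as.integer(start_res); end_res <- as.integer(end_res)
  np <- nchar(model$protein)
  if (start_res < 1L || end_res > np || start_res > end_res) {
    stop("residue range out of bounds (protein has ", np, " residues)",
         call. = FALSE)
  }
  cut_cds <- guides$cut_cds
  if (all(is.na(cut_cds))) cut_cds <- guides$cut_pos # enumerated on CDS
  lo <- 3L * (start_res - 1L)
  hi <- 3L * end_res
  keep <- !is.na(cut_cds) & cut_cds >= lo & cut_cds < hi
  out <- guides[keep, , drop = FALSE]
  out$cut_cds <- cut_cds[keep]
  out$cut_res <- out$cut_cds %/% 3L + 1L
  rownames(out) <- NULL
  out
}

#' Write a guide library table to TSV
#'
#' Column layout mirrors a published sgRNA library sheet: id, protospacer,
#' PAM, strand, then 1-based coordinates. Output is bit-stable across runs.
#'
#' @param guides Guide table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_library_table <- function(guides, path) {
  tab <- data.frame(
    guide_id = guides$guide_id,
    protospacer = guides$protospacer,
    pam = guides$pam,
    strand = guides$strand,
    start_1based = guides$start + 1L,
    cut_pos_1based = guides$cut_pos + 1L,
    cut_res = guides$cut_res,
    in_cds = guides$in_cds,
    stringsAsFactors = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a guide library table written by [write_library_table()]
#'
#' @param path TSV path.
#' @return Guide table in internal (0-based) coordinates.
#' @export
read_library_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  data.frame(
    guide_id = tab$guide_id, protospacer = tab$protospacer, pam = tab$pam,
    strand = tab$strand, start = tab$start_1based - 1L,
    cut_pos = tab$cut_pos_1based - 1L,
    cut_cds = if ("cut_cds" %in% names(tab)) tab$cut_cds else NA_integer_,
    cut_res = tab$cut_res, in_cds = tab$in_cds,
    stringsAsFactors = FALSE
  )
}
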