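# Cloning-construct design: annealed oligo pairs with Golden-Gate (BsaI)
# overhangs and polycistronic tRNA-gRNA (PTG) assemblies.

BSAI_SITES <- c("GGTCTC", "GAGACC")

#' Design an annealed oligo pair for BsaI Golden-Gate cloning
#'
#' The forward oligo is the overhang fill `GGCA` followed by the
#' protospacer; the reverse oligo is `AAAC` followed by the reverse
#' complement of the protospacer. Annealing leaves 4-nt 5' single-stranded
#' ends complementary to a BsaI-digested acceptor (here the pRGEB32-style
#' sgRNA cassette).
#'
#' @param guides Guide table rows (or a character vector of protospacers).
#' @param overhang_fwd,overhang_rev 4-nt overhang fills; defaults `GGCA`
#'   and `AAAC`. Other acceptor vectors use other fills.
#' @param prepend_g Prepend a `G` to the protospacer for pol III
#'   transcription initiation (default off; the platform's oligos carry
#'   none).
#' @param guide_len Expected protospacer length.
#' @return `data.frame` with `guide_id`, `forward_oligo`, `reverse_oligo`.
#' @examples
#' design_cloning_oligos(data.frame(guide_id = "sg-001",
#'                                  protospacer = strrep("A", 20)))
#' @export
design_cloning_oligos <- function(guides, overhang_fwd = "GGCA",
                                  overhang_rev = "AAAC",
                                  prepend_g = FALSE, guide_len = 20L) {
  if (is.character(guides)) {
    guides <- data.frame(
      guide_id = sprintf("sg-%03d", seq_along(guides)),
      protospacer = guides, stringsAsFactors = FALSE
    )
  }
  proto <- toupper(guides$protospacer)
  bad <- nchar(proto) != guide_len
  if (any(bad)) {
    stop("protospacer length != ", guide_len, " for: ",
         paste(guides$guide_id[bad], collapse = ", "), call. = FALSE)
  }
  if (prepend_g) proto <- ifelse(substr(proto, 1, 1) == "G", proto,
                                 paste0("G", proto))
  data.frame(
    guide_id = guides$guide_id,
    forward_oligo = paste0(overhang_fwd, proto),
    reverse_oligo = paste0(overhang_rev, revcomp(proto)),
    stringsAsFactors = FALSE
  )
}

#' Assemble a polycistronic tRNA-gRNA (PTG) construct
#'
#' One tandem `tRNA + protospacer + scaffold` unit per guide, in input
#' order, optionally bracketed by flanking sequences. The tRNA and
#' scaffold are required inputs: the platform's own sequences are not
#' published, so none are hard-coded (a synthetic example pair ships in
#' `inst/extdata/`).
#'
#' @param guides Guide table rows in the desired unit order.
#' @param trna,scaffold Non-empty DNA strings.
#' @param flank5,flank3 Optional flanking sequences.
#' @param name Construct name.
#' @param allow_duplicates Permit repeated guide_ids (default `FALSE`).
#' @return List of class `ptg_construct`: `name`, `unit_order`, `trna`,
#'   `scaffold`, `sequence`.
#' @export
assemble_ptg <- function(guides, trna, scaffold, flank5 = "", flank3 = "",
                         name = "PTG", allow_duplicates = FALSE) {
  if (nrow(guides) < 1L) stop("empty guide list", call. = FALSE)
  if (nchar(trna) == 0L || nchar(scaffold) == 0L) {
    stop("tRNA and scaffold must be non-empty", call. = FALSE)
  }
  dup <- guides$guide_id[duplicated(guides$guide_id)]
  if (length(dup) > 0L && !allow_duplicates) {
    stop("duplicate guide_id(s) in PTG: ", paste(unique(dup), collapse = ", "),
         "; set allow_duplicates = TRUE to override", call. = FALSE)
  }
  trna <- toupper(trna); scaffold <- toupper(scaffold)
  units <- paste0(trna, toupper(guides$protospacer), scaffold)
  structure(
    list(name = name, unit_order = guides$guide_id, trna = trna,
         scaffold = scaffold,
         sequence = paste0(toupper(flank5), paste(units, collapse = ""),
                           toupper(flank3))),
    class = "ptg_construct"
  )
}

#' @export
print.ptg_construct <- function(x, ...) {
  cat("ptg_construct:", x$name, "(", length(x$unit_order), "units:",
      paste(x$unit_order, collapse = ", "), ")\n")
  cat("  length:", nchar(x$sequence), "nt\n")
  invisible(x)
}

#' Warn about internal BsaI sites in an assembled oligo duplex
#'
#' An internal `GGTCTC`/`GAGACC` in either oligo strand (including sites
#' spanning the overhang-protospacer junction) would be re-cut during
#' Golden-Gate assembly.
#'
#' @param protospacer Protospacer string.
#' @param overhang_fwd,overhang_rev Overhang fills used in the oligos.
#' @return Character vector of warnings; empty when clean.
#' @export
validate_bsai <- function(protospacer, overhang_fwd = "GGCA",
                          overhang_rev = "AAAC") {
  oligos <- c(
    forward = paste0(overhang_fwd, toupper(protospacer)),
    reverse = paste0(overhang_rev, revcomp(toupper(protospacer)))
  )
  out <- character(0)
  for (nm in names(oligos)) {
    for (site in BSAI_SITES) {
      if (grepl(site, oligos[[nm]], fixed = TRUE)) {
        out <- c(out, sprintf(
          "internal BsaI site %s in %s oligo (%s)", site, nm, oligos[[nm]]))
      }
    }
  }
  out
}

#' Write an oligo order sheet
#' @param oligos Output of [design_cloning_oligos()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_oligo_sheet <- function(oligos, path) {
  write.table(oligos, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
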