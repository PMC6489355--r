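# Protein-level consequence calling: frame classification, residue-level
# realignment of wild-type vs mutant protein, and decomposition of the
# diff into substitution / deletion / insertion / delins records with
# field-style one-letter labels (Q157del, K1049R, D223_G232del, fs).

#' Classify the reading-frame consequence of a variant set
#'
#' `frameshift` iff the net indel length across the allele is not
#' divisible by 3; `silent` when there are no variants, or when all
#' variants are substitutions that leave the protein unchanged (checkable
#' only when `model` is supplied); otherwise `in_frame`.
#'
#' @param variants Variant `data.frame` from one allele.
#' @param model Optional [gene_model], needed to detect synonymous
#'   substitutions.
#' @return One of `"silent"`, `"frameshift"`, `"in_frame"`.
#' @export
classify_frame <- function(variants, model = NULL) {
  if (nrow(variants) == 0L) return("silent")
  net <- sum(nchar(variants$alt_allele) - nchar(variants$ref_allele))
  if (net %% 3L != 0L) return("frameshift")
  if (all(variants$kind == "substitution") && !is.null(model)) {
    mut <- apply_variants(model$cds, variants)
    if (sub("\\*$", "", translate_cds(mut)) == model$protein) {
      return("silent")
    }
  }
  "in_frame"
}

.aa_label_del <- function(wt_chars, start_res, end_res) {
  if (start_res == end_res) {
    sprintf("%s%ddel", wt_chars[start_res], start_res)
  } else {
    sprintf("%s%d_%s%ddel", wt_chars[start_res], start_res,
            wt_chars[end_res], end_res)
  }
}

.aa_label_ins <- function(wt_chars, after_res, alt) {
  n <- length(wt_chars)
  left <- max(after_res, 1L)
  right <- min(after_res + 1L, n)
  sprintf("%s%d_%s%dins%s", wt_chars[left], left, wt_chars[right], right, alt)
}

.aa_label_delins <- function(wt_chars, start_res, end_res, alt) {
  if (start_res == end_res) {
    sprintf("%s%ddelins%s", wt_chars[start_res], start_res, alt)
  } else {
    sprintf("%s%d_%s%ddelins%s", wt_chars[start_res], start_res,
            wt_chars[end_res], end_res, alt)
  }
}

.change_row <- function(kind, start_res, end_res, ref_aa, alt_aa, label) {
  data.frame(kind = kind, start_res = start_res, end_res = end_res,
             ref_aa = ref_aa, alt_aa = alt_aa, label = label,
             stringsAsFactors = FALSE)
}

.empty_changes <- function() {
  .change_row(character(0), integer(0), integer(0), character(0),
              character(0), character(0))
}

# Decompose one mixed (delins) residue run into isolated substitutions
# plus one contiguous indel when such a decomposition preserves at least
# one residue; ties between equal-cost placements are broken toward the
# 3'-most indel. The indel keeps its in-run placement (no further
# 3'-shifting out of the run): this is what reports H1048Q + K1049del
# rather than splitting the edit around the downstream matching lysine.
.decompose_delins <- function(refrun, altrun, start0, wt_chars) {
  r <- strsplit(refrun, "", fixed = TRUE)[[1]]
  a <- strsplit(altrun, "", fixed = TRUE)[[1]]
  rl <- length(r); al <- length(a)
  stopifnot(rl != al, rl > 0L, al > 0L)
  if (rl > al) { # net deletion of d residues
    d <- rl - al
    best_k <- -1L; best_mis <- .Machine$integer.max
    for (k in 0:al) {
      kept <- r[setdiff(seq_len(rl), k + seq_len(d))]
      mis <- sum(kept != a)
      if (mis < best_mis || (mis == best_mis && k > best_k)) {
        best_mis <- mis; best_k <- k
      }
    }
    if (best_mis >= al && al > 1L) {
      # several replacement residues, none anchored: one delins record
      s <- start0 + 1L; e <- start0 + rl
      return(.change_row("delins", s, e, refrun, altrun,
                         .aa_label_delins(wt_chars, s, e, altrun)))
    }
    k <- best_k
    rows <- list()
    kept_idx <- setdiff(seq_len(rl), k + seq_len(d))
    for (t in seq_len(al)) {
      ri <- kept_idx[t]
      if (r[ri] != a[t]) {
        res <- start0 + ri
        rows[[length(rows) + 1L]] <- .change_row(
          "substitution", res, res, r[ri], a[t],
          sprintf("%s%d%s", r[ri], res, a[t]))
      }
    }
    s <- start0 + k + 1L; e <- start0 + k + d
    rows[[length(rows) + 1L]] <- .change_row(
      "deletion", s, e, paste(r[k + seq_len(d)], collapse = ""), "",
      .aa_label_del(wt_chars, s, e))
    do.call(rbind, rows)
  } else { # net insertion of d residues
    d <- al - rl
    best_k <- -1L; best_mis <- .Machine$integer.max
    for (k in 0:rl) {
      kept_alt <- a[setdiff(seq_len(al), k + seq_len(d))]
      mis <- sum(kept_alt != r)
      if (mis < best_mis || (mis == best_mis && k > best_k)) {
        best_mis <- mis; best_k <- k
      }
    }
    if (best_mis >= rl && rl > 1L) {
      s <- start0 + 1L; e <- start0 + rl
      return(.change_row("delins", s, e, refrun, altrun,
                         .aa_label_delins(wt_chars, s, e, altrun)))
    }
    k <- best_k
    ins <- paste(a[k + seq_len(d)], collapse = "")
    kept_idx <- setdiff(seq_len(al), k + seq_len(d))
    rows <- list()
    for (t in seq_len(rl)) {
      if (r[t] != a[kept_idx[t]]) {
        res <- start0 + t
        rows[[length(rows) + 1L]] <- .change_row(
          "substitution", res, res, r[t], a[kept_idx[t]],
          sprintf("%s%d%s", r[t], res, a[kept_idx[t]]))
      }
    }
    after_res <- start0 + k
    rows[[length(rows) + 1L]] <- .change_row(
      "insertion", max(after_res, 1L),
      min(after_res + 1L, length(wt_chars)), "", ins,
      .aa_label_ins(wt_chars, after_res, ins))
    do.call(rbind, rows)
  }
}

#' Protein-level consequence of a DNA variant set
#'
#' The mutant CDS is rebuilt from the (normalized) variants and
#' translated. In-frame alleles are diffed against the wild-type protein
#' by residue-level global alignment (same affine-gap aligner as the DNA
#' stage); isolated pure indel runs are 3'-normalized and mixed runs
#' decomposed into substitutions plus one contiguous indel. Frameshift
#' alleles report the first divergent residue with an `fs` label and the
#' downstream new-stop position as metadata only.
#'
#' @param model A [gene_model].
#' @param variants Normalized variant `data.frame` (one allele), e.g.
#'   from [genotype()].
#' @param allele_id Identifier carried into the report.
#' @return Object of class `consequence_report`: `allele_id`, `frame`,
#'   `changes` (ProteinChange `data.frame`), `domains_hit`,
#'   `knockout_candidate`, `fs_new_stop`.
#' @examples
#' m <- build_gene_model(cds = "ATGCATAAGAAGGGTTAA")
#' v <- genotype(m, "ATGCATAAGGGTTAA") # deletes one AAG from the K-K run
#' protein_consequence(m, v)$changes$label # "K3del" (3'-most lysine)
#' @export
protein_consequence <- function(model, variants, allele_id = "allele") {
  wt <- model$protein
  wt_chars <- strsplit(wt, "", fixed = TRUE)[[1]]
  rep0 <- structure(
    list(allele_id = allele_id, frame = "silent", changes = .empty_changes(),
         domains_hit = character(0), knockout_candidate = FALSE,
         fs_new_stop = NA_integer_),
    class = "consequence_report"
  )
  if (nrow(variants) == 0L) return(rep0)
  if (any(variants$cds_start + nchar(variants$ref_allele) > nchar(model$cds) |
          variants$cds_start < 0L)) {
    stop("variant outside CDS", call. = FALSE)
  }

  mut_cds <- apply_variants(model$cds, variants)
  net <- nchar(mut_cds) - nchar(model$cds)

  if (net %% 3L != 0L) { # frameshift
    ncod <- nchar(mut_cds) %/% 3L
    mut_aa <- if (ncod > 0L) {
      strsplit(translate_cds(substr(mut_cds, 1L, 3L * ncod)), "",
               fixed = TRUE)[[1]]
    } else character(0)
    nmin <- min(length(wt_chars), length(mut_aa))
    diffpos <- which(wt_chars[seq_len(nmin)] != mut_aa[seq_len(nmin)])
    r <- if (length(diffpos) > 0L) diffpos[1L] else min(nmin + 1L,
                                                        length(wt_chars))
    new_stop <- {
      st <- which(mut_aa == "*")
      st <- st[st >= r]
      if (length(st) > 0L) st[1L] else NA_integer_
    }
    rep0$frame <- "frameshift"
    rep0$changes <- .change_row("frameshift", r, r, wt_chars[r], "",
                                sprintf("%s%dfs", wt_chars[r], r))
    rep0$knockout_candidate <- TRUE
    rep0$fs_new_stop <- new_stop
    return(rep0)
  }

  mut_prot <- sub("\\*$", "", translate_cds(mut_cds))
  if (mut_prot == wt) {
    rep0$frame <- "silent"
    return(rep0)
  }

  aln <- align_global(wt, mut_prot)
  runs <- call_dna_variants(aln)            # residue-space runs
  runs <- normalize_3prime(runs, wt)        # 3'-shift isolated pure indels

  rows <- list()
  for (k in seq_len(nrow(runs))) {
    kind <- runs$kind[k]; s0 <- runs$cds_start[k]
    ra <- runs$ref_allele[k]; aa <- runs$alt_allele[k]
    if (kind == "substitution") {
      rchars <- strsplit(ra, "", fixed = TRUE)[[1]]
      achars <- strsplit(aa, "", fixed = TRUE)[[1]]
      for (t in seq_along(rchars)) {
        res <- s0 + t
        rows[[length(rows) + 1L]] <- .change_row(
          "substitution", res, res, rchars[t], achars[t],
          sprintf("%s%d%s", rchars[t], res, achars[t]))
      }
    } else if (kind == "deletion") {
      s <- s0 + 1L; e <- s0 + nchar(ra)
      rows[[length(rows) + 1L]] <- .change_row(
        "deletion", s, e, ra, "", .aa_label_del(wt_chars, s, e))
    } else if (kind == "insertion") {
      rows[[length(rows) + 1L]] <- .change_row(
        "insertion", max(s0, 1L), min(s0 + 1L, length(wt_chars)), "", aa,
        .aa_label_ins(wt_chars, s0, aa))
    } else {
      rows[[length(rows) + 1L]] <- .decompose_delins(ra, aa, s0, wt_chars)
    }
  }
  changes <- do.call(rbind, rows)
  changes <- changes[order(changes$start_res, changes$end_res), ,
                     drop = FALSE]
  rownames(changes) <- NULL

  rep0$frame <- "in_frame"
  rep0$changes <- changes
  rep0$knockout_candidate <- any(grepl("*", changes$alt_aa, fixed = TRUE))
  rep0
}

#' @export
print.consequence_report <- function(x, ...) {
  cat("consequence_report:", x$allele_id, "-", x$frame,
      if (x$knockout_candidate) "(knockout candidate)" else "", "\n")
  if (nrow(x$changes) > 0L) {
    cat(" ", paste(x$changes$label, collapse = ", "), "\n")
  }
  if (length(x$domains_hit) > 0L) {
    cat("  domains:", paste(x$domains_hit, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Annotate a consequence report with affected protein domains
#'
#' A domain is hit when any reported change interval intersects its
#' residue range. A frameshift affects everything downstream, so every
#' domain ending at or after the first divergent residue is flagged.
#'
#' @param report A [protein_consequence()] report.
#' @param table A [domain_table()].
#' @return The report with `domains_hit` filled in.
#' @export
annotate_domains <- function(report, table) {
  if (nrow(table) == 0L || nrow(report$changes) == 0L) {
    report$domains_hit <- character(0)
    return(report)
  }
  if (report$frame == "frameshift") {
    r <- report$changes$start_res[1L]
    report$domains_hit <- table$name[table$end_res >= r]
    return(report)
  }
  hit <- vapply(seq_len(nrow(table)), function(k) {
    any(report$changes$start_res <= table$end_res[k] &
          report$changes$end_res >= table$start_res[k])
  }, logical(1))
  report$domains_hit <- table$name[hit]
  report
}

#' Write consequence reports as TSV and JSON
#'
#' @param reports List of [protein_consequence()] reports.
#' @param tsv,json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the summary `data.frame`.
#' @export
write_consequence_report <- function(reports, tsv = NULL, json = NULL) {
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(
      allele_id = r$allele_id, frame = r$frame,
      changes = paste(r$changes$label, collapse = ";"),
      domains_hit = paste(r$domains_hit, collapse = ";"),
      knockout_candidate = r$knockout_candidate,
      stringsAsFactors = FALSE
    )
  }))
  if (!is.null(tsv)) {
    write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    payload <- lapply(reports, function(r) {
      list(allele_id = r$allele_id, frame = r$frame, changes = r$changes,
           domains_hit = r$domains_hit,
           knockout_candidate = r$knockout_candidate)
    })
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(tab)
}
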