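# Synthetic-fixture generator: Cas9 cut-and-NHEJ repair outcomes at guide
# cut sites with a recorded ground truth, so genotyping and consequence
# calling can be tested without external data. The size laws are invented
# defaults (the platform's repair spectrum is not published): truncated
# geometric sizes, deletion probability 0.7, cap 30 nt.

#' Repair-outcome simulation parameters
#'
#' @param p_deletion Probability an event is a deletion (else insertion).
#' @param deletion_size_geometric_p,insertion_size_geometric_p Success
#'   parameter of the geometric size law (support >= 1).
#' @param min_event,max_event Truncation bounds on event size; setting
#'   them equal forces a degenerate (fixed-size) law.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return List of class `repair_params`.
#' @export
repair_params <- function(p_deletion = 0.7,
                          deletion_size_geometric_p = 0.3,
                          insertion_size_geometric_p = 0.3,
                          min_event = 1L, max_event = 30L, seed = 42L) {
  stopifnot(p_deletion >= 0, p_deletion <= 1,
            deletion_size_geometric_p > 0, deletion_size_geometric_p <= 1,
            insertion_size_geometric_p > 0, insertion_size_geometric_p <= 1,
            min_event >= 1L, max_event >= min_event)
  structure(
    list(p_deletion = p_deletion,
         deletion_size_geometric_p = deletion_size_geometric_p,
         insertion_size_geometric_p = insertion_size_geometric_p,
         min_event = as.integer(min_event),
         max_event = as.integer(max_event), seed = as.integer(seed)),
    class = "repair_params"
  )
}

# geometric on {1,2,...} truncated to [lo, hi], by rejection
.rgeom_trunc <- function(p, lo, hi) {
  repeat {
    s <- rgeom(1L, p) + 1L
    if (s >= lo && s <= hi) return(s)
  }
}

.empty_sim <- function() {
  structure(
    list(alleles = data.frame(allele_id = character(0),
                              guide_id = character(0),
                              sequence = character(0),
                              truth_frame = character(0),
                              stringsAsFactors = FALSE),
         truth = cbind(allele_id = character(0), .empty_variants())),
    class = "simulated_alleles"
  )
}

#' Simulate NHEJ repair alleles at a guide cut site
#'
#' Each allele carries one event: a deletion with probability
#' `p_deletion`, otherwise an insertion, placed at the blunt cut. Deletion
#' intervals span the cut bond with the left extent drawn uniformly;
#' insertion bases are uniform random. Sizes follow the truncated
#' geometric laws. Fully reproducible from `params$seed`.
#'
#' @param model A [gene_model].
#' @param guide One row of a guide table (its CDS-space cut coordinate is
#'   used), or directly an integer 0-based CDS cut coordinate.
#' @param params A [repair_params()].
#' @param n Number of alleles.
#' @return Object of class `simulated_alleles`: `$alleles` (allele_id,
#'   guide_id, sequence, truth_frame) and `$truth` (DNA variant rows keyed
#'   by allele_id).
#' @export
simulate_repair <- function(model, guide, params = repair_params(), n) {
  n <- as.integer(n)
  stopifnot(n >= 0L)
  if (n == 0L) return(.empty_sim())
  if (is.numeric(guide)) {
    cut <- as.integer(guide); gid <- "manual"
  } else {
    cut <- if (!is.na(guide$cut_cds[1])) guide$cut_cds[1] else guide$cut_pos[1]
    gid <- guide$guide_id[1]
  }
  cds <- model$cds
  L <- nchar(cds)
  if (cut < 0L || cut >= L - 1L) stop("cut site outside sequence", call. = FALSE)

  set.seed(params$seed)
  alleles <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    rejections <- 0L
    repeat {
      is_del <- runif(1L) < params$p_deletion
      if (is_del) {
        size <- .rgeom_trunc(params$deletion_size_geometric_p,
                             params$min_event, params$max_event)
        left <- sample.int(size + 1L, 1L) - 1L # bases removed left of bond
        start <- cut + 1L - left               # 0-based deletion start
        if (start >= 0L && start + size <= L) {
          v <- data.frame(kind = "deletion", cds_start = start,
                          ref_allele = substr(cds, start + 1L, start + size),
                          alt_allele = "", normalized = FALSE,
                          stringsAsFactors = FALSE)
          break
        }
      } else {
        size <- .rgeom_trunc(params$insertion_size_geometric_p,
                             params$min_event, params$max_event)
        ins <- paste(sample(DNA_ALPHABET, size, replace = TRUE),
                     collapse = "")
        v <- data.frame(kind = "insertion", cds_start = cut + 1L,
                        ref_allele = "", alt_allele = ins,
                        normalized = FALSE, stringsAsFactors = FALSE)
        break
      }
      rejections <- rejections + 1L
      if (rejections == 100L) {
        warning("100 rejected placements at cut ", cut,
                "; sequence end too close for requested sizes",
                call. = FALSE)
      }
    }
    aid <- sprintf("sim-%04d", i)
    truths[[i]] <- cbind(allele_id = aid, v)
    alleles[[i]] <- data.frame(
      allele_id = aid, guide_id = gid,
      sequence = apply_variants(cds, v),
      truth_frame = classify_frame(v),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(alleles = do.call(rbind, alleles), truth = do.call(rbind, truths)),
    class = "simulated_alleles"
  )
}

#' Simulate dual-guide (PTG) repair outcomes
#'
#' With probability `p_excise` the fragment between the two cut bonds is
#' excised as one deletion; otherwise two independent single-cut events
#' are composed (one at each cut).
#'
#' @param model A [gene_model].
#' @param guide1,guide2 Guide rows or 0-based CDS cut coordinates (cut1 <
#'   cut2 after ordering).
#' @param params A [repair_params()].
#' @param n Number of alleles.
#' @param p_excise Probability of fragment excision.
#' @return `simulated_alleles` object.
#' @export
simulate_ptg_repair <- function(model, guide1, guide2,
                                params = repair_params(), n,
                                p_excise = 0.5) {
  getcut <- function(g) {
    if (is.numeric(g)) as.integer(g)
    else if (!is.na(g$cut_cds[1])) g$cut_cds[1] else g$cut_pos[1]
  }
  cuts <- sort(c(getcut(guide1), getcut(guide2)))
  cds <- model$cds
  set.seed(params$seed)
  # Pre-draw per-allele seeds so single-cut simulations stay independent.
  sub_seeds <- sample.int(.Machine$integer.max, 2L * n)
  excise <- runif(n) < p_excise
  alleles <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    if (excise[i]) {
      start <- cuts[1] + 1L
      size <- cuts[2] - cuts[1]
      v <- data.frame(kind = "deletion", cds_start = start,
                      ref_allele = substr(cds, start + 1L, start + size),
                      alt_allele = "", normalized = FALSE,
                      stringsAsFactors = FALSE)
    } else {
      p1 <- params; p1$seed <- sub_seeds[2L * i - 1L]
      p2 <- params; p2$seed <- sub_seeds[2L * i]
      v1 <- simulate_repair(model, cuts[1], p1, 1L)$truth
      v2 <- simulate_repair(model, cuts[2], p2, 1L)$truth
      v <- rbind(v1[, -1], v2[, -1])
      v <- v[order(v$cds_start), , drop = FALSE]
      # overlapping edits cannot be applied as independent variants;
      # collapse to the excision representation instead
      if (nrow(v) == 2L &&
          v$cds_start[1] + nchar(v$ref_allele[1]) > v$cds_start[2]) {
        e <- max(v$cds_start[1] + nchar(v$ref_allele[1]),
                 v$cds_start[2] + nchar(v$ref_allele[2]))
        s <- v$cds_start[1]
        v <- data.frame(kind = "deletion", cds_start = s,
                        ref_allele = substr(cds, s + 1L, e),
                        alt_allele = paste0(v$alt_allele, collapse = ""),
                        normalized = FALSE, stringsAsFactors = FALSE)
        v$kind <- .variant_kind(v$ref_allele, v$alt_allele)
      }
    }
    aid <- sprintf("ptg-%04d", i)
    truths[[i]] <- cbind(allele_id = aid, v)
    alleles[[i]] <- data.frame(
      allele_id = aid, guide_id = "ptg",
      sequence = apply_variants(cds, v),
      truth_frame = classify_frame(v),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(alleles = do.call(rbind, alleles), truth = do.call(rbind, truths)),
    class = "simulated_alleles"
  )
}

#' Keep only in-frame simulated alleles
#'
#' Models the survivability filter an essential gene imposes: alleles
#' whose net indel length is not divisible by 3 (frameshifts) are never
#' recovered.
#'
#' @param sim A `simulated_alleles` object.
#' @return Filtered `simulated_alleles`.
#' @export
in_frame_filter <- function(sim) {
  keep <- sim$alleles$truth_frame == "in_frame"
  ids <- sim$alleles$allele_id[keep]
  structure(
    list(alleles = sim$alleles[keep, , drop = FALSE],
         truth = sim$truth[sim$truth$allele_id %in% ids, , drop = FALSE]),
    class = "simulated_alleles"
  )
}

#' @export
print.simulated_alleles <- function(x, ...) {
  cat("simulated_alleles:", nrow(x$alleles), "alleles (",
      sum(x$alleles$truth_frame == "in_frame"), "in-frame )\n")
  invisible(x)
}
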