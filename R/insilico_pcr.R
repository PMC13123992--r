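# Mismatch-tolerant in-silico PCR of degenerate primer pairs.

# One-strand scan: forward primer sites and reverse-complemented reverse
# primer sites with <= max_mismatch set-mismatches; legal pairings are
# forward site then non-overlapping downstream reverse site with total span
# <= max_amplicon. Per forward site only the shortest legal amplicon is kept,
# then any hit strictly nested inside another kept hit is suppressed
# (dominant short-product convention).
scan_strand <- function(pair, seq_masks, max_mismatch, max_amplicon) {
  fwd <- iupac_masks(pair$forward)
  rev_rc <- iupac_masks(reverse_complement_iupac(pair$reverse))
  lf <- length(fwd)
  lr <- length(rev_rc)

  fmm <- slide_mismatches(fwd, seq_masks)
  rmm <- slide_mismatches(rev_rc, seq_masks)
  f_pos <- which(fmm <= max_mismatch)   # 1-based window starts
  r_pos <- which(rmm <= max_mismatch)
  if (length(f_pos) == 0L || length(r_pos) == 0L) {
    return(empty_hits())
  }

  hits <- vector("list", length(f_pos))
  n_kept <- 0L
  for (fs in f_pos) {
    # reverse window must start at/after the forward footprint ends and the
    # full product fs .. rs+lr-1 must stay within max_amplicon
    ok <- r_pos[r_pos >= fs + lf & (r_pos + lr - fs) <= max_amplicon]
    if (length(ok) == 0L) next
    rs <- ok[1L]  # nearest downstream site = shortest product
    n_kept <- n_kept + 1L
    hits[[n_kept]] <- c(start = fs, end = rs + lr,
                        fwd_mm = fmm[fs], rev_mm = rmm[rs])
  }
  if (n_kept == 0L) return(empty_hits())
  h <- as.data.frame(do.call(rbind, hits[seq_len(n_kept)]))

  # suppress hits strictly nested inside any other candidate (the outermost
  # containing hit is itself never nested, so this is order-independent)
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    for (j in seq_len(nrow(h))) {
      if (i == j) next
      nested <- h$start[j] <= h$start[i] && h$end[i] <= h$end[j] &&
        (h$start[j] < h$start[i] || h$end[i] < h$end[j])
      if (nested) keep[i] <- FALSE
    }
  }
  h[keep, , drop = FALSE]
}

empty_hits <- function() {
  data.frame(start = integer(0), end = integer(0),
             fwd_mm = integer(0), rev_mm = integer(0))
}

#' Find in-silico PCR products of a primer pair in one reference sequence
#'
#' Scans the plus strand for forward-primer binding sites within
#' `max_mismatch` IUPAC-set mismatches and, downstream of each, for sites
#' matching the reverse complement of the reverse primer, keeping products
#' whose total span does not exceed `max_amplicon`; the scan is repeated with
#' the primer roles swapped on the minus strand. Per forward site the
#' shortest legal product is reported and products strictly nested inside a
#' reported one are suppressed. Coordinates are 0-based half-open on the plus
#' strand; `amplicon_seq` is the product 5'-3' beginning with the
#' forward-primer footprint (so for minus-strand hits it is the reverse
#' complement of the plus-strand slice).
#'
#' @param pair A [primer_pair()].
#' @param record Reference sequence (character scalar, IUPAC tolerated).
#' @param max_mismatch Per-primer mismatch tolerance (default 2).
#' @param max_amplicon Maximum product span in bases; defaults to twice the
#'   pair's expected amplicon (or 2000 when that is unknown).
#' @param record_id Optional id copied into the result.
#' @return Data frame with columns `record_id`, `strand` ("+"/"-"), `start`,
#'   `end` (0-based half-open), `fwd_mm`, `rev_mm`, `amplicon_seq`, sorted by
#'   (start, end); zero rows when nothing amplifies.
#' @export
find_amplicons <- function(pair, record, max_mismatch = 2L,
                           max_amplicon = NULL, record_id = NA_character_) {
  stopifnot(inherits(pair, "primer_pair"), max_mismatch >= 0L)
  if (is.null(max_amplicon)) {
    max_amplicon <- if (!is.na(pair$expected_amplicon)) {
      2L * pair$expected_amplicon
    } else 2000L
  }
  min_span <- nchar(pair$forward) + nchar(pair$reverse)
  if (max_amplicon <= min_span) {
    stop("max_amplicon must exceed the combined primer length (", min_span, ")")
  }
  record <- toupper(record)
  L <- nchar(record)
  seq_masks <- iupac_masks(record)

  plus <- scan_strand(pair, seq_masks, max_mismatch, max_amplicon)
  minus <- scan_strand(pair, rev(comp_mask(seq_masks)), max_mismatch,
                       max_amplicon)

  out <- rbind(
    if (nrow(plus)) data.frame(strand = "+", plus),
    if (nrow(minus)) data.frame(
      strand = "-",
      start = L - minus$end, end = L - minus$start,
      fwd_mm = minus$fwd_mm, rev_mm = minus$rev_mm)
  )
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(record_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      fwd_mm = integer(0), rev_mm = integer(0),
                      amplicon_seq = character(0)))
  }
  # convert 1-based window starts to 0-based half-open plus-strand coords
  is_plus <- out$strand == "+"
  out$start[is_plus] <- out$start[is_plus] - 1L
  out$end[is_plus] <- out$end[is_plus] - 1L
  # minus-strand entries were computed from 1-based coords on the rc:
  # rc-window [s, e) (1-based s, exclusive e) maps to plus [L - e + 1, L - s + 1)
  out$start[!is_plus] <- out$start[!is_plus] + 1L
  out$end[!is_plus] <- out$end[!is_plus] + 1L

  seqs <- substring(record, out$start + 1L, out$end)
  seqs[!is_plus] <- vapply(seqs[!is_plus], reverse_complement_iupac,
                           character(1), USE.NAMES = FALSE)
  out <- data.frame(record_id = record_id, strand = out$strand,
                    start = as.integer(out$start), end = as.integer(out$end),
                    fwd_mm = as.integer(out$fwd_mm),
                    rev_mm = as.integer(out$rev_mm),
                    amplicon_seq = seqs)
  out[order(out$start, out$end), , drop = FALSE]
}

# complement of a 4-bit base mask: swap A<->T (1<->8) and C<->G (2<->4)
comp_mask <- function(m) {
  bitwOr(bitwOr(ifelse(bitwAnd(m, 1L) != 0L, 8L, 0L),
                ifelse(bitwAnd(m, 8L) != 0L, 1L, 0L)),
         bitwOr(ifelse(bitwAnd(m, 2L) != 0L, 4L, 0L),
                ifelse(bitwAnd(m, 4L) != 0L, 2L, 0L)))
}

#' Run in-silico PCR over a reference set and summarize specificity
#'
#' Applies [find_amplicons()] for every (primer pair, reference record)
#' combination and aggregates per-taxon amplification: one amplification-table
#' row per pair x record with at least one hit (the best hit by total
#' mismatches, ties broken by position), plus a specificity report counting
#' amplified species by family and class and the percentage of amplified
#' species belonging to the target family.
#'
#' @param pairs List of [primer_pair()] objects (default the shipped
#'   waterfowl ND2 pairs).
#' @param references Named character vector of sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param lineage Data frame with columns `record_id`, `species`, `genus`,
#'   `family`, `tribe`, `class` (one row per record).
#' @param max_mismatch Per-primer mismatch tolerance (default 2).
#' @param target_family Family counted as target (default "Anatidae").
#' @return List with elements `amplification` (data frame: `pair`,
#'   `record_id`, `species`, `family`, `class`, `strand`, `start`, `end`,
#'   `fwd_mm`, `rev_mm`, `amplicon_len`, `n_hits`), `by_family`, `by_class`
#'   (amplified record/species counts) and `specificity` (list with
#'   `target_species_amplified`, `nontarget_species_amplified`,
#'   `pct_target`).
#' @export
run_insilico_pcr <- function(pairs = default_primer_pairs(), references,
                             lineage, max_mismatch = 2L,
                             target_family = "Anatidae") {
  if (inherits(references, "DNAStringSet")) {
    references <- as.character(references)
  }
  stopifnot(is.character(references))
  if (length(references) > 0 && is.null(names(references))) {
    stop("references must be named by record id")
  }

  rows <- list()
  for (pair in pairs) {
    for (rid in names(references)) {
      hits <- find_amplicons(pair, references[[rid]],
                             max_mismatch = max_mismatch, record_id = rid)
      if (nrow(hits) == 0L) next
      best <- hits[order(hits$fwd_mm + hits$rev_mm, hits$start), ][1L, ]
      lin <- lineage[match(rid, lineage$record_id), ]
      if (is.na(lin$record_id[1L])) {
        warning("record '", rid, "' missing from lineage table; ",
                "counted as unclassified", call. = FALSE)
        lin <- data.frame(species = paste0("unclassified:", rid),
                          family = "unclassified", class = "unclassified")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pair = pair$name, record_id = rid,
        species = lin$species, family = lin$family, class = lin$class,
        strand = best$strand, start = best$start, end = best$end,
        fwd_mm = best$fwd_mm, rev_mm = best$rev_mm,
        amplicon_len = best$end - best$start, n_hits = nrow(hits))
    }
  }

  amp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair = character(0), record_id = character(0),
               species = character(0), family = character(0),
               class = character(0), strand = character(0),
               start = integer(0), end = integer(0), fwd_mm = integer(0),
               rev_mm = integer(0), amplicon_len = integer(0),
               n_hits = integer(0))

  sp_fam <- unique(amp[, c("species", "family", "class")])
  by_family <- as.data.frame(table(family = sp_fam$family),
                             responseName = "species_amplified")
  by_class <- as.data.frame(table(class = sp_fam$class),
                            responseName = "species_amplified")
  n_target <- sum(sp_fam$family == target_family)
  n_nontarget <- nrow(sp_fam) - n_target
  pct_target <- if (nrow(sp_fam) > 0L) 100 * n_target / nrow(sp_fam) else NA_real_

  list(amplification = amp, by_family = by_family, by_class = by_class,
       specificity = list(target_family = target_family,
                          target_species_amplified = n_target,
                          nontarget_species_amplified = n_nontarget,
                          pct_target = pct_target))
}
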