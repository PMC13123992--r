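# ASV table processing: taxonomic assignment from BLAST-style hit tables,
# negative-control filtering, depth standardization, aggregation to a
# date x taxon community matrix.

#' Construct an ASV table
#'
#' Pairs an ASV x sample count matrix with its sample metadata and validates
#' the contract between them.
#'
#' @param counts Non-negative ASV x sample matrix (rownames = ASV ids,
#'   colnames = sample ids).
#' @param meta Data frame with columns `sample_id`, `date`, `sample_type`
#'   (one of field, field_blank, filtration_blank, extraction_blank,
#'   pcr_blank), `replicate`.
#' @return An `asv_table` list with elements `counts` and `meta`.
#' @export
asv_table <- function(counts, meta) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  ok_types <- c("field", "field_blank", "filtration_blank",
                "extraction_blank", "pcr_blank")
  if (!all(meta$sample_type %in% ok_types)) {
    stop("unknown sample_type(s): ",
         paste(setdiff(unique(meta$sample_type), ok_types), collapse = ", "))
  }
  missing <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing) > 0) {
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  }
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  rownames(meta) <- NULL
  meta$date <- as.Date(meta$date)
  structure(list(counts = counts, meta = meta), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("<asv_table> %d ASVs x %d samples (%d field, %d control)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$meta$sample_type == "field"),
              sum(x$meta$sample_type != "field")))
  invisible(x)
}

field_cols <- function(tab) which(tab$meta$sample_type == "field")

#' Assign taxonomy to ASVs from a BLAST-style hit table
#'
#' Per ASV, hits are ranked by (score desc, identity desc) and truncated to
#' the top five; let B be the hits attaining the maximum percent identity
#' among those. A single species in B at identity >= 98% is assigned at
#' species rank. Multiple tied species resolve to their lowest common rank:
#' one genus gives genus, one family gives family, otherwise the ASV is
#' excluded. Below 98% the assignment falls back to the lowest common rank
#' among B (genus or family, never species). ASVs with no hits are excluded
#' with basis `no_hits`.
#'
#' @param hits Data frame with columns `asv_id`, `subject_species`,
#'   `subject_genus`, `subject_family`, `pct_identity`, `score`.
#' @param identity_threshold Species-level identity threshold (default 98).
#' @param asv_ids Optional full set of ASV ids, so ASVs absent from the hit
#'   table receive a `no_hits` exclusion row.
#' @return Data frame with one row per ASV: `asv_id`, `rank` (species /
#'   genus / family / excluded), `name`, `best_identity`, `basis`.
#' @export
assign_taxonomy <- function(hits, identity_threshold = 98,
                            asv_ids = NULL) {
  if (nrow(hits) > 0) {
    if (!is.numeric(hits$pct_identity) || anyNA(hits$pct_identity) ||
        any(hits$pct_identity < 0 | hits$pct_identity > 100)) {
      stop("pct_identity must be numeric in [0, 100]")
    }
  }
  all_ids <- unique(c(as.character(hits$asv_id), asv_ids))

  one <- function(id) {
    h <- hits[hits$asv_id == id, , drop = FALSE]
    if (nrow(h) == 0L) {
      return(data.frame(asv_id = id, rank = "excluded", name = NA_character_,
                        best_identity = NA_real_, basis = "no_hits"))
    }
    h <- h[order(-h$score, -h$pct_identity), , drop = FALSE]
    h <- utils::head(h, 5L)
    best_id <- max(h$pct_identity)
    B <- h[h$pct_identity == best_id, , drop = FALSE]
    species <- unique(B$subject_species)
    genera <- unique(B$subject_genus)
    families <- unique(B$subject_family)

    if (best_id >= identity_threshold && length(species) == 1L) {
      return(data.frame(asv_id = id, rank = "species", name = species,
                        best_identity = best_id,
                        basis = "single_species_ge98"))
    }
    sub98 <- best_id < identity_threshold
    if (length(genera) == 1L) {
      return(data.frame(asv_id = id, rank = "genus", name = genera,
                        best_identity = best_id,
                        basis = if (sub98) "sub98_lca_genus" else
                          "tie_lca_genus"))
    }
    if (length(families) == 1L) {
      return(data.frame(asv_id = id, rank = "family", name = families,
                        best_identity = best_id,
                        basis = if (sub98) "sub98_lca_family" else
                          "tie_lca_family"))
    }
    data.frame(asv_id = id, rank = "excluded", name = NA_character_,
               best_identity = best_id, basis = "below_family_excluded")
  }
  out <- do.call(rbind, lapply(all_ids, one))
  rownames(out) <- NULL
  out
}

#' Negative-control based filtering threshold
#'
#' Default (`per_asv`) mode: for each ASV, sum its reads across all
#' extraction-blank and PCR-blank samples; the threshold is the mean of the
#' non-zero sums (0 when all sums are zero). The alternative `per_control`
#' mode averages the non-zero per-control column totals instead; the
#' filtering sentence this implements is ambiguous between the two readings.
#' Field and filtration blanks never enter the computation.
#'
#' @param table An [asv_table()].
#' @param mode `"per_asv"` (default) or `"per_control"`.
#' @return Scalar threshold in reads.
#' @export
control_filter_threshold <- function(table, mode = c("per_asv",
                                                     "per_control")) {
  mode <- match.arg(mode)
  ctrl <- which(table$meta$sample_type %in% c("extraction_blank",
                                              "pcr_blank"))
  if (length(ctrl) == 0L) {
    stop("no extraction or PCR negative-control samples present; ",
         "the control filter cannot be computed")
  }
  if (mode == "per_asv") {
    s <- rowSums(table$counts[, ctrl, drop = FALSE])
  } else {
    s <- colSums(table$counts[, ctrl, drop = FALSE])
  }
  s <- s[s > 0]
  if (length(s) == 0L) 0 else mean(s)
}

#' Remove low-count ASVs using a control-derived threshold
#'
#' Removes whole ASV rows whose total read count across field samples is
#' strictly below the threshold ("fewer than" is strict: an ASV exactly at
#' the threshold is retained). Blank columns are carried through untouched
#' for QC reporting.
#'
#' @param table An [asv_table()].
#' @param threshold Reads (>= 0), typically from
#'   [control_filter_threshold()].
#' @return Filtered [asv_table()] with attributes `n_removed` and
#'   `removed_asvs`.
#' @export
apply_control_filter <- function(table, threshold) {
  stopifnot(threshold >= 0)
  totals <- rowSums(table$counts[, field_cols(table), drop = FALSE])
  keep <- totals >= threshold
  out <- asv_table(table$counts[keep, , drop = FALSE], table$meta)
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "removed_asvs") <- rownames(table$counts)[!keep]
  if (sum(!keep) > 0) {
    message(sum(!keep), " ASV(s) removed at threshold ",
            format(threshold, digits = 4))
  }
  out
}

#' Standardize field samples to the minimum sequencing depth
#'
#' Proportionally rescales each field sample to the minimum field-sample
#' depth: every count in sample `j` (depth `D_j`) is multiplied by
#' `D_min / D_j`. Values are left fractional; blank columns pass through
#' unchanged. Zero-depth field samples are dropped with a warning.
#'
#' @param table An [asv_table()].
#' @return An [asv_table()] with real-valued field counts whose column sums
#'   all equal the minimum depth.
#' @export
standardize_depth <- function(table) {
  fc <- field_cols(table)
  if (length(fc) == 0L) stop("no field samples to standardize")
  depths <- colSums(table$counts[, fc, drop = FALSE])
  if (any(depths == 0)) {
    bad <- colnames(table$counts)[fc][depths == 0]
    warning("dropping zero-depth field sample(s): ",
            paste(bad, collapse = ", "), call. = FALSE)
    keep_samples <- setdiff(colnames(table$counts), bad)
    table <- asv_table(table$counts[, keep_samples, drop = FALSE],
                       table$meta[table$meta$sample_id %in% keep_samples, ])
    fc <- field_cols(table)
    depths <- colSums(table$counts[, fc, drop = FALSE])
  }
  d_min <- min(depths)
  counts <- table$counts * 1.0
  counts[, fc] <- sweep(counts[, fc, drop = FALSE], 2, d_min / depths, "*")
  out <- asv_table(counts, table$meta)
  attr(out, "min_depth") <- d_min
  out
}

#' Aggregate an ASV table to a date x taxon community matrix
#'
#' Sums (standardized) reads over ASVs assigned to the same taxon, then over
#' same-date field replicates, and finally pools the configured
#' indistinguishable species pairs. Excluded ASVs are dropped; the grand
#' total over retained ASVs is conserved through all three steps.
#'
#' @param table An [asv_table()], typically filtered and standardized.
#' @param assignments Output of [assign_taxonomy()].
#' @param pools List of species pairs to pool
#'   (default [default_species_pools()]; use `list()` for none).
#' @return A [community_matrix()] with provenance `"standardized_reads"`.
#' @export
aggregate_to_dates <- function(table, assignments,
                               pools = default_species_pools()) {
  fc <- field_cols(table)
  asv_names <- rownames(table$counts)
  tax <- assignments$name[match(asv_names, assignments$asv_id)]
  rank <- assignments$rank[match(asv_names, assignments$asv_id)]
  keep <- !is.na(rank) & rank != "excluded"

  m <- table$counts[keep, fc, drop = FALSE]
  taxa <- tax[keep]
  by_taxon <- rowsum(m, group = taxa)

  dates <- as.character(table$meta$date[fc])
  by_date <- rowsum(t(by_taxon), group = dates)  # date x taxon

  out <- pool_taxa(by_date, pools)
  out <- out[order(as.Date(rownames(out))), , drop = FALSE]
  community_matrix(out, provenance = "standardized_reads")
}

#' Per-date species means over community checklists
#'
#' For each (date, species), the mean count across that date's checklists; a
#' species absent from a checklist counts as 0 in that checklist (checklists
#' are complete: every bird observed is reported). Dates with no checklist
#' are excluded with a warning when explicitly requested.
#'
#' @param checklists Data frame with columns `checklist_id`, `date`,
#'   `species`, `count`.
#' @param dates Optional dates to restrict to (default: all dates present).
#' @return A [community_matrix()] with provenance `"checklist_mean"` and an
#'   attribute `n_checklists` (named per-date checklist counts) for
#'   downstream at-least-3 filtering.
#' @export
checklist_means <- function(checklists, dates = NULL) {
  checklists$date <- as.Date(checklists$date)
  if (is.null(dates)) {
    dates <- sort(unique(checklists$date))
  } else {
    dates <- as.Date(dates)
    missing <- dates[!dates %in% checklists$date]
    if (length(missing) > 0) {
      warning("no checklists on date(s): ",
              paste(missing, collapse = ", "), "; excluded", call. = FALSE)
      dates <- dates[dates %in% checklists$date]
    }
  }
  species <- sort(unique(checklists$species))
  n_cl <- integer(length(dates))
  vals <- matrix(0, nrow = length(dates), ncol = length(species),
                 dimnames = list(as.character(dates), species))
  for (i in seq_along(dates)) {
    cl <- checklists[checklists$date == dates[i], , drop = FALSE]
    ids <- unique(cl$checklist_id)
    n_cl[i] <- length(ids)
    # absent-as-zero: divide summed counts by the number of checklists
    sums <- tapply(cl$count, cl$species, sum)
    vals[i, names(sums)] <- as.numeric(sums) / n_cl[i]
  }
  out <- community_matrix(vals, provenance = "checklist_mean")
  attr(out, "n_checklists") <- stats::setNames(n_cl, as.character(dates))
  out
}

#' Focal survey table to community matrix
#'
#' @param focal Data frame with columns `date`, `species`, `count` (one
#'   exhaustive survey per date).
#' @return A [community_matrix()] with provenance `"focal_counts"`.
#' @export
focal_matrix <- function(focal) {
  focal$date <- as.Date(focal$date)
  dates <- sort(unique(focal$date))
  species <- sort(unique(focal$species))
  vals <- matrix(0, nrow = length(dates), ncol = length(species),
                 dimnames = list(as.character(dates), species))
  for (i in seq_len(nrow(focal))) {
    vals[as.character(focal$date[i]), focal$species[i]] <-
      vals[as.character(focal$date[i]), focal$species[i]] + focal$count[i]
  }
  community_matrix(vals, provenance = "focal_counts")
}

#' One-call ASV processing pipeline
#'
#' Chains [assign_taxonomy()], [control_filter_threshold()],
#' [apply_control_filter()], [standardize_depth()] and
#' [aggregate_to_dates()], returning the community matrix plus a QC report.
#'
#' @param table An [asv_table()].
#' @param hits Hit table (see [assign_taxonomy()]).
#' @param pools Species pairs to pool (default [default_species_pools()]).
#' @param control_threshold_mode Passed to [control_filter_threshold()].
#' @return List with `community` (a [community_matrix()]), `assignments`,
#'   `threshold`, `n_removed`, `removed_asvs`, `min_depth`.
#' @export
process_asv_table <- function(table, hits,
                              pools = default_species_pools(),
                              control_threshold_mode = "per_asv") {
  assignments <- assign_taxonomy(hits, asv_ids = rownames(table$counts))
  threshold <- control_filter_threshold(table,
                                        mode = control_threshold_mode)
  filtered <- apply_control_filter(table, threshold)
  standardized <- standardize_depth(filtered)
  community <- aggregate_to_dates(standardized, assignments, pools)
  list(community = community, assignments = assignments,
       threshold = threshold, n_removed = attr(filtered, "n_removed"),
       removed_asvs = attr(filtered, "removed_asvs"),
       min_depth = attr(standardized, "min_depth"))
}
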