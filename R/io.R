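# Plain-text readers/writers for the pipeline's exchange formats: TSV
# tables and FASTA reference sets.

write_tsv0 <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv0 <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write / read a reference FASTA plus lineage table
#'
#' FASTA is wrapped at 80 columns; the lineage TSV has header
#' `record_id species genus family tribe class`.
#'
#' @param references List as from [simulate_references()] (`sequences`,
#'   `lineage`).
#' @param fasta_path,lineage_path Output file paths.
#' @return Invisibly, the paths written.
#' @export
write_reference_fasta <- function(references, fasta_path, lineage_path) {
  seqs <- Biostrings::DNAStringSet(references$sequences)
  Biostrings::writeXStringSet(seqs, filepath = fasta_path, width = 80L)
  write_tsv0(references$lineage, lineage_path)
  invisible(c(fasta_path, lineage_path))
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(fasta_path, lineage_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  list(sequences = stats::setNames(as.character(seqs), names(seqs)),
       lineage = read_tsv0(lineage_path))
}

#' Write / read an ASV count table with sample metadata
#'
#' Counts TSV: rows = ASV ids (first column `asv_id`), columns = sample ids.
#' Metadata TSV header: `sample_id date sample_type replicate`.
#'
#' @param table An [asv_table()].
#' @param counts_path,meta_path File paths.
#' @return `write_asv_table` invisibly returns the paths; `read_asv_table`
#'   returns an [asv_table()].
#' @export
write_asv_table <- function(table, counts_path, meta_path) {
  df <- data.frame(asv_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  write_tsv0(df, counts_path)
  write_tsv0(table$meta, meta_path)
  invisible(c(counts_path, meta_path))
}

#' @rdname write_asv_table
#' @export
read_asv_table <- function(counts_path, meta_path) {
  df <- read_tsv0(counts_path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$asv_id
  asv_table(counts, read_tsv0(meta_path))
}

#' Write / read a BLAST-style hit table
#'
#' TSV header: `asv_id subject_species subject_genus subject_family
#' pct_identity score`. `read_hit_table` also accepts other column orders
#' via `col_map`, a named character vector mapping the standard names to the
#' file's column names.
#'
#' @param hits Hit table data frame.
#' @param path File path.
#' @param col_map Optional named character vector, e.g.
#'   `c(asv_id = "qseqid", pct_identity = "pident", score = "bitscore", ...)`.
#' @return `read_hit_table` returns the hit table with standard column
#'   names.
#' @export
write_hit_table <- function(hits, path) {
  write_tsv0(hits, path)
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path, col_map = NULL) {
  df <- read_tsv0(path)
  if (!is.null(col_map)) {
    missing <- setdiff(col_map, names(df))
    if (length(missing) > 0) {
      stop("columns absent from hit table: ", paste(missing, collapse = ", "))
    }
    df <- df[, col_map, drop = FALSE]
    names(df) <- names(col_map)
  }
  needed <- c("asv_id", "subject_species", "subject_genus",
              "subject_family", "pct_identity", "score")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("hit table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df[, needed]
}

#' Write / read a date x taxon community matrix
#'
#' TSV with dates as rows (first column `date`) and taxa as columns.
#'
#' @param x A [community_matrix()].
#' @param path File path.
#' @param provenance Provenance tag to restore on read.
#' @return `read_community_matrix` returns a [community_matrix()].
#' @export
write_community_matrix <- function(x, path) {
  df <- data.frame(date = rownames(x), unclass(x), check.names = FALSE)
  write_tsv0(df, path)
  invisible(path)
}

#' @rdname write_community_matrix
#' @export
read_community_matrix <- function(path, provenance = "standardized_reads") {
  df <- read_tsv0(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$date
  community_matrix(m, provenance = provenance)
}

#' Write all synthetic-data outputs to a directory
#'
#' Emits the full exchange-format bundle from one [simulate_dataset()] run:
#' reference FASTA + lineage TSV, ASV counts + sample metadata TSVs, hit
#' table TSV, focal survey and checklist TSVs, and the true abundance
#' matrix.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(fasta = file.path(dir, "references.fasta"),
         lineage = file.path(dir, "lineage.tsv"),
         counts = file.path(dir, "asv_counts.tsv"),
         meta = file.path(dir, "sample_metadata.tsv"),
         hits = file.path(dir, "hit_table.tsv"),
         focal = file.path(dir, "focal_surveys.tsv"),
         checklists = file.path(dir, "checklists.tsv"),
         truth = file.path(dir, "true_abundance.tsv"))
  write_reference_fasta(sim$references, p["fasta"], p["lineage"])
  write_asv_table(asv_table(sim$reads$counts, sim$reads$meta),
                  p["counts"], p["meta"])
  write_hit_table(sim$reads$hits, p["hits"])
  write_tsv0(sim$surveys$focal, p["focal"])
  write_tsv0(sim$surveys$checklists, p["checklists"])
  write_community_matrix(sim$truth, p["truth"])
  invisible(p)
}
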