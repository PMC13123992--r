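# Date x taxon community matrix container and species-pair pooling.

#' Construct a date x taxon community matrix
#'
#' A numeric matrix with dates as rows (rownames in `YYYY-MM-DD` form,
#' strictly increasing) and taxa as columns, tagged with its provenance:
#' standardized eDNA reads, focal visual counts, checklist means, or the
#' simulator's true abundances.
#'
#' @param values Non-negative numeric matrix; rownames must parse as dates.
#' @param provenance One of `"standardized_reads"`, `"focal_counts"`,
#'   `"checklist_mean"`, `"truth"`.
#' @return A `community_matrix` (numeric matrix with a `provenance`
#'   attribute).
#' @export
community_matrix <- function(values,
                             provenance = c("standardized_reads",
                                            "focal_counts",
                                            "checklist_mean", "truth")) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(values < 0)) stop("community matrix values must be non-negative")
  d <- as.Date(rownames(values))
  if (anyNA(d)) stop("rownames must be parseable dates (YYYY-MM-DD)")
  if (is.unsorted(d, strictly = TRUE)) stop("dates must be strictly increasing")
  structure(values, provenance = provenance, class = c("community_matrix",
                                                       class(values)))
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("<community_matrix> %d dates x %d taxa (%s)\n",
              nrow(x), ncol(x), attr(x, "provenance")))
  print(unclass(x), ...)
  invisible(x)
}

cm_dates <- function(x) as.Date(rownames(x))

#' Default indistinguishable species pairs to pool
#'
#' The ND2 metabarcodes cannot separate three waterfowl species pairs;
#' visual and eDNA abundances for each pair are therefore summed into one
#' pooled taxon before comparison: mallard/American black duck, tundra
#' swan/trumpeter swan, and greater/lesser scaup.
#'
#' @return List of length-2 character vectors of scientific names.
#' @export
default_species_pools <- function() {
  list(
    c("Anas platyrhynchos", "Anas rubripes"),
    c("Cygnus columbianus", "Cygnus buccinator"),
    c("Aythya marila", "Aythya affinis")
  )
}

#' Pool species pairs in a community matrix
#'
#' Sums each pair's columns into one pooled taxon named
#' `"<member1>/<member2>"`. Pairs with no member present are skipped with a
#' message; pairs with one member present are renamed to the pooled label so
#' both layers (visual, eDNA) use identical taxon names.
#'
#' @param x A [community_matrix()] (or plain date x taxon matrix).
#' @param pools List of length-2 character vectors
#'   (default [default_species_pools()]).
#' @return Matrix of the same class with pooled columns; the grand total is
#'   conserved.
#' @export
pool_taxa <- function(x, pools = default_species_pools()) {
  prov <- attr(x, "provenance")
  x <- unclass(x)
  for (pair in pools) {
    present <- pair[pair %in% colnames(x)]
    pooled_name <- paste(pair, collapse = "/")
    if (length(present) == 0L) {
      message("pool ", pooled_name, ": no member present; skipped")
      next
    }
    pooled <- rowSums(x[, present, drop = FALSE])
    x <- x[, setdiff(colnames(x), present), drop = FALSE]
    x <- cbind(x, pooled)
    colnames(x)[ncol(x)] <- pooled_name
  }
  if (!is.null(prov)) x <- community_matrix(x, provenance = prov)
  x
}
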