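# IUPAC nucleotide handling: bitmask representation, set-intersection
# matching, degenerate expansion, reverse complement.

# A=1, C=2, G=4, T=8; a degenerate code is the OR of its bases.
.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

# Integer bitmask vector for a nucleotide string; errors on non-IUPAC input.
iupac_masks <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  m <- .IUPAC_MASK[chars]
  if (anyNA(m)) {
    bad <- unique(chars[is.na(m)])
    stop("non-IUPAC character(s) in sequence: ", paste(bad, collapse = ", "))
  }
  unname(m)
}

#' Count mismatches between a degenerate primer and a sequence window
#'
#' A position matches when the IUPAC base-set of the primer symbol and the
#' base-set of the window symbol intersect; the mismatch count is the number
#' of positions with empty intersection. Both arguments may carry degenerate
#' codes (reference ambiguities such as N match any primer symbol).
#'
#' @param primer IUPAC nucleotide string.
#' @param window Nucleotide string of the same length.
#' @return Integer mismatch count.
#' @examples
#' iupac_mismatch_count("ACTTCCTRACCCAAGCAG", "ACTTCCTAACCCAAGCAG") # 0
#' iupac_mismatch_count("RYN", "CAC") # 1
#' @export
iupac_mismatch_count <- function(primer, window) {
  pm <- iupac_masks(primer)
  wm <- iupac_masks(window)
  if (length(pm) != length(wm)) {
    stop("primer and window must have equal length (",
         length(pm), " vs ", length(wm), ")")
  }
  sum(bitwAnd(pm, wm) == 0L)
}

#' Expand a degenerate primer into all concrete sequences
#'
#' @param primer IUPAC nucleotide string.
#' @param max_expansions Safety cap on the number of concrete sequences.
#' @return Character vector of all A/C/G/T sequences the primer denotes; its
#'   length is the product of per-position degeneracies.
#' @examples
#' expand_degenerate("ATTCAGCCYCCYAGYGC") # 8 sequences (three Y)
#' @export
expand_degenerate <- function(primer, max_expansions = 65536L) {
  masks <- iupac_masks(primer)
  base_sets <- lapply(masks, function(m) {
    c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) != 0L]
  })
  n <- prod(vapply(base_sets, length, integer(1)))
  if (n > max_expansions) {
    stop("degenerate expansion of size ", n, " exceeds cap ", max_expansions)
  }
  grid <- do.call(expand.grid,
                  c(rev(base_sets), list(stringsAsFactors = FALSE)))
  apply(grid[, rev(seq_along(base_sets)), drop = FALSE], 1L, paste0,
        collapse = "")
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Degenerate codes are complemented set-wise (R to Y, B to V, ...).
#'
#' @param x IUPAC nucleotide string.
#' @return The reverse complement as a character string.
#' @export
reverse_complement_iupac <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  comp <- .IUPAC_COMPLEMENT[chars]
  if (anyNA(comp)) {
    stop("non-IUPAC character(s) in sequence: ",
         paste(unique(chars[is.na(comp)]), collapse = ", "))
  }
  paste0(rev(unname(comp)), collapse = "")
}

# Mismatch profile of a pattern slid over a subject: returns an integer
# vector v where v[i] is the IUPAC-set mismatch count of the pattern against
# subject[i .. i+k-1], for all i in 1 .. L-k+1. O(k) vectorized passes.
slide_mismatches <- function(pattern_masks, subject_masks) {
  k <- length(pattern_masks)
  L <- length(subject_masks)
  if (L < k) return(integer(0))
  n_win <- L - k + 1L
  mm <- integer(n_win)
  for (j in seq_len(k)) {
    mm <- mm + (bitwAnd(subject_masks[j:(j + n_win - 1L)],
                        pattern_masks[j]) == 0L)
  }
  mm
}
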