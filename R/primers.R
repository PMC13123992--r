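# Primer pair data model and the shipped waterfowl ND2 defaults.

#' Construct a primer pair
#'
#' A named forward/reverse pair of IUPAC-degenerate primers with the expected
#' insert (between-primer) length and full amplicon size. When both expected
#' lengths are given they must satisfy
#' `expected_amplicon == expected_insert + nchar(forward) + nchar(reverse)`
#' (the amplicon includes both primer footprints).
#'
#' @param name Short identifier for the pair.
#' @param forward,reverse Primer sequences, 5'-3', IUPAC codes allowed.
#' @param target_group Taxonomic group the pair targets (free text).
#' @param expected_insert,expected_amplicon Expected insert / amplicon length
#'   in bases, or `NA` when unknown.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, target_group = NA_character_,
                        expected_insert = NA_integer_,
                        expected_amplicon = NA_integer_) {
  iupac_masks(forward)  # validates alphabet
  iupac_masks(reverse)
  if (!is.na(expected_insert) && !is.na(expected_amplicon)) {
    implied <- expected_insert + nchar(forward) + nchar(reverse)
    if (implied != expected_amplicon) {
      stop("inconsistent pair '", name, "': insert ", expected_insert,
           " + primer lengths ", nchar(forward), "+", nchar(reverse),
           " = ", implied, " != expected amplicon ", expected_amplicon)
    }
  }
  structure(
    list(name = name, forward = toupper(forward), reverse = toupper(reverse),
         target_group = target_group,
         expected_insert = as.integer(expected_insert),
         expected_amplicon = as.integer(expected_amplicon)),
    class = "primer_pair"
  )
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s (%s)\n  F: %s\n  R: %s\n  insert %s nt, amplicon %s nt\n",
              x$name, x$target_group, x$forward, x$reverse,
              x$expected_insert, x$expected_amplicon))
  invisible(x)
}

#' Waterfowl ND2 tribe-targeted primer pairs
#'
#' The three mitochondrial ND2 primer pairs targeting the North American
#' Anatidae tribes: 197F/524R (Anserini/Cygnini, 297 nt insert, 332 nt
#' amplicon), 419F/659R (Anatini/Cairinini/Oxyura, 200/241 nt) and 220F/436R
#' (Aythyini/Mergini, 179/217 nt).
#'
#' @return Named list of three `primer_pair` objects.
#' @export
default_primer_pairs <- function() {
  list(
    `197F/524R` = primer_pair(
      "197F/524R",
      forward = "ACTTCCTRACCCAAGCAG",
      reverse = "ATTCAGCCYCCYAGYGC",
      target_group = "Anserini/Cygnini",
      expected_insert = 297L, expected_amplicon = 332L),
    `419F/659R` = primer_pair(
      "419F/659R",
      forward = "TYATRAARTTYCCCCCRC",
      reverse = "GATGTYATGATYGYRTARAGRTA",
      target_group = "Anatini/Cairinini/Oxyura",
      expected_insert = 200L, expected_amplicon = 241L),
    `220F/436R` = primer_pair(
      "220F/436R",
      forward = "TCCGCYYTWGTCCTRTTCT",
      reverse = "GTGGRGGRAAYTTYATGAG",
      target_group = "Aythyini/Mergini",
      expected_insert = 179L, expected_amplicon = 217L)
  )
}

# Map a tribe label (as used in species parameter tables) to its pair name.
tribe_pair_name <- function(tribe) {
  switch(tribe,
         "Anserini/Cygnini" = "197F/524R",
         "Anatini/Cairinini/Oxyura" = "419F/659R",
         "Aythyini/Mergini" = "220F/436R",
         stop("unknown tribe: ", tribe))
}
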