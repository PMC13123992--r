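# Independent brute-force in-silico PCR oracle: expands both degenerate
# primers into every concrete sequence, slides each expansion over both
# strands counting exact Hamming mismatches, enumerates legal pairings and
# applies the same pairing-resolution convention as the package (shortest
# product per forward site, strictly nested products suppressed). Shares no
# code with the implementation under test.

orc_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

orc_expand <- function(p) {
  sets <- orc_sets[strsplit(p, "")[[1]]]
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

orc_rc <- function(s) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

orc_random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# minimum Hamming distance over expansions at every window start (1-based)
orc_site_mm <- function(expansions, chars) {
  k <- nchar(expansions[1])
  L <- length(chars)
  if (L < k) return(numeric(0))
  nw <- L - k + 1L
  best <- rep(Inf, nw)
  for (e in expansions) {
    ec <- strsplit(e, "")[[1]]
    mm <- integer(nw)
    for (j in seq_len(k)) mm <- mm + (chars[j:(j + nw - 1L)] != ec[j])
    best <- pmin(best, mm)
  }
  best
}

orc_scan <- function(fwd, rev, s, max_mm, max_amp) {
  chars <- strsplit(s, "")[[1]]
  fe <- orc_expand(fwd)
  re <- vapply(orc_expand(rev), orc_rc, character(1), USE.NAMES = FALSE)
  lf <- nchar(fwd)
  lr <- nchar(rev)
  fmm <- orc_site_mm(fe, chars)
  rmm <- orc_site_mm(re, chars)
  fpos <- which(fmm <= max_mm)
  rpos <- which(rmm <= max_mm)
  hits <- list()
  for (fs in fpos) {
    ok <- rpos[rpos >= fs + lf & (rpos + lr - fs) <= max_amp]
    if (length(ok) == 0L) next
    rs <- min(ok)
    hits[[length(hits) + 1L]] <- data.frame(
      start = fs, end = rs + lr,
      fwd_mm = as.integer(fmm[fs]), rev_mm = as.integer(rmm[rs]))
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      fwd_mm = integer(0), rev_mm = integer(0)))
  }
  h <- do.call(rbind, hits)
  keep <- vapply(seq_len(nrow(h)), function(i) {
    !any(h$start <= h$start[i] & h$end >= h$end[i] &
           (h$start < h$start[i] | h$end > h$end[i]))
  }, logical(1))
  h[keep, , drop = FALSE]
}

oracle_amplicons <- function(pair, s, max_mm, max_amp) {
  L <- nchar(s)
  plus <- orc_scan(pair$forward, pair$reverse, s, max_mm, max_amp)
  minus <- orc_scan(pair$forward, pair$reverse, orc_rc(s), max_mm, max_amp)
  out <- rbind(
    if (nrow(plus) > 0) data.frame(
      strand = "+", start = plus$start - 1L, end = plus$end - 1L,
      fwd_mm = plus$fwd_mm, rev_mm = plus$rev_mm),
    if (nrow(minus) > 0) data.frame(
      strand = "-", start = L - minus$end + 1L, end = L - minus$start + 1L,
      fwd_mm = minus$fwd_mm, rev_mm = minus$rev_mm))
  if (is.null(out)) {
    out <- data.frame(strand = character(0), start = integer(0),
                      end = integer(0), fwd_mm = integer(0),
                      rev_mm = integer(0))
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# concrete primer site with exactly n_mut positions mutated to a base
# outside the primer symbol's base-set
orc_mutated_site <- function(primer, n_mut = 0) {
  site <- strsplit(sample(orc_expand(primer), 1), "")[[1]]
  psym <- strsplit(primer, "")[[1]]
  if (n_mut > 0) {
    for (pos in sample(length(site), n_mut)) {
      outside <- setdiff(c("A", "C", "G", "T"), orc_sets[[psym[pos]]])
      site[pos] <- sample(outside, 1)
    }
  }
  paste0(site, collapse = "")
}

# template with one planted product: flanks + fwd site + insert + rc(rev)
orc_template <- function(pair, insert = pair$expected_insert,
                         fwd_mut = 0, rev_mut = 0,
                         flanks = c(60, 60), minus = FALSE) {
  s <- paste0(orc_random_nt(flanks[1]),
              orc_mutated_site(pair$forward, fwd_mut),
              orc_random_nt(insert),
              orc_rc(orc_mutated_site(pair$reverse, rev_mut)),
              orc_random_nt(flanks[2]))
  if (minus) orc_rc(s) else s
}

hit_coords <- function(h) {
  out <- h[, c("strand", "start", "end", "fwd_mm", "rev_mm")]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
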