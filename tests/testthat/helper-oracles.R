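# Independent brute-force oracles. Deliberately naive and self-contained
# (own reverse complement, own IUPAC sets) so they share no code path with
# the implementation they check.

oracle_revcomp <- function(s) {
  if (nchar(s) == 0L) return("")
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s),
                     "", fixed = TRUE)[[1]]), collapse = "")
}

# Every 23-nt window on both strands with an NGG PAM, full window inside
# the 0-based half-open region [rs, re); ambiguous windows skipped.
oracle_sites <- function(seq, rs = 0L, re = nchar(seq)) {
  rows <- list()
  n <- nchar(seq)
  if (re - rs < 23L)
    return(data.frame(protospacer = character(0), pam = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  for (a0 in seq(rs, re - 23L)) {
    if (a0 < 0L || a0 + 23L > n) next
    w <- substr(seq, a0 + 1L, a0 + 23L)
    if (grepl("[^ACGT]", w)) next
    if (substr(w, 22L, 23L) == "GG")
      rows[[length(rows) + 1L]] <- data.frame(
        protospacer = substr(w, 1L, 20L), pam = substr(w, 21L, 23L),
        strand = "+", start = a0, end = a0 + 20L, stringsAsFactors = FALSE)
    if (substr(w, 1L, 2L) == "CC")
      rows[[length(rows) + 1L]] <- data.frame(
        protospacer = oracle_revcomp(substr(w, 4L, 23L)),
        pam = oracle_revcomp(substr(w, 1L, 3L)),
        strand = "-", start = a0 + 3L, end = a0 + 23L,
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(protospacer = character(0), pam = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# Position-by-position degenerate matching at every offset and strand.
oracle_primer_hits <- function(seq, primer, max_mismatch) {
  count_mm <- function(pat, txt) {
    p <- strsplit(pat, "", fixed = TRUE)[[1]]
    t <- strsplit(txt, "", fixed = TRUE)[[1]]
    sum(vapply(seq_along(p), function(i)
      !(t[i] %in% oracle_iupac_sets[[p[i]]]), logical(1)))
  }
  L <- nchar(primer); n <- nchar(seq)
  rows <- list()
  if (n >= L) {
    for (o in 0:(n - L)) {
      txt <- substr(seq, o + 1L, o + L)
      for (st in c("+", "-")) {
        pat <- if (st == "+") primer else oracle_revcomp(primer)
        mm <- count_mm(pat, txt)
        if (mm <= max_mismatch)
          rows[[length(rows) + 1L]] <- data.frame(
            offset = o, strand = st, mismatches = mm,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(offset = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Does `kmer` occur (either strand) in any of `seqs`? Plain substring scan.
oracle_occurs <- function(kmer, seqs) {
  any(grepl(kmer, seqs, fixed = TRUE)) ||
    any(grepl(oracle_revcomp(kmer), seqs, fixed = TRUE))
}

# Exhaustive innermost pairing on both orientations; returns the sorted
# multiset of amplicon sequences (forward-primer orientation).
oracle_amplicons <- function(seq, fwd, rev, min_len, max_len) {
  foot_starts <- function(s, pat) {
    L <- nchar(pat); n <- nchar(s)
    if (n < L) return(integer(0))
    hits <- integer(0)
    for (o in 0:(n - L)) {
      txt <- substr(s, o + 1L, o + L)
      p <- strsplit(pat, "", fixed = TRUE)[[1]]
      t <- strsplit(txt, "", fixed = TRUE)[[1]]
      ok <- all(vapply(seq_along(p), function(i)
        t[i] %in% oracle_iupac_sets[[p[i]]], logical(1)))
      if (ok) hits <- c(hits, o)
    }
    hits
  }
  one_orientation <- function(s) {
    res <- character(0)
    fs <- foot_starts(s, fwd)
    rs <- foot_starts(s, oracle_revcomp(rev))
    for (f in fs) {
      ends <- rs[rs >= f + nchar(fwd)] + nchar(rev)
      lens <- ends - f
      ok <- which(lens >= min_len)
      if (length(ok) == 0L) next
      k <- ok[which.min(lens[ok])]
      if (lens[k] > max_len) next
      res <- c(res, substr(s, f + 1L, ends[k]))
    }
    res
  }
  sort(c(one_orientation(seq), one_orientation(oracle_revcomp(seq))))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

random_iupac <- function(n) paste(
  sample(c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
           "B", "D", "H", "V", "N"), n, replace = TRUE), collapse = "")

random_protospacer <- function() random_dna(20L)
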