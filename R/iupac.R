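# IUPAC nucleotide code tables shared by the primer scanner, guide
# enumeration and the synthetic generator. Degenerate codes are expanded to
# concrete A/C/G/T sets; an ambiguity code in the *subject* of a comparison
# never counts as a match (missing data is treated conservatively).

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_CODES <- names(IUPAC_SETS)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

# MATCH[p, t]: does concrete subject base t satisfy pattern code p?
# Columns exist for all 15 codes so ambiguous subject bases index cleanly
# (always FALSE).
IUPAC_MATCH <- local({
  m <- matrix(FALSE, nrow = 15, ncol = 15,
              dimnames = list(IUPAC_CODES, IUPAC_CODES))
  for (p in IUPAC_CODES) m[p, IUPAC_SETS[[p]]] <- TRUE
  m
})

.validate_iupac <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  if (nchar(seq) == 0L) return(invisible(seq))
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_CODES, collapse = "")), seq)
  if (bad) {
    chars <- unique(strsplit(seq, "", fixed = TRUE)[[1]])
    offending <- setdiff(chars, IUPAC_CODES)
    stop(what, " contains non-IUPAC characters: ",
         paste(offending, collapse = ", "), call. = FALSE)
  }
  invisible(seq)
}

#' Reverse complement with full IUPAC support
#'
#' Complements every IUPAC nucleotide code (degenerate codes map to their
#' complementary sets, e.g. R -> Y) and reverses the string. The operation is
#' an involution: `revcomp(revcomp(s)) == s`.
#'
#' @param seq Character vector of uppercase IUPAC DNA strings (may contain
#'   empty strings).
#' @return Character vector of reverse complements, same length as `seq`.
#' @examples
#' revcomp("AACG")  # "CGTT"
#' revcomp("R")     # "Y"
#' @export
revcomp <- function(seq) {
  if (!is.character(seq)) stop("seq must be character", call. = FALSE)
  vapply(seq, function(s) {
    .validate_iupac(s, "seq")
    if (nchar(s) == 0L) return("")
    comp <- chartr(paste(names(IUPAC_COMPLEMENT), collapse = ""),
                   paste(IUPAC_COMPLEMENT, collapse = ""), s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Count mismatches between a degenerate pattern and a subject
#'
#' Position-wise comparison of two equal-length strings. A position matches
#' iff the subject base is one of the concrete bases denoted by the pattern's
#' IUPAC code; an ambiguity code in the subject never matches (conservative
#' handling of missing data in references).
#'
#' @param pattern IUPAC string, may contain degenerate codes (e.g. a primer).
#' @param text Subject string of the same length.
#' @return Integer count of non-matching positions.
#' @examples
#' iupac_match("CASC", "CAGC")  # 0: S = C/G
#' iupac_match("NNNN", "ACGT")  # 0
#' @export
iupac_match <- function(pattern, text) {
  .validate_iupac(pattern, "pattern")
  .validate_iupac(text, "text")
  if (nchar(pattern) != nchar(text))
    stop("pattern and text lengths differ (", nchar(pattern), " vs ",
         nchar(text), ")", call. = FALSE)
  if (nchar(pattern) == 0L) return(0L)
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  t <- strsplit(text, "", fixed = TRUE)[[1]]
  sum(!IUPAC_MATCH[cbind(p, t)])
}

# Mismatch counts of `pattern` against every offset of `text`.
# Returns an integer vector of length nchar(text) - nchar(pattern) + 1
# (empty when the pattern is longer than the text); offset i (1-based)
# aligns pattern[1] with text[i].
mismatch_profile <- function(pattern, text) {
  L <- nchar(pattern)
  n <- nchar(text)
  if (L == 0L || n < L) return(integer(0))
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  t <- strsplit(text, "", fixed = TRUE)[[1]]
  k <- n - L + 1L
  mm <- integer(k)
  for (j in seq_len(L)) {
    mm <- mm + !IUPAC_MATCH[p[j], t[j:(j + k - 1L)]]
  }
  mm
}

# Deterministically instantiate degenerate codes to a concrete base
# (first member of each code's set).
instantiate_degenerate <- function(seq) {
  .validate_iupac(seq, "seq")
  if (nchar(seq) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) IUPAC_SETS[[ch]][1], character(1)),
        collapse = "")
}

gc_fraction <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(NA_real_)
  (n - nchar(gsub("[GC]", "", seq))) / n
}
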