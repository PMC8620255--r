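# In-silico PCR: locate degenerate primer binding sites on both strands and
# extract primer-flanked amplicons oriented forward-primer -> reverse-primer.
# All reported coordinates are 0-based half-open on the source plus strand,
# the convention used throughout the guide-design layer.

#' Construct a primer pair
#'
#' Both primers are given 5'->3' as synthesized; the reverse primer's
#' footprint on the template plus strand is its reverse complement.
#'
#' @param name Label for the pair.
#' @param forward,reverse IUPAC nucleotide strings, length >= 10.
#' @return Object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  .validate_iupac(forward, "forward primer")
  .validate_iupac(reverse, "reverse primer")
  if (nchar(forward) < 10L || nchar(reverse) < 10L)
    stop("primers must be at least 10 nt long", call. = FALSE)
  structure(list(name = name, forward = forward, reverse = reverse),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s\n  forward: %s\n  reverse: %s\n",
              x$name, x$forward, x$reverse))
  invisible(x)
}

#' Load a named primer pair from the packaged primer config
#'
#' The package ships a primer table (`inst/extdata/primer_sets.tsv`) with the
#' eukaryotic 18S V4 "universal" pair (`universal_V4`, the default used
#' throughout) and alternative sets. A path to a user TSV with columns
#' `name`, `forward`, `reverse` may be given instead.
#'
#' @param name Primer-set name, or a path to a primer TSV containing it.
#' @param file Optional primer table path overriding the packaged one.
#' @return A `primer_pair`.
#' @export
primer_set <- function(name = "universal_V4", file = NULL) {
  if (is.null(file)) {
    if (file.exists(name)) { file <- name; name <- NULL }
    else file <- system.file("extdata", "primer_sets.tsv", package = "ampliguide")
  }
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (is.null(name)) {
    if (nrow(tab) < 1L) stop("primer file '", file, "' is empty", call. = FALSE)
    row <- tab[1L, ]
  } else {
    hit <- which(tab$name == name)
    if (length(hit) == 0L)
      stop("primer set '", name, "' not found in ", file, call. = FALSE)
    row <- tab[hit[1L], ]
  }
  primer_pair(row$name, row$forward, row$reverse)
}

#' Find degenerate-primer matches on both strands
#'
#' Scans the plus strand for the primer and the minus strand (i.e. the plus
#' strand for the primer's reverse complement). Degenerate codes in the
#' primer match their base sets; ambiguity codes in the subject never count
#' as matches.
#'
#' @param seq Subject nucleotide string (IUPAC).
#' @param primer Primer string 5'->3' (IUPAC, may be degenerate).
#' @param max_mismatch Maximum mismatches allowed (default 0).
#' @return data.frame with columns `offset` (0-based start of the footprint
#'   on the plus strand), `strand` (`"+"`/`"-"`), `mismatches`; sorted by
#'   offset. Empty when the primer is longer than the subject.
#' @export
find_primer_matches <- function(seq, primer, max_mismatch = 0L) {
  .validate_iupac(seq, "seq")
  .validate_iupac(primer, "primer")
  if (max_mismatch < 0L) stop("max_mismatch must be >= 0", call. = FALSE)
  hits <- function(pat, strand) {
    mm <- mismatch_profile(pat, seq)
    keep <- which(mm <= max_mismatch)
    if (length(keep) == 0L) return(NULL)
    data.frame(offset = keep - 1L, strand = strand,
               mismatches = mm[keep], stringsAsFactors = FALSE)
  }
  out <- rbind(hits(primer, "+"), hits(revcomp(primer), "-"))
  if (is.null(out))
    return(data.frame(offset = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

make_amplicon <- function(record, start, end, strand, sequence,
                          fwd_len, rev_len, n_products) {
  structure(
    list(source_accession = record$accession,
         start = start, end = end, strand = strand,
         sequence = sequence,
         interior = c(fwd_len, nchar(sequence) - rev_len),
         taxonomy = record$levels,
         species = record$species,
         n_products = n_products),
    class = "amplicon"
  )
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon> %s [%d,%d) strand %s, %d nt (interior [%d,%d))\n",
              x$source_accession, x$start, x$end, x$strand,
              nchar(x$sequence), x$interior[1], x$interior[2]))
  invisible(x)
}

# Innermost pairing on one orientation: for each forward-primer start,
# the nearest downstream reverse-primer footprint giving a product inside
# the length window. Returns 0-based [start, end) pairs.
.pair_one_orientation <- function(seq, primers, constraints) {
  lenF <- nchar(primers$forward)
  lenR <- nchar(primers$reverse)
  fh <- find_primer_matches(seq, primers$forward, constraints$max_mismatch)
  fh <- fh[fh$strand == "+", , drop = FALSE]
  if (nrow(fh) == 0L) return(NULL)
  rh <- find_primer_matches(seq, primers$reverse, constraints$max_mismatch)
  rh <- rh[rh$strand == "-", , drop = FALSE]   # revcomp(reverse) on plus
  if (nrow(rh) == 0L) return(NULL)
  res <- NULL
  for (f in fh$offset) {
    ends <- rh$offset + lenR
    lens <- ends - f
    ok <- which(rh$offset >= f + lenF & lens >= constraints$min_len)
    if (length(ok) == 0L) next
    k <- ok[which.min(lens[ok])]          # innermost (shortest) product
    if (lens[k] > constraints$max_len) next
    res <- rbind(res, c(start = f, end = ends[k]))
  }
  res
}

#' Extract primer-flanked amplicons from a reference record
#'
#' Emulates PCR with a degenerate primer pair: each forward-primer hit is
#' paired with the nearest downstream reverse-primer footprint on the same
#' amplifiable orientation (the innermost product, which dominates PCR).
#' Amplicons from minus-strand templates are reverse-complemented so the
#' returned sequence always reads forward-primer -> reverse-primer; both
#' primer footprints are included and the `interior` interval excludes them.
#'
#' @param record A `reference_record`.
#' @param primers A `primer_pair`.
#' @param constraints List with `min_len`, `max_len` (product length window,
#'   footprints included; default 50-2000) and `max_mismatch` per primer
#'   (default 0, degeneracy only).
#' @return List of `amplicon` objects (possibly empty). When a record yields
#'   more than one product each amplicon's `n_products` field flags it.
#' @export
extract_amplicons <- function(record, primers,
                              constraints = list(min_len = 50L,
                                                 max_len = 2000L,
                                                 max_mismatch = 0L)) {
  constraints <- utils::modifyList(
    list(min_len = 50L, max_len = 2000L, max_mismatch = 0L), constraints)
  if (constraints$min_len < nchar(primers$forward) + nchar(primers$reverse))
    stop("min_len must be at least the summed primer lengths", call. = FALSE)
  seq <- record$sequence
  L <- nchar(seq)
  lenF <- nchar(primers$forward); lenR <- nchar(primers$reverse)

  plus <- .pair_one_orientation(seq, primers, constraints)
  rc <- revcomp(seq)
  minus <- .pair_one_orientation(rc, primers, constraints)

  out <- list()
  nprod <- (if (is.null(plus)) 0L else nrow(plus)) +
           (if (is.null(minus)) 0L else nrow(minus))
  if (!is.null(plus)) {
    for (i in seq_len(nrow(plus))) {
      s <- unname(plus[i, "start"]); e <- unname(plus[i, "end"])
      out[[length(out) + 1L]] <- make_amplicon(
        record, s, e, "+", substr(seq, s + 1L, e), lenF, lenR, nprod)
    }
  }
  if (!is.null(minus)) {
    for (i in seq_len(nrow(minus))) {
      s <- unname(minus[i, "start"]); e <- unname(minus[i, "end"])
      # map [s, e) on the reverse complement back to plus coordinates
      out[[length(out) + 1L]] <- make_amplicon(
        record, L - e, L - s, "-", substr(rc, s + 1L, e), lenF, lenR, nprod)
    }
  }
  out
}

# All amplicons across a record list, silently skipping records without one.
extract_all_amplicons <- function(records, primers, constraints = list()) {
  out <- list()
  for (r in records) out <- c(out, extract_amplicons(r, primers, constraints))
  out
}
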