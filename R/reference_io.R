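# Reference I/O: SILVA-style SSU FASTA with semicolon-delimited taxonomy in
# the header ("accession<space>Level0;Level1;...;Species"), plus a plain
# dialect for toy inputs where the whole header is a single-level taxonomy.
# Sequences are normalized to uppercase DNA (U -> T) on read.

#' Construct a reference record
#'
#' @param accession Identifier string.
#' @param levels Taxonomy path, root first (character vector); the deepest
#'   non-empty label becomes the species name.
#' @param sequence Nucleotide string (IUPAC; uppercased, U normalized to T).
#' @return Object of class `reference_record` with fields `accession`,
#'   `levels`, `species`, `sequence`.
#' @export
reference_record <- function(accession, levels, sequence) {
  make_reference_record(accession, levels, sequence)
}

make_reference_record <- function(accession, levels, sequence) {
  levels <- as.character(levels)
  levels <- levels[nzchar(levels)]
  if (length(levels) == 0L)
    stop("taxonomy for record '", accession, "' is empty", call. = FALSE)
  sequence <- normalize_sequence(sequence, accession)
  structure(
    list(accession = accession,
         levels = levels,
         species = levels[length(levels)],
         sequence = sequence),
    class = "reference_record"
  )
}

normalize_sequence <- function(sequence, accession = "<record>") {
  s <- chartr("u", "T", toupper(sequence))
  s <- chartr("U", "T", s)
  if (nchar(s) == 0L)
    stop("record '", accession, "' has an empty sequence", call. = FALSE)
  .validate_iupac(s, paste0("sequence of record '", accession, "'"))
  s
}

#' @export
print.reference_record <- function(x, ...) {
  cat(sprintf("<reference_record> %s | %s | %d nt\n",
              x$accession, paste(x$levels, collapse = ";"),
              nchar(x$sequence)))
  invisible(x)
}

#' Read an SSU reference FASTA with taxonomy-bearing headers
#'
#' Parses a (possibly line-wrapped) FASTA file into reference records. With
#' `dialect = "silva"` each header must be
#' `accession<space>Taxon;Path;...;Species`; with `dialect = "plain"` the
#' full header becomes a single-level taxonomy and the accession. Sequences
#' are uppercased and U is normalized to T.
#'
#' @param path Path to a FASTA file.
#' @param dialect `"silva"` (default) or `"plain"`.
#' @return List of `reference_record` objects in file order (empty list for
#'   an empty file).
#' @export
read_reference_fasta <- function(path, dialect = c("silva", "plain")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("cannot read reference FASTA: '", path, "' does not exist",
         call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(list())
  headers <- names(set)
  seqs <- unname(as.character(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    hdr <- headers[i]
    if (dialect == "silva") {
      sp <- regexpr(" ", hdr, fixed = TRUE)
      if (sp < 0L || sp == nchar(hdr))
        stop("SILVA-dialect header without taxonomy: '", hdr, "'",
             call. = FALSE)
      accession <- substr(hdr, 1L, sp - 1L)
      tax <- substr(hdr, sp + 1L, nchar(hdr))
      levels <- trimws(strsplit(tax, ";", fixed = TRUE)[[1]])
      if (length(levels[nzchar(levels)]) == 0L)
        stop("SILVA-dialect header without taxonomy: '", hdr, "'",
             call. = FALSE)
    } else {
      accession <- hdr
      levels <- hdr
    }
    out[[i]] <- make_reference_record(accession, levels, seqs[i])
  }
  out
}

#' Write reference records to FASTA
#'
#' Inverse of [read_reference_fasta()]: headers are
#' `accession<space>semicolon-joined-taxonomy` (silva dialect) or the bare
#' accession (plain). Round-trips losslessly.
#'
#' @param records List of `reference_record` objects.
#' @param path Output file path.
#' @param dialect Header dialect, as in [read_reference_fasta()].
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(records, path, dialect = c("silva", "plain")) {
  dialect <- match.arg(dialect)
  seqs <- vapply(records, function(r) r$sequence, character(1))
  headers <- vapply(records, function(r) {
    if (dialect == "silva")
      paste0(r$accession, " ", paste(r$levels, collapse = ";"))
    else r$accession
  }, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Partition reference records into host clade and microeukaryotes
#'
#' A record is a *host* record iff any taxonomy level equals one of
#' `host_keywords` (case-insensitive exact label match) — by default the
#' metazoan and land-plant clades. A record is a *microeukaryote* iff its
#' root level indicates Eukaryota and no host keyword matches. Everything
#' else (prokaryotes, unrooted entries) is dropped with a message.
#'
#' @param records List of `reference_record` objects.
#' @param host_keywords Character vector of clade labels marking the host
#'   side; must be non-empty.
#' @return Object of class `clade_partition`: list with `host`, `micro`
#'   (record lists), `selector` (the keywords) and `n_dropped`.
#' @export
clade_partition <- function(records,
                            host_keywords = c("Metazoa", "Animalia", "Embryophyta")) {
  if (length(host_keywords) == 0L)
    stop("host_keywords must be non-empty", call. = FALSE)
  kw <- tolower(host_keywords)
  host <- list(); micro <- list(); dropped <- 0L
  for (r in records) {
    lv <- tolower(r$levels)
    if (any(lv %in% kw)) {
      host[[length(host) + 1L]] <- r
    } else if (grepl("^eukaryota", lv[1])) {
      micro[[length(micro) + 1L]] <- r
    } else {
      dropped <- dropped + 1L
    }
  }
  if (dropped > 0L)
    message(dropped, " non-eukaryote record(s) dropped from partition")
  structure(
    list(host = host, micro = micro,
         selector = host_keywords, n_dropped = dropped),
    class = "clade_partition"
  )
}

#' @export
print.clade_partition <- function(x, ...) {
  cat(sprintf("<clade_partition> %d host / %d microeukaryote records (%d dropped)\n",
              length(x$host), length(x$micro), x$n_dropped))
  cat("  host keywords:", paste(x$selector, collapse = ", "), "\n")
  invisible(x)
}

host_species_names <- function(partition) {
  unique(vapply(partition$host, function(r) r$species, character(1)))
}
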