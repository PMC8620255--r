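# Guide design: enumerate SpCas9-compatible target sites (20-nt protospacer
# immediately 5' of an NGG PAM, either strand), screen them for absence in a
# microeukaryote reference via an exact 20-mer index, rank the survivors and
# assemble sgRNA template oligos.
#
# Coordinates on amplicons are 0-based half-open on the amplicon plus strand.
# For a "+" site the PAM occupies [end, end+3); for a "-" site, [start-3, start).

.datatable.aware <- TRUE

empty_sites <- function() {
  data.frame(protospacer = character(0), pam = character(0),
             strand = character(0), start = integer(0), end = integer(0),
             source_accession = character(0), source_taxon = character(0),
             stringsAsFactors = FALSE)
}

#' Enumerate Cas9-compatible guide target sites in an amplicon
#'
#' Returns every position on either strand where a 20-mer is immediately
#' followed 3' by an NGG PAM, with the full 23-nt window inside the chosen
#' region. Windows containing IUPAC ambiguity codes are skipped (a guide must
#' be synthesizable; ambiguity in a reference is missing data). By default
#' the search region is the amplicon interior, excluding both primer
#' footprints: those are universal by construction and a cut must fall
#' between the primer-extension start points to abolish amplification.
#'
#' @param x An `amplicon`, or a plain nucleotide string (then treated as
#'   `region = "full"` with no primer footprints).
#' @param region `"interior"` (default) or `"full"`.
#' @return data.frame with columns `protospacer`, `pam`, `strand`, `start`,
#'   `end` (0-based half-open protospacer interval on plus coordinates),
#'   `source_accession`, `source_taxon`; sorted by `start`, then `"+"`
#'   before `"-"`.
#' @export
enumerate_guide_sites <- function(x, region = c("interior", "full")) {
  region <- match.arg(region)
  if (is.character(x)) {
    seq <- toupper(x[1])
    .validate_iupac(seq, "sequence")
    acc <- NA_character_; taxon <- NA_character_
    bounds <- c(0L, nchar(seq))
  } else {
    seq <- x$sequence
    acc <- x$source_accession; taxon <- x$species
    bounds <- if (region == "interior") as.integer(x$interior)
              else c(0L, nchar(seq))
  }
  n <- nchar(seq)
  rs <- bounds[1]; re <- bounds[2]
  if (re - rs < 23L || n < 23L) return(empty_sites())

  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  # prefix[i + 1] = number of ambiguous bases in positions 1..i (1-based)
  prefix <- c(0L, cumsum(!(chars %in% c("A", "C", "G", "T"))))
  pure <- function(w0, len) prefix[w0 + len + 1L] - prefix[w0 + 1L] == 0L

  rows <- list()
  pair <- chars[-n] == chars[-1]
  gg <- which(pair & chars[-n] == "G")   # 1-based i: positions (i, i+1) are GG
  for (i in gg) {
    start0 <- i - 22L
    if (start0 < rs || i + 1L > re) next
    if (!pure(start0, 23L)) next
    rows[[length(rows) + 1L]] <- data.frame(
      protospacer = substr(seq, i - 21L, i - 2L),
      pam = substr(seq, i - 1L, i + 1L),
      strand = "+", start = start0, end = start0 + 20L,
      source_accession = acc, source_taxon = taxon,
      stringsAsFactors = FALSE)
  }
  cc <- which(pair & chars[-n] == "C")   # plus-strand CC = minus-strand PAM GG
  for (i in cc) {
    w0 <- i - 1L                         # 0-based window start (PAM start)
    if (w0 < rs || i + 22L > re) next
    if (!pure(w0, 23L)) next
    rows[[length(rows) + 1L]] <- data.frame(
      protospacer = revcomp(substr(seq, i + 3L, i + 22L)),
      pam = revcomp(substr(seq, i, i + 2L)),
      strand = "-", start = i + 2L, end = i + 22L,
      source_accession = acc, source_taxon = taxon,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty_sites())
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.index_items <- function(x) {
  lapply(x, function(it) {
    if (inherits(it, "amplicon"))
      list(accession = it$source_accession, species = it$species,
           sequence = it$sequence)
    else
      list(accession = it$accession, species = it$species,
           sequence = it$sequence)
  })
}

#' Build an exact-match 20-mer index over a sequence set
#'
#' Indexes every 20-mer of every input sequence and of its reverse
#' complement (strand `"-"`), so that querying a protospacer finds
#' occurrences in either orientation — double-stranded DNA is cut regardless
#' of which strand carries the protospacer. 20-mers containing ambiguity
#' codes are skipped.
#'
#' @param x List of `amplicon` objects (the V4 screening scope, default in
#'   the design pipeline) or `reference_record` objects (full-sequence
#'   scope).
#' @param scope Label recorded on the index: `"amplicon"` or
#'   `"full_sequence"`.
#' @return Object of class `kmer_index`: the keyed k-mer table plus the
#'   source sequences (kept for mismatch-tolerant rescans).
#' @export
build_kmer_index <- function(x, scope = c("amplicon", "full_sequence")) {
  scope <- match.arg(scope)
  items <- .index_items(x)
  tabs <- list()
  seqs <- data.frame(accession = character(0), species = character(0),
                     sequence = character(0), stringsAsFactors = FALSE)
  for (it in items) {
    seqs <- rbind(seqs, data.frame(accession = it$accession,
                                   species = it$species,
                                   sequence = it$sequence,
                                   stringsAsFactors = FALSE))
    for (strand in c("+", "-")) {
      s <- if (strand == "+") it$sequence else revcomp(it$sequence)
      nn <- nchar(s)
      if (nn < 20L) next
      starts <- seq_len(nn - 19L)
      ks <- substring(s, starts, starts + 19L)
      ks <- ks[grepl("^[ACGT]{20}$", ks)]
      if (length(ks) == 0L) next
      tabs[[length(tabs) + 1L]] <- data.table::data.table(
        kmer = ks, accession = it$accession, species = it$species,
        strand = strand)
    }
  }
  idx <- if (length(tabs) == 0L)
    data.table::data.table(kmer = character(0), accession = character(0),
                           species = character(0), strand = character(0))
  else unique(data.table::rbindlist(tabs))
  data.table::setkeyv(idx, "kmer")
  structure(list(index = idx, sequences = seqs, scope = scope),
            class = "kmer_index")
}

#' Query a k-mer index for exact hits of a 20-mer
#'
#' @param index A `kmer_index`.
#' @param kmer A 20-nt A/C/G/T string.
#' @return data.frame of hits with columns `kmer`, `accession`, `species`,
#'   `strand` (strand of the indexed sequence on which the k-mer reads
#'   5'->3'); zero rows when absent.
#' @export
kmer_query <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  .query <- kmer  # local name so data.table does not resolve the column
  hits <- index$index[data.table::J(.query), nomatch = NULL]
  as.data.frame(hits)
}

.validate_protospacer <- function(protospacer) {
  if (!is.character(protospacer) || length(protospacer) != 1L ||
      is.na(protospacer) || nchar(protospacer) != 20L ||
      !grepl("^[ACGT]{20}$", protospacer))
    stop("protospacer must be a 20-nt A/C/G/T string", call. = FALSE)
  invisible(protospacer)
}

#' Screen a protospacer against a microeukaryote reference index
#'
#' A guide is *taxon-specific* iff its 20-nt protospacer occurs in no indexed
#' microeukaryote sequence on either strand. PAM context in the off-target
#' is deliberately not required (conservative: a partial match without PAM
#' still disqualifies the guide). With `max_mismatch > 0` an exhaustive
#' sliding-window rescan of the indexed sequences is used instead of the
#' exact index.
#'
#' @param protospacer 20-nt A/C/G/T string.
#' @param micro_index `kmer_index` over the microeukaryote side.
#' @param max_mismatch Mismatch tolerance for off-target calling (default 0,
#'   the exact-match criterion).
#' @param host_index Optional `kmer_index` over host sequences; fills the
#'   `host_hits` field.
#' @return Object of class `specificity_result` with fields `protospacer`,
#'   `host_hits` (species names), `micro_hits` (data.frame species,
#'   accession), `verdict` (`"taxon_specific"` or `"off_target_micro"`) and
#'   `max_mismatch_used`.
#' @export
screen_guide <- function(protospacer, micro_index, max_mismatch = 0L,
                         host_index = NULL) {
  .validate_protospacer(protospacer)
  stopifnot(inherits(micro_index, "kmer_index"))
  if (max_mismatch == 0L) {
    hits <- kmer_query(micro_index, protospacer)
    micro_hits <- unique(hits[, c("species", "accession")])
  } else {
    seqs <- micro_index$sequences
    hit <- logical(nrow(seqs))
    for (i in seq_len(nrow(seqs))) {
      s <- seqs$sequence[i]
      mm <- c(mismatch_profile(protospacer, s),
              mismatch_profile(protospacer, revcomp(s)))
      hit[i] <- length(mm) > 0L && min(mm) <= max_mismatch
    }
    micro_hits <- unique(seqs[hit, c("species", "accession")])
  }
  rownames(micro_hits) <- NULL
  host_hits <- character(0)
  if (!is.null(host_index))
    host_hits <- unique(kmer_query(host_index, protospacer)$species)
  structure(
    list(protospacer = protospacer,
         host_hits = host_hits,
         micro_hits = micro_hits,
         verdict = if (nrow(micro_hits) == 0L) "taxon_specific"
                   else "off_target_micro",
         max_mismatch_used = as.integer(max_mismatch)),
    class = "specificity_result"
  )
}

#' @export
print.specificity_result <- function(x, ...) {
  cat(sprintf("<specificity_result> %s: %s (%d microeukaryote hit(s), mm<=%d)\n",
              x$protospacer, x$verdict, nrow(x$micro_hits),
              x$max_mismatch_used))
  invisible(x)
}

# Count microeukaryote taxa with a near-hit (<= 1 mismatch, either strand)
# for each candidate protospacer; used as the primary ranking key.
.near_hit_counts <- function(protospacers, micro_seqs) {
  if (length(protospacers) == 0L) return(integer(0))
  if (nrow(micro_seqs) == 0L) return(rep(0L, length(protospacers)))
  both <- lapply(seq_len(nrow(micro_seqs)), function(i)
    c(micro_seqs$sequence[i], revcomp(micro_seqs$sequence[i])))
  vapply(protospacers, function(p) {
    n <- 0L
    for (i in seq_len(nrow(micro_seqs))) {
      mm <- c(mismatch_profile(p, both[[i]][1]),
              mismatch_profile(p, both[[i]][2]))
      if (length(mm) > 0L && min(mm) <= 1L) n <- n + 1L
    }
    n
  }, integer(1), USE.NAMES = FALSE)
}

default_design_params <- function(params = list()) {
  utils::modifyList(
    list(region = "interior",
         scope = "amplicon",
         max_mismatch = 0L,          # off-target screen tolerance
         primer_max_mismatch = 0L,
         min_len = 50L, max_len = 2000L,
         rank_near_hits = TRUE),
    params)
}

empty_guides <- function() {
  data.frame(protospacer = character(0), pam = character(0),
             strand = character(0), start = integer(0), end = integer(0),
             source_accessions = character(0), taxon = character(0),
             near_hits_1mm = integer(0), gc = numeric(0),
             verdict = character(0), stringsAsFactors = FALSE)
}

# Shared screen/dedup/rank tail of the two design entry points.
.screen_and_rank <- function(sites, micro_index, params) {
  if (nrow(sites) == 0L) return(empty_guides())
  protos <- unique(sites$protospacer)
  specific <- character(0)
  for (p in protos) {
    res <- screen_guide(p, micro_index, max_mismatch = params$max_mismatch)
    if (res$verdict == "taxon_specific") specific <- c(specific, p)
  }
  if (length(specific) == 0L) {
    warning("no taxon-specific guide site found", call. = FALSE)
    return(empty_guides())
  }
  rows <- lapply(specific, function(p) {
    sub <- sites[sites$protospacer == p, , drop = FALSE]
    first <- sub[which.min(sub$start), , drop = FALSE]
    data.frame(
      protospacer = p, pam = first$pam, strand = first$strand,
      start = first$start, end = first$end,
      source_accessions = paste(sort(unique(sub$source_accession)),
                                collapse = ","),
      taxon = paste(sort(unique(sub$source_taxon)), collapse = ","),
      gc = gc_fraction(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$near_hits_1mm <- if (isTRUE(params$rank_near_hits))
    .near_hit_counts(out$protospacer, micro_index$sequences)
  else rep(NA_integer_, nrow(out))
  out$verdict <- "taxon_specific"
  key <- if (isTRUE(params$rank_near_hits)) out$near_hits_1mm else 0L
  out <- out[order(key, abs(out$gc - 0.5), out$start, out$protospacer), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("protospacer", "pam", "strand", "start", "end",
          "source_accessions", "taxon", "near_hits_1mm", "gc", "verdict")]
}

#' Design taxon-specific guides for a host from its reference sequences
#'
#' The full design pipeline: extract primer-flanked amplicons from the host
#' sequences, enumerate Cas9-compatible sites in each, screen every unique
#' protospacer against the microeukaryote side of the reference partition,
#' and return only taxon-specific sites, deduplicated by protospacer with
#' source accessions aggregated. Ranking is deterministic: fewest 1-mismatch
#' microeukaryote near-hits, then GC fraction closest to 0.5, then 5'-most
#' position, then lexicographic protospacer.
#'
#' @param host_records List of `reference_record`s for the host taxon (all
#'   sequence variants).
#' @param partition A `clade_partition`; its `micro` side is the off-target
#'   reference.
#' @param primers A `primer_pair` (default the packaged `universal_V4` set).
#' @param params List of overrides merged over the defaults:
#'   `region` ("interior"), `scope` ("amplicon" screens extracted V4
#'   amplicons, "full_sequence" screens whole reference sequences),
#'   `max_mismatch` (0), `primer_max_mismatch` (0), `min_len`/`max_len`
#'   (50/2000), `rank_near_hits` (TRUE). A prebuilt `kmer_index` may be
#'   passed as `micro_index` to avoid re-indexing the reference when
#'   designing for many hosts.
#' @return Ranked data.frame of taxon-specific guides with columns
#'   `protospacer`, `pam`, `strand`, `start`, `end`, `source_accessions`,
#'   `taxon`, `near_hits_1mm`, `gc`, `verdict`. Zero rows (with a warning)
#'   when no specific site exists — a valid outcome.
#' @export
design_for_host <- function(host_records, partition,
                            primers = primer_set(), params = list()) {
  params <- default_design_params(params)
  constraints <- list(min_len = params$min_len, max_len = params$max_len,
                      max_mismatch = params$primer_max_mismatch)
  host_amps <- extract_all_amplicons(host_records, primers, constraints)
  if (length(host_amps) == 0L)
    stop("primers do not amplify host: no amplicon found with primer set '",
         primers$name, "'", call. = FALSE)
  micro_index <- if (!is.null(params$micro_index)) params$micro_index
                 else .micro_index_for(partition, primers, params, constraints)
  sites <- do.call(rbind, c(list(empty_sites()),
                            lapply(host_amps, enumerate_guide_sites,
                                   region = params$region)))
  .screen_and_rank(sites, micro_index, params)
}

.micro_index_for <- function(partition, primers, params, constraints) {
  if (identical(params$scope, "full_sequence")) {
    build_kmer_index(partition$micro, scope = "full_sequence")
  } else {
    build_kmer_index(extract_all_amplicons(partition$micro, primers,
                                           constraints),
                     scope = "amplicon")
  }
}

#' Design guides for an arbitrary gene against a background set
#'
#' Generic-gene variant of [design_for_host()]: no primer step — the whole
#' target sequence is the search region — and the background records (full
#' sequences) form the off-target index. Useful for any gene with a
#' reference set to screen against (other rRNA regions, metabolic genes, ...).
#'
#' @param target A `reference_record` holding the gene sequence.
#' @param background List of `reference_record`s to screen against (may be
#'   empty, in which case every PAM-adjacent site is returned).
#' @param params As in [design_for_host()]; `region` is forced to `"full"`.
#' @return Ranked guide data.frame, as [design_for_host()].
#' @export
design_for_gene <- function(target, background, params = list()) {
  params <- default_design_params(params)
  params$region <- "full"
  sites <- enumerate_guide_sites(target$sequence, region = "full")
  if (nrow(sites) > 0L) {
    sites$source_accession <- target$accession
    sites$source_taxon <- target$species
  }
  micro_index <- build_kmer_index(background, scope = "full_sequence")
  .screen_and_rank(sites, micro_index, params)
}
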