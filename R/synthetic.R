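# Synthetic reference generator with a planted truth table. Emulates a
# host + microeukaryote SSU reference at desk scale: every record amplifies
# with the default primer pair, each host interior carries a known number of
# planted taxon-specific target sites (absent from every microeukaryote
# record) and of shared sites (copied into a microeukaryote record), and the
# generator returns the exact truth table for recovery tests.
#
# Exact recovery is guaranteed by construction, not by luck:
#   * interiors are GG/CC-free, so the only PAM-bearing windows are the
#     planted inserts (20-mer + TGG, wrapped in A);
#   * each host's background interior is mirrored into one microeukaryote
#     record, so every non-planted host 20-mer has an off-target hit;
#   * planted specific 20-mers are verified absent (both strands) from all
#     microeukaryote records after generation.
# The guarantee holds for the default interior search region; it requires
# n_micro >= n_host (one mirror per host).

# Random A/C/G/T string with no GG or CC dinucleotide.
.gc_free_random <- function(n) {
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, n, replace = TRUE)
  repeat {
    bad <- which(s[-1] == s[-n] & s[-1] %in% c("G", "C")) + 1L
    if (length(bad) == 0L) break
    for (i in bad) s[i] <- sample(setdiff(bases, s[i - 1L]), 1L)
  }
  paste(s, collapse = "")
}

#' Generate a synthetic host + microeukaryote reference with planted sites
#'
#' Emits host and microeukaryote reference records that all amplify with the
#' given primer pair. Each host interior carries `n_specific_per_host`
#' planted Cas9-compatible sites (20-mer + TGG PAM) absent from every
#' microeukaryote record, and `n_shared` sites also present in a
#' microeukaryote record; [design_for_host()] with default parameters
#' recovers exactly the planted specific set. The same seed reproduces the
#' reference byte-identically.
#'
#' @param n_host Number of host species (one record each).
#' @param n_micro Number of microeukaryote records; must be `>= n_host`
#'   (each host background is mirrored into one microeukaryote record so
#'   that only planted sites can be taxon-specific).
#' @param seq_len Total record length in nt, primer footprints included
#'   (default 420, inside the expected 380-450 bp V4 product range).
#' @param n_specific_per_host,n_shared Planted site counts per host.
#' @param seed Integer seed.
#' @param primers A `primer_pair`; degenerate positions are instantiated to
#'   concrete bases in the templates.
#' @return List with `host` and `micro` (record lists), `truth` (named list:
#'   host species -> sorted planted specific protospacers), `shared` (named
#'   list of planted shared protospacers), `primers`, `params`.
#' @export
generate_synthetic_reference <- function(n_host = 5L, n_micro = 20L,
                                         seq_len = 420L,
                                         n_specific_per_host = 2L,
                                         n_shared = 2L, seed,
                                         primers = primer_set()) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_host < 1L) stop("n_host must be >= 1", call. = FALSE)
  if (n_micro < n_host)
    stop("n_micro must be >= n_host (one background mirror per host)",
         call. = FALSE)
  fwd <- instantiate_degenerate(primers$forward)
  rev_foot <- revcomp(instantiate_degenerate(primers$reverse))
  interior_len <- seq_len - nchar(fwd) - nchar(rev_foot)
  k <- n_specific_per_host + n_shared
  insert_len <- 25L  # "A" + 20-mer + "TGG" + "A"
  if (interior_len < 23L)
    stop("seq_len too short: interior must be at least 23 nt", call. = FALSE)
  if (k > 0L && interior_len < k * insert_len + (k + 1L) * 2L)
    stop("infeasible parameters: ", k, " planted sites do not fit in a ",
         interior_len, " nt interior", call. = FALSE)

  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  slot_starts <- if (k > 0L) {
    gap <- (interior_len - k * insert_len) %/% (k + 1L)
    vapply(base::seq_len(k), function(i) gap * i + insert_len * (i - 1L) + 1L,
           integer(1))
  } else integer(0)

  for (attempt in 1:5) {
    planted <- character(0)
    fresh_20mer <- function() {
      repeat {
        m <- .gc_free_random(20L)
        if (!(m %in% planted)) { planted <<- c(planted, m); return(m) }
      }
    }
    hosts <- list(); micros <- list()
    truth <- list(); shared_out <- list()
    for (i in base::seq_len(n_host)) {
      background <- .gc_free_random(interior_len)
      spec <- if (n_specific_per_host > 0L)
        vapply(base::seq_len(n_specific_per_host), function(j) fresh_20mer(),
               character(1)) else character(0)
      shr <- if (n_shared > 0L)
        vapply(base::seq_len(n_shared), function(j) fresh_20mer(),
               character(1)) else character(0)
      host_int <- background; micro_int <- background
      inserts <- c(spec, shr)
      for (j in seq_along(inserts)) {
        piece <- paste0("A", inserts[j], "TGG", "A")
        s <- slot_starts[j]
        substr(host_int, s, s + insert_len - 1L) <- piece
        if (j > length(spec))  # shared sites mirrored into the micro record
          substr(micro_int, s, s + insert_len - 1L) <- piece
      }
      sp_name <- paste0("Synthetic_host_", i)
      hosts[[i]] <- make_reference_record(
        sprintf("SYNH%03d", i),
        c("Eukaryota", "Animalia", paste0("SynthHostClass_", i), sp_name),
        paste0(fwd, host_int, rev_foot))
      micros[[i]] <- make_reference_record(
        sprintf("SYNM%03d", i),
        c("Eukaryota", "SAR", paste0("SynthMicroClass_", i),
          paste0("Synthetic_micro_", i)),
        paste0(fwd, micro_int, rev_foot))
      truth[[sp_name]] <- sort(spec)
      shared_out[[sp_name]] <- sort(shr)
    }
    for (i in seq.int(n_host + 1L, length.out = n_micro - n_host)) {
      micros[[i]] <- make_reference_record(
        sprintf("SYNM%03d", i),
        c("Eukaryota", "SAR", paste0("SynthMicroClass_", i),
          paste0("Synthetic_micro_", i)),
        paste0(fwd, .gc_free_random(interior_len), rev_foot))
    }

    # construction scan: planted specific 20-mers absent from every
    # microeukaryote record, both strands
    micro_seqs <- vapply(micros, function(r) r$sequence, character(1))
    ok <- TRUE
    for (spec in truth) for (m in spec) {
      if (any(grepl(m, micro_seqs, fixed = TRUE)) ||
          any(grepl(revcomp(m), micro_seqs, fixed = TRUE))) ok <- FALSE
    }
    if (ok)
      return(list(host = hosts, micro = micros, truth = truth,
                  shared = shared_out, primers = primers,
                  params = list(n_host = n_host, n_micro = n_micro,
                                seq_len = seq_len,
                                n_specific_per_host = n_specific_per_host,
                                n_shared = n_shared, seed = seed)))
  }
  stop("failed to generate a collision-free reference in 5 attempts",
       call. = FALSE)  # nocov: ~4^-20 per site per attempt
}
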