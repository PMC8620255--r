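# Per-taxon guide-site database: for every host species in a reference
# partition, the Cas9-compatible sites in its primer-flanked amplicons and
# which of them are taxon-specific (absent from all microeukaryote
# references). Keyed by species name, with accession provenance per entry;
# the same protospacer found in several host species is listed under each
# (breadth summaries need the cross-listing).

DB_FORMAT_VERSION <- 1L

empty_db_entries <- function() {
  data.frame(species = character(0), protospacer = character(0),
             pam = character(0), strand = character(0),
             source_accessions = character(0),
             compatible = logical(0), taxon_specific = logical(0),
             stringsAsFactors = FALSE)
}

#' Build a per-taxon database of guide target sites
#'
#' For each host species in the partition: extract amplicons from all its
#' sequence variants, enumerate compatible sites in the chosen region,
#' screen each unique protospacer against the microeukaryote side, and store
#' compatible / taxon-specific flags. Species whose records yield no
#' amplicon are recorded with an explicit `no_amplicon` flag.
#'
#' @param partition A `clade_partition` with at least one host record.
#' @param primers A `primer_pair`.
#' @param params Design parameters, as in [design_for_host()].
#' @param reference_label Free-text provenance label stored in the database.
#' @return Object of class `guide_database`: list with `entries` (one row
#'   per species x site), `species` (per-species summary with counts and
#'   `no_amplicon`), `params`, `reference_label`.
#' @export
build_database <- function(partition, primers = primer_set(),
                           params = list(), reference_label = "unnamed") {
  stopifnot(inherits(partition, "clade_partition"))
  if (length(partition$host) == 0L)
    stop("partition has no host records", call. = FALSE)
  params <- default_design_params(params)
  constraints <- list(min_len = params$min_len, max_len = params$max_len,
                      max_mismatch = params$primer_max_mismatch)
  micro_index <- .micro_index_for(partition, primers, params, constraints)

  species <- host_species_names(partition)
  entries <- empty_db_entries()
  summaries <- list()
  for (sp in species) {
    recs <- Filter(function(r) r$species == sp, partition$host)
    amps <- extract_all_amplicons(recs, primers, constraints)
    if (length(amps) == 0L) {
      summaries[[length(summaries) + 1L]] <- data.frame(
        species = sp, n_records = length(recs), n_amplicons = 0L,
        no_amplicon = TRUE, n_compatible = 0L, n_specific = 0L,
        stringsAsFactors = FALSE)
      message("species '", sp, "' skipped: no amplicon with primer set '",
              primers$name, "'")
      next
    }
    sites <- do.call(rbind, c(list(empty_sites()),
                              lapply(amps, enumerate_guide_sites,
                                     region = params$region)))
    n_specific <- 0L
    if (nrow(sites) > 0L) {
      for (p in unique(sites$protospacer)) {
        sub <- sites[sites$protospacer == p, , drop = FALSE]
        res <- screen_guide(p, micro_index,
                            max_mismatch = params$max_mismatch)
        is_spec <- res$verdict == "taxon_specific"
        if (is_spec) n_specific <- n_specific + 1L
        first <- sub[which.min(sub$start), , drop = FALSE]
        entries <- rbind(entries, data.frame(
          species = sp, protospacer = p, pam = first$pam,
          strand = first$strand,
          source_accessions = paste(sort(unique(sub$source_accession)),
                                    collapse = ","),
          compatible = TRUE, taxon_specific = is_spec,
          stringsAsFactors = FALSE))
      }
    }
    summaries[[length(summaries) + 1L]] <- data.frame(
      species = sp, n_records = length(recs), n_amplicons = length(amps),
      no_amplicon = FALSE,
      n_compatible = length(unique(sites$protospacer)),
      n_specific = n_specific, stringsAsFactors = FALSE)
  }
  rownames(entries) <- NULL
  structure(
    list(entries = entries,
         species = do.call(rbind, summaries),
         params = params,
         reference_label = reference_label),
    class = "guide_database"
  )
}

#' @export
print.guide_database <- function(x, ...) {
  cat(sprintf("<guide_database> '%s': %d species, %d site entries (%d taxon-specific)\n",
              x$reference_label, nrow(x$species), nrow(x$entries),
              sum(x$entries$taxon_specific)))
  invisible(x)
}

#' Coverage statistics of a guide database
#'
#' Summarizes, over host species: how many yielded an amplicon, how many
#' have at least one taxon-specific site, and the per-taxon min/mean/max of
#' compatible and taxon-specific site counts (means to 1 decimal). Because
#' "unique sites" can be counted per protospacer string or per
#' taxon-site pair, both totals are reported.
#'
#' @param db A `guide_database`.
#' @return List with `n_taxa`, `n_with_amplicon`, `n_with_specific_site`,
#'   `fraction_with_specific_site`, `compatible_sites` and `specific_sites`
#'   (each `c(min, mean, max)` over all taxa),
#'   `n_unique_specific_protospacers`, `n_specific_taxon_site_pairs`.
#' @export
coverage_stats <- function(db) {
  stopifnot(inherits(db, "guide_database"))
  if (is.null(db$species) || nrow(db$species) == 0L)
    stop("database is empty", call. = FALSE)
  sp <- db$species
  rng <- function(x) c(min = min(x), mean = round(mean(x), 1), max = max(x))
  spec <- db$entries[db$entries$taxon_specific, , drop = FALSE]
  list(
    n_taxa = nrow(sp),
    n_with_amplicon = sum(!sp$no_amplicon),
    n_with_specific_site = sum(sp$n_specific > 0L),
    fraction_with_specific_site = sum(sp$n_specific > 0L) / nrow(sp),
    compatible_sites = rng(sp$n_compatible),
    specific_sites = rng(sp$n_specific),
    n_unique_specific_protospacers = length(unique(spec$protospacer)),
    n_specific_taxon_site_pairs = nrow(spec)
  )
}

#' Taxonomic breadth of a single guide site
#'
#' Counts, at every taxonomy level, the distinct labels among host records
#' whose amplicons contain the protospacer (either strand, exact match) —
#' i.e. how broad a taxonomic group one sgRNA can cut.
#'
#' @param protospacer 20-nt A/C/G/T string.
#' @param partition A `clade_partition`.
#' @param primers A `primer_pair`.
#' @param constraints Amplicon constraints, as in [extract_amplicons()].
#' @return Object of class `breadth_summary`: list with `protospacer`,
#'   `per_level` (data.frame `level` 1-based from the root, `n_labels`),
#'   `species_count` (distinct species whose amplicons carry the site).
#' @export
breadth_summary <- function(protospacer, partition, primers = primer_set(),
                            constraints = list()) {
  .validate_protospacer(protospacer)
  rc <- revcomp(protospacer)
  hit_tax <- list()
  hit_species <- character(0)
  for (r in partition$host) {
    amps <- extract_amplicons(r, primers, constraints)
    found <- any(vapply(amps, function(a)
      grepl(protospacer, a$sequence, fixed = TRUE) ||
      grepl(rc, a$sequence, fixed = TRUE), logical(1)))
    if (found) {
      hit_tax[[length(hit_tax) + 1L]] <- r$levels
      hit_species <- c(hit_species, r$species)
    }
  }
  max_depth <- if (length(hit_tax) == 0L) 0L
               else max(vapply(hit_tax, length, integer(1)))
  per_level <- data.frame(level = seq_len(max_depth),
                          n_labels = vapply(seq_len(max_depth), function(i) {
                            labs <- unlist(lapply(hit_tax, function(lv)
                              if (length(lv) >= i) lv[i] else NULL))
                            length(unique(labs))
                          }, integer(1)))
  structure(list(protospacer = protospacer, per_level = per_level,
                 species_count = length(unique(hit_species))),
            class = "breadth_summary")
}

#' @export
print.breadth_summary <- function(x, ...) {
  cat(sprintf("<breadth_summary> %s cuts %d species\n", x$protospacer,
              x$species_count))
  if (nrow(x$per_level) > 0L)
    cat(paste(sprintf("  level %d: %d label(s)", x$per_level$level,
                      x$per_level$n_labels), collapse = "\n"), "\n")
  invisible(x)
}

#' Look up database entries by species name
#'
#' Case-insensitive exact match on the species name (or substring match with
#' `substring = TRUE`). The returned status distinguishes a species absent
#' from the database from one present with zero sites.
#'
#' @param db A `guide_database`.
#' @param name Species name to look up.
#' @param substring Match by substring instead of exact label.
#' @return List with `entries` (matching rows), `status` (`"found"`,
#'   `"no_sites"` or `"not in database"`).
#' @export
search_by_name <- function(db, name, substring = FALSE) {
  stopifnot(inherits(db, "guide_database"))
  keys <- db$species$species
  sel <- if (substring) grepl(tolower(name), tolower(keys), fixed = TRUE)
         else tolower(keys) == tolower(name)
  if (!any(sel))
    return(list(entries = empty_db_entries(), status = "not in database"))
  matched <- keys[sel]
  entries <- db$entries[db$entries$species %in% matched, , drop = FALSE]
  rownames(entries) <- NULL
  list(entries = entries,
       status = if (nrow(entries) > 0L) "found" else "no_sites")
}

#' Write a guide database to TSV with a JSON parameter sidecar
#'
#' One TSV row per guide entry, plus `<path>.params.json` carrying the
#' design parameters, the reference label, the per-species summary and the
#' format version. [read_database()] round-trips losslessly.
#'
#' @param db A `guide_database`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_database <- function(db, path) {
  stopifnot(inherits(db, "guide_database"))
  utils::write.table(db$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sidecar <- paste0(path, ".params.json")
  jsonlite::write_json(
    list(format_version = DB_FORMAT_VERSION,
         reference_label = db$reference_label,
         params = db$params,
         species = db$species),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a guide database written by [write_database()]
#'
#' @param path TSV path; `<path>.params.json` must sit beside it.
#' @return A `guide_database`.
#' @export
read_database <- function(path) {
  if (!file.exists(path))
    stop("database file '", path, "' does not exist", call. = FALSE)
  sidecar <- paste0(path, ".params.json")
  if (!file.exists(sidecar))
    stop("missing parameter sidecar '", sidecar, "'", call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$format_version) ||
      meta$format_version != DB_FORMAT_VERSION)
    stop("unsupported database format version '", meta$format_version,
         "' (expected ", DB_FORMAT_VERSION, ")", call. = FALSE)
  entries <- utils::read.delim(path, stringsAsFactors = FALSE,
                               colClasses = c(
                                 species = "character",
                                 protospacer = "character",
                                 pam = "character",
                                 strand = "character",
                                 source_accessions = "character",
                                 compatible = "logical",
                                 taxon_specific = "logical"))
  species <- as.data.frame(meta$species, stringsAsFactors = FALSE)
  structure(
    list(entries = entries, species = species,
         params = meta$params, reference_label = meta$reference_label),
    class = "guide_database"
  )
}
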