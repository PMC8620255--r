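# sgRNA template-oligo assembly: promoter + 20-nt target site + scaffold
# overlap, the DNA oligo used to transcribe the sgRNA in vitro.

#' Default sgRNA template-oligo scheme
#'
#' Loads the packaged scheme config (`inst/extdata/sgrna_scheme.json`): a T7
#' promoter appended 5' of the target site and a 14-nt scaffold-overlap
#' appended 3', matching standard T7 in-vitro sgRNA transcription kits. T7
#' transcription initiates most efficiently on G, hence the optional
#' `require_leading_g` switch.
#'
#' @param file Optional path to a JSON scheme overriding the packaged one
#'   (fields `promoter`, `overlap`, `require_leading_g`).
#' @return List with elements `promoter`, `overlap`, `require_leading_g`.
#' @export
default_sgrna_scheme <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "sgrna_scheme.json", package = "ampliguide")
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  list(promoter = toupper(cfg$promoter),
       overlap = toupper(cfg$overlap),
       require_leading_g = isTRUE(cfg$require_leading_g))
}

#' Assemble an sgRNA template oligo from a protospacer
#'
#' Concatenates `promoter + protospacer + overlap`. If
#' `scheme$require_leading_g` is set and the protospacer does not start with
#' G, a single G is prepended to the protospacer segment (and
#' `leading_g_added` records it), so the T7 transcript starts with G.
#'
#' @param protospacer 20-nt A/C/G/T string.
#' @param scheme Scheme list as returned by [default_sgrna_scheme()].
#' @return Object of class `sgrna_oligo`: list with `protospacer`,
#'   `promoter`, `overlap`, `oligo`, `leading_g_added`.
#' @export
build_sgrna_template <- function(protospacer, scheme = default_sgrna_scheme()) {
  .validate_protospacer(protospacer)
  .validate_iupac(scheme$promoter, "promoter")
  .validate_iupac(scheme$overlap, "overlap")
  spacer_segment <- protospacer
  leading_g_added <- FALSE
  if (isTRUE(scheme$require_leading_g) &&
      substr(protospacer, 1L, 1L) != "G") {
    spacer_segment <- paste0("G", protospacer)
    leading_g_added <- TRUE
  }
  structure(
    list(protospacer = protospacer,
         promoter = scheme$promoter,
         overlap = scheme$overlap,
         oligo = paste0(scheme$promoter, spacer_segment, scheme$overlap),
         leading_g_added = leading_g_added),
    class = "sgrna_oligo"
  )
}

#' @export
print.sgrna_oligo <- function(x, ...) {
  cat(sprintf("<sgrna_oligo> %d nt%s\n  %s\n", nchar(x$oligo),
              if (x$leading_g_added) " (leading G added)" else "", x$oligo))
  invisible(x)
}
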