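# Small in-code fixtures shared across test files.

toy_primers <- function() primer_pair("toy", "ACCGTAGCTAGGATCA", "GTACCGATTGCAGTCA")

# Record whose plus strand is exactly fwd + interior + revcomp(rev).
toy_record <- function(interior, primers = toy_primers(),
                       accession = "X1",
                       taxonomy = c("Eukaryota", "Testia", "Testus examplei")) {
  reference_record(accession, taxonomy,
                   paste0(primers$forward, interior, revcomp(primers$reverse)))
}

write_fasta_text <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
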