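---
title: "Taxon-specific Cas9 guide design and host-amplicon depletion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taxon-specific Cas9 guide design and host-amplicon depletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliguide)
```

## The problem

18S rRNA metabarcoding of a host-associated eukaryotic microbiome has a
dominant-template problem: "universal" eukaryotic V4 primers amplify the
host's 18S along with everything else, and because host tissue vastly
outnumbers its protistan and fungal associates, most sequencing reads are
host. One remedy is to cleave the host's amplifiable template with
CRISPR-Cas9 before (and between) PCR rounds, using a single-guide RNA whose
20-nt guide sequence occurs in the host's V4 amplicon but in no
microeukaryote's. Cut templates lose a primer footprint, cannot re-amplify,
and the short cut pieces are removed by SPRI bead size selection, so the
library that reaches the sequencer is depleted of host and enriched for the
microbial eukaryotes of interest.

`ampliguide` implements the computational side of this workflow:

1. **Reference handling** — SILVA-style SSU FASTA with semicolon taxonomy
   paths, partitioned into a host clade (metazoa + land plants by default)
   and microeukaryotes.
2. **In-silico PCR** — degenerate-primer matching on both strands and
   extraction of primer-flanked amplicons, oriented forward-primer →
   reverse-primer.
3. **Guide design** — enumeration of SpCas9-compatible sites (20-mer + NGG
   PAM, either strand), exact 20-mer screening against the microeukaryote
   reference, deterministic ranking, and sgRNA template-oligo assembly.
4. **Per-taxon database** — compatible and taxon-specific site catalogs per
   host species, with coverage and taxonomic-breadth statistics.
5. **Depletion simulation** — a stochastic model of the two-round
   cut / PCR / size-selection procedure on a mock community.

## The guide-design model

For SpCas9, a cleavable site is a 20-nt protospacer whose 3' end abuts an
NGG protospacer-adjacent motif (PAM) on the same strand. `ampliguide`
enumerates every such 23-nt window on both strands of the amplicon and
skips windows containing IUPAC ambiguity codes: a guide has to be
synthesizable, and an ambiguous base in a reference is missing data, not
biology.

A candidate is called **taxon-specific** when its 20-mer occurs — on either
strand, since double-stranded DNA is cut regardless of which strand the
protospacer sits on — in no microeukaryote reference sequence. Three
deliberate conservatisms:

* **Exact matching** (`max_mismatch = 0`) is the default criterion; a
  tolerance up to 3 mismatches is exposed for sensitivity analysis, since
  Cas9 tolerates some mismatches, particularly PAM-distal ones.
* **No PAM requirement in the off-target**: a microeukaryote 20-mer match
  disqualifies a guide even without an adjacent NGG. This errs toward
  protecting microbial taxa from accidental cutting.
* **Ambiguity codes in the subject never match** a primer or guide base.

The default search region is the **amplicon interior**, with both primer
footprints excluded: footprints are near-universal by construction (the
primers bind them in all eukaryotes), so sites there would rarely pass
screening, and a cut must fall between the primer-extension start points to
abolish amplification. `region = "full"` is available for parity checks.

Screening scope defaults to extracted microeukaryote **amplicons** (the V4
search space that the sequencing assay sees); `scope = "full_sequence"`
screens whole reference sequences instead, relevant when the first cut acts
on genomic DNA.

Ranking has no field-standard answer, so the package uses a deterministic,
documented order: fewest microeukaryote taxa with a 1-mismatch near-hit
(fewer near-neighbours means more margin for Cas9's mismatch tolerance),
then GC fraction closest to 0.5 (extreme-GC guides tend to perform poorly),
then 5'-most position, then lexicographic protospacer as the final
tie-break.

Identical protospacers found in several host species are stored under each
species in the database; taxonomic breadth summaries (how many species,
genera, classes one guide can cut) rely on that cross-listing.

## Primers and oligos

The packaged default primer set `universal_V4` is the widely used
eukaryotic 18S V4 pair TAReuk454FWD1 (`CCAGCASCYGCGGTAATTCC`) / TAReukREV3
(`ACTTTCGTTCTTGATYRA`), which yields ~380–450 bp products; an alternative
V4 pair is included, and any pair can be supplied as a TSV. Primer matching
allows the primer's degenerate codes their full base sets and defaults to
zero additional mismatches: real PCR tolerates some, but exact degenerate
matching is the reproducible in-silico proxy, and the tolerance is a
parameter. When a primer pair matches a reference more than once, each
forward hit is paired with its nearest downstream reverse footprint (the
innermost product, which dominates PCR kinetics) and the amplicons carry an
`n_products` flag.

Template oligos for T7 in-vitro sgRNA transcription are assembled as
`promoter + protospacer + 14-nt scaffold overlap`. The promoter and overlap
strings are configuration (`inst/extdata/sgrna_scheme.json`), shipped with
the standard T7/scaffold constants; `require_leading_g` optionally prepends
a G when the protospacer lacks one, since T7 initiates most efficiently
on G.

## The depletion model

`simulate_ccsas()` models each round as: every intact molecule of a member
whose amplicon contains at least one supplied guide site is cut
independently with probability `efficiency`; cut molecules lose a primer
footprint, cannot re-amplify, and their fragments (blunt cut 3 nt 5' of the
PAM, the standard SpCas9 convention, configurable) fall below the SPRI
threshold for V4-scale amplicons, so cut molecules leave the library.
Members without a guide match pass through unchanged. PCR between rounds is
treated as composition-preserving — amplification bias is explicitly out of
model. The residual host fraction after `r` rounds therefore concentrates
around the closed form `(1 − efficiency)^r`, and the simulator reports both
the observed and the closed-form value.

Defaults are fixed once as the workflow's study conditions: `efficiency =
0.97` (single-round residual 3%, at the midpoint of typical observed
single-round residuals of a few percent — a calibration, not ground truth),
`rounds = 2`, `cut_offset = 3`, `size_threshold = 300` bp (the 0.8:1
bead:DNA SPRI cutoff; the gentler 1:1 cleanup used for uncut libraries
corresponds to ~200 bp).

## The synthetic reference generator

Reference-scale guide databases depend on a multi-gigabyte SSU download, so
the test bed is a generator that emulates the structure of such a reference
at desk scale while making the right answer *provable*:

* every record is `forward-footprint + interior + reverse-footprint`, so
  all records amplify;
* interiors are GG/CC-dinucleotide-free, so the **only** PAM-bearing
  windows are the planted inserts (`A` + 20-mer + `TGG` + `A`);
* each host's background interior is mirrored into one microeukaryote
  record, so every non-planted host 20-mer has an off-target hit and can
  never be reported as specific (this requires `n_micro >= n_host`);
* planted *specific* 20-mers are verified absent from all microeukaryote
  records on both strands after generation; planted *shared* 20-mers are
  copied into the mirror record and must screen as off-target.

Defaults are 5 host species, 20 microeukaryote records, 420 nt records
(within the expected V4 product range), 2 specific + 2 shared sites per
host. The generator is seed-deterministic down to the FASTA bytes.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: realistic 18S sequence composition and
conservation structure (real V4 regions share most of their 20-mers across
taxa, so real specific sites are much rarer than planted ones), intra-species
sequence variants, ambiguity codes from real base callers, taxonomies with
uneven depth and synonymy, chimeras and database mislabels, and any wet-lab
effect (cut-efficiency variation between guides, PCR bias, bead-cleanup
losses). The planted-truth tests certify the algorithmic pipeline, not
field performance on any particular organism.

## Numerical and design choices

* Coordinates are 0-based half-open throughout the guide/cut layer; cut
  coordinates are boundaries (a cut at `c` splits `[0, c)` / `[c, len)`).
* All randomized stages take explicit seeds and restore the caller's RNG
  state.
* `sort()`-sensitive outputs are ordered by numeric position and fixed
  strand order (`+` before `-`), never by locale.
* The per-taxon database serializes as TSV plus a JSON parameter sidecar
  with a format version; reading verifies the version.
* Degenerate cases are defined, not accidental: empty FASTA → empty list;
  primers absent → empty amplicon list; no specific guide → empty,
  warned-about result (a genuine biological outcome: a host whose V4 is
  shared verbatim with a protist has no specific site); a mock-community
  member the primers do not amplify is excluded with a warning.

Problem sizes used in the shipped tests (200 random amplicons for the
enumeration oracle, 50 generator replicates for exact recovery, 100,000
host molecules and 20 replicates per efficiency for the depletion closed
form) were chosen as the smallest sizes at which the binomial error bands
are tight enough to be meaningful.

## A worked example

```{r example}
ref <- generate_synthetic_reference(seed = 42)
part <- clade_partition(c(ref$host, ref$micro))
guides <- design_for_host(list(ref$host[[1]]), part, ref$primers)
guides[, c("protospacer", "pam", "strand", "start", "near_hits_1mm", "gc")]

build_sgrna_template(guides$protospacer[1])

db <- build_database(part, ref$primers, reference_label = "synthetic demo")
unlist(coverage_stats(db)[c("n_taxa", "n_with_specific_site",
                            "fraction_with_specific_site")])

comm <- mock_community(
  taxon = c(ref$host[[1]]$species, ref$micro[[8]]$species),
  template = c(ref$host[[1]]$sequence, ref$micro[[8]]$sequence),
  molecules = c(100000L, 5000L), is_host = c(TRUE, FALSE))
simulate_ccsas(comm, guides$protospacer, cut_model(), ref$primers, seed = 7)
```

## Known limitations

* No guide-activity scoring (no on-target efficiency models) and no
  chromatin or RNA secondary-structure effects; ranking is a
  specificity-margin heuristic.
* Exact-match screening against a finite reference cannot rule out cutting
  of taxa missing from that reference.
* The depletion model is per-molecule Bernoulli with a shared efficiency;
  real cut efficiency differs between guides, between genomic DNA and
  amplicons, and with Cas9:sgRNA stoichiometry.
* No sequencing-read simulation, chimera formation, or blocking-primer
  competition modeling.
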