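test_that("enumerate_guide_sites obeys the PAM rule on forced constructions", {
  s <- enumerate_guide_sites(paste0(strrep("A", 20), "TGG"), region = "full")
  expect_identical(nrow(s), 1L)
  expect_identical(s$strand, "+")
  expect_identical(s$protospacer, strrep("A", 20))
  expect_identical(s$pam, "TGG")
  expect_identical(c(s$start, s$end), c(0L, 20L))

  s <- enumerate_guide_sites(paste0("CCA", strrep("T", 20)), region = "full")
  expect_identical(nrow(s), 1L)
  expect_identical(s$strand, "-")
  expect_identical(s$protospacer, strrep("A", 20))
  expect_identical(c(s$start, s$end), c(3L, 23L))

  expect_identical(nrow(enumerate_guide_sites(strrep("A", 100),
                                              region = "full")), 0L)
  # ambiguous windows are skipped entirely
  with_n <- paste0(strrep("A", 10), "N", strrep("A", 9), "TGG")
  expect_identical(nrow(enumerate_guide_sites(with_n, region = "full")), 0L)
})

test_that("enumeration equals the sliding-window oracle, full and interior", {
  set.seed(808)
  for (rep in 1:20) {
    seq <- random_dna(400)
    got <- enumerate_guide_sites(seq, region = "full")
    exp <- oracle_sites(seq)
    expect_identical(got[, names(exp)], exp)
  }
  # interior region excludes windows touching the primer footprints
  P <- toy_primers()
  for (rep in 1:10) {
    rec <- toy_record(random_dna(200), P)
    a <- extract_amplicons(rec, P)[[1]]
    got <- enumerate_guide_sites(a, region = "interior")
    exp <- oracle_sites(a$sequence, a$interior[1], a$interior[2])
    expect_identical(got[, names(exp)], exp)
  }
})

test_that("kmer index contains both strands and matches a substring-scan oracle", {
  P <- toy_primers()
  amp23 <- structure(list(source_accession = "A1", species = "sp",
                          sequence = paste0(strrep("A", 10), "CGTACGTACGTAC"),
                          interior = c(0L, 23L)), class = "amplicon")
  idx <- build_kmer_index(list(amp23))
  # 4 plus-strand windows + their reverse complements
  expect_setequal(unique(idx$index$strand), c("-", "+"))
  expect_identical(nrow(unique(idx$index[, "kmer"])), 8L)

  empty <- build_kmer_index(list())
  expect_identical(nrow(kmer_query(empty, strrep("A", 20))), 0L)

  set.seed(909)
  ref <- generate_synthetic_reference(seed = 11)
  amps <- unlist(lapply(ref$micro, extract_amplicons, primers = ref$primers),
                 recursive = FALSE)
  idx <- build_kmer_index(amps)
  seqs <- vapply(amps, `[[`, character(1), "sequence")
  for (i in 1:100) {
    probe <- if (i %% 2 == 0) random_protospacer()
             else { s <- sample(seqs, 1); o <- sample(nchar(s) - 19L, 1)
                    substr(s, o, o + 19L) }
    expect_identical(nrow(kmer_query(idx, probe)) > 0L,
                     oracle_occurs(probe, seqs))
  }
})

test_that("querying a k-mer and its revcomp gives strand-mirrored results", {
  ref <- generate_synthetic_reference(seed = 12)
  amps <- unlist(lapply(ref$micro[1:5], extract_amplicons,
                        primers = ref$primers), recursive = FALSE)
  idx <- build_kmer_index(amps)
  set.seed(13)
  s <- amps[[2]]$sequence
  probe <- substr(s, 40, 59)
  fwd <- kmer_query(idx, probe)
  rev <- kmer_query(idx, revcomp(probe))
  expect_identical(nrow(fwd), nrow(rev))
  key <- function(df) df[order(df$accession, df$strand),
                         c("accession", "species")]
  expect_identical(key(fwd), key(rev))
  flip <- c("+" = "-", "-" = "+")
  expect_setequal(paste(fwd$accession, fwd$strand),
                  paste(rev$accession, flip[rev$strand]))
})

test_that("screen_guide calls off-targets on either strand, exact or 1-mm", {
  p <- random_protospacer()
  empty <- build_kmer_index(list())
  expect_identical(screen_guide(p, empty)$verdict, "taxon_specific")

  holder <- function(seq) structure(
    list(source_accession = "M1", species = "Protistus x", sequence = seq,
         interior = c(0L, nchar(seq))), class = "amplicon")
  set.seed(14)
  p <- random_protospacer()
  verbatim <- build_kmer_index(list(holder(paste0(random_dna(30), p,
                                                  random_dna(30)))))
  res <- screen_guide(p, verbatim)
  expect_identical(res$verdict, "off_target_micro")
  expect_identical(res$micro_hits$species, "Protistus x")

  rc_only <- build_kmer_index(list(holder(paste0(random_dna(30), revcomp(p),
                                                 random_dna(30)))))
  expect_identical(screen_guide(p, rc_only)$verdict, "off_target_micro")

  # 1-mismatch neighbour: invisible at mm=0, caught at mm=1
  near <- p
  substr(near, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                  substr(p, 10, 10))[1]
  near_idx <- build_kmer_index(list(holder(paste0(random_dna(10), near,
                                                  random_dna(10)))))
  expect_identical(screen_guide(p, near_idx, max_mismatch = 0L)$verdict,
                   "taxon_specific")
  expect_identical(screen_guide(p, near_idx, max_mismatch = 1L)$verdict,
                   "off_target_micro")

  expect_error(screen_guide("ACGT", empty), "20-nt")
  expect_error(screen_guide(paste0(strrep("A", 19), "N"), empty), "20-nt")
})

test_that("design_for_host recovers planted guides and handles degenerate cases", {
  ref <- generate_synthetic_reference(seed = 21)
  part <- clade_partition(c(ref$host, ref$micro))
  h <- ref$host[[1]]
  g <- design_for_host(list(h), part, ref$primers)
  expect_identical(sort(g$protospacer), ref$truth[[h$species]])
  expect_true(all(g$verdict == "taxon_specific"))

  # host identical to a protist: nothing can be specific
  twin_part <- structure(list(host = list(h),
                              micro = list(reference_record(
                                "M0", c("Eukaryota", "SAR", "Twin sp"),
                                h$sequence)),
                              selector = "Animalia", n_dropped = 0L),
                         class = "clade_partition")
  expect_warning(g0 <- design_for_host(list(h), twin_part, ref$primers),
                 "no taxon-specific")
  expect_identical(nrow(g0), 0L)

  # two host sequence variants sharing a site: one row, accessions aggregated
  h2 <- reference_record("SYNH901", h$levels, h$sequence)
  g2 <- design_for_host(list(h, h2), part, ref$primers)
  expect_identical(sort(g2$protospacer), ref$truth[[h$species]])
  expect_true(all(g2$source_accessions ==
                  paste(sort(c(h$accession, "SYNH901")), collapse = ",")))

  # primers that do not amplify the host
  expect_error(design_for_host(list(toy_record(random_dna(100))), part,
                               ref$primers),
               "do not amplify")
})

test_that("design ranking is deterministic and ordered by near-hits then GC", {
  ref <- generate_synthetic_reference(seed = 22)
  part <- clade_partition(c(ref$host, ref$micro))
  g1 <- design_for_host(list(ref$host[[2]]), part, ref$primers)
  g2 <- design_for_host(list(ref$host[[2]]), part, ref$primers)
  expect_identical(g1, g2)
  expect_true(all(diff(g1$near_hits_1mm) >= 0))
})

test_that("design_for_gene screens against a background without a primer step", {
  set.seed(23)
  target <- reference_record("GENE1", c("Eukaryota", "Hostia", "Hostus x"),
                             random_dna(1000))
  # background containing the target itself: every site self-hits
  expect_warning(g_self <- design_for_gene(target, list(target)),
                 "no taxon-specific")
  expect_identical(nrow(g_self), 0L)

  # empty background: all PAM-adjacent sites are returned
  g_all <- design_for_gene(target, list())
  expect_identical(sort(unique(g_all$protospacer)),
                   sort(unique(oracle_sites(target$sequence)$protospacer)))

  # seeded target + 10 background records: equals enumerate + scan oracle
  bg <- lapply(1:10, function(i)
    reference_record(paste0("BG", i), c("Eukaryota", "Backgroundia",
                                        paste0("Back sp", i)),
                     random_dna(800)))
  g <- design_for_gene(target, bg)
  bg_seqs <- vapply(bg, `[[`, character(1), "sequence")
  exp <- unique(oracle_sites(target$sequence)$protospacer)
  exp <- exp[!vapply(exp, oracle_occurs, logical(1), seqs = bg_seqs)]
  expect_setequal(g$protospacer, exp)
})

test_that("emitted sites re-extract correctly and design is strand-closed", {
  ref <- generate_synthetic_reference(seed = 24)
  part <- clade_partition(c(ref$host, ref$micro))
  for (h in ref$host[1:3]) {
    amps <- extract_amplicons(h, ref$primers)
    sites <- enumerate_guide_sites(amps[[1]], region = "interior")
    for (k in seq_len(nrow(sites))) {
      s <- sites[k, ]
      seq <- amps[[1]]$sequence
      if (s$strand == "+") {
        expect_identical(substr(seq, s$start + 1, s$end), s$protospacer)
        expect_identical(substr(seq, s$end + 1, s$end + 3), s$pam)
      } else {
        expect_identical(revcomp(substr(seq, s$start + 1, s$end)),
                         s$protospacer)
        expect_identical(revcomp(substr(seq, s$start - 2, s$start)), s$pam)
      }
      expect_identical(substr(s$pam, 2, 3), "GG")
    }
    # designing on the reverse complement yields the same protospacer multiset
    g_fwd <- design_for_host(list(h), part, ref$primers)
    h_rc <- reference_record(h$accession, h$levels, revcomp(h$sequence))
    g_rc <- design_for_host(list(h_rc), part, ref$primers)
    expect_identical(sort(g_fwd$protospacer), sort(g_rc$protospacer))
  }
})

test_that("sgRNA template oligos assemble and decompose per the scheme", {
  scheme <- default_sgrna_scheme()
  expect_identical(nchar(scheme$overlap), 14L)

  g_start <- paste0("G", random_protospacer())
  g_start <- substr(g_start, 1, 20)
  o <- build_sgrna_template(g_start, utils::modifyList(scheme,
                                                       list(require_leading_g = TRUE)))
  expect_false(o$leading_g_added)
  expect_identical(nchar(o$oligo), nchar(scheme$promoter) + 20L + 14L)

  aaa <- strrep("A", 20)
  o2 <- build_sgrna_template(aaa, utils::modifyList(scheme,
                                                    list(require_leading_g = TRUE)))
  expect_true(o2$leading_g_added)
  expect_identical(o2$oligo, paste0(scheme$promoter, "G", aaa, scheme$overlap))

  expect_error(build_sgrna_template(strrep("A", 19)), "20-nt")
})
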