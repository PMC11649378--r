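test_that("parsing assembles transcripts and applies the error contracts", {
  lines <- c(
    gff_header(),
    gff_gene("chr1", "+", "g1",
             list(t1 = list(exons = iv(1, 100, 201, 300),
                            cds = iv(1, 100, 201, 300)),
                  t2 = list(exons = iv(1, 100), cds = iv(1, 100)))),
    gff_row("chr1", "CDS", 900, 950, "+", "orphan.c1", "missing_tx",
            phase = "0")
  )
  f <- write_gff_fixture(lines)
  expect_warning(genes <- parse_annotations(f), "unresolvable Parent")
  expect_length(genes, 1L)
  expect_length(genes[["g1"]]$transcripts, 2L)
  tx <- genes[["g1"]]$transcripts[["t1"]]
  expect_equal(nrow(tx$exons), 2L)
  expect_equal(nrow(tx$cds), 2L)
  expect_error(suppressWarnings(parse_annotations(tempfile())))
})

test_that("CDS-only annotations are supported via cds_as_exons", {
  lines <- c(
    gff_header(),
    gff_row("chr1", "gene", 1, 300, "+", "g1"),
    gff_row("chr1", "mRNA", 1, 300, "+", "t1", "g1"),
    gff_row("chr1", "CDS", 1, 100, "+", "t1.c1", "t1", phase = "0"),
    gff_row("chr1", "CDS", 201, 300, "+", "t1.c2", "t1", phase = "0")
  )
  f <- write_gff_fixture(lines)
  expect_length(parse_annotations(f), 0L)  # no exon rows, flag off
  genes <- parse_annotations(f, cds_as_exons = TRUE)
  rec <- compute_gene_record(trim_to_cds(select_canonical(genes[[1]])))
  expect_equal(rec$intron_ratio, 0.5)
})

test_that("canonical selection maximizes total CDS with a deterministic tie-break", {
  fx <- crafted_fixtures()
  rec <- extract_single_record(fx$canonical_max)
  expect_record_matches(rec, fx$canonical_max$expect)

  # tie: both file orders give the lexicographically smallest id
  tie <- fx$canonical_tie
  rec1 <- extract_single_record(tie)
  expect_equal(rec1$transcript_id, "tA")
  expect_record_matches(rec1, tie$expect)
  flipped <- tie
  flipped$lines <- gff_gene("chr1", "+", "g6",
                            list(tA = list(exons = iv(1, 100, 201, 300),
                                           cds = iv(1, 100, 201, 300)),
                                 tB = list(exons = iv(1, 200),
                                           cds = iv(1, 200))))
  rec2 <- extract_single_record(flipped)
  expect_equal(rec2$transcript_id, "tA")
  expect_equal(rec2$intron_ratio, rec1$intron_ratio)
})

test_that("trimming, intron inference and record arithmetic match hand computation", {
  fx <- crafted_fixtures()
  for (nm in names(fx)) {
    expect_record_matches(extract_single_record(fx[[nm]]), fx[[nm]]$expect)
  }
})

test_that("zero-gap adjacent exons emit no intron but warn", {
  tx <- transcript_model("t", "g", "chr1", "+",
                         exons = iv(1, 100, 101, 200),
                         cds = iv(1, 100, 101, 200))
  expect_warning(introns <- infer_introns(tx), "zero gap")
  expect_equal(nrow(introns), 0L)
})

test_that("reverse-strand mirrored genes yield identical feature values", {
  fx <- crafted_fixtures()
  plus <- extract_single_record(fx$two_exon)
  minus <- extract_single_record(fx$minus_strand)
  for (field in c("n_introns", "total_intron_len", "total_exon_len",
                  "intron_ratio", "intronless")) {
    expect_equal(minus[[field]], plus[[field]])
  }
})

test_that("species summaries follow the stated conventions", {
  recs <- list(
    a = structure(list(gene_id = "a", transcript_id = "a.t", n_introns = 1L,
                       intron_lengths = 100, total_intron_len = 100,
                       total_exon_len = 200, intron_ratio = 0.5,
                       intronless = FALSE), class = "gene_record"),
    b = structure(list(gene_id = "b", transcript_id = "b.t", n_introns = 0L,
                       intron_lengths = numeric(0), total_intron_len = 0,
                       total_exon_len = 300, intron_ratio = 0,
                       intronless = TRUE), class = "gene_record")
  )
  s <- summarize_species(recs, genome_size = 1e4)
  expect_equal(s$mean_intron_ratio, 0.25)   # intronless genes count as 0
  expect_equal(s$fraction_intronless, 0.5)
  expect_equal(s$log10_mean_intron_ratio, log10(0.25))

  # pooled (not per-gene-mean) intron length: {100} and {300, 500} -> 300
  recs$b$intron_lengths <- c(300, 500)
  recs$b$n_introns <- 2L
  recs$b$intronless <- FALSE
  expect_equal(summarize_species(recs)$mean_intron_len, 300)

  # no introns genome-wide: flagged missing
  recs2 <- recs["a"]
  recs2$a$intron_lengths <- numeric(0)
  expect_true(is.na(summarize_species(recs2)$mean_intron_len))
})

test_that("genome size sums sequence-region headers and rejects ambiguity", {
  f <- write_gff_fixture(gff_header(list(c("chr1", 1, 1000),
                                         c("chr2", 1, 500))))
  expect_equal(genome_size_from_headers(f), 1500)
  f2 <- write_gff_fixture(c("##gff-version 3",
                            "##sequence-region chr1 1 2000"))
  expect_equal(genome_size_from_headers(f2), 2000)
  f3 <- write_gff_fixture(gff_header(list(c("chr1", 1, 10),
                                          c("chr1", 1, 20))))
  expect_error(genome_size_from_headers(f3), "duplicated")
  f4 <- write_gff_fixture("##gff-version 3")
  expect_error(genome_size_from_headers(f4), "sequence-region")
})

test_that("extraction round-trips the synthetic generator exactly", {
  set.seed(7)
  spec <- genome_spec(n_genes = 120, intronless_fraction = 0.15,
                      utr_prob = 0.4, alt_transcript_prob = 0.3, n_seqs = 2,
                      species_id = "rt")
  sim <- simulate_genome(spec)
  f <- tempfile(fileext = ".gff3")
  write_genome(sim, f)
  gs <- extract_gene_structures(f, "rt")
  expect_equal(nrow(gs$table), 120L)
  expect_equal(gs$summary$mean_intron_ratio, sim$truth$mean_intron_ratio)
  expect_equal(gs$summary$mean_intron_len, sim$truth$mean_intron_len)
  expect_equal(gs$summary$fraction_intronless, sim$truth$fraction_intronless)
  expect_equal(gs$summary$genome_size, sim$truth$genome_size)

  # span identity: exon + intron totals equal the trimmed gene span
  genes <- parse_annotations(f)
  for (g in genes) {
    tx <- trim_to_cds(select_canonical(g))
    rec <- compute_gene_record(tx)
    span <- max(tx$exons[, 2]) - min(tx$exons[, 1]) + 1
    expect_equal(rec$total_exon_len + rec$total_intron_len, span)
  }
  unlink(f)
})

test_that("distribution exports honor the intronless flag", {
  set.seed(8)
  sim <- simulate_genome(genome_spec(n_genes = 60, intronless_fraction = 0.5,
                                     species_id = "d"))
  with_il <- feature_distribution(sim$records, "intron_ratio", TRUE)
  no_il <- feature_distribution(sim$records, "intron_ratio", FALSE)
  expect_equal(length(with_il), 60L)
  expect_equal(sum(with_il == 0), 60L - length(no_il))
  expect_true(all(no_il > 0))
})
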