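# Crafted GFF3 fixtures with hand-computed gene-structure records, plus
# small helpers shared across tests.

gff_header <- function(regions = list(c("chr1", 1, 5000))) {
  c("##gff-version 3",
    vapply(regions, function(r) {
      sprintf("##sequence-region %s %d %d", r[[1]],
              as.integer(r[[2]]), as.integer(r[[3]]))
    }, ""))
}

gff_row <- function(seq, type, start, end, strand, id, parent = NULL,
                    phase = ".") {
  attrs <- paste0("ID=", id)
  if (!is.null(parent)) attrs <- paste0(attrs, ";Parent=", parent)
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t%s\t%s",
          seq, type, as.integer(start), as.integer(end), strand, phase, attrs)
}

# one transcript's worth of rows
gff_tx <- function(seq, strand, gid, tid, exons, cds) {
  span <- range(c(exons, cds))
  c(gff_row(seq, "mRNA", span[1], span[2], strand, tid, gid),
    unlist(lapply(seq_len(nrow(exons)), function(i) {
      gff_row(seq, "exon", exons[i, 1], exons[i, 2], strand,
              paste0(tid, ".e", i), tid)
    })),
    unlist(lapply(seq_len(nrow(cds)), function(i) {
      gff_row(seq, "CDS", cds[i, 1], cds[i, 2], strand,
              paste0(tid, ".c", i), tid, phase = "0")
    })))
}

gff_gene <- function(seq, strand, gid, txs) {
  spans <- lapply(txs, function(tx) range(c(tx$exons, tx$cds)))
  span <- range(unlist(spans))
  c(gff_row(seq, "gene", span[1], span[2], strand, gid),
    unlist(lapply(names(txs), function(tid) {
      gff_tx(seq, strand, gid, tid, txs[[tid]]$exons, txs[[tid]]$cds)
    })))
}

write_gff_fixture <- function(lines) {
  f <- tempfile(fileext = ".gff3")
  writeLines(lines, f)
  f
}

iv <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)

# The hand-computed fixture catalogue: each entry carries GFF3 body lines
# (one gene) and the expected canonical gene record after trimming.
crafted_fixtures <- function() {
  list(
    two_exon = list(
      lines = gff_gene("chr1", "+", "g1",
                       list(t1 = list(exons = iv(1, 100, 201, 300),
                                      cds = iv(1, 100, 201, 300)))),
      expect = list(n_introns = 1, total_intron_len = 100,
                    total_exon_len = 200, intron_ratio = 0.5,
                    intronless = FALSE)
    ),
    single_exon = list(
      lines = gff_gene("chr1", "+", "g2",
                       list(t1 = list(exons = iv(401, 700),
                                      cds = iv(401, 700)))),
      expect = list(n_introns = 0, total_intron_len = 0,
                    total_exon_len = 300, intron_ratio = 0,
                    intronless = TRUE)
    ),
    # trimming removes the first exon and clips the terminal ones:
    # exons (250,300),(401,450); intron (301,400)
    utr_trim = list(
      lines = gff_gene("chr1", "+", "g3",
                       list(t1 = list(exons = iv(1, 100, 201, 300, 401, 500),
                                      cds = iv(250, 300, 401, 450)))),
      expect = list(n_introns = 1, total_intron_len = 100,
                    total_exon_len = 101, intron_ratio = 100 / 101,
                    intronless = FALSE)
    ),
    clip_single = list(
      lines = gff_gene("chr1", "+", "g4",
                       list(t1 = list(exons = iv(1, 500),
                                      cds = iv(100, 400)))),
      expect = list(n_introns = 0, total_intron_len = 0,
                    total_exon_len = 301, intron_ratio = 0,
                    intronless = TRUE)
    ),
    # canonical = transcript with maximal total CDS (300 beats 150)
    canonical_max = list(
      lines = gff_gene("chr1", "+", "g5",
                       list(tA = list(exons = iv(1, 100, 201, 400),
                                      cds = iv(1, 100, 201, 400)),
                            tB = list(exons = iv(1, 150),
                                      cds = iv(1, 150)))),
      expect = list(n_introns = 1, total_intron_len = 100,
                    total_exon_len = 300, intron_ratio = 1 / 3,
                    intronless = FALSE)
    ),
    # CDS tie 200 vs 200: lexicographically smallest transcript id wins
    canonical_tie = list(
      lines = gff_gene("chr1", "+", "g6",
                       list(tB = list(exons = iv(1, 200),
                                      cds = iv(1, 200)),
                            tA = list(exons = iv(1, 100, 201, 300),
                                      cds = iv(1, 100, 201, 300)))),
      expect = list(n_introns = 1, total_intron_len = 100,
                    total_exon_len = 200, intron_ratio = 0.5,
                    intronless = FALSE)
    ),
    # reverse strand, mirrored coordinates of two_exon
    minus_strand = list(
      lines = gff_gene("chr1", "-", "g7",
                       list(t1 = list(exons = iv(701, 800, 901, 1000),
                                      cds = iv(701, 800, 901, 1000)))),
      expect = list(n_introns = 1, total_intron_len = 100,
                    total_exon_len = 200, intron_ratio = 0.5,
                    intronless = FALSE)
    ),
    # three exons with gaps of 1 and 19
    tiny_gaps = list(
      lines = gff_gene("chr1", "+", "g8",
                       list(t1 = list(exons = iv(1, 10, 12, 20, 40, 50),
                                      cds = iv(1, 10, 12, 20, 40, 50)))),
      expect = list(n_introns = 2, total_intron_len = 20,
                    total_exon_len = 30, intron_ratio = 2 / 3,
                    intronless = FALSE)
    ),
    # transcript without CDS is dropped; the one with CDS is used
    no_cds_dropped = list(
      lines = c(gff_row("chr1", "gene", 1, 90, "+", "g9"),
                gff_row("chr1", "mRNA", 1, 90, "+", "g9.t1", "g9"),
                gff_row("chr1", "exon", 1, 90, "+", "g9.t1.e1", "g9.t1"),
                gff_tx("chr1", "+", "g9", "g9.t2", iv(1, 90), iv(1, 90))),
      expect = list(n_introns = 0, total_intron_len = 0,
                    total_exon_len = 90, intron_ratio = 0,
                    intronless = TRUE)
    ),
    # large intron between short exons
    long_intron = list(
      lines = gff_gene("chr1", "+", "g10",
                       list(t1 = list(exons = iv(1, 50, 2051, 2100),
                                      cds = iv(1, 50, 2051, 2100)))),
      expect = list(n_introns = 1, total_intron_len = 2000,
                    total_exon_len = 100, intron_ratio = 20,
                    intronless = FALSE)
    )
  )
}

extract_single_record <- function(fixture) {
  f <- write_gff_fixture(c(gff_header(), fixture$lines))
  genes <- parse_annotations(f)
  rec <- compute_gene_record(trim_to_cds(select_canonical(genes[[1]])))
  unlink(f)
  rec
}

expect_record_matches <- function(rec, expect) {
  testthat::expect_equal(rec$n_introns, expect$n_introns)
  testthat::expect_equal(rec$total_intron_len, expect$total_intron_len)
  testthat::expect_equal(rec$total_exon_len, expect$total_exon_len)
  testthat::expect_equal(rec$intron_ratio, expect$intron_ratio)
  testthat::expect_equal(rec$intronless, expect$intronless)
}
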