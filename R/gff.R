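# GFF3 gene-structure extraction: canonical transcripts, CDS-span trimming,
# intron inference, per-gene and per-species feature statistics.

#' Parse a GFF3 annotation into gene models
#'
#' Reads gene/mRNA/exon/CDS features from a GFF3 file and assembles, for each
#' gene, the set of its transcript models (exon and CDS intervals, 1-based
#' inclusive). Features whose `Parent` attribute cannot be resolved are
#' skipped with a warning; mRNAs without any CDS interval are dropped; genes
#' left with no valid transcript are excluded (their count is reported in the
#' `n_excluded` attribute). Genes whose transcripts sit on multiple sequences
#' or mixed strands are excluded with a warning.
#'
#' @param file Path to a GFF3 file.
#' @param cds_as_exons If `TRUE`, transcripts that carry CDS rows but no exon
#'   rows use their CDS intervals as exons (for CDS-only annotations).
#' @return A named list of genes. Each gene is a list with `gene_id` and
#'   `transcripts`, itself a named list of transcript models (see
#'   [transcript_model()]).
#' @export
parse_annotations <- function(file, cds_as_exons = FALSE) {
  gr <- rtracklayer::import(file, format = "gff3")
  type <- as.character(gr$type)
  keep <- type %in% c("gene", "mRNA", "exon", "CDS")
  gr <- gr[keep]
  type <- type[keep]

  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  # a feature may list several parents (e.g. exons shared by transcripts)
  parent_l <- if (!is.null(gr$Parent)) gr$Parent else S4Vectors::SimpleList(rep(list(character(0)), length(gr)))

  df <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type,
    id = id,
    stringsAsFactors = FALSE
  )
  np <- lengths(parent_l)
  expand <- rep(seq_len(nrow(df)), pmax(np, 1L))
  parent <- character(length(expand))
  parent[] <- NA_character_
  has_p <- rep(np > 0L, pmax(np, 1L))
  parent[has_p] <- unlist(parent_l)
  df <- df[expand, , drop = FALSE]
  df$parent <- parent

  gene_rows <- df[df$type == "gene" & !is.na(df$id), , drop = FALSE]
  gene_ids <- unique(gene_rows$id)

  mrna <- df[df$type == "mRNA", , drop = FALSE]
  bad_mrna <- is.na(mrna$parent) | !(mrna$parent %in% gene_ids)
  if (any(bad_mrna)) {
    warning(sum(bad_mrna), " mRNA feature(s) with unresolvable Parent skipped")
    mrna <- mrna[!bad_mrna, , drop = FALSE]
  }
  tx_ids <- unique(mrna$id)

  child <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  bad_child <- is.na(child$parent) | !(child$parent %in% tx_ids)
  if (any(bad_child)) {
    warning(sum(bad_child), " exon/CDS feature(s) with unresolvable Parent skipped")
    child <- child[!bad_child, , drop = FALSE]
  }

  exon_by_tx <- split(child[child$type == "exon", , drop = FALSE],
                      child$parent[child$type == "exon"])
  cds_by_tx <- split(child[child$type == "CDS", , drop = FALSE],
                     child$parent[child$type == "CDS"])

  genes <- list()
  n_excluded <- 0L
  for (g in gene_ids) {
    gm <- mrna[mrna$parent == g, , drop = FALSE]
    txs <- list()
    for (k in seq_len(nrow(gm))) {
      tid <- gm$id[k]
      ex <- exon_by_tx[[tid]]
      cd <- cds_by_tx[[tid]]
      if (is.null(cd) || nrow(cd) == 0L) next  # no CDS: drop transcript
      cds_iv <- as.matrix(cd[order(cd$start), c("start", "end")])
      if (is.null(ex) || nrow(ex) == 0L) {
        if (!cds_as_exons) next
        ex_iv <- cds_iv
      } else {
        ex_iv <- as.matrix(ex[order(ex$start), c("start", "end")])
      }
      txs[[tid]] <- transcript_model(
        transcript_id = tid, gene_id = g,
        seq_id = gm$seq_id[k], strand = gm$strand[k],
        exons = ex_iv, cds = cds_iv
      )
    }
    if (length(txs) == 0L) {
      n_excluded <- n_excluded + 1L
      next
    }
    seqs <- unique(vapply(txs, `[[`, "", "seq_id"))
    strands <- unique(vapply(txs, `[[`, "", "strand"))
    if (length(seqs) > 1L || length(strands) > 1L) {
      warning("gene ", g, " spans multiple sequences or strands; excluded")
      n_excluded <- n_excluded + 1L
      next
    }
    genes[[g]] <- list(gene_id = g, transcripts = txs)
  }
  attr(genes, "n_excluded") <- n_excluded
  genes
}

#' Construct a transcript model
#'
#' @param transcript_id,gene_id,seq_id,strand Identifiers and location.
#' @param exons,cds Two-column matrices of 1-based inclusive `(start, end)`
#'   intervals, sorted by start.
#' @return A list of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, seq_id, strand, exons, cds) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  cds <- matrix(as.numeric(cds), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  cds <- cds[order(cds[, 1]), , drop = FALSE]
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         seq_id = seq_id, strand = strand, exons = exons, cds = cds),
    class = "transcript_model"
  )
}

#' Select the canonical transcript of a gene
#'
#' The canonical transcript is the one with the maximal total CDS length
#' (sum of CDS interval lengths in bp). Ties are broken by the
#' lexicographically smallest transcript id, so the choice does not depend
#' on file order.
#'
#' @param gene A gene entry as returned by [parse_annotations()].
#' @return The canonical `transcript_model`, or `NULL` if no transcript has
#'   CDS intervals.
#' @export
select_canonical <- function(gene) {
  txs <- gene$transcripts
  tot <- vapply(txs, function(tx) {
    if (nrow(tx$cds) == 0L) return(-Inf)
    sum(tx$cds[, 2] - tx$cds[, 1] + 1)
  }, numeric(1))
  if (all(!is.finite(tot))) return(NULL)
  best <- which(tot == max(tot))
  if (length(best) > 1L) {
    ids <- vapply(txs[best], `[[`, "", "transcript_id")
    best <- best[order(ids)[1L]]
  }
  txs[[best]]
}

#' Trim a transcript to its CDS span
#'
#' UTR annotations are often unreliable, so all exonic sequence upstream of
#' the first CDS base and downstream of the last one is discarded: exons
#' wholly outside the CDS span `[S, E]` are removed and exons partially
#' overlapping it are clipped to it. CDS intervals are unchanged.
#'
#' @param tx A `transcript_model` with at least one CDS interval.
#' @return The trimmed `transcript_model`.
#' @export
trim_to_cds <- function(tx) {
  stopifnot(nrow(tx$cds) >= 1L)
  S <- min(tx$cds[, 1])
  E <- max(tx$cds[, 2])
  ex <- tx$exons
  keep <- ex[, 2] >= S & ex[, 1] <= E
  ex <- ex[keep, , drop = FALSE]
  ex[, 1] <- pmax(ex[, 1], S)
  ex[, 2] <- pmin(ex[, 2], E)
  tx$exons <- ex
  tx
}

#' Infer introns from a trimmed transcript
#'
#' Introns are the gaps between consecutive exons: for exons ending at
#' `prev_end` and starting at `next_start`, the intron is
#' `(prev_end + 1, next_start - 1)` with length `next_start - prev_end - 1`.
#' A zero-length gap (adjacent exons) emits no intron and a warning, since it
#' is an annotation artifact.
#'
#' @param tx A trimmed `transcript_model` with exons sorted by start.
#' @return A two-column matrix of intron `(start, end)` intervals (0 rows if
#'   the transcript is single-exon).
#' @export
infer_introns <- function(tx) {
  ex <- tx$exons
  n <- nrow(ex)
  if (n <= 1L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  starts <- ex[-1L, 1]
  ends <- ex[-n, 2]
  len <- starts - ends - 1
  if (any(len <= 0)) {
    warning("adjacent exons with zero gap in transcript ", tx$transcript_id,
            "; no intron emitted")
  }
  keep <- len > 0
  cbind(start = ends[keep] + 1, end = starts[keep] - 1)
}

#' Compute per-gene structure features
#'
#' From a trimmed canonical transcript, computes the number of introns, the
#' intron lengths, total intron and exon lengths, the intron ratio (total
#' intron length / total exon length), and the intronless flag.
#'
#' @param tx A trimmed `transcript_model`.
#' @return A list of class `gene_record` with fields `gene_id`,
#'   `transcript_id`, `n_introns`, `intron_lengths`, `total_intron_len`,
#'   `total_exon_len`, `intron_ratio`, `intronless`.
#' @export
compute_gene_record <- function(tx) {
  introns <- infer_introns(tx)
  il <- if (nrow(introns)) introns[, 2] - introns[, 1] + 1 else numeric(0)
  tel <- sum(tx$exons[, 2] - tx$exons[, 1] + 1)
  stopifnot(tel >= 1)
  structure(
    list(gene_id = tx$gene_id, transcript_id = tx$transcript_id,
         n_introns = length(il), intron_lengths = il,
         total_intron_len = sum(il), total_exon_len = tel,
         intron_ratio = sum(il) / tel, intronless = length(il) == 0L),
    class = "gene_record"
  )
}

#' Tabulate gene records
#'
#' @param records List of `gene_record` objects.
#' @return A data.frame with one row per gene (scalar fields only).
#' @export
gene_record_table <- function(records) {
  data.frame(
    gene_id = vapply(records, `[[`, "", "gene_id"),
    transcript_id = vapply(records, `[[`, "", "transcript_id"),
    n_introns = vapply(records, `[[`, 0, "n_introns"),
    total_intron_len = vapply(records, `[[`, 0, "total_intron_len"),
    total_exon_len = vapply(records, `[[`, 0, "total_exon_len"),
    intron_ratio = vapply(records, `[[`, 0, "intron_ratio"),
    intronless = vapply(records, `[[`, FALSE, "intronless"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Summarize gene-structure features for one species
#'
#' Means are taken across all genes, including intronless ones (intron ratio
#' 0). `mean_intron_len` is the mean of the genome-wide pooled intron-length
#' distribution, not a mean of per-gene means. log10 variants are computed
#' from the species-level means of the length and ratio features; the mean
#' number of introns is never log-transformed.
#'
#' @param records List of `gene_record` objects (at least one).
#' @param genome_size Assembly size in bp (e.g. from
#'   [genome_size_from_headers()]), or `NA`.
#' @param species_id Species identifier.
#' @return One-row data.frame of class `species_summary`.
#' @export
summarize_species <- function(records, genome_size = NA_real_,
                              species_id = "species") {
  stopifnot(length(records) >= 1L)
  tab <- gene_record_table(records)
  pooled <- unlist(lapply(records, `[[`, "intron_lengths"), use.names = FALSE)
  mean_il <- if (length(pooled)) mean(pooled) else NA_real_
  out <- data.frame(
    species_id = species_id,
    n_genes = nrow(tab),
    mean_intron_ratio = mean(tab$intron_ratio),
    mean_intron_len = mean_il,
    mean_n_introns = mean(tab$n_introns),
    mean_total_intron_len = mean(tab$total_intron_len),
    mean_total_exon_len = mean(tab$total_exon_len),
    fraction_intronless = mean(tab$intronless),
    genome_size = genome_size,
    stringsAsFactors = FALSE
  )
  out$log10_mean_intron_ratio <- log10(out$mean_intron_ratio)
  out$log10_mean_intron_len <- log10(out$mean_intron_len)
  out$log10_mean_total_intron_len <- log10(out$mean_total_intron_len)
  out$log10_mean_total_exon_len <- log10(out$mean_total_exon_len)
  class(out) <- c("species_summary", "data.frame")
  out
}

#' Extract a genome-wide feature distribution
#'
#' @param records List of `gene_record` objects.
#' @param feature One of `"intron_ratio"` (per gene), `"intron_length"`
#'   (pooled per-intron values genome-wide), `"n_introns"` (per gene).
#' @param include_intronless Keep intronless genes in per-gene distributions
#'   (default `TRUE`; they carry ratio 0 / count 0).
#' @return Numeric vector of observations.
#' @export
feature_distribution <- function(records,
                                 feature = c("intron_ratio", "intron_length", "n_introns"),
                                 include_intronless = TRUE) {
  feature <- match.arg(feature)
  if (feature == "intron_length") {
    return(unlist(lapply(records, `[[`, "intron_lengths"), use.names = FALSE))
  }
  vals <- vapply(records, `[[`, 0,
                 if (feature == "intron_ratio") "intron_ratio" else "n_introns")
  if (!include_intronless) {
    vals <- vals[!vapply(records, `[[`, FALSE, "intronless")]
  }
  unname(vals)
}

#' Assembly size from GFF3 sequence-region directives
#'
#' Sums `end - start + 1` over all `##sequence-region` header lines.
#'
#' @param file Path to a GFF3 file.
#' @return Total assembly length in bp.
#' @export
genome_size_from_headers <- function(file) {
  lines <- readLines(file)
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (length(sr) == 0L) {
    stop("no ##sequence-region directives found; pass the assembly size explicitly")
  }
  parts <- strsplit(trimws(sr), "[ \t]+")
  ids <- vapply(parts, `[[`, "", 2L)
  if (anyDuplicated(ids)) {
    stop("duplicated ##sequence-region id(s): ambiguous assembly")
  }
  starts <- as.numeric(vapply(parts, `[[`, "", 3L))
  ends <- as.numeric(vapply(parts, `[[`, "", 4L))
  sum(ends - starts + 1)
}

#' Run the full gene-structure extraction for one species
#'
#' Parses the annotation, selects the canonical transcript of every gene,
#' trims it to the CDS span, infers introns and computes per-gene records,
#' the species summary, and genome-wide feature distributions.
#'
#' @param file Path to a GFF3 file.
#' @param species_id Species identifier used in outputs.
#' @param genome_size Assembly size in bp; if `NULL`, taken from the file's
#'   `##sequence-region` headers (NA if absent).
#' @param cds_as_exons Passed to [parse_annotations()].
#' @param include_intronless Passed to [feature_distribution()] for the
#'   per-gene distributions.
#' @return List of class `gene_structure` with `records` (list of
#'   `gene_record`), `table` (per-gene data.frame), `summary`
#'   (`species_summary`), `distributions` (named list of numeric vectors).
#' @export
extract_gene_structures <- function(file, species_id = "species",
                                    genome_size = NULL, cds_as_exons = FALSE,
                                    include_intronless = TRUE) {
  genes <- parse_annotations(file, cds_as_exons = cds_as_exons)
  if (length(genes) == 0L) stop("no valid genes in ", file)
  if (is.null(genome_size)) {
    genome_size <- tryCatch(genome_size_from_headers(file),
                            error = function(e) NA_real_)
  }
  records <- list()
  for (g in genes) {
    can <- select_canonical(g)
    if (is.null(can)) next
    records[[can$gene_id]] <- compute_gene_record(trim_to_cds(can))
  }
  structure(
    list(
      species_id = species_id,
      records = records,
      table = gene_record_table(records),
      summary = summarize_species(records, genome_size, species_id),
      distributions = list(
        intron_ratio = feature_distribution(records, "intron_ratio",
                                            include_intronless),
        intron_length = feature_distribution(records, "intron_length"),
        n_introns = feature_distribution(records, "n_introns",
                                         include_intronless)
      )
    ),
    class = "gene_structure"
  )
}

#' @export
print.gene_structure <- function(x, ...) {
  s <- x$summary
  cat("Gene structures for", x$species_id, "-", s$n_genes, "genes\n")
  cat(sprintf("  mean intron ratio     %.4f\n", s$mean_intron_ratio))
  cat(sprintf("  mean introns/transcript %.3f\n", s$mean_n_introns))
  cat(sprintf("  mean intron length    %.1f bp\n", s$mean_intron_len))
  cat(sprintf("  fraction intronless   %.3f\n", s$fraction_intronless))
  invisible(x)
}

#' Write extraction outputs as TSV files
#'
#' @param x A `gene_structure` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_gene_structures <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genes = file.path(dir, paste0(x$species_id, "_genes.tsv")),
    summary = file.path(dir, paste0(x$species_id, "_summary.tsv"))
  )
  utils::write.table(x$table, paths["genes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(x$summary), paths["summary"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (f in names(x$distributions)) {
    p <- file.path(dir, paste0(x$species_id, "_", f, ".txt"))
    writeLines(format(x$distributions[[f]], trim = TRUE, scientific = FALSE), p)
    paths[f] <- p
  }
  invisible(paths)
}
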