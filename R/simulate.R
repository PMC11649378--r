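# Synthetic inputs with known ground truth: annotated genomes (GFF3),
# ultrametric dated trees, and Brownian traits with optional clade rate
# shifts. All randomness uses R's RNG, so set.seed() gives byte-identical
# output.

#' Simulate an ultrametric dated tree
#'
#' Pure-birth (Yule) topology with node times rescaled so the root age
#' equals `depth_myr`; tips sit at age 0.
#'
#' @param n_tips Number of tips (>= 2).
#' @param depth_myr Root age in Myr.
#' @return Ultrametric `phylo` with tips `s01, s02, ...`.
#' @export
simulate_tree <- function(n_tips, depth_myr = 100) {
  stopifnot(n_tips >= 2)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * depth_myr / depth
  tree$tip.label <- sprintf("s%02d", seq_len(n_tips))
  tree
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Along each branch the trait increments by
#' `Normal(0, sigma2 * multiplier_b * l_b)`, where the per-branch
#' multiplier defaults to 1 and can be raised inside named clades to create
#' rate shifts. All node states are recorded, so the truth is available for
#' recovery tests; tip values equal the root plus the telescoping sum of
#' path increments exactly.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param sigma2 Base BM rate (trait units^2 per Myr).
#' @param root Root state.
#' @param clade_multipliers Named numeric vector of rate multipliers per
#'   clade (e.g. `c(cladeA = 5)`), applied to branches assigned to the
#'   clade via [assign_branches()].
#' @param clade_map Required when `clade_multipliers` is given.
#' @return List of class `bm_sim`: `tip_values` (named), `node_states`
#'   (all nodes), `branch_multipliers`, `sigma2`, `root`.
#' @export
simulate_bm <- function(tree, sigma2, root = 0, clade_multipliers = NULL,
                        clade_map = NULL) {
  ntip <- length(tree$tip.label)
  n_node <- ntip + tree$Nnode
  mult <- rep(1, nrow(tree$edge))
  if (!is.null(clade_multipliers)) {
    stopifnot(!is.null(clade_map), all(clade_multipliers > 0))
    lab <- assign_branches(tree, clade_map)
    for (cl in names(clade_multipliers)) {
      mult[lab == cl] <- clade_multipliers[[cl]]
    }
  }
  states <- rep(NA_real_, n_node)
  root_node <- ntip + 1L
  states[root_node] <- root
  ord <- order(ape::node.depth.edgelength(tree)[tree$edge[, 2]])
  incr <- stats::rnorm(nrow(tree$edge), 0,
                       sqrt(sigma2 * mult * tree$edge.length))
  for (e in ord) {
    states[tree$edge[e, 2]] <- states[tree$edge[e, 1]] + incr[e]
  }
  tips <- states[seq_len(ntip)]
  names(tips) <- tree$tip.label
  names(states) <- c(tree$tip.label, as.character((ntip + 1L):n_node))
  structure(list(tip_values = tips, node_states = states,
                 branch_multipliers = mult, sigma2 = sigma2, root = root),
            class = "bm_sim")
}

#' Specification of a synthetic annotated genome
#'
#' Gene-structure laws: exon counts for intron-bearing genes follow a
#' shifted Poisson (`2 + Poisson(exon_count_mean - 2)`) or are fixed;
#' exon and intron lengths are log-normal, parameterized by median and
#' log-sd (`sdlog = 0` gives deterministic lengths); an optional second
#' log-normal component for introns emulates a distinct within-genome
#' intron population. CDS equals the exons by default, so CDS-span
#' trimming is a no-op unless UTR decoration is enabled (`utr_prob`),
#' which extends terminal exons and adds untranslated exons beyond the
#' CDS span to exercise trimming.
#'
#' @param n_genes Number of genes.
#' @param exon_count_mean Mean exon count of intron-bearing genes (>= 2).
#' @param exon_count_law `"shifted_poisson"` or `"fixed"`.
#' @param exon_len_median,exon_len_sdlog Log-normal exon-length law (bp).
#' @param intron_len_median,intron_len_sdlog Log-normal intron-length law.
#' @param intron_len_mixture Optional list `(prop, median, sdlog)` for a
#'   second intron-length component.
#' @param intronless_fraction Probability a gene is single-exon.
#' @param n_seqs Number of sequences (chromosomes).
#' @param alt_transcript_prob Probability a gene gains a second, shorter-CDS
#'   transcript (exercises canonical selection).
#' @param utr_prob Probability a gene is decorated with UTR exons.
#' @param species_id Identifier used in the emitted GFF3 and summaries.
#' @return List of class `genome_spec`.
#' @export
genome_spec <- function(n_genes = 1000, exon_count_mean = 5,
                        exon_count_law = c("shifted_poisson", "fixed"),
                        exon_len_median = 150, exon_len_sdlog = 0.5,
                        intron_len_median = 300, intron_len_sdlog = 0.8,
                        intron_len_mixture = NULL,
                        intronless_fraction = 0.1, n_seqs = 1,
                        alt_transcript_prob = 0, utr_prob = 0,
                        species_id = "species") {
  exon_count_law <- match.arg(exon_count_law)
  stopifnot(n_genes >= 1, exon_count_mean >= 2,
            intronless_fraction >= 0, intronless_fraction <= 1)
  structure(as.list(environment()), class = "genome_spec")
}

draw_lengths <- function(n, median, sdlog, mixture = NULL) {
  if (n == 0L) return(numeric(0))
  if (!is.null(mixture)) {
    pick <- stats::runif(n) < mixture$prop
    out <- numeric(n)
    out[pick] <- stats::rlnorm(sum(pick), log(mixture$median), mixture$sdlog)
    out[!pick] <- stats::rlnorm(sum(!pick), log(median), sdlog)
  } else {
    out <- stats::rlnorm(n, log(median), sdlog)
  }
  pmax(1, round(out))
}

#' Simulate an annotated genome with known gene-structure truth
#'
#' Genes are placed without overlap on `n_seqs` sequences; for each gene an
#' intronless Bernoulli, an exon count and exon/intron lengths are drawn,
#' and gene/mRNA/exon/CDS rows are emitted with `##sequence-region` headers
#' sized to contain all genes. The realized per-gene records (computed from
#' the drawn numbers, independently of any parser) are returned as ground
#' truth.
#'
#' @param spec A [genome_spec()].
#' @return List of class `genome_sim`: `lines` (GFF3 text), `records`
#'   (realized `gene_record` list), `truth` (realized `species_summary`),
#'   `spec`.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  n <- spec$n_genes
  intronless <- stats::runif(n) < spec$intronless_fraction
  n_exons <- ifelse(
    intronless, 1L,
    if (spec$exon_count_law == "fixed") round(spec$exon_count_mean)
    else 2L + stats::rpois(n, spec$exon_count_mean - 2)
  )

  seq_of <- rep_len(seq_len(spec$n_seqs), n)
  cursor <- rep(1000, spec$n_seqs)
  lines <- character(0)
  body <- vector("list", n)
  records <- vector("list", n)

  for (g in seq_len(n)) {
    k <- n_exons[g]
    ex_len <- draw_lengths(k, spec$exon_len_median, spec$exon_len_sdlog)
    in_len <- draw_lengths(k - 1L, spec$intron_len_median,
                           spec$intron_len_sdlog, spec$intron_len_mixture)
    sq <- seq_of[g]
    start <- cursor[sq]
    # core (coding) exon intervals
    ex <- matrix(0, k, 2)
    pos <- start
    for (i in seq_len(k)) {
      ex[i, ] <- c(pos, pos + ex_len[i] - 1)
      pos <- ex[i, 2] + (if (i < k) in_len[i] else 0) + 1
    }
    gid <- sprintf("%s_g%05d", spec$species_id, g)
    tid <- paste0(gid, ".t1")
    cds <- ex

    # optional UTR decoration: extend terminal exons beyond the CDS span
    # and add an untranslated exon upstream
    utr_ex <- ex
    if (spec$utr_prob > 0 && stats::runif(1) < spec$utr_prob) {
      ext5 <- sample(20:80, 1)
      ext3 <- sample(20:80, 1)
      utr_ex[1, 1] <- max(1, utr_ex[1, 1] - ext5)
      utr_ex[k, 2] <- utr_ex[k, 2] + ext3
      if (utr_ex[1, 1] > 120) {
        utr_ex <- rbind(c(utr_ex[1, 1] - 100 - sample(30:60, 1),
                          utr_ex[1, 1] - 100), utr_ex)
      }
    }
    gene_start <- min(utr_ex[, 1])
    gene_end <- max(utr_ex[, 2])
    strand <- sample(c("+", "-"), 1)
    seq_name <- sprintf("%s_chr%d", spec$species_id, sq)

    rows <- c(
      sprintf("%s\tgsevol\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              seq_name, as.integer(gene_start), as.integer(gene_end), strand, gid),
      sprintf("%s\tgsevol\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              seq_name, as.integer(gene_start), as.integer(gene_end), strand, tid, gid),
      sprintf("%s\tgsevol\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
              seq_name, as.integer(utr_ex[, 1]), as.integer(utr_ex[, 2]), strand, tid,
              seq_len(nrow(utr_ex)), tid),
      sprintf("%s\tgsevol\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s",
              seq_name, as.integer(cds[, 1]), as.integer(cds[, 2]), strand, tid,
              seq_len(nrow(cds)), tid)
    )
    if (spec$alt_transcript_prob > 0 && k >= 2L &&
        stats::runif(1) < spec$alt_transcript_prob) {
      tid2 <- paste0(gid, ".t2")
      ex2 <- ex[-k, , drop = FALSE]  # drops the last exon: shorter CDS
      rows <- c(rows,
        sprintf("%s\tgsevol\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                seq_name, as.integer(min(ex2[, 1])), as.integer(max(ex2[, 2])), strand, tid2, gid),
        sprintf("%s\tgsevol\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                seq_name, as.integer(ex2[, 1]), as.integer(ex2[, 2]), strand, tid2,
                seq_len(nrow(ex2)), tid2),
        sprintf("%s\tgsevol\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s",
                seq_name, as.integer(ex2[, 1]), as.integer(ex2[, 2]), strand, tid2,
                seq_len(nrow(ex2)), tid2))
    }
    body[[g]] <- rows
    cursor[sq] <- gene_end + 500

    records[[g]] <- structure(
      list(gene_id = gid, transcript_id = tid,
           n_introns = k - 1L, intron_lengths = in_len,
           total_intron_len = sum(in_len), total_exon_len = sum(ex_len),
           intron_ratio = sum(in_len) / sum(ex_len),
           intronless = k == 1L),
      class = "gene_record"
    )
  }
  names(records) <- vapply(records, `[[`, "", "gene_id")

  seq_len_bp <- cursor + 500
  header <- c("##gff-version 3",
              sprintf("##sequence-region %s_chr%d 1 %d",
                      spec$species_id, seq_len(spec$n_seqs),
                      as.integer(round(seq_len_bp))))
  lines <- c(header, unlist(body))
  truth <- summarize_species(records, genome_size = sum(round(seq_len_bp)),
                             species_id = spec$species_id)
  structure(list(lines = lines, records = records, truth = truth,
                 spec = spec),
            class = "genome_sim")
}

#' Write a simulated genome to a GFF3 file
#'
#' @param sim A `genome_sim`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_genome <- function(sim, file) {
  writeLines(sim$lines, file)
  invisible(file)
}

#' Build a complete synthetic comparative study
#'
#' Simulates a dated tree, evolves species-level gene-structure traits
#' (log10 mean intron ratio, log10 mean intron length, mean intron count)
#' under Brownian motion -- optionally with a rate-shifted clade -- and
#' tunes each species' genome spec so its expected extracted summary
#' matches the simulated species mean: the exon count is fixed at
#' `k + 1` exons for `k = round(mean intron count)`, intron lengths are
#' log-normal with mean matched to the species' intron-length mean, and the
#' (constant) exon length solves
#' `ratio = (k * mean_intron_len) / ((k + 1) * exon_len)`.
#'
#' @param n_species Number of species.
#' @param tree_depth Root age (Myr).
#' @param n_genes Genes per genome.
#' @param root_ratio Intron ratio at the root (untransformed).
#' @param root_intron_len Mean intron length at the root (bp).
#' @param root_n_introns Mean intron count at the root.
#' @param sigma2_log_ratio BM rate of log10 intron ratio (per Myr).
#' @param sigma2_log_len BM rate of log10 intron length.
#' @param sigma2_count BM rate of intron count.
#' @param shift_multiplier Rate multiplier applied to the log-ratio trait in
#'   the shifted clade (1 = homogeneous rates).
#' @param intron_len_sdlog Within-genome log-sd of intron lengths.
#' @return List of class `study_sim`: `tree`, `clade_map` (two clades split
#'   at the root), `genomes` (named list of `genome_sim`), `truth` (list
#'   with the log-ratio `bm_sim`, per-species targets, shift multiplier).
#' @export
build_study_fixture <- function(n_species = 16, tree_depth = 500,
                                n_genes = 300, root_ratio = 3,
                                root_intron_len = 500, root_n_introns = 5,
                                sigma2_log_ratio = 2e-4,
                                sigma2_log_len = 1e-4,
                                sigma2_count = 2e-3,
                                shift_multiplier = 1,
                                intron_len_sdlog = 0.6) {
  tree <- simulate_tree(n_species, tree_depth)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  side_a <- descendants_of(tree, kids[1])
  clade_map <- data.frame(
    tip = tree$tip.label,
    phylum = ifelse(seq_len(ntip) %in% side_a, "cladeA", "cladeB"),
    kingdom = "synthetica",
    stringsAsFactors = FALSE
  )

  mult <- if (shift_multiplier != 1) c(cladeA = shift_multiplier) else NULL
  sim_ratio <- simulate_bm(tree, sigma2_log_ratio, root = log10(root_ratio),
                           clade_multipliers = mult, clade_map = clade_map)
  sim_len <- simulate_bm(tree, sigma2_log_len, root = log10(root_intron_len))
  sim_cnt <- simulate_bm(tree, sigma2_count, root = root_n_introns)

  genomes <- list()
  targets <- data.frame(species = tree$tip.label,
                        ratio = 10^sim_ratio$tip_values,
                        intron_len = 10^sim_len$tip_values,
                        n_introns = pmax(1, round(sim_cnt$tip_values)))
  for (i in seq_len(ntip)) {
    sp <- tree$tip.label[i]
    r <- targets$ratio[i]
    m_il <- targets$intron_len[i]
    k <- targets$n_introns[i]
    exon_len <- k * m_il / ((k + 1) * r)
    if (exon_len < 1) {
      stop("unattainable mean combination for ", sp,
           ": ratio must be <= n_introns * intron_len / (n_exons * 1 bp)")
    }
    # log-normal mean matching: meanlog = log(mean) - sdlog^2 / 2
    med <- exp(log(m_il) - intron_len_sdlog^2 / 2)
    spec <- genome_spec(
      n_genes = n_genes, exon_count_mean = k + 1, exon_count_law = "fixed",
      exon_len_median = exon_len, exon_len_sdlog = 0,
      intron_len_median = med, intron_len_sdlog = intron_len_sdlog,
      intronless_fraction = 0, species_id = sp
    )
    genomes[[sp]] <- simulate_genome(spec)
  }

  structure(
    list(tree = tree, clade_map = clade_map, genomes = genomes,
         truth = list(log_ratio = sim_ratio, log_intron_len = sim_len,
                      n_introns = sim_cnt, targets = targets,
                      shift_multiplier = shift_multiplier)),
    class = "study_sim"
  )
}
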