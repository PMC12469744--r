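#' @importFrom stats plogis qlogis rpois runif rnorm
#' @importFrom utils write.table read.delim
NULL

# maximal distances any window convention reaches from a gene body
.MARGIN_UP <- 2000L    # upstream_only reaches 2000 bp 5' of the TSS
.MARGIN_DOWN <- 2000L  # symmetric margin so either strand fits

#' A planted cis-regulatory motif
#'
#' Planted motifs stand in for the short (5-15 bp) enriched sequences found
#' near differentially expressed genes; each occurrence adds `effect` to the
#' log-odds that the carrying gene is an up-regulated DEG.
#'
#' @param id motif identifier.
#' @param consensus DNA string over A/C/G/T, length 5-15.
#' @param effect per-occurrence increment on the up-DEG logit.
#' @param placement_rate expected (Poisson) occurrences planted per gene
#'   regulatory span.
#' @param orientation_both_strands if `TRUE` (default) each planted copy is
#'   reverse-complemented with probability 0.5.
#' @return a `planted_motif` object.
#' @export
planted_motif <- function(id, consensus, effect = 0,
                          placement_rate = 1,
                          orientation_both_strands = TRUE) {
  consensus <- toupper(consensus)
  if (!grepl("^[ACGT]+$", consensus))
    stop("consensus must be a non-empty string over A/C/G/T")
  if (nchar(consensus) < 5L || nchar(consensus) > 15L)
    stop("consensus length must be between 5 and 15 bp")
  if (placement_rate < 0) stop("placement_rate must be >= 0")
  structure(list(id = as.character(id), consensus = consensus,
                 effect = effect, placement_rate = placement_rate,
                 orientation_both_strands = isTRUE(orientation_both_strands)),
            class = "planted_motif")
}

#' Configuration of the synthetic multi-accession dataset
#'
#' Defines the generative conditions the downstream analysis assumes: several
#' accessions derived from one reference by low-frequency substitutions,
#' genes grouped into families, planted motifs whose occurrence counts drive
#' DEG status through a logistic model, and an up:non DEG ratio near 1:11.
#'
#' @param n_chromosomes,chrom_length,n_genes number and length (bp) of
#'   chromosomes, and number of genes. Genes are placed so that every window
#'   convention fits on its chromosome.
#' @param n_families number of gene families; `n_genes >= n_families >= 1`.
#' @param n_accessions number of accessions (default 5, as in the cold
#'   acclimation panel).
#' @param snp_rate per-base substitution probability per derived accession
#'   (default 0.005; in `[0, 1)`).
#' @param planted_motifs list of [planted_motif()] objects.
#' @param baseline_logit intercept of the label model; default
#'   `qlogis(deg_ratio_target / (1 + deg_ratio_target))` so that with zero
#'   motif effects the realized up:non ratio matches `deg_ratio_target`.
#' @param deg_ratio_target target DEG:non-DEG ratio (default 1/11).
#' @param spike_seq the 5-bp spike-in positive-control sequence
#'   (default "AAGGG").
#' @param gene_length gene body length in bp.
#' @param gc background GC fraction (bases are i.i.d.; default 0.5).
#' @param family_mode `"blocks"` assigns families as contiguous runs of gene
#'   indices; `"shuffled"` scatters them (for split-robustness checks).
#' @param seed integer seed; all generation is deterministic given the config.
#' @return a validated `synth_config` object.
#' @export
synth_config <- function(n_chromosomes = 1L, chrom_length = 200000L,
                         n_genes = 20L, n_families = 5L,
                         n_accessions = 5L, snp_rate = 0.005,
                         planted_motifs = list(),
                         baseline_logit = NULL,
                         deg_ratio_target = 1 / 11,
                         spike_seq = "AAGGG",
                         gene_length = 1000L, gc = 0.5,
                         family_mode = c("blocks", "shuffled"),
                         seed = 1L) {
  family_mode <- match.arg(family_mode)
  if (n_genes > 0 && (n_families < 1L || n_genes < n_families))
    stop("need n_genes >= n_families >= 1")
  if (snp_rate < 0 || snp_rate >= 1)
    stop("snp_rate must satisfy 0 <= snp_rate < 1")
  if (!grepl("^[ACGT]+$", toupper(spike_seq)))
    stop("spike_seq must match [ACGT]+")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (deg_ratio_target <= 0) stop("deg_ratio_target must be positive")
  for (m in planted_motifs)
    if (!inherits(m, "planted_motif")) stop("planted_motifs must be planted_motif objects")
  if (is.null(baseline_logit))
    baseline_logit <- qlogis(deg_ratio_target / (1 + deg_ratio_target))
  cfg <- structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes), n_families = as.integer(n_families),
    n_accessions = as.integer(n_accessions), snp_rate = snp_rate,
    planted_motifs = planted_motifs, baseline_logit = baseline_logit,
    deg_ratio_target = deg_ratio_target, spike_seq = toupper(spike_seq),
    gene_length = as.integer(gene_length), gc = gc,
    family_mode = family_mode, seed = as.integer(seed)
  ), class = "synth_config")
  cfg
}

# one gene "slot": full margins on both sides plus a spacer, so that the
# maximal windows of neighbouring genes never overlap
.slot_size <- function(cfg) cfg$gene_length + .MARGIN_UP + .MARGIN_DOWN + 200L

.genes_per_chrom <- function(cfg) {
  n <- cfg$n_genes
  k <- cfg$n_chromosomes
  base <- n %/% k
  extra <- n %% k
  base + (seq_len(k) <= extra)
}

.check_capacity <- function(cfg) {
  if (cfg$n_genes == 0L) return(invisible(cfg))
  per <- max(.genes_per_chrom(cfg))
  need <- per * .slot_size(cfg)
  if (need > cfg$chrom_length)
    stop("chromosome too short: ", per, " genes with their maximal windows need ",
         need, " bp but chrom_length is ", cfg$chrom_length,
         " (deficit ", need - cfg$chrom_length, " bp)")
  invisible(cfg)
}

.random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# strand-specific regulatory span of a gene on reference coordinates:
# the union of every window convention for that strand
.gene_span <- function(start, end, strand) {
  if (strand == "+") c(start - .MARGIN_UP, end + 1000L)
  else c(start - 1000L, end + .MARGIN_UP)
}

#' Generate the reference genome and gene annotation
#'
#' Builds i.i.d. background chromosomes, places non-overlapping genes (with
#' room for every window convention), assigns gene families, and plants
#' Poisson-distributed motif occurrences uniformly within each gene's
#' regulatory span (reverse-complemented with probability 0.5 when the motif
#' is double-stranded). Placement positions are rejection-sampled so planted
#' occurrences never overwrite each other. Deterministic for a fixed config.
#'
#' @param config a [synth_config()].
#' @return a `synth_reference` list: `genome` (named character vector),
#'   `annotations` (data.frame: gene_id, chrom, start, end, strand,
#'   family_id), `placements` (data.frame of planted copies), `motif_counts`
#'   (genes x motifs matrix of occurrences found by scanning the realized
#'   spans; these are the counts that drive labels) and `config`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  .check_capacity(config)
  set.seed(config$seed)
  genome <- vapply(seq_len(config$n_chromosomes), function(i)
    .random_dna(config$chrom_length, config$gc), character(1))
  names(genome) <- sprintf("chr%d", seq_len(config$n_chromosomes))

  if (config$n_genes == 0L) {
    ann <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), family_id = character(),
                      stringsAsFactors = FALSE)
    return(structure(list(genome = genome, annotations = ann,
                          placements = .empty_placements(),
                          motif_counts = matrix(0L, 0L, length(config$planted_motifs)),
                          config = config),
                     class = "synth_reference"))
  }

  per_chrom <- .genes_per_chrom(config)
  slot <- .slot_size(config)
  chrom <- rep(names(genome), per_chrom)
  idx_in_chrom <- unlist(lapply(per_chrom, seq_len), use.names = FALSE)
  start <- (idx_in_chrom - 1L) * slot + .MARGIN_UP + 1L
  end <- start + config$gene_length - 1L
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  fam_sizes <- .genes_per_chrom(list(n_genes = config$n_genes,
                                     n_chromosomes = config$n_families))
  family <- rep(sprintf("fam%04d", seq_len(config$n_families)), fam_sizes)
  if (config$family_mode == "shuffled") family <- sample(family)
  ann <- data.frame(
    gene_id = sprintf("g%05d", seq_len(config$n_genes)),
    chrom = chrom, start = start, end = end, strand = strand,
    family_id = family, stringsAsFactors = FALSE)

  placements <- .plant_motifs(genome, ann, config)
  genome <- placements$genome
  counts <- scan_motif_counts(genome, ann, config$planted_motifs)

  structure(list(genome = genome, annotations = ann,
                 placements = placements$placements,
                 motif_counts = counts, config = config),
            class = "synth_reference")
}

.empty_placements <- function() {
  data.frame(gene_id = character(), motif_id = character(),
             pos = integer(), inserted_strand = character(),
             stringsAsFactors = FALSE)
}

.plant_motifs <- function(genome, ann, config) {
  placements <- list()
  if (length(config$planted_motifs) == 0L || nrow(ann) == 0L)
    return(list(genome = genome, placements = .empty_placements()))
  for (ci in names(genome)) {
    chrom_seq <- genome[[ci]]
    genes <- ann[ann$chrom == ci, , drop = FALSE]
    for (gi in seq_len(nrow(genes))) {
      g <- genes[gi, ]
      span <- .gene_span(g$start, g$end, g$strand)
      span[1] <- max(span[1], 1L)
      span[2] <- min(span[2], nchar(chrom_seq))
      occupied <- integer(0)  # positions already covered by a planted copy
      for (m in config$planted_motifs) {
        w <- nchar(m$consensus)
        n_occ <- rpois(1L, m$placement_rate)
        for (k in seq_len(n_occ)) {
          for (try in 1:100) {
            pos <- span[1] + floor(runif(1) * (span[2] - span[1] - w + 2L))
            if (!any(seq.int(pos, pos + w - 1L) %in% occupied)) break
            pos <- NA_integer_
          }
          if (is.na(pos)) next
          ins <- m$consensus
          ins_strand <- "+"
          if (m$orientation_both_strands && runif(1) < 0.5) {
            ins <- .revcomp(ins)
            ins_strand <- "-"
          }
          substr(chrom_seq, pos, pos + w - 1L) <- ins
          occupied <- c(occupied, seq.int(pos, pos + w - 1L))
          placements[[length(placements) + 1L]] <-
            data.frame(gene_id = g$gene_id, motif_id = m$id, pos = pos,
                       inserted_strand = ins_strand, stringsAsFactors = FALSE)
        }
      }
    }
    genome[[ci]] <- chrom_seq
  }
  pl <- if (length(placements)) do.call(rbind, placements) else .empty_placements()
  list(genome = genome, placements = pl)
}

#' Count motif occurrences in each gene's regulatory span
#'
#' Scans the realized sequence (so substitutions that destroy an occurrence,
#' and chance background occurrences, are both reflected). Matches on both
#' strands when the motif is double-stranded.
#'
#' @param genome named character vector of chromosomes.
#' @param annotations gene annotation data.frame.
#' @param motifs list of [planted_motif()] (or objects with `consensus` and
#'   `orientation_both_strands`).
#' @return integer matrix, genes x motifs, dimnames gene_id x motif id.
#' @export
scan_motif_counts <- function(genome, annotations, motifs) {
  n <- nrow(annotations)
  counts <- matrix(0L, n, length(motifs),
                   dimnames = list(annotations$gene_id,
                                   vapply(motifs, `[[`, "", "id")))
  if (n == 0L || length(motifs) == 0L) return(counts)
  spans <- character(n)
  for (i in seq_len(n)) {
    g <- annotations[i, ]
    sp <- .gene_span(g$start, g$end, g$strand)
    spans[i] <- substr(genome[[g$chrom]], max(sp[1], 1L),
                       min(sp[2], nchar(genome[[g$chrom]])))
  }
  ss <- DNAStringSet(spans)
  for (j in seq_along(motifs)) {
    m <- motifs[[j]]
    cnt <- vcountPattern(m$consensus, ss)
    rc <- .revcomp(m$consensus)
    if (m$orientation_both_strands && rc != m$consensus)
      cnt <- cnt + vcountPattern(rc, ss)
    counts[, j] <- cnt
  }
  counts
}

#' Derive an accession genome by random substitutions
#'
#' Each base is independently substituted, with probability `snp_rate`, to a
#' uniformly chosen different base. Length is preserved (no indels), so
#' coordinates stay shared across accessions as in a pseudogenome panel.
#'
#' @param genome named character vector of chromosomes.
#' @param snp_rate substitution probability per bp, in `[0, 1)`.
#' @param seed integer seed; deterministic per seed.
#' @return a genome of the same shape.
#' @export
derive_accession <- function(genome, snp_rate, seed) {
  if (snp_rate < 0 || snp_rate >= 1)
    stop("snp_rate must satisfy 0 <= snp_rate < 1")
  set.seed(seed)
  if (snp_rate == 0) return(genome)
  bases <- c("A", "C", "G", "T")
  for (ci in names(genome)) {
    chars <- strsplit(genome[[ci]], "", fixed = TRUE)[[1L]]
    hit <- which(runif(length(chars)) < snp_rate)
    cur <- match(chars[hit], bases)
    hit <- hit[!is.na(cur)]          # never mutate N
    cur <- cur[!is.na(cur)]
    if (length(hit)) {
      shift <- sample.int(3L, length(hit), replace = TRUE)
      chars[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
      genome[[ci]] <- paste(chars, collapse = "")
    }
  }
  genome
}

#' Assign DEG labels from the logistic label model
#'
#' For gene g in a given accession, `P(up) = plogis(b0 + sum_m b_m c_gm)`
#' where `c_gm` is the motif occurrence count in that accession's sequence.
#' Genes not drawn "up" are drawn "down" with the baseline probability
#' `plogis(b0)`, so both DEG contrasts have the target prevalence when motif
#' effects are zero; everything else is "non". Exactly one status per
#' (gene, accession).
#'
#' @param annotations gene annotation data.frame.
#' @param config a [synth_config()]; supplies the intercept and motif effects.
#' @param motif_counts either `NULL` (all-zero counts), one genes x motifs
#'   matrix used for every accession, or a list of such matrices, one per
#'   accession (counts scanned after accession-specific substitutions).
#' @param accessions accession identifiers; default `acc01..accNN`.
#' @param seed seed for the label draws (default `config$seed + 1`).
#' @return data.frame: gene_id, accession, status in up/down/non.
#' @export
assign_labels <- function(annotations, config, motif_counts = NULL,
                          accessions = NULL, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(accessions))
    accessions <- sprintf("acc%02d", seq_len(config$n_accessions))
  if (is.null(seed)) seed <- config$seed + 1L
  set.seed(seed)
  n <- nrow(annotations)
  effects <- vapply(config$planted_motifs, `[[`, numeric(1), "effect")
  base_p <- plogis(config$baseline_logit)
  out <- vector("list", length(accessions))
  for (a in seq_along(accessions)) {
    cm <- if (is.null(motif_counts)) NULL
          else if (is.list(motif_counts)) motif_counts[[a]]
          else motif_counts
    eta <- rep(config$baseline_logit, n)
    if (!is.null(cm) && length(effects))
      eta <- eta + as.numeric(cm %*% effects)
    p_up <- plogis(eta)
    u1 <- runif(n)
    u2 <- runif(n)
    status <- ifelse(u1 < p_up, "up", ifelse(u2 < base_p, "down", "non"))
    out[[a]] <- data.frame(gene_id = annotations$gene_id,
                           accession = accessions[a], status = status,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate the full multi-accession study
#'
#' Orchestrates [generate_reference()], [derive_accession()] (accession 1 is
#' the unmutated reference, mirroring a panel that includes the reference
#' genotype), per-accession motif re-scanning, and [assign_labels()]. Labels
#' are drawn after mutation, so genotypes differ in both sequence and status.
#'
#' @param config a [synth_config()].
#' @return list: `reference` (the `synth_reference`), `genomes` (named list,
#'   one genome per accession), `labels`, `motif_counts` (list per accession),
#'   `annotations`, `config`.
#' @export
simulate_cold_deg <- function(config) {
  ref <- generate_reference(config)
  acc_ids <- sprintf("acc%02d", seq_len(config$n_accessions))
  genomes <- vector("list", config$n_accessions)
  names(genomes) <- acc_ids
  genomes[[1L]] <- ref$genome
  for (a in seq_len(config$n_accessions)[-1L])
    genomes[[a]] <- derive_accession(ref$genome, config$snp_rate,
                                     seed = config$seed + 7919L * a)
  counts <- lapply(genomes, function(g)
    scan_motif_counts(g, ref$annotations, config$planted_motifs))
  labels <- assign_labels(ref$annotations, config, motif_counts = counts,
                          accessions = acc_ids)
  list(reference = ref, genomes = genomes, labels = labels,
       motif_counts = counts, annotations = ref$annotations, config = config)
}

#' Write the simulated dataset to disk
#'
#' Emits one 60-column FASTA per accession, a single GFF3 gene annotation
#' (1-based inclusive, `ID=` and `family=` attributes), a label TSV
#' (header gene_id/accession/status) and a family TSV. Round-trips losslessly
#' through [read_genome_fasta()], [read_annotations()] and [read_labels()].
#'
#' @param genomes named list of genomes (accession -> named character vector).
#' @param annotations gene annotation data.frame.
#' @param labels label data.frame (gene_id, accession, status).
#' @param out_dir output directory, created if missing.
#' @return invisibly, the character vector of written paths.
#' @export
write_outputs <- function(genomes, annotations, labels, out_dir) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory ", out_dir)
  paths <- character(0)
  for (acc in names(genomes)) {
    p <- file.path(out_dir, paste0(acc, ".fasta"))
    writeXStringSet(DNAStringSet(genomes[[acc]]), p, width = 60L)
    paths <- c(paths, p)
  }
  gff <- file.path(out_dir, "genes.gff3")
  if (nrow(annotations)) {
    gr <- GenomicRanges::GRanges(
      seqnames = annotations$chrom,
      ranges = IRanges::IRanges(annotations$start, annotations$end),
      strand = annotations$strand)
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- annotations$gene_id
    S4Vectors::mcols(gr)$family <- annotations$family_id
    rtracklayer::export(gr, gff, format = "gff3")
  } else {
    writeLines("##gff-version 3", gff)
  }
  lab <- file.path(out_dir, "labels.tsv")
  write.table(labels, lab, sep = "\t", quote = FALSE, row.names = FALSE)
  fam <- file.path(out_dir, "families.tsv")
  write.table(unique(annotations[, c("gene_id", "family_id")]), fam,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, gff, lab, fam))
}

#' Read a GFF3 gene annotation written by [write_outputs()]
#'
#' @param path GFF3 file.
#' @return data.frame: gene_id, chrom, start, end, strand, family_id
#'   (1-based inclusive coordinates).
#' @export
read_annotations <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(
    gene_id = as.character(S4Vectors::mcols(gr)$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    family_id = as.character(S4Vectors::mcols(gr)$family),
    stringsAsFactors = FALSE)
}

#' Read a label TSV written by [write_outputs()]
#' @param path TSV with header gene_id/accession/status.
#' @return data.frame.
#' @export
read_labels <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}
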