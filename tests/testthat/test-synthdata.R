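small_cfg <- function(...) {
  synth_config(n_chromosomes = 2, chrom_length = 60000, n_genes = 10,
               n_families = 4, ...)
}

test_that("generation is deterministic and files are byte-identical", {
  cfg <- small_cfg(seed = 9,
                   planted_motifs = list(planted_motif("m1", "ACGTATTACG",
                                                       placement_rate = 1)))
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$annotations, r2$annotations)

  lab1 <- assign_labels(r1$annotations, cfg, r1$motif_counts)
  lab2 <- assign_labels(r2$annotations, cfg, r2$motif_counts)
  expect_identical(lab1, lab2)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_outputs(list(acc01 = r1$genome), r1$annotations, lab1, d1)
  write_outputs(list(acc01 = r2$genome), r2$annotations, lab2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("zero genes yields background DNA and an empty annotation", {
  cfg <- synth_config(n_chromosomes = 1, chrom_length = 5000, n_genes = 0,
                      n_families = 1, seed = 1)
  ref <- generate_reference(cfg)
  expect_equal(nrow(ref$annotations), 0)
  expect_equal(nchar(ref$genome[["chr1"]]), 5000)
  expect_match(ref$genome[["chr1"]], "^[ACGT]+$")
})

test_that("a too-short chromosome is rejected with the deficit named", {
  cfg <- synth_config(n_chromosomes = 1, chrom_length = 8000, n_genes = 5,
                      n_families = 2, seed = 1)
  expect_error(generate_reference(cfg), "deficit")
})

test_that("planted occurrences match the placement rate, counted by regex", {
  m <- planted_motif("m1", "ACGTATTACG", placement_rate = 2.0)  # 10-mer:
  # background hits are ~1e-4 per gene and cannot disturb the mean
  cfg <- synth_config(n_chromosomes = 4, chrom_length = 660000, n_genes = 500,
                      n_families = 50, planted_motifs = list(m), seed = 13)
  ref <- generate_reference(cfg)
  out <- withr::local_tempdir()
  write_outputs(list(acc01 = ref$genome), ref$annotations,
                data.frame(gene_id = character(), accession = character(),
                           status = character()), out)
  genome <- read_genome_fasta(file.path(out, "acc01.fasta"))
  ann <- read_annotations(file.path(out, "genes.gff3"))
  rc <- revcomp_chr("ACGTATTACG")
  count_gene <- function(i) {
    g <- ann[i, ]
    span <- if (g$strand == "+") c(g$start - 2000, g$end + 1000)
            else c(g$start - 1000, g$end + 2000)
    s <- substr(genome[[g$chrom]], span[1], span[2])
    hits <- function(p) {
      m <- gregexpr(p, s, fixed = TRUE)[[1]]
      sum(m > 0)
    }
    hits("ACGTATTACG") + hits(rc)
  }
  counts <- vapply(seq_len(nrow(ann)), count_gene, numeric(1))
  se <- sqrt(2.0 / 500)
  expect_lt(abs(mean(counts) - 2.0), 3 * se)
  # conservation: regex counts on the emitted FASTA equal the generator's
  # scanned bookkeeping (snp_rate plays no role on the reference)
  expect_equal(unname(counts), unname(ref$motif_counts[ann$gene_id, "m1"]))
})

test_that("derive_accession substitutes at the requested rate, no indels", {
  g <- c(chr1 = random_dna(1e6, seed = 21))
  expect_identical(derive_accession(g, 0, seed = 1), g)
  g2 <- derive_accession(g, 0.01, seed = 2)
  expect_equal(nchar(g2[["chr1"]]), 1e6)
  mism <- sum(strsplit(g[["chr1"]], "")[[1]] != strsplit(g2[["chr1"]], "")[[1]])
  expect_lt(abs(mism - 10000), 3 * sqrt(1e6 * 0.01 * 0.99))
  expect_identical(derive_accession(g, 0.01, seed = 2), g2)
  expect_error(derive_accession(g, 1, seed = 1), "snp_rate")
})

test_that("label model is calibrated at zero effects", {
  cfg <- synth_config(n_genes = 12000, n_families = 100, n_accessions = 1,
                      deg_ratio_target = 1 / 11, seed = 3)
  ann <- data.frame(gene_id = sprintf("g%05d", 1:12000), chrom = "chr1",
                    start = 1, end = 2, strand = "+", family_id = "f1")
  lab <- assign_labels(ann, cfg, seed = 17)
  up_frac <- mean(lab$status == "up")
  bounds <- qbinom(c(0.005, 0.995), 12000, 1 / 12) / 12000
  expect_gt(up_frac, bounds[1])
  expect_lt(up_frac, bounds[2])
  expect_equal(nrow(lab), 12000)  # exactly one status per (gene, accession)
})

test_that("saturating and degenerate intercepts behave as limits", {
  m <- planted_motif("m1", "ACGTATTACG", effect = 50)
  cfg <- synth_config(n_genes = 2000, n_families = 10,
                      n_accessions = 1, planted_motifs = list(m), seed = 4)
  ann <- data.frame(gene_id = sprintf("g%04d", 1:2000), chrom = "chr1",
                    start = 1, end = 2, strand = "+", family_id = "f1")
  counts <- matrix(1L, 2000, 1, dimnames = list(ann$gene_id, "m1"))
  lab <- assign_labels(ann, cfg, counts, seed = 5)
  expect_gte(mean(lab$status == "up"), 0.999)

  cfg2 <- synth_config(n_genes = 2000, n_families = 10, n_accessions = 1,
                       baseline_logit = -50, seed = 4)
  lab2 <- assign_labels(ann, cfg2, seed = 6)
  expect_equal(sum(lab2$status %in% c("up", "down")), 0)
})

test_that("outputs round-trip and have the expected file count", {
  cfg <- small_cfg(n_accessions = 5, seed = 31)
  sim <- simulate_cold_deg(cfg)
  out <- withr::local_tempdir()
  paths <- write_outputs(sim$genomes, sim$annotations, sim$labels, out)
  expect_equal(sum(grepl("\\.fasta$", paths)), 5)
  expect_equal(sum(grepl("\\.gff3$", paths)), 1)
  expect_equal(sum(grepl("\\.tsv$", paths)), 2)

  ann2 <- read_annotations(file.path(out, "genes.gff3"))
  expect_equal(ann2[order(ann2$gene_id), ],
               sim$annotations[order(sim$annotations$gene_id), ],
               ignore_attr = TRUE)
  lab2 <- read_labels(file.path(out, "labels.tsv"))
  expect_equal(lab2, sim$labels, ignore_attr = TRUE)
  g2 <- read_genome_fasta(file.path(out, "acc03.fasta"))
  expect_identical(g2, sim$genomes[["acc03"]])

  # empty label table still writes a valid header-only TSV
  out2 <- withr::local_tempdir()
  write_outputs(sim$genomes[1], sim$annotations,
                sim$labels[0, ], out2)
  lines <- readLines(file.path(out2, "labels.tsv"))
  expect_equal(lines, "gene_id\taccession\tstatus")
})

test_that("snp_rate 0 preserves planted occurrences across accessions", {
  m <- planted_motif("m1", "ACGTATTACG", placement_rate = 1.5)
  cfg <- small_cfg(planted_motifs = list(m), snp_rate = 0, seed = 8)
  sim <- simulate_cold_deg(cfg)
  for (a in names(sim$motif_counts))
    expect_identical(sim$motif_counts[[a]], sim$reference$motif_counts)
})

test_that("config invariants are enforced", {
  expect_error(synth_config(n_genes = 3, n_families = 5), "n_families")
  expect_error(synth_config(snp_rate = 1), "snp_rate")
  expect_error(synth_config(spike_seq = "AAGXG"), "ACGT")
  expect_error(planted_motif("m", "ACG"), "length")
  expect_error(planted_motif("m", "ACGTN"), "A/C/G/T")
})
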