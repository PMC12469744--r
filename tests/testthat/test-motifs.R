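# helper: windows of length L with a motif implanted at a random position
# in a given fraction of them
implant_windows <- function(n, L, motif, frac, seed) {
  set.seed(seed)
  w <- vapply(seq_len(n), function(i) random_dna(L), "")
  carry <- seq_len(round(n * frac))
  for (i in carry) {
    pos <- sample.int(L - nchar(motif) + 1, 1)
    substr(w[i], pos, pos + nchar(motif) - 1) <- motif
  }
  w
}

test_that("downsampling is uniform without replacement and respects bounds", {
  pool <- sprintf("w%02d", 1:20)
  full <- downsample_control(pool, 20, seed = 1)
  expect_setequal(full, pool)
  expect_length(downsample_control(pool, 0), 0)
  expect_error(downsample_control(pool, 21), "pool")

  # membership frequency of any window ~ n/|pool| = 0.25
  freq <- rowMeans(vapply(1:300, function(s)
    pool %in% downsample_control(pool, 5, seed = s), logical(20)))
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 300)))
})

test_that("internal Fisher scan equals the hypergeometric-tail oracle", {
  set.seed(23)
  for (i in 1:200) {
    nD <- sample(10:200, 1)
    nC <- sample(10:200, 1)
    a <- sample(0:nD, 1)
    c <- sample(0:nC, 1)
    p_scan <- degcnn:::.fisher_enrichment_p(a, c, nD, nC)
    p_oracle <- fisher.test(matrix(c(a, nD - a, c, nC - c), 2,
                                   byrow = TRUE),
                            alternative = "greater")$p.value
    expect_equal(p_scan, p_oracle, tolerance = 1e-10)
  }
})

test_that("a strongly enriched planted 8-mer is the first discovered motif", {
  motif <- "GATTACAG"
  deg <- implant_windows(200, 150, motif, 0.90, seed = 5)
  ctl <- implant_windows(200, 150, motif, 0.08, seed = 6)
  found <- discover_motifs(deg, ctl, seed = 1)
  expect_gte(length(found), 1)
  # both-strand counting makes a k-mer and its reverse complement the same
  # discovery; either orientation is a recovery
  expect_true(found[[1]]$consensus %in% c(motif, revcomp_chr(motif)))
  expect_lt(found[[1]]$e_value, 0.05)
  expect_gte(found[[1]]$deg_frequency, 0.8)
  # 2x2 margins add up
  cts <- found[[1]]$counts
  expect_equal(unname(cts["a"] + cts["b"]), 200)
  expect_equal(unname(cts["c"] + cts["d"]), 200)
  # the reported p equals a Fisher test on the reported table
  expect_equal(found[[1]]$p_value,
               fisher.test(matrix(cts, 2, byrow = TRUE),
                           alternative = "greater")$p.value,
               tolerance = 1e-10)
})

test_that("identical sets and a zero threshold yield no motifs", {
  w <- implant_windows(50, 100, "GATTACAG", 0.5, seed = 7)
  expect_length(discover_motifs(w, w, seed = 1), 0)
  deg <- implant_windows(100, 100, "GATTACAG", 0.9, seed = 8)
  ctl <- implant_windows(100, 100, "GATTACAG", 0.05, seed = 9)
  expect_length(discover_motifs(deg, ctl, alpha = 0, seed = 1), 0)
})

test_that("motif matches are found on the reverse strand too", {
  motif <- "GATTACAG"
  deg <- implant_windows(150, 120, revcomp_chr(motif), 0.9, seed = 10)
  ctl <- implant_windows(150, 120, "AAAAAAAA", 0.0, seed = 11)
  found <- discover_motifs(deg, ctl, seed = 1)
  expect_gte(length(found), 1)
  expect_true(found[[1]]$consensus %in% c(motif, revcomp_chr(motif)))
})

test_that("per-gene motif counts count distinct motifs, not occurrences", {
  motifs <- discover_motifs(
    implant_windows(100, 100, "GATTACAG", 0.95, seed = 12),
    implant_windows(100, 100, "GATTACAG", 0.02, seed = 13), seed = 1)
  w <- c(g1 = "GATTACAG",                        # exact consensus: count 1
         g2 = random_dna(60, seed = 14),          # likely 0
         g3 = paste0("GATTACAG", random_dna(40, seed = 15), "GATTACAG"))
  counts <- count_motifs_per_gene(w, motifs)
  expect_equal(unname(counts["g1"]), 1)
  expect_lte(unname(counts["g2"]), length(motifs))
  expect_equal(unname(counts["g3"]), 1)  # two occurrences, one distinct motif
  expect_error(count_motifs_per_gene(w, list()), "nonempty")
})

test_that("planted-data counts agree with the generator's bookkeeping", {
  m <- planted_motif("m1", "ACGTATTACG", placement_rate = 1)
  cfg <- synth_config(n_chromosomes = 2, chrom_length = 80000, n_genes = 14,
                      n_families = 5, n_accessions = 1,
                      planted_motifs = list(m), seed = 17)
  sim <- simulate_cold_deg(cfg)
  spans <- vapply(seq_len(nrow(sim$annotations)), function(i) {
    g <- sim$annotations[i, ]
    sp <- if (g$strand == "+") c(g$start - 2000, g$end + 1000)
          else c(g$start - 1000, g$end + 2000)
    substr(sim$genomes[[1]][[g$chrom]], sp[1], sp[2])
  }, "")
  names(spans) <- sim$annotations$gene_id
  got <- count_motifs_per_gene(spans, list(m))
  expect_identical(unname(got > 0),
                   unname(sim$reference$motif_counts[, "m1"] > 0))
})

test_that("self-match against a PFM library scores 1 with a tiny p-value", {
  pfm <- consensus_to_pfm("ACGTTGCAAT")
  res <- match_to_library(pfm, list(self = pfm), n_shuffles = 200, seed = 1)
  expect_equal(res$score[res$target == "self"], 1)
  expect_lt(res$p_value[res$target == "self"], 0.05)
  expect_equal(res$offset[res$target == "self"], 0)
})

test_that("a uniform query cannot match sharp PFMs", {
  q <- matrix(0.25, 4, 8)
  lib <- list(sharp = consensus_to_pfm("ACGTTGCA"))
  res <- match_to_library(q, lib, n_shuffles = 100, seed = 1)
  expect_false(any(res$significant))
  expect_equal(res$score, 0)  # zero-variance columns carry no signal
})

test_that("a reverse-complemented PFM is recovered in the reverse orientation", {
  pfm <- consensus_to_pfm("ACGTTGCAAT")
  q <- degcnn:::.pfm_revcomp(pfm)
  res <- match_to_library(q, list(orig = pfm), n_shuffles = 100, seed = 1)
  expect_equal(res$orientation, "-")
  expect_equal(res$score, 1)
  expect_error(match_to_library(consensus_to_pfm("ACGTA")[, 1:3],
                                list(orig = pfm)), "min_overlap")
})

test_that("MEME minimal format round-trips PFMs", {
  motifs <- list(a = consensus_to_pfm("ACGTTGCA"),
                 b = matrix(c(0.7, 0.1, 0.1, 0.1,
                              0.25, 0.25, 0.25, 0.25), 4, 2))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(motifs, path)
  back <- read_meme(path)
  expect_equal(back$a, motifs$a, ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(back$b, motifs$b, ignore_attr = TRUE, tolerance = 1e-6)
})
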