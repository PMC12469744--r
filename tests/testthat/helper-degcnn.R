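# fixtures are built in code: no data files

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a labeled_set built straight from sequences (any length), bypassing
# genome extraction; used for fast CNN and dataset tests
make_set <- function(seqs, labels, families = NULL, accession = "acc01",
                     mode = "upstream_only") {
  n <- length(seqs)
  L <- nchar(seqs[1])
  x <- array(0, c(n, L, 4))
  for (i in seq_len(n)) x[i, , ] <- one_hot(seqs[i])
  if (is.null(families)) families <- sprintf("fam%03d", seq_len(n))
  labeled_set(x, seqs, labels, sprintf("g%04d", seq_len(n)),
              rep(accession, n), families, mode)
}

# separable toy data: positives carry AAGGG at positions 1-5
make_spike_set <- function(n, L = 60, pos_frac = 0.5, seed = 1) {
  set.seed(seed)
  lab <- as.integer(runif(n) > pos_frac)   # 0 = DEG carries the spike
  seqs <- vapply(seq_len(n), function(i) random_dna(L), "")
  fam <- sprintf("fam%03d", ((seq_len(n) - 1) %% 40) + 1)
  s <- make_set(seqs, lab, families = fam)
  inject_spike(s, "AAGGG", target_class = 0L)
}

# brute-force step integration of the precision-recall curve,
# independent of pr_auc()'s cumulative-sum implementation
prauc_bruteforce <- function(score, pos) {
  ths <- sort(unique(score), decreasing = TRUE)
  prec <- rec <- numeric(length(ths))
  for (i in seq_along(ths)) {
    sel <- score >= ths[i]
    prec[i] <- sum(pos & sel) / sum(sel)
    rec[i] <- sum(pos & sel) / sum(pos)
  }
  sum(diff(c(0, rec)) * prec)
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}
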