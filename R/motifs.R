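#' @importFrom stats phyper cor
#' @import data.table
NULL

#' Randomly down-sample the non-DEG control windows
#'
#' The non-DEG class outnumbers DEGs about 11:1; enrichment is therefore
#' tested against a uniform, without-replacement sample of the non-DEG
#' windows, by default of the same size as the DEG set.
#'
#' @param non_deg_windows character vector of windows.
#' @param n sample size (must not exceed the pool size).
#' @param seed seed; deterministic per seed.
#' @return character vector of length `n`.
#' @export
downsample_control <- function(non_deg_windows, n, seed = 1L) {
  if (n > length(non_deg_windows))
    stop("cannot sample ", n, " windows from a pool of ",
         length(non_deg_windows))
  set.seed(seed)
  if (n == 0L) return(character(0))
  non_deg_windows[sample.int(length(non_deg_windows), n)]
}

# per-window presence counts of every k-mer (both strands optionally);
# returns data.table(kmer, n) where n = number of windows containing >= 1 hit
.kmer_presence <- function(windows, k_range, both_strands) {
  if (both_strands) windows <- c(windows, .revcomp(windows))
  pieces <- vector("list", length(windows) * length(k_range))
  wins <- integer(length(pieces))
  pi <- 0L
  for (wi in seq_along(windows)) {
    w <- windows[wi]
    L <- nchar(w)
    for (k in k_range) {
      if (L < k) next
      pi <- pi + 1L
      pieces[[pi]] <- unique(substring(w, 1:(L - k + 1L), k:L))
      wins[pi] <- wi
    }
  }
  pieces <- pieces[seq_len(pi)]
  # a window and its reverse complement are the same window: presence on
  # either strand counts once, via the fold-back and unique() below
  kmer <- NULL; n <- NULL  # appease R CMD check
  dt <- data.table(kmer = unlist(pieces, use.names = FALSE),
                   win = rep(wins[seq_len(pi)], lengths(pieces)))
  if (both_strands) {
    nw <- length(windows) / 2L
    dt[, win := ((win - 1L) %% nw) + 1L]
    dt <- unique(dt)
  }
  dt <- dt[!grepl("N", kmer, fixed = TRUE)]
  dt[, .(n = .N), by = kmer]
}

.hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

.mask_matches <- function(windows, consensus) {
  mask <- strrep("N", nchar(consensus))
  windows <- gsub(consensus, mask, windows, fixed = TRUE)
  rc <- .revcomp(consensus)
  if (rc != consensus) windows <- gsub(rc, mask, windows, fixed = TRUE)
  windows
}

# one-sided (enrichment) Fisher p for the 2x2 presence table
# [a, nD - a; c, nC - c]; equals the hypergeometric upper tail.
.fisher_enrichment_p <- function(a, c, nD, nC) {
  phyper(a - 1L, a + c, (nD - a) + (nC - c), nD, lower.tail = FALSE)
}

#' De novo k-mer motif discovery by enrichment
#'
#' A desk-scale screen with the same contract as a STREME run: iteratively
#' propose the k-mer (over all lengths in `k_range`, both strands) whose
#' presence/absence 2x2 table against the control set has the smallest
#' one-sided Fisher p-value; the e-value is that p-value times the number of
#' distinct candidates evaluated in the round. Candidates with e-value at or
#' below `alpha` are emitted and their matches masked; candidates within
#' Hamming distance 1 of an already emitted motif are treated as the same
#' motif (masked, not re-emitted). The search stops after `stop_after`
#' consecutive rounds whose best e-value exceeds `alpha`.
#'
#' @param deg_windows,control_windows character vectors of window sequences.
#' @param k_range integer k-mer lengths to scan (default 5:12).
#' @param alpha e-value threshold (default 0.05).
#' @param stop_after consecutive failures before stopping (default 3).
#' @param seed kept for interface stability; the scan is deterministic.
#' @param both_strands match k-mers on both strands (default TRUE).
#' @param max_rounds hard cap on discovery rounds.
#' @return a `motif_set`: list of `motif` objects (id, consensus, pfm,
#'   p_value, e_value, deg_frequency, counts a/b/c/d), sorted by e-value.
#'   `as.data.frame()` gives the enrichment report.
#' @export
discover_motifs <- function(deg_windows, control_windows, k_range = 5:12,
                            alpha = 0.05, stop_after = 3L, seed = 1L,
                            both_strands = TRUE, max_rounds = 25L) {
  if (!length(deg_windows) || !length(control_windows))
    stop("both window sets must be nonempty")
  set.seed(seed)
  nD <- length(deg_windows)
  nC <- length(control_windows)
  motifs <- list()
  failures <- 0L
  kmer <- NULL; p <- NULL; a <- NULL; n <- NULL  # NSE bindings
  for (round in seq_len(max_rounds)) {
    cd <- .kmer_presence(deg_windows, k_range, both_strands)
    cc <- .kmer_presence(control_windows, k_range, both_strands)
    setnames(cd, "n", "a")
    setnames(cc, "n", "c")
    tab <- merge(cd, cc, by = "kmer", all = TRUE)
    if (nrow(tab) == 0L) break
    tab[is.na(tab)] <- 0L
    n_candidates <- nrow(tab)
    tab[, p := .fisher_enrichment_p(a, c, nD, nC)]
    setorder(tab, p, -a, kmer)
    best <- tab[1L]
    e_value <- best$p * n_candidates
    if (e_value <= alpha) {
      merged <- FALSE
      for (m in motifs) {
        if (.hamming(best$kmer, m$consensus) <= 1L) { merged <- TRUE; break }
      }
      if (!merged) {
        motifs[[length(motifs) + 1L]] <- structure(list(
          id = sprintf("m%02d", length(motifs) + 1L),
          consensus = best$kmer,
          pfm = consensus_to_pfm(best$kmer),
          p_value = best$p, e_value = e_value,
          deg_frequency = best$a / nD,
          counts = c(a = best$a, b = nD - best$a,
                     c = best$c, d = nC - best$c)
        ), class = "motif")
        failures <- 0L
      }
      deg_windows <- .mask_matches(deg_windows, best$kmer)
      control_windows <- .mask_matches(control_windows, best$kmer)
    } else {
      # a failed round masks nothing, so every following round would see the
      # same windows and the same best candidate: the `stop_after` consecutive
      # failures accumulate deterministically without rescanning
      failures <- failures + stop_after
      if (failures >= stop_after) break
    }
  }
  motifs <- motifs[order(vapply(motifs, `[[`, numeric(1), "e_value"))]
  structure(motifs, class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat("<motif_set> of", length(x), "motifs\n")
  if (length(x)) print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.motif_set <- function(x, ...) {
  if (!length(x))
    return(data.frame(id = character(), consensus = character(),
                      length = integer(), p_value = numeric(),
                      e_value = numeric(), deg_frequency = numeric()))
  data.frame(
    id = vapply(x, `[[`, "", "id"),
    consensus = vapply(x, `[[`, "", "consensus"),
    length = vapply(x, function(m) nchar(m$consensus), integer(1)),
    p_value = vapply(x, `[[`, numeric(1), "p_value"),
    e_value = vapply(x, `[[`, numeric(1), "e_value"),
    deg_frequency = vapply(x, `[[`, numeric(1), "deg_frequency"),
    stringsAsFactors = FALSE)
}

#' Position frequency matrix of an exact consensus
#' @param consensus DNA string.
#' @return 4 x L matrix (rows A, C, G, T), columns summing to 1.
#' @export
consensus_to_pfm <- function(consensus) {
  t(one_hot(consensus))
}

#' Count discovered motifs per gene
#'
#' The count for a gene is the number of distinct motifs with at least one
#' match (either strand) in any of the gene's windows -- the quantity compared
#' between correctly and incorrectly predicted genes.
#'
#' @param windows named character vector of windows; names are gene ids and
#'   may repeat (several windows per gene).
#' @param motifs a `motif_set` or list of objects with a `consensus`.
#' @return named integer vector, one entry per gene.
#' @export
count_motifs_per_gene <- function(windows, motifs) {
  if (!length(motifs)) stop("motifs must be nonempty")
  genes <- unique(names(windows))
  if (is.null(genes)) stop("windows must be named by gene id")
  out <- setNames(integer(length(genes)), genes)
  if (!length(windows)) return(out)
  ss <- DNAStringSet(windows)
  for (m in motifs) {
    hit <- vcountPattern(m$consensus, ss) > 0L
    rc <- .revcomp(m$consensus)
    if (rc != m$consensus) hit <- hit | (vcountPattern(rc, ss) > 0L)
    gene_hit <- tapply(hit, names(windows), any)
    out[names(gene_hit)] <- out[names(gene_hit)] + as.integer(gene_hit)
  }
  out
}

# ---- PFM library matching ------------------------------------------------

.pfm_revcomp <- function(pfm) {
  pfm[c("T", "G", "C", "A"), rev(seq_len(ncol(pfm))), drop = FALSE]
}

# Pearson correlation of two frequency columns; zero-variance columns
# (e.g. uniform background) carry no orientation information and score 0
.col_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

.best_alignment_score <- function(q, p, min_overlap) {
  Lq <- ncol(q); Lp <- ncol(p)
  best <- -Inf; best_off <- NA_integer_
  for (off in seq(-(Lq - min_overlap), Lp - min_overlap)) {
    i <- seq_len(Lq)
    j <- i + off
    keep <- j >= 1L & j <= Lp
    if (sum(keep) < min_overlap) next
    sc <- mean(vapply(which(keep),
                      function(ii) .col_cor(q[, ii], p[, ii + off]),
                      numeric(1)))
    if (sc > best) { best <- sc; best_off <- off }
  }
  list(score = best, offset = best_off)
}

#' Match a discovered motif against a PFM library
#'
#' For every library PFM, scores all alignment offsets (both orientations)
#' with at least `min_overlap` overlapping columns by the mean per-column
#' Pearson correlation of the frequency vectors, and estimates a p-value as
#' the fraction of column-shuffled queries whose best score reaches the
#' observed one.
#'
#' @param query a `motif` or a 4 x L PFM matrix (rows A, C, G, T).
#' @param library named list of 4 x L PFM matrices (see [read_meme()]).
#' @param min_overlap minimum aligned columns (default 5).
#' @param n_shuffles column shuffles for the null (default 1000).
#' @param seed seed for the shuffles.
#' @return data.frame: target, score, orientation, offset, p_value,
#'   significant (p < 0.05), ordered by p then -score.
#' @export
match_to_library <- function(query, library, min_overlap = 5L,
                             n_shuffles = 1000L, seed = 1L) {
  q <- if (inherits(query, "motif")) query$pfm else query
  stopifnot(is.matrix(q), nrow(q) == 4L)
  rownames(q) <- c("A", "C", "G", "T")
  if (ncol(q) < min_overlap)
    stop("query has ", ncol(q), " columns; need at least min_overlap = ",
         min_overlap)
  for (p in library)
    if (!is.matrix(p) || nrow(p) != 4L) stop("library PFMs must be 4 x L matrices")
  set.seed(seed)
  shuffles <- replicate(n_shuffles, sample.int(ncol(q)), simplify = FALSE)
  res <- lapply(names(library), function(nm) {
    p <- library[[nm]]
    rownames(p) <- c("A", "C", "G", "T")
    fwd <- .best_alignment_score(q, p, min_overlap)
    rev <- .best_alignment_score(.pfm_revcomp(q), p, min_overlap)
    if (fwd$score >= rev$score) {
      obs <- fwd; orient <- "+"
    } else {
      obs <- rev; orient <- "-"
    }
    null_scores <- vapply(shuffles, function(sh) {
      qs <- q[, sh, drop = FALSE]
      max(.best_alignment_score(qs, p, min_overlap)$score,
          .best_alignment_score(.pfm_revcomp(qs), p, min_overlap)$score)
    }, numeric(1))
    pval <- mean(null_scores >= obs$score)
    data.frame(target = nm, score = obs$score, orientation = orient,
               offset = obs$offset, p_value = pval,
               significant = pval < 0.05, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$p_value, -out$score), , drop = FALSE]
}

#' Write motifs in MEME minimal format
#' @param motifs a `motif_set`, list of `motif` objects, or named list of
#'   4 x L PFMs.
#' @param path output file.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  if (inherits(motifs, "motif_set") ||
      (length(motifs) && inherits(motifs[[1]], "motif"))) {
    ids <- vapply(motifs, `[[`, "", "id")
    pfms <- lapply(motifs, `[[`, "pfm")
  } else {
    ids <- names(motifs)
    pfms <- motifs
  }
  for (i in seq_along(pfms)) {
    pfm <- pfms[[i]]
    writeLines(sprintf("MOTIF %s", ids[i]), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(pfm)), con)
    writeLines(apply(t(pfm), 1L, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from MEME minimal format
#' @param path MEME file.
#' @return named list of 4 x L PFM matrices (rows A, C, G, T).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  idx <- grep("^MOTIF ", lines)
  out <- list()
  for (i in idx) {
    id <- sub("^MOTIF\\s+(\\S+).*$", "\\1", lines[i])
    hdr <- i + 1L
    while (hdr <= length(lines) && !grepl("letter-probability matrix", lines[hdr]))
      hdr <- hdr + 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    pfm <- t(mat)
    rownames(pfm) <- c("A", "C", "G", "T")
    out[[id]] <- pfm
  }
  out
}
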