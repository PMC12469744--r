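#' @importFrom Biostrings DNAStringSet reverseComplement readDNAStringSet
#'   writeXStringSet vcountPattern
NULL

# Window conventions, relative to the gene's 5'->3' orientation.
# A window of convention (up, down) anchored at position a covers offsets
# -up .. +down-1, i.e. the anchor base itself is the first "downstream" base.
.window_conventions <- data.frame(
  name   = c("streme_tss", "streme_tts", "cnn_tss", "cnn_tts", "upstream_only"),
  anchor = c("tss", "tts", "tss", "tts", "tss"),
  up_bp  = c(500L, 500L, 1000L, 500L, 2000L),
  down_bp = c(500L, 500L, 500L, 1000L, 0L),
  stringsAsFactors = FALSE
)

#' Window conventions for regulatory-region extraction
#'
#' Returns the five supported window conventions: `streme_tss`/`streme_tts`
#' (500 bp either side of the TSS/TTS, used for the motif-enrichment screen),
#' `cnn_tss` (1000 up / 500 down of the TSS) and `cnn_tts` (500 up / 1000 down
#' of the TTS) used as CNN input, and `upstream_only` (2000 bp upstream of
#' the TSS).
#'
#' @return data.frame with columns name, anchor, up_bp, down_bp.
#' @export
window_conventions <- function() .window_conventions

.get_convention <- function(convention) {
  i <- match(convention, .window_conventions$name)
  if (is.na(i))
    stop("unknown window convention: '", convention, "' (see window_conventions())")
  .window_conventions[i, ]
}

.revcomp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

#' Extract a strand-oriented regulatory window
#'
#' The anchor is the TSS (annotated gene start on `+`, gene end on `-`) or the
#' TTS (gene end on `+`, gene start on `-`). The window spans `up_bp` bases
#' before through `down_bp` bases after the anchor in the gene's 5'->3'
#' orientation; minus-strand windows are reverse-complemented so that
#' "upstream" is always leftmost. Overhang beyond the chromosome ends is
#' filled with `N`; the result always has length `up_bp + down_bp`.
#'
#' @param genome named character vector of chromosome sequences (see
#'   [read_genome_fasta()]).
#' @param gene one [GeneAnnotation][gene_annotation] row: a list or one-row
#'   data.frame with `chrom`, `start`, `end`, `strand` (1-based inclusive).
#' @param convention one of the names in [window_conventions()].
#' @return a single DNA string.
#' @export
extract_window <- function(genome, gene, convention) {
  cv <- .get_convention(convention)
  chrom <- as.character(gene$chrom)
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not present in genome")
  chrom_seq <- genome[[chrom]]
  chrom_len <- nchar(chrom_seq)
  strand <- as.character(gene$strand)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")

  if (strand == "+") {
    anchor <- if (cv$anchor == "tss") gene$start else gene$end
    a <- anchor - cv$up_bp
    b <- anchor + cv$down_bp - 1L
  } else {
    anchor <- if (cv$anchor == "tss") gene$end else gene$start
    # offsets -up..+down-1 in gene orientation map to reference
    # positions anchor+up .. anchor-down+1
    a <- anchor - cv$down_bp + 1L
    b <- anchor + cv$up_bp
  }
  lo <- max(a, 1L)
  hi <- min(b, chrom_len)
  core <- if (lo > hi) "" else substr(chrom_seq, lo, hi)
  out <- paste0(strrep("N", lo - a), core, strrep("N", b - hi))
  if (strand == "-") out <- .revcomp(out)
  out
}

#' One-hot encode a DNA sequence
#'
#' Channels are ordered A, C, G, T. `N` rows are all zero, so the matrix sum
#' equals the number of non-N bases. Case-insensitive.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @return an `L x 4` numeric matrix with column names A, C, G, T.
#' @export
one_hot <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  idx <- match(chars, bases)
  bad <- which(is.na(idx) & chars != "N")
  if (length(bad))
    stop("cannot encode character '", chars[bad[1L]], "' at position ", bad[1L])
  m <- matrix(0, nrow = length(chars), ncol = 4L,
              dimnames = list(NULL, bases))
  ok <- which(!is.na(idx))
  m[cbind(ok, idx[ok])] <- 1
  m
}

#' Decode a one-hot matrix back to sequence
#'
#' All-zero rows decode to `N`.
#'
#' @param mat an `L x 4` one-hot matrix (channels A, C, G, T).
#' @return DNA string of length `L`.
#' @export
decode_one_hot <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) == 4L)
  bases <- c("A", "C", "G", "T")
  out <- rep("N", nrow(mat))
  hit <- max.col(mat, ties.method = "first")
  nonzero <- rowSums(mat) > 0
  out[nonzero] <- bases[hit[nonzero]]
  paste(out, collapse = "")
}

#' Build the model input for one gene in one accession
#'
#' `both_regions` concatenates the `cnn_tss` window (1000 bp upstream + 500 bp
#' downstream of the TSS) and then the `cnn_tts` window (500 bp upstream +
#' 1000 bp downstream of the TTS), for 3000 bp in total; `upstream_only` uses
#' the single 2000 bp window upstream of the TSS.
#'
#' @param gene one annotation row (see [extract_window()]).
#' @param accession accession identifier carried through to the result.
#' @param genome named character vector of that accession's chromosomes.
#' @param mode `"both_regions"` (L = 3000) or `"upstream_only"` (L = 2000).
#' @param label optional 0/1 label (0 = DEG, 1 = non-DEG).
#' @return a `regulatory_input` object: gene_id, accession_id, conventions,
#'   sequence, onehot, label.
#' @export
build_input <- function(gene, accession, genome,
                        mode = c("both_regions", "upstream_only"),
                        label = NULL) {
  mode <- match.arg(mode)
  if (mode == "both_regions") {
    conventions <- c("cnn_tss", "cnn_tts")
    seq <- paste0(extract_window(genome, gene, "cnn_tss"),
                  extract_window(genome, gene, "cnn_tts"))
  } else {
    conventions <- "upstream_only"
    seq <- extract_window(genome, gene, "upstream_only")
  }
  structure(list(
    gene_id = as.character(gene$gene_id),
    accession_id = as.character(accession),
    conventions = conventions,
    sequence = seq,
    onehot = one_hot(seq),
    label = label
  ), class = "regulatory_input")
}

#' @export
print.regulatory_input <- function(x, ...) {
  cat("<regulatory_input> gene", x$gene_id, "accession", x$accession_id,
      "| mode:", paste(x$conventions, collapse = "+"),
      "| L =", nchar(x$sequence), "\n")
  invisible(x)
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector, one element per chromosome.
#' @export
read_genome_fasta <- function(path) {
  ss <- readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
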