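#' Construct a labeled set of regulatory inputs
#'
#' A `labeled_set` bundles the one-hot tensor, the raw window sequences and
#' the record metadata for one DEG contrast. Each (gene, accession) pair is
#' one record, so a gene appears once per accession. Label 0 is the DEG class
#' of the contrast under study, label 1 the non-DEG class.
#'
#' @param x numeric array `N x L x 4` (channels A, C, G, T).
#' @param seq character vector of the N window sequences.
#' @param label integer vector of 0/1 labels.
#' @param gene_id,accession,family_id record metadata vectors.
#' @param mode `"both_regions"` or `"upstream_only"`.
#' @return a `labeled_set`.
#' @export
labeled_set <- function(x, seq, label, gene_id, accession, family_id,
                        mode = "both_regions") {
  n <- length(label)
  stopifnot(dim(x)[1] == n, length(seq) == n, length(gene_id) == n,
            length(accession) == n, length(family_id) == n,
            all(label %in% c(0L, 1L)))
  structure(list(x = x, seq = seq, label = as.integer(label),
                 gene_id = as.character(gene_id),
                 accession = as.character(accession),
                 family_id = as.character(family_id), mode = mode),
            class = "labeled_set")
}

#' @export
print.labeled_set <- function(x, ...) {
  cts <- class_counts(x)
  cat("<labeled_set> ", length(x$label), " records (", x$mode,
      ", L = ", dim(x$x)[2], ") | class 0 (DEG): ", cts[["0"]],
      ", class 1 (non): ", cts[["1"]], "\n", sep = "")
  invisible(x)
}

#' Class counts of a labeled set
#' @param set a [labeled_set()].
#' @return named integer vector with elements `"0"` (DEG) and `"1"` (non).
#' @export
class_counts <- function(set) {
  c("0" = sum(set$label == 0L), "1" = sum(set$label == 1L))
}

#' Subset a labeled set by record index
#' @param set a [labeled_set()].
#' @param idx integer indices (repeats allowed, e.g. for oversampling).
#' @return a [labeled_set()].
#' @export
subset_records <- function(set, idx) {
  labeled_set(set$x[idx, , , drop = FALSE], set$seq[idx], set$label[idx],
              set$gene_id[idx], set$accession[idx], set$family_id[idx],
              set$mode)
}

#' Assemble labeled inputs for one contrast across accessions
#'
#' Extracts the model windows for every gene whose status (in the given
#' accession) is either the contrast class or "non", encodes them, and labels
#' the contrast class 0 and non-DEGs 1.
#'
#' @param genomes named list of per-accession genomes.
#' @param annotations gene annotation data.frame (with `family_id`).
#' @param labels data.frame gene_id/accession/status.
#' @param contrast `"up"` or `"down"`: the DEG class of interest.
#' @param mode window mode, see [build_input()].
#' @return a [labeled_set()].
#' @export
build_labeled_set <- function(genomes, annotations, labels,
                              contrast = c("up", "down"),
                              mode = c("both_regions", "upstream_only")) {
  contrast <- match.arg(contrast)
  mode <- match.arg(mode)
  keep <- labels[labels$status %in% c(contrast, "non"), , drop = FALSE]
  keep <- keep[keep$accession %in% names(genomes), , drop = FALSE]
  ann_idx <- match(keep$gene_id, annotations$gene_id)
  if (anyNA(ann_idx)) stop("labels refer to genes absent from the annotation")
  n <- nrow(keep)
  L <- if (mode == "both_regions") 3000L else 2000L
  x <- array(0, dim = c(n, L, 4L))
  seqs <- character(n)
  for (i in seq_len(n)) {
    inp <- build_input(annotations[ann_idx[i], ], keep$accession[i],
                       genomes[[keep$accession[i]]], mode = mode)
    seqs[i] <- inp$sequence
    x[i, , ] <- inp$onehot
  }
  labeled_set(x, seqs, as.integer(keep$status == "non"),
              keep$gene_id, keep$accession,
              annotations$family_id[ann_idx], mode)
}

#' Specification of the family-disjoint split
#'
#' @param test_fraction fraction of records held out as the test set
#'   (default 0.20).
#' @param validation_fraction_of_train fraction of the remaining training
#'   records carved out as the validation set (default 0.20).
#' @param seed seed for the family shuffle.
#' @return a `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.20,
                       validation_fraction_of_train = 0.20, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1 ||
      validation_fraction_of_train <= 0 || validation_fraction_of_train >= 1)
    stop("fractions must be in (0, 1)")
  structure(list(test_fraction = test_fraction,
                 validation_fraction_of_train = validation_fraction_of_train,
                 seed = as.integer(seed)), class = "split_spec")
}

# greedy family accumulation: shuffle families, then take whole families
# until the cumulative record fraction reaches the target
.greedy_families <- function(family_of_record, fams, target_fraction) {
  sizes <- vapply(fams, function(f) sum(family_of_record == f), integer(1))
  cum <- cumsum(sizes) / length(family_of_record)
  k <- which(cum >= target_fraction)[1L]
  if (is.na(k)) k <- length(fams)
  fams[seq_len(k)]
}

#' Split records into train/validation/test with family disjointness
#'
#' Genes from the same family share regulatory sequence by descent, so a
#' random gene-level split would leak training information into the test set.
#' Units of assignment are therefore whole gene families: the family list is
#' shuffled and families are accumulated greedily until the target record
#' fraction is reached, first for the test set, then (from the remainder) for
#' the validation set. No family appears in more than one partition.
#'
#' @param records a [labeled_set()] or a data.frame with a `family_id` column.
#' @param spec a [split_spec()].
#' @return list with elements `train`, `validation`, `test` of the same type
#'   as `records`.
#' @export
split_by_family <- function(records, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  fam <- if (inherits(records, "labeled_set")) records$family_id
         else records$family_id
  if (is.null(fam)) stop("records must carry a family_id")
  fams <- unique(fam)
  if (length(fams) < 3L)
    stop("need at least 3 gene families to split, got ", length(fams))
  set.seed(spec$seed)
  fams <- sample(fams)
  test_f <- .greedy_families(fam, fams, spec$test_fraction)
  rest <- setdiff(fams, test_f)
  fam_rest <- fam[fam %in% rest]
  val_f <- .greedy_families(fam_rest, rest, spec$validation_fraction_of_train)
  part <- ifelse(fam %in% test_f, "test",
                 ifelse(fam %in% val_f, "validation", "train"))
  take <- function(p) {
    idx <- which(part == p)
    if (inherits(records, "labeled_set")) subset_records(records, idx)
    else records[idx, , drop = FALSE]
  }
  list(train = take("train"), validation = take("validation"),
       test = take("test"))
}

#' Oversample the minority class to a 1:1 ratio
#'
#' Resamples minority-class records with replacement until both classes have
#' equal counts; majority records are untouched. Apply to the training set
#' only -- validation and test sets must keep the original class ratio.
#'
#' @param set a [labeled_set()].
#' @param seed seed for the resampling.
#' @return a [labeled_set()] with equal class counts.
#' @export
oversample <- function(set, seed = 1L) {
  stopifnot(inherits(set, "labeled_set"))
  cts <- class_counts(set)
  if (any(cts == 0L)) stop("both classes must be nonempty to oversample")
  if (cts[["0"]] == cts[["1"]]) return(set)
  minority <- if (cts[["0"]] < cts[["1"]]) 0L else 1L
  need <- abs(diff(cts))
  set.seed(seed)
  extra <- sample(which(set$label == minority), need, replace = TRUE)
  subset_records(set, c(seq_along(set$label), extra))
}

#' Overwrite the start of positive-class windows with a spike sequence
#'
#' Replaces the first `nchar(spike_seq)` bases of the upstream window of every
#' record of `target_class` with `spike_seq` (default "AAGGG"), keeping the
#' sequence and the one-hot encoding consistent. A deterministic, perfectly
#' predictive positive control: a model unable to learn it is limited by its
#' architecture, not by the data. Idempotent.
#'
#' @param set a [labeled_set()].
#' @param spike_seq DNA string over A/C/G/T, at most the window length.
#' @param target_class label value whose records are spiked (default 0, the
#'   DEG class).
#' @return the modified [labeled_set()]; the number of records modified is
#'   available as `attr(result, "n_spiked")`.
#' @export
inject_spike <- function(set, spike_seq = "AAGGG", target_class = 0L) {
  stopifnot(inherits(set, "labeled_set"))
  spike_seq <- toupper(spike_seq)
  if (!grepl("^[ACGT]+$", spike_seq))
    stop("spike_seq must match [ACGT]+")
  k <- nchar(spike_seq)
  if (k > dim(set$x)[2]) stop("spike longer than the window")
  idx <- which(set$label == target_class)
  if (length(idx)) {
    substr(set$seq[idx], 1L, k) <- spike_seq
    s_oh <- one_hot(spike_seq)
    for (j in seq_len(k))
      for (ch in 1:4)
        set$x[idx, j, ch] <- s_oh[j, ch]
  }
  attr(set, "n_spiked") <- length(idx)
  set
}
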