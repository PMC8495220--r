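# Clone assignment: records sharing V gene, J gene and CDR3 length are linked
# when their CDR3 nucleotide identity reaches the chain threshold; clones are
# the connected components of that link graph (single linkage). Records are
# bucketed by (V gene, J gene, CDR3 length) first, which cannot change the
# partition because links are impossible across buckets.

#' CDR3 nucleotide identity between two equal-length sequences
#'
#' @param a,b Nucleotide strings of equal length.
#' @return Fraction of matching positions in `[0, 1]`.
#' @export
cdr3_identity <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("cdr3_identity requires equal-length sequences; group by length first")
  ia <- utf8ToInt(a)
  sum(ia == utf8ToInt(b)) / length(ia)
}

# Maximum Hamming distance still meeting `identity >= threshold` on length L.
max_mismatches <- function(L, threshold) floor((1 - threshold) * L + 1e-9)

# Pairwise Hamming distances between the columns of an integer code matrix
# (L x u), via per-base indicator cross-products.
hamming_matrix <- function(codes) {
  L <- nrow(codes)
  matches <- matrix(0, ncol(codes), ncol(codes))
  for (b in c(65L, 67L, 71L, 84L)) { # A C G T
    I <- codes == b
    storage.mode(I) <- "double"
    matches <- matches + crossprod(I)
  }
  L - matches
}

seq_codes <- function(seqs, L) {
  matrix(utf8ToInt(paste(seqs, collapse = "")), nrow = L)
}

# Connected components of sequences within one (V, J, length) bucket at the
# given identity threshold. Returns an integer component label per sequence.
bucket_components <- function(seqs, threshold) {
  u <- length(seqs)
  if (u == 1L) return(1L)
  L <- nchar(seqs[1L])
  dmax <- max_mismatches(L, threshold)
  if (dmax <= 0) return(seq_len(u)) # only identical sequences link; seqs are distinct
  if (u == 2L) {
    codes <- seq_codes(seqs, L)
    linked <- sum(codes[, 1L] != codes[, 2L]) <= dmax
    return(if (linked) c(1L, 1L) else 1:2)
  }
  d <- hamming_matrix(seq_codes(seqs, L))
  # union-find over linked pairs
  parent <- seq_len(u)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  idx <- which(d <= dmax & upper.tri(d), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    ri <- find(idx[k, 1L]); rj <- find(idx[k, 2L])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(u), find, integer(1))
  match(roots, unique(roots))
}

# Shared core: clone labels for a record data frame. Identical (V, J, CDR3)
# tuples collapse to one vertex before pairwise comparison; the returned
# labels are per input record. Singleton buckets and buckets holding a single
# distinct sequence take a fast path.
clone_labels <- function(records, threshold) {
  n <- nrow(records)
  if (n == 0L) return(integer(0))
  v <- strip_allele(records$v_call)
  j <- strip_allele(records$j_call)
  len <- nchar(records$cdr3_nt)
  bucket <- paste(v, j, len, sep = "\r")
  labels <- integer(n)
  offset <- 0L
  for (idx in split(seq_len(n), bucket)) {
    if (length(idx) == 1L) {
      labels[idx] <- offset + 1L
      offset <- offset + 1L
      next
    }
    seqs <- records$cdr3_nt[idx]
    uniq <- unique(seqs)
    if (length(uniq) == 1L) {
      labels[idx] <- offset + 1L
      offset <- offset + 1L
      next
    }
    comp_u <- bucket_components(uniq, threshold)
    comp <- comp_u[match(seqs, uniq)]
    labels[idx] <- comp + offset
    offset <- offset + max(comp)
  }
  labels
}

#' Assign records of one sample and chain to clones
#'
#' Partitions the records into connected components of the graph whose edges
#' join records with equal V gene, equal J gene (allele suffixes stripped),
#' equal CDR3 length and CDR3 identity at or above `threshold` (inclusive).
#'
#' @param records Record data frame (columns `v_call`, `j_call`, `cdr3_nt`,
#'   `count`) from a single sample and chain.
#' @param threshold Identity threshold in `(0, 1]`; see [chain_threshold()].
#' @return A `clone_table`: list with `assignment` (integer clone label per
#'   record), `clones` (data frame `clone_id`, `n_members`, `clone_reads`) and
#'   `n_clones`.
#' @export
assign_clones <- function(records, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  labels <- clone_labels(records, threshold)
  if (length(labels) == 0L) {
    return(structure(list(assignment = integer(0),
                          clones = data.frame(clone_id = integer(0),
                                              n_members = integer(0),
                                              clone_reads = integer(0)),
                          n_clones = 0L),
                     class = "clone_table"))
  }
  reads <- as.vector(rowsum(as.numeric(records$count), labels))
  members <- as.vector(table(labels))
  structure(list(
    assignment = labels,
    clones = data.frame(clone_id = sort(unique(labels)),
                        n_members = members,
                        clone_reads = as.integer(reads)),
    n_clones = max(labels)
  ), class = "clone_table")
}

#' @export
print.clone_table <- function(x, ...) {
  cat(sprintf("clone_table: %d clones over %d records, %d reads\n",
              x$n_clones, length(x$assignment), sum(x$clones$clone_reads)))
  invisible(x)
}

# Clonotype identifiers are stable across runs: the tuple
# chain|V|J|length|<lexicographically smallest member CDR3>.

#' Build the samples x clonotypes count matrix
#'
#' Pools the records of every sample (one chain class), clusters them globally
#' with the same single-linkage clone definition as [assign_clones()], and
#' fills the count matrix with each sample's reads per global cluster
#' (clonotype). Zero cells are true zeros.
#'
#' @param cohort An `ir_cohort`.
#' @param chain Chain to pool (e.g. `"IGK"`).
#' @param threshold Identity threshold; default taken from the chain class.
#' @return A `clonotype_matrix`: list with `counts` (samples x clonotypes
#'   integer matrix, dimnames set), `clonotype_ids`, `chain`, `threshold`,
#'   and `assignment` (pooled record data frame with its clonotype id).
#' @export
build_clonotype_matrix <- function(cohort, chain, threshold = NULL) {
  stopifnot(inherits(cohort, "ir_cohort"))
  chain <- match.arg(chain, IR_CHAINS)
  threshold <- threshold %||% chain_threshold(chain)
  rec <- cohort$records[cohort$records$chain == chain, , drop = FALSE]
  samples <- cohort_samples(cohort)
  if (nrow(rec) == 0L) {
    counts <- matrix(0L, nrow = length(samples), ncol = 0,
                     dimnames = list(samples, NULL))
    return(structure(list(counts = counts, clonotype_ids = character(0),
                          chain = chain, threshold = threshold,
                          assignment = cbind(rec, clonotype_id = character(0))),
                     class = "clonotype_matrix"))
  }
  labels <- clone_labels(rec, threshold)
  # smallest member CDR3 per cluster, vectorised: first row per label after
  # ordering by (label, cdr3)
  ord <- order(labels, rec$cdr3_nt)
  first <- ord[!duplicated(labels[ord])]
  ids_by_label <- paste(chain, strip_allele(rec$v_call[first]),
                        strip_allele(rec$j_call[first]),
                        nchar(rec$cdr3_nt[first]), rec$cdr3_nt[first],
                        sep = "|")
  # `first` is ordered by label value, so position k holds label k's id
  rec$clonotype_id <- ids_by_label[labels]
  all_ids <- sort(unique(ids_by_label))
  counts <- matrix(0L, nrow = length(samples), ncol = length(all_ids),
                   dimnames = list(samples, all_ids))
  row <- match(rec$sample_id, samples)
  col <- match(rec$clonotype_id, all_ids)
  lin <- (col - 1L) * length(samples) + row
  agg <- rowsum(as.numeric(rec$count), lin)
  counts[as.integer(rownames(agg))] <- as.integer(agg)
  structure(list(counts = counts, clonotype_ids = colnames(counts),
                 chain = chain, threshold = threshold, assignment = rec),
            class = "clonotype_matrix")
}

#' @export
print.clonotype_matrix <- function(x, ...) {
  cat(sprintf("clonotype_matrix [%s, threshold %.2f]: %d samples x %d clonotypes\n",
              x$chain, x$threshold, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Drop rarely shared clonotypes
#'
#' Keeps clonotypes present (count > 0) in at least `min_presence` of the
#' samples. An all-but-one-zero column carries no cross-sample compositional
#' information, and the pooled matrix is extremely sparse without this filter.
#' When no clonotype passes, the chain has insufficient cross-sample overlap
#' for compositional analysis (the situation reported for T-cell chains) and
#' an error of class `tumorir_insufficient_overlap` is signalled.
#'
#' @param cmat A `clonotype_matrix`.
#' @param min_presence Minimum fraction of samples a clonotype must appear in
#'   (default 0.05).
#' @return The filtered `clonotype_matrix`.
#' @export
filter_clonotypes <- function(cmat, min_presence = 0.05) {
  stopifnot(inherits(cmat, "clonotype_matrix"))
  pres <- colMeans(cmat$counts > 0)
  keep <- pres >= min_presence
  if (!any(keep)) {
    stop(structure(class = c("tumorir_insufficient_overlap", "error", "condition"),
                   list(message = sprintf(
                     "insufficient overlapping clonotypes: no %s clonotype present in >= %.0f%% of samples",
                     cmat$chain, 100 * min_presence), call = NULL)))
  }
  cmat$counts <- cmat$counts[, keep, drop = FALSE]
  cmat$clonotype_ids <- colnames(cmat$counts)
  cmat
}
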