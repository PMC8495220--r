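# Richness (receptor expression) and diversity (Shannon entropy of the clone
# size distribution), plus the read-level subsampling sensitivity analysis.

#' Receptor expression (richness) of a sample
#'
#' The fraction of a sample's mapped reads assigned to a receptor chain,
#' `M / (N + M)`, where `M` is the receptor-mapped read count and `N` the
#' count of reads mapping to anything else.
#'
#' @param M Receptor-mapped reads (non-negative).
#' @param N Other mapped reads (non-negative).
#' @return Fraction in `[0, 1]`. Vectorised over `M` and `N`.
#' @export
receptor_expression <- function(M, N) {
  if (any(M < 0) || any(N < 0)) stop("read counts must be non-negative")
  if (any(M + N == 0)) stop("expression undefined when M + N = 0")
  M / (N + M)
}

#' Shannon entropy of a clone size distribution
#'
#' `H = -sum(p_i * log2(p_i))` with `p_i` the read fraction of clone `i`.
#' Ranges from 0 (a single clone) to `log2(N)` (uniform over `N` clones).
#'
#' @param clone_reads Vector of positive clone read counts.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(clone_reads) {
  if (length(clone_reads) == 0L) stop("empty clone read vector")
  if (any(clone_reads <= 0)) stop("clone reads must be positive")
  p <- clone_reads / sum(clone_reads)
  -sum(p * log2(p))
}

# One read-level subsample of a record table: draw `n_reads` of the M reads
# without replacement (each read equally likely) and return the records with
# their subsampled counts (zero-count records dropped).
subsample_records <- function(records, n_reads) {
  read_owner <- rep.int(seq_len(nrow(records)), records$count)
  drawn <- sample(read_owner, n_reads, replace = FALSE)
  cnt <- tabulate(drawn, nbins = nrow(records))
  out <- records[cnt > 0, , drop = FALSE]
  out$count <- cnt[cnt > 0]
  out
}

#' Subsampling sensitivity of repertoire metrics
#'
#' For each proportion, repeatedly draws that fraction of the sample's reads
#' without replacement at read level, reassigns clones on the subsample, and
#' recomputes the requested metrics. Reports the mean and standard deviation
#' over replicates. A proportion that yields zero reads is reported as
#' missing with a warning.
#'
#' @param records Record data frame for one sample and chain.
#' @param proportions Fractions in `(0, 1]` of reads to keep.
#' @param reps Number of random subsamples per proportion (default 10).
#' @param seed Integer seed for reproducibility.
#' @param threshold Identity threshold for clone reassignment.
#' @param metrics Any of `"entropy"`, `"gini_v"`, `"gini_c"`.
#' @return Data frame with columns `proportion`, `metric`, `mean`, `sd`.
#' @export
subsample_metrics <- function(records, proportions, reps = 10, seed = 1L,
                              threshold = 0.90,
                              metrics = c("entropy", "gini_v", "gini_c")) {
  stopifnot(all(proportions > 0), all(proportions <= 1), reps >= 1)
  metrics <- match.arg(metrics, several.ok = TRUE)
  set.seed(seed)
  M <- sum(records$count)
  out <- list()
  for (prop in proportions) {
    n_reads <- floor(prop * M)
    if (n_reads == 0L) {
      warning(sprintf("proportion %.3g draws zero reads; reported as missing", prop))
      out[[length(out) + 1L]] <- data.frame(proportion = prop, metric = metrics,
                                            mean = NA_real_, sd = NA_real_)
      next
    }
    vals <- matrix(NA_real_, nrow = reps, ncol = length(metrics),
                   dimnames = list(NULL, metrics))
    for (r in seq_len(reps)) {
      sub <- subsample_records(records, n_reads)
      ct <- assign_clones(sub, threshold)
      if ("entropy" %in% metrics)
        vals[r, "entropy"] <- shannon_entropy(ct$clones$clone_reads)
      if (any(c("gini_v", "gini_c") %in% metrics)) {
        net <- build_network(sub, threshold)
        gm <- suppressWarnings(network_metrics(net))
        if ("gini_v" %in% metrics) vals[r, "gini_v"] <- gm$gini_v
        if ("gini_c" %in% metrics) vals[r, "gini_c"] <- gm$gini_c
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      proportion = prop, metric = metrics,
      mean = colMeans(vals)[metrics],
      sd = apply(vals, 2, stats::sd)[metrics])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Subsampling sensitivity of Shannon entropy
#'
#' Convenience wrapper around [subsample_metrics()] for entropy alone,
#' mirroring the sensitivity analysis design (10 random subsamples per
#' proportion, mean as the final estimate).
#'
#' @inheritParams subsample_metrics
#' @return Data frame with columns `proportion`, `mean`, `sd`.
#' @export
subsample_entropy <- function(records, proportions, reps = 10, seed = 1L,
                              threshold = 0.90) {
  res <- subsample_metrics(records, proportions, reps, seed, threshold,
                           metrics = "entropy")
  res[, c("proportion", "mean", "sd")]
}

#' Diversity summary for every sample and chain of a cohort
#'
#' @param cohort An `ir_cohort`.
#' @param chains Chains to summarise (default: those present).
#' @return Data frame with `sample_id`, `chain`, `group`, `expression`
#'   (M/(N+M)), `entropy` (bits), `n_clones`. Samples without records for a
#'   chain get expression 0 and missing entropy.
#' @export
diversity_table <- function(cohort, chains = NULL) {
  stopifnot(inherits(cohort, "ir_cohort"))
  chains <- chains %||% sort(unique(cohort$records$chain))
  out <- list()
  for (ch in chains) {
    thr <- chain_threshold(ch)
    M <- receptor_reads(cohort, ch)
    for (sid in cohort_samples(cohort)) {
      recs <- sample_records(cohort, sid, ch)
      N <- cohort$metadata$other_reads[cohort$metadata$sample_id == sid]
      if (nrow(recs) == 0L) {
        ent <- NA_real_; ncl <- 0L
      } else {
        ct <- assign_clones(recs, thr)
        ent <- shannon_entropy(ct$clones$clone_reads)
        ncl <- ct$n_clones
      }
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, chain = ch,
        group = cohort$metadata$group[cohort$metadata$sample_id == sid],
        expression = receptor_expression(M[[sid]], N),
        entropy = ent, n_clones = ncl)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
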