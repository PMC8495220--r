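# Reading and writing AIRR-style clonotype tables and sample metadata.
#
# A cohort is a light S3 container with two data frames:
#   $records  — one row per distinct receptor nucleotide sequence
#               (sample_id, chain, v_call, j_call, cdr3_nt, count)
#   $metadata — one row per sample
#               (sample_id, group, other_reads, survival_time, event,
#                age, sex, stage)
# The receptor-mapped read total M of a sample is always derived from the
# record counts; the non-receptor total N comes from metadata$other_reads.

# Canonical column names and accepted aliases (AIRR Rearrangement names plus
# MiXCR export headers), all matched case-insensitively.
AIRR_ALIASES <- c(
  sample_id = "sample_id", sample = "sample_id", sampleid = "sample_id",
  chain = "chain", locus = "chain",
  v_call = "v_call", allvhitswithscore = "v_call", bestvhit = "v_call",
  j_call = "j_call", alljhitswithscore = "j_call", bestjhit = "j_call",
  cdr3_nt = "cdr3_nt", junction = "cdr3_nt", nseqcdr3 = "cdr3_nt",
  count = "count", duplicate_count = "count", clonecount = "count"
)

REQUIRED_RECORD_COLS <- c("sample_id", "chain", "v_call", "j_call", "cdr3_nt", "count")
REQUIRED_META_COLS <- c("sample_id", "group", "other_reads")

new_ir_cohort <- function(records, metadata) {
  structure(list(records = records, metadata = metadata), class = "ir_cohort")
}

#' Construct a repertoire cohort from record and metadata data frames
#'
#' @param records Data frame with columns `sample_id`, `chain`, `v_call`,
#'   `j_call`, `cdr3_nt`, `count` (one row per distinct receptor sequence).
#' @param metadata Data frame keyed by `sample_id` with at least `group` and
#'   `other_reads`; `survival_time`, `event`, `age`, `sex`, `stage` optional.
#' @return An object of class `ir_cohort`.
#' @export
ir_cohort <- function(records, metadata) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  miss <- setdiff(REQUIRED_RECORD_COLS, names(records))
  if (length(miss) && nrow(records) > 0)
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) == 0) records <- empty_records()
  miss <- setdiff(REQUIRED_META_COLS, names(metadata))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  unknown <- setdiff(unique(records$sample_id), metadata$sample_id)
  if (length(unknown))
    stop("records reference sample_id(s) absent from metadata: ",
         paste(unknown, collapse = ", "))
  bad_chain <- setdiff(unique(records$chain), IR_CHAINS)
  if (length(bad_chain))
    stop("unknown chain(s): ", paste(bad_chain, collapse = ", "))
  if (nrow(records)) {
    if (any(records$count < 1) || any(records$count != round(records$count)))
      stop("record counts must be positive integers")
    records$count <- as.integer(records$count)
    if (any(!nzchar(records$cdr3_nt))) stop("empty cdr3_nt in records")
    if (any(grepl("[^ACGT]", records$cdr3_nt)))
      stop("non-ACGT character in cdr3_nt")
  }
  if (any(metadata$other_reads < 0)) stop("other_reads must be non-negative")
  rownames(records) <- NULL
  rownames(metadata) <- NULL
  new_ir_cohort(records, metadata)
}

empty_records <- function() {
  data.frame(sample_id = character(), chain = character(),
             v_call = character(), j_call = character(),
             cdr3_nt = character(), count = integer(),
             stringsAsFactors = FALSE)
}

#' @export
print.ir_cohort <- function(x, ...) {
  cat(sprintf("ir_cohort: %d samples, %d records, chains: %s\n",
              nrow(x$metadata), nrow(x$records),
              paste(sort(unique(x$records$chain)), collapse = ", ")))
  invisible(x)
}

#' Sample identifiers of a cohort
#' @param cohort An `ir_cohort`.
#' @return Character vector of sample ids.
#' @export
cohort_samples <- function(cohort) cohort$metadata$sample_id

#' Records of one sample, optionally restricted to a chain
#' @param cohort An `ir_cohort`.
#' @param sample_id Sample identifier.
#' @param chain Optional chain name to restrict to.
#' @return Data frame of records.
#' @export
sample_records <- function(cohort, sample_id, chain = NULL) {
  r <- cohort$records[cohort$records$sample_id == sample_id, , drop = FALSE]
  if (!is.null(chain)) r <- r[r$chain == chain, , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Receptor-mapped read totals M per sample
#'
#' M is derived from the record counts of the chains present (optionally one
#' chain or one chain class).
#'
#' @param cohort An `ir_cohort`.
#' @param chain Optional chain (`"IGK"`) or chain class (`"IG"`, `"TR"`).
#' @return Named integer vector over all samples (zero where no records).
#' @export
receptor_reads <- function(cohort, chain = NULL) {
  r <- cohort$records
  if (!is.null(chain)) {
    keep <- if (chain %in% c("IG", "TR")) startsWith(r$chain, chain)
            else r$chain == chain
    r <- r[keep, , drop = FALSE]
  }
  m <- stats::setNames(rep(0L, nrow(cohort$metadata)), cohort$metadata$sample_id)
  if (nrow(r)) {
    agg <- tapply(r$count, r$sample_id, sum)
    m[names(agg)] <- as.integer(agg)
  }
  m
}

normalise_airr_names <- function(df, required, what) {
  nm <- tolower(names(df))
  mapped <- AIRR_ALIASES[nm]
  nm[!is.na(mapped)] <- mapped[!is.na(mapped)]
  names(df) <- nm
  df <- df[, !duplicated(names(df)), drop = FALSE]
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s is missing mandatory column(s): %s",
                 what, paste(miss, collapse = ", ")))
  df
}

#' Read an AIRR-style clonotype table and sample metadata into a cohort
#'
#' Accepts AIRR Rearrangement column names (`junction`, `duplicate_count`, ...)
#' and common MiXCR export headers (`cloneCount`, `allVHitsWithScore`, ...) via
#' an alias table. CDR3 strings are uppercased; rows with an empty CDR3 are
#' dropped (reported via a message); rows with non-ACGT characters are rejected
#' with a warning. Comma-separated V/J hit lists keep the first call. M is
#' recomputed from record counts; N is taken from the metadata column
#' `other_reads`.
#'
#' @param path Path to the tab-separated clonotype table (header row required).
#' @param metadata_path Path to the tab-separated metadata table keyed by
#'   `sample_id`.
#' @return An `ir_cohort`.
#' @export
read_airr_table <- function(path, metadata_path) {
  rec <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  rec <- normalise_airr_names(rec, REQUIRED_RECORD_COLS, "clonotype table")
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  meta <- normalise_airr_names(meta, REQUIRED_META_COLS, "metadata table")

  vv <- first_call(rec$v_call)
  jj <- first_call(rec$j_call)
  if (vv$n_multi + jj$n_multi > 0)
    message(sprintf("kept first listed V/J call for %d row(s) with multiple candidates",
                    vv$n_multi + jj$n_multi))
  rec$v_call <- vv$call
  rec$j_call <- jj$call

  up <- toupper(rec$cdr3_nt)
  n_case <- sum(up != rec$cdr3_nt)
  if (n_case > 0) message(sprintf("uppercased CDR3 in %d row(s)", n_case))
  rec$cdr3_nt <- up

  empty <- !nzchar(rec$cdr3_nt) | is.na(rec$cdr3_nt)
  if (any(empty)) {
    message(sprintf("dropped %d row(s) with empty CDR3", sum(empty)))
    rec <- rec[!empty, , drop = FALSE]
  }
  bad <- grepl("[^ACGT]", rec$cdr3_nt)
  if (any(bad)) {
    warning(sprintf("rejected %d record(s) with non-ACGT characters in CDR3",
                    sum(bad)))
    rec <- rec[!bad, , drop = FALSE]
  }
  rec$count <- as.integer(rec$count)
  if (anyNA(rec$count)) stop("non-integer read counts in clonotype table")
  rec <- rec[, REQUIRED_RECORD_COLS, drop = FALSE]
  ir_cohort(rec, meta)
}

#' Write a cohort back to AIRR-style TSV files
#'
#' Round-trip safe: reading the written pair reproduces all record fields and
#' metadata exactly. Samples with no records still appear in the metadata file
#' (their M is zero by construction).
#'
#' @param cohort An `ir_cohort`.
#' @param path Output path for the clonotype table.
#' @param metadata_path Output path for the metadata table.
#' @return Invisibly, the two paths.
#' @export
write_airr_table <- function(cohort, path, metadata_path) {
  stopifnot(inherits(cohort, "ir_cohort"))
  if (nrow(cohort$metadata) == 0) stop("cohort is empty")
  utils::write.table(cohort$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, metadata_path))
}

#' Filter samples by clone count
#'
#' Applies the sample-level quality filter: a sample is retained when its
#' clone count for the requested chain class is at least `min_clones`
#' (strictly-less-than exclusion). Clones are assigned per chain with the
#' class threshold (0.90 for IG, 0.95 for TR) and summed over the chains of
#' the class, so IG and TR filtering are independent of each other.
#'
#' @param cohort An `ir_cohort`.
#' @param min_clones Minimum clone count to retain a sample (default 100).
#' @param chain_class `"IG"` or `"TR"`.
#' @param threshold Identity threshold; defaults to the class threshold.
#' @return The filtered `ir_cohort` (records and metadata restricted to the
#'   retained samples).
#' @export
filter_samples <- function(cohort, min_clones = 100, chain_class = c("IG", "TR"),
                           threshold = NULL) {
  stopifnot(inherits(cohort, "ir_cohort"))
  if (min_clones < 0) stop("min_clones must be non-negative")
  chain_class <- match.arg(chain_class)
  threshold <- threshold %||% (if (chain_class == "IG") 0.90 else 0.95)
  keep <- vapply(cohort_samples(cohort), function(sid) {
    recs <- sample_records(cohort, sid)
    recs <- recs[startsWith(recs$chain, chain_class), , drop = FALSE]
    n <- 0L
    for (ch in unique(recs$chain)) {
      n <- n + assign_clones(recs[recs$chain == ch, , drop = FALSE],
                             threshold = threshold)$n_clones
    }
    n >= min_clones
  }, logical(1))
  ids <- cohort_samples(cohort)[keep]
  new_ir_cohort(
    records = {
      r <- cohort$records[cohort$records$sample_id %in% ids, , drop = FALSE]
      rownames(r) <- NULL
      r
    },
    metadata = {
      m <- cohort$metadata[cohort$metadata$sample_id %in% ids, , drop = FALSE]
      rownames(m) <- NULL
      m
    }
  )
}
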