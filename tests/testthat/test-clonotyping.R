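test_that("cdr3_identity is the fraction of matching positions and demands equal length", {
  expect_equal(cdr3_identity("ACGT", "ACGT"), 1.0)
  expect_equal(cdr3_identity("ACGT", "ACGA"), 0.75)
  expect_equal(cdr3_identity("AAAAAAAAAA", "AAAAAAAAAT"), 0.9)
  expect_error(cdr3_identity("ACGT", "ACGTA"), "equal-length")
})

test_that("single linkage joins transitively and the threshold is inclusive", {
  # pairwise mismatches s1-s2: 1, s2-s3: 1, s1-s3: 2; identity 0.8 < 0.9
  # between the extremes, joined through the middle sequence
  rec <- make_records(c("AAAAAAAAAA", "TAAAAAAAAA", "TTAAAAAAAA"))
  ct <- assign_clones(rec, 0.90)
  expect_equal(ct$n_clones, 1L)
  expect_equal(ct$clones$n_members, 3L)
  # identical CDR3 but different V gene never links
  rec2 <- make_records(c("AAAAAAAAAA", "AAAAAAAAAA"), v = c("IGKV1*01", "IGKV2*01"))
  expect_equal(assign_clones(rec2, 0.90)$n_clones, 2L)
  # identity exactly at the threshold joins (>= rule)
  rec3 <- make_records(c("AAAAAAAAAA", "AAAAAAAAAT"))
  expect_equal(assign_clones(rec3, 0.90)$n_clones, 1L)
  expect_same_partition(assign_clones(rec3, 0.90)$assignment, oracle_clones(rec3, 0.90))
  # allele suffixes are stripped before V/J equality
  rec4 <- make_records(c("AAAAAAAAAA", "AAAAAAAAAA"), v = c("IGKV1*01", "IGKV1*02"))
  expect_equal(assign_clones(rec4, 0.90)$n_clones, 1L)
})

test_that("empty input yields an empty clone table, not an error", {
  ct <- assign_clones(make_records(character(0)), 0.90)
  expect_equal(ct$n_clones, 0L)
  expect_equal(nrow(ct$clones), 0L)
})

test_that("clone assignment matches the brute-force pairwise oracle on random inputs", {
  set.seed(101)
  for (rep in 1:40) {
    rec <- random_records(n = sample(5:120, 1))
    for (thr in c(0.90, 0.95)) {
      expect_same_partition(assign_clones(rec, thr)$assignment,
                            oracle_clones(rec, thr))
    }
  }
})

test_that("raising the threshold only refines the partition and order does not matter", {
  set.seed(202)
  for (rep in 1:15) {
    rec <- random_records(n = 60)
    lo <- assign_clones(rec, 0.90)$assignment
    hi <- assign_clones(rec, 0.95)$assignment
    # refinement: records together at 0.95 are together at 0.90
    for (cl in unique(hi)) {
      expect_length(unique(lo[hi == cl]), 1L)
    }
    perm <- sample.int(nrow(rec))
    shuffled <- assign_clones(rec[perm, , drop = FALSE], 0.90)$assignment
    expect_same_partition(shuffled[order(perm)], lo)
    # read conservation
    ct <- assign_clones(rec, 0.90)
    expect_equal(sum(ct$clones$clone_reads), sum(rec$count))
    expect_equal(ct$clones$n_members, as.vector(table(ct$assignment)))
  }
})

test_that("the clonotype matrix shares exact clones across samples and respects the length gate", {
  meta <- data.frame(sample_id = c("a", "b"), group = c("tumor", "normal"),
                     other_reads = 10)
  shared <- rbind(cbind(sample_id = "a", make_records("ACGTACGTACGT", count = 3L)),
                  cbind(sample_id = "b", make_records("ACGTACGTACGT", count = 5L)))
  cm <- build_clonotype_matrix(ir_cohort(shared, meta), "IGK")
  expect_equal(dim(cm$counts), c(2L, 1L))
  expect_equal(unname(cm$counts[, 1]), c(3L, 5L))

  # all-different CDR3 lengths: block-diagonal, no shared columns
  diff_len <- rbind(cbind(sample_id = "a", make_records("ACGTACGTACGT", count = 3L)),
                    cbind(sample_id = "b", make_records("ACGTACGTACGTAA", count = 5L)))
  cm2 <- build_clonotype_matrix(ir_cohort(diff_len, meta), "IGK")
  expect_equal(dim(cm2$counts), c(2L, 2L))
  expect_true(all(colSums(cm2$counts > 0) == 1L))
  # row sums never exceed the sample M
  expect_true(all(rowSums(cm2$counts) <= receptor_reads(ir_cohort(diff_len, meta))))
})

test_that("every planted discriminative clonotype maps to exactly one matrix column", {
  cfg <- sim_config(n_tumor = 6, n_normal = 6, reads_mean = c(tumor = 2000, normal = 1000),
                    clones_mean = c(tumor = 80, normal = 50),
                    public_pool_size = 50, seed = 33)
  sim <- simulate_cohort(cfg)
  cm <- build_clonotype_matrix(sim$cohort, "IGK")
  ids <- planted_clonotype_ids(cm, sim$truth)
  expect_length(ids, 10L)
  expect_false(anyNA(ids))
  expect_equal(anyDuplicated(ids), 0L)
  expect_true(all(ids %in% cm$clonotype_ids))
})

test_that("clonotype ids are stable across runs and the pooled partition matches the oracle", {
  set.seed(77)
  rec <- random_records(40)
  rec$sample_id <- sample(c("a", "b"), 40, TRUE)
  rec$chain <- "IGK"
  meta <- data.frame(sample_id = c("a", "b"), group = "tumor", other_reads = 1)
  co <- ir_cohort(rec, meta)
  cm1 <- build_clonotype_matrix(co, "IGK")
  cm2 <- build_clonotype_matrix(co, "IGK")
  expect_identical(cm1$counts, cm2$counts)
  expect_same_partition(match(cm1$assignment$clonotype_id, cm1$clonotype_ids),
                        oracle_clones(rec, 0.90))
})

test_that("filter_clonotypes signals insufficient overlap when nothing is shared", {
  meta <- data.frame(sample_id = letters[1:4], group = "tumor", other_reads = 1)
  rec <- do.call(rbind, lapply(1:4, function(i) {
    cbind(sample_id = letters[i],
          make_records(paste(rep(c("A", "C", "G", "T")[i], 12), collapse = ""),
                       v = paste0("IGKV", i, "*01")))
  }))
  cm <- build_clonotype_matrix(ir_cohort(rec, meta), "IGK")
  expect_error(filter_clonotypes(cm, min_presence = 0.5),
               class = "tumorir_insufficient_overlap")
})
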