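test_that("a fixed seed reproduces a sample bit-identically and counts sum to M", {
  cfg <- sim_config()
  a <- simulate_repertoire(cfg, "tumor", seed = 5)
  b <- simulate_repertoire(cfg, "tumor", seed = 5)
  expect_identical(a, b)
  expect_equal(sum(a$records$count), a$M)
  expect_equal(sum(a$clones$clone_reads), a$M)
})

test_that("the Dirichlet concentration controls clone-size inequality as the oracle predicts", {
  base <- function(a) sim_config(clones_mean = c(tumor = 50, normal = 50),
                                 alpha = c(tumor = a, normal = a),
                                 reads_mean = c(tumor = 3000, normal = 3000),
                                 public_pool_size = 0, n_discriminative = 0)
  gini_sim <- function(a, seeds) {
    mean(vapply(seeds, function(s)
      gini(simulate_repertoire(base(a), "tumor", seed = s)$clones$clone_reads),
      numeric(1)))
  }
  even <- gini_sim(1e4, 1:30)
  expanded <- gini_sim(0.05, 1:30)
  expect_lt(even, 0.1)
  expect_gt(expanded, 0.6)
  # oracle: Gini of multinomial reads over Dirichlet weights (surviving
  # clones), i.e. the Dirichlet-multinomial process stated by the design
  set.seed(99)
  oracle <- function(a) mean(replicate(100, {
    g <- stats::rgamma(50, a)
    reads <- drop(stats::rmultinom(1, 3000, g / sum(g)))
    gini(reads[reads > 0])
  }))
  expect_lt(abs(even - oracle(1e4)), 0.05)
  expect_lt(abs(expanded - oracle(0.05)), 0.1)
})

test_that("decreasing the concentration raises Gini and lowers entropy at fixed clone count", {
  cfg <- function(a) sim_config(clones_mean = c(tumor = 60, normal = 60),
                                alpha = c(tumor = a, normal = a),
                                reads_mean = c(tumor = 2000, normal = 2000),
                                public_pool_size = 0, n_discriminative = 0)
  stats_at <- function(a) {
    g <- h <- numeric(50)
    for (s in 1:50) {
      reads <- simulate_repertoire(cfg(a), "tumor", seed = s)$clones$clone_reads
      g[s] <- gini(reads); h[s] <- shannon_entropy(reads)
    }
    c(gini = mean(g), entropy = mean(h))
  }
  lo <- stats_at(0.2); hi <- stats_at(5)
  expect_gt(lo["gini"], hi["gini"])
  expect_lt(lo["entropy"], hi["entropy"])
})

test_that("every member sequence stays within the identity threshold of its clone ancestor", {
  cfg <- sim_config(reads_mean = c(tumor = 4000, normal = 1000),
                    mutation_rate = 0.05, member_rate = 0.1)
  for (seed in 1:5) {
    s <- simulate_repertoire(cfg, "tumor", seed = seed)
    anc <- s$clones
    rec <- s$records
    ok <- vapply(seq_len(nrow(rec)), function(i) {
      cand <- which(anc$v_call == rec$v_call[i] & anc$j_call == rec$j_call[i] &
                      nchar(anc$cdr3_nt) == nchar(rec$cdr3_nt[i]))
      any(vapply(cand, function(ci)
        cdr3_identity(anc$cdr3_nt[ci], rec$cdr3_nt[i]) >= 0.90, logical(1)))
    }, logical(1))
    expect_true(all(ok))
  }
})

test_that("a zero mutation cap downgrades members to ancestor copies with a warning", {
  cfg <- sim_config(chain = "TRA", threshold = 0.95,
                    cdr3_lengths = c(12, 14), cdr3_length_probs = c(1, 1),
                    reads_mean = c(tumor = 1000, normal = 500),
                    clones_mean = c(tumor = 20, normal = 20),
                    member_rate = 0.3, public_pool_size = 0,
                    n_discriminative = 0)
  expect_warning(s <- simulate_repertoire(cfg, "tumor", seed = 2),
                 "mutation cap")
  # with the cap in force all records are pure ancestors
  expect_true(all(s$records$cdr3_nt %in% s$clones$cdr3_nt))
})

test_that("simulate_cohort is seed-deterministic and keeps the planted bookkeeping", {
  cfg <- sim_config(n_tumor = 8, n_normal = 8,
                    reads_mean = c(tumor = 2000, normal = 1000),
                    clones_mean = c(tumor = 100, normal = 50),
                    public_pool_size = 60, seed = 21)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort$records, b$cohort$records)
  expect_identical(a$cohort$metadata, b$cohort$metadata)
  expect_equal(nrow(a$truth$planted), 10L)
  expect_equal(sum(a$truth$pool$planted), 10L)
  # M bookkeeping: metadata-independent M equals summed counts per sample
  M <- receptor_reads(a$cohort)
  agg <- tapply(a$cohort$records$count, a$cohort$records$sample_id, sum)
  expect_equal(unname(M[names(agg)]), as.integer(agg))
  # tumor samples carry fully observed survival, normals none
  md <- a$cohort$metadata
  expect_true(all(is.finite(md$survival_time[md$group == "tumor"])))
  expect_true(all(md$event[md$group == "tumor"] == 1L))
  expect_true(all(is.na(md$survival_time[md$group == "normal"])))
})

test_that("null constructions behave: h2 = 0 removes the kernel effect and no planting empties the truth", {
  cfg0 <- sim_config(n_tumor = 6, n_normal = 2, h2 = 0,
                     reads_mean = c(tumor = 1500, normal = 800),
                     clones_mean = c(tumor = 60, normal = 40),
                     public_pool_size = 40, seed = 3)
  s0 <- simulate_cohort(cfg0)
  expect_equal(s0$truth$sigma2_k, 0)
  expect_true(all(s0$truth$p == 0))

  cfg_np <- sim_config(n_tumor = 4, n_normal = 4, n_discriminative = 0,
                       reads_mean = c(tumor = 1500, normal = 800),
                       clones_mean = c(tumor = 60, normal = 40),
                       public_pool_size = 40, seed = 4)
  snp <- simulate_cohort(cfg_np)
  expect_equal(nrow(snp$truth$planted), 0L)
  cm <- build_clonotype_matrix(snp$cohort, "IGK")
  expect_length(planted_clonotype_ids(cm, snp$truth), 0L)
})

test_that("planting more clonotypes than clones per sample is a parameter error", {
  expect_error(sim_config(clones_mean = c(tumor = 50, normal = 5),
                          n_discriminative = 10), "n_discriminative")
})

test_that("simulated survival respects the configured variance split", {
  set.seed(8)
  K <- linear_kernel(matrix(rnorm(40 * 20), 40))
  s <- simulate_survival(K, h2 = 0.5, total_sd = 100, seed = 9)
  expect_equal(s$sigma2_k, 5000)
  expect_equal(s$sigma2_e, 5000)
  # long-run variance of p matches sigma2_k * mean diag(K) = sigma2_k
  set.seed(10)
  ps <- replicate(300, simulate_survival(K, h2 = 0.5, total_sd = 100)$p)
  expect_equal(mean(apply(ps, 1, var) / diag(K)), 5000, tolerance = 0.15)
  # h2 = 1 and h2 = 0 are both well defined
  expect_true(all(simulate_survival(K, h2 = 0, total_sd = 50, seed = 1)$p == 0))
  expect_true(all(simulate_survival(K, h2 = 1, total_sd = 50, seed = 1)$e == 0))
})
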