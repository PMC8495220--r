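test_that("gini reproduces the equal, two-value and one-hot closed forms", {
  expect_equal(gini(c(5, 5, 5, 5)), 0.0)
  expect_equal(gini(c(1, 3)), 0.25)
  expect_equal(gini(c(0, 0, 0, 1000)), 0.75) # one-hot: (n-1)/n at n = 4
  expect_error(gini(c(0, 0)), "all-zero")
  expect_error(gini(c(-1, 2)), "negative")
  expect_error(gini(numeric(0)))
})

test_that("gini agrees with both the pairwise and the sorted-rank oracles and is scale invariant", {
  set.seed(12)
  for (i in 1:200) {
    x <- stats::rgamma(sample(2:60, 1), shape = stats::runif(1, 0.2, 5))
    expect_equal(gini(x), gini_pairwise(x), tolerance = 1e-12)
    expect_equal(gini(x), gini_sorted(x), tolerance = 1e-12)
    expect_equal(gini(13 * x), gini(x), tolerance = 1e-12)
    expect_lt(gini(x), 1)
  }
  # one-hot approaches 1 as n grows
  expect_equal(gini(c(rep(0, 999), 1)), 0.999)
})

test_that("identical reads collapse into one vertex and near-identical vertices link", {
  rec <- make_records(rep("AAAAAAAAAAAA", 3), count = 1L)
  net <- build_network(rec, 0.90)
  expect_equal(nrow(net$vertices), 1L)
  expect_equal(net$vertices$size, 3L)
  expect_equal(net$n_clusters, 1L)
  expect_equal(igraph::ecount(net$graph), 0)

  # two vertices at identity 11/12 > 0.90: one edge, one cluster
  rec2 <- make_records(c("AAAAAAAAAAAA", "AAAAAAAAAAAT"), count = c(4L, 2L))
  net2 <- build_network(rec2, 0.90)
  expect_equal(nrow(net2$vertices), 2L)
  expect_equal(igraph::ecount(net2$graph), 1)
  expect_equal(net2$n_clusters, 1L)
})

test_that("network metrics match the pairwise Gini forms on the stated cluster fixtures", {
  # 10 singleton clusters of unit vertices: perfect equality
  cdr3 <- vapply(1:10, function(i) paste(rep(c("A", "C", "G", "T"), 3)[sample(12)],
                                         collapse = ""), character(1))
  rec <- make_records(cdr3, v = paste0("IGKV", 1:10, "*01"), count = 1L)
  net <- build_network(rec, 0.90)
  m <- network_metrics(net)
  expect_equal(m$gini_v, 0)
  expect_equal(m$gini_c, 0)

  # one 9-vertex cluster plus 9 singletons: cluster sizes [9, 1 x 9], gini 0.4
  big <- c(strrep("A", 12),
           vapply(1:8, function(i) {
             s <- rep("A", 12); s[i] <- "T"; paste(s, collapse = "")
           }, character(1)))
  singles <- vapply(1:9, function(i) paste(rep(c("C", "G", "T"), 4), collapse = ""),
                    character(1))
  rec2 <- rbind(make_records(big, v = "IGKV1*01"),
                make_records(singles, v = paste0("IGKV", 2:10, "*01")))
  net2 <- build_network(rec2, 0.90)
  expect_equal(net2$n_clusters, 10L)
  expect_equal(network_metrics(net2)$gini_c, 0.4)
  expect_equal(network_metrics(net2)$gini_c, gini_pairwise(c(9, rep(1, 9))))

  # single cluster is degenerate: gini_c 0 with a warning, gini_v on sizes
  rec3 <- make_records(c(strrep("A", 12), paste0(strrep("A", 11), "T")),
                       count = c(10L, 1L))
  net3 <- build_network(rec3, 0.90)
  expect_warning(m3 <- network_metrics(net3), "single-cluster")
  expect_equal(m3$gini_c, 0)
  expect_equal(m3$gini_v, gini_pairwise(c(10, 1)))
})

test_that("cluster size can be measured in reads instead of vertices", {
  rec <- rbind(make_records(c(strrep("A", 12), paste0(strrep("A", 11), "T")),
                            count = c(10L, 6L)),
               make_records(strrep("C", 12), v = "IGKV2*01", count = 4L))
  net <- build_network(rec, 0.90)
  expect_equal(network_metrics(net, "vertices")$gini_c, gini_pairwise(c(2, 1)))
  expect_equal(network_metrics(net, "reads")$gini_c, gini_pairwise(c(16, 4)))
})

test_that("network components reproduce assign_clones on random inputs", {
  set.seed(303)
  for (rep in 1:30) {
    rec <- random_records(n = sample(10:100, 1))
    rec$count <- sample.int(5, nrow(rec), TRUE)
    for (thr in c(0.90, 0.95)) {
      net <- build_network(rec, thr)
      ct <- assign_clones(rec, thr)
      # map each record to its vertex, compare the induced partitions
      vkey <- paste(sub("\\*.*$", "", rec$v_call), sub("\\*.*$", "", rec$j_call),
                    rec$cdr3_nt)
      nkey <- paste(net$vertices$v_call, net$vertices$j_call, net$vertices$cdr3_nt)
      expect_same_partition(net$membership[match(vkey, nkey)], ct$assignment)
      # vertex sizes conserve reads
      expect_equal(sum(net$vertices$size), sum(rec$count))
    }
  }
})

test_that("an empty record set yields an empty network with missing metrics", {
  net <- build_network(make_records(character(0)), 0.90)
  m <- network_metrics(net)
  expect_true(is.na(m$gini_v) && is.na(m$gini_c))
})

test_that("clonally expanded simulated samples have larger cluster Gini than even ones", {
  # small Dirichlet concentration (expansion) vs very large (even clones)
  wins <- 0L
  n_pairs <- 20L
  for (seed in seq_len(n_pairs)) {
    cfg_exp <- sim_config(clones_mean = c(tumor = 50, normal = 50),
                          alpha = c(tumor = 0.05, normal = 0.05),
                          reads_mean = c(tumor = 4000, normal = 4000),
                          public_pool_size = 0, n_discriminative = 0)
    cfg_even <- sim_config(clones_mean = c(tumor = 50, normal = 50),
                           alpha = c(tumor = 1e4, normal = 1e4),
                           reads_mean = c(tumor = 4000, normal = 4000),
                           public_pool_size = 0, n_discriminative = 0)
    g_exp <- network_metrics(build_network(
      simulate_repertoire(cfg_exp, "tumor", seed = seed)$records, 0.90))$gini_c
    g_even <- network_metrics(build_network(
      simulate_repertoire(cfg_even, "tumor", seed = seed + 1000)$records, 0.90))$gini_c
    wins <- wins + (g_exp > g_even)
  }
  expect_gte(wins, n_pairs - 1L)
})
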