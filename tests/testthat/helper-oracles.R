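# Independent oracles and fixture builders shared across the test files.
# The oracles deliberately avoid the package's bucketing/vectorisation: the
# clone oracle is a naive O(n^2) union-find over all record pairs, and the
# Gini oracles are the two closed forms evaluated directly.

# Brute-force single-linkage clone partition: every pair of records is
# compared on V gene, J gene (allele suffix stripped), CDR3 length and
# position-wise identity.
oracle_clones <- function(records, threshold) {
  n <- nrow(records)
  if (n == 0L) return(integer(0))
  v <- sub("\\*.*$", "", records$v_call)
  j <- sub("\\*.*$", "", records$j_call)
  s <- records$cdr3_nt
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      if (v[a] != v[b] || j[a] != j[b]) next
      if (nchar(s[a]) != nchar(s[b])) next
      ident <- sum(utf8ToInt(s[a]) == utf8ToInt(s[b])) / nchar(s[a])
      if (ident >= threshold) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Canonical form of a partition label vector, for comparing partitions up to
# relabelling.
canon_partition <- function(labels) match(labels, unique(labels))

expect_same_partition <- function(a, b) {
  expect_equal(canon_partition(a), canon_partition(b))
}

# Gini: naive pairwise-difference form.
gini_pairwise <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# Gini: sorted-rank closed form.
gini_sorted <- function(x) {
  n <- length(x)
  xs <- sort(x)
  sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * mean(xs))
}

# Random record tables with non-trivial clone structure: a few cluster seeds
# per (V, J, length) stratum, each spawning mutated variants, plus loners.
random_records <- function(n, n_v = 3, n_j = 2, lengths = c(12, 15),
                           mutations_max = 3) {
  bases <- c("A", "C", "G", "T")
  out <- vector("list", n)
  n_seeds <- max(1L, n %/% 5L)
  seeds <- lapply(seq_len(n_seeds), function(i) {
    L <- sample(lengths, 1L)
    list(v = paste0("IGKV", sample.int(n_v, 1L), "*0", sample.int(2, 1L)),
         j = paste0("IGKJ", sample.int(n_j, 1L)),
         s = paste(sample(bases, L, replace = TRUE), collapse = ""))
  })
  for (i in seq_len(n)) {
    sd_ <- seeds[[sample.int(n_seeds, 1L)]]
    s <- strsplit(sd_$s, "")[[1]]
    k <- sample.int(mutations_max + 1L, 1L) - 1L
    if (k > 0) {
      pos <- sample.int(length(s), k)
      for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    }
    out[[i]] <- data.frame(v_call = sd_$v, j_call = sd_$j,
                           cdr3_nt = paste(s, collapse = ""),
                           count = sample.int(20, 1L),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Minimal record table from parallel vectors.
make_records <- function(cdr3, v = "IGKV1*01", j = "IGKJ1*01", count = 1L,
                         chain = "IGK") {
  data.frame(chain = rep_len(chain, length(cdr3)),
             v_call = rep_len(v, length(cdr3)),
             j_call = rep_len(j, length(cdr3)), cdr3_nt = cdr3,
             count = rep_len(as.integer(count), length(cdr3)),
             stringsAsFactors = FALSE)
}

# Cohort with two trivial samples, used by the IO round-trip tests.
tiny_cohort <- function() {
  rec <- rbind(
    cbind(sample_id = "s1", make_records(c("ACGTACGTACGT", "GGGGGGGGGGGG"),
                                         count = c(5L, 1000000L))),
    cbind(sample_id = "s2", make_records("TTTTGGGGCCCC", v = "IGKV2*01",
                                         count = 7L)))
  meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                     group = c("tumor", "normal", "normal"),
                     other_reads = c(1e6, 2e6, 3e6),
                     survival_time = c(350.5, NA, NA),
                     event = c(1L, NA, NA),
                     age = c(64L, 50L, 51L), sex = c("female", "male", "male"),
                     stage = c(2L, NA, NA), stringsAsFactors = FALSE)
  ir_cohort(rec, meta)
}

# Marginal posterior of (sigma2_k, sigma2_e) on a grid, integrating beta
# (flat prior) and the random effect analytically:
#   y | s2k, s2e ~ N(X beta, s2k K + s2e I), beta flat
# log marginal = -1/2 log|V| - 1/2 log|X' V^-1 X| - 1/2 y' P y + log priors.
grid_posterior_means <- function(y, X, K, hyper, n_grid = 60,
                                 lo = 1e-3, hi = 50) {
  vy <- stats::var(y)
  s2_grid <- exp(seq(log(lo * vy), log(hi * vy), length.out = n_grid))
  lp <- matrix(NA_real_, n_grid, n_grid)
  ldinvchisq <- function(s2, nu, S) {
    -(nu / 2 + 1) * log(s2) - nu * S / (2 * s2)
  }
  for (a in seq_len(n_grid)) {
    for (b in seq_len(n_grid)) {
      s2k <- s2_grid[a]; s2e <- s2_grid[b]
      V <- s2k * K + diag(s2e, length(y))
      cv <- chol(V)
      Vi_y <- backsolve(cv, forwardsolve(t(cv), y))
      Vi_X <- backsolve(cv, forwardsolve(t(cv), X))
      XtViX <- crossprod(X, Vi_X)
      bhat <- solve(XtViX, crossprod(X, Vi_y))
      quad <- sum(y * Vi_y) - sum(crossprod(X, Vi_y) * bhat)
      # the + log(s2) terms are the Jacobian of the log-spaced grid
      lp[a, b] <- -sum(log(diag(cv))) - 0.5 * determinant(XtViX)$modulus -
        0.5 * quad + ldinvchisq(s2k, hyper$nu_k, hyper$S_k) +
        ldinvchisq(s2e, hyper$nu_e, hyper$S_e) + log(s2k) + log(s2e)
    }
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  list(mean_s2k = sum(rowSums(w) * s2_grid),
       mean_s2e = sum(colSums(w) * s2_grid))
}
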