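# Synthetic repertoire cohorts with the statistical structure the analysis
# assumes: Dirichlet-multinomial clone sizes (one concentration knob tunes
# clonal expansion), ancestor CDR3s with capped within-clone point mutation
# (so clone membership is recoverable by construction), a shared "public"
# clonotype pool with group-matched expected abundances (a meaningful null for
# selection), planted group-discriminative clonotypes, and survival outcomes
# linked to the tumor clonotype profile through a linear kernel with a chosen
# variance fraction.

DNA_CODES <- c(65L, 67L, 71L, 84L) # A C G T

#' Simulation configuration
#'
#' Defaults emulate, at desk scale, the cohort structure the pipeline is
#' built for: 144 tumor and 180 normal samples, with tumors carrying more
#' receptor reads, more clones and a smaller Dirichlet concentration
#' (clonal expansion) than normal tissue.
#'
#' @param n_tumor,n_normal Samples per group.
#' @param reads_mean Named mean receptor reads per sample,
#'   `c(tumor =, normal =)` (negative-binomial with `reads_dispersion`).
#' @param reads_dispersion Negative-binomial size parameter.
#' @param other_reads Non-receptor mapped reads N per sample.
#' @param clones_mean Named mean private clone count per sample (Poisson).
#' @param alpha Named Dirichlet concentration of private clone sizes; small
#'   values concentrate reads into few clones (clonal expansion).
#' @param cdr3_lengths,cdr3_length_probs CDR3 nucleotide length support
#'   (even lengths 12-60 by default) and sampling weights.
#' @param n_v_genes,n_j_genes Sizes of the V and J gene pools (uniform usage).
#' @param mutation_rate Per-base within-clone point mutation probability;
#'   mutations per sequence are capped at `floor((1 - threshold) * L)` so
#'   every member stays within the identity threshold of its ancestor.
#' @param member_rate Scale of each clone's biological variant pool: a clone
#'   with repertoire share `w` carries ~ `member_rate * w * 2e4` distinct
#'   mutated variants besides its ancestor. Reads are multinomial over that
#'   fixed pool, so variant richness reflects the cell population and the
#'   observed member count saturates with sequencing depth; the unmutated
#'   ancestor always retains reads.
#' @param public_pool_size,public_prob,public_share Size of the shared
#'   clonotype pool, per-sample structural inclusion probability of each pool
#'   clone (default 1: observed presence/absence then emerges from read
#'   sampling at each clone's abundance), and the expected total read share
#'   of pool clones (identical in both groups, so pool clones are null
#'   features for selection).
#' @param n_factors,factor_loading_sd Number of latent clonotype modules and
#'   the SD of each public clone's loading on its module's per-sample
#'   activity score. Modules modulate public clonotype abundances
#'   log-linearly, identically in both groups; they give the cross-sample
#'   profile the correlated module structure bulk repertoires show and the
#'   linear kernel a structured (identifiable) spectrum.
#' @param n_discriminative Planted clonotypes enriched in tumors (always
#'   included in every sample's composition).
#' @param discriminative_log2_effect Log2 fold difference in expected
#'   relative abundance of planted clonotypes, tumor over normal.
#' @param discriminative_base_share Expected relative abundance of one
#'   planted clonotype in a normal sample.
#' @param h2 Fraction of prognostic phenotypic variance carried by the
#'   kernel random effect, in `[0, 1]`.
#' @param survival_noise_sd Total SD (days) of the non-systematic part of
#'   survival; split as `sigma2_k = h2 * sd^2`, `sigma2_e = (1 - h2) * sd^2`.
#' @param baseline_survival Intercept of the survival model (days).
#' @param chain,threshold Chain simulated and its identity threshold.
#' @param seed Integer seed fixing the entire cohort.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_tumor = 144, n_normal = 180,
                       reads_mean = c(tumor = 8000, normal = 2000),
                       reads_dispersion = 10,
                       other_reads = 1e6,
                       clones_mean = c(tumor = 500, normal = 100),
                       alpha = c(tumor = 0.5, normal = 10),
                       cdr3_lengths = seq(12, 60, by = 2),
                       cdr3_length_probs = NULL,
                       n_v_genes = 30, n_j_genes = 5,
                       mutation_rate = 0.02, member_rate = 0.05,
                       public_pool_size = 300, public_prob = 1,
                       public_share = 0.3,
                       n_factors = 25, factor_loading_sd = 1,
                       n_discriminative = 10,
                       discriminative_log2_effect = 2,
                       discriminative_base_share = 0.004,
                       h2 = 0.24, survival_noise_sd = 300,
                       baseline_survival = 900,
                       chain = "IGK", threshold = 0.90,
                       seed = 1L) {
  cfg <- list(n_tumor = n_tumor, n_normal = n_normal, reads_mean = reads_mean,
              reads_dispersion = reads_dispersion, other_reads = other_reads,
              clones_mean = clones_mean, alpha = alpha,
              cdr3_lengths = cdr3_lengths,
              cdr3_length_probs = cdr3_length_probs %||%
                stats::dnorm(cdr3_lengths, 36, 9),
              n_v_genes = n_v_genes, n_j_genes = n_j_genes,
              mutation_rate = mutation_rate, member_rate = member_rate,
              public_pool_size = public_pool_size, public_prob = public_prob,
              public_share = public_share,
              n_factors = n_factors, factor_loading_sd = factor_loading_sd,
              n_discriminative = n_discriminative,
              discriminative_log2_effect = discriminative_log2_effect,
              discriminative_base_share = discriminative_base_share,
              h2 = h2, survival_noise_sd = survival_noise_sd,
              baseline_survival = baseline_survival,
              chain = match.arg(chain, IR_CHAINS), threshold = threshold,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_tumor >= 0, n_normal >= 0, n_tumor + n_normal >= 1,
              all(reads_mean > 0), reads_dispersion > 0, other_reads >= 0,
              all(clones_mean > 0), all(alpha > 0),
              all(cdr3_lengths >= 1), length(cdr3_length_probs) == length(cdr3_lengths),
              n_v_genes >= 1, n_j_genes >= 1,
              mutation_rate >= 0, mutation_rate < 1,
              member_rate >= 0, member_rate < 1,
              public_pool_size >= 0, public_prob >= 0, public_prob <= 1,
              public_share >= 0, public_share < 1,
              n_factors >= 0, factor_loading_sd >= 0,
              n_discriminative >= 0, discriminative_base_share >= 0,
              h2 >= 0, h2 <= 1, survival_noise_sd >= 0,
              threshold > 0, threshold <= 1)
  })
  if (cfg$n_discriminative > min(cfg$clones_mean))
    stop("n_discriminative exceeds the per-sample clone count")
  structure(cfg, class = "sim_config")
}

# `n` random CDR3 nucleotide strings with lengths drawn from the configured
# distribution, generated in one base draw.
random_cdr3 <- function(config, n = 1L) {
  L <- sample(config$cdr3_lengths, n, replace = TRUE,
              prob = config$cdr3_length_probs)
  bases <- sample(DNA_CODES, sum(L), replace = TRUE)
  f <- factor(rep.int(seq_len(n), L), levels = seq_len(n))
  unname(vapply(split(bases, f), intToUtf8, character(1)))
}

# Shared clonotype pool: public clones with group-matched expected shares and
# planted clones with a tumor/normal share ratio of 2^effect.
make_pool <- function(config) {
  n_pub <- config$public_pool_size
  n_pl <- config$n_discriminative
  n <- n_pub + n_pl
  if (n == 0L) return(NULL)
  pool <- data.frame(
    v_call = paste0(config$chain, "V", sample.int(config$n_v_genes, n, TRUE), "*01"),
    j_call = paste0(config$chain, "J", sample.int(config$n_j_genes, n, TRUE), "*01"),
    cdr3_nt = random_cdr3(config, n),
    planted = rep(c(FALSE, TRUE), c(n_pub, n_pl)),
    stringsAsFactors = FALSE)
  q_pub <- if (n_pub > 0) {
    raw <- stats::rlnorm(n_pub, 0, 1)
    raw / sum(raw) * config$public_share /
      max(config$public_prob, .Machine$double.eps)
  } else numeric(0)
  pool$q_normal <- c(q_pub, rep(config$discriminative_base_share, n_pl))
  pool$q_tumor <- c(q_pub, rep(config$discriminative_base_share *
                                 2^config$discriminative_log2_effect, n_pl))
  # Latent clonotype-module structure: each public clone belongs to one of
  # n_factors modules and loads on that module's per-sample activity score,
  # modulating its abundance log-linearly. Planted clones carry no loading,
  # so their only group-dependent behaviour is the planted effect itself.
  # The multiplier exp(l u) is normalised by its lognormal mean exp(l^2/2)
  # so the expected share of each public clone stays at its q.
  pool$loadings <- matrix(0, n, max(config$n_factors, 0L))
  if (config$n_factors > 0 && n_pub > 0) {
    module <- sample.int(config$n_factors, n_pub, replace = TRUE)
    strength <- stats::rnorm(n_pub, 0, config$factor_loading_sd)
    pool$loadings[cbind(seq_len(n_pub), module)] <- strength
  }
  pool$log_mult_offset <- -rowSums(pool$loadings^2) / 2
  pool
}

mutate_codes <- function(codes, k) {
  pos <- sample.int(length(codes), k)
  for (p in pos) {
    alt <- DNA_CODES[DNA_CODES != codes[p]]
    codes[p] <- alt[sample.int(3L, 1L)]
  }
  codes
}

#' Simulate one repertoire sample
#'
#' Draws a private clone count from the group mean, private clone relative
#' sizes from a symmetric Dirichlet (tumor settings use a smaller
#' concentration, inducing expansion), includes pool clones at their expected
#' shares with gamma noise, distributes reads multinomially over clones and
#' then over member sequences within each clone. Members are ancestor copies
#' with 1 to `floor((1 - threshold) * L)` point mutations, so every member
#' keeps at least threshold identity to its ancestor and the ancestor always
#' retains at least one read. M is the realised read total.
#'
#' @param config A [sim_config()].
#' @param group `"tumor"` or `"normal"`.
#' @param seed Optional integer seed (bit-identical output for equal seeds).
#' @param pool Optional shared clonotype pool (from [simulate_cohort()]);
#'   `NULL` simulates private clones only.
#' @return A `sim_sample`: list with `records` (chain, v_call, j_call,
#'   cdr3_nt, count), `M`, and `clones` (per-clone source, ancestor and read
#'   total, the simulation truth).
#' @export
simulate_repertoire <- function(config, group = c("tumor", "normal"),
                                seed = NULL, pool = NULL) {
  stopifnot(inherits(config, "sim_config"))
  group <- match.arg(group)
  if (!is.null(seed)) set.seed(seed)

  n_priv <- max(1L, stats::rpois(1L, config$clones_mean[[group]]))
  if (!is.null(pool)) {
    qcol <- if (group == "tumor") pool$q_tumor else pool$q_normal
    inc <- pool$planted | stats::runif(nrow(pool)) < config$public_prob
    pool_inc <- pool[inc, , drop = FALSE]
    q_inc <- qcol[inc]
    if (sum(q_inc) > 0.8) q_inc <- q_inc * 0.8 / sum(q_inc) # guard: keep private mass
  } else {
    pool_inc <- NULL
    q_inc <- numeric(0)
  }

  w_priv <- rdirichlet1(n_priv, config$alpha[[group]]) * (1 - sum(q_inc))
  fac <- if (config$n_factors > 0) stats::rnorm(config$n_factors) else numeric(0)
  fac_mult <- if (length(q_inc) && config$n_factors > 0)
    exp(drop(pool_inc$loadings %*% fac) + pool_inc$log_mult_offset)
  else rep(1, length(q_inc))
  w_pool <- q_inc * fac_mult * stats::rgamma(length(q_inc), shape = 5, rate = 5)
  w <- c(w_priv, w_pool)
  w <- w / sum(w)

  anc <- data.frame(
    v_call = paste0(config$chain, "V",
                    sample.int(config$n_v_genes, n_priv, TRUE), "*01"),
    j_call = paste0(config$chain, "J",
                    sample.int(config$n_j_genes, n_priv, TRUE), "*01"),
    cdr3_nt = random_cdr3(config, n_priv),
    source = rep("private", n_priv),
    stringsAsFactors = FALSE)
  if (!is.null(pool_inc) && nrow(pool_inc)) {
    anc <- rbind(anc, data.frame(
      v_call = pool_inc$v_call, j_call = pool_inc$j_call,
      cdr3_nt = pool_inc$cdr3_nt,
      source = ifelse(pool_inc$planted, "planted", "public"),
      stringsAsFactors = FALSE))
  }

  M <- max(1L, stats::rnbinom(1L, size = config$reads_dispersion,
                              mu = config$reads_mean[[group]]))
  clone_reads <- drop(stats::rmultinom(1L, M, w))
  live <- which(clone_reads > 0L)

  warn_cap <- FALSE
  seq_list <- cnt_list <- vector("list", length(live))
  for (i in seq_along(live)) {
    ci <- live[i]
    r <- clone_reads[ci]
    seq0 <- anc$cdr3_nt[ci]
    L <- nchar(seq0)
    cap <- max_mismatches(L, config$threshold)
    # the clone's biological variant pool scales with its share of the
    # repertoire (cell population), not with sequencing depth; reads are
    # then multinomial over the pool, so observed richness saturates with
    # depth and read-level subsampling is exactly consistent
    n_var <- if (r > 1L && config$mutation_rate > 0 && config$member_rate > 0)
      min(2000L, stats::rpois(1L, config$member_rate * w[ci] * 2e4)) else 0L
    if (n_var > 0L && cap == 0L) {
      warn_cap <- TRUE
      n_var <- 0L
    }
    if (n_var == 0L) {
      seq_list[[i]] <- seq0
      cnt_list[[i]] <- r
      next
    }
    # ancestor keeps at least one read and about half in expectation
    conc <- c(max(2, n_var), rep(1, n_var))
    wm <- stats::rgamma(n_var + 1L, shape = conc, rate = 1)
    cnt <- drop(stats::rmultinom(1L, r - 1L, wm / sum(wm)))
    cnt[1L] <- cnt[1L] + 1L
    obs <- which(cnt[-1L] > 0L)
    kprob <- stats::dbinom(seq_len(cap), L, config$mutation_rate)
    if (sum(kprob) == 0) kprob <- rep(1, cap)
    ks <- sample.int(cap, length(obs), replace = TRUE, prob = kprob)
    codes0 <- utf8ToInt(seq0)
    members <- vapply(ks, function(k) intToUtf8(mutate_codes(codes0, k)),
                      character(1))
    seq_list[[i]] <- c(seq0, members)
    cnt_list[[i]] <- c(cnt[1L], cnt[-1L][obs])
  }
  if (warn_cap)
    warning("mutation cap of 0 at the current threshold: member sequences kept identical to their ancestor")

  n_per_clone <- lengths(seq_list)
  rec <- data.frame(
    v_call = rep.int(anc$v_call[live], n_per_clone),
    j_call = rep.int(anc$j_call[live], n_per_clone),
    cdr3_nt = unlist(seq_list, use.names = FALSE) %||% character(0),
    count = as.integer(unlist(cnt_list, use.names = FALSE) %||% integer(0)),
    stringsAsFactors = FALSE)
  # collapse identical tuples (distinct clones virtually never collide)
  key <- paste(rec$v_call, rec$j_call, rec$cdr3_nt, sep = "\r")
  if (anyDuplicated(key)) {
    cnt <- rowsum(as.numeric(rec$count), key)
    first <- !duplicated(key)
    rec <- rec[first, , drop = FALSE]
    rec$count <- as.integer(cnt[key[first], 1L])
  }
  rec <- cbind(chain = config$chain, rec, stringsAsFactors = FALSE)
  rec$count <- as.integer(rec$count)
  rownames(rec) <- NULL

  clones <- cbind(anc[live, , drop = FALSE],
                  clone_reads = as.integer(clone_reads[live]))
  rownames(clones) <- NULL
  structure(list(records = rec, M = sum(rec$count), clones = clones),
            class = "sim_sample")
}

#' Draw survival outcomes linked to a kernel
#'
#' `y = X beta + p + e` with `p ~ N(0, K sigma2_k)` and
#' `e ~ N(0, I sigma2_e)`, where `sigma2_k = h2 * total_sd^2` and
#' `sigma2_e = (1 - h2) * total_sd^2`, so the repertoire carries exactly the
#' fraction `h2` of the non-systematic phenotypic variance in expectation.
#'
#' @param K Kernel matrix (from [linear_kernel()]).
#' @param X Design matrix of systematic effects; default intercept only.
#' @param beta Coefficients for `X`; by default a baseline of 900 days on the
#'   intercept (and zero elsewhere), keeping the floor at day 1 inactive.
#' @param h2 Kernel variance fraction in `[0, 1]`.
#' @param total_sd Total SD of the non-systematic part.
#' @param seed Optional integer seed.
#' @return List with `y` (days, floored at 1), `p`, `e`, `sigma2_k`,
#'   `sigma2_e`, `h2`.
#' @export
simulate_survival <- function(K, X = NULL, beta = NULL, h2, total_sd = 300,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(K)
  if (is.null(X)) X <- matrix(1, n, 1)
  beta <- beta %||% c(900, rep(0, ncol(X) - 1L))
  sigma2_k <- h2 * total_sd^2
  sigma2_e <- (1 - h2) * total_sd^2
  p <- if (sigma2_k > 0) {
    ev <- eigen(K, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    drop(ev$vectors %*% (sqrt(lam * sigma2_k) * stats::rnorm(n)))
  } else rep(0, n)
  e <- stats::rnorm(n, 0, sqrt(sigma2_e))
  y <- pmax(1, drop(X %*% beta) + p + e)
  list(y = y, p = p, e = e, sigma2_k = sigma2_k, sigma2_e = sigma2_e, h2 = h2)
}

#' Simulate a full cohort with planted signals and a truth record
#'
#' Generates tumor and normal samples (see [simulate_repertoire()]), injects
#' the planted discriminative clonotypes, builds the tumor clonotype matrix
#' (presence-filtered, CLR offset 1), computes the linear kernel, and draws
#' tumor survival through [simulate_survival()] at the configured variance
#' fraction. Normal samples carry no survival (mirroring normal-tissue
#' donors); tumor events are fully observed.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (an `ir_cohort`), `truth` (planted clonotype
#'   ancestors, true `h2`, variance components, `beta`, per-sample seeds),
#'   `clonotype_matrix` (tumor samples), `clr` and `kernel`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pool <- make_pool(config)
  n <- config$n_tumor + config$n_normal
  groups <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))
  ids <- sprintf("%s%02d", groups, c(seq_len(config$n_tumor),
                                     seq_len(config$n_normal)))
  seeds <- sample.int(.Machine$integer.max - 1L, n)

  age <- round(ifelse(groups == "tumor", stats::rnorm(n, 65, 11),
                      stats::rnorm(n, 50, 12)))
  sex <- ifelse(stats::runif(n) < ifelse(groups == "tumor", 0.46, 0.40),
                "female", "male")
  stage <- ifelse(groups == "tumor",
                  sample(1:4, n, TRUE, prob = c(11, 124, 3, 4)), NA)

  sims <- vector("list", n)
  rec_list <- vector("list", n)
  for (i in seq_len(n)) {
    sims[[i]] <- simulate_repertoire(config, groups[i], seed = seeds[i],
                                     pool = pool)
    ri <- sims[[i]]$records
    rec_list[[i]] <- cbind(sample_id = ids[i], ri, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec_list)

  metadata <- data.frame(sample_id = ids, group = groups,
                         other_reads = config$other_reads,
                         survival_time = NA_real_, event = NA_integer_,
                         age = age, sex = sex, stage = stage,
                         stringsAsFactors = FALSE)
  cohort <- ir_cohort(records, metadata)

  tumor_ids <- ids[groups == "tumor"]
  cmat <- clr <- K <- NULL
  surv <- list(sigma2_k = NA_real_, sigma2_e = NA_real_, p = NULL)
  beta_true <- c(config$baseline_survival, -8, 60, -120)
  if (length(tumor_ids) >= 2L) {
    tumor_cohort <- new_ir_cohort(
      records[records$sample_id %in% tumor_ids, , drop = FALSE],
      metadata[metadata$sample_id %in% tumor_ids, , drop = FALSE])
    cmat <- build_clonotype_matrix(tumor_cohort, config$chain, config$threshold)
    cmat <- filter_clonotypes(cmat)
    clr <- clr_transform(cmat)
    K <- linear_kernel(clr$values)

    tm <- metadata[metadata$sample_id %in% tumor_ids, , drop = FALSE]
    X <- cbind(intercept = 1, age = tm$age - 65,
               female = as.numeric(tm$sex == "female"), stage = tm$stage - 2)
    surv <- simulate_survival(K, X, beta_true, h2 = config$h2,
                              total_sd = config$survival_noise_sd)
    cohort$metadata$survival_time[match(tumor_ids, cohort$metadata$sample_id)] <- surv$y
    cohort$metadata$event[match(tumor_ids, cohort$metadata$sample_id)] <- 1L
  }

  planted <- if (!is.null(pool)) pool[pool$planted, c("v_call", "j_call", "cdr3_nt"),
                                      drop = FALSE] else NULL
  truth <- list(planted = planted, h2 = config$h2,
                sigma2_k = surv$sigma2_k, sigma2_e = surv$sigma2_e,
                beta = beta_true, p = surv$p,
                sample_seeds = stats::setNames(seeds, ids),
                pool = pool, config = config)
  list(cohort = cohort, truth = truth, clonotype_matrix = cmat, clr = clr,
       kernel = K)
}

#' Map planted clonotype ancestors to clonotype matrix columns
#'
#' Each planted ancestor is located among the pooled records of the matrix;
#' the id of the global cluster containing it is returned (the simulator's
#' mutation cap guarantees the ancestor's cluster holds the planted clone).
#'
#' @param cmat A `clonotype_matrix`.
#' @param truth Truth record from [simulate_cohort()].
#' @return Character vector of clonotype ids, `NA` where a planted ancestor
#'   produced no reads in any sample of the matrix.
#' @export
planted_clonotype_ids <- function(cmat, truth) {
  stopifnot(inherits(cmat, "clonotype_matrix"))
  pl <- truth$planted
  if (is.null(pl) || nrow(pl) == 0L) return(character(0))
  asg <- cmat$assignment
  key <- paste(strip_allele(asg$v_call), strip_allele(asg$j_call), asg$cdr3_nt)
  pkey <- paste(strip_allele(pl$v_call), strip_allele(pl$j_call), pl$cdr3_nt)
  asg$clonotype_id[match(pkey, key)]
}
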