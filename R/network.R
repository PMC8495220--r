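# Per-sample clonal network: vertices are unique receptor sequences sized by
# their identical-read count, edges follow the clone definition, connected
# components are the clones. Gini indices of vertex and cluster sizes
# quantify clonal expansion and clonal dominance.

#' Gini coefficient of a non-negative value distribution
#'
#' Population form `sum_i sum_j |x_i - x_j| / (2 n^2 mean(x))`, computed via
#' the equivalent sorted-rank expression, with no small-sample correction.
#' Zero expresses perfect equality; values approach 1 for maximal inequality
#' (a one-hot vector gives `(n - 1) / n`).
#'
#' @param values Non-negative values, not all zero.
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini <- function(values) {
  if (length(values) == 0L) stop("empty value vector")
  if (any(values < 0)) stop("negative values not allowed")
  if (all(values == 0)) stop("all-zero input: Gini undefined")
  n <- length(values)
  x <- sort(values)
  sum((2 * seq_len(n) - n - 1) * x) / (n^2 * mean(x))
}

#' Build the clonal network of one sample
#'
#' Collapses identical (V gene, J gene, CDR3) tuples into vertices whose size
#' is the summed read count, adds an edge between vertices satisfying the
#' clone definition (equal V/J gene and CDR3 length, identity at or above
#' `threshold`), and takes connected components as clones. The component
#' partition coincides with [assign_clones()] on the same records.
#'
#' @param records Record data frame for a single sample and chain.
#' @param threshold Identity threshold.
#' @return A `repertoire_network`: list with `vertices` (data frame `v_call`,
#'   `j_call`, `cdr3_nt`, `size`), `graph` (igraph object), `membership`
#'   (component label per vertex) and `n_clusters`. Empty input yields an
#'   empty network.
#' @export
build_network <- function(records, threshold) {
  if (nrow(records) == 0L) {
    return(structure(list(vertices = data.frame(), graph = igraph::make_empty_graph(),
                          membership = integer(0), n_clusters = 0L),
                     class = "repertoire_network"))
  }
  v <- strip_allele(records$v_call)
  j <- strip_allele(records$j_call)
  key <- paste(v, j, records$cdr3_nt, sep = "\r")
  size <- rowsum(as.numeric(records$count), key)
  first <- !duplicated(key)
  vertices <- data.frame(v_call = v[first], j_call = j[first],
                         cdr3_nt = records$cdr3_nt[first],
                         stringsAsFactors = FALSE)
  vertices$size <- as.integer(size[paste(vertices$v_call, vertices$j_call,
                                         vertices$cdr3_nt, sep = "\r"), 1L])
  # edges within (V, J, length) buckets at the identity threshold
  bucket <- paste(vertices$v_call, vertices$j_call, nchar(vertices$cdr3_nt),
                  sep = "\r")
  edges <- list()
  for (idx in split(seq_len(nrow(vertices)), bucket)) {
    if (length(idx) < 2L) next
    L <- nchar(vertices$cdr3_nt[idx[1L]])
    dmax <- max_mismatches(L, threshold)
    if (dmax <= 0) next
    codes <- seq_codes(vertices$cdr3_nt[idx], L)
    if (length(idx) == 2L) {
      if (sum(codes[, 1L] != codes[, 2L]) <= dmax)
        edges[[length(edges) + 1L]] <- cbind(idx[1L], idx[2L])
      next
    }
    d <- hamming_matrix(codes)
    hit <- which(d <= dmax & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit))
      edges[[length(edges) + 1L]] <- cbind(idx[hit[, 1L]], idx[hit[, 2L]])
  }
  em <- if (length(edges)) do.call(rbind, edges) else matrix(integer(0), ncol = 2)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(vertices) - igraph::vcount(g)))
  igraph::V(g)$size <- vertices$size
  comp <- igraph::components(g)
  structure(list(vertices = vertices, graph = g,
                 membership = as.integer(comp$membership),
                 n_clusters = comp$no),
            class = "repertoire_network")
}

#' @export
print.repertoire_network <- function(x, ...) {
  cat(sprintf("repertoire_network: %d vertices, %d edges, %d clusters\n",
              nrow(x$vertices), igraph::ecount(x$graph), x$n_clusters))
  invisible(x)
}

#' Gini indices of a clonal network
#'
#' `gini_v` is the Gini coefficient of vertex sizes (identical-read counts;
#' clonal expansion) and `gini_c` the Gini coefficient of cluster sizes
#' (clonal dominance). Cluster size is measured in vertices by default;
#' `cluster_size = "reads"` uses summed reads instead. A single-cluster
#' network has no inequality to measure and reports `gini_c = 0` with a
#' degeneracy warning; an empty network reports both as missing.
#'
#' @param network A `repertoire_network`.
#' @param cluster_size `"vertices"` (default) or `"reads"`.
#' @return List with `gini_v` and `gini_c`.
#' @export
network_metrics <- function(network, cluster_size = c("vertices", "reads")) {
  stopifnot(inherits(network, "repertoire_network"))
  cluster_size <- match.arg(cluster_size)
  if (nrow(network$vertices) == 0L)
    return(list(gini_v = NA_real_, gini_c = NA_real_))
  gv <- gini(network$vertices$size)
  sizes <- if (cluster_size == "vertices") {
    tabulate(network$membership, nbins = network$n_clusters)
  } else {
    as.vector(rowsum(as.numeric(network$vertices$size), network$membership))
  }
  if (length(sizes) == 1L) {
    warning("single-cluster network: gini_c reported as 0 (degenerate)")
    gc_ <- 0
  } else {
    gc_ <- gini(sizes)
  }
  list(gini_v = gv, gini_c = gc_)
}

#' Network metrics for every sample of a cohort
#'
#' @param cohort An `ir_cohort`.
#' @param chain Chain to analyse.
#' @param threshold Identity threshold; default from the chain class.
#' @param cluster_size Passed to [network_metrics()].
#' @return Data frame with `sample_id`, `group`, `gini_v`, `gini_c`,
#'   `n_vertices`, `n_clusters`.
#' @export
network_table <- function(cohort, chain, threshold = NULL,
                          cluster_size = "vertices") {
  stopifnot(inherits(cohort, "ir_cohort"))
  threshold <- threshold %||% chain_threshold(chain)
  out <- lapply(cohort_samples(cohort), function(sid) {
    net <- build_network(sample_records(cohort, sid, chain), threshold)
    gm <- suppressWarnings(network_metrics(net, cluster_size))
    data.frame(sample_id = sid,
               group = cohort$metadata$group[cohort$metadata$sample_id == sid],
               gini_v = gm$gini_v, gini_c = gm$gini_c,
               n_vertices = nrow(net$vertices), n_clusters = net$n_clusters)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
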