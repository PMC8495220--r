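#' @keywords internal
"_PACKAGE"

# Chains handled by the pipeline and the identity threshold class each belongs to.
IR_CHAINS <- c("IGH", "IGK", "IGL", "TRA", "TRB")

#' Default CDR3 identity threshold for a chain
#'
#' Immunoglobulin chains use 0.90 nucleotide identity, T-cell receptor chains
#' 0.95, following the clone definition used throughout the pipeline.
#'
#' @param chain Chain name, one of `IGH`, `IGK`, `IGL`, `TRA`, `TRB`.
#' @return A single numeric threshold.
#' @export
chain_threshold <- function(chain) {
  chain <- match.arg(chain, IR_CHAINS)
  if (startsWith(chain, "IG")) 0.90 else 0.95
}

# Strip the allele suffix ("*01") from a V/J gene call so clone equality is at
# the gene level.
strip_allele <- function(call) sub("\\*.*$", "", call)

# First call of a comma-separated MiXCR-style hit list; returns the calls and
# the number of rows that carried more than one candidate.
first_call <- function(call) {
  multi <- grepl(",", call, fixed = TRUE)
  list(call = sub(",.*$", "", call), n_multi = sum(multi))
}

# Symmetric Dirichlet draw via normalised gammas.
rdirichlet1 <- function(n, alpha) {
  g <- stats::rgamma(n, shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- rep(1, n) # numerically degenerate tiny alpha
  g / sum(g)
}

# Scaled-inverse-chi-square draw with df nu and scale S.
rscinvchisq <- function(nu, S) nu * S / stats::rchisq(1L, df = nu)

`%||%` <- function(a, b) if (is.null(a)) b else a
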