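## Log-space upper-tail hypergeometric sum shared by the membership-prediction
## and over-representation tests. Accumulating log-binomial terms through
## logsumexp keeps the sum stable for networks and backgrounds up to ~1e5.
hg_upper_tail <- function(k, N, K, n) {
  if (k == 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  m <- k:hi
  lt <- lchoose(K, m) + lchoose(N - K, n - m) - lchoose(N, n)
  mx <- max(lt)
  min(1, exp(mx + log(sum(exp(lt - mx)))))
}

#' Upper-tail hypergeometric probability for network overlap
#'
#' Probability that a protein with `n` interaction partners, drawn from a
#' network of `N` proteins of which `M` belong to a given pathway, has at
#' least `k` partners inside the pathway:
#' \deqn{\Pr(X \ge k) = \sum_{m=k}^{\min(n,M)} \binom{M}{m}\binom{N-M}{n-m} / \binom{N}{n}.}
#' Computed by log-space accumulation of the binomial terms.
#'
#' All arguments are vectorised and recycled.
#'
#' @param k Observed in-pathway partner count (tail threshold).
#' @param N Proteins in the network.
#' @param M Network proteins that are pathway members.
#' @param n Interaction partners of the protein.
#' @return Probabilities in `[0, 1]`.
#' @export
hypergeom_tail <- function(k, N, M, n) {
  len <- max(length(k), length(N), length(M), length(n))
  k <- rep_len(k, len); N <- rep_len(N, len)
  M <- rep_len(M, len); n <- rep_len(n, len)
  if (!is_count(k) || !is_count(N) || !is_count(M) || !is_count(n)) {
    abort_domain("k, N, M, n must be non-negative integers")
  }
  if (any(M > N) || any(n > N) || any(k > pmin(n, M))) {
    abort_domain("bounds violated: need M <= N, n <= N, 0 <= k <= min(n, M)")
  }
  vapply(seq_len(len), function(i) hg_upper_tail(k[i], N[i], M[i], n[i]),
         numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment
#' `q_(i) = min(1, min_{j>=i} p_(j) * m / j)` in input order.
#'
#' @param p_values Probabilities in `[0, 1]`.
#' @return Adjusted probabilities, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) && (!is.numeric(p_values) || anyNA(p_values) ||
                           any(p_values < 0) || any(p_values > 1))) {
    abort_domain("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation p-value for a query/pathway overlap
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between a query list and a pathway, given the selected background:
#' \deqn{p = \sum_{x=N_u}^{\min(N_U, N_{Pw})}
#'   \binom{N_{Pw}}{x}\binom{N_S-N_{Pw}}{N_U-x} / \binom{N_S}{N_U}}
#' (the one-sided Fisher exact test).
#'
#' Arguments are vectorised and recycled.
#'
#' @param N_S Background size: distinct members annotated to at least one
#'   selected pathway.
#' @param N_Pw Pathway size within the background.
#' @param N_U Query members present in the background.
#' @param N_u Query/pathway overlap.
#' @return Probabilities in `[0, 1]`.
#' @export
enrichment_p <- function(N_S, N_Pw, N_U, N_u) {
  len <- max(length(N_S), length(N_Pw), length(N_U), length(N_u))
  N_S <- rep_len(N_S, len); N_Pw <- rep_len(N_Pw, len)
  N_U <- rep_len(N_U, len); N_u <- rep_len(N_u, len)
  if (!is_count(N_S) || !is_count(N_Pw) || !is_count(N_U) || !is_count(N_u)) {
    abort_domain("contingency counts must be non-negative integers")
  }
  if (any(N_Pw > N_S) || any(N_U > N_S) || any(N_u > pmin(N_U, N_Pw))) {
    abort_domain("bounds violated: need N_Pw <= N_S, N_U <= N_S, N_u <= min(N_U, N_Pw)")
  }
  vapply(seq_len(len), function(i) hg_upper_tail(N_u[i], N_S[i], N_Pw[i], N_U[i]),
         numeric(1))
}
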