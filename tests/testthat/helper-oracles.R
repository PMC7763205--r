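# Independent brute-force oracles the implementation is checked against.
# These deliberately share no code with the package internals.

# Greedy complete-linkage agglomeration by full O(N^3) re-scan: at each step
# scan every cluster pair, take the pair with the smallest maximum cross
# distance, record the merge height. Returns the N-1 merge heights in order.
naive_complete_linkage_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (i in 2:length(clusters)) {
      for (j in 1:(i - 1)) {
        dij <- max(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d) {
          best_d <- dij
          best <- c(j, i)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Two-sided Fisher p for a 2x2 table by exhaustive hypergeometric summation:
# sum the probabilities of every achievable table no more probable than the
# observed one (with the conventional 1e-7 relative tie tolerance).
fisher_two_sided_oracle <- function(k_obs, K_term, n_list, N_bg) {
  k_all <- max(0, n_list + K_term - N_bg):min(n_list, K_term)
  probs <- stats::dhyper(k_all, K_term, N_bg - K_term, n_list)
  p_obs <- probs[k_all == k_obs]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# One-sided (over-representation) tail by direct summation.
fisher_greater_oracle <- function(k_obs, K_term, n_list, N_bg) {
  k_all <- max(0, n_list + K_term - N_bg):min(n_list, K_term)
  probs <- stats::dhyper(k_all, K_term, N_bg - K_term, n_list)
  sum(probs[k_all >= k_obs])
}

# Elementwise-membership Venn decomposition of three sets.
brute_venn <- function(a, b, c_) {
  u <- unique(c(a, b, c_))
  lab <- vapply(u, function(x) {
    paste0(if (x %in% a) "A" else "", if (x %in% b) "B" else "",
           if (x %in% c_) "C" else "")
  }, character(1))
  list(A_only = u[lab == "A"], B_only = u[lab == "B"], C_only = u[lab == "C"],
       AB = u[lab == "AB"], AC = u[lab == "AC"], BC = u[lab == "BC"],
       ABC = u[lab == "ABC"])
}

# Pairwise shared-gene counts by a double loop over subjects.
brute_similarity <- function(genes_by_subject) {
  n <- length(genes_by_subject)
  a <- matrix(0, n, n, dimnames = list(names(genes_by_subject), names(genes_by_subject)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) a[i, j] <- length(intersect(genes_by_subject[[i]], genes_by_subject[[j]]))
    }
  }
  a
}

# Benjamini-Hochberg by its defining formula: adj_i = min over j >= rank(i)
# of p_(j) * m / j, computed on the sorted values and mapped back.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(sorted[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}
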