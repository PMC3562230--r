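# Independent oracles used by the tests. These deliberately avoid the code
# paths they check.

# Fisher's exact two-sided p by brute-force enumeration over all 2x2 tables
# with the observed margins: sum the hypergeometric probabilities of every
# table no more probable than the observed one.
fisher_enumeration_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Product-limit estimator computed step by step from first principles
# (deaths processed before censorings at tied times).
km_hand <- function(time, event) {
  ord <- order(time, -event)
  time <- time[ord]; event <- event[ord]
  s <- 1; out_t <- numeric(0); out_s <- numeric(0)
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / at_risk)
    out_t <- c(out_t, t); out_s <- c(out_s, s)
  }
  data.frame(time = out_t, surv = out_s)
}

# tiny reference used across tests: "ACGTCGCG" with TSS at base 1 and a
# region spanning the whole string
tiny_reference <- function() {
  promoter_reference("ACGTCGCG", tss_offset = 1,
                     regions = list(whole = c(1, 9)))
}

# wide percent matrix with given per-case values recycled across 24 sites
percent_profile <- function(values, n_sites = 24) {
  m <- matrix(rep(values, length.out = n_sites), nrow = 1)
  colnames(m) <- paste0("cpg_", seq_len(n_sites))
  rownames(m) <- "case_1"
  m
}
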