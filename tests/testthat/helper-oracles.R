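# Independent oracles and in-code fixtures used across the suite. These are
# deliberately naive re-derivations (enumeration, brute force, closed form)
# kept separate from the package's own code paths.

# Every non-increasing positive integer abundance vector with S parts
# summing to n (naive recursion, independent of the package's enumerator).
oracle_partitions <- function(n, s, cap = n) {
  if (s == 0) {
    if (n == 0) return(list(integer(0))) else return(list())
  }
  if (n < s) return(list())
  out <- list()
  for (first in seq(min(cap, n - s + 1), 1)) {
    for (tail in oracle_partitions(n - first, s - 1, first)) {
      out[[length(out) + 1]] <- c(first, tail)
    }
  }
  out
}

# grid of all small abundance vectors used by the invariant tests
oracle_small_vectors <- function(max_s = 5, max_n = 12) {
  out <- list()
  for (s in 1:max_s) {
    for (n in s:max_n) {
      out <- c(out, oracle_partitions(n, s))
    }
  }
  out
}

# Duncan oracle: pairwise "not significantly different" matrix built by
# exhaustively testing every contiguous span of the ranked means and
# applying the protection rule (any raw-non-significant span shields every
# pair it contains). Means/MSw/df computed from scratch.
oracle_duncan_nsd <- function(groups, alpha = 0.05) {
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  ord <- order(-means, names(groups))
  means <- means[ord]
  ns <- lengths(groups)[ord]
  df_w <- sum(ns) - k
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  ms_w <- ss_w / df_w
  n_h <- k / sum(1 / ns)
  nsd <- diag(TRUE, k)
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      p <- j - i + 1
      rp <- qtukey(1 - (1 - (1 - alpha)^(p - 1)), p, df_w) * sqrt(ms_w / n_h)
      if (means[i] - means[j] <= rp + 1e-12) {
        # the whole span [i, j] is homogeneous: shield every inner pair
        for (a in i:j) for (b in i:j) nsd[a, b] <- TRUE
      }
    }
  }
  dimnames(nsd) <- list(names(groups)[ord], names(groups)[ord])
  nsd
}

# do two groups share at least one letter in a duncan_mrt display?
shares_letter <- function(mrt, g1, g2) {
  l1 <- strsplit(mrt$letters[mrt$group == g1], "")[[1]]
  l2 <- strsplit(mrt$letters[mrt$group == g2], "")[[1]]
  length(intersect(l1, l2)) > 0
}

# tiny two-plant community built in code
make_toy_community <- function() {
  community_table(
    isolates = data.frame(
      plant = c("P1", "P1", "P1", "P2", "P2"),
      location = c("PAWD", "PAWD", "PAWD", "NCAH", "NCAH"),
      tissue = c("leaf", "stem", "leaf", "root", "root"),
      morphospecies = c("Alpha sp.1", "Alpha sp.2", "Beta sp.1",
                        "Alpha sp.1", "Gamma sp.1"),
      genus = c("Alpha", "Alpha", "Beta", "Alpha", "Gamma"),
      colony_count = c(4, 2, 1, 3, 3)
    ),
    tallies = data.frame(
      plant = c("P1", "P1", "P2"),
      tissue = c("leaf", "stem", "root"),
      segments_examined = c(12, 12, 12),
      segments_colonized = c(5, 2, 6)
    ),
    provenance = "toy"
  )
}
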