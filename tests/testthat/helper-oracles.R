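# Independent brute-force oracles used across the suite. These are written
# against the mathematical definitions, not against the package internals.

# optimal global affine-gap alignment score by exhaustive recursion
# (gap of length g costs open + (g-1)*ext); feasible for sequences <= 8 nt
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               open = -5, ext = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    # prev: 0 none/diag, 1 gap consuming a, 2 gap consuming b
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, 0))
    }
    if (i <= length(av)) {
      g <- if (prev == 1) ext else open
      best <- max(best, g + rec(i + 1, j, 1))
    }
    if (j <= length(bv)) {
      g <- if (prev == 2) ext else open
      best <- max(best, g + rec(i, j + 1, 2))
    }
    best
  }
  rec(1, 1, 0)
}

# minimum substitution count on a fixed topology by exhaustive enumeration
# of internal-node states, per column (gap/N = free state)
oracle_parsimony <- function(msa, tree) {
  m <- unclass(msa)
  bases <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  edges <- tree$edge
  total <- 0
  for (col in seq_len(ncol(m))) {
    obs <- m[tree$tip.label, col]
    combos <- as.matrix(expand.grid(rep(list(bases), nint),
                                    stringsAsFactors = FALSE))
    best <- Inf
    for (r in seq_len(nrow(combos))) {
      state <- character(ntip + nint)
      state[seq_len(ntip)] <- obs
      state[ntip + seq_len(nint)] <- combos[r, ]
      cost <- 0
      for (e in seq_len(nrow(edges))) {
        p <- state[edges[e, 1]]; c_ <- state[edges[e, 2]]
        if (p %in% bases && c_ %in% bases && p != c_) cost <- cost + 1
      }
      best <- min(best, cost)
    }
    total <- total + best
  }
  total
}

# one-tailed Fisher p by complete enumeration over tables with fixed margins
oracle_fisher_one_tail <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  sum(probs[(lo:hi) >= a])
}

# random coding sequence without stop codons
random_cds <- function(n_codons) {
  paste(sample(phygst:::SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}
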