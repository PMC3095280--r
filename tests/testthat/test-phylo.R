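# build a 2-row alignment with a prescribed count of transitions and
# transversions over n sites
pair_with_PQ <- function(n, n_ts, n_tv) {
  a <- rep("A", n)
  b <- a
  if (n_ts > 0) b[seq_len(n_ts)] <- "G"                 # A->G transitions
  if (n_tv > 0) b[n_ts + seq_len(n_tv)] <- "T"          # A->T transversions
  gst_msa(c("x", "y"), c(paste(a, collapse = ""), paste(b, collapse = "")))
}

test_that("distance models: p, Jukes-Cantor and Kimura two-parameter", {
  m <- gst_msa(c("x", "y"), c("ACGTACGT", "ACGTACGT"))
  for (mod in c("p", "JC", "K2P")) {
    expect_equal(distance_matrix(m, mod)$d["x", "y"], 0)
  }
  # K2P closed form at P=0.1, Q=0.05 over 1000 sites
  mq <- pair_with_PQ(1000, 100, 50)
  expect_equal(distance_matrix(mq, "K2P")$d["x", "y"], 0.1701812,
               tolerance = 1e-6)
  # cross-check against an independent implementation
  dnab <- ape::as.DNAbin(t(sapply(msa_strings(mq),
                                  function(s) strsplit(tolower(s), "")[[1]])))
  expect_equal(distance_matrix(mq, "K2P")$d["x", "y"],
               as.numeric(ape::dist.dna(dnab, "K80")), tolerance = 1e-9)
  expect_equal(distance_matrix(mq, "JC")$d["x", "y"],
               as.numeric(ape::dist.dna(dnab, "JC69")), tolerance = 1e-9)

  # JC >= p for 0 < p < 3/4; K2P == JC exactly when Q = 2P
  for (nd in c(10, 100, 200)) {
    mp <- pair_with_PQ(1000, nd, 2 * nd)
    p <- distance_matrix(mp, "p")$d["x", "y"]
    jc <- distance_matrix(mp, "JC")$d["x", "y"]
    k2p <- distance_matrix(mp, "K2P")$d["x", "y"]
    expect_gt(jc, p)
    expect_equal(k2p, jc, tolerance = 1e-12)
  }
  # saturation flag with a lower-bound value
  msat <- pair_with_PQ(100, 0, 80)
  dsat <- suppressWarnings(distance_matrix(msat, "JC"))
  expect_true(dsat$saturated["x", "y"])
  expect_true(is.finite(dsat$d["x", "y"]))
})

test_that("neighbor-joining: closed forms, additive recovery, degeneracy", {
  d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(0.05, 0.15, 0.25))

  # exact recovery of additive matrices from random trees (topology+lengths)
  set.seed(41)
  for (n in c(6, 7, 8)) {
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- runif(nrow(true$edge), 0.05, 0.5)
    D <- cophenetic(true)
    got <- nj_tree(D[true$tip.label, true$tip.label])
    expect_setequal(tree_bipartitions(got), tree_bipartitions(true))
    expect_equal(cophenetic(got)[true$tip.label, true$tip.label], D,
                 tolerance = 1e-8)
    # independent implementation agrees on topology
    expect_setequal(tree_bipartitions(got),
                    tree_bipartitions(ape::nj(D)))
  }

  # all-equal distances: resolved topology with zero internal branches
  deq <- matrix(0.2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(deq) <- 0
  treq <- nj_tree(deq)
  internal <- treq$edge[, 2] > length(treq$tip.label)
  expect_true(all(abs(treq$edge.length[internal]) < 1e-12))
  expect_true(all(treq$edge.length >= 0))
})

test_that("bootstrap supports are reproducible and find clean splits", {
  # two 3-leaf clades separated by 20 diagnostic columns
  set.seed(42)
  core <- strsplit(random_cds(20), "")[[1]][1:40]
  blockA <- paste(core, collapse = "")
  coreB <- core; coreB[seq(1, 40, 2)] <- "A"; coreB[seq(2, 40, 2)] <- "T"
  blockB <- paste(coreB, collapse = "")
  mutate1 <- function(s, pos, b) { x <- strsplit(s, "")[[1]]; x[pos] <- b
                                   paste(x, collapse = "") }
  msa <- gst_msa(c("a1", "a2", "a3", "b1", "b2", "b3"),
                 c(blockA, mutate1(blockA, 2, "C"), mutate1(blockA, 5, "C"),
                   blockB, mutate1(blockB, 9, "C"), mutate1(blockB, 13, "C")))
  tr1 <- bootstrap_support(msa, replicates = 200, seed = 7)
  tr2 <- bootstrap_support(msa, replicates = 200, seed = 7)
  expect_identical(write_newick(tr1), write_newick(tr2))
  key <- paste(sort(c("a1", "a2", "a3")), collapse = "/")
  below <- phygst:::.tips_below(tr1)
  ntip <- 6
  found <- FALSE
  for (k in seq_len(tr1$Nnode)) {
    side <- sort(below[[ntip + k]])
    if (identical(side, c("a1", "a2", "a3")) ||
        identical(side, c("b1", "b2", "b3"))) {
      found <- TRUE
      expect_equal(as.numeric(tr1$node.label[k]), 100)
    }
  }
  expect_true(found)
})

test_that("Fitch length equals exhaustive small-parsimony", {
  m0 <- gst_msa(letters[1:4], rep("ACGT", 4))
  tr <- read_newick("((a,b),(c,d));")
  expect_equal(fitch_length(m0, tr), 0)
  m1 <- gst_msa(letters[1:4], c("AA", "AA", "TT", "TT"))
  expect_equal(fitch_length(m1, tr), 2)
  expect_error(fitch_length(gst_msa("a", "AC"), tr), "leaf without sequence")

  set.seed(43)
  for (k in 1:3) {
    labs <- paste0("t", 1:6)
    seqs <- vapply(labs, function(x)
      paste(sample(c("A", "C", "G", "T", "-"), 6, replace = TRUE,
                   prob = c(.24, .24, .24, .24, .04)), collapse = ""),
      character(1))
    msa <- gst_msa(labs, seqs)
    tree <- ape::rtree(6, rooted = FALSE, tip.label = labs)
    expect_equal(fitch_length(msa, tree), oracle_parsimony(msa, tree))
    # invariant to leaf order permutation
    perm <- sample(labs)
    msa_p <- gst_msa(perm, seqs[perm])
    expect_equal(fitch_length(msa_p, tree), fitch_length(msa, tree))
  }
})

test_that("exhaustive parsimony enumerates all topologies, finds the truth", {
  m4 <- gst_msa(letters[1:4], c("AAAA", "AAAA", "TTTT", "TTTT"))
  r4 <- exhaustive_parsimony(m4)
  expect_equal(r4$n_topologies, 3)
  m6 <- gst_msa(paste0("t", 1:6),
                c("AAAAAA", "AAAAAT", "AATAAA", "TTAAAA", "TTAAAT", "TTTAAA"))
  r6 <- exhaustive_parsimony(m6)
  expect_equal(r6$n_topologies, 105)
  expect_error(exhaustive_parsimony(gst_msa(paste0("x", 1:12),
                                            rep("ACGT", 12))), "exhaustive")

  # 30 clean informative sites on a known 6-leaf topology
  set.seed(44)
  true <- read_newick("((a,b),(c,d),(e,f));")
  blocks <- list(c("a", "b"), c("c", "d"), c("e", "f"))
  L <- 30
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqs <- setNames(rep(list(base), 6), c("a", "b", "c", "d", "e", "f"))
  for (bi in seq_along(blocks)) {
    cols <- ((bi - 1) * 10 + 1):(bi * 10)
    for (lf in blocks[[bi]]) {
      seqs[[lf]][cols] <- chartr("ACGT", "GTAC", seqs[[lf]][cols])
    }
  }
  msa <- gst_msa(names(seqs), vapply(seqs, paste, character(1), collapse = ""))
  res <- exhaustive_parsimony(msa)
  expect_equal(length(res$trees), 1)
  expect_setequal(tree_bipartitions(res$trees[[1]]), tree_bipartitions(true))
})

test_that("clade labels follow the nearest anchored clade after midpoint rooting", {
  # tetraploid contigs grouping with diploid anchors
  tr <- read_newick(paste0("((hA:0.01,(tA1:0.01,tA2:0.01):0.005):0.1,",
                           "(rD:0.01,(tD1:0.01,tD2:0.01):0.005):0.1);"))
  asg <- assign_clades(tr, c(hA = "A", rD = "D"), "PHYC")
  expect_equal(unname(asg$labels[c("tA1", "tA2")]), rep("PHYC.A", 2))
  expect_equal(unname(asg$labels[c("tD1", "tD2")]), rep("PHYC.D", 2))

  # single anchor: every leaf inherits its label
  tr2 <- read_newick("((x:1,y:1):1,(anc:1,z:1):1);")
  asg2 <- assign_clades(tr2, c(anc = "A"), "PHYB")
  expect_true(all(asg2$labels == "PHYB.A"))

  expect_error(assign_clades(tr2, c(nope = "A"), "PHYB"), "anchor missing")
})
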