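# Distance matrices, neighbor-joining, bootstrap, parsimony, clade labeling.
#
# Trees are ape "phylo" objects throughout; all trees are built and reported
# unrooted (midpoint rooting is used transiently for clade labeling only).

#' Pairwise distance matrix from an alignment
#'
#' Models: `"p"` (uncorrected proportion of differences), `"JC"`
#' (Jukes-Cantor) and `"K2P"` (Kimura two-parameter,
#' d = -1/2 log(1-2P-Q) - 1/4 log(1-2Q) with P and Q the observed
#' transition and transversion proportions). Gaps and Ns are ignored:
#' `complete_deletion` (default) drops every column containing any gap/N,
#' `pairwise_deletion` drops sites per pair. Pairs whose correction is
#' undefined are flagged saturated and carry a finite lower-bound value.
#'
#' @param msa `gst_msa`
#' @param model `"p"`, `"JC"` or `"K2P"`
#' @param gap_policy `"complete_deletion"` or `"pairwise_deletion"`
#' @return list of class `"gst_dist"`: `labels`, `d` (symmetric matrix),
#'   `model`, `saturated` (logical matrix)
#' @export
distance_matrix <- function(msa, model = c("p", "JC", "K2P"),
                            gap_policy = c("complete_deletion",
                                           "pairwise_deletion")) {
  model <- match.arg(model)
  gap_policy <- match.arg(gap_policy)
  m <- unclass(msa)
  n <- nrow(m)
  stopifnot(n >= 2L)
  labels <- rownames(m)
  isb <- m %in% c("A", "C", "G", "T"); dim(isb) <- dim(m)
  if (gap_policy == "complete_deletion") {
    keep <- colSums(isb) == n
    m <- m[, keep, drop = FALSE]
    isb <- isb[, keep, drop = FALSE]
  }
  purine <- m == "A" | m == "G"
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  sat <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- isb[i, ] & isb[j, ]
      nsite <- sum(ok)
      if (nsite == 0L) stop("zero comparable sites for pair ",
                            labels[i], " / ", labels[j])
      diff <- ok & (m[i, ] != m[j, ])
      p <- sum(diff) / nsite
      if (model == "p") {
        val <- p; is_sat <- FALSE
      } else if (model == "JC") {
        arg <- 1 - 4 * p / 3
        is_sat <- arg <= 0
        val <- -3 / 4 * log(max(arg, 1e-8))
      } else {
        ts <- sum(diff & (purine[i, ] == purine[j, ]))   # A<->G or C<->T
        P <- ts / nsite
        Q <- p - P
        a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
        is_sat <- a1 <= 0 || a2 <= 0
        val <- -0.5 * log(max(a1, 1e-8)) - 0.25 * log(max(a2, 1e-8))
      }
      d[i, j] <- d[j, i] <- val
      sat[i, j] <- sat[j, i] <- is_sat
    }
  }
  if (any(sat)) warning("saturated pair(s) present; values are lower bounds")
  structure(list(labels = labels, d = d, model = model, saturated = sat),
            class = "gst_dist")
}

.dist_mat <- function(dm) {
  if (inherits(dm, "gst_dist")) dm$d
  else if (is.matrix(dm)) dm
  else as.matrix(dm)
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Canonical agglomeration on the Studier-Keppler Q criterion. Ties are
#' broken by the lexicographically lowest label pair. Negative branch
#' lengths are clamped to zero with the deficit moved to the sibling branch
#' of the join, so path lengths are preserved.
#'
#' @param dm `gst_dist` or symmetric labeled matrix
#' @return unrooted `ape::phylo`
#' @export
nj_tree <- function(dm) {
  D <- .dist_mat(dm)
  labels <- rownames(D)
  n <- length(labels)
  stopifnot(n >= 3L)
  if (inherits(dm, "gst_dist") && any(dm$saturated)) {
    warning("saturated distances used at their lower-bound values")
  }

  ntip <- n
  # node bookkeeping for the growing phylo edge list
  next_node <- ntip + 2L                  # ntip+1 reserved for the root join
  active_ids <- seq_len(ntip)             # phylo node ids of active clusters
  active_lab <- labels                    # tie-break labels of clusters
  edges <- matrix(0L, 0L, 2L)
  elen <- numeric(0)

  while (length(active_ids) > 3L) {
    r <- nrow(D)
    rs <- rowSums(D)
    Q <- (r - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: lowest label pair
    keys <- apply(cand, 1L, function(ij) {
      pr <- sort(c(active_lab[ij[1]], active_lab[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- min(pick); j <- max(pick)

    bi <- 0.5 * D[i, j] + (rs[i] - rs[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    # clamp negatives, moving the deficit to the sibling branch
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_id <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(new_id, active_ids[i]), c(new_id, active_ids[j]))
    elen <- c(elen, bi, bj)

    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    dnew <- dnew[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    new_lab <- min(active_lab[c(i, j)])
    active_lab <- c(active_lab[-c(i, j)], new_lab)
    active_ids <- c(active_ids[-c(i, j)], new_id)
    rownames(D) <- colnames(D) <- active_lab
  }

  # final join of the last three clusters onto the (trifurcating) root
  root <- ntip + 1L
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  bl <- c(b1, b2, b3)
  for (k in seq_len(3L)) {
    if (bl[k] < 0) {
      others <- setdiff(1:3, k)
      bl[others] <- bl[others] + bl[k] / 2
      bl[k] <- 0
    }
  }
  edges <- rbind(edges, cbind(root, active_ids))
  elen <- c(elen, bl)

  # renumber internal nodes to ape convention (root = ntip+1, then others);
  # our internal ids are already >= ntip+1 with root == ntip+1
  tr <- list(edge = edges, edge.length = elen, tip.label = labels,
             Nnode = max(edges) - ntip)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Bootstrap supports for the NJ tree of an alignment
#'
#' Columns are resampled with replacement; the support of each internal
#' bipartition of the point-estimate tree is the percentage of replicate NJ
#' trees containing it. Supports are stored as internal node labels.
#'
#' @param msa `gst_msa`
#' @param model distance model, see [distance_matrix()]
#' @param replicates number of bootstrap replicates
#' @param seed integer seed (mandatory for reproducibility)
#' @param gap_policy passed to [distance_matrix()]
#' @return `ape::phylo` with `node.label` support percentages
#' @export
bootstrap_support <- function(msa, model = "p", replicates = 500L, seed = 1L,
                              gap_policy = "complete_deletion") {
  stopifnot(replicates >= 1L)
  m <- unclass(msa)
  point <- nj_tree(distance_matrix(msa, model, gap_policy))
  parts <- tree_bipartitions(point)
  nvar <- sum(apply(m, 2L, function(col) {
    b <- col[col %in% c("A", "C", "G", "T")]
    length(unique(b)) > 1L
  }))
  counts <- setNames(numeric(length(parts)), parts)
  used <- 0L
  if (nvar < 2L) {
    warning("fewer than 2 variable columns; supports reported as 0")
  } else {
    set.seed(seed)
    for (b in seq_len(replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_msa <- m[, cols, drop = FALSE]
      class(rep_msa) <- c("gst_msa", "matrix", "array")
      tr <- tryCatch(nj_tree(distance_matrix(rep_msa, model, gap_policy)),
                     error = function(e) NULL)
      if (is.null(tr)) next
      used <- used + 1L
      hit <- parts %in% tree_bipartitions(tr)
      counts[hit] <- counts[hit] + 1
    }
  }
  supp <- if (used > 0L) 100 * counts / used else counts * 0
  .set_support_labels(point, supp)
}

# write per-bipartition supports into node labels of an unrooted phylo
.set_support_labels <- function(tree, supports) {
  tips <- tree$tip.label
  ntip <- length(tips)
  lab <- character(tree$Nnode)
  below <- .tips_below(tree)
  for (k in seq_len(tree$Nnode)) {
    side <- sort(below[[ntip + k]])
    if (length(side) <= 1L || length(side) >= ntip - 1L) { lab[k] <- ""; next }
    other <- sort(setdiff(tips, side))
    a <- paste(side, collapse = "/"); b <- paste(other, collapse = "/")
    key <- if (a < b) a else b
    lab[k] <- if (key %in% names(supports)) format(round(supports[[key]])) else ""
  }
  tree$node.label <- lab
  tree
}

# leaf labels under each node (tips and internals) of a phylo
.tips_below <- function(tree) {
  ntip <- length(tree$tip.label)
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

## ---- parsimony -------------------------------------------------------------

.FITCH_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

#' Fitch small-parsimony length of a tree on an alignment
#'
#' Sum over columns of the minimum number of nucleotide changes on the given
#' topology; gaps and Ns are treated as missing (any state, no cost).
#'
#' @param msa `gst_msa`
#' @param tree `ape::phylo`; every leaf must be an alignment row
#' @return integer change count
#' @export
fitch_length <- function(msa, tree) {
  m <- unclass(msa)
  miss <- setdiff(tree$tip.label, rownames(m))
  if (length(miss)) stop("leaf without sequence: ", paste(miss, collapse = ", "))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  L <- ncol(m)
  tr <- ape::reorder.phylo(tree, "postorder")
  states <- matrix(0L, nnode, L)
  for (i in seq_len(ntip)) {
    b <- .FITCH_BITS[m[tr$tip.label[i], ]]
    b[is.na(b)] <- 15L                     # gap / N: any state
    states[i, ] <- b
  }
  cost <- integer(L)
  visited <- logical(nnode)
  visited[seq_len(ntip)] <- TRUE
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    if (!visited[parent]) {
      states[parent, ] <- states[child, ]
      visited[parent] <- TRUE
    } else {
      inter <- bitwAnd(states[parent, ], states[child, ])
      empty <- inter == 0L
      cost <- cost + empty
      states[parent, ] <- ifelse(empty,
                                 bitwOr(states[parent, ], states[child, ]),
                                 inter)
    }
  }
  sum(cost)
}

# enumerate all unrooted topologies over the given labels as edge lists
.enumerate_topologies <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3L)
  # nodes: 1..n tips, internal nodes numbered from n+1
  base <- list(list(edge = rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L)),
                    nint = 1L))
  if (n == 3L) return(base)
  trees <- base
  for (leaf in 4:n) {
    grown <- list()
    for (tr in trees) {
      ne <- nrow(tr$edge)
      for (e in seq_len(ne)) {
        new_int <- n + tr$nint + 1L
        edge <- tr$edge
        u <- edge[e, 1L]; v <- edge[e, 2L]
        edge[e, ] <- c(u, new_int)
        edge <- rbind(edge, c(new_int, v), c(new_int, leaf))
        grown[[length(grown) + 1L]] <- list(edge = edge, nint = tr$nint + 1L)
      }
    }
    trees <- grown
  }
  trees
}

.edgelist_to_phylo <- function(edge, labels, nint) {
  n <- length(labels)
  tr <- list(edge = edge, tip.label = labels, Nnode = nint)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Exhaustive maximum-parsimony search
#'
#' Enumerates all (2n-5)!! unrooted topologies for n leaves and scores each
#' with [fitch_length()], returning every minimum-length tree.
#'
#' @param msa `gst_msa`
#' @param max_taxa refuse to enumerate beyond this many leaves
#' @return list with `trees` (list of `phylo`), `length` (minimum changes)
#'   and `n_topologies` examined
#' @export
exhaustive_parsimony <- function(msa, max_taxa = 10L) {
  labels <- rownames(unclass(msa))
  n <- length(labels)
  if (n > max_taxa) {
    stop("more than ", max_taxa,
         " taxa: exhaustive search impractical, use nj_tree()")
  }
  topos <- .enumerate_topologies(labels)
  lens <- vapply(topos, function(tp) {
    fitch_length(msa, .edgelist_to_phylo(tp$edge, labels, tp$nint))
  }, numeric(1))
  best <- which(lens == min(lens))
  list(trees = lapply(topos[best], function(tp)
         .edgelist_to_phylo(tp$edge, labels, tp$nint)),
       length = min(lens),
       n_topologies = length(topos))
}

## ---- clade labeling --------------------------------------------------------

#' Assign subfamily/genome clade labels from anchor taxa
#'
#' The tree is midpoint-rooted (for labeling only); each non-anchor leaf is
#' labeled `<subfamily>.<genome>` after the genome of the anchors in its
#' smallest enclosing anchor-containing clade. Leaves whose smallest such
#' clade mixes anchor genomes are `"unresolved"`.
#'
#' @param tree `ape::phylo`
#' @param anchors named character vector: leaf label -> genome label (the
#'   diploid A- and D-genome reference contigs)
#' @param subfamily subfamily name used as the label prefix (e.g. `"PHYB"`)
#' @return list of class `"clade_assignment"`: `labels` (named vector over
#'   non-anchor leaves), `anchors`
#' @export
assign_clades <- function(tree, anchors, subfamily) {
  missing_anchor <- setdiff(names(anchors), tree$tip.label)
  if (length(missing_anchor)) {
    stop("anchor missing from tree: ", paste(missing_anchor, collapse = ", "))
  }
  rooted <- phangorn::midpoint(tree)
  ntip <- length(rooted$tip.label)
  parent_of <- integer(ntip + rooted$Nnode)
  parent_of[rooted$edge[, 2L]] <- rooted$edge[, 1L]
  tips_below <- .tips_below(rooted)
  root <- ntip + 1L
  out <- character(0)
  leaves <- setdiff(rooted$tip.label, names(anchors))
  for (lf in leaves) {
    node <- which(rooted$tip.label == lf)
    label <- "unresolved"
    repeat {
      node <- parent_of[node]
      if (node == 0L) break
      anc_here <- intersect(tips_below[[node]], names(anchors))
      if (length(anc_here)) {
        g <- unique(anchors[anc_here])
        label <- if (length(g) == 1L) paste(subfamily, g, sep = ".") else
          "unresolved"
        break
      }
      if (node == root) break
    }
    out[lf] <- label
  }
  structure(list(labels = out, anchors = anchors, subfamily = subfamily),
            class = "clade_assignment")
}
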