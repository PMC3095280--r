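# Clone-to-contig assembly by shared diagnostic SNPs, consensus calling
# with correction of sporadic polymerase errors, PCR-chimera screening by a
# maximal-chi-square breakpoint scan, and the clone-count bias test.
#
# The grouping rule mirrors the study design: an alignment column is
# diagnostic when at least two distinct alleles are each supported by at
# least two clones; a variant carried by a single clone is presumed a Taq
# substitution error and corrected toward the consensus.

#' Find diagnostic SNP (and shared indel) sites among aligned clones
#'
#' @param aligned_clones `gst_msa` (>= 2 rows)
#' @param min_support minimum clones per allele (default 2)
#' @return data.frame with `column` (0-based), `alleles`
#'   (comma-separated `base:count`), `indel` flag, plus a list-column
#'   `clone_ids` mapping each supported allele to its clones
#' @export
find_diagnostic_sites <- function(aligned_clones, min_support = 2L) {
  m <- unclass(aligned_clones)
  stopifnot(nrow(m) >= 2L)
  symbols <- c("A", "C", "G", "T", "-")
  counts <- vapply(symbols, function(b) colSums(m == b),
                   numeric(ncol(m)))              # L x 5
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L,
                                      dimnames = list(NULL, symbols))
  supported <- counts >= min_support
  diag_cols <- which(rowSums(supported) >= 2L)
  cols <- integer(0); alleles <- character(0); indel <- logical(0)
  ids_per <- list()
  for (j in diag_cols) {
    col <- m[, j]
    sup <- symbols[supported[j, ]]
    cols <- c(cols, j - 1L)
    alleles <- c(alleles, paste(sup, counts[j, sup], sep = ":",
                                collapse = ","))
    indel <- c(indel, "-" %in% sup)
    ids_per[[length(ids_per) + 1L]] <-
      lapply(setNames(nm = sup), function(b) rownames(m)[col == b])
  }
  out <- data.frame(column = cols, alleles = alleles, indel = indel,
                    stringsAsFactors = FALSE)
  out$clone_ids <- ids_per
  out
}

# IUPAC code for a set of tied consensus bases (gap excluded)
.tie_code <- function(bases) {
  bases <- setdiff(bases, c("-", "N"))
  if (!length(bases)) return("N")
  iupac_code(bases)
}

#' Assemble clone sequences into locus contigs
#'
#' Clones are grouped by their haplotype over the diagnostic sites; groups
#' are merged by single linkage whenever two haplotypes differ at fewer
#' than `min_shared_sites` sites and share no supported indel difference,
#' so the surviving contigs differ at >= `min_shared_sites` diagnostic
#' SNPs (or >= 1 shared indel). The consensus is the column-wise majority
#' over members (ties become IUPAC ambiguity codes, flagged); positions
#' where exactly one member disagrees are recorded as corrected errors.
#' Clones with > 20% N are excluded and logged.
#'
#' @param aligned_clones `gst_msa`
#' @param min_support minimum clones per diagnostic allele
#' @param min_shared_sites diagnostic-site differences required to call
#'   two contigs distinct
#' @param taxon taxon label stamped on the contigs
#' @return list of contigs, each a list with `id`, `taxon`, `members`,
#'   `consensus` (ungapped string), `consensus_gapped`, `corrected`
#'   (data.frame clone/column), `ambiguous_columns`, `clade`; excluded
#'   clones in `attr(,"excluded")`
#' @export
assemble_contigs <- function(aligned_clones, min_support = 2L,
                             min_shared_sites = 2L, taxon = NA_character_) {
  m <- unclass(aligned_clones)
  stopifnot(nrow(m) >= min_support)
  frac_n <- rowMeans(m == "N")
  excluded <- rownames(m)[frac_n > 0.2]
  if (length(excluded)) m <- m[frac_n <= 0.2, , drop = FALSE]
  msa_kept <- m; class(msa_kept) <- c("gst_msa", "matrix", "array")
  sites <- find_diagnostic_sites(msa_kept, min_support)
  n <- nrow(m)

  if (nrow(sites) == 0L) {
    groups <- list(rownames(m))
  } else {
    hap <- m[, sites$column + 1L, drop = FALSE]
    hap_key <- apply(hap, 1L, paste, collapse = "")
    uniq <- unique(hap_key)
    # pairwise haplotype distances (sites where both have a supported call)
    k <- length(uniq)
    hmat <- do.call(rbind, strsplit(uniq, ""))
    merge_ok <- matrix(FALSE, k, k)
    for (x in seq_len(k)) {
      for (y in seq_len(k)) {
        if (x == y) { merge_ok[x, y] <- TRUE; next }
        dif <- hmat[x, ] != hmat[y, ]
        indel_dif <- any(dif & sites$indel &
                           (hmat[x, ] == "-" | hmat[y, ] == "-"))
        merge_ok[x, y] <- (sum(dif) < min_shared_sites) && !indel_dif
      }
    }
    # single-linkage components over the mergeable relation
    comp <- seq_len(k)
    repeat {
      changed <- FALSE
      for (x in seq_len(k)) for (y in seq_len(k)) {
        if (merge_ok[x, y] && comp[y] != comp[x]) {
          comp[comp == comp[y]] <- comp[x]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    groups <- lapply(unique(comp), function(cc) {
      rownames(m)[hap_key %in% uniq[comp == cc]]
    })
  }
  # deterministic order: by size desc, then first member name
  first <- vapply(groups, function(g) sort(g)[1L], character(1))
  groups <- groups[order(-lengths(groups), first)]

  symbols2 <- c("A", "C", "G", "T", "-", "N")
  contigs <- list()
  for (gi in seq_along(groups)) {
    rows <- m[groups[[gi]], , drop = FALSE]
    cnt <- vapply(symbols2, function(b) colSums(rows == b),
                  numeric(ncol(rows)))            # L x 6
    if (ncol(rows) == 1L) cnt <- matrix(cnt, nrow = 1L,
                                        dimnames = list(NULL, symbols2))
    cnt[, "N"] <- 0                               # N never wins the consensus
    mx <- do.call(pmax, as.data.frame(cnt))
    n_top <- rowSums(cnt == mx)
    cons <- symbols2[max.col(cnt, ties.method = "first")]
    amb <- which(n_top > 1L)
    for (j in amb) cons[j] <- .tie_code(symbols2[cnt[j, ] == mx[j]])
    corrected <- list()
    if (nrow(rows) > 1L) {
      fix_cols <- which(n_top == 1L & mx == nrow(rows) - 1L)
      for (j in fix_cols) {
        dis <- which(rows[, j] != cons[j])
        corrected[[length(corrected) + 1L]] <-
          data.frame(clone = rownames(rows)[dis], column = j - 1L,
                     observed = rows[dis, j], consensus = cons[j],
                     stringsAsFactors = FALSE)
      }
    }
    gapped <- paste(cons, collapse = "")
    contigs[[gi]] <- list(
      id = sprintf("%s_ctg%02d", ifelse(is.na(taxon), "set", taxon), gi),
      taxon = taxon,
      members = groups[[gi]],
      consensus = gsub("-", "", gapped, fixed = TRUE),
      consensus_gapped = gapped,
      corrected = if (length(corrected)) do.call(rbind, corrected) else
        data.frame(clone = character(0), column = integer(0),
                   observed = character(0), consensus = character(0)),
      ambiguous_columns = amb - 1L,
      clade = NA_character_)
  }
  attr(contigs, "excluded") <- excluded
  attr(contigs, "diagnostic_sites") <- sites
  contigs
}

# vectorized max chi-square over ordered breakpoints of a 1/2 match vector
.max_chisq_scan <- function(mvec) {
  k <- length(mvec)
  A <- sum(mvec == 1L); B <- k - A
  if (A == 0L || B == 0L || k < 2L) return(list(stat = 0, split = NA_integer_))
  a <- cumsum(mvec == 1L)[-k]           # parent1 matches left of breakpoint
  i <- seq_len(k - 1L)
  b <- i - a
  # 2x2: [a, A-a; b, B-b], chi2 = k (ad-bc)^2 / (r1 r2 c1 c2)
  r1 <- i; r2 <- k - i
  num <- (a * (B - b) - (A - a) * b)^2 * k
  den <- r1 * r2 * A * B
  stat <- num / den
  best <- which.max(stat)
  list(stat = stat[best], split = best)
}

# permutation null of the max chi-square scan, cached by (k, A)
.perm_null <- function(k, A, n_perm) {
  key <- paste(k, A, n_perm, sep = "_")
  cache <- .phygst_cache$chimera_null
  if (is.null(cache)) cache <- .phygst_cache$chimera_null <- new.env(parent = emptyenv())
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  base <- c(rep(1L, A), rep(2L, k - A))
  null <- vapply(seq_len(n_perm), function(b) {
    .max_chisq_scan(sample(base))$stat
  }, numeric(1))
  cache[[key]] <- null
  null
}

#' Screen clones for PCR-mediated recombination (chimeras)
#'
#' For every clone and contig pair, the clone is scored 1/2 at each
#' informative site (columns where the two contig consensuses differ) by
#' which parent it matches; a maximal-chi-square scan over ordered
#' breakpoints is compared against a site-permutation null (`n_perm`
#' permutations, seeded). Clones with `p <= alpha` for some parent pair
#' are called, with the breakpoint interval spanning the flanking
#' informative sites of the best split. Clones offering < 4 informative
#' sites for every pair are skipped (logged).
#'
#' @param aligned_clones `gst_msa`
#' @param contigs result of [assemble_contigs()] (>= 2 contigs)
#' @param n_perm permutations for the null (>= 999 recommended)
#' @param alpha call threshold on the permutation p-value
#' @param seed integer seed
#' @param min_members parent contigs must have at least this many member
#'   clones; unsupported singleton clusters (themselves chimera
#'   candidates) are never treated as recombination parents
#' @param max_mosaic_mismatch a call additionally requires the two-parent
#'   mosaic at the best split to reproduce the clone up to this many
#'   mismatches (a true PCR recombinant is an exact splice of its
#'   templates apart from sporadic polymerase error), and to fit at least
#'   two mismatches better than any single contig
#' @return data.frame of calls: `clone_id`, `parent1`, `parent2`,
#'   `breakpoint_lo`, `breakpoint_hi` (1-based inclusive alignment
#'   columns), `stat`, `p_value`; skipped clones in `attr(,"skipped")`
#' @export
detect_chimeras <- function(aligned_clones, contigs, n_perm = 999L,
                            alpha = 0.05, seed = 1L, min_members = 2L,
                            max_mosaic_mismatch = 2L) {
  if (length(contigs) < 2L) stop("need >= 2 contigs to screen for chimeras")
  m <- unclass(aligned_clones)
  if (!is.null(seed)) set.seed(seed)
  cons <- lapply(contigs, function(ct) strsplit(ct$consensus_gapped, "")[[1L]])
  eligible <- which(vapply(contigs, function(ct) length(ct$members),
                           integer(1)) >= min_members)
  if (length(eligible) < 2L) {
    out <- data.frame(clone_id = character(0), parent1 = character(0),
                      parent2 = character(0), breakpoint_lo = integer(0),
                      breakpoint_hi = integer(0), stat = numeric(0),
                      p_value = numeric(0))
    attr(out, "skipped") <- rownames(m)
    return(out)
  }
  calls <- list(); skipped <- character(0)
  pair_idx <- combn(eligible, 2L)
  base_set <- c("A", "C", "G", "T")

  member_of <- setNames(rep(NA_integer_, nrow(m)), rownames(m))
  for (ci in seq_along(contigs)) member_of[contigs[[ci]]$members] <- ci

  for (cl in rownames(m)) {
    clone <- m[cl, ]
    # mismatch profile of the clone against every eligible parent consensus
    mis <- lapply(eligible, function(ci) {
      p <- cons[[ci]]
      ok <- clone %in% base_set & p %in% base_set
      ok & clone != p
    })
    names(mis) <- as.character(eligible)
    # best single-origin fit, ignoring the clone's own cluster (a cluster
    # made of co-breakpoint chimeras must not vouch for its members)
    others <- setdiff(eligible, member_of[[cl]])
    d_single <- if (length(others)) {
      min(vapply(as.character(others), function(k) sum(mis[[k]]), numeric(1)))
    } else Inf
    own_idx <- member_of[[cl]]
    own_size <- if (is.na(own_idx)) 0L else length(contigs[[own_idx]]$members)
    any_informative <- FALSE
    best <- NULL
    for (pc in seq_len(ncol(pair_idx))) {
      i <- pair_idx[1L, pc]; j <- pair_idx[2L, pc]
      # a recombination parent must be better supported than the clone's
      # own cluster (a pair involving the own cluster is always testable);
      # co-breakpoint chimera clusters cannot vouch against their equals
      own_in_pair <- !is.na(own_idx) && (i == own_idx || j == own_idx)
      if (!own_in_pair &&
          min(length(contigs[[i]]$members),
              length(contigs[[j]]$members)) <= own_size) next
      p1 <- cons[[i]]; p2 <- cons[[j]]
      inf <- which(p1 != p2 & p1 %in% base_set & p2 %in% base_set)
      hit1 <- clone[inf] == p1[inf]
      hit2 <- clone[inf] == p2[inf]
      use <- xor(hit1, hit2)
      sites <- inf[use]
      mvec <- ifelse(hit1[use], 1L, 2L)
      if (length(mvec) < 4L) next
      any_informative <- TRUE
      scan <- .max_chisq_scan(mvec)
      if (scan$stat <= 0) next
      # the two-parent mosaic at the best split must reproduce the clone
      # near-perfectly and clearly beat every single-contig explanation;
      # lineage-shared sites that merely cluster positionally fail this
      # even when the chi-square scan is formally significant
      bp <- sites[scan$split]
      m1 <- cumsum(mis[[as.character(i)]]); m2 <- cumsum(mis[[as.character(j)]])
      d_mosaic <- min(m1[bp] + m2[length(clone)] - m2[bp],
                      m2[bp] + m1[length(clone)] - m1[bp])
      if (d_single - d_mosaic < 2 || d_mosaic > max_mosaic_mismatch) next
      null <- .perm_null(length(mvec), sum(mvec == 1L), n_perm)
      p <- (1 + sum(null >= scan$stat - 1e-9)) / (n_perm + 1)
      if (p <= alpha &&
          (is.null(best) || p < best$p_value ||
             (p == best$p_value && scan$stat > best$stat))) {
        best <- data.frame(
          clone_id = cl,
          parent1 = contigs[[i]]$id, parent2 = contigs[[j]]$id,
          breakpoint_lo = sites[scan$split],
          breakpoint_hi = sites[scan$split + 1L],
          stat = scan$stat, p_value = p, stringsAsFactors = FALSE)
      }
    }
    if (!any_informative) skipped <- c(skipped, cl)
    if (!is.null(best)) calls[[length(calls) + 1L]] <- best
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(clone_id = character(0), parent1 = character(0),
               parent2 = character(0), breakpoint_lo = integer(0),
               breakpoint_hi = integer(0), stat = numeric(0),
               p_value = numeric(0))
  attr(out, "skipped") <- skipped
  out
}

#' Goodness-of-fit test for clone-count amplification bias
#'
#' Pearson chi-square against the expected clade proportions
#' (df = k - 1). When any expected count is below 5 and there are two
#' categories, an exact binomial p-value is also reported.
#'
#' @param observed named vector of clone counts per clade
#' @param expected_proportions same-length proportions summing to 1
#'   (default equal)
#' @return list: `chi2`, `df`, `p`, and `p_exact` (`NA` unless computed)
#' @export
clone_count_bias_test <- function(observed, expected_proportions = NULL) {
  k <- length(observed)
  stopifnot(k >= 2L)
  tot <- sum(observed)
  if (tot == 0) stop("zero total clone count")
  if (is.null(expected_proportions)) expected_proportions <- rep(1 / k, k)
  stopifnot(length(expected_proportions) == k,
            abs(sum(expected_proportions) - 1) < 1e-8)
  expd <- tot * expected_proportions
  chi2 <- sum((observed - expd)^2 / expd)
  df <- k - 1L
  p <- pchisq(chi2, df, lower.tail = FALSE)
  p_exact <- NA_real_
  if (any(expd < 5) && k == 2L) {
    p_exact <- stats::binom.test(observed[1L], tot,
                                 expected_proportions[1L])$p.value
  }
  list(chi2 = chi2, df = df, p = p, p_exact = p_exact)
}
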