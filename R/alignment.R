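# Pairwise and star-progressive multiple alignment.
#
# The study's amplicons are high-identity (>94%) gene fragments, so a star
# alignment around the most central sequence is adequate; the pairwise core
# is an exact global affine-gap DP (Gotoh), optionally banded for speed on
# near-identical long amplicons (the band is widened adaptively until the
# score stabilizes, so banded results match the exact DP on these data).

#' Optimal global pairwise alignment with affine gap costs
#'
#' A gap of length g costs `gap_open + (g-1)*gap_extend`. Tie-breaking in
#' the traceback is deterministic: diagonal preferred, then gap in the
#' second sequence, then gap in the first.
#'
#' @param a,b `gst_seqs` rows or nucleotide strings
#' @param match,mismatch,gap_open,gap_extend scoring parameters
#' @param band half-width of an optional alignment band (`NULL` = exact
#'   full DP)
#' @return 2-row `gst_msa` with attribute `"score"`
#' @export
pairwise_align <- function(a, b, match = 1, mismatch = -1, gap_open = -5,
                           gap_extend = -1, band = NULL) {
  lst_a <- is.list(a) || is.data.frame(a)
  lst_b <- is.list(b) || is.data.frame(b)
  ida <- if (lst_a && !is.null(a$id)) a$id[1L] else "a"
  idb <- if (lst_b && !is.null(b$id)) b$id[1L] else "b"
  sa <- toupper(if (lst_a) a$residues[1L] else as.character(a))
  sb <- toupper(if (lst_b) b$residues[1L] else as.character(b))
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence")
  res <- .align_affine_cpp(sa, sb, match, mismatch, gap_open, gap_extend,
                           if (is.null(band)) -1L else as.integer(band), FALSE)
  out <- gst_msa(c(ida, idb), c(res$a, res$b))
  attr(out, "score") <- res$score
  out
}

# score only, with adaptive banding: double the band until the score stops
# improving (guaranteed exact once the optimal path fits inside the band)
.pair_score <- function(sa, sb, match = 1, mismatch = -1, gap_open = -5,
                        gap_extend = -1) {
  b <- 8L + abs(nchar(sa) - nchar(sb))
  full <- max(nchar(sa), nchar(sb))
  s <- .align_affine_cpp(sa, sb, match, mismatch, gap_open, gap_extend, b, TRUE)$score
  while (b < full) {
    b2 <- min(full, 4L * b)
    s2 <- .align_affine_cpp(sa, sb, match, mismatch, gap_open, gap_extend, b2, TRUE)$score
    if (s2 <= s) return(s2)
    b <- b2; s <- s2
  }
  s
}

#' Star-progressive multiple alignment
#'
#' The center is the sequence maximizing the summed pairwise alignment
#' scores (ties broken by input order); the others are merged against it
#' under "once a gap, always a gap". Row order equals input order.
#'
#' @param seqs `gst_seqs` (>= 1 row)
#' @inheritParams pairwise_align
#' @return `gst_msa`
#' @export
star_msa <- function(seqs, match = 1, mismatch = -1, gap_open = -5,
                     gap_extend = -1) {
  n <- nrow(seqs)
  stopifnot(n >= 1L)
  if (n == 1L) return(gst_msa(seqs$id, seqs$residues))
  strs <- toupper(seqs$residues)

  # center selection by summed pairwise score
  tot <- numeric(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- if (strs[i] == strs[j]) nchar(strs[i]) * match else
        .pair_score(strs[i], strs[j], match, mismatch, gap_open, gap_extend)
      tot[i] <- tot[i] + s
      tot[j] <- tot[j] + s
    }
  }
  center <- which.max(tot)

  # master center string grows gaps as sequences are merged
  master <- strsplit(strs[center], "", fixed = TRUE)[[1L]]
  rows <- vector("list", n)
  rows[[center]] <- master
  for (k in seq_len(n)[-center]) {
    aln <- pairwise_align(list(id = "c", residues = paste(master[master != "-"],
                                                          collapse = "")),
                          list(id = "s", residues = strs[k]),
                          match, mismatch, gap_open, gap_extend)
    ac <- unclass(aln)[1L, ]          # center (ungapped master) aligned
    as_ <- unclass(aln)[2L, ]
    # map the pairwise alignment onto the gapped master: existing master
    # columns keep their order; pairwise columns where the center gained a
    # new gap are spliced in after their anchoring master column
    nongap_idx <- which(master != "-")      # master cols carrying center bases
    ac_nongap <- which(ac != "-")           # matching pairwise columns
    stopifnot(length(nongap_idx) == length(ac_nongap))
    newgap_pi <- which(ac == "-")
    t_before <- cumsum(ac != "-")[newgap_pi]
    anchor <- rep(0L, length(newgap_pi))
    anchor[t_before > 0L] <- nongap_idx[t_before[t_before > 0L]]
    keys <- c(seq_along(master), anchor + newgap_pi * 1e-9)
    ord <- order(keys)
    src <- c(seq_along(master), rep(NA_integer_, length(newgap_pi)))[ord]
    master_pw <- rep(NA_integer_, length(master))
    master_pw[nongap_idx] <- ac_nongap
    pw_src <- c(master_pw, newgap_pi)[ord]

    master <- ifelse(is.na(src), "-", master[src])
    for (q in seq_along(rows)) {
      if (!is.null(rows[[q]]) && q != center) {
        rows[[q]] <- ifelse(is.na(src), "-", rows[[q]][src])
      }
    }
    rows[[center]] <- master
    rows[[k]] <- ifelse(is.na(pw_src), "-", as_[pw_src])
  }
  gst_msa(seqs$id, vapply(rows, paste, character(1), collapse = ""))
}

#' Alignment summary statistics
#'
#' Identical sites are columns with a single residue state and no gap.
#' Mean pairwise similarity uses pairwise deletion by default: for each
#' sequence pair, matches divided by columns where both have an unambiguous
#' base. Indel events are maximal gap runs summed over rows. When `frame`
#' is given, stop codons are counted over the ungapped rows in that frame.
#'
#' @param msa `gst_msa`
#' @param frame optional reading frame (0/1/2) for the stop-codon scan
#' @param gap_policy `"pairwise_deletion"` (default) or
#'   `"complete_deletion"` for the similarity computation
#' @return list of class `"alignment_stats"`: `length`,
#'   `mean_pairwise_similarity` (percent), `identical_sites`,
#'   `identical_pct`, `indel_events`, `stop_codons`
#' @export
alignment_stats <- function(msa, frame = NULL,
                            gap_policy = c("pairwise_deletion",
                                           "complete_deletion")) {
  gap_policy <- match.arg(gap_policy)
  m <- unclass(msa)
  n <- nrow(m); L <- ncol(m)
  ident <- sum(apply(m, 2L, function(col) {
    all(col != "-") && length(unique(col)) == 1L
  }))
  base <- m %in% c("A", "C", "G", "T")
  dim(base) <- dim(m)
  keep_cols <- if (gap_policy == "complete_deletion") {
    which(colSums(base) == n)
  } else seq_len(L)
  sims <- numeric(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ok <- keep_cols[base[i, keep_cols] & base[j, keep_cols]]
        if (!length(ok)) stop("no comparable sites for pair ",
                              rownames(m)[i], " / ", rownames(m)[j])
        sims <- c(sims, 100 * mean(m[i, ok] == m[j, ok]))
      }
    }
  }
  indels <- sum(vapply(seq_len(n), function(i) {
    r <- rle(m[i, ] == "-")
    sum(r$values)
  }, numeric(1)))
  stops <- NA_integer_
  if (!is.null(frame)) {
    if (L < 3L) stop("alignment too short for a reading-frame scan")
    stops <- sum(vapply(seq_len(n), function(i) {
      pep <- translate_cds(msa_ungap(msa, i), frame)
      lengths(regmatches(pep, gregexpr("*", pep, fixed = TRUE)))
    }, numeric(1)))
  }
  structure(list(length = L,
                 mean_pairwise_similarity = if (length(sims)) mean(sims) else 100,
                 identical_sites = ident,
                 identical_pct = 100 * ident / L,
                 indel_events = indels,
                 stop_codons = stops),
            class = "alignment_stats")
}
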