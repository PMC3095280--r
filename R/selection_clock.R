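# Nei-Gojobori synonymous/nonsynonymous analysis, Fisher's exact selection
# test, and synonymous-clock calibration and dating.
#
# Site counting and pathway averaging follow Nei & Gojobori's unweighted
# method: fractional synonymous sites per codon position, multi-difference
# codons averaged over all orderings of single steps, pathways through stop
# codons excluded. Rates are Jukes-Cantor corrected:
# K = -(3/4) log(1 - 4p/3), undefined (saturated) for p >= 3/4 and then
# reported as the bound ">2.0" with numeric floor 2.0.

KS_SATURATION_FLOOR <- 2.0

#' Synonymous/nonsynonymous site counts of one codon
#'
#' For each position the fraction of the single-base changes that are
#' synonymous; changes creating stop codons are excluded from the
#' denominator of that position. `s + n = 3` holds exactly when no neighbor
#' is a stop.
#'
#' @param codon 3-letter string over A/C/G/T, not a stop codon
#' @return named numeric `c(s = , n = )`
#' @export
ng_sites <- function(codon) {
  codon <- toupper(codon)
  if (!codon %in% names(GENETIC_CODE_STD)) stop("invalid codon: ", codon)
  if (GENETIC_CODE_STD[[codon]] == "*") stop("stop codon: ", codon)
  tab <- .ng_site_table()
  unlist(tab[codon, c("s", "n")])
}

# memoized per-codon site table
.ng_site_table <- function() {
  if (!is.null(.phygst_cache$ng_sites)) return(.phygst_cache$ng_sites)
  bases <- c("A", "C", "G", "T")
  tab <- data.frame(s = numeric(length(SENSE_CODONS)),
                    n = numeric(length(SENSE_CODONS)),
                    row.names = SENSE_CODONS)
  for (codon in SENSE_CODONS) {
    aa <- GENETIC_CODE_STD[[codon]]
    ch <- strsplit(codon, "", fixed = TRUE)[[1L]]
    s <- 0
    for (pos in 1:3) {
      alt_syn <- 0L; alt_ok <- 0L
      for (b in setdiff(bases, ch[pos])) {
        mut <- ch; mut[pos] <- b
        mut_codon <- paste(mut, collapse = "")
        maa <- GENETIC_CODE_STD[[mut_codon]]
        if (maa == "*") next
        alt_ok <- alt_ok + 1L
        if (maa == aa) alt_syn <- alt_syn + 1L
      }
      if (alt_ok > 0L) s <- s + alt_syn / alt_ok
    }
    tab[codon, ] <- c(s, 3 - s)
  }
  .phygst_cache$ng_sites <- tab
  tab
}

# pathway-averaged (Sd, Nd) for one codon pair; pathways through stops are
# excluded (all-blocked pairs fall back to averaging over all pathways)
.ng_pair_diffs <- function(c1, c2) {
  key <- paste0(c1, c2)
  cache <- .phygst_cache$ng_pairs
  if (is.null(cache)) cache <- .phygst_cache$ng_pairs <- new.env(parent = emptyenv())
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  a <- strsplit(c1, "", fixed = TRUE)[[1L]]
  b <- strsplit(c2, "", fixed = TRUE)[[1L]]
  pos <- which(a != b)
  res <- if (length(pos) == 0L) c(sd = 0, nd = 0) else {
    perms <- if (length(pos) == 1L) list(pos) else {
      if (length(pos) == 2L) list(pos, rev(pos)) else {
        do.call(c, lapply(1:3, function(i) {
          rest <- pos[-i]
          list(c(pos[i], rest), c(pos[i], rev(rest)))
        }))
      }
    }
    path_sd <- numeric(0); path_nd <- numeric(0)
    all_sd <- numeric(0); all_nd <- numeric(0)
    for (ord in perms) {
      cur <- a; sdv <- 0; ndv <- 0; blocked <- FALSE
      for (p in ord) {
        nxt <- cur; nxt[p] <- b[p]
        cc <- paste(cur, collapse = ""); nc <- paste(nxt, collapse = "")
        if (GENETIC_CODE_STD[[nc]] == "*" && nc != c2) blocked <- TRUE
        if (GENETIC_CODE_STD[[cc]] == GENETIC_CODE_STD[[nc]]) sdv <- sdv + 1
        else ndv <- ndv + 1
        cur <- nxt
      }
      all_sd <- c(all_sd, sdv); all_nd <- c(all_nd, ndv)
      if (!blocked) { path_sd <- c(path_sd, sdv); path_nd <- c(path_nd, ndv) }
    }
    if (length(path_sd)) c(sd = mean(path_sd), nd = mean(path_nd))
    else c(sd = mean(all_sd), nd = mean(all_nd))
  }
  cache[[key]] <- res
  res
}

#' Jukes-Cantor correction of a proportion of differences
#'
#' @param p proportion in `[0, 1]`
#' @return corrected distance; for `p >= 3/4` the saturation floor
#'   (`2.0`) with attributes `saturated = TRUE` and `bound = ">2.0"`
#' @export
jc_correct <- function(p) {
  if (is.na(p) || p < 0 || p > 1) stop("p must be in [0, 1]")
  if (p >= 0.75) {
    return(structure(KS_SATURATION_FLOOR, saturated = TRUE,
                     bound = sprintf(">%.1f", KS_SATURATION_FLOOR)))
  }
  structure(-0.75 * log(1 - 4 * p / 3), saturated = FALSE)
}

#' Pairwise Nei-Gojobori Ka/Ks analysis of two aligned coding sequences
#'
#' @param cds_a,cds_b in-frame aligned coding sequences of equal length
#'   (multiple of 3); codons containing gaps or Ns in either sequence are
#'   skipped
#' @return list of class `"codon_pairwise"`: `S_sites`, `N_sites`, `Sd`,
#'   `Nd`, `ps`, `pn`, `Ks`, `Ka`, `ka_ks`, `saturated_s`, `saturated_n`,
#'   `codons_compared`
#' @export
ng_pairwise <- function(cds_a, cds_b) {
  if (is.list(cds_a) || is.data.frame(cds_a)) cds_a <- cds_a$residues[1L]
  if (is.list(cds_b) || is.data.frame(cds_b)) cds_b <- cds_b$residues[1L]
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) stop("sequences differ in length")
  if (nchar(cds_a) %% 3L != 0L) stop("length not a multiple of 3")
  L <- nchar(cds_a) %/% 3L
  starts <- seq.int(1L, by = 3L, length.out = L)
  ca <- substring(cds_a, starts, starts + 2L)
  cb <- substring(cds_b, starts, starts + 2L)
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb) &
    !(ca %in% STOP_CODONS) & !(cb %in% STOP_CODONS)
  ca <- ca[ok]; cb <- cb[ok]
  sites <- .ng_site_table()
  S <- sum((sites[ca, "s"] + sites[cb, "s"]) / 2)
  N <- sum((sites[ca, "n"] + sites[cb, "n"]) / 2)
  Sd <- 0; Nd <- 0
  for (k in seq_along(ca)) {
    if (ca[k] == cb[k]) next
    d <- .ng_pair_diffs(ca[k], cb[k])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  Ks <- jc_correct(min(ps, 1))
  Ka <- jc_correct(min(pn, 1))
  structure(list(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
                 ps = ps, pn = pn,
                 Ks = as.numeric(Ks), Ka = as.numeric(Ka),
                 ka_ks = if (as.numeric(Ks) > 0) as.numeric(Ka) / as.numeric(Ks)
                         else NA_real_,
                 saturated_s = isTRUE(attr(Ks, "saturated")),
                 saturated_n = isTRUE(attr(Ka, "saturated")),
                 codons_compared = length(ca)),
            class = "codon_pairwise")
}

#' Fisher's exact test for an excess of synonymous substitutions
#'
#' The 2x2 table contrasts observed differences with available sites:
#' `[[round(Sd), round(S_sites)], [round(Nd), round(N_sites)]]` (rounding
#' half-up). The one-tailed p-value is the hypergeometric probability of a
#' synonymous difference count at least as large as observed, i.e. the
#' directional test for purifying selection.
#'
#' @param Sd,S_sites,Nd,N_sites fractional counts from [ng_pairwise()] or
#'   a group average
#' @param tails `"one"` (default) or `"two"`
#' @return p-value
#' @export
fisher_selection_test <- function(Sd, S_sites, Nd, N_sites,
                                  tails = c("one", "two")) {
  tails <- match.arg(tails)
  stopifnot(Sd >= 0, Nd >= 0, S_sites >= Sd, N_sites >= Nd)
  rh <- function(x) floor(x + 0.5)          # round half-up
  a <- rh(Sd); b <- rh(S_sites); c_ <- rh(Nd); d <- rh(N_sites)
  if (a + c_ == 0) return(1)
  k <- a + c_                                # total differences drawn
  m <- a + b; n <- c_ + d
  if (tails == "one") {
    p <- 1 - phyper(a - 1, m, n, k)
  } else {
    probs <- dhyper(max(0, k - n):min(k, m), m, n, k)
    pobs <- dhyper(a, m, n, k)
    p <- sum(probs[probs <= pobs * (1 + 1e-7)])
  }
  min(p, 1)
}

#' Calibrate a synonymous molecular clock
#'
#' @param Ks_cal synonymous divergence accumulated since the calibration
#'   split (substitutions per synonymous site, both lineages summed)
#' @param T_cal age of the calibration split in MY
#' @param T_range optional `c(min, max)` age range for the calibration
#' @return list of class `"clock_calibration"`: `Ks_cal`, `T_cal`, `r`
#'   (substitutions/synonymous site/MY per lineage), optional `r_range`
#' @export
calibrate_rate <- function(Ks_cal, T_cal, T_range = NULL) {
  if (Ks_cal <= 0 || T_cal <= 0) stop("calibration inputs must be positive")
  r <- Ks_cal / (2 * T_cal)
  out <- list(Ks_cal = Ks_cal, T_cal = T_cal, r = r)
  if (!is.null(T_range)) {
    stopifnot(length(T_range) == 2L, all(T_range > 0))
    out$T_range <- sort(T_range)
    out$r_range <- sort(Ks_cal / (2 * out$T_range))
  }
  structure(out, class = "clock_calibration")
}

#' Date a divergence node from its synonymous divergence
#'
#' @param Ks_node pairwise Ks at the node (not saturated)
#' @param calibration a [calibrate_rate()] result
#' @return list: `T_mya` and, when the calibration has a range, `T_range`
#' @export
date_node <- function(Ks_node, calibration) {
  stopifnot(inherits(calibration, "clock_calibration"))
  if (isTRUE(attr(Ks_node, "saturated"))) {
    stop("saturated Ks: dating unreliable")
  }
  if (Ks_node < 0) stop("Ks must be >= 0")
  out <- list(T_mya = Ks_node / (2 * calibration$r))
  if (!is.null(calibration$r_range)) {
    out$T_range <- sort(Ks_node / (2 * calibration$r_range))
  }
  out
}

#' Homeolog/ortholog group comparison (diploid vs tetraploid categories)
#'
#' Enumerates the A-origin x D-origin sequence pairs of one category --
#' `"D-D"` (diploid vs diploid), `"D-T"` (each diploid vs opposite-genome
#' tetraploid contigs), `"T-T"` (tetraploid A-origin vs D-origin, within and
#' across species) -- runs [ng_pairwise()] on each pair and averages the
#' counts. The group Ka/Ks is mean(Ka)/mean(Ks); the Fisher p uses the
#' averaged counts.
#'
#' @param seqs named character vector of in-frame aligned sequences
#' @param meta data.frame with columns `id`, `ploidy` (`"diploid"` /
#'   `"tetraploid"`) and `genome_origin` (`"A"` / `"D"`)
#' @param category `"D-D"`, `"D-T"` or `"T-T"`
#' @param label region label carried into the result
#' @return list of class `"group_comparison"`
#' @export
group_comparison <- function(seqs, meta, category = c("D-D", "D-T", "T-T"),
                             label = "") {
  category <- match.arg(category)
  stopifnot(all(meta$id %in% names(seqs)))
  dipA <- meta$id[meta$ploidy == "diploid" & meta$genome_origin == "A"]
  dipD <- meta$id[meta$ploidy == "diploid" & meta$genome_origin == "D"]
  tetA <- meta$id[meta$ploidy == "tetraploid" & meta$genome_origin == "A"]
  tetD <- meta$id[meta$ploidy == "tetraploid" & meta$genome_origin == "D"]
  pairs <- switch(category,
    "D-D" = expand.grid(a = dipA, b = dipD, stringsAsFactors = FALSE),
    "D-T" = rbind(expand.grid(a = dipA, b = tetD, stringsAsFactors = FALSE),
                  expand.grid(a = tetA, b = dipD, stringsAsFactors = FALSE)),
    "T-T" = expand.grid(a = tetA, b = tetD, stringsAsFactors = FALSE))
  if (nrow(pairs) == 0L) stop("no sequence pairs for category ", category)
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    ng_pairwise(seqs[[pairs$a[k]]], seqs[[pairs$b[k]]])
  })
  mean_of <- function(f) mean(vapply(res, `[[`, numeric(1), f))
  Sd <- mean_of("Sd"); S <- mean_of("S_sites")
  Nd <- mean_of("Nd"); N <- mean_of("N_sites")
  Ks <- mean_of("Ks"); Ka <- mean_of("Ka")
  structure(list(label = label, category = category, n_pairs = nrow(pairs),
                 pairs = pairs,
                 S_dif = Sd, S_pos = S, Ks = Ks,
                 NS_dif = Nd, NS_pos = N, Ka = Ka,
                 ka_ks = if (Ks > 0) Ka / Ks else if (Ka == 0) 0 else Inf,
                 saturated = any(vapply(res, `[[`, logical(1), "saturated_s")),
                 fisher_p = fisher_selection_test(Sd, S, Nd, N)),
            class = "group_comparison")
}

#' Cross-node divergence summary (speciation vs duplication nodes)
#'
#' Takes a per-node divergence table (columns `node`, `s_dif`, `ks`,
#' `ns_dif`, `ka`, optionally `ka_ks` and `k2p`; `ks` may be a bound string
#' like `">2.0"`, used at its numeric floor). Node Ka/Ks ratios are taken
#' from the `ka_ks` column when supplied (bounds such as `"<0.061"` at
#' their numeric value), otherwise computed as `ka/ks`. Reports the mean
#' and population s.d. of Ka/Ks over `speciation_nodes` and the fold excess
#' of `duplication_node` relative to `reference_node`.
#'
#' @param node_table data.frame as above
#' @param speciation_nodes node names averaged for the baseline
#' @param duplication_node,reference_node nodes compared for the fold ratio
#'   (optional)
#' @return list of class `"node_summary"`
#' @export
summarize_nodes <- function(node_table, speciation_nodes,
                            duplication_node = NULL, reference_node = NULL) {
  stopifnot(all(speciation_nodes %in% node_table$node))
  num <- function(x) as.numeric(gsub("[<>]", "", as.character(x)))
  ks <- num(node_table$ks)
  kaks <- if (!is.null(node_table$ka_ks)) num(node_table$ka_ks)
          else node_table$ka / ks
  names(kaks) <- node_table$node
  base <- kaks[speciation_nodes]
  out <- list(table = node_table,
              kaks = kaks,
              mean_kaks = mean(base),
              sd_kaks = sqrt(mean((base - mean(base))^2)))
  if (!is.null(duplication_node) && !is.null(reference_node)) {
    out$fold <- kaks[[duplication_node]] / kaks[[reference_node]]
  }
  structure(out, class = "node_summary")
}
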