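# Degenerate primer design, fold-degeneracy and in-silico PCR.
#
# Primers are IUPAC strings that may contain 'I' (deoxyinosine). Inosine is
# treated as a universal-pairing analog: it matches any template base during
# annealing, but multiplies the synthesis degeneracy (4-fold by default,
# since the oligo pool view treats it as one of four bases at that position).

#' Construct a degenerate primer
#'
#' @param name primer name
#' @param residues IUPAC string (A/C/G/T/R/Y/S/W/K/M/B/D/H/V/N plus I)
#' @param orientation `"forward"` or `"reverse"`
#' @return list of class `"iupac_primer"`
#' @export
iupac_primer <- function(name, residues, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("empty primer sequence")
  ch <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% names(IUPAC_SETS))
  if (length(bad)) {
    stop("unknown primer code '", ch[bad[1L]], "' at position ", bad[1L])
  }
  structure(list(name = name, residues = residues, orientation = orientation),
            class = "iupac_primer")
}

.primer_residues <- function(primer) {
  if (inherits(primer, "iupac_primer")) primer$residues else toupper(primer)
}

#' Fold-degeneracy of a degenerate primer
#'
#' The number of distinct concrete oligonucleotides in the synthesis pool:
#' the product over positions of the size of each code's base set (R/Y/S/W/
#' K/M = 2, B/D/H/V = 3, N = 4, A/C/G/T = 1). Inosine counts as
#' `inosine_multiplicity`-fold (default 4).
#'
#' @param primer `iupac_primer` or IUPAC string
#' @param inosine_multiplicity multiplicity assigned to `I` positions
#' @return integer-valued numeric (can exceed `.Machine$integer.max` for very
#'   degenerate primers)
#' @export
fold_degeneracy <- function(primer, inosine_multiplicity = 4L) {
  residues <- .primer_residues(primer)
  ch <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% names(IUPAC_SETS))
  if (length(bad)) {
    stop("unknown primer code '", ch[bad[1L]], "' at position ", bad[1L])
  }
  mult <- vapply(ch, function(k) {
    if (k == "I") as.numeric(inosine_multiplicity) else length(IUPAC_SETS[[k]])
  }, numeric(1))
  prod(mult)
}

#' Reverse-translate a conserved peptide into a degenerate primer
#'
#' For each residue the codon set of the standard genetic code is collapsed
#' column-wise to the minimal IUPAC code. With `collapse = "inosine3rd"`,
#' fully degenerate (`N`) third codon positions are replaced by inosine.
#' A reverse-orientation primer is the reverse complement of the collapsed
#' string (inosine self-complements).
#'
#' @param peptide amino-acid string (20 standard residues)
#' @param collapse `"iupac"` or `"inosine3rd"`
#' @param orientation primer orientation; `"reverse"` emits the reverse
#'   complement
#' @param name primer name
#' @return `iupac_primer`
#' @export
reverse_translate <- function(peptide, collapse = c("iupac", "inosine3rd"),
                              orientation = c("forward", "reverse"),
                              name = peptide) {
  collapse <- match.arg(collapse)
  orientation <- match.arg(orientation)
  aa <- strsplit(toupper(peptide), "", fixed = TRUE)[[1L]]
  codes <- character(0)
  for (a in aa) {
    codons <- CODONS_BY_AA[[a]]
    if (is.null(codons) || a == "*") stop("no codon for residue '", a, "'")
    cmat <- matrix(unlist(strsplit(codons, "", fixed = TRUE)), ncol = 3L,
                   byrow = TRUE)
    col_codes <- vapply(1:3, function(j) iupac_code(cmat[, j]), character(1))
    if (collapse == "inosine3rd" && col_codes[3L] == "N") col_codes[3L] <- "I"
    codes <- c(codes, col_codes)
  }
  residues <- paste(codes, collapse = "")
  if (orientation == "reverse") residues <- revcomp(residues)
  iupac_primer(name, residues, orientation)
}

#' Count annealing mismatches of a primer against a template window
#'
#' A position matches when the template base is in the primer code's base
#' set; inosine matches any base. Each mismatch is classified as transition
#' or transversion against the code's base set: transition if any set member
#' has the template base as its transition partner (A/G, C/T), transversion
#' otherwise; positions where the set contains both transition and
#' transversion partners are flagged ambiguous.
#'
#' @param primer `iupac_primer` or IUPAC string
#' @param template_window template residues on the primer's annealing
#'   strand, same length as the primer
#' @param template_id,start,strand optional bookkeeping carried into the
#'   report
#' @return list of class `"primer_binding_report"` with fields
#'   `mismatches` and a `mismatch_positions` data.frame (0-based `index`,
#'   `code`, `base`, `class`, `ambiguous`)
#' @export
count_mismatches <- function(primer, template_window, template_id = NA_character_,
                             start = NA_integer_, strand = "plus") {
  residues <- .primer_residues(primer)
  template_window <- toupper(template_window)
  if (nchar(residues) != nchar(template_window)) {
    stop("window length (", nchar(template_window),
         ") != primer length (", nchar(residues), ")")
  }
  pc <- strsplit(residues, "", fixed = TRUE)[[1L]]
  tc <- strsplit(template_window, "", fixed = TRUE)[[1L]]
  idx <- integer(0); cls <- character(0); amb <- logical(0)
  for (i in seq_along(pc)) {
    set <- IUPAC_SETS[[pc[i]]]
    if (is.null(set)) stop("unknown primer code '", pc[i], "' at position ", i)
    if (tc[i] %in% set) next                      # match (I matches any base)
    is_ts <- any(TRANSITION_OF[set] == tc[i])
    is_tv <- any(set != tc[i] & TRANSITION_OF[set] != tc[i])
    idx <- c(idx, i - 1L)
    cls <- c(cls, if (is_ts) "transition" else "transversion")
    amb <- c(amb, is_ts && is_tv)
  }
  structure(list(
    template_id = template_id,
    start = start, end = if (is.na(start)) NA_integer_ else start + length(pc),
    strand = strand,
    mismatches = length(idx),
    mismatch_positions = data.frame(index = idx, code = pc[idx + 1L],
                                    base = tc[idx + 1L], class = cls,
                                    ambiguous = amb, stringsAsFactors = FALSE)
  ), class = "primer_binding_report")
}

#' In-silico PCR
#'
#' Enumerates all forward-primer sites on the plus strand and all reverse
#' sites on the minus strand with at most `max_mismatch` mismatches each,
#' and reports every site pair whose product length (primers included) lies
#' in `product_range`. Coordinates are 0-based half-open on the template.
#'
#' @param template `gst_seqs` row (or list with `id` and `residues`)
#' @param fwd,rev forward / reverse `iupac_primer`
#' @param max_mismatch maximum mismatches tolerated per primer
#' @param product_range numeric `c(min, max)` product length
#' @return list of amplicons, each a list with `template_id`, `start`,
#'   `end`, `product`, `fwd_report`, `rev_report`; empty list when no site
#'   pair qualifies
#' @export
in_silico_pcr <- function(template, fwd, rev, max_mismatch = 0L,
                          product_range = c(100, 5000)) {
  stopifnot(max_mismatch >= 0L, product_range[1L] <= product_range[2L])
  lst <- is.list(template) || is.data.frame(template)
  tid <- if (lst && !is.null(template$id)) template$id[1L] else NA_character_
  seq <- toupper(if (lst) template$residues[1L] else as.character(template))
  L <- nchar(seq)
  fres <- .primer_residues(fwd); rres <- .primer_residues(rev)
  fl <- nchar(fres); rl <- nchar(rres)

  scan_sites <- function(primer_res, minus) {
    pl <- nchar(primer_res)
    if (pl > L) return(list())
    hits <- list()
    for (s in 0:(L - pl)) {
      win <- substr(seq, s + 1L, s + pl)
      win_anneal <- if (minus) revcomp(win) else win
      rep <- count_mismatches(primer_res, win_anneal, template_id = tid,
                              start = s, strand = if (minus) "minus" else "plus")
      if (rep$mismatches <= max_mismatch) hits[[length(hits) + 1L]] <- rep
    }
    hits
  }

  fhits <- scan_sites(fres, minus = FALSE)
  rhits <- scan_sites(rres, minus = TRUE)
  out <- list()
  for (fh in fhits) {
    for (rh in rhits) {
      start <- fh$start; end <- rh$start + rl
      if (fh$start + fl > rh$start) next          # fwd site must precede rev
      plen <- end - start
      if (plen < product_range[1L] || plen > product_range[2L]) next
      out[[length(out) + 1L]] <- list(
        template_id = tid, start = start, end = end,
        product = substr(seq, start + 1L, end),
        fwd_report = fh, rev_report = rh)
    }
  }
  if (length(out)) out <- out[order(vapply(out, `[[`, numeric(1), "start"))]
  out
}
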