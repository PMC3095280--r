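# Nucleotide alphabets and the standard genetic code.
#
# IUPAC degeneracy codes plus 'I' (2'-deoxyinosine), which is not an IUPAC
# code but is common in degenerate primers as a universal-pairing analog.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  I = c("A", "C", "G", "T")
)

# minimal IUPAC code for each base set, keyed by sorted concatenation
.iupac_code_of <- local({
  codes <- setdiff(names(IUPAC_SETS), "I")
  key <- vapply(codes, function(k) paste(sort(IUPAC_SETS[[k]]), collapse = ""),
                character(1))
  setNames(codes, key)
})

#' Minimal IUPAC code covering a set of bases
#' @param bases character vector over A/C/G/T
#' @return single IUPAC character
#' @keywords internal
iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- .iupac_code_of[[key]]
  if (is.null(code)) stop("no IUPAC code for base set: ", key)
  code
}

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N",
  I = "I", `-` = "-"
)

#' Reverse complement of a nucleotide string (IUPAC + inosine aware)
#' @param x character scalar
#' @return character scalar
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  ch <- rev(strsplit(x, "", fixed = TRUE)[[1L]])
  out <- IUPAC_COMPLEMENT[ch]
  if (anyNA(out)) {
    stop("cannot complement character(s): ",
         paste(unique(ch[is.na(out)]), collapse = ", "))
  }
  paste(out, collapse = "")
}

# standard genetic code, stops as '*'
GENETIC_CODE_STD <- local({
  b <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1L]]
  first_two <- as.vector(t(outer(b, b, paste0)))       # TT, TC, TA, TG, CT, ...
  codons <- as.vector(vapply(first_two, function(p) paste0(p, b), character(4)))
  setNames(aa, codons)
})

STOP_CODONS <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD == "*"]
SENSE_CODONS <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]

# codons for each amino acid (standard code)
CODONS_BY_AA <- split(names(GENETIC_CODE_STD), GENETIC_CODE_STD)

# transition partner of each base (A<->G, C<->T)
TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")

#' Translate amino-acid for one codon ('X' if any N, '*' for stop)
#' @keywords internal
codon_aa <- function(codon) {
  if (grepl("N", codon, fixed = TRUE)) return("X")
  aa <- GENETIC_CODE_STD[[codon]]
  if (is.null(aa)) stop("unknown codon: ", codon)
  aa
}
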