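# Core sequence containers and standard-format IO.
#
# Sequences are kept in a plain data.frame (class "gst_seqs") with columns
# id / taxon / genome / residues; trees are ape "phylo" objects; alignments
# are character matrices of single residues (class "gst_msa").

GENOME_LEVELS <- c("A", "D", "AD", "unknown")

#' Construct a set of sequences
#'
#' @param id character vector of unique short identifiers
#' @param taxon taxon label per sequence
#' @param genome genome-of-origin label, one of `"A"`, `"D"`, `"AD"`,
#'   `"unknown"` (diploid A- and D-genome cottons and AD allotetraploids)
#' @param residues nucleotide strings over A/C/G/T/N; lowercase and `U` are
#'   normalized on construction
#' @return data.frame of class `"gst_seqs"`
#' @export
gst_seqs <- function(id, residues, taxon = NA_character_,
                     genome = "unknown") {
  n <- length(id)
  taxon <- rep_len(as.character(taxon), n)
  genome <- rep_len(as.character(genome), n)
  residues <- toupper(as.character(residues))
  residues <- gsub("U", "T", residues, fixed = TRUE)
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(residues))) stop("empty residues for id: ",
                                   paste(id[!nzchar(residues)], collapse = ", "))
  bad <- grepl("[^ACGTN]", residues)
  if (any(bad)) stop("non-ACGTN residues in: ", paste(id[bad], collapse = ", "))
  if (any(!genome %in% GENOME_LEVELS)) {
    stop("genome must be one of ", paste(GENOME_LEVELS, collapse = "/"))
  }
  out <- data.frame(id = as.character(id), taxon = taxon, genome = genome,
                    residues = residues, stringsAsFactors = FALSE)
  class(out) <- c("gst_seqs", "data.frame")
  out
}

#' Read sequences from a FASTA file
#'
#' Headers follow the convention `id|taxon|genome`; fields beyond the id are
#' optional (`genome` defaults to `"unknown"`). Records are uppercased and
#' `U` converted to `T` on read.
#'
#' @param path FASTA file
#' @return `gst_seqs`
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) {
    return(gst_seqs(character(0), character(0)))
  }
  hdr <- sub("\\s.*$", "", names(set))
  parts <- strsplit(hdr, "|", fixed = TRUE)
  id <- vapply(parts, `[`, character(1), 1L)
  taxon <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_,
                  character(1))
  genome <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "unknown",
                   character(1))
  gst_seqs(id, as.character(set), taxon, genome)
}

#' Write sequences to FASTA (wrapped at 70 columns)
#'
#' @param seqs `gst_seqs`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  hdr <- ifelse(is.na(seqs$taxon) & seqs$genome == "unknown", seqs$id,
                paste(seqs$id, ifelse(is.na(seqs$taxon), "", seqs$taxon),
                      seqs$genome, sep = "|"))
  set <- Biostrings::BStringSet(setNames(seqs$residues, hdr))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Translate a nucleotide sequence
#'
#' Standard genetic code; stops are rendered `*`, codons containing `N` as
#' `X`; a trailing partial codon is dropped.
#'
#' @param residues nucleotide string
#' @param frame 0, 1 or 2 (offset in nucleotides)
#' @return peptide string
#' @export
translate_cds <- function(residues, frame = 0L) {
  stopifnot(frame %in% 0:2)
  residues <- toupper(residues)
  if (nchar(residues) - frame < 3L) stop("sequence shorter than one codon in frame")
  s <- substring(residues, frame + 1L)
  ncod <- nchar(s) %/% 3L
  starts <- seq.int(1L, by = 3L, length.out = ncod)
  codons <- substring(s, starts, starts + 2L)
  paste(vapply(codons, codon_aa, character(1), USE.NAMES = FALSE), collapse = "")
}

## ---- multiple alignment container ------------------------------------------

#' Construct a multiple alignment from equal-length gapped strings
#'
#' @param ids row identifiers
#' @param gapped character vector of gapped sequences (`-` for gaps)
#' @return character matrix of class `"gst_msa"` (rows = sequences)
#' @export
gst_msa <- function(ids, gapped) {
  stopifnot(length(ids) == length(gapped))
  len <- unique(nchar(gapped))
  if (length(len) != 1L) stop("alignment rows differ in length")
  m <- matrix(unlist(strsplit(toupper(gapped), "", fixed = TRUE), use.names = FALSE),
              nrow = length(gapped), byrow = TRUE,
              dimnames = list(as.character(ids), NULL))
  class(m) <- c("gst_msa", class(m))
  m
}

#' Gapped row strings of an alignment
#' @param msa `gst_msa`
#' @return named character vector
#' @export
msa_strings <- function(msa) {
  apply(unclass(msa), 1L, paste, collapse = "")
}

#' Ungapped source sequence of one alignment row
#' @keywords internal
msa_ungap <- function(msa, row) {
  x <- unclass(msa)[row, ]
  paste(x[x != "-"], collapse = "")
}

## ---- trees (ape phylo) and Newick IO ---------------------------------------

#' Read a Newick tree
#'
#' Internal node labels are interpreted as bootstrap support percentages.
#'
#' @param text Newick string
#' @return `ape::phylo`
#' @export
read_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: unbalanced or empty input")
  tr
}

#' Write a tree as Newick
#'
#' Branch lengths are printed with six significant decimals; internal node
#' labels (bootstrap supports) are retained.
#'
#' @param tree `ape::phylo`
#' @return Newick string
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree, digits = 6)
}

#' Canonical bipartition set of an unrooted tree
#'
#' Each internal edge is encoded as the lexicographically smaller of the two
#' leaf-label sets it separates, as a single `/`-joined string. Trivial
#' (leaf) bipartitions are omitted.
#'
#' @param tree `ape::phylo`
#' @return character vector (sorted)
#' @export
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  parts <- ape::prop.part(tree)
  out <- character(0)
  for (p in parts) {
    side <- sort(tips[p])
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    other <- sort(setdiff(tips, side))
    a <- paste(side, collapse = "/")
    b <- paste(other, collapse = "/")
    out <- c(out, if (a < b) a else b)
  }
  sort(unique(out))
}
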