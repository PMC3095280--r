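# Published reference values bundled as plain-text tables: the degenerate
# primer panel, the per-node and per-homeolog divergence estimates from the
# cotton phytochrome GST survey (sequence data at GenBank
# HM143735-HM143763), and the accession manifest for the optional,
# network-dependent integration check.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "phygst")
  if (!nzchar(path)) stop("missing bundled file: ", file)
  path
}

#' Published degenerate primer panel
#'
#' The hinge-region and subfamily-specific primers of the cotton
#' phytochrome GST survey, with their published fold-degeneracies and the
#' value recomputed under the consistent product rule (inosine 4-fold).
#' Three rows disagree with their published degeneracy under any consistent
#' rule; `consistent` flags the rows where the two match.
#'
#' @return data.frame: `name`, `sequence`, `orientation`,
#'   `published_degeneracy`, `computed_degeneracy`, `consistent`
#' @export
gst_primers <- function() {
  tab <- read.delim(.extdata("primers_cotton_phytochrome.tsv"),
                    stringsAsFactors = FALSE)
  tab$computed_degeneracy <- vapply(tab$sequence, fold_degeneracy, numeric(1))
  # a published "0" marks a nondegenerate primer (single oligo, 1-fold)
  tab$consistent <- tab$computed_degeneracy == tab$published_degeneracy |
    (tab$published_degeneracy == 0 & tab$computed_degeneracy == 1)
  tab
}

#' Published per-node divergence estimates (deep phytochrome nodes)
#'
#' Kimura two-parameter distance, synonymous and nonsynonymous differences
#' and Jukes-Cantor-corrected rates for the deep hinge-region divergence
#' nodes: speciation nodes 1A/1B/1C/1E (one per subfamily) and the PHYA
#' duplication node 3. Saturated values are bound strings (`">2.0"`).
#'
#' @return data.frame with columns `node`, `k2p`, `s_dif`, `ks`,
#'   `ns_dif`, `ka`, `ka_ks`
#' @export
phy_node_divergence <- function() {
  read.delim(.extdata("node_divergence_cotton_phytochrome.tsv"),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Published homeolog divergence table (A- vs D-genome comparisons)
#'
#' Mean synonymous/nonsynonymous differences, sites, rates and Fisher
#' p-values for diploid-diploid (D-D), diploid-tetraploid (D-T) and
#' tetraploid-tetraploid (T-T) comparisons per sequence region.
#'
#' @return data.frame
#' @export
phy_homeolog_divergence <- function() {
  read.delim(.extdata("homeolog_divergence_cotton_phytochrome.tsv"),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' GenBank accessions of the cotton phytochrome GSTs
#'
#' The 29 contig sequences (HM143735-HM143763) underlying the published
#' alignment statistics. Downloading them enables the optional integration
#' check in `scripts/integration_genbank.R`; the package itself never
#' requires network access.
#'
#' @return character vector of accession ids
#' @export
genbank_accessions <- function() {
  readLines(.extdata("genbank_accessions_cotton_phytochrome.txt"))
}
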