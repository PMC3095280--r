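# End-to-end orchestration: simulate or ingest clone FASTAs, assemble
# contigs, screen chimeras, align consensus sequences across taxa, build
# NJ trees with bootstrap, label clades from diploid anchors, run the
# Ka/Ks group comparisons and clock dating, and emit report tables.

#' Default pipeline configuration
#'
#' @param mode `"simulate"` (cotton-like preset) or `"fasta"`
#' @param seed integer seed driving every stochastic stage
#' @param out_dir optional output directory for FASTA/Newick/TSV artifacts
#' @param fasta_sets (fasta mode) named list: subfamily -> character vector
#'   of clone FASTA paths
#' @param anchors named map taxon -> genome (`"A"`/`"D"`/`"AD"`); diploid
#'   (A/D) taxa anchor the clade labeling
#' @param min_support,min_shared_sites assembly thresholds
#' @param chimera_n_perm,chimera_alpha chimera-screen parameters
#' @param distance_model `"p"`, `"JC"` or `"K2P"`
#' @param bootstrap bootstrap replicates for tree supports (0 disables)
#' @param calibration list `(Ks, T, range)` for the synonymous clock;
#'   defaults to the deep eudicot calibration Ks 1.82 at 85 (68-96) MY
#' @return config list of class `"pipeline_config"`
#' @export
pipeline_config <- function(mode = c("simulate", "fasta"), seed = 1L,
                            out_dir = NULL, fasta_sets = NULL,
                            anchors = c(Gher = "A", Grai = "D",
                                        Ghir = "AD", Gbar = "AD"),
                            min_support = 2L, min_shared_sites = 2L,
                            chimera_n_perm = 999L, chimera_alpha = 0.05,
                            distance_model = "p", bootstrap = 500L,
                            calibration = list(Ks = 1.82, T = 85,
                                               range = c(68, 96))) {
  mode <- match.arg(mode)
  if (mode == "fasta") {
    if (is.null(fasta_sets)) stop("fasta mode needs fasta_sets")
    missing <- unlist(fasta_sets)[!file.exists(unlist(fasta_sets))]
    if (length(missing)) stop("input file(s) not found: ",
                              paste(missing, collapse = ", "))
  }
  structure(list(mode = mode, seed = as.integer(seed), out_dir = out_dir,
                 fasta_sets = fasta_sets, anchors = anchors,
                 min_support = min_support, min_shared_sites = min_shared_sites,
                 chimera_n_perm = chimera_n_perm, chimera_alpha = chimera_alpha,
                 distance_model = distance_model, bootstrap = bootstrap,
                 calibration = calibration),
            class = "pipeline_config")
}

# identity alignment for equal-length clone sets, star MSA otherwise
.align_clones <- function(seqs) {
  if (length(unique(nchar(seqs$residues))) == 1L) {
    gst_msa(seqs$id, seqs$residues)
  } else {
    star_msa(seqs)
  }
}

# assemble one taxon's clone set, screening and removing chimeric clones.
# The screen is run twice: a first pass removes recombinant clones (and
# with them any co-breakpoint chimera clusters), and every clone is then
# re-screened against the cleaned contigs, whose consensuses are reliable
# recombination parents. Contigs supported by a single clone are not
# reported as loci; their members are logged as unassigned.
.assemble_taxon <- function(clones, cfg, seed) {
  tx <- clones$taxon[1L]
  msa <- .align_clones(clones)
  asm <- function(cl) assemble_contigs(.align_clones(cl), cfg$min_support,
                                       cfg$min_shared_sites, taxon = tx)
  contigs <- assemble_contigs(msa, cfg$min_support, cfg$min_shared_sites,
                              taxon = tx)
  chim <- NULL
  equal_len <- length(unique(nchar(clones$residues))) == 1L
  if (length(contigs) >= 2L) {
    chim <- detect_chimeras(msa, contigs, n_perm = cfg$chimera_n_perm,
                            alpha = cfg$chimera_alpha, seed = seed)
    if (nrow(chim) && equal_len) {
      clean <- clones[!clones$id %in% chim$clone_id, , drop = FALSE]
      if (nrow(clean) >= cfg$min_support) {
        ctg_clean <- asm(clean)
        if (length(ctg_clean) >= 2L) {
          chim <- detect_chimeras(msa, ctg_clean,
                                  n_perm = cfg$chimera_n_perm,
                                  alpha = cfg$chimera_alpha, seed = seed + 1L)
        }
      }
    }
    if (nrow(chim)) {
      clones <- clones[!clones$id %in% chim$clone_id, , drop = FALSE]
      msa <- .align_clones(clones)
      contigs <- asm(clones)
    }
  }
  supported <- vapply(contigs, function(ct) length(ct$members) >= 2L,
                      logical(1))
  unassigned <- unlist(lapply(contigs[!supported], `[[`, "members"))
  list(contigs = contigs[supported], chimeras = chim, msa = msa,
       unassigned = unassigned)
}

# detect a duplication-type bipartition: every taxon represented on both
# sides of an internal edge; returns the most balanced such split or NULL
.paralog_split <- function(tree, taxon_of) {
  tips <- tree$tip.label
  taxa <- unique(taxon_of[tips])
  below <- .tips_below(tree)
  ntip <- length(tips)
  best <- NULL
  for (k in seq_len(tree$Nnode)) {
    side <- below[[ntip + k]]
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    other <- setdiff(tips, side)
    if (all(taxa %in% taxon_of[side]) && all(taxa %in% taxon_of[other])) {
      bal <- abs(length(side) - length(other))
      if (is.null(best) || bal < best$bal) {
        best <- list(side = side, other = other, bal = bal)
      }
    }
  }
  best
}

.ploidy_of <- function(genome) ifelse(genome == "AD", "tetraploid", "diploid")

# per-subfamily cross-taxon analysis: alignment, tree, clades, comparisons
.analyse_subfamily <- function(subfamily, contigs_all, cfg, calib, seed) {
  ids <- vapply(contigs_all, `[[`, character(1), "id")
  taxa <- vapply(contigs_all, `[[`, character(1), "taxon")
  res <- list(subfamily = subfamily, contig_ids = ids, taxa = taxa)
  if (length(ids) < 3L) {
    res$error <- "fewer than 3 contigs; no tree built"
    return(res)
  }
  cons <- gst_seqs(ids, vapply(contigs_all, `[[`, character(1), "consensus"),
                   taxa, cfg$anchors[taxa])
  msa <- star_msa(cons)
  res$alignment_stats <- alignment_stats(msa)
  tree <- if (cfg$bootstrap > 0L) {
    bootstrap_support(msa, cfg$distance_model, cfg$bootstrap, seed = seed)
  } else {
    nj_tree(distance_matrix(msa, cfg$distance_model))
  }
  res$tree <- tree
  res$newick <- write_newick(tree)

  taxon_of <- setNames(taxa, ids)
  genome_of_taxon <- cfg$anchors
  diploid_ids <- ids[genome_of_taxon[taxa] %in% c("A", "D")]

  split <- .paralog_split(tree, taxon_of)
  groups <- if (!is.null(split)) {
    # order paralog groups by the lexicographically first diploid member
    g <- list(split$side, split$other)
    firsts <- vapply(g, function(s) {
      d <- sort(intersect(s, diploid_ids))
      if (length(d)) d[1L] else sort(s)[1L]
    }, character(1))
    g <- g[order(firsts)]
    setNames(g, paste0(subfamily, seq_along(g)))
  } else {
    setNames(list(ids), subfamily)
  }

  clades <- character(0)
  for (gname in names(groups)) {
    gids <- groups[[gname]]
    ganchors <- intersect(gids, diploid_ids)
    if (!length(ganchors)) {
      clades[gids] <- "unresolved"
      next
    }
    anc <- setNames(genome_of_taxon[taxon_of[ganchors]], ganchors)
    clades[ganchors] <- paste(gname, anc, sep = ".")
    non_anchor <- setdiff(gids, ganchors)
    if (length(non_anchor)) {
      if (length(gids) >= 3L) {
        sub_msa <- msa[gids, , drop = FALSE]
        class(sub_msa) <- c("gst_msa", "matrix", "array")
        sub_tree <- nj_tree(distance_matrix(sub_msa, cfg$distance_model))
        asg <- assign_clades(sub_tree, anc, gname)
        clades[names(asg$labels)] <- asg$labels
      } else {
        # two contigs: the non-anchor inherits the anchor's clade
        clades[non_anchor] <- paste(gname, anc[1L], sep = ".")
      }
    }
  }
  res$clades <- clades

  # group comparisons per paralog group (A- vs D-origin homeologs)
  aligned <- msa_strings(msa)
  L3 <- (nchar(aligned[1L]) %/% 3L) * 3L
  aligned <- substr(aligned, 1L, L3)
  comparisons <- list()
  for (gname in names(groups)) {
    gids <- groups[[gname]]
    meta <- data.frame(
      id = gids,
      ploidy = .ploidy_of(genome_of_taxon[taxon_of[gids]]),
      genome_origin = sub("^.*\\.", "", clades[gids]),
      stringsAsFactors = FALSE)
    meta <- meta[meta$genome_origin %in% c("A", "D"), , drop = FALSE]
    for (cat in c("D-D", "D-T", "T-T")) {
      cmp <- tryCatch(group_comparison(aligned, meta, cat, label = gname),
                      error = function(e) NULL)
      if (!is.null(cmp)) comparisons[[paste(gname, cat)]] <- cmp
    }
  }
  res$comparisons <- comparisons

  # duplication dating when a paralog split exists
  if (length(groups) == 2L) {
    g1 <- groups[[1L]]; g2 <- groups[[2L]]
    ksv <- c()
    for (x in g1) for (y in g2) {
      ng <- ng_pairwise(aligned[[x]], aligned[[y]])
      if (!ng$saturated_s) ksv <- c(ksv, ng$Ks)
    }
    if (length(ksv)) {
      res$duplication_ks <- mean(ksv)
      res$duplication_date <- date_node(mean(ksv), calib)
    }
  }
  res
}

#' Run the full GST pipeline
#'
#' Executes, per amplicon set: clone alignment, diagnostic-SNP contig
#' assembly, chimera screening and removal, cross-taxon consensus
#' alignment, NJ tree (with bootstrap supports), anchor-based clade
#' labeling, homeolog Ka/Ks group comparisons with Fisher tests, and
#' synonymous-clock dating of any detected paralog duplication. A failure
#' in one amplicon set is recorded in the report without aborting the
#' others.
#'
#' @param config a [pipeline_config()] (or YAML file path readable by
#'   `yaml::read_yaml` describing the same fields)
#' @return list of class `"run_report"`: per-set results, `inventory`
#'   data.frame (taxon x subfamily contig counts), `provenance`
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    cfg_list <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, cfg_list)
  }
  stopifnot(inherits(config, "pipeline_config"))
  calib <- calibrate_rate(config$calibration$Ks, config$calibration$T,
                          config$calibration$range)

  if (config$mode == "simulate") {
    preset <- preset_cotton_like(config$seed)
    clone_sets <- lapply(preset$sets, `[[`, "clones")
    truth <- lapply(preset$sets, `[[`, "truth")
  } else {
    clone_sets <- lapply(config$fasta_sets, function(files) {
      do.call(rbind, lapply(files, read_fasta))
    })
    truth <- NULL
  }

  report <- list(sets = list(), provenance = list(
    seed = config$seed, mode = config$mode,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("phygst"))))
  inventory <- list()
  stage_seed <- config$seed

  for (sf in names(clone_sets)) {
    set_res <- tryCatch({
      clones <- clone_sets[[sf]]
      contigs_all <- list(); chimera_calls <- list(); unassigned <- character(0)
      for (tx in unique(clones$taxon)) {
        stage_seed <- stage_seed + 2L
        asm <- .assemble_taxon(clones[clones$taxon == tx, , drop = FALSE],
                               config, seed = stage_seed)
        contigs_all <- c(contigs_all, asm$contigs)
        unassigned <- c(unassigned, asm$unassigned)
        if (!is.null(asm$chimeras) && nrow(asm$chimeras)) {
          chimera_calls[[tx]] <- asm$chimeras
        }
        inventory[[length(inventory) + 1L]] <-
          data.frame(taxon = tx, subfamily = sf,
                     n_contigs = length(asm$contigs),
                     stringsAsFactors = FALSE)
      }
      stage_seed <- stage_seed + 1L
      res <- .analyse_subfamily(sf, contigs_all, config, calib,
                                seed = stage_seed)
      res$contigs <- contigs_all
      res$unassigned_clones <- unassigned
      res$chimeras <- if (length(chimera_calls))
        do.call(rbind, chimera_calls) else NULL
      res
    }, error = function(e) list(subfamily = sf,
                                error = conditionMessage(e)))
    report$sets[[sf]] <- set_res
  }
  report$inventory <- do.call(rbind, inventory)
  if (!is.null(truth)) report$truth <- truth
  class(report) <- "run_report"

  if (!is.null(config$out_dir)) .write_report(report, config)
  report
}

.write_report <- function(report, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (sf in names(report$sets)) {
    res <- report$sets[[sf]]
    if (!is.null(res$error)) next
    cons <- gst_seqs(vapply(res$contigs, `[[`, character(1), "id"),
                     vapply(res$contigs, `[[`, character(1), "consensus"),
                     vapply(res$contigs, `[[`, character(1), "taxon"))
    write_fasta(cons, file.path(config$out_dir, paste0(sf, "_contigs.fasta")))
    writeLines(res$newick, file.path(config$out_dir, paste0(sf, "_tree.nwk")))
    if (!is.null(res$chimeras)) {
      write.table(res$chimeras,
                  file.path(config$out_dir, paste0(sf, "_chimeras.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  write.table(report$inventory, file.path(config$out_dir, "inventory.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tabs <- make_report_tables(report)
  write.table(tabs$divergence, file.path(config$out_dir, "divergence.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

.fmt_bound <- function(x, saturated, floor_val = KS_SATURATION_FLOOR) {
  if (saturated) sprintf(">%.1f", floor_val) else format(round(x, 3))
}

#' Divergence report tables (homeolog-comparison layout)
#'
#' One row per region x category with the columns
#' `S dif | S pos | Ks | NS dif | NS pos | Ka | Ka/Ks | P`; saturated
#' rates rendered as bounds (e.g. `">2.0"`) with numeric companions.
#'
#' @param report a [run_pipeline()] result
#' @return list with `divergence` (data.frame) and `inventory`
#' @export
make_report_tables <- function(report) {
  rows <- list()
  for (sf in names(report$sets)) {
    res <- report$sets[[sf]]
    if (!is.null(res$error) || is.null(res$comparisons)) next
    for (cmp in res$comparisons) {
      rows[[length(rows) + 1L]] <- data.frame(
        Sequence = cmp$label, Comparison = cmp$category,
        `S dif` = round(cmp$S_dif, 2), `S pos` = round(cmp$S_pos, 2),
        Ks = .fmt_bound(cmp$Ks, cmp$saturated),
        Ks_num = round(cmp$Ks, 4),
        `NS dif` = round(cmp$NS_dif, 2), `NS pos` = round(cmp$NS_pos, 2),
        Ka = round(cmp$Ka, 4),
        `Ka/Ks` = if (cmp$saturated) paste0("<", round(cmp$ka_ks, 3)) else
          format(round(cmp$ka_ks, 3)),
        KaKs_num = round(cmp$ka_ks, 4),
        P = round(cmp$fisher_p, 4),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  div <- if (length(rows)) do.call(rbind, rows) else
    data.frame(Sequence = character(0))
  list(divergence = div, inventory = report$inventory)
}
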