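# Codon-level gene-family simulator: segmental duplication, speciation,
# allopolyploid merger, purifying selection, then clone sampling with
# polymerase error, amplification bias and PCR-mediated recombinants.
#
# Selection is implemented as rate-calibrated thinning: mutations are
# proposed at the neutral synonymous rate (transitions weighted kappa) and
# nonsynonymous proposals are accepted with probability omega, so the
# realized synonymous divergence of a pair separated for time t converges
# to 2*t*rate_syn per synonymous site and the realized Ka/Ks to omega --
# closed forms the test suite uses as oracles. Proposals creating stop
# codons are rejected.

#' Build an event schedule for the gene-family simulator
#'
#' @param ancestor_codons length of the ancestral coding sequence in codons
#' @param events list of events, each a list with `time_mya` and `kind`
#'   (`"duplication"`: fields `lineage`, `locus`, `new_loci` (2 names);
#'   `"speciation"`: fields `lineage`, `into` (2 names);
#'   `"polyploid_merge"`: fields `parents` (2 names), `into`); times must be
#'   strictly decreasing toward the present
#' @param omega Ka/Ks target of purifying selection (acceptance probability
#'   of nonsynonymous proposals); scalar or named per-lineage vector with a
#'   `"default"` entry
#' @param kappa transition/transversion rate ratio of the proposal process
#' @param rate_syn synonymous substitutions per synonymous site per MY per
#'   lineage
#' @param genomes named map lineage -> genome label (`A`/`D`/`AD`/`unknown`)
#' @param root_lineage name of the starting lineage
#' @param ancestor optional ancestral sequence (otherwise random sense
#'   codons are drawn when the simulation runs)
#' @return list of class `"event_schedule"`
#' @export
event_schedule <- function(ancestor_codons, events, omega = 0.1, kappa = 2,
                           rate_syn = 0.011, genomes = c(anc = "unknown"),
                           root_lineage = "anc", ancestor = NULL) {
  stopifnot(ancestor_codons >= 1L, all(omega >= 0), kappa > 0, rate_syn > 0)
  times <- vapply(events, `[[`, numeric(1), "time_mya")
  if (length(times) > 1L && any(diff(times) >= 0)) {
    stop("event times must be strictly decreasing toward the present")
  }
  known <- root_lineage
  for (ev in events) {
    kind <- ev$kind
    if (kind == "duplication") {
      if (!ev$lineage %in% known) stop("duplication in unknown lineage ", ev$lineage)
      stopifnot(length(ev$new_loci) == 2L)
    } else if (kind == "speciation") {
      if (!ev$lineage %in% known) stop("speciation of unknown lineage ", ev$lineage)
      stopifnot(length(ev$into) == 2L)
      known <- c(setdiff(known, ev$lineage), ev$into)
    } else if (kind == "polyploid_merge") {
      miss <- setdiff(ev$parents, known)
      if (length(miss)) stop("merge references missing lineage: ",
                             paste(miss, collapse = ", "))
      known <- c(known, ev$into)
    } else stop("unknown event kind: ", kind)
  }
  structure(list(ancestor_codons = as.integer(ancestor_codons), events = events,
                 omega = omega, kappa = kappa, rate_syn = rate_syn,
                 genomes = genomes, root_lineage = root_lineage,
                 ancestor = ancestor),
            class = "event_schedule")
}

# per-codon single-base change table (excluding changes to stops), cached
.codon_changes <- function() {
  if (!is.null(.phygst_cache$codon_changes)) return(.phygst_cache$codon_changes)
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (codon in SENSE_CODONS) {
    ch <- strsplit(codon, "", fixed = TRUE)[[1L]]
    pos <- integer(0); alt <- character(0); syn <- logical(0); ts <- logical(0)
    for (p in 1:3) {
      for (b in setdiff(bases, ch[p])) {
        mut <- ch; mut[p] <- b
        maa <- GENETIC_CODE_STD[[paste(mut, collapse = "")]]
        if (maa == "*") next
        pos <- c(pos, p); alt <- c(alt, b)
        syn <- c(syn, maa == GENETIC_CODE_STD[[codon]])
        ts <- c(ts, TRANSITION_OF[[ch[p]]] == b)
      }
    }
    out[[codon]] <- data.frame(pos = pos, alt = alt, syn = syn, ts = ts,
                               stringsAsFactors = FALSE)
  }
  .phygst_cache$codon_changes <- out
  out
}

# kappa-weighted per-codon opportunity weights for one change class, cached
.codon_class_weights <- function(kappa, synonymous) {
  key <- paste0(if (synonymous) "syn" else "non", "_w_", format(kappa))
  hit <- .phygst_cache[[key]]
  if (!is.null(hit)) return(hit)
  chg <- .codon_changes()
  w <- vapply(SENSE_CODONS, function(codon) {
    tab <- chg[[codon]]
    tab <- tab[tab$syn == synonymous, , drop = FALSE]
    sum(ifelse(tab$ts, kappa, 1))
  }, numeric(1))
  .phygst_cache[[key]] <- w
  w
}

# evolve one coding sequence for dt MY; returns seq and realized increments
.evolve_branch <- function(codons, dt, omega, kappa, rate_syn) {
  if (dt <= 0) return(list(codons = codons, ks = 0, ka = 0, nsyn = 0L, nnon = 0L))
  sites <- .ng_site_table()
  S <- sum(sites[codons, "s"]); N <- sum(sites[codons, "n"])
  n_syn <- rpois(1L, rate_syn * dt * S)
  n_non <- rpois(1L, rate_syn * dt * omega * N)
  kinds <- sample(rep(c(TRUE, FALSE), c(n_syn, n_non)))   # TRUE = synonymous
  chg <- .codon_changes()
  for (is_syn in kinds) {
    w <- .codon_class_weights(kappa, is_syn)[codons]
    if (sum(w) == 0) next                                  # no opportunity
    ci <- sample.int(length(codons), 1L, prob = w)
    tab <- chg[[codons[ci]]]
    tab <- tab[tab$syn == is_syn, , drop = FALSE]
    ri <- sample.int(nrow(tab), 1L, prob = ifelse(tab$ts, kappa, 1))
    mut <- strsplit(codons[ci], "", fixed = TRUE)[[1L]]
    mut[tab$pos[ri]] <- tab$alt[ri]
    codons[ci] <- paste(mut, collapse = "")
  }
  list(codons = codons, ks = n_syn / S, ka = n_non / N,
       nsyn = n_syn, nnon = n_non)
}

.lineage_omega <- function(omega, lineage) {
  if (length(omega) == 1L && is.null(names(omega))) return(omega)
  if (lineage %in% names(omega)) return(omega[[lineage]])
  if ("default" %in% names(omega)) return(omega[["default"]])
  stop("no omega for lineage ", lineage)
}

#' Simulate a duplicated gene family along an event schedule
#'
#' @param schedule an [event_schedule()]
#' @param seed integer seed, or `NULL` to use the current RNG state
#' @return list with `loci` (`gst_seqs`, id = `<taxon>_<locus>`) and
#'   `truth` (class `"sim_truth"`): per-locus table, realized pairwise
#'   `ks_pair` / `ka_pair` matrices, and the ancestral sequence
#' @export
evolve_family <- function(schedule, seed = NULL) {
  stopifnot(inherits(schedule, "event_schedule"))
  if (!is.null(seed)) set.seed(seed)
  ncod <- schedule$ancestor_codons
  anc <- schedule$ancestor
  if (is.null(anc)) {
    anc_codons <- sample(SENSE_CODONS, ncod, replace = TRUE)
  } else {
    if (nchar(anc) %% 3L != 0L) stop("ancestor length not a multiple of 3")
    starts <- seq.int(1L, by = 3L, length.out = nchar(anc) %/% 3L)
    anc_codons <- substring(toupper(anc), starts, starts + 2L)
    if (any(anc_codons %in% STOP_CODONS)) stop("ancestor contains a stop codon")
    ncod <- length(anc_codons)
  }

  split_counter <- 0L
  new_instance <- function(codons, history) list(codons = codons,
                                                 ks = 0, ka = 0,
                                                 history = history)
  split_instance <- function(inst) {
    split_counter <<- split_counter + 1L
    entry <- list(id = split_counter, ks = inst$ks, ka = inst$ka)
    h <- c(inst$history, list(entry))
    list(list(codons = inst$codons, ks = inst$ks, ka = inst$ka, history = h),
         list(codons = inst$codons, ks = inst$ks, ka = inst$ka, history = h))
  }

  lineages <- setNames(list(setNames(list(new_instance(anc_codons, list())),
                                     "locus")), schedule$root_lineage)
  # seed locus name: single ancestral locus named after the first duplication
  # target if any, else "locus"
  times <- vapply(schedule$events, `[[`, numeric(1), "time_mya")
  now <- if (length(times)) times[1L] else 0

  advance <- function(lineages, dt) {
    for (ln in names(lineages)) {
      om <- .lineage_omega(schedule$omega, ln)
      for (lc in names(lineages[[ln]])) {
        inst <- lineages[[ln]][[lc]]
        ev <- .evolve_branch(inst$codons, dt, om, schedule$kappa,
                             schedule$rate_syn)
        inst$codons <- ev$codons
        inst$ks <- inst$ks + ev$ks
        inst$ka <- inst$ka + ev$ka
        lineages[[ln]][[lc]] <- inst
      }
    }
    lineages
  }

  for (ev in schedule$events) {
    lineages <- advance(lineages, now - ev$time_mya)
    now <- ev$time_mya
    if (ev$kind == "duplication") {
      ln <- ev$lineage
      lc <- if (!is.null(ev$locus) && ev$locus %in% names(lineages[[ln]]))
        ev$locus else names(lineages[[ln]])[1L]
      pair <- split_instance(lineages[[ln]][[lc]])
      lineages[[ln]][[lc]] <- NULL
      lineages[[ln]][[ev$new_loci[1L]]] <- pair[[1L]]
      lineages[[ln]][[ev$new_loci[2L]]] <- pair[[2L]]
    } else if (ev$kind == "speciation") {
      ln <- ev$lineage
      a <- list(); b <- list()
      for (lc in names(lineages[[ln]])) {
        pair <- split_instance(lineages[[ln]][[lc]])
        a[[lc]] <- pair[[1L]]; b[[lc]] <- pair[[2L]]
      }
      lineages[[ln]] <- NULL
      lineages[[ev$into[1L]]] <- a
      lineages[[ev$into[2L]]] <- b
    } else {                                   # polyploid_merge
      merged <- list()
      for (par in ev$parents) {
        g <- schedule$genomes[[par]]
        suffix <- if (is.null(g) || g == "unknown") par else g
        for (lc in names(lineages[[par]])) {
          pair <- split_instance(lineages[[par]][[lc]])
          lineages[[par]][[lc]] <- pair[[1L]]
          merged[[paste(lc, suffix, sep = ".")]] <- pair[[2L]]
        }
      }
      lineages[[ev$into]] <- merged
    }
  }
  lineages <- advance(lineages, now)

  # emit sequences + truth
  ids <- character(0); taxa <- character(0); genomes <- character(0)
  locus_lab <- character(0); insts <- list()
  for (ln in names(lineages)) {
    g <- schedule$genomes[[ln]]
    if (is.null(g)) g <- "unknown"
    for (lc in names(lineages[[ln]])) {
      lab <- if (g %in% c("A", "D") && !grepl("\\.", lc))
        paste(lc, g, sep = ".") else lc
      ids <- c(ids, paste(ln, lab, sep = "_"))
      taxa <- c(taxa, ln); genomes <- c(genomes, g); locus_lab <- c(locus_lab, lab)
      insts[[length(insts) + 1L]] <- lineages[[ln]][[lc]]
    }
  }
  seqs <- gst_seqs(ids, vapply(insts, function(i) paste(i$codons, collapse = ""),
                               character(1)), taxa, genomes)

  n <- length(ids)
  ks_pair <- matrix(0, n, n, dimnames = list(ids, ids))
  ka_pair <- matrix(0, n, n, dimnames = list(ids, ids))
  mrca_acc <- function(h1, h2, field) {
    ids1 <- vapply(h1, `[[`, integer(1), "id")
    ids2 <- vapply(h2, `[[`, integer(1), "id")
    common <- intersect(ids1, ids2)
    if (!length(common)) return(0)
    h1[[match(max(common), ids1)]][[field]]
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ks_pair[i, j] <- insts[[i]]$ks + insts[[j]]$ks -
        2 * mrca_acc(insts[[i]]$history, insts[[j]]$history, "ks")
      ka_pair[i, j] <- insts[[i]]$ka + insts[[j]]$ka -
        2 * mrca_acc(insts[[i]]$history, insts[[j]]$history, "ka")
    }
  }
  truth <- structure(list(
    loci = data.frame(id = ids, taxon = taxa, genome = genomes,
                      locus = locus_lab, stringsAsFactors = FALSE),
    ks_pair = ks_pair, ka_pair = ka_pair,
    ancestor = paste(anc_codons, collapse = ""),
    clones = NULL), class = "sim_truth")
  list(loci = seqs, truth = truth)
}

#' Clone-sampling configuration
#'
#' @param clones clones per taxon (scalar or named by taxon)
#' @param taq_error_rate substitutions per site introduced by the
#'   polymerase (default 2e-4)
#' @param amplification_bias named relative weights per locus label
#'   (default equal)
#' @param chimera_rate probability that a clone is a two-parent PCR
#'   recombinant (scalar or named by taxon)
#' @param seed integer seed or `NULL`
#' @return list of class `"clone_sampling_config"`
#' @export
clone_sampling_config <- function(clones = 10L, taq_error_rate = 2e-4,
                                  amplification_bias = NULL,
                                  chimera_rate = 0, seed = NULL) {
  stopifnot(all(clones >= 1L), taq_error_rate >= 0, taq_error_rate <= 1,
            all(chimera_rate >= 0), all(chimera_rate <= 1))
  if (!is.null(amplification_bias) && any(amplification_bias <= 0)) {
    stop("amplification weights must be > 0")
  }
  structure(list(clones = clones, taq_error_rate = taq_error_rate,
                 amplification_bias = amplification_bias,
                 chimera_rate = chimera_rate, seed = seed),
            class = "clone_sampling_config")
}

.per_taxon <- function(x, taxon, default) {
  if (is.null(x)) return(default)
  if (!is.null(names(x))) {
    if (taxon %in% names(x)) return(x[[taxon]])
    if ("default" %in% names(x)) return(x[["default"]])
    return(default)
  }
  x[[1L]]
}

#' Sample sequenced clones from simulated loci
#'
#' Each clone is drawn from a locus of its taxon with probability
#' proportional to the amplification weight; with probability
#' `chimera_rate` it is instead a two-parent recombinant with a uniform
#' breakpoint between two distinct loci. Polymerase errors are applied
#' after chimera formation, independently per site. A chimera requested in
#' a taxon with a single locus falls back to a normal clone (logged).
#'
#' @param loci `gst_seqs` of true locus sequences (one amplicon set)
#' @param truth `sim_truth` to update (may be `NULL`)
#' @param cfg a [clone_sampling_config()]
#' @return list with `clones` (`gst_seqs`) and `truth` (clone table in
#'   `truth$clones`, error positions in `truth$clone_errors`)
#' @export
sample_clones <- function(loci, truth = NULL, cfg = clone_sampling_config()) {
  stopifnot(nrow(loci) >= 1L, inherits(cfg, "clone_sampling_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  bases <- c("A", "C", "G", "T")
  rows <- list(); errs <- list()
  out_id <- character(0); out_res <- character(0); out_taxon <- character(0)
  out_genome <- character(0)
  for (taxon in unique(loci$taxon)) {
    lt <- loci[loci$taxon == taxon, , drop = FALSE]
    L <- unique(nchar(lt$residues))
    if (length(L) != 1L) stop("loci of one amplicon set must share length")
    w <- vapply(lt$id, function(id) .per_taxon(cfg$amplification_bias, id, 1),
                numeric(1))
    # allow weights keyed by locus label suffix of the id as well
    if (!is.null(cfg$amplification_bias)) {
      for (k in seq_len(nrow(lt))) {
        for (nm in names(cfg$amplification_bias)) {
          if (grepl(nm, lt$id[k], fixed = TRUE)) w[k] <- cfg$amplification_bias[[nm]]
        }
      }
    }
    ncl <- .per_taxon(cfg$clones, taxon, 10L)
    chim_p <- .per_taxon(cfg$chimera_rate, taxon, 0)
    for (i in seq_len(ncl)) {
      cid <- sprintf("%s_c%03d", taxon, i)
      want_chimera <- runif(1) < chim_p
      if (want_chimera && nrow(lt) >= 2L) {
        pr <- sample.int(nrow(lt), 2L, prob = w)
        bp <- sample.int(L - 1L, 1L)
        res <- paste0(substr(lt$residues[pr[1L]], 1L, bp),
                      substr(lt$residues[pr[2L]], bp + 1L, L))
        row <- data.frame(clone_id = cid, taxon = taxon,
                          source_locus = lt$id[pr[1L]],
                          parent2 = lt$id[pr[2L]], breakpoint = bp,
                          chimera = TRUE, chimera_requested = TRUE,
                          stringsAsFactors = FALSE)
      } else {
        src <- sample.int(nrow(lt), 1L, prob = w)
        res <- lt$residues[src]
        row <- data.frame(clone_id = cid, taxon = taxon,
                          source_locus = lt$id[src],
                          parent2 = NA_character_, breakpoint = NA_integer_,
                          chimera = FALSE, chimera_requested = want_chimera,
                          stringsAsFactors = FALSE)
      }
      n_err <- rbinom(1L, L, cfg$taq_error_rate)
      epos <- integer(0)
      if (n_err > 0L) {
        epos <- sort(sample.int(L, n_err))
        ch <- strsplit(res, "", fixed = TRUE)[[1L]]
        for (p in epos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
        res <- paste(ch, collapse = "")
      }
      row$n_errors <- n_err
      rows[[length(rows) + 1L]] <- row
      errs[[cid]] <- epos
      out_id <- c(out_id, cid); out_res <- c(out_res, res)
      out_taxon <- c(out_taxon, taxon)
      out_genome <- c(out_genome, lt$genome[1L])
    }
  }
  clone_tab <- do.call(rbind, rows)
  if (is.null(truth)) truth <- structure(list(), class = "sim_truth")
  truth$clones <- rbind(truth$clones, clone_tab)
  truth$clone_errors <- c(truth$clone_errors, errs)
  list(clones = gst_seqs(out_id, out_res, out_taxon, out_genome),
       truth = truth)
}

## ---- cotton-like preset ----------------------------------------------------

PRESET_TAXA <- data.frame(
  taxon = c("Gher", "Grai", "Ghir", "Gbar"),
  genome = c("A", "D", "AD", "AD"),
  ploidy = c("diploid", "diploid", "tetraploid", "tetraploid"),
  stringsAsFactors = FALSE)

# amplicon geometry and clone numbers emulating the study design
PRESET_SETS <- list(
  PHYA = list(codons = 120L, duplication = TRUE,  clones = c(Gher = 50L, Grai = 50L, Ghir = 50L, Gbar = 50L), chimera = 0),
  PHYB = list(codons = 687L, duplication = FALSE, clones = c(Gher = 20L, Grai = 20L, Ghir = 20L, Gbar = 20L), chimera = c(Gher = 0, Grai = 0, Ghir = 0.2, Gbar = 0.2)),
  PHYC = list(codons = 340L, duplication = FALSE, clones = c(Gher = 20L, Grai = 20L, Ghir = 20L, Gbar = 20L), chimera = 0),
  PHYE = list(codons = 110L, duplication = FALSE, clones = c(Gher = 10L, Grai = 10L, Ghir = 20L, Gbar = 20L), chimera = 0))

# event timeline (MY ago): segmental duplication of the PHYA ancestor,
# A/D-genome speciation, allopolyploid merger, tetraploid speciation
PRESET_TIMES <- c(duplication = 14, speciation_AD = 3.2, merge = 1.5,
                  split_tetraploids = 1.0)

.preset_schedule <- function(subfamily, spec) {
  genomes <- c(anc = "unknown", Gher = "A", Grai = "D", AD = "AD",
               Ghir = "AD", Gbar = "AD")
  ev <- list()
  if (spec$duplication) {
    ev <- c(ev, list(list(time_mya = PRESET_TIMES[["duplication"]],
                          kind = "duplication", lineage = "anc",
                          locus = subfamily,
                          new_loci = paste0(subfamily, 1:2))))
  }
  ev <- c(ev, list(
    list(time_mya = PRESET_TIMES[["speciation_AD"]], kind = "speciation",
         lineage = "anc", into = c("Gher", "Grai")),
    list(time_mya = PRESET_TIMES[["merge"]], kind = "polyploid_merge",
         parents = c("Gher", "Grai"), into = "AD"),
    list(time_mya = PRESET_TIMES[["split_tetraploids"]], kind = "speciation",
         lineage = "AD", into = c("Ghir", "Gbar"))))
  event_schedule(spec$codons, ev, omega = 0.1, kappa = 2, rate_syn = 0.011,
                 genomes = genomes, root_lineage = "anc")
}

#' Cotton-like simulation preset
#'
#' Two diploids (A- and D-genome) and two allotetraploids; a PHYA-like
#' subfamily duplicated before the A/D split plus single-copy PHYB/C/E-like
#' subfamilies; hinge-length amplicons (~330-360 bp) and one long ~2 kb
#' amplicon carrying PCR chimeras in the tetraploids. Deterministic for a
#' fixed seed. The true contig inventory is 2 PHYA + 1 each of B/C/E per
#' diploid and 4 PHYA + 2 each of B/C/E per tetraploid (ten genes).
#'
#' @param seed integer seed
#' @param out_dir optional directory: writes `<taxon>_<subfamily>.fasta`
#'   per taxon and subfamily plus `truth_loci.tsv` / `truth_clones.tsv`
#' @return list of class `"cotton_preset"`: per-subfamily `sets` (each
#'   with `loci`, `clones`, `truth`), `taxa`, and `expected_contigs`
#' @export
preset_cotton_like <- function(seed = 1L, out_dir = NULL) {
  set.seed(seed)
  sets <- list()
  for (subfamily in names(PRESET_SETS)) {
    spec <- PRESET_SETS[[subfamily]]
    # seed locus is named after the subfamily so emitted labels read
    # PHYB.A, PHYA1.D, ...
    sch <- .preset_schedule(subfamily, spec)
    fam <- evolve_family(sch, seed = NULL)
    # rename the undifferentiated root locus for single-copy subfamilies
    if (!spec$duplication) {
      fam$loci$id <- sub("_locus", paste0("_", subfamily), fam$loci$id)
      fam$truth$loci$id <- fam$loci$id
      fam$truth$loci$locus <- sub("^locus", subfamily, fam$truth$loci$locus)
      dimnames(fam$truth$ks_pair) <- list(fam$loci$id, fam$loci$id)
      dimnames(fam$truth$ka_pair) <- list(fam$loci$id, fam$loci$id)
    }
    cfg <- clone_sampling_config(clones = spec$clones, taq_error_rate = 2e-4,
                                 chimera_rate = spec$chimera, seed = NULL)
    smp <- sample_clones(fam$loci, fam$truth, cfg)
    sets[[subfamily]] <- list(loci = fam$loci, clones = smp$clones,
                              truth = smp$truth)
  }
  expected <- do.call(rbind, lapply(names(PRESET_SETS), function(sf) {
    data.frame(taxon = PRESET_TAXA$taxon, subfamily = sf,
               n_contigs = ifelse(PRESET_TAXA$ploidy == "diploid",
                                  ifelse(sf == "PHYA", 2L, 1L),
                                  ifelse(sf == "PHYA", 4L, 2L)),
               stringsAsFactors = FALSE)
  }))
  out <- structure(list(sets = sets, taxa = PRESET_TAXA,
                        expected_contigs = expected, seed = seed),
                   class = "cotton_preset")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (sf in names(sets)) {
      cl <- sets[[sf]]$clones
      for (tx in unique(cl$taxon)) {
        write_fasta(cl[cl$taxon == tx, , drop = FALSE],
                    file.path(out_dir, paste0(tx, "_", sf, ".fasta")))
      }
    }
    loci_tab <- do.call(rbind, lapply(names(sets), function(sf)
      cbind(subfamily = sf, sets[[sf]]$truth$loci)))
    clone_tab <- do.call(rbind, lapply(names(sets), function(sf)
      cbind(subfamily = sf, sets[[sf]]$truth$clones)))
    write.table(loci_tab, file.path(out_dir, "truth_loci.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(clone_tab, file.path(out_dir, "truth_clones.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}
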