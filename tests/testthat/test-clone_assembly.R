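# shared fixture: two diverged parents with clones, some chimeric
make_clone_set <- function(seed, n_clones = 40, chimera_rate = 0.3,
                           codons = 300, taq = 2e-4) {
  set.seed(seed)
  sch <- event_schedule(codons, list(
    list(time_mya = 3.2, kind = "speciation", lineage = "anc",
         into = c("A", "D"))),
    genomes = c(anc = "unknown", A = "A", D = "D"))
  fam <- evolve_family(sch, seed = NULL)
  loci <- fam$loci
  loci$taxon <- "T"
  cfg <- clone_sampling_config(clones = n_clones, taq_error_rate = taq,
                               chimera_rate = chimera_rate, seed = NULL)
  smp <- sample_clones(loci, NULL, cfg)
  list(loci = loci, clones = smp$clones, truth = smp$truth$clones)
}

test_that("diagnostic sites need two alleles each supported by two clones", {
  m0 <- gst_msa(paste0("c", 1:6), rep("ACGTA", 6))
  expect_equal(nrow(find_diagnostic_sites(m0)), 0)

  m1 <- gst_msa(paste0("c", 1:6), c(rep("AAA", 3), rep("ATA", 3)))
  s1 <- find_diagnostic_sites(m1)
  expect_equal(s1$column, 1)                    # 0-based
  expect_false(s1$indel)

  # a singleton variant is presumed polymerase error, not a site
  m2 <- gst_msa(paste0("c", 1:6), c(rep("AAA", 5), "ATA"))
  expect_equal(nrow(find_diagnostic_sites(m2)), 0)

  # shared indels are reported and flagged
  m3 <- gst_msa(paste0("c", 1:6), c(rep("A-GT", 3), rep("ACGT", 3)))
  s3 <- find_diagnostic_sites(m3)
  expect_true(any(s3$indel))
})

test_that("contig assembly corrects sporadic errors and splits true loci", {
  set.seed(61)
  locus <- random_cds(100)
  clones <- rep(locus, 10)
  err1 <- strsplit(locus, "")[[1]]; err1[50] <- setdiff(c("A","C","G","T"), err1[50])[1]
  err2 <- strsplit(locus, "")[[1]]; err2[200] <- setdiff(c("A","C","G","T"), err2[200])[1]
  clones[3] <- paste(err1, collapse = ""); clones[7] <- paste(err2, collapse = "")
  msa <- gst_msa(paste0("c", 1:10), clones)
  ctg <- assemble_contigs(msa, taxon = "tx")
  expect_length(ctg, 1)
  expect_equal(nrow(ctg[[1]]$corrected), 2)
  expect_equal(ctg[[1]]$consensus, locus)

  # two clones differing at a single site stay in one contig
  m2 <- gst_msa(c("x", "y"), c("AAAAAA", "AATAAA"))
  expect_length(assemble_contigs(m2), 1)

  # preset amplicons: two loci per diploid, four per tetraploid
  pre <- preset_cotton_like(seed = 2)
  cl <- pre$sets$PHYA$clones
  for (tx in c("Grai", "Ghir")) {
    ct <- cl[cl$taxon == tx, ]
    ctg <- assemble_contigs(gst_msa(ct$id, ct$residues), taxon = tx)
    expect_length(ctg, ifelse(tx == "Grai", 2, 4))
    cons <- vapply(ctg, `[[`, character(1), "consensus")
    expect_setequal(cons, pre$sets$PHYA$loci$residues[
      pre$sets$PHYA$loci$taxon == tx])
  }
})

test_that("no clone is lost or double-assigned by assembly", {
  cs <- make_clone_set(62, chimera_rate = 0)
  msa <- gst_msa(cs$clones$id, cs$clones$residues)
  ctg <- assemble_contigs(msa, taxon = "T")
  members <- unlist(lapply(ctg, `[[`, "members"))
  expect_false(any(duplicated(members)))
  expect_setequal(c(members, attr(ctg, "excluded")), cs$clones$id)
})

test_that("clones with excessive Ns are excluded and logged", {
  set.seed(63)
  locus <- random_cds(40)
  noisy <- paste0(strrep("N", 40), substr(locus, 41, 120))
  msa <- gst_msa(paste0("c", 1:5), c(rep(locus, 4), noisy))
  ctg <- assemble_contigs(msa)
  expect_equal(attr(ctg, "excluded"), "c5")
  expect_length(ctg, 1)
})

test_that("chimera screen: power, false positives and breakpoint intervals", {
  cs <- make_clone_set(64, n_clones = 40, chimera_rate = 0.4, codons = 400)
  msa <- gst_msa(cs$clones$id, cs$clones$residues)
  ctg <- assemble_contigs(msa, taxon = "T")
  ch <- detect_chimeras(msa, ctg, seed = 65)
  truth_ch <- cs$truth$clone_id[cs$truth$chimera]
  expect_gt(length(truth_ch), 5)
  # every call is a true simulated recombinant at this divergence
  expect_true(all(ch$clone_id %in% truth_ch))
  expect_gt(sum(truth_ch %in% ch$clone_id) / length(truth_ch), 0.6)
  # called breakpoint intervals bracket the simulated breakpoints
  for (k in seq_len(nrow(ch))) {
    b <- cs$truth$breakpoint[cs$truth$clone_id == ch$clone_id[k]]
    expect_true(b >= ch$breakpoint_lo[k] - 1 && b <= ch$breakpoint_hi[k])
  }

  # clones identical to a parent are never called
  cs0 <- make_clone_set(66, n_clones = 30, chimera_rate = 0, taq = 0)
  msa0 <- gst_msa(cs0$clones$id, cs0$clones$residues)
  ctg0 <- assemble_contigs(msa0, taxon = "T")
  ch0 <- detect_chimeras(msa0, ctg0, seed = 67)
  expect_equal(nrow(ch0), 0)
})

test_that("a clean mid-sequence split is significant at the permutation floor", {
  # parents differing at 20 spread sites; chimera switches after site 10
  set.seed(68)
  p1 <- strsplit(random_cds(100), "")[[1]]
  p2 <- p1
  sites <- seq(10, 295, length.out = 20)
  p2[sites] <- vapply(p1[sites], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  chim <- c(p1[1:150], p2[151:300])
  rows <- c(replicate(5, paste(p1, collapse = "")),
            replicate(5, paste(p2, collapse = "")),
            paste(chim, collapse = ""))
  msa <- gst_msa(c(paste0("a", 1:5), paste0("b", 1:5), "chi"), rows)
  ctg <- assemble_contigs(msa, taxon = "T")
  ch <- detect_chimeras(msa, ctg, n_perm = 999, seed = 69)
  expect_true("chi" %in% ch$clone_id)
  expect_lte(ch$p_value[ch$clone_id == "chi"], 0.001)
  expect_true(ch$breakpoint_lo[ch$clone_id == "chi"] <= 150 &&
                ch$breakpoint_hi[ch$clone_id == "chi"] >= 151)
})

test_that("clone-count bias test matches the chi-square closed form", {
  b <- clone_count_bias_test(c(D = 16, A = 0))
  expect_equal(b$chi2, 16)
  expect_equal(b$df, 1)
  expect_equal(b$p, 6.33e-5, tolerance = 1e-2)
  expect_lt(b$p, 0.005)
  expect_true(is.na(b$p_exact))                # expected counts are 8/8, >= 5
  b2 <- clone_count_bias_test(c(D = 8, A = 8))
  expect_equal(b2$chi2, 0); expect_equal(b2$p, 1)
  b3 <- clone_count_bias_test(c(a = 3, b = 3, c = 3))
  expect_equal(b3$chi2, 0); expect_equal(b3$df, 2); expect_equal(b3$p, 1)
  expect_error(clone_count_bias_test(c(a = 0, b = 0)), "zero total")
})
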