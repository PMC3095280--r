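test_that("per-codon site counts match direct enumeration", {
  expect_equal(unname(ng_sites("ATG")), c(0, 3))
  expect_equal(unname(ng_sites("TTT")), c(1 / 3, 8 / 3), tolerance = 1e-12)
  expect_error(ng_sites("TAA"), "stop")
  expect_error(ng_sites("AXG"), "invalid")

  # enumeration oracle over every sense codon, with stop-exclusion
  code <- phygst:::GENETIC_CODE_STD
  bases <- c("A", "C", "G", "T")
  for (codon in names(code)[code != "*"]) {
    ch <- strsplit(codon, "")[[1]]
    s_exp <- 0
    has_stop_neighbor <- FALSE
    for (pos in 1:3) {
      syn <- 0; ok <- 0
      for (b in setdiff(bases, ch[pos])) {
        mut <- ch; mut[pos] <- b
        aa <- code[[paste(mut, collapse = "")]]
        if (aa == "*") { has_stop_neighbor <- TRUE; next }
        ok <- ok + 1
        if (aa == code[[codon]]) syn <- syn + 1
      }
      if (ok > 0) s_exp <- s_exp + syn / ok
    }
    got <- ng_sites(codon)
    expect_equal(unname(got["s"]), s_exp, tolerance = 1e-12, info = codon)
    expect_equal(unname(got["s"] + got["n"]), 3, tolerance = 1e-12)
  }
})

test_that("pairwise counts use pathway averaging and conserve differences", {
  z <- ng_pairwise("ATGATG", "ATGATG")
  expect_equal(c(z$Sd, z$Nd, z$Ks, z$Ka), c(0, 0, 0, 0))

  # TTT vs GTA: one pathway has 1 syn + 1 nonsyn, the other 2 nonsyn
  p <- ng_pairwise("TTT", "GTA")
  expect_equal(p$Sd, 0.5)
  expect_equal(p$Nd, 1.5)

  # Sd + Nd equals the plain nucleotide difference count (property)
  set.seed(51)
  for (k in 1:10) {
    a <- random_cds(50)
    bv <- strsplit(a, "")[[1]]
    idx <- sample(150, 12)
    bv[idx] <- sample(c("A", "C", "G", "T"), 12, replace = TRUE)
    b <- paste(bv, collapse = "")
    starts <- seq(1, 148, 3)
    ca <- substring(a, starts, starts + 2); cb <- substring(b, starts, starts + 2)
    keep <- !(ca %in% phygst:::STOP_CODONS) & !(cb %in% phygst:::STOP_CODONS)
    ndiff <- sum(strsplit(paste(ca[keep], collapse = ""), "")[[1]] !=
                   strsplit(paste(cb[keep], collapse = ""), "")[[1]])
    r <- ng_pairwise(a, b)
    expect_equal(r$Sd + r$Nd, ndiff, tolerance = 1e-9)
    expect_equal(r$S_sites + r$N_sites, 3 * r$codons_compared,
                 tolerance = 1e-9)
  }
  expect_error(ng_pairwise("ATG", "ATGATG"), "length")
  expect_error(ng_pairwise("ATGA", "ATGA"), "multiple of 3")
})

test_that("Jukes-Cantor correction and its saturation bound", {
  expect_equal(as.numeric(jc_correct(0)), 0)
  expect_equal(as.numeric(jc_correct(0.5)), 0.8239592, tolerance = 1e-6)
  sat <- jc_correct(0.76)
  expect_true(attr(sat, "saturated"))
  expect_equal(as.numeric(sat), 2.0)
  expect_equal(attr(sat, "bound"), ">2.0")
  expect_error(jc_correct(1.2), "0, 1")
})

test_that("Fisher selection test matches the enumeration oracle", {
  # homeolog PHYB 2.1 kb diploid-diploid counts reproduce the published p
  p <- fisher_selection_test(8.0, 377.33, 7.0, 1293.67)
  expect_lt(abs(p - 0.010), 0.001)
  expect_equal(fisher_selection_test(0, 100, 0, 300), 1)

  expect_equal(fisher_selection_test(4, 56, 1, 206),
               oracle_fisher_one_tail(4, 56, 1, 206), tolerance = 1e-12)
  set.seed(52)
  for (k in 1:20) {
    m <- sample(5:300, 1); n <- sample(5:300, 1)
    kk <- sample(1:min(m, 15), 1)
    a <- sample(0:kk, 1); c_ <- kk - a
    expect_equal(fisher_selection_test(a, m, c_, n),
                 oracle_fisher_one_tail(a, m, c_, n), tolerance = 1e-9)
  }
  # two-tailed agrees with fisher.test on the same table
  tab <- matrix(c(8, 377, 7, 1294), 2, byrow = TRUE)
  expect_equal(fisher_selection_test(8, 377, 7, 1294, tails = "two"),
               fisher.test(tab)$p.value, tolerance = 1e-6)
})

test_that("clock calibration and node dating invert exactly", {
  cal <- calibrate_rate(1.82, 85, T_range = c(68, 96))
  expect_equal(cal$r, 0.0107, tolerance = 1e-3)
  dn <- date_node(0.309, cal)
  expect_equal(dn$T_mya, 14.43, tolerance = 0.01)
  expect_equal(calibrate_rate(0.2, 10)$r, 0.01)
  # round trip: date(2 r T) = T
  for (Tm in c(1, 14, 85)) {
    expect_equal(date_node(2 * cal$r * Tm, cal)$T_mya, Tm, tolerance = 1e-12)
  }
  expect_error(calibrate_rate(-1, 10), "positive")
  ks_sat <- structure(2.0, saturated = TRUE)
  expect_error(date_node(ks_sat, cal), "saturated")
})

test_that("node summaries: mean, population s.d. and fold contrasts", {
  nt <- phy_node_divergence()
  s <- summarize_nodes(nt, c("1A", "1B", "1C", "1E"), "3", "1A")
  expect_equal(s$mean_kaks, 0.0785, tolerance = 1e-4)
  expect_equal(s$sd_kaks, 0.0143, tolerance = 1e-2)
  expect_equal(s$fold, 2.40, tolerance = 0.01)
  s1 <- summarize_nodes(nt, "1B")
  expect_equal(s1$mean_kaks, 0.090)
  expect_equal(s1$sd_kaks, 0)
})

test_that("group comparisons average pair counts and fractional means arise", {
  set.seed(53)
  base <- random_cds(80)
  mut <- function(s, n) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(length(v), n)
    v[idx] <- vapply(v[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(v, collapse = "")
  }
  seqs <- c(dA = base, dD = mut(base, 4), tA1 = mut(base, 1), tA2 = mut(base, 2),
            tD1 = mut(base, 5), tD2 = mut(base, 6))
  meta <- data.frame(id = names(seqs),
                     ploidy = c("diploid", "diploid", rep("tetraploid", 4)),
                     genome_origin = c("A", "D", "A", "A", "D", "D"))
  dd <- group_comparison(seqs, meta, "D-D")
  expect_equal(dd$n_pairs, 1)
  one <- ng_pairwise(seqs[["dA"]], seqs[["dD"]])
  expect_equal(dd$S_dif, one$Sd)
  expect_equal(dd$Ks, one$Ks)

  dt <- group_comparison(seqs, meta, "D-T")
  expect_equal(dt$n_pairs, 4)                 # dA x {tD1,tD2} + {tA1,tA2} x dD
  manual <- lapply(list(c("dA", "tD1"), c("dA", "tD2"),
                        c("tA1", "dD"), c("tA2", "dD")),
                   function(pr) ng_pairwise(seqs[[pr[1]]], seqs[[pr[2]]]))
  expect_equal(dt$S_dif, mean(vapply(manual, `[[`, numeric(1), "Sd")))
  expect_equal(dt$Ka, mean(vapply(manual, `[[`, numeric(1), "Ka")))
  # group ratio is mean(Ka)/mean(Ks), not the mean of ratios
  expect_equal(dt$ka_ks, dt$Ka / dt$Ks)
  tt <- group_comparison(seqs, meta, "T-T")
  expect_equal(tt$n_pairs, 4)
  expect_error(group_comparison(seqs, meta[meta$genome_origin == "A", ], "D-D"),
               "no sequence pairs")
})
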