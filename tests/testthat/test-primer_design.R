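test_that("fold-degeneracy is the product of per-position base-set sizes", {
  expect_equal(fold_degeneracy("ACGT"), 1)
  expect_equal(fold_degeneracy("CRCAIGCRTAICKARIGGRWAIGG"), 16384)
  expect_equal(fold_degeneracy("CAWGCATACCTWAGMGGRAAI"), 64)
  expect_equal(fold_degeneracy("NNN"), 64)
  expect_equal(fold_degeneracy("III", inosine_multiplicity = 1), 1)
  expect_error(fold_degeneracy("ACXG"), "position 3")
  # multiplicative under concatenation
  set.seed(5)
  codes <- names(phygst:::IUPAC_SETS)
  for (k in 1:10) {
    p <- paste(sample(codes, 5, replace = TRUE), collapse = "")
    q <- paste(sample(codes, 4, replace = TRUE), collapse = "")
    expect_equal(fold_degeneracy(paste0(p, q)),
                 fold_degeneracy(p) * fold_degeneracy(q))
  }
})

test_that("published primer panel: validated rows match, known outliers flagged", {
  pr <- gst_primers()
  expect_true(all(pr$consistent[pr$name %in%
                                  c("PHYdeg-R", "PHYAdeg-R", "1010-F")]))
  # three published degeneracies are internally inconsistent under any
  # uniform counting rule; the consistent product rule is kept
  outliers <- pr[pr$name %in% c("PHYdeg-F", "PHYBdeg-R", "2848-R"), ]
  expect_false(any(outliers$consistent))
  expect_equal(outliers$computed_degeneracy[order(outliers$name)],
               c(4, 3072, 256)[order(c("2848-R", "PHYdeg-F", "PHYBdeg-R"))])
})

# expand a degenerate primer into all concrete oligos (I treated as N)
expand_primer <- function(res) {
  sets <- lapply(strsplit(res, "")[[1]], function(k) phygst:::IUPAC_SETS[[k]])
  apply(as.matrix(expand.grid(sets, stringsAsFactors = FALSE)), 1,
        paste, collapse = "")
}

test_that("reverse translation collapses codon sets to minimal IUPAC codes", {
  expect_equal(reverse_translate("M")$residues, "ATG")
  expect_equal(fold_degeneracy(reverse_translate("M")), 1)

  hy <- reverse_translate("HY")
  expect_equal(hy$residues, "CAYTAY")
  expect_equal(fold_degeneracy(hy), 4)
  # enumeration oracle: every expansion translates back to the peptide
  expect_true(all(vapply(expand_primer(hy$residues), translate_cds,
                         character(1)) == "HY"))

  pf <- reverse_translate("PFPLRYAC", collapse = "inosine3rd",
                          orientation = "reverse")
  expect_equal(nchar(pf$residues), 24)
  fwd <- reverse_translate("PFPLRYAC", collapse = "inosine3rd")
  expect_equal(pf$residues, revcomp(fwd$residues))
  # degeneracy equals the product of per-column set sizes of the forward
  # construction (enumeration oracle on the non-inosine collapse)
  plain <- reverse_translate("PFPLRYAC")
  sizes <- vapply(strsplit(plain$residues, "")[[1]],
                  function(k) length(phygst:::IUPAC_SETS[[k]]), numeric(1))
  expect_equal(fold_degeneracy(plain), prod(sizes))
  # the collapsed primer always covers every true codon spelling (superset)
  set.seed(8)
  aas <- setdiff(unique(phygst:::GENETIC_CODE_STD), "*")
  for (k in 1:5) {
    pep <- paste(sample(aas, 2), collapse = "")
    pr <- reverse_translate(pep)
    spellings <- as.matrix(expand.grid(
      phygst:::CODONS_BY_AA[[substr(pep, 1, 1)]],
      phygst:::CODONS_BY_AA[[substr(pep, 2, 2)]]))
    spellings <- apply(spellings, 1, paste, collapse = "")
    expect_true(all(spellings %in% expand_primer(pr$residues)))
  }
  # exact round trip for residues whose codon sets are IUPAC boxes
  # (the 6-codon families L/R/S collapse to a strict superset)
  for (k in 1:5) {
    pep <- paste(sample(setdiff(aas, c("L", "R", "S")), 2), collapse = "")
    pr <- reverse_translate(pep)
    expect_true(all(vapply(expand_primer(pr$residues), translate_cds,
                           character(1)) == pep))
  }
  expect_error(reverse_translate("A*"), "no codon")
})

test_that("mismatch counting respects IUPAC sets and classifies ts/tv", {
  expect_equal(count_mismatches("CAYTAY", "CATTAC")$mismatches, 0)
  r <- count_mismatches("ACGT", "ACGA")
  expect_equal(r$mismatches, 1)
  expect_equal(r$mismatch_positions$index, 3)   # 0-based
  r2 <- count_mismatches("RRRR", "CCCC")
  expect_equal(r2$mismatches, 4)
  expect_true(all(r2$mismatch_positions$class == "transversion"))
  # inosine matches any base
  expect_equal(count_mismatches("IIII", "ACGT")$mismatches, 0)
  # A vs G is a transition
  r3 <- count_mismatches("A", "G")
  expect_equal(r3$mismatch_positions$class, "transition")
  expect_error(count_mismatches("ACGT", "ACG"), "length")
})

test_that("in-silico PCR finds site pairs within mismatch and size limits", {
  set.seed(21)
  fwd <- iupac_primer("F", "ATCGGATTCA")
  rev <- iupac_primer("R", "GGCCTTAAGG", "reverse")
  mid <- strrep("CA", 150)       # low-complexity spacer: no spurious sites
  template <- gst_seqs("tpl", paste0("ATCGGATTCA", mid, revcomp("GGCCTTAAGG")))
  amp <- in_silico_pcr(template, fwd, rev, max_mismatch = 0)
  expect_length(amp, 1)
  expect_equal(amp[[1]]$start, 0)
  expect_equal(amp[[1]]$end, 320)
  expect_equal(amp[[1]]$product, template$residues)

  # a primer with 3 extra mismatches fails a 2-mismatch threshold
  bad_fwd <- iupac_primer("F2", "ATCGGCGGCA")
  expect_length(in_silico_pcr(template, bad_fwd, rev, max_mismatch = 2), 0)
  # missing reverse site
  t2 <- gst_seqs("t2", paste0("ACGTACGTAC", mid))
  expect_length(in_silico_pcr(t2, fwd, rev, max_mismatch = 0), 0)

  # brute-force oracle over every window on random templates
  for (k in 1:5) {
    tpl <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
    f <- substr(tpl, 3, 8)
    r <- revcomp(substr(tpl, 40, 45))
    amps <- in_silico_pcr(gst_seqs("t", tpl), iupac_primer("f", f),
                          iupac_primer("r", r, "reverse"),
                          max_mismatch = 0, product_range = c(10, 60))
    # oracle: exact string search
    fpos <- gregexpr(f, tpl, fixed = TRUE)[[1]]
    rpos <- gregexpr(revcomp(r), tpl, fixed = TRUE)[[1]]
    n_expected <- 0
    for (fp in fpos) for (rp in rpos) {
      if (fp > 0 && rp > 0 && fp + nchar(f) - 1 <= rp - 1 + nchar(r) &&
          fp + 6 <= rp) {
        len <- rp + nchar(r) - fp
        if (len >= 10 && len <= 60 && rp >= fp + nchar(f)) {
          n_expected <- n_expected + 1
        }
      }
    }
    expect_equal(length(amps), n_expected)
  }
})
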