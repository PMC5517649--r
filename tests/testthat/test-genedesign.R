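# Backtranslation, restriction-site control, self-annealing repair.

tb <- codonUsageTable()

test_that("the codon table is complete and normalised", {
  expect_setequal(unique(tb$aa), aa20)
  sums <- tapply(tb$freq, tb$aa, sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_true(all(TrefoilForge:::.GENETIC_CODE[tb$codon] == tb$aa))
})

test_that("backtranslation round-trips exactly in both modes", {
  set.seed(19)
  for (mode in c("max", "sample")) {
    prot <- paste(sample(aa20, 100, replace = TRUE), collapse = "")
    g <- backtranslate(prot, tb, mode = mode, seed = 7)
    expect_identical(TrefoilForge:::.translate(g@coding), prot)
  }
  expect_identical(backtranslate("M", tb)@coding, "ATG")
  expect_error(backtranslate("MXK", tb), "non-standard")
  # sample mode is seed-reproducible
  g1 <- backtranslate("MKLMKL", tb, mode = "sample", seed = 3)
  g2 <- backtranslate("MKLMKL", tb, mode = "sample", seed = 3)
  expect_identical(g1@coding, g2@coding)
})

test_that("sampled codon frequencies follow the table (binomial check)", {
  prot <- strrep("L", 10000)
  g <- backtranslate(prot, tb, mode = "sample", seed = 5)
  codons <- substring(g@coding, seq(1, 29998, 3), seq(3, 30000, 3))
  fCTG <- mean(codons == "CTG")
  pCTG <- tb$freq[tb$codon == "CTG"]
  expect_lt(abs(fCTG - pCTG), 3 * sqrt(pCTG * (1 - pCTG) / 10000))
})

test_that("site scanning reports 0-based hits once per occurrence", {
  hits <- scanSites("AACATATGAA", c(NdeI = "CATATG"))
  expect_equal(nrow(hits), 1L)        # palindromic site: no double count
  expect_equal(hits$position, 2L)
  # a non-palindromic enzyme is found on both strands
  hits2 <- scanSites("AAGGTCTCAA", c(BsaI = "GGTCTC"))
  expect_equal(hits2$position, 2L)
  hits3 <- scanSites(TrefoilForge:::.revcomp("AAGGTCTCAA"),
                     c(BsaI = "GGTCTC"))
  expect_equal(nrow(hits3), 1L)
  expect_equal(hits3$strand, "-")
  expect_error(scanSites("ACGU"), "A/C/G/T")
})

test_that("random-sequence hit counts match the combinatorial expectation", {
  set.seed(31)
  L <- 1000L
  counts <- vapply(1:200, function(i) {
    dna <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    nrow(scanSites(dna, c(NdeI = "CATATG")))
  }, numeric(1))
  expected <- (L - 5) / 4096
  sigma <- sqrt(expected / 200)     # Poisson-scale error of the mean
  expect_lt(abs(mean(counts) - expected), 3 * sigma)
})

test_that("internal sites are removed by a single silent edit", {
  g <- backtranslate("MKTHMAYW", tb)        # His-Met encodes CATATG
  expect_equal(nrow(scanSites(g@coding)), 1L)
  g2 <- removeInternalSites(g)
  expect_equal(nrow(scanSites(g2@coding)), 0L)
  expect_equal(nrow(g2@edits), 1L)
  expect_identical(g2@protein, "MKTHMAYW")
  # a clean design is returned unchanged with an empty log
  g3 <- removeInternalSites(g2)
  expect_identical(g3@coding, g2@coding)
  expect_equal(nrow(g3@edits), nrow(g2@edits))
})

test_that("planted inverted repeats are repaired and verified brute-force", {
  # Glu-Phe as GAA TTC repeated gives the self-complementary 12-mer
  # GAATTCGAATTC: a hairpin stem with >= 10 bp reverse-complement matches
  codons <- c(M = "ATG", K = "AAA", T = "ACC", E = "GAA", F = "TTC",
              A = "GCG", R = "CGC")
  prot <- "MKTEFEFAKRT"
  coding <- paste(codons[TrefoilForge:::.splitChars(prot)], collapse = "")
  planted <- methods::new("GeneDesign", coding = coding, protein = prot)
  expect_gt(nrow(TrefoilForge:::.invertedRepeats(planted@coding, 10L)), 0L)
  expect_gt(bruteInvertedRepeats(planted@coding, 10L), 0L)
  fixed <- suppressWarnings(fixSelfAnnealing(planted, stemMin = 10L,
                                             table = tb))
  expect_equal(nrow(fixed@residual), 0L)
  expect_equal(bruteInvertedRepeats(fixed@coding, 10L), 0L)
  expect_identical(TrefoilForge:::.translate(fixed@coding),
                   planted@protein)
  expect_gt(nrow(fixed@edits), 0L)
})

test_that("a repeat-free gene passes through self-annealing repair unchanged", {
  g <- backtranslate("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", tb)
  pre <- g@coding
  g2 <- fixSelfAnnealing(g)
  expect_identical(g2@coding, pre)
  expect_equal(nrow(g2@edits), 0L)
})

test_that("the assembled construct is flanked and internally clean", {
  rep47 <- substr(paste0("MDG", strrep("KTAYIAEHG", 6)), 1, 47)
  full <- concatenateWithLinkers(substr(rep47, 1, 47), "singleG")
  g <- backtranslate(full$sequence, tb)
  g <- removeInternalSites(g)
  g <- suppressWarnings(fixSelfAnnealing(g))
  cons <- buildConstruct(g)
  expect_equal(nrow(cons$internalSites), 0L)
  expect_true(startsWith(cons$construct, "CATATG"))
  expect_true(endsWith(cons$construct, "CTCGAG"))
  # edits (if any) are all synonymous
  if (nrow(g@edits)) {
    same <- TrefoilForge:::.GENETIC_CODE[g@edits$from] ==
      TrefoilForge:::.GENETIC_CODE[g@edits$to]
    expect_true(all(same))
  }
})
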