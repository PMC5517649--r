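# Threading features, coarse energy, ranking, motif checks.

test_that("environment features match a brute-force all-pairs scan", {
  set.seed(17)
  ca <- matrix(rnorm(45, sd = 5), 15, 3)
  seq15 <- paste(sample(aa20, 15, replace = TRUE), collapse = "")
  ft <- threadSequence(ca, seq15)
  D <- as.matrix(dist(ca))
  expect_equal(ft$neighborCount, as.integer(rowSums(D <= 10) - 1L))
  Db <- as.matrix(dist(ft$cbeta))
  brute <- which(Db <= 8 & abs(row(Db) - col(Db)) >= 2 & upper.tri(Db),
                 arr.ind = TRUE)
  expect_equal(nrow(ft$contacts), nrow(brute))
  expect_setequal(paste(ft$contacts$i, ft$contacts$j),
                  paste(brute[, 1], brute[, 2]))
  expect_error(threadSequence(ca, "AAA"), "length")
})

test_that("neighbour counts follow the 10-Angstrom definition on a collinear toy", {
  ca <- cbind(c(0, 3.8, 7.6), 0, 0)
  ft <- threadSequence(ca, "GGG")
  expect_equal(ft$neighborCount, c(2L, 2L, 2L))   # all within 10 A
  expect_equal(nrow(ft$contacts), 1L)             # the (1,3) pair at 7.6 A
})

test_that("symmetric sequences on symmetric backbones give equal per-repeat terms", {
  s <- makeC3Backbone()
  reps <- extractRepeats(s, s@metadata$repeats)
  bb <- symmetrize(reps$A, fitC3Axis(reps))
  stacked <- do.call(rbind, subunitCoords(bb))     # three subunit chains
  sq <- strrep(attr(reps$A, "seq"), 3)
  su <- rep(1:3, each = 47L)
  ft <- threadSequence(stacked, sq, chains = su)
  for (k in 2:3)
    expect_equal(ft$neighborCount[su == 1L], ft$neighborCount[su == k])
  # per-repeat burial sums agree within 1e-9
  h <- TrefoilForge:::.HYDROPHOBICITY[ft$types]
  b1 <- sum((h * ft$neighborCount)[su == 1L])
  b2 <- sum((h * ft$neighborCount)[su == 2L])
  expect_lt(abs(b1 - b2), 1e-9)
  # per-repeat contact-distance multisets are identical
  halves <- rbind(data.frame(r = su[ft$contacts$i], d = ft$contacts$dist),
                  data.frame(r = su[ft$contacts$j], d = ft$contacts$dist))
  ms <- lapply(split(round(halves$d, 9), halves$r), sort)
  expect_equal(ms[[1]], ms[[2]])
  expect_equal(ms[[1]], ms[[3]])
})

test_that("the coarse energy matches a hand-computed toy", {
  # collinear chain, spacing 3.8: contacts are exactly (1,3) and (2,4)
  ca <- cbind(c(0, 3.8, 7.6, 11.4), 0, 0)
  ft <- threadSequence(ca, "GGGG")   # Gly: C-beta = CA
  expect_equal(nrow(ft$contacts), 2L)
  M <- contactMatrix()
  en <- scoreDesign(ft, cavityVolume = 0)
  expect_equal(en@contact, unname(M["G", "G"] * 2))
  expect_equal(en@burial, 0)            # Gly hydrophobicity is zero
  expect_equal(en@clash, 0)
  expect_lt(abs(en@total -
                  unname(defaultWeights()["contact"] * en@contact)), 1e-9)
  # mixed types: interior Trp is collinear, so its C-beta stays at CA
  ft2 <- threadSequence(ca, "GWGG")
  en2 <- scoreDesign(ft2, cavityVolume = 0)
  handContact <- unname(M["G", "G"] + M["W", "G"])
  expect_lt(abs(en2@contact - handContact), 1e-9)
})

test_that("an introduced near-contact raises the clash term strictly", {
  ca <- cbind(c(0, 3.8, 7.6, 11.4, 15.2), 0, 0)
  base <- scoreDesign(threadSequence(ca, "GGGGG"))
  ca2 <- ca
  ca2[5, ] <- c(0, 0, 2)    # 2.0 A from residue 1 (|i-j| = 4)
  clashed <- scoreDesign(threadSequence(ca2, "GGGGG"))
  expect_equal(base@clash, 0)
  expect_gt(clashed@clash, 0)
  expect_gt(clashed@total, base@total)
})

test_that("scores are invariant under rigid motion of the backbone", {
  set.seed(23)
  ca <- matrix(rnorm(60, sd = 6), 20, 3)
  sq <- paste(sample(aa20, 20, replace = TRUE), collapse = "")
  e1 <- scoreDesign(threadSequence(ca, sq), cavityVolume = 12)
  R <- TrefoilForge:::.rotationAbout(rnorm(3), runif(1, 0, 2 * pi))
  ca2 <- ca %*% t(R) + matrix(rnorm(3, sd = 30), 20, 3, byrow = TRUE)
  e2 <- scoreDesign(threadSequence(ca2, sq), cavityVolume = 12)
  expect_lt(abs(e1@total - e2@total), 1e-9)
})

test_that("ranking is deterministic and respects the selection criteria", {
  designs <- data.frame(
    id = c("a", "b", "c"),
    total = c(-5, -9, -7),
    rmsd = c(0.5, 1.4, 0.9),
    cavityVolume = c(120, 100, 40))
  r <- rankAndSelect(designs)
  expect_equal(unname(r$selections["energy"]), "b")
  expect_equal(unname(r$selections["rmsd"]), "a")
  expect_equal(unname(r$selections["cavity"]), "c")
  expect_equal(r$table$id, c("b", "c", "a"))
  # order independence
  r2 <- rankAndSelect(designs[c(3, 1, 2), ])
  expect_identical(r$selections, r2$selections)
  expect_identical(r$table, r2$table)
  # single design is all three selections
  r1 <- rankAndSelect(designs[2, ])
  expect_true(all(r1$selections == "b"))
  expect_error(rankAndSelect(designs[0, ]), "empty")
})

test_that("motif patterns are found per repeat", {
  rep1 <- "AAAAHTDRHAAAAA"
  rep2 <- "AAHPSGGAAAAAAA"
  rep3 <- strrep("A", 14)
  seqFull <- paste0(rep1, rep2, rep3)
  mapList <- list(1:14, 15:28, 29:42)
  m <- motifCheck(seqFull, mapList)
  expect_true(m$HxDxH[1]); expect_equal(m$HxDxH_at[1], 5)
  expect_false(m$HPxGG[1])
  expect_true(m$HPxGG[2]); expect_equal(m$HPxGG_at[2], 3)
  expect_false(m$HxDxH[3] || m$HPxGG[3])
})
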