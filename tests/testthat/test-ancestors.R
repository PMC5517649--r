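# Ancestral sequence reconstruction: model, pruning, posteriors,
# candidate sampling.

model <- substitutionModel("JTT")

test_that("the substitution model is a valid normalised reversible chain", {
  expect_lt(max(abs(rowSums(model@Q))), 1e-12)
  expect_lt(max(abs(model@pi %*% model@Q)), 1e-12)
  expect_lt(abs(sum(-diag(model@Q) * model@pi) - 1), 1e-9)
  P <- transitionMatrix(model, 0.7)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  expect_rigid_equal(transitionMatrix(model, 0), diag(20), 1e-12)
  wag <- substitutionModel("WAG")
  expect_false(isTRUE(all.equal(wag@Q, model@Q)))
})

test_that("identical sequences align without gaps; guides are honoured", {
  aln <- alignRepeats(c(A = "HKLM", B = "HKLM", C = "HKLM"))
  expect_equal(dim(aln), c(3L, 4L))
  expect_false(any(aln == "-"))
  # a guide pairing placing one deletion
  seqs <- c(A = "HKLMQ", B = "HKMQ")
  guide <- list(data.frame(idxA = c(1, 2, 4, 5), idxB = c(1, 2, 3, 4)))
  aln2 <- alignRepeats(seqs, guide)
  expect_identical(paste(aln2[2, ], collapse = ""), "HK-MQ")
  # unguided alignment places the same gap
  aln3 <- alignRepeats(seqs)
  expect_identical(paste(aln3[2, ], collapse = ""), "HK-MQ")
})

test_that("pruning equals brute-force enumeration over root states", {
  set.seed(8)
  for (rep in 1:5) {
    aln <- matrix(sample(aa20, 9, replace = TRUE), 3, 3,
                  dimnames = list(c("A", "B", "C"), NULL))
    bl <- c(A = runif(1, 0, 1.5), B = runif(1, 0, 1.5),
            C = runif(1, 0, 1.5))
    got <- pruningLoglik(aln, bl, model)
    want <- vapply(seq_len(ncol(aln)), function(s)
      log(bruteSiteLik(aln[, s], bl, model)), numeric(1))
    expect_lt(max(abs(got$siteLogLik - want)), 1e-10)
    expect_lt(abs(got$logLik - sum(want)), 1e-10)
  }
})

test_that("a single site with zero branches returns the prior of the residue", {
  aln <- matrix("H", 3, 1, dimnames = list(c("A", "B", "C"), NULL))
  got <- pruningLoglik(aln, c(A = 0, B = 0, C = 0), model)
  expect_lt(abs(got$logLik - log(model@pi[["H"]])), 1e-12)
})

test_that("the likelihood is invariant to leaf order and gaps are missing data", {
  aln <- rbind(A = c("H", "K", "-"), B = c("H", "A", "W"),
               C = c("D", "K", "W"))
  bl <- c(A = 0.4, B = 0.2, C = 0.9)
  l1 <- pruningLoglik(aln, bl, model)$logLik
  l2 <- pruningLoglik(aln[c(3, 1, 2), ], bl, model)$logLik
  expect_lt(abs(l1 - l2), 1e-12)
  # the gapped site equals the two-leaf likelihood
  aln2 <- rbind(B = "W", C = "W")
  l3 <- pruningLoglik(aln2, bl[c("B", "C")], model)$logLik
  expect_lt(abs(pruningLoglik(aln[, 3, drop = FALSE], bl, model)$logLik -
                  l3), 1e-12)
})

test_that("pruning matches phangorn on a random alignment", {
  set.seed(15)
  aln <- matrix(sample(aa20, 60, replace = TRUE), 3, 20,
                dimnames = list(c("A", "B", "C"), NULL))
  bl <- c(A = 0.3, B = 0.5, C = 0.1)
  tr <- ape::read.tree(text = "(A:0.3,B:0.5,C:0.1);")
  pd <- phangorn::phyDat(aln, type = "AA")
  ref <- phangorn::pml(tr, pd, model = "JTT")$logLik
  expect_lt(abs(pruningLoglik(aln, bl, model)$logLik - ref), 1e-6)
})

test_that("marginal root posteriors match brute-force Bayes", {
  aln <- rbind(A = "H", B = "H", C = "D")
  bl <- c(A = 0.5, B = 0.5, C = 0.5)
  post <- marginalPosterior(aln, bl, model)
  want <- brutePosterior(c("H", "H", "D"), bl, model)
  expect_lt(max(abs(post@prob[1, ] - want)), 1e-12)
  expect_lt(abs(sum(post@prob[1, ]) - 1), 1e-9)
  # vanishing branches concentrate all mass on the shared residue
  post0 <- marginalPosterior(rbind(A = "H", B = "H", C = "H"),
                             c(A = 1e-9, B = 1e-9, C = 1e-9), model)
  expect_gt(post0@prob[1, "H"], 1 - 1e-6)
})

test_that("posterior entropy grows with a common branch-length scale", {
  aln <- rbind(A = c("H", "K", "W", "A"), B = c("H", "K", "W", "C"),
               C = c("H", "R", "W", "A"))
  entropy <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  scales <- c(0.05, 0.2, 0.5, 1, 2)
  H <- vapply(scales, function(sc) {
    post <- marginalPosterior(aln, c(A = sc, B = sc, C = sc), model)
    mean(apply(post@prob, 1, entropy))
  }, numeric(1))
  expect_true(all(diff(H) > 0))
})

test_that("branch lengths are recovered by maximum likelihood", {
  # identical sequences: all branches collapse to zero
  alnSame <- matrix("K", 3, 30, dimnames = list(c("A", "B", "C"), NULL))
  t0 <- inferTree(alnSame, model)
  expect_true(all(t0$edge.length < 1e-6))
  # known branch lengths (0.3, 0.3, 0.3), 200 sites: within 30% on average
  recovered <- sapply(1:5, function(seed) {
    ev <- evolveSequences(200L, c(A = 0.3, B = 0.3, C = 0.3), model,
                          seed = seed)
    aln <- alignRepeats(ev$leaves)
    tr <- inferTree(aln, model)
    tr$edge.length
  })
  expect_lt(max(abs(rowMeans(recovered) - 0.3)), 0.09)
  # a divergent leaf earns the strictly largest branch
  ev <- evolveSequences(150L, c(A = 0, B = 0, C = 0.8), model, seed = 2)
  aln <- alignRepeats(ev$leaves)
  tr <- inferTree(aln, model)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_gt(bl[["C"]], max(bl[c("A", "B")]))
})

test_that("candidate sampling is seeded, sized and MAP-consistent", {
  set.seed(30)
  P <- matrix(0, 5, 20, dimnames = list(NULL, aa20))
  P[cbind(1:5, match(c("H", "K", "L", "M", "W"), aa20))] <- 1
  post <- new("AncestralPosterior", prob = P, logLik = 0,
              siteLogLik = numeric(5))
  cs <- sampleCandidates(post, 4, seed = 1)
  expect_equal(nrow(candidates(cs)), 4L)
  expect_true(all(candidates(cs)$sequence == "HKLMW"))
  expect_equal(sum(candidates(cs)$provenance == "MAP"), 1L)
  # reproducibility
  ev <- evolveSequences(60L, c(A = 0.4, B = 0.4, C = 0.4), model, seed = 6)
  aln <- alignRepeats(ev$leaves)
  post2 <- marginalPosterior(aln, inferTree(aln, model), model)
  c1 <- sampleCandidates(post2, 20, seed = 9)
  c2 <- sampleCandidates(post2, 20, seed = 9)
  expect_identical(candidates(c1), candidates(c2))
  c3 <- sampleCandidates(post2, 20, seed = 10)
  expect_false(identical(candidates(c1)$sequence,
                         candidates(c3)$sequence))
  expect_error(sampleCandidates(post2, 0), "at least one")
})

test_that("sampled site frequencies follow the posterior (binomial check)", {
  P <- matrix(0, 1, 20, dimnames = list(NULL, aa20))
  P[1, "H"] <- 0.7; P[1, "D"] <- 0.3
  post <- new("AncestralPosterior", prob = P, logLik = 0,
              siteLogLik = 0)
  cs <- sampleCandidates(post, 10000, seed = 3, includeMap = FALSE)
  fH <- mean(candidates(cs)$sequence == "H")
  sigma <- sqrt(0.7 * 0.3 / 10000)
  expect_lt(abs(fH - 0.7), 3 * sigma)
})

test_that("the MAP ancestor recovers the true ancestor on synthetic repeats", {
  id <- vapply(1:5, function(seed) {
    ev <- evolveSequences(120L, c(A = 0.2, B = 0.2, C = 0.2), model,
                          seed = seed)
    aln <- alignRepeats(ev$leaves)
    tr <- inferTree(aln, model)
    rec <- mapSequence(marginalPosterior(aln, tr, model))
    mean(TrefoilForge:::.splitChars(rec) ==
           TrefoilForge:::.splitChars(ev$root))
  }, numeric(1))
  expect_gte(mean(id), 0.9)
})

test_that("evolution fixtures honour their scenario", {
  # zero branches copy the root
  ev0 <- evolveSequences("HKLMW", c(A = 0, B = 0, C = 0), model, seed = 1)
  expect_true(all(ev0$leaves == "HKLMW"))
  # determinism
  e1 <- evolveSequences(80L, c(A = 0.5, B = 0.2, C = 0.9), model, seed = 4)
  e2 <- evolveSequences(80L, c(A = 0.5, B = 0.2, C = 0.9), model, seed = 4)
  expect_identical(e1, e2)
  # long branches: identity near the closed-form expectation
  t <- 5
  P <- transitionMatrix(model, t)
  expIdent <- sum(model@pi * diag(P))
  ev <- evolveSequences(400L, c(A = t, B = t, C = t), model, seed = 12)
  obs <- mean(vapply(ev$leaves, function(s)
    mean(TrefoilForge:::.splitChars(s) ==
           TrefoilForge:::.splitChars(ev$root)), numeric(1)))
  sigma <- sqrt(expIdent * (1 - expIdent) / (3 * 400))
  expect_lt(abs(obs - expIdent), 3 * sigma)
})
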