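# Rigid-body superposition and structure-guided identity.

test_that("kabsch recovers identity and known rotations exactly", {
  set.seed(42)
  a <- matrix(rnorm(30), 10, 3)
  fit0 <- kabsch(a, a)
  expect_lt(fit0@rmsd, 1e-12)
  expect_rigid_equal(fit0@rotation, diag(3), 1e-9)
  expect_rigid_equal(fit0@translation, c(0, 0, 0), 1e-9)

  R <- TrefoilForge:::.rotationAbout(c(2, -1, 0.5), 1.1)
  b <- a %*% t(R) + matrix(c(3, -2, 7), 10, 3, byrow = TRUE)
  fit <- kabsch(a, b)
  expect_lt(fit@rmsd, 1e-9)
  expect_rigid_equal(fit@rotation, R, 1e-6)
  # applying the transform reproduces the reported rmsd
  resid <- applyTransform(a, fit) - b
  expect_lt(abs(sqrt(sum(resid^2) / 10) - fit@rmsd), 1e-9)
})

test_that("kabsch rejects degenerate input", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  same <- matrix(1, 5, 3)
  expect_error(kabsch(same, same), "degenerate|coincident")
})

test_that("kabsch RMSD matches a quaternion grid-search oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    a <- matrix(rnorm(30), 10, 3)
    R <- TrefoilForge:::.rotationAbout(rnorm(3), runif(1, 0, pi))
    b <- a %*% t(R) + matrix(rnorm(3), 10, 3, byrow = TRUE) +
      matrix(rnorm(30, sd = 0.5), 10, 3)
    expect_lt(abs(kabsch(a, b)@rmsd - gridOracleRmsd(a, b)), 1e-3)
  }
})

test_that("RMSD is invariant under common rigid motions", {
  set.seed(7)
  a <- matrix(rnorm(36), 12, 3)
  b <- a + matrix(rnorm(36, sd = 0.3), 12, 3)
  base <- kabsch(a, b)@rmsd
  for (k in 1:5) {
    R <- TrefoilForge:::.rotationAbout(rnorm(3), runif(1, 0, 2 * pi))
    tv <- matrix(rnorm(3, sd = 10), 12, 3, byrow = TRUE)
    expect_lt(abs(kabsch(a %*% t(R) + tv, b %*% t(R) + tv)@rmsd - base),
              1e-9)
  }
  # superposed RMSD never exceeds the raw deviation
  expect_lte(base, sqrt(sum((a - b)^2) / 12) + 1e-12)
})

test_that("trimmed superposition drops exactly the displaced outliers", {
  set.seed(11)
  a <- matrix(rnorm(90, sd = 4), 30, 3)
  b <- a
  out <- c(4, 17, 25)
  b[out, ] <- b[out, ] + matrix(c(12, 12, 12), 3, 3)  # >> 3x cutoff
  fit <- trimmedSuperpose(a, b, cutoff = 3.5)
  expect_true(fit@trimmed)
  expect_equal(sort(setdiff(1:30, fit@correspondence$idxA)), out)
  expect_equal(fit@nAtoms, 27L)
  # direct distance check on the retained set
  d <- sqrt(rowSums((applyTransform(a, fit) - b)^2))
  expect_true(all(d[fit@correspondence$idxA] <= 3.5))

  ident <- trimmedSuperpose(a, a)
  expect_equal(ident@nAtoms, 30L)
  expect_lt(ident@rmsd, 1e-12)
  # trimming can only lower the RMSD
  expect_lte(fit@rmsd, kabsch(a, b)@rmsd)
})

test_that("structure-guided identity gives 100% to self and scales with mutations", {
  tmpl <- makeC3Backbone(L = 47L)
  tr <- caTrace(tmpl, "A", c(1, 50))
  sq <- substr(as.character(extractSequence(tmpl, "A")), 1, 50)
  A <- list(trace = tr, seq = sq)
  expect_equal(structureGuidedIdentity(A, A)$identity, 100)
  sq2 <- sq
  for (i in c(2, 11, 21, 31, 41)) substr(sq2, i, i) <- "W"
  B <- list(trace = tr, seq = sq2)
  r <- structureGuidedIdentity(A, B)
  expect_equal(r$identity, 90.0)
  expect_equal(r$nPaired, 50L)
  # symmetry of the identity measure
  r2 <- structureGuidedIdentity(B, A)
  expect_lt(abs(r$identity - r2$identity), 0.1 + 1e-9)
})

test_that("kabsch agrees with an independent reference implementation", {
  set.seed(13)
  a <- matrix(rnorm(60), 20, 3)
  b <- a + matrix(rnorm(60, sd = 0.4), 20, 3)
  ref <- bio3d::fit.xyz(fixed = as.numeric(t(b)), mobile = as.numeric(t(a)),
                        fixed.inds = 1:60, mobile.inds = 1:60)
  refRmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - b)^2)))
  expect_lt(abs(kabsch(a, b)@rmsd - refRmsd), 1e-6)
})
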