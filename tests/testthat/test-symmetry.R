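# Repeat extraction, axis fitting, symmetrisation, linkers, grafting.

test_that("repeat extraction on an exact-C3 fixture gives identical traces", {
  s <- makeC3Backbone()
  reps <- extractRepeats(s, s@metadata$repeats)
  expect_named(reps, c("A", "B", "C"))
  expect_lt(kabsch(reps$A, reps$B)@rmsd, 1e-9)
  expect_lt(kabsch(reps$A, reps$C)@rmsd, 1e-9)
  expect_equal(nchar(attr(reps$A, "seq")), 47L)
})

test_that("noise on one repeat shows up only in pairs involving it", {
  s <- makeC3Backbone()
  a <- atoms(s)
  set.seed(3)
  third <- a$resseq > 94
  a$x[third] <- a$x[third] + rnorm(sum(third), sd = 0.3)
  s@atoms <- a
  reps <- extractRepeats(s, s@metadata$repeats)
  expect_lt(kabsch(reps$A, reps$B)@rmsd, 1e-9)
  expect_gt(kabsch(reps$A, reps$C)@rmsd, 0.1)
  expect_gt(kabsch(reps$B, reps$C)@rmsd, 0.1)
})

test_that("axis fitting recovers the exact threefold axis and angle", {
  s <- makeC3Backbone()
  reps <- extractRepeats(s, s@metadata$repeats)
  ax <- fitC3Axis(reps)
  expect_lt(abs(abs(sum(ax@direction * c(0, 0, 1))) - 1), 1e-6)
  expect_lt(abs(ax@angle - 120), 1e-6)
})

test_that("axis fitting is equivariant under rigid motion of the fixture", {
  s <- makeC3Backbone()
  reps <- extractRepeats(s, s@metadata$repeats)
  set.seed(21)
  R <- TrefoilForge:::.rotationAbout(rnorm(3), runif(1, 0, 2 * pi))
  tv <- rnorm(3, sd = 20)
  reps2 <- lapply(reps, function(tr) {
    m <- as.matrix(tr[, c("x", "y", "z")]) %*% t(R) +
      matrix(tv, nrow(tr), 3, byrow = TRUE)
    data.frame(x = m[, 1], y = m[, 2], z = m[, 3])
  })
  ax2 <- fitC3Axis(reps2)
  expect_gte(abs(sum(ax2@direction * as.numeric(R %*% c(0, 0, 1)))),
             1 - 1e-6)
})

test_that("axis recovery from noisy fixtures stays within 2 degrees", {
  errs <- vapply(1:5, function(seed) {
    s <- makeC3Backbone(noise = 0.3, seed = seed)
    reps <- extractRepeats(s, s@metadata$repeats)
    ax <- fitC3Axis(reps)
    acos(pmin(1, abs(sum(ax@direction * c(0, 0, 1))))) * 180 / pi
  }, numeric(1))
  expect_true(all(errs < 2))
})

test_that("symmetrize reproduces the fixture from its own repeat and axis", {
  s <- makeC3Backbone()
  reps <- extractRepeats(s, s@metadata$repeats)
  ax <- fitC3Axis(reps)
  bb <- symmetrize(reps$A, ax)
  sc <- subunitCoords(bb)
  for (k in 1:3)
    expect_lt(max(abs(sc[[k]] - as.matrix(reps[[k]][, c("x", "y", "z")]))),
              1e-6)
})

test_that("symmetrize output is exactly C3 and refits to 120 degrees", {
  s <- makeC3Backbone(noise = 0.2, seed = 9)
  reps <- extractRepeats(s, s@metadata$repeats)
  ax <- fitC3Axis(reps)
  bb <- symmetrize(reps$A, ax)
  sc <- subunitCoords(bb)
  for (i in 1:3) {
    j <- i %% 3 + 1
    rot <- TrefoilForge:::.rotateUnit(sc[[i]], bb@axis, 1L, 3L)
    expect_lt(sqrt(sum((rot - sc[[j]])^2) / nrow(rot)), 1e-6)
  }
  ax2 <- fitC3Axis(sc)
  expect_lt(abs(ax2@angle - 120), 1e-6)
})

test_that("the rigid-body search lowers the packing objective", {
  s <- makeC3Backbone()
  reps <- extractRepeats(s, s@metadata$repeats)
  ax <- fitC3Axis(reps)
  # push the repeat towards the axis to create a deliberately bad start
  bad <- reps$A
  m <- as.matrix(bad[, c("x", "y", "z")])
  m[, 1:2] <- m[, 1:2] * 0.55
  bad$x <- m[, 1]; bad$y <- m[, 2]; bad$z <- m[, 3]
  u0 <- TrefoilForge:::.asUnitTable(bad)
  before <- TrefoilForge:::.packObjective(TrefoilForge:::.unitCA(u0), ax)$value
  bb <- symmetrize(bad, ax, rigidSearch = TRUE)
  expect_lt(bb@objective, before)
})

test_that("steric collapse is reported as a packing error", {
  s <- makeC3Backbone()
  reps <- extractRepeats(s, s@metadata$repeats)
  ax <- fitC3Axis(reps)
  bad <- reps$A
  m <- as.matrix(bad[, c("x", "y", "z")])
  m[, 1:2] <- m[, 1:2] * 0.05     # everything on the axis
  bad$x <- m[, 1]; bad$y <- m[, 2]; bad$z <- m[, 3]
  expect_error(symmetrize(bad, ax), "clash")
})

test_that("linker concatenation arithmetic matches both junction schemes", {
  rep47 <- strrep("A", 47)
  sG <- concatenateWithLinkers(rep47, "singleG")
  expect_equal(sG$length, 143L)
  gpos <- sG$map$global[sG$map$unit == 0L]
  expect_equal(gpos, c(48L, 96L))
  expect_identical(substr(sG$sequence, 48, 48), "G")
  expect_identical(substr(sG$sequence, 96, 96), "G")

  gdg <- concatenateWithLinkers(rep47, "GDG")
  expect_equal(gdg$length, 147L)
  expect_equal(gdg$map$global[gdg$map$unit == 0L], c(48:50, 98:100))
  expect_identical(substr(gdg$sequence, 48, 50), "GDG")
  expect_identical(substr(gdg$sequence, 98, 100), "GDG")

  none <- concatenateWithLinkers(rep47, "")
  expect_equal(none$length, 141L)
  # the numbering map is a bijection onto 1..total
  for (cc in list(sG, gdg, none))
    expect_equal(sort(cc$map$global), seq_len(cc$length))
})

test_that("grafting an identical donor leaves coordinates unchanged", {
  s <- makeC3Backbone()
  reps <- extractRepeats(s, s@metadata$repeats)
  bb <- symmetrize(reps$A, fitC3Axis(reps))
  donor <- realizeBackbone(bb, linkerLen = 0L)   # geometry == host
  g <- graftLinker(bb, donor, c(42, 47))
  expect_lt(max(abs(as.matrix(g@unit[, c("x", "y", "z")]) -
                      as.matrix(bb@unit[, c("x", "y", "z")]))), 1e-6)
  expect_equal(sum(g@unit$provenance == "donor"), 6L)
})

test_that("a 9-residue graft carries the donor tryptophan", {
  s <- makeC3Backbone()
  reps <- extractRepeats(s, s@metadata$repeats)
  bb <- symmetrize(reps$A, fitC3Axis(reps))
  donor <- makeDonor(bb)
  g9 <- graftLinker(bb, donor, c(39, 47))
  expect_equal(sum(g9@unit$provenance == "donor"), 9L)
  expect_true("TRP" %in% g9@unit$resname[g9@unit$provenance == "donor"])
  g6 <- graftLinker(bb, donor, c(42, 47))
  expect_false("TRP" %in% g6@unit$resname[g6@unit$provenance == "donor"])
  # graft preserves exact C3 symmetry
  sc <- subunitCoords(g9)
  rot <- TrefoilForge:::.rotateUnit(sc[[1]], g9@axis, 1L, 3L)
  expect_lt(sqrt(sum((rot - sc[[2]])^2) / nrow(rot)), 1e-6)
})

test_that("a displaced donor fails the anchor-RMSD gate", {
  s <- makeC3Backbone()
  reps <- extractRepeats(s, s@metadata$repeats)
  bb <- symmetrize(reps$A, fitC3Axis(reps))
  donor <- realizeBackbone(bb, linkerLen = 0L)
  a <- atoms(donor)
  # scatter the post-junction anchors in different directions so that no
  # rigid motion can reconcile the anchor geometry
  for (rr in 48:50) {
    i <- which(a$resseq == rr)
    a[i, c("x", "y", "z")] <- a[i, c("x", "y", "z")] +
      8 * diag(3)[rr - 47, ]
  }
  donor@atoms <- a
  expect_error(graftLinker(bb, donor, c(39, 47)), "anchor")
})

test_that("regularisation restores stretched bonds and only descends", {
  # ideal chain: no net movement
  chain <- cbind(seq(0, by = 3.8, length.out = 12), 0, 0)
  out <- regularizeBackbone(chain)
  expect_lt(max(abs(out - chain)), 1e-6)
  # stretch one bond by 0.5 A: restored within 0.02 A
  stretched <- chain
  stretched[7:12, 1] <- stretched[7:12, 1] + 0.5
  out2 <- regularizeBackbone(stretched, maxSteps = 2000L)
  d <- sqrt(rowSums(diff(out2)^2))
  expect_lt(max(abs(d - 3.8)), 0.02)
  # random jitter: objective strictly decreases
  set.seed(4)
  jit <- chain + matrix(rnorm(36, sd = 0.2), 12, 3)
  out3 <- regularizeBackbone(jit)
  tr <- attr(out3, "objective")
  expect_true(all(diff(tr) <= 0))
  expect_lt(tr[length(tr)], tr[1])
})
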