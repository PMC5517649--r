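# Shared fixtures and independent oracles for the test suite.

aa20 <- TrefoilForge:::.AA1

# --- quaternion grid-search oracle for the optimal superposition RMSD ---
# rmsd^2 = (|a0|^2 + |b0|^2 - 2 tr(R H)) / n with H = a0' b0, so the
# brute-force minimum over rotations only needs tr(R H) maximised on a
# rotation grid (Fibonacci axes x angle sweep), refined locally.
gridOracleRmsd <- function(a, b) {
  n <- nrow(a)
  a0 <- sweep(a, 2, colMeans(a)); b0 <- sweep(b, 2, colMeans(b))
  H <- crossprod(a0, b0)
  ssum <- sum(a0^2) + sum(b0^2)
  axes <- function(N) {
    i <- seq_len(N) - 0.5
    phi <- acos(1 - 2 * i / N)
    th <- pi * (1 + sqrt(5)) * i
    cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  }
  trRH <- function(ax, ang) {
    R <- TrefoilForge:::.rotationAbout(ax, ang)
    sum(R * H)
  }
  best <- -Inf; bestAx <- c(0, 0, 1); bestAng <- 0
  A <- axes(500)
  for (k in seq_len(nrow(A))) {
    for (ang in seq(0, 2 * pi, by = 2 * pi / 180)) {
      v <- trRH(A[k, ], ang)
      if (v > best) { best <- v; bestAx <- A[k, ]; bestAng <- ang }
    }
  }
  # local refinement: shrink a grid around the incumbent
  span <- 0.05
  for (round in 1:6) {
    for (dx in seq(-span, span, length.out = 5)) {
      for (dy in seq(-span, span, length.out = 5)) {
        ax <- TrefoilForge:::.unit(bestAx + c(dx, dy, 0))
        for (ang in seq(bestAng - span, bestAng + span,
                        length.out = 9)) {
          v <- trRH(ax, ang)
          if (v > best) { best <- v; bestAx <- ax; bestAng <- ang }
        }
      }
    }
    span <- span / 3
  }
  sqrt(max(ssum - 2 * best, 0) / n)
}

# --- brute-force phylogenetic likelihood over all root states ---
bruteSiteLik <- function(column, bl, model) {
  tot <- 0
  for (a in 1:20) {
    pr <- model@pi[a]
    for (k in seq_along(bl)) {
      st <- column[k]
      if (st %in% aa20) {
        P <- transitionMatrix(model, bl[k])
        pr <- pr * P[a, match(st, aa20)]
      }
    }
    tot <- tot + pr
  }
  unname(tot)
}

brutePosterior <- function(column, bl, model) {
  num <- vapply(1:20, function(a) {
    pr <- model@pi[a]
    for (k in seq_along(bl)) {
      st <- column[k]
      if (st %in% aa20) {
        P <- transitionMatrix(model, bl[k])
        pr <- pr * P[a, match(st, aa20)]
      }
    }
    pr
  }, numeric(1))
  num / sum(num)
}

# --- brute-force inverted-repeat scan (all substring pairs) ---
bruteInvertedRepeats <- function(dna, stemMin = 10L) {
  n <- nchar(dna)
  found <- 0L
  for (i in seq_len(n - stemMin + 1L)) {
    si <- substr(dna, i, i + stemMin - 1L)
    rc <- TrefoilForge:::.revcomp(si)
    for (j in seq_len(n - stemMin + 1L)) {
      if (j <= i) next
      if (substr(dna, j, j + stemMin - 1L) == rc) found <- found + 1L
    }
  }
  found
}

# --- synthetic donor matched to a backbone's junction geometry ---
# Realises the backbone without linkers, so that residues (L-8)..L flow
# straight into the next subunit; relabels the donor segment (with a
# hallmark tryptophan only in the 9-residue window).
makeDonor <- function(backbone, L = 47L) {
  donor <- realizeBackbone(backbone, linkerLen = 0L)
  a <- atoms(donor)
  dseq <- c("G", "W", "S", "T", "N", "A", "T", "G", "S")
  a$resname[(L - 8L):L] <- TrefoilForge:::.AA3FROM1[dseq]
  donor@atoms <- a
  donor@id <- "synthetic_donor"
  donor
}

# --- pseudo-symmetric template with divergent repeat sequences ---
# Repeats evolved from a known ancestor; both binding motifs are planted
# at fixed offsets in the ancestor and restored in each leaf so that the
# motif cassette behaves like a conserved site.
makeDivergentTemplate <- function(L = 47L, t = 0.2, seed = 5L,
                                  noise = 0) {
  model <- substitutionModel("JTT")
  ev <- evolveSequences(as.integer(L), c(A = t, B = t, C = t), model,
                        seed = seed)
  plant <- function(s) {
    substr(s, 5L, 9L) <- "HTDRH"
    substr(s, 15L, 19L) <- "HPSGG"
    s
  }
  root <- plant(ev$root)
  leaves <- vapply(ev$leaves, plant, character(1))
  st <- makeC3Backbone(L = L, noise = noise, seed = seed,
                       sequence = unname(leaves))
  st@metadata$trueAncestor <- root
  st
}

expect_rigid_equal <- function(object, expected, tol = 1e-9) {
  expect_lt(max(abs(object - expected)), tol)
}
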