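# Synthetic fixtures: exact and noisy C3 backbones, sequences evolved
# from a known ancestor, and hollow atom shells with analytic cavity
# volume. All generators are pure functions of (parameters, seed).

# One repeat built as zig-zag beta-strand C-alpha traces in a local
# frame: `strands` strands run along z, separated by `strandSep` in y,
# connected by single turn residues; consecutive C-alpha spacing is
# exactly `spacing`.
.repeatTrace <- function(L, strands, spacing, strandSep, zig) {
  perStrand <- (L - (strands - 1L)) / strands
  if (perStrand != floor(perStrand) || perStrand < 3L)
    stop("repeat length incompatible with the strand count")
  dz <- sqrt(spacing^2 - (2 * zig)^2)
  pts <- matrix(0, 0L, 3L)
  dirUp <- TRUE
  for (s in seq_len(strands)) {
    z0 <- if (dirUp) 0 else dz * (perStrand - 1L)
    zs <- z0 + (if (dirUp) 1 else -1) * dz * (seq_len(perStrand) - 1L)
    xs <- zig * (-1)^(seq_len(perStrand) - 1L)
    ys <- rep((s - 1L) * strandSep, perStrand)
    pts <- rbind(pts, cbind(xs, ys, zs))
    if (s < strands) {
      # one turn residue bridging to the next strand
      zend <- zs[perStrand]
      w <- sqrt(spacing^2 - (strandSep / 2)^2)
      turn <- c(0, (s - 1L) * strandSep + strandSep / 2,
                zend + (if (dirUp) 1 else -1) * w)
      pts <- rbind(pts, turn)
      dirUp <- !dirUp
    }
  }
  unname(pts)
}

#' Generate a C3-symmetric beta-trefoil-like C-alpha backbone
#'
#' One repeat is built as zig-zag strand traces (consecutive C-alpha
#' spacing exactly `spacing` at zero noise), placed at `radialOffset`
#' from the z axis as a tangential wall, and replicated at exact 120
#' degree rotations about z. Gaussian coordinate noise is then applied
#' independently per atom; `noise` is the RMS total displacement per atom
#' (per-coordinate standard deviation `noise/sqrt(3)`), so the expected
#' pairwise repeat RMSD of two noisy copies is about `sqrt(2) * noise`.
#'
#' @param L repeat length in residues (default 47, the trefoil
#'   subdomain).
#' @param strands strands per repeat.
#' @param spacing consecutive C-alpha distance, Angstrom.
#' @param strandSep inter-strand separation, Angstrom.
#' @param radialOffset distance of the repeat wall from the symmetry
#'   axis, Angstrom.
#' @param noise RMS atomic displacement sigma, Angstrom (0 = exact
#'   symmetry).
#' @param seed RNG seed for the noise.
#' @param sequence optional one-letter repeat sequence(s) of length L
#'   used for residue names: a single string replicated over the three
#'   repeats, or a character vector of three per-repeat sequences (a
#'   divergent pseudo-symmetric template). Default: poly-Ala with a
#'   binding-motif cassette.
#' @return A [ProteinStructure-class] with one chain of 3 L residues;
#'   `metadata` records the repeat ranges and the true axis.
#' @export
makeC3Backbone <- function(L = 47L, strands = 4L, spacing = 3.8,
                           strandSep = 4.8, radialOffset = 6.2,
                           noise = 0, seed = 1L, sequence = NULL) {
  if (L < 20L) stop("repeat length must be at least 20")
  if (noise < 0) stop("noise must be non-negative")
  rep1 <- .repeatTrace(L, strands, spacing, strandSep, zig = 0.25)
  # centre the wall tangentially and push it out along +x
  rep1[, 2L] <- rep1[, 2L] - mean(range(rep1[, 2L]))
  rep1[, 1L] <- rep1[, 1L] + radialOffset
  coords <- NULL
  for (k in 0:2) {
    R <- .rotationAbout(c(0, 0, 1), k * 2 * pi / 3)
    coords <- rbind(coords, rep1 %*% t(R))
  }
  D <- stats::dist(coords)   # parameter check on the noise-free geometry
  if (min(D) < 2.5)
    stop(sprintf("geometry parameters produce CA-CA distance %.2f A", min(D)))
  if (noise > 0) {
    coords <- coords + .withSeed(seed, {
      matrix(stats::rnorm(length(coords), sd = noise / sqrt(3)),
             nrow(coords), 3L)
    })
  }
  if (is.null(sequence)) {
    base <- strrep("A", L)
    # plant the two binding motifs so motif checks have a true positive
    substr(base, 5L, 9L) <- "HTDRH"
    substr(base, 15L, 19L) <- "HPSGG"
    sequence <- base
  }
  if (length(sequence) == 1L) sequence <- rep(sequence, 3L)
  if (length(sequence) != 3L || any(nchar(sequence) != L))
    stop("sequence must be one string of length L, or three of them")
  resname <- unname(.AA3FROM1[.splitChars(paste(sequence, collapse = ""))])
  st <- .structureFromCA(coords, resname = resname, id = "c3_fixture",
                         metadata = list(
                           repeats = data.frame(start = c(1L, L + 1L,
                                                          2L * L + 1L),
                                                end = c(L, 2L * L, 3L * L)),
                           axis = c(0, 0, 1), L = L, noise = noise,
                           seed = seed))
  st
}

#' Evolve repeat sequences from a known ancestor
#'
#' Simulates substitution along each branch of a (star) tree by sampling
#' child states from P(t) = exp(Qt), site by site, starting from a known
#' root sequence. Used to test ancestral reconstruction against the true
#' ancestor.
#'
#' @param root one-letter root sequence, or an integer length to sample a
#'   root from the model's equilibrium frequencies.
#' @param tree an `ape` star tree or named numeric branch lengths (one
#'   per leaf), expected substitutions per site.
#' @param model a [SubstitutionModel-class].
#' @param seed RNG seed.
#' @return list with `leaves` (named character vector) and `root`.
#' @export
evolveSequences <- function(root, tree, model = substitutionModel("JTT"),
                            seed = 1L) {
  bl <- .starBranchLengths(tree, NULL)
  if (is.null(names(bl))) names(bl) <- LETTERS[seq_along(bl)]
  .withSeed(seed, {
    if (is.numeric(root) && length(root) == 1L)
      root <- paste(sample(.AA1, root, replace = TRUE, prob = model@pi),
                    collapse = "")
    .checkProteinString(root, "root sequence")
    ridx <- match(.splitChars(root), .AA1)
    leaves <- vapply(names(bl), function(lv) {
      P <- transitionMatrix(model, bl[[lv]])
      child <- vapply(ridx, function(a)
        sample.int(20L, 1L, prob = P[a, ]), integer(1))
      paste(.AA1[child], collapse = "")
    }, character(1))
    list(leaves = leaves, root = root)
  })
}

#' Generate a hollow spherical shell of atoms
#'
#' Atoms of radius `atomRadius` are placed by Fibonacci-sphere tiling on
#' a sphere of radius `innerRadius + atomRadius`, so the inner void
#' surface sits at `innerRadius`. The tiling density is chosen so the
#' maximum gap between neighbouring atom centres is at most `maxGap`,
#' which seals the shell against the solvent probe. The analytic volume
#' of the probe-eroded interior ball, (4/3) pi (innerRadius -
#' smallProbe)^3, is recorded in the metadata.
#'
#' @param innerRadius radius of the interior void surface, Angstrom.
#' @param atomRadius van der Waals radius of the shell atoms (carbon by
#'   default).
#' @param maxGap maximum centre-to-centre gap of the tiling, Angstrom.
#' @param smallProbe probe radius used for the analytic volume.
#' @param enforceSeal error when the tiling is too sparse to seal the
#'   shell against the small probe; set `FALSE` to build a deliberately
#'   leaky shell.
#' @param capOpening half-angle (degrees) of a polar aperture left open
#'   in the shell; an opening wide enough for the large probe makes the
#'   interior continuous with bulk solvent (no cavity).
#' @return A [ProteinStructure-class] of HETATM-free carbon pseudo-atoms;
#'   `metadata$analyticVolume` holds the analytic interior volume.
#' @export
makeShell <- function(innerRadius = 8, atomRadius = 1.7, maxGap = 1.0,
                      smallProbe = 1.4, enforceSeal = TRUE,
                      capOpening = 0) {
  if (innerRadius <= atomRadius + 1.4)
    stop("inner radius must exceed atomRadius + 1.4")
  R <- innerRadius + atomRadius
  # Fibonacci sphere with N points: typical nearest-neighbour distance
  # ~ sqrt(4 pi R^2 / N); pick N for the requested maximum gap.
  N <- ceiling(4 * pi * R^2 / (0.4 * maxGap^2))
  i <- seq_len(N) - 0.5
  phi <- acos(1 - 2 * i / N)
  theta <- pi * (1 + sqrt(5)) * i
  pts <- R * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  if (capOpening > 0) pts <- pts[phi * 180 / pi > capOpening, , drop = FALSE]
  # verify the seal: max nearest-neighbour gap
  nn <- vapply(seq_len(nrow(pts)), function(k) {
    d <- sqrt(rowSums(sweep(pts[-k, , drop = FALSE], 2L, pts[k, ])^2))
    min(d)
  }, numeric(1))
  if (enforceSeal && max(nn) > 2 * smallProbe)
    stop(sprintf("tiling too sparse to seal the shell (max gap %.2f A)",
                 max(nn)))
  st <- .structureFromCA(pts, resname = "UNK", id = "shell")
  st@atoms$name <- "C"
  st@atoms$element <- "C"
  st@metadata <- list(
    analyticVolume = 4 / 3 * pi * (innerRadius - smallProbe)^3,
    innerRadius = innerRadius, atomRadius = atomRadius, n = N)
  st
}
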