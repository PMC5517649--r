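# Rigid-body superposition, trimmed overlays and structure-guided identity.

.asCoordMatrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
  if (!is.matrix(x) || ncol(x) != 3L)
    stop("coordinates must be an n x 3 matrix or a trace data.frame")
  storage.mode(x) <- "double"
  x
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation and translation mapping `a` onto `b`, computed
#' by singular value decomposition of the covariance matrix with the
#' usual determinant sign correction, so the returned rotation is always
#' proper (det +1).
#'
#' @param a,b paired n x 3 coordinate matrices (or trace data.frames with
#'   `x`, `y`, `z` columns), n >= 3.
#' @return A [SuperpositionResult-class]; applying the transform to `a`
#'   (see [applyTransform()]) reproduces the reported RMSD against `b`.
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' R <- diag(3)[, c(2, 3, 1)]  # a proper rotation
#' fit <- kabsch(a, a %*% t(R))
#' fit@rmsd
#' @export
kabsch <- function(a, b) {
  a <- .asCoordMatrix(a); b <- .asCoordMatrix(b)
  n <- nrow(a)
  if (nrow(b) != n) stop("point sets must have equal length")
  if (n < 3L) stop("at least 3 point pairs are required")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2L, ca); b0 <- sweep(b, 2L, cb)
  if (max(svd(a0)$d) < 1e-12)
    stop("degenerate geometry: points are coincident")
  H <- crossprod(a0, b0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) stop("degenerate geometry in superposition")
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tvec <- cb - as.numeric(R %*% ca)
  resid <- b - (a %*% t(R) + matrix(tvec, n, 3L, byrow = TRUE))
  rmsd <- sqrt(sum(resid^2) / n)
  new("SuperpositionResult", rotation = R, translation = tvec, rmsd = rmsd,
      nAtoms = as.integer(n),
      correspondence = data.frame(idxA = seq_len(n), idxB = seq_len(n)),
      trimmed = FALSE)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix or trace data.frame.
#' @param fit a [SuperpositionResult-class], or a list with `rotation` and
#'   `translation`.
#' @return transformed coordinates, same shape as the input.
#' @export
applyTransform <- function(coords, fit) {
  R <- if (is(fit, "SuperpositionResult")) fit@rotation else fit$rotation
  tv <- if (is(fit, "SuperpositionResult")) fit@translation else fit$translation
  m <- .asCoordMatrix(coords)
  out <- m %*% t(R) + matrix(tv, nrow(m), 3L, byrow = TRUE)
  if (is.data.frame(coords)) {
    coords$x <- out[, 1]; coords$y <- out[, 2]; coords$z <- out[, 3]
    coords
  } else out
}

.rmsdOf <- function(a, b) sqrt(sum((a - b)^2) / nrow(a))

#' Iteratively trimmed superposition
#'
#' Superposes, drops pairs whose post-fit distance exceeds `cutoff`, and
#' repeats until the retained set is stable. The retained set only ever
#' shrinks (pairs are never re-admitted), so the retained count is
#' non-increasing across iterations.
#'
#' @param a,b paired coordinate matrices or trace data.frames.
#' @param cutoff distance cutoff in Angstrom (default 3.5, the
#'   conventional C-alpha equivalence threshold).
#' @param maxIter maximum trim iterations.
#' @param ids optional data.frame of pair identifiers (one row per pair)
#'   carried into the correspondence table.
#' @return A [SuperpositionResult-class] with `trimmed = TRUE`; the
#'   correspondence holds the retained pair indices.
#' @export
trimmedSuperpose <- function(a, b, cutoff = 3.5, maxIter = 20L, ids = NULL) {
  a <- .asCoordMatrix(a); b <- .asCoordMatrix(b)
  if (nrow(a) != nrow(b)) stop("point sets must have equal length")
  keep <- seq_len(nrow(a))
  fit <- NULL
  for (iter in seq_len(maxIter)) {
    if (length(keep) < 3L)
      stop("trimmed correspondence fell below 3 pairs before convergence")
    fit <- kabsch(a[keep, , drop = FALSE], b[keep, , drop = FALSE])
    d <- sqrt(rowSums((applyTransform(a[keep, , drop = FALSE], fit) -
                         b[keep, , drop = FALSE])^2))
    if (all(d <= cutoff)) break
    # drop only the worst offenders (at most 10% per round) so that a
    # fit skewed by gross outliers cannot discard genuine equivalences
    over <- which(d > cutoff)
    nDrop <- min(length(over), max(1L, ceiling(0.1 * length(keep))))
    worst <- over[order(d[over], decreasing = TRUE)][seq_len(nDrop)]
    keep <- keep[-worst]
  }
  if (length(keep) < 3L)
    stop("trimmed correspondence fell below 3 pairs before convergence")
  corr <- data.frame(idxA = keep, idxB = keep)
  if (!is.null(ids)) corr <- cbind(corr, ids[keep, , drop = FALSE])
  new("SuperpositionResult", rotation = fit@rotation,
      translation = fit@translation, rmsd = fit@rmsd,
      nAtoms = length(keep), correspondence = corr, trimmed = TRUE)
}

#' @export
setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: %d atoms, RMSD %.3f A%s\n",
              object@nAtoms, object@rmsd,
              if (object@trimmed) " (trimmed)" else ""))
})

# Sequence-order-preserving one-to-one residue pairing of two CA traces
# after superposition: dynamic programme maximising the number of pairs
# within `cutoff`, ties resolved towards smaller total distance.
.pairResidues <- function(ta, tb, cutoff) {
  n <- nrow(ta); m <- nrow(tb)
  D <- sqrt(outer(ta[, 1], tb[, 1], "-")^2 +
            outer(ta[, 2], tb[, 2], "-")^2 +
            outer(ta[, 3], tb[, 3], "-")^2)
  sc <- ifelse(D <= cutoff, 1e6 + (cutoff - D), -Inf)
  F <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    Fi <- F[i, ]; Fi1 <- F[i + 1L, ]
    for (j in seq_len(m)) {
      best <- max(Fi[j] + sc[i, j], Fi[j + 1L], Fi1[j])
      Fi1[j + 1L] <- best
    }
    F[i + 1L, ] <- Fi1
  }
  # traceback
  i <- n; j <- m; pa <- integer(0); pb <- integer(0)
  while (i > 0L && j > 0L) {
    if (is.finite(sc[i, j]) &&
        abs(F[i + 1L, j + 1L] - (F[i, j] + sc[i, j])) < 1e-9) {
      pa <- c(i, pa); pb <- c(j, pb); i <- i - 1L; j <- j - 1L
    } else if (F[i + 1L, j + 1L] == F[i, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(idxA = pa, idxB = pb, dist = D[cbind(pa, pb)])
}

#' Structure-guided pairwise sequence identity
#'
#' Superposes two C-alpha traces (iteratively trimmed seed), pairs
#' residues one-to-one in sequence order when their C-alpha distance is
#' within `pairingCutoff`, and reports the percentage of paired positions
#' with identical residues. The denominator is the number of structurally
#' paired positions, as in structure-based alignments.
#'
#' @param structA,structB [ProteinStructure-class] objects, or lists with
#'   elements `trace` (a [caTrace()] data.frame) and `seq` (one-letter
#'   string of the same length).
#' @param chainA,chainB chain identifiers (used for structure inputs).
#' @param pairingCutoff C-alpha pairing distance, Angstrom.
#' @param trimCutoff cutoff for the seed superposition.
#' @return list with `identity` (percent, reported to 0.1), `nPaired`,
#'   `pairs` (data.frame of paired indices, residues, distances) and the
#'   seed `fit`.
#' @export
structureGuidedIdentity <- function(structA, structB, chainA = NULL,
                                    chainB = NULL, pairingCutoff = 5,
                                    trimCutoff = 3.5) {
  getTS <- function(s, chain) {
    if (is(s, "ProteinStructure")) {
      if (is.null(chain)) chain <- s@atoms$chain[!s@atoms$het][1L]
      list(trace = caTrace(s, chain),
           seq = as.character(extractSequence(s, chain)))
    } else s
  }
  A <- getTS(structA, chainA); B <- getTS(structB, chainB)
  ta <- .asCoordMatrix(A$trace); tb <- .asCoordMatrix(B$trace)
  sa <- .splitChars(A$seq); sb <- .splitChars(B$seq)
  if (length(sa) != nrow(ta) || length(sb) != nrow(tb))
    stop("sequence and trace lengths disagree")
  # seed superposition on the common prefix pairing by order
  k <- min(nrow(ta), nrow(tb))
  fit <- trimmedSuperpose(ta[seq_len(k), ], tb[seq_len(k), ],
                          cutoff = trimCutoff)
  ta2 <- applyTransform(ta, fit)
  pr <- .pairResidues(ta2, tb, pairingCutoff)
  if (length(pr$idxA) < 10L)
    stop("fewer than 10 residues could be structurally paired")
  same <- sa[pr$idxA] == sb[pr$idxB]
  identity <- round(100 * mean(same), 1L)
  list(identity = identity, nPaired = length(pr$idxA),
       pairs = data.frame(idxA = pr$idxA, idxB = pr$idxB,
                          resA = sa[pr$idxA], resB = sb[pr$idxB],
                          dist = pr$dist, identical = same),
       fit = fit)
}
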