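# Maximum-likelihood ancestral sequence reconstruction over the repeat
# sequences: substitution models, Felsenstein pruning, marginal root
# posteriors and candidate sampling.

#' Construct a 20-state amino-acid substitution model
#'
#' Builds the reversible rate matrix Q from published exchangeabilities
#' and equilibrium frequencies (JTT by default, WAG selectable),
#' normalised to one expected substitution per site at stationarity, and
#' precomputes the symmetric eigendecomposition used for transition
#' matrices P(t) = exp(Qt). The numerical model data are taken from
#' phangorn at run time.
#'
#' @param name `"JTT"` or `"WAG"`.
#' @return A [SubstitutionModel-class].
#' @examples
#' m <- substitutionModel("JTT")
#' range(rowSums(transitionMatrix(m, 0.5)))
#' @export
substitutionModel <- function(name = c("JTT", "WAG")) {
  name <- match.arg(name)
  raw <- get(paste0(".", name), envir = asNamespace("phangorn"))
  p <- as.numeric(raw$bf)
  S <- matrix(0, 20L, 20L)
  S[lower.tri(S)] <- raw$Q          # column-major lower triangle
  S <- S + t(S)
  Q <- S * rep(p, each = 20L)       # Q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * p)        # one expected substitution per site
  sqp <- sqrt(p)
  B <- Q * (sqp %o% (1 / sqp))      # similar symmetric matrix
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  dimnames(Q) <- list(.AA1, .AA1)
  new("SubstitutionModel", name = name, Q = Q, pi = stats::setNames(p, .AA1),
      decomposition = list(values = e$values, vectors = e$vectors,
                           sqp = sqp, isqp = 1 / sqp))
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed exactly through the symmetric eigendecomposition of the
#' reversible rate matrix.
#'
#' @param model a [SubstitutionModel-class].
#' @param t branch length in expected substitutions per site (>= 0).
#' @return 20 x 20 stochastic matrix.
#' @export
transitionMatrix <- function(model, t) {
  if (t < 0) stop("branch length must be non-negative")
  d <- model@decomposition
  E <- d$vectors %*% (exp(d$values * t) * t(d$vectors))
  P <- (d$isqp %o% d$sqp) * E
  P[P < 0] <- 0
  dimnames(P) <- dimnames(model@Q)
  P
}

#' @export
setMethod("show", "SubstitutionModel", function(object) {
  cat(sprintf("SubstitutionModel '%s': 20 states, normalised, reversible\n",
              object@name))
})

#' Align the three repeat sequences
#'
#' With a structure-guided pairing the alignment columns follow it
#' exactly; otherwise a progressive Needleman-Wunsch alignment (BLOSUM62,
#' affine gaps: open 10, extend 0.5, through Biostrings) anchors the
#' second and third sequences to the first.
#'
#' @param seqs character vector of (three) repeat sequences.
#' @param guidePairing optional list of data.frames (one per non-first
#'   sequence) with columns `idxA` (position in `seqs[1]`) and `idxB`
#'   (position in that sequence), strictly increasing in both columns, as
#'   produced by [structureGuidedIdentity()].
#' @return character matrix, one row per sequence, gap `"-"`.
#' @export
alignRepeats <- function(seqs, guidePairing = NULL) {
  if (length(seqs) < 2L) stop("at least two sequences are required")
  if (is.null(names(seqs)))
    names(seqs) <- LETTERS[seq_along(seqs)]
  for (s in seqs) .checkProteinString(s, "repeat sequence", allow = "X")
  if (length(unique(nchar(seqs))) == 1L && is.null(guidePairing)) {
    # equal lengths align column-to-column (the symmetric-repeat case)
    m <- do.call(rbind, lapply(seqs, .splitChars))
    rownames(m) <- names(seqs)
    return(m)
  }
  if (!is.null(guidePairing)) {
    return(.alignFromGuide(seqs, guidePairing))
  }
  ref <- seqs[[1L]]
  rows <- list(.splitChars(ref))
  for (i in seq_along(seqs)[-1L]) {
    pa <- Biostrings::pairwiseAlignment(
      ref, seqs[[i]], substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5, type = "global")
    ap <- .splitChars(as.character(Biostrings::alignedPattern(pa)))
    as_ <- .splitChars(as.character(Biostrings::alignedSubject(pa)))
    # project subject letters onto reference coordinates
    refpos <- cumsum(ap != "-")
    proj <- rep("-", nchar(ref))
    hit <- ap != "-" & as_ != "-"
    proj[refpos[hit]] <- as_[hit]
    rows[[i]] <- proj
  }
  m <- do.call(rbind, rows)
  rownames(m) <- names(seqs)
  m
}

.alignFromGuide <- function(seqs, guidePairing) {
  if (length(guidePairing) != length(seqs) - 1L)
    stop("need one guide pairing per non-reference sequence")
  ref <- .splitChars(seqs[[1L]])
  ncolref <- length(ref)
  rows <- list(ref)
  for (i in seq_along(guidePairing)) {
    g <- guidePairing[[i]]
    if (any(diff(g$idxA) <= 0) || any(diff(g$idxB) <= 0))
      stop("guide pairing must be strictly increasing in both sequences")
    s <- .splitChars(seqs[[i + 1L]])
    if (max(g$idxB) > length(s) || max(g$idxA) > ncolref)
      stop("guide pairing indexes beyond sequence length")
    proj <- rep("-", ncolref)
    proj[g$idxA] <- s[g$idxB]
    rows[[i + 1L]] <- proj
  }
  m <- do.call(rbind, rows)
  rownames(m) <- names(seqs)
  m
}

# Leaf conditional-likelihood array: sites x 20 x leaves. Gaps and X are
# missing data (all-ones conditionals).
.leafConditionals <- function(alignment) {
  S <- ncol(alignment); n <- nrow(alignment)
  arr <- array(1, dim = c(S, 20L, n))
  for (k in seq_len(n)) {
    idx <- match(alignment[k, ], .AA1)
    obs <- !is.na(idx)
    m <- matrix(0, S, 20L)
    m[cbind(which(obs), idx[obs])] <- 1
    m[!obs, ] <- 1
    arr[, , k] <- m
  }
  arr
}

.starBranchLengths <- function(tree, alignment) {
  if (inherits(tree, "phylo")) {
    root <- ape::Ntip(tree) + 1L
    if (!all(tree$edge[, 1L] == root))
      stop("only star trees (every leaf attached to the root) are supported")
    bl <- tree$edge.length[match(seq_len(ape::Ntip(tree)), tree$edge[, 2L])]
    stats::setNames(bl, tree$tip.label)
  } else if (is.numeric(tree)) {
    if (is.null(names(tree))) names(tree) <- rownames(alignment)
    tree
  } else stop("tree must be an ape phylo or a named numeric vector")
}

# Per-site root partial likelihood matrix: prod over leaves of P(t) L_k.
.rootPartials <- function(alignment, bl, model) {
  arr <- .leafConditionals(alignment)
  leaves <- rownames(alignment)
  part <- matrix(1, ncol(alignment), 20L)
  for (k in seq_along(leaves)) {
    P <- transitionMatrix(model, bl[[leaves[k]]])
    part <- part * (arr[, , k] %*% t(P))
  }
  part
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' For the three-leaf star tree used in repeat symmetrisation the
#' likelihood of each site is sum_a pi_a prod_k (P(t_k) L_k)_a, with gaps
#' treated as missing data.
#'
#' @param alignment character matrix from [alignRepeats()] (rows named by
#'   leaf).
#' @param tree an `ape` star tree with branch lengths, or a named numeric
#'   vector of branch lengths per leaf.
#' @param model a [SubstitutionModel-class].
#' @return list with `logLik` (total) and `siteLogLik`.
#' @export
pruningLoglik <- function(alignment, tree, model) {
  if (ncol(alignment) == 0L) stop("zero-length alignment")
  bl <- .starBranchLengths(tree, alignment)
  if (!all(rownames(alignment) %in% names(bl)))
    stop("tree leaves do not match alignment rows")
  part <- .rootPartials(alignment, bl, model)
  siteL <- as.numeric(part %*% model@pi)
  if (any(!is.finite(log(siteL))))
    stop("non-finite site likelihood")
  list(logLik = sum(log(siteL)), siteLogLik = log(siteL))
}

#' Fit star-tree branch lengths by maximum likelihood
#'
#' Each leaf branch is optimised in turn by golden-section search
#' (`stats::optimize`) on the pruning likelihood, cycling until the
#' improvement falls below `tol`.
#'
#' @param alignment character matrix from [alignRepeats()].
#' @param model a [SubstitutionModel-class].
#' @param maxLength upper bound for any branch length.
#' @param tol convergence tolerance on the log-likelihood.
#' @return an `ape` star tree (`phylo`) with fitted branch lengths and a
#'   `logLik` attribute.
#' @export
inferTree <- function(alignment, model = substitutionModel("JTT"),
                      maxLength = 10, tol = 1e-6) {
  if (ncol(alignment) == 0L) stop("zero-length alignment")
  leaves <- rownames(alignment)
  bl <- stats::setNames(rep(0.1, length(leaves)), leaves)
  ll <- pruningLoglik(alignment, bl, model)$logLik
  repeat {
    for (lv in leaves) {
      f <- function(t) {
        b2 <- bl; b2[lv] <- t
        pruningLoglik(alignment, b2, model)$logLik
      }
      op <- stats::optimize(f, c(0, maxLength), maximum = TRUE,
                            tol = 1e-8)
      if (op$objective >= f(bl[lv])) bl[lv] <- op$maximum
    }
    llNew <- pruningLoglik(alignment, bl, model)$logLik
    if (llNew - ll < tol) { ll <- llNew; break }
    ll <- llNew
  }
  # an optimum at the numerical lower boundary is an exact zero
  bl[bl < 1e-6] <- 0
  tr <- ape::read.tree(text = paste0(
    "(", paste(sprintf("%s:%.10f", leaves, bl), collapse = ","), ");"))
  attr(tr, "logLik") <- ll
  tr
}

#' Marginal posterior of the root state per site
#'
#' P(root = a | data) proportional to pi_a prod_k (P(t_k) L_k)_a,
#' normalised per site.
#'
#' @inheritParams pruningLoglik
#' @return An [AncestralPosterior-class].
#' @export
marginalPosterior <- function(alignment, tree, model) {
  bl <- .starBranchLengths(tree, alignment)
  part <- .rootPartials(alignment, bl, model)
  w <- part * rep(model@pi, each = nrow(part))
  siteL <- rowSums(w)
  if (any(siteL <= 0) || any(!is.finite(siteL)))
    stop("non-finite site likelihood")
  post <- w / siteL
  colnames(post) <- .AA1
  new("AncestralPosterior", prob = post, logLik = sum(log(siteL)),
      siteLogLik = log(siteL))
}

#' @export
setMethod("show", "AncestralPosterior", function(object) {
  cat(sprintf("AncestralPosterior: %d sites, logLik %.3f\n",
              nrow(object@prob), object@logLik))
})

#' Maximum-a-posteriori ancestral sequence
#'
#' @param posterior an [AncestralPosterior-class].
#' @return one-letter character string (ties resolved towards the first
#'   amino acid in ARNDCQEGHILKMFPSTWYV order).
#' @export
mapSequence <- function(posterior) {
  paste(.AA1[apply(posterior@prob, 1L, which.max)], collapse = "")
}

#' Sample candidate ancestral sequences from the per-site posteriors
#'
#' Sites are drawn independently from their marginal root posteriors
#' (the 2000-candidate pool of the design protocol is the default scale);
#' the MAP sequence can be included as the first candidate. The log
#' posterior probability of every candidate is recorded. Reproducible
#' under a fixed seed.
#'
#' @param posterior an [AncestralPosterior-class].
#' @param n number of candidates (>= 1).
#' @param seed RNG seed.
#' @param includeMap include the MAP sequence (as candidate `"MAP"`).
#' @return A [CandidateSet-class] with exactly `n` candidates.
#' @export
sampleCandidates <- function(posterior, n = 2000L, seed = 1L,
                             includeMap = TRUE) {
  if (n < 1L) stop("at least one candidate must be requested")
  P <- posterior@prob
  S <- nrow(P)
  nSample <- n - as.integer(includeMap)
  draws <- .withSeed(seed, {
    vapply(seq_len(S), function(s)
      sample.int(20L, nSample, replace = TRUE, prob = P[s, ]),
      integer(nSample))
  })
  if (nSample == 1L) draws <- matrix(draws, nrow = 1L)
  logP <- log(pmax(P, .Machine$double.xmin))
  seqs <- character(0); lp <- numeric(0)
  if (nSample > 0L) {
    seqs <- apply(draws, 1L, function(i) paste(.AA1[i], collapse = ""))
    lp <- vapply(seq_len(nSample), function(r)
      sum(logP[cbind(seq_len(S), draws[r, ])]), numeric(1))
  }
  cand <- data.frame(id = sprintf("cand%04d", seq_len(nSample)),
                     sequence = seqs, logPosterior = lp,
                     provenance = "sampled", stringsAsFactors = FALSE)
  if (includeMap) {
    mapIdx <- apply(P, 1L, which.max)
    mapSeq <- paste(.AA1[mapIdx], collapse = "")
    cand <- rbind(data.frame(id = "MAP", sequence = mapSeq,
                             logPosterior = sum(logP[cbind(seq_len(S),
                                                           mapIdx)]),
                             provenance = "MAP", stringsAsFactors = FALSE),
                  cand)
  }
  new("CandidateSet", candidates = cand, seed = as.integer(seed))
}

#' @export
setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet: %d candidates (%s MAP), seed %d\n",
              nrow(object@candidates),
              if (any(object@candidates$provenance == "MAP")) "with"
              else "no", object@seed))
})

#' @rdname sampleCandidates
#' @param x a [CandidateSet-class].
#' @export
candidates <- function(x) x@candidates
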