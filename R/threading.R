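# Coarse-grained threading: map a candidate sequence onto a fixed
# backbone, score it with a documented contact/burial/clash/cavity
# energy, and select designs.

# Fauchere-Pliska octanol hydrophobicity scale (Gly = 0 by the scale's
# convention); used for the burial term and to derive the additive
# contact potential.
.HYDROPHOBICITY <- c(A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
                     Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
                     L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
                     S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22)

#' Pairwise contact potential
#'
#' A knowledge-based-style 20 x 20 contact matrix of the additive form
#' e(a, b) = -w (h_a + h_b), with h the Fauchere-Pliska octanol
#' hydrophobicity. Additive hydrophobicity terms are the dominant
#' component of statistical contact potentials, and the form keeps the
#' scale transparent; favourable (negative) energies reward hydrophobic
#' contacts. Symmetric by construction.
#'
#' @param weight scale factor w.
#' @return 20 x 20 numeric matrix, dimnames ARNDCQEGHILKMFPSTWYV.
#' @export
contactMatrix <- function(weight = 0.3) {
  h <- .HYDROPHOBICITY[.AA1]
  M <- -weight * outer(h, h, "+")
  dimnames(M) <- list(.AA1, .AA1)
  M
}

#' Default scoring weights
#'
#' @return named numeric: contact 1, burial 1, clash 10, cavity 0.05.
#' @export
defaultWeights <- function() c(contact = 1, burial = 1, clash = 10,
                               cavity = 0.05)

# Pseudo-C-beta positions: 1.5 A from CA along the bisector pointing away
# from the two chain neighbours; Gly (and degenerate geometry) uses CA.
.pseudoCbeta <- function(ca, types, chains = rep(1L, nrow(ca))) {
  n <- nrow(ca)
  cb <- ca
  for (i in seq_len(n)) {
    if (types[i] == "G") next
    v <- c(0, 0, 0)
    if (i > 1L && chains[i - 1L] == chains[i])
      v <- v + .unitOrZero(ca[i, ] - ca[i - 1L, ])
    if (i < n && chains[i + 1L] == chains[i])
      v <- v + .unitOrZero(ca[i, ] - ca[i + 1L, ])
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) next
    cb[i, ] <- ca[i, ] + 1.5 * v / nv
  }
  cb
}

.unitOrZero <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(0, 0, 0) else v / n
}

#' Thread a sequence onto a backbone
#'
#' Computes the per-residue environment features used by the coarse
#' energy: neighbour count (C-alpha atoms within 10 A, excluding self),
#' and the contact list of residue pairs whose pseudo-C-beta points
#' (1.5 A from CA along the local bisector direction; glycine uses CA)
#' are within 8 A, excluding sequence neighbours (|i - j| < 2).
#'
#' @param backbone a [ProteinStructure-class] (C-alpha representation,
#'   e.g. from [realizeBackbone()]) or an n x 3 C-alpha matrix.
#' @param sequence one-letter sequence of length equal to the number of
#'   backbone residues.
#' @param chains optional per-residue chain/subunit labels; the
#'   sequence-neighbour exclusion (and the pseudo-C-beta local frame)
#'   applies within a chain only, so the three subunits of a symmetric
#'   assembly can be treated as separate chains.
#' @return list with `types`, `ca`, `cbeta`, `neighborCount`, `contacts`
#'   (data.frame `i`, `j`, `dist`), `caDist` (full C-alpha distance
#'   matrix) and `bonded` (logical matrix of excluded near-in-sequence
#'   pairs).
#' @export
threadSequence <- function(backbone, sequence, chains = NULL) {
  ca <- if (is(backbone, "ProteinStructure")) {
    a <- atoms(backbone)
    as.matrix(a[trimws(a$name) == "CA" & !a$het, c("x", "y", "z")])
  } else .asCoordMatrix(backbone)
  types <- .splitChars(sequence)
  .checkProteinString(sequence, "design sequence")
  if (length(types) != nrow(ca))
    stop("sequence length ", length(types), " does not match backbone (",
         nrow(ca), " residues)")
  if (is.null(chains)) chains <- rep(1L, nrow(ca))
  D <- as.matrix(stats::dist(ca))
  nc <- rowSums(D <= 10 & D > 0)
  cb <- .pseudoCbeta(ca, types, chains)
  Db <- as.matrix(stats::dist(cb))
  bonded <- abs(row(D) - col(D)) < 2L &
    outer(chains, chains, "==")
  sel <- which(Db <= 8 & !bonded & upper.tri(Db), arr.ind = TRUE)
  contacts <- data.frame(i = sel[, 1L], j = sel[, 2L],
                         dist = Db[sel])
  contacts <- contacts[order(contacts$i, contacts$j), , drop = FALSE]
  rownames(contacts) <- NULL
  list(types = types, ca = ca, cbeta = cb, neighborCount = as.integer(nc),
       contacts = contacts, caDist = D, bonded = bonded)
}

#' Score threaded features with the coarse energy
#'
#' Terms: `contact` = sum of contact-matrix entries over the contact
#' list; `burial` = minus the sum of hydrophobicity times neighbour count
#' (burying hydrophobic residues is favourable); `clash` = soft-sphere
#' sum of (4 - d)^2 over non-bonded C-alpha pairs closer than 4 A;
#' `cavity` = the supplied cavity volume. Total = weighted sum; lower is
#' better. Deterministic.
#'
#' @param features output of [threadSequence()].
#' @param weights named weights (see [defaultWeights()]).
#' @param cavityVolume cavity volume of the design, cubic Angstrom.
#' @param M contact matrix (see [contactMatrix()]).
#' @return An [EnergyBreakdown-class].
#' @export
scoreDesign <- function(features, weights = defaultWeights(),
                        cavityVolume = 0, M = contactMatrix()) {
  if (!all(is.finite(weights))) stop("non-finite weights")
  tp <- features$types
  if (any(!tp %in% .AA1)) stop("unknown residue type in sequence")
  cc <- features$contacts
  contact <- if (nrow(cc)) sum(M[cbind(tp[cc$i], tp[cc$j])]) else 0
  burial <- -sum(.HYDROPHOBICITY[tp] * features$neighborCount)
  D <- features$caDist
  bonded <- if (is.null(features$bonded))
    abs(row(D) - col(D)) < 2L else features$bonded
  ncl <- D < 4 & !bonded & upper.tri(D)
  clash <- sum((4 - D[ncl])^2)
  total <- unname(weights["contact"] * contact + weights["burial"] * burial +
                    weights["clash"] * clash +
                    weights["cavity"] * cavityVolume)
  new("EnergyBreakdown", contact = contact, burial = unname(burial),
      clash = clash, cavity = cavityVolume, weights = weights,
      total = total)
}

#' @export
setMethod("show", "EnergyBreakdown", function(object) {
  cat(sprintf(paste0("EnergyBreakdown: total %.3f (contact %.3f, burial ",
                     "%.3f, clash %.3f, cavity %.1f A^3)\n"),
              object@total, object@contact, object@burial, object@clash,
              object@cavity))
})

#' Rank scored designs and pick the selection triple
#'
#' Designs are sorted by total energy (ascending). Three selections are
#' named: the energy-best, the RMSD-best and the cavity-best design. Ties
#' are broken by the other two criteria lexicographically (in the order
#' energy, RMSD, cavity, skipping the primary one), then by candidate id,
#' so the result is a deterministic function of the design set regardless
#' of input order.
#'
#' @param designs data.frame with columns `id`, `total`, `rmsd`,
#'   `cavityVolume` (plus any others, carried through).
#' @return list with `table` (sorted) and `selections` (named character:
#'   `energy`, `rmsd`, `cavity`).
#' @export
rankAndSelect <- function(designs) {
  if (!nrow(designs)) stop("empty design set")
  need <- c("id", "total", "rmsd", "cavityVolume")
  if (!all(need %in% names(designs)))
    stop("design table lacks columns: ",
         paste(setdiff(need, names(designs)), collapse = ", "))
  pick <- function(primary, others) {
    o <- do.call(order, c(unname(designs[c(primary, others)]),
                          list(designs$id)))
    designs$id[o[1L]]
  }
  sel <- c(energy = pick("total", c("rmsd", "cavityVolume")),
           rmsd = pick("rmsd", c("total", "cavityVolume")),
           cavity = pick("cavityVolume", c("total", "rmsd")))
  tab <- designs[do.call(order, unname(designs[c("total", "rmsd",
                                                 "cavityVolume", "id")])), ,
                 drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, selections = sel)
}

#' Check the galactose-binding sequence motifs per repeat
#'
#' Searches each repeat for the HxDxH (His, any, Asp, any, His) and HPxGG
#' (His, Pro, any, Gly, Gly) patterns characteristic of the mussel-lectin
#' galactose binding sites.
#'
#' @param sequence full-chain one-letter sequence.
#' @param repeatMap data.frame mapping positions to repeats (columns
#'   `global`, `unit`; linker positions have unit 0), e.g. from
#'   [concatenateWithLinkers()]; or a list of per-repeat index vectors.
#' @return data.frame with one row per repeat: `repeat_`, `HxDxH`,
#'   `HPxGG` (logical) and the 1-based offsets of the first match within
#'   the repeat (`NA` when absent).
#' @export
motifCheck <- function(sequence, repeatMap) {
  idxList <- if (is.data.frame(repeatMap)) {
    units <- sort(unique(repeatMap$unit[repeatMap$unit > 0L]))
    lapply(units, function(u) repeatMap$global[repeatMap$unit == u])
  } else repeatMap
  res <- lapply(seq_along(idxList), function(k) {
    sub <- paste(.splitChars(sequence)[idxList[[k]]], collapse = "")
    m1 <- regexpr("H.D.H", sub)
    m2 <- regexpr("HP.GG", sub)
    data.frame(repeat_ = LETTERS[k],
               HxDxH = m1 > 0, HxDxH_at = ifelse(m1 > 0, m1, NA),
               HPxGG = m2 > 0, HPxGG_at = ifelse(m2 > 0, m2, NA))
  })
  do.call(rbind, res)
}
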