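# Repeat extraction, C3 axis fitting, exact symmetrisation, linker
# concatenation and donor-linker grafting.

#' Extract the three repeats of a beta-trefoil
#'
#' @param x a [ProteinStructure-class].
#' @param repeatDef repeat boundaries: a data.frame with columns `start`,
#'   `end` and optionally `chain` (three rows), or a list of three
#'   `c(start, end)` vectors. All three ranges must resolve to complete
#'   C-alpha traces of the same length.
#' @param chain default chain used when `repeatDef` has no chain column.
#' @return named list (`A`, `B`, `C`) of trace data.frames, each with an
#'   attached one-letter `seq` attribute.
#' @export
extractRepeats <- function(x, repeatDef, chain = NULL) {
  if (is.list(repeatDef) && !is.data.frame(repeatDef))
    repeatDef <- data.frame(start = vapply(repeatDef, `[`, 0, 1L),
                            end = vapply(repeatDef, `[`, 0, 2L))
  if (nrow(repeatDef) != 3L) stop("repeatDef must define three ranges")
  if (is.null(repeatDef$chain)) {
    if (is.null(chain)) chain <- x@atoms$chain[!x@atoms$het][1L]
    repeatDef$chain <- chain
  }
  out <- vector("list", 3L)
  fullseq <- list()
  for (i in 1:3) {
    tr <- caTrace(x, repeatDef$chain[i],
                  c(repeatDef$start[i], repeatDef$end[i]))
    miss <- attr(tr, "missing")
    if (length(miss))
      stop("repeat ", LETTERS[i], " has residues without CA: ",
           paste(miss, collapse = ", "))
    sq <- extractSequence(x, repeatDef$chain[i])
    resno <- attr(sq, "resno")
    pick <- match(tr$resseq, resno)
    attr(tr, "seq") <- paste(.splitChars(as.character(sq))[pick],
                             collapse = "")
    out[[i]] <- tr
  }
  L <- vapply(out, nrow, 0L)
  if (length(unique(L)) != 1L)
    stop("repeat ranges have unequal lengths: ", paste(L, collapse = "/"))
  names(out) <- c("A", "B", "C")
  out
}

#' Fit the (pseudo-)threefold axis of three repeats
#'
#' The rotations A to B and B to C are estimated by Kabsch superposition,
#' averaged as quaternions (sign-aligned), and the axis of the mean
#' rotation is returned. The reported angle is the pre-projection mean of
#' the two rotation angles; downstream symmetrisation always uses the
#' exact 120 degrees about this axis. The axis passes through the grand
#' centroid of the three repeats (the centroid of a C3 orbit lies on the
#' axis).
#'
#' @param repeats list of three paired coordinate matrices or trace
#'   data.frames (equal length, residue-paired by position).
#' @return A [SymmetryAxis-class].
#' @export
fitC3Axis <- function(repeats) {
  m <- lapply(repeats, .asCoordMatrix)
  if (length(m) != 3L) stop("three repeats are required")
  f1 <- kabsch(m[[1]], m[[2]])
  f2 <- kabsch(m[[2]], m[[3]])
  q1 <- .quatFromRotation(f1@rotation)
  q2 <- .quatFromRotation(f2@rotation)
  if (sum(q1 * q2) < 0) q2 <- -q2
  qm <- (q1 + q2) / 2
  qm <- qm / sqrt(sum(qm^2))
  ang <- function(q) 2 * atan2(sqrt(sum(q[2:4]^2)), q[1]) * 180 / pi
  meanAngle <- mean(c(ang(q1), ang(q2)))
  if (abs(meanAngle - 120) > 40)
    stop(sprintf(paste0("mean repeat-to-repeat rotation is %.1f degrees; ",
                        "not a threefold arrangement"), meanAngle))
  dir <- .unit(qm[2:4])
  centre <- colMeans(rbind(m[[1]], m[[2]], m[[3]]))
  new("SymmetryAxis", direction = dir, point = as.numeric(centre),
      angle = meanAngle)
}

#' @export
setMethod("show", "SymmetryAxis", function(object) {
  cat(sprintf(
    "SymmetryAxis: direction (%.4f, %.4f, %.4f), angle %.3f deg\n",
    object@direction[1], object@direction[2], object@direction[3],
    object@angle))
})

# Coordinates of the unit rotated by k * 360/n degrees about the axis.
.rotateUnit <- function(coords, axis, k, n) {
  R <- .rotationAbout(axis@direction, k * 2 * pi / n)
  p <- axis@point
  sweep(sweep(coords, 2L, p) %*% t(R), 2L, -p)
}

# Packing objective between symmetry mates: soft-sphere clash (CA pairs
# closer than 4 A) minus a contact reward (pairs between 4.5 and 8 A).
.packObjective <- function(unitCA, axis, n = 3L) {
  a <- unitCA
  b <- .rotateUnit(unitCA, axis, 1L, n)       # all interfaces equivalent
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2 +
              outer(a[, 3], b[, 3], "-")^2)
  clash <- sum(pmax(0, 4 - d)^2)
  contacts <- sum(d >= 4.5 & d <= 8)
  list(value = n * (10 * clash - contacts), minDist = min(d))
}

.unitCA <- function(unit) {
  ca <- unit[trimws(unit$name) == "CA", , drop = FALSE]
  as.matrix(ca[, c("x", "y", "z")])
}

#' Build an exactly C3-symmetric backbone from one repeat
#'
#' Places `n` copies of the template repeat at exact multiples of 360/n
#' degrees about the axis. With `rigidSearch = TRUE` the template's spin
#' about the axis and its axial and radial offsets are optimised first by
#' a staged cyclic search (spin over \[0, 120) degrees in 1-degree steps,
#' offsets over +/-3 A in 0.25 A steps) against a coarse packing
#' objective (soft-sphere clash minus interface contacts).
#'
#' @param template repeat template: a trace data.frame from [caTrace()]
#'   or [extractRepeats()], a unit table (columns `resno`, `resname`,
#'   `name`, `x`, `y`, `z`), or a [ProteinStructure-class] (first chain).
#' @param axis a [SymmetryAxis-class]; its angle may be the fitted
#'   pseudo-symmetric value, the construction always uses exactly 120
#'   degrees (2 pi / n).
#' @param n symmetry order.
#' @param rigidSearch optimise template placement before symmetrising.
#' @return A [SymmetricBackbone-class].
#' @export
symmetrize <- function(template, axis, n = 3L, rigidSearch = FALSE) {
  unit <- .asUnitTable(template)
  n <- as.integer(n)
  if (rigidSearch) {
    unit <- .rigidSearchUnit(unit, axis, n)
  }
  ob <- .packObjective(.unitCA(unit), axis, n)
  if (ob$minDist < 2.5)
    stop(sprintf(paste0("unresolvable steric clash: interface CA-CA ",
                        "distance %.2f A at optimum"), ob$minDist))
  new("SymmetricBackbone", unit = unit, axis = axis, order = n,
      objective = ob$value)
}

.asUnitTable <- function(template) {
  if (is(template, "ProteinStructure")) {
    a <- template@atoms
    a <- a[!a$het & trimws(a$name) %in% c("N", "CA", "C", "O"), ,
           drop = FALSE]
    a <- a[a$chain == a$chain[1L], , drop = FALSE]
    return(data.frame(resno = a$resseq, resname = a$resname,
                      name = trimws(a$name), x = a$x, y = a$y, z = a$z,
                      provenance = "template", stringsAsFactors = FALSE))
  }
  if (is.data.frame(template)) {
    if (all(c("resno", "name") %in% names(template))) {
      template$provenance <- if (is.null(template$provenance))
        "template" else template$provenance
      return(template[, c("resno", "resname", "name", "x", "y", "z",
                          "provenance")])
    }
    if (all(c("resseq", "x", "y", "z") %in% names(template))) {
      sq <- attr(template, "seq")
      resname <- if (!is.null(sq)) .AA3FROM1[.splitChars(sq)] else
        rep("GLY", nrow(template))
      return(data.frame(resno = seq_len(nrow(template)), resname = resname,
                        name = "CA", x = template$x, y = template$y,
                        z = template$z, provenance = "template",
                        stringsAsFactors = FALSE))
    }
  }
  stop("unsupported template representation")
}

.rigidSearchUnit <- function(unit, axis, n) {
  xyz <- as.matrix(unit[, c("x", "y", "z")])
  dirz <- axis@direction; p0 <- axis@point
  centroid <- colMeans(xyz)
  radial <- centroid - p0
  radial <- radial - sum(radial * dirz) * dirz
  radial <- if (sqrt(sum(radial^2)) < 1e-9) c(1, 0, 0) else .unit(radial)
  place <- function(spin, dz, dr) {
    R <- .rotationAbout(dirz, spin * pi / 180)
    m <- sweep(sweep(xyz, 2L, p0) %*% t(R), 2L, -p0)
    sweep(m, 2L, -(dz * dirz + dr * radial))
  }
  val <- function(spin, dz, dr) {
    u <- unit; m <- place(spin, dz, dr)
    ca <- m[trimws(unit$name) == "CA", , drop = FALSE]
    .packObjective(ca, axis, n)$value
  }
  cur <- c(spin = 0, dz = 0, dr = 0)
  best <- val(cur[1], cur[2], cur[3])
  for (cycle in 1:2) {
    for (spin in seq(0, 119, by = 1)) {
      v <- val(spin, cur[2], cur[3])
      if (v < best) { best <- v; cur[1] <- spin }
    }
    for (dz in seq(-3, 3, by = 0.25)) {
      v <- val(cur[1], dz, cur[3])
      if (v < best) { best <- v; cur[2] <- dz }
    }
    for (dr in seq(-3, 3, by = 0.25)) {
      v <- val(cur[1], cur[2], dr)
      if (v < best) { best <- v; cur[3] <- dr }
    }
  }
  m <- place(cur[1], cur[2], cur[3])
  unit$x <- m[, 1]; unit$y <- m[, 2]; unit$z <- m[, 3]
  unit
}

#' @export
setMethod("show", "SymmetricBackbone", function(object) {
  cat(sprintf(
    "SymmetricBackbone: C%d, unit of %d residues (%d donor), objective %s\n",
    object@order, length(unique(object@unit$resno)),
    length(unique(object@unit$resno[object@unit$provenance == "donor"])),
    if (is.na(object@objective)) "NA" else sprintf("%.2f", object@objective)))
})

#' Subunit coordinates of a symmetric backbone
#'
#' @param backbone a [SymmetricBackbone-class].
#' @param what `"CA"` for C-alpha only or `"all"` atoms of the unit.
#' @return list of n coordinate matrices, one per subunit.
#' @export
subunitCoords <- function(backbone, what = c("CA", "all")) {
  what <- match.arg(what)
  u <- backbone@unit
  m <- if (what == "CA") .unitCA(u) else as.matrix(u[, c("x", "y", "z")])
  lapply(seq_len(backbone@order) - 1L, function(k)
    .rotateUnit(m, backbone@axis, k, backbone@order))
}

#' Realise a symmetric backbone as a single-chain structure
#'
#' Subunits are laid down in rotation order; at each of the n-1 chain
#' junctions `linkerLen` linker residues are inserted with coordinates
#' interpolated between the flanking C-alpha positions (they can be
#' regularised afterwards with [regularizeBackbone()]). Residues are
#' renumbered 1..total.
#'
#' @param backbone a [SymmetricBackbone-class].
#' @param linkerLen number of linker residues per junction (0 for none).
#' @param linkerSeq one-letter sequence of the inserted linker (recycled
#'   to `linkerLen`).
#' @return A [ProteinStructure-class] (C-alpha representation) with a
#'   `map` entry in `metadata`: data.frame `global`, `subunit` (0 =
#'   linker), `local`, `provenance`.
#' @export
realizeBackbone <- function(backbone, linkerLen = 1L, linkerSeq = "G") {
  subs <- subunitCoords(backbone, "CA")
  u <- backbone@unit
  ca <- u[trimws(u$name) == "CA", , drop = FALSE]
  L <- nrow(ca)
  n <- backbone@order
  lseq <- .splitChars(paste(rep(strsplit(linkerSeq, "")[[1]],
                                length.out = max(linkerLen, 1L)),
                            collapse = ""))[seq_len(linkerLen)]
  coords <- NULL; resname <- character(0)
  map <- data.frame(global = integer(0), subunit = integer(0),
                    local = integer(0), provenance = character(0))
  for (k in seq_len(n)) {
    coords <- rbind(coords, subs[[k]])
    resname <- c(resname, ca$resname)
    map <- rbind(map, data.frame(global = NA_integer_, subunit = k,
                                 local = seq_len(L),
                                 provenance = ca$provenance))
    if (k < n && linkerLen > 0L) {
      a <- subs[[k]][L, ]; b <- subs[[k + 1L]][1L, ]
      frac <- seq_len(linkerLen) / (linkerLen + 1L)
      li <- t(vapply(frac, function(f) a + f * (b - a), numeric(3)))
      coords <- rbind(coords, li)
      resname <- c(resname, unname(.AA3FROM1[lseq]))
      map <- rbind(map, data.frame(global = NA_integer_, subunit = 0L,
                                   local = seq_len(linkerLen),
                                   provenance = "linker"))
    }
  }
  map$global <- seq_len(nrow(map))
  .structureFromCA(coords, resname = resname, id = "symmetric_backbone",
                   metadata = list(map = map, axis = backbone@axis))
}

#' Concatenate a repeat sequence into a full-chain design
#'
#' Two junction schemes are supported: single glycine residues at the
#' junctions (`"singleG"`; a 47-residue repeat gives the 143-residue
#' chain with glycines at 48 and 96) and Gly-Asp-Gly tripeptide linkers
#' (`"GDG"`; the same repeat gives 147 residues with linkers at 48-50 and
#' 97-99). An arbitrary `linkerSeq` (possibly empty) may be given
#' instead.
#'
#' @param repeatSeq one-letter repeat sequence (length L).
#' @param linkerSeq linker inserted at each of the n-1 junctions; or one
#'   of the scheme names `"singleG"` (= `"G"`) / `"GDG"`.
#' @param n number of repeats.
#' @return list with `sequence`, `length`, `map` (data.frame `global`,
#'   `unit` (0 for linker positions), `local`) and `scheme`.
#' @export
concatenateWithLinkers <- function(repeatSeq, linkerSeq = "singleG", n = 3L) {
  scheme <- linkerSeq
  if (identical(linkerSeq, "singleG")) linkerSeq <- "G"
  else if (identical(linkerSeq, "GDG")) linkerSeq <- "GDG"
  else scheme <- if (nzchar(linkerSeq)) "custom" else "none"
  .checkProteinString(repeatSeq, "repeat sequence")
  if (nzchar(linkerSeq)) .checkProteinString(linkerSeq, "linker sequence")
  L <- nchar(repeatSeq); nl <- nchar(linkerSeq)
  pieces <- character(0)
  map <- data.frame(global = integer(0), unit = integer(0),
                    local = integer(0))
  for (k in seq_len(n)) {
    pieces <- c(pieces, repeatSeq)
    map <- rbind(map, data.frame(global = NA, unit = k, local = seq_len(L)))
    if (k < n && nl > 0L) {
      pieces <- c(pieces, linkerSeq)
      map <- rbind(map, data.frame(global = NA, unit = 0L,
                                   local = seq_len(nl)))
    }
  }
  seqfull <- paste(pieces, collapse = "")
  map$global <- seq_len(nchar(seqfull))
  list(sequence = seqfull, length = nchar(seqfull), map = map,
       scheme = scheme)
}

#' Graft a donor linker segment into each junction
#'
#' Replaces the last `k` residues of the repeat unit with a donor segment
#' (geometry and sequence), after superposing the donor anchors (three
#' residues on each side of the donor range) onto the corresponding host
#' anchors (the three residues preceding the replaced segment and the
#' first three residues of the next symmetry mate). Because the backbone
#' stores a single unit, the same graft appears in all three junctions
#' and exact C3 symmetry is preserved by construction. Grafted residues
#' carry `"donor"` provenance.
#'
#' @param backbone a [SymmetricBackbone-class].
#' @param donor donor [ProteinStructure-class].
#' @param donorRange `c(start, end)` residue numbers of the donor segment
#'   (length k, in 6 or 9).
#' @param donorChain donor chain (default: first chain).
#' @param anchorRmsdMax reject the graft when the anchor superposition
#'   RMSD exceeds this value (Angstrom).
#' @return the modified [SymmetricBackbone-class].
#' @export
graftLinker <- function(backbone, donor, donorRange, donorChain = NULL,
                        anchorRmsdMax = 1.5) {
  k <- donorRange[2L] - donorRange[1L] + 1L
  if (!k %in% c(6L, 9L))
    stop("donor segment must be 6 or 9 residues, got ", k)
  if (is.null(donorChain))
    donorChain <- donor@atoms$chain[!donor@atoms$het][1L]
  dtr <- caTrace(donor, donorChain)
  pos <- match(seq(donorRange[1L], donorRange[2L]), dtr$resseq)
  pre <- match(seq(donorRange[1L] - 3L, donorRange[1L] - 1L), dtr$resseq)
  post <- match(seq(donorRange[2L] + 1L, donorRange[2L] + 3L), dtr$resseq)
  if (anyNA(c(pos, pre, post)))
    stop("donor range or its 3-residue anchors missing from donor chain")
  dseg <- as.matrix(dtr[pos, c("x", "y", "z")])
  danch <- as.matrix(dtr[c(pre, post), c("x", "y", "z")])
  dsq <- extractSequence(donor, donorChain)
  dres <- .AA3FROM1[.splitChars(as.character(dsq))[match(dtr$resseq[pos],
                                                  attr(dsq, "resno"))]]

  u <- backbone@unit
  ca <- u[trimws(u$name) == "CA", , drop = FALSE]
  L <- nrow(ca)
  if (k + 3L > L) stop("repeat unit too short for a ", k, "-residue graft")
  hostIdx <- seq(L - k + 1L, L)
  hostPre <- seq(L - k - 2L, L - k)
  nextSub <- .rotateUnit(.unitCA(u), backbone@axis, 1L, backbone@order)
  hanch <- rbind(as.matrix(ca[hostPre, c("x", "y", "z")]),
                 nextSub[1:3, , drop = FALSE])
  fit <- kabsch(danch, hanch)
  if (fit@rmsd > anchorRmsdMax)
    stop(sprintf("anchor superposition RMSD %.2f A exceeds %.2f A",
                 fit@rmsd, anchorRmsdMax))
  newseg <- applyTransform(dseg, fit)

  # replace the CA rows of the grafted residues (unit is CA-level here)
  if (!all(trimws(u$name) == "CA"))
    u <- u[trimws(u$name) == "CA", , drop = FALSE]  # graft is CA-level
  u$x[hostIdx] <- newseg[, 1]
  u$y[hostIdx] <- newseg[, 2]
  u$z[hostIdx] <- newseg[, 3]
  u$resname[hostIdx] <- unname(dres)
  u$provenance[hostIdx] <- "donor"
  out <- backbone
  out@unit <- u
  out@linker <- c(backbone@linker,
                  list(graft = list(k = k, donor = donor@id,
                                    donorRange = donorRange,
                                    anchorRmsd = fit@rmsd)))
  validObject(out)
  out
}

#' Regularise backbone geometry
#'
#' Gradient descent on harmonic bond-length restraints (consecutive
#' C-alpha spacing 3.8 A) plus a soft-sphere clash term between
#' non-bonded pairs closer than 4 A. Steps are accepted only when the
#' objective does not increase (backtracking line search), so the
#' objective is non-increasing over iterations. For a
#' [SymmetricBackbone-class] the minimisation runs on the realised chain
#' and exact symmetry is re-imposed afterwards from the first subunit.
#'
#' @param x an n x 3 C-alpha coordinate matrix, or a
#'   [SymmetricBackbone-class].
#' @param weights named weights for the `bond` and `clash` terms.
#' @param maxSteps maximum descent steps.
#' @param bondLength ideal consecutive C-alpha distance, Angstrom.
#' @param ... passed to methods.
#' @return same type as `x`; matrices carry an `objective` attribute with
#'   the per-iteration objective values.
#' @export
regularizeBackbone <- function(x, weights = c(bond = 1, clash = 1),
                               maxSteps = 200L, bondLength = 3.8, ...) {
  if (is(x, "SymmetricBackbone")) {
    real <- realizeBackbone(x, ...)
    m <- as.matrix(atoms(real)[, c("x", "y", "z")])
    m2 <- regularizeBackbone(m, weights, maxSteps, bondLength)
    map <- real@metadata$map
    first <- map$subunit == 1L
    u <- x@unit[trimws(x@unit$name) == "CA", , drop = FALSE]
    u$x <- m2[first, 1]; u$y <- m2[first, 2]; u$z <- m2[first, 3]
    out <- x; out@unit <- u
    return(out)
  }
  m <- .asCoordMatrix(x)
  n <- nrow(m)
  objGrad <- function(p) {
    g <- matrix(0, n, 3L)
    dv <- p[-1L, , drop = FALSE] - p[-n, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    obj <- weights["bond"] * sum((d - bondLength)^2)
    coef <- 2 * weights["bond"] * (d - bondLength) / pmax(d, 1e-9)
    g[-n, ] <- g[-n, ] - coef * dv
    g[-1L, ] <- g[-1L, ] + coef * dv
    # clash: non-bonded pairs (|i-j| >= 2) closer than 4 A
    D <- as.matrix(stats::dist(p))
    off <- abs(row(D) - col(D)) >= 2L & D < 4 & upper.tri(D)
    if (any(off)) {
      idx <- which(off, arr.ind = TRUE)
      dd <- D[off]
      obj <- obj + weights["clash"] * sum((4 - dd)^2)
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1L]; j <- idx[r, 2L]
        v <- p[i, ] - p[j, ]
        cf <- -2 * weights["clash"] * (4 - dd[r]) / max(dd[r], 1e-9)
        g[i, ] <- g[i, ] + cf * v
        g[j, ] <- g[j, ] - cf * v
      }
    }
    list(obj = obj, grad = g)
  }
  step <- 0.05
  og <- objGrad(m)
  trace <- og$obj
  for (it in seq_len(maxSteps)) {
    if (!is.finite(og$obj)) stop("non-finite regularisation objective")
    if (og$obj < 1e-12) break
    cand <- m - step * og$grad
    ogc <- objGrad(cand)
    if (ogc$obj <= og$obj) {
      m <- cand; og <- ogc; step <- step * 1.2
    } else {
      step <- step / 2
      if (step < 1e-8) break
    }
    trace <- c(trace, og$obj)
  }
  attr(m, "objective") <- trace
  m
}
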