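# Dual-probe grid detection of internal cavities.

# Per-element van der Waals radii (Angstrom).
.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
          SE = 1.90)

# Coarse per-residue-type radii for C-alpha-level design models, derived
# from standard mean residue volumes via r = (3V / 4 pi)^(1/3).
.RESVOL <- c(G = 60, A = 89, S = 89, C = 109, D = 111, P = 113, N = 114,
             T = 116, E = 138, V = 140, Q = 144, H = 153, M = 163,
             I = 167, L = 167, K = 169, R = 174, F = 190, Y = 194,
             W = 228)
.residueRadius <- function(types) (3 * .RESVOL[types] / (4 * pi))^(1 / 3)

# FFT-based binary dilation of a 3D logical array by a Euclidean ball.
.dilateBall <- function(mask, radiusVox) {
  dm <- dim(mask)
  ax <- function(n) { i <- 0:(n - 1L); pmin(i, n - i) }
  dx <- ax(dm[1L]); dy <- ax(dm[2L]); dz <- ax(dm[3L])
  d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  kern <- d2 <= radiusVox^2 + 1e-9
  conv <- Re(fft(fft(array(as.numeric(mask), dm)) * fft(array(as.numeric(kern), dm)),
                 inverse = TRUE)) / prod(dm)
  conv > 0.5
}

# 6-connected flood fill of `free` starting from the box faces (or given
# seeds), by iterative shift-dilation.
.floodFill <- function(free, seeds = NULL) {
  dm <- dim(free)
  vis <- array(FALSE, dm)
  if (is.null(seeds)) {
    vis[1L, , ] <- free[1L, , ]; vis[dm[1L], , ] <- free[dm[1L], , ]
    vis[, 1L, ] <- vis[, 1L, ] | free[, 1L, ]
    vis[, dm[2L], ] <- vis[, dm[2L], ] | free[, dm[2L], ]
    vis[, , 1L] <- vis[, , 1L] | free[, , 1L]
    vis[, , dm[3L]] <- vis[, , dm[3L]] | free[, , dm[3L]]
  } else vis <- seeds & free
  repeat {
    grown <- vis
    grown[-1L, , ] <- grown[-1L, , ] | vis[-dm[1L], , ]
    grown[-dm[1L], , ] <- grown[-dm[1L], , ] | vis[-1L, , ]
    grown[, -1L, ] <- grown[, -1L, ] | vis[, -dm[2L], ]
    grown[, -dm[2L], ] <- grown[, -dm[2L], ] | vis[, -1L, ]
    grown[, , -1L] <- grown[, , -1L] | vis[, , -dm[3L]]
    grown[, , -dm[3L]] <- grown[, , -dm[3L]] | vis[, , -1L]
    grown <- grown & free
    if (!any(grown & !vis)) break
    vis <- grown
  }
  vis
}

# Mark voxels within (radius_i) of any atom centre.
.occupancyMask <- function(centers, radii, origin, dm, spacing) {
  mask <- array(FALSE, dm)
  for (rv in unique(round(radii, 6))) {
    sub <- which(abs(radii - rv) < 1e-6)
    span <- ceiling(rv / spacing)
    off <- expand.grid(i = -span:span, j = -span:span, k = -span:span)
    keep <- (off$i^2 + off$j^2 + off$k^2) * spacing^2 <= (rv + spacing)^2
    off <- off[keep, , drop = FALSE]
    offd2 <- cbind(off$i, off$j, off$k)
    for (a in sub) {
      c0 <- (centers[a, ] - origin) / spacing
      base <- round(c0)
      vox <- sweep(offd2, 2L, -base)           # base + offsets
      cent <- sweep(vox, 2L, c0)               # voxel - centre, in voxels
      d2 <- rowSums(cent^2) * spacing^2
      ok <- d2 <= rv^2 &
        vox[, 1L] >= 0 & vox[, 1L] < dm[1L] &
        vox[, 2L] >= 0 & vox[, 2L] < dm[2L] &
        vox[, 3L] >= 0 & vox[, 3L] < dm[3L]
      if (any(ok)) {
        v <- vox[ok, , drop = FALSE] + 1L
        mask[cbind(v[, 1L], v[, 2L], v[, 3L])] <- TRUE
      }
    }
  }
  mask
}

# Label 6-connected components among the given voxel linear indices.
.components6 <- function(idx, dm) {
  if (!length(idx)) return(integer(0))
  nx <- dm[1L]; ny <- dm[2L]
  key <- sort(idx)
  pos <- seq_along(key)
  lab <- integer(length(key))
  nb <- function(i) {
    x <- (i - 1L) %% nx + 1L
    y <- ((i - 1L) %/% nx) %% ny + 1L
    out <- c(if (x > 1L) i - 1L, if (x < nx) i + 1L,
             if (y > 1L) i - nx, if (y < ny) i + nx,
             i - nx * ny, i + nx * ny)
    out[out >= 1L & out <= prod(dm)]
  }
  cur <- 0L
  for (s in pos) {
    if (lab[s]) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      hit <- match(nb(key[v]), key)
      hit <- hit[!is.na(hit)]
      hit <- hit[lab[hit] == 0L]
      if (length(hit)) { lab[hit] <- cur; queue <- c(queue, hit) }
    }
  }
  lab[match(idx, key)]
}

.cavityCore <- function(centers, radii, smallProbe, largeProbe, spacing,
                        minVolume) {
  if (smallProbe <= 0 || largeProbe <= 0 || spacing <= 0)
    stop("probes and spacing must be positive")
  if (!nrow(centers)) stop("no atoms supplied for cavity detection")
  margin <- 2 * largeProbe
  lo <- apply(centers, 2L, min) - max(radii) - margin
  hi <- apply(centers, 2L, max) + max(radii) + margin
  dm <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  protein <- .occupancyMask(centers, radii + smallProbe, lo, dm, spacing)
  blockedLarge <- .occupancyMask(centers, radii + largeProbe, lo, dm,
                                 spacing)
  outside <- .floodFill(!blockedLarge)
  swept <- .dilateBall(outside, largeProbe / spacing)
  bulk <- swept & !protein
  cavity <- !protein & !bulk
  idx <- which(cavity)
  lab <- .components6(idx, dm)
  comp <- data.frame(component = integer(0), nVoxels = integer(0),
                     volume = numeric(0), cx = numeric(0), cy = numeric(0),
                     cz = numeric(0))
  vox <- data.frame(component = integer(0), x = numeric(0), y = numeric(0),
                    z = numeric(0))
  if (length(idx)) {
    ix <- (idx - 1L) %% dm[1L]
    iy <- ((idx - 1L) %/% dm[1L]) %% dm[2L]
    iz <- (idx - 1L) %/% (dm[1L] * dm[2L])
    X <- lo[1L] + ix * spacing
    Y <- lo[2L] + iy * spacing
    Z <- lo[3L] + iz * spacing
    keepId <- 0L
    for (cid in sort(unique(lab))) {
      sel <- lab == cid
      volume <- sum(sel) * spacing^3
      if (volume < minVolume) next
      keepId <- keepId + 1L
      comp <- rbind(comp, data.frame(
        component = keepId, nVoxels = sum(sel), volume = volume,
        cx = mean(X[sel]), cy = mean(Y[sel]), cz = mean(Z[sel])))
      vox <- rbind(vox, data.frame(component = keepId, x = X[sel],
                                   y = Y[sel], z = Z[sel]))
    }
  }
  new("CavityResult", components = comp, voxels = vox, spacing = spacing,
      params = list(smallProbe = smallProbe, largeProbe = largeProbe,
                    minVolume = minVolume, gridDim = dm, origin = lo,
                    counts = c(protein = sum(protein), bulk = sum(bulk),
                               cavity = sum(cavity))))
}

#' Detect internal cavities with a dual-probe grid
#'
#' Voxels within (vdW radius + small probe) of any atom are protein;
#' the bulk solvent is the region swept by a large probe rolled from
#' outside the bounding box (flood fill of large-probe-accessible space
#' from the box faces, dilated by the large-probe radius); the remaining
#' voxels are cavity. Connected components (6-connectivity) smaller than
#' `minVolume` are discarded. Deterministic for fixed inputs.
#'
#' @param x a [ProteinStructure-class].
#' @param smallProbe small (solvent) probe radius, Angstrom.
#' @param largeProbe large probe radius, Angstrom.
#' @param spacing grid spacing, Angstrom.
#' @param minVolume minimum cavity volume kept, cubic Angstrom.
#' @param includeHet include HETATM (ligand) atoms; waters are always
#'   excluded.
#' @return A [CavityResult-class].
#' @examples
#' shell <- makeShell(innerRadius = 8)
#' detectCavities(shell)
#' @export
detectCavities <- function(x, smallProbe = 1.4, largeProbe = 4.0,
                           spacing = 0.6, minVolume = 5,
                           includeHet = FALSE) {
  a <- atoms(x)
  a <- a[a$resname != "HOH", , drop = FALSE]
  if (!includeHet) a <- a[!a$het, , drop = FALSE]
  if (!nrow(a)) stop("no atoms for cavity detection")
  el <- toupper(trimws(a$element))
  radii <- .VDW[el]
  radii[is.na(radii)] <- .VDW["C"]
  .cavityCore(as.matrix(a[, c("x", "y", "z")]), unname(radii), smallProbe,
              largeProbe, spacing, minVolume)
}

#' Total cavity volume of a C-alpha-level design model
#'
#' Runs the same dual-probe grid on the coarse representation, with
#' per-residue-type radii derived from mean residue volumes (the model
#' carries no side-chain atoms). The result feeds the cavity penalty of
#' [scoreDesign()] and the cavity-best selection.
#'
#' @param backbone a [ProteinStructure-class] C-alpha model, a
#'   [SymmetricBackbone-class] (realised with its linker scheme first),
#'   or an n x 3 C-alpha matrix.
#' @param sequence one-letter sequence assigning residue types (defaults
#'   to the model's residue names).
#' @inheritParams detectCavities
#' @return list with `volume` (total cubic Angstrom over retained
#'   cavities) and `result` (the [CavityResult-class]).
#' @export
cavityVolumeForDesign <- function(backbone, sequence = NULL,
                                  smallProbe = 1.4, largeProbe = 4.0,
                                  spacing = 0.6, minVolume = 5) {
  if (is(backbone, "SymmetricBackbone"))
    backbone <- realizeBackbone(backbone)
  if (is(backbone, "ProteinStructure")) {
    a <- atoms(backbone)
    a <- a[trimws(a$name) == "CA" & !a$het, , drop = FALSE]
    centers <- as.matrix(a[, c("x", "y", "z")])
    if (is.null(sequence)) {
      sequence <- paste(ifelse(is.na(.AA3[a$resname]), "G",
                               .AA3[a$resname]), collapse = "")
    }
  } else {
    centers <- .asCoordMatrix(backbone)
    if (is.null(sequence)) sequence <- strrep("G", nrow(centers))
  }
  types <- .splitChars(sequence)
  if (length(types) != nrow(centers))
    stop("sequence length does not match the number of residues")
  radii <- unname(.residueRadius(types))
  res <- .cavityCore(centers, radii, smallProbe, largeProbe, spacing,
                     minVolume)
  list(volume = sum(res@components$volume), result = res)
}

#' @export
setMethod("show", "CavityResult", function(object) {
  cat(sprintf("CavityResult: %d cavities, total volume %.1f A^3 (spacing %.2f A)\n",
              nrow(object@components), sum(object@components$volume),
              object@spacing))
})

#' Total cavity volume
#'
#' @param x a [CavityResult-class].
#' @return numeric, cubic Angstrom.
#' @export
cavityVolume <- function(x) sum(x@components$volume)
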