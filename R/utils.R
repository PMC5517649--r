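# Shared internal helpers.

# 3-letter -> 1-letter residue codes (selenomethionine handled by caller).
.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
          GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
          LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
          SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.AA3FROM1 <- stats::setNames(names(.AA3), unname(.AA3))

# Standard genetic code, DNA alphabet.
.GENETIC_CODE <- local({
  gc <- as.character(Biostrings::GENETIC_CODE)
  stats::setNames(gc, chartr("U", "T", names(Biostrings::GENETIC_CODE)))
})

.translate <- function(dna) {
  n <- nchar(dna)
  if (n == 0L) return("")
  codons <- substring(dna, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  paste(.GENETIC_CODE[codons], collapse = "")
}

.revcomp <- function(dna) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(dna, "")[[1]]), collapse = ""))
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

# Rotation matrix for `angle` (radians) about unit axis `n` (Rodrigues).
.rotationAbout <- function(n, angle) {
  n <- .unit(n)
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Quaternion (w, x, y, z) from a rotation matrix; w >= 0.
.quatFromRotation <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3L + 1L; k <- j %% 3L + 1L
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

.rotationFromQuat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

.checkProteinString <- function(seq, what = "sequence", allow = "") {
  bad <- gsub(paste0("[", paste0(.AA1, collapse = ""), allow, "]"), "", seq)
  if (nchar(bad))
    stop(what, " contains non-standard letters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  invisible(TRUE)
}

.splitChars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
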