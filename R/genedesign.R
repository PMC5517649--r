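# Backtranslation to an expression-ready gene: codon usage, restriction
# site control, self-annealing repair.

# Representative E. coli K-12 codon usage (relative fraction within each
# amino acid, rounded to 0.01 and renormalised). Users may supply their
# own table in the same layout.
.ECOLI_K12 <- local({
  txt <- c(
    "A GCG 0.36", "A GCC 0.27", "A GCA 0.21", "A GCT 0.16",
    "R CGC 0.40", "R CGT 0.38", "R CGG 0.10", "R CGA 0.06", "R AGA 0.04",
    "R AGG 0.02",
    "N AAC 0.55", "N AAT 0.45",
    "D GAT 0.63", "D GAC 0.37",
    "C TGC 0.55", "C TGT 0.45",
    "Q CAG 0.65", "Q CAA 0.35",
    "E GAA 0.68", "E GAG 0.32",
    "G GGC 0.40", "G GGT 0.34", "G GGG 0.15", "G GGA 0.11",
    "H CAT 0.57", "H CAC 0.43",
    "I ATT 0.51", "I ATC 0.42", "I ATA 0.07",
    "L CTG 0.50", "L TTA 0.13", "L TTG 0.13", "L CTC 0.10", "L CTT 0.10",
    "L CTA 0.04",
    "K AAA 0.74", "K AAG 0.26",
    "M ATG 1.00",
    "F TTT 0.57", "F TTC 0.43",
    "P CCG 0.52", "P CCA 0.19", "P CCT 0.16", "P CCC 0.13",
    "S AGC 0.28", "S TCT 0.15", "S TCC 0.15", "S AGT 0.15", "S TCG 0.15",
    "S TCA 0.12",
    "T ACC 0.43", "T ACG 0.27", "T ACT 0.17", "T ACA 0.13",
    "W TGG 1.00",
    "Y TAT 0.57", "Y TAC 0.43",
    "V GTG 0.37", "V GTT 0.26", "V GTC 0.22", "V GTA 0.15")
  f <- utils::read.table(text = paste(txt, collapse = "\n"),
                         col.names = c("aa", "codon", "freq"),
                         stringsAsFactors = FALSE)
  f
})

.ENZYMES <- c(NdeI = "CATATG", XhoI = "CTCGAG")

#' Codon usage table
#'
#' @param organism table label; `"ecoli_k12"` ships with the package.
#' @return data.frame with columns `aa` (one-letter), `codon`, `freq`;
#'   frequencies sum to 1 within each amino acid, codons sorted by
#'   decreasing frequency (ties alphabetical).
#' @export
codonUsageTable <- function(organism = "ecoli_k12") {
  if (!identical(organism, "ecoli_k12"))
    stop("unknown codon table: ", organism)
  f <- .ECOLI_K12
  f$freq <- stats::ave(f$freq, f$aa, FUN = function(x) x / sum(x))
  f[order(f$aa, -f$freq, f$codon), , drop = FALSE]
}

.checkCodonTable <- function(table) {
  if (!all(c("aa", "codon", "freq") %in% names(table)))
    stop("codon table needs aa, codon, freq columns")
  bad <- vapply(split(table$freq, table$aa), function(x)
    abs(sum(x) - 1) > 1e-9 || any(x < 0), logical(1))
  if (any(bad))
    stop("codon frequencies must be non-negative and sum to 1 per amino acid")
  if (!all(.AA1 %in% table$aa))
    stop("codon table must cover all 20 amino acids")
  if (any(.GENETIC_CODE[table$codon] != table$aa))
    stop("codon table codons disagree with the standard genetic code")
  invisible(TRUE)
}

#' Backtranslate a protein to a coding DNA sequence
#'
#' `mode = "max"` uses the highest-frequency codon per residue (ties by
#' alphabetical codon); `mode = "sample"` draws each codon from the table
#' frequencies under the seed. The translation round trip is exact by
#' construction and enforced by the class validity.
#'
#' @param protein one-letter protein sequence (standard 20 letters only).
#' @param table codon usage table (see [codonUsageTable()]).
#' @param mode `"max"` or `"sample"`.
#' @param seed RNG seed for `"sample"` mode.
#' @return A [GeneDesign-class].
#' @examples
#' backtranslate("MKT", codonUsageTable())
#' @export
backtranslate <- function(protein, table = codonUsageTable(),
                          mode = c("max", "sample"), seed = 1L) {
  mode <- match.arg(mode)
  .checkProteinString(protein, "protein")
  .checkCodonTable(table)
  aas <- .splitChars(protein)
  byAA <- split(table[, c("codon", "freq")], table$aa)
  codons <- if (mode == "max") {
    vapply(aas, function(a) {
      t <- byAA[[a]]
      t$codon[order(-t$freq, t$codon)][1L]
    }, character(1))
  } else {
    .withSeed(seed, vapply(aas, function(a) {
      t <- byAA[[a]]
      t$codon[sample.int(nrow(t), 1L, prob = t$freq)]
    }, character(1)))
  }
  new("GeneDesign", coding = paste(codons, collapse = ""),
      protein = protein, table = "ecoli_k12")
}

#' Scan a DNA sequence for restriction sites
#'
#' Reports all occurrences on the given strand and its reverse
#' complement, as 0-based positions on the forward strand. A palindromic
#' site is reported once per occurrence.
#'
#' @param dna DNA string (ACGT).
#' @param enzymes named character vector of recognition sequences
#'   (defaults to NdeI `CATATG` and XhoI `CTCGAG`).
#' @return data.frame with columns `enzyme`, `position` (0-based, forward
#'   strand), `strand`.
#' @export
scanSites <- function(dna, enzymes = .ENZYMES) {
  if (grepl("[^ACGT]", dna)) stop("DNA sequence must use A/C/G/T only")
  subj <- Biostrings::DNAString(dna)
  out <- data.frame(enzyme = character(0), position = integer(0),
                    strand = character(0))
  for (e in names(enzymes)) {
    site <- enzymes[[e]]
    fwd <- Biostrings::start(Biostrings::matchPattern(site, subj)) - 1L
    hits <- data.frame(enzyme = rep(e, length(fwd)), position = fwd,
                       strand = rep("+", length(fwd)))
    rcsite <- .revcomp(site)
    if (!identical(rcsite, site)) {
      rev <- Biostrings::start(Biostrings::matchPattern(rcsite, subj)) - 1L
      hits <- rbind(hits, data.frame(enzyme = rep(e, length(rev)),
                                     position = rev,
                                     strand = rep("-", length(rev))))
    }
    out <- rbind(out, hits)
  }
  out <- out[order(out$position, out$enzyme), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Synonymous codons of `codon`, ordered by decreasing table frequency.
.synonyms <- function(codon, table) {
  aa <- .GENETIC_CODE[[codon]]
  t <- table[table$aa == aa & table$codon != codon, , drop = FALSE]
  t$codon[order(-t$freq, t$codon)]
}

.applyCodon <- function(design, codonIndex, newCodon, reason) {
  s <- design@coding
  from <- substr(s, 3L * codonIndex - 2L, 3L * codonIndex)
  substr(s, 3L * codonIndex - 2L, 3L * codonIndex) <- newCodon
  design@coding <- s
  design@edits <- rbind(design@edits,
                        data.frame(codonIndex = codonIndex, from = from,
                                   to = newCodon, reason = reason))
  design
}

#' Remove internal restriction sites by silent mutation
#'
#' Every internal occurrence of the flanking enzymes' sites (either
#' strand) is broken by replacing one overlapping codon with its
#' highest-frequency synonymous alternative that removes the site.
#' Translation is unchanged; edits are logged.
#'
#' @param design a [GeneDesign-class].
#' @param enzymes named recognition sequences.
#' @param table codon usage table.
#' @return the repaired [GeneDesign-class].
#' @export
removeInternalSites <- function(design, enzymes = .ENZYMES,
                                table = codonUsageTable()) {
  for (pass in 1:50) {
    hits <- scanSites(design@coding, enzymes)
    if (!nrow(hits)) break
    h <- hits[1L, ]
    site <- enzymes[[h$enzyme]]
    cods <- seq(floor(h$position / 3) + 1L,
                ceiling((h$position + nchar(site)) / 3))
    cods <- cods[cods >= 1L & cods <= nchar(design@coding) / 3]
    fixed <- FALSE
    for (ci in cods) {
      cur <- substr(design@coding, 3L * ci - 2L, 3L * ci)
      for (alt in .synonyms(cur, table)) {
        cand <- .applyCodon(design, ci, alt, paste0("remove ", h$enzyme))
        span <- substr(cand@coding, max(1L, h$position - 4L),
                       h$position + nchar(site) + 5L)
        if (!grepl(site, span) && !grepl(.revcomp(site), span)) {
          design <- cand; fixed <- TRUE; break
        }
      }
      if (fixed) break
    }
    if (!fixed)
      stop("restriction site at position ", h$position,
           " cannot be removed by silent edits")
  }
  if (nrow(scanSites(design@coding, enzymes)))
    stop("internal restriction sites persist after the edit budget")
  validObject(design)
  design
}

# All pairs (i, j), i < j, of exact reverse-complement matches of length
# `stemMin` (0-based start positions); brute force over k-mers.
.invertedRepeats <- function(dna, stemMin = 10L) {
  n <- nchar(dna)
  if (n < 2L * stemMin) {
    return(data.frame(i = integer(0), j = integer(0)))
  }
  starts <- seq_len(n - stemMin + 1L)
  kmers <- substring(dna, starts, starts + stemMin - 1L)
  rc <- vapply(kmers, .revcomp, character(1), USE.NAMES = FALSE)
  idx <- split(starts, kmers)   # k-mers may recur; keep every position
  res <- list()
  for (r in seq_along(starts)) {
    js <- idx[[rc[r]]]
    if (is.null(js)) next
    js <- js[js > starts[r]]
    if (length(js))
      res[[length(res) + 1L]] <- data.frame(i = starts[r], j = js)
  }
  pairs <- if (length(res)) do.call(rbind, res) else
    data.frame(i = integer(0), j = integer(0))
  pairs$i <- pairs$i - 1L; pairs$j <- pairs$j - 1L   # 0-based
  pairs
}

#' Repair self-annealing segments by silent mutation
#'
#' Self-annealing is operationalised as an exact reverse-complement match
#' of length >= `stemMin` between two positions of the sequence (hairpin
#' stems and inverted repeats). Each match is broken by swapping a codon
#' overlapping the downstream copy to its next-most-frequent synonym,
#' iterating to a fixpoint. If synonymous options are exhausted the
#' residual matches are reported with a warning (not an error).
#' Restriction-site cleanliness is preserved: an edit that would create a
#' site of the given enzymes is rejected.
#'
#' @param design a [GeneDesign-class].
#' @param stemMin minimum stem length, nucleotides.
#' @param window reserved for hairpin/inverted-repeat classification in
#'   the report; detection itself considers all position pairs.
#' @param enzymes sites that edits must not create.
#' @param table codon usage table.
#' @return the repaired [GeneDesign-class]; unrepaired matches (if any)
#'   are stored in the `residual` slot.
#' @export
fixSelfAnnealing <- function(design, stemMin = 10L, window = 50L,
                             enzymes = .ENZYMES,
                             table = codonUsageTable()) {
  nCodon <- nchar(design@coding) / 3L
  tried <- new.env(parent = emptyenv())
  for (pass in seq_len(10L * nCodon)) {
    pairs <- .invertedRepeats(design@coding, stemMin)
    if (!nrow(pairs)) break
    p <- pairs[1L, ]
    before <- nrow(pairs)
    cods <- seq(floor(p$j / 3) + 1L, ceiling((p$j + stemMin) / 3))
    cods <- unique(c(cods, seq(floor(p$i / 3) + 1L,
                               ceiling((p$i + stemMin) / 3))))
    cods <- cods[cods >= 1L & cods <= nCodon]
    fixed <- FALSE
    for (ci in cods) {
      cur <- substr(design@coding, 3L * ci - 2L, 3L * ci)
      key <- paste(ci, cur)
      if (!is.null(tried[[key]])) next
      for (alt in .synonyms(cur, table)) {
        cand <- .applyCodon(design, ci, alt, "break self-annealing")
        if (nrow(scanSites(cand@coding, enzymes))) next
        if (nrow(.invertedRepeats(cand@coding, stemMin)) < before) {
          design <- cand; fixed <- TRUE; break
        }
      }
      if (fixed) break
      tried[[key]] <- TRUE
    }
    if (!fixed) {
      res <- pairs
      res$length <- stemMin
      design@residual <- res
      warning(nrow(pairs), " self-annealing segment(s) could not be ",
              "removed by silent edits")
      break
    }
  }
  validObject(design)
  design
}

#' Assemble the final construct with flanking restriction sites
#'
#' The NdeI site supplies the initiator ATG when the protein begins with
#' methionine (`CAT` + coding `ATG...`); otherwise the full `CATATG` is
#' prepended. A TAA stop codon and the XhoI site are appended.
#'
#' @param design a [GeneDesign-class] (run [removeInternalSites()] and
#'   [fixSelfAnnealing()] first).
#' @return list with `construct` (DNA string), `codingStart` (0-based),
#'   and `internalSites` (data.frame; empty for a clean design, the
#'   intended flanking occurrences are excluded).
#' @export
buildConstruct <- function(design) {
  coding <- design@coding
  five <- if (startsWith(coding, "ATG")) "CAT" else "CATATG"
  construct <- paste0(five, coding, "TAA", "CTCGAG")
  hits <- scanSites(construct, .ENZYMES)
  ndeAt <- if (identical(five, "CAT")) 0L else 0L
  xhoAt <- nchar(construct) - 6L
  internal <- hits[!(hits$enzyme == "NdeI" & hits$position == ndeAt) &
                     !(hits$enzyme == "XhoI" & hits$position == xhoAt), ,
                   drop = FALSE]
  list(construct = construct, codingStart = nchar(five),
       internalSites = internal)
}

#' @export
setMethod("show", "GeneDesign", function(object) {
  cat(sprintf("GeneDesign: %d bp coding %d residues, %d silent edit(s)%s\n",
              nchar(object@coding), nchar(object@protein),
              nrow(object@edits),
              if (nrow(object@residual))
                sprintf(", %d residual self-annealing segment(s)",
                        nrow(object@residual)) else ""))
})
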