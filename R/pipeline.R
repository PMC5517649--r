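# Orchestration of a full symmetric-trefoil design run.

#' Build and validate a design-run configuration
#'
#' @param template template structure: a [ProteinStructure-class] or a
#'   PDB path.
#' @param repeatRanges repeat boundaries (see [extractRepeats()]).
#' @param donor donor structure for linker grafting (structure or path);
#'   required when a graft variant is requested.
#' @param donorRange `c(start, end)` of the 9-residue donor linker
#'   segment, ending at the donor's own junction; the 6-residue graft
#'   uses its junction-proximal last six residues.
#' @param nCandidates number of ancestral candidates (the full protocol
#'   uses 2000; scale down for quick runs).
#' @param model substitution model name (`"JTT"` or `"WAG"`).
#' @param weights scoring weights (see [defaultWeights()]).
#' @param linkerScheme junction scheme for the realised chain:
#'   `"singleG"` or `"GDG"`.
#' @param variants backbone variants to run, a subset of
#'   `c("nograft", "graft6", "graft9")`.
#' @param cavitySpacing grid spacing for the per-design cavity volume
#'   (coarser than the analysis default to keep scoring fast).
#' @param cavityPerDesign compute the cavity volume per candidate
#'   (sequence-dependent radii); `FALSE` reuses the backbone MAP-sequence
#'   volume for all candidates of a variant.
#' @param rigidSearch run the rigid-body placement search in
#'   [symmetrize()].
#' @param seed master RNG seed.
#' @return validated config (list, class `trefoilConfig`).
#' @export
designConfig <- function(template, repeatRanges, donor = NULL,
                         donorRange = NULL, nCandidates = 50L,
                         model = c("JTT", "WAG"),
                         weights = defaultWeights(),
                         linkerScheme = c("singleG", "GDG"),
                         variants = c("nograft", "graft6", "graft9"),
                         cavitySpacing = 1.0, cavityPerDesign = TRUE,
                         rigidSearch = FALSE, seed = 1L) {
  model <- match.arg(model)
  linkerScheme <- match.arg(linkerScheme)
  variants <- match.arg(variants, several.ok = TRUE)
  if (is.character(template)) {
    if (!file.exists(template)) stop("template path does not exist: ",
                                     template)
    template <- readPDB(template)
  }
  if (is.character(donor)) {
    if (!file.exists(donor)) stop("donor path does not exist: ", donor)
    donor <- readPDB(donor)
  }
  if (any(grepl("^graft", variants))) {
    if (is.null(donor) || is.null(donorRange))
      stop("graft variants need a donor structure and donorRange")
    if (donorRange[2L] - donorRange[1L] + 1L != 9L)
      stop("donorRange must span 9 residues")
  }
  if (nCandidates < 1L) stop("nCandidates must be >= 1")
  cfg <- list(template = template, repeatRanges = repeatRanges,
              donor = donor, donorRange = donorRange,
              nCandidates = as.integer(nCandidates), model = model,
              weights = weights, linkerScheme = linkerScheme,
              variants = variants, cavitySpacing = cavitySpacing,
              cavityPerDesign = cavityPerDesign,
              rigidSearch = rigidSearch, seed = as.integer(seed))
  class(cfg) <- "trefoilConfig"
  cfg
}

.configHash <- function(config) {
  raw <- serialize(config, NULL, version = 2L)
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(raw, f)
  unname(tools::md5sum(f))
}

.stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  val <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  log$rows[[length(log$rows) + 1L]] <-
    data.frame(stage = name, seconds = proc.time()[["elapsed"]] - t0)
  val
}

#' Run the full symmetric design pipeline
#'
#' Template to repeats to ancestors to symmetric backbones (with
#' optional donor-linker grafts) to threaded, scored and selected
#' designs. Deterministic under a fixed configuration and seed.
#'
#' @param config a configuration from [designConfig()].
#' @return A [RunReport-class].
#' @export
runDesign <- function(config) {
  stopifnot(inherits(config, "trefoilConfig"))
  log <- new.env(); log$rows <- list()

  reps <- .stage("extract_repeats", log,
                 extractRepeats(config$template, config$repeatRanges))
  seqs <- vapply(reps, attr, "", "seq")
  aln <- .stage("align", log, alignRepeats(seqs))
  model <- substitutionModel(config$model)
  tree <- .stage("infer_tree", log, inferTree(aln, model))
  post <- .stage("posterior", log, marginalPosterior(aln, tree, model))
  cands <- .stage("sample_candidates", log,
                  sampleCandidates(post, config$nCandidates,
                                   seed = config$seed))
  axis <- .stage("fit_axis", log, fitC3Axis(reps))
  backbone0 <- .stage("symmetrize", log,
                      symmetrize(reps$A, axis,
                                 rigidSearch = config$rigidSearch))

  linkerSeq <- if (config$linkerScheme == "singleG") "G" else "GDG"
  linkerLen <- nchar(linkerSeq)
  L <- ncol(aln)

  rows <- list()
  for (variant in config$variants) {
    bb <- switch(variant,
      nograft = backbone0,
      graft6 = .stage("graft6", log,
        graftLinker(backbone0, config$donor,
                    c(config$donorRange[2L] - 5L, config$donorRange[2L]))),
      graft9 = .stage("graft9", log,
        graftLinker(backbone0, config$donor, config$donorRange)))
    real <- realizeBackbone(bb, linkerLen = linkerLen,
                            linkerSeq = linkerSeq)
    map <- real@metadata$map
    caAll <- as.matrix(atoms(real)[, c("x", "y", "z")])
    # RMSD to the natural template over the repeat positions
    tmplCA <- do.call(rbind, lapply(reps, .asCoordMatrix))
    modelCA <- caAll[map$subunit > 0L, , drop = FALSE]
    rmsd <- kabsch(modelCA, tmplCA)@rmsd
    # donor-provenance positions keep the donor sequence
    donorPos <- map$global[map$provenance == "donor"]
    unitResname <- bb@unit$resname[trimws(bb@unit$name) == "CA"]
    donorLetters <- .AA3[unitResname[map$local[map$provenance == "donor"]]]
    bbVol <- NULL
    for (ci in seq_len(nrow(candidates(cands)))) {
      cand <- candidates(cands)[ci, ]
      full <- concatenateWithLinkers(cand$sequence, config$linkerScheme)
      fseq <- .splitChars(full$sequence)
      if (length(donorPos)) fseq[donorPos] <- donorLetters
      fseq <- paste(fseq, collapse = "")
      if (config$cavityPerDesign || is.null(bbVol)) {
        vol <- cavityVolumeForDesign(caAll, fseq,
                                     spacing = config$cavitySpacing)$volume
        if (is.null(bbVol)) bbVol <- vol
      } else vol <- bbVol
      feats <- threadSequence(caAll, fseq)
      en <- scoreDesign(feats, config$weights, cavityVolume = vol)
      mot <- motifCheck(fseq, full$map)
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0(variant, ".", cand$id), backbone = variant,
        candidate = cand$id, total = en@total, contact = en@contact,
        burial = en@burial, clash = en@clash, rmsd = rmsd,
        cavityVolume = vol, motifAll = all(mot$HxDxH) && all(mot$HPxGG),
        logPosterior = cand$logPosterior,
        provenance = cand$provenance, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  sel <- .stage("rank_select", log, rankAndSelect(tab))
  new("RunReport", table = sel$table, selections = sel$selections,
      config = list(model = config$model, variants = config$variants,
                    nCandidates = config$nCandidates,
                    linkerScheme = config$linkerScheme,
                    cavitySpacing = config$cavitySpacing,
                    rigidSearch = config$rigidSearch),
      log = do.call(rbind, log$rows), seed = config$seed,
      hash = .configHash(config))
}

#' @export
setMethod("show", "RunReport", function(object) {
  cat(sprintf("RunReport: %d designs over %s; selections: %s\n",
              nrow(object@table),
              paste(object@config$variants, collapse = "/"),
              paste(names(object@selections), object@selections,
                    sep = "=", collapse = ", ")))
})

#' Write a run report to disk
#'
#' Emits the machine-readable tables: the full candidate table
#' (`candidates.tsv`, byte-identical across reruns of the same
#' configuration and seed), the energy-vs-RMSD scatter data
#' (`scatter.tsv`), and a JSON summary (`summary.json`) with the
#' selections, the motif-gate pass rate and the cavity-volume
#' distribution. The motif gate flags rather than filters: motif-failing
#' designs stay in the table with `motifAll = FALSE`.
#'
#' @param report a [RunReport-class].
#' @param dir output directory (created if needed).
#' @return list of written paths, invisibly.
#' @export
designReport <- function(report, dir) {
  stopifnot(is(report, "RunReport"))
  if (nrow(report@table) == 0L) stop("empty candidate table")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "candidates.tsv")
  utils::write.table(report@table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  scat <- file.path(dir, "scatter.tsv")
  utils::write.table(report@table[, c("id", "total", "rmsd")], scat,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- list(
    selections = as.list(report@selections),
    nDesigns = nrow(report@table),
    motifPassRate = mean(report@table$motifAll),
    cavityVolume = list(
      min = min(report@table$cavityVolume),
      median = stats::median(report@table$cavityVolume),
      max = max(report@table$cavityVolume)),
    seed = report@seed, configHash = report@hash, config = report@config)
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, js, auto_unbox = TRUE, digits = NA)
  invisible(list(candidates = tsv, scatter = scat, summary = js))
}
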