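#' @import methods
NULL

.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Atomic protein structure
#'
#' A hierarchical atomic model (chains, residues, atoms) held as a flat
#' atom table in file order. Waters and other HETATM records are retained
#' but flagged (`het` column) and excluded from protein selections by
#' default.
#'
#' @slot atoms data.frame with columns `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `resseq`, `icode`, `x`, `y`, `z`, `occupancy`,
#'   `element`, `het`.
#' @slot id character entry identifier.
#' @slot source character source file path (or `"memory"`).
#' @slot metadata list of free-form metadata (e.g. analytic cavity volume
#'   for synthetic shell fixtures).
#'
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  slots = c(atoms = "data.frame", id = "character", source = "character",
            metadata = "list"),
  prototype = prototype(id = NA_character_, source = "memory",
                        metadata = list()))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "altloc", "resname", "chain", "resseq",
            "icode", "x", "y", "z", "occupancy", "element", "het")
  if (!all(need %in% names(a)))
    return(paste("atom table lacks columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) && !all(is.finite(c(a$x, a$y, a$z))))
    return("non-finite atom coordinates")
  occ <- a$occupancy[!is.na(a$occupancy)]
  if (length(occ) && (any(occ < 0) || any(occ > 1)))
    return("occupancy outside [0, 1]")
  TRUE
})

#' Result of a rigid-body superposition
#'
#' @slot rotation 3x3 orthonormal matrix, det +1.
#' @slot translation length-3 numeric, Angstrom.
#' @slot rmsd numeric root-mean-square deviation after superposition.
#' @slot nAtoms integer number of paired atoms used.
#' @slot correspondence data.frame of retained pairs (`idxA`, `idxB`, and
#'   optionally residue identifiers).
#' @slot trimmed logical, whether iterative trimming was applied.
#'
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
  slots = c(rotation = "matrix", translation = "numeric", rmsd = "numeric",
            nAtoms = "integer", correspondence = "data.frame",
            trimmed = "logical"))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(R %*% t(R) - diag(3))) > 1e-9) return("rotation not orthonormal")
  if (abs(det(R) - 1) > 1e-9) return("rotation determinant != +1")
  if (object@rmsd < 0) return("negative rmsd")
  if (object@nAtoms < 3L) return("fewer than 3 paired atoms")
  TRUE
})

#' A (pseudo-)threefold symmetry axis
#'
#' @slot direction unit 3-vector.
#' @slot point a point on the axis, Angstrom.
#' @slot angle rotation angle in degrees; for a fitted pseudo-C3 axis this
#'   is the pre-projection mean of the two repeat-to-repeat rotation
#'   angles (an exactly symmetric structure reports 120).
#'
#' @exportClass SymmetryAxis
setClass("SymmetryAxis",
  slots = c(direction = "numeric", point = "numeric", angle = "numeric"))

setValidity("SymmetryAxis", function(object) {
  if (length(object@direction) != 3L) return("direction must be length 3")
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
    return("direction must be a unit vector")
  if (length(object@point) != 3L) return("point must be length 3")
  if (object@angle <= 0 || object@angle >= 360)
    return("angle must lie in (0, 360)")
  TRUE
})

#' An exactly Cn-symmetric backbone built from one repeat unit
#'
#' The assembly is stored as one template repeat unit plus the axis; the
#' full chain is generated by rotating the unit by multiples of 360/n
#' degrees, so subunit equivalence holds exactly by construction.
#'
#' @slot unit data.frame for the repeat unit: `resno` (unit-local residue
#'   number), `resname`, `name` (atom name), `x`, `y`, `z`, `provenance`
#'   (`"template"` or `"donor"`).
#' @slot axis [SymmetryAxis-class].
#' @slot order integer symmetry order n (3 for a trefoil).
#' @slot linker list describing the junction scheme: `seq` (one-letter
#'   linker sequence inserted at each junction) and `scheme` label.
#' @slot objective numeric value of the packing objective at construction
#'   (NA when no rigid search was run).
#'
#' @exportClass SymmetricBackbone
setClass("SymmetricBackbone",
  slots = c(unit = "data.frame", axis = "SymmetryAxis", order = "integer",
            linker = "list", objective = "numeric"),
  prototype = prototype(order = 3L,
                        linker = list(seq = "G", scheme = "singleG"),
                        objective = NA_real_))

setValidity("SymmetricBackbone", function(object) {
  need <- c("resno", "resname", "name", "x", "y", "z", "provenance")
  if (!all(need %in% names(object@unit)))
    return("unit table lacks required columns")
  if (object@order < 2L) return("order must be >= 2")
  TRUE
})

#' A 20-state amino-acid substitution model
#'
#' Reversible rate matrix in the order ARNDCQEGHILKMFPSTWYV, normalised to
#' one expected substitution per site at stationarity.
#'
#' @slot name model tag (e.g. `"JTT"`).
#' @slot Q 20x20 rate matrix, rows sum to zero.
#' @slot pi equilibrium frequencies, sum 1.
#' @slot decomposition list with the symmetric eigendecomposition used for
#'   matrix exponentials (`values`, `vectors`, `sqp`, `isqp`).
#'
#' @exportClass SubstitutionModel
setClass("SubstitutionModel",
  slots = c(name = "character", Q = "matrix", pi = "numeric",
            decomposition = "list"))

setValidity("SubstitutionModel", function(object) {
  Q <- object@Q; p <- object@pi
  if (!all(dim(Q) == c(20L, 20L))) return("Q must be 20x20")
  if (abs(sum(p) - 1) > 1e-9) return("frequencies must sum to 1")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) return("negative off-diagonal rate")
  if (max(abs(rowSums(Q))) > 1e-9) return("Q rows must sum to 0")
  if (max(abs(p %*% Q)) > 1e-10) return("pi Q != 0 (not stationary)")
  TRUE
})

#' Per-site posterior distribution of the root (ancestral) state
#'
#' @slot prob sites x 20 matrix of posterior probabilities, rows sum to 1,
#'   columns in the order ARNDCQEGHILKMFPSTWYV.
#' @slot logLik total log-likelihood of the data under the model and tree.
#' @slot siteLogLik per-site log-likelihood values.
#'
#' @exportClass AncestralPosterior
setClass("AncestralPosterior",
  slots = c(prob = "matrix", logLik = "numeric", siteLogLik = "numeric"))

setValidity("AncestralPosterior", function(object) {
  P <- object@prob
  if (ncol(P) != 20L) return("posterior must have 20 columns")
  if (any(P < 0)) return("negative posterior entry")
  if (nrow(P) && max(abs(rowSums(P) - 1)) > 1e-9)
    return("posterior rows must sum to 1")
  TRUE
})

#' A pool of candidate ancestral sequences
#'
#' @slot candidates data.frame with columns `id`, `sequence`,
#'   `logPosterior`, `provenance` (`"MAP"` or `"sampled"`).
#' @slot seed integer RNG seed used for sampling.
#'
#' @exportClass CandidateSet
setClass("CandidateSet",
  slots = c(candidates = "data.frame", seed = "integer"))

setValidity("CandidateSet", function(object) {
  cc <- object@candidates
  if (!all(c("id", "sequence", "logPosterior", "provenance") %in% names(cc)))
    return("candidate table lacks required columns")
  if (sum(cc$provenance == "MAP") > 1L)
    return("MAP sequence must appear at most once")
  TRUE
})

#' Coarse-grained energy of a threaded design
#'
#' @slot contact statistical pair-potential sum over C-beta proxy contacts.
#' @slot burial hydrophobicity-weighted burial term.
#' @slot clash soft-sphere clash term.
#' @slot cavity cavity volume entering the penalty, cubic Angstrom.
#' @slot weights named numeric weights (`contact`, `burial`, `clash`,
#'   `cavity`).
#' @slot total weighted sum of the four terms.
#'
#' @exportClass EnergyBreakdown
setClass("EnergyBreakdown",
  slots = c(contact = "numeric", burial = "numeric", clash = "numeric",
            cavity = "numeric", weights = "numeric", total = "numeric"))

setValidity("EnergyBreakdown", function(object) {
  w <- object@weights
  if (!all(c("contact", "burial", "clash", "cavity") %in% names(w)))
    return("weights must name contact, burial, clash, cavity")
  tot <- w["contact"] * object@contact + w["burial"] * object@burial +
    w["clash"] * object@clash + w["cavity"] * object@cavity
  if (abs(tot - object@total) > 1e-9)
    return("total is not the weighted sum of the terms")
  TRUE
})

#' Internal cavities detected on a voxel grid
#'
#' @slot components data.frame with one row per cavity: `component`,
#'   `nVoxels`, `volume` (cubic Angstrom), `cx`, `cy`, `cz` (centroid).
#' @slot voxels data.frame of cavity voxel centres (`component`, `x`, `y`,
#'   `z`).
#' @slot spacing grid spacing, Angstrom.
#' @slot params list of detection parameters (probes, min volume).
#'
#' @exportClass CavityResult
setClass("CavityResult",
  slots = c(components = "data.frame", voxels = "data.frame",
            spacing = "numeric", params = "list"))

setValidity("CavityResult", function(object) {
  if (object@spacing <= 0) return("spacing must be positive")
  if (nrow(object@components) && any(object@components$volume < 0))
    return("negative cavity volume")
  TRUE
})

#' A designed coding sequence
#'
#' @slot coding coding DNA string (ACGT, no stop codon).
#' @slot protein the encoded protein (one-letter).
#' @slot flanks named character vector of flanking elements in order
#'   (e.g. NdeI site, coding, stop, XhoI site are assembled by
#'   [buildConstruct()]).
#' @slot edits data.frame log of silent edits: `codonIndex`, `from`, `to`,
#'   `reason`.
#' @slot table codon-usage table label.
#' @slot residual data.frame of unrepaired self-annealing segments (empty
#'   when repair reached a fixpoint).
#'
#' @exportClass GeneDesign
setClass("GeneDesign",
  slots = c(coding = "character", protein = "character", flanks = "character",
            edits = "data.frame", table = "character", residual = "data.frame"),
  prototype = prototype(
    flanks = c(NdeI = "CATATG", XhoI = "CTCGAG"),
    edits = data.frame(codonIndex = integer(), from = character(),
                       to = character(), reason = character()),
    residual = data.frame(i = integer(), j = integer(), length = integer())))

setValidity("GeneDesign", function(object) {
  dna <- object@coding
  if (nchar(dna) %% 3L != 0L) return("coding length must be a multiple of 3")
  if (grepl("[^ACGT]", dna)) return("coding must use A/C/G/T only")
  if (.translate(dna) != object@protein)
    return("coding region does not translate to the stated protein")
  TRUE
})

#' Report of a full design run
#'
#' @slot table data.frame of scored designs across backbone variants.
#' @slot selections named character vector: ids of the energy-best
#'   (`energy`), RMSD-best (`rmsd`) and cavity-best (`cavity`) designs.
#' @slot config the validated run configuration (list).
#' @slot log data.frame of per-stage wall times.
#' @slot seed integer master seed.
#' @slot hash character hash of the configuration.
#'
#' @exportClass RunReport
setClass("RunReport",
  slots = c(table = "data.frame", selections = "character", config = "list",
            log = "data.frame", seed = "integer", hash = "character"))

setValidity("RunReport", function(object) {
  if (nrow(object@table) == 0L) return("empty design table")
  if (!all(object@selections %in% object@table$id))
    return("selections must reference rows of the design table")
  TRUE
})
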