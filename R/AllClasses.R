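#' @import methods
NULL

# Residue identifiers ("keys") used throughout are "<chain>:<resno><icode>",
# e.g. "A:69". Author numbering, 1-based, ranges inclusive.

#' PdbStructure: a parsed protein structure
#'
#' Holds polymer atoms (ATOM records) as a per-atom table and HETATM groups as
#' a list of [CLLigand] objects. Residues are ordered by chain, then author
#' residue number, then insertion code.
#'
#' @slot id Character structure identifier.
#' @slot atoms `data.frame` with columns `chain`, `resno`, `icode`, `resid`
#'   (three-letter), `aa` (one-letter, `"X"` for nonstandard), `elety` (atom
#'   name), `element`, `x`, `y`, `z`, `occ`.
#' @slot ligands List of [CLLigand] objects parsed from HETATM records.
#' @export
setClass("PdbStructure",
         representation(id = "character", atoms = "data.frame",
                        ligands = "list"),
         prototype(id = "structure", ligands = list()))

setValidity("PdbStructure", function(object) {
  need <- c("chain", "resno", "icode", "resid", "aa", "elety",
            "element", "x", "y", "z", "occ")
  a <- object@atoms
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a)) {
    if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
      return("atom coordinates must be finite")
    if (any(!nzchar(a$element))) return("element symbols must be non-empty")
    if (!all(.validAA(a$aa))) return("aa must be a standard one-letter code or 'X'")
    first <- !duplicated(paste(a$chain, a$resno, a$icode))
    f <- a[first, c("chain", "resno", "icode")]
    if (is.unsorted(order(f$chain, f$resno, f$icode), strictly = TRUE) ||
        !identical(order(f$chain, f$resno, f$icode), seq_len(nrow(f))))
      return("residues must be ordered by chain, residue number, insertion code")
  }
  TRUE
})

#' SequenceRecord: an amino-acid sequence with a numbering offset
#'
#' Position `i` of `seq` has biological number `i + offset`.
#'
#' @slot id Character identifier.
#' @slot seq One-letter amino-acid string (alphabet: 20 standard letters + X).
#' @slot offset Integer numbering offset.
#' @export
setClass("SequenceRecord",
         representation(id = "character", seq = "character",
                        offset = "integer"),
         prototype(offset = 0L))

setValidity("SequenceRecord", function(object) {
  if (!nzchar(object@seq)) return("seq must be non-empty")
  ch <- strsplit(object@seq, "")[[1]]
  if (!all(.validAA(ch)))
    return("seq contains letters outside the 20 standard amino acids + X")
  TRUE
})

#' ExonMap: exon to protein-residue ranges
#'
#' Full-length (FL) numbering, 1-based inclusive, non-overlapping, sorted by
#' start.
#'
#' @slot entries `data.frame` with columns `exon_id` (character), `start`,
#'   `end` (integer).
#' @export
setClass("ExonMap", representation(entries = "data.frame"))

setValidity("ExonMap", function(object) {
  e <- object@entries
  if (!all(c("exon_id", "start", "end") %in% names(e)))
    return("entries needs columns exon_id, start, end")
  if (nrow(e)) {
    if (any(e$start > e$end)) return("exon start must be <= end")
    if (any(e$start < 1)) return("exon ranges must be >= 1")
    if (is.unsorted(e$start, strictly = TRUE))
      return("exon entries must be sorted by start")
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)]))
      return("exon ranges must not overlap")
  }
  TRUE
})

#' AccessibilityProfile: per-residue solvent accessibility
#'
#' @slot residues `data.frame` with columns `key`, `chain`, `resno`, `icode`,
#'   `aa`, `sasa` (absolute, A^2), `relAcc` (SASA / max-ASA), `buried`
#'   (logical, `relAcc < threshold`).
#' @slot threshold Burial threshold on relative accessibility (strict `<`).
#' @slot probeRadius Probe radius (A) used for the underlying SASA.
#' @slot nSpherePoints Number of sampling points per atom.
#' @export
setClass("AccessibilityProfile",
         representation(residues = "data.frame", threshold = "numeric",
                        probeRadius = "numeric", nSpherePoints = "integer"),
         prototype(threshold = 0.1, probeRadius = 1.4, nSpherePoints = 960L))

setValidity("AccessibilityProfile", function(object) {
  r <- object@residues
  need <- c("key", "chain", "resno", "icode", "aa", "sasa", "relAcc", "buried")
  if (!all(need %in% names(r)))
    return(paste("residues must have columns:", paste(need, collapse = ", ")))
  if (nrow(r)) {
    if (any(r$sasa < 0)) return("absolute SASA must be >= 0")
    if (!identical(r$buried, r$relAcc < object@threshold))
      return("buried flag must equal relAcc < threshold")
  }
  TRUE
})

#' ContactGraph: residue-residue contacts
#'
#' Unordered residue-key pairs whose minimum heavy-atom distance is within the
#' cutoff.
#'
#' @slot pairs Two-column character matrix of residue keys (each row one
#'   unordered pair, no self-pairs).
#' @slot cutoff Distance cutoff (A).
#' @export
setClass("ContactGraph",
         representation(pairs = "matrix", cutoff = "numeric"))

setValidity("ContactGraph", function(object) {
  p <- object@pairs
  if (ncol(p) != 2) return("pairs must have two columns")
  if (nrow(p) && any(p[, 1] == p[, 2])) return("self-pairs are not allowed")
  TRUE
})

#' CoreSet: connected components of buried residues
#'
#' @slot components List of character vectors of residue keys; each component
#'   has >= 2 members, all buried.
#' @slot buried Character vector of all buried residue keys.
#' @export
setClass("CoreSet",
         representation(components = "list", buried = "character"))

setValidity("CoreSet", function(object) {
  comp <- object@components
  if (length(comp)) {
    if (any(lengths(comp) < 2)) return("core components must have >= 2 members")
    all_m <- unlist(comp)
    if (anyDuplicated(all_m)) return("core components must be disjoint")
    if (!all(all_m %in% object@buried))
      return("core members must be buried residues")
  }
  TRUE
})

#' GapProfile: position-specific gap-open penalties
#'
#' One open penalty per template position, interpolated between `gMax` (fully
#' buried) and `gMin` (fully exposed), plus a single extension penalty.
#'
#' @slot open Numeric vector of per-position gap-open penalties.
#' @slot extend Gap extension penalty.
#' @slot gMax Open penalty at relative accessibility 0 (buried).
#' @slot gMin Open penalty at relative accessibility >= 1 (exposed).
#' @export
setClass("GapProfile",
         representation(open = "numeric", extend = "numeric",
                        gMax = "numeric", gMin = "numeric"))

setValidity("GapProfile", function(object) {
  if (!(object@gMax >= object@gMin && object@gMin > object@extend &&
        object@extend >= 0))
    return("need gMax >= gMin > extend >= 0")
  if (length(object@open) &&
      (any(object@open < object@gMin - 1e-9) ||
       any(object@open > object@gMax + 1e-9)))
    return("open penalties must lie in [gMin, gMax]")
  TRUE
})

#' PairAlignment: a global pairwise alignment
#'
#' Column `k` aligns target position `targetIdx[k]` with template position
#' `templateIdx[k]`; `NA` marks a gap. Indices are sequence positions
#' (1-based, before applying each record's numbering offset).
#'
#' @slot targetIdx Integer vector (NA = gap in target).
#' @slot templateIdx Integer vector (NA = gap in template).
#' @slot score Total alignment score.
#' @slot matrixName Substitution matrix identifier.
#' @slot target,template The aligned [SequenceRecord] objects.
#' @export
setClass("PairAlignment",
         representation(targetIdx = "integer", templateIdx = "integer",
                        score = "numeric", matrixName = "character",
                        target = "SequenceRecord", template = "SequenceRecord"))

setValidity("PairAlignment", function(object) {
  ti <- object@targetIdx; si <- object@templateIdx
  if (length(ti) != length(si)) return("index vectors must match in length")
  if (any(is.na(ti) & is.na(si))) return("column with two gaps")
  if (is.unsorted(ti[!is.na(ti)], strictly = TRUE) ||
      is.unsorted(si[!is.na(si)], strictly = TRUE))
    return("indices must be strictly increasing")
  TRUE
})

#' Pocket: a detected structural cleft
#'
#' Grid-based pocket: the retained protein-solvent-protein grid points of one
#' 26-connected cluster, with volume, mouth count and lining residues.
#'
#' @slot points `n x 3` matrix of pocket grid-point coordinates (A).
#' @slot spacing Grid spacing (A).
#' @slot volume Pocket volume, `n_points * spacing^3` (A^3).
#' @slot mouths Number of openings to bulk solvent (0 for enclosed cavities).
#' @slot lining Character vector of lining residue keys.
#' @slot gridOrigin Coordinate of grid index (1,1,1).
#' @slot gridDim Integer grid dimensions.
#' @slot pspThreshold Minimum number of enclosing scan directions (of 7).
#' @slot probeRadius Probe radius (A) added to atom radii for occupancy.
#' @export
setClass("Pocket",
         representation(points = "matrix", spacing = "numeric",
                        volume = "numeric", mouths = "integer",
                        lining = "character", gridOrigin = "numeric",
                        gridDim = "integer", pspThreshold = "integer",
                        probeRadius = "numeric"))

setValidity("Pocket", function(object) {
  if ((nrow(object@points) > 0) != (object@volume > 0))
    return("volume must be > 0 iff points are non-empty")
  if (object@mouths < 0) return("mouth count must be >= 0")
  TRUE
})

#' PatchSet: exposed basic-residue surface patches
#'
#' @slot patches List of character vectors of residue keys (disjoint; members
#'   basic and non-buried).
#' @slot centroids `k x 3` matrix of patch centroid coordinates.
#' @slot linkDistance Single-linkage distance (A).
#' @slot minSize Minimum patch size reported.
#' @export
setClass("PatchSet",
         representation(patches = "list", centroids = "matrix",
                        linkDistance = "numeric", minSize = "integer"))

setValidity("PatchSet", function(object) {
  if (length(object@patches)) {
    if (anyDuplicated(unlist(object@patches)))
      return("patches must be disjoint")
    if (nrow(object@centroids) != length(object@patches))
      return("one centroid per patch required")
  }
  TRUE
})

#' SegmentAnnotation: labelled sequence segments
#'
#' @slot segments `data.frame` with columns `start`, `end` (residue numbering,
#'   inclusive) and `label` (`"TM"` or `"disordered"`).
#' @slot method Character description of the heuristic that produced them.
#' @export
setClass("SegmentAnnotation",
         representation(segments = "data.frame", method = "character"),
         prototype(method = ""))

setValidity("SegmentAnnotation", function(object) {
  s <- object@segments
  if (!all(c("start", "end", "label") %in% names(s)))
    return("segments needs columns start, end, label")
  if (nrow(s)) {
    if (any(s$start > s$end)) return("segment start must be <= end")
    for (lb in unique(s$label)) {
      ss <- s[s$label == lb, , drop = FALSE]
      ss <- ss[order(ss$start), , drop = FALSE]
      if (nrow(ss) > 1 && any(ss$start[-1] <= ss$end[-nrow(ss)]))
        return("segments of the same label must not overlap")
    }
  }
  TRUE
})

#' CLLigand: a (cardiolipin-like) ligand instance
#'
#' @slot id Ligand identifier.
#' @slot atoms `data.frame` with columns `name`, `element`, `x`, `y`, `z`.
#' @slot groups List of phosphate groups, each a list with elements `P`
#'   (atom row index of the phosphorus) and `O` (row indices of its bonded
#'   oxygens). Cardiolipin-like ligands have exactly two groups.
#' @export
setClass("CLLigand",
         representation(id = "character", atoms = "data.frame",
                        groups = "list"))

setValidity("CLLigand", function(object) {
  a <- object@atoms
  if (!all(c("name", "element", "x", "y", "z") %in% names(a)))
    return("atoms needs columns name, element, x, y, z")
  for (g in object@groups) {
    if (!all(c("P", "O") %in% names(g))) return("each group needs P and O")
    if (length(g$P) != 1) return("each phosphate group has exactly one P")
  }
  TRUE
})

#' SpacingStats: summary of phosphate-group spacings
#'
#' @slot spacings Per-ligand spacing values (A).
#' @slot mean Sample mean (A).
#' @slot sd Sample standard deviation (n-1 denominator; 0 when n = 1).
#' @slot n Number of ligands.
#' @export
setClass("SpacingStats",
         representation(spacings = "numeric", mean = "numeric",
                        sd = "numeric", n = "integer"))

setValidity("SpacingStats", function(object) {
  if (object@n != length(object@spacings)) return("n must match spacings")
  if (object@sd < 0) return("sd must be >= 0")
  TRUE
})

#' AnnotationReport: full pipeline output
#'
#' @slot sections Named list of stage outputs (accessibility summary, core
#'   components, pockets, cleft tabulation, patches, net charge, segments,
#'   ligand statistics).
#' @slot mutations `data.frame` of per-mutation annotations (one row per
#'   accepted input mutation).
#' @slot rejected `data.frame` of rejected mutation rows with reasons.
#' @slot metadata Named list (configuration, seed, package version).
#' @export
setClass("AnnotationReport",
         representation(sections = "list", mutations = "data.frame",
                        rejected = "data.frame", metadata = "list"))
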