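# Accessor generics and show methods. Slot access from user code should go
# through these.

#' @describeIn PdbStructure-accessors Per-residue table (one row per polymer
#'   residue) with columns `key`, `chain`, `resno`, `icode`, `aa`.
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @describeIn PdbStructure-accessors Per-atom table.
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @describeIn PdbStructure-accessors Ligand list.
#' @export
setGeneric("ligands", function(x) standardGeneric("ligands"))

#' Accessors for PdbStructure
#'
#' @param x A [PdbStructure].
#' @name PdbStructure-accessors
NULL

.resKey <- function(a) paste0(a$chain, ":", a$resno,
                              ifelse(nzchar(a$icode), a$icode, ""))

#' @rdname PdbStructure-accessors
#' @export
setMethod("residueTable", "PdbStructure", function(x) {
  a <- x@atoms
  first <- !duplicated(paste(a$chain, a$resno, a$icode))
  r <- a[first, c("chain", "resno", "icode", "aa")]
  rownames(r) <- NULL
  cbind(key = .resKey(r), r, stringsAsFactors = FALSE)
})

#' @rdname PdbStructure-accessors
#' @export
setMethod("atomTable", "PdbStructure", function(x) x@atoms)

#' @rdname PdbStructure-accessors
#' @export
setMethod("ligands", "PdbStructure", function(x) x@ligands)

#' One-letter sequence of a structure chain
#'
#' @param x A [PdbStructure].
#' @param chain Chain identifier; default the first chain.
#' @return A [SequenceRecord] whose offset makes `position i + offset` equal
#'   the author residue number of the first residue minus one (only exact when
#'   numbering is consecutive).
#' @export
setGeneric("chainSequence", function(x, chain = NULL) standardGeneric("chainSequence"))

#' @rdname chainSequence
#' @export
setMethod("chainSequence", "PdbStructure", function(x, chain = NULL) {
  r <- residueTable(x)
  if (is.null(chain)) chain <- r$chain[1]
  r <- r[r$chain == chain, , drop = FALSE]
  if (!nrow(r)) stop("no residues in chain ", chain)
  new("SequenceRecord", id = paste0(x@id, "_", chain),
      seq = paste(r$aa, collapse = ""), offset = as.integer(r$resno[1] - 1L))
})

#' @describeIn AccessibilityProfile-accessors Per-residue accessibility table.
#' @export
setGeneric("accessibilityTable", function(x) standardGeneric("accessibilityTable"))

#' @describeIn AccessibilityProfile-accessors Named logical burial flags,
#'   keyed by residue.
#' @export
setGeneric("isBuried", function(x) standardGeneric("isBuried"))

#' @describeIn AccessibilityProfile-accessors Named relative accessibilities.
#' @export
setGeneric("relAcc", function(x) standardGeneric("relAcc"))

#' Accessors for AccessibilityProfile
#'
#' @param x An [AccessibilityProfile].
#' @name AccessibilityProfile-accessors
NULL

#' @rdname AccessibilityProfile-accessors
#' @export
setMethod("accessibilityTable", "AccessibilityProfile", function(x) x@residues)

#' @rdname AccessibilityProfile-accessors
#' @export
setMethod("isBuried", "AccessibilityProfile", function(x)
  stats::setNames(x@residues$buried, x@residues$key))

#' @rdname AccessibilityProfile-accessors
#' @export
setMethod("relAcc", "AccessibilityProfile", function(x)
  stats::setNames(x@residues$relAcc, x@residues$key))

#' Core components accessor
#'
#' @param x A [CoreSet].
#' @return List of character vectors of residue keys.
#' @export
setGeneric("coreComponents", function(x) standardGeneric("coreComponents"))

#' @rdname coreComponents
#' @export
setMethod("coreComponents", "CoreSet", function(x) x@components)

#' Contact pairs accessor
#'
#' @param x A [ContactGraph].
#' @return Two-column character matrix of residue-key pairs.
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))

#' @rdname contactPairs
#' @export
setMethod("contactPairs", "ContactGraph", function(x) x@pairs)

#' Pocket accessors
#'
#' @param x A [Pocket].
#' @name Pocket-accessors
NULL

#' @describeIn Pocket-accessors Pocket volume in A^3.
#' @export
setGeneric("pocketVolume", function(x) standardGeneric("pocketVolume"))

#' @rdname Pocket-accessors
#' @export
setMethod("pocketVolume", "Pocket", function(x) x@volume)

#' @describeIn Pocket-accessors Number of mouths (openings to bulk solvent).
#' @export
setGeneric("mouthCount", function(x) standardGeneric("mouthCount"))

#' @rdname Pocket-accessors
#' @export
setMethod("mouthCount", "Pocket", function(x) x@mouths)

#' @describeIn Pocket-accessors Lining residue keys.
#' @export
setGeneric("liningResidues", function(x) standardGeneric("liningResidues"))

#' @rdname Pocket-accessors
#' @export
setMethod("liningResidues", "Pocket", function(x) x@lining)

#' @describeIn Pocket-accessors Pocket grid-point coordinates.
#' @export
setGeneric("pocketPoints", function(x) standardGeneric("pocketPoints"))

#' @rdname Pocket-accessors
#' @export
setMethod("pocketPoints", "Pocket", function(x) x@points)

#' Exon table accessor
#'
#' @param x An [ExonMap].
#' @return `data.frame` with columns `exon_id`, `start`, `end`.
#' @export
setGeneric("exonTable", function(x) standardGeneric("exonTable"))

#' @rdname exonTable
#' @export
setMethod("exonTable", "ExonMap", function(x) x@entries)

#' Segment table accessor
#'
#' @param x A [SegmentAnnotation].
#' @return `data.frame` with columns `start`, `end`, `label`.
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' @rdname segmentTable
#' @export
setMethod("segmentTable", "SegmentAnnotation", function(x) x@segments)

#' Patch members accessor
#'
#' @param x A [PatchSet].
#' @return List of character vectors of residue keys, one per patch.
#' @export
setGeneric("patchMembers", function(x) standardGeneric("patchMembers"))

#' @rdname patchMembers
#' @export
setMethod("patchMembers", "PatchSet", function(x) x@patches)

#' Patch centroids accessor
#'
#' @param x A [PatchSet].
#' @return `k x 3` matrix of centroid coordinates.
#' @export
setGeneric("patchCentroids", function(x) standardGeneric("patchCentroids"))

#' @rdname patchCentroids
#' @export
setMethod("patchCentroids", "PatchSet", function(x) x@centroids)

#' Alignment accessors
#'
#' @param x A [PairAlignment].
#' @name PairAlignment-accessors
NULL

#' @describeIn PairAlignment-accessors Total alignment score.
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' @rdname PairAlignment-accessors
#' @export
setMethod("alignmentScore", "PairAlignment", function(x) x@score)

#' @describeIn PairAlignment-accessors Column table with target/template
#'   sequence positions (NA = gap) and residue letters.
#' @export
setGeneric("alignedColumns", function(x) standardGeneric("alignedColumns"))

#' @rdname PairAlignment-accessors
#' @export
setMethod("alignedColumns", "PairAlignment", function(x) {
  tch <- strsplit(x@target@seq, "")[[1]]
  sch <- strsplit(x@template@seq, "")[[1]]
  data.frame(
    target = x@targetIdx, template = x@templateIdx,
    targetAA = ifelse(is.na(x@targetIdx), "-", tch[x@targetIdx]),
    templateAA = ifelse(is.na(x@templateIdx), "-", sch[x@templateIdx]),
    stringsAsFactors = FALSE)
})

#' Spacing statistics accessors
#'
#' @param x A [SpacingStats].
#' @name SpacingStats-accessors
NULL

#' @describeIn SpacingStats-accessors Mean spacing (A).
#' @export
setGeneric("spacingMean", function(x) standardGeneric("spacingMean"))

#' @rdname SpacingStats-accessors
#' @export
setMethod("spacingMean", "SpacingStats", function(x) x@mean)

#' @describeIn SpacingStats-accessors Sample standard deviation (A).
#' @export
setGeneric("spacingSd", function(x) standardGeneric("spacingSd"))

#' @rdname SpacingStats-accessors
#' @export
setMethod("spacingSd", "SpacingStats", function(x) x@sd)

#' @describeIn SpacingStats-accessors Per-ligand spacings (A).
#' @export
setGeneric("spacingValues", function(x) standardGeneric("spacingValues"))

#' @rdname SpacingStats-accessors
#' @export
setMethod("spacingValues", "SpacingStats", function(x) x@spacings)

#' Report accessors
#'
#' @param x An [AnnotationReport].
#' @name AnnotationReport-accessors
NULL

#' @describeIn AnnotationReport-accessors Per-mutation annotation table.
#' @export
setGeneric("mutationAnnotations", function(x) standardGeneric("mutationAnnotations"))

#' @rdname AnnotationReport-accessors
#' @export
setMethod("mutationAnnotations", "AnnotationReport", function(x) x@mutations)

#' @describeIn AnnotationReport-accessors Named list of stage outputs.
#' @export
setGeneric("reportSections", function(x) standardGeneric("reportSections"))

#' @rdname AnnotationReport-accessors
#' @export
setMethod("reportSections", "AnnotationReport", function(x) x@sections)

# --- show methods -----------------------------------------------------------

setMethod("show", "PdbStructure", function(object) {
  r <- residueTable(object)
  cat("PdbStructure", object@id, "\n")
  cat("  ", nrow(object@atoms), " atoms, ", nrow(r), " residues, ",
      length(unique(r$chain)), " chain(s), ", length(object@ligands),
      " ligand(s)\n", sep = "")
})

setMethod("show", "SequenceRecord", function(object) {
  n <- nchar(object@seq)
  cat("SequenceRecord", object@id, "(", n, "aa, offset", object@offset, ")\n")
  cat("  ", if (n > 60) paste0(substr(object@seq, 1, 57), "...")
      else object@seq, "\n", sep = "")
})

setMethod("show", "AccessibilityProfile", function(object) {
  r <- object@residues
  cat("AccessibilityProfile:", nrow(r), "residues;",
      sum(r$buried), "buried (relAcc <", object@threshold, ")\n")
})

setMethod("show", "CoreSet", function(object) {
  cat("CoreSet:", length(object@components), "component(s), sizes",
      paste(lengths(object@components), collapse = ", "), "\n")
})

setMethod("show", "Pocket", function(object) {
  cat("Pocket:", nrow(object@points), "grid points, volume",
      round(object@volume, 1), "A^3,", object@mouths, "mouth(s),",
      length(object@lining), "lining residues\n")
})

setMethod("show", "ExonMap", function(object) {
  cat("ExonMap with", nrow(object@entries), "exon(s)\n")
  if (nrow(object@entries)) print(object@entries, row.names = FALSE)
})

setMethod("show", "PairAlignment", function(object) {
  cols <- alignedColumns(object)
  cat("PairAlignment (", object@target@id, " vs ", object@template@id,
      "): ", nrow(cols), " columns, score ", round(object@score, 2),
      "\n", sep = "")
})

setMethod("show", "PatchSet", function(object) {
  cat("PatchSet:", length(object@patches), "patch(es), sizes",
      paste(lengths(object@patches), collapse = ", "), "\n")
})

setMethod("show", "SegmentAnnotation", function(object) {
  cat("SegmentAnnotation (", object@method, "): ",
      nrow(object@segments), " segment(s)\n", sep = "")
  if (nrow(object@segments)) print(object@segments, row.names = FALSE)
})

setMethod("show", "SpacingStats", function(object) {
  cat("SpacingStats: n =", object@n, ", mean =", round(object@mean, 2),
      "A, sd =", round(object@sd, 2), "A\n")
})

setMethod("show", "CLLigand", function(object) {
  cat("CLLigand", object@id, "with", nrow(object@atoms), "atoms and",
      length(object@groups), "phosphate group(s)\n")
})

setMethod("show", "AnnotationReport", function(object) {
  cat("AnnotationReport\n")
  cat("  sections:", paste(names(object@sections), collapse = ", "), "\n")
  cat("  mutations annotated:", nrow(object@mutations),
      "; rejected:", nrow(object@rejected), "\n")
})
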