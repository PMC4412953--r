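# cli_pipeline: end-to-end orchestration over the analysis stages and
# TSV/JSON reporting. A thin command-line wrapper lives in
# inst/scripts/annotate.R.

.defaultConfig <- function() {
  list(probeRadius = 1.4, nSpherePoints = 960L, burialThreshold = 0.1,
       contactCutoff = 4.5, gridSpacing = 1.0, pspThreshold = 4L,
       minPoints = 30L, liningDistance = 4.0, patchLinkDistance = 15,
       patchMinSize = 3L, patchDistance = 10, tmWindow = 19L,
       tmThreshold = 1.6, disorderWindow = 21L, dvThreshold = 20,
       clTolerance = 3.0, modeledRegion = c(41L, 245L))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full annotation pipeline
#'
#' Orchestrates accessibility/core analysis, cleft detection and exon
#' tabulation, patch/charge/segment analysis, mutation classification and
#' (optionally) ligand phosphate geometry, and assembles an
#' [AnnotationReport]. In table-only mode the mutation table must carry a
#' `location` column (printed labels accepted) and no structure is required;
#' this is how published mutation tables are reproduced without the original
#' model coordinates.
#'
#' @param structure A [PdbStructure], a PDB file path, or `NULL` (table-only
#'   mode).
#' @param sequence A [SequenceRecord] or FASTA path (first record used).
#' @param exonMap An [ExonMap] or TSV path.
#' @param mutations Mutation `data.frame` (see [readMutationTable()]) or TSV
#'   path.
#' @param ligandList Optional list of [CLLigand] or a PDB path whose HETATM
#'   groups are used.
#' @param tableOnly Use the mutation table's own `location` column instead
#'   of computing locations from the structure.
#' @param catalytic Integer catalytic positions; default: the first HX4D
#'   motif of `sequence` (His and Asp positions).
#' @param outDir Optional output directory; writes `report_mutations.tsv`,
#'   `report_cleft_by_exon.tsv` and `run_summary.json` (report bodies are
#'   deterministic; no timestamps).
#' @param seed Seed recorded in the metadata and used for any stochastic
#'   stage (none in the default pipeline).
#' @param config Named list overriding entries of the default configuration
#'   (probe radius, thresholds, window sizes, ...).
#' @param verbose Log stage progress to standard error.
#' @return An [AnnotationReport].
#' @export
annotateStructure <- function(structure = NULL, sequence, exonMap, mutations,
                              ligandList = NULL, tableOnly = FALSE,
                              catalytic = NULL, outDir = NULL, seed = NULL,
                              config = list(), verbose = FALSE) {
  cfg <- utils::modifyList(.defaultConfig(), config)
  log0 <- function(...) if (verbose) message("[taz3d] ", ...)

  if (is.character(structure)) structure <- .stage("read_structure",
                                                   readStructure(structure))
  if (is.character(sequence))
    sequence <- .stage("read_sequence", readFastaSequences(sequence)[[1]])
  if (is.character(exonMap)) exonMap <- .stage("read_exon_map",
                                               readExonMap(exonMap))
  if (is.character(mutations))
    mutations <- .stage("read_mutations",
                        readMutationTable(mutations, strict = FALSE))
  if (is.character(ligandList))
    ligandList <- .stage("read_ligands", ligands(readStructure(ligandList)))
  rejected <- attr(mutations, "rejected")
  if (is.null(rejected)) rejected <- mutations[0, , drop = FALSE]

  sections <- list(config = cfg)

  log0("sequence analysis")
  hx <- .stage("find_hx4d", findHX4D(sequence))
  if (is.null(catalytic))
    catalytic <- if (nrow(hx)) c(hx$his[1], hx$asp[1]) else integer(0)
  reg <- cfg$modeledRegion
  ch <- .seqChars(sequence)
  e5 <- exonTable(exonMap)
  e5 <- e5[e5$exon_id == "5", , drop = FALSE]
  dom <- setdiff(seq(reg[1], min(reg[2], length(ch))),
                 if (nrow(e5)) seq(e5$start[1], e5$end[1]) else integer(0))
  sections$charge <- list(
    full = netFormalCharge(sequence),
    modeledDomainDelta5 = netFormalCharge(ch[dom]))
  sections$hx4d <- hx
  sections$tm <- .stage("tm_segments",
                        tmSegments(sequence, cfg$tmWindow, cfg$tmThreshold))
  sections$disorder <- .stage("disorder_segments",
                              disorderSegments(sequence, cfg$disorderWindow))

  profile <- patches <- NULL
  cleftKeys <- character(0)
  if (!is.null(structure)) {
    log0("accessibility and core")
    profile <- .stage("accessibility", accessibilityProfile(
      structure, probeRadius = cfg$probeRadius,
      nSpherePoints = cfg$nSpherePoints, threshold = cfg$burialThreshold))
    contacts <- .stage("contacts",
                       residueContacts(structure, cfg$contactCutoff))
    core <- .stage("core", structuralCore(profile, contacts))
    sections$accessibility <- list(
      nResidues = nrow(accessibilityTable(profile)),
      nBuried = sum(isBuried(profile)))
    sections$core <- coreComponents(core)
    sections$coreStats <- coreHydrophobicStats(core, structure)

    log0("pocket detection")
    pockets <- .stage("pockets", detectPockets(
      structure, spacing = cfg$gridSpacing, pspThreshold = cfg$pspThreshold,
      minPoints = cfg$minPoints, probeRadius = cfg$probeRadius,
      contactDistance = cfg$liningDistance))
    sections$pockets <- pockets
    if (length(pockets)) {
      cleftKeys <- liningResidues(pockets[[1]])
      sections$cleftByExon <- .stage("tabulate_by_exon",
                                     tabulateByExon(cleftKeys, exonMap))
    }

    log0("surface patches")
    patches <- .stage("patches", basicPatch(
      structure, profile, linkDistance = cfg$patchLinkDistance,
      minSize = cfg$patchMinSize))
    sections$patches <- patches
  }

  log0("mutation classification")
  mut <- mutations
  if (tableOnly) {
    if (!("location" %in% names(mut)))
      stop("table-only mode requires a 'location' column in the mutation table")
  } else {
    if (is.null(structure))
      stop("structural mutation classification requires a structure; ",
           "use tableOnly = TRUE to classify from a printed location column")
    locs <- character(nrow(mut))
    for (i in seq_len(nrow(mut)))
      locs[i] <- .stage("classify_location", classifyLocation(
        mut$position[i], catalytic = catalytic, cleft = cleftKeys,
        profile = profile, patches = patches, structure = structure,
        patchDistance = cfg$patchDistance))
    mut$location <- locs
  }
  mut <- .stage("effect_flags",
                annotateMutations(mut, dvThreshold = cfg$dvThreshold))

  if (!is.null(ligandList) && length(ligandList)) {
    log0("ligand geometry")
    sections$ligandSpacing <- .stage("ligand_spacing",
                                     aggregateSpacing(ligandList))
    if (!is.null(structure)) {
      r <- residueTable(structure)
      basics <- intersect(cleftKeys, r$key[r$aa %in% c("K", "R")])
      if (length(basics) >= 2)
        sections$basicPairs <- .stage("basic_pairs", matchBasicPairs(
          basics, structure, sections$ligandSpacing,
          tolerance = cfg$clTolerance))
    }
  }

  report <- new("AnnotationReport", sections = sections, mutations = mut,
                rejected = rejected,
                metadata = list(seed = seed, config = cfg,
                                package = as.character(utils::packageVersion("taz3d"))))
  if (!is.null(outDir)) .writeReport(report, outDir)
  report
}

.writeReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outDir, c("report_mutations.tsv",
                               "report_cleft_by_exon.tsv",
                               "run_summary.json"))
  ok <- FALSE
  on.exit(if (!ok) unlink(paths), add = TRUE)
  mut <- report@mutations
  mut$electrostatic <- ifelse(mut$electrostatic, "X", "")
  mut$stability <- ifelse(mut$stability, "X", "")
  utils::write.table(mut, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cbe <- report@sections$cleftByExon
  if (is.null(cbe))
    cbe <- data.frame(exon_id = character(0), count = integer(0),
                      fraction = numeric(0))
  utils::write.table(cbe, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- list(
    package = report@metadata$package,
    seed = report@metadata$seed,
    config = report@metadata$config,
    nMutations = nrow(report@mutations),
    nRejected = nrow(report@rejected),
    charge = report@sections$charge,
    nPockets = length(report@sections$pockets),
    pocketVolumes = vapply(report@sections$pockets, pocketVolume, numeric(1)),
    pocketMouths = vapply(report@sections$pockets, mouthCount, integer(1)),
    nPatches = length(if (is.null(report@sections$patches)) list()
                      else patchMembers(report@sections$patches)),
    tm = report@sections$tm@segments,
    disorder = report@sections$disorder@segments)
  jsonlite::write_json(summary, paths[3], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  ok <- TRUE
  invisible(paths)
}
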