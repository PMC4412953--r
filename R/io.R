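# core_io: readers/writers for PDB structures, FASTA sequences and the TSV
# exon-map / mutation tables, plus HGVS-p parsing and FL <-> Delta5 numbering.

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records of the selected model into a [PdbStructure]; HETATM
#' records (excluding waters) are routed to ligands. Alternate locations are
#' resolved to the highest occupancy, ties broken by altloc letter order.
#' Nonstandard residues are kept with one-letter code `"X"`. Hydrogens are
#' retained in the atom table but ignored by all heavy-atom computations.
#'
#' @param path Path to a PDB-format file.
#' @param modelIndex Model to read from multi-model files (default 1).
#' @param id Structure identifier; defaults to the file base name.
#' @return A [PdbStructure].
#' @export
#' @examples
#' s <- buildHelix("AGSL")
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(s, f)
#' readStructure(f)
readStructure <- function(path, modelIndex = 1L, id = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = modelIndex > 1L, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e)))
  a <- pdb$atom
  if (modelIndex > 1L) {
    xyz <- pdb$xyz
    if (nrow(xyz) < modelIndex)
      stop("model ", modelIndex, " not present (", nrow(xyz), " models)")
    m <- matrix(xyz[modelIndex, ], ncol = 3, byrow = TRUE)
    a$x <- m[, 1]; a$y <- m[, 2]; a$z <- m[, 3]
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  a$chain[is.na(a$chain)] <- " "
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  # altloc resolution: highest occupancy, then altloc letter order;
  # original atom order within a residue is preserved
  a$.ord <- seq_len(nrow(a))
  keya <- paste(a$chain, a$resno, a$insert, a$elety)
  ord <- order(keya, -a$o, a$alt)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety)), , drop = FALSE]
  a <- a[order(a$.ord), , drop = FALSE]

  el <- a$elesy
  if (is.null(el)) el <- rep("", nrow(a))
  el[is.na(el) | !nzchar(el)] <-
    toupper(substr(gsub("[^A-Za-z].*", "", a$elety[is.na(el) | !nzchar(el)]), 1, 1))
  el <- toupper(el)

  prot <- a$type == "ATOM"
  het <- a$type == "HETATM" & !(a$resid %in% c("HOH", "WAT", "DOD"))
  if (!any(prot)) stop("no ATOM records found in ", path)

  ap <- a[prot, , drop = FALSE]
  o <- order(ap$chain, ap$resno, ap$insert)
  ap <- ap[o, , drop = FALSE]
  atoms <- data.frame(
    chain = ap$chain, resno = as.integer(ap$resno), icode = ap$insert,
    resid = ap$resid, aa = aaThreeToOne(ap$resid), elety = ap$elety,
    element = el[prot][o], x = ap$x, y = ap$y, z = ap$z, occ = ap$o,
    stringsAsFactors = FALSE)

  ligs <- list()
  if (any(het)) {
    ah <- a[het, , drop = FALSE]
    elh <- el[het]
    keyl <- paste(ah$chain, ah$resno, ah$resid)
    for (k in unique(keyl)) {
      sel <- keyl == k
      ligs[[length(ligs) + 1L]] <- .makeLigand(
        id = paste0(ah$resid[sel][1], "_", ah$chain[sel][1], ah$resno[sel][1]),
        atoms = data.frame(name = ah$elety[sel], element = elh[sel],
                           x = ah$x[sel], y = ah$y[sel], z = ah$z[sel],
                           stringsAsFactors = FALSE))
    }
  }
  new("PdbStructure", id = id, atoms = atoms, ligands = ligs)
}

# Build a CLLigand, detecting phosphate groups (each P with oxygens within
# bondDistance).
.makeLigand <- function(id, atoms, bondDistance = 1.8) {
  pidx <- which(toupper(atoms$element) == "P")
  oidx <- which(toupper(atoms$element) == "O")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  groups <- lapply(pidx, function(p) {
    if (!length(oidx)) return(list(P = p, O = integer(0)))
    d <- sqrt(colSums((t(xyz[oidx, , drop = FALSE]) - xyz[p, ])^2))
    list(P = p, O = oidx[d <= bondDistance])
  })
  new("CLLigand", id = id, atoms = atoms, groups = groups)
}

#' Write a structure to a PDB file
#'
#' Polymer atoms are written as ATOM records, ligand atoms as HETATM.
#' Coordinates round-trip through [readStructure()] at PDB precision
#' (3 decimals).
#'
#' @param structure A [PdbStructure].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeStructure <- function(structure, path) {
  a <- structure@atoms
  xyz <- c(t(as.matrix(a[, c("x", "y", "z")])))
  lig <- structure@ligands
  type <- rep("ATOM", nrow(a))
  resid <- a$resid; chain <- a$chain; resno <- a$resno
  elety <- a$elety; occ <- a$occ; insert <- a$icode
  if (length(lig)) {
    maxres <- if (nrow(a)) max(a$resno) else 0L
    for (i in seq_along(lig)) {
      la <- lig[[i]]@atoms
      xyz <- c(xyz, c(t(as.matrix(la[, c("x", "y", "z")]))))
      type <- c(type, rep("HETATM", nrow(la)))
      resid <- c(resid, rep(substr(lig[[i]]@id, 1, 3), nrow(la)))
      chain <- c(chain, rep("L", nrow(la)))
      resno <- c(resno, rep(maxres + i, nrow(la)))
      elety <- c(elety, la$name)
      occ <- c(occ, rep(1, nrow(la)))
      insert <- c(insert, rep("", nrow(la)))
    }
  }
  insert[!nzchar(insert)] <- ""
  bio3d::write.pdb(file = path, xyz = xyz, type = type, resno = resno,
                   resid = resid, chain = chain, elety = elety, o = occ,
                   insert = insert)
  invisible(path)
}

#' Read amino-acid sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param offset Numbering offset applied to every record (position `i` has
#'   biological number `i + offset`).
#' @return List of [SequenceRecord] objects, named by FASTA identifier.
#' @export
readFastaSequences <- function(path, offset = 0L) {
  ss <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(ss), function(i) {
    id <- strsplit(names(ss)[i], "\\s+")[[1]][1]
    new("SequenceRecord", id = id,
        seq = toupper(as.character(ss[[i]])), offset = as.integer(offset))
  })
  names(out) <- vapply(out, function(r) r@id, character(1))
  out
}

#' Read an exon map from TSV
#'
#' Expects a tab-delimited file with header columns `exon_id`, `start`, `end`
#' (full-length protein numbering, 1-based inclusive). Lines starting with
#' `#` are ignored. Entries are validated (start <= end, no overlaps) and
#' returned sorted by start.
#'
#' @param path Path to the TSV file.
#' @return An [ExonMap].
#' @export
readExonMap <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         comment.char = "#", colClasses = "character")
  if (!nrow(d)) return(new("ExonMap", entries = data.frame(
    exon_id = character(0), start = integer(0), end = integer(0),
    stringsAsFactors = FALSE)))
  if (!all(c("exon_id", "start", "end") %in% names(d)))
    stop("exon map needs columns exon_id, start, end")
  e <- data.frame(exon_id = d$exon_id, start = as.integer(d$start),
                  end = as.integer(d$end), stringsAsFactors = FALSE)
  if (any(is.na(e$start)) || any(is.na(e$end)))
    stop("non-integer exon boundaries in ", path)
  if (any(e$start > e$end)) stop("exon with start > end in ", path)
  e <- e[order(e$start), , drop = FALSE]
  rownames(e) <- NULL
  if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)]))
    stop("overlapping exon ranges in ", path)
  new("ExonMap", entries = e)
}

#' Exon containing a residue position
#'
#' @param position Integer vector of FL residue positions.
#' @param exonMap An [ExonMap].
#' @return Character vector of exon ids (`NA` where unassigned).
#' @export
exonOf <- function(position, exonMap) {
  e <- exonTable(exonMap)
  vapply(position, function(p) {
    hit <- which(e$start <= p & e$end >= p)
    if (length(hit)) e$exon_id[hit[1]] else NA_character_
  }, character(1))
}

#' Parse an HGVS protein missense notation
#'
#' Accepts strings of the form `p.<Ref3><pos><Alt3>` (e.g. `"p.Gly197Arg"`).
#'
#' @param text Character vector of HGVS-p strings.
#' @return `data.frame` with columns `hgvs_p`, `ref`, `position`, `alt`.
#' @export
#' @examples
#' parseHgvsP("p.His69Gln")
parseHgvsP <- function(text) {
  m <- regmatches(text, regexec("^p\\.([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", text))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad))
    stop("malformed HGVS-p notation: ", paste(text[bad], collapse = ", "))
  ref <- aaThreeToOne(vapply(m, `[`, character(1), 2))
  alt <- aaThreeToOne(vapply(m, `[`, character(1), 4))
  pos <- as.integer(vapply(m, `[`, character(1), 3))
  if (any(ref == "X") || any(alt == "X"))
    stop("unknown residue code in: ",
         paste(text[ref == "X" | alt == "X"], collapse = ", "))
  if (any(pos < 1)) stop("HGVS position must be >= 1")
  if (any(ref == alt))
    stop("reference and alternate residues identical in: ",
         paste(text[ref == alt], collapse = ", "))
  data.frame(hgvs_p = text, ref = ref, position = pos, alt = alt,
             stringsAsFactors = FALSE)
}

#' Read a missense mutation table from TSV
#'
#' Expects tab-delimited text with header columns `hgvs_p` and `exon`;
#' additional columns (e.g. printed location/flag/effect columns of a
#' published table) are carried through untouched. Lines starting with `#`
#' are ignored.
#'
#' @param path Path to the TSV file.
#' @param strict If `TRUE` (default) a malformed HGVS string aborts with the
#'   offending row index; if `FALSE` such rows are dropped with a warning and
#'   returned in the `"rejected"` attribute.
#' @return `data.frame` with columns `hgvs_p`, `ref`, `position`, `alt`,
#'   `exon` plus any extra input columns.
#' @export
readMutationTable <- function(path, strict = TRUE) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         comment.char = "#", colClasses = "character")
  if (!nrow(d)) {
    out <- data.frame(hgvs_p = character(0), ref = character(0),
                      position = integer(0), alt = character(0),
                      stringsAsFactors = FALSE)
    if (!("exon" %in% names(d))) d$exon <- character(0)
    out <- cbind(out, d[, setdiff(names(d), "hgvs_p"), drop = FALSE])
    attr(out, "rejected") <- out[0, ]
    return(out)
  }
  if (!("hgvs_p" %in% names(d)))
    stop("mutation table needs column hgvs_p")
  if (!("exon" %in% names(d))) d$exon <- NA_character_
  parsed <- lapply(seq_len(nrow(d)), function(i)
    tryCatch(parseHgvsP(d$hgvs_p[i]), error = function(e) {
      if (strict)
        stop("row ", i, " of ", path, ": ", conditionMessage(e), call. = FALSE)
      NULL
    }))
  ok <- !vapply(parsed, is.null, logical(1))
  if (any(!ok))
    warning(sum(!ok), " malformed mutation row(s) dropped: rows ",
            paste(which(!ok), collapse = ", "))
  p <- do.call(rbind, parsed[ok])
  extra <- d[ok, setdiff(names(d), "hgvs_p"), drop = FALSE]
  out <- cbind(p, extra, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rejected") <- cbind(row = which(!ok),
                                 d[!ok, , drop = FALSE])
  out
}

#' Convert between full-length and Delta5 residue numbering
#'
#' The Delta5 isoform lacks exon 5. FL positions below the exon-5 start map
#' to themselves; FL positions above the exon-5 end map to
#' `position - length(exon 5)`; FL positions inside exon 5 have no Delta5
#' counterpart and map to `NA`. `"d5_to_fl"` is the inverse on its range.
#'
#' @param position Integer vector of residue positions (>= 1).
#' @param direction `"fl_to_d5"` or `"d5_to_fl"`.
#' @param exonMap An [ExonMap] containing exon `"5"`.
#' @return Integer vector; `NA` marks undefined positions.
#' @export
#' @examples
#' em <- packagedFixtures()$exonMap
#' mapNumbering(155, "fl_to_d5", em)  # 125
#' mapNumbering(130, "fl_to_d5", em)  # NA: inside exon 5
mapNumbering <- function(position, direction = c("fl_to_d5", "d5_to_fl"),
                         exonMap) {
  direction <- match.arg(direction)
  if (any(position < 1)) stop("position must be >= 1")
  e <- exonTable(exonMap)
  i5 <- which(e$exon_id == "5")
  if (!length(i5)) stop("exon map does not contain exon 5")
  s5 <- e$start[i5[1]]; e5 <- e$end[i5[1]]
  len5 <- e5 - s5 + 1L
  if (direction == "fl_to_d5") {
    out <- ifelse(position < s5, position,
                  ifelse(position > e5, position - len5, NA_integer_))
  } else {
    out <- ifelse(position < s5, position, position + len5)
  }
  as.integer(out)
}
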