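# synthetic_data: deterministic generators for ideal backbones, pocket
# constructs with known ground truth, and cardiolipin-like ligands.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Build an ideal peptide backbone with fixed torsions
#'
#' Places N, CA, C, O (and CB for non-Gly) atoms with standard bond lengths
#' and angles and the requested phi/psi torsions (omega fixed at 180).
#' Optionally adds a pseudo side-chain terminal nitrogen for Lys/Arg
#' (extended along the CA-CB direction) so basic-patch geometry is testable
#' on ideal constructs.
#'
#' @param seq One-letter amino-acid string (length >= 4 for secondary
#'   structure work; >= 1 accepted).
#' @param phi,psi Backbone torsions in degrees (defaults: ideal alpha helix
#'   -57/-47).
#' @param chain Chain identifier.
#' @param id Structure id.
#' @param startResno First residue number.
#' @param sidechainN Place NZ (Lys) / NH1 (Arg) pseudo-atoms.
#' @return A [PdbStructure].
#' @export
#' @examples
#' h <- buildHelix("LLLLLLLLLLLL")
#' table(assignSecondaryStructure(h))
buildHelix <- function(seq, phi = -57, psi = -47, chain = "A",
                       id = "helix", startResno = 1L, sidechainN = FALSE) {
  if (!is.finite(phi) || !is.finite(psi)) stop("torsions must be finite")
  ch <- .seqChars(seq)
  if (!all(.validAA(ch))) stop("invalid amino-acid letters in seq")
  n <- length(ch)
  bNCA <- 1.458; bCAC <- 1.525; bCN <- 1.329
  aNCAC <- 111.2; aCACN <- 116.2; aCNCA <- 121.7
  N <- CA <- C <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(bNCA, 0, 0)
  t0 <- (180 - aNCAC) * pi / 180
  C[[1]] <- CA[[1]] + bCAC * c(cos(t0), sin(t0), 0)
  for (i in seq_len(n)[-1]) {
    N[[i]] <- .placeAtom(N[[i - 1]], CA[[i - 1]], C[[i - 1]], bCN, aCACN, psi)
    CA[[i]] <- .placeAtom(CA[[i - 1]], C[[i - 1]], N[[i]], bNCA, aCNCA, 180)
    C[[i]] <- .placeAtom(C[[i - 1]], N[[i]], CA[[i]], bCAC, aNCAC, phi)
  }
  rows <- list()
  addAtom <- function(resno, aa, name, el, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = resno, icode = "",
      resid = aaOneToThree(aa), aa = aa, elety = name, element = el,
      x = xyz[1], y = xyz[2], z = xyz[3], occ = 1,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    rn <- startResno + i - 1L
    addAtom(rn, ch[i], "N", "N", N[[i]])
    addAtom(rn, ch[i], "CA", "C", CA[[i]])
    addAtom(rn, ch[i], "C", "C", C[[i]])
    O <- .placeAtom(N[[i]], CA[[i]], C[[i]], 1.231, 120.8, psi + 180)
    addAtom(rn, ch[i], "O", "O", O)
    if (ch[i] != "G") {
      CB <- .placeAtom(C[[i]], N[[i]], CA[[i]], 1.521, 110.4, -122.6)
      addAtom(rn, ch[i], "CB", "C", CB)
      if (sidechainN && ch[i] %in% c("K", "R")) {
        dirCB <- (CB - CA[[i]]) / sqrt(sum((CB - CA[[i]])^2))
        addAtom(rn, ch[i], if (ch[i] == "K") "NZ" else "NH1", "N",
                CA[[i]] + 5.0 * dirCB)
      }
    }
  }
  new("PdbStructure", id = id, atoms = do.call(rbind, rows),
      ligands = list())
}

# One pseudo-atom-per-residue structure from a coordinate matrix.
.atomsToStructure <- function(xyz, id, chain = "A") {
  n <- nrow(xyz)
  new("PdbStructure", id = id, atoms = data.frame(
    chain = chain, resno = seq_len(n), icode = "", resid = "ALA",
    aa = "A", elety = "CA", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
    stringsAsFactors = FALSE), ligands = list())
}

.ringPoints <- function(radius, z, spacing) {
  if (radius <= 0) return(matrix(c(0, 0, z), 1, 3))
  k <- max(3L, ceiling(2 * pi * radius / spacing))
  th <- 2 * pi * (seq_len(k) - 1) / k
  cbind(radius * cos(th), radius * sin(th), z)
}

#' Build a pocket construct with known ground truth
#'
#' Pseudo-atom shells enclosing a known void: `"cavity"` (spherical shell,
#' fully enclosed), `"cup"` (cylindrical well with a closed bottom, one
#' opening) and `"tube"` (open cylinder, two openings). Each atom is its own
#' residue so lining-residue recovery can be scored. The ground-truth lining
#' is the designed wall (and, for the cup, floor) residues; near an opening
#' the detected pocket may stop up to about one pocket radius short of the
#' rim, which bounds the achievable lining recovery from below.
#'
#' @param kind `"cavity"`, `"cup"` or `"tube"`.
#' @param radius Shell/cylinder radius in A (default 8 for cavity, 6
#'   otherwise).
#' @param length Cylinder length/height in A (default 16 for cup, 32 for
#'   tube).
#' @param atomSpacing Approximate wall atom spacing (default 2.0 A).
#' @param probeRadius Probe radius used for the feasibility check of the
#'   void size (default 1.4 A).
#' @param seed Optional seed for coordinate jitter.
#' @param jitter Gaussian jitter sd applied to atom positions (default 0).
#' @return List with `structure` ([PdbStructure]), `lining` (ground-truth
#'   residue keys), `mouths` (expected count), `kind` and `params`.
#' @export
#' @examples
#' cav <- buildPocketConstruct("cavity")
#' cav$mouths  # 0 by construction
buildPocketConstruct <- function(kind = c("cavity", "cup", "tube"),
                                 radius = NULL, length = NULL,
                                 atomSpacing = 2.0, probeRadius = 1.4,
                                 seed = NULL, jitter = 0) {
  kind <- match.arg(kind)
  rocc <- 1.7 + probeRadius   # occupied radius of a carbon pseudo-atom
  if (kind == "cavity") {
    if (is.null(radius)) radius <- 8
    if (radius - rocc < 1.5)
      stop("cavity radius too small to hold any grid point")
    nAtoms <- ceiling(4 * pi * radius^2 / atomSpacing^2)
    xyz <- fibonacciSphere(nAtoms) * radius
    gtIdx <- seq_len(nrow(xyz))
    mouths <- 0L
  } else {
    if (is.null(radius)) radius <- 6
    if (is.null(length)) length <- if (kind == "cup") 16 else 32
    if (radius - rocc < 1.5)
      stop("cylinder radius too small to hold any grid point")
    zs <- seq(0, length, by = atomSpacing)
    wall <- do.call(rbind, lapply(zs, function(z)
      .ringPoints(radius, z, atomSpacing)))
    wallZ <- wall[, 3]
    if (kind == "cup") {
      disk <- do.call(rbind, lapply(seq(0, radius - atomSpacing,
                                        by = atomSpacing), function(r)
        .ringPoints(r, 0, atomSpacing)))
      xyz <- rbind(disk, wall)
      mouths <- 1L
    } else {
      xyz <- wall
      mouths <- 2L
    }
    gtIdx <- seq_len(nrow(xyz))
  }
  if (jitter > 0) {
    xyz <- .withSeed(seed, xyz + matrix(stats::rnorm(3 * nrow(xyz), 0, jitter),
                                        nrow(xyz), 3))
  }
  s <- .atomsToStructure(xyz, id = paste0(kind, "_construct"))
  r <- residueTable(s)
  list(structure = s, lining = r$key[gtIdx], mouths = mouths, kind = kind,
       params = list(radius = radius, length = length,
                     atomSpacing = atomSpacing, seed = seed,
                     jitter = jitter))
}

#' Generate cardiolipin-like ligands with parameterized phosphate spacing
#'
#' Each ligand has two phosphate groups (one P, four tetrahedral O each);
#' the oxygen-centroid separation is drawn from
#' `Normal(meanSpacing, jitterSd)` (truncated at 0) and the ligand is placed
#' at a random orientation and offset. Deterministic for a fixed seed.
#'
#' @param n Number of ligands (>= 1).
#' @param meanSpacing Target mean centroid spacing in A (default 8.1, the
#'   survey mean for cardiolipin).
#' @param jitterSd Spacing standard deviation in A (default 0.4).
#' @param seed Integer seed.
#' @return List of [CLLigand] objects.
#' @export
#' @examples
#' ll <- makeClLigands(5, seed = 1)
#' spacingMean(aggregateSpacing(ll))
makeClLigands <- function(n, meanSpacing = 8.1, jitterSd = 0.4, seed = 1L) {
  stopifnot(n >= 1, jitterSd >= 0)
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  .withSeed(seed, {
    lapply(seq_len(n), function(i) {
      d <- max(0, stats::rnorm(1, meanSpacing, jitterSd))
      rot <- randomRotation()
      shift <- stats::runif(3, -20, 20)
      g1 <- rbind(c(0, 0, 0), tet * 1.51)
      g2 <- sweep(rbind(c(0, 0, 0), tet * 1.51), 2, c(d, 0, 0), "+")
      xyz <- rbind(g1, g2) %*% t(rot)
      xyz <- sweep(xyz, 2, shift, "+")
      atoms <- data.frame(
        name = c("P1", paste0("O1", 1:4), "P2", paste0("O2", 1:4)),
        element = rep(c("P", "O", "P", "O"), c(1, 4, 1, 4)),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        stringsAsFactors = FALSE)
      new("CLLigand", id = sprintf("CL_%03d", i), atoms = atoms,
          groups = list(list(P = 1L, O = 2:5), list(P = 6L, O = 7:10)))
    })
  })
}
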