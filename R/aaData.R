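#' @title Amino-acid reference tables
#' @description Reference tables used across the package: one/three-letter
#' codes, Kyte-Doolittle hydropathy, theoretical maximum accessible surface
#' areas, Zamyatnin side-chain volumes, van der Waals radii and the default
#' formal-charge scheme.
#' @name aaData
NULL

.AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
          Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
          L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
          S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

.AA3TO1 <- structure(names(.AA3), names = toupper(.AA3))

#' Kyte-Doolittle hydropathy values
#'
#' Per-residue hydropathy index on the standard scale (Ile 4.5 ... Arg -4.5).
#'
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
#' @examples
#' kyteDoolittle()[["I"]]
kyteDoolittle <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

#' Theoretical maximum accessible surface areas
#'
#' Per-residue maximum solvent-accessible surface area (A^2) used to normalize
#' absolute SASA into relative accessibility (theoretical values of Tien et
#' al.). Relative accessibility below the burial threshold defines a buried
#' residue.
#'
#' @return Named numeric vector (A^2) over the 20 standard amino acids.
#' @export
maxAsaTable <- function() {
  c(A = 129, R = 274, N = 195, D = 193, C = 167,
    Q = 225, E = 223, G = 104, H = 224, I = 197,
    L = 201, K = 236, M = 224, F = 240, P = 159,
    S = 155, T = 172, W = 285, Y = 263, V = 174)
}

#' Zamyatnin residue volumes
#'
#' Mean amino-acid residue volumes (A^3) used for the side-chain volume-change
#' stability rule.
#'
#' @return Named numeric vector (A^3).
#' @export
residueVolumes <- function() {
  c(A =  88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
    Q = 143.8, E = 138.4, G =  60.1, H = 153.2, I = 166.7,
    L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
    S =  89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)
}

.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
          H = 1.20, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

#' Van der Waals radii by element
#'
#' @param element Character vector of element symbols.
#' @param default Radius (A) for elements absent from the table.
#' @param onUnknown `"default"` to fall back to `default` silently,
#'   `"warn"` to warn once, `"error"` to stop.
#' @return Numeric vector of radii (A).
#' @export
vdwRadius <- function(element, default = 1.70,
                      onUnknown = c("warn", "default", "error")) {
  onUnknown <- match.arg(onUnknown)
  el <- toupper(element)
  r <- .VDW[el]
  miss <- is.na(r)
  if (any(miss)) {
    if (onUnknown == "error")
      stop("unknown element(s): ", paste(unique(el[miss]), collapse = ", "))
    if (onUnknown == "warn")
      warning("unknown element(s) ", paste(unique(el[miss]), collapse = ", "),
              "; using default radius ", default)
    r[miss] <- default
  }
  unname(r)
}

#' Default hydrophobic residue set
#'
#' Hydrophobic amino acids used for core statistics and core-conservation
#' counts, aligned with the hydrophobic shading classes of structure-annotated
#' alignments (C,I,L,M,V plus the aromatic F,W,Y and Ala).
#'
#' @return Character vector of one-letter codes.
#' @export
hydrophobicSet <- function() c("A", "C", "F", "I", "L", "M", "V", "W", "Y")

#' Formal charge scheme
#'
#' Two views of amino-acid charge. `charges` holds per-residue formal charges
#' for net-charge sums (Lys/Arg +1, Asp/Glu -1, all others 0; His contributes
#' 0). `classes` holds the charge class used by the mutation electrostatic
#' rule: `negative` (D,E), `positive` (K,R), `histidine` (H), `neutral`
#' otherwise. Histidine forming its own class is what lets His substitutions
#' flag as electrostatic while leaving the net-charge sum unchanged.
#'
#' @return List with elements `charges` (named numeric) and `classes`
#'   (named character), each covering the 20 standard amino acids.
#' @export
#' @examples
#' chargeScheme()$charges[["K"]]
#' chargeScheme()$classes[["H"]]
chargeScheme <- function() {
  charges <- stats::setNames(numeric(20), .AA1)
  charges[c("K", "R")] <- 1
  charges[c("D", "E")] <- -1
  classes <- stats::setNames(rep("neutral", 20), .AA1)
  classes[c("D", "E")] <- "negative"
  classes[c("K", "R")] <- "positive"
  classes["H"] <- "histidine"
  list(charges = charges, classes = classes)
}

#' Convert three-letter residue codes to one-letter
#'
#' Unknown or nonstandard codes become `"X"`.
#'
#' @param x Character vector of three-letter codes (any case).
#' @return Character vector of one-letter codes.
#' @export
aaThreeToOne <- function(x) {
  out <- .AA3TO1[toupper(x)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Convert one-letter residue codes to three-letter
#'
#' @param x Character vector of one-letter codes.
#' @return Character vector of three-letter codes; `"Xaa"` for unknowns.
#' @export
aaOneToThree <- function(x) {
  out <- .AA3[toupper(x)]
  out[is.na(out)] <- "Xaa"
  unname(out)
}

.validAA <- function(x) x %in% c(.AA1, "X")
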