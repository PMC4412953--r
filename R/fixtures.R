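# Packaged fixtures: the transcribed mutation table, the exon map,
# the per-exon cleft-residue counts, and a synthetic tafazzin-like sequence
# standing in for the (non-redistributable) database accession.

#' Synthetic tafazzin-like sequence
#'
#' A deterministic 292-residue construct with the documented ground truth of
#' human tafazzin built in: an N-terminal hydrophobic stretch (residues
#' 7-27) that a hydropathy scan reports as the single transmembrane helix;
#' the HX4D catalytic motif at His69/Asp74 (the only motif occurrence);
#' the basic cleft/patch residues Arg57, Arg94, Lys106, Lys117, Arg123,
#' Lys152, Arg233; a hydrophilic, charged-rich exon-5 region (125-154, with
#' Phe128) that the charge-hydropathy heuristic labels disordered; and a
#' modeled-domain (41-245 minus exon 5) net formal charge of +5. It is a
#' synthetic stand-in, not the biological sequence: residue identities
#' outside these anchors are filler.
#'
#' @return A [SequenceRecord] (id `"TAZ_synthetic"`, offset 0).
#' @export
tazSyntheticSequence <- function() {
  bg <- strsplit("SLTAGQVNPS", "")[[1]]
  s <- bg[((seq_len(292) - 1) %% 10) + 1]
  s[1] <- "M"
  s[2:6] <- c("A", "S", "T", "P", "Q")
  s[7:27] <- strsplit("LLVALLAGVLLIPLVVAFGLL", "")[[1]]
  s[28:39] <- strsplit("SGTPQSNTSGSQ", "")[[1]]
  fix <- c(`40` = "N", `43` = "T", `50` = "L", `51` = "Y", `54` = "I",
           `57` = "R", `62` = "P", `69` = "H", `71` = "S", `74` = "D",
           `80` = "G", `82` = "L", `94` = "R", `101` = "D", `104` = "F",
           `106` = "K", `110` = "S", `116` = "G", `117` = "K", `118` = "C",
           `119` = "V", `123` = "R", `124` = "G", `161` = "G", `169` = "L",
           `174` = "W", `178` = "F", `183` = "V", `195` = "G", `197` = "G",
           `209` = "I", `210` = "L", `212` = "L", `214` = "H", `216` = "G",
           `233` = "R", `240` = "G")
  s[as.integer(names(fix))] <- fix
  s[125:154] <- strsplit("ESPFKEDSGQEKSDNEQKSPEKDGSEQKDS", "")[[1]]
  s[187] <- "K"
  new("SequenceRecord", id = "TAZ_synthetic",
      seq = paste(s, collapse = ""), offset = 0L)
}

#' Packaged fixtures
#'
#' Bundle of the in-package fixtures: the 39-row missense mutation table
#' (with printed location/flag/effect columns), the tafazzin exon map
#' (exon 5 = 125-154), the published per-exon counts of the 57
#' substrate-binding-cleft residues, the catalytic positions \{69, 74\}, and
#' the synthetic tafazzin-like sequence.
#'
#' @return Named list: `mutations` (data.frame), `exonMap` ([ExonMap]),
#'   `cleftCountsByExon` (named integer vector, exons 2,4,6,7,8,9),
#'   `catalytic` (integer vector), `sequence` ([SequenceRecord]), and
#'   `paths` of the underlying TSV files.
#' @export
#' @examples
#' fx <- packagedFixtures()
#' nrow(fx$mutations)                 # 39
#' length(unique(fx$mutations$position))  # 33
packagedFixtures <- function() {
  mutPath <- system.file("extdata", "taz_mutations.tsv", package = "taz3d",
                         mustWork = TRUE)
  exonPath <- system.file("extdata", "taz_exon_map.tsv", package = "taz3d",
                          mustWork = TRUE)
  list(
    mutations = readMutationTable(mutPath),
    exonMap = readExonMap(exonPath),
    cleftCountsByExon = c(`2` = 10L, `4` = 18L, `6` = 15L, `7` = 5L,
                          `8` = 6L, `9` = 3L),
    catalytic = c(69L, 74L),
    sequence = tazSyntheticSequence(),
    paths = c(mutations = mutPath, exonMap = exonPath))
}
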