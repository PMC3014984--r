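## Exact algebra over IUPAC-degenerate codons: expansion, translation,
## amino-acid multiplicities, stop detection, and the polar/nonpolar/turn
## residue-class codons of the binary-code design.

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

## class -> canonical degenerate codon of the binary code:
##   POLAR    VAN -> K,H,E,Q,D,N        (6 residues)
##   NONPOLAR NTN -> M,L,I,V,F          (5 residues)
##   TURN     VRS -> Q,E,N,D,H,K,R,S,G  (9 residues)
.CLASS_CODON <- c(POLAR = "VAN", NONPOLAR = "NTN", TURN = "VRS")

.normalizeCodon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || is.na(codon))
    stop("codon must be a single character string")
  codon <- chartr("u", "t", codon)      # RNA input tolerated
  codon <- toupper(chartr("U", "T", codon))
  if (nchar(codon) != 3L)
    stop("codon must have exactly 3 symbols, got '", codon, "'")
  syms <- strsplit(codon, "")[[1L]]
  bad <- setdiff(syms, names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad))
    stop("invalid IUPAC DNA symbol '", bad[1L], "' in codon '", codon, "'")
  codon
}

#' Expand a degenerate codon to its concrete codons
#'
#' A degenerate codon is written with IUPAC nucleotide ambiguity symbols
#' (e.g. \code{V} = A/C/G, \code{R} = A/G, \code{N} = A/C/G/T); the physical
#' oligonucleotide mixture contains every concrete codon in the Cartesian
#' product of the three per-symbol base sets.
#'
#' @param codon a 3-symbol IUPAC DNA codon (case-insensitive; U is read as T).
#' @return Sorted character vector of concrete 3-base codons.
#' @examples
#' expandCodon("VAN")  # the 12 codons of the polar-class mixture
#' @export
expandCodon <- function(codon) {
  codon <- .normalizeCodon(codon)
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP[strsplit(codon, "")[[1L]]], "")
  grid <- expand.grid(sets[[1L]], sets[[2L]], sets[[3L]],
                      stringsAsFactors = FALSE)
  sort(paste0(grid[[1L]], grid[[2L]], grid[[3L]]))
}

#' Translate a concrete codon
#'
#' Standard genetic code (translation table 1, the \emph{E. coli} host code);
#' the three stop codons return \code{"*"}.
#'
#' @param codon a concrete 3-base DNA codon.
#' @return Single 1-letter amino acid, or \code{"*"} for a stop.
#' @examples
#' translateCodon("ATG")
#' translateCodon("TAA")
#' @export
translateCodon <- function(codon) {
  codon <- .normalizeCodon(codon)
  if (!all(strsplit(codon, "")[[1L]] %in% c("A", "C", "G", "T")))
    stop("codon '", codon, "' is degenerate; expand it first")
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Amino acids encoded by a degenerate codon
#'
#' Union of the translations of the full expansion; stops are excluded from
#' the set (use \code{\link{containsStop}} to flag them).
#'
#' @inheritParams expandCodon
#' @return Sorted character vector of 1-letter amino acids.
#' @examples
#' aminoAcidSet("VAN")  # K H E Q D N: the six polar residues
#' aminoAcidSet("VRS")  # the nine turn residues
#' @export
aminoAcidSet <- function(codon) {
  aa <- vapply(expandCodon(codon), translateCodon, character(1L))
  sort(unique(aa[aa != "*"]))
}

#' Codon multiplicity of each amino acid under a degenerate codon
#'
#' When a library position is synthesized as an equimolar degenerate codon,
#' each amino acid is sampled in proportion to how many concrete codons
#' encode it; e.g. under \code{NTN} leucine is enriched 6/16. Multiplicities
#' (plus the stop count reported in the \code{"stops"} attribute) sum to the
#' expansion size.
#'
#' @inheritParams expandCodon
#' @return Named integer vector of multiplicities, decreasing, with an
#'   integer attribute \code{"stops"} counting stop codons in the expansion.
#' @examples
#' aminoAcidProfile("NTN")  # L:6 V:4 I:3 F:2 M:1
#' @export
aminoAcidProfile <- function(codon) {
  aa <- vapply(expandCodon(codon), translateCodon, character(1L))
  tab <- table(aa[aa != "*"])
  prof <- sort(stats::setNames(as.integer(tab), names(tab)), decreasing = TRUE)
  attr(prof, "stops") <- sum(aa == "*")
  prof
}

#' Does a degenerate codon's expansion contain a stop?
#'
#' Library positions must be stop-free or variants are lost at preselection.
#'
#' @inheritParams expandCodon
#' @return \code{TRUE} iff any concrete expansion translates to a stop.
#' @examples
#' containsStop("VAN")  # FALSE: V excludes T at the first base
#' containsStop("TRR")  # TRUE: expansion contains TAA, TAG, TGA
#' @export
containsStop <- function(codon) {
  any(vapply(expandCodon(codon), translateCodon, character(1L)) == "*")
}

#' Canonical degenerate codon of a residue class
#'
#' The binary code assigns one degenerate codon per design class:
#' \code{VAN} for polar, \code{NTN} for nonpolar, \code{VRS} for turn
#' positions.
#'
#' @param className one of \code{"POLAR"}, \code{"NONPOLAR"}, \code{"TURN"}.
#' @return The 3-symbol degenerate codon.
#' @examples
#' classCodon("POLAR")
#' @export
classCodon <- function(className) {
  if (!is.character(className) || length(className) != 1L ||
      !className %in% names(.CLASS_CODON))
    stop("unknown residue class '", paste(className, collapse = ","),
         "'; must be POLAR, NONPOLAR or TURN")
  unname(.CLASS_CODON[className])
}

#' Residue-class table of the binary code
#'
#' @return Named list (POLAR, NONPOLAR, TURN), each element a list with the
#'   canonical degenerate \code{codon} and the sorted \code{aminoAcids} it
#'   encodes.
#' @examples
#' residueClasses()$NONPOLAR
#' @export
residueClasses <- function() {
  lapply(stats::setNames(names(.CLASS_CODON), names(.CLASS_CODON)),
         function(cl) list(codon = classCodon(cl),
                           aminoAcids = aminoAcidSet(classCodon(cl))))
}
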