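## S4 class definitions and validity methods.

.RESIDUE_CLASSES <- c("POLAR", "NONPOLAR", "TURN")

#' TemplateSpec: a binary-patterned design template
#'
#' Ordered per-position specification of a designed protein: each position is
#' either FIXED (a single residue) or COMBINATORIAL (a residue class of the
#' binary code), and carries a segment label (helix1..helix4, turn1..turn3,
#' ncap, ccap). The per-class multiplicities used for diversity calculations
#' are carried alongside (defaults NONPOLAR 5, POLAR 6, TURN 8).
#'
#' @slot name template identifier.
#' @slot positions a \code{DataFrame} with columns \code{index} (1-based,
#'   contiguous), \code{segment}, \code{role} (\code{FIXED} or
#'   \code{COMBINATORIAL}) and \code{value} (a residue letter or a class
#'   name).
#' @slot classMultiplicities named numeric: effective amino-acid count per
#'   combinatorial position, by class.
#' @aliases TemplateSpec
#' @exportClass TemplateSpec
setClass("TemplateSpec",
  representation(name = "character",
                 positions = "DataFrame",
                 classMultiplicities = "numeric"))

setValidity("TemplateSpec", function(object) {
  p <- object@positions
  need <- c("index", "segment", "role", "value")
  if (!all(need %in% colnames(p)))
    return(paste("positions must have columns", paste(need, collapse = ", ")))
  n <- nrow(p)
  if (n == 0L) return("template has no positions")
  if (!identical(as.integer(p$index), seq_len(n)))
    return("position indices must be contiguous from 1")
  if (!all(p$role %in% c("FIXED", "COMBINATORIAL")))
    return("role must be FIXED or COMBINATORIAL")
  fx <- p$role == "FIXED"
  if (any(!p$value[fx] %in% .AA20))
    return(paste0("invalid fixed residue '",
                  p$value[fx][!p$value[fx] %in% .AA20][1L], "'"))
  if (any(!p$value[!fx] %in% .RESIDUE_CLASSES))
    return(paste0("unknown residue class '",
                  p$value[!fx][!p$value[!fx] %in% .RESIDUE_CLASSES][1L], "'"))
  if (!all(.RESIDUE_CLASSES %in% names(object@classMultiplicities)))
    return("classMultiplicities must name POLAR, NONPOLAR and TURN")
  TRUE
})

#' SynthLibrary: an in-silico synthesized library
#'
#' A set of library members sampled from a template: DNA sequences, their
#' translations (NA where a frameshift makes translation undefined), and the
#' record of injected synthesis-error events.
#'
#' @slot dna a \code{DNAStringSet}, one entry per member (names are ids).
#' @slot protein character vector of translations; \code{NA} when the DNA
#'   length is not a multiple of 3.
#' @slot frameshift logical, TRUE where the reading frame is broken.
#' @slot events \code{DataFrame} of applied error events (\code{id},
#'   \code{type}, \code{ntPosition}, \code{length}).
#' @slot template name of the originating template.
#' @slot seed integer RNG seed used to synthesize the members.
#' @slot weighting sampling scheme (\code{uniform_codon} or
#'   \code{uniform_amino_acid}).
#' @aliases SynthLibrary
#' @exportClass SynthLibrary
setClass("SynthLibrary",
  representation(dna = "DNAStringSet",
                 protein = "character",
                 frameshift = "logical",
                 events = "DataFrame",
                 template = "character",
                 seed = "integer",
                 weighting = "character"))

setValidity("SynthLibrary", function(object) {
  n <- length(object@dna)
  if (length(object@protein) != n || length(object@frameshift) != n)
    return("dna, protein and frameshift must have equal length")
  TRUE
})

#' ConformityReport: validation of a protein against the template
#'
#' Result of the indel-aware alignment of an observed protein to a design
#' template: per-position class calls, violations, localized indels and the
#' conformity score (fraction of aligned combinatorial positions whose
#' residue lies in the position's class set).
#'
#' @slot sequenceLength length of the observed protein in residues.
#' @slot alignedPairs \code{DataFrame}: \code{templateIndex},
#'   \code{sequenceIndex}, \code{residue}, \code{segment}, \code{role},
#'   \code{class}, \code{conforms}.
#' @slot violations \code{DataFrame} subset of non-conforming positions.
#' @slot indels \code{DataFrame}: \code{kind} (insertion/deletion),
#'   \code{length} (residues), \code{segment}, \code{templatePosition}.
#' @slot conformityScore numeric in [0, 1].
#' @slot alignmentScore optimal global alignment score.
#' @slot template name of the template aligned against.
#' @aliases ConformityReport
#' @exportClass ConformityReport
setClass("ConformityReport",
  representation(sequenceLength = "integer",
                 alignedPairs = "DataFrame",
                 violations = "DataFrame",
                 indels = "DataFrame",
                 conformityScore = "numeric",
                 alignmentScore = "numeric",
                 template = "character"))

setValidity("ConformityReport", function(object) {
  s <- object@conformityScore
  if (length(s) != 1L || is.na(s) || s < 0 || s > 1)
    return("conformityScore must be a single value in [0, 1]")
  TRUE
})

#' FrequencyEstimate: complementation frequency of a rescue screen
#'
#' Raw and false-positive-corrected complementation frequency with an exact
#' Clopper-Pearson 95\% confidence interval and a \code{"~1/X"} display
#' rendering at one significant figure.
#'
#' @slot raw selective / total colony proportion after dilution correction.
#' @slot adjusted raw times the confirmed fraction of retested colonies.
#' @slot ciLow,ciHigh exact 95\% binomial interval on the adjusted proportion.
#' @slot display \code{"~1/X"} rendering at one significant figure.
#' @slot counts the input plate counts, as a list.
#' @aliases FrequencyEstimate
#' @exportClass FrequencyEstimate
setClass("FrequencyEstimate",
  representation(raw = "numeric", adjusted = "numeric",
                 ciLow = "numeric", ciHigh = "numeric",
                 display = "character", counts = "list"))

setValidity("FrequencyEstimate", function(object) {
  if (object@adjusted > object@raw + 1e-12)
    return("adjusted frequency cannot exceed raw frequency")
  TRUE
})

#' CoverageStats: library coverage of the theoretical diversity
#'
#' Expected number of distinct designs among the sampled members and a
#' birthday-problem collision bound, for a theoretical diversity that may be
#' astronomically large (held exactly as a big integer).
#'
#' @slot diversity exact theoretical diversity (a \code{bignat}).
#' @slot sampled number of sampled members.
#' @slot expectedUnique expected number of distinct designs.
#' @slot collisionBound birthday bound sampled^2 / (2 diversity), capped at 1.
#' @aliases CoverageStats
#' @exportClass CoverageStats
setClass("CoverageStats",
  representation(diversity = "ANY", sampled = "numeric",
                 expectedUnique = "numeric", collisionBound = "numeric"))
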