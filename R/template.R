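## Template model: the designed 102-residue 4-helix-bundle template,
## template file IO, position counts, exact theoretical diversity, and the
## degenerate gene.

## Most-used E. coli K-12 codon per amino acid; used to emit concrete codons
## at fixed template positions (the design only constrains combinatorial
## positions, but a degenerate gene needs a deterministic choice).
.ECOLI_PREFERRED_CODON <- c(
  A = "GCG", C = "TGC", D = "GAT", E = "GAA", F = "TTT",
  G = "GGC", H = "CAT", I = "ATC", K = "AAA", L = "CTG",
  M = "ATG", N = "AAC", P = "CCG", Q = "CAG", R = "CGC",
  S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAT")

## One period of the amphipathic helix pattern: polar (P) / nonpolar (N)
## arranged so the nonpolar face tracks the 3.6-residue-per-turn repeat.
.HELIX_REPEAT <- strsplit("PNPPNNPPNPPNNP", "")[[1L]]

.DEFAULT_MULTIPLICITIES <- c(NONPOLAR = 5, POLAR = 6, TURN = 8)

#' Construct a TemplateSpec
#'
#' @param name template identifier.
#' @param segment character vector of segment labels, one per position.
#' @param role character vector, \code{"FIXED"} or \code{"COMBINATORIAL"}.
#' @param value residue letter (fixed) or class name (combinatorial).
#' @param classMultiplicities named numeric, per-class effective amino-acid
#'   counts used by \code{\link{theoreticalDiversity}} in declared mode.
#' @return A validated \linkS4class{TemplateSpec}.
#' @examples
#' TemplateSpec("mini", segment = c("ncap", "helix1", "helix1"),
#'              role = c("FIXED", "COMBINATORIAL", "COMBINATORIAL"),
#'              value = c("M", "POLAR", "NONPOLAR"))
#' @export
TemplateSpec <- function(name, segment, role, value,
                         classMultiplicities = .DEFAULT_MULTIPLICITIES) {
  n <- length(value)
  pos <- S4Vectors::DataFrame(index = seq_len(n),
                              segment = as.character(segment),
                              role = as.character(role),
                              value = as.character(value))
  methods::new("TemplateSpec", name = as.character(name), positions = pos,
               classMultiplicities = classMultiplicities)
}

#' @describeIn templateLength number of residues in the template.
#' @export
setMethod("templateLength", "TemplateSpec",
          function(x) nrow(x@positions))

#' Template length
#'
#' @param x a \linkS4class{TemplateSpec}.
#' @return Integer number of positions.
#' @rdname templateLength
#' @name templateLength
NULL

#' Per-position table of a template
#'
#' @param x a \linkS4class{TemplateSpec}.
#' @return The positions \code{DataFrame}.
#' @rdname templatePositions
#' @export
setMethod("templatePositions", "TemplateSpec", function(x) x@positions)

setMethod("show", "TemplateSpec", function(object) {
  cnt <- positionCounts(object)
  cat("TemplateSpec '", object@name, "': ", templateLength(object),
      " positions\n", sep = "")
  cat("  combinatorial: NONPOLAR ", cnt[["NONPOLAR"]], ", POLAR ",
      cnt[["POLAR"]], ", TURN ", cnt[["TURN"]], "; fixed ",
      cnt[["FIXED"]], "\n", sep = "")
  cat("  segments: ", paste(unique(object@positions$segment), collapse = " "),
      "\n", sep = "")
})

#' The packaged default 4-helix-bundle template
#'
#' A 102-residue template with 22 nonpolar, 34 polar and 12 turn
#' combinatorial positions plus 34 fixed positions: four amphipathic helix
#' segments whose combinatorial positions follow the binary repeat
#' PNPPNNPPNPPNNP, separated by three turns carrying four combinatorial turn
#' positions each, with Gly-rich fixed turn flanks and a fixed N-terminal
#' Met. Fixed-residue identities are a documented synthetic stand-in (the
#' design constrains classes and counts, not fixed identities) and are
#' user-replaceable via a template file.
#'
#' @return A \linkS4class{TemplateSpec} of length 102.
#' @examples
#' tpl <- defaultTemplate()
#' positionCounts(tpl)
#' @export
defaultTemplate <- function() {
  helixComb <- function(len, phase) {
    .HELIX_REPEAT[((phase - 1L + seq_len(len) - 1L) %% 14L) + 1L]
  }
  seg <- character(0); role <- character(0); val <- character(0)
  add <- function(s, r, v) {
    seg <<- c(seg, rep(s, length(v))); role <<- c(role, rep(r, length(v)))
    val <<- c(val, v)
  }
  addHelix <- function(name, len, phase) {
    add(name, "FIXED", c("D", "A"))                       # N-side fixed flank
    pat <- helixComb(len, phase)
    add(name, "COMBINATORIAL", ifelse(pat == "P", "POLAR", "NONPOLAR"))
    add(name, "FIXED", c("K", "G"))                       # C-side fixed flank
  }
  addTurn <- function(name) {
    add(name, "FIXED", "G")
    add(name, "COMBINATORIAL", rep("TURN", 4L))
    add(name, "FIXED", "G")
  }
  add("ncap", "FIXED", c("M", "G", "S", "D"))
  addHelix("helix1", 15L, 1L); addTurn("turn1")
  addHelix("helix2", 13L, 3L); addTurn("turn2")
  addHelix("helix3", 15L, 1L); addTurn("turn3")
  addHelix("helix4", 13L, 3L)
  add("ccap", "FIXED", c("G", "S", "R", "E", "L", "Q", "K", "N"))
  TemplateSpec("bp4helix102", seg, role, val)
}

#' Position counts by role and class
#'
#' @param x a \linkS4class{TemplateSpec}.
#' @return Named integer vector (\code{NONPOLAR}, \code{POLAR}, \code{TURN},
#'   \code{FIXED}) summing to the template length.
#' @rdname positionCounts
#' @export
setMethod("positionCounts", "TemplateSpec", function(x) {
  p <- x@positions
  out <- stats::setNames(integer(4L), c("NONPOLAR", "POLAR", "TURN", "FIXED"))
  out["FIXED"] <- sum(p$role == "FIXED")
  for (cl in .RESIDUE_CLASSES)
    out[cl] <- sum(p$role == "COMBINATORIAL" & p$value == cl)
  out
})

#' Exact theoretical diversity of a template
#'
#' Product over combinatorial positions of the per-class amino-acid
#' multiplicity, computed in exact big-integer arithmetic. In
#' \code{"declared"} mode the template's declared multiplicities are used
#' (default 5/6/8, giving 5^22 x 6^34 x 8^12 for the default template, which
#' rounds to 5e+52); \code{"codon_derived"} instead counts the amino acids
#' actually encoded by each class codon (5/6/9 - the turn codon VRS encodes
#' nine residues, so this mode is about 4.1-fold larger).
#'
#' @param x a \linkS4class{TemplateSpec}.
#' @param mode \code{"declared"} or \code{"codon_derived"}.
#' @return A \code{\link{bignat}} exact integer; render with
#'   \code{\link{sciSignif}} or \code{format}.
#' @examples
#' sciSignif(theoreticalDiversity(defaultTemplate()))$string
#' @rdname theoreticalDiversity
#' @export
setMethod("theoreticalDiversity", "TemplateSpec", function(x, mode) {
  mode <- match.arg(mode, c("declared", "codon_derived"))
  cnt <- positionCounts(x)
  mult <- if (mode == "declared") x@classMultiplicities else
    vapply(.RESIDUE_CLASSES,
           function(cl) length(aminoAcidSet(classCodon(cl))), numeric(1L))
  d <- bignat(1)
  for (cl in .RESIDUE_CLASSES)
    for (i in seq_len(cnt[[cl]])) d <- d * mult[[cl]]
  d
})

#' Degenerate gene of a template
#'
#' Emits the 3N-symbol degenerate DNA encoding the template: combinatorial
#' positions emit their class's canonical degenerate codon (VAN/NTN/VRS),
#' fixed positions the most-used \emph{E. coli} codon for the residue. No
#' position's codon set contains a stop.
#'
#' @param x a \linkS4class{TemplateSpec}.
#' @return A \code{DNAString} of length 3 x template length.
#' @examples
#' degenerateGene(defaultTemplate())
#' @rdname degenerateGene
#' @export
setMethod("degenerateGene", "TemplateSpec", function(x) {
  p <- x@positions
  codons <- ifelse(p$role == "FIXED",
                   .ECOLI_PREFERRED_CODON[p$value],
                   .CLASS_CODON[p$value])
  Biostrings::DNAString(paste(codons, collapse = ""))
})

## ---- template file IO ------------------------------------------------------

#' Parse a template specification
#'
#' Reads either the TSV format (columns \code{index segment role value},
#' \code{#} comments allowed) or a compact pattern string: one character per
#' position, an uppercase residue letter for a fixed position or lowercase
#' \code{n}/\code{p}/\code{t} for a combinatorial nonpolar/polar/turn
#' position (lowercase escapes avoid collision with the residue letters
#' N, P, T). In compact form, segments are inferred: runs of n/p become
#' helix1..k, runs of t become turn1..k, a leading fixed run is the ncap, a
#' trailing one the ccap, and interior fixed runs join the preceding
#' segment.
#'
#' @param file path to a template file (used unless \code{text} is given).
#' @param text template content as a character scalar or vector of lines.
#' @param name template identifier (defaults to the file base name).
#' @return A validated \linkS4class{TemplateSpec}.
#' @examples
#' parseTemplate(text = "Mpnppnnpp")
#' @export
parseTemplate <- function(file = NULL, text = NULL, name = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply 'file' or 'text'")
    text <- readLines(file, warn = FALSE)
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(file))
  }
  if (is.null(name)) name <- "template"
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  keep <- !grepl("^\\s*(#|$)", lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty template: no content lines")
  if (grepl("\t", lines[1L]) || grepl("^\\s*index\\b", lines[1L]))
    .parseTemplateTSV(lines, lineNo, name)
  else
    .parseTemplateCompact(paste(trimws(lines), collapse = ""), name)
}

.parseTemplateTSV <- function(lines, lineNo, name) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(tolower(trimws(fields[[1L]][1L])), "index")) {
    fields <- fields[-1L]; lineNo <- lineNo[-1L]
  }
  if (!length(fields)) stop("empty template: header only")
  bad <- which(lengths(fields) < 4L)
  if (length(bad))
    stop("line ", lineNo[bad[1L]], ": expected 4 tab-separated fields")
  m <- do.call(rbind, lapply(fields, function(f) trimws(f[1:4])))
  idx <- suppressWarnings(as.integer(m[, 1L]))
  if (anyNA(idx)) stop("line ", lineNo[which(is.na(idx))[1L]],
                       ": non-integer index")
  if (anyDuplicated(idx)) stop("line ",
    lineNo[which(duplicated(idx))[1L]], ": duplicate index ",
    idx[which(duplicated(idx))[1L]])
  o <- order(idx)
  if (!identical(idx[o], seq_along(idx)))
    stop("position indices must be contiguous from 1")
  role <- toupper(m[o, 3L]); value <- m[o, 4L]
  fx <- role == "FIXED"
  value[fx] <- toupper(value[fx])
  value[!fx] <- toupper(value[!fx])
  badRes <- which(fx & !value %in% .AA20)
  if (length(badRes))
    stop("line ", lineNo[o][badRes[1L]], ": invalid residue '",
         value[badRes[1L]], "'")
  badCls <- which(!fx & !value %in% .RESIDUE_CLASSES)
  if (length(badCls))
    stop("line ", lineNo[o][badCls[1L]], ": unknown class '",
         value[badCls[1L]], "'")
  TemplateSpec(name, m[o, 2L], role, value)
}

.parseTemplateCompact <- function(s, name) {
  ch <- strsplit(s, "")[[1L]]
  if (!length(ch)) stop("empty template: no content lines")
  cls <- c(n = "NONPOLAR", p = "POLAR", t = "TURN")
  cat_ <- ifelse(ch %in% names(cls), ifelse(ch == "t", "T", "H"), "F")
  bad <- which(cat_ == "F" & !ch %in% .AA20)
  if (length(bad))
    stop("invalid template character '", ch[bad[1L]], "' at position ",
         bad[1L])
  r <- rle(cat_)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  seg <- character(length(ch)); hN <- 0L; tN <- 0L
  for (k in seq_along(r$values)) {
    lab <- switch(r$values[k],
      H = { hN <- hN + 1L; paste0("helix", hN) },
      T = { tN <- tN + 1L; paste0("turn", tN) },
      F = if (k == 1L) "ncap" else if (k == length(r$values)) "ccap"
          else seg[starts[k] - 1L])
    seg[starts[k]:ends[k]] <- lab
  }
  role <- ifelse(cat_ == "F", "FIXED", "COMBINATORIAL")
  value <- ifelse(cat_ == "F", ch, cls[ch])
  TemplateSpec(name, seg, role, value)
}

#' Write a template as TSV
#'
#' Writes the \code{index segment role value} TSV form;
#' \code{\link{parseTemplate}} of the output reproduces the template exactly.
#'
#' @param template a \linkS4class{TemplateSpec}.
#' @param file output path, or \code{""} to return the text invisibly.
#' @return Invisibly, the lines written.
#' @export
writeTemplate <- function(template, file = "") {
  p <- template@positions
  lines <- c(paste0("# template: ", template@name),
             "index\tsegment\trole\tvalue",
             paste(p$index, p$segment, p$role, p$value, sep = "\t"))
  if (nzchar(file)) writeLines(lines, file)
  invisible(lines)
}

## segment -> vector of template indices
.segmentIndices <- function(template) {
  p <- template@positions
  split(p$index, factor(p$segment, levels = unique(p$segment)))
}
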