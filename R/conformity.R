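## Indel-aware validation of observed proteins against the binary-patterned
## template: class-aware global alignment with affine gaps, per-position
## conformity calls, indel localization, and amphipathic-helix geometry.

## Eisenberg consensus hydrophobicity scale
.EISENBERG <- c(
  A =  0.62, R = -2.53, N = -0.78, D = -0.90, C =  0.29,
  Q = -0.85, E = -0.74, G =  0.48, H = -0.40, I =  1.38,
  L =  1.06, K = -1.50, M =  0.64, F =  1.19, P =  0.12,
  S = -0.18, T = -0.05, W =  0.81, Y =  0.26, V =  1.08)

#' Eisenberg consensus hydrophobicity scale
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
eisenbergScale <- function() .EISENBERG

#' Alignment scoring parameters
#'
#' Position-specific scores for aligning a protein to a template: a residue
#' at a combinatorial position scores \code{classMatch} if it belongs to the
#' position's class set and \code{classMismatch} otherwise; fixed positions
#' use \code{fixedMatch}/\code{fixedMismatch}. Gaps are affine: a run of
#' length L costs \code{gapOpen + L * gapExtend}. Terminal gaps are penalized
#' (true global alignment), since observed hits are full-length ORFs.
#'
#' @param classMatch,classMismatch scores at combinatorial positions.
#' @param fixedMatch,fixedMismatch scores at fixed positions.
#' @param gapOpen,gapExtend affine gap penalties (non-positive).
#' @return A list of class \code{"AlignmentParams"}.
#' @export
alignmentParams <- function(classMatch = 2, classMismatch = -2,
                            fixedMatch = 3, fixedMismatch = -3,
                            gapOpen = -8, gapExtend = -1) {
  stopifnot(classMatch > classMismatch, gapOpen <= 0, gapExtend <= 0)
  structure(list(classMatch = classMatch, classMismatch = classMismatch,
                 fixedMatch = fixedMatch, fixedMismatch = fixedMismatch,
                 gapOpen = gapOpen, gapExtend = gapExtend),
            class = "AlignmentParams")
}

.checkProtein <- function(protein) {
  if (methods::is(protein, "AAString") || methods::is(protein, "AAStringSet"))
    protein <- as.character(protein)[1L]
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein))
    stop("protein must be a single non-empty sequence")
  res <- strsplit(toupper(protein), "")[[1L]]
  bad <- setdiff(res, .AA20)
  if (length(bad))
    stop("non-standard residue character '", bad[1L], "' in protein")
  res
}

## per-template-position score of every residue: m x 20 matrix
.scoreMatrix <- function(template, params) {
  p <- template@positions
  classSets <- lapply(residueClasses(), `[[`, "aminoAcids")
  S <- matrix(params$classMismatch, nrow = nrow(p), ncol = length(.AA20),
              dimnames = list(NULL, .AA20))
  for (i in seq_len(nrow(p))) {
    if (p$role[i] == "FIXED") {
      S[i, ] <- params$fixedMismatch
      S[i, p$value[i]] <- params$fixedMatch
    } else {
      S[i, classSets[[p$value[i]]]] <- params$classMatch
    }
  }
  S
}

#' Align an observed protein to a template
#'
#' Global (end-to-end) optimal alignment of a protein against the template
#' under class-aware position-specific scoring with affine gaps, by dynamic
#' programming (Gotoh three-state recursion). Ties are broken
#' deterministically: diagonal, then insertion (extra protein residue), then
#' deletion (skipped template position).
#'
#' @param protein a protein sequence (character or \code{AAString}).
#' @param template a \linkS4class{TemplateSpec}.
#' @param params an \code{\link{alignmentParams}} object.
#' @return A list with \code{score} and \code{path}, a data.frame of
#'   alignment columns with \code{op} (\code{match}/\code{insertion}/
#'   \code{deletion}), \code{templateIndex} and \code{sequenceIndex}
#'   (\code{NA} on the gapped side).
#' @export
alignToTemplate <- function(protein, template, params = alignmentParams()) {
  res <- .checkProtein(protein)
  stopifnot(methods::is(template, "TemplateSpec"))
  m <- templateLength(template)
  n <- length(res)
  S <- .scoreMatrix(template, params)
  go <- params$gapOpen; ge <- params$gapExtend
  NEG <- -.Machine$double.xmax / 4

  M <- matrix(NEG, m + 1L, n + 1L)  # ends in a match column
  X <- matrix(NEG, m + 1L, n + 1L)  # ends in insertion (gap in template)
  Y <- matrix(NEG, m + 1L, n + 1L)  # ends in deletion (gap in protein)
  M[1L, 1L] <- 0
  if (n > 0L) X[1L, 2L:(n + 1L)] <- go + ge * seq_len(n)
  if (m > 0L) Y[2L:(m + 1L), 1L] <- go + ge * seq_len(m)

  sres <- match(res, .AA20)
  for (i in seq_len(m)) {
    Si <- S[i, ]
    for (j in seq_len(n)) {
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + Si[sres[j]]
      X[i + 1L, j + 1L] <- max(M[i + 1L, j] + go + ge,
                               X[i + 1L, j] + ge,
                               Y[i + 1L, j] + go + ge)
      Y[i + 1L, j + 1L] <- max(M[i, j + 1L] + go + ge,
                               X[i, j + 1L] + go + ge,
                               Y[i, j + 1L] + ge)
    }
  }
  fin <- c(M[m + 1L, n + 1L], X[m + 1L, n + 1L], Y[m + 1L, n + 1L])
  state <- c("M", "X", "Y")[which.max(fin)]   # which.max: first max = priority
  score <- max(fin)

  eq <- function(a, b) abs(a - b) < 1e-9
  i <- m; j <- n
  ops <- character(0); ti <- integer(0); si <- integer(0)
  while (i > 0L || j > 0L) {
    if (state == "M") {
      ops <- c("match", ops); ti <- c(i, ti); si <- c(j, si)
      cur <- M[i + 1L, j + 1L] - S[i, sres[j]]
      state <- if (eq(cur, M[i, j])) "M" else if (eq(cur, X[i, j])) "X" else "Y"
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      ops <- c("insertion", ops); ti <- c(NA_integer_, ti); si <- c(j, si)
      cur <- X[i + 1L, j + 1L]
      state <- if (i == 0L && j == 1L) "M"
               else if (eq(cur, M[i + 1L, j] + go + ge)) "M"
               else if (eq(cur, X[i + 1L, j] + ge)) "X" else "Y"
      j <- j - 1L
    } else {
      ops <- c("deletion", ops); ti <- c(i, ti); si <- c(NA_integer_, si)
      cur <- Y[i + 1L, j + 1L]
      state <- if (j == 0L && i == 1L) "M"
               else if (eq(cur, M[i, j + 1L] + go + ge)) "M"
               else if (eq(cur, X[i, j + 1L] + go + ge)) "X" else "Y"
      i <- i - 1L
    }
  }
  list(score = score,
       path = data.frame(op = ops, templateIndex = ti, sequenceIndex = si))
}

## collapse gap runs in an alignment path into indel events
.indelEvents <- function(path, template) {
  p <- template@positions
  runs <- rle(path$op)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  out <- list()
  for (k in seq_along(runs$values)) {
    op <- runs$values[k]
    if (op == "match") next
    rows <- starts[k]:ends[k]
    len <- length(rows)
    if (op == "deletion") {
      ## majority segment over the deleted template positions;
      ## ties resolved toward the N-terminal-most segment
      segs <- p$segment[path$templateIndex[rows]]
      tab <- table(factor(segs, levels = unique(p$segment)))
      seg <- names(tab)[which.max(tab)]
      anchor <- path$templateIndex[rows[1L]]
    } else {
      ## insertion columns carry no template index; anchor on the template
      ## position aligned immediately before the run (after it at the N-term)
      before <- path$templateIndex[seq_len(starts[k] - 1L)]
      before <- before[!is.na(before)]
      anchor <- if (length(before)) max(before) else {
        after <- path$templateIndex[-seq_len(ends[k])]
        min(after[!is.na(after)], nrow(p))
      }
      seg <- p$segment[anchor]
    }
    out[[length(out) + 1L]] <- data.frame(
      kind = op, length = len, segment = seg, templatePosition = anchor)
  }
  if (!length(out))
    return(S4Vectors::DataFrame(kind = character(0), length = integer(0),
                                segment = character(0),
                                templatePosition = integer(0)))
  S4Vectors::DataFrame(do.call(rbind, out))
}

#' Validate a protein against the binary pattern
#'
#' Aligns the protein to the template (allowing indels), calls every aligned
#' position against the design - fixed positions must match their residue,
#' combinatorial positions must carry a residue from their class set -
#' localizes insertion/deletion runs to template segments, and scores
#' conformity as the fraction of aligned combinatorial positions whose
#' residue is in the position's class set.
#'
#' @inheritParams alignToTemplate
#' @return A \linkS4class{ConformityReport}.
#' @examples
#' lib <- sampleLibrary(defaultTemplate(), 1, seed = 7)
#' rpt <- conformityReport(proteinSeqs(lib)[[1]], defaultTemplate())
#' conformityScore(rpt)
#' @export
conformityReport <- function(protein, template, params = alignmentParams()) {
  res <- .checkProtein(protein)
  aln <- alignToTemplate(protein, template, params)
  p <- template@positions
  classSets <- lapply(residueClasses(), `[[`, "aminoAcids")
  mt <- aln$path[aln$path$op == "match", , drop = FALSE]
  residue <- res[mt$sequenceIndex]
  role <- p$role[mt$templateIndex]
  value <- p$value[mt$templateIndex]
  conforms <- ifelse(role == "FIXED", residue == value,
                     mapply(function(r, cl) r %in% classSets[[cl]],
                            residue, value))
  pairs <- S4Vectors::DataFrame(
    templateIndex = mt$templateIndex, sequenceIndex = mt$sequenceIndex,
    residue = residue, segment = p$segment[mt$templateIndex],
    role = role, class = ifelse(role == "FIXED", NA_character_, value),
    conforms = unname(conforms))
  comb <- pairs$role == "COMBINATORIAL"
  score <- if (any(comb)) mean(pairs$conforms[comb]) else 1
  methods::new("ConformityReport",
               sequenceLength = length(res),
               alignedPairs = pairs,
               violations = pairs[!pairs$conforms, , drop = FALSE],
               indels = .indelEvents(aln$path, template),
               conformityScore = score,
               alignmentScore = aln$score,
               template = template@name)
}

#' @describeIn ConformityReport-accessors conformity score in [0, 1].
#' @export
setMethod("conformityScore", "ConformityReport", function(x) x@conformityScore)

#' @describeIn ConformityReport-accessors localized indel events.
#' @export
setMethod("indels", "ConformityReport", function(x) x@indels)

#' @describeIn ConformityReport-accessors non-conforming aligned positions.
#' @export
setMethod("violations", "ConformityReport", function(x) x@violations)

#' @describeIn ConformityReport-accessors per-column alignment table.
#' @export
setMethod("alignedPairs", "ConformityReport", function(x) x@alignedPairs)

#' Accessors for ConformityReport
#'
#' @param x a \linkS4class{ConformityReport}.
#' @name ConformityReport-accessors
#' @rdname ConformityReport-accessors
NULL

setMethod("show", "ConformityReport", function(object) {
  cat("ConformityReport vs '", object@template, "': sequence length ",
      object@sequenceLength, "\n", sep = "")
  cat("  conformity score ", format(object@conformityScore, digits = 4),
      "; violations ", nrow(object@violations), "\n", sep = "")
  ind <- object@indels
  if (nrow(ind)) {
    for (k in seq_len(nrow(ind)))
      cat("  ", ind$kind[k], " of ", ind$length[k], " residue(s) in ",
          ind$segment[k], " (template position ", ind$templatePosition[k],
          ")\n", sep = "")
  } else cat("  no indels\n")
})

#' Hydrophobic moment of a helical segment
#'
#' Magnitude of the vector sum of per-residue hydrophobicities placed at
#' successive angles of \code{delta} degrees around the helical wheel
#' (default 100 = 360/3.6, the alpha-helical repeat). An amphipathic
#' segment, with nonpolar residues clustered on one face, has a large
#' moment; an 18-residue homopolymer at 100 degrees spans exactly five turns
#' and has moment 0.
#'
#' @param segment residue sequence (character scalar or vector).
#' @param delta angular step per residue, degrees.
#' @param scale named hydrophobicity scale; default Eisenberg consensus.
#' @return Non-negative moment magnitude.
#' @examples
#' hydrophobicMoment(strrep("L", 18))  # ~0: five full turns cancel
#' @export
hydrophobicMoment <- function(segment, delta = 100, scale = eisenbergScale()) {
  res <- if (length(segment) > 1L) toupper(segment)
         else strsplit(toupper(segment), "")[[1L]]
  if (!length(res)) stop("segment must be non-empty")
  bad <- setdiff(res, names(scale))
  if (length(bad))
    stop("residue '", bad[1L], "' missing from the hydrophobicity scale")
  h <- scale[res]
  th <- (seq_along(res) - 1L) * delta * pi / 180
  sqrt(sum(h * cos(th))^2 + sum(h * sin(th))^2)
}

#' Per-helix face segregation summary
#'
#' For each helix segment of the template, reports the hydrophobic moment of
#' the aligned residues and the circular mean wheel angle of the
#' nonpolar-class positions - the direction of the designed hydrophobic
#' face. A conformant amphipathic member concentrates hydrophobicity near
#' that angle.
#'
#' @inheritParams alignToTemplate
#' @param delta angular step per residue, degrees.
#' @param scale named hydrophobicity scale.
#' @return A data.frame with one row per helix: \code{segment},
#'   \code{nResidues}, \code{moment}, \code{nonpolarFaceAngle} (degrees in
#'   [0, 360)).
#' @export
faceSegregationScore <- function(protein, template,
                                 params = alignmentParams(),
                                 delta = 100, scale = eisenbergScale()) {
  rpt <- conformityReport(protein, template, params)
  pairs <- rpt@alignedPairs
  helices <- unique(pairs$segment[grepl("^helix", pairs$segment)])
  rows <- lapply(helices, function(h) {
    sub <- pairs[pairs$segment == h, , drop = FALSE]
    sub <- sub[order(sub$templateIndex), , drop = FALSE]
    th <- (sub$templateIndex - min(sub$templateIndex)) * delta * pi / 180
    npl <- !is.na(sub$class) & sub$class == "NONPOLAR"
    ang <- if (any(npl)) {
      a <- atan2(mean(sin(th[npl])), mean(cos(th[npl]))) * 180 / pi
      (a + 360) %% 360
    } else NA_real_
    data.frame(segment = h, nResidues = nrow(sub),
               moment = hydrophobicMoment(sub$residue, delta, scale),
               nonpolarFaceAngle = ang)
  })
  do.call(rbind, rows)
}

#' Text rendering of a conformity report
#'
#' Plain-text analogue of a color-coded pattern figure: the aligned residues
#' with an annotation line marking polar (\code{o}), nonpolar (\code{*}) and
#' turn (\code{-}) combinatorial positions, fixed positions (\code{.}), and
#' violations (\code{!}).
#'
#' @param report a \linkS4class{ConformityReport}.
#' @param width wrap width in columns.
#' @return Character vector of lines.
#' @export
renderPattern <- function(report, width = 60L) {
  pairs <- report@alignedPairs
  marks <- ifelse(!pairs$conforms, "!",
           ifelse(pairs$role == "FIXED", ".",
           ifelse(pairs$class == "POLAR", "o",
           ifelse(pairs$class == "NONPOLAR", "*", "-"))))
  resLine <- paste(pairs$residue, collapse = "")
  markLine <- paste(marks, collapse = "")
  starts <- seq(1L, nchar(resLine), by = width)
  unlist(lapply(starts, function(s) {
    c(substr(resLine, s, s + width - 1L),
      substr(markLine, s, s + width - 1L), "")
  }))
}
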