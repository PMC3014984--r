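## Seeded in-silico synthesis of library members, the oligo-synthesis error
## model, the frame/stop preselection filter, and fixture generation.

## evaluate expr under a given seed without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## codon pool and sampling probabilities for one template position
.codonPool <- function(role, value, weighting) {
  if (role == "FIXED") {
    return(list(codons = unname(.ECOLI_PREFERRED_CODON[value]), prob = 1))
  }
  codons <- expandCodon(classCodon(value))
  if (weighting == "uniform_codon") {
    prob <- rep(1 / length(codons), length(codons))
  } else {  # uniform_amino_acid: residue uniform, then a codon for it
    aa <- vapply(codons, translateCodon, character(1L))
    mult <- table(aa)
    prob <- 1 / (length(mult) * as.numeric(mult[aa]))
  }
  list(codons = codons, prob = prob)
}

.emptyEvents <- function() {
  S4Vectors::DataFrame(id = character(0), type = character(0),
                       ntPosition = integer(0), length = integer(0))
}

.translateOrNA <- function(dna) {
  n <- nchar(dna)
  out <- rep(NA_character_, length(dna))
  ok <- n %% 3L == 0L & n > 0L
  if (any(ok))
    out[ok] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(dna[ok]), no.init.codon = TRUE))
  out
}

.newSynthLibrary <- function(ids, dna, events, template, seed, weighting) {
  prot <- .translateOrNA(dna)
  dss <- Biostrings::DNAStringSet(dna)
  names(dss) <- ids
  methods::new("SynthLibrary", dna = dss, protein = prot,
               frameshift = nchar(dna) %% 3L != 0L,
               events = events, template = template,
               seed = as.integer(seed), weighting = weighting)
}

#' Sample library members from a template
#'
#' Draws \code{n} member genes from the template's degenerate design. Under
#' \code{uniform_codon} weighting each combinatorial position draws uniformly
#' over the degenerate codon's concrete expansion (so, e.g., Leu is enriched
#' 6/16 at NTN positions, mirroring an equimolar nucleotide mixture); under
#' \code{uniform_amino_acid} the residue is drawn uniformly from the class
#' set and then a codon for it. Identical seeds give identical libraries.
#'
#' @param template a \linkS4class{TemplateSpec}.
#' @param n number of members (\code{n = 0} gives an empty library).
#' @param seed integer RNG seed.
#' @param weighting \code{"uniform_codon"} or \code{"uniform_amino_acid"}.
#' @return A \linkS4class{SynthLibrary}.
#' @examples
#' lib <- sampleLibrary(defaultTemplate(), n = 3, seed = 1)
#' proteinSeqs(lib)
#' @export
sampleLibrary <- function(template, n, seed,
                          weighting = c("uniform_codon", "uniform_amino_acid")) {
  weighting <- match.arg(weighting)
  stopifnot(methods::is(template, "TemplateSpec"), n >= 0)
  n <- as.integer(n)
  p <- template@positions
  ids <- sprintf("%s_%05d", template@name, seq_len(n))
  if (n == 0L)
    return(.newSynthLibrary(character(0), character(0), .emptyEvents(),
                            template@name, seed, weighting))
  cols <- .withSeed(seed, lapply(seq_len(nrow(p)), function(i) {
    pool <- .codonPool(p$role[i], p$value[i], weighting)
    if (length(pool$codons) == 1L) rep(pool$codons, n)
    else sample(pool$codons, n, replace = TRUE, prob = pool$prob)
  }))
  dna <- do.call(paste0, cols)
  .newSynthLibrary(ids, dna, .emptyEvents(), template@name, seed, weighting)
}

#' Oligo-synthesis error model
#'
#' Error rates for in-silico synthesis: indels occur at codon boundaries with
#' probability \code{indelRate} per boundary, with lengths (in nucleotides)
#' drawn from a geometric distribution with mean \code{indelLengthMean};
#' substitutions occur per base with probability \code{substitutionRate}.
#' Defaults (1e-3, 3, 0) make indel variants rare but observable, matching a
#' library in which occasional synthesis errors survive preselection.
#'
#' @param indelRate per-codon-boundary indel probability.
#' @param indelLengthMean mean indel length in nucleotides (geometric).
#' @param substitutionRate per-base substitution probability.
#' @return A list of class \code{"ErrorModel"}.
#' @export
errorModel <- function(indelRate = 1e-3, indelLengthMean = 3,
                       substitutionRate = 0) {
  stopifnot(indelRate >= 0, indelRate <= 1,
            substitutionRate >= 0, substitutionRate <= 1,
            indelLengthMean >= 1)
  structure(list(indelRate = indelRate, indelLengthMean = indelLengthMean,
                 substitutionRate = substitutionRate), class = "ErrorModel")
}

## edit one DNA string; returns list(dna, events data.frame)
.applyErrorsOne <- function(dna, model) {
  bases <- strsplit(dna, "")[[1L]]
  ev <- list()
  if (model$substitutionRate > 0) {
    hit <- which(stats::runif(length(bases)) < model$substitutionRate)
    for (i in hit) {
      bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
      ev[[length(ev) + 1L]] <- list(type = "substitution", ntPosition = i,
                                    length = 1L)
    }
  }
  nBound <- length(bases) %/% 3L + 1L          # boundaries before codon 1..after last
  hit <- which(stats::runif(nBound) < model$indelRate)
  for (b in rev(hit)) {                        # right-to-left keeps offsets valid
    at <- (b - 1L) * 3L                        # nt offset of the boundary
    len <- stats::rgeom(1L, 1 / model$indelLengthMean) + 1L
    if (stats::runif(1L) < 0.5) {
      ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      bases <- append(bases, ins, after = at)
      ev[[length(ev) + 1L]] <- list(type = "insertion", ntPosition = at + 1L,
                                    length = len)
    } else {
      del <- seq(at + 1L, min(at + len, length(bases)))
      if (!length(del)) next
      bases <- bases[-del]
      ev[[length(ev) + 1L]] <- list(type = "deletion", ntPosition = at + 1L,
                                    length = length(del))
    }
  }
  list(dna = paste(bases, collapse = ""), events = ev)
}

#' Apply a synthesis error model to a library
#'
#' Edits each member's DNA according to the error model (errors act at the
#' DNA level), records the applied events, and re-translates wherever the
#' edited length remains a multiple of 3; frameshifted members get an
#' \code{NA} protein and are flagged.
#'
#' @param lib a \linkS4class{SynthLibrary}.
#' @param model an \code{\link{errorModel}}.
#' @param seed integer RNG seed.
#' @return A new \linkS4class{SynthLibrary} with edited DNA and recorded
#'   events.
#' @export
applyErrorModel <- function(lib, model = errorModel(), seed) {
  stopifnot(methods::is(lib, "SynthLibrary"), inherits(model, "ErrorModel"))
  dna <- as.character(lib@dna)
  ids <- names(lib@dna)
  res <- .withSeed(seed, lapply(dna, .applyErrorsOne, model = model))
  newDna <- vapply(res, `[[`, character(1L), "dna")
  evs <- do.call(rbind, lapply(seq_along(res), function(i) {
    e <- res[[i]]$events
    if (!length(e)) return(NULL)
    data.frame(id = ids[i],
               type = vapply(e, `[[`, character(1L), "type"),
               ntPosition = vapply(e, function(x) as.integer(x$ntPosition),
                                   integer(1L)),
               length = vapply(e, function(x) as.integer(x$length),
                               integer(1L)))
  }))
  events <- if (is.null(evs)) .emptyEvents() else S4Vectors::DataFrame(evs)
  .newSynthLibrary(ids, newDna, events, lib@template, seed, lib@weighting)
}

#' Frame/stop preselection filter
#'
#' Partitions a library into members that survive preselection (DNA length a
#' multiple of 3 and a stop-free translation) and those that do not; variants
#' whose synthesis errors preserve frame and introduce no stop codon pass.
#'
#' @param lib a \linkS4class{SynthLibrary}.
#' @return List with \code{passing} and \code{failing}
#'   \linkS4class{SynthLibrary} objects (an exhaustive, disjoint partition).
#' @export
preselect <- function(lib) {
  stopifnot(methods::is(lib, "SynthLibrary"))
  ok <- !lib@frameshift & !is.na(lib@protein) &
    !grepl("*", lib@protein, fixed = TRUE)
  list(passing = lib[which(ok)], failing = lib[which(!ok)])
}

## in-frame codon-level DNA surgery used by makeFixtures
.insertCodons <- function(dna, afterResidue, codons) {
  at <- 3L * afterResidue
  paste0(substr(dna, 1L, at), paste(codons, collapse = ""),
         substr(dna, at + 1L, nchar(dna)))
}

.deleteCodons <- function(dna, fromResidue, nResidues) {
  from <- 3L * (fromResidue - 1L) + 1L
  to <- 3L * (fromResidue + nResidues - 1L)
  paste0(substr(dna, 1L, from - 1L), substr(dna, to + 1L, nchar(dna)))
}

#' Generate named validator test fixtures
#'
#' Builds a deterministic set of test proteins from the default template:
#' three fully conformant members; \code{fixA}, a 105-residue variant with a
#' 4-residue insertion at the helix1 midpoint and a 1-residue deletion at the
#' helix4 midpoint; \code{fixB}, a 106-residue variant with an 11-residue
#' insertion in helix2 and a 7-residue deletion in helix4; and \code{violW},
#' a member carrying a tryptophan (a residue in no design class) at a
#' combinatorial position.
#'
#' @param template a \linkS4class{TemplateSpec}; the indel fixtures assume
#'   the default 4-helix layout.
#' @param seed integer RNG seed.
#' @param file optional path; if given, the proteins are written as 60-column
#'   FASTA.
#' @return A named \code{AAStringSet} (conformant1..3, fixA, fixB, violW).
#' @examples
#' fx <- makeFixtures(seed = 1)
#' width(fx)[c("fixA", "fixB")]
#' @export
makeFixtures <- function(template = defaultTemplate(), seed = 42L,
                         file = NULL) {
  segIdx <- .segmentIndices(template)
  mid <- function(seg) {
    idx <- segIdx[[seg]]
    idx[ceiling(length(idx) / 2)]
  }
  lib <- sampleLibrary(template, 6L, seed = seed)
  dna <- as.character(lib@dna)
  insCodon <- function(n, class) .withSeed(seed + n, {
    sample(expandCodon(classCodon(class)), n, replace = TRUE)
  })

  fixA <- .deleteCodons(dna[4L], mid("helix4"), 1L)
  fixA <- .insertCodons(fixA, mid("helix1"), insCodon(4L, "POLAR"))
  fixB <- .deleteCodons(dna[5L], mid("helix4") - 3L, 7L)
  fixB <- .insertCodons(fixB, mid("helix2"), insCodon(11L, "NONPOLAR"))

  p <- template@positions
  firstNP <- p$index[p$role == "COMBINATORIAL" & p$value == "NONPOLAR"][1L]
  violW <- dna[6L]
  substr(violW, 3L * (firstNP - 1L) + 1L, 3L * firstNP) <- "TGG"

  prot <- .translateOrNA(c(dna[1:3], fixA, fixB, violW))
  out <- Biostrings::AAStringSet(prot)
  names(out) <- c("conformant1", "conformant2", "conformant3",
                  "fixA", "fixB", "violW")
  if (!is.null(file))
    Biostrings::writeXStringSet(out, file, width = 60L)
  out
}

#' Write library sequences as FASTA
#'
#' @param lib a \linkS4class{SynthLibrary}.
#' @param file output path.
#' @param what \code{"dna"} or \code{"protein"} (frameshifted members are
#'   dropped from protein output).
#' @return Invisibly, the file path.
#' @export
writeLibraryFasta <- function(lib, file, what = c("dna", "protein")) {
  what <- match.arg(what)
  if (what == "dna") {
    Biostrings::writeXStringSet(lib@dna, file, width = 60L)
  } else {
    ok <- !is.na(lib@protein)
    aas <- Biostrings::AAStringSet(lib@protein[ok])
    names(aas) <- names(lib@dna)[ok]
    Biostrings::writeXStringSet(aas, file, width = 60L)
  }
  invisible(file)
}

## ---- SynthLibrary methods --------------------------------------------------

#' @describeIn SynthLibrary-accessors DNA sequences as a \code{DNAStringSet}.
#' @export
setMethod("dnaSeqs", "SynthLibrary", function(x) x@dna)

#' @describeIn SynthLibrary-accessors translations (\code{NA} where
#'   frameshifted), named by member id.
#' @export
setMethod("proteinSeqs", "SynthLibrary",
          function(x) stats::setNames(x@protein, names(x@dna)))

#' @describeIn SynthLibrary-accessors applied error events.
#' @export
setMethod("errorEvents", "SynthLibrary", function(x) x@events)

#' Accessors for SynthLibrary
#'
#' @param x a \linkS4class{SynthLibrary}.
#' @name SynthLibrary-accessors
#' @rdname SynthLibrary-accessors
NULL

#' @export
setMethod("length", "SynthLibrary", function(x) length(x@dna))

#' @export
setMethod("[", "SynthLibrary", function(x, i, j, ..., drop = TRUE) {
  ids <- names(x@dna)[i]
  ev <- x@events[x@events$id %in% ids, , drop = FALSE]
  methods::initialize(x, dna = x@dna[i], protein = x@protein[i],
                      frameshift = x@frameshift[i], events = ev)
})

setMethod("show", "SynthLibrary", function(object) {
  cat("SynthLibrary of ", length(object), " members (template '",
      object@template, "', seed ", object@seed, ", ", object@weighting,
      ")\n", sep = "")
  cat("  frameshifted: ", sum(object@frameshift),
      "; error events: ", nrow(object@events), "\n", sep = "")
})
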