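## Statistics of the auxotroph-rescue screen: complementation frequency with
## false-positive correction and exact confidence intervals, probability of
## recovering a rescuer, library coverage, and small report utilities.

#' Plate counts from a rescue screen
#'
#' @param selective colonies on selective (minimal) plates.
#' @param rich colonies on rich plates (total transformants).
#' @param selDilution,richDilution fold dilution factors (>= 1).
#' @param retested colonies picked for restreak/retransformation.
#' @param confirmed of those, how many reconfirmed (true positives).
#' @return A validated list of class \code{"PlateCounts"}.
#' @export
plateCounts <- function(selective, rich, selDilution = 1, richDilution = 1,
                        retested = 0, confirmed = 0) {
  stopifnot(selective >= 0, rich >= 0, retested >= 0, confirmed >= 0,
            confirmed <= retested, selDilution >= 1, richDilution >= 1)
  structure(list(selective = selective, rich = rich,
                 selDilution = selDilution, richDilution = richDilution,
                 retested = retested, confirmed = confirmed),
            class = "PlateCounts")
}

## exact (Clopper-Pearson) binomial interval via beta quantiles; x may be
## non-integer after false-positive scaling
.clopperPearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- ifelse(x <= 0, 0, stats::qbeta(a, x, n - x + 1))
  hi <- ifelse(x >= n, 1, stats::qbeta(1 - a, x + 1, n - x))
  cbind(lo = lo, hi = hi)
}

## "~1/X" at one significant figure: round the proportion first, then the
## reciprocal (reproduces ~1/50,000 for 2.1e-5 and ~1/10,000 for 1.1e-4)
.displayFrequency <- function(p) {
  if (p <= 0) return("0")
  x <- signif(1 / signif(p, 1), 1)
  paste0("~1/", formatC(round(x), format = "d", big.mark = ","))
}

#' Complementation frequency of a rescue screen
#'
#' The raw frequency divides selective-plate colonies (rescued
#' transformants) by rich-plate colonies (total transformants), after
#' dilution correction. The adjusted frequency corrects for false positives
#' that fail to restreak or retransform, multiplying by the confirmed
#' fraction of retested colonies (no correction when none were retested).
#' An exact Clopper-Pearson 95\% interval is attached to the adjusted
#' proportion - appropriate because selective counts are typically tiny.
#'
#' @param counts a \code{\link{plateCounts}} object.
#' @return A \linkS4class{FrequencyEstimate}.
#' @examples
#' complementationFrequency(plateCounts(selective = 40, rich = 120000,
#'                                      retested = 40, confirmed = 30))
#' @export
complementationFrequency <- function(counts) {
  stopifnot(inherits(counts, "PlateCounts"))
  nTotal <- counts$rich * counts$richDilution
  if (nTotal <= 0) stop("rich colony count is zero: frequency undefined")
  raw <- (counts$selective * counts$selDilution) / nTotal
  adj <- if (counts$retested > 0) raw * counts$confirmed / counts$retested
         else raw
  ci <- .clopperPearson(adj * nTotal, nTotal)
  methods::new("FrequencyEstimate", raw = raw, adjusted = adj,
               ciLow = unname(ci[1L, "lo"]), ciHigh = unname(ci[1L, "hi"]),
               display = .displayFrequency(adj), counts = unclass(counts))
}

setMethod("show", "FrequencyEstimate", function(object) {
  cat("FrequencyEstimate: raw ", signif(object@raw, 3), ", adjusted ",
      signif(object@adjusted, 3), " (", object@display, ")\n", sep = "")
  cat("  95% CI [", signif(object@ciLow, 3), ", ", signif(object@ciHigh, 3),
      "]\n", sep = "")
})

#' Probability of recovering at least one rescuer
#'
#' With a complementation frequency f and N independent transformants, the
#' chance that at least one rescuer is plated is 1 - (1 - f)^N, evaluated in
#' log space so that frequencies of 1e-6 with 1e7 transformants do not
#' underflow.
#'
#' @param frequency complementation frequency in [0, 1] (vectorized).
#' @param transformants number of transformants (>= 0, vectorized).
#' @return Probability in [0, 1].
#' @examples
#' rescueProbability(1e-6, 1e6)  # ~ 1 - exp(-1)
#' @export
rescueProbability <- function(frequency, transformants) {
  stopifnot(all(frequency >= 0), all(frequency <= 1), all(transformants >= 0))
  out <- -expm1(transformants * log1p(-frequency))
  out[frequency == 1 & transformants > 0] <- 1
  out[transformants == 0] <- 0
  out
}

#' Expected distinct designs in a sampled library
#'
#' Coverage of an astronomically large design space by a finite library:
#' expected distinct designs D (1 - (1 - 1/D)^s) for diversity D and sample
#' size s, plus the birthday-problem collision bound s^2 / (2 D) capped at
#' 1. Computed in log space; D may be a \code{\link{bignat}}.
#'
#' @param diversity theoretical diversity (\code{bignat} or numeric >= 1).
#' @param sampled number of sampled members (>= 0).
#' @return A \linkS4class{CoverageStats}.
#' @examples
#' expectedUnique(theoreticalDiversity(defaultTemplate()), 1.5e6)
#' @export
expectedUnique <- function(diversity, sampled) {
  div <- if (inherits(diversity, "bignat")) diversity else bignat(diversity)
  D <- as.numeric(div)
  stopifnot(D >= 1, sampled >= 0)
  eu <- if (sampled == 0) 0
        else if (D == 1) 1
        else -D * expm1(sampled * log1p(-1 / D))
  eu <- min(eu, sampled, D)
  methods::new("CoverageStats", diversity = div, sampled = sampled,
               expectedUnique = eu,
               collisionBound = min(1, sampled^2 / (2 * D)))
}

setMethod("show", "CoverageStats", function(object) {
  cat("CoverageStats: diversity ", sciSignif(object@diversity)$string,
      ", sampled ", format(object@sampled, big.mark = ","), "\n", sep = "")
  cat("  expected unique ", format(object@expectedUnique, digits = 6),
      "; collision bound ", format(object@collisionBound, digits = 3),
      "\n", sep = "")
})

#' Read a plate-count table and compute frequencies
#'
#' Input TSV columns: \code{strain selective rich sel_dilution rich_dilution
#' retested confirmed} (missing dilution/retest columns default to 1/0).
#'
#' @param file path to the TSV.
#' @return A data.frame with raw, adjusted, CI and display columns, one row
#'   per strain.
#' @export
complementationTable <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (is.null(df$sel_dilution)) df$sel_dilution <- 1
  if (is.null(df$rich_dilution)) df$rich_dilution <- 1
  if (is.null(df$retested)) df$retested <- 0
  if (is.null(df$confirmed)) df$confirmed <- 0
  rows <- lapply(seq_len(nrow(df)), function(i) {
    fe <- complementationFrequency(plateCounts(
      df$selective[i], df$rich[i], df$sel_dilution[i], df$rich_dilution[i],
      df$retested[i], df$confirmed[i]))
    data.frame(strain = df$strain[i], raw = fe@raw, adjusted = fe@adjusted,
               ci_low = fe@ciLow, ci_high = fe@ciHigh, display = fe@display)
  })
  do.call(rbind, rows)
}

#' Expand an accession range
#'
#' Parses ranges like \code{"FR718891 - FR718908"} into the full vector of
#' accession identifiers (here 18 of them, endpoints included).
#'
#' @param range character scalar, \code{"PREFIXnnn - PREFIXmmm"} (the second
#'   prefix may be omitted).
#' @return Character vector of accessions.
#' @examples
#' length(parseAccessionRange("FR718891 - FR718908"))
#' @export
parseAccessionRange <- function(range) {
  m <- regmatches(range,
    regexec("^\\s*([A-Za-z]+)(\\d+)\\s*[-–]\\s*([A-Za-z]*)(\\d+)\\s*$",
            range))[[1L]]
  if (!length(m)) stop("cannot parse accession range '", range, "'")
  pre1 <- m[2L]; from <- m[3L]; pre2 <- m[4L]; to <- m[5L]
  if (nzchar(pre2) && pre2 != pre1)
    stop("accession prefixes differ: '", pre1, "' vs '", pre2, "'")
  a <- as.numeric(from); b <- as.numeric(to)
  if (b < a) stop("accession range end precedes start")
  sprintf(paste0(pre1, "%0", nchar(from), "d"), seq(a, b))
}

#' Genome fractions replaced by de novo genes
#'
#' Arithmetic of the headline claim: rescuing \code{rescued} genes out of a
#' genome of \code{totalGenes} replaces 100 * rescued / totalGenes percent
#' of the genome, and 100 * rescued / (essentialCore + minimalExtra) percent
#' of the genes required for growth on minimal media (genes essential under
#' all conditions plus those additionally required on nutrient-poor media).
#'
#' @param rescued number of distinct genes rescued (default 4).
#' @param totalGenes genome gene count (default 4000).
#' @param essentialCore genes essential under all conditions (default 290).
#' @param minimalExtra genes additionally required on minimal media
#'   (default 107).
#' @return Named numeric: \code{genomePercent},
#'   \code{minimalEssentialPercent}.
#' @examples
#' genomeFraction()
#' @export
genomeFraction <- function(rescued = 4, totalGenes = 4000,
                           essentialCore = 290, minimalExtra = 107) {
  c(genomePercent = 100 * rescued / totalGenes,
    minimalEssentialPercent = 100 * rescued / (essentialCore + minimalExtra))
}
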