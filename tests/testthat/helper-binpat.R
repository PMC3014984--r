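# Shared helpers: independent oracles kept deliberately naive.

# brute-force expansion of a degenerate codon by nested loops over the
# IUPAC base sets (independent of expandCodon's expand.grid route)
bruteExpand <- function(codon) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
           W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
           V = "ACG", N = "ACGT")
  syms <- strsplit(toupper(codon), "")[[1]]
  out <- character(0)
  for (a in strsplit(map[syms[1]], "")[[1]])
    for (b in strsplit(map[syms[2]], "")[[1]])
      for (d in strsplit(map[syms[3]], "")[[1]])
        out <- c(out, paste0(a, b, d))
  sort(out)
}

# score one explicit alignment (list of ops) under the affine scheme:
# each maximal gap run costs gapOpen + len * gapExtend
scoreAlignment <- function(ops, tplRes, seqRes, scoreAt, params) {
  s <- 0; i <- 0; j <- 0; run <- ""
  for (op in ops) {
    if (op == "match") {
      i <- i + 1; j <- j + 1
      s <- s + scoreAt(i, seqRes[j])
      run <- ""
    } else {
      if (op != run) s <- s + params$gapOpen
      s <- s + params$gapExtend
      run <- op
      if (op == "insertion") j <- j + 1 else i <- i + 1
    }
  }
  s
}

# brute-force optimal global alignment score by enumerating every op string
# (exponential; only for instances of length <= 8)
bruteForceAlignScore <- function(protein, template, params = alignmentParams()) {
  tpl <- templatePositions(template)
  seqRes <- strsplit(protein, "")[[1]]
  m <- nrow(tpl); n <- length(seqRes)
  classSets <- lapply(residueClasses(), `[[`, "aminoAcids")
  scoreAt <- function(i, r) {
    if (tpl$role[i] == "FIXED") {
      if (r == tpl$value[i]) params$fixedMatch else params$fixedMismatch
    } else if (r %in% classSets[[tpl$value[i]]]) params$classMatch
    else params$classMismatch
  }
  best <- -Inf
  rec <- function(i, j, ops) {
    if (i == m && j == n) {
      best <<- max(best, scoreAlignment(ops, tpl$value, seqRes, scoreAt, params))
      return(invisible())
    }
    if (i < m && j < n) rec(i + 1, j + 1, c(ops, "match"))
    if (j < n) rec(i, j + 1, c(ops, "insertion"))
    if (i < m) rec(i + 1, j, c(ops, "deletion"))
  }
  rec(0, 0, character(0))
  best
}

# tiny templates for alignment tests, built through the public parser
miniTemplate <- function(pattern) parseTemplate(text = pattern, name = "mini")
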