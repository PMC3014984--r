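test_that("affine-gap DP equals brute-force enumeration on small instances", {
  set.seed(21)
  classSets <- lapply(residueClasses(), `[[`, "aminoAcids")
  patterns <- c("Mnp", "nppn", "MKnpt", "ptpn", "Mn")
  for (pat in patterns) {
    tpl <- miniTemplate(pat)
    m <- templateLength(tpl)
    for (rep in 1:6) {
      n <- sample(max(1, m - 2):min(8, m + 2), 1)
      prot <- paste(sample(c("L", "K", "E", "V", "G", "W", "M"), n,
                           replace = TRUE), collapse = "")
      expect_equal(alignToTemplate(prot, tpl)$score,
                   bruteForceAlignScore(prot, tpl),
                   info = paste(pat, prot))
    }
  }
})

test_that("gap-free optimum dominates for a conformant full-length member", {
  tpl <- defaultTemplate()
  lib <- sampleLibrary(tpl, 1, seed = 30)
  aln <- alignToTemplate(proteinSeqs(lib)[[1]], tpl)
  expect_identical(nrow(aln$path), 102L)
  expect_true(all(aln$path$op == "match"))
  p <- templatePositions(tpl)
  perfect <- sum(ifelse(p$role == "FIXED", 3, 2))
  expect_equal(aln$score, perfect)
})

test_that("degenerate alignment inputs are rejected", {
  tpl <- defaultTemplate()
  expect_error(alignToTemplate("", tpl), "non-empty")
  expect_error(alignToTemplate("MKLX", tpl), "X")
  expect_error(conformityReport("MKLB", tpl), "B")
})

test_that("validator recovers the fixture indel architectures exactly", {
  tpl <- defaultTemplate()
  fx <- makeFixtures(seed = 5)

  ra <- conformityReport(as.character(fx[["fixA"]]), tpl)
  expect_identical(ra@sequenceLength, 105L)
  ia <- as.data.frame(indels(ra))
  ia <- ia[order(ia$kind), ]
  expect_identical(ia$kind, c("deletion", "insertion"))
  expect_identical(ia$length[ia$kind == "insertion"], 4L)
  expect_identical(ia$segment[ia$kind == "insertion"], "helix1")
  expect_identical(ia$length[ia$kind == "deletion"], 1L)
  expect_identical(ia$segment[ia$kind == "deletion"], "helix4")

  rb <- conformityReport(as.character(fx[["fixB"]]), tpl)
  expect_identical(rb@sequenceLength, 106L)
  ib <- as.data.frame(indels(rb))
  expect_identical(ib$length[ib$kind == "insertion"], 11L)
  expect_identical(ib$segment[ib$kind == "insertion"], "helix2")
  expect_identical(ib$length[ib$kind == "deletion"], 7L)
  expect_identical(ib$segment[ib$kind == "deletion"], "helix4")

  # sequence-length arithmetic: template + insertions - deletions
  for (rpt in list(ra, rb)) {
    ind <- as.data.frame(indels(rpt))
    expect_identical(rpt@sequenceLength,
                     102L + sum(ind$length[ind$kind == "insertion"]) -
                       sum(ind$length[ind$kind == "deletion"]))
  }
})

test_that("indel round-trip recovers injected lengths and segments", {
  # indels of total length <= 15 injected at segment midpoints
  tpl <- defaultTemplate()
  lib <- sampleLibrary(tpl, 1, seed = 31)
  dna <- as.character(dnaSeqs(lib))
  segs <- split(templatePositions(tpl)$index, templatePositions(tpl)$segment)
  mid <- function(s) segs[[s]][ceiling(length(segs[[s]]) / 2)]
  insertAt <- function(d, res, codons)
    paste0(substr(d, 1, 3 * res), paste(codons, collapse = ""),
           substr(d, 3 * res + 1, nchar(d)))
  deleteAt <- function(d, res, n)
    paste0(substr(d, 1, 3 * (res - 1)), substr(d, 3 * (res + n - 1) + 1, nchar(d)))
  set.seed(32)
  cases <- list(list(seg = "helix3", kind = "insertion", len = 6),
                list(seg = "helix2", kind = "deletion", len = 5),
                list(seg = "turn2", kind = "insertion", len = 2),
                list(seg = "helix1", kind = "deletion", len = 3))
  for (cs in cases) {
    d <- if (cs$kind == "insertion")
      insertAt(dna, mid(cs$seg),
               sample(expandCodon("VAN"), cs$len, replace = TRUE))
    else deleteAt(dna, mid(cs$seg) - cs$len %/% 2, cs$len)
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(d)))
    rpt <- conformityReport(prot, tpl)
    ind <- as.data.frame(indels(rpt))
    expect_identical(nrow(ind), 1L, info = cs$seg)
    expect_identical(ind$kind, cs$kind, info = cs$seg)
    expect_identical(ind$length, as.integer(cs$len), info = cs$seg)
    expect_identical(ind$segment, cs$seg, info = cs$seg)
  }
})

test_that("class violations are listed and conformity is class-invariant", {
  tpl <- defaultTemplate()
  fx <- makeFixtures(seed = 5)
  rw <- conformityReport(as.character(fx[["violW"]]), tpl)
  v <- as.data.frame(violations(rw))
  expect_identical(nrow(v), 1L)
  expect_identical(v$residue, "W")
  expect_identical(v$class, "NONPOLAR")
  comb <- sum(positionCounts(tpl)[c("NONPOLAR", "POLAR", "TURN")])
  expect_equal(conformityScore(rw), (comb - 1) / comb)

  # swapping residues within a class set leaves the score at 1
  p <- templatePositions(tpl)
  lib <- sampleLibrary(tpl, 1, seed = 33)
  res <- strsplit(proteinSeqs(lib)[[1]], "")[[1]]
  classSets <- lapply(residueClasses(), `[[`, "aminoAcids")
  set.seed(34)
  for (i in p$index[p$role == "COMBINATORIAL"])
    res[i] <- sample(classSets[[p$value[i]]], 1)
  rpt <- conformityReport(paste(res, collapse = ""), tpl)
  expect_equal(conformityScore(rpt), 1)
  expect_identical(nrow(indels(rpt)), 0L)
})

test_that("hydrophobic moment follows the helical-wheel geometry", {
  # 18 residues x 100 degrees = 5 full turns: unit contributions cancel
  expect_equal(hydrophobicMoment(strrep("L", 18)), 0, tolerance = 1e-10)
  # single residue: |scale value|
  expect_equal(hydrophobicMoment("K"), abs(eisenbergScale()[["K"]]))
  # delta = 0: collinear vectors, moment = |sum|
  expect_equal(hydrophobicMoment("LKLV", delta = 0),
               abs(sum(eisenbergScale()[c("L", "K", "L", "V")])))
  expect_error(hydrophobicMoment("LKX"), "X")
  expect_error(hydrophobicMoment(""), "non-empty")

  # idealized binary repeat beats random shuffles of the same composition
  seg <- strsplit("PNPPNNPPNPPNNP", "")[[1]]
  scale <- c(N = 1, P = -1)
  ideal <- hydrophobicMoment(seg, 100, scale)
  set.seed(35)
  shuffled <- replicate(1000, hydrophobicMoment(sample(seg), 100, scale))
  expect_gt(ideal, mean(shuffled))
})

test_that("face segregation distinguishes conformant from polar-only helices", {
  tpl <- defaultTemplate()
  p <- templatePositions(tpl)
  classSets <- lapply(residueClasses(), `[[`, "aminoAcids")
  set.seed(36)
  drawMember <- function(polarEverywhere) {
    res <- character(102)
    for (i in p$index) {
      res[i] <- if (p$role[i] == "FIXED") p$value[i]
      else if (polarEverywhere && p$value[i] == "NONPOLAR")
        sample(classSets$POLAR, 1)   # violations: polar residues on the N face
      else sample(classSets[[p$value[i]]], 1)
    }
    paste(res, collapse = "")
  }
  pairs <- replicate(100, {
    good <- faceSegregationScore(drawMember(FALSE), tpl)
    flat <- faceSegregationScore(drawMember(TRUE), tpl)
    mean(good$moment) - mean(flat$moment)
  })
  expect_gt(mean(pairs), 0)
  fss <- faceSegregationScore(drawMember(FALSE), tpl)
  expect_identical(nrow(fss), 4L)  # one entry per helix
  expect_identical(fss$segment, paste0("helix", 1:4))
})

test_that("pattern rendering marks classes and violations", {
  tpl <- defaultTemplate()
  fx <- makeFixtures(seed = 5)
  lines <- renderPattern(conformityReport(as.character(fx[["violW"]]), tpl))
  marks <- paste(lines[seq(2, length(lines), 3)], collapse = "")
  expect_identical(sum(strsplit(marks, "")[[1]] == "!"), 1L)
  expect_true(all(c("o", "*", "-", ".") %in% strsplit(marks, "")[[1]]))
})
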