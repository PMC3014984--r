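---
title: "Binary patterning of combinatorial protein libraries: model and methods"
author: "binpat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary patterning of combinatorial protein libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binpat)
```

## The binary code model

The binary code strategy designs folded proteins by specifying only the
*pattern* of polar (P) and nonpolar (N) residues along the chain, matched to
the solvent-exposed and buried faces of a target fold. For an amphipathic
α-helix the structural repeat is 3.6 residues per turn, so a period-14
pattern such as `PNPPNNPPNPPNNP` places all N positions on one helical face
(100° of wheel angle per residue). Four such helices connected by turns give
a 4-helix bundle with a buried hydrophobic core, without specifying any
individual residue at the patterned positions.

The genetic code makes this constructible as a single degenerate gene:

* polar positions use the degenerate codon **VAN**, encoding exactly the six
  polar residues Lys, His, Glu, Gln, Asp, Asn;
* nonpolar positions use **NTN**, encoding the five nonpolar residues Met,
  Leu, Ile, Val, Phe;
* combinatorial turn positions use **VRS**, encoding Gln, Glu, Asn, Asp,
  His, Lys, Arg, Ser, Gly

(IUPAC symbols: V = A/C/G, R = A/G, S = C/G, N = A/C/G/T). None of the
three codon sets contains a stop codon, so every in-frame synthesis product
translates full-length. The `codon_algebra` functions (`expandCodon`,
`aminoAcidSet`, `aminoAcidProfile`, `containsStop`) implement this algebra
exactly, by exhaustive expansion against the standard genetic code
(translation table 1 only — the host is *E. coli*; RNA input is normalized
to DNA, case to uppercase).

## The default template

`defaultTemplate()` encodes a 102-residue 4-helix-bundle design with

* 22 nonpolar, 34 polar, and 12 combinatorial turn positions,
* 34 fixed positions, and
* segments ncap, helix1–4, turn1–3, ccap, with four combinatorial turn
  positions per turn.

**Helix layout.** A design constraint worth recording: every 14-residue
window of the period-14 repeat contains exactly 6 N positions, so four
equal 14-position helices would give 24 nonpolar positions — incompatible
with the 22/34 split. The packaged template therefore uses helices whose
combinatorial cores are windows of the periodic repeat of lengths
15/13/15/13 at phases 1/3/1/3, giving 6+5+6+5 = 22 N and 9+8+9+8 = 34 P.
Each helix core is a contiguous window of the cyclic repeat, so the face
geometry is preserved; the phase of a helix relative to the repeat is
physically arbitrary.

**Fixed residues.** The identities and placement of the 34 fixed positions
(N-terminal Met, Gly-rich turn flanks, short helix caps, an 8-residue
C-terminal cap) are a documented synthetic stand-in: the quantities this
package computes — counts, classes, diversity, indel localization — depend
only on the segment structure and classes, not on which residue is fixed
where. Users with a concrete design replace the layout via the template TSV
(`index  segment  role  value`; see `parseTemplate`), which round-trips
exactly through `writeTemplate`. Fixed positions emit the most-used
*E. coli* codon in `degenerateGene`, a deterministic choice packaged as a
constant table. The template includes the initiator Met as fixed position 1,
i.e. the 102 residues count the Met.

## Theoretical diversity

With 5 nonpolar choices at 22 positions, 6 polar at 34, and 8 turn choices
at 12, the amino-acid sequence diversity is

$$5^{22} \times 6^{34} \times 8^{12} \approx 5 \times 10^{52}.$$

`theoreticalDiversity` computes this as an exact big integer (a small
base-10⁴ digit-vector implementation, since the product has 53 digits and
exceeds double precision) and `sciSignif` rounds it for display. Two modes
are provided because the turn multiplicity is genuinely ambiguous: the VRS
codon encodes **9** amino acids, yet the conventional diversity formula uses
**8** per turn position. `mode = "declared"` (the default) uses the declared
5/6/8 multiplicities; `mode = "codon_derived"` counts the amino acids each
class codon actually encodes (5/6/9), which is ≈4.11× larger. No claim is
made about which number the physical library realized; both are one function
call away.

```{r diversity}
tpl <- defaultTemplate()
positionCounts(tpl)
sciSignif(theoreticalDiversity(tpl))$string
```

## In-silico library synthesis

`sampleLibrary(template, n, seed, weighting)` draws member genes
codon-by-codon. Two weightings bracket the physical synthesis chemistry:

* `uniform_codon` (default): each concrete codon of the degenerate mixture
  is equiprobable, as in an equimolar base mixture — so Leu appears at 6/16
  at NTN positions, Val at 4/16, etc.;
* `uniform_amino_acid`: the residue is drawn uniformly from the class set,
  then a codon for it — an idealized unbiased library.

The per-position nucleotide ratios of any real synthesis run are not part of
this model; `uniform_codon` is a default, not a claim about a physical
library.

`errorModel` simulates oligonucleotide-synthesis errors at the DNA level
(where they actually occur): indels at codon boundaries with probability
`indelRate` per boundary, lengths geometric with mean `indelLengthMean`
nucleotides, plus per-base substitutions. The defaults (10⁻³ per boundary,
mean 3 nt, substitutions off) make indel variants rare but reliably
observable in libraries of a few thousand members; all three are plain
arguments. `preselect` then applies the biological filter: variants whose
edited gene keeps the reading frame (length ≡ 0 mod 3) and encodes no stop
survive; this is why observed indel variants are multiples of one codon in
effect and why the class codons being stop-free matters.

All sampling takes an explicit integer seed and uses a private RNG scope
(the caller's `.Random.seed` is saved and restored), so the same
`(template, n, seed, weighting)` gives byte-identical FASTA output.

## Indel-aware conformity validation

Observed rescuing sequences can carry insertions and deletions from
synthesis errors — e.g. a 105-residue variant with a 4-residue insertion in
helix 1 plus a 1-residue deletion in helix 4, or a 106-residue variant with
an 11-residue insertion in helix 2 and a 7-residue deletion in helix 4
(`makeFixtures` builds exactly these architectures for testing). Calling a
sequence "conformant" therefore requires alignment, not positionwise
comparison.

`alignToTemplate` is a global Gotoh dynamic program with position-specific
scoring against the template: at a combinatorial position any residue of
the class set scores `classMatch`, anything else `classMismatch`; fixed
positions score `fixedMatch`/`fixedMismatch`; gaps are affine with a run of
length L costing `gapOpen + L·gapExtend`. Defaults are +2/−2, +3/−3, −8/−1.
These were chosen so that a single out-of-register codon is cheaper to
explain as a short gap than as a cascade of class mismatches (one mismatch
flip costs 4–6 points, a one-residue gap 9), which is what makes the
fixture architectures the unique optima; all six numbers are arguments.
Terminal gaps are penalized — observed hits are full-length ORFs, so the
alignment is truly global. Ties break deterministically: diagonal, then
insertion, then deletion. Degenerate inputs (empty protein, non-standard
residue letters) are rejected with the offending character named.

`conformityReport` classifies every aligned position, lists violations,
collapses gap runs into indel events, and scores conformity as the fraction
of aligned combinatorial positions whose residue lies in the position's
class set (fixed-position mismatches are reported as violations but do not
enter the score — they measure a different kind of error). Deletions are
attributed to the segment containing the majority of the deleted template
positions (ties to the N-terminal-most segment); insertions, whose columns
carry no template index, are anchored on the template position aligned
immediately before the run. Indel events report the template-coordinate
anchor; the aligned-pairs table carries both template and sequence indices,
so positions can be read in either coordinate system.

`hydrophobicMoment` and `faceSegregationScore` quantify the amphipathic
geometry the pattern is designed to produce: the moment is the magnitude of
the vector sum of per-residue hydrophobicities at 100°/residue (default
scale: Eisenberg consensus, replaceable), and the per-helix summary reports
the moment together with the circular mean wheel angle of the designed
nonpolar face. Useful identities: an 18-residue homopolymer spans exactly
five turns at 100° and has moment 0; at δ = 0 the moment degenerates to
|Σh|.

## Screen statistics

`complementationFrequency` implements the screen estimator: raw frequency =
(selective colonies × selective dilution) / (rich colonies × rich
dilution); the adjusted frequency multiplies by the confirmed fraction of
retested colonies, the simplest correction for false positives that fail to
restreak or retransform (no retests ⇒ no correction). The 95% interval is
exact Clopper–Pearson via beta quantiles rather than a normal
approximation, because selective counts are routinely below 10; after
false-positive scaling the effective count can be non-integral, which the
beta-quantile form handles continuously. The display form "~1/X" rounds the
*proportion* to one significant figure and then the reciprocal (this is the
rule that renders 1.1×10⁻⁴ as ~1/10,000 rather than ~1/9,000).

`rescueProbability(f, N) = 1 − (1−f)^N` and
`expectedUnique(D, s) = D(1 − (1−1/D)^s)` are both evaluated in log space
(`log1p`/`expm1`): with f ~ 10⁻⁶ and N ~ 10⁷, or D ~ 10⁵², the naive forms
underflow. `expectedUnique` accepts the exact big-integer diversity and
also reports the birthday collision bound s²/(2D) capped at 1.

## What the generator emulates — and what it does not

The synthesis simulator reproduces the *combinatorial* structure of a
binary-patterned library: class-constrained residues, codon-multiplicity
bias, frame/stop preselection, and rare codon-boundary indels. It does not
model vector or cloning sequence, assembly chemistry of real oligo
libraries, position-dependent synthesis error rates, expression level, or —
most importantly — any biological activity. A passing test suite shows the
design arithmetic, the sampling distributions, and the validator are
correct; it says nothing about whether any member folds or rescues a
deletion strain, which are wet-lab outcomes outside the scope of software.

## Numerical choices and problem sizes

* Diversity: exact integer arithmetic; rounding is round-half-up on the
  decimal digit string, with carry (9.6 → 10 promotes the exponent).
* Alignment DP uses a finite negative sentinel (−`double.xmax`/4) instead
  of −Inf to keep arithmetic clean; score-path equality checks use a 10⁻⁹
  tolerance so non-integer user scores also trace back correctly.
* Tests validate the aligner against brute-force enumeration of all
  alignments on templates of length ≤ 8 (the enumeration is exponential),
  sampling checks use 3 binomial standard errors at library sizes of
  3,000–5,000 members, interval coverage uses 10⁴ binomial replicates at
  p = 10⁻⁴, n = 10⁵, and birthday-coverage checks use diversities ≤ 10³
  with 400 simulation replicates. These sizes make the statistical
  assertions sharp while keeping the full suite fast on a single CPU.

## Known limitations

* The fixed-residue identities in the packaged template are a stand-in, so
  `degenerateGene` output is a valid but not historical gene sequence.
* Indel localization is reported at the optimal-alignment gap, which for
  gaps inside runs of identical class context is defined by the
  deterministic tie-break, not by the (unknowable) physical event position;
  segment attribution is robust to this, exact nucleotide position is not.
* The error model treats indel occurrence as independent across codon
  boundaries; real mis-assembly events can be correlated.
* `complementationFrequency`'s false-positive correction is the plug-in
  multiplicative estimator; a beta-binomial treatment of the retest step is
  deliberately out of scope.
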