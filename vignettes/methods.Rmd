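---
title: "Methods: models, thresholds and design choices in epitrio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices in epitrio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitrio)
```

# The problem

A *secondary epimutation* is stable, heritable promoter hypermethylation of
a gene caused by a sequence variant elsewhere. The configuration `epitrio`
targets is a reverse–forward–reverse gene trio (R1–F2–R3): the middle gene
F2 overlaps R1 head-to-head at its 5′ end (the two promoters share a
bidirectional CpG island) and R3 tail-to-tail at its 3′ end. A
splice-acceptor variant in R3 that skips R3's terminal exon — and with it
the polyA termination signal — lets antisense transcription continue
through F2 into the shared island, silencing the F2 allele *in cis* by
methylation. The package implements the computational stages by which such
a lesion is found: allele-resolved bisulfite epigrams, methylome-wide
outlier and carrier screening, epi-linkage-disequilibrium structure,
annotation scanning for the trio geometry, variant co-segregation, and
strand-aware readthrough detection.

All genomic coordinates are **0-based half-open** internally; GFF3 and
variant-table positions are converted at the parse/serialize boundary only.
Strand is mandatory internally; strandless BED defaults to `+` with a
warning.

# Bisulfite epigrams

## Model

Bisulfite treatment converts unmethylated cytosine to uracil (read as T);
methylated CpG cytosines resist conversion. For a cloned, Sanger-sequenced
amplicon aligned to its reference region:

* at each CpG cytosine: `C` → methylated (1), `T` → unmethylated (0),
  anything else missing;
* at each non-CpG cytosine: `T` counts converted, `C` unconverted; the
  conversion rate is converted/(converted+unconverted);
* a clone passes QC only when its rate is **strictly greater than 0.95**
  (the ">95% converted" rule; a clone at exactly 19/20 = 0.95 fails);
* the parental allele is assigned by exact base match at a
  methylation-neutral tagging SNP (e.g. a promoter G/T polymorphism).

Because QC uses non-CpG cytosines only, the conversion rate is invariant
under any change of methylation state — the QC and the signal are
measured on disjoint position sets. A tagging SNP may not coincide with a
CpG cytosine (rejected); if it lands on a non-CpG cytosine it is removed
from the QC set, since an allele base call there would masquerade as a
conversion failure.

## Assumptions and input contract

Clones are consumed pre-aligned: same length as the reference, no indels,
reported on the bisulfite top strand. Bisulfite read alignment and
reverse-complement detection are deliberately out of scope — the assay this
models sequences short cloned amplicons whose orientation is fixed by the
cloning primers.

## The mono-allelic call

`call_monoallelic_epimutation()` reports the SNP base of the epimutated
allele when one allele's methylation fraction is ≥ `hyper_min` (default
0.9) while the other's is ≤ `hypo_max` (default 0.1), with at least
`min_clones_per_allele` (default 3) clones per allele; `"none"` when both
alleles are ≤ `hypo_max`; `"indeterminate"` otherwise. The thresholds are
package defaults, not literature claims: published epigrams of this type
are near-binary, but no numeric call rule is stated anywhere, so the rule
is exposed as configuration. The positive call is gated on the clone-count
minimum; the `"none"` call is not, following the stated rule literally.
Missing CpG calls are excluded from fractions, never imputed.

# Methylome screening

## Beta categorisation

Array beta values are categorised ENCODE-style: β ≤ 0.2 fully unmethylated
(UU, dosage 0), β ≥ 0.6 fully methylated (MM, dosage 2), strictly between
partially methylated (PM, dosage 1). The boundaries sit *in* the outer
categories; the three classes partition [0, 1] exactly (tested on a
10⁻³ grid).

## MVP scan

Per probe over the case/control probe intersection: signed difference of
group means Δβ = mean(case) − mean(control), Welch (unequal-variance)
two-sample t with two-sided p, Bonferroni over the number of probes that
actually received a test. "A t-test" underdetermines the variant; Welch is
chosen because the case group is tiny (here, 3) and nothing justifies
pooling variances — the choice is recorded in the output metadata
(`m_tested` attribute, t statistics in the table). The hypermethylation
flag fires at Δβ ≥ 0.3 (the epi-Manhattan horizontal line); a mirrored
hypomethylation flag is reported for completeness since the method is
symmetric even though the motivating hit is hypermethylation. With a single
case the Δβ is still reported and the p is missing. Probes with fewer than
2 non-missing values in either group are not tested and do not enter the
Bonferroni denominator.

## Carrier screen and allele frequency

A cohort subject is a **carrier** when every non-missing probe of the
epimutation block categorises non-UU (all block β > 0.2) — the default
reconstruction of "the same hypermethylation" given that the published
screen states no numeric rule. A stricter `all_pm` rule (every block probe
PM, the heterozygous intermediate signature) is selectable. Subjects
missing more than half the block are excluded and reported.

The allele frequency under the heterozygous-carrier assumption is
`n_carriers / (2 N)`. The ceiling is the estimate rounded **up to one
significant figure** — the "not higher than" convention: 1 carrier in 1040
subjects gives 1/2080 ≈ 4.81×10⁻⁴, ceiling 5×10⁻⁴. With zero carriers the
ceiling is the one-carrier frequency so the bound never collapses to an
unobservable zero. (An alternative reading of the bound,
`(n+1)/(2N)` rounded up, yields 1×10⁻³ for the same cohort and contradicts
the printed bound it is meant to reproduce; the package uses the
convention that does reproduce it.)

# Epi-linkage disequilibrium

## Premise

PM (dosage 1) is treated as an *unphased heterozygous epigenotype*: the two
alleles of a subject carry different methylation states at the probe. This
is the modelling premise that makes two-locus LD machinery applicable to
methylation dosages; it is implied, not stated, by the method it
reconstructs, and it is exactly true for a mono-allelic epimutation.

## EM estimator

For dosage pairs (g₁, g₂) at two adjacent probes, the four epihaplotype
frequencies (UU, UM, MU, MM) are estimated by the standard two-locus EM:
initialisation at linkage-equilibrium products of observed allele
frequencies; the E-step splits double heterozygotes (1,1) between cis
(MM/UU) and trans (MU/UM) phase in proportion to current haplotype
frequencies (all other genotypes are phase-unambiguous); the M-step
re-normalises expected haplotype counts. Iteration stops when the
log-likelihood gain drops below `tol = 1e-10` or at `max_iter = 1000`;
the log-likelihood is asserted non-decreasing at every step. Then
`D = f(MM) − pA·pB` and `r² = D²/(pA qA pB qB)`. A single start suffices:
the two-locus biallelic profile likelihood is unimodal in practice and an
independent grid oracle guards against spurious optima in the tests.

**Degenerate inputs.** A monomorphic locus leaves r² undefined; it is
reported as `NA`, never coerced to 0 (this matters for block building,
where an undefined pair breaks a run instead of vetoing it with a zero).

## Grid oracle

The test oracle maximises the multinomial genotype likelihood over the
haplotype simplex *without* EM. Genotype margins are phase-invariant, so
the maximiser's allele frequencies equal the observed ones and the search
reduces exactly to one dimension: the MM-haplotype frequency within its
Fréchet bounds `[max(0, pA+pB−1), min(pA,pB)]`. A grid at step 10⁻³
localises the maximiser. Because `∂r²/∂f(MM) = 2D/(pA qA pB qB)` can reach
double digits, the raw grid's r² discretisation error can exceed the 10⁻³
agreement tolerance the oracle is meant to enforce; a bracketed
golden-section polish (`stats::optimize`, tolerance 10⁻¹⁰, within ± one
grid step) removes that error so the comparison measures EM convergence,
not grid granularity. The oracle shares no code with the EM iteration.

## Composite haplotype method

The phase-free composite estimator from dosages:
Δ = cov(g₁,g₂)/2 with 1/n normalisation; within-locus Hardy–Weinberg
departures d_A = freq(g₁=2) − pA² (d_B analogous);
`r²_CHM = Δ²/((pA qA + d_A)(pB qB + d_B))`. The method is named without
formulas in the methodology it reconstructs; these are the classical
composite-disequilibrium definitions. A vanishing corrected denominator is
reported undefined and flagged. Under random union of haplotypes (no HW
departure) CHM and EM agree within sampling error; on the
perfect-concordance configuration (half the subjects (0,0), half (2,2))
both equal 1 exactly, with no floating-point slack.

## Blocks

`build_blocks()` turns maximal runs of consecutive same-chromosome pairs
with defined r² ≥ `r2_min` (default 0.8, ties included) into epi-haplotype
blocks of ≥ 2 probes. The block rule in the source methodology is
unstated; this run-based rule is the package's own definition and is
documented as such. Numeric agreement with the commercial implementation
used originally (SVS) is explicitly out of scope.

# Trio scanning

Gene extents are transcript-level spans, not exon unions, matching the
browser-level visual inspection the scan replaces. With 0-based half-open
intervals and P on `+`, M on `−`:

* **tail-to-tail**: `P.start < M.start ≤ P.end ≤ M.end` — the overlap
  contains both 3′ ends; containment is excluded (only end-to-end partial
  overlaps qualify);
* **head-to-head**: `M.start < P.start ≤ M.end ≤ P.end`, or divergent
  non-overlapping with TSS gap ≤ `promoter_window` (default 1000 bp,
  exposed; "antisense with" has no numeric definition in the source, so
  proximity substitutes for overlap at the promoter end);
* **trio**: a tail-to-tail pair plus a head-to-head partner of the middle
  gene on the opposite strand, with at least one CpG island overlapping
  both promoter windows (TSS ± window) of the head-to-head pair. Islands
  are strandless (UCSC convention). Each trio is reported once with the
  island of maximal joint promoter overlap; the `F1R2F1` pattern is the
  exact strand mirror and is recovered by the same predicates.

The published trio counts (385 pairs → 99 trios: 82 + 17) require an
external pair database, a specific annotation release and manual curation;
they are not desk-reproducible and the package does not attempt them.
Instead, recovery is demonstrated on planted annotations in which every
decoy violates exactly one predicate (same-strand flank, missing island,
or no 3′ overlap, cycled), so each predicate is independently load-bearing.

# Antisense readthrough

Reads are single stranded intervals (BED6); split/junction reads and
transcript assembly are out of scope — the readthrough call is made from
coverage geometry. Library orientation is configurable (`forward`: read
strand equals RNA strand; `reverse` flips), since protocol mismatch is the
most common silent error in strand analysis.

`detect_readthrough()` computes per-base coverage on the strand of the
tail-to-tail flank (R3) over the combined span and requires three
conditions: **contiguity** — one covered run (depth ≥ `min_depth`,
default 5) containing at least one base in the R3 body and one base in the
F2-exclusive body, i.e. crossing the gene junction; **extent** — the
covered fraction of the F2-exclusive body ≥ `min_fraction` (default 0.5);
**dominance** — antisense/sense read-count ratio over F2 ≥ `min_ratio`
(default 1).

The fraction's denominator is the *F2-exclusive* body (bases overlapping an
opposite-strand trio partner removed) rather than the full F2 span: the
trio genes overlap by construction, so ordinary sense transcription of R1
and R3 covers the F2 overlap ends even in a completely readthrough-free
library. Restricting to the exclusive body makes the statistic measure only
the aberrant signal, and a readthrough-free library scores exactly 0. The
thresholds are package choices; the phenomenon they quantify is reported
qualitatively ("high" vs "undetectable") in the source.

`acceptor_disruption()` is strand-aware: for each intron the canonical
acceptor dinucleotide occupies the last two intronic bases before the
downstream exon in transcription order; a hit at either base predicts
skipping of that exon — with loss of the polyA termination signal when the
exon is terminal (the R3 lesion that causes readthrough), otherwise an
internal exon skip. Positions −1 and −2 are the whole canonical site; −3
is `none`.

# Variant co-segregation

Variants arrive as a TSV (full VCF mechanics are out of scope; the
computation is the filter logic). Filtering keeps the likely
protein-damaging classes (nonsense, splice site, frameshift indel,
missense) with maximum population MAF ≤ 0.001 — strictly greater than
0.001 is removed, exactly 0.001 kept. Co-segregation under the dominant
heterozygous model keeps variants `het` in every epimutation carrier and
`hom_ref` in every non-carrier. Missing genotypes fail a variant in strict
mode (default) or are skipped in lenient mode; how the original analysis
handled missingness is unstated, so both are exposed. Filter and
segregation commute, and tightening the MAF bound can only shrink the
output (both properties tested).

# The synthetic world

The generators encode one fixed "stated world"; its parameters were chosen
once, before the acceptance measurements, and are not tuned to outcomes.

* **Locus** (`gen_locus`): a 462-bp island carrying exactly 32 CpG sites
  and a G/T tag SNP — the island span, CpG count and tag polymorphism of
  the motivating locus — inside an R1–F2–R3 trio whose overlaps satisfy
  both pair predicates; R3 has 6 exons so the terminal-exon acceptor case
  is representable.
* **Clones** (`gen_clones`): 30 clones per allele, conversion efficiency
  0.99 (typical of a successful bisulfite experiment; the QC filter then
  drops an occasional clone), optional uniform base errors (default 0).
  The default allele states are the mono-allelic epimutation: tag allele
  fully methylated, other allele unmethylated.
* **Cohort** (`gen_beta_cohort`): 1040 controls (690 + 350) with one
  planted heterozygous carrier, 3 cases, an 8-probe block inside
  hypermethylated flanks (100 probes total). Beta noise uses Beta
  distributions at the category centres: UU ~ Beta(2, 18) (mean 0.1, the
  loose dispersion of an unmethylated array probe; ~8% of single draws
  stray above 0.2, which exercises the all-probes carrier rule against
  per-probe noise), MM ~ Beta(18, 2), and the carrier PM state
  ~ Beta(25, 25) (mean 0.5, sd 0.07) — a tight allelic 50/50 intermediate,
  as expected when exactly one allele is fully methylated. Only thresholds,
  not distributions, are stated in the source; these shapes are the
  package's stated world.
* **Reads** (`gen_reads`): sense reads uniform over the three gene bodies;
  a `readthrough_frac` fraction tiles the R3 strand from mid-R3 across the
  junction through F2 into R1's first exon. Read length 80 bp, default
  10⁴ reads.
* **Annotation** (`gen_annotation`): planted trios and one-violation
  decoys on isolated 20-kb slabs (no cross-slab geometry is possible, so
  precision failures can only come from predicate bugs).
* **Variants** (`gen_variants`): one splice-acceptor variant (MAF 5×10⁻⁴)
  segregating in a 6-sample, 3-carrier pedigree among 100 decoys that are
  each common, benign, or pattern-breaking.

**What a green test does not establish.** The generators emulate the
*statistical structure* the methods assume, not real data: no array
measurement-error model (probe cross-hybridisation, batch effects, cell
composition), no sequence-composition realism beyond CpG placement, no
alignment artefacts, no population stratification, clean binary pedigree
status. Recovery on this world validates the algorithms and their
contracts; it does not validate robustness to the failure modes of real
HM450K or RNA-Seq data, which the non-goals exclude.

Determinism: every generator derives an independent sub-stream from the
config seed and restores the caller's RNG state; identical configs yield
byte-identical serialized artifacts (hash-tested through the writers).

# Known limitations

* Bisulfite clone alignment, hemimethylation and NGS (per-read BAM)
  bisulfite data are out of scope; clones must be pre-aligned.
* Single-probe MVPs only; no DMR calling, normalisation or batch
  correction.
* Epi-LD is pairwise; no multi-locus phasing, no D′ triangle rendering
  (exports only), and no numeric compatibility with SVS.
* Trio scanning is transcript-level; exon-level overlap variants of the
  pair definitions are not implemented.
* Readthrough detection has no junction evidence — contiguous coverage is
  a proxy that a spliced readthrough transcript could in principle violate.
* The cryptic in-exon acceptor described for the motivating locus is
  descriptive, not algorithmic, and is not modelled.
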