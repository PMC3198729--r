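---
title: "Designing and scoring allele-specific RNAi effectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and scoring allele-specific RNAi effectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asiRNA)
```

## The problem

Autosomal dominant, gain-of-function point mutations — such as the
alpha-synuclein A30P and LRRK2 G2019S substitutions linked to Parkinson's
disease — produce a toxic transcript that differs from its essential
wild-type counterpart by a single nucleotide. RNA interference can in
principle remove the mutant transcript while sparing the wild type: a guide
(antisense) strand designed fully complementary to the mutant allele carries
exactly one mismatch against the wild-type allele, and if that mismatch
falls at a position the silencing machinery tolerates poorly, silencing
becomes allele-selective.

Which guide position tolerates the mismatch least is not predictable from
sequence alone, so the practical workflow is a *walk-through screen*: build
a panel of guides with the variant aligned at each successive guide
position, screen them against matched wild-type and mutant reporters, and
quantify discrimination. asiRNA implements that workflow end to end —
panel design, mismatch classification, secondary-mismatch variants, the
wet-lab construct artifacts, cleavage-site verification by 5'RACE, and the
screen statistics.

## Coordinate model

Everything is 1-based and inclusive on the sense strand, and every output
header repeats this convention. A guide of length $L$ (default 19) is
numbered $P1..PL$ from its 5' end. Aligning the variant at guide position
$p$ targets the sense window

$$[\, s - (L - p),\; s + (p - 1) \,]$$

around SNV position $s$, and guide position $q$ pairs with sense position
$t(q) = \mathrm{window\_end} - q + 1$ (the strands are antiparallel), so
$t(p) = s$. The guide is the RNA reverse complement of the *mutant* window:
zero mismatches to the mutant allele, exactly one — the *primary mismatch*
— to the wild type, at $P p$.

```{r}
locus <- synthetic_locus_g2019s(seed = 1)
guide_for_position(locus, p = 4)
```

Guide length is configurable in 19–23 nt. The default of 19 is the
classical siRNA core; published short-hairpin constructs in this design
family print one antisense sequence per construct, so both hairpin arms are
taken to be the same length as the guide.

## Mismatch classes and the strength table

`classify_pair(target, guide)` is total over the 16 ordered RNA pairs:
Watson–Crick; the G:U wobble (near-canonical stability, and therefore the
weakest discriminating mismatch — exactly what a G-to-A transition such as
G2019S produces against the wild-type allele); purine:purine (e.g. the G:G
clash an A30P-targeting guide makes with wild type — two double-ring bases
forced between the backbones, the most disruptive geometry);
pyrimidine:pyrimidine; and the remaining A:C/C:A pairs.

Secondary-mismatch selection by "weakest"/"strongest" needs a total order
on mismatches, which the field has only in fragments (single-mismatch
discrimination rankings). The packaged strength table encodes that partial
knowledge as ordinal scores — wobble weakest (1), A:C/U:C/C:A/C:U (2), U:U
(3), C:C and the purine:purine pairs (4), G:G maximal (5), Watson–Crick 0.
The exact integers are an editorial choice, flagged as such in the file's
provenance line; any total table with the same ordering can be swapped in
via `read_strength_table()`. Ties are broken by the fixed base order
A < C < G < U so selection is deterministic.

## Secondary mismatches

A second deliberate guide substitution mismatches *both* alleles (k
mismatches to the mutant, k+1 to the wild type) and can widen the
discrimination window at the cost of some on-target potency.
`secondary_variants()` implements the placement strategies used in
walk-through screens: immediately 3' of the variant alignment
(`adjacent_3prime`, guide position $p+1$ — this is the placement that turns
the A30P p13 guide into the p1314 construct), the mirrored `adjacent_5prime`,
a `separated` position, and `cleavage_opposite` (positions 9–11, opposite
the predicted cut site, aiming to destabilise the cleavage platform
itself).

Construct ids reproduce the field's naming: `p13` (single mismatch),
`p1314` (adjacent 3' double with an explicit base), `p11_9C` / `p11_10U`
(other doubles, substituted base appended), with `:weak`/`:strong` suffixed
when the base was chosen from the strength table rather than given
explicitly.

```{r}
d11 <- guide_for_position(locus, 11)
names(secondary_variants(d11, "cleavage_opposite", position = 9))
```

## Construct artifacts

`sirna_duplex()` renders the 19-mer core with 2-nt dT overhangs on both
strands; the passenger is the exact reverse complement of the guide core,
including at secondary-mismatch positions (the duplex is fully paired; the
mismatches exist only against the target).

`u6_primer()` assembles the PCR reverse primer that appends a Pol-III
hairpin to a U6 promoter template, using the five-segment scaffold
`AAAAAA ..slotA.. TGGGTCAGG ..slotS.. GGTGTTTCGTCCTTTCCACAA`. The scaffold's
slot labels and its stated architecture (antisense species in the hairpin's
3' arm) cannot both be read literally: pasting guide DNA into the slot
labelled "antisense" of a *reverse* primer would transcribe the guide in
the 5' arm. The package honours the architecture by default
(`slot_mode = "architecture"`): slotA receives the DNA reverse complement
of the antisense arm, slotS the guide DNA, and the predicted transcript is
`sense_arm + loop + guide + UUUUUU`. The literal reading remains available
(`slot_mode = "literal"`) and the choice is recorded in the object. Under
reverse-primer geometry the fixed `TGGGTCAGG` segment transcribes as the
loop `CCUGACCCA`, which is the default; the same-orientation reading
`UGGGUCAGG` is selectable. The transcript is rendered with six
template-encoded U's; Pol-III termination typically leaves a ~2-nt U
overhang, carried as metadata rather than trimmed, since the mature 3' end
is heterogeneous in practice.

`luciferase_insert()` extracts the reporter target window (52 nt by
default) for each allele and emits annealing oligos with XhoI/NotI sticky
ends for directional cloning behind Renilla luciferase. The even-width
window cannot be centred exactly; the package places 26 nt of 5' flank and
25 nt of 3' flank (SNV at window position 27) and records the offset. The
wild-type and mutant inserts differ at exactly the SNV, so any differential
knockdown is attributable to the single mismatch.

## 5'RACE cleavage mapping

RISC cleaves a fully complementary target at a fixed position relative to
the guide, leaving a 3' fragment with a 5' phosphate. Ligating an RNA
adapter to that phosphate (capped full-length mRNA is chemically excluded)
and sequencing across the adapter:transcript junction localises the cut.
`simulate_cleavage()` / `ligate_adapter()` / `map_junction()` model exactly
this: the mapper requires the adapter as an exact read prefix (mismatches
configurable), then a unique exact transcript match of at least
`min_anchor` (12) nt; anything else is a no-call. Junction matching is
exact with no indel handling because the reads this models are
Sanger-quality products of band-stab PCR, not high-throughput reads.

The cleavage convention is the parameter `gstar`: the guide position paired
with the fragment's 5'-most nucleotide. The default is 11, matching the
empirical observation that degradation-product 5' ends align to the 11th
guide nucleotide. Note a one-position subtlety: the classical description
"cleavage opposite guide positions 10 and 11" refers to the scissile
phosphate between the target bases paired to P10 and P11, under which the
3' fragment's first base pairs P10, i.e. `gstar = 10` in this package's
mapping. The two statements differ by one position; rather than silently
resolving the tension the package exposes `gstar`, keeps simulator and
mapper self-consistent for any value, and tests the round trip over
`gstar` 9–12.

## Screen statistics

Dual-luciferase plates are normalized as Renilla:firefly per well, then
divided by the mean nonspecific-control ratio for the same target;
dual-fluorescence plates subtract mean background per channel (floored at
zero, with a warning), then divide by the mean background-subtracted
control, channels independent. Both schemes are scale-invariant.

For each construct, with normalized relative expressions $r_{wt}$ and
$r_{mut}$ (control = 1):

* percent silencing $= 100\,(1 - r)$;
* fold discrimination $= r_{wt} / r_{mut}$ — the package defines the ratio
  this way (mutant-selective > 1) because it reproduces printed fold values
  from printed percentages to within rounding;
* silencing difference $=$ mutant silencing $-$ wild-type silencing, in
  percentage points;
* p-value from the unpaired two-tailed t test on the replicate groups,
  equal-variance (Student) by default with Welch behind a flag, matching
  the field's standard analysis. No multiple-testing correction is applied
  by default because screens of this kind report raw p-values; apply
  `p.adjust()` downstream if desired. A fully silenced allele
  ($r_{mut} = 0$) reports an infinite fold with a flag rather than an
  error; replicate groups with zero variance (e.g. noiseless simulations)
  report `p = NA` in the pipeline, while the bare t test keeps the
  conventions p = 1 for identical constant groups and an error for
  constant groups with different means.

`simulate_screen()` generates synthetic plates under mean-one
multiplicative log-normal noise with a stated coefficient of variation
($\sigma_{\log} = \sqrt{\log(1 + CV^2)}$, mean-log $-\sigma_{\log}^2/2$),
six replicate wells per group by default — the replicate structure of the
screens this models — plus nonspecific-control and background wells in the
same schema the readers accept. `cv = 0` recovers the true values exactly
through the full pipeline, which anchors the noiseless-limit tests.

### What the simulations do and do not show

The generator emulates replicate structure, background, control
normalization and multiplicative measurement noise. It does not emulate
transfection-efficiency covariance between channels, reporter secondary
structure, saturation, plate-position effects, or biological (as opposed to
measurement) variability — so passing recovery tests demonstrates the
statistical machinery is unbiased and calibrated under the stated noise
model, not that any particular wet screen will reach a given fold.

One calibration property worth knowing: the two-sample t statistic holds
its nominal level on the replicate groups themselves (type-I error ≈ 0.05
at n = 6, 10% CV), but dividing both groups by *noisy* control means —
which is what the standard normalization does — adds shared between-group
variance the t test does not see, inflating the realised pipeline-level
type-I error well above nominal (about 0.15 under the same conditions).
This is a property of control-normalized screen designs generally, not of
the implementation; treat pipeline p-values near the threshold with
caution, or increase control replication.

## Problem sizes and numerical choices

The test suite exercises: FASTA round trips at 300 records; walk-through
panels over all positions on randomized 120–250-nt loci; RACE round trips
over 3 random loci x 16 alignment positions x 4 cleavage conventions;
screen recovery over 200 simulated plates (n = 6, CV 10%) and t-test
calibration over 2000 null draws. These sizes were chosen to give
Monte-Carlo standard errors comfortably inside the asserted bands while
keeping the default test run fast. All simulation tests fix their seeds;
all sequence tests are exact string comparisons.

## Known limitations

* Degenerate (IUPAC) bases are rejected everywhere; the design rules are
  defined only on concrete bases.
* No efficacy prediction: thermodynamic asymmetry, seed-region off-target
  search and target secondary-structure accessibility are out of scope —
  the package designs and scores discrimination screens, it does not
  predict silencing potency.
* Dicer processing of hairpins is assumed faithful (the expressed
  antisense arm is taken as the active guide); the RACE module exists
  precisely to verify that assumption experimentally.
* The mapper aligns reads to a single supplied transcript, not a
  transcriptome.
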