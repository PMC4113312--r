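---
title: "Comparative genomics of a pre-duplication esocid genome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative genomics of a pre-duplication esocid genome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`esoxsynt` implements the comparative-genomic toolkit used to evaluate
whether a teleost genome that escaped the salmonid-specific whole-genome
duplication (WGD) can serve as a pre-duplication reference: reciprocal
best-hit (RBH) homologue detection on transcript sets, percent-identity
duplication profiles, linkage-group-by-chromosome synteny matrices with
fusion/fission and chimeric-scaffold logic, half-sib microsatellite
linkage mapping, and FPKM tissue-specialization scoring. Because the
analyses are defined by statistical signatures rather than by one
dataset, the package ships a genome-evolution simulator that generates
inputs with known truth; every analysis is validated by recovering what
the simulator planted.

# The aligner and the RBH homology criterion

All homology statements reduce to affine-gap Smith–Waterman local
alignment (implemented in C++), with unit match/mismatch scores and a
gap of length $k$ costing $-2 - k$. Percent identity is
$100 \cdot \text{matches}/\text{columns}$ with internal gap columns in
the denominator; this is one of several conventions in circulation, and
it is fixed here and exposed through the alignment result rather than
configurable per call. Two filters gate every hit: at least 100 aligned
columns, and a raw score of at least 40. The score threshold stands in
for a database-search significance cutoff; classical E-value statistics
need a database-size model that a self-contained toolkit does not have,
and in practice the 100-column filter dominates.

A pair is a homologue iff each member is the other's single best
passing hit (reciprocal best hits). Ties are resolved by score, then
identity, then lexicographic subject id, which makes the whole pipeline
deterministic. Within-species searches exclude self-hits; pairs are
stored once in canonical order, so RBH output is a partial matching.

For synteny work, RBH pairs must additionally have at least 50% of
*each* sequence covered by non-overlapping local alignments. Coverage
uses greedy best-first HSP tiling — take the best local alignment, mask
its footprint, repeat — rather than optimal weighted interval
scheduling; the greedy tiling mirrors how practitioners read HSP tables
and is exact in all test configurations.

**Banding.** With `band = w > 0` the dynamic program is restricted to
diagonals $|j - i| \le w$; out-of-band cells act as fresh local starts,
so a banded score is a lower bound of the unbanded optimum and equal to
it whenever the optimal path stays within the band — always true for
the simulator's full-length, indel-free homologues. `band = 0` runs the
exact full recursion, and the oracle-equivalence tests compare it
against an independent reference implementation. Pipeline defaults use
`band = 32`; the large simulation studies use `band = 16`, which is
still loose by an order of magnitude for indel-free data.

# Duplication profiles

Pair identities are binned by floor into 1% bins, with identities of
exactly 100 assigned to a closed top bin so that undiverged duplicates
remain countable. Peaks are read from a zero-padded moving average
(window 3 bins) as local maxima with prominence at least 5% of the
total pair count; within a smoothed plateau the peak is placed on the
bin with the largest raw count, since smoothing alone would shift a
sharp peak toward its emptier neighbour. Both knobs are exposed; the
defaults were chosen once against the generator's sharp peaks. Band
classification uses the conventional boundaries: identity above 97 is
"recent", the inclusive 77–89 band is the ancient-duplication
candidate band, everything else "other" — a partition, so every pair
receives exactly one label.

A practical note on local alignment and exact identities: the
generator diverges a duplicate pair at exactly `round(d * L)` sites, so
the *full-length* pair identity is exactly $1 - d$. A local aligner may
trim a mismatch-rich end, nudging the realized identity slightly above
the generator value. At $d = 0.18$ the mass stays overwhelmingly in the
82 bin; the tests therefore assert the modal bin and peak locations
rather than per-pair exactness after alignment (pre-alignment
exactness is asserted separately on the sequences themselves).

# Synteny matrices and pattern calls

Each coverage-filtered orthologue pair contributes one count to the
cell (focal linkage group of the transcript's anchored scaffold,
comparator chromosome of the orthologue). Gene positions are collapsed
to midpoints, `(start + end) / 2`, and strand is ignored throughout.
Full counts are kept internally; cells below 3 are masked only in
exported views, mirroring the "<3 removed for clarity" convention of
published tables.

Pattern calls formalize the qualitative reading of such tables:

* a chromosome holding $\ge$ 50% of a linkage group's row mass is that
  group's *dominant* chromosome (argmax ties report all tied columns);
* two focal groups sharing a dominant chromosome in **all** comparators
  are read as a focal-lineage **fission** of one ancestral chromosome;
* the same sharing confined to a strict subset of comparators is read
  as a lineage-specific **fusion** in the comparators where it appears;
* against a post-WGD comparator, a row with exactly two chromosomes
  each holding $\ge$ 20% of the row mass carries the **duplication
  signature**.

The 0.5 / 0.2 / 0.8 (dominance / duplication / scaffold purity)
fractions are package inventions that make the visual reading
reproducible; all are arguments.

Scaffold diagnosis follows the published decision logic: a scaffold is
*consistent* if one chromosome holds $\ge$ 80% of its hits in every
comparator; otherwise the best single breakpoint splitting its ordered
hits into two chromosome-pure halves is found, and the verdict is
*translocation* when the flanking scaffolds on the linkage group
corroborate both halves (in either scaffold orientation; the group's
majority chromosome may stand in for a missing terminal flank),
*reorganized_context* when the group's scaffolds hit $\ge$ 4
chromosomes interleaved, else *chimera_suspect*. Verdicts are withheld
below 5 mapped orthologues.

# Linkage mapping

The design is a two-father/single-mother half-sib family genotyped at
multi-allelic microsatellites, analysed as a pseudo-testcross: each
heterozygous parent is treated as a backcross parent, transmissions are
resolved per progeny where the other parent's genotype permits, and
phase is unknown. For a marker pair with $n$ doubly informative
meioses and $x$ transmission switches, the recombinant count is
$r = \min(x, n - x)$ (the better phase) and

$$\mathrm{LOD} = r\log_{10}\hat r + (n-r)\log_{10}(1-\hat r) + n\log_{10} 2,
\qquad \hat r = r/n,$$

with $\mathrm{LOD} = n\log_{10}2$ at $r = 0$. Markers with more than
15% missing genotypes are dropped before analysis unless explicitly
kept (the keep-list mirrors the practice of retaining a single
group-joining marker); Mendelian-inconsistent progeny calls are set to
missing with a warning, since no error policy is standard.

Groups form by single-linkage at LOD $\ge$ 4.0 per parent; an edge with
$3.0 \le \mathrm{LOD} < 4.0$ in one parent joins two clusters only when
another parent links the same pair at $\ge$ 4.0. A caveat worth stating
plainly: LOD 4.0 is a *pointwise* threshold. With ~500 markers there
are on the order of $10^5$ between-chromosome pairs, and at $n \approx
92$ meioses each has probability $\approx 1.4\times10^{-5}$ of reaching
LOD 4 by chance, so one to three spurious joins per genome scan are
*expected*; recovering the chromosome number exactly in repeated
simulations at this scale would require a genome-wide (multiplicity
corrected) threshold nearer 6. The package implements the stated
thresholds and reports what they yield; the validation suite measures
this honestly rather than hiding it.

Within a group, markers are ordered by a greedy chain on pairwise
$\hat r$ (tightest pair first, extend at both ends) followed by a
deterministic 2-opt + or-opt refinement that applies any segment
reversal or single-marker relocation strictly reducing the sum of
adjacent $\hat r$, in a fixed scan order to a fixed point. The greedy
chain alone proved measurably suboptimal at tight spacings (it left
orders whose objective the true order beat); the refinement closes that
gap while staying deterministic. Residual misorders at 500 progeny are
data-limited terminal swaps where the estimated order genuinely scores
better than the truth — no two-point method can resolve those.

Distances default to Kosambi, $d = 25\ln\frac{1+2\hat r}{1-2\hat r}$,
the common choice for fish maps (Haldane available); meioses are
*simulated* without interference, so Kosambi mapping compresses the
true scale by ~2% at the default spacing — visible, and within the
tolerances used. Sex-specific maps are merged through shared markers:
orientation by rank agreement, male-only markers interpolated piecewise
linearly between shared anchors, groups without shared markers reported
unmergeable rather than guessed.

# Expression specialization

FPKM is $F \cdot 10^9 / (L \cdot M)$ with $F$ the fragment count, $L$
the transcript length in bp and $M$ the tissue's mapped total
(column sums when self-contained). A transcript is specialized in a
tissue when its FPKM there exceeds its cross-tissue mean by more than
3 sample standard deviations ($n-1$ denominator), computed *including*
the candidate tissue — the literal reading of "average across all
tissues". Both the denominator convention and the multiplier are
arguments; no log transform is applied because the rule is defined on
FPKM directly. Per-tissue specialized counts, sorted descending, give
the tissue complexity ranking; top-10 tables break FPKM ties by
transcript id.

# The simulator: what it emulates, and what it does not

The generator produces: an ancestral karyotype (default 24
chromosomes, the inferred pre-fission state behind extant 2N = 48/50
teleost karyotypes) of non-overlapping random genes; WGDs that double
chromosomes and genes with divergence split randomly between the two
copies at exactly `round(d * L)` distinct sites (defaults 0.18 for the
ancient teleost round, 0.06 for a recent salmonid-like round, 0.03 for
very recent duplicates — identity is parameterized directly because
the identity-to-time mapping is not modelled); speciation divergence
applied gene-wise; fission / fusion / translocation directives with
between-gene breakpoints; scaffold fragmentation at inter-gene points
with optional flagged chimera injection; half-sib meioses without
crossover interference (inverse-Haldane recombination probabilities,
sex-specific maps, missing-completely-at-random genotype dropout,
default 48 + 44 progeny); and a 13-tissue expression panel with
log-normal × Poisson baseline counts and planted one-tissue
specializations (default boost ×100).

Deliberate idealizations, and hence the limits of what green tests
show about real data: substitutions are placed at an exact count of
distinct sites rather than i.i.d., so downstream identity peaks are
sharp by construction; indels are off by default so identity
bookkeeping stays exact (the `indel_rate` knob exists for aligner
stress tests); genes are random sequences without codon structure,
repeats, paralogy beyond the planted events, or GC heterogeneity; no
read-level sequencing, assembly error (beyond injected chimeras), or
genotyping error model. Passing recovery tests demonstrates that the
analysis logic is correct and calibrated at realistic signal levels,
not that it is robust to artefacts the generator does not produce.

# Validation scenarios and problem sizes

The packaged scenarios (also rerun by `scripts/acceptance.R`) use:
~280 duplicate pairs for peak recovery; a 24-chromosome × 30-gene
ancestor against duplicated and unduplicated comparator lineages for
the synteny signature; an 8 × 12 clade with one injected fission and
fusion; a 6 × 36 assembly with one mid-scaffold translocation and two
injected chimeras; and 25 × 20 markers over 92 (grouping) or 500
(ordering/length) progeny. These sizes were chosen as the smallest at
which the signatures are unambiguous for the deterministic checks and
the stochastic ones are adequately powered, while a full validation run
stays in the minutes range on a laptop core.

# Known limitations

* No E-value model, protein-space alignment, or seeding heuristics; the
  band is the only speed lever, and homology at diagonal offsets larger
  than the band needs `band = 0`.
* No Ks/dS estimation or mixture-model dating of duplication peaks.
* No multipoint likelihood ordering; two-point ordering cannot resolve
  terminal adjacent swaps at tight spacings, and chance LOD-4 joins at
  large marker counts are expected (see above).
* Merged maps are a display interpretation anchored on shared markers,
  not a joint likelihood estimate.
* Gene-order (collinearity-block) statistics are out of scope beyond
  the per-scaffold ordered-hit breakpoint search.
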