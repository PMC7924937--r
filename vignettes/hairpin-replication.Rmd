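---
title: "Models and methods: replication by hybridization of DNA double hairpins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: replication by hybridization of DNA double hairpins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HairpinReplicator)
```

## The system

The package analyses a ligation-free molecular replicator built from 16 DNA
strands of 82–84 nt. Each strand folds into a *double hairpin*: two
stem-loops of 30–37 nt flanking an unpaired central *information domain* of
exactly 15 nt. The information domain encodes a binary symbol — one 15-mer
for bit `0`, another for bit `1` — and strands come in four positions
(A–D) and two senses (sense / antisense, the latter written with a trailing
`*`, e.g. `0A*`). Antisense strands carry the reverse complement of the
sense information domain, so a string of four antisense strands is a
template on which the four matching sense strands can assemble by
hybridization alone. The design is periodic with period four: the
3' hairpin of each sense strand is complementary to the 5' hairpin of the
next, so adjacent strands bound to the same template interconnect through
high-melting *backbone duplexes*, and the assembled string of four is
itself a template for the complementary string. Replication of the binary
*meta-sequence* (e.g. `0010`) is therefore cross-catalytic and needs no
covalent chemistry; an asymmetric thermal oscillation (a long hold at a
base temperature, a one-second spike at a peak temperature) alternately
permits templated assembly and separates replicate from template.

`StrandLibrary` holds the 16 strands (a `DNAStringSet` plus per-strand
metadata). `findInformationDomains()` recovers the two information domains
from the sequences themselves: per bit, the unique 15-mer present in all
four sense strands whose reverse complement is present in all four
antisense strands. `annotateLibrary()` then locates each domain by exact
substring (or reverse-complement) match and assigns the flanking prefix
and suffix as the 5' and 3' hairpin regions. Coordinates are 1-based and
closed, the Bioconductor convention, so spans interoperate directly with
`IRanges`-style tooling; the three spans tile each strand exactly. The
hairpin/stem boundary within the flanks is not resolved further — nothing
downstream needs it.

`validateDesign()` checks the two design rules that make the mechanism
work: (i) each consecutive sense pair shares a long complementary stretch
between 3' hairpin and 5' hairpin (a sliding-window search tolerating up
to 3 mismatches, since the stems carry designed mismatches; the packaged
library gives stretches of 28–32 nt), and (ii) the thermodynamic ordering
Tm(information-domain duplex) < Tm(backbone duplexes), the window that
lets the peak temperature separate replicate from template while leaving
replicates intact.

## Duplex thermodynamics

All binding energetics use two-state nearest-neighbor (NN) thermodynamics:
the duplex enthalpy and entropy are sums over dinucleotide stacking steps,
plus initiation and terminal penalties, taken from the unified
oligonucleotide parameter set with the published internal-mismatch tables;
terminally mismatched base pairs use terminal-mismatch parameters. Two
modeling choices deserve note:

* **Tandem mismatches.** No published NN parameters exist for steps in
  which both base pairs are non-Watson–Crick (the original analysis used a
  partition-function package that does not need them). Such steps
  contribute no stacking here, i.e. the two mismatched pairs neither
  stabilise nor penalise beyond losing their stacks. This only affects
  multi-mutant duplexes with adjacent mutations; since it always weakens
  the duplex, it cannot turn a rejected mutant into an accepted one under
  the tolerance criterion below. The number of such steps is recorded in
  every `DuplexThermo`.
* **Salt correction.** The replication buffer contains 150 mM NaCl and
  20 mM MgCl2. We fold the divalent into a sodium equivalent,
  \[Na^+_{eq}\] = \[Na^+\] + 120·sqrt(\[Mg^{2+}\]/mM) mM, and apply the
  standard entropic correction ΔS = ΔS(1 M) + 0.368·(N−1)·ln\[Na^+_{eq}\].
  This is the simplest member of the empirical mixed-salt family; for this
  buffer it agrees with the more elaborate 1/Tm-based corrections to
  within the parameter-set uncertainty, and it keeps (ΔH, ΔS) as the only
  state, so every derived quantity stays closed-form.

Free energies are reported at 37 °C by default (the design-software
convention). The bimolecular melting temperature at equal strand
concentrations is Tm = 1000·ΔH / (ΔS + R·ln(C_T/4)) − 273.15 with C_T the
total strand concentration, default 400 nM (two strands at 200 nM). The
unbound fraction at any temperature solves the mass-action equilibrium
A + B ⇌ AB; `unboundFraction()` uses the numerically stable root
2/(1 + sqrt(1 + 4K·C_T/2)), which is exactly 0.5 at Tm. Under these
conventions the derived bit-0 domain gives ΔG(37 °C) = −14.4 kcal/mol and
Tm = 50.6 °C, and the backbone duplexes melt at 80–84 °C — the ordering
the design requires, with the info-domain values within the expected
parameter-set tolerance (±1.5 kcal/mol, ±3 °C) of the values the library
was designed around (−15.4 kcal/mol, 48 °C). Figure-level read-offs that
depend on the measured transition steepness (e.g. an unbound fraction of
0.08 at 45 °C) are reproduced qualitatively, not digit-for-digit: the
two-state NN curve at this strand concentration is somewhat shallower
than the measured one.

`fitMeltingCurve()` inverts measured curves: the signal is modeled as
linear lower/upper baselines mixed by the two-state unbound fraction,
parameterised by (ΔH, Tm) and fitted by Levenberg–Marquardt least squares
with multi-start over ΔH (−60, −100, −150 kcal/mol). Degenerate inputs
(constant signal, or data captured by a single straight line with
R² > 0.995) raise a "no transition" error instead of returning a
meaningless fit.

## Mutant sequence space and the tolerance criterion

Replication fidelity is bounded through the energetics of mutated
duplexes: the template's information domain paired against every
complement at Hamming distance k ("k point mutations").
`enumerateMutants()` yields each mutant exactly once in a deterministic
order (mutated position sets lexicographic, substituted bases
alphabetical), so cached distributions are reproducible byte-for-byte;
mutants are represented 3'→5', aligned so position i pairs template
position i, and "terminal" marks mutations at either end of the 15-mer.
For k = 3 there are C(15,3)·3³ = 12,285 mutants; `energyDistribution()`
computes all their ΔG values in about a second via a vectorized batch NN
sum, optionally caching to a TSV keyed by (sequence, k, buffer,
temperature).

The replication mechanism tolerates a duplex destabilisation of roughly
10 °C in Tm, equivalently ΔG ≥ −12.5 kcal/mol; `fractionMeetingCriterion()`
reports the fraction of a mutant shell at or above that threshold. The
criterion is implemented in its free-energy form directly (the Tm form
would add a second model-dependent conversion). Mutant counts use
*exactly* k mutations, matching the phrasing "containing three point
mutations"; distributions for smaller k are one call away if the
cumulative variant is wanted. `splitByPositionClass()` partitions a shell
into internal-only and terminal-containing mutants, since terminal
mismatches are energetically much milder and motivate the refined
(N = 13, K = 2) fidelity projection below.

## Cross-catalytic growth

Templated growth over thermal cycles follows the two-species linear model

$$\frac{dc}{dt} = k\,\bar c + k_0, \qquad
  \frac{d\bar c}{dt} = k\,c + k_0,$$

with t in cycle units, k the cross-catalysis rate and k₀ the spontaneous
(untemplated) formation rate. In sum/difference coordinates the solution
is closed-form (`closedForm()`): the sum grows as e^{kt} toward
exponential amplification, the difference decays as e^{−kt}, and for
c ≈ c̄ the model is plain exponential growth per cycle. The model ignores
monomer depletion, so `fitCrossCatalytic()` excludes points above a
configurable fraction (default 50%) of the per-strand total concentration
before jointly least-squares fitting shared (k, k₀) across traces with
different initial template concentrations (c₀ = 0 convention). Fitting
uses a multi-start grid over (k, k₀) with box-constrained BFGS — the
surface is mildly nonconvex when only low-template traces are present —
and uncertainties come from a seeded bootstrap over whole traces.
`initialVelocity()` returns the model-derived v₀ = k·c̄₀ + k₀, affine in
the template concentration with slope k.

`simulateSerialTransfer()` alternates closed-form growth segments with a
multiplicative dilution of the product species every few cycles
(concentrations are recorded at every integer cycle, pre-dilution at
transfer points); with fresh monomers a replicator survives dilution at
near-constant concentration, while the control without fresh monomers
decays geometrically. `fitDilutionFactor()` refits the dilution as the
single free parameter with (k, k₀) held fixed, by 1-D least squares on
(0, 1]. `fitSigmoid()` fits a three-parameter logistic to sedimentation
traces and reports the relative concentration increase
(plateau − first frame)/first frame, flagging flat traces instead of
fitting them.

## Replication fidelity

The per-information-domain fidelity maps to a hypothetical per-nucleotide
fidelity p through the cumulative binomial

$$p_K(N) = \sum_{k=0}^{K-1} \binom{N}{k}\, p^{N-k}(1-p)^k,$$

the probability of fewer than K errors over N nucleotides — implemented
as `pbinom(K-1, N, 1-p)` with the upper limit K−1 taken literally.
`invertPerNtFidelity()` solves p_K(N) = target by bracketed root finding
(p_K is strictly increasing in p on (0,1), so the root is unique;
tolerance 10⁻⁹). The defining anchors of the convention are the two
printed projections: a measured domain fidelity of 0.62 gives p = 0.85
at (N = 15, K = 3) and p = 0.90 at (N = 13, K = 2); the refined pair is
treated as user input, not derived. Endpoint arithmetic from
defective-set experiments is provided as `endpointDomainFidelity()`
(1 − c_defect/c_full) and `multiDefectYield()` (independent defects
multiply).

## The per-cycle simulator

`stepCycle()`/`runProtocol()` implement the four-step mechanism
explicitly, with every probability derived from the thermodynamic module:

0. *Activation*: fast cooling closes all free hairpins (bookkeeping only).
1. *Templated binding*: each template position is occupied by its matching
   strand with the info-duplex bound fraction at the base temperature,
   scaled by a monomer-availability factor m/(m + K_half), K_half = 5 nM.
   If the matching strand is knocked out, the wrong-bit strand can bind at
   a reduced relative occupancy (default 0.1) — binding competition means
   this channel is negligible when the right strand is present.
2. *Backbone closure*: each of the four junctions closes with probability
   p_zip during the base hold, driven by hairpin open–close fluctuations;
   the hairpin is a configurable two-state unit (ΔH = −60 kcal/mol,
   midpoint 52 °C — not printed anywhere, chosen so fluctuations are rare
   but present at 45 °C) and p_zip = 1 − exp(−z·f_open) with z calibrated
   once so p_zip = 0.9 at the 45 °C reference. Growth within the hold is
   integrated exactly (matrix-exponential propagator of the affine linear
   system), so a cycle is not an Euler step. The per-cycle gain prefactor
   is calibrated once so that the ideal limit reproduces k = 0.16 cycle⁻¹,
   and the spontaneous channel — proportional to the squared hairpin
   open fraction — is calibrated to k₀ = 0.4 nM cycle⁻¹ at 45 °C.
   Full-versus-partial branching uses a gap-persistence model: over the
   20-minute hold a position gets several binding attempts (default 4),
   so it stays empty only with probability (1 − occupancy)⁴. Complete
   strand sets therefore make almost no 3:4 partials, while knockouts
   funnel most flux into the partial pool, as observed on gels.
3. *Separation*: at the peak temperature new replicates are released as
   active templates with the info-duplex unbound fraction (≈1 at 67 °C),
   and whole complexes are destroyed — any of the four backbone duplexes
   melting dissolves the assembly — with material credited back to the
   monomer pool. Driving the peak into the backbone melting range is not
   an error; it produces the observed yield collapse.

The simulator's correctness anchor is the *reduction property*: with
occupancies, zipping and release set to 1 and destruction and depletion
off, the per-cycle map equals the cross-catalytic closed form (the test
requires 10⁻³ relative error; the exact propagator achieves machine
precision). Mass is conserved exactly every cycle (monomers + 4× tetramer
pools + 3× partials). A stochastic variant draws Poisson production and
binomial release/destruction on molecule counts (default 100 molecules
per nM); its seeded mean matches the deterministic run. Saturation is
emergent, not imposed: monomer depletion throttles growth through the
availability factor, and production is clamped to the available stock.

`temperatureScan()` reruns the simulator over peak- or base-temperature
grids. The scans reproduce the experimental orderings: yields are flat to
~72 °C peak, collapse across the backbone melting range (below 20% of the
67 °C yield by 78 °C); templated rates drop sharply at 39 °C (closed
hairpins stall zipping) and decline above the info-domain melting point,
while the spontaneous channel rises steeply above 45 °C.

## Synthetic data

No deposited datasets exist for this system — the quantitative traces
were gel quantifications — so the `gen*()` family supplies seeded
surrogates for every input: per-cycle amplification traces (closed-form
trajectories sampled at integer cycles), serial-transfer survivor/control
pairs, two-state melting curves with linear baselines, endpoint tables
for defective sets (means 37 nM full, 14 nM single defect, 37·0.16 nM for
double defects, the non-adjacent pattern defaulting to the same mean),
and uniform random strand pools as negative controls. The noise model is
multiplicative Gaussian (σ_rel = 0.10, matching band-intensity
quantification) plus a 1 nM additive floor (detection limit), clamped at
zero. Every generator is a pure function of its parameters and seed.

What the generators do *not* emulate: gel-specific artifacts (band
overlap, lane distortion), correlated errors across cycles from shared
calibration lanes, complex-resolved speciation (everything tetramer-like
is one product pool, mirroring how yields were quantified), and the
spatial physics of agglomeration and sedimentation. Tests passing on
synthetic data therefore demonstrate that the estimators recover the
generating parameters under the stated noise — parameter-recovery and
property checks — not that the models fit real gels.

## Numerical choices and problem sizes

Bisection/`uniroot` tolerances are 10⁻⁹; optimizer multi-starts are fixed
grids (no randomness in point estimates); bootstrap and all generators
take explicit seeds. The test suite exercises the full 12,285-mutant
shell, joint fits over 700 synthetic points (5 template concentrations ×
20 replicates × 7 cycles), 1,000 seeded stochastic simulator runs, and
6-cycle temperature scans — sizes chosen so the whole suite runs in well
under a minute while keeping Monte-Carlo standard errors far below the
asserted tolerances.

## Known limitations

* The NN parameter set and salt model carry an uncertainty of order
  1 kcal/mol on a 15-mer; absolute free energies inherit it, while
  mutant-versus-perfect *differences* are more reliable.
* Two-state melting ignores partial zippering and hairpin competition in
  the free strands; melting curves of the 82–84 nt strands themselves are
  out of scope (only duplex regions are modeled).
* The growth model is linear and the simulator's saturation is a
  mean-field availability factor; neither resolves the 3:4/4:3 complex
  kinetics within a cycle.
* The simulator's hairpin stability, mismatch occupancy and binding
  attempts are calibrated or assumed, not measured; conclusions drawn
  from it are structural (orderings, reductions, conservation), not
  absolute yields.
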