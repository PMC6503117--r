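---
title: "Adjacency-matrix EMU decomposition and isotope labeling simulation"
author: "EMUnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjacency-matrix EMU decomposition and isotope labeling simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EMUnet)
```

## The problem

Steady-state ¹³C metabolic flux analysis infers intracellular fluxes from
the isotope labeling patterns that a ¹³C-labeled substrate imprints on
downstream metabolites. The forward problem — given a flux distribution and
a tracer, predict each metabolite's mass distribution vector (MDV, the
fractions of the M+0 … M+n isotopologues) — requires following individual
carbon atoms through every reaction. Full isotopomer models carry `2^n`
unknowns per n-carbon metabolite and become unwieldy even for modest
networks.

The Elementary Metabolite Unit (EMU) framework avoids this blow-up. An EMU
is a non-empty subset of one metabolite's carbons, written `Met_ijk` (e.g.
`Glu_12345`, `OAA_234`). Only the EMUs that can influence a requested
measurement need to be balanced, and EMUs of the same size form linear
systems that can be solved in a cascade of increasing size. EMUnet
implements this decomposition through adjacency matrices: the network
becomes a metabolite adjacency matrix (MAM) whose cells hold the reactions
converting row into column metabolite, and the decomposition produces one
EMU adjacency matrix (EAM) per EMU size, from which the balance matrices
are read off by transposition.

## Model input

A model is a plain-text list of atom-mapped reactions. Atom maps assign one
lowercase letter per carbon; reversible reactions (`<->`) are split on load
into forward/backward pairs `idf`/`idb` with mirrored maps, and rotational
molecular symmetry is declared explicitly:

```
v5: Suc (abcd) -> Fum (abcd)
v6: Fum (abcd) <-> OAA (abcd)
symmetric: Fum 1-4,2-3
```

Symmetry is declared rather than inferred because a carbon-skeleton model
file carries no structural information from which a rotation axis could be
deduced. Cofactors and carbon-free species are omitted entirely: the method
tracks carbon only, so they could never carry label. Carbon counts are
inferred from the atom maps and cross-checked across the file; every
product letter must be sourced from a reactant letter.

Two fixtures ship with the package. `loadFixture("tca")` is a small TCA
cycle (aspartate and acetyl-CoA in, glutamate and CO₂ out) whose complete
decomposition is worked through below. `loadFixture("xylose")` covers
xylose catabolism in *Clostridium acetobutylicum*: the phosphoketolase
(PKT) split of xylulose-5-phosphate into acetyl-phosphate and
glyceraldehyde-3-phosphate, the reversible non-oxidative pentose phosphate
pathway, glycolysis down to pyruvate, and the fermentative product branches
(acetate, ethanol, butyrate, butanol, acetone). The oxidative pentose
phosphate pathway and the TCA cycle are deliberately absent from that
model: the former is inactive in this organism, the latter cannot influence
the labeling of the metabolites upstream of pyruvate. The xylose reaction
list is a synthetic transcription assembled from standard clostridial
biochemistry (its file header says so); it is faithful to the published
network topology but individual atom maps follow textbook enzyme
mechanisms.

## Decomposition, reduction, equivalent EMUs

```{r decompose}
tca <- loadFixture("tca")
dec <- decomposeEMU(tca, "Glu_12345")
countVariables(dec)
```

`decomposeEMU()` walks breadth-first from the target: each EMU's precursors
are traced through the atom maps of all reactions producing its metabolite.
A condensation reaction splits an EMU across several reactant molecules;
the resulting convolution term is a known source whose factors restart the
search at their own (smaller) sizes. Traversal stops at substrate EMUs,
whose MDVs are fixed by the tracer.

Two reductions shrink the system without changing any simulated MDV:

* **Unimolecular lumping** (`reduceUnimolecular()`). In steady state a
  labeling pattern changes only at convolutions, so an EMU whose entire
  influx arrives through a single reaction simply carries the
  coefficient-weighted mixture of its sources and can be substituted out.
  Its column is deleted and its row occurrences are renamed to the
  precursor term(s), repeatedly, until no such column remains. Target EMUs
  and convolution factors are kept. When orientation averaging of a
  symmetric molecule has split the single influx reaction over two cells,
  the column is still lumped — the criterion is one *reaction*, not one
  cell.
* **Equivalent-EMU combination** (`combineEquivalents()`). A rotationally
  symmetric molecule such as fumarate is processed by enzymes in either
  orientation, so `Fum_2` and `Fum_3` are indistinguishable and satisfy
  identical balances. Each equivalence class is merged into its
  lexicographically smallest member; row coefficients add, column
  coefficients add and are divided by the class size.

```{r reduce}
red <- combineEquivalents(reduceUnimolecular(dec))
countVariables(red)
countVariablesBySize(red)
```

`countVariables()` counts unknown EMU variables: substrate EMUs and
convolution terms are known sources and never count, and two EMUs that are
equivalent under a declared symmetry count once even before they are
explicitly merged, since they are a single independent quantity. With that
convention the TCA example needs 24 variables at full decomposition and 9
after both reductions.

During decomposition a symmetric molecule encountered as a precursor
contributes both orientations of its atom map, each with half weight, so
both orientations appear as columns of the raw EAMs; the weights of the
orientations of any one precursor always sum to the unsplit coefficient.

## Balance assembly and the size cascade

For each size the EAM is turned into a linear system by one transposition
rule: the diagonal is set to the negative flux-weighted column sum (the
total influx of each unknown EMU), the transposed upper square block is
`A`, and the transposed lower block with entries negated is `B`, giving
`A X = B Y` with `Y` the known source MDVs — substrate EMUs first, then
convolutions of already-solved smaller EMUs (a convolution of MDVs is their
Cauchy product). `solveCascade()` solves the sizes in ascending order by
dense LU factorization; the systems here have at most tens of unknowns, so
no iterative solver is warranted. A singular `A` is reported with the EMU
names of the offending block, which in practice means an EMU with no
external influx (a disconnected loop or a zeroed flux).

```{r cascade}
fl <- c(v1 = 1, v2 = 1, v3 = 0.4, v4 = 0.6, v5 = 0.6,
        v6f = 0.8, v6b = 0.2, v7 = 0.4)
res <- solveCascade(red, fl, "AcCoA:12@1.0")
res[["Glu_12345"]]
fractionalLabeling(res[["Glu_12345"]])
```

Numerical conventions: solved MDV entries in `(-1e-9, 0)` are treated as
round-off, clamped to zero and the vector renormalized; anything more
negative raises an error, since it indicates a malformed model rather than
floating-point noise. Natural ¹³C abundance is *not* injected into
substrate MDVs — simulations describe pure tracers, and correcting measured
spectra for natural abundance is a measurement-processing step outside this
package's scope.

Fractional labeling summarizes an MDV as the average fraction of labeled
carbons, FL = (Σᵢ i·mᵢ)/n ∈ [0, 1]. Two invariants make good end-to-end
checks and are part of the test suite: feeding a mixture of uniformly
labeled and unlabeled substrate at fraction p forces FL = p for every EMU
in the network, and MDVs are invariant under global rescaling of the flux
vector.

## The isotopomer oracle

`simulateIsotopomers()` solves the same steady state at full isotopomer
resolution (`2^n` states per metabolite) and `marginalizeIsotopomers()`
projects any EMU's MDV out of it. It shares no code with the EMU path —
symmetry is handled by the same orientation-averaging *convention* but
implemented independently — so agreement between the two is a strong
correctness check, and the test suite demands agreement within 1e-8 on
both fixtures over randomized fluxes and tracers. Because condensation
reactions make the isotopomer balance bilinear, it is solved by
Gauss-Seidel fixed-point iteration (tolerance 1e-12 on the largest change
per sweep, at most 1e5 sweeps, optional damping); each update is
renormalized to unit sum because the bilinear terms would otherwise square
floating-point drift every sweep. The oracle is deliberately limited to
metabolites of at most 12 carbons: it exists to validate small networks,
not to perform at scale.

## Flux sampling, tracer screening, ratio estimation

The xylose application asks a design question — which commercially
available xylose tracer and which measurable readout EMU best report the
PKT flux ratio v2/v1 (PKT flux over total xylose uptake) — and an inverse
question: given measured acetate FL values, what is that ratio?

Both rest on `sampleFluxes()`, which draws random flux vectors subject to
the internal mass balances. The sampling scheme is a package design choice
(several schemes would be defensible): the uptake flux is fixed at 1, the
free net fluxes — the non-pivot columns under column-pivoted QR of the
internal stoichiometric matrix — are drawn uniformly on [0, 1], dependent
fluxes are solved from the balances, and any candidate with a negative
irreversible net flux is rejected and redrawn. Each reversible pair then
receives an exchange flux e with log₁₀ e uniform on [−3, 1] (in uptake
units), giving `vf = max(net, 0) + e` and `vb = max(−net, 0) + e`; the wide
log-uniform range reflects how strongly isomerase/transketolase/
transaldolase exchange can scramble labeling without moving net flux.
Everything is reproducible from one integer seed. Correlation statistics
computed from such a screen depend quantitatively on this scheme — with a
different prior over the flux cone the same network yields somewhat
different rank correlations — which is why the package's tests assert the
direction and structure of the association rather than one scheme-specific
correlation value.

`simulatePanel()` runs the full factorial (sample × tracer × readout) FL
table, decomposing once and reusing each sample's assembled matrices across
tracers. `rankDesigns()` scores each (tracer, readout) pair by the Spearman
rank correlation of FL against the flux ratio and by the slope of the
ordinary least-squares regression of FL on the ratio (the regression
direction follows the screening plots: FL on the y axis). A pair whose FL
is constant across samples — the uniformly-labeled control mixture is the
canonical case — carries no flux information; it is flagged and sorted to
the bottom rather than silently ranked by an undefined correlation.

```{r screen}
xyl <- loadFixture("xylose")
samples <- sampleFluxes(xyl, 200, seed = 1, ratioFlux = "v2")
panel <- simulatePanel(xyl, c(exp = "Xyl:12@1.0"),
                       c("AC_12", "G3P_123", "EtOH_12"), samples)
rankDesigns(panel)
```

Under 100% 1,2-¹³C xylose the acetate EMUs `AC_1`, `AC_2` and `AC_12`
carry *identical* FL in every sample: acetate descends from carbons whose
positional enrichments are forced equal by the atom maps under this tracer.
The test suite asserts this equality to 1e-9 per sample — a useful
consistency check on the network transcription itself, since an erroneous
atom map would typically break it.

`estimateFluxRatio()` inverts the screen by accept/reject: samples whose
simulated FL lies within `mean ± tol` for *every* measured readout are
kept, and the PKT ratio is summarized as the mean and the 2.5th/97.5th
percentiles of the accepted ratios (a percentile interval over the
matched samples; the measurement tolerances act as the acceptance window).
A run with zero accepted samples raises an error suggesting more samples
or wider tolerances rather than returning an empty estimate.

```{r estimate}
acPanel <- simulatePanel(xyl, c(exp = "Xyl:12@1.0"),
                         c("AC_1", "AC_2", "AC_12"), samples)
estimateFluxRatio(acPanel, data.frame(
  readout = c("AC_1", "AC_2", "AC_12"),
  fl = c(0.462, 0.469, 0.465),
  tol = c(0.018, 0.012, 0.015)))
```

## Problem sizes, tests, and limitations

The test suite exercises the TCA fixture at full size (its decomposition
and reduction run in well under a second) and the xylose fixture with
panels of 1000 flux samples; oracle-equivalence checks use 20 random flux
draws and two tracers per fixture, which keeps the brute-force isotopomer
runs to a few minutes in total. The synthetic-measurement recovery check
reuses one 1000-sample panel and treats each of 100 randomly chosen samples
in turn as the "true" experiment, asking that the percentile interval of
the matched samples contain the generating ratio; with a 95% interval this
is expected to succeed for about 95 of 100 trials, so it is a calibration
check rather than a guarantee.

What passing these tests does and does not show: the generator emulates
steady-state labeling of a noise-free measurement under an exactly known
network. Real data add measurement noise, natural-abundance contributions,
possible inhomogeneity of intracellular pools, and network uncertainty;
none of these are modeled here. Isotopically nonstationary (kinetic)
labeling, MS fragment correction matrices, cumomer/bondomer transforms,
and the full inverse problem (flux fitting by residual minimization) are
out of scope. The EMU naming scheme uses digit position strings and so
supports metabolites of at most nine carbons — ample for central carbon
metabolism, which both fixtures top out at seven.
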