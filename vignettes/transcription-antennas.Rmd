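---
title: "Modeling transcription antennas: binding thermodynamics, search kinetics and sequence statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling transcription antennas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfantenna)
```

## The problem

A developmental transcription factor (TF) must keep one specific site
per target gene responsive while being present at only tens of
thousands of copies per cell. The homeodomain TFs that recognize the
palindromic hexamer `TAATTA` solve this with a graded affinity
spectrum: strong binding to the consensus, intermediate binding to
*degenerate consensus* sites (A/T-rich near-matches), and weak
electrostatic binding to any DNA. Because regulatory DNA in flies is
~57% A/T, degenerate sites cluster densely in the noncoding parts of
target genes and act as a *transcription antenna*: a capture region
that soaks up TF molecules and funnels them to the specific site by
sliding. This package implements the three computational layers of
that picture — an equilibrium binding landscape, a four-state kinetic
model, and motif statistics — plus the fitting machinery (K_D
titrations, FCS autocorrelations) and synthetic-data generators that
make the whole pipeline testable end to end.

## The site energy model

Every 6-bp window on either strand of an N-bp duplex is a potential
site; there are 2(N−5) of them. Site energies are additive over three
interaction channels plus one cooperative term:

* **Electrostatic.** Each backbone contact contributes
  $\Delta G_{\mathrm{elec}}(I) = \Delta G^0 e^{-\sqrt{I}}$ with the
  Debye–Hückel prefactor $\Delta G^0 = -8.18$ kJ/mol and ionic
  strength $I$ in mol/L. A central site makes 6 contacts, a site
  within one helical turn of a duplex end one fewer. The energy
  function was calibrated with 6 central contacts; the structural
  footprint suggests 8, and `energy_params(elec_contacts =
  "extended")` exposes that variant (with a logged notice, since the
  fitted constants belong to the 6-contact convention).
* **Specific.** Each base matching the consensus core tetrad
  (positions 2–5 of `TAATTA`) contributes −3.53 kJ/mol.
* **Degenerate.** Any other A or T in the site (positions 1 and 6
  always; core positions when not matching) contributes −1.75 kJ/mol,
  reflecting the narrow minor groove and higher flexibility of
  A/T-rich DNA. G/C bases outside the core contribute nothing.
* **Cooperative.** Sites carrying the first five, last five, or all
  six consensus bases gain $\delta_{16} + (\delta_{15} +
  \delta_{26})/2 \in \{0, 0.5, 1, 2\}$ times −3.91 kJ/mol, the
  non-additive gain of locking into the specific complex.

The PWM variant replaces the specific/degenerate/cooperative channels
by log-odds energies $-RT\ln(p_k^B/0.25)$ with no cooperativity; PWMs
are user-supplied (JASPAR-style), regularized with a 10⁻³
pseudo-count. RT uses R = 8.314 J mol⁻¹ K⁻¹ at T = 297 K.

With $S = \sum_x e^{-\Delta G_x/RT}$ and the weight prefactor
$w_0 = 5\times10^{-4}$ M⁻¹, the partition function at total DNA
concentration [DNA] is $Q = 1 + [\mathrm{DNA}]\,w_0 S$, and the global
dissociation constant is $K_D = 1/(w_0 S)$. [DNA] is the *total* DNA
concentration (ligand-excess approximation, matching titration designs
where DNA is at least as abundant as protein).

### Numerical and boundary choices

* **End margin.** A site is "central" iff the whole window lies more
  than `end_margin` (default 10 bp, one helical turn) from both duplex
  ends. The margin could equally be anchored at the window's first
  base on its own strand; we use the strand-independent window rule
  because it is the only convention under which both of the model's
  structural symmetries hold exactly — the energy multiset is
  invariant under reverse complement, and a palindromic window has
  identical energies on the two strands.
* **Coordinates.** 1-based closed intervals internally (the native
  IRanges convention); all reports are 1-based inclusive.
* **Degenerate inputs.** Sequences below 6 bp are rejected; exactly
  6 bp yields 2 sites. Hard-masked or ambiguous bases (N, IUPAC
  codes) are rejected at read time rather than skipped, because every
  window enters the partition function.
* **Ionic strength.** $\Delta G^0$ is treated as the $I\to0$
  Debye–Hückel prefactor (the alternative — the value at the 50 mM
  assay condition — is not distinguishable from the printed
  constants; the prefactor reading keeps the screening formula
  self-contained). Buffer-to-I conversion is the caller's duty;
  `ionic_strength(nacl_M)` adds a 0.01 M buffer contribution.

The model deliberately ignores DNA secondary structure (relevant for
G/C-rich designs), multi-protein occupancy and protein-concentration
effects; those are outside its scope.

## Fitting the energy model

`fit_binding_params()` is least squares in log10 K_D space (titration
errors are approximately lognormal and the dynamic range spans
decades). The structure variant frees the four energy constants; the
PWM variant frees only $\Delta G^0$. Because the site energy is linear
in the constants given the interaction counts, each construct's count
matrix is precomputed once and an objective evaluation is a single
matrix product — the global fit over dozens of constructs takes
milliseconds. Optimization is bounded Levenberg–Marquardt (±50 kJ/mol
boxes) with 10 seeded random restarts; 1σ errors come from the
covariance at the optimum. Records with reported uncertainties are
inverse-variance weighted; the two variants are compared with a
variance-ratio F test (they are not nested, so this is a documented
heuristic, not a partial F-test). Replicate K_D estimates combine by
normalized inverse-squared-uncertainty weights, with combined
uncertainty $1/\sqrt{\sum \sigma_i^{-2}}$.

## The four-state antenna model

States: `C_F` (cell milieu), `A_F` (free inside the antenna volume),
`D_eg` (bound to the degenerate cluster), `SB` (specific site). The
generator (columns = source states, columns sum to zero) is solved by
eigendecomposition: the zero-eigenvalue eigenvector is the stationary
distribution, the other eigenvalue magnitudes are the relaxation
rates, and eigen-expansion of an initial condition yields the phase
amplitudes. An ill-conditioned eigenbasis triggers a logged fallback
to scaling-and-squaring matrix-exponential propagation.

The default cellular scenario: 1 nM TF, entry rate
$10^6\,\mathrm{M^{-1}s^{-1}}\times 1\,\mathrm{nM} = 10^{-3}$ s⁻¹,
escape set by the 1000/0.033 μm³ volume ratio and quoted at two
significant figures (30 s⁻¹ — the precision at which the scenario is
defined, and the value that reproduces the published populations
exactly), 900 degenerate sites at $K_{D,2} = 10^{-7}$ M, one specific
site at $K_{D,3} = 10^{-8}$ M, off-rates $k_{-2} = 100$ and $k_{-3} =
10$ s⁻¹ from a $10^9\,\mathrm{M^{-1}s^{-1}}$ intrinsic on-rate, and
sliding at 200 bp/ms over a mean 2.5 kbp separation (80 s⁻¹).

**The reconciliation.** The published association rates for this
scenario ($k_3 = 10^7$ s⁻¹, $k_2 = 900\times10^7$ s⁻¹, with the
80 s⁻¹ slide oriented *onto* the specific site) violate detailed
balance on the `A_F–D_eg–SB` cycle by a factor ~8×10³ and produce
neither the published relaxation spectrum nor the published
populations. The default `reconcile = TRUE` uses the effective
$k_3 = 3\times10^4$ s⁻¹ with $k_2 = 900\,k_3$, orients the fast
80 s⁻¹ slide from `SB` into the cluster and fixes the return slide by
exact detailed balance ($80 \times (k_3 k_{-2})/(k_{-3} k_2) = 80/90
\approx 0.89$ s⁻¹). This preserves every pairwise equilibrium ratio
the published outputs satisfy and reproduces all seven of them
(eigenvalue magnitudes $2.7\times10^7$, 91, $1.1\times10^{-3}$ s⁻¹;
populations 0.099, $3.3\times10^{-6}$, 0.891, 0.0099) at their printed
precision. The physical origin of the effective $k_3$ is not
derivable from the stated antenna volume and on-rate; it is kept as a
documented constant. `reconcile = FALSE` exposes the literal published
set with a warning.

```{r kinetics}
sol <- solve_kinetics(rate_matrix(derive_rates()))
sol
copy_number_partition(sol, total_copies = 30000, n_genes = 200)
```

The intermediate phase (~11 ms) is the time for a TF molecule inside
the antenna to find the specific site; the partition shows ~135 of 150
per-gene copies held in the antenna and fewer than 15 anywhere else.

**Stochastic cross-check.** `simulate_jumps()` estimates the
stationary state by time-weighted jump-chain occupancy with
batch-mean standard errors. The cellular parameterization itself is
too metastable for jump-count-limited sampling — `C_F` exchanges at
$10^{-3}$ s⁻¹, so $10^6$ jumps visit it about once — so the
Gillespie-vs-spectral validation in the test suite runs on a
moderately stiff antenna rate set (same topology, detailed balance
imposed) where the chain mixes within the jump budget. This checks
the machinery; the cellular numbers are checked against their closed
forms instead.

## Motif statistics

Expected counts under i.i.d. bases at A/T content $a$ use
$p = a/2$ per consensus base (all consensus bases are A/T) and
$(1-p)$ per required mismatch, times $L-5$ windows: consensus
$p^6(L-5)$; each of the two quintets $(1-p)p^5(L-5)$; each of the
three quartets $(1-p)^2p^4(L-5)$. Observed counting enforces the
matching exclusion — a quintet window must mismatch the consensus at
its sixth in-frame position, a quartet at both remaining positions —
so the observed statistic estimates exactly what the formula computes
and no window is counted for two classes. Counting is single-strand:
the consensus and quartet sets are closed under reverse complement
and the two quintets are mutual reverse complements, so totals equal
double-strand single-variant counts. Windows straddling a
region boundary are attributed to the region containing their first
base, which makes RR + CDS counts exactly additive; expected counts
treat each region fragment independently (fragments under 6 bp
contribute nothing). Ratios are reported without significance tests.

## FCS model

$G(t) = G_F G_T G_D$ with the two-component 3D diffusion term kept in
its published normalization — squared-brightness numerator over a
plain $1/\langle N\rangle$ — and the textbook
composition-weighted form available via `normalization = "textbook"`.
Two published expressions are dimensionally inconsistent and are
implemented in their corrected forms: the free fraction is
$P = 1/(1 + [\mathrm{DNA}]/K_D)$ (not $1/(1+K_D[\mathrm{DNA}])$),
and the diffusion time is $\tau_D = \omega_{xy}^2/4D$ (not
$\omega_{xy}/4D$). Both corrections restore the obvious limits
($P\to1$ as $[\mathrm{DNA}]\to0$; $\tau$ in seconds). Titration fits
share one log10 K_D across decays with per-decay $\langle N\rangle$;
diffusion times, aspect ratio and the triplet/free-dye terms are
fixed globally (floating the aspect ratio per titration is possible
in principle but hurts identifiability at realistic noise). Lags
below 10⁻⁶ s are excluded, emulating the after-pulsing guard applied
to measured decays. Intervals are 2σ (95%).

## Synthetic data: what it does and does not emulate

The generators reproduce the *designed* statistical structure of the
experimental inputs: base composition (57% A/T genomic, lower in
CDS), the G/C-rich Markov rule (G/C with probability 0.82 after G/C,
always G/C after A/T — hence zero consecutive A/T pairs and a
stationary A/T fraction of 0.18/1.18 ≈ 0.153), declustered
compositions (exact multiset, homo-runs ≤ 2 via rejection sampling —
the published "minimize clustering" rule names no algorithm, so a
verifiable constraint was chosen), implanted consensus/degenerate
sites, antenna-like gene architectures, lognormal K_D noise and
relative Gaussian FCS noise. They do **not** emulate chromatin
context, nucleosome occupancy, real genomic repeat structure,
correlated instrument noise, or DNA secondary structure in G/C-rich
constructs. Passing recovery tests on these inputs therefore
demonstrates correctness of the estimators under the stated noise
models, not robustness to every artifact of real data.

Every generator is a pure function of its configuration and a single
integer seed; pipeline-level runs derive per-stage seeds
deterministically from a master seed.

## Validation scales

The test suite validates each stochastic stage at sizes chosen to
give stable statistics in seconds: the brute-force landscape oracle
on 100 random sequences up to 200 bp; parameter recovery on 20
replicate 30-construct titrations at 0.05 log10-unit noise (each true
constant within ±2σ in ≥90% of replicates); FCS K_D recovery within
±0.1 log10 in ≥90% of 20 noisy 7-point titrations; motif
expected-vs-observed agreement within 3 standard errors over 200
kilobase-scale sequences; and a 10⁶-jump Gillespie run against the
spectral stationary state. These sizes are the package's validation
conditions; the estimators themselves have no built-in size limits.

## Known limitations

* The structure-based energetics are specific to 6-bp homeodomain
  sites; other motif widths require a different core/cooperativity
  scheme (the PWM variant generalizes more readily).
* The variance-ratio model comparison is heuristic for non-nested
  variants.
* The antenna model is well-mixed within each state: no spatial
  diffusion gradients, chromatin accessibility dynamics or multi-TF
  competition.
* Gene-region analysis assumes one gene per sequence record and takes
  the supplied FASTA strand as the coding strand.
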