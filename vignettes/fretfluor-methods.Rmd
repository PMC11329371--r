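---
title: "Models and methods behind fretfluor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretfluor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement this package models

A FRETfluor is a small DNA duplex carrying a Cy3 donor and a Cy5 acceptor
whose spacing (N base pairs), local sequence context and attachment
chemistry set a reproducible spectroscopic signature. Read out one molecule
at a time in an anti-Brownian electrokinetic (ABEL) trap under pulsed
donor excitation, each trapped molecule yields a multi-parameter signature:
background-subtracted green and red brightness, a FRET proximity ratio, and
a single-exponential donor lifetime fitted to TCSPC microtimes. Signatures
cluster tightly per construct, so a well-chosen palette of constructs acts
as a set of spectroscopic barcodes, and the positional confinement of the
trapped object separates free labels from target-bound complexes without
washing.

`fretfluor` implements the full analysis path — photon-stream segmentation,
per-level estimation, Gaussian cluster modelling, misclassification-driven
palette design, and confinement-based binding calls — together with a
synthetic photon-stream generator that realises exactly the statistical
model the analysis assumes, so every stage is testable without
experimental data.

## The generative model (what the simulator emulates)

`simulate_stream()` draws trapping events as a Poisson process (queued so
at most one molecule is trapped at a time), with exponential dwell times.
Within an event with FRET efficiency $E$, donor-excitation photons arrive
as Poisson streams with

$$ r_\mathrm{green} = B_0 (1 - E) P, \qquad
   r_\mathrm{red} = B_0\, E\, s\, P, $$

where $B_0$ is the family's donor-only brightness (counts ms$^{-1}$
µW$^{-1}$), $P$ the excitation power (µW) and $s$ a relative acceptor
detection scale (default 1). Green microtimes are exponential with the
FRET-shortened effective lifetime

$$ \tau_\mathrm{eff} = \tau_{D0} (1 - E), $$

convolved with the IRF and wrapped on the 60 MHz excitation period
(incomplete-decay conditions); red microtimes add an acceptor decay
(default 1 ns) on top of the donor transfer delay. Acceptor photobleaching
(exponential waiting time) and optional two-state blinking revert the
construct to donor-only emission: $E = 0$, lifetime back to $\tau_{D0}$.
Uniform Poisson background is added per channel, and photons split 50/50
between parallel and perpendicular detectors.

The $\tau_\mathrm{eff} = \tau_{D0}(1-E)$ coupling is the simulator's
ground-truth model and enforces the lifetime-vs-FRET anticorrelation the
multi-parameter readout exploits. Registry FRET efficiencies default to the
sixth-power distance law $E = 1/(1 + (N \cdot \mathrm{rise}/R_0)^6)$ with a
linear rise of 0.34 nm/bp and $R_0 = 5.4$ nm (a literature-scale Cy3/Cy5
value); measured per-construct values can override them in the registry
YAML. Default excitation power is 80 µW, chosen once so that a
mid-brightness construct produces a total arrival rate near 25 kHz, the
regime the analysis defaults (150 ms levels, thousands of photons per
level) are tuned for.

What the simulator does *not* emulate: spectral crosstalk and direct
acceptor excitation (correction parameters are exposed but default
neutral), polarization anisotropy (channels are summed, never analysed),
detector dead time and afterpulsing, multi-exponential dye photophysics,
and any coupling between the molecule's position in the trap and its
emission rate. Passing tests therefore demonstrate correctness of the
estimators under the stated model, not robustness to every instrumental
nonideality of real data.

## Trap dynamics

`simulate_trap_trajectory()` uses a discrete proportional-feedback model
per axis,

$$ x_{t+1} = x_t - g\,\hat x_t + \sqrt{2 D \Delta t}\, \xi_t, \qquad
   \hat x_t = x_t + \epsilon_t, $$

with gain $g \in (0, 1]$ (default 0.5), feedback period $\Delta t$
(default 0.1 ms) and localization noise $\epsilon$ (default 30 nm sd).
With noise-free estimates the true position is AR(1) with stationary
variance $2 D \Delta t / (1 - (1-g)^2)$ — the closed form the tests check.
Event diffusion coefficients follow Stokes–Einstein scaling
$D \propto 1/r$ from the construct's hydrodynamic radius (default 2 nm,
$D \approx 107$ µm²/s), with a ×3 radius multiplier for target-bound
complexes; only the *relative* confinement matters downstream, which is why
a simple multiplier suffices.

`estimate_diffusion()` inverts the same dynamics: subtracting the recorded
feedback kick from each increment leaves the pure Brownian step, whose
variance is $2 D \Delta t$. This deliberately avoids a full Kalman
smoother; with noisy estimates the estimator is biased upward by the noise
variance, which is why binding calls use the confinement spread rather
than $\hat D$ directly.

## Segmentation

* **Binning and background.** The stream is binned at 10 ms per channel.
  Background is estimated per channel by K-means over the bin counts for
  $K = 1 \ldots K_\mathrm{max}$ (default 3), scored by AIC. The AIC uses
  the *mixture* likelihood of the K rates found by K-means (Poisson
  components weighted by cluster occupancy): a hard-assignment likelihood
  keeps rewarding splits of a single homogeneous rate and drives $K$ to
  the maximum, while the mixture likelihood plateaus at the true component
  count. The background rate is the mean of the lowest-rate component.
* **Change points.** Photon-by-photon likelihood-ratio bisection per
  channel: for a segment of $n$ photons spanning $T$, the split at photon
  $k$ maximising
  $LLR(k) = k\ln(k/T_1) + (n-k)\ln((n-k)/T_2) - n\ln(n/T)$
  is accepted when $2\,LLR$ exceeds the $\alpha$-critical value, and both
  sides are searched recursively. Critical values are calibrated by Monte
  Carlo on homogeneous Poisson segments — 1000 replicates per photon-count
  decade, representative $n$ at the decade's upper bound (conservative
  within the decade) capped at $10^4$, cached per session. Segments with
  fewer than 30 photons are never split (guards the asymptotics).
* **Merging and levels.** Per-channel change points within 10 ms (one
  display bin) collapse to their photon-weighted mean. The merged points
  partition the acquisition into candidate levels; levels are retained
  when longer than 150 ms (100 ms profile for simple mixtures), since
  shorter levels degrade classification.

## Per-level estimation

Brightness is background-subtracted counts per ms per µW, with parallel
and perpendicular channels summed per colour; negative subtractions clamp
to zero with a flag. The FRET value applies the standard corrections
$A' = R - \alpha G - \delta(G+R)$, $E = A'/(A' + \gamma G)$ and reduces to
the proximity ratio $R/(R+G)$ at the neutral defaults — sufficient when
FRET serves only to separate signatures.

The donor lifetime is fitted by maximum likelihood to the green parallel
microtimes only, under a model density built on the TCSPC grid: a
single-exponential decay wrapped on the excitation period, circularly
convolved (FFT) with the IRF, plus a uniform background fraction. Two
numerical details matter:

* the IRF is discretized at bin *starts*, cancelling the half-bin shift
  between floor-quantized photon microtimes and the discrete convolution
  (without it, $\hat\tau$ biases high by about half a TCSPC bin);
* the background fraction defaults to a per-level estimate — expected
  background photons over observed photons in the fitting channel — which
  removes the upward bias that uniform background photons otherwise impose
  on dim levels.

The likelihood is maximised by bracketed search on $[0.05, 10]$ ns to
$10^{-3}$ ns; the confidence interval comes from the observed information.
Fits with fewer than 100 photons are refused (the information-based CI is
unreliable below that). A single exponential is used even though real dye
decays are multi-exponential: at per-level photon counts the
single-exponential fit classifies labels more robustly.

## Classification and palette design

Levels are clustered by K-means in (green brightness, red brightness,
donor lifetime), z-scored per axis because the units are incommensurate,
with k-means++ seeding and 20 restarts under a fixed seed (plain
random-point initialization covers K tight clusters too rarely, and Lloyd
iterations cannot split a merged pair afterwards). `K = "auto"` selects the cluster
count by the AIC of a diagonal Gaussian mixture over a candidate range
(same rationale as the background AIC: a classification likelihood
overfits, a mixture likelihood does not); K-means still performs the
assignment at the chosen K.

Each cluster becomes an axis-aligned 3D Gaussian: iterated mean/sd with
rejection of points beyond 3 cluster sd on any axis (≤ 10 passes). No
covariance is fitted. The pairwise misclassification $p(a \to b)$ is the
mass of $a$'s Gaussian on $b$'s side of the equal-density decision surface
(equal priors) — the natural generalisation of the classical two-Gaussian
tail overlap, to which it reduces exactly in the equal-σ one-axis case
($\Phi(-d/2\sigma)$, the test oracle). The integral is Monte Carlo with a
fixed seed; identical clusters return 0.5 by convention. The confusion
matrix evaluates all ordered pairs; its diagonal is one minus the row's
off-diagonal mass — a pairwise approximation, documented as such, matching
the pair-by-pair framing of palette design.

Compatible label subsets are maximum cliques of the graph whose edges
connect pairs with both directed misclassification probabilities at or
below the threshold (default 2.5%); the search is exact (igraph's clique
enumeration, feasible well beyond 41 nodes) and verified against
brute-force subset enumeration in tests. Accuracy-versus-photon-budget
curves truncate simulated levels to M photons, rebuild signatures and
classify against competitor models; when too few photons reach the
lifetime fitter the lifetime axis is dropped for that budget and flagged.

## Binding analysis

Confinement points are the per-group (default M = 1000 photons) standard
deviations of the *estimated* positions — what an instrument records —
over each group's time span. A two-component diagonal Gaussian mixture on
$(\sigma_x, \sigma_y)$ is kept only if AIC prefers it over one component;
the tighter component is labelled bound (a larger complex diffuses more
slowly and is confined more tightly), calls with posterior below 0.9 are
ambiguous, and a one-component preference returns all-unbound with a
no-binding-detected flag. Binding efficiency is the bound fraction of
unambiguous calls with Clopper–Pearson intervals; `unit = "event"`
collapses calls to one majority call per trapping event first, the right
unit when binding is a per-molecule property and long dwells would
otherwise be over-weighted.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed; a `run_config()` seed
derives all stage seeds, and identical configs give byte-identical
outputs (the stream container round-trips records bit-exactly, which is
why it is written in shortest round-trip decimal and read with a
correctly-rounded parser). The test-suite and acceptance problem sizes are
the package's own choices for desk-scale verification: lifetime recovery
at $10^4$ photons, change-point calibration over 500–1000 homogeneous
streams of 200–300 photons, pairwise-overlap checks at $2\times 10^5$
draws, a nine-construct palette (AB12–AB20) simulated for 300 s at
~25 kHz for the end-to-end classification check, and 100 trapping events
for binding recovery. The AB12–AB20 palette spans model-derived FRET
efficiencies from 0.84 down to 0.20 — the regime where all three signature
axes are informative; below N = 12 the model-derived $E$ approaches 1 and
the green channel carries too few photons for a lifetime fit, which is a
property of the sixth-power distance model rather than of the estimators.

## Known limitations

* Registry FRET values are model-derived unless overridden; absolute
  cluster positions therefore match the distance model, not any particular
  instrument's calibration.
* FRET correction parameters pass through but default neutral; the FRET
  axis is a proximity ratio, not an absolute efficiency.
* The confusion-matrix diagonal is a pairwise approximation; with many
  mutually overlapping clusters it can undercount total leakage.
* The diffusion estimator ignores localization-noise inflation; binding
  discrimination relies on confinement spread, not on $\hat D$ accuracy.
* Blinking is a simple two-state telegraph and is off by default.
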