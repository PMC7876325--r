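---
title: "Modelling cell energy metabolism as coupled networks of non-autonomous phase oscillators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cell energy metabolism as coupled networks of non-autonomous phase oscillators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabosc)
```

## The model

Cellular ATP production runs through two oscillatory processes — glycolysis
in the cytosol and oxidative phosphorylation (OXPHOS) in the mitochondria —
fed by glucose and oxygen supplies whose influence is itself oscillatory and
never at a truly constant frequency. `metabosc` models this system with
phase-only (Kuramoto) oscillators: amplitude dynamics, metabolite masses and
reaction kinetics are deliberately out of scope, which keeps the system
thermodynamically open and puts the oscillation, not a perturbed steady
state, at the centre of the description.

The state is the vector of unwrapped phases of $2N + 2M$ oscillators:
$N$ glycolysis oscillators $\theta_{GO,i}$ with their glucose drivers
$\theta_{G,i}$, and $M$ OXPHOS oscillators $\theta_{MO,i}$ with their oxygen
drivers $\theta_{O,i}$. The governing equations are

$$
\begin{aligned}
\dot\theta_{G,i} &= \omega_{G,i}(t), \qquad
\dot\theta_{O,i} = \omega_{O,i}(t),\\
\dot\theta_{GO,i} &= \omega_{GO,i}(t)
  + \frac{K_{GO}}{N}\sum_{j=1}^{N} W_{ij}\,\sin(\theta_{GO,j}-\theta_{GO,i})
  - \varepsilon_G \sin(\theta_{GO,i}-\theta_{G,i})
  + F_{GO}\, r_{MO} \sin(\Psi_{MO}-\theta_{GO,i}),\\
\dot\theta_{MO,i} &= \omega_{MO,i}(t)
  + \frac{K_{MO}}{M}\sum_{j=1}^{M} W_{ij}\,\sin(\theta_{MO,j}-\theta_{MO,i})
  - \varepsilon_O \sin(\theta_{MO,i}-\theta_{O,i})
  \pm F_{MO}\, r_{GO} \sin(\Psi_{GO}-\theta_{MO,i}),
\end{aligned}
$$

where $r_X e^{i\Psi_X} = \frac1n \sum_k e^{i\theta_{X,k}}$ is the Kuramoto
mean field of network $X$: each network feels the other only through its
collective phasor, not through individual oscillators. Every natural
frequency is non-autonomous,
$\omega_{X,i}(t) = \omega_X + A_X \sin(\omega_{Xm} t + t_i)$, with a fixed
per-oscillator offset $t_i$ drawn uniformly on $[0, 1/\omega_{Xm}]$, so all
oscillators of an element share the same mean frequency and the same
deterministic modulation cycle but sit at slightly different points of it.
This deterministic frequency variation — rather than noise — is what makes
intermittent synchronization possible and observable in finite-time
analysis. An optional additive white frequency noise $\sigma\eta(t)$ on the
network oscillators recovers the stochastic formulation of the
individual-oscillator ($N = M = 1$) predecessor model; it requires the
fixed-step integrator (the increment is applied Euler–Maruyama style) and
defaults to $\sigma = 0$.

### Ring weighting

Within a network the oscillators are all-to-all coupled, with the weight
depending on the index separation around a ring (`ring_distance()`), which
stands in for physical distance in diffusive molecular exchange. The source
of this model is ambiguous about the functional form of the printed
weighting $W_{|i-j|}$, and the package exposes four readings
(`weight_kernel()`): `linear_growth` ($W\cdot d$), `harmonic_decay`
($W/d$), `power_decay` ($W^d$) and `uniform`.

The default is the **literal printed form** $W_{ij} = W \cdot d(i,j)$,
and this was a deliberate, empirically forced choice. The prose around the
formula says the weighting should *decrease* with index difference, which
suggests $W/d$; but with the $1/N$ normalisation and the reference coupling
$K = 0.025$, a decaying kernel leaves an effective intra-network coupling
of roughly $2K\ln(N/2)/N$ (about $0.007$ at $N=20$ and $0.002$ at $N=100$),
far too weak against the differential frequency modulation: measured
time-averaged order parameters at low inter-network coupling are then
$\approx 0.22$ (harmonic) and $\approx 0.37$ (uniform), i.e. *both networks
disordered* — contradicting the headline behaviour this model family
reports, namely that the networks themselves are never desynchronized and
total desynchronization disappears once networks are introduced. The
literal $W\cdot d$ kernel gives order parameters $\approx 0.99$ at the same
points and reproduces that behaviour at every grid cell we test. A literal
implementation of the printed formula is also what a straightforward
translation of the equations into code would produce. Users who want the
decaying-weight reading can select it per run.

### The sign of the OXPHOS mean-field term

As printed, the OXPHOS equation *subtracts* its whole inter-network term,
making the MO←GO mean-field coupling repulsive, while the individual
oscillator model it generalises has the corresponding term attractive — as
are all three other coupling terms. The package default is the attractive
sign (`mo_go_sign = "attractive"`), again empirically forced: under the
repulsive sign the two mean-field terms cancel on the $F_{GO} = F_{MO}$
diagonal (to first order in mean-field reduction,
$\dot\delta = \Delta\omega - (F_{GO} r_{MO} - F_{MO} r_{GO})\sin\delta$ for
the mean-field separation $\delta$), so the time-varying scenario below —
which lives exactly on that diagonal — produces no initial synchronized
episode at all (peak $s \approx 0.15$, flat), while the attractive sign
produces the reported spike-then-decline. The printed sign remains
selectable for comparison.

## Numerical integration

Two schemes are implemented in compiled code (`integrate_model()`):

* `"adaptive"` — an embedded Dormand–Prince 5(4) pair with standard
  error-per-step control (`rel_tol` $10^{-7}$, `abs_tol` $10^{-9}$ by
  default), FSAL, steps aligned to schedule breakpoints, and cubic Hermite
  dense output onto the uniform sampling grid. No error-controlled ODE
  solver package is available in the target environment, so the scheme is
  implemented here; the phase equations are non-stiff (the reference work
  used a stiffness-capable variable-step BDF method, but the contract is
  the tolerance, not the scheme). `h_max` (default 2 s) bounds the step so
  the third-order dense-output interpolant stays far below the integration
  tolerance for this model's time scales; against the zero-coupling closed
  form the sampled phases are accurate to $\sim 10^{-10}$ rad over 1000 s.
* `"rk4"` — the classical fixed-step four-stage Runge–Kutta scheme
  (default step 0.01 s), used for the time-varying scenario and required
  when frequency noise is on. Fourth-order step convergence is verified in
  the test suite.

Runs default to the reference protocol: 10,000 s integrated, sampled every
0.1 s ("sampling frequency of 0.1 s" is read as a sampling *interval*: a
0.1 Hz grid would leave only 1,000 samples against oscillation periods of
100–200 s), first 5,000 s discarded as transient (`discard_transient()`).
Initial phases are uniform on $[0, 2\pi)$ — the source randomises them
without stating a distribution — and, together with the modulation offsets,
derive from `config$seed`; noise increments derive from `spec$seed`.
Time-varying couplings are piecewise-quadratic `schedule()`s evaluated at
the current time, with negative evaluations clamped to zero (and warned
about, once per run).

## Synchronization analysis

Finite-time synchronization is classified per the reference criteria
(`classify_pair()`, `classify_network()`, `classify_regime()`):

* a **pair** (oscillator vs its driver, or oscillator vs the other
  network's mean-field phase) is *permanently* synchronized when the phase
  coherence of its difference exceeds 0.9 **and** the difference stays
  inside a $2\pi$ band over the whole window; *intermittently* when the
  coherence exceeds 0.9 but the difference slips ($\geq 2\pi$ range);
  *none* otherwise. Phase coherence is the modulus of the time-averaged
  unit phasor of the difference; non-autonomous series modulate away from
  their coherent mean, which is why the threshold sits at 0.9 rather than
  near 1.
* a **network** is synchronized when its time-averaged order parameter
  exceeds 0.5, *permanently* if $r$ varies by less than 0.2 (max − min)
  over the window — a non-autonomous network's $r$ breathes with the
  modulation even when highly ordered — and *intermittently* otherwise.

The mean-field phase $\Psi$ used by the inter-network modes is unwrapped
over time before differencing (so boundedness stays meaningful), and
samples with $r < 10^{-6}$ carry the previous $\Psi$, since the argument is
undefined at $r = 0$. Per-oscillator verdicts are combined into one label
per mode by majority vote with ties broken toward the weaker label
(none < intermittent < permanent); the source classifies one label per mode
without saying how per-oscillator verdicts combine, so the aggregation rule
is ours. The six labels map to the catalogued regime colors
(`regime_colors()`); combinations outside the catalogue are reported
`"unlisted"`, never forced into a listed color. `classify_regime()` warns
when the analysis window is shorter than ten modulation periods — note the
reference protocol itself (5,000 s against 1,000–2,000 s modulation
periods) triggers this warning; classification on such windows is usable
but seed-sensitive at regime boundaries.

## The coupling-plane sweep

`run_sweep()` maps the $(F_{GO}, F_{MO})$ plane. The reference grid is
$50 \times 50 = 2{,}500$ cells at steps of 0.006; the grid is anchored at
zero ($0.006k$, $k = 0..49$, so the axis tops out at 0.294) because the
zero-coupling corners carry interpretation, and the printed 2,500 total
forces the choice between including 0 or 0.3 — the alternative is one flag
away (`include_zero = FALSE`). Each cell runs with seed
`base_seed + cell index`, making the map independent of evaluation order
and worker count. The full reference sweep at $N = M = 100$ and 10,000 s is
hours of CPU and ships as the `"full"` preset; routine validation uses the
`"desk"` preset ($N = M = 20$, 3,000 s with 1,500 s transient, $10 \times
10$ grid at steps of 0.03), which preserves the qualitative structure:
networks ordered everywhere, no inter-network synchronization at
$F_{GO} = F_{MO} = 0$, and the mutually synchronized (dark blue) family
filling the large-$F$ region.

## The starved-HeLa scenario

`run_hela()` reproduces the time-varying experiment: 800 s of the full
model at $N = M = 100$ with Table-valued angular frequencies (glycolysis
mean period $\approx 6.7$ s, OXPHOS $\approx 3.3$ s, modulation frequencies
$3\pi/100$ and $3\pi/50$ rad/s $= 0.015$ and 0.03 Hz, amplitudes $3\pi/30$
and $3\pi/15$ rad/s — all entries are read as angular frequencies in rad/s,
consistent with the reference parameter table where $2\pi/200$ "Hz" means a
200 s period; this reading also places the glycolysis modulation at
0.015 Hz, inside the 0.01–0.02 Hz band extracted from the measurements).
The couplings follow piecewise-quadratic schedules fitted to the measured
fluorescence decay ($A = 9.511\times10^{-7}$, $B = 1.931\times10^{-3}$):
$\varepsilon_G = -At^2 + Bt + 0.025$ until 356 s and 0.7 afterwards (the
narrative attributes the ramp to "$\epsilon_{GO}$", but the parameter table
assigns it to $\varepsilon_G$, and the table is authoritative here);
$F_{GO} = F_{MO} = At^2 - Bt + 0.6$ until 383 s and 0 afterwards — the same
polynomial continues across the 356 s breakpoint, as the table repeats it,
and it crosses zero at $\approx 382.95$ s so the clamp hands over to the
zero segment continuously (within $10^{-4}$). The printed segment bounds
"0–355.9 / 356–382.9 / 383–800" are implemented as half-open
$[0, 356) / [356, 383) / [383, 800]$. Integration is fixed-step RK4
(0.01 s, i.e. several hundred steps per oscillation period) with no
transient discard: the initial spike is part of the output.

The scenario's output is the modified two-network order parameter
$$ s(t) = \frac{1}{N+M}\left|\sum_i e^{i\theta_{GO,i}} +
\sum_j e^{i\theta_{MO,j}}\right|, $$
the collective amplitude of both networks together, comparable to
single-cell NADH fluorescence (maximal when glycolysis and OXPHOS act
coherently). With the default seeds the curve shows the reported shape: an
initial synchronized episode ($s$ up to $\approx 0.8$) while
$F_{GO} = F_{MO} = 0.6$ holds the networks mutually locked, a declining
oscillatory phase as the couplings fade, and a low, still-oscillating tail
(mean $s \approx 0.37$ over 50–300 s vs $\approx 0.23$ over 600–800 s).

One caveat we document rather than hide: the spectral content of $s(t)$ is
dominated by order-parameter *breathing*, which is driven by the rectified
differential modulation spread ($\sigma^2(t) \propto \sin^2 \omega_m t$),
so power appears at $2\omega_{GOm}/2\pi = 0.03$ Hz and its harmonics as
well as in the 0.01–0.02 Hz band. With the default five seeds the
seed-averaged periodogram of the post-exhaustion window (383–800 s,
detrended by a 100 s running mean) peaks at $\approx 0.019$ Hz, inside the
measured band, but other seed sets can promote the 0.06 Hz harmonic to the
top: the in-band dominance is real but fragile, and single-seed curves vary
(the source itself notes the curve depends on the randomized initial
phases).

## Synthetic fixtures: what a green test establishes

`make_pair_fixture()` and `make_network_fixture()` generate series whose
ground-truth label is guaranteed by construction — locked differences with
small bounded iid jitter (not integrated white noise, so boundedness cannot
be lost by accident), discrete $2\pi$ slips whose post-hoc brute-force
coherence is verified at generation time, linear drifts spanning $\geq 10$
cycles, and network scatters whose order parameter follows the
wrapped-normal closed form $r = e^{-\sigma_c^2/2}$ (checked against the
requested label at generation). They validate the *metrics and
classifiers*, not the model: a diagonal confusion matrix on 50 seeds per
kind establishes that the 0.9/2π/0.5/0.2 rules are implemented correctly,
not that the model produces any particular regime. Fixtures do not emulate
measured NADH data or any time–frequency structure.

## Defaults worth knowing

| Parameter | Default | Why |
|---|---|---|
| `K, eps` (fixed couplings) | 0.025 rad/s | reference parameter set |
| `F_GO, F_MO` sweep range | 0–0.294, step 0.006 | 2,500-cell reference grid anchored at 0 |
| `W` | 1 | only relative weights matter |
| `N = M` | 100 | large enough for the mean-field approximation |
| `t_total / t_transient` | 10,000 / 5,000 s | reference protocol |
| `sample_interval` | 0.1 s | 10 Hz output grid |
| `rel_tol / abs_tol` | 1e-7 / 1e-9 | unstated in the source; chosen so tolerance, not scheme, limits accuracy |
| `h_max` | 2 s | keeps Hermite dense-output error ≪ tolerance |
| `rk4_step` | 0.01 s | ≥ several hundred steps per period in the HeLa scenario |
| offsets $t_i$ | U[0, 1/ω_m] | printed range; spans < 1 rad of modulation phase (`"phase"` mode gives full-cycle offsets) |
| initial phases | U[0, 2π) | source randomises them without stating a law |

## Known limitations

* No amplitude dynamics, metabolite concentrations or mass-action
  kinetics; no spatial embedding beyond the ring index; no intercellular
  coupling; no wavelet/time–frequency coherence or surrogate testing of
  measured data.
* Regime classification on short windows (fewer than ~10 modulation
  periods, including the reference protocol itself) is seed-sensitive near
  regime boundaries; the reference work reports reproducible "islands" in
  its maps for the same reason.
* The kernel form and the OXPHOS mean-field sign are corrected readings of
  an ambiguous source, as argued above; both alternatives remain available
  per run and flow through the identical pipeline.

```{r example, eval = FALSE}
# a desk-scale regime map and the HeLa scenario
pr <- sweep_preset("desk", seed = 1)
map <- run_sweep(pr$grid, pr$config, pr$spec)
glance(map)
autoplot(map)

h <- run_hela(hela_spec(seed = 1))
glance(h)
autoplot(h)
```
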