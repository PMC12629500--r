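---
title: "Methods: moment analysis of AONCB neurons with synchronous inputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moment analysis of AONCB neurons with synchronous inputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoncb)
```

## Model

The all-or-none-conductance-based (AONCB) neuron has subthreshold dynamics

$$\tau \dot V = (V_L - V) + g_e(t)(V_e - V) + g_i(t)(V_i - V) + I/G,$$

with leak reversal $V_L = 0$ mV, reversal potentials $V_i < 0 < V_e$,
membrane time constant $\tau = C/G$, and a constant current term $I/G$
(`Irest`). Synapses activate all-or-none for a duration $\tau_s \ll \tau$;
each input $k$ contributes a dimensionless weight $w_k = g_k \tau_s / C$.
Defaults follow common cortical values: $\tau$ = 15 ms, $V_e$ = 60 mV,
$V_i$ = −10 mV (relative to the leak reversal).

In the instantaneous-synapse limit the conductance drive is a compound
Poisson process: synaptic events occur at rate $b$, and each event carries
an aggregate jump $(W_e, W_i)$ equal to the summed weights of all inputs
coactivating at that event. A `jump_model` stores this distribution either
as discrete atoms (jump vectors across a set of neuron labels with
probabilities) or as a seeded sampler. Input synchrony lives entirely in
the law of $(W_e, W_i)$.

### Synchrony parameterization

Within a homogeneous pool of $K$ inputs at rate $r$, synchrony is captured
by the exchangeable beta-binomial model: at each event the number of
coactivating inputs is a binomial draw whose success probability is
beta-distributed with shape $\beta = 1/\rho - 1$, giving pairwise spiking
correlation $\rho$ and higher-order correlations
$\rho_n = \prod_{j=1}^{n-1} j/(\beta + j)$ (in particular
$\rho_3 = 2\rho^2/(1+\rho)$). Event-rate conservation fixes the collective
event rate through $b\,\mathbb{E}[k] = K r$; for the beta-binomial model
$b = r\beta\,(\psi(K+\beta) - \psi(\beta))$ with $\psi$ the digamma
function, decreasing in $\rho$ because synchronous events recruit more
inputs each. `as_jump_model()` converts a `beta_binomial_model` to the atom
representation; `jump_model_ei()` superposes independent excitatory and
inhibitory pools.

### Marcus jump rule

A conductance jump multiplies the instantaneous driving force, so the naive
Itô-style increment is wrong. The physically consistent update is the
limit of the smooth dynamics as $\tau_s \to 0$ (the Marcus rule):

$$V^+ = \mathcal{V} + (V^- - \mathcal{V})\,e^{-(W_e + W_i)}, \qquad
\mathcal{V} = \frac{W_e V_e + W_i V_i}{W_e + W_i}.$$

This is a convex relaxation toward the mixed reversal potential
$\mathcal{V}$, so the voltage never leaves $(V_i, V_e)$ regardless of jump
size. `marcus_jump()` exposes the update; the C++ kernels in
`src/marcus.cpp` use the anchored form above rather than the algebraically
identical increment $(\mathcal{V}-V)(1-e^{-W})$, because the anchored form
also respects the closed interval $[V_i, V_e]$ in floating point when
$e^{-W}$ underflows for saturating aggregate weights.

## Exact stationary moments

Event times are Poisson, so the voltage law seen just before an event
equals the time-stationary law (PASTA). Setting the stationary drift of
$\prod_a (V_a - I/G)^{c_a}$ to zero for a multiset of neuron labels with
counts $c$ balances the smooth relaxation against the expected jump change
and produces a *triangular* linear system: the moment of total order
$n = \sum_a c_a$ depends only on moments of order $< n$ of subsets of the
same labels. `general_mixed_moment()` solves this recursion with
memoization over count vectors; `moment_table()` tabulates shifted
($\mu$) and centered ($M$) moments to a requested order;
`stationary_mean()`, `stationary_variance()`, `stationary_covariance()`
and `third_moment()` are convenience specializations, each verified in the
test suite against independently coded compact forms such as

$$M_2 = \frac{b\,\mathbb{E}[R^2 (1-Y)^2]}{2/\tau + b\,\mathbb{E}[1-Y^2]},
\qquad R = \mathcal{V} - m,\; Y = e^{-(W_e+W_i)}.$$

Atoms with exactly zero jump for every neuron in the multiset contribute
nothing and are handled without division by zero. The recursion is exact
for discrete-atom models; sampler-backed models are first discretized by
`as_atom_model()` (Monte Carlo, seeded), which introduces sampling error —
prefer atom representations when available.

### Small-weight approximations

Expanding the exact formulas to leading order in the weights yields the
closed forms used throughout the analysis: `small_weight_mean()`,
`variance_small_weight()` (synchrony enters as the amplification
$1 + \rho(K-1)$ per pool, plus cross-pool terms
$\rho_{ij}\sqrt{r_i r_j}\,w_i w_j K_i K_j$ signed by the product of
driving forces), `covariance_small_weight()`,
`excitatory_variability_share()` ($q$), `correlation_shared_inputs()`
($\rho_V = f_e q + f_i (1-q)$), `kappa_synchrony()` and
`correlation_synchrony()` (with the bound $\rho_V < \rho'/\rho$),
`third_moment_small_weight_excitation()` and
`skewness_excitation_approx()` (skewness sign change at drive
$1/(2\tau)$), `gap_junction_means()`, `heterogeneity_equivalent_variance()`
($1 + \mathrm{CV}^2$ factor), and `faulty_transmission_transform()`
(release probability $p$ with weight compensation $K' = K/p$). The test
suite checks first-order convergence of these forms toward the exact
engine under weight halving. Note that with synchrony the compensated
failure transform leaves the mean exactly invariant but changes variance
and skewness at relative order $\rho(1-p)/(1+(K-1)\rho)$, because the
amplification factor $1+\rho(K-1)$ is not homogeneous under $K \mapsto
K/p$, $\rho \mapsto p\rho$.

## Correlated spike-train generator

`sample_raster()` produces binned spike counts for $L$ homogeneous pools
with a block-structured correlation matrix $\{\rho_{ij}\}$:

1. Per pool, the bin-wise spiking probability $\theta_i$ is beta-distributed
   with mean $r_i\,\Delta t$ and intraclass correlation $\rho_{ii}$
   (`beta_marginal_params()`), reproducing the beta-binomial count law
   within a bin.
2. Across pools, the $\theta_i$ are coupled by a Gaussian copula whose
   latent correlation is calibrated (`calibrate_copula_sigma()`, 64-node
   Gauss–Legendre quadrature plus root finding) so that
   $\mathbb{E}[\theta_i \theta_j] = \sqrt{r_i r_j}\,\rho_{ij}\,\Delta t$,
   i.e. measured pairwise count correlations match the requested
   $\rho_{ij}$ exactly at the bin scale.
3. Given $\theta$, inputs spike independently within the bin (conditionally
   independent Bernoulli), so within-pool correlation is exactly
   $\rho_{ii}$.

Feasibility requires $\rho_{ij} \le \sqrt{\rho_{ii}\rho_{jj}}$, enforced at
`correlation_spec()` construction. Realism considerations: the generator
models instantaneous (within-bin) synchrony only; temporal spread is added
separately by `jitter_spikes()` (i.i.d. Gaussian displacement, reflected at
the recording edges), and `empirical_count_correlation()` /
`mean_pairwise_count_correlation()` measure the resulting correlations at
arbitrary window sizes, reproducing the characteristic decay of measured
count correlation with jitter scale. Negative correlations are outside the
framework.

## Numerics and estimation

**Simulation.** `simulate_population()` is event-driven and exact:
between events the solution is a known exponential, and jumps use the
Marcus update, so stored post-event voltages carry no discretization
error. `simulate_gap_junction_pair()` integrates the coupled pair exactly
in the symmetric/antisymmetric eigenbasis (decay rates $1/\tau$ and
$(1+2g)/\tau$). `simulate_finite_synapse()` provides an Euler integration
of the finite-$\tau_s$ dynamics ($\tau_s = \epsilon\tau$) as an
independent check that the jump limit is attained.

**Estimation.** `empirical_summary()` computes time-averaged moments of
orders 1–3 from the piecewise-exponential trace in closed form (no
sampling grid for single-neuron moments; coupled pairs use a fine midpoint
grid), discards a burn-in (default $20\tau$), and attaches block-bootstrap
standard errors (default blocks of $100\tau$), which respect the trace's
autocorrelation. Acceptance-grade checks compare simulated moments to the
exact engine within four bootstrap standard errors across randomized
models.

## Design and limitations

- The theory engine is exact only for the instantaneous-synapse,
  Poisson-event model; finite $\tau_s$ effects are $O(\epsilon)$ and
  checked numerically, not expanded analytically.
- The moment recursion's cost grows combinatorially with order and number
  of labels; the default cap is order 6.
- Spike generation (threshold/reset) is deliberately absent: the package
  targets subthreshold statistics, and all formulas assume the passive
  dynamics above.
- The copula generator calibrates second moments only; higher-order
  cross-pool synchrony follows from the copula choice rather than being
  independently specifiable.
- Only nonnegative spiking correlations are representable.

## Reproducibility

All stochastic functions take explicit seeds. `run_experiment()` exposes
the main parameter sweeps as seeded, config-driven runners;
`scripts/acceptance.R` recomputes the headline worked numbers at runtime
from the public API.
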