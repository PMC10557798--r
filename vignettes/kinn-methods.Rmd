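---
title: "Kinetically interpretable neural networks: models, search and transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetically interpretable neural networks: models, search and transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinn)
```

## The modelling problem

Cas9 cleaves a DNA target after a multi-step recognition process — PAM
binding, R-loop formation, catalytic activation — whose step rates depend on
the guide-RNA/target pairing. Kinetic profiling assays observe a single
exponential cleavage rate per gRNA–target pair; in vivo screens observe only
a binary edited/unedited outcome. A kinetically interpretable neural network
(KINN) predicts these observables through a model whose *parameters are the
rate constants of a linear kinetic scheme*, so a trained model can be read
back as a set of ordinary differential equations.

## Linear kinetic schemes

A scheme is a directed graph over enzymatic states with rate constants
$k_{\alpha\beta}$. The occupancy dynamics are $\dot s = K s$ with
$K_{\alpha\beta} = k_{\beta\alpha} - \delta_{\alpha\beta}\sum_\gamma
k_{\alpha\gamma}$; columns of $K$ sum to zero, so total occupancy is
conserved and `propagate()` (a matrix-exponential solve via
`Matrix::expm`) keeps $\sum_\alpha s_\alpha = 1$ at all times. Note the
sign convention: we define the dynamics so that the solution is
$s(t) = s_\infty + e^{Kt}(s(0) - s_\infty)$ — the relaxation direction is
carried by $K$'s nonpositive eigenvalues, and `propagate` is tested
against an independent adaptive ODE integrator.

The steady state is computed by the King–Altman (KA) method: enumerate
every *KA diagram* — a directed spanning in-tree with $n-1$ edges, all
paths converging on one terminal state — and form

$$ (s_\infty)_\alpha = \frac{\sum_{\ell \to \alpha} \kappa_\ell}
        {\sum_{\ell'} \kappa_{\ell'}}, \qquad
   \kappa_\ell = \prod_{ij \in \ell} k_{ij} . $$

`enumerate_ka_diagrams()` uses exhaustive enumeration over per-state
outgoing-edge choices, which is exact and fast at the intended scheme sizes
(3–6 states); it is cross-checked against a brute-force subset search in the
test suite. Irreversible steps are simply absent edges: no diagram can use
them, and no zero-weight placeholder rows appear in the diagram matrix.

The measurable *activity* is the flux through the designated
product-forming transitions, $\nu = \sum_{\alpha\beta \in \mathrm{act}}
\tilde k_{\alpha\beta} s_\alpha$.

### The depleting-reservoir system and the slow mode

Kinetic profiling assays watch uncut DNA disappear, which is not a steady
state. The corresponding generator $K'$ drops the product-return entry of
the cut edge, so $\det K' \neq 0$, and the observed single-exponential
cleavage rate is $-\lambda$ for the nonzero eigenvalue of $K'$ closest to
zero (`slow_eigen_rate()`). For the four-state cleavage cycle two exact
identities connect the two pictures (`char_poly_identities()`):

* $\det K' = k_{01} k_{12} k_{23} k_{\mathrm{cut}}$ (binding rate scaled by
  the reservoir concentration), and
* $a_1(K) = a_1(K') = \sum_{\ell'} \kappa_{\ell'}$, the KA denominator,

whence $-\lambda \approx a_0/a_1$, which is exactly the KA activity. When
the cut step is much slower than every other rate the approximation is
tight (the tests check 5% agreement at a 100-fold separation), which is why
a steady-state KA head can be trained on single-rate data.

Numerical care: diagram weights are accumulated as
$\exp(\sum \log k - \max)$ (log-sum-exp) so rate ratios of $10^6$ do not
overflow; determinants and characteristic-polynomial coefficients of the
(tridiagonal) cycle matrices use sequential elimination without pivoting,
which telescopes the cycle products almost exactly where a generic LU loses
several digits; eigen tie-breaks prefer the larger real part, and a slow
mode with a material imaginary component triggers a warning reporting both
components.

## KINN construction

Each rate gets a *sequence window* $[i, j)$ on the encoded input and a
single-filter convolution of kernel size $d$:
$\log k_{\alpha\beta} = \sum \mathrm{Conv}(x_{i:j}; W_{\alpha\beta}) +
b_{\alpha\beta}$. With $d = 1$ this is a weighted sum of per-position
pairing contributions — exactly the additive free-energy picture — and with
$d = j - i$ it collapses to a fully connected layer on the window.

The rates feed a *static* binary diagram layer $B$ (one row per KA diagram,
one column per rate): diagram log-weights are $B \log k$, and occupancies
are obtained by a per-terminal-state grouped softmax — numerators
$\sum_{\ell \to \alpha} e^{B_\ell \log k}$ over a shared denominator. A
plain softmax over $B \log k$ would normalize over *diagrams* rather than
states; the grouped form equals the KA expression exactly and reduces to
the plain softmax in the special case where each state owns a single
diagram. The activity layer then multiplies exponentiated rates into the
occupancies of their source states.

The output head is $y = \sigma_o(\sigma_\nu(\nu W_t + b_t) W_o + b_o)$ with
$\sigma$'s searchable over {identity, softplus, exponential}. By default
the head is the *untrained identity*, i.e. $y = \nu$: the raw activity is
the predicted cleavage rate. This default reflects two things. First, a
final mapping is only warranted when the activity–measurement relation is
known to be nonlinear. Second, the activity of a typical cleavage model is
numerically small (order $10^{-4}$–$1\ \mathrm{s^{-1}}$) while adaptive
gradient steps on the head's *additive* parameters are of order the
learning rate; a trainable identity head therefore tends to push early
predictions negative, where a log-scale loss has no gradient. Users fitting
assays with a known nonlinearity can opt in with
`kinn_link(trainable = TRUE)` and a smaller learning rate.

An alternative output head (`output_head = "eigen_rate"`) replaces the KA
activity with the slow eigen-rate of $K'$ built from the predicted rates.
Both heads are differentiable — the eigen head through left/right
eigenvector perturbation theory, $\partial\lambda/\partial K'_{ij} = w_i
v_j / (w^\top v)$ — and both satisfy a finite-difference gradient contract
at $10^{-4}$ relative tolerance.

### Training

`kinn_fit()` runs full-batch Adam (default learning rate 0.05, up to a few
hundred epochs) on mean squared error of the **log** cleavage rate — labels
span several decades, so a linear-scale loss would be dominated by the
fastest cleavers; linear MSE remains available via
`train_config(loss = "mse")`. Kernels initialize from a small-variance
normal and biases at the log of the label median, which starts the rates
inside the label range and keeps the KA softmax unsaturated. Early stopping
watches validation Pearson and restores the best epoch; since a full-batch
"epoch" is a single optimizer step, the default patience is 30 steps. All randomness flows from the config seed, so identical calls give
bitwise-identical histories.

## Sequence encodings

Two deterministic encodings are provided:

* **Pairing encoding** (`encode_pairing`, $L \times 4$): each position's
  pair is reduced to one of four classes — Watson–Crick complementary, or
  one of three mismatch classes indexed by the cyclic offset of the target
  base from the complementary one. The class is a deterministic function of
  the pair, the guide's U equals T, and the target is recoverable given the
  guide.
* **Alignment encoding** (`encode_invivo`, $25 \times 13$): 4 channels
  one-hot the reference (PAM + guide) base, 4 channels one-hot a
  substitution, 4 an insertion, and 1 flags a deletion. The column layout
  is fixed PAM-proximal first: 3 PAM columns, 20 guide columns, then up to
  2 columns absorbing insertions; unused padding columns are all-zero.
  The layout order is a package convention (the parts are standard, their
  order is not), and every downstream window coordinate refers to it.
  Alignments needing more than 2 insertion columns are rejected rather
  than truncated, keeping the encoding injective and round-trippable.

All coordinates in files, windows and logs are 0-based half-open.

## The simulator defines the study conditions

`sim_config()` plants a fully known sequence→rate→label mechanism for the
four-state cleavage cycle, and its defaults are the benchmark conditions:
sequences of $L = 50$ nt; only positions $[5, 40)$ matter; that active
region is tiled by seven disjoint 5-nt windows, one per rate constant in
the fixed edge order $k_{01}, k_{10}, k_{12}, k_{21}, k_{23}, k_{32},
k_{30}$ (the order is a package convention). Rates follow the Arrhenius
form

$$ k_{\alpha\beta} = k_0 \exp\Big[\mp \tfrac{1}{k_B T}
     \sum_{i \in \Omega_{\alpha\beta}} \Delta\bar G(x_i, \xi_i)\Big], $$

negative sign for forward transitions ($\alpha < \beta$), positive
otherwise — the rule goes by state index, so the cycle-closing cut
$k_{30}$ takes the positive sign. $\Delta\bar G$ is $-1$ for complementary
pairs; each mismatch class draws once per transition from
$\{-0.1, 0.1, 1\}$ under the config seed and is frozen, so a dataset is a
pure function of (config, seed). The free-energy increments are
dimensionless multiples of the thermal energy, hence $k_B T = 1$.
$k_0 = 0.01\ \mathrm{s^{-1}}$ ($\mathrm{s^{-1} nMol^{-1}}$ on the binding
step, which is additionally scaled by the reservoir concentration
$D_u = 1$ nMol; only the binding step carries the concentration unit).
Labels are the slow eigen-rate of $K'$, and under the defaults they span
more than two decades.

The 16 possible pair identities are reduced to 4 classes so that the
planted free-energy function is *exactly* linear in the 4-channel pairing
encoding; a kernel-size-1 KINN with the true windows can represent the
generating rates exactly, which is what makes the recovery benchmark a
clean identifiability test rather than an approximation contest.

The binary in vivo benchmark (`simulate_invivo`) scores random alignments
(substitutions at 8% per position, occasional 1-nt indels) with a planted
KINN on the 13-channel encoding, adds a context effect
$\delta$ — an additive per-G bonus computed from the aligned target plus
Gaussian noise — and draws labels from
$p = \mathrm{sigmoid}(a(\log k + \delta - \theta))$ with $\theta$ at the
quantile giving the requested positive fraction (default 5%; real
compilations are far more imbalanced, but a desk-scale benchmark needs
enough positives for stable average precision). The true $\delta$ is
stored for recovery tests. What this generator does *not* emulate:
read-level sequencing noise, assay-specific link functions, chromatin
context, or guide-specific activity scales — so passing tests demonstrate
correct mechanics and learnability under the planted model, not
performance on real screens.

## Architecture search

The probabilistic model-building genetic algorithm searches the per-rate
window hyperparameters $(i, j-i, d)$. Priors are categorical ("multinomial
over an integer interval" is read as a uniform categorical): the start
$i$ over $[\phi(k) - w/2,\ \phi(k) + w/2]$ where the anchor function
$\phi$ places the forward rate $k_{\alpha,\alpha+1}$ at
$\mathrm{round}(L(\alpha+1)/n)$ — for a four-state scheme on a 20-bp input,
$\phi(k_{01}) = 5$, $\phi(k_{12}) = 10$, $\phi(k_{23}) = 15$; backward
rates inherit their forward partner's anchor and the cycle-closing cut is
anchored by its origin state (the worked placement only covers forward
steps, so these are package conventions). Window length is uniform over
$[1, 5]$ and kernel size uniform over $[1, j-i]$, re-truncated after the
length draw; sampling truncates supports so every sampled spec is valid by
construction. Defaults $w = 10$, 10 generations, population $m = 10$
($m$ is the stated population size; $w$ and the generation count are
package choices sized so a full search runs in minutes on one CPU).

Each generation trains its $m$ architectures under a budgeted config (few
epochs, early stopping) and scores validation Pearson. The expected
fitness $C_t$ is the *current generation's* mean (a running aggregate is
the other defensible reading; the current-generation mean reacts faster
and is what the update rule needs). Architectures with fitness strictly
above $C_t$ survive and contribute one Dirichlet pseudo-count to every
categorical cell they chose (uniform concentration 1 at initialization —
the gentlest conjugate update; nothing in the method fixes its magnitude).
If no architecture exceeds the mean (e.g. all-equal fitness), the top half
by fitness survives with deterministic index tie-breaking, guaranteeing
progress. `kinn_search(adapt = FALSE)` freezes the prior, giving the
matched-budget random-sampling baseline used in the comparison tests.

One empirical subtlety matters for benchmarking search against random
sampling: under the default $w = 10$ the per-rate start supports hold only
11 positions, and a 10 x 10 budget draws enough samples that *both* arms
reach the best fitness attainable inside the prior — the adaptive
posterior still raises the population's mean fitness substantially, but
the final-best statistic saturates and the comparison degenerates to a
tie. The search-vs-random test therefore widens the window to $w = 24$, a
regime where uniform sampling cannot exhaust the space within the budget
and posterior concentration pays off in the final best as well.

## Transfer to binary in vivo outcomes

A pretrained KINN is wrapped as a frozen layer: its log rates $\kappa(x)$
are computed from the alignment encoding, a trainable convolutional
backbone produces one modifier $\delta_\ell$ per rate from the same input,
and the in vivo rates $k' = e^{\kappa + \delta}$ flow through the same KA
and activity layers into a sigmoid over an affine map of **log** activity
(log rather than raw activity as the scalar input — the choice is open,
and log keeps the sigmoid input well-scaled across rate decades). The
frozen parameters are fingerprinted before and after every training run;
the fingerprint must be identical.

The backbone menu mirrors a small 7-slot convolutional model space: first
convolution (kernels 1/3/5, a dilated kernel, an inception-like layer of
parallel 1/3/5 kernels concatenated, or a linear positionwise map), an
optional second convolution, dropout over the grid $\{0.1, 0.3, 0.5\}$, a
bidirectional recurrent layer of 32 or 16 units, and a flatten slot
(plain, attention pooling, or a 64-unit dense layer). Identity is
available in every slot except the first convolution and the flatten. The
recurrent layer is a bidirectional tanh RNN: at 25 positions and these
widths a gated cell adds parameters without changing what the selection
experiments measure. Training uses class-weighted binary cross-entropy
(positive weight defaults to the negative/positive ratio) with minibatch
Adam, validation average precision per epoch, early stopping, and
best-epoch restoration.

`select_model()` searches the discrete (backbone, pretrained-KINN) space
by seeded *random search*: with spaces of a few thousand combinations and
budgets of tens of evaluations, random search is a strong, fully
reproducible baseline and keeps every piece of the search inspectable —
the learned-controller alternative optimizes the same space. Reported
per-slot selection frequencies summarize the top models; the top-$n$
models form an ensemble whose prediction is the mean probability (mean
rather than rank-average: it preserves calibration and satisfies the
convexity bound on log-loss).

Splits are by guide everywhere (`split_by_guide`): a guide's records never
straddle train and validation, which is the leakage-avoiding convention
for sequence models with repeated guides.

## Problem sizes and determinism

The test suite runs entirely on synthetic data generated at test time: the
null-space oracle sweeps 1,000 random 3–6-state schemes; dynamics are
checked against adaptive ODE integration on 100 schemes; the recovery
benchmark trains on 2,000 simulated records and evaluates rate recovery on
5,000; the search comparison runs two arms of 10 generations x 10
architectures over 5 seeds; the transfer comparison uses 5,000-record
binary datasets over 5 seeds plus a 3-seed negative control. These sizes
were chosen so each suite completes in minutes on a single CPU while
leaving the tested effects far from their decision thresholds. Every
stochastic component takes an explicit integer seed; datasets, fits,
searches and transfer runs are bitwise-reproducible given (inputs, seed).

## Known limitations

* Kinetics are linear (first-order) only: no concentration coupling,
  stochastic kinetics, or multi-substrate competition.
* Diagram enumeration is exhaustive; beyond ~8 states with dense edge sets
  it would need the incremental spanning-tree algorithm as a fast path.
* The identity-head positivity argument assumes the KA activity head; with
  a trainable nonlinear head the log-loss floor clamp can zero gradients
  for strongly negative predictions.
* The transfer backbone is intentionally small; it is a vehicle for the
  frozen-KINN + modifier design, not a state-of-the-art sequence encoder.
* Searching the number of states itself is out of scope — run separate
  searches per state count and compare.
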