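---
title: "Exact learning dynamics of two-layer linear networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact learning dynamics of two-layer linear networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lindynet)
```

## The model and what is being solved

A two-layer linear network maps inputs $x \in \mathbb{R}^{N_i}$ to
predictions $\hat y = W_2 W_1 x$ through a hidden layer of width $N_h$, and
is trained by full-batch gradient descent with learning rate $\eta$ on the
mean squared error $\mathcal{L} = \tfrac{1}{2}\langle \|\hat y - y\|^2
\rangle$ over $P$ training pairs. Although the network function is linear
in $x$, the loss is non-convex in the weights and the training dynamics are
nonlinear — this model class reproduces stage-like learning, saddle
plateaus, and representation formation while staying analytically
tractable.

The data enter only through three statistics: the input correlation
$\Sigma^{xx} = \frac{1}{P}\sum_n x_n x_n^T$, the input–output correlation
$\Sigma^{yx} = \frac{1}{P}\sum_n y_n x_n^T$, and the mean squared target
norm. In the continuous-time (gradient-flow) limit with time constant
$\tau = 1/\eta$, the dynamics of the stacked statistics

$$Q = \begin{bmatrix} W_1^T \\ W_2 \end{bmatrix}, \qquad
Q Q^T = \begin{bmatrix} W_1^T W_1 & (W_2 W_1)^T \\ W_2 W_1 & W_2 W_2^T
\end{bmatrix}$$

obey a matrix Riccati equation with a closed-form solution. The package
implements that solution in its numerically stable general form
(`exact_qqt()`), the original matrix-exponential form kept as an
independent cross-check (`riccati_fukumizu()`), the aligned-initialisation
form (`aligned_dynamics()`), explicit two-mode results
(`two_by_two_offdiag_peak()`, `sigmoid_mode()`), and the single-layer
closed form (`shallow_dynamics()`). A discrete gradient-descent simulator
(`simulate_gd()`, `simulate_nonlinear()`) acts as the verification oracle
for every formula.

## Assumptions and how they are checked

The closed forms hold under four structural assumptions, all checked
numerically by `validate_assumptions()`:

1. **Whitened inputs**, $\Sigma^{xx} = I$. All built-in generators
   construct this exactly (one-hot inputs are scaled by $\sqrt{P}$ because
   the correlations are defined with a $1/P$ average).
2. **Zero-balanced initial weights**, $W_1 W_1^T = W_2^T W_2$. This is a
   conserved quantity of the flow; all init constructors produce it
   exactly via the symmetric square-root factorisation
   $W_1 = O S^{1/2} V^T$, $W_2 = U S^{1/2} O^T$ with a seed-controlled
   orthonormal hidden gauge $O$ (any asymmetric split of $S$ would break
   balancedness).
3. **Full rank**: both $\Sigma^{yx}$ and the initial function $W_2 W_1(0)$
   have rank $\min(N_i, N_o)$, which requires $N_h \ge \min(N_i, N_o)$.
4. **Non-singular alignment**: with compact SVDs
   $W_2 W_1(0) = U S V^T$ and $\Sigma^{yx} = \tilde U \tilde S \tilde V^T$,
   the matrix $B = U^T \tilde U + V^T \tilde V$ must be invertible.
   Equal input/output dimensions are needed only by the reference
   matrix-exponential route.

The general solution is assembled from decaying exponentials
$E(t) = e^{-\tilde S t/\tau}$ only, which is what makes it stable at
arbitrary $t$; the matrix-exponential form contains growing modes and is
usable only at early times (both routes agree to $\sim 10^{-12}$ on their
common domain, which the tests exploit).

### The orientation obstruction behind Assumption 4

A fact worth knowing before sampling "random" initialisations: on square
tasks, $B$ is *exactly* singular — not merely ill-conditioned — whenever
$\det(W_2 W_1(0))$ and $\det(\Sigma^{yx})$ have opposite signs. Writing
$B = U^T(\tilde U \tilde V^T + U V^T)\tilde V$, the inner sum is a sum of
two orthogonal matrices, and when the product of their determinants is
$-1$ the rotation $V U^T \tilde U \tilde V^T$ necessarily has a $-1$
eigenvalue, so the sum is singular. Half of unconditioned random draws
therefore sit on a separatrix in at least one mode; full sign reversal
($W_2 W_1(0) = -\Sigma^{yx}$) is the extreme case in which every mode is
anti-aligned and the flow converges to the zero function. The package
provides `compatible_balanced_init()`, which redraws deterministically
until $\min \mathrm{sv}(B) > 0.1$, and all experiment presets sample
initialisations through it. Discrete gradient descent, by contrast,
escapes these separatrices through its own rounding noise, which is why
simulations from mismatched inits still reach the global optimum —
slowly.

In *odd* dimensions the reversal separatrix is stronger still: since
$\det(-\Sigma) = -\det(\Sigma)$, an $\varepsilon$-perturbation of the
reversed function cannot repair the orientation, and the perturbed $B$
stays exactly singular for every small $\varepsilon$. The perturbative
saddle diagnostic of `exact_qqt(..., b_fallback_eps =)` is therefore only
meaningful in even dimensions, and the reversal preset uses
$N_i = N_o = 4$. The fallback is never applied silently: a singular $B$
without an explicit `b_fallback_eps` is an error that names the
separatrix and suggests the simulator.

## Derived observables

* **Loss.** For whitened inputs the sample loss reduces exactly to
  $\tfrac12\|W_{tot} - \Sigma^{yx}\|_F^2 + c$ with
  $c = \tfrac12(\langle\|y\|^2\rangle - \|\Sigma^{yx}\|_F^2)$
  (`loss_from_function()`; non-whitened correlations are rejected and the
  simulator's sample-based loss is suggested instead).
* **Hidden representational similarity.** The kernel
  $\phi(x)^T\phi(x')$ of hidden representations is computed from the
  $Q Q^T$ blocks two ways — $X^T(W_1^TW_1)X$ from the input weights, or
  $X^T (W_2W_1)^T (W_2W_2^T)^+ (W_2W_1) X$ from the output side — which
  agree identically under balancedness; the redundancy is kept as an
  internal consistency check. At convergence the RSM equals the task's own
  structure $P\,\tilde V \tilde S \tilde V^T$ for *every* zero-balanced
  initialisation scale: fast exponential learning from large balanced
  weights still ends in a rich representation.
* **Finite-width NTK.** $\Theta = (X^TX)\otimes(W_2W_2^T) +
  (X^TW_1^TW_1X)\otimes I$ in sample-major ordering. Because the display
  form is easy to get subtly wrong, `ntk_jacobian()` rebuilds the kernel
  from the explicit parameter Jacobian and the tests require agreement to
  $10^{-10}$ over every shape with $N_i, N_o, N_h \le 4$, $P \le 3$. Note
  that for balanced inits the relative NTK movement over training
  decreases with initialisation scale only below the scale at which the
  initial kernel matches the task's: beyond it the movement saturates
  towards 1, because balanced inits always converge to the rich solution
  and must shed their large initial kernel.
* **Forgetting.** After converging on task $j$ the function is
  $\Sigma^{yx}_j$ exactly, so the loss on task $i$ is
  $\tfrac12\|\Sigma^{yx}_j - \Sigma^{yx}_i\|_F^2 + c_i$
  (`forgetting_loss()`): forgetting in this model is a pure task-similarity
  quantity, computable before training starts. `continual_run()` verifies
  this against both the analytic and the simulated engine, chaining legs
  through the rank factorisation `factor_qqt()` (the weights are only
  determined up to an orthogonal hidden gauge, which is seed-controlled
  and irrelevant to every observable).

## Two-mode special cases: exact versus printed forms

In the aligned two-mode setting with equal singular values $s$, the
cross-coupling $b(t)$ peaks at an interior time. Maximising the exact
aligned solution gives

$$t_{peak} = \frac{\tau}{4s}\ln\frac{s^2 - s(a_1+a_2) + \Delta}{\Delta},
\qquad \Delta = a_1 a_2 - b(0)^2,$$

whose small-init limit ($\Delta \ll s^2$) is the compact formula
implemented by `two_by_two_offdiag_peak()`,
$t_{peak} = \frac{\tau}{4s}\ln\frac{s(s-a_1-a_2)}{\Delta}$. The omitted
$+\Delta$ shifts the peak by $O(\Delta/s^2)\,\tau$, so the formula (and
its tests) live in the small-init regime $a_{1,2} \lesssim 0.05\,s$.
Similarly, the sigmoidal mode trajectory
$a_1(t) = s\,a_1(0)\,/\,(e^{-2st/\tau}[s-a_1(0)-a_2(0)] + a_1(0)+a_2(0))$
is the exact dominant-mode solution when $A(0)^TA(0)$ is rank-one
coherent ($b(0)^2 = a_1 a_2$); for generic small inits it describes the
first learning phase but its $t \to \infty$ limit is
$s\,a_1(0)/(a_1(0)+a_2(0))$, not $s$, so cross-checks against the exact
solution use coherent draws over the dominant mode's learning window.

## The simulator as oracle

`simulate_gd()` iterates the exact correlation-matrix gradients
$W_1 \mathrel{+}= \eta W_2^T(\Sigma^{yx} - W_2W_1\Sigma^{xx})$ (and
symmetrically for $W_2$) with simultaneous updates; one iteration advances
flow time by $\eta\tau = 1$, so iteration $k$ is compared with the
analytic solution at $t = k$ on the $\tau = 1/\eta$ clock. Discretisation
error is $O(\eta)$: the agreement preset measures median analytic-vs-GD
loss deviations across $\eta \in \{5\cdot 10^{-2}, 5\cdot 10^{-3},
5\cdot 10^{-4}\}$ and requires them to fall monotonically, reaching
$\le 10^{-3}$ at the smallest rate.

Balancedness is conserved by the *flow* but not by discrete GD: each step
adds an $O(\eta^2)$ defect
$\eta^2(W_2^TGG^TW_2 - W_1G^TGW_1^T)$, which integrates to an $O(\eta)$
drift over a learning transient. The conservation test therefore bounds
the gap after $10^4$ steps by $10\,\eta\,\|\nabla\mathcal{L}(0)\|$ rather
than by machine epsilon. With a tanh hidden layer nothing is conserved at
all — the gap grows by two to four orders of magnitude on the same task,
which is also why pre-computed forgetting predictions fail for nonlinear
networks.

`simulate_nonlinear()` applies tanh or ReLU at the hidden layer only,
keeping the two-weight-matrix architecture; routed with a linear
activation it reproduces `simulate_gd()` bit-for-bit, which is tested.
Saddle escape in simulations relies on float rounding plus an optional
explicit Gaussian kick at $t = 0$ (`noise_scale`, default 0; the reversal
preset uses $10^{-12}$ so that escape times are set by a known noise floor
rather than by rounding accidents).

## Synthetic tasks

`make_random_whitened_task()` builds $X$ from a scaled random orthogonal
matrix ($\Sigma^{xx} = I$ exactly, $P = N_i$) and synthesises
$\Sigma^{yx}$ from random orthonormal factors; default singular values are
drawn uniformly from $[0.5, 2]$ so that no mode's timescale dominates a
simulation budget by more than a factor of four — prescribed spectra are
realised exactly when supplied. `make_hierarchy_task()` builds the
$P = 2^{depth}$-item semantic tree (depth 3: the classic eight-item living
kingdom) with one feature slot per tree node: a shared root feature of
magnitude 1 and, per internal node at level $\ell$, a
$\pm 1/\sqrt{\ell+2}$ feature distinguishing its left and right subtrees.
The feature rows are mutually orthogonal, so the task is full rank, and
the input RSM $\tilde V \tilde S \tilde V^T$ exhibits the nested block
structure — siblings more similar than cousins, cousins than cross-tree
pairs — that the rich regime imprints on the hidden layer. The exact
feature values of the original figure-level task are not published; this
generator reproduces the structural class, not those numbers, and is
deterministic so that every test and preset is reproducible.

What these generators deliberately do not emulate: non-whitened input
statistics, label noise, sampled (non-exhaustive) item sets, and
unbalanced initialisations. Passing tests therefore demonstrate
correctness of the solutions under the theory's assumptions, not
robustness of the phenomenology to their violation.

## Numerical choices

* Rank truncation in compact SVDs: drop singular values below $10^{-10}$
  of the largest — far below any spectrum used here, far above float
  noise. Tied singular values are allowed; their vectors are only ever
  used in rotation-invariant products.
* $B$ counts as singular below an absolute $10^{-10}$ on its smallest
  singular value; past that an inverse is meaningless in double
  precision.
* The bracket in the general solution is solved (never inverted) as a
  symmetric system, with a hard refusal past condition number $10^{12}$;
  the same ceiling guards the matrix-exponential route's inner inverse.
* Orthogonal-complement bases are never materialised: the solution needs
  only the projectors $I - \tilde U\tilde U^T$ and $I - \tilde V\tilde
  V^T$, which are unique.
* Default time grids: 200 log-spaced points on $[10^{-3}, 50]\,\tau/\min
  \tilde S$, covering early transients through convergence (the slowest
  mode's residual at the grid end is $e^{-100} \approx 10^{-44}$).
* Problem sizes in tests and presets — dimensions 2–6, hidden widths up to
  8, $10^4$–$10^5$ GD steps, 10–50 random draws per property — were chosen
  as the smallest sizes at which every phenomenon (rank deficiency,
  unequal dimensions, large and small scales, saddle transits) is
  exercised; all scale linearly if larger studies are wanted.

## Known limitations

* No exact solution is provided for singular $B$ (reversal learning): the
  $\varepsilon$-perturbation is a diagnostic of the saddle limit, not a
  solution on the separatrix, and in odd dimensions not even that.
* Unbalanced initialisations (the truly lazy regime with frozen random
  hidden structure) are outside the solution class; the simulator will run
  them, the solvers will refuse.
* Individual weights are recoverable only up to a time-varying orthogonal
  hidden transformation; `factor_qqt()` fixes an arbitrary gauge.
* Networks deeper than two layers, mini-batch or stochastic gradients, and
  non-whitened input dynamics are out of scope.
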