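---
title: "Inferring synaptic polarity: models, assumptions and design choices"
author: "SynapticPolarity authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring synaptic polarity: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SynapticPolarity)
```

## The problem

A chemical synapse either excites its postsynaptic partner (+1) or
inhibits it (-1). Connectome reconstructions tell us *which* directed
neuron pairs are connected, but rarely with which polarity, because
dynamic measurements of synaptic effect remain low-throughput. This
package infers the missing signs computationally, under three
progressively weaker data regimes:

1. **Connectome model (CM)** — both single-neuron gene expression and a
   curated signed wiring-rule network are available.
2. **Spatial connectome model (SCM)** — expression is available, wiring
   rules are not, but some polarities are known from experiment.
3. **Generalized connectome model (GCM)** and closed-form signed
   predictors (SL2, SL3, SPA) — only the partially signed network
   itself is available.

The canonical application is the *C. elegans* chemical connectome
(about 295 neurons, 3 principal neurotransmitters, ~42 receptors
participating in curated rules), but every function operates on generic
labelled matrices.

## The connectome model

Let $X$ be the neuron-by-NT expression matrix of the presynaptic side,
$Y$ the neuron-by-receptor matrix of the postsynaptic side, and $O$ the
signed NT-by-receptor wiring-rule matrix ($O_{kl} = +1$ excitatory,
$-1$ inhibitory, $0$ no rule). The CM assigns each directed pair the
weight

$$B = X\,O\,Y^{\top}, \qquad A = \operatorname{sign}(B).$$

Expression is binarized before use (`expressed` $\Leftrightarrow$
value $> 0$): the curated data are effectively presence/absence
calls, and the model is a *rule count* — $B_{ij}$ is the number of
excitatory minus the number of inhibitory rules whose NT is expressed
by $i$ and whose receptor by $j$. Using raw expression levels as
weights would silently turn a combinatorial model into an
expression-magnitude model; `binarizeExpression()` makes the convention
explicit and `cmWeights()` applies it internally.

`classifyPairs()` reproduces the conventional four-way classification
of observed connections: *known* (all contributing rules share one
sign), *complex* (rules of both signs), *unknown* (expression on both
sides but no applicable rule) and *excluded* (no presynaptic NT or no
postsynaptic receptor expression). The CM's contribution is that
most *complex* pairs are resolvable by the sign of the rule majority
(`resolveComplex()`); exact cancellations ($B = 0$) stay unresolved.

```{r cm-example}
# a pair supported by four excitatory rules and one inhibitory rule
X <- ExpressionMatrix(matrix(c(1, 0), 2, 1,
    dimnames = list(c("pre", "post"), "Glu")))
Y <- ExpressionMatrix(matrix(rep(c(0, 1), c(5, 5)), 2, 5, byrow = TRUE,
    dimnames = list(c("pre", "post"), paste0("r", 1:5))))
O <- WiringRuleNetwork(matrix(c(1, 1, 1, 1, -1), 1,
    dimnames = list("Glu", paste0("r", 1:5))))
scoreValues(cmWeights(X, O, Y))["pre", "post"]
```

## The spatial connectome model

Without curated rules, the SCM *learns* a real-valued rule matrix
$\tilde O$ from the known polarities. Writing $a = \mathrm{vec}(A)$
(row-major) and $K = X \otimes Y$, the linear model $a = K o$ is
truncated to the rows corresponding to connections of known polarity
(the "spatial" constraint — pairs without an observed connection or
without a known sign carry no information about the rules) and solved
by ridge regression:

$$\tilde o = (K'^{\top} K' + \alpha I)^{-1} K'^{\top} a'.$$

`buildDesign()` materializes only the truncated design (one row per
training pair, the Kronecker product of the matching expression rows;
column $(k-1) n_R + l$ is rule $(k, l)$), never the full
$N^2 \times n_{NT} n_R$ matrix. `ridgeFit()` solves the normal
equations; at $\alpha = 0$ it returns the minimum-norm least-squares
solution via the Moore–Penrose pseudoinverse (with a warning when the
normal matrix is singular). The two analytic limits — $\tilde o
\propto K'^{\top} a'$ as $\alpha \to \infty$ and $\tilde o = K'^{+} a'$
as $\alpha \to 0$ — are covered by tests.

Scores for *all* pairs come from substituting $\tilde O$ back into the
bilinear form (`scmScores()`), ranking pairs by $|score|$
(`rankPredictions()`; ties broken deterministically on presynaptic then
postsynaptic label) and reading operating points off the running
precision curve.

**Choosing $\alpha$.** `selectAlpha()` scans a logarithmic grid
(default $10^{-3}$–$10^{3}$, 121 points) and keeps the $\alpha$ that
maximizes the rank at which the target precision (default 0.95) is
still attained against a reference set — by default the complex
connections resolved by the CM, which serve as an independent
pseudo-ground-truth because they are excluded from SCM training. Ties
break toward larger $\alpha$ (the smoothest competitive model). The
grid density is a package choice; the selection criterion is the
model family's standard one.

## The generalized connectome model

With neither expression nor rules, polarity inference becomes signed
link-sign prediction on $A$ itself. Eliminating the expression
matrices from the SCM equation yields the bilinear form

$$A = A\,W\,A$$

with an unknown neuron-by-neuron generalized rule matrix $W$.
`gcmFit()` offers two solvers, and the difference matters:

* **`solver = "inverse"`** (default): $W(\alpha) = (A^{\top}A +
  \alpha I)^{-1} A^{\top}$, the ridge-regularized pseudoinverse of
  $A$. Its limits are the model's two anchor behaviours: at
  $\alpha \to 0$, $W = A^{+}$ and $A W A = A$ — the overfitting limit
  that refits the observed signs exactly and predicts nothing new; at
  $\alpha \to \infty$, $W \propto A^{\top}$ and the scores become
  $A A^{\top} A$, the signed length-3 score. `alpha = Inf` is accepted
  and returns the closed form directly.
* **`solver = "dual"`**: the vectorized equation is truncated to the
  training pairs and solved as a ridge regression over the $N^2$
  entries of $W$, exactly as in the SCM. Because features far outnumber
  samples, the solve is done in the dual: the Gram matrix factorizes as
  $\langle \text{row}_{(i,j)}, \text{row}_{(i',j')} \rangle =
  \langle A_{i\cdot}, A_{i'\cdot}\rangle\,
  \langle A_{\cdot j}, A_{\cdot j'}\rangle$, so the Kronecker design is
  never formed.

The two solvers agree in the $\alpha \to 0$ refit limit but *not* for
large $\alpha$: the dual solution tends to $W \propto A^{\top} A
A^{\top}$ (scores $(AA^{\top})^2 A$, a length-5 path count) rather
than $A^{\top}$. We verified this numerically — the Spearman rank
agreement between the dual solution at $\alpha = 10^6$ and the SL3
score is about 0.96, versus $> 0.999$ for the inverse solver. Since
the heavily regularized limit is the recommended operating point of
the GCM and its defining connection to path-based link prediction is
the SL3 reduction, the inverse solver is the default; the dual solver
is retained as the truncation-faithful alternative for finite-$\alpha$
sweeps with partial training sets. The model's prediction is cubic in
$A$ either way (doubling $A$ scales the heavily regularized scores
by 8).

## Closed-form signed predictors

* **SL2** (`sl2Scores()`): $A^{\top}A + AA^{\top}$ — signed common
  pre-/postsynaptic partners, the structural-balance principle at
  triangle level. Even path length makes it blind to a global sign
  flip.
* **SL3** (`sl3Scores()`): $A A^{\top} A$ — signed paths of length
  three (forward, backward, forward), equivalently $A S_{in}$ or
  $S_{out} A$.
* **SPA** (`spaScores()`): $k^{+,out}_i k^{+,in}_j -
  k^{-,out}_i k^{-,in}_j$ — preferential attachment run independently
  on the positive and negative layers. Edges of unknown polarity do
  not contribute to the signed degrees: the formula is defined on
  signed degrees, and an unsigned edge has no layer to attach to.

All three use integer arithmetic on ternary inputs, so scores and
score cutoffs are exact.

## Evaluation protocol

`precisionCurve()` walks a ranking and accumulates
$p(r) = \tfrac1r \sum_{i \le r} a_i$ with $a_i$ the 0/1 sign-agreement
indicator; `thresholdForPrecision()` returns the largest rank with
$p(r) \ge$ target and the absolute-score cutoff at that rank. The
analytic baseline for sign-matched random guessing with positive
fraction $p$ is $p^2 + (1-p)^2$ (`randomBaseline()`; 0.5392 at
$p = 0.64$).

`kfoldCV()` partitions the known pairs into unstratified uniform
random folds (the fold seed is an explicit argument and is recorded in
CLI artifacts). Each method is refit with the test fold withheld — the
SCM re-learns its rules from the remaining folds; network-based
methods see the signed network with test entries zeroed — and the mean
curve averages per-rank precision over folds, truncated to the
shortest fold (the averaging convention for unequal fold lengths is a
package choice). Folds whose test pairs all score zero produce no
ranking and are excluded from the mean with a warning.
`subsampleExperiment()` refits the SCM on random fractions of the
known network against a fixed reference, 25 repetitions per fraction
by default (the repetition count is a package choice).

## The planted-rule generator

`generatePlanted()` draws Bernoulli NT and receptor expression, a
sparse ternary rule network, and a Bernoulli directed mask, then
derives the ground-truth signs and catalog *through the CM itself*, so
by construction the zero-noise dataset satisfies the end-to-end
identity $A_{full} = \operatorname{sign}(X O Y^{\top})$ on the mask.
`hideFraction` relabels a share of known pairs as unknown (held-out
ground truth for recovery experiments); `labelNoise` flips retained
signs.

Default parameters emulate the curated *C. elegans* dataset and were
calibrated once, then frozen: 295 neurons, 3 NTs, 42 receptors,
`pExpressNT = 0.40`, `pExpressR = 0.09`, `ruleDensity = 0.28`,
`pRulePositive = 0.61`, `edgeDensity = 0.05`. This yields roughly
1.5–1.7k known pairs per seed with a positive share averaging ~0.64,
about a thousand complex and several hundred unknown connections, and
an excluded class — the class proportions the CM literature reports.
Two deliberate simplifications:

* **Expression is i.i.d. Bernoulli**, not organized into anatomical
  neuron classes; this suffices for the statistical structure the
  bilinear model assumes, but real expression is strongly clustered.
  Passing tests therefore demonstrate correctness of the machinery and
  recoverability under the model's own assumptions, not performance on
  biologically structured noise (correlated curation errors, systematic
  expression dropouts).
* **Rule signs are stratified, not i.i.d.** With only a few dozen
  rules per draw, per-rule Bernoulli signs make the positive share of
  the derived labels swing wildly between seeds (we measured 0.34–0.82).
  Each NT instead receives a fixed count of excitatory rules,
  interleaved across receptors ordered by realized expression usage, so
  heavily and lightly used rules carry both signs and the label
  composition is controlled (0.58–0.70 across seeds) while individual
  rule placement stays random.

## Numerical choices and degenerate inputs

* Ridge solves use dense normal equations (feature counts are at most
  $n_{NT} n_R \approx 126$) or the dual Gram form (sample counts a few
  thousand); $\alpha = 0$ falls back to `MASS::ginv`.
* Ranking ties break on $(-|s|,\ \text{pre},\ \text{post})$ with a
  radix sort — fully deterministic across platforms.
* `sign(0) = 0` everywhere: a zero score is "no prediction", never a
  polarity; zero-score pairs are dropped from rankings rather than
  assigned arbitrarily.
* Degenerate inputs error early with specific messages: empty
  expression tables, negative expression, non-ternary rule inputs where
  ternary is required, training pairs without signs, empty training
  sets, folds without test pairs, overlapping contributions in
  `unionReport()`.

## Scale of the shipped experiments

The test-suite and acceptance-script experiments run at the package's
default problem size (295 neurons; 1.5k training pairs; 10-fold CV; a
10-fraction x 10-repetition subsampling grid; 20 random networks for
the GCM/SL3 agreement check), which completes in well under a minute
and matches the desk-scale regime the models were designed for.
Nothing in the implementation caps larger inputs; memory grows with
$N^2$ for the network methods and with training pairs x rule slots for
the SCM.

## Known limitations

* The SCM's learned $\tilde O$ is minimal in squared weight, a formal
  device — individual learned rules carry no guaranteed biological
  meaning, and systematic expression errors can surface as spurious
  compensatory rules.
* Connection-level only: multi-synapse pairs are treated as one
  directed connection; synapse-level weighting is out of scope.
* No significance calibration against degree-preserving randomized
  ensembles is included; precision against held-out or CM-resolved
  references is the only quality measure.
* The GCM solver choice (see above) reflects a genuine ambiguity in
  how the bilinear model's regularized solution is defined; both
  definitions are shipped and tested, and their large-$\alpha$
  behaviours differ by design.
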