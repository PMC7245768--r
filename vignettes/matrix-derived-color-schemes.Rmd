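---
title: "Deriving alignment color schemes from substitution matrices"
author: "MatrixPalette"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving alignment color schemes from substitution matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MatrixPalette)
```

## The problem

Alignment viewers color residues so that the eye can pick out conserved
and variable columns. Hand-made schemes encode chemical categories, which
need not agree with evolutionary exchangeability: ClustalX-style palettes
give alanine and tryptophan the same hydrophobic color although their
substitution score is among the lowest in BLOSUM62. MatrixPalette treats
scheme design as an embedding problem: place one point per symbol in a
perceptually uniform color space so that perceived color differences are
proportional to substitution-matrix distances.

## From scores to distances

For a score table $M$ over $N$ symbols the raw distance of a pair is the
average drop relative to self-substitution,
$D'_{ij} = ((M_{ii}-M_{ij})+(M_{jj}-M_{ji}))/2$ for $j<i$. Averaging the
two directions makes asymmetric inputs legal (with a warning). Diagonal
dominance ($M_{ii}$ maximal in row and column $i$) is expected but not
enforced: a violating matrix yields negative raw distances and a warning,
because the property is a convention of well-formed matrices rather than
a mathematical requirement. $D = D'/\langle D'\rangle$ removes the score
scale; the mean over the $n = N(N-1)/2$ strict-lower-triangle entries —
zeros included, since the triangle is a structural choice, not a value
filter — is exactly 1 afterwards. A constant matrix (all distances zero)
cannot be normalized and is rejected.

## Color space and constraints

Optimization happens in CIE L\*a\*b\* (D65 white point, 2° observer),
where Euclidean displacement roughly tracks perceived difference; the
scoring metric is the full CIEDE2000 formula (the Euclidean distance is
available as a fast opt-in approximation). Only part of L\*a\*b\* is
displayable in sRGB, so subspace membership couples user box constraints
(inclusive bounds on L\*, a\*, b\*) with a gamut test: the color must
convert to linear RGB channels inside $[0,1]$ within $10^{-9}$. The
XYZ→RGB matrix is the exact inverse of the standard RGB→XYZ matrix and
the white point is the image of $(1,1,1)$, so round trips and the white
point are exact at floating-point resolution. Bounds are treated as
inclusive throughout: at floating-point resolution the distinction from
strict inequalities is immaterial, and inclusive bounds give a simpler,
testable contract.

Sampling from a subspace is by rejection from the bounding box; where a\*
or b\* is unbounded the box defaults to $[-128, 128]$, which covers the
displayable gamut with margin. An empty subspace is detected by a
rejection budget ($10^5$ consecutive misses).

## The score

With pairwise color differences $C_{ij}$ and the scale factor
$f_s = n/\sum C_{ij}$ (so $f_s\langle C\rangle = 1$), the total score is
$S_T = S_H + S_C$ with $S_H = \sum (f_s C_{ij} - D_{ij})^2$ and
$S_C = f_c/\langle C\rangle$. $S_H$ alone is scale-free — shrinking a
scheme uniformly would not change it — which is exactly why the contrast
term exists: $S_C$ decays as the mean difference grows, pushing the
optimizer toward high-contrast embeddings. The weight $f_c$ has no
published default; the package uses 500, chosen once so that $S_C$
(≈ 15 at $\langle C\rangle \approx 35$) and $S_H$ (tens) are the same
order of magnitude for random 20-symbol conformations in the default
subspace, so neither term dominates at initialization. It is exposed as
a parameter (`fc`, `--contrast`).

A conformation with all colors identical has $\langle C\rangle = 0$; the
public scoring API treats this as an error, while inside the annealing
loop it scores $+\infty$ so the sampler can simply move away from it.

## Optimization

The search space is the $3N$-vector of color components constrained to
the subspace. Simulated annealing is adapted to this continuous problem
by annealing both the temperature and the step size with geometric
schedules: $\beta(t) = \beta_0 e^{t/\tau}$ and
$\Delta x(t) = \Delta x_0 e^{-t/\tau_x}$ — the classic single-parameter,
monotone choice. Each step perturbs every color by independent uniform
draws from $[-\Delta x(t), \Delta x(t)]$ per component; a color whose
move would leave the subspace keeps its previous position (per-color
rejection rather than whole-conformation rejection, which would stall
acceptance for large $N$; a one-color-per-step mode is available).
Metropolis acceptance applies to the total score. Each instance tracks
its best-so-far conformation and score, the worst score visited, and the
full current-score trajectory.

Defaults: 20,000 steps, $\beta_0 = 1$, $\tau = $ steps/4,
$\Delta x_0 = 10$ Lab units, $\tau_x = $ steps/2, ensemble of 8
instances seeded consecutively from a master seed. These produce
converged 20-symbol schemes in roughly a second per instance; all are
overridable. All randomness flows through R's RNG, so a seed fixes the
entire ensemble bit-for-bit.

## Diagnostics: the Z-score against random sampling

Whether the annealer is doing better than blind search is measured by
drawing one uniform conformation per iteration, scoring it, and tracking
the running mean $\mu(t)$ and (unbiased, $n-1$) standard deviation
$\sigma(t)$ of those scores. The diagnostic
$Z(t) = -(\langle S_T\rangle_{SA}(t) - \mu(t))/\sigma(t)$ uses the
ensemble mean of current-state scores at step $t$; the sign makes $Z$
positive when the ensemble is ahead. Early on $|Z|$ is small (the
optimizer is indistinguishable from sampling); it grows as the schedule
cools. At $10^5$ iterations on the default subspace the package reaches
late-stage $Z \approx 5.8$ for BLOSUM62 and $Z \approx 3.1$ for the
IDENTITY matrix (means over the final 5% of steps; both recomputed by
`scripts/acceptance.R` and the test suite). The IDENTITY matrix is
systematically lower: all pairs are equidistant, a target that a
three-dimensional embedding of 20 points cannot meet well, so the gap to
random sampling — whose samples are equally frustrated — is smaller.
Exact Z magnitudes depend on the contrast factor and schedule constants,
which are package choices; the ordering and plateaus are stable across
seeds (observed spread ≈ 0.01–0.07 across master seeds).

## Degenerate inputs and numerical choices

* 2-symbol alphabets always reach $S_H = 0$: one pair fixes $f_s$.
* Known optimum for testing: three equidistant symbols with $f_c = 0$
  under the Euclidean metric admit $S_T = 0$ (any equilateral triangle).
  The annealer is validated against it inside the finite sampling box
  (gamut test off). The box matters: with a\*/b\* fully unbounded the
  conformation can random-walk to a scale of several hundred Lab units,
  where the fixed absolute step width can no longer refine the shape and
  roughly one seed in ten stalls near (but not at) the optimum. Inside
  the box, 50/50 tested seeds reached scores below $10^{-3}$ (typically
  below $10^{-5}$).
* Hex quantization: sRGB channels are rounded half-away-from-zero to
  8 bits; the reconstruction error is below 1 CIEDE2000 unit, the
  tolerance used when verifying emitted schemes against their subspace.
* The running baseline variance uses cumulative sums in double
  precision, adequate for $10^5$ samples of scores of order $10^2$.

## What the generator and tests do and do not show

Test problems are built from bundled real matrices (BLOSUM62, PAM250)
and synthetic ones (identity-style, random symmetric with dominant
diagonals). Random matrices exercise the algebraic contracts
(normalization, invariances, oracle equality) but are not distributed
like curated log-odds matrices; conclusions about visual quality of
schemes for real alphabets rest on the BLOSUM62/PAM250 runs and, for
perceptual claims, on CIEDE2000 — itself only an approximate model of
human color difference, fit to patch-viewing experiments, not to small
glyphs on screens. Passing tests therefore demonstrate correctness of
the construction and optimizer behavior, not that a given scheme is
aesthetically optimal for a particular display or viewer.

## Known limitations

* The optimizer is heuristic: no optimality guarantee at finite time;
  the ensemble minimum is simply the best of several independent runs.
* Schemes are not unique — any isometry of color space that stays inside
  the subspace leaves the score unchanged, so different seeds give
  different but equally scoring palettes.
* Symbols outside the matrix alphabet (gaps, ambiguity codes) receive no
  color by design.
* Problem sizes used in the bundled checks (ensembles of 8 × 10^5
  steps, baselines of 10^5 samples) were chosen to give stable Z
  plateaus for 20-symbol alphabets; much larger alphabets may need
  longer schedules.
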