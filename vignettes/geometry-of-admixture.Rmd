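---
title: "Admixture proportions from the geometry of f-statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture proportions from the geometry of f-statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixgeom)
```

## The model

A panel of allele frequencies for $s$ SNPs embeds every population as a
point $\vec p \in [0,1]^s$, the *allele-frequency phase space*. A 2-way
admixture event creates a hybrid on the segment between its donors,

$$\vec p_x = \alpha\,\vec p_a + (1-\alpha)\,\vec p_b,
  \qquad \alpha \in [0,1],$$

and a 3-way event places the hybrid inside the donor triangle,
$\vec p_x = \alpha\vec p_a + \beta\vec p_b + (1-\alpha-\beta)\vec p_c$.
After the event every population performs an independent Brownian-like
walk (genetic drift), so the observed proxies form a triangle (2-way) or
a tetrahedron (3-way) instead of the collinear/coplanar inception
configuration. The estimation problem is to recover the mixing
proportions from the drifted proxies.

All quantities used here are the classical f-statistics, normalized as
means over SNPs:

* $f_2(a,b) = \frac1s\sum_k (p_{ak}-p_{bk})^2$ — squared distance per SNP;
* $f_3(a,b;x) = \frac1s\sum_k (p_{xk}-p_{ak})(p_{xk}-p_{bk})$ — the scalar
  product at vertex $x$; negative iff the angle $\phi$ at $x$ is obtuse,
  which is the classical admixture test;
* $f_4(a,b;i,j) = \frac1s\sum_k (p_{ak}-p_{bk})(p_{ik}-p_{jk})$ — the
  drift shared by the two pairs;
* $f_4'(a,b;i,j) = s\,f_4(a,b;i,j)/f_2(i,j)$ — the renormalized form: the
  component of $a-b$ along the direction defined by auxiliary pair
  $(i,j)$.

## Why project onto auxiliary-pair directions

Each unordered pair $(i,j)$ of the $k$ auxiliary ("right"/outgroup)
populations defines a direction in phase space; the $d = k(k-1)/2$
directions span a random low-dimensional subspace. Two high-dimension
facts make this subspace useful:

1. *Johnson–Lindenstrauss*: random projections approximately preserve
   pairwise distances, so the donor–hybrid configuration survives;
2. *quasi-orthogonality*: an isotropic random displacement (drift) in
   high dimension is nearly orthogonal to any fixed direction, so the
   post-admixture drift of the focal populations is largely removed by
   the projection.

In the subspace the hybrid model becomes, pair by pair,
$f_4'(x,b;i,j) = \alpha f_4'(a,b;i,j)$, and the least-squares solution is
the through-origin slope

$$\hat\alpha = \frac{\sum_{i<j} f_4'(x,b;i,j)\, f_4'(a,b;i,j)}
                    {\sum_{i<j} f_4'^2(a,b;i,j)},$$

implemented by `alpha_jl()` on the point set from `build_f4_point_set()`.
The slope is identically a weighted average of single-pair f4-ratios
$f_4(x,b;i,j)/f_4(a,b;i,j)$ with weights $f_4'^2(a,b;i,j)$
(`pair_diagnostics()` tabulates this decomposition), which is why
auxiliary pairs with large shared drift with the donors dominate the
estimate and why a lone f4-ratio (`f4_ratio()`, the $k=2$ collapse) can
be erratic. The 3-way analogue fits a plane through the origin to
$\{f_4'(a,c), f_4'(b,c), f_4'(x,c)\}$ (`fit3_jl()`).

Two diagnostics quantify the reconstruction: the angle $\varphi$ at the
hybrid vertex after projection (`angle_varphi()`; 180° = perfectly
collinear, the inception geometry) and, for 3-way fits, the
dimensionless flatness index $3V/A^{3/2}$ of the donor–hybrid
tetrahedron before and after projection (`flatness_index()`; 0 =
coplanar). $V$ comes from the Cayley–Menger determinant of the six
pairwise squared distances and $A$ from Heron's formula, so both need
only $f_2$-type distances.

## Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| degenerate-pair tolerance | `build_f4_point_set*` | `1e-12` on $f_2(i,j)$ | a pair of identical auxiliaries defines no direction; excluded and counted |
| unreliable-ratio tolerance | `f4_ratio` | `1e-12` on $|f_4|$ | guards the standalone ratio against zero shared drift |
| treeness threshold | `treeness_check` | $3\times$ analytic SE of each $f_4$ | the source framework states only "$\neq 0$"; the SE of the per-SNP product mean is the natural scale |
| confidence intervals | all fits | normal-theory, through-origin df | the cited procedure is "fit through zero and obtain the slope and its confidence interval"; SNP-block jackknife is out of scope |
| cosine clamping | angles | $[-1,1]$ | absorbs floating-point overshoot before `acos` |

Mixing coefficients are **not** clipped to $[0,1]$: out-of-range
estimates are reported with a warning because they are diagnostically
meaningful (introgression, wrong donor set).

## The synthetic world

`simulate_panel()` generates panels by tree-structured Brownian drift:
ancestral frequencies uniform on $(0.1, 0.9)$ (an ascertained
common-variant panel; avoids immediate boundary pile-up), then Gaussian
increments per branch with the branch's standard deviation, reflected
into $[0,1]$ (reflection rather than truncation, to avoid mass
accumulating exactly at the bounds). `default_drift_tree()` encodes a
two-clade topology: donor $a$ with auxiliaries `s1, s2, ...` in one
clade, donor $b$ with `d1, d2, ...` in the other, a few `w` auxiliaries
at the root. Cross-clade auxiliary pairs share the two clade-head
branches with the $(a,b)$ pair — large shared drift, large weight — while
within-clade pairs share none; `w` pairs are intermediate. Defaults
$\sigma_{\text{top}} = 0.10$, $\sigma_{\text{tip}} = 0.07$ give
between-clade $f_2 \approx 0.02$–$0.04$, the scale of continental human
population pairs. These values were fixed once, before any acceptance
measurement, and are not adjusted to outcomes.

For three donors the second clade splits into two subclades, one holding
donor $b$ and one holding donor $c$, each with part of the `d`
auxiliaries. This internal structure is necessary, not cosmetic: in a
flat clade no auxiliary pair shares drift with the $b-c$ direction, all
$f_4'(b,c;i,j)$ predictors vanish, and $\beta$ and $\gamma$ are not
separable in the subspace.

Post-admixture drift is emulated by `add_post_admixture_noise()`:
$\epsilon\delta$ with $\delta \sim U[-1,1]$ added per SNP to the donors
and the hybrid (configurable), redrawing $\delta$ whenever the result
leaves $[0,1]$. The hybrid itself is the *exact* convex combination
before noise, so zero-noise recovery is exact to machine precision — a
property the test suite asserts for every estimator.

What the generator does **not** emulate: mutation, recombination,
finite-sample allele-frequency error, ascertainment bias, gene flow
after the event, and coalescent population-size dynamics. A green test
therefore establishes correctness of the estimators under pure
drift-plus-noise, not robustness to everything real panels contain.

## Numerical choices and degenerate inputs

* Auxiliary labels are sorted and pairs enumerated lexicographically, so
  point sets and reports are reproducible regardless of input order.
* Through-origin fits use the closed-form normal equations (slope) or a
  QR factorization (plane); rank deficiency (collinear donors,
  duplicated populations) raises an error naming the degenerate
  direction.
* $\gamma$ is always computed as $1-\alpha-\beta$, with its CI from the
  propagated coefficient covariance.
* A negative Cayley–Menger determinant beyond tolerance (non-embeddable
  distances) clamps the flatness index to 0 with a warning; the index
  also carries an `apex_inside_base` flag (barycentric check) because a
  tetrahedron warped enough to project the hybrid outside the donor
  triangle makes the height-over-base reading unreliable.
* The third treeness quartet is printed in the source framework with an
  undefined fourth label; it is implemented as $f_4(x,b;c,a)$ by
  symmetry, with the substituted population exposed as an argument.

## Known limitations

The bounded-uniform noise with resampling at the boundaries is not
zero-mean for frequencies within $\epsilon$ of 0 or 1. Panels with
appreciable boundary mass therefore acquire a small systematic
displacement of the focal populations that is *not* isotropic, so the
projection cannot fully deplete it. In the default synthetic world this
produces an absolute bias of about $0.005$ in $\hat\alpha$ that
saturates for $\epsilon \ge 0.1$; at the edge of the non-introgression
regime ($\alpha = 0.2$, $\epsilon = 0.2$) the resulting mean relative
error measured by the acceptance suite is about 2.7%, slightly above
the 2% figure the method reports on a 12-times-larger real panel (the
variance term shrinks with $s$; the boundary bias does not). The
introgression regime ($\alpha$ near 0 or 1) amplifies everything, as
the framework itself warns. Error bars on the input frequencies are not
propagated into the fits.

## A worked example

```{r example}
spec <- simulation_spec(s = 20000, seed = 11)
panel <- simulate_panel(spec)
panel <- make_hybrid(panel, c("a", "b"), c(0.4, 0.6))
panel <- add_post_admixture_noise(panel, c("a", "b", "x"), 0.1, seed = 12)
cfg <- admixture_config2("x", "a", "b",
                         setdiff(pop_names(panel), c("a", "b", "x")))
fit_admixture2(panel, cfg)
```

The subspace estimate sits on the nominal 0.4 while the full-space
estimate is visibly dragged by the noise; $\varphi$ near 180° certifies
the reconstruction.
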