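---
title: "Analytic scaling laws for GLCM Haralick features on linear gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic scaling laws for GLCM Haralick features on linear gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HaralickScaling)
```

## The problem

Haralick texture features are scalar summaries of the gray-level
co-occurrence matrix (GLCM) and are used throughout biomedical image
analysis, radiomics and remote sensing. Their values, however, depend
strongly on acquisition and preprocessing parameters — above all on the
number of gray levels $N_g$ (bit depth $b$, $N_g = 2^b$) and on the
displacement vector $d$ used to probe the texture. Without a principled
normalization, features computed at 8-bit and 16-bit quantization of the
same scene are not comparable, which undermines cross-study
reproducibility.

This package implements the GLCM, four Haralick features, and
closed-form *scaling laws* for those features on a class of images where
they can be derived exactly: one-dimensional linear gray-level
gradients. The laws expose how each feature scales with $N_g$, the
gradient magnitude $\nabla$ (gray levels per pixel), and $d$, and they
justify normalization factors that remove the leading $N_g$ dependence.

## Conventions

The GLCM of an image $I(x, y)$ (x right, y down, origin upper-left) at
displacement $d = (\Delta x, \Delta y)$ counts ordered pairs

$$P_d(i, j) = \#\{(x, y) : I(x, y) = i,\; I(x + \Delta x, y + \Delta y) = j\},$$

normalized by the total pair count $R$ to probabilities
$p_d(i, j) = P_d(i, j) / R$. `computeGLCM()` follows this definition
with ordered (non-symmetric) counting by default; `symmetric = TRUE`
adds the transposed counts. Two boundary conventions are provided:

* **non-cyclic** (default): pairs whose target leaves the image are
  dropped, so $R = (N_x - 1) N_y$ for unit horizontal and
  $(N_y - 1) N_x$ for unit vertical displacement — the convention of
  standard GLCM libraries;
* **cyclic**: target coordinates wrap modulo the image size
  ($R = N_x N_y$). On an image containing a whole number of periods of
  a periodic pattern this removes edge effects entirely, which is what
  makes the analytic laws *exact* rather than asymptotic. It is the
  package's reference surface for validation.

The four features, computed from the stored (unsymmetrized) $p_d$:

* Energy / angular second moment $f_1 = \sum_{ij} p^2$;
* Contrast $f_2 = \sum_k k^2\, p_{x-y}(k)$ with
  $p_{x-y}(k) = \sum_{|i-j|=k} p(i,j)$;
* Correlation $f_3 = (\sum_{ij} i j\, p - \mu_x \mu_y)/(\sigma_x \sigma_y)$,
  `NaN` with a warning when a marginal is degenerate;
* Homogeneity / inverse difference moment, in two weight variants:
  $f_5 = \sum_{ij} p/(1 + |i - j|)$ (`"abs"`) and Haralick's original
  $\sum_{ij} p/(1 + (i - j)^2)$ (`"squared"`). Both are exposed because
  the common library definition ("homogeneity") uses the absolute
  difference while the classical definition squares it; the analytic
  law below is derived for the absolute variant and carries over to the
  squared one by substituting squared offsets in the denominators.

## Linear gradients and GLCM symmetry

A one-dimensional linear gradient with magnitude $\nabla$ steps through
the lattice $\{0, \nabla, 2\nabla, \dots\}$ and, at the top of the gray
range, wraps back to 0. The generator `makeLinearGradient()` renders
this as a periodic sawtooth over the *lattice*, with period

$$\tilde N_g = 1 + \lfloor (N_g - 1)/\nabla \rfloor$$

pixels — the number of distinct levels visited. The wrap is over the
lattice rather than modulo $N_g$: for $N_g = 7$, $\nabla = 2$ a column
reads $0, 2, 4, 6, 0, \dots$ and never visits odd levels. Were the wrap
taken modulo $N_g$, off-lattice levels would appear whenever
$\nabla \nmid (N_g - 1)$, the GLCM would gain extra entries, and the
closed forms below would fail. A `phase` parameter (default 0, i.e.
patterns start at level 0) shifts the starting point on the lattice;
`sign = -1` renders descending gradients, which merely transpose the
GLCM and change no feature value.

For such an image probed along the gradient axis at scalar displacement
$d$ (reduced to $d_\mathrm{eff} = d \bmod \tilde N_g$), the cyclic GLCM
has exactly $\tilde N_g$ nonzero entries, all equal to $1/\tilde N_g$:
$m_1 = \tilde N_g - d_\mathrm{eff}$ on the superdiagonal at gray-level
offset $k = d_\mathrm{eff}\nabla$, and $m_2 = d_\mathrm{eff}$ wrapped
entries on the subdiagonal at $k = -m_1\nabla$ (`diagonalSplit()`).
$d_\mathrm{eff} = 0$ is the degenerate whole-period shift — a diagonal
GLCM — which the package flags rather than rejects.

## The scaling laws

With $\tilde N_g$ and the diagonal split in hand, the features of the
cyclic GLCM follow by direct summation (`predictAll()`):

$$f_1 = \frac{1}{\tilde N_g}, \qquad
  f_2 = \nabla^2\, d_\mathrm{eff} (\tilde N_g - d_\mathrm{eff}), \qquad
  f_3 = 1 - \frac{6\, d_\mathrm{eff} (\tilde N_g - d_\mathrm{eff})}
             {(\tilde N_g - 1)(\tilde N_g + 1)},$$

$$f_5 = \frac{1}{\tilde N_g}\left[
    \frac{\tilde N_g - d_\mathrm{eff}}{1 + d_\mathrm{eff}\nabla}
  + \frac{d_\mathrm{eff}}{1 + (\tilde N_g - d_\mathrm{eff})\nabla}
  \right].$$

Energy is independent of $d$; Contrast and $1 - f_3$ share the
parabolic $d(\tilde N_g - d)$ shape; Correlation is independent of
$\nabla$ (the gray-level scale cancels); IDM decays roughly like
$1/(1 + d\nabla)$ for $d \le \tilde N_g/2$. Eliminating $\tilde N_g$
links Energy and Contrast directly:
$f_2 = \nabla^2 d\,(1/f_1 - d)$ (`contrastFromASM()`). Two printed
renderings of these formulas are ambiguous in the source material; both
were resolved by brute-force enumeration on small lattices: the $f_3$
denominator is $(\tilde N_g - 1)(\tilde N_g + 1)$ (it alone reproduces
$f_3 = -0.2$ at $\tilde N_g = 4$, $d = 1$), and the Energy–Contrast
relation carries $\nabla^2$, not $\nabla$ (it alone is consistent with
the $f_2$ law).

```{r laws}
predictAll(nLevels = 7, nabla = 2, d = 1)
```

### Normalization

Since $f_1 = 1/\tilde N_g \approx \nabla/N_g$, multiplying by $N_g$
makes Energy asymptotically independent of bit depth; likewise
$f_2 \propto N_g$ suggests dividing by $N_g$; $f_3$ and $f_5$ are
already asymptotically invariant. `normalizeFeatures()` implements this
as the `"paper"` scheme $(f_1 N_g,\; f_2/N_g,\; f_3,\; f_5)$ and, for
comparison, the `"lofstedt"` scheme from the empirical radiomics
literature $(f_1 N_g^2,\; f_2/N_g^2,\; f_3,\;$ IDM with weight
$1/(1 + ((i-j)/N_g)^2))$. The scaling laws show the $N_g^2$ factors
overcorrect: normalized Energy then grows linearly in $N_g$ instead of
being flat. The rescaled-IDM variant is implemented exactly as defined;
note that its weight is strictly below 1 off the diagonal, so the claim
sometimes attached to it — that it reduces identically to 1 — cannot
hold exactly, and the package treats it as a formula, not an identity.

### Inverting the Energy law

`estimateGradient()` recovers candidate gradient magnitudes from a
measured Energy: $\hat{\tilde N}_g = \operatorname{round}(1/f_1)$
(rejecting values more than 0.5 from an integer; R's round-half-to-even
applies at exact ties), then all $\nabla \in [1, N_g - 1]$ with
$1 + \lfloor (N_g-1)/\nabla \rfloor = \hat{\tilde N}_g$. The floor makes
the inversion non-unique — for $N_g = 9$, $f_1 = 1/3$ both $\nabla = 3$
and $4$ qualify — so a set is returned; supplying a measured Contrast at
a known $d$ narrows it to the best-matching candidate.

## Validation harness

`runSweep()` reproduces the numeric-vs-analytic comparison: one
sawtooth image per $\nabla$, GLCMs at displacements $d$ along the
gradient axis, measured features next to predictions, with per-row
absolute and relative errors. `sweepSummary()` reports worst-case
errors; `sweepShapes()` checks the qualitative curve shapes (Energy
flat in $d$, Contrast and $1 - f_3$ parabolic, IDM decreasing);
`plotSweep()` draws measured points over analytic lines.

```{r sweep}
rows <- runSweep(nLevels = 16, gradients = c(1, 3), displacements = 1:4,
                 width = 8, height = 96, mode = "cyclic")
sweepSummary(rows)
```

### Numerical and design choices

* **Cyclic height snapping.** In cyclic mode `runSweep()` snaps the
  image height down to a whole number of periods $\tilde N_g$ (at least
  one), because exactness requires equal occupancy of every lattice
  level; the requested height is used verbatim in non-cyclic mode.
* **Tolerances.** Cyclic rows are compared at `1e-12` (pure floating
  point); non-cyclic rows at 2% relative by default. Rows where the
  prediction is 0 fall back to absolute error; degenerate rows
  ($d_\mathrm{eff} = 0$, or $f_3$ undefined) are flagged, not dropped.
* **Finite-image caveat.** The non-cyclic convention loses exactly the
  pairs that straddle the image border, and for a phase-0 sawtooth the
  within-period position of the wrap transitions coincides with the
  cropped tail. The $m_2$ wrapped entries carry the huge
  $k^2 = (m_1\nabla)^2$ weight in Contrast, so losing a border's worth
  of them perturbs $f_2$ (and $f_3$) by a relative amount of order one
  over the number of complete periods — a few percent for
  $\tilde N_g \ll N_y$, but tens of percent when only a handful of
  periods fit (e.g. $N_g = 256$, $\nabla = 1$, $N_y = 1024$: four
  periods). This is a property of the finite-image protocol itself, not
  of any particular implementation; the cyclic mode exists precisely to
  separate the law from the boundary artifact, and the relative error
  of large-$|k|$-sensitive features in non-cyclic mode should be judged
  against this $1/q$ floor, not against machine precision.
* **Dense-matrix cap.** `computeGLCM()` refuses $N_g > 4096$ (a dense
  $65536^2$ matrix for native 16-bit input is not a sensible object)
  and points to `quantizeImage()`, which bins linearly with edges
  uniform on $[0, \max + 1)$.
* **Problem sizes.** The package's own test suite validates exactness
  on $N_g \in \{4, 7, 8, 16, 256\}$, $\nabla \le 7$, $d \le 8$ with
  whole-period cyclic images a few columns wide (the GLCM of a vertical
  gradient is independent of image width, so narrow images lose
  nothing), and runs the finite-image protocol at the full
  $1024 \times 1024$, 8-bit size.

## What the generator does and does not emulate

The synthetic images are *pure* one-dimensional linear gradients:
exact lattice values, no noise, no second gradient direction, no
nonlinearity, no natural-texture statistics. That is by design — this
is the class on which the laws are theorems, so agreement to $10^{-12}$
in cyclic mode is a correctness check of both the GLCM pipeline and the
closed forms. It is *not* evidence that the normalization factors
remove bit-depth dependence on real images, where gradients are only
locally linear and noise repopulates off-diagonal GLCM entries. What
carries over to real data is the leading-order scaling in $N_g$ that
the factors correct, not exact invariance.

## Known limitations

* Only the four features with derived laws are implemented; the
  remaining Haralick features (entropies, sum/difference statistics,
  information measures of correlation) are out of scope.
* Laws are for one-dimensional gradients probed along the gradient
  axis; for a displacement with a component across the gradient, the
  cyclic GLCM is unchanged (intensity is constant across the gradient),
  so the effective scalar displacement is the along-axis component.
* Gradient estimation assumes the image actually is a linear gradient;
  on other textures `estimateGradient()` merely inverts whatever Energy
  value it is given.
* PNG I/O is 8-bit; use TIFF for 16-bit data.
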