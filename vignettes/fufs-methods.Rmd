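---
title: "Computing Fu's Fs: exact log-space sums and a saddle-point estimator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing Fu's Fs: exact log-space sums and a saddle-point estimator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fufs)
```

## The statistic

Under the neutral infinite-alleles model, the Ewens sampling formula gives
the distribution of the number of distinct alleles $K$ in a sample of $n$
sequences with scaled mutation parameter $\theta$:

$$\Pr(K = k) = \frac{|S_n(k)|\,\theta^k}{(\theta)_n},$$

where $(\theta)_n = \theta(\theta+1)\cdots(\theta+n-1)$ and $S_n(k)$ is a
(signed) Stirling number of the first kind, with $|S_n(k)|$ counting
permutations of $n$ elements with $k$ cycles. The tail probability

$$S'_{n,m}(\theta) = \Pr(K \ge m) = \frac{1}{(\theta)_n}\sum_{k=m}^{n} |S_n(k)|\,\theta^k$$

is the probability of observing at least as many alleles as the $m$ actually
seen, and Fu's Fs is its logit,
$F_s = \ln\{S'/(1-S')\}$. In practice $\theta$ is estimated by the average
pairwise nucleotide difference $\theta_\pi$.

Two things go wrong numerically. $|S_n(k)|$ and $(\theta)_n$ overflow
double precision already for $n$ in the low hundreds, and when $S' \to 1$
the difference $1 - S'$ loses all significant digits. Both engines in this
package are organised entirely around those two hazards.

## Exact engine

Every addend $|S_n(k)|\,\theta^k$ is non-negative, so the whole computation
can live in log space with no cancellation. `log_stirling_row(n)` builds
$\ln |S_n(k)|$ for a whole row from the recurrence
$|S_{n+1}(k)| = |S_n(k-1)| + n\,|S_n(k)|$, carried out with vectorised
log-sum-exp and keeping a single row in memory ($O(n)$ storage, $O(n^2)$
work). With $\ell_k = \ln|S_n(k)| + k\ln\theta$, the two tails are partial
log-sum-exps over the *same* term set:

$$\ln S' = \operatorname{LSE}_{k\ge m}\,\ell_k - \operatorname{LSE}_{k}\,\ell_k,
\qquad
\ln T' = \operatorname{LSE}_{k<m}\,\ell_k - \operatorname{LSE}_{k}\,\ell_k,$$

so $S' + T' = 1$ holds by construction (one is stored, the other derived),
the Pochhammer normaliser cancels, and

$$F_s = \operatorname{LSE}_{k\ge m}\,\ell_k - \operatorname{LSE}_{k<m}\,\ell_k$$

is exact on both sides of $S' = 1/2$ — there is no subtraction of nearly
equal quantities anywhere. The branch label on the result records which tail
carries less mass (ties go to the T-branch; both relations agree to machine
precision there). The scaled-ratio path
$f_n(\theta) = n!\,\Gamma(\theta)/\Gamma(\theta+n)$
(`log_pochhammer_ratio()`, with its one-step recursion as an independent
cross-check) is retained as a separate overflow-control identity and test
surface, though the partial-LSE formulation makes it unnecessary in the hot
path.

The engine refuses $n > 20{,}000$: the quadratic recurrence is the wrong
tool there, and a hard error is more honest than silent minutes-long
degradation. Degenerate $m = 1$ returns $F_s = +\infty$ with a
`"closed-form"` flag rather than an exception — $S' = 1$ exactly, and batch
callers need a sentinel.

Two independent oracles validate the engine: an exact big-integer
implementation of the same recurrence (`stirling_first_kind()`, base-$10^7$
digit arithmetic, exact for all $n \le 250$), and a rational-arithmetic
evaluation of the full sums for rational $\theta$ used in the tests for all
$n \le 30$.

## Asymptotic estimator

For large $n$ the estimator avoids Stirling numbers entirely. It is
formulated in a raised-index frame $n' = n-1$, $m' = m-1$ (the index shift
is isolated in `fu_fs_asymptotic()`; the solver functions are
frame-agnostic). Three ingredients:

* $\varphi(z) = \ln\Gamma(z+n'+1) - \ln\Gamma(z+1) - m'\ln z$, whose
  positive saddle $z_0$ solves the digamma equation
  $\psi(z+n'+1) - \psi(z+1) - m'/z = 0$;
* $\chi(t) = n'\ln(1+t) - m'\ln t$, with stationary point
  $t_0 = m'/(n'-m')$;
* the transformation parameter $\tau$, the positive solution of
  $\chi(\tau) = \chi(t_0) + \varphi(\theta) - \varphi(z_0)$ on the branch
  with $\operatorname{sign}(\tau - t_0) = \operatorname{sign}(\theta - z_0)$.

The tail is then approximated by a regularised incomplete beta main term
plus a first-order correction,

$$S'_{n,m}(\theta) \approx I_x(m',\, n'-m'+1) + e^{-\chi(\tau)}\binom{n'}{m'-1} g(t_0),
\qquad x = \frac{\tau}{1+\tau},$$

with $g(t_0) = f(t_0) - 1/(t_0-\tau)$ and
$f(t_0) = \sqrt{\chi''(t_0)/\varphi''(z_0)}\,/(z_0-\theta)$. Two details of
this formula are typeset ambiguously in flat renderings of its source: the
coefficient must be read as the binomial $\binom{n'}{m'-1}$ (it is the
coefficient of $t^{m'-1}$ extracted from $(1+t)^{n'}$ when the integrand is
split), and the ratio $\chi''(t_0)/\varphi''(z_0)$ sits under a square root
(it is $(dz/dt)^2$ at the saddle). Both readings are confirmed numerically:
with them, all seven published benchmark values reproduce to the printed
digits (`run_table1()`).

$z_0$ is also the transition value of $\theta$ at which $S' = 1/2$ and Fs
changes sign. For $\theta < z_0$ the estimator forms $S'$ and
$F_s = \ln\{S'/(1-S')\}$; for $\theta > z_0$ it forms the complementary
tail $T' \approx I_{1-x}(n'-m'+1, m') - R'$ and $F_s = \ln\{(1-T')/T'\}$,
so the statistic keeps full relative accuracy on whichever side the small
tail is. Probabilities are assembled in log space throughout
(`pbeta(..., log.p = TRUE)`, the correction as
$\exp(-\chi(\tau) + \ln\binom{n'}{m'-1})$), so tails as small as
$e^{-1200}$ are represented without underflow.

### Numerical choices

* **Root finding.** $z_0$: bracketed `uniroot` on $[10^{-10}, z_{hi}]$ with
  $z_{hi}$ doubled from $m'$ until $\varphi'$ changes sign, then Newton
  polish with the trigamma derivative; accepted only if
  $|\varphi'(z_0)| \le 10^{-12}\max(1, m'/z_0)$. $\tau$: bracketed on the
  branch selected by the sign condition, starting from the local quadratic
  guess $t_0 \pm \sqrt{2\Delta/\chi''(t_0)}$, Newton-polished to a relative
  residual below $10^{-12}$; failure to bracket is a hard error with
  diagnostics, never a silent fallback.
* **Near the transition.** As $\tau \to t_0$, $f(t_0)$ and $1/(t_0-\tau)$
  diverge individually and their difference loses digits. Within
  $|\tau - t_0| < 10^{-4}\max(t_0, 1)$ the function falls back to the exact
  engine (flagged in the diagnostics); beyond the exact ceiling it drops the
  correction and keeps the main term, with a warning — near the transition
  $F_s \approx 0$ and the main term alone is accurate there.
* **Clamping.** The first-order sum can stray outside $(0,1)$ at extreme
  parameters (a negative sum, or $\ge 1$). Such values are clamped to
  $[10^{-300}, 1-10^{-16}]$ with a diagnostic flag rather than raising, so
  batch scans keep running and the event stays auditable. Legitimately tiny
  log-domain tails are *not* clamped — only genuine excursions outside the
  unit interval.
* **Dispatch.** `fu_fs(method = "auto")` uses the exact engine below
  $n = 50$ (where it is effectively free) and the estimator above; the
  threshold is an argument, not a constant, because nothing in the theory
  picks 50 — the benchmark table shows the estimator is already at
  $3\times10^{-4}$ mollified error by $n = 25$.

## Alignment summaries

`summarize_alignment()` computes $n$, the alignment length $L$, the allele
count $m$ (distinct full-length sequences after uppercasing and U→T mapping;
gap characters participate in identity), and

$$\theta_\pi = \frac{2}{n(n+1)} \sum_{i<j} \operatorname{dist}(D_i, D_j).$$

The $n(n+1)$ denominator is the convention this statistic was defined with,
and is the default (`convention = "paper"`). The conventional mean over the
$\binom{n}{2}$ pairs uses $n(n-1)$ and is available as
`convention = "tajima"`; the two differ by $(n-1)/(n+1)$ and neither is
silently corrected to the other — for small $n$ the choice visibly moves
$\theta_\pi$ and hence Fs, so it is surfaced as an explicit argument.
Site comparison defaults to pairwise deletion (columns with a non-ACGT
character in either sequence are skipped for that pair), with a strict mode
that errors instead; alignments with gaps are common and the statistic's
definition is silent on them, so the permissive choice is the default and
the policy is recorded in the output row.

## Validation harness and what it shows

`run_table1()` recomputes the seven published benchmark triples with both
engines; it checks each Fs against the printed value within one unit in the
last printed decimal place and each implied error against the printed error
column within a factor of two. (One printed asymptotic value, at
$n = 1000$, is itself misrounded in its last digit — 40-digit arbitrary
precision arithmetic places the estimator at $-112.4249939$ — which is why
the comparison allows one unit rather than half.)

`run_sweep()` draws $(n, m, \theta)$ triples the way the published accuracy
experiment did — $n$ uniform on 50–500, $m$ uniform on $2..n$, $\theta$
uniform on 1–50, in that order from a single seeded generator — and compares
the two engines pointwise with the mollified error
$\delta = |F_s - \tilde F_s| / \max(|F_s|, 1)$, which degrades from relative
to absolute error exactly where Fs crosses zero. The test suite runs 1,000
draws (the published experiment ran 10,000; a thousand is ample to pin the
"fraction below $10^{-3}$" summary well above its 0.95 bound) and asserts
byte-identical reproduction under a fixed seed. `run_error_grid()` is the
deterministic companion — $n \in \{100, 500\}$, $m/n \in \{0.1,\dots,0.9\}$,
$\theta \in \{10, 20, \dots, 500\}$, 900 points concentrated around the
transition region where the error peaks — and its maximum mollified error
(about $3.6\times10^{-4}$) is the package's headline accuracy bound.

These harnesses compare the estimator against this package's own exact
engine, which is mathematically the same quantity an arbitrary-precision
reference would produce (the tests tie the exact engine to independent
big-integer and rational oracles up to $n = 30$ and $n = 250$
respectively). What the sweeps emulate is parameter space, not data: they
say nothing about alignment quality, missing data, or whether $\theta_\pi$
is a good estimate of $\theta$ for a particular locus — only that, given
$(n, m, \theta)$, the fast estimator agrees with the exact statistic.

## Known limitations

* The exact engine is $O(n^2)$ and capped at $n = 20{,}000$; the estimator
  has no such cap but its error bound is established empirically only over
  the swept ranges ($n \le 2000$ against printed values, $n \le 500$
  densely).
* Only the first-order correction is implemented; higher-order terms of the
  underlying expansion would be needed to push below $\sim10^{-4}$ mollified
  error at small $n$.
* The inversion problem (recovering $\theta$ from a target $S'$ or Fs) is
  out of scope.
* $F_s = +\infty$ at $m = 1$ is a deliberate sentinel, and downstream code
  must expect it.
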