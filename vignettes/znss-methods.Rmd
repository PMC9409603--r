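---
title: "Z-number soft sets: model, similarity measure and diagnostic workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Z-number soft sets: model, similarity measure and diagnostic workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(znss)
```

## The model

A soft set maps each parameter (here: a symptom) to a fuzzy subset of a
universe of alternatives. A *Z-number soft set* (ZnSS) refines every such
judgment into a pair $(\mu, \gamma) \in [0,1]^2$: $\mu$ is the membership
degree — how strongly the alternative satisfies the parameter — and
$\gamma$ is the reliability degree attached to that membership judgment.
The pair encodes statements such as "the fever is *surely* very high":
$\mu$ captures "very high", $\gamma$ captures "surely". Everything in this
package works on numeric pairs; linguistic Z-numbers with explicit
membership functions over words are out of scope, since every judgment is
assumed already converted to $[0,1]$ values.

A `znss` object stores an ordered universe, an ordered declared parameter
list, and two numeric matrices (`mu`, `r`) over the *present* parameters.
A parameter may be declared but absent — an observer silent on a symptom —
in which case it has no column at all. This distinction matters: encoding
absence as an all-$(0,1)$ column would contaminate unions, because the
probabilistic sum of $\gamma$ with 1 is 1, not $\gamma$. Under the union,
a parameter present in only one operand therefore keeps that operand's
column unchanged; only parameters present in both are combined cellwise.
That reading is the only one consistent with the published union table,
which copies the one-sided column verbatim.

## Operations and norms

Cell-level operations are componentwise:

* complement $(\mu,\gamma) \mapsto (1-\mu,\, 1-\gamma)$;
* union by a t-conorm, intersection by a t-norm.

The default norm pair is product/probabilistic-sum
($a * b = ab$, $a \circ b = a + b - ab$), which is what all the published
worked tables use; `norm = "minmax"` switches to the Zadeh max/min pair.
The choice is a single argument on every operation, defaulting to
`"product"`.

Subset is the componentwise order ($\mu_1 \le \mu_2$ and
$\gamma_1 \le \gamma_2$ cellwise, plus containment of the present parameter
sets), equality is mutual subsethood — equivalently, identical present
parameters and identical cells. The null set has every cell $(0,1)$
("certainly absent") and the absolute set $(1,1)$. Two classical-looking
identities, $F \cap \varnothing = \varnothing$ and
$F \cup \varnothing = F$, *fail on the reliability component* under the
product norms ($\gamma \cdot 1 = \gamma \neq 1$;
$\gamma \circ 1 = 1 \neq \gamma$). The cell-level definitions — which the
published tables follow — take precedence here, so the package asserts
those identities on the membership component only and documents the
deviation rather than patching either definition.

## Similarity

For two sets over the same parameterized universe, each shared parameter
$j$ gets a two-component ratio similarity

$$M_j = \Bigl(1 - \tfrac{\sum_i |\mu_A - \mu_B|}{\sum_i (\mu_A + \mu_B)}\Bigr)
        \times
        \Bigl(1 - \tfrac{\sum_i |\gamma_A - \gamma_B|}{\sum_i (\gamma_A + \gamma_B)}\Bigr),$$

and the overall score is $S = \max_j M_j$. Both components lie in $[0,1]$
because $\sum|a-b| \le \sum(a+b)$ for nonnegative entries; $S$ is symmetric
and equals 1 on equal sets, and for a crisp set (cells all $(1,0)$ or
$(0,1)$) the similarity to its complement is exactly 0.

Numerical choices:

* **Zero denominators.** If both columns are identically zero the ratio is
  $0/0$; the component is defined as 1, the limit for identical columns.
  The event is recorded in the report's `zero_denominator` field and logged
  by the CLI.
* **Aggregation.** $\max$ follows the definition; an arithmetic-mean
  aggregate is available (`aggregate = "mean"`) for sensitivity studies,
  since a max can be carried by a single lucky parameter. The default
  remains max.
* **Ties** in the argmax resolve to the first parameter in column order.
* **Parameter sets** must match exactly by default; `shared_only = TRUE`
  scores the ordered intersection instead, for exploratory comparisons of
  partially overlapping reports. No internal rounding is performed; the
  print method displays 3 decimals.

One published property — monotonicity of $S$ along subset chains — is
proved in the source material using an ordering on reliabilities *opposite*
to its own subset definition. It is not guaranteed under the definitions as
stated, so this package checks it only empirically and does not assert it.

## The diagnostic workflow

1. Fix disease-model ZnSS over a shared universe and symptom list.
2. Collect observer reports as ZnSS.
3. Fuse the reports by a left fold of the union. With all parameters shared
   the cellwise t-conorm makes the result independent of grouping and
   observer order; the test suite checks both to $10^{-12}$.
4. Score the fused set against each model with the similarity measure.
5. Rank descending. Ties keep input order and are flagged explicitly; an
   optional `min_score` threshold withholds the recommendation when even
   the best score is poor (off by default — the published procedure always
   picks the maximum).

No clinical knowledge is embedded: the packaged disease models are toy
profiles for method demonstration only.

## Fixtures, flags and what the reference tables actually support

The published worked-example tables ship verbatim as CSV fixtures. When a
printed cell disagrees with the value produced by the tables' own cell
rules by at least one unit in its last printed decimal (an absolute 0.01
for these two-decimal tables), the recomputation tests do not silently
overwrite it: the cell is *flagged* in the fixture metadata, the flag list
is frozen, and tests assert that the set of mismatching cells equals the
frozen list exactly — so any silent edit of a fixture breaks the suite.
The flagged cells are: one complement reliability (a 0.4 printed as 0.5),
one union membership (0.19 printed as 0.18), three intersection
reliabilities (0.8 printed as 0.08), and four cells of the fused patient
table; a further fused cell (0.595 printed as 0.59) is within printed
precision and recorded as a truncation note instead.

```{r}
attr(paper_fixture("fused_t10"), "flags")
```

Consequences worth knowing before citing the case study: scored against
the printed fused table, four of eight influenza-model parameter
similarities and three COVID-model ones reproduce to three decimals; the
remaining published values (including the 0.899 and 0.803 that decide the
published headline ranking) do not follow from the printed tables, and
under correct arithmetic the two best scores become 0.765 vs 0.785 —
reversing the ranking. The package reproduces the internally consistent
values and documents the rest; the headline ranking is deliberately not a
reproduction target.

## Numerical design notes

* **Complement involution.** Plain `1 - (1 - x)` drifts one ulp for
  decimals such as 0.1, so the complement re-rounds at the 15th decimal.
  Double complement then restores any judgment recorded with at most 15
  decimals exactly; values of full binary precision (e.g. from continuous
  jitter) round-trip to within $10^{-15}$.
* **Norm clamping.** The probabilistic sum is clamped into its
  mathematical envelope $[\max(a,b), 1]$ and the product into
  $[0, \min(a,b)]$, so boundary identities (combining with 0 or 1, the
  absolute-set absorptions, the subset sandwich
  $F\cap F \subseteq F \subseteq F\cup F$) hold exactly despite rounding.
* **Equality vs tolerance.** `znss_equal()` compares cells exactly — it is
  a definition-level identity. Property tests compare derived quantities
  (associativity, fusion regrouping) at $10^{-12}$.
* **Serialization.** CSV/JSON writers emit up to 6 significant digits; no
  computation ever depends on serialized precision, and the round-trip
  tests work on grid-valued sets where the round trip is exact.

## The random generator

`random_znss()` draws every cell independently and uniformly from the 0.1
grid by default, mirroring the one-decimal judgment style of the reference
tables; cells are generated as `k/steps` so each value is the nearest
double of its decimal (naive `seq()` accumulation would fall off the grid
and spuriously break exact-involution checks). `perturb_reliability()`
adds bounded uniform noise to $\gamma$ only, for sensitivity studies of
the reliability channel.

What the generated data does *not* emulate: correlated symptoms, observer
bias (each cell is independent), informative absence patterns, or any
clinical plausibility. Passing property suites on such data demonstrates
the algebraic and metric laws of the calculus, not diagnostic validity on
real patients.

Problem sizes used by the test suite — hundreds of random instances up to
$6 \times 6$, plus the desk-scale published tables — were chosen because
every law checked is dimension-independent and counterexamples to the
floating-point edge cases (boundary values, ties, zero denominators) are
just as likely on small instances, which keep the suite fast and the
failures readable.
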