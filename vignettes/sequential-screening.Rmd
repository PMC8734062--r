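---
title: "Sequential screening tests: model, planning and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential screening tests: model, planning and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqppv)
library(tibble)
```

## The problem

A screening test is summarised by its sensitivity $a = P(T^+\mid D^+)$ and
specificity $b = P(T^-\mid D^-)$. What a clinician actually needs after a
positive result is the positive predictive value
$$\rho(\phi) = \frac{a\phi}{a\phi + (1-b)(1-\phi)},$$
which depends on the disease prevalence (or patient-specific pre-test
probability) $\phi$. Most screened conditions are rare, and at low $\phi$ even
an excellent test has a poor PPV: at $a = 0.9$, $b = 0.8$, $\phi = 0.1$, only
one positive in three is a true positive. The mirror-image negative predictive
value is $\sigma(\phi) = b(1-\phi) / \big((1-a)\phi + b(1-\phi)\big)$.

`seqppv` implements the Bayesian-updating answer to this: repeat the *same*
test and feed each posterior back in as the next prior. On the odds scale each
positive result multiplies the disease odds by the positive likelihood ratio
$LR^+ = a/(1-b)$, so after $n$ consecutive positives
$$\rho_n(\phi) = \frac{a^n\phi}{a^n\phi + (1-b)^n(1-\phi)},
\qquad
\operatorname{logit}\rho_n = \operatorname{logit}\phi + n \ln LR^+ .$$

```{r}
sequential_ppv(0.9, 0.8, 0.1, n = 1:4)
```

## Planning: how many positive tests are enough?

Solving $\rho_n = \rho$ for real-valued $n$ gives the continuous requirement
$$n = \frac{\ln\!\big[\rho(\phi-1)/(\phi(\rho-1))\big]}{\ln\!\big[a/(1-b)\big]}
    = \frac{\operatorname{logit}\rho - \operatorname{logit}\phi}{\ln LR^+},$$
which depends on the test only through $\ln LR^+$ — that is why the reference
tables are keyed by $\ln LR^+$ rather than $(a,b)$ pairs, and why
`required_iterations_continuous()` accepts either parameterisation. Tests are
discrete, so the usable answer is the ceiling: when 2.8 tests are "needed",
3 guarantee the target and 2 fall short.

```{r}
required_iterations(0.9, 0.8, 0.1, target = 0.95)
```

`required_iterations()` classifies every scenario rather than returning a bare
number, because the formula has sharp edges:

* **already_satisfied** — $\phi \ge \rho$: the prior alone meets the target,
  zero tests needed. The raw ceiling would be zero or negative; we floor the
  integer count at 0 and label it, since a negative number of tests has no
  clinical meaning.
* **infeasible_uninformative** — $a + b = 1$ (detected at tolerance
  $10^{-12}$): $LR^+ = 1$, every positive leaves the posterior exactly at the
  prior forever.
* **infeasible_negative** — $a + b < 1$: $\ln LR^+ < 0$, positives are
  evidence *against* disease, and the continuous count is negative.
* **unreachable** — $\phi = 0$, or a target of 1 with $\phi < 1$: no finite
  number of imperfect tests attains a perfect PPV, so targets $\ge 1$ are
  rejected as arguments.

A deliberate modelling note: the long-run limit of $\rho_n$ is sometimes
stated in terms of whether the sensitivity exceeds $0.5$, but the algebra of
$\rho_n$ depends on $a$ versus $1-b$ (equivalently $a + b$ versus 1); the two
coincide only when $b = 0.5$. `convergence_class()` and the feasibility labels
implement the $a \gtrless 1-b$ condition throughout.

## Where PPV and NPV cross

$\rho$ increases and $\sigma$ decreases in $\phi$, so they cross exactly once,
at
$$\phi_i = \frac{-b^2 + b - \sqrt{ab(ab - a + 1 - b)}}{a^2 - b^2 - a + b}.$$
Below $\phi_i$ a negative result is more trustworthy than a positive one. The
denominator factors as $(a-b)(a+b-1)$ and vanishes on two lines, $a = b$ and
$a + b = 1$; on both, symmetry forces the crossing to $\phi_i = 1/2$ (at
$a+b=1$, $\rho(\phi)=\phi$ and $\sigma(\phi)=1-\phi$), and the implementation
returns that limit whenever $|(a-b)(a+b-1)| \le 10^{-12}$ instead of dividing
0 by 0. For clinically useful tests the crossover often lands mid-range, but
it is an observation, not a theorem — $a = 0.99$, $b = 0.51$ puts it near
0.83:

```{r}
intersection_prevalence(c(0.9, 0.99), c(0.8, 0.51))
```

## Reference tables and the tablecloth surface

`reference_table()` regenerates the published planning grids: rows
$\ln LR^+ = 0.5, 1.0, \dots, 5.0$, columns
$\phi \in \{0.02, 0.05, 0.07, 0.1, 0.15, 0.2\}$, one table per target
$\rho \in \{0.99, 0.95, 0.75, 0.50\}$. Cells are the *continuous* counts
rounded half-up to 2 decimals; the ceiling is applied to the continuous value
when an integer count is wanted, never to the rounded display value. Half-up
display rounding reproduces every one of the 240 published cells (verified
copies ship in `inst/extdata/`), so the convention is settled by the data
rather than assumed. `tablecloth()` evaluates the integer count over a full
sensitivity × specificity × prevalence cross; infeasible cells are carried as
`NA` with a reason, exported as `"INF"` in CSV and `null` in JSON, and never
as negative integers.

```{r}
reference_table(0.99)
```

## Numerical choices

* All posteriors are computed on the log-odds scale
  (`plogis(qlogis(phi) + n * log(a/(1-b)))`). This is algebraically exact and
  cannot underflow to 0/0: $n = 10^4$ and far beyond are fine, whereas the
  naive $a^n$ form underflows near $n \approx 700$ for typical $a$.
* Probability-equality decisions ($a+b=1$ detection, degenerate-input checks)
  use an absolute tolerance of $10^{-12}$; root-level identities (crossover,
  inverse consistency) are tested at $10^{-9}$.
* Degenerate inputs that make a posterior 0/0 — specificity 1 with prevalence
  0 and a positive result, or an observed sequence with probability zero under
  both disease states — raise explicit undefined-result errors rather than
  returning a number.
* Display rounding is half-up (`floor(100x + 0.5)/100`), not R's default
  round-half-even, to match the published tables.

## The simulator: what it emulates and what it does not

`simulate_sequential_testing()` validates the closed forms on a synthetic
population: disease status is Bernoulli($\phi$) per subject and each subject
receives `n_tests` repeats with $P(+\mid D)=a$, $P(+\mid \lnot D)=1-b$. The
empirical PPV among all-positive subjects carries a binomial standard error
$\sqrt{\hat p(1-\hat p)/n_{\text{all}+}}$, and the all-positive fraction
converges to $a^n\phi + (1-b)^n(1-\phi)$. A single seeded generator drives
each run and the seed is echoed in every report.

The closed forms assume repeats are independent given disease status. Real
repeat testing — same specimen, same sitting, same reader — often is not, so
the simulator has a `correlation` knob: with probability $c$ a subject's
repeats are all copies of one Bernoulli draw, with probability $1-c$ they are
independent. This mixture preserves the marginal per-test sensitivity and
specificity exactly and gives within-subject correlation $c$ between any two
repeats. As $c \to 1$ repeats add no information and the all-positive PPV
collapses to the single-test value; `independence_violation_report()` reports
how much of the theoretical sequential gain survives:

```{r}
independence_violation_report(
  n_subjects = 50000, prevalence = 0.1, sensitivity = 0.9, specificity = 0.8,
  n_tests = 3, seed = 7, correlation = 0.5)[
    , c("correlation", "empirical_ppv", "analytic_independent_ppv",
        "single_test_ppv", "sequential_gain_realised")]
```

What the simulator does *not* emulate: a second, different confirmatory test;
temporal drift in the measured biology; testing whose continuation depends on
earlier results (the closed forms require that subjects with negative interim
results would keep being tested); and any fitted dependence model — the
correlation knob illustrates the caveat, it does not estimate it from data.
Passing tests therefore show internal consistency of the mathematics under
the stated sampling model, not clinical validity of sequential screening.

## Problem sizes and defaults

Monte-Carlo checks in the test suite use $2\times10^4$–$10^5$ subjects for
property checks and $2\times10^5$ for the headline two-test validation
($a=0.9$, $b=0.8$, $\phi=0.1$), sizes at which the binomial standard error of
the empirical PPV is about $0.003$ — small enough to detect any real
disagreement with the closed form while keeping a full run in seconds. The
default simulator settings mirror that scenario. Reference-table defaults are
exactly the published grids above.

## Known limitations

The model treats sensitivity and specificity as fixed, known constants; in
practice they are estimates with sampling error that this package does not
propagate. Planning is one-directional (PPV after consecutive positives);
there is no NPV-targeted analogue of the iteration count. And the ceiling
count answers "how many consecutive positives suffice", not whether obtaining
that many independent repeats is feasible or ethical in a given clinical
pathway.
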