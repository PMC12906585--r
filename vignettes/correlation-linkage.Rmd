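---
title: "Correlation-based recombination fractions, linkage maps and genomic mating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-based recombination fractions, linkage maps and genomic mating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrlink)
```

## The model

Consider two biallelic loci in a population derived from a cross of two
inbred lines followed by repeated self-fertilization. Code each genotype by
the number of alleles inherited from one designated parent, so
$X \in \{0, 1, 2\}$ at each locus. Write $\theta$ for the recombination
fraction between the loci and $H_t = (1/2)^{t-1}$ for the heterozygosity of
selfing generation $t$ (so $t = 2$ is an F~2~). Under two assumptions — no
segregation distortion and no crossover interference — the Pearson
correlation between the two coded loci satisfies

$$r = 1 - 2\theta$$

for *every* generation $t \ge 2$: both the variance $1 - H_t$ and the
covariance $(1 - H_t)(1 - 2\theta)$ carry the same heterozygosity factor,
which cancels. This yields a closed-form estimator

$$\hat\theta = \tfrac12 (1 - \hat r), \qquad
  s_{\hat\theta} = \frac{1 - \hat r^2}{2\sqrt{n - 3}},$$

the second expression being half the classical large-sample standard error
of a correlation coefficient. A negative sample correlation would map to
$\hat\theta > 1/2$, outside the parameter space; `estimate_pcorr()` sets
$r := 0$ (hence $\hat\theta = 1/2$), flags the estimate as clamped, and
evaluates the standard error at the clamped $r$, which keeps the formula
well defined ($s = 1/(2\sqrt{n-3})$).

Two likelihood-based references are implemented alongside:

* **Codominant EM** (`estimate_em_codominant()`): the observed 3×3 genotype
  table is fully informative except for the double heterozygote, which mixes
  the non-recombinant and doubly recombinant phases. EM imputes that split;
  the M step is the recombinant-gamete share
  $\theta \leftarrow (m_2 + 2\rho\,m_{22})/(2n)$ with posterior
  $\rho = \theta^2 / (\theta^2 + (1-\theta)^2)$, where $m_2$ weights the
  corner double-recombinant cells twice and the single-recombinant side
  cells once.
* **Dominant EM** (`estimate_em_dominant()`): the classical four-phenotype
  formulation for dominant markers in coupling phase, parameterized by
  $\pi = (1 - \theta)^2$. The double-dominant class mixes a $1/2$ component
  with a $\pi/4$ component; after convergence $\hat\theta = 1 - \sqrt{\hat\pi}$.

Standard errors for both EM estimators use Louis' observed information: the
expected complete-data information minus the variance of the complete-data
score, both evaluated under the posterior of the missing indicator at the
converged estimate. For the codominant model,

$$I(\hat\theta) = \frac{m_2 + 2\rho m_{22}}{\hat\theta^2}
 + \frac{m_0 + 2(1-\rho) m_{22}}{(1-\hat\theta)^2}
 - \frac{4 m_{22}\, \rho(1-\rho)}{\hat\theta^2 (1-\hat\theta)^2},$$

and for the dominant model (with $\rho = \pi/(2+\pi)$)

$$I(\hat\pi) = \frac{\rho\, n_{AB} + n_{ab}}{\hat\pi^2}
 + \frac{n_{Ab} + n_{aB}}{(1-\hat\pi)^2}
 - \frac{n_{AB}\, \rho(1-\rho)}{\hat\pi^2},
 \qquad \operatorname{var}(\hat\theta) = \frac{\operatorname{var}(\hat\pi)}{4\hat\pi}.$$

These expressions were derived from the complete-data likelihoods; the test
suite gates them against a numerical second derivative of the observed-data
log likelihood (relative agreement $10^{-3}$ at interior optima), and gates
the EM fixed points against a grid-plus-refine numerical maximizer
($10^{-6}$). Boundary estimates ($\hat\theta = 0$, or $\hat\pi \in \{0,1\}$)
report an undefined standard error rather than zero, because the observed
information degenerates there.

A quick look at the estimators on a published pair of adjacent rice markers
(191 F~2~ individuals, double heterozygote count 100):

```{r}
tab <- joint_count_table(matrix(c(41, 4, 0,
                                  0, 100, 3,
                                  0, 2, 41), 3, 3, byrow = TRUE))
estimate_pcorr(tab)
estimate_em_codominant(tab)
estimate_em_dominant(collapse_to_phenotypes(tab))
```

## Segregation diagnostics

The correlation identity requires Mendelian segregation. Before trusting
`estimate_pcorr()`, test each locus against the generation-$t$ expectation
$\big(\tfrac{1-H_t}{2}, H_t, \tfrac{1-H_t}{2}\big)$ with
`segregation_chisq()` (df = 2, upper-tail p, no continuity correction). The
simulation studies below show what distortion does to each estimator. For
random populations structured in families, `pooled_correlation()` estimates
the within-family correlation by pooling deviation cross-products over
families; within-family linkage disequilibrium reflects linkage even when
population-level disequilibrium does not.

## From estimates to maps

`estimate_adjacent()` sweeps within-chromosome adjacent marker pairs in
physical order (the package deliberately does no marker ordering: modern
physical maps fix the order, and with complete codominant data pairwise and
multi-point estimates coincide for adjacent markers). `assemble_map()`
converts each $\hat\theta$ with the Haldane mapping function

$$\hat d = -\tfrac{1}{2}\log(1 - 2\hat\theta) \times 100 \text{ cM},$$

and accumulates positions per chromosome. The function diverges at
$\theta = 1/2$, which the clamp rule can produce, so estimates at or above
0.4999 are mapped to the distance at 0.4999 and flagged rather than made
infinite. Failed pairs (e.g. a monomorphic marker) contribute 0 cM and keep
an audit flag instead of aborting the chromosome. `compare_methods()`
reports both pooled and per-chromosome correlations between two estimate
sets, since the pooling convention behind any single summary number is a
reporting choice.

## What the simulator emulates

`ft_simulator` provides two deliberately different modes.

**Table mode** (`simulate_ft_pair()`): i.i.d. draws of a genotype pair from
the generation-$t$ 9-cell distribution, with $\theta$ read as the effective
generation-$t$ recombination fraction. The distribution is constructed from
its constraints: margins $\big(\tfrac{1-H}{2}, H, \tfrac{1-H}{2}\big)$, the
four single-recombinant cells $H\theta(1-\theta)$, the double-heterozygote
phase mixture $H\,[(1-\theta)^2 + \theta^2]$, and the two corner classes
solved from the margin and covariance constraints
(coupling corner $\tfrac12(1-\theta)\,[(1-H) - H\theta]$). This is the
unique assignment that keeps those cells, stays a proper distribution over
$\theta \in [0, 0.5]$ and $t \ge 2$, preserves $r = 1 - 2\theta$ exactly,
and reduces to the textbook F~2~ table at $t = 2$. It also makes the F~2~
EM estimator exactly consistent at every $t$ (its fixed point is $\theta$),
which the property tests verify. Table mode is fast and is what the
estimator unit tests use.

**Mechanistic mode** (`simulate_ft_genome()`): single-seed descent with
explicit meioses. Founders are fixed for alternative alleles, the F~1~ is
fully heterozygous with known phase, and each generation selfs one offspring
per line. Gametes come from the meiosis engine: per chromosome, a
Bernoulli(1/2) start haplotype, a Poisson crossover count with mean equal to
the chromosome length in Morgans (zero crossovers allowed — no obligate
chiasma), and i.i.d. uniform crossover positions; markers are read off the
mosaic. Recombination accumulates over the $t-1$ meioses, so estimated map
length grows with $t$ — only this mode reproduces the cross-generation map
expansion, which is why both modes exist rather than a single reading of the
effective-$\theta$ question.

Segregation distortion re-weights the four gamete-class probabilities
multiplicatively before renormalization (`distortion_spec()`): "allelic"
favors gametes carrying one allele at the first locus (AB, Ab), and
"nonrecombinant" favors the parental classes (AB, ab). The default weight is
2 — strong enough to make the qualitative effects unambiguous at n = 200
while keeping all classes observable; it is a parameter, not an estimate.
Distortion applies independently to both gametes of every meiosis. Favoring
parental gametes shrinks the transmitted recombinant share below $\theta$
(all estimators biased downward); allelic distortion leaves the recombinant
share at $\theta$ but skews the margins, which hits the correlation method
hardest while the codominant EM stays nearly unbiased — the simulation tests
reproduce both patterns.

What passing these tests does **not** show about real data: the simulator
draws no genotyping errors, no missing-data mechanism beyond pairwise
deletion, no crossover interference, and no residual heterozygosity in the
founders. Real map expansion can also be inflated by genotyping error, which
the mechanistic mode cannot mimic.

## The genomic-mating workflow

`simulate_base_population()` builds an F~2~ of $n = 500$ individuals with 20
chromosomes × 101 markers (1 marker/cM; 2020 markers) via the meiosis
engine, assigns each marker an additive effect
$\gamma_k \sim N(0, \sigma_\gamma^2 = 0.5)$ and a dominance deviation
$\delta_k \sim N(0, \sigma_\delta^2 = 1.0)$ (the "0.5"/"1.0" are read as
variances; the config exposes both so the reading can be flipped), and
phenotypes $y = \mu + Z\gamma + W\delta + \varepsilon$ with $Z$ the 0/1/2
additive codes and $W$ the 0/1/0 heterozygosity indicator. The residual
variance is a parameter; its default 1000 was chosen once to put broad-sense
heritability near 0.72 at this genome scale (the marker-scaled genetic
variances are $C_\gamma \sigma_\gamma^2 \approx 1.5\times10^3$ and
$C_\delta \sigma_\delta^2 \approx 1.0\times10^3$).

The mixed model uses the normalized kinships
$K_\gamma = ZZ'/C_\gamma$, $K_\delta = WW'/C_\delta$,
$C = \operatorname{tr}(XX')/n$, so
$\operatorname{var}(y) = K_\gamma\sigma^2_A + K_\delta\sigma^2_D + I\sigma^2_E$.
`fit_reml()` maximizes the restricted log likelihood directly over the log
variances with Nelder–Mead — a deliberate choice of a robust derivative-free
scheme over a faster AI-REML iteration, since the three-parameter problem is
small and the log scale enforces non-negativity; correctness is gated by
parameter recovery on simulated data (mean estimates over 20 replicates
within 10% of the generating values), not by algorithm identity. Fixed
effects are intercept-only: the base population has no systematic
environmental structure, and the design matrix argument accepts anything
richer. GBLUP breeding values follow as conditional expectations
($\hat\xi_\gamma = \hat\sigma^2_A K_\gamma \hat V^{-1}(y - X\hat\beta)$,
likewise for dominance), and `backsolve_marker_effects()` converts them to
per-marker effects through the minimum-norm identities
$\hat\gamma = Z'(ZZ')^{-}\hat\xi_\gamma$ — a pseudoinverse with relative
eigenvalue tolerance $10^{-10}$, since $WW'$ is routinely rank deficient;
the attainable projection $Z\hat\gamma = \hat\xi_\gamma$ is preserved to
numerical precision.

Selection mirrors the illustration protocol: rank by EBV, top 9 as dams,
ranks 10–12 as sires (both counts are parameters). Each candidate cross is
scored two ways:

* **Expectation**: per-marker Mendelian expectations
  $E(Z) = (g_s + g_d)/2$ and
  $E(W) = \tfrac{g_s}{2}(1-\tfrac{g_d}{2}) + (1-\tfrac{g_s}{2})\tfrac{g_d}{2}$,
  weighted by the estimated effects. Exact and instant.
* **Simulation**: $N$ virtual progeny from simulated parental meioses. Its
  mean estimates the same quantity (the two agree within Monte-Carlo error,
  cross by cross), but it additionally yields the Mendelian-sampling spread
  of a single progeny, reported as `se` — information the expectation method
  cannot provide. The spread of one progeny, not the standard error of the
  mean, is the quantity a breeder needs, so that is what is labeled.

`enumerate_mating_schemes()` lists all $d!/(v!)^s$ assignments of $d$ dams
to $s$ sires ($v = d/s$ each) in lexicographic order of the sire-group
combinations, `search_best_scheme()` scores each scheme by its mean assigned
cross value and returns the argmax (ties broken deterministically by lowest
canonical index) together with the gain over the all-scheme average. Counts
are exact: products of binomial coefficients, with an exact decimal digit
string from small big-integer arithmetic for counts beyond double precision
(e.g. $100!/(10!)^{10} \approx 2.357\times10^{92}$, whose enumeration is of
course refused by the cap). Only exhaustive search is provided; heuristic
search for large $(d, s)$ is out of scope.

```{r}
count_mating_schemes(9, 3)
```

## Numerical choices and defaults

| Parameter | Default | Why |
|---|---|---|
| `theta_init` | 0.25 | phase-agnostic midpoint of the domain |
| `tol` (EM) | 1e-10 | parameter-scale change; both EM maps contract fast |
| `max_iter` | 1000 | far above observed need (≈10 iterations typical) |
| Haldane cap | 0.4999 | keeps clamped estimates finite on the map |
| pseudoinverse rtol | 1e-10 | rank decisions on `ZZ'`/`WW'` eigenvalues |
| distortion weight | 2 | unambiguous effects with all classes observable |
| `residual_var` | 1000 | broad-sense heritability ≈ 0.72 at the default scale |

Degenerate inputs are errors, not guesses: empty tables, all-missing pairs,
monomorphic margins (no correlation exists), non-divisible $d/s$. EM
non-convergence within `max_iter` is flagged on the estimate, never silent.
The percent gain of mate allocation is only meaningful for traits on a
positive scale (it is relative to the random-mating average).

Problem sizes used by the test suite were chosen to make each statistical
property sharp at modest cost: two-locus studies use n = 200 with 100
replicates on a grid $\theta \in \{0, 0.05, \dots, 0.45\}$; meiosis checks
use $10^5$ gametes; map-expansion uses one 100 cM chromosome with 11
markers, n = 191 lines and 50 replicates per generation; REML recovery uses
20 replicates of the full 500 × 2020 configuration; and every candidate
cross in a 3 × 9 table is checked expectation-vs-simulation at N = 1000
progeny.

## Known limitations

* The correlation identity — and therefore `estimate_pcorr()` — fails under
  segregation distortion; the chi-square diagnostic should precede it.
* All estimators here are two-point; no multi-point likelihood, no
  interference model, no repulsion-phase parameterization of the dominant
  collapse.
* The generic-$t$ joint table treats $\theta$ as the generation-effective
  parameter; cumulative-recombination questions need the mechanistic
  simulator.
* REML assumes dense, PSD kinships and $n$ in the hundreds; no sparse or
  large-$n$ machinery is included.
* Exhaustive mating search scales as $d!/(v!)^s$ and is capped; this package
  provides no heuristic alternative.
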