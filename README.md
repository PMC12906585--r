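# corrlink

Fast pairwise recombination-fraction estimation for selfing biparental
populations, linkage-map construction, and a genomic-mating workflow — for
plant and animal breeders and quantitative geneticists working with
F<sub>t</sub> (F<sub>2</sub>, F<sub>3</sub>, …) populations genotyped at
ordered biallelic markers coded 0/1/2.

## The statistic at the core

In an F<sub>t</sub> population from inbred founders (no segregation
distortion, no crossover interference), the Pearson correlation *r* between
the allele-count codes of two loci obeys

    r = 1 − 2θ        for every generation t ≥ 2,

where θ is the recombination fraction. So θ can be estimated without
iteration as

    θ̂ = (1 − r̂)/2,     s(θ̂) = (1 − r̂²) / (2√(n − 3)),

with a clamp to θ̂ = 0.5 when r̂ < 0. The package implements this estimator
alongside two EM references — the codominant 3×3-genotype model and the
classical dominant four-phenotype model — both with Louis
observed-information standard errors, plus:

* segregation-distortion chi-square diagnostics (1:2:1 and the
  generation-t generalization) and the pooled within-family correlation;
* Haldane linkage maps (d = −50·ln(1 − 2θ̂) cM) from adjacent-marker sweeps;
* an F<sub>t</sub> simulator: fast table-mode draws, and a mechanistic
  single-seed-descent mode built on a gamete-level meiosis engine (Poisson
  crossovers, no interference), with optional segregation distortion;
* genomic mating: REML variance components for additive + dominance
  kinships, GBLUP breeding values, marker-effect back-solving, progeny
  prediction by Mendelian expectation and by simulated meiosis, and
  exhaustive mate-allocation search with exact scheme counting.

## Worked example

Two adjacent rice markers, 191 F<sub>2</sub> individuals, as a 3×3 joint
count table (rows/columns are the codes 0, 1, 2):

```r
library(corrlink)
tab <- joint_count_table(matrix(c(41,   4,  0,
                                   0, 100,  3,
                                   0,   2, 41), 3, 3, byrow = TRUE))
estimate_pcorr(tab)
#> theta = 0.02557 (se = 0.00363), method = pcorr, n = 191
#>   r = 0.94886
estimate_em_codominant(tab)
#> theta = 0.02387 (se = 0.00792), method = em_codominant, n = 191
#>   EM iterations = 8 (converged)
estimate_em_dominant(collapse_to_phenotypes(tab))
#> theta = 0.02192 (se = 0.01093), method = em_dominant, n = 191
#>   pi = 0.95663
#>   EM iterations = 7 (converged)
```

The three estimates agree closely; the correlation method needs no
iteration, and the dominance model (which discards genotype detail) pays
with the largest standard error. Check segregation before trusting the
correlation method:

```r
segregation_chisq(rowSums(unclass(tab)), t = 2)
#> segregation chi-square: X2 = 1.2199, df = 2, p = 0.5434
```

A small simulate-and-map round trip, and the mate-allocation combinatorics:

```r
map <- marker_map(paste0("m", 1:3), "1", 1:3, position_cm = c(0, 10, 20))
g <- simulate_ft_genome(map, t = 2, n = 100, seed = 3)
write_linkage_map(assemble_map(estimate_adjacent(g, map, "em_codominant")), "map.tsv")
#> chromosome  marker  theta_to_next  se_theta      cm_to_next   cm_cumulative
#> 1           m1      0.08354389136  0.02053098689 9.141351189  0
#> 1           m2      0.1444189875   0.0269319354  17.0427496   9.141351189
#> 1           m3                                                26.18410079

count_mating_schemes(9, 3)   # 9 dams split over 3 sires
#> [1] 1680
```

The 10 cM spacing corresponds to θ = 0.0906; with n = 100 the interval
estimates scatter around that value and the cumulative map length is near
the simulated 20 cM.

A command-line front end wraps these functions
(`inst/cli/corrlink.R pair|estimate|map|simulate-ft|sim-study`); logs go to
stderr, results to TSV.

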