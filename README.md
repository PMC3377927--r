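# epiqtl

Interval mapping of **pairs of interacting, multiallelic QTL** in a
full-sib family from a cross of two outbred, heterozygous parents — the
standard mapping design for forest trees and other outcrossing species
that cannot be inbred.

At a fully informative locus the offspring inherits allele *u* ∈ {1, 2}
from parent P1 and *v* ∈ {3, 4} from parent P2, so each QTL segregates
four genotypes (`13, 14, 23, 24`) and a pair of QTL segregates sixteen.
`epiqtl` decomposes the sixteen genotypic values **u** into sixteen
genetic effects

> **a** = (μ, α₁, β₁, γ₁, α₂, β₂, γ₂, I<sub>αα</sub>, I<sub>αβ</sub>,
> I<sub>βα</sub>, I<sub>ββ</sub>, J<sub>αγ</sub>, J<sub>βγ</sub>,
> K<sub>γα</sub>, K<sub>γβ</sub>, L<sub>γγ</sub>)ᵀ

via an orthogonal ±1 design matrix (**u** = **D a**, **a** = **D**ᵀ**u**/16):
per-parent additive effects (α for P1's allele substitution, β for P2's),
per-locus dominance (γ), and a nine-component epistatic block that splits
additive×additive interaction by parental origin (four *I* terms),
additive×dominance (two *J*), dominance×additive (two *K*) and
dominance×dominance (one *L*).

Because QTL genotypes are unobserved, the phenotype model at fixed
positions is a 16-component normal mixture whose weights ω are the
conditional QTL-genotype probabilities given the flanking markers (Haldane
map, Markov gamete model).  The package provides:

* exact EM fitting of the mixture (closed-form E and M steps, compiled
  core, deterministic initialisation), unconstrained or under any
  single-effect null constraint solved exactly by a Lagrange multiplier;
* two-dimensional likelihood-ratio scans over position-pair grids, with
  Churchill–Doerge-style permutation thresholds;
* likelihood-ratio tests of all fifteen genetic effects, with
  parametric-bootstrap critical values;
* a full-sib family simulator (the built-in design: one 100 cM group,
  six equidistant markers, QTL at 30 and 70 cM, heritability-scaled
  residual noise) plus a replicated parameter-recovery study driver;
* tidyverse-style interfaces throughout: tibbles in and out, `tidy()` /
  `glance()` methods, `autoplot()` for LR surfaces, TSV file formats and
  an `exec/epiqtl` command-line tool
  (`simulate` / `scan` / `permute` / `effects`).

## Worked example

Simulate a family of 800 offspring with two epistatic QTL at 30 and
70 cM (heritability 0.4, all fifteen effects nonzero), then scan for the
pair:

```r
library(epiqtl)

fam <- simulate_family(sim_preset(n = 800, h2 = 0.4, seed = 1))
sc  <- scan_qtl_pair(fam, "G1", step = 2)
sc
#> <fs_scan> 1040 position pairs (step 2 cM)
#>   max LR = 223.282 at G1:32 x G1:70 cM
```

The scan evaluates the EM fit at 1040 position pairs and finds the LR
maximum at 32 and 70 cM — within one grid step and one marker interval of
the planted 30/70.  Is the peak significant?  Compare it against a
permutation threshold:

```r
permutation_threshold(fam, "G1", n_perm = 100, alpha = 0.05,
                      step = 10, seed = 1)
#> <fs_perm> 100 permutations, alpha = 0.05, threshold = 42.638
```

LR = 223.3 far exceeds the 5% critical value of 42.6: a clear QTL pair.
The fitted genotypic values at the peak convert to effect estimates:

```r
tidy(sc$best_fit)
#> # A tibble: 16 x 2
#>    effect  value
#>  1 mu     50.8        # true 50
#>  2 alpha1  1.01       # true  2
#>  3 beta1   1.98       # true  3
#>  4 gamma1  2.96       # true  4
#>  ...
#> 13 J_bg   -5.69       # true -4.5
#> 16 L_gg   -4.37       # true -5
```

and each effect gets its own constrained-likelihood test:

```r
tests <- effect_tests(fam, "G1", 32, "G1", 70, full = sc$best_fit)
dplyr::arrange(tests, dplyr::desc(lr))
#> # A tibble: 15 x 4
#>   effect estimate loglik_constrained    lr
#> 1 J_bg      -5.69             -3372.  29.7
#> 2 K_gb       4.20             -3366.  18.9
#> 3 L_gg      -4.37             -3365.  17.1
#> ...
```

The strongest signals are the additive×dominance and dominance-involving
epistatic terms — exactly the components a biallelic model cannot even
express.  Single-replicate estimates at n = 800 carry sampling noise of
roughly ±1 trait unit per effect; the replicated study below shows the
estimators are unbiased.

The same pipeline runs from the shell:

```sh
exec/epiqtl simulate --n 800 --h2 0.4 --seed 1 --out data/
exec/epiqtl scan --map data/map.tsv --geno data/geno.tsv \
    --pheno data/pheno.tsv --groups G1 --step 2 --out results.tsv
exec/epiqtl permute --map data/map.tsv --geno data/geno.tsv \
    --pheno data/pheno.tsv --groups G1 --n-perm 1000 --seed 1 \
    --results results.tsv
```

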