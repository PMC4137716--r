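# kcm — Kronecker-product mechanistic codon models

`kcm` is an R package for fitting and simulating mechanistic codon
substitution models in which the 61 × 61 generator over sense codons is
built from three per-position 4 × 4 nucleotide exchangeability matrices via
a Kronecker product.  It is aimed at molecular evolution researchers who
want to ask, on protein-coding alignments with a fixed tree:

* do instantaneous **double and triple nucleotide substitutions** within a
  codon improve the fit over classical single-hit models (M0)?
* does **rate variation among the three codon positions** matter?
* what happens to the **selection estimate ω = dN/dS** when those two
  features are allowed?

## The model

Each codon position *i* carries a symmetric nucleotide matrix *qᵢ* with
unit diagonal and six free rates.  The codon generator is

&nbsp;&nbsp;&nbsp;&nbsp;Q = (q₁ ⊗ q₂ ⊗ q₃) Π, restricted to sense codons,

with Π the diagonal matrix of codon frequencies; nonsynonymous entries are
multiplied by ω, multi-hit entries by a switch α ∈ {0, 1}; the diagonal is
fixed to make rows sum to zero, and the matrix is scaled to one expected
substitution per codon per unit branch length.  Because each *qᵢ* has ones
on the diagonal, a single-nucleotide change costs one rate, a double change
the product of two, a triple the product of three — so the full 61 × 61 rate
structure (1,830 exchangeabilities in a general symmetric model) is
expressed with at most 18 rates plus ω.  Model variants: `KCM19x` (three
distinct matrices, multi-hits on, k = 19), `KCM7x` (one shared matrix,
k = 7), their single-hit restrictions `KCM19xM0`/`KCM7xM0` (α = 0), the
neutral variant `KCM19x_neutral` (ω ≡ 1, k = 18), and the `M0` baseline
(κ, ω; k = 2).  Models are compared with small-sample AICc; a flux-based
corrected ω accounts for positional heterogeneity and multi-hit events.

## Worked example

Simulate one 15-taxon, 150-codon alignment under a generator whose
double/triple substitution rates carry ~11% of the substitution flux
("scheme B"), then compare the single-hit baseline with two multi-hit
variants:

```r
library(kcm)

tree   <- random_tree(15, seed = 42)
Q_true <- build_scheme_matrix("B", omega_factor = 1, seed = 42)
multi_hit_fraction(Q_true)
#> [1] 0.11

aln <- simulate_alignment(tree, Q_true, n_codons = 150, seed = 42)
cmp <- compare_models(aln, tree, c("M0", "KCM7x", "KCM19x"),
                      n_starts = 1, seed = 1)
cmp$table
#>    model   lnL  k  AICc omega delta_AICc_vs_first
#> 1     M0 -6564  2 13132 1.131                0.00
#> 2  KCM7x -6528  7 13070 1.172               61.28
#> 3 KCM19x -6516 19 13075 1.226               56.24
```

Both multi-hit models beat M0 by ~56–61 AICc units on data that truly
contain multi-hit events, even after paying for 5 and 17 extra parameters;
the tied `KCM7x` wins here because the generating positions are homogeneous.
The corrected selection estimate divides the fitted nonsynonymous/synonymous
flux ratio by its value under a neutral reference (ω = 1, positional
matrices averaged):

```r
corrected_omega(cmp$fits$KCM19x)
#> fluxes per codon: synonymous 0.20412, nonsynonymous 0.79588
#> neutral reference: synonymous 0.23510, nonsynonymous 0.76490
#> omega: raw 1.2264, corrected 1.1984
```

Alignments are read with `read_codon_alignment()` (FASTA or PHYLIP, stop
codons rejected with coordinates), trees with `read_tree()` (Newick, via
ape).  A command-line front end covering fit / compare / simulate /
replicate-study / correct-omega / gtr-by-position lives at
`inst/cli/kcm.R`, e.g.

```sh
Rscript inst/cli/kcm.R simulate --scheme C --factor 2.0 --taxa 15 --codons 150 --seed 7 --out-prefix rep1
Rscript inst/cli/kcm.R fit --aln rep1.fasta --tree rep1.nwk --model KCM19x --seed 1 --out fit.json
```

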