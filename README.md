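# MatrixPalette

Color schemes for multiple-sequence-alignment visualization are usually
drawn by hand, grouping amino acids by chemical intuition (hydrophobic =
one hue, charged = another). MatrixPalette instead derives the scheme from
the same object the alignment itself is built on: the substitution matrix.
Each symbol of the alphabet is assigned a point in CIE L\*a\*b\* color
space such that pairwise *perceptual* color differences are proportional
to pairwise *evolutionary* distances — similar symbols get similar colors,
dissimilar symbols get distant colors. Because the method only needs a
substitution matrix, it works equally for amino acids (BLOSUM62, PAM250),
for structural alphabets such as protein blocks, and for schemes
constrained to color-vision-deficiency-safe regions of color space.

It is intended for bioinformaticians who build alignment figures and want
a reproducible, matrix-consistent palette, exported as a JSON map from
symbol to sRGB hex color.

## Method

From a substitution matrix *M* over *N* symbols, a strictly
lower-triangular distance matrix is built as

    D'_ij = ((M_ii − M_ij) + (M_jj − M_ji)) / 2,   j < i
    D     = D' / ⟨D'⟩

so that the mean distance over the n = N(N−1)/2 pairs is exactly 1. A
*color conformation* assigns one L\*a\*b\* point per symbol; its pairwise
CIEDE2000 differences form the matrix *C*, related to *D* through the
dynamic scale factor f_s = n / ΣC. The total score

    S_T = S_H + S_C,   S_H = Σ (f_s C_ij − D_ij)²,   S_C = f_c / ⟨C⟩

combines a harmonic (spring) term whose equilibrium lengths are the target
distances with a reciprocal contrast term that rewards spread-out schemes
(weight f_c, default 500). S_T is minimized over a user-constrained,
sRGB-displayable region of L\*a\*b\* space by an ensemble of independent
simulated-annealing instances that anneal both the inverse temperature
β(t) = β₀ e^{t/τ} and the move half-width Δx(t) = Δx₀ e^{−t/τ_x}. The
ensemble optimum (minimum best-so-far score) becomes the scheme; a
random-sampling baseline and the diagnostic

    Z(t) = −(⟨S_T⟩_SA(t) − μ(t)) / σ(t)

quantify how many baseline standard deviations the optimizer beats pure
uniform sampling of the same subspace.

## Worked example

```r
library(MatrixPalette)

res <- generateScheme("BLOSUM62", colorSubspace(60, 75),
                      annealingConfig(), seed = 1L)
bestScore(res$ensemble)
#> [1] 24.16207
head(schemeColors(res$scheme))
#>         A         R         N         D         C         Q
#> "#8d919f" "#409cb1" "#4f9f80" "#0cccb6" "#fe20f7" "#69c5d5"
```

The ensemble best score of about 24.2 decomposes (via
`totalScore(bestConformation(res$ensemble), distanceMatrix(readSubstitutionMatrix("BLOSUM62")))`)
into a harmonic residual of ~7.8 — the remaining mismatch between scaled
color differences and matrix distances, summed over 190 pairs — and a
contrast score of ~16.4, i.e. a mean pairwise CIEDE2000 difference of
~31: a widely spread scheme. Hues are meaningful only relative to each
other; lightness was confined to 60 ≤ L\* ≤ 75 so dark symbol glyphs stay
legible on every background color.

The same pipeline is available from the shell:

```sh
exec/matrix-palette --matrix BLOSUM62 --lmin 60 --lmax 75 --seed 1 \
    --out scheme.json --trace diagnostics.tsv
# red-green CVD-friendly scheme: drop the green half-plane
exec/matrix-palette --amin 0 --lmin 50 --lmax 80 --seed 1 --out cvd.json
```

Identical flags and seed give byte-identical JSON. The optional TSV trace
records the ensemble mean/std, the running best score, the
random-sampling baseline and Z(t) on a logarithmic step stride.

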