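# miRKinet

Kinetic modeling and single-cell inference of miRNA target repression
parameters.

## The problem

A miRNA loaded into Argonaute (Ago) represses hundreds of mRNA targets at
once, and the targets compete for the same limited pool of Ago–miRNA
complexes. How strongly an individual target responds to rising miRNA
levels depends on its own kinetics — transcription rate α, free-mRNA decay
rate δ, binding rate k_on, dissociation rate k_off, and the decay rate
k_cat of the miRNA-bound form — and on everyone else's, because the
competitors set how much free Ago–miRNA (A_F) is left. miRKinet is for
quantitative/systems biologists who want to (i) simulate such competing
target networks deterministically or stochastically, (ii) infer per-target
interaction constants from noisy single-cell expression data spanning a
wide miRNA-induction range, and (iii) reason about competing-RNA (ceRNA)
crosstalk.

## The model and the inference

Each target's steady-state total level is

    T* = T0 / (1 + f (T0/T∞ − 1)),   f = A_F / (A_F + K_M),

with T0 = α/δ (no miRNA), T∞ = α/k_cat (saturating miRNA), and
K_M = (k_off + k_cat)/k_on. Solving T* = (T0+T∞)/2 gives the target's
critical free-Ago concentration A_F^C = K_M·T∞/T0 — the sensitivity
parameter of its dose–response.

Given a cells × targets expression matrix with a per-cell miRNA proxy, the
transform (T0/T∞ − 1)/(T0/T − 1) − 1 applied to smoothed, margin-bounded
levels equals K_M^i / A_F^j — a positive rank-1 matrix. Its leading
singular triplet yields per-cell free-Ago levels and per-target K_M (up to
one global scale factor), an averaging step refines K_M using the more
precisely estimated A_F, and A_F^C follows per target. The package also
ships the in-silico benchmark generator used to validate all of this
(300 targets, 4,000 virtual cells, calibrated log-normal measurement
noise), sliding-window single-cell statistics (C_V and pairwise-correlation
curves against a background panel), CPM/pseudocount preprocessing for UMI
count matrices, and deterministic ceRNA titration scenarios.

## A worked example

```r
library(miRKinet)

# a small synthetic benchmark: 40 targets, 600 cells, moderate noise
spec <- benchmark_spec(M = 40, N = 600, noise_sd = 0.4, seed = 7)
bm <- generate_benchmark(spec)
bm$matrix
#> <ExpressionMatrix> 600 cells x 40 genes; proxy range [1.17e-12, 1.54e+04]

res <- run_inference(bm$matrix, inference_config(n_low = 240, n_high = 30))
res
#> <InferenceResult> 67 cells, 40 targets; rank-1 residual 0.0322; scale unidentified (1)

head(res$targets, 3)
#>   target        T0     Tinf   K_M_svd       K_M     A_F_C
#> 1     t1  46.53972 19.87024 0.9960448 0.9787312 0.4178715
#> 2     t2 124.75563 56.46762 0.7715019 0.7506644 0.3397701
#> 3     t3 289.12874 67.69831 1.6402450 1.5993633 0.3744843

cor(log(bm$truth$A_F_C[match(res$targets$target, bm$truth$target)]),
    log(res$targets$A_F_C))
#> [1] 0.7102646
```

`res$targets` holds, per retained target, the estimated no-miRNA and
saturating levels (T0, T∞), the raw SVD and refined Michaelis–Menten
constants (`K_M_svd`, `K_M`; both carry the unidentified global scale) and
the critical free-Ago concentration `A_F_C`; `res$cells` holds the
per-cell free-Ago estimates over the responsive cell interval. The final
correlation compares inferred and true sensitivities on the log scale —
the benchmark's headline recovery metric.

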