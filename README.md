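# dbpmkl — DNA-binding protein prediction with multiple kernel learning

Determining whether a protein binds DNA from its sequence alone is a
standard binary classification problem in protein function annotation:
wet-lab assays (ChIP, EMSA, X-ray) are slow and expensive, and most
sequences have no solved structure. `dbpmkl` implements a
sequence-based predictor for computational biologists who have protein
FASTA files (and, ideally, PSI-BLAST PSSM profiles) and want calibrated
cross-validated predictions plus insight into *which* sequence
representation carries the signal.

## The method

Six descriptors are computed per protein:

| descriptor | input | dimension |
|---|---|---|
| GE (global encoding) | sequence | 315 |
| MCD (multi-scale composition/transition/distribution) | sequence | 882 |
| NMBAC (normalized Moreau–Broto autocorrelation) | sequence | 180 |
| PSSM-AB (average blocks) | PSSM | 400 |
| PSSM-DWT (wavelet statistics) | PSSM | 320 |
| PsePSSM (pseudo-PSSM) | PSSM | 220 |

Each feature matrix is min–max scaled and turned into an RBF Gram matrix
`K_i(x, x') = exp(-γ_i ||x - x'||²)`. The six kernels are fused into
`K* = Σ_i β_i K_i` with weights `β` on the probability simplex chosen by
centered kernel alignment: with `U = I - (1/N)11'` the centering
projection, `a_i = ⟨U K_i U, y y'⟩_F` and `M_ef = ⟨U K_e U, U K_f U⟩_F`,
the weights solve the convex quadratic program

```
min_β  β'(M + λL)β − 2 β'a      s.t.  β ≥ 0,  Σβ = 1
```

where `L = D − W` is the graph Laplacian of the kernel–kernel cosine
similarities `W`, and `λ` (default 0.8) smooths the weights toward
uniform so that no single kernel dominates on noise. The combined kernel
feeds a precomputed-kernel C-SVM (`C = 2` by default), and performance
is reported as ACC / SN / SP / MCC / AUC under stratified k-fold,
leave-one-out, or independent-test evaluation — with scalers, kernel
weights, and the SVM all re-fit inside every training fold.

## Worked example

No external data is needed: the package ships a synthetic benchmark
generator that emulates the curated datasets (sequences ≥ 50 residues
over the 20 canonical amino acids, paired PSSM profiles, balanced
labels, class signal controlled by one knob).

```r
library(dbpmkl)

d <- make_fixture_dataset(n_pos = 60, n_neg = 60,
                          length_range = c(60, 120),
                          signal_strength = 0.8, seed = 1)
rep_cka <- kfold_cv(d, dbp_config(strategy = "cka"), k = 5)
rep_cka
#> <dbp_eval> fixture_s0.80_seed1 5-fold CV (strategy: cka)
#>  ACC SN SP MCC AUC
#>    1  1  1   1   1

model <- dbp_train(d, dbp_config())
tidy(model)        # kernel weights: which representation carries signal
autoplot(rep_cka)  # ROC curve
```

At `signal_strength = 0.8` the planted class signal is strong and the
pipeline recovers it perfectly (all five metrics 1.0 above); at
`signal_strength = 0` the same pipeline stays at chance (5-fold ACC
0.50 on the null fixture), which is the honest sanity check that no
information leaks from test folds into training.

The command-line front end wires the same steps together
(`inst/cli/dbpmkl.R`):

```sh
Rscript inst/cli/dbpmkl.R fixtures --out data --n-pos 30 --n-neg 30 --signal 0.8 --seed 1
Rscript inst/cli/dbpmkl.R cv --data data --out report.json --kfold 5
Rscript inst/cli/dbpmkl.R train --data data --model model.json
Rscript inst/cli/dbpmkl.R predict --model model.json --data data --out pred.tsv
```

Real data: point `extract`/`train`/`cv` at a FASTA file, a directory of
PSI-BLAST ASCII PSSMs (`-out_ascii_pssm`, one `<id>.pssm` per record),
and a two-column `labels.tsv` (+1 = DNA-binding). `--sequence-only`
restricts to the three profile-free descriptors when no PSSMs are
available.

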