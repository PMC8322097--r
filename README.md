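# scampi

Statistical classification analysis of membrane-protein images: pixel-based
discrimination of grayscale fluorescence microscopy images (e.g. TIRF frames
of T cell receptors on differently coated surfaces) from small samples, with
no feature engineering and no training of a deep model.

The package is aimed at microscopists and image analysts who have on the
order of 100 single-channel images per condition and want a fast,
interpretable classifier with per-image class-membership probabilities.

## The model

Each image `v` (an `m x n` intensity matrix) is modelled as a spatial-lag
regression of every interior pixel on its immediate causal neighbours:

```
v[i,j] = b01 * v[i,j-1] + b10 * v[i-1,j] + b11 * v[i-1,j-1] + e[i,j]
```

a digital analogue of a stationary advection/diffusion PDE. The
coefficients are estimated by no-intercept OLS over the fully interior
region (a 280x280 image gives N = 279 x 279 = 77,841 samples for 3
parameters), with a White (HC0) heteroskedasticity-robust covariance for
the Student-t significance tests, and the lag order is grown only while
every coefficient stays significant — in practice one lag suffices.

The per-image coefficient vectors are then classified:

* **FLD** — a two-class Fisher linear discriminant `v_c ~ Sw^-1 (mB - mA)`
  projects each image to a scalar; the midpoint of the class projection
  means is the decision threshold.
* **LR** — a binary logistic regression on the projections turns each test
  image's projection into a probability of belonging to class B.

Baseline statistics (threshold spreading area, lognormal fits of
above-background signal, KS normality of the coefficient columns, a
Kullback minimum-discrimination-information comparison of projection sets)
and a seeded synthetic-image simulator are included, so the whole pipeline
is testable without any microscopy data.

## Worked example

Two synthetic classes built from the one-lag recursion, with per-image
coefficients drawn around the class means of the stimulated (OKT3) and
immobilized (PLL) conditions so that cell-to-cell variability is present;
unstable draws are screened out by `lag_recursion_stable()`:

```r
library(scampi)

make_class <- function(center, sd, label, n = 100, master_seed = 1) {
  set.seed(master_seed)
  betas <- matrix(rnorm(n * 3, rep(center, each = n), rep(sd, each = n)), n)
  betas <- betas[apply(betas, 1, lag_recursion_stable), , drop = FALSE]
  imgs <- lapply(seq_len(nrow(betas)), function(r) {
    simulate_lag_image(lag_sim_spec(shape = c(128, 128), beta = betas[r, ],
                                    seed = master_seed * 1000 + r))
  })
  names(imgs) <- sprintf("%s_%03d", label, seq_along(imgs))
  imgs
}
okt3 <- make_class(c(0.6443, 0.6674, -0.3438), c(0.0314, 0.0316, 0.0541),
                   "OKT3", master_seed = 1)
pll  <- make_class(c(0.5671, 0.5943, -0.1992), c(0.0612, 0.0613, 0.1043),
                   "PLL", master_seed = 2)
n <- min(length(okt3), length(pll))
report <- run_pipeline(run_config(okt3[1:n], pll[1:n], "OKT3", "PLL",
                                  train_count = round(0.8 * n), seed = 3,
                                  max_lag = 1))
report
report$fld
report$classification$confusion
head(report$probabilities, 4)
```

prints

```
<run_report> OKT3 vs PLL: 104 images
test accuracy 0.950 (training 0.929)
<fld_model> OKT3 vs PLL
v_c:  -0.7604 -0.6478 0.0456
projection means -0.9299 / -0.7909, threshold -0.8604
training accuracy 0.929
      predicted
truth  OKT3 PLL
  OKT3   10   0
  PLL     1   9
      file label projection  probability
1 OKT3_007  OKT3 -0.9438421 1.036557e-08
2 OKT3_013  OKT3 -0.9392297 4.940656e-08
3 OKT3_014  OKT3 -0.9049487 5.395605e-03
4 OKT3_024  OKT3 -0.9067003 2.989077e-03
```

Reading: of the 104 images (52 per class after stability screening), 80%
train the discriminant and the remaining 10 + 10 are tested; 19 of 20 are
classified correctly. The projection direction `v_c` weights the
horizontal and vertical lag coefficients most; the logistic probabilities
are the probability of the OKT3-like class, near 0 for confident PLL-like
projections and near 1 for confident OKT3-like ones. The accuracy of a
single split varies split to split — on real data expect figures in the
80–90% range, not a fixed number.

## Command line

```sh
scampi=$(Rscript -e 'cat(system.file("cli", "scampi", package = "scampi"))')
Rscript $scampi simulate --spec spec.json --n 100 --out imgs/ --seed 1
Rscript $scampi fit-models --input imgs/ --out fits/
Rscript $scampi discriminate --class-a pll/ --class-b okt3/ --train 80 --seed 1 --out run/
Rscript $scampi probabilities --run run/
Rscript $scampi baselines --input imgs/ --out base.csv --spread-threshold 200
```

Input images are single-channel TIFF (8/16-bit unsigned or 32-bit float,
uncompressed), ASCII PGM or headerless CSV; reports are CSV/JSON with
floats fixed to 12 significant digits so identical runs are byte-identical.

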