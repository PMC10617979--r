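# ledmesh — local eigenprojection disentanglement for generative mesh models

`ledmesh` trains generative models of fixed-topology anatomical surface
meshes — variational autoencoders and two GAN flavours built from spiral
convolutions and quadric mesh sampling — whose latent variables are
*disentangled by construction across anatomical regions*. It is aimed at
researchers in statistical shape modelling and geometric morphometrics who
work with corresponded mesh populations (heads, bodies, organs) and want a
latent code in which one block of variables controls one labelled region.

## The idea

All meshes share one topology and a per-vertex segmentation into `F`
attributes (nose, jaw, ... — here: template sectors). Each shape `X` is
summarized per vertex by a **signed distance** from the training mean `M`:

    sd_i(X) = sign(⟨X_i − M_i, n_i⟩) · ‖X_i − M_i‖,

with `n_i` the frozen vertex normals of the mean mesh. For each attribute
`ω`, the Kirchhoff graph Laplacian `K_ω = D_ω − A_ω` of its subgraph is
eigendecomposed once; the `κ` graph Fourier modes `U*_ω` with the
highest-variance projections of the training signed distances, with their
training mean `m*_ω` and spread `s*_ω`, define a standardized local
spectral descriptor. The **local eigenprojection (LE) loss** ties latent
block `z_ω` to it:

    L_LE(X, z) = (1 / Fκ) Σ_ω ‖ z_ω − ((U*_ω)ᵀ sd(X_ω) − m*_ω) / s*_ω ‖₁

The LED-VAE objective adds two gradient-routed LE terms to the usual
reconstruction + Tutte-Laplacian smoothness + KL losses,

    L = L_R + α L_L + β L_KL + η₁ L_LE(X, μ) + η₂ L_LE(X′, μ),

where the `η₁` term updates only the encoder and the `η₂` term only the
generator; LED-LSGAN and LED-WGAN add `η L_LE(X′, z)` to their generator
objectives. Because the eigenvectors are orthogonal and attribute-local,
latent blocks inherit orthogonality and locality. With all LE weights at 0
the models reduce exactly to their vanilla counterparts.

Since the usual head/body datasets are license-restricted, the package
ships a synthetic population generator (icosphere template, per-attribute
Laplacian-eigenvector deformation fields with Gaussian coefficients) whose
local projections are Gaussian by construction, plus a bimodal variant for
normality diagnostics. Ground-truth factors are returned for recovery
tests. Everything — networks, hand-derived gradients, quadric sampling,
metrics — is implemented in the package and verified against closed forms
and brute-force oracles in the test suite.

## Worked example

```r
library(ledmesh)

spec  <- synthetic_spec()                       # N = 642, 4 attributes
pop   <- sample_population(spec, 889, seed = 7) # 800 train / 44 val / 45 test
stats <- compute_template_stats(pop)
basis <- fit_spectral_basis(pop, stats, kappa = 3)

led <- fit_generative_model(pop, stats, train_config("vae", seed = 5),
                            basis = basis,
                            arch = network_arch(latent_dim = 12))
van <- fit_generative_model(pop, stats,
                            train_config("vae", eta1 = 0, eta2 = 0, seed = 5),
                            arch = network_arch(latent_dim = 12))

lab <- pop$topology$attribute_labels
loc <- function(m) disentanglement_localization_score(
  traversal_distance_map(m, stats, lab), kappa = 3)
cat("LED median loc:", round(median(loc(led)), 2),
    " VAN:", round(median(loc(van)), 2), "\n")
cat("VP LED:", round(vp_metric(led, seed = 11), 1),
    " VP VAN:", round(vp_metric(van, seed = 11), 1),
    " chance:", round(100 / 12, 1), "\n")
```

On one CPU this trains both models in a few minutes and prints (output of
an actual run):

```
LED median loc: 7.46  VAN: 0.91
VP LED: 75.7  VP VAN: 59.9  chance: 8.3
```

The localization score of a latent dimension is the mean traversal-induced
vertex displacement inside its designated attribute divided by the largest
mean displacement in any other attribute — 7.5 means traversing a latent
moves its own region ~7× more than any other region, while the vanilla
VAE's latents are unlocalized (~1). The VP score is the accuracy of a
few-shot classifier predicting which single latent dimension differs
between two generated shapes; both models beat chance, and the LED model is
clearly higher.

Editing a trained model:

```r
z2 <- attribute_resample(numeric(12), omega = 2, kappa = 3, seed = 1)
ed <- direct_manipulate(led, stats, lab, z0 = numeric(12),
                        S = which(lab == 2)[1:3],
                        Y = matrix(...),       # 3 x 3 target positions
                        kappa = 3)
```

`direct_manipulate()` optimizes only the latent block of the touched
attribute (adam, 50 iterations, lr 0.1); the other blocks are returned
bit-identical.

A thin command-line front end over the same pipeline lives at
`inst/cli/ledmesh.R` (`synth`, `fit-basis`, `train`, `sample`, `evaluate`,
`edit`, `run-all`, driven by a YAML config).

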