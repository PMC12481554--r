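---
title: "Augmenting scarce LFIA image data with an attention Wasserstein GAN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Augmenting scarce LFIA image data with an attention Wasserstein GAN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Lateral flow immunoassay (LFIA) strips report an analyte through two
colored bands on a nitrocellulose membrane: a *control line* that must
always develop (flow validity) and a *test line* whose darkness grows with
analyte concentration. Convolutional classifiers can grade strip
photographs into concentration classes (blank / low / high), but training
them normally requires thousands of labelled photos — unavailable for
novel biomarkers or emerging pathogens. `stripgan` implements the
data-scarcity workaround this package is built around: synthesize
additional strip images with a Wasserstein GAN carrying a direct spatial
self-attention block, quality-filter the synthetic images, mix them with
real data, and train/evaluate the classifier on the mixture.

Because no public strip-photo collection accompanies this workflow, the
package ships a procedural simulator that plays the role of the camera:
every stage of the pipeline is exercised end to end against simulated
strips with known ground truth.

## The simulator and what it does (and does not) emulate

`renderStrip()` draws a bright membrane (intensity 0.85), darkens the
control band (at 30% of the strip height) and the test band (at 60%) by
their multiplicative contrasts, applies a multiplicative linear lighting
ramp oriented at a configurable angle (default amplitude ±15%), adds
i.i.d. Gaussian sensor noise, and clips to `[0, 1]`. Band thickness is 4%
of the height. `sampleStripSet()` draws class-balanced datasets: the low
class mixes 0.25 and 0.5 µg/mL, the high class 0.75 and 1 µg/mL, and the
test-line contrast rises linearly in concentration
(mean `0.15 + 0.5·c`, sd 0.03) so that the empirical band darkness is
strictly monotone across the five levels. The default render size,
3×660×50, matches the standardized resolution of the preprocessing chain;
the test suite works on 16×16 down-scaled "minis" (`miniStripSet()`) for
speed.

The simulator is deliberately minimal: it captures the *statistical
structure* that matters to the downstream models (monotone band contrast,
a constitutive control line, nuisance illumination, sensor noise) but not
membrane texture, optics, perspective, or glare. Consequently a passing
test suite demonstrates that the pipeline mechanics are correct and that
the GAN can recover a simple image family — it does not certify accuracy
numbers on real phone photographs, which depend on a data distribution
this package cannot reproduce. The lighting model in particular is a
stand-in chosen for simplicity (a linear ramp), not a claim about any
specific capture rig.

## Preprocessing chain

`cropToEdges()` segments the strip as the luminance-above-threshold
foreground, crops the tight bounding box and resizes bilinearly to
660×50. `padToSquare()` zero-pads symmetrically to 660×660 (305 columns a
side), conserving pixel mass exactly. `cropLines()` crops a window
spanning the two line rows — given explicitly or found by
`detectLineRows()` — extended by 20% of the inter-line distance on each
side, and resizes to 128×128. Automatic detection takes the two deepest
local minima of the row-mean luminance profile after a moving-average
smooth whose window equals the nominal band thickness (4% of the height);
that window choice turns each flat dark band into a valley peaked at the
band centre, which is what makes detection land within a few pixels of
the true centres. A blank strip (control line only) has a single valley
and raises a `lineDetectionFailure` carrying the profile for inspection.

`augmentRotations()` produces `round(360/step)` rotations (default step
3.6°, i.e. 100 per input; 3,000 inputs become 300,000 images). Rotation
is about the image centre with bilinear interpolation and zero fill;
cosines within 1e-12 of 0/±1 are snapped so that multiples of 90° are
exact pixel permutations and angle 0 is the bit-exact identity. The chain
rotates the final 128×128 crop rather than the raw photo — a pipeline
decision recorded here and in the configuration, as the alternative order
is equally defensible. `rotationSweep()` shares one sparse warp matrix
per angle across a whole batch and can stream counts without
materializing the augmented set.

## Direct spatial self-attention

The attention block owns three 1×1 feature extractors `W_f`, `W_g`,
`W_v` (query/key/value) and a scalar residual weight γ initialized to
exactly 0. The classical self-attention of image GANs flattens the
feature map into an `N×N` position-by-position product; the direct
variant implemented here never reshapes or transposes the feature tensor.
Instead the query and key maps are contracted over channels into a single
score map, softmax-normalized over all positions (with max-subtraction
for stability):

  s[h,w] = Σ_c f(x)[c,h,w]·g(x)[c,h,w],  M = softmax(s),
  o[c,h,w] = H·W · M[h,w] · v(x)[c,h,w],  y = γ·o + x.

The `H·W` factor keeps `o` on the scale of `v(x)` (a uniform map has
weight `1/(H·W)` everywhere). Because γ starts at 0 the block is a
bit-exact identity at construction and eases into the residual path as
training moves γ — the forward pass literally computes `0·o + x`, which
is exact in IEEE arithmetic for finite activations. A consequence of the
purely spatial formulation is exact equivariance: flipping or transposing
the input flips or transposes the map, which the test suite uses as the
structural check that no position-flattening happens anywhere in the
path. The price of the direct form is expressiveness — one shared spatial
map instead of one map per query position (the classical formulation);
the benefit is an interpretable `H×W` heat map (`attentionMap()`,
exportable via `writeAttentionMap()`) and no tensor reshuffling.

## The GAN

The generator maps a noise vector (default 128-dim, toy 32-dim) through a
dense projection to a full-resolution seed feature map, two stride-2
convolution encoder stages, the attention block at the deepest scale,
and two upsample+convolution decoder stages with skip connections from
the encoder (a U-Net layout; all convolutions zero-pad, keeping border
behaviour fixed), ending in a 3-channel convolution squashed by a
sigmoid. The critic mirrors the encoder and ends in a linear head — no
sigmoid, and no logarithm anywhere: the critic loss is
`mean(fake) − mean(real)`, the generator loss `−mean(fake)`. Training
alternates `criticSteps` critic updates (each followed by clipping every
critic weight to `[−c, c]`) with one generator update, under RMSProp.
Disabling the attention flag removes exactly the attention parameters
and yields the plain WGAN baseline used for comparison.

Unstated architectural details are package decisions, all exposed in
`ganConfig()`: encoder widths B, 2B, 4B from `baseChannels` with a slim
B-channel decoder (strip images need little decoder capacity, and the
decoder convolutions dominate the flop count), attention inserted at the
deepest scale of both networks, clip value 0.01, five critic steps per
generator step, RMSProp at 5e-5 (the canonical WGAN schedule). One generator is trained per class label, since quality
control and mixing need class-labelled synthetic images; a conditional
single-model variant would be the natural alternative but couples the
classes through shared weights.

Two numerical choices deserve note. First, the sigmoid output bias is
initialized to the logit of the training-set mean intensity, so early
training effort goes into band structure rather than global brightness.
Second, the *toy profile* (`toyGANConfig()`: 16×16 images, 16 base
channels, 200 generator steps, 2 critic steps, clip 0.05, learning rate
2e-4) deliberately departs from the canonical schedule: a 200-step run
at clip 0.01/lr 5e-5 moves the generator barely at all, so the toy
profile trades Lipschitz tightness for convergence within a desk-scale
budget. Training aborts with the partial loss history attached if any
loss goes non-finite.

A monitor of distribution recovery is recorded alongside the losses: the
exact empirical 1-Wasserstein distance (`wasserstein1d()`, sorted-sample
matching for equal sizes, quantile-function integral otherwise) between
the test-band-darkness marginals of a real sample and a freshly generated
sample. On the toy task this monitor falls from initialization to the end
of training in the majority of seeds — the property the test suite
asserts, rather than any absolute image-quality score.

## Quality control of generated images

`ssim()` is the canonical structural similarity index (11×11 Gaussian
window, σ = 1.5, C1 = 0.01², C2 = 0.03², valid windows, channel-averaged);
`ssim(x, x)` is exactly 1 because every term of the ratio is computed
symmetrically. `avgHash()` is the standard perceptual average hash
(grayscale, bilinear resize to √bits×√bits, threshold at the mean), and
`hammingDist()` counts differing bits. `filterGenerated()` makes a
deterministic greedy pass in input order, rejecting a candidate iff
against any already-accepted image `ssim > ssimMax` *or*
`hamming < hammingMin`. The thresholds are nowhere specified by the
workflow this reproduces, so the defaults (0.95 / 4 on a 64-bit hash) are
a conservative de-duplication choice, fully configurable. By default both
metrics are always consulted, so the accepted set provably contains no
violating pair (the test suite re-checks this exhaustively); an optional
hash prefilter skips SSIM when the Hamming distance is ≥ 2·hammingMin,
an O(n·k) speedup appropriate for large batches. The comparison set is
the accepted synthetic pool only — de-duplication targets redundant
synthesis, not resemblance to real data.

One calibration matters at toy scale: at 16×16, two *distinct real*
simulated strips routinely reach SSIM ≈ 0.99 and hash distance 0, so the
128-scale defaults would reject genuine diversity. The experiment
profile therefore uses `ssimMax = 0.995, hammingMin = 0` (reject only
near-exact duplicates) with the exact, non-prefiltered path — note that
with `hammingMin = 0` the prefilter would skip every SSIM computation,
which is why the profile disables it.

## Datasets, mixing, splits

`mixDatasets()` supports the two composition framings used in the
experiments: a ratio mode (fraction of real records, subsampling the
over-represented pool per class, seeded) and an absolute-count mode
(exact real/synthetic counts, as in 300 + 2,700 or 30 + 2,970
compositions). Records are never duplicated, per-class balance is
preserved, and provenance is retained. `holdoutSplit()` is a stratified,
seeded 80:20 hold-out (stratification is a package decision — it keeps
toy-scale class balance meaningful). `relabel()` maps between the
three-class, binary (blank→negative, rest→positive) and five-level
(concentration-valued) schemes; five-level requires concentration
metadata and therefore refuses GAN records, which only carry their class.

## Classifier and evaluation

The test-suite backbone is `tiny_cnn`: inputs centred by −0.5, three
stride-2 3×3 convolution blocks (8/16/32 channels), global average
pooling, and a linear softmax head. Input centring is a conditioning
choice: with raw `[0,1]` strip images (mean ≈ 0.8) convergence within a
few epochs was seed-dependent; centring removed that sensitivity. The
heavyweight backbone names (ResNet50, MobileNetV2, EfficientNet-B0) are
accepted by the model registry so configurations naming them parse, but
no builtin constructors ship — `registerClassifier()` lets a user plug
one in. Training follows the reference recipe by default (cross-entropy,
Adam at 1e-4, batch 32, 100 epochs, 128×128 inputs); the toy profile
(`toyTrainConfig()`) uses 16×16 inputs, 8 epochs and Adam at 5e-3, sized
so a 300-image training run takes seconds. The best-validation-accuracy
checkpoint (earliest epoch on ties) is retained; when the validation
split mixes provenances, checkpoints are ranked by accuracy on its
*real* records — the quantity the classifier is ultimately deployed on —
while the logged curves still report the full split.

Evaluation: `predictProba()` (softmax rows, normalized within 1e-6),
`confusionCounts()` (rows = truth), `classMetrics()` (one-vs-rest
SEN/SPE/PPV/NPV with zero-denominator ratios reported as `NA`, never 0),
`rocCurves()` (one-vs-rest threshold sweep, trapezoid AUC — verified in
the tests against an O(n²) concordance oracle and against pROC), and
`tsneEmbed()` (seeded Barnes–Hut t-SNE, an export-only diagnostic).

## The experiment grid

`runExperiment()` executes, for every cell of a declared grid
(composition × size): simulate → subsample the cell's real records →
train one GAN per class *on those records* → generate → QC-filter → mix →
80:20 split → train classifier → evaluate on one shared, freshly seeded
simulated test set. Every stage seed derives deterministically from the
configuration seed, trained GANs are memoized by (class, seed, training
record ids) so repeated cells are skipped, and a rerun of the same
configuration is byte-identical. Failed cells are reported per cell
without sinking the rest of the grid. Training the GANs on each cell's
own real subset is what makes the composition sweep informative: with 1%
real data the generators see three images and produce correspondingly
poor synthetic data, reproducing the qualitative ordering (50/50 mixed
well above 1%-real) without claiming the original absolute accuracies,
which depended on the unavailable photo set.

`augmentationOnlyBaseline()` builds the comparison arm that uses only
geometric augmentation (rotations + flips, no GAN) at the configured
size and reports a row with the identical schema.

Default problem sizes are toy by design — 16×16 strips, a 300-record
pool, 200-step GANs, ≤10-epoch classifiers — so the full grid completes
in minutes on one CPU; paper-scale sizes are configuration values, not
code constants. The acceptance checks run the grid at exactly these
defaults (200-step GANs) with 10-epoch classifiers over three seeds.

## Known limitations

* All conclusions from the test suite concern simulated strips; real
  phone photographs add texture, optics and color effects the simulator
  does not model.
* The GAN engine is plain R (im2col convolutions over BLAS); it is sized
  for 16–32 px toy images, not for 128×128 production training.
* Weight clipping (not gradient penalty) is the only Lipschitz device,
  matching the original WGAN recipe; WGAN-GP, spectral normalization and
  FID scoring are out of scope.
* The direct attention uses one shared spatial map; the classical
  N×N attention is available conceptually as the ablation point but not
  as a trainable option.
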