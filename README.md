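# seadapt

Semi-supervised domain adaptation for patch-based multispectral benthic
habitat classification.

## The problem

Mapping seagrass and neighbouring habitat classes (sea, sand, land,
intertidal) from 8-band satellite imagery works well where dense expert
labels exist, but a classifier trained at one site transfers poorly to
another: atmosphere, water column and substrate shift both the marginal
pixel distribution and the per-class spectral signatures. At a new site one
typically has abundant *unlabeled* pixels and at most a handful of labeled
ones per class.

`seadapt` implements a two-step adaptation of a convolutional patch
classifier \(f = C \circ G\) (predicting the class of a pixel from the
5×5×8 window centred on it) to such a target site:

1. **Adversarial marginal alignment.** A target embedding \(G_t\),
   initialised from the frozen source embedding \(G_s\), is trained against
   a domain discriminator \(D\) using only unlabeled pixels from both
   sites, aligning \(p(G_t(x^t))\) with \(p(G_s(x^s))\):
   discriminator loss
   \(-\mathbb E[\log D(G_s(x^s))] - \mathbb E[\log(1-D(G_t(x^t)))]\),
   generator loss \(-\mathbb E[\log D(G_t(x^t))]\).
2. **Few-shot contrastive semantic alignment.** With *n* labeled target
   samples per class, paired against 400 drawn source samples per class,
   both embeddings are jointly optimised under
   \(L = L_C + L_{SA} + L_{CS}\): cross-entropy on both domains' labeled
   samples, the semantic alignment term
   \(\tfrac12\lVert G_s(x^s_i)-G_t(x^t_j)\rVert\) over same-class
   cross-domain pairs, and the class separation penalty
   \(\tfrac12\max(0, m-\lVert G_s(x^s_i)-G_t(x^t_j)\rVert)^2\) over
   different-class pairs.

The package also provides the single-step baselines (source-only,
adversarial-only, fine-tuning, contrastive-only), raster/label-mask I/O,
a synthetic cross-site scene generator with known generative truth,
stratified k-fold cross-validation, scene-wide classification maps, t-SNE
embedding export, and radiometric calibration of imagery against in situ
optical stations.

## Worked example

Generate a synthetic source/target pair with a strong cross-site shift,
adapt with 5 labeled target pixels per class, and compare against the
un-adapted model (reduced epoch counts so the example runs in about two
minutes):

```r
library(seadapt)

regime <- benchmark_suite(seed = 1)$strong   # fixed-shift benchmark regime
pair   <- generate_scene_pair(regime)

cfg <- train_config(source_epochs = 10, adversarial_epochs = 30,
                    ccsa_epochs = 24, seed = 1)
fit <- run_two_step(pair$source$scene, pair$source$mask,
                    pair$target$scene, pair$target$mask,
                    shots = 5, config = cfg,
                    methods = c("source-only", "proposed"))
fit
```

```
Two-step semi-supervised domain adaptation fit
  classes: seagrass, sea, sand, land, intertidal
  shots per class: 5   seed: 1
  source training accuracy: 0.9999
  target-domain accuracy:
    source-only  0.8753
    proposed     0.9861
```

The source-trained model drops eleven accuracy points on the shifted site;
the adapted model recovers to within about one point of the within-site
ceiling while having seen only 25 labeled target pixels.
`predict(fit, scene)` then produces a full classification map
(`label_mask`), and `write_label_map()` renders it with the conventional
colormap (seagrass green, sea blue, sand cyan, land yellow, intertidal
magenta).

A command-line wrapper over the same functions is installed at
`inst/scripts/seadapt` (subcommands `synth`, `train-source`, `adapt`,
`evaluate`, `map`, `tsne`, `atmcorr`).

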