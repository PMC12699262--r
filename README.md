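# episcope

Epidermis-centric analysis of skin histology images in R.

Histological examination of skin biopsies concentrates its diagnostic
signal in a narrow strip of tissue: the epidermis and the
basement-membrane zone (BMZ), the junction where the epidermis meets the
dermis. `episcope` is a toolkit for whole-slide-image style analysis built
around that strip, for researchers comparing large sets of skin sections
(e.g. young vs aged, diseased vs healthy) who need the extraction,
quantification and classification steps to run without manual annotation.

The pipeline:

* **Stain normalization** — Macenko's method: stain vectors from the
  extreme angles of the optical-density point cloud's principal plane,
  concentrations rescaled to a reference.
* **Unsupervised epidermis segmentation** — Felzenszwalb superpixels guide
  an iteratively self-trained per-image CNN (conv → ReLU → norm blocks, 1×1
  conv + softmax); cluster selection, a diagonal-span filter that discards
  follicle/gland/vessel-dominated masks, and morphological
  (corrosion–expansion) cleanup yield a "level-1" epidermis-oriented image.
* **Hierarchical patch sampling** — 512×512 *level-2* patches along the
  epidermis mask, 128×128 *level-3* patches along the epidermis–dermis
  boundary (the BMZ), with a filter keeping patches that contain both
  tissues diagonally.
* **Morphometrics** — with EB/ES the epidermis–dermis and
  epidermis–corneum boundaries:
  thickness = mean<sub>i</sub> d(ES<sub>i</sub>, EB) (px) and
  rete ridge score = var<sub>j</sub> d(EB<sub>j</sub>, ES) (px²),
  where d is the shortest point-to-polyline distance. Flat junction ⇒
  score 0; pronounced rete ridges ⇒ large score.
* **Radiomics** — a pinned 106-feature vector per patch (18 first-order,
  GLCM/GLRLM/GLSZM/NGTDM/GLDM texture families, diagnostics) and a
  random-forest ranking selecting the top 5 features.
* **Classification + interpretation** — a compact CNN (SGD, learning rate
  0.01, batch size 1) evaluated under slide-level 5-fold cross-validation
  (accuracy, ROC-AUC, PR-AUC, macro-F1, with a leakage guard), and
  Grad-CAM heatmaps tracing the image regions that drive the classifier.
* **Synthetic data** — a generator of H&E-like three-layer skin images
  (sinusoidal rete ridges, nuclei, noise, rotation) with exact ground-truth
  masks and boundary polylines, so the whole pipeline is testable offline.

## Worked example

Generate a synthetic section, segment the epidermis without supervision,
and quantify it:

```r
library(episcope)

params <- synthetic_skin_params(image_height = 96, image_width = 96,
  corneum_thickness = 16, epidermis_thickness = 26, ridge_amplitude = 6,
  ridge_wavelength = 48, nucleus_density = 60, seed = 3)
sample <- generate_sample(params)
sample
#> <synthetic_skin_sample 96x96, epidermis area 2496 px, seed 3>

cfg <- seg_config(felzenszwalb_scale = 150, felzenszwalb_min_size = 120,
                  n_channels = 10, n_conv_blocks = 1, max_iterations = 60,
                  seed = 103)
sp <- compute_superpixels(sample$image, cfg)
sp
#> <superpixel_map: 5 segments over 96 x 96>

labels <- iterative_unsupervised_segment(sample$image, sp, cfg)
sel <- select_epidermis_cluster(labels, sample$image)
sum(sel$mask & sample$epidermis_mask) / sum(sel$mask | sample$epidermis_mask)
#> [1] 0.996                      # IoU against the generator's ground truth

morpho <- mask_morphometrics(refine_mask(sel$mask, min_area = 128), sample$image)
morpho
#> <morphometric_result: thickness 23.34 px (m=96), rete ridge score 15.71 px^2 (n=92)>
```

The recovered thickness (23.3 px) sits just under the generated 26 px —
boundary statistics read off a pixel mask carry a ≈1-px grid bias, and the
morphological cleanup shaves the band edges slightly. The positive rete
ridge score reflects the amplitude-6 sinusoidal junction; a flat junction
scores 0.

Radiomic features come from the same image:

```r
fv <- extract_features(sample$image)
fv
#> <radiomic_feature_vector NA: 106 features, 0 NaN-replaced>
fv$values["firstorder_Median"]; fv$values["glcm_ClusterShade"]
#> 187.5
#> -28.582
```

A command-line front end over the same functions is in
`inst/cli/episcope.R` (`simulate`, `normalize`, `segment`, `sample`,
`morpho`, `radiomics`, `rank`, `train`, `gradcam`).

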