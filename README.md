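# pathograph

Dual-branch classification of histology tiles that treats tissue
architecture as a first-class signal. Growth patterns of lung
adenocarcinoma (lepidic, acinar, papillary, micropapillary, solid) are
graded largely from the *spatial organisation* of tumor cells, which a
whole-image CNN sees only implicitly. pathograph makes that structure
explicit: nuclei become nodes of a cell graph that a graph convolutional
network embeds, a VGG-style encoder embeds the whole tile, and the two
views are fused multiplicatively before classification. Slide-level
pattern proportions are reported in the clinical convention of 5%
increments.

The package is aimed at computational-pathology researchers who want a
fully inspectable, CPU-scale reference implementation of this
architecture, with a synthetic benchmark whose classes differ *only* in
spatial point pattern.

## The model

For a tile with $m$ segmented nuclei:

* **Cell graph.** Node $i$ carries 8 shape features (second-moments
  ellipse axes, orientation, eccentricity, roundness $4\pi A/P^2$, area,
  solidity, perimeter), 4 GLCM texture features (dissimilarity,
  homogeneity, ASM, energy $=\sqrt{\text{ASM}}$) and a pluggable
  12-dimensional patch descriptor. Edges follow
  $a_{ij} = 1 \iff j \in \text{KNN}(i) \wedge D(i,j) < d$ (default
  $K = 5$), symmetrized to an undirected $A$.
* **GCN branch.** $H^{(l+1)} = \sigma(\tilde D^{-1/2}\tilde A
  \tilde D^{-1/2} H^{(l)} W^{(l)})$ with $\tilde A = A + I$; mean
  readout and a linear map give $h_c$.
* **CNN branch.** Conv/ReLU/maxpool stages halving the spatial size,
  then a fully connected layer: $h_s$ (length 1024 for the `vgg16`
  variant, 64 for the desk-scale `vgg_small`).
* **Gated Kronecker fusion.** $z_m = \sigma(W_{cs\to m}[h_c; h_s])$,
  $h_{m,\text{gated}} = z_m \odot \text{ReLU}(W_m h_m)$,
  $h_{\text{fusion}} = h_c \otimes h_s$, one fully connected layer,
  softmax, mean cross-entropy $-\sum_b p_b \log q_b$.
* **Nucleus contours** are represented in polar form: a center plus 36
  ray lengths at 10° steps, decodable to a polygon/mask. A classical
  Otsu + distance-transform-watershed fallback segmenter lets the
  pipeline run when no instance masks are provided.
* **Metrics.** Per class (one-vs-rest): $P = \frac{TP}{TP+FP}$,
  $R = \frac{TP}{TP+FN}$, $F1S = \frac{2TP}{2TP+FP+FN}$; overall
  accuracy $\frac{TP+TN}{TP+TN+FP+FN}$.

All numerics (graph convolutions, the im2col CNN, gated fusion, Adam,
backpropagation) are implemented in plain R on top of BLAS matrix
products — there is no external deep-learning dependency, and every
gradient is verified against numeric differentiation in the tests.

## Worked example

```r
library(pathograph)

# 20 labeled tiles per class: ring-like "gland", dense "sheet",
# sparse "scattered" point patterns
dir <- tempfile()
generate_dataset(n_per_class = 20, base_seed = 1, out_dir = dir)
ds <- prepare_dataset(read_manifest(file.path(dir, "manifest.csv")))

# two-stage protocol: branches at lr 1e-3, fused fine-tune at 1e-5
cks  <- train_two_stage(ds, train_config(seed = 1))
evaluate_model(cks$fused, ds, split = "test")$metrics
```

```
Confusion matrix (rows = true):
     [,1] [,2] [,3]
[1,]    2    1    0
[2,]    0    3    0
[3,]    0    0    3

Per-class one-vs-rest metrics (%):
 class TP FP FN TN   P      R    F1S
     1  2  0  1  6 100  66.67  80.00
     2  3  1  0  5  75 100.00  85.71
     3  3  0  0  6 100 100.00 100.00

Overall accuracy: 88.89%
```

88.89% is 8 of the 9 held-out tiles of this deliberately small demo; at
the benchmark scale (100 tiles per class) the fused model reaches 100%
test accuracy and the GCN-only branch 97.8% (see the acceptance script
below). The three synthetic classes share identical nucleus shapes,
sizes and intensities; only the point pattern differs, so separation
comes from spatial structure.

Slide quantification takes any per-tile classifier — a trained
checkpoint or a plain function. With a composite slide assembled from 6
gland and 4 sheet tiles:

```r
rep <- quantify_slide(slide_image, tumor_mask, classifier, tile = 256)
print(rep)
#> Tiles classified: 10
#>   gland         6 tiles  raw  60.00%  rounded  60%
#>   sheet         4 tiles  raw  40.00%  rounded  40%
#> Dominant pattern: gland
```

A thin CLI covering the same steps ships in `inst/cli/pathograph`
(`synth`, `train`, `eval`, `quantify` subcommands).

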