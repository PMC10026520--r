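# ccrecluster

Index-set clustering of candidate cis-regulatory elements (cCREs) across an
ordered series of cell types.

## The problem

Chromatin-accessibility experiments (ATAC-seq, DNase-seq) across a panel of
related cell types — for example a hematopoietic differentiation series —
identify hundreds of thousands of cCREs. Grouping them by their activity
pattern across cell types is the first step toward interpreting their
regulatory roles, but distance-based clustering (K-means, hierarchical,
Gaussian mixtures) tends to swallow small but biologically coherent groups
into large clusters, and its continuous cluster space is hard to read
against a discrete cell-type hierarchy.

`ccrecluster` instead encodes each cCRE as a **binary index**: one bit per
cell type (1 = a peak was called there), ordered along a user-supplied cell
differentiation tree. All cCREs sharing an index form an **Index-Set (IS)**
— so every distinct presence/absence pattern is guaranteed its own cluster,
no matter how small. The pipeline then:

1. **Filters** sparse ISs with a negative-binomial (NB) background fitted to
   IS sizes (top 5% excluded from the fit; threshold at
   Benjamini–Hochberg-adjusted upper-tail *p* < 0.01).
2. **Rescues** the cCREs of filtered ISs into abundant ISs with a quadratic
   discriminant model: per abundant IS *i* the signal vectors are modeled as
   a multivariate Gaussian and each filtered cCRE *x* scores

   P_i(x) = −½ log|Σ_i| − ½ (x−μ_i)′ Σ_i⁻¹ (x−μ_i) + log P0_i

   where P0_i is the IS's share of cCREs. A softmax turns scores into
   posteriors; a cCRE whose best posterior is below 0.5 joins a null IS,
   otherwise its index is replaced by the winning IS's index (correcting the
   spurious peak call).
3. **Merges** final ISs into **Meta-ISs** by complete-linkage hierarchical
   clustering of IS mean-signal vectors, with the cluster count chosen by
   AIC.
4. **Annotates** each cCRE with a single dominant epigenetic state per cell
   type from a 200 bp genome segmentation (four deterministic tie-break
   rules), and summarizes representative states and colors per cluster.
5. **Evaluates** results with a sliding-window Shannon entropy over the
   sorted binary map (lower = more ordered = more interpretable), a
   noise-injection adjusted-Rand-index reproducibility protocol, and a
   K-means rare-cluster recovery frequency.

## Worked example

The package ships a seeded synthetic-fixture generator (13 hematopoietic-like
cell types, 5 planted index patterns with abundances 2000/1000/500/300/174,
5% spurious-peak-call noise, 200 singleton noise patterns, 300 background
intervals):

```r
library(ccrecluster)
cfg <- fixture_config(seed = 1)
fx  <- generate_fixture(cfg, "fixture_dir")
res <- run_pipeline(run_config(
  peaks = fx$paths$peaks, signals = fx$paths$signals,
  tree = fx$paths$tree, out_dir = "run_dir",
  master = fx$paths$master, states = fx$paths$states,
  colors = fx$paths$colors, seed = 1))
str(res$manifest$counts)
```

prints (computed, not typed in):

```
List of 9
 $ n_ccres           : int 4474
 $ n_dropped_all_zero: int 301
 $ n_initial_is      : int 212
 $ n_abundant_is     : int 5
 $ threshold_size    : int 166
 $ n_rescued         : int 413
 $ null_size         : int 0
 $ n_final_is        : int 6
 $ K_meta            : int 4
```

Reading: 4474 master intervals; 301 overlap no peak and are dropped; the
remaining 4173 cCREs fall into 212 distinct indices; the NB background sets
the abundance threshold at 166 cCREs, keeping exactly the 5 planted ISs; all
413 cCREs of the filtered ISs are rescued into an abundant IS (none land in
the null class); the 5 abundant ISs (+ null) merge into 4 Meta-ISs. The
final IS table shows the planted patterns with high mean signal exactly on
their active bits:

```
                      index   status size       HSC       CMP
1 1_1_1_1_1_1_1_1_1_1_1_1_1 abundant 2177 8.0223254 8.0344989
2 1_1_1_1_1_0_0_0_0_0_0_0_0 abundant 1011 8.2371589 8.2437326
3 0_1_1_1_0_0_0_0_0_0_0_0_0 abundant  503 0.4251758 8.2363115
4 0_0_0_1_0_0_0_0_0_0_0_0_0 abundant  173 0.3979024 0.3927166
5 0_0_0_0_0_0_0_0_1_1_1_1_1 abundant  309 0.4227920 0.4218129
```

`evaluate_run("run_dir", seed = 1)` adds the entropy/ARI/rarity tables; at
window height N = 5 the sorted map scores SE = 1.356 nats over the first 2
cell types and 3.175 nats over all 13.

Output files under `run_dir/`: `ccre_catalog.tsv` (per-cCRE original/final
index, status, rescue posterior), `is_catalog.tsv`, `meta_map.tsv`,
`meta_catalog.tsv`, `aic.json`, `ccre_states.tsv`,
`representative_states.tsv`, `binary_map.pdf`, `is_mean_signal.pdf`,
`manifest.json` (counts + md5 checksums).

A command-line front end wraps the same steps:

```sh
exec/ccrecluster simulate --out fixture_dir --seed 42
exec/ccrecluster run --peaks a.bed,b.bed --signals a.bg,b.bg \
    --cells A,B --tree tree.txt --out run_dir
exec/ccrecluster eval --out run_dir
```

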