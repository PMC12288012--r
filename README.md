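# kpcarc

Identify and rank the residues that drive a protein's scalar property —
an activation distance, a folding RMSD — from a multi-frame conformational
ensemble.

Structural ensembles from molecular-dynamics simulation are huge and
high-dimensional, while the biology is usually tracked by one scalar order
parameter per frame. `kpcarc` finds the low-dimensional representation in
which that parameter is most legible, then asks which residues' motions
carry it:

1. **Angular kernel.** Each atom at aligned position (x, y, z), with
   r = √(x²+y²+z²), is mapped to one bounded feature
   K = λ₁·cos²(x/r) + λ₂·cos²(y/r) + λ₃·sin²(z/r), where the weights
   (λ₁, λ₂, λ₃) lie on the unit simplex.
2. **PCA embedding.** The frames × atoms feature matrix is mean-centred and
   projected onto its top two principal components.
3. **Correlation ratio.** Each candidate embedding is scored by
   Cr = S·R²/√V, where S and R² come from a line fitted to per-quintile
   means of the property along standardized PC1, and V is the mean
   within-quintile variance. A grid search over the 15 simplex-lattice
   weight triples (spacing 0.25) keeps the embedding with the highest Cr.
4. **Reaction-coordinate ranking.** On that fixed optimal embedding, every
   residue's α-carbon polar angle θ = arccos(z/r) is scored with the same
   Cr and residues are ranked by it. Strongly co-varying top-ranked
   residues (|Pearson r| of their θ series above a threshold) form a
   residue-level dynamical network.

The package also quantifies the β-carbon reduction — the ratio of the best
Cr using CB atoms only to the best Cr using all atoms — and ships a
synthetic-ensemble generator with planted driver residues, so the entire
pipeline is validated end-to-end by signal recovery without any MD data.

## Worked example

Generate a 30-residue, 2000-frame ensemble in which residues A5, A15 and
A25 undergo a two-state angular transition that determines the property,
then run the full pipeline:

```r
library(kpcarc)

ens    <- generate_ensemble(synthetic_spec(seed = 7))
search <- find_optimal_representation(ens$trajectory, ens$property)
search
#> <rc_search> 15 weight triples (custom); best K(0, 0, 1) with Cr = 3.09

ranking <- rank_reaction_coordinates(ens$trajectory, search$best_embedding)
print(ranking, n = 5)
#> <rc_ranking> 30 residues scored; top 5:
#>  rank residue_label residue_index         Cr          S        R2          V
#>     1            A5             4 2.48753106 0.26656348 0.9992247 0.01146544
#>     2           A15            14 2.47497264 0.26661480 0.9988821 0.01157860
#>     3           A25            24 2.45286067 0.26723573 0.9997381 0.01186358
#>     4           A27            26 0.03025588 0.03087650 0.7799697 0.63356629
#>     5            A9             8 0.02812969 0.02774812 0.7901304 0.60748412

residue_network(ranking, top_k = 3, threshold = 0.7)
#>   residue_a residue_b    weight passes
#> 1        A5       A15 0.8762615   TRUE
#> 2        A5       A25 0.8707745   TRUE
#> 3       A15       A25 0.8720845   TRUE
```

The three planted drivers take the top three ranks, with Cr some eighty
times the noise floor (driver θ tracks the property almost perfectly, so
R² ≈ 1 and the within-quintile variance V is small); the winning kernel
puts all weight on λ₃, the term sensitive to motion along the polar angle;
and the drivers form a fully connected network clique at |r| ≈ 0.87,
comfortably above the 0.7 edge threshold.

For real data, read a multi-model PDB with `read_structures()`, superpose
with `align_frames()`, and build the property with `compute_rmsd()` or
`compute_pair_distance()` (e.g. the Cα contact between the helix-3 and
helix-6 residues R131 and L272 of the β₂ adrenergic receptor:
`compute_pair_distance(traj, "R131", "L272")`). A thin command-line
wrapper over these functions lives at `inst/scripts/kpcarc-cli.R`
(subcommands `simulate`, `property`, `search`, `rank`, `network`).

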