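# guildfill

Analysis pipeline for point-count surveys of a bird guild split into
native and non-native species, built around one ecological question: when
a human-modified habitat (here, rice fields) filters out part of the
native community, do non-native species fill the vacated functional space
by exploiting the resources natives under-use?

The package is aimed at community ecologists working with distance-sampled
point counts, mixed-type trait tables and resource-availability grids.  It
provides, as composable functions and as one orchestrated pipeline:

- **Detectability** — half-normal point-transect detection functions
  g(r) = exp(−r²/2σ²) with covariates on log σ (emergent vegetation,
  trees and bushes, flock size), fitted by the truncated conditional
  likelihood and selected by AIC over all simplifications of the global
  model; disc-averaged detection probability
  p = (2σ²/w²)(1 − e^{−w²/2σ²}); densities as count/p; and a
  native × habitat detectability-bias test.
- **Resource selection** — Jacobs index J = (u − a)/(u + a − 2ua) per
  species × resource × activity, with availability conditioned on the
  point counts where the species was recorded, and rank-sum group
  contrasts; community-weighted mean plant weight-holding capacity from
  quadrats.
- **Functional diversity** — Gower distance on mixed traits, dendrogram
  with the linkage maximising the cophenetic correlation, branch-length
  FD ∈ [0, 1] per community, uniform and occurrence-frequency null models
  (species drawn without replacement, richness held fixed), and
  SES = (FD_obs − μ_null)/σ_null.
- **Habitat gradients** — 0/+1/+2 association scores mapped onto ordered
  wet–dry and open–closed gradients by a max-over-habitats rule, group
  profiles ± SE, and the gradient position of maximal native/non-native
  divergence.
- **Inference** — site-random-intercept models fitted by ML with
  likelihood-ratio tests, Moran's I residual diagnostics with permutation
  p-values, and Wilcoxon–Mann–Whitney comparisons.
- **Synthetic surveys** — a generator with known ground truth
  (`paper_like_config()`, `generate_survey()`, `generate_traits()`,
  `generate_quadrats()`) emulating the study design: 51 rice + 10
  non-rice sites, up to 16 point counts per site, 4 non-native + 13
  native species, 49-cell availability grids, 100 m truncation.

See `vignettes/guildfill-methods.Rmd` for the statistical details and
design decisions.

## Worked example

```r
library(guildfill)

cfg    <- paper_like_config()                       # the study conditions
sim    <- generate_survey(cfg, seed = 1)
traits <- generate_traits(n_native = 13, n_nonnative = 4, seed = 3)
run    <- run_pipeline(sim$dataset, traits = traits, n_iter = 1000, seed = 1)

sim$dataset
#> survey_dataset: 61 sites, 456 point counts, 843 observations, 17 species

run$inference$tests$nonnative_density[c("estimate", "chisq", "p")]
#> non-native density, rice effect = 6.86 (chisq = 30.73, p = 3e-08)
run$inference$tests$native_fd[c("estimate", "chisq", "p")]
#> native FD, rice effect = -0.0272 (chisq = 13.92, p = 0.000)
run$inference$tests$all_fd[c("estimate", "chisq", "p")]
#> all-species FD, rice effect = 0.0046 (chisq = 0.26, p = 0.608)

run$fd$dendrogram
#> dendrogram_model: 17 species, average linkage, cophenetic r = 0.633,
#> total branch length = 5.915

run$selection$comparisons[["shelter.emergent"]]
#> Wilcoxon-Mann-Whitney: W = 0 , p = 0.003864 (n1 = 13 , n2 = 4)
```

Reading the numbers: non-native birds are substantially denser in rice
fields (the rice effect is the fitted difference in detectability-corrected
density per surveyed disc, tested by a likelihood-ratio test with a site
random intercept), the functional diversity of the *native* community is
lower in rice fields, yet the FD of the *combined* community shows no
rice-field deficit — the non-natives plug the gap.  W = 0 in the shelter
comparison means every native species' Jacobs index for emergent
vegetation lies below every non-native's: the non-natives preferentially
shelter in exactly the vegetation rice fields provide.  All of this
recovers, from raw simulated observations, the contrasts the generator
programmed in.

Per-stage functions (`fit_all_species()`, `estimate_density()`,
`selection_table()`, `gower_distance()`, `null_ses()`, `morans_i()`, ...)
expose each step individually; `guild_summary()` gives occupancy and
body-mass descriptives.  A thin CLI over the same functions lives at
`inst/scripts/guildfill.R` (`simulate`, `validate`, `run`).

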