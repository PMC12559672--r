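# metapatch

Wintering waterbirds redistribute across a floodplain and its surrounding
lakes as water levels change. **metapatch** analyses such systems as
*species–patch metacommunity networks*: one bipartite graph per hydrological
period, with species and habitat patches as nodes and species occurrence in
a patch as a link. Temporal change in the link set is measured with the
Jaccard dissimilarity and partitioned two ways:

* β_Temporal = β_Extinction + β_Colonization — links lost versus gained
  between two periods;
* β_Temporal = β_Local + β_Regional + β_Landscape + β_RL — changed links
  classified by whether the species node and the patch node persist across
  both periods (both persist → local rewiring; species turnover → regional;
  patch turnover → landscape; both → regional-landscape).

Around this core the package provides network-level metrics (connectance,
NODF nestedness, Barber bipartite modularity), node-level metrics (degree,
nestedness contribution *cnodf* as a focal-node-null z-score, temporal CV),
classic diversity indices (Shannon–Wiener, Pielou evenness, Bray–Curtis),
hydrological covariates (inundation duration and the InD1/InD2 classes,
October-mean regime labelling, shoreline shape index, NDVI), and a seeded
synthetic metacommunity generator that emulates four hydrological regimes —
early recession (ER), late recession (LR), normal recession (NR) and extreme
drought (ED) — over river-connected patches beside stable surrounding lakes.
It is aimed at community ecologists studying metacommunity assembly,
extinction–colonization dynamics and habitat-patch importance from repeated
multi-site surveys.

## Worked example

Simulate the default four-regime world and partition the link dynamics:

```r
library(metapatch)

cfg  <- scenario_config(seed = 1)   # 12 river patches + 10 stable lakes
pool <- species_pool(seed = 1)      # 40 species, 9 functional groups
s    <- scenario_suite(cfg, pool, seed = 1)

nets <- lapply(s$periods, function(p) build_network(to_abundance_matrix(s, p)))
names(nets) <- s$periods

beta_pair(nets$NR, nets$ED)[, 1:4]
#>       pair beta_temporal beta_extinction beta_colonization
#> 1   NR->ED    0.08114286      0.01828571        0.06285714

beta_pair(nets$NR, nets$LR)[, 1:4]
#>       pair beta_temporal beta_extinction beta_colonization
#> 1   NR->LR    0.09378664      0.05509965        0.03868699
```

Between a normal recession and the extreme drought, 8.1% of species–patch
links changed and colonization dominated (0.063 vs 0.018): birds squeezed
out of the drying river system colonized the stable surrounding lakes.
Between a normal and a late recession, extinction dominated (0.055 vs
0.039): high water concentrated the scarce open-water species back into the
river patches and their marginal stable-lake links winked out.

The same survey drives the rest of the pipeline:

```r
run_pipeline(list(seed = 1), "results")
```

which writes per-patch and per-subregion diversity profiles, per-period
network metrics, per-node degree/cnodf series with CVs, the full
beta-partition table, a Mann–Whitney comparison of node CVs between species
and patches, a keystone-patch ranking, and a JSON run manifest. The
`analysis/` directory holds the same workflow as numbered narrative
scripts (`01_simulate.R` … `05_hydro_covariates.R`); run them in order from
the repository root. Stage 1 prints, for seed 1:

```text
ER:  268657 birds, 4.0% in the stable surrounding lakes
LR:  269117 birds, 3.5% in the stable surrounding lakes
NR:  268619 birds, 3.6% in the stable surrounding lakes
ED:  269339 birds, 5.9% in the stable surrounding lakes
```

— the stable lakes take their largest share of birds under extreme drought,
the refuge effect the partition statistics quantify at the link level.

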