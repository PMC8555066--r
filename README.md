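# metastrack

Multi-sample tumor phylogenetics and metastatic migration inference in R.

When many tumor sites from one patient are sequenced jointly — for example a
primary breast tumor plus dozens of rapid-autopsy metastases with matched
normal tissue — the pattern of shared and private somatic variants, copy
number changes and allele fractions encodes how the cancer spread.
`metastrack` reconstructs that history end to end:

1. **Somatic variant table** — read a joint multi-sample VCF, apply strict
   quality/depth/mask filters, and call variants somatic when, in *every*
   matched normal, VAF < 0.1 or fewer than 5 alternate reads.
2. **Copy-number profiles** — bin FACETS-style segment log2 ratios into 1-Mb
   windows, cluster samples by UPGMA on Euclidean distances, and group
   samples that share discrete CNV events (the "metastatic waves").
3. **Allele-specific states** — infer which parental allele was amplified or
   lost from inherited heterozygous variant AFs under the purity mixture
   model `AF = (p·m + (1−p)) / (p·c + 2(1−p))` for a variant on `m` of `c`
   tumor copies, and order states by the no-resurrection rule (a lost allele
   never returns), which yields a partial time order over waves.
4. **Sample phylogeny** — encode presence/absence of somatic variants on
   copy-stable chromosomes (present iff AF > 0.1), cluster identical
   occurrence vectors, flag mixture samples that violate the infinite sites
   assumption, and build the perfect phylogeny with branch lengths in
   variant counts.
5. **Subclone trees** — cluster variants by AF level across samples, convert
   cluster mean AFs to cellular prevalences (`CP = 2·AF/p` for het variants
   on copy-neutral loci, with general copy-state correction), exhaustively
   enumerate all rooted subclone trees consistent with the parent–child sum
   constraint `CP(parent) + 0.1 ≥ Σ CP(children)` per sample, and keep the
   minimal-violation solution.
6. **Migration graph** — classify seeding events between sites: *monoclonal*
   (a subclone at partial prevalence in its harbor site and ≈100% in the
   seeded site), *polyclonal* (related subclones at low prevalence in both
   sites), *recolonization* (a descendant returning to an established site
   while its evolutionary intermediates stand alone only at the origin
   site), plus *subclonal incubator* detection (an ancestor–descendant chain
   evolving at one site, each link seeding further sites).

A fully seeded synthetic-cohort simulator (`simulate_cohort()`) generates
multi-site cohorts with known ground truth — subclone tree, per-branch
mutations, site compositions realizing named seeding scenarios, CNV/LOH
states, purities and binomial read counts — and drives the validation suite.

## Worked example

Simulate an "incubator" cohort — five subclones evolving as a chain at lung
site `I`, each founding a further site — at 60× depth, then reconstruct it:

```r
library(metastrack)

co       <- simulate_cohort(seed = 42, scenario = "incubator", depth_mean = 60)
variants <- call_somatic(co$variants)
rec      <- reconstruct_subclones(variants, co$purity, chroms = "chr14")
rec$solutions
#> <mst_solutions> 1 tree(s), root C1, chosen #1 (violation 0.05371)
round(rec$prev, 2)
#>    P    I M3   M4   M5
#> C1 1 1.00  1 1.00 1.00
#> C2 0 0.70  1 1.00 1.00
#> C3 0 0.39  0 0.98 0.95
#> C5 0 0.21  0 0.00 1.00

mg <- infer_migration(rec$atlas, primary = "P")
mg
#> <mst_migration> 5 sites, 3 events; incubators: I
tidy(mg)
#>   source target       kind subclones ambiguous
#> 1      I     M3 monoclonal        C2     FALSE
#> 2      I     M4 monoclonal     C2,C3     FALSE
#> 3      I     M5 monoclonal  C2,C3,C5     FALSE
```

Reading the output: cluster `C1` is the truncal clone (prevalence ~1
everywhere); `C2`–`C5` form a chain that exists at partial prevalence only at
site `I` (0.70 → 0.39 → 0.21), while each link reaches full prevalence at one
of `M3`–`M5`. That is the incubator signature: the chain evolved at `I` and
seeded the other sites monoclonally, so `I` is flagged as an incubator and
every seeding edge is sourced there. `autoplot(mg)` draws the migration
graph; `migration_dot(mg)` exports it as DOT.

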