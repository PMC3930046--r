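# octopop

SNP discovery and population assignment for octoploid sturgeons.

## The problem

"High chromosome number" sturgeons (the Ponto-Caspian Russian, Persian
and Siberian sturgeons among them) are functional octoploids: every
nuclear locus is present as two paralogous tetrasomic sets — eight
similar genomic copies.  In pooled sequencing reads this creates a trap
for SNP discovery: an apparently heterozygous pileup position can be a
true within-locus polymorphism, or a fixed difference between the two
paralogs (a paralogous sequence variant, PSV) that looks heterozygous in
every individual and is useless for population genetics.

The read-count signature separates them.  With total B-allele dosage
*d* of 8 copies and error rate *e*, the expected B-read fraction is

    p_d = (d/8)(1 - e) + (1 - d/8) e

A site where one tetrasomic paralog is fixed (AAAA) and the other is
balanced-heterozygous (AABB) has *d* = 2 and an expected **3:1**
major:minor ratio — a usable SNP candidate.  Alternatively fixed
paralogs (AAAA+BBBB, *d* = 4) give a **1:1** ratio — a PSV to reject.
`octopop` classifies sites by maximum-likelihood dosage over all nine
values of *d*, then carries the surviving panel through the downstream
population analysis:

* **io_formats** — allele-count TSV, genotype CSV, strict biallelic
  GenePop, bracketed-marker tables (a 12-marker sturgeon assignment
  panel ships as a fixture), Newick.
* **simulate** — octoploid read counts with known dosage truth, and
  Balding–Nichols multi-population genotype matrices with controlled
  divergence (defaults mirror the sturgeon study: populations of 14,
  14, 5, 28 and 5 individuals at 123 loci).
* **discovery** — `classify_sites()`, `call_candidates()` (best-scoring
  panel selection, default 384), `coverage_tally()`.
* **qc** — `filter_informative_loci()` drops loci homozygous or
  heterozygous across all individuals; `mapping_fraction()` for
  read-mapping arithmetic.
* **popgen** — allele frequencies, Latter's F_ST distance
  (Σ squared frequency differences / Σ expected between-population
  heterozygosity), Weir–Cockerham θ, deterministic UPGMA, locus
  bootstrap supports.
* **assignment** — HWE assignment likelihoods with 1/(2n+1)
  zero-frequency correction, leave-one-out accuracy, resampling-based
  locus ranking, minimal-panel selection.

## Worked example

```r
library(octopop)

# --- discovery: four sites at depth 200, e = 0.01 ---------------------
sites <- sim_octoploid_sites(dosage_paralog1 = c(0L, 4L, 0L, 2L),
                             dosage_paralog2 = c(2L, 0L, 0L, 2L),
                             depth = 200, error_rate = 0.01, seed = 42)
classify_sites(sites, error_rate = 0.01, min_coverage = 100)
#>      est_id count_a count_b mle_dosage    site_class
#> 1 SIM000001     151      49          2 candidate_snp
#> 2 SIM000002      99     101          4           psv
#> 3 SIM000003     196       4          0   monomorphic
#> 4 SIM000004     100     100          4           psv
```

Site 1 (49/200 ≈ a 3:1 ratio) is the AAAA+AABB configuration — a panel
candidate.  Sites 2 and 4 sit at 1:1: PSVs, rejected.  Note site 4 is a
*true* d = 4 even though both its paralogs are heterozygous — read
counts alone cannot tell AAAA+BBBB from AABB+AABB, which is why all
d = 4 sites are excluded.

```r
# --- population pipeline at the study design --------------------------
mat <- sim_study_matrix(pop_sim_config(), seed = 7)   # 66 ind x 123 loci
res <- filter_informative_loci(mat)
tr  <- bootstrap_tree(res$matrix, n_reps = 100, seed = 8)
write_newick(tr)
#> ((((pop1:0.019,pop2:0.019)100:0.025,pop3:0.045)93:0.019,
#>   pop4:0.063)100:0.070,pop5:0.133);          # (line-wrapped)

wc_fst(res$matrix)$multilocus
#> 0.0979

leave_one_out_accuracy(res$matrix)
#> leave-one-out assignment: overall accuracy 0.712
#>  pop1  pop2  pop3  pop4  pop5
#> 0.500 0.429 0.200 1.000 1.000
```

The tree places the two low-divergence river populations (pop1, pop2)
as a 100%-supported cherry, with the most drifted population (pop5) as
the outgroup — the structure the simulation's drift defaults encode.
Assignment is perfect for the divergent populations and near chance for
the two nearly identical river populations — the expected behaviour for
weakly diverged stocks sharing an ancestral gene pool.

```r
rk  <- rank_loci(res$matrix, seed = 9)   # resamples of 100,100,100,500
sel <- select_min_panel(res$matrix, rk, target_accuracy = 0.8)
sel$reached
#> FALSE    # this 5-locus consensus cannot reach 80% here: pop1/pop2
#>          # are nearly panmictic, so their individuals stay confusable
```

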