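# coevodock

Coevolution-guided modeling of two-chain protein complexes.

When two interacting proteins belong to the same domain family — as the
iron–sulfur proteins mitoNEET and NAF-1 both carry the CDGSH domain — the
family's multiple sequence alignment records the residue–residue couplings
that evolution has maintained. `coevodock` turns those couplings into a
structural model of the heterocomplex:

1. **Mean-field direct coupling analysis (DCA).** Sequences are reweighted at
   80% identity, single- and pair-column frequencies are estimated with a
   pseudocount λ = M<sub>eff</sub>, couplings come from the inverse of the
   column-pair covariance matrix, e<sub>ij</sub> = −(C<sup>−1</sup>)<sub>ij</sub>,
   and each column pair is scored by direct information (DI): the mutual
   information of the two-site direct distribution
   P<sup>dir</sup><sub>ij</sub>(A,B) ∝ exp(e<sub>ij</sub>(A,B)) μ<sub>i</sub>(A) μ<sub>j</sub>(B),
   whose single-site factors are fixed so its marginals match the data.
2. **Exclusion filtering.** Couplings explained by the monomeric fold
   (intrachain contacts), by solvent burial (Shrake–Rupley relative SASA),
   or by a known homodimer interface are removed; the top-K survivors (K = 20
   by default) are the predicted inter-protein contacts, carried in both
   chain orientations since the family alignment cannot tell them apart.
3. **Restrained docking.** Each monomer is held near its crystal geometry by
   a C-alpha structure-based (Go-type) model; the two chains start 75 Å
   apart in a random orientation and are assembled by simulated-annealing
   Langevin dynamics (T* 1.2 → 0.2) under flat-bottom coupling restraints
   (10 Å bound, with a short-range contact well) plus one restraint holding
   the two metal-cluster sites — the centroids of the 3 Cys + 1 His
   coordinating residues — at 12 Å, the distance compatible with 2Fe-2S
   cluster transfer. Ten replicas are run; the model with fewest steric
   clashes (inter-chain C-alpha pairs under 3.8 Å) is selected.
4. **Evaluation.** Per-pair minimum distances, restraint satisfaction, the
   inter-cluster distance, clash audit, and a single-interface connectivity
   score.

A synthetic-data layer provides full ground truth — Potts-sampled alignments
with planted couplings, and toy bead-chain complexes with a designed
interface — so the whole pipeline is testable end to end. The methods
vignette (`vignettes/coevodock-methods.Rmd`) documents the model, defaults,
and design choices.

## Worked example: DCA on a synthetic family

```r
library(coevodock)
set.seed(42)
pl <- data.frame(i = c(3L, 11L), j = c(9L, 17L), strength = 1.5)
al <- sample_potts_msa(potts_spec(L = 20, q = 8, M = 800,
                                  couplings = pl, seed = 42))
al
#> msa: 800 sequences x 20 columns (q = 8, 20 match columns)
w  <- compute_weights(al, x = 0.8)
fr <- compute_frequencies(al, w)        # pseudocount = Meff
cp <- infer_couplings(fr)
di <- di_matrix(cp, fr)
head(rank_pairs(di, min_separation = 0), 4)
#>    i  j         DI
#> 1  3  9 0.15099386
#> 2 11 17 0.12380295
#> 3  7 15 0.01171645
#> 4  2 19 0.01159751
```

The two planted couplings, (3, 9) and (11, 17), top the DI ranking with an
order of magnitude of headroom over the background; that background level
(here ~0.012) is the finite-sampling noise floor of the mean-field estimator
and is characterized in the vignette.

## Worked example: the full synthetic pipeline

```r
cfg <- coevodock_config(seed = 7)   # 30-residue toy complex, M = 1130 MSA
run_pipeline(cfg, "flagship_out")
rep <- jsonlite::read_json("flagship_out/report.json", simplifyVector = TRUE)
str(rep[c("cluster_distance", "fraction_within", "clash_count",
          "restraint_satisfaction", "single_interface", "interface_rmsd")])
#> List of 6
#>  $ cluster_distance      : num 12
#>  $ fraction_within       : num 1
#>  $ clash_count           : int 0
#>  $ restraint_satisfaction: num 1
#>  $ single_interface      : num 1
#>  $ interface_rmsd        : num 1.58
```

Reading: the docked model places the two ligand-site centroids 12.03 Å apart
(the designed cluster-transfer distance), every candidate coupling pair sits
within 10 Å, the selected replica has no steric clashes, all satisfied pairs
form one connected interface, and the complex matches the designed geometry
to 1.58 Å interface RMSD. Re-running with the same config and seed
reproduces every output file byte for byte.

The same pipeline runs on real inputs — a family alignment (FASTA or
Stockholm), two monomer PDB files, optional homodimer assemblies and the
cluster-coordinating residue lists — via the `paths` entries of
`coevodock_config()`, with `filter = list(use_exclusions = TRUE, K = 20)`.
A thin command-line front end is installed at `inst/scripts/coevodock`
(`coevodock all --out run1 --seed 1 [--config cfg.yaml]`).

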