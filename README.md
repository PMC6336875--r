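# dipscan

Analysis pipeline for **domain insertion profiling by sequencing
(DIP-seq)** of a membrane protein. A transposon places a domain cassette at
quasi-random positions of a coding sequence; FACS splits the expressing
library into surface-expressed (SE) and not-surface-expressed (NSE) pools;
junction sequencing reads out each pool's insertion sites. dipscan turns
those reads into per-residue **permissibility** scores, compares
permissibility across inserted domains (**differential permissibility**, a
candidate signature of latent allosteric capacity), models permissibility
from protein properties with decision trees, and implements the
flow-cytometry statistics of the accompanying channel-function and
light-modulation assays. It is written for protein engineers running
domain-insertion screens on channels and transporters (the worked example
mimics a Kir2.1-style screen) and for anyone re-analysing such screens.

## The statistic at the core

Permissibility of residue *i* in replicate *j* is the enrichment between
sorted pools,

```
F(i,j) = r_SE(i,j)/t_SE(j) - r_NSE(i,j)/t_NSE(j)
```

with `r` the productive (in-frame, forward) read count at residue *i* and
`t` the pool's productive total. `F` is NA wherever either pool lacks
reads. The replicate mean `G(i)` is z-scored for structure mapping and
binarized at 0 (1 = permissive) for site comparisons and model training.
Two sites metrics compare domains A and B: the **Hamming criterion**
(binarized bits disagree, reported over jointly scored sites) and the
per-site **Euclidean distance** `|z_A - z_B|`, smoothed with a 15-residue
moving average to call differential regions above +1 SD.

The package's six modules — synthetic data generation, insertion calling,
permissibility scoring, differential analysis, decision-tree modeling,
flow statistics — are documented in `vignettes/dipscan-methods.Rmd`.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data with known ground truth (each is self-contained; stage 1 writes the
inputs the later stages read):

```sh
Rscript analysis/01_simulate.R         # reference, truth, pools, reads
Rscript analysis/02_call_insertions.R  # junction calling + tally
Rscript analysis/03_score.R            # F -> G -> z -> binary
Rscript analysis/04_differential.R     # Hamming/Euclidean/regions
Rscript analysis/05_model.R            # decision trees, CV, withholding
Rscript analysis/06_flow.R             # RMP + light-modulation statistics
```

Output actually printed by a run (seed 1):

```
called 10000/10000 pairs; 100.00% exact (position + orientation); 1679 productive
PDZ: scored 99.8% of sites, Spearman(G, true p_se) = 0.912
Cib81: scored 99.5% of sites, Spearman(G, true p_se) = 0.919
differential sites (Hamming): 40/433 (9%)
rank-sum, Euclidean distance at differential vs other sites: U = 15708, p = 1.14e-25
PDZ: trained on 99.5%, CV AUC 0.882 (0.489 without dynamic), top feature mode_6
```

Reading it: every simulated read pair was assigned its true insertion
position and orientation; mean permissibility recovers the ground-truth
surface-expression ranking (Spearman 0.91–0.92); the Hamming criterion
flags exactly the 40 sites simulated with a domain-dependent
surface-expression gap; differential distance concentrates at those sites
(rank-sum p ≈ 1e-25); and the depth-4 tree predicts binarized
permissibility from the dynamic (mobility-like) features alone — removing
them collapses the cross-validated AUC to chance.

In R, the same pipeline is a few calls:

```r
library(dipscan)
cfg  <- sim_config(seed = 1, n_variants = 1e5, depth_per_pool = 2e5)
expt <- simulate_experiment(cfg, n_residues = 437)   # 435 scoreable sites
sc   <- score_experiment(expt)                       # F, G, z, binary per domain
hamming_differential(sc$PDZ$binary, sc$Cib81$binary)$percent_string
#> "9%"
coverage_report(170, 293)$percent_string
#> "58.0%"
```

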