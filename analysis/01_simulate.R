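#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs: reference CDS, insertion cassettes,
# ground-truth site classes, per-replicate libraries sorted into SE/NSE
# pools, and one library's junction read pairs.
#
# Writes: results/reference.fasta, results/cassette_<name>.fasta,
#         results/truth.tsv, results/counts_<domain>_rep<r>_<pool>.tsv,
#         results/reads_R1.fastq, results/reads_R2.fastq

suppressMessages(library(dipscan))
dir.create("results", showWarnings = FALSE)
seed <- 1

cfg <- sim_config(seed = seed, n_variants = 1e5, depth_per_pool = 2e5,
                  n_replicates = 3)
exp1 <- simulate_experiment(cfg, n_residues = 437)

writeLines(c(">reference", exp1$reference$cds), "results/reference.fasta")
cassettes <- example_cassettes(seed = seed + 100)
for (cs in cassettes) {
  writeLines(c(paste0(">", cs$name), cs$full_nt),
             sprintf("results/cassette_%s.fasta", cs$name))
}
write.table(exp1$truth, "results/truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (d in names(exp1$counts)) {
  for (r in seq_along(exp1$counts[[d]])) {
    for (pool in c("se", "nse")) {
      ct <- exp1$counts[[d]][[r]][[pool]]
      write.table(data.frame(aa_pos = ct$aa_pos, count = ct$count),
                  sprintf("results/counts_%s_rep%d_%s.tsv", d, r,
                          toupper(pool)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
}

# junction reads for one 10,000-variant library of the PDZ cassette
cfg_reads <- sim_config(seed = seed + 1, n_variants = 10000)
lib <- simulate_library(exp1$reference, cfg_reads)
rd <- simulate_reads(lib, exp1$reference, cassettes[["PDZ"]], cfg_reads)
write_fastq(rd$id, rd$r1, "results/reads_R1.fastq")
write_fastq(rd$id, rd$r2, "results/reads_R2.fastq")

cat("simulated", nrow(exp1$truth), "sites,",
    sum(exp1$truth$site_class == "differential"), "differential;",
    length(rd$id), "read pairs\n")
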