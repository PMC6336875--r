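# Shared fixtures, all built in code at test time.

tiny_reference <- function(n = 40, seed = 1) make_reference(n, seed = seed)

tiny_cassette <- function(seed = 101) example_cassettes(seed = seed)[["PDZ"]]

counts_fixture <- function(aa, cnt, pool = "SE") {
  dip_counts(aa, cnt, pool = pool, replicate = 1L, domain = "PDZ")
}

profile_fixture <- function(values, aa = seq_along(values)) {
  se <- dip_counts(aa, rep(1L, length(values)))
  p <- enrichment(se, dip_counts(aa, rep(1L, length(values))))
  p$score <- as.numeric(values)
  p
}

# minimal synthetic structure: 3 residues x 2 atoms, written with bio3d
write_tiny_pdb <- function(path, resno = c(6, 7, 8)) {
  n_atom <- 2 * length(resno)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(seq_len(3 * n_atom)),
    resno = rep(resno, each = 2),
    resid = rep("ALA", n_atom),
    eleno = seq_len(n_atom),
    elety = rep(c("N", "CA"), length(resno)),
    chain = rep("A", n_atom),
    o = rep(1, n_atom),
    b = rep(0, n_atom))
  path
}

# small but fully exercised experiment for module tests
small_experiment <- function(seed = 7) {
  cfg <- sim_config(seed = seed, n_variants = 2e4, depth_per_pool = 4e4,
                    n_replicates = 2)
  simulate_experiment(cfg, n_residues = 102)
}
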