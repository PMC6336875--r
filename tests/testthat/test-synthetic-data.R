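# Synthetic-data generator: reference, truth, library, sorting, reads,
# features and flow events.

test_that("reference genes are deterministic, stop-free and well-formed", {
  ref <- make_reference(435, seed = 1)
  expect_equal(nchar(ref$cds), 1305)
  expect_equal(ref$n_residues, 435)
  expect_identical(substr(ref$cds, 1, 3), "ATG")
  codons <- substring(ref$cds, seq(1, 1302, 3), seq(3, 1304, 3))
  expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  expect_identical(make_reference(10, seed = 7), make_reference(10, seed = 7))
  expect_error(make_reference(9, seed = 1), "n_residues")
})

test_that("cassettes translate consistently and enforce linker lengths", {
  cass <- dip_cassette("toy", insert_aa = "MKL")
  expect_match(cass$full_nt, "^GCTAGC")          # Ala-Ser N-linker
  expect_error(dip_cassette("bad", insert_aa = "MK", linker_n = "ASA"),
               "linker")
  expect_error(dip_cassette("bad", insert_aa = "MK", insert_nt = "ATGCTG"),
               "translate")
  full_aa <- paste0("AS", "MKL", "GSA")
  expect_identical(
    as.character(Biostrings::translate(Biostrings::DNAString(cass$full_nt))),
    full_aa)
})

test_that("ground truth covers every site with configured probabilities", {
  ref <- make_reference(437, seed = 1)
  tr <- simulate_truth(ref, seed = 3)
  expect_equal(nrow(tr), 435)
  expect_setequal(unique(tr$site_class),
                  c("permissive", "scaffold", "differential", "intermediate"))
  expect_equal(sum(tr$site_class == "differential"), 40)
  ps <- p_se_matrix(tr)
  expect_true(all(ps >= 0 & ps <= 1))
  # differential gap is exactly the configured 0.7 vs 0.1
  d <- tr$site_class == "differential"
  expect_true(all(abs(ps[d, "PDZ"] - ps[d, "Cib81"]) == 0.6))
  # non-differential sites are identical across domains
  expect_true(all(ps[!d, "PDZ"] == ps[!d, "Cib81"]))
  # determinism
  expect_identical(tr, simulate_truth(ref, seed = 3))
  # all-permissive corner
  tr1 <- simulate_truth(ref, class_fractions = c(permissive = 1), seed = 1)
  expect_true(all(tr1$site_class == "permissive"))
  expect_true(all(p_se_matrix(tr1) == 0.8))
  expect_error(simulate_truth(ref, class_fractions = c(permissive = 0.5)),
               "sum to 1")
})

test_that("library positions follow the 5'-depressed weight", {
  ref <- make_reference(200, seed = 2)
  # b = 0: uniform over positions (chi-squared goodness of fit)
  cfg0 <- sim_config(seed = 4, n_variants = 1e5, bias_amplitude = 0)
  lib0 <- simulate_library(ref, cfg0)
  by_pos <- tapply(lib0$count, lib0$nt_pos, sum)
  gof <- chisq.test(as.integer(by_pos))
  expect_gt(gof$p.value, 0.01)
  # 5' bias depresses early positions
  cfgb <- sim_config(seed = 4, n_variants = 1e5, bias_amplitude = 0.8,
                     bias_length_scale = 150)
  libb <- simulate_library(ref, cfgb)
  first50 <- sum(libb$count[libb$nt_pos < 150])
  last50 <- sum(libb$count[libb$nt_pos >= nchar(ref$cds) - 6 - 150])
  expect_lt(first50, last50)
  # empty library
  cfg_empty <- sim_config(seed = 1, n_variants = 0)
  expect_equal(nrow(simulate_library(ref, cfg_empty)), 0)
})

test_that("productive fraction is 1/6 under uniform bias and orientation", {
  ref <- make_reference(200, seed = 2)
  cfg <- sim_config(seed = 9, n_variants = 6e4, bias_amplitude = 0)
  lib <- simulate_library(ref, cfg)
  prod <- lib$orientation == "forward" & lib$nt_pos %% 3 == 0
  expect_lt(abs(sum(lib$count[prod]) / sum(lib$count) - 1 / 6), 0.01)
})

test_that("sorting splits cells by p_se and conserves reads", {
  ref <- make_reference(102, seed = 5)
  # enough cells per variant that binomial sequencing error dominates
  cfg <- sim_config(seed = 5, n_variants = 2e5, depth_per_pool = 1e6)
  lib <- simulate_library(ref, cfg)
  # p_se identically 1: NSE pool is empty
  tr1 <- simulate_truth(ref, class_fractions = c(permissive = 1), seed = 1,
                        p_se_table = list(permissive = 1))
  res1 <- simulate_sort_counts(lib, tr1, "PDZ", cfg, replicate_seed = 2)
  expect_equal(res1$nse$t, 0)
  expect_equal(res1$se$t, cfg$depth_per_pool)
  # p_se = 0.5 at high depth: per-site SE and NSE read fractions agree
  tr5 <- simulate_truth(ref, class_fractions = c(permissive = 1), seed = 1,
                        p_se_table = list(permissive = 0.5))
  res5 <- simulate_sort_counts(lib, tr5, "PDZ", cfg, replicate_seed = 3)
  dfrac <- res5$se$count / res5$se$t - res5$nse$count / res5$nse$t
  expect_lt(max(abs(dfrac)), 0.005)
  # conservation and determinism
  expect_equal(sum(res5$se$count), res5$se$t)
  expect_identical(res5, simulate_sort_counts(lib, tr5, "PDZ", cfg,
                                              replicate_seed = 3))
  expect_error(simulate_sort_counts(lib, tr5, "nope", cfg, 1), "domain")
})

test_that("mean enrichment increases with configured p_se", {
  ref <- make_reference(102, seed = 6)
  cfg <- sim_config(seed = 6, n_variants = 2e4, depth_per_pool = 1e5)
  lib <- simulate_library(ref, cfg)
  tr <- simulate_truth(ref,
                       class_fractions = c(scaffold = 1 / 3,
                                           intermediate = 1 / 3,
                                           permissive = 1 / 3),
                       p_se_table = list(scaffold = 0.1, intermediate = 0.5,
                                         permissive = 0.9),
                       seed = 2)
  res <- simulate_sort_counts(lib, tr, "PDZ", cfg, replicate_seed = 4)
  f <- enrichment(res$se, res$nse)
  class_means <- tapply(f$score, tr$site_class, mean, na.rm = TRUE)
  expect_true(class_means[["scaffold"]] < class_means[["intermediate"]])
  expect_true(class_means[["intermediate"]] < class_means[["permissive"]])
})

test_that("simulated reads span the junction with the duplicated 5-mer", {
  ref <- make_reference(40, seed = 3)
  cass <- tiny_cassette()
  cfg <- sim_config(seed = 8, n_variants = 50, read_length = 50)
  lib <- data.frame(nt_pos = 21L, orientation = "forward", count = 1L)
  rd <- simulate_reads(lib, ref, cass, cfg)
  # upstream read: reference flank ends at nt 26 = 21 + duplication
  flank <- substr(ref$cds, 2, 26)        # 25 bases ending at 0-based 26
  expect_identical(substr(rd$r1, 1, 25), flank)
  expect_identical(substr(rd$r1, 26, 50), substr(cass$full_nt, 1, 25))
  # downstream mate (reverse-complemented): resumes at nt 21, so its
  # reverse complement ends with cds[21:46) whose first 5 bases repeat
  # the duplicated 5-mer cds[21:26)
  r2rc <- dipscan:::revcomp(rd$r2)
  expect_identical(substr(r2rc, 26, 30), substr(ref$cds, 22, 26))
  expect_identical(substr(r2rc, 26, 50), substr(ref$cds, 22, 46))
  # determinism at scale
  lib2 <- simulate_library(make_reference(102, seed = 5),
                           sim_config(seed = 2, n_variants = 2000))
  ref2 <- make_reference(102, seed = 5)
  rd_a <- simulate_reads(lib2, ref2, cass, sim_config(seed = 2))
  rd_b <- simulate_reads(lib2, ref2, cass, sim_config(seed = 2))
  expect_identical(rd_a, rd_b)
  expect_error(simulate_reads(lib, ref, cass, sim_config(read_length = 20)),
               "read_length")
})

test_that("FASTQ round trip preserves ids and sequences", {
  ref <- make_reference(40, seed = 3)
  cass <- tiny_cassette()
  cfg <- sim_config(seed = 8, n_variants = 20, read_length = 50)
  lib <- simulate_library(make_reference(102, seed = 5),
                          sim_config(seed = 3, n_variants = 20))
  rd <- simulate_reads(lib, make_reference(102, seed = 5), cass, cfg)
  fp <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rd$id, rd$r1, fp)
  back <- read_fastq(fp)
  expect_identical(back$id, rd$id)
  expect_identical(back$seq, rd$r1)
  tr <- truth_from_ids(rd$id)
  expect_identical(sort(unique(tr$orientation)),
                   sort(unique(lib$orientation)))
})

test_that("feature tables have the stated shape and signal structure", {
  ref <- make_reference(437, seed = 1)
  tr <- simulate_truth(ref, seed = 3)
  ft <- simulate_features(tr, effect_size = 1.0, seed = 5)
  expect_equal(dim(ft), c(435, 5 + 21 + 20))
  cats <- attr(ft, "categories")
  expect_equal(unname(table(cats)[c("static", "conservation", "dynamic")]),
               c(5L, 21L, 20L), ignore_attr = TRUE)
  # effect_size 1: some dynamic feature correlates with binary permissibility
  lab <- as.integer(tr$site_class == "permissive")
  rho <- abs(cor(as.matrix(ft), lab, method = "spearman"))
  expect_gt(max(rho[cats == "dynamic", 1]), 0.3)
  # effect_size 0: features sit inside sampling noise (|r| < 0.1 covers
  # ~2 SE at n = 435) in at least 95% of feature-by-run draws
  frac_ok <- vapply(1:100, function(s) {
    f0 <- simulate_features(tr, effect_size = 0, seed = 1000 + s)
    mean(abs(cor(as.matrix(f0), lab)) < 0.1)
  }, numeric(1))
  expect_gte(mean(frac_ok), 0.95)
  expect_error(simulate_features(tr, n_static = 0), "counts")
})

test_that("flow events follow the mixture, bleaching and light models", {
  expect_error(simulate_flow(activity = 1.2), "activity")
  # activity 0: single depolarized component (no low-dye mass)
  ev0 <- simulate_flow(activity = 0, n_events = 5000, seed = 1)
  expect_lt(mean(ev0$dye < 500), 0.01)
  expect_true(all(diff(ev0$t_acq) > 0))
  expect_true(all(as.matrix(ev0[, 1:6]) >= 0))
  # bleach_rate 0: dye distribution independent of acquisition time
  ev <- simulate_flow(activity = 0.5, n_events = 20000, seed = 2)
  ks <- suppressWarnings(ks.test(ev$dye[1:10000], ev$dye[10001:20000]))
  expect_gt(ks$p.value, 0.01)
  # light_shift 0: dark and light draws indistinguishable
  d <- simulate_flow(0.5, light_shift = 0, n_events = 20000, seed = 3)
  l <- simulate_flow(0.5, light_shift = 0, n_events = 20000, seed = 4)
  expect_gt(suppressWarnings(ks.test(d$dye, l$dye))$p.value, 0.01)
  # bleaching decays intensities multiplicatively
  evb <- simulate_flow(0.5, bleach_rate = 1e-3, n_events = 10000, seed = 5)
  expect_lt(median(evb$dye[9001:10000]), median(evb$dye[1:1000]))
})
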