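# Correlation matrices, property correlations, differential-site metrics,
# moving-average smoothing, rank-sum tests and structure annotation.

test_that("correlation matrices honor the NA-as-zero policy and cluster", {
  m <- cbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, NA, 3), d = c(1, 0, 3))
  cm <- correlation_matrix(m)
  expect_equal(diag(cm$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cm$r["a", "b"], -1)
  expect_equal(cm$r["c", "d"], 1)        # NA -> 0 makes them identical
  expect_equal(cm$r, t(cm$r), tolerance = 1e-12)
  # pairwise-complete policy drops the NA row instead
  cm2 <- correlation_matrix(m, na_policy = "complete")
  expect_equal(cm2$r["c", "d"], 1)       # both remaining points collinear
  # constant vector warns and yields NA
  expect_warning(cmc <- correlation_matrix(cbind(x = c(1, 2, 3),
                                                 y = c(5, 5, 5))),
                 "constant")
  expect_true(is.na(cmc$r["x", "y"]))
  expect_error(correlation_matrix(m[, 1, drop = FALSE]), ">= 2")
  expect_error(correlation_matrix(m[1:2, ]), ">= 3")
})

test_that("duplicate profiles cluster together, away from anticorrelated", {
  base <- sin(seq(0.1, 6, length.out = 50))
  m <- cbind(copy1 = base, anti = -base, copy2 = base)
  cm <- correlation_matrix(m)
  ord <- cm$labels[cm$cluster_order]
  pos <- match(c("copy1", "copy2"), ord)
  expect_equal(abs(diff(pos)), 1)        # the copies are adjacent
  # position-axis correlations work on the rows of the same layout
  cp <- correlation_matrix(cbind(m, m), axis = "position")
  expect_equal(dim(cp$r), c(50, 50))
})

test_that("property correlations are rank-invariant and need alignment", {
  g <- matrix(seq(0.01, 1, length.out = 100), ncol = 1,
              dimnames = list(1:100, "PDZ"))
  f <- cbind(same = g[, 1], mono = exp(3 * g[, 1]), noise = rev(g[, 1]))
  rownames(f) <- 1:100
  rho <- property_correlation(g, f)
  expect_equal(rho["PDZ", "same"], 1)
  expect_equal(rho["PDZ", "mono"], 1)    # monotone transform preserves rank
  expect_equal(rho["PDZ", "noise"], -1)
  expect_error(property_correlation(g[1:2, , drop = FALSE],
                                    f[1:2, , drop = FALSE]), "fewer than 3")
  # independent noise rarely correlates at n = 435
  ok <- vapply(1:40, function(s) {
    withr::with_seed(s, {
      gn <- matrix(rnorm(435), dimnames = list(1:435, "d"))
      fn <- matrix(rnorm(435), dimnames = list(1:435, "f"))
      abs(property_correlation(gn, fn)[1, 1]) < 0.12
    })
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("Hamming criterion counts disagreeing bits over joint support", {
  hd <- hamming_differential(c(1, 0, 1), c(1, 1, 0))
  expect_equal(hd$n_diff, 2)
  expect_equal(hd$n_compared, 3)
  expect_equal(hamming_differential(c(1, 0, 1), c(1, 0, 1))$n_diff, 0)
  # NA in either profile removes the site from the comparison
  hdna <- hamming_differential(c(1, NA, 1, 0), c(0, 1, NA, 0))
  expect_equal(hdna$n_compared, 2)
  expect_equal(hdna$n_diff, 1)
  expect_true(all(is.na(hdna$flag[2:3])))
  # the printed-percentage convention: 69 differential of 229 is "30%"
  a <- rep(c(1, 0), length.out = 229)
  b <- a
  b[1:69] <- 1 - b[1:69]
  hp <- hamming_differential(a, b)
  expect_equal(hp$n_diff, 69)
  expect_equal(hp$percent_string, "30%")
  expect_error(hamming_differential(c(1, 0), c(1, 0, 1)), "lengths")
})

test_that("Euclidean site distance is the absolute z difference", {
  ed <- euclidean_difference(c(1, 0, -1), c(1, 2, 1))
  expect_equal(ed$d, c(0, 2, 2))
  expect_equal(euclidean_difference(c(1, 2), c(1, 2))$d, c(0, 0))
  # symmetry
  za <- rnorm(20)
  zb <- rnorm(20)
  expect_equal(euclidean_difference(za, zb), euclidean_difference(zb, za))
  expect_error(euclidean_difference(1:3, 1:4), "lengths")
})

test_that("moving averages match a brute-force oracle and call regions", {
  # window 1 is the identity
  za <- rnorm(30)
  zb <- rnorm(30)
  s1 <- smoothed_zdiff(za, zb, window = 1)
  expect_equal(s1$smoothed, za - zb)
  # constant difference: degenerate (SD 0), no regions
  sc <- smoothed_zdiff(rep(2, 31), rep(1.5, 31), window = 15)
  expect_true(sc$degenerate)
  expect_equal(nrow(sc$regions), 0)
  expect_true(all(abs(sc$smoothed[8:24] - 0.5) < 1e-12))
  # a single central spike produces one region containing the spike
  zs <- rep(0, 31)
  zs[16] <- 10
  sp <- smoothed_zdiff(zs, rep(0, 31), window = 15)
  expect_equal(nrow(sp$regions), 1)
  expect_true(sp$regions$start <= 16 && sp$regions$end >= 16)
  # oracle equivalence vs zoo::rollapply on NA-bearing inputs up to n = 100
  skip_if_not_installed("zoo")
  for (s in 1:5) {
    withr::with_seed(300 + s, {
      n <- sample(40:100, 1)
      a <- rnorm(n)
      b <- rnorm(n)
      a[sample(n, 6)] <- NA
      w <- sample(c(7, 15, 21), 1)
    })
    got <- smoothed_zdiff(a, b, window = w)$smoothed
    oracle <- zoo::rollapply(a - b, width = w, partial = TRUE, fill = NA,
                             FUN = function(v) {
                               if (sum(!is.na(v)) >= min(8, w)) {
                                 mean(v, na.rm = TRUE)
                               } else NA_real_
                             })
    expect_equal(got, as.numeric(oracle))
  }
  expect_error(smoothed_zdiff(za, zb, window = 4), "odd")
  expect_error(smoothed_zdiff(za, zb, window = 31), "length")
})

test_that("rank-sum comparisons agree with enumeration and wilcox.test", {
  rs <- ranksum_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$statistic, 0)
  same <- ranksum_compare(1:4, 1:4)
  expect_gte(same$p.value, 0.99)
  # exact mode equals the brute-force permutation distribution
  withr::with_seed(42, {
    a <- rnorm(5)
    b <- rnorm(5) + 0.5
  })
  rs_ex <- ranksum_compare(a, b, alternative = "two.sided")
  pooled <- c(a, b)
  u_of <- function(xa, xb) sum(outer(xa, xb, ">")) +
    0.5 * sum(outer(xa, xb, "=="))
  us <- apply(combn(10, 5), 2,
              function(idx) u_of(pooled[idx], pooled[-idx]))
  u_obs <- u_of(a, b)
  p_brute <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  expect_equal(rs_ex$p.value, p_brute, tolerance = 1e-12)
  expect_equal(rs_ex$statistic, u_obs)
  # tie-free exact p also matches wilcox.test's exact p
  wt <- wilcox.test(a, b, exact = TRUE)
  expect_equal(rs_ex$p.value, wt$p.value, tolerance = 1e-12)
  # approximate path tracks wilcox.test's normal approximation
  withr::with_seed(43, {
    big_a <- rnorm(30)
    big_b <- rnorm(40) + 0.4
  })
  rs_ap <- ranksum_compare(big_a, big_b)
  wt_ap <- wilcox.test(big_a, big_b, exact = FALSE, correct = FALSE)
  expect_equal(rs_ap$p.value, wt_ap$p.value, tolerance = 1e-9)
  expect_error(ranksum_compare(numeric(0), 1:3), "empty")
})

test_that("scores land in the PDB B-factor column and round-trip", {
  fp_in <- withr::local_tempfile(fileext = ".pdb")
  fp_out <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(fp_in, resno = c(6, 7, 8))
  scores <- c(`7` = 1.5, `8` = -0.25)
  expect_message(write_scores_to_structure(scores, fp_in, fp_out),
                 "sentinel")
  back <- bio3d::read.pdb(fp_out)
  expect_true(all(back$atom$b[back$atom$resno == 7] == 1.50))
  expect_true(all(back$atom$b[back$atom$resno == 8] == -0.25))
  # residue 6 has no score: sentinel
  expect_true(all(back$atom$b[back$atom$resno == 6] == -99.0))
  # round trip at 2 decimals
  scores2 <- c(`6` = 0.123, `7` = 2.718, `8` = -1.414)
  write_scores_to_structure(scores2, fp_in, fp_out)
  back2 <- bio3d::read.pdb(fp_out)
  got <- tapply(back2$atom$b, back2$atom$resno, unique)
  expect_equal(as.numeric(got[c("6", "7", "8")]),
               round(scores2, 2), ignore_attr = TRUE)
  expect_error(write_scores_to_structure(scores, "no-such-file.pdb", fp_out),
               "PDB")
})
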