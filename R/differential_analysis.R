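## Differential permissibility analysis: correlation matrices with
## clustering, property correlations, Hamming/Euclidean differential-site
## metrics, moving-average region calling, rank-sum comparisons, and
## structure annotation.

#' Assemble profiles into a positions-by-datasets matrix
#'
#' @param profiles named list of `dip_profile`s on a common position grid
#' @return numeric matrix, rownames = `aa_pos`, colnames = dataset labels
#' @export
profile_matrix <- function(profiles) {
  aa <- profiles[[1]]$aa_pos
  for (p in profiles) {
    if (!identical(p$aa_pos, aa)) stop_invalid("position grids differ")
  }
  m <- vapply(profiles, profile_values, numeric(length(aa)))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(profiles))
  rownames(m) <- aa
  colnames(m) <- names(profiles)
  m
}

#' Correlation matrix of datasets or positions, with clustering
#'
#' Pearson (default) correlations between dataset columns
#' (`axis = "dataset"`) or position rows (`axis = "position"`). Under the
#' default `na_policy = "zero"` NA values are replaced by 0 before
#' correlating (removing those positions entirely would add sampling noise
#' when comparing datasets); `"complete"` uses pairwise-complete
#' observations. Constant vectors produce NA correlations with a warning.
#' Average-linkage hierarchical clustering on the distance `1 - r` provides
#' `cluster_order`.
#'
#' @param x positions-by-datasets matrix (see [profile_matrix()])
#' @param axis correlate `"dataset"` columns or `"position"` rows
#' @param method `"pearson"` (default) or `"spearman"`
#' @param na_policy `"zero"` (default) or `"complete"`
#' @return a `dip_cormat`: list with `r`, `labels`, `cluster_order`
#' @export
correlation_matrix <- function(x, axis = c("dataset", "position"),
                               method = c("pearson", "spearman"),
                               na_policy = c("zero", "complete")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  na_policy <- match.arg(na_policy)
  m <- as.matrix(x)
  if (axis == "position") m <- t(m)
  if (ncol(m) < 2) stop_invalid("need >= 2 vectors to correlate")
  if (nrow(m) < 3) stop_invalid("need >= 3 points per vector")
  if (na_policy == "zero") {
    m[is.na(m)] <- 0
    r <- suppressWarnings(stats::cor(m, method = method))
  } else {
    r <- suppressWarnings(stats::cor(m, method = method,
                                     use = "pairwise.complete.obs"))
  }
  if (anyNA(r)) {
    warning("constant vector(s): correlations set to NA", call. = FALSE)
  }
  if (is.null(colnames(m))) colnames(r) <- rownames(r) <- seq_len(ncol(m))
  d <- 1 - r
  d[is.na(d)] <- 2          # maximal dissimilarity for degenerate vectors
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  structure(list(r = r, labels = colnames(r), cluster_order = hc$order,
                 hclust = hc),
            class = "dip_cormat")
}

#' Spearman correlations between mean profiles and protein properties
#'
#' Rank correlations (average ranks on ties) between each domain's mean
#' permissibility profile and each protein property, over the jointly
#' complete, trimmed positions.
#'
#' @param mean_profiles positions-by-domains matrix (rownames = `aa_pos`) or
#'   named list of mean `dip_profile`s
#' @param features a `dip_features` (or positions-by-features matrix with
#'   `aa_pos` rownames)
#' @param method correlation method, default `"spearman"`
#' @return matrix domains x features of correlations, with attribute
#'   `categories` carried over from the feature table
#' @export
property_correlation <- function(mean_profiles, features,
                                 method = "spearman") {
  if (is.list(mean_profiles) && !is.matrix(mean_profiles) &&
      !is.data.frame(mean_profiles)) {
    mean_profiles <- profile_matrix(mean_profiles)
  }
  g <- as.matrix(mean_profiles)
  f <- as.matrix(features)
  common <- intersect(rownames(g), rownames(f))
  g <- g[common, , drop = FALSE]
  f <- f[common, , drop = FALSE]
  ok <- stats::complete.cases(g) & stats::complete.cases(f)
  if (sum(ok) < 3) stop_invalid("fewer than 3 aligned complete positions")
  rho <- stats::cor(g[ok, , drop = FALSE], f[ok, , drop = FALSE],
                    method = method)
  structure(rho, categories = attr(features, "categories"))
}

#' Differential sites by the Hamming criterion
#'
#' Compares two binarized profiles position-wise: over positions non-NA in
#' both, a site is differential where the bits disagree (XOR). Reports the
#' per-site flags, the differential count over the compared count, and the
#' integer percentage (e.g. 69/229 renders as "30%").
#'
#' @param binA,binB binary `dip_profile`s or 0/1/NA vectors of equal length
#' @return a `dip_diffset`: list with `aa_pos`, `flag`
#'   (`"differential"`/`"concordant"`/NA), `n_diff`, `n_compared`, `percent`
#'   and `percent_string`
#' @export
hamming_differential <- function(binA, binB) {
  a <- profile_values(binA)
  b <- profile_values(binB)
  if (length(a) != length(b)) stop_invalid("profile lengths differ")
  compared <- !is.na(a) & !is.na(b)
  flag <- rep(NA_character_, length(a))
  flag[compared] <- ifelse(a[compared] != b[compared],
                           "differential", "concordant")
  n_diff <- sum(flag == "differential", na.rm = TRUE)
  n_compared <- sum(compared)
  pct <- if (n_compared > 0) round_half_up(100 * n_diff / n_compared, 0)
         else NA_real_
  structure(list(aa_pos = profile_positions(binA), flag = flag,
                 n_diff = n_diff, n_compared = n_compared, percent = pct,
                 percent_string = sprintf("%d%%", as.integer(pct))),
            class = "dip_diffset")
}

#' Per-position Euclidean difference of two z-profiles
#'
#' In one dimension the Euclidean distance at a site is `|zA(i) - zB(i)|`;
#' NA where either profile is NA.
#'
#' @param zA,zB z-scored `dip_profile`s or numeric vectors of equal length
#' @return list with `aa_pos`, `d` (per-position distance), `mean` and
#'   `norm` (Euclidean norm over non-NA positions)
#' @export
euclidean_difference <- function(zA, zB) {
  a <- profile_values(zA)
  b <- profile_values(zB)
  if (length(a) != length(b)) stop_invalid("profile lengths differ")
  d <- abs(a - b)
  list(aa_pos = profile_positions(zA), d = d,
       mean = mean(d, na.rm = TRUE),
       norm = sqrt(sum(d^2, na.rm = TRUE)))
}

#' Moving-average of a z-score difference with region calling
#'
#' Centered moving average (default window 15 residues) of `zA - zB`. Each
#' window's mean uses the available (in-range, non-NA) values only and is NA
#' below `min_values` contributing values (windows narrower than
#' `min_values`, e.g. `window = 1`, require all their values instead).
#' `sd_threshold` is the sample SD of the smoothed series (or of the raw
#' difference with `sd_source = "raw"`); regions are the maximal runs where
#' the smoothed series exceeds `+1` SD (one-sided, matching the shading of
#' positive excursions; `two_sided = TRUE` uses `|value| > SD`).
#'
#' @param zA,zB z-scored `dip_profile`s or numeric vectors
#' @param window odd window width, at most the profile length
#' @param min_values minimum contributing values per window
#' @param sd_source SD of the `"smoothed"` (default) or `"raw"` series
#' @param two_sided call regions on both signs
#' @return a `dip_smoothed`: list with `aa_pos`, `smoothed`, `sd_threshold`,
#'   `regions` (data frame `start`, `end` in `aa_pos` units), `degenerate`
#' @export
smoothed_zdiff <- function(zA, zB, window = 15, min_values = 8,
                           sd_source = c("smoothed", "raw"),
                           two_sided = FALSE) {
  sd_source <- match.arg(sd_source)
  a <- profile_values(zA)
  b <- profile_values(zB)
  if (length(a) != length(b)) stop_invalid("profile lengths differ")
  n <- length(a)
  if (window %% 2 == 0) stop_invalid("window must be odd")
  if (window > n) stop_invalid("window exceeds profile length")
  diff <- a - b
  half <- (window - 1L) %/% 2L
  need <- min(min_values, window)
  sm <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    vals <- diff[lo:hi]
    k <- sum(!is.na(vals))
    if (k >= need) sm[i] <- mean(vals, na.rm = TRUE)
  }
  src <- if (sd_source == "smoothed") sm else diff
  sd_thr <- stats::sd(src, na.rm = TRUE)
  degenerate <- is.na(sd_thr) || sd_thr == 0
  aa <- profile_positions(zA)
  regions <- data.frame(start = integer(0), end = integer(0))
  if (!degenerate) {
    over <- if (two_sided) abs(sm) > sd_thr else sm > sd_thr
    over[is.na(over)] <- FALSE
    r <- rle(over)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    regions <- data.frame(start = aa[starts[keep]], end = aa[ends[keep]])
  }
  structure(list(aa_pos = aa, smoothed = sm, sd_threshold = sd_thr,
                 regions = regions, degenerate = degenerate,
                 window = window),
            class = "dip_smoothed")
}

#' Unpaired Wilcoxon rank-sum (Mann-Whitney) comparison
#'
#' The statistic is `U`, the number of (a, b) pairs with `a > b` plus half
#' the ties. For `nA, nB <= 8` (unless overridden) the p-value is computed
#' by exact enumeration of all label assignments of the pooled values (ties
#' handled naturally); otherwise by the tie-corrected normal approximation
#' without continuity correction. `alternative = "less"` tests that `a`
#' tends below `b`.
#'
#' @param a,b non-empty numeric vectors
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`
#' @param exact force (TRUE) or suppress (FALSE) enumeration; default chooses
#'   by sample size
#' @return list with `statistic` (U), `p.value`, `method`, `alternative`
#' @export
ranksum_compare <- function(a, b,
                            alternative = c("two.sided", "less", "greater"),
                            exact = NULL) {
  alternative <- match.arg(alternative)
  if (length(a) == 0 || length(b) == 0) stop_invalid("empty input")
  na <- length(a); nb <- length(b)
  u_stat <- function(xa, xb) {
    r <- rank(c(xa, xb))
    sum(r[seq_along(xa)]) - length(xa) * (length(xa) + 1) / 2
  }
  u <- u_stat(a, b)
  if (is.null(exact)) exact <- na <= 8 && nb <= 8
  if (exact) {
    pooled <- c(a, b)
    combs <- utils::combn(na + nb, na)
    us <- apply(combs, 2, function(idx) {
      u_stat(pooled[idx], pooled[-idx])
    })
    p_le <- mean(us <= u + 1e-9)
    p_ge <- mean(us >= u - 1e-9)
    p <- switch(alternative,
                less = p_le, greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    method <- "exact enumeration"
  } else {
    nn <- na + nb
    ties <- table(c(a, b))
    mu <- na * nb / 2
    sig2 <- na * nb / 12 *
      ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    z <- (u - mu) / sqrt(sig2)
    p <- switch(alternative,
                less = stats::pnorm(z),
                greater = stats::pnorm(z, lower.tail = FALSE),
                two.sided = min(1, 2 * stats::pnorm(-abs(z))))
    method <- "normal approximation with tie correction"
  }
  list(statistic = u, p.value = p, method = method,
       alternative = alternative)
}

#' Write per-residue scores into the B-factor column of a PDB file
#'
#' Every ATOM record of a mapped residue receives that residue's score
#' (PDB format renders B-factors at 2 decimals); residues absent from the
#' score map receive the sentinel. The structure is read and written with
#' bio3d.
#'
#' @param scores named numeric vector (names = residue numbers) or data
#'   frame with columns `aa_pos`, `score`
#' @param pdb_file input PDB path
#' @param out_file output PDB path
#' @param chain optional chain id restriction for the mapping
#' @param sentinel B-factor for unmapped or NA residues
#' @return invisibly, a data frame of the per-residue B-factors written;
#'   the number of unmapped residues is reported with a message
#' @export
write_scores_to_structure <- function(scores, pdb_file, out_file,
                                      chain = NULL, sentinel = -99.0) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$score, scores$aa_pos)
  }
  pdb <- tryCatch(bio3d::read.pdb(pdb_file),
                  error = function(e) {
                    stop_invalid("malformed PDB file '", pdb_file, "': ",
                                 conditionMessage(e))
                  })
  atom <- pdb$atom
  sel <- rep(TRUE, nrow(atom))
  if (!is.null(chain)) sel <- atom$chain %in% chain
  b <- atom$b
  idx <- match(as.character(atom$resno), names(scores))
  mapped <- sel & !is.na(idx) & !is.na(scores[idx])
  b[sel] <- sentinel
  b[mapped] <- scores[idx[mapped]]
  pdb$atom$b <- b
  unmapped <- unique(atom$resno[sel & !mapped])
  if (length(unmapped) > 0) {
    message(length(unmapped), " residue(s) without a score received the ",
            "sentinel B-factor ", sentinel)
  }
  bio3d::write.pdb(pdb, file = out_file)
  invisible(unique(data.frame(resno = atom$resno[sel], b = b[sel])))
}
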