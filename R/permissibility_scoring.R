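## Permissibility scoring: per-replicate enrichment F, replicate mean G,
## z-scores, near-zero trimming and binarization.
##
## F(i, j) = r_SE(i)/t_SE - r_NSE(i)/t_NSE for replicate j, with t the total
## productive reads of the pool. Positions lacking reads in either pool are
## NA and excluded from every downstream step except the dataset/position
## correlation analyses, whose NA-as-zero policy lives in the differential
## module.

.profile <- function(aa_pos, score, type, replicate = NA_integer_,
                     domain = NA_character_, extra = NULL) {
  out <- data.frame(aa_pos = as.integer(aa_pos), score = as.numeric(score))
  if (!is.null(extra)) out <- cbind(out, extra)
  structure(out, type = type, replicate = replicate, domain = domain,
            class = c("dip_profile", "data.frame"))
}

#' Per-replicate permissibility enrichment
#'
#' Computes `F(i) = r_SE(i)/t_SE - r_NSE(i)/t_NSE` over the common position
#' grid of the two pools. Positions with zero reads in either pool are NA:
#' only positions with reads in both samples enter enrichment.
#'
#' @param se,nse `dip_counts` for the surface-expressed and
#'   not-surface-expressed pools of one replicate/domain
#' @return a `dip_profile` (type `"enrichment"`) with columns `aa_pos`,
#'   `score`
#' @export
enrichment <- function(se, nse) {
  if (se$t == 0 || nse$t == 0) stop_invalid("empty pool (t = 0)")
  if (!identical(se$aa_pos, nse$aa_pos)) {
    stop_invalid("SE and NSE tables are on different position grids")
  }
  f <- se$count / se$t - nse$count / nse$t
  f[!(se$count > 0 & nse$count > 0)] <- NA_real_
  .profile(se$aa_pos, f, "enrichment",
           replicate = se$replicate, domain = se$domain)
}

#' Mean permissibility over replicates
#'
#' `G(i)` is the mean of `F(i)` over the replicates where `F(i)` is defined;
#' NA only where no replicate has a value. With `strict = TRUE` the sum of
#' available values is divided by the total replicate count `n` instead
#' (positions missing in one replicate are then pulled toward 0).
#'
#' @param profiles list of enrichment `dip_profile`s for one domain
#' @param strict divide by total replicate count rather than by the number of
#'   non-NA replicates
#' @return a `dip_profile` (type `"mean"`) with columns `aa_pos`, `score`,
#'   `n_used`
#' @export
mean_profile <- function(profiles, strict = FALSE) {
  if (length(profiles) == 0) stop_invalid("empty profile list")
  aa <- profiles[[1]]$aa_pos
  for (p in profiles) {
    if (!identical(p$aa_pos, aa)) stop_invalid("position grids differ")
  }
  m <- vapply(profiles, function(p) p$score, numeric(length(aa)))
  if (length(profiles) == 1) m <- matrix(m, ncol = 1)
  n_used <- rowSums(!is.na(m))
  denom <- if (strict) length(profiles) else n_used
  g <- rowSums(m, na.rm = TRUE) / denom
  g[n_used == 0] <- NA_real_
  .profile(aa, g, "mean", domain = attr(profiles[[1]], "domain"),
           extra = data.frame(n_used = as.integer(n_used)))
}

#' Z-score a mean permissibility profile
#'
#' Centers and scales the non-NA values to mean 0 and sample SD 1
#' (denominator n - 1); NA positions are preserved and excluded from the
#' moments.
#'
#' @param profile a `dip_profile` (or numeric vector)
#' @return a `dip_profile` (type `"zscore"`)
#' @export
zscore_profile <- function(profile) {
  v <- profile_values(profile)
  ok <- !is.na(v)
  if (sum(ok) < 2) stop_invalid("need >= 2 non-NA positions to z-score")
  s <- stats::sd(v[ok])
  if (s == 0) stop_invalid("constant profile cannot be z-scored")
  z <- (v - mean(v[ok])) / s
  .profile(profile_positions(profile), z, "zscore",
           domain = attr(profile, "domain"))
}

profile_values <- function(x) {
  if (inherits(x, "dip_profile")) x$score else as.numeric(x)
}

profile_positions <- function(x) {
  if (inherits(x, "dip_profile")) x$aa_pos else seq_along(x)
}

#' Near-zero trimming mask
#'
#' A position is kept iff the fraction of datasets whose value lies in the
#' open band `(-eps, +eps)` — with NA counted as in-band — does not exceed
#' `max_fraction`. The presets used in the analyses are `6/16` for the
#' dataset/position correlation matrices and `1/2` for the property
#' correlations.
#'
#' @param values matrix or data frame, positions x datasets
#' @param eps half-width of the near-zero band
#' @param max_fraction largest tolerated in-band fraction
#' @return logical keep-mask over positions
#' @export
trim_near_zero <- function(values, eps = 1e-4, max_fraction = 6 / 16) {
  if (eps <= 0) stop_invalid("eps must be > 0")
  if (max_fraction < 0 || max_fraction > 1) {
    stop_invalid("max_fraction must be in [0, 1]")
  }
  m <- as.matrix(values)
  in_band <- is.na(m) | abs(m) < eps
  rowMeans(in_band) <= max_fraction
}

#' Binarize a permissibility profile
#'
#' 1 (permissive) where the value exceeds `threshold`, 0 (not permissive)
#' where it does not; NA preserved. The default cut at 0 calls a site
#' permissive when it is enriched toward the surface-expressed pool.
#'
#' @param profile a `dip_profile` or numeric vector
#' @param threshold finite cut-point
#' @return a `dip_profile` (type `"binary"`) with values in \{0, 1, NA\}
#' @export
binarize <- function(profile, threshold = 0) {
  if (!is.finite(threshold)) stop_invalid("threshold must be finite")
  v <- profile_values(profile)
  b <- ifelse(is.na(v), NA_real_, as.numeric(v > threshold))
  .profile(profile_positions(profile), b, "binary",
           domain = attr(profile, "domain"))
}

#' Coverage report
#'
#' Renders the number of scored positions out of the total as a percentage,
#' rounded half-up at the requested precision (e.g. 170/293 at one decimal is
#' "58.0%", 293/435 at zero decimals is "67%").
#'
#' @param n_scored count of scored positions, or a `dip_profile` whose
#'   non-NA positions are counted
#' @param n_total total candidate positions (> 0, >= `n_scored`)
#' @param digits decimals of the rendered percentage
#' @return list with `n_scored`, `n_total`, `percent` (numeric, rounded
#'   half-up) and `percent_string`
#' @export
coverage_report <- function(n_scored, n_total, digits = 1) {
  if (inherits(n_scored, "dip_profile")) {
    n_scored <- sum(!is.na(n_scored$score))
  }
  if (n_total <= 0) stop_invalid("n_total must be > 0")
  if (n_scored > n_total) stop_invalid("n_scored exceeds n_total")
  pct <- 100 * n_scored / n_total
  list(n_scored = as.integer(n_scored), n_total = as.integer(n_total),
       percent = round_half_up(pct, digits),
       percent_string = percent_string(pct, digits))
}

#' Write / read a profile TSV
#'
#' Columns `aa_pos`, `value`, `na_flag`, `replicate`, `domain`, `type`.
#'
#' @param profile a `dip_profile`
#' @param path file path
#' @return the path (write) or a `dip_profile` (read)
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(aa_pos = profile$aa_pos,
                   value = ifelse(is.na(profile$score), 0, profile$score),
                   na_flag = as.integer(is.na(profile$score)),
                   replicate = attr(profile, "replicate"),
                   domain = attr(profile, "domain"),
                   type = attr(profile, "type"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  v <- df$value
  v[df$na_flag == 1] <- NA_real_
  .profile(df$aa_pos, v, df$type[1], replicate = df$replicate[1],
           domain = df$domain[1])
}
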