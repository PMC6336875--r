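## Flow-cytometry statistics for the resting-membrane-potential (RMP) and
## light-modulation assays: arcsinh transform, sequential gating, the
## lower-50% wild-type function gate, one-sided variant-vs-control tests,
## and the light/dark chi-squared dissimilarity with photobleaching
## normalization.

#' Hyperbolic-arcsine transform of fluorescence channels
#'
#' `x -> asinh(x / cofactor)` applied to the named channels (default: the
#' voltage-dye channel only). The cofactor sets the linear-to-log crossover;
#' 150 is a common cytometry default.
#'
#' @param events a `dip_flow` data frame
#' @param cofactor positive scale factor
#' @param channels channel names to transform
#' @return the event table with transformed channels
#' @export
arcsinh_transform <- function(events, cofactor = 150, channels = "dye") {
  if (cofactor <= 0) stop_invalid("cofactor must be > 0")
  for (ch in channels) {
    if (!ch %in% names(events)) stop_invalid("unknown channel '", ch, "'")
    events[[ch]] <- asinh(events[[ch]] / cofactor)
  }
  events
}

#' Gate constructors
#'
#' `gate_rect` keeps events inside rectangle bounds on one or two channels
#' (inclusive; `-Inf`/`Inf` for open sides). `gate_quantile` keeps events
#' below or above a data-derived quantile cut of one channel; the cut is
#' computed from `reference` events when supplied to [apply_gates()],
#' otherwise from the gated sample itself.
#'
#' @param channels one or two channel names
#' @param min,max numeric bounds aligned with `channels`
#' @param channel channel name for the quantile gate
#' @param q quantile in (0, 1)
#' @param side keep events `"below"` or `"above"` the cut
#' @param reference logical: derive the cut from the reference sample
#' @return a gate object for [gate_spec()]
#' @export
gate_rect <- function(channels, min = -Inf, max = Inf) {
  structure(list(type = "rect", channels = channels,
                 min = rep_len(min, length(channels)),
                 max = rep_len(max, length(channels))),
            class = "dip_gate")
}

#' @rdname gate_rect
#' @export
gate_quantile <- function(channel, q, side = c("below", "above"),
                          reference = FALSE) {
  side <- match.arg(side)
  if (q <= 0 || q >= 1) stop_invalid("q must be in (0, 1)")
  structure(list(type = "quantile", channels = channel, q = q, side = side,
                 reference = reference),
            class = "dip_gate")
}

#' Ordered gating specification
#'
#' @param ... gates from [gate_rect()] / [gate_quantile()], applied in order
#' @return a `dip_gatespec`
#' @export
gate_spec <- function(...) {
  gates <- list(...)
  for (g in gates) {
    if (!inherits(g, "dip_gate")) stop_invalid("not a gate object")
  }
  structure(gates, class = "dip_gatespec")
}

#' Apply a sequential gating specification
#'
#' Gates are applied in order; event order and acquisition indices are
#' preserved. Quantile gates marked `reference = TRUE` derive their cut from
#' `reference_events` (e.g. the wild-type sample); others from the current
#' sample.
#'
#' @param events a `dip_flow` data frame
#' @param spec a `dip_gatespec`
#' @param reference_events optional reference event table for data-derived
#'   cuts
#' @return the surviving subset of `events`
#' @export
apply_gates <- function(events, spec, reference_events = NULL) {
  for (g in spec) {
    for (ch in g$channels) {
      if (!ch %in% names(events)) stop_invalid("unknown channel '", ch, "'")
    }
    if (g$type == "rect") {
      keep <- rep(TRUE, nrow(events))
      for (i in seq_along(g$channels)) {
        v <- events[[g$channels[i]]]
        keep <- keep & v >= g$min[i] & v <= g$max[i]
      }
    } else {
      src <- if (isTRUE(g$reference)) {
        if (is.null(reference_events)) {
          stop_invalid("gate requires reference_events")
        }
        reference_events[[g$channels]]
      } else {
        events[[g$channels]]
      }
      cut <- stats::quantile(src, g$q, names = FALSE)
      v <- events[[g$channels]]
      keep <- if (g$side == "below") v < cut else v >= cut
    }
    events <- events[keep, , drop = FALSE]
  }
  events
}

#' Default whole-cell / singlet / transfection gating chain
#'
#' Approximates the assay's gating: scatter-area rectangle for whole cells,
#' FSC area-vs-height band for singlets, then a marker-positive quantile
#' gate for transfected cells.
#'
#' @param marker_q lower marker quantile excluded as untransfected
#' @return a `dip_gatespec`
#' @export
default_gates <- function(marker_q = 0.25) {
  gate_spec(
    gate_rect(c("fsc_a", "ssc_a"), min = c(1e4, 5e3), max = c(3e5, 3e5)),
    gate_rect("fsc_h", min = 1e3),
    gate_quantile("marker", q = marker_q, side = "above"))
}

#' Percent of hyperpolarized cells relative to the wild-type gate
#'
#' The functional gate is the lower 50% of the wild-type dye histogram: the
#' threshold is the wild-type median, and the score is the percentage of
#' variant events strictly below it (more hyperpolarized = lower dye
#' signal). Wild type scored against itself gives 50% up to discreteness.
#'
#' @param variant_events,wt_events gated, transformed `dip_flow` tables
#' @param channel dye channel name
#' @return percentage in `[0, 100]`
#' @export
hyperpolarized_percent <- function(variant_events, wt_events,
                                   channel = "dye") {
  if (nrow(variant_events) == 0 || nrow(wt_events) == 0) {
    stop_invalid("empty event set")
  }
  thr <- stats::median(wt_events[[channel]])
  100 * mean(variant_events[[channel]] < thr)
}

#' One-sided Welch t test of variant function against control
#'
#' Compares replicate-level percent-hyperpolarized scores of a variant with
#' the control (no-channel) scores; `alternative = "greater"` tests for
#' retained function.
#'
#' @param variant_means,control_means replicate score vectors (>= 2 each)
#' @param alternative test direction
#' @return list with `statistic` (t), `p.value`, `df`, `method`
#' @export
function_test <- function(variant_means, control_means,
                          alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(variant_means) < 2 || length(control_means) < 2) {
    stop_invalid("need >= 2 replicates per group")
  }
  ht <- stats::t.test(variant_means, control_means,
                      alternative = alternative)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       df = unname(ht$parameter), method = "Welch two-sample t test")
}

#' Pearson chi-squared statistic of a 2x2 in/out-of-gate table
#'
#' @param in_a,n_a in-gate and total event counts of condition A
#' @param in_b,n_b in-gate and total event counts of condition B
#' @return list with `chi2` and the 2x2 `table`
#' @export
chi2_2x2 <- function(in_a, n_a, in_b, n_b) {
  tab <- matrix(c(in_a, n_a - in_a, in_b, n_b - in_b), nrow = 2,
                dimnames = list(c("in_gate", "out_gate"), c("A", "B")))
  if (any(tab < 0)) stop_invalid("negative cell counts")
  chi2 <- if (in_a == in_b && n_a == n_b) 0 else
    unname(suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$statistic))
  list(chi2 = chi2, table = tab)
}

#' Light/dark dissimilarity of the hyperpolarized fraction
#'
#' A custom gate containing the `q` (default 15%) most hyperpolarized cells
#' — the lowest dye intensities — is derived from the non-illuminated (dark)
#' sample; events of both samples falling into that gate are counted and
#' compared with the Pearson chi-squared statistic (no continuity
#' correction) on the 2x2 in/out-of-gate by dark/light table.
#'
#' @param dark,light `dip_flow` event tables (gated, same channels)
#' @param q hyperpolarized-gate quantile in (0, 1)
#' @param channel dye channel name
#' @return list with `chi2`, `table`, `threshold`, `q`, and the total event
#'   count `n_total`
#' @export
light_dissimilarity <- function(dark, light, q = 0.15, channel = "dye") {
  if (q <= 0 || q >= 1) stop_invalid("q must be in (0, 1)")
  if (nrow(dark) == 0 || nrow(light) == 0) stop_invalid("empty event set")
  thr <- stats::quantile(dark[[channel]], q, names = FALSE)
  in_d <- sum(dark[[channel]] <= thr)
  in_l <- sum(light[[channel]] <= thr)
  res <- chi2_2x2(in_d, nrow(dark), in_l, nrow(light))
  c(res, list(threshold = thr, q = q, n_total = nrow(dark) + nrow(light)))
}

#' Normalize per-challenge dissimilarities and average
#'
#' The raw Pearson chi-squared grows proportionally with the event count, so
#' per-challenge values are divided by their total event counts
#' (Cramer-style scale removal), which also corrects for the smaller
#' effective counts of photobleached late-acquisition challenges. When a
#' matched wild-type reference is supplied, each normalized value is further
#' divided by the wild-type's normalized value for that challenge. The mean
#' over challenges is the variant's dissimilarity score.
#'
#' @param per_challenge_chi2 chi-squared statistics, one per K+ challenge
#' @param per_challenge_event_counts total event counts per challenge
#' @param wt_reference_chi2 optional wild-type normalized values (chi2 / N)
#'   per challenge
#' @return a `LightDissimilarity`-style list: `chi2`, `normalized`, `mean`,
#'   `method`
#' @export
normalize_and_average <- function(per_challenge_chi2,
                                  per_challenge_event_counts,
                                  wt_reference_chi2 = NULL) {
  k <- length(per_challenge_chi2)
  if (length(per_challenge_event_counts) != k) {
    stop_invalid("challenge lists have different lengths")
  }
  norm <- per_challenge_chi2 / per_challenge_event_counts
  method <- "chi2 / N"
  if (!is.null(wt_reference_chi2)) {
    if (length(wt_reference_chi2) != k) {
      stop_invalid("challenge lists have different lengths")
    }
    norm <- norm / wt_reference_chi2
    method <- "chi2 / N, relative to matched wild type"
  }
  list(chi2 = per_challenge_chi2, normalized = norm, mean = mean(norm),
       method = method)
}

#' Many-to-one comparison of variant scores against wild type
#'
#' Dunnett's test (single-step multivariate-t adjustment, via multcomp) of
#' every variant group against the control group, or the conservative
#' Bonferroni fallback. Both methods adjust the same pooled-variance
#' many-to-one t statistics, so the Bonferroni p-values are always at least
#' as large as Dunnett's.
#'
#' @param scores named list of replicate score vectors, one per group,
#'   including the control
#' @param control name of the control group (default `"WT"`)
#' @param method `"dunnett"` (default) or `"bonferroni"`
#' @return data frame `variant`, `estimate` (difference vs control),
#'   `p_adjusted`, `method`
#' @export
many_to_one_test <- function(scores, control = "WT",
                             method = c("dunnett", "bonferroni")) {
  method <- match.arg(method)
  if (!control %in% names(scores)) stop_invalid("missing control group")
  if (any(vapply(scores, length, 1L) < 2)) {
    stop_invalid("need >= 2 replicates per group")
  }
  groups <- c(control, setdiff(names(scores), control))
  df <- data.frame(
    score = unlist(scores, use.names = FALSE),
    group = factor(rep(names(scores), vapply(scores, length, 1L)),
                   levels = groups))
  means <- vapply(scores, mean, numeric(1))
  est <- means[setdiff(groups, control)] - means[control]
  fit <- stats::aov(score ~ group, data = df)
  if (method == "dunnett") {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
    p <- as.numeric(summary(gl)$test$pvalues)
  } else {
    k <- length(groups) - 1
    mse <- sum(stats::residuals(fit)^2) / fit$df.residual
    n_c <- length(scores[[control]])
    p <- vapply(setdiff(groups, control), function(v) {
      se_v <- sqrt(mse * (1 / length(scores[[v]]) + 1 / n_c))
      t_v <- (means[v] - means[control]) / se_v
      min(1, k * 2 * stats::pt(-abs(t_v), fit$df.residual))
    }, numeric(1))
  }
  data.frame(variant = setdiff(groups, control), estimate = unname(est),
             p_adjusted = p, method = method, row.names = NULL)
}
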