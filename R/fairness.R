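# Equalized-opportunity fairness audit: subgroup true positive rates, TPR
# disparity, bootstrap Mann-Whitney subgroup testing with diagnosis-matched
# population resampling, turnaround-time odds ratios with exact tests, and
# the two-proportion superiority-trial sample-size calculator.

#' True positive rate of a cohort subset
#'
#' @param table data.frame with binary columns `y` (truth) and `y_hat`
#'   (prediction).
#' @param subset optional logical or integer row subset (default: all rows).
#' @param subset_name label used in error messages.
#' @return exact count ratio in \[0,1\].
#' @export
tpr <- function(table, subset = NULL, subset_name = "subset") {
  rows <- if (is.null(subset)) table else table[subset, , drop = FALSE]
  pos <- rows$y == 1
  if (!any(pos)) stop("no positives in ", subset_name, ": TPR undefined")
  sum(pos & rows$y_hat == 1) / sum(pos)
}

#' TPR disparity of a subgroup
#'
#' Subgroup TPR minus whole-population TPR, in \[-1, 1\]; zero when the
#' group is the whole population. Larger absolute values indicate greater
#' deviation from equalized opportunity.
#'
#' @param table cohort data.frame with `y` and `y_hat`.
#' @param group logical or integer row subset defining the sensitive group.
#' @return a `disparity_result` list: `tpr_group`, `tpr_pop`, `disparity`.
#' @export
tpr_disparity <- function(table, group) {
  tg <- tpr(table, group, "group")
  tp <- tpr(table, NULL, "population")
  structure(list(tpr_group = tg, tpr_pop = tp, disparity = tg - tp),
            class = "disparity_result")
}

#' Bootstrap test for subgroup TPR disparity
#'
#' Per iteration, `n_per_draw` patients are resampled with replacement from
#' the subgroup and `n_per_draw` diagnosis-matched patients from the study
#' population (population draws stratified to reproduce the subgroup draw's
#' label-pattern frequencies). The two TPR distributions are compared with a
#' one-sided Mann-Whitney U test of the null "subgroup TPR is not less than
#' population TPR".
#'
#' @param table cohort data.frame with `y`, `y_hat` and the label columns
#'   named in `match_cols` (used for diagnosis matching; defaults to `y`).
#' @param group logical or integer subset defining the subgroup.
#' @param n_per_draw patients per bootstrap draw.
#' @param iterations bootstrap iterations.
#' @param seed integer seed.
#' @param match_cols columns defining the diagnosis pattern to match.
#' @param positives_only draw from positives only instead of all patients.
#' @return a `disparity_result` with `p_value`, `n_boot` and the bootstrap
#'   `draws`.
#' @export
bootstrap_disparity_test <- function(table, group, n_per_draw = 200L,
                                     iterations = 20L, seed = 1L,
                                     match_cols = "y",
                                     positives_only = FALSE) {
  gidx <- if (is.logical(group)) which(group) else as.integer(group)
  if (!any(table$y[gidx] == 1)) stop("group has no positives")
  pattern <- do.call(paste, c(table[match_cols], sep = "|"))
  pool_g <- if (positives_only) gidx[table$y[gidx] == 1] else gidx
  strata <- split(seq_len(nrow(table)), pattern)
  with_seed(seed, {
    draw_tprs <- function() {
      repeat {
        g <- pool_g[sample.int(length(pool_g), n_per_draw, replace = TRUE)]
        if (any(table$y[g] == 1)) break
      }
      repeat {
        p <- vapply(g, function(i) {
          s <- strata[[pattern[i]]]
          s[sample.int(length(s), 1L)]
        }, 1L)
        if (any(table$y[p] == 1)) break
      }
      c(tpr(table, g, "bootstrap group"), tpr(table, p, "bootstrap population"))
    }
    draws <- t(vapply(seq_len(iterations), function(i) draw_tprs(), numeric(2L)))
    colnames(draws) <- c("group", "population")
    pv <- suppressWarnings(
      stats::wilcox.test(draws[, "group"], draws[, "population"],
                         alternative = "less", exact = FALSE)$p.value)
    res <- tpr_disparity(table, gidx)
    res$p_value <- pv
    res$n_boot <- iterations
    res$draws <- draws
    res
  })
}

#' Odds ratio with Fisher exact test
#'
#' Sample odds ratio `(a*d) / (b*c)` for a 2x2 table, with the
#' Haldane-Anscombe 0.5 correction on zero cells (flagged), a Woolf log-OR
#' 95% confidence interval, and the exact conditional two-sided Fisher
#' p-value.
#'
#' @param exposed counts `c(events, non_events)` in the exposed group.
#' @param reference counts `c(events, non_events)` in the reference group.
#' @param conf_level confidence level.
#' @return list with `or`, `ci`, `p`, and `corrected` (zero-cell flag).
#' @export
odds_ratio_fisher <- function(exposed, reference, conf_level = 0.95) {
  cts <- c(exposed, reference)
  if (any(cts < 0)) stop("negative counts")
  if (sum(cts) == 0) stop("all-zero table")
  m <- matrix(c(exposed, reference), 2L, 2L, byrow = TRUE)
  p <- stats::fisher.test(m)$p.value
  corrected <- any(m == 0)
  mc <- if (corrected) m + 0.5 else m
  or <- (mc[1, 1] * mc[2, 2]) / (mc[1, 2] * mc[2, 1])
  se <- sqrt(sum(1 / mc))
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-zc, zc) * se)
  list(or = or, ci = ci, p = p, corrected = corrected)
}

#' Turnaround-time odds-ratio audit over an attribute
#'
#' Dichotomizes turnaround time at `threshold` days and, for every level of
#' the attribute other than the reference level, computes the odds ratio of
#' a late report versus the reference level with [odds_ratio_fisher()].
#' P-values receive family-wise correction across the attribute's levels.
#'
#' @param meta data.frame with the attribute column and `turnaround_days`
#'   (e.g. from [cohort_metadata()]).
#' @param attribute attribute column name.
#' @param reference_level reference level (default: first level).
#' @param threshold days defining a late report.
#' @param p_adjust `"holm"` (default) or `"bonferroni"`.
#' @return data.frame with one row per non-reference level: `or`, `ci_lo`,
#'   `ci_hi`, `p`, `p_adj`.
#' @export
audit_turnaround_bias <- function(meta, attribute, reference_level = NULL,
                                  threshold = 7, p_adjust = c("holm", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  lev <- unique(as.character(meta[[attribute]]))
  if (is.null(reference_level)) reference_level <- lev[1L]
  late <- meta$turnaround_days > threshold
  ref <- meta[[attribute]] == reference_level
  rows <- lapply(setdiff(lev, reference_level), function(l) {
    sel <- meta[[attribute]] == l
    r <- odds_ratio_fisher(c(sum(late & sel), sum(!late & sel)),
                           c(sum(late & ref), sum(!late & ref)))
    data.frame(level = l, or = r$or, ci_lo = r$ci[1], ci_hi = r$ci[2], p = r$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out
}

#' Sample size for a parallel superiority trial with binary outcome
#'
#' Normal-approximation two-group formula: per-group
#' `n = (z_{1-alpha} + z_{1-power})^2 * (p1 q1 + p2 q2 / r) /
#' (p2 - p1 - margin)^2`, rounded up, with allocation ratio `r`; the total
#' over both groups is returned.
#'
#' @param p_control control-arm success proportion, in (0,1).
#' @param p_experimental experimental-arm proportion, in (0,1).
#' @param margin superiority margin (> 0).
#' @param alpha one-sided type-I error rate.
#' @param power target power.
#' @param allocation experimental-to-control allocation ratio.
#' @return total sample size (integer).
#' @export
superiority_sample_size <- function(p_control, p_experimental, margin,
                                    alpha = 0.05, power = 0.8,
                                    allocation = 1) {
  if (any(c(p_control, p_experimental) <= 0 | c(p_control, p_experimental) >= 1))
    stop("proportions must be in (0,1)")
  if (margin <= 0) stop("margin must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must be in (0,1)")
  z <- stats::qnorm(1 - alpha) + stats::qnorm(power)
  eff <- p_experimental - p_control - margin
  n_c <- z^2 * (p_control * (1 - p_control) +
                p_experimental * (1 - p_experimental) / allocation) / eff^2
  n_c <- ceiling(n_c)
  n_e <- ceiling(allocation * n_c)
  as.integer(n_c + n_e)
}
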