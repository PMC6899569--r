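significance_bin <- function(p) {
  ifelse(p <= 1e-4, "red",
         ifelse(p <= 0.01, "yellow",
                ifelse(p <= 0.05, "green", "blue")))
}

#' Two-way ANOVA for sex-by-genotype comparisons
#'
#' Fits `value ~ sex * genotype` and reports type-II sums-of-squares F
#' tests for both main effects and the interaction (type II so unbalanced
#' group sizes do not leak one factor's effect into the other's test).
#' With zero residual variance (all cells constant) F is undefined and p
#' is reported as 1.
#'
#' @param values Numeric response.
#' @param sex,genotype Factors (coerced) of the same length as `values`.
#' @return A data frame (one row per effect) with `effect`, `df`,
#'   `df_residual`, `F`, `p` and the Fig-style significance `bin`.
#' @export
two_way_anova <- function(values, sex, genotype) {
  sex <- factor(sex); genotype <- factor(genotype)
  if (length(values) != length(sex) || length(values) != length(genotype))
    stop("values and factors must have equal length")
  cells <- table(sex, genotype)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: sex=%s, genotype=%s",
                 rownames(cells)[empty[1]], colnames(cells)[empty[2]]))
  }
  if (any(cells < 2))
    stop("each design cell needs at least 2 observations")
  dat <- data.frame(value = values, sex = sex, genotype = genotype)
  fit <- lm(value ~ sex * genotype, data = dat)
  effects <- c("sex", "genotype", "sex:genotype")
  resid_var <- sum(residuals(fit)^2)
  df_res <- fit$df.residual
  if (resid_var < .Machine$double.eps * sum(values^2 + 1)) {
    # degenerate: no within-cell variance; F undefined, report p = 1
    out <- data.frame(effect = effects, df = NA_integer_,
                      df_residual = df_res, F = NA_real_, p = 1)
  } else {
    a <- car::Anova(fit, type = 2)
    rows <- match(effects, rownames(a))
    out <- data.frame(effect = effects, df = a$Df[rows],
                      df_residual = df_res, F = a$`F value`[rows],
                      p = a$`Pr(>F)`[rows])
  }
  out$bin <- significance_bin(out$p)
  out
}

#' Paired one-tailed littermate t test
#'
#' WT and KO values are paired by litter; the test is on the pair
#' differences, one-sided in a direction that must be declared per
#' endpoint. Identical pairs (all differences zero) give t = 0 and
#' p = 0.5 by the boundary convention.
#'
#' @param wt,ko Paired numeric vectors (same length, n >= 2), ordered so
#'   element i of each comes from the same litter.
#' @param direction `"ko_gt_wt"` tests KO > WT; `"ko_lt_wt"` tests
#'   KO < WT.
#' @return A one-row data frame with `t`, `df`, `p`, `mean_difference`
#'   and significance `bin`.
#' @export
paired_one_tailed_t <- function(wt, ko,
                                direction = c("ko_gt_wt", "ko_lt_wt")) {
  direction <- match.arg(direction)
  if (length(wt) != length(ko))
    stop("wt and ko must be paired vectors of equal length")
  if (length(wt) < 2) stop("at least 2 littermate pairs are required")
  d <- ko - wt
  if (sd(d) == 0) {
    tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p_greater <- if (tstat == 0) 0.5 else if (tstat > 0) 0 else 1
    p <- if (direction == "ko_gt_wt") p_greater else 1 - p_greater
    out <- data.frame(t = tstat, df = length(d) - 1L, p = p,
                      mean_difference = mean(d))
  } else {
    alt <- if (direction == "ko_gt_wt") "greater" else "less"
    tt <- t.test(ko, wt, paired = TRUE, alternative = alt)
    out <- data.frame(t = unname(tt$statistic),
                      df = unname(tt$parameter), p = tt$p.value,
                      mean_difference = unname(tt$estimate))
  }
  out$bin <- significance_bin(out$p)
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' `dCt = Ct_target - Ct_reference` per sample; `ddCt` subtracts the mean
#' `dCt` of the calibrator group; fold change is `2^(-ddCt)` (reference
#' gene conventionally GAPDH).
#'
#' @param ct_target,ct_reference Ct values per sample (equal length, all
#'   finite; `ct_reference` is the housekeeping gene).
#' @param calibrator Logical vector marking the calibrator-group samples
#'   (at least one).
#' @return Numeric vector of fold changes, one per sample.
#' @export
ddct_fold <- function(ct_target, ct_reference, calibrator) {
  if (length(ct_target) != length(ct_reference) ||
      length(ct_target) != length(calibrator))
    stop("ct_target, ct_reference and calibrator must have equal length")
  if (any(!is.finite(ct_reference)))
    stop("missing reference-gene Ct values")
  if (any(!is.finite(ct_target))) stop("missing target-gene Ct values")
  if (!any(calibrator)) stop("calibrator group is empty")
  dct <- ct_target - ct_reference
  ddct <- dct - mean(dct[calibrator])
  2^(-ddct)
}

#' Bin per-position p-values for the significance heat map
#'
#' Bins follow the published convention: red p <= 0.0001; yellow
#' 0.0001 < p <= 0.01; green 0.01 < p <= 0.05; blue p > 0.05.
#'
#' @param p P-values in `[0, 1]`.
#' @param position Optional axial positions (% bone length) for the rows.
#' @param endpoint Optional endpoint label.
#' @return Data frame with `position`, `endpoint`, `p` and `bin` (ordered
#'   factor red < yellow < green < blue).
#' @export
significance_heatmap <- function(p, position = seq_along(p),
                                 endpoint = NA_character_) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  data.frame(position = position, endpoint = endpoint, p = p,
             bin = factor(significance_bin(p),
                          levels = c("red", "yellow", "green", "blue"),
                          ordered = TRUE))
}
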