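#' Ventral-inferior / dorsal-superior WSS ratio
#'
#' The ratio of the mean WSS over the ventral and inferior walls to the mean
#' over the dorsal and superior walls, optionally restricted to one
#' trisection segment. Both means are area-weighted via
#' [regional_mean_wss()]; the ratio is invariant under global scaling of the
#' WSS field.
#'
#' @param field a `wss_field`.
#' @param labels a [wall_labels()] object on the same mesh.
#' @param segment optional `"proximal"`, `"middle"` or `"distal"`.
#' @return the ratio (dimensionless).
#' @export
rwss_vi_ds <- function(field, labels, segment = NULL) {
  lab <- labels$labels
  sel <- rep(TRUE, nrow(lab))
  if (!is.null(segment)) sel <- lab$segment == segment
  vi <- sel & lab$quadrant %in% c("ventral", "inferior")
  ds <- sel & lab$quadrant %in% c("dorsal", "superior")
  if (!any(vi) || !any(ds))
    stop("empty wall group in the requested segment", call. = FALSE)
  regional_mean_wss(field, which(vi)) / regional_mean_wss(field, which(ds))
}

#' Inner / outer curve-wall WSS ratio
#'
#' Mean WSS on the inner wall of the vessel curve divided by the mean on the
#' outer wall, optionally restricted to one segment. Errors on a straight
#' vessel (all faces undefined).
#'
#' @inheritParams rwss_vi_ds
#' @return the ratio (dimensionless).
#' @export
rwss_inner_outer <- function(field, labels, segment = NULL) {
  lab <- labels$labels
  sel <- rep(TRUE, nrow(lab))
  if (!is.null(segment)) sel <- lab$segment == segment
  inn <- sel & lab$curve_side == "inner"
  out <- sel & lab$curve_side == "outer"
  if (!any(inn) || !any(out))
    stop("curve sides undefined (straight vessel?)", call. = FALSE)
  regional_mean_wss(field, which(inn)) / regional_mean_wss(field, which(out))
}

#' Paired-sample t-test
#'
#' Two-sided paired t on matched measurements (e.g. plaque-containing vs
#' normal walls of the same vessel).
#'
#' @param a,b equal-length numeric vectors, n >= 2.
#' @return list(t, df, p).
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("paired samples must have equal length >= 2", call. = FALSE)
  if (stats::sd(a - b) == 0)
    stop("zero variance of differences", call. = FALSE)
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Two-sample t-test from summary statistics or raw data
#'
#' Welch's unequal-variance t (default) or Student's pooled t from group
#' means, SDs and sizes — the form needed to compare published group
#' summaries. Raw-data vectors may be passed instead via `x` and `y`.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @param x,y optional raw vectors (override the summaries).
#' @param var_equal pooled-variance Student form instead of Welch.
#' @return list(t, df, p).
#' @export
#' @examples
#' two_sample_t_summary(49.3, 16.0, 25, 56.4, 15.0, 43)$p   # ~0.07
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                 x = NULL, y = NULL, var_equal = FALSE) {
  if (!is.null(x) && !is.null(y)) {
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tstat <- (mean1 - mean2) / se
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Omnibus F over k groups followed by all pairwise pooled-variance t-tests
#' with Bonferroni correction, each corrected p capped at 1.000 (the form
#' used in regional WSS comparison tables).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param correction only `"bonferroni"` is offered.
#' @return list(F, df1, df2, p, pairwise) where `pairwise` is a data.frame
#'   of group pairs with raw and corrected p-values.
#' @export
one_way_anova_posthoc <- function(groups, correction = "bonferroni") {
  correction <- match.arg(correction, "bonferroni")
  k <- length(groups)
  if (k < 2L || any(lengths(groups) < 2L))
    stop("need >= 2 groups with n >= 2 each", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  if (stats::sd(y) == 0) {
    # all values identical: no variance to partition
    nm <- names(groups) %||% paste0("g", seq_len(k))
    pairs <- utils::combn(k, 2)
    return(list(F = 0, df1 = k - 1L, df2 = length(y) - k, p = 1,
                pairwise = data.frame(group1 = nm[pairs[1, ]],
                                      group2 = nm[pairs[2, ]],
                                      p_raw = 1, p_bonferroni = 1)))
  }
  gf <- factor(rep(seq_len(k), lengths(groups)),
               labels = names(groups) %||% paste0("g", seq_len(k)))
  fit <- stats::lm(y ~ gf)
  av <- stats::anova(fit)
  Fv <- av$`F value`[1]
  p <- av$`Pr(>F)`[1]
  mse <- av$`Mean Sq`[2]
  dfe <- av$Df[2]
  nm <- levels(gf)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  pw <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                   p_raw = NA_real_, p_bonferroni = NA_real_)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(mse * (1 / length(groups[[i1]]) + 1 / length(groups[[i2]])))
    tstat <- (mean(groups[[i1]]) - mean(groups[[i2]])) / se
    praw <- 2 * stats::pt(-abs(tstat), dfe)
    pw$p_raw[j] <- praw
    pw$p_bonferroni[j] <- min(1, m * praw)
  }
  list(F = Fv, df1 = av$Df[1], df2 = dfe, p = p, pairwise = pw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value by summing the probabilities of all tables (with
#' the observed margins) no more probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list(p, odds_ratio).
#' @export
#' @examples
#' fisher_exact(matrix(c(2, 14, 23, 29), 2))$p   # ~0.036
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L) || any(table < 0) ||
      any(table != round(table)))
    stop("need a 2x2 table of non-negative integer counts", call. = FALSE)
  ht <- stats::fisher.test(table)
  list(p = ht$p.value, odds_ratio = unname(ht$estimate))
}

#' Cohen's kappa for two categorical raters
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)}, flagged
#' "excellent" above 0.75. Undefined (NA) when both raters use a single
#' identical category (no chance correction possible).
#'
#' @param a,b equal-length vectors of categorical ratings.
#' @param threshold excellence threshold, default 0.75.
#' @return list(kappa, p_observed, p_expected, excellent).
#' @export
cohen_kappa <- function(a, b, threshold = 0.75) {
  if (length(a) != length(b)) stop("ratings must have equal length",
                                   call. = FALSE)
  lev <- sort(unique(c(as.character(a), as.character(b))))
  tab <- table(factor(a, lev), factor(b, lev)) / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - pe) < .Machine$double.eps * 8)
    return(list(kappa = NA_real_, p_observed = po, p_expected = pe,
                excellent = NA))
  k <- (po - pe) / (1 - pe)
  list(kappa = k, p_observed = po, p_expected = pe,
       excellent = k > threshold)
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}}
#' with subject (rows) mean square \eqn{MS_R}, rater (columns) mean square
#' \eqn{MS_C}, residual \eqn{MS_E}, n subjects and k raters. Flagged
#' "excellent" above 0.75; undefined when the between-subject variance is
#' zero.
#'
#' @param measurements n x k numeric matrix (subjects x raters).
#' @param threshold excellence threshold, default 0.75.
#' @return list(icc, ms_rows, ms_cols, ms_error, excellent, model).
#' @export
icc_agreement <- function(measurements, threshold = 0.75) {
  m <- as.matrix(measurements)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters",
                             call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  if (ms_r <= .Machine$double.eps * max(1, abs(grand)))
    return(list(icc = NA_real_, ms_rows = ms_r, ms_cols = ms_c,
                ms_error = ms_e, excellent = NA,
                model = "two-way random, absolute agreement, single"))
  icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
  list(icc = icc, ms_rows = ms_r, ms_cols = ms_c, ms_error = ms_e,
       excellent = icc > threshold,
       model = "two-way random, absolute agreement, single")
}

#' Regional WSS summary table
#'
#' Per segment x quadrant area-weighted mean WSS rows, in the layout of a
#' regional comparison table, as a data frame ready for CSV export.
#'
#' @param field a `wss_field`.
#' @param labels a [wall_labels()] object.
#' @param vessel_id identifier column value.
#' @return data.frame with vessel_id, segment, quadrant, mean_wss_pa,
#'   total_area_m2, n_faces.
#' @export
regional_wss_table <- function(field, labels, vessel_id = "vessel_1") {
  lab <- labels$labels
  out <- NULL
  for (seg in levels(lab$segment)) for (qd in levels(lab$quadrant)) {
    sel <- which(lab$segment == seg & lab$quadrant == qd)
    sel_ok <- sel[!field$excluded[sel]]
    if (!length(sel_ok)) next
    out <- rbind(out, data.frame(
      vessel_id = vessel_id, segment = seg, quadrant = qd,
      mean_wss_pa = regional_mean_wss(field, sel),
      total_area_m2 = sum(field$face_area[sel_ok]),
      n_faces = length(sel_ok)))
  }
  out
}
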