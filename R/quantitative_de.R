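# Replicated quantitative stage on subcutaneous fat: empirical-Bayes
# moderated two-group tests for the four line/diet contrasts, BH FDR, the
# fold/FDR/floor candidate filter, and diet-response classification.
#
# The moderated-t scheme is implemented here directly: per-probe residual
# variances are shrunk towards a common prior variance s0^2 with prior
# degrees of freedom d0, both estimated by method-of-moments on the log
# residual variances under a scaled inverse-chi-square model. At d0 = 0 the
# statistic reduces exactly to the ordinary pooled two-sample t.

# group label FC/FF/LC/LF from line + diet
quant_group <- function(samples) {
  paste0(samples$line, ifelse(samples$diet == "highfat", "F", "C"))
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf))
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    step <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + step
    if (abs(step) < 1e-10 * x) break
  }
  x
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits a scaled inverse-chi-square prior for per-probe residual variances
#' by method of moments on `log(s^2)`: the excess spread of the observed log
#' variances over the sampling spread `trigamma(df/2)` determines the prior
#' degrees of freedom `d0`, and the mean determines the prior variance
#' `s0_sq`. When the observed spread does not exceed the theoretical
#' sampling minimum, `d0 = Inf` (complete shrinkage to a common variance).
#'
#' @param variances Per-probe residual variances (>= 10 positive values).
#' @param df Residual degrees of freedom each variance was estimated with.
#' @return A `variance_prior`: list with `d0` (prior df, possibly `Inf`) and
#'   `s0_sq` (prior variance).
#' @export
estimate_variance_prior <- function(variances, df) {
  variances <- variances[is.finite(variances)]
  if (any(variances < 0)) stop("negative residual variance")
  pos <- variances[variances > 0]
  if (length(pos) < 10) stop("need >= 10 probes with positive variance")
  if (diff(range(pos)) < 1e-12 * max(pos)) {
    return(structure(list(d0 = Inf, s0_sq = pos[1]), class = "variance_prior"))
  }
  e <- log(pos)
  excess <- var(e) - trigamma(df / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e) - digamma(df / 2) + log(df / 2))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(mean(e) - digamma(df / 2) + log(df / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat(sprintf("variance_prior: d0 = %s, s0_sq = %.4g\n",
              format(x$d0), x$s0_sq))
  invisible(x)
}

# per-probe residual variances pooled across the four groups (log2 scale)
pooled_residual_variance <- function(logm, groups) {
  ss <- 0
  df <- 0
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2) next
    mu <- rowMeans(logm[, cols, drop = FALSE])
    ss <- ss + rowSums((logm[, cols, drop = FALSE] - mu)^2)
    df <- df + length(cols) - 1
  }
  list(s2 = ss / df, df = df)
}

#' Moderated two-group t-test for one line/diet contrast
#'
#' Tests one of the four contrasts `FCvsLC`, `FFvsLF`, `FFvsFC`, `LFvsLC`
#' (first group minus second, log2 scale). Per-probe variances are shrunk
#' towards the prior: `s_tilde^2 = (d0 s0^2 + df s^2) / (d0 + df)`; the
#' statistic is `t = dmean / sqrt(s_tilde^2 (1/n1 + 1/n2))` referred to a t
#' distribution on `d0 + df` degrees of freedom. With `d0 = 0` this is the
#' ordinary pooled two-sample t-test.
#'
#' @param study Quantitative [expression_study()] (groups FC/FF/LC/LF from
#'   line x diet, >= 2 replicates each).
#' @param contrast One of `"FCvsLC"`, `"FFvsLF"`, `"FFvsFC"`, `"LFvsLC"`.
#' @param prior A `variance_prior`, or `NULL` to estimate one from the
#'   contrast's pooled residual variances. Use `list(d0 = 0)` for the
#'   unmoderated test.
#' @param epsilon Intensity floor before the log2 transform.
#' @param adjust If `TRUE` (default) append BH-adjusted p-values.
#' @return `data.frame` with one row per probe: `probe_id`, `contrast`,
#'   `mean_1`, `mean_2` (linear AU group means), `fold_linear` (signed fold
#'   of the linear means), `log2_fold` (difference of log2 means),
#'   `residual_var`, `t`, `df_total`, `p`, and `padj` when `adjust`.
#' @export
moderated_t_test <- function(study, contrast = CONTRASTS, prior = NULL,
                             epsilon = 1, adjust = TRUE) {
  stopifnot(inherits(study, "expression_study"))
  if (study$design != "quantitative") stop("moderated_t_test requires a quantitative design")
  contrast <- match.arg(contrast)
  g1 <- substr(contrast, 1, 2)
  g2 <- substr(contrast, 5, 6)
  groups <- quant_group(study$samples)
  i1 <- which(groups == g1)
  i2 <- which(groups == g2)
  if (length(i1) < 2 || length(i2) < 2) {
    stop("contrast ", contrast, " needs >= 2 replicates per group")
  }
  logm <- log2(floor_eps(study$intensities, epsilon))
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(logm[, i1, drop = FALSE])
  m2 <- rowMeans(logm[, i2, drop = FALSE])
  df <- n1 + n2 - 2
  s2 <- (rowSums((logm[, i1, drop = FALSE] - m1)^2) +
           rowSums((logm[, i2, drop = FALSE] - m2)^2)) / df
  if (is.null(prior)) prior <- estimate_variance_prior(s2, df)
  d0 <- prior$d0
  s0 <- prior$s0_sq %||% 0
  s_tilde <- if (is.infinite(d0)) rep(s0, length(s2)) else {
    (d0 * s0 + df * s2) / (d0 + df)
  }
  delta <- m1 - m2
  se <- sqrt(s_tilde * (1 / n1 + 1 / n2))
  t_stat <- ifelse(delta == 0, 0, delta / se)
  df_total <- d0 + df
  p <- ifelse(delta == 0, 1, 2 * pt(-abs(t_stat), df = df_total))
  lin1 <- rowMeans(study$intensities[, i1, drop = FALSE])
  lin2 <- rowMeans(study$intensities[, i2, drop = FALSE])
  res <- data.frame(
    probe_id = rownames(study$intensities),
    contrast = contrast,
    mean_1 = lin1, mean_2 = lin2,
    fold_linear = signed_fold_change(lin1, lin2, epsilon = epsilon),
    log2_fold = delta,
    residual_var = s2,
    t = t_stat,
    df_total = df_total,
    p = p,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  if (adjust) res$padj <- bh_adjust(res$p)
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment: with p-values sorted ascending,
#' `q_i = min_{j >= i} (p_j * m / j)` capped at 1, returned in input order.
#' Ties receive equal adjusted values.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Fold / FDR / intensity-floor candidate filter
#'
#' The quantitative reporting criterion: a probe is retained for a contrast
#' when its linear fold exceeds the threshold (`|fold| > fold`), its
#' BH-adjusted p-value is below `alpha`, and the mean expression of the
#' higher group exceeds the intensity floor.
#'
#' @param results One or more [moderated_t_test()] result frames (rows may
#'   mix contrasts).
#' @param fold Linear fold threshold (default 2, strict `>`).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param floor Intensity floor in AU for the higher group (default 100).
#' @return Named list per contrast, each a list of probe-id vectors `up`
#'   (first group higher) and `down`.
#' @export
de_candidate_filter <- function(results, fold = 2, alpha = 0.05, floor = 100) {
  if (is.null(results$padj)) stop("results lack a `padj` column")
  keep <- abs(results$fold_linear) > fold &
    results$padj < alpha &
    pmax(results$mean_1, results$mean_2) > floor
  out <- lapply(split(results[keep, , drop = FALSE], results$contrast[keep]),
                function(df) list(up = df$probe_id[df$fold_linear > 0],
                                  down = df$probe_id[df$fold_linear < 0]))
  for (ct in setdiff(unique(results$contrast), names(out))) {
    out[[ct]] <- list(up = character(), down = character())
  }
  out
}

#' Classify the diet response of each probe
#'
#' Labels each probe by the pattern of line and diet effects across the four
#' group means, given per-contrast significance flags (typically the
#' [de_candidate_filter()] outcome or `padj < alpha`):
#'
#' * `interaction_opposing` - the F-vs-L effect is significant on both diets
#'   with opposite signs.
#' * `diet_amplified` - the F-vs-L effect is significant on both diets with
#'   a common sign, at least one within-line diet contrast is significant,
#'   and the high-fat line effect is larger in magnitude than the
#'   control-diet one.
#' * `line_only` - F-vs-L significant on both diets, no within-line diet
#'   significance.
#' * `diet_only` - a within-line diet contrast is significant but neither
#'   line contrast is.
#' * `null` - anything else.
#'
#' Labels are assigned in the precedence order listed, so each probe gets
#' exactly one.
#'
#' @param means `data.frame` or matrix with columns `FC`, `FF`, `LC`, `LF`
#'   of linear-AU group means (rows = probes).
#' @param significant Logical `data.frame`/matrix with columns `FCvsLC`,
#'   `FFvsLF`, `FFvsFC`, `LFvsLC`.
#' @param epsilon Intensity floor before log ratios.
#' @return Character vector of labels, one per probe.
#' @export
classify_diet_response <- function(means, significant, epsilon = 1) {
  means <- as.data.frame(means)
  significant <- as.data.frame(significant)
  stopifnot(all(c("FC", "FF", "LC", "LF") %in% names(means)),
            all(CONTRASTS %in% names(significant)),
            nrow(means) == nrow(significant))
  l2 <- function(a, b) log2(floor_eps(a, epsilon)) - log2(floor_eps(b, epsilon))
  lfc_c <- l2(means$FC, means$LC)   # line effect, control diet
  lfc_h <- l2(means$FF, means$LF)   # line effect, high-fat diet
  line_both <- significant$FCvsLC & significant$FFvsLF
  diet_any <- significant$FFvsFC | significant$LFvsLC
  label <- rep("null", nrow(means))
  label[diet_any & !significant$FCvsLC & !significant$FFvsLF] <- "diet_only"
  label[line_both & !diet_any] <- "line_only"
  label[line_both & diet_any & sign(lfc_c) == sign(lfc_h) &
          abs(lfc_h) > abs(lfc_c)] <- "diet_amplified"
  label[line_both & sign(lfc_c) * sign(lfc_h) < 0] <- "interaction_opposing"
  label
}

#' Group means of a quantitative study
#'
#' @param study Quantitative [expression_study()].
#' @return `data.frame` with columns `probe_id`, `FC`, `FF`, `LC`, `LF`
#'   (linear-AU group means).
#' @export
quant_group_means <- function(study) {
  stopifnot(inherits(study, "expression_study"),
            study$design == "quantitative")
  groups <- quant_group(study$samples)
  out <- data.frame(probe_id = rownames(study$intensities),
                    stringsAsFactors = FALSE)
  for (g in c("FC", "FF", "LC", "LF")) {
    cols <- which(groups == g)
    if (!length(cols)) stop("missing group ", g)
    out[[g]] <- rowMeans(study$intensities[, cols, drop = FALSE])
  }
  out
}
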