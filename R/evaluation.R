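#' Kendall tau-b rank correlation with tie-corrected significance
#'
#' `tau_b = (P - Q) / sqrt((P + Q + T_x)(P + Q + T_y))`, where P and Q count
#' concordant and discordant pairs and `T_x`, `T_y` count pairs tied only in
#' x or only in y. Significance uses the normal approximation of the null
#' distribution of `S = P - Q` with the standard tie-corrected variance.
#'
#' @param ratings ordinal ratings: a factor/character over [bpe_levels] or a
#'   numeric vector.
#' @param scores numeric vector of the same length (n >= 3).
#' @return An object of class `correlation_result`: `tau_b`, `z_statistic`,
#'   `p_value` (two-sided), `n`.
#' @export
kendall_tau_b <- function(ratings, scores) {
  x <- if (is.numeric(ratings)) ratings else as.numeric(factor(ratings, levels = bpe_levels))
  y <- as.numeric(scores)
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("kendall_tau_b: need n >= 3")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("kendall_tau_b: tau is undefined when all ratings or all scores are tied")
  }
  dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  s <- dx[up] * dy[up]
  P <- sum(s > 0); Q <- sum(s < 0)
  # denominator counts pairs not tied in x (resp. y): n0 - n1 and n0 - n2
  n0 <- n * (n - 1) / 2
  tcnt <- table(x); ucnt <- table(y)
  n1 <- sum(tcnt * (tcnt - 1) / 2); n2 <- sum(ucnt * (ucnt - 1) / 2)
  tau <- (P - Q) / sqrt((n0 - n1) * (n0 - n2))
  # tie-corrected variance of S
  ti <- as.numeric(tcnt); ui <- as.numeric(ucnt)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(ti * (ti - 1) * (2 * ti + 5)); vu <- sum(ui * (ui - 1) * (2 * ui + 5))
  v1 <- sum(ti * (ti - 1)) * sum(ui * (ui - 1)) / (2 * n * (n - 1))
  v2 <- sum(ti * (ti - 1) * (ti - 2)) * sum(ui * (ui - 1) * (ui - 2)) /
    (9 * n * (n - 1) * (n - 2))
  varS <- (v0 - vt - vu) / 18 + v1 + v2
  z <- (P - Q) / sqrt(varS)
  p <- 2 * pnorm(-abs(z))
  structure(list(tau_b = tau, z_statistic = z, p_value = p, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Kendall tau-b = %.4f (z = %.3f, p = %.3g, n = %d)\n",
              x$tau_b, x$z_statistic, x$p_value, x$n))
  invisible(x)
}

#' Dichotomize ordinal BPE ratings for a classification task
#'
#' `minimal_vs_marked` keeps only the two extreme levels (minimal = negative,
#' marked = positive) and drops mild/moderate exams; `low_vs_high` keeps all
#' exams with minimal+mild negative and moderate+marked positive.
#'
#' @param ratings factor/character over [bpe_levels].
#' @param task `"minimal_vs_marked"` or `"low_vs_high"`.
#' @return list with `labels` (0/1 integer), `keep` (logical index into the
#'   input), `n_pos`, `n_neg`.
#' @export
dichotomize <- function(ratings, task = c("minimal_vs_marked", "low_vs_high")) {
  task <- match.arg(task)
  r <- factor(as.character(ratings), levels = bpe_levels)
  if (any(is.na(r))) stop("dichotomize: unknown rating levels present")
  if (task == "minimal_vs_marked") {
    keep <- r %in% c("minimal", "marked")
    labels <- as.integer(r[keep] == "marked")
  } else {
    keep <- rep(TRUE, length(r))
    labels <- as.integer(r %in% c("moderate", "marked"))
  }
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L) stop("dichotomize: positive class is empty for task ", task)
  if (n_neg == 0L) stop("dichotomize: negative class is empty for task ", task)
  list(labels = labels, keep = keep, n_pos = n_pos, n_neg = n_neg)
}

# DeLong variance components of the empirical AUC
.delong_se <- function(scores, labels) {
  xs <- scores[labels == 1L]; ys <- scores[labels == 0L]
  m <- length(xs); n <- length(ys)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  V10 <- vapply(xs, function(a) mean(psi(a, ys)), 0)
  V01 <- vapply(ys, function(b) mean(psi(xs, b)), 0)
  s10 <- if (m > 1) var(V10) else 0
  s01 <- if (n > 1) var(V01) else 0
  sqrt(s10 / m + s01 / n)
}

#' ROC analysis of BPE scores against dichotomized ratings
#'
#' The default empirical method estimates AUC as the Mann-Whitney statistic
#' `U / (n_pos * n_neg)` with ties counted 0.5, its standard error with the
#' DeLong estimator, and significance against chance (AUC = 0.5) with a
#' two-sided z-test, Bonferroni-corrected by `n_comparisons`. The optional
#' `"binormal"` method adds a conventional binormal maximum-likelihood fit
#' (Dorfman-Alf on rank-binned data); the AUC reported is then
#' `pnorm(a / sqrt(1 + b^2))` while SE/p remain the empirical ones.
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector (1 = positive class); both classes non-empty.
#' @param method `"empirical"` or `"binormal"`.
#' @param n_comparisons Bonferroni family size (default 1).
#' @param n_bins number of rank bins for the binormal fit.
#' @return An object of class `roc_result`: `auc`, `se`, `z`, `p_vs_chance`,
#'   `p_corrected`, `n_pos`, `n_neg`, `curve_points` (data.frame fpr/tpr,
#'   from (0,0) to (1,1)), `method`, and for the binormal method `binormal`
#'   (list a, b, auc).
#' @export
roc_analysis <- function(scores, labels, method = c("empirical", "binormal"),
                         n_comparisons = 1L, n_bins = 10L) {
  method <- match.arg(method)
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("roc_analysis: both classes must be non-empty")
  xs <- scores[labels == 1L]; ys <- scores[labels == 0L]
  r <- rank(c(xs, ys))
  U <- sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2
  auc <- U / (n_pos * n_neg)
  degenerate <- length(unique(scores)) == 1L
  se <- if (degenerate) Inf else .delong_se(scores, labels)
  if (degenerate) warning("roc_analysis: single-valued scores; AUC 0.5 with infinite SE")
  z <- (auc - 0.5) / se
  p <- if (is.nan(z)) 1 else 2 * pnorm(-abs(z))
  # empirical curve over unique thresholds
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(xs >= t), 0)
  fpr <- vapply(th, function(t) mean(ys >= t), 0)
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  curve <- curve[order(curve$fpr, curve$tpr), ]
  res <- list(auc = auc, se = se, z = z, p_vs_chance = p,
              p_corrected = min(1, p * n_comparisons),
              n_pos = n_pos, n_neg = n_neg, curve_points = curve,
              method = method)
  if (method == "binormal") res$binormal <- .binormal_fit(scores, labels, n_bins)
  structure(res, class = "roc_result")
}

# Conventional binormal ROC fit (Dorfman-Alf) on rank-binned scores:
# latent decision variable with N(0,1) negatives, N(a/b... parameterized so
# TPF(c) = pnorm(a - b * c), FPF(c) = pnorm(-c) at cutoffs c.
.binormal_fit <- function(scores, labels, n_bins = 10L) {
  br <- unique(quantile(scores, seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3L) return(list(a = NA_real_, b = NA_real_, auc = NA_real_))
  bins <- cut(scores, breaks = br, include.lowest = TRUE)
  k <- nlevels(bins)
  pos <- table(bins[labels == 1L]); neg <- table(bins[labels == 0L])
  nll <- function(par) {
    a <- par[1]; b <- exp(par[2])
    cuts <- c(-Inf, sort(par[3:(k + 1)]), Inf)
    pn <- diff(pnorm(cuts))             # negatives ~ N(0, 1)
    pp <- diff(pnorm(b * cuts - a))     # positives ~ N(a/b, 1/b) on the latent axis
    pn <- pmax(pn, 1e-12); pp <- pmax(pp, 1e-12)
    -(sum(neg * log(pn)) + sum(pos * log(pp)))
  }
  init <- c(1, 0, qnorm(seq_len(k - 1) / k))
  fit <- try(optim(init, nll, method = "BFGS", control = list(maxit = 500)), silent = TRUE)
  if (inherits(fit, "try-error")) return(list(a = NA_real_, b = NA_real_, auc = NA_real_))
  a <- fit$par[1]; b <- exp(fit$par[2])
  list(a = a, b = b, auc = pnorm(a / sqrt(1 + b^2)))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f +/- %.3f (%s; n_pos = %d, n_neg = %d)\n",
              x$auc, x$se, x$method, x$n_pos, x$n_neg))
  cat(sprintf("  z vs chance = %.3f, p = %.3g (Bonferroni-corrected p = %.3g)\n",
              x$z, x$p_vs_chance, x$p_corrected))
  if (!is.null(x$binormal) && is.finite(x$binormal$auc)) {
    cat(sprintf("  binormal fit: a = %.3f, b = %.3f, AUC = %.3f\n",
                x$binormal$a, x$binormal$b, x$binormal$auc))
  }
  invisible(x)
}

#' Summarize after/before lesion-removal score ratios by lesion size
#'
#' Pairs each exam's affected-breast score before and after electronic lesion
#' removal for one image variant, computes the per-exam ratio, and aggregates
#' by rating level and lesion-size bin.
#'
#' @param records data.frame of score records (see [score_grid()]), covering
#'   at least the affected region of the chosen variant with both removal
#'   states.
#' @param sizes data.frame with columns `exam_id` and `lesion_size_mm`.
#' @param projection_type,time_point,rescale_mode the image variant to use
#'   (default: original-intensity second post-contrast MIP).
#' @param size_breaks breaks (mm) for lesion-size bins.
#' @return list with `per_exam` (exam_id, rating, lesion_size_mm, before,
#'   after, ratio), `by_level`, and `by_size_bin` aggregate data.frames.
#' @export
ratio_vs_size_table <- function(records, sizes, projection_type = "MIP",
                                time_point = 2L, rescale_mode = "original",
                                size_breaks = c(0, 10, 20, 40, Inf)) {
  sel <- records$region == "affected" &
    records$projection_type == projection_type &
    records$time_point == time_point &
    records$rescale_mode == rescale_mode
  rec <- records[sel, ]
  ids <- unique(rec$exam_id)
  rows <- list()
  for (id in ids) {
    before <- rec$score[rec$exam_id == id & !rec$lesion_removed]
    after <- rec$score[rec$exam_id == id & rec$lesion_removed]
    if (length(before) != 1L || length(after) != 1L) {
      message("ratio_vs_size_table: skipping ", id, " (missing before/after pair)")
      next
    }
    sz <- sizes$lesion_size_mm[match(id, sizes$exam_id)]
    rows[[length(rows) + 1L]] <- data.frame(
      exam_id = id, rating = rec$rating[rec$exam_id == id][1],
      lesion_size_mm = sz, before = before, after = after,
      ratio = removal_ratio(after, before), stringsAsFactors = FALSE)
  }
  per_exam <- do.call(rbind, rows)
  per_exam$size_bin <- cut(per_exam$lesion_size_mm, breaks = size_breaks,
                           include.lowest = TRUE)
  by_level <- aggregate(ratio ~ rating, per_exam, mean)
  by_bin <- aggregate(ratio ~ size_bin, per_exam, mean)
  list(per_exam = per_exam, by_level = by_level, by_size_bin = by_bin)
}

#' Plot an ROC curve / ratio-vs-size summary
#' @param x a `roc_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$curve_points$fpr, x$curve_points$tpr, type = "l",
                 xlab = "False positive fraction", ylab = "True positive fraction",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f +/- %.3f", x$auc, x$se))
  invisible(x)
}
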