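# The statistical layer: two-step strength-duration regression (Lapicque fit
# to the TAC, then a log-linear model for the intensity threshold), one-sided
# paired Wilcoxon signed-rank excitability scoring, and ranked relative-change
# summaries.

adj_r2 <- function(obs, fitted, n_par) {
  n <- length(obs)
  r2 <- 1 - sum((obs - fitted)^2) / sum((obs - mean(obs))^2)
  1 - (1 - r2) * (n - 1) / (n - n_par - 1)
}

#' Lapicque strength-duration fit to the TAC
#'
#' Fits `TAC = TAC_0 / (1 - exp(-pd / tau))`: `TAC_0` is the rheobase-like
#' asymptote the TAC approaches at long pulses, `tau` the chronaxie-like time
#' constant (at `pd << tau` the curve behaves as `TAC_0 * tau / pd`).
#'
#' @param pd Pulse durations, ms (> 0, at least 3 values).
#' @param tac TAC values (same sign throughout; nA or uA — units are carried
#'   by the caller).
#' @return A `lapicque_fit` object with `tac_0`, `tau` and the adjusted R^2.
#' @export
lapicque_fit <- function(pd, tac) {
  stopifnot(length(pd) >= 3, length(pd) == length(tac), all(pd > 0))
  sgn <- sign(stats::median(tac))
  y <- tac * sgn
  if (max(y) - min(y) < 1e-10 * max(y)) {
    # flat strength-duration data: the asymptote is identified, tau is not
    return(structure(list(
      tac_0 = mean(y) * sgn, tau = min(pd) / 20, adj_r2 = 1,
      n = length(pd), data = tibble::tibble(pd = pd, tac = tac), sign = sgn
    ), class = "lapicque_fit"))
  }
  # fit on the log scale: strength-duration data spans decades and its noise
  # is multiplicative, so log-residual least squares is the consistent model
  ly <- log(y)
  starts <- lapply(c(min(pd) / 5, stats::median(pd) / 5, max(pd) / 2),
                   function(tau0) list(l0 = log(min(y)), tau = tau0))
  fit <- NULL
  errs <- character(0)
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(ly ~ l0 - log(1 - exp(-pd / tau)),
                        start = start, lower = c(-Inf, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("Lapicque fit did not converge (tau starts tried: ",
         paste(signif(vapply(starts, `[[`, numeric(1), "tau"), 3),
               collapse = ", "), "): ", errs[length(errs)])
  cf <- stats::coef(fit)
  structure(list(
    tac_0 = exp(unname(cf["l0"])) * sgn, tau = unname(cf["tau"]),
    adj_r2 = adj_r2(ly, stats::fitted(fit), 2),
    n = length(pd), data = tibble::tibble(pd = pd, tac = tac),
    sign = sgn
  ), class = "lapicque_fit")
}

#' Predict from a Lapicque fit
#' @param object A `lapicque_fit`.
#' @param pd Pulse durations, ms.
#' @param ... Unused.
#' @return Fitted TAC values.
#' @export
predict.lapicque_fit <- function(object, pd, ...) {
  object$tac_0 / (1 - exp(-pd / object$tau))
}

#' @export
print.lapicque_fit <- function(x, ...) {
  cat("<lapicque_fit> TAC_0 =", signif(x$tac_0, 5), ", tau =",
      signif(x$tau, 5), "ms, adj R^2 =", signif(x$adj_r2, 5), "\n")
  invisible(x)
}

#' @export
tidy.lapicque_fit <- function(x, ...) {
  tibble::tibble(term = c("tac_0", "tau"), estimate = c(x$tac_0, x$tau))
}

#' @importFrom generics glance
#' @export
glance.lapicque_fit <- function(x, ...) {
  tibble::tibble(adj_r2 = x$adj_r2, n = x$n)
}

#' Log-linear threshold regression
#'
#' Ordinary least squares of `log10(I_th)` on `log10(G_max)` and
#' `log10(TAC_hat)`, where `TAC_hat` is the Lapicque prediction for each
#' pulse duration: `log10 I_th = a_G log10 G_max + a_pd log10 TAC_hat + c`.
#' The adjusted R^2 uses the `n - 3` denominator (two slopes plus the
#' intercept).
#'
#' @param g_max Expression levels, uS (> 0).
#' @param tac_hat Lapicque-fitted TAC magnitudes (> 0).
#' @param i_th Intensity thresholds, mW/mm^2 (> 0); sentinel `NA` rows are
#'   dropped.
#' @return A `threshold_regression` object with `a_g`, `a_pd`, `c`, `adj_r2`
#'   and the underlying `lm` fit.
#' @export
threshold_regression <- function(g_max, tac_hat, i_th) {
  keep <- !is.na(i_th)
  g_max <- g_max[keep]; tac_hat <- tac_hat[keep]; i_th <- i_th[keep]
  stopifnot(all(g_max > 0), all(tac_hat > 0), all(i_th > 0))
  if (length(unique(g_max)) < 2)
    stop("a_G unidentifiable: a single G_max value (rank-deficient design)")
  if (length(unique(tac_hat)) < 2)
    stop("a_pd unidentifiable: a single TAC_hat value")
  df <- data.frame(lg = log10(g_max), lt = log10(tac_hat), li = log10(i_th))
  fit <- stats::lm(li ~ lg + lt, data = df)
  if (any(is.na(stats::coef(fit)))) stop("collinear design")
  cf <- stats::coef(fit)
  structure(list(
    a_g = unname(cf["lg"]), a_pd = unname(cf["lt"]), c = unname(cf["(Intercept)"]),
    adj_r2 = suppressWarnings(summary(fit)$adj.r.squared),
    n = nrow(df), lm = fit
  ), class = "threshold_regression")
}

#' @export
print.threshold_regression <- function(x, ...) {
  cat("<threshold_regression> a_G =", signif(x$a_g, 4), ", a_pd =",
      signif(x$a_pd, 4), ", c =", signif(x$c, 4), ", adj R^2 =",
      signif(x$adj_r2, 5), "\n")
  invisible(x)
}

#' @export
tidy.threshold_regression <- function(x, ...) {
  tibble::tibble(term = c("a_g", "a_pd", "c"),
                 estimate = c(x$a_g, x$a_pd, x$c))
}

#' @export
glance.threshold_regression <- function(x, ...) {
  tibble::tibble(adj_r2 = x$adj_r2, n = x$n)
}

# ---------------------------------------------------------------------------
# Wilcoxon signed-rank

#' One-sided paired Wilcoxon signed-rank test
#'
#' Tests whether `x` is stochastically greater (or less) than `y` on paired
#' samples. Zero differences are discarded (the standard zero-discard
#' convention); the exact null distribution (`stats::psignrank`) is used for
#' 25 or fewer nonzero pairs without ties, otherwise the normal approximation
#' with tie correction and continuity correction.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param alternative `"greater"` (x > y) or `"less"`.
#' @return A list with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n_used` (nonzero pairs), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("unpaired inputs: lengths differ")
  d <- x - y
  if (alternative == "less") d <- -d
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p_value = 1, n_used = 0,
                          method = "degenerate"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    p <- stats::psignrank(v - 1, n, lower.tail = FALSE)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    p <- stats::pnorm((v - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
    method <- "normal approximation"
  }
  list(statistic = v, p_value = p, n_used = n, method = method)
}

#' Excitability scores from pairwise Wilcoxon tests
#'
#' Every ordered pair of classes is compared with a one-sided paired Wilcoxon
#' signed-rank test; a class collects 1, 0.1 or 0.01 points for every class it
#' beats with p < 0.001, < 0.01 or < 0.05, respectively. With `k` classes the
#' maximum score is `k - 1` (41 for the 42 classes of the Monte Carlo-field
#' analysis).
#'
#' @param data Long tibble with columns `class`, `value` and a pairing key
#'   column (same set of keys per class).
#' @param direction `"less"` to reward significantly lower metric values
#'   (thresholds), `"greater"` for significantly higher ones (SoFPAN).
#' @param class,value,key Column names.
#' @return An `excitability_scores` tibble: `class`, `score`, ordered from
#'   most to least excitable; the pairwise p-value matrix is attached as
#'   attribute `p_matrix`.
#' @export
excitability_scores <- function(data, direction = c("less", "greater"),
                                class = "class", value = "value",
                                key = "key") {
  direction <- match.arg(direction)
  cl <- data[[class]]; val <- data[[value]]; kk <- data[[key]]
  classes <- unique(cl)
  k <- length(classes)
  keys <- sort(unique(kk))
  mats <- lapply(classes, function(ci) {
    v <- val[cl == ci][match(keys, kk[cl == ci])]
    if (anyNA(v) || sum(cl == ci) != length(keys))
      stop("unpaired inputs: class '", ci, "' does not cover every key")
    v
  })
  pmat <- matrix(NA_real_, k, k, dimnames = list(classes, classes))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    pmat[i, j] <- wilcoxon_signed_rank(mats[[i]], mats[[j]],
                                       alternative = direction)$p_value
  }
  pts <- function(p) ifelse(p < 0.001, 1, ifelse(p < 0.01, 0.1,
                                                 ifelse(p < 0.05, 0.01, 0)))
  score <- rowSums(pts(pmat), na.rm = TRUE)
  out <- tibble::tibble(class = classes, score = unname(score))
  out <- out[order(-out$score), ]
  structure(out, class = c("excitability_scores", class(out)),
            p_matrix = pmat)
}

#' Ranked relative-change summary
#'
#' Given per-condition metric values for classes ordered from worst to best
#' rank, computes the relative change of the metric at every rank step for
#' every condition, the per-step medians, and their average: "moving up one
#' rank changes the metric on average by the average of medians". The
#' summary depends on the ranking order by construction.
#'
#' @param data Long tibble with columns `class`, `value`, `key` (condition).
#' @param ranking Character vector of classes from lowest to highest rank.
#' @param class,value,key Column names.
#' @return A list: `steps` (tibble with `from`, `to`, `median_change`),
#'   `average_of_medians`.
#' @export
ranked_relative_change <- function(data, ranking, class = "class",
                                   value = "value", key = "key") {
  if (length(ranking) < 2) stop("need at least 2 ranks")
  cl <- data[[class]]; val <- data[[value]]; kk <- data[[key]]
  keys <- sort(unique(kk))
  series <- lapply(ranking, function(ci) val[cl == ci][match(keys, kk[cl == ci])])
  steps <- lapply(seq_len(length(ranking) - 1), function(s) {
    rel <- (series[[s + 1]] - series[[s]]) / series[[s]]
    tibble::tibble(from = ranking[s], to = ranking[s + 1],
                   median_change = stats::median(rel, na.rm = TRUE))
  })
  steps <- dplyr::bind_rows(steps)
  list(steps = steps, average_of_medians = mean(steps$median_change))
}
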