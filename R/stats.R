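#' Block-average per-contraction values
#'
#' Reproduces the study's reporting units: each subject's per-contraction
#' values are first expressed as a percentage of that subject's maximum over
#' the whole protocol, then averaged within blocks, and finally summarised
#' across subjects (mean and SD per block). Two groupings are supported:
#' `"four_sets"` (blocks of 4 consecutive sets: 1-4, 5-8, ...) and
#' `"five_intervals"` (five 20% intervals of the contraction sequence, 32
#' contractions each under the default protocol).
#'
#' @param values data.frame with columns `subject`, `set`, `rep` and the
#'   value column named by `var`.
#' @param var name of the value column.
#' @param grouping `"four_sets"` or `"five_intervals"`.
#' @param normalize express values as % of the per-subject protocol maximum
#'   (default TRUE).
#' @return data.frame with `block`, `mean`, `sd`, `n_subjects`.
#' @export
block_average <- function(values, var, grouping = c("four_sets",
                                                    "five_intervals"),
                          normalize = TRUE) {
  grouping <- match.arg(grouping)
  need <- c("subject", "set", "rep", var)
  if (!all(need %in% names(values)))
    stop("invalid-input: values must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  df <- values[order(values$subject, values$set, values$rep), ]
  v <- df[[var]]
  if (normalize) {
    mx <- stats::ave(v, df$subject, FUN = max)
    if (any(mx <= 0))
      stop("invalid-input: non-positive per-subject maximum", call. = FALSE)
    v <- 100 * v / mx
  }
  if (grouping == "four_sets") {
    blk <- (df$set - 1L) %/% 4L + 1L
    labels <- sprintf("sets %d-%d", (sort(unique(blk)) - 1L) * 4L + 1L,
                      sort(unique(blk)) * 4L)
  } else {
    idx <- stats::ave(seq_along(v), df$subject, FUN = seq_along)
    per <- stats::ave(seq_along(v), df$subject, FUN = length)
    blk <- pmin(5L, (idx - 1L) %/% ceiling(per / 5) + 1L)
    labels <- sprintf("interval %d", sort(unique(blk)))
  }
  subj_block <- stats::aggregate(v, list(subject = df$subject, block = blk),
                                 FUN = mean)
  out <- stats::aggregate(subj_block$x, list(block = subj_block$block),
                          FUN = function(z) c(mean(z), stats::sd(z), length(z)))
  out <- out[order(out$block), , drop = FALSE]
  data.frame(block = labels, mean = out$x[, 1], sd = out$x[, 2],
             n_subjects = as.integer(out$x[, 3]), stringsAsFactors = FALSE)
}

#' Percent change between a pre and a post value
#'
#' `(post - pre) / pre * 100`. When summarising a group, the package
#' computes the change per subject first and then averages (mean of ratios),
#' since subject-level mean +/- SD changes are the reporting convention;
#' note this differs from the ratio of group means.
#'
#' @param pre,post numeric values (vectorised); `pre` must be non-zero.
#' @return percent change.
#' @export
percent_change <- function(pre, post) {
  if (any(pre == 0)) stop("invalid-input: pre value must be non-zero",
                          call. = FALSE)
  (post - pre) / pre * 100
}

#' Blood lactate accumulation
#'
#' Difference between post- and pre-exercise blood lactate concentration.
#'
#' @param pre,post concentrations in mmol/L.
#' @return accumulation in mmol/L (negative values are allowed).
#' @export
lactate_accumulation <- function(pre, post) post - pre

#' OLS regression on z-scored variables (standardized coefficients)
#'
#' All variables are standardized to zero mean and unit SD before an
#' ordinary least-squares fit, so the coefficients are standardized betas.
#'
#' @param y numeric response.
#' @param X numeric matrix or data.frame of predictors (no constant columns).
#' @return list of class `regression_result`: `r2`, `beta` (named),
#'   `p_values`, `predictors`, `n`.
#' @export
ols_standardized <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (n <= ncol(X) + 1L)
    stop("invalid-input: need n > p + 1 observations", call. = FALSE)
  if (any(apply(X, 2, stats::sd) == 0))
    stop("invalid-input: constant predictor column", call. = FALSE)
  if (qr(cbind(1, scale(X)))$rank < ncol(X) + 1L)
    stop("collinearity: predictor matrix is rank deficient", call. = FALSE)
  zy <- as.numeric(scale(y))
  zX <- scale(X)
  fit <- stats::lm(zy ~ zX)
  sm <- summary(fit)
  beta <- stats::coef(fit)[-1]
  names(beta) <- colnames(X)
  p <- sm$coefficients[-1, 4]
  names(p) <- colnames(X)
  structure(list(r2 = sm$r.squared, beta = beta, p_values = p,
                 predictors = colnames(X), n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> R2 = %.3f, n = %d\n", x$r2, x$n))
  if (length(x$beta))
    print(data.frame(beta = round(x$beta, 3), p = signif(x$p_values, 3)))
  else cat("  (empty model: no predictor entered)\n")
  invisible(x)
}

#' Forward stepwise regression with standardized coefficients
#'
#' Predictors enter one at a time in order of R-squared gain, as long as the
#' entering predictor's partial F-test has `p < alpha_in` and it is not too
#' collinear (|r| > `r_guard`) with an already-included predictor. With a
#' single surviving predictor this reduces to a simple linear regression;
#' with none the returned model is empty and flagged.
#'
#' @param y numeric response.
#' @param X numeric matrix or data.frame of candidate predictors.
#' @param alpha_in entry threshold on the partial F-test p-value (0.05).
#' @param r_guard collinearity guard on the correlation with included
#'   predictors (0.9).
#' @return a `regression_result` (standardized betas over the included
#'   predictors, `included` in entry order, `empty` flag).
#' @export
forward_stepwise <- function(y, X, alpha_in = 0.05, r_guard = 0.9) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  included <- character(0)
  r2_cur <- 0
  repeat {
    candidates <- setdiff(colnames(X), included)
    if (!length(candidates)) break
    best <- NULL
    for (v in candidates) {
      if (length(included) &&
          any(abs(stats::cor(X[, v], X[, included, drop = FALSE])) > r_guard))
        next
      cols <- c(included, v)
      fit <- stats::lm(y ~ X[, cols, drop = FALSE])
      r2_new <- summary(fit)$r.squared
      if (is.null(best) || r2_new > best$r2) best <- list(v = v, r2 = r2_new)
    }
    if (is.null(best)) break
    p_full <- length(included) + 1L
    f_stat <- (best$r2 - r2_cur) / ((1 - best$r2) / (n - p_full - 1L))
    p_val <- stats::pf(f_stat, 1, n - p_full - 1L, lower.tail = FALSE)
    if (!is.finite(p_val) || p_val >= alpha_in) break
    included <- c(included, best$v)
    r2_cur <- best$r2
  }
  if (!length(included)) {
    return(structure(list(r2 = 0, beta = numeric(0), p_values = numeric(0),
                          predictors = character(0), included = character(0),
                          n = n, empty = TRUE),
                     class = "regression_result"))
  }
  res <- ols_standardized(y, X[, included, drop = FALSE])
  res$included <- included
  res$empty <- FALSE
  res
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way ANOVA on a complete balanced subjects-by-
#' conditions table: `F = MS_condition / MS_(condition x subject)` with
#' `df = (k - 1, (k - 1)(n - 1))`. No sphericity correction is applied by
#' default; a Greenhouse-Geisser corrected p-value is available as an
#' option.
#'
#' @param values numeric matrix, rows = subjects, columns = conditions.
#' @param gg_correction also report the Greenhouse-Geisser corrected test
#'   (default FALSE).
#' @return list with `F`, `df1`, `df2`, `p`, the mean squares, and (if
#'   requested) `epsilon`/`p_gg`.
#' @export
rm_anova <- function(values, gg_correction = FALSE) {
  values <- as.matrix(values)
  if (any(!is.finite(values)))
    stop("unbalanced-design: missing cells in the subjects x conditions table",
         call. = FALSE)
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L)
    stop("invalid-input: need at least 2 subjects and 2 conditions",
         call. = FALSE)
  grand <- mean(values)
  cond_means <- colMeans(values)
  subj_means <- rowMeans(values)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f <- if (ms_err > 0) ms_cond / ms_err else if (ms_cond == 0) 0 else Inf
  out <- list(F = f, df1 = df1, df2 = df2,
              p = stats::pf(f, df1, df2, lower.tail = FALSE),
              ms_condition = ms_cond, ms_error = ms_err, n = n, k = k)
  if (gg_correction) {
    S <- stats::cov(values)
    dbar <- mean(diag(S)); sbar <- mean(S)
    rowbar <- rowMeans(S)
    num <- (k * (dbar - sbar))^2
    den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowbar^2) + k^2 * sbar^2)
    eps <- if (den > 0) num / den else 1
    eps <- min(1, max(1 / (k - 1), eps))
    out$epsilon <- eps
    out$p_gg <- stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE)
  }
  out
}

#' Tukey HSD post hoc test on repeated-measures condition means
#'
#' Studentized-range test on all pairwise condition differences using the
#' repeated-measures ANOVA error term (`MS_(condition x subject)` with its
#' degrees of freedom).
#'
#' @param values numeric matrix, rows = subjects, columns = conditions (the
#'   table that was fed to [rm_anova()]).
#' @param ms_error,df_error error mean square and df; taken from
#'   [rm_anova()] on `values` when omitted.
#' @return data.frame with one row per pair: `a`, `b`, `diff`, `q`, `p`.
#' @export
tukey_posthoc <- function(values, ms_error = NULL, df_error = NULL) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (is.null(ms_error) || is.null(df_error)) {
    an <- rm_anova(values)
    ms_error <- an$ms_error; df_error <- an$df2
  }
  if (ms_error <= 0) stop("invalid-input: non-positive error mean square",
                          call. = FALSE)
  m <- colMeans(values)
  labs <- colnames(values)
  if (is.null(labs)) labs <- paste0("c", seq_len(k))
  pairs <- utils::combn(k, 2)
  se <- sqrt(ms_error / n)
  out <- data.frame(
    a = labs[pairs[1, ]], b = labs[pairs[2, ]],
    diff = m[pairs[2, ]] - m[pairs[1, ]], stringsAsFactors = FALSE)
  out$q <- abs(out$diff) / se
  out$p <- stats::ptukey(out$q, nmeans = k, df = df_error, lower.tail = FALSE)
  rownames(out) <- NULL
  out
}

#' Fit a mono-exponential rise and report its asymptote
#'
#' Least-squares fit of `y(t) = A - (A - y0) * exp(-t / tau)` (asymptote
#' `A`, baseline `y0`, time constant `tau`). Initialisation is by grid
#' search over `tau` (each candidate reduces the problem to a linear fit);
#' the best candidate seeds a Levenberg-Marquardt refinement. A flat series
#' returns the constant as asymptote with `tau` flagged unidentifiable.
#'
#' @param t time in seconds.
#' @param y response values (e.g. 30-s-averaged VO2).
#' @param tau_grid grid of candidate time constants in seconds.
#' @return list of class `expfit_result`: `asymptote`, `tau`, `baseline`,
#'   `sse`, `identifiable`.
#' @export
fit_monoexp <- function(t, y, tau_grid = exp(seq(log(2), log(1000),
                                                 length.out = 60))) {
  if (length(t) != length(y) || length(y) < 5L)
    stop("invalid-input: need at least 5 (t, y) points", call. = FALSE)
  if (stats::sd(y) < 1e-10 * max(1, abs(mean(y)))) {
    return(structure(list(asymptote = mean(y), tau = NA_real_,
                          baseline = mean(y), sse = sum((y - mean(y))^2),
                          identifiable = FALSE), class = "expfit_result"))
  }
  best <- NULL
  for (tau in tau_grid) {
    e <- exp(-t / tau)
    fit <- stats::lm(y ~ e)
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(tau = tau, A = stats::coef(fit)[1],
                   B = stats::coef(fit)[2], sse = sse)
  }
  A0 <- unname(best$A); y00 <- unname(best$A + best$B); tau0 <- best$tau
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A - (A - y0) * exp(-t / tau),
                      start = list(A = A0, y0 = y00, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    if (is.null(best))
      stop("fit-failure: mono-exponential fit did not converge", call. = FALSE)
    return(structure(list(asymptote = A0, tau = tau0, baseline = y00,
                          sse = best$sse, identifiable = TRUE),
                     class = "expfit_result"))
  }
  cf <- stats::coef(fit)
  structure(list(asymptote = unname(cf["A"]), tau = unname(cf["tau"]),
                 baseline = unname(cf["y0"]),
                 sse = sum(stats::resid(fit)^2), identifiable = TRUE),
            class = "expfit_result")
}

#' @export
print.expfit_result <- function(x, ...) {
  cat(sprintf("<expfit_result> asymptote = %.3f, tau = %s s, baseline = %.3f\n",
              x$asymptote,
              if (is.na(x$tau)) "unidentifiable" else sprintf("%.1f", x$tau),
              x$baseline))
  invisible(x)
}
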