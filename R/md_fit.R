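# Binomial-mixture maximum-likelihood estimation of the ctDNA fraction
# (MD ratio) and the Wald MRD score.
#
# Model: for each selected methylation block j, the methylated read count
# in plasma is k_j ~ Binomial(n_j, theta_j(alpha)) with
#   theta_j(alpha) = alpha * p_T_j + (1 - alpha) * p_N_j,
# alpha in [0,1] the fraction of cfDNA derived from the tumor. theta is
# linear in alpha and the binomial log-likelihood is concave in theta,
# so l(alpha) is concave and has a unique interior maximum (or a flat
# stretch when p_T ~= p_N everywhere).

#' Mixture methylation rate of one block
#'
#' The expected methylated fraction of a block when a fraction `alpha` of
#' cfDNA derives from tumor: `alpha * p_T + (1 - alpha) * p_N`, clamped
#' to `[1e-6, 1 - 1e-6]` so fully (un)methylated blocks cannot produce
#' `log(0)` downstream. Vectorised over all arguments.
#'
#' @param alpha Tumor (ctDNA) fraction in \[0,1\].
#' @param p_T Tumor methylation rate in \[0,1\].
#' @param p_N Normal-plasma background rate in \[0,1\].
#' @return The clamped mixture rate theta.
#' @export
mixture_rate <- function(alpha, p_T, p_N) {
  clamp_rate(alpha * p_T + (1 - alpha) * p_N)
}

#' Mixture-model log-likelihood of the ctDNA fraction
#'
#' Sum over blocks of `k * log(theta) + (n - k) * log(1 - theta)` with
#' `theta = mixture_rate(alpha, p_T, p_N)`; binomial coefficients are
#' constant in `alpha` and omitted. Vectorised over `alpha`.
#'
#' @param alpha Numeric vector of candidate ctDNA fractions in \[0,1\].
#' @param blocks Data frame with columns `k`, `n`, `p_T`, `p_N`
#'   (see [make_mixture_blocks()]).
#' @return Log-likelihood value(s), one per element of `alpha`.
#' @export
md_loglik <- function(alpha, blocks) {
  stopifnot(all(c("k", "n", "p_T", "p_N") %in% names(blocks)))
  if (nrow(blocks) == 0L) stop("empty block set", call. = FALSE)
  p_T <- clamp_rate(blocks$p_T); p_N <- clamp_rate(blocks$p_N)
  vapply(alpha, function(a) {
    th <- mixture_rate(a, p_T, p_N)
    sum(blocks$k * log(th) + (blocks$n - blocks$k) * log1p(-th))
  }, numeric(1))
}

#' Fisher information for the ctDNA fraction
#'
#' Expected information `I(alpha) = sum_j n_j (p_T_j - p_N_j)^2 /
#' (theta_j (1 - theta_j))`, the negative expected curvature of
#' [md_loglik()]. Its inverse is the asymptotic variance of the MLE.
#'
#' @inheritParams md_loglik
#' @param alpha A single ctDNA fraction in \[0,1\].
#' @return The information, a non-negative scalar.
#' @export
fisher_information <- function(alpha, blocks) {
  stopifnot(length(alpha) == 1L, alpha >= 0, alpha <= 1)
  p_T <- clamp_rate(blocks$p_T); p_N <- clamp_rate(blocks$p_N)
  th <- mixture_rate(alpha, p_T, p_N)
  sum(blocks$n * (p_T - p_N)^2 / (th * (1 - th)))
}

#' Fit the MD ratio (ctDNA fraction) of a plasma sample
#'
#' Maximises [md_loglik()] over `alpha` in \[0,1\] by bounded scalar
#' optimisation, evaluates the Fisher information at the maximum, and
#' derives the Wald MRD score `alpha_hat * sqrt(I(alpha_hat))` testing
#' the null `alpha = 0`. Zero-read blocks are dropped before fitting
#' (they carry no likelihood contribution) but are counted. A flat
#' likelihood — all blocks with `p_T ~= p_N`, or tied values at the
#' optimum — resolves conservatively to the smallest maximiser, so a
#' completely uninformative sample returns `alpha_hat = 0`, infinite
#' variance and `wald = 0`.
#'
#' @param blocks Data frame with columns `k`, `n`, `p_T`, `p_N`; one row
#'   per selected methylation block (see [make_mixture_blocks()]).
#' @param sample_id Optional sample label stored on the fit.
#' @return An object of class `md_fit`: a list with `alpha_hat`,
#'   `variance` (`1/I(alpha_hat)`, possibly `Inf`), `wald`, `loglik`
#'   (at the maximum), `n_blocks_used`, `n_reads_used`, `sample_id` and
#'   the fitted `blocks`.
#' @seealso [call_mrd()] for positivity, [mrd_score()] for the Wald
#'   statistic alone.
#' @examples
#' blocks <- data.frame(k = 10, n = 100, p_T = 1 - 1e-6, p_N = 1e-6)
#' fit <- fit_md_ratio(blocks)   # closed form: alpha_hat = k/n = 0.10
#' coef(fit)
#' @export
fit_md_ratio <- function(blocks, sample_id = NA_character_) {
  stopifnot(all(c("k", "n", "p_T", "p_N") %in% names(blocks)))
  if (nrow(blocks) == 0L) stop("empty block set", call. = FALSE)
  stopifnot(all(blocks$k >= 0), all(blocks$k <= blocks$n))
  used <- blocks[blocks$n > 0L, , drop = FALSE]
  if (nrow(used) == 0L || sum(used$n) == 0) {
    stop("no informative reads", call. = FALSE)
  }

  ll <- function(a) md_loglik(a, used)
  opt <- stats::optimize(ll, interval = c(0, 1), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  # candidates: interior optimum and both boundaries; prefer the smallest
  # alpha among (numerically) tied maxima — conservative toward the null
  cand <- c(0, opt$maximum, 1)
  vals <- c(ll(0), opt$objective, ll(1))
  best <- max(vals)
  alpha_hat <- min(cand[vals >= best - 1e-8])
  loglik <- vals[match(alpha_hat, cand)]

  info <- fisher_information(alpha_hat, used)
  variance <- if (info > 0) 1 / info else Inf
  wald <- if (alpha_hat > 0 && info > 0) alpha_hat * sqrt(info) else 0

  structure(list(alpha_hat = alpha_hat, variance = variance, wald = wald,
                 loglik = loglik, n_blocks_used = nrow(used),
                 n_reads_used = sum(used$n), n_blocks_dropped =
                   nrow(blocks) - nrow(used),
                 sample_id = sample_id, blocks = used),
            class = "md_fit")
}

#' Wald MRD score of a fitted MD ratio
#'
#' `alpha_hat / SE(alpha_hat) = alpha_hat * sqrt(I(alpha_hat))`; zero
#' when the estimate sits on the null boundary or the data carry no
#' information.
#'
#' @param fit An `md_fit` object.
#' @return The Wald statistic, a non-negative scalar.
#' @export
mrd_score <- function(fit) {
  stopifnot(inherits(fit, "md_fit"))
  fit$wald
}

#' Call methylation MRD positivity
#'
#' Positive when the Wald MRD score strictly exceeds the threshold; the
#' default 1.96 is the standard-normal upper-2.5% quantile, so under the
#' boundary null (`alpha = 0`) roughly 2.5% of negative samples exceed it.
#'
#' @param sample_id Sample label.
#' @param fit An `md_fit` object.
#' @param threshold Positivity cutoff on the Wald score, default 1.96.
#' @return An object of class `mrd_call`: list with `sample_id`,
#'   `estimate` (the fit), `positive`, `threshold`.
#' @export
call_mrd <- function(sample_id, fit, threshold = 1.96) {
  stopifnot(inherits(fit, "md_fit"), is.numeric(threshold))
  structure(list(sample_id = sample_id, estimate = fit,
                 positive = fit$wald > threshold, threshold = threshold),
            class = "mrd_call")
}

#' @export
print.md_fit <- function(x, digits = 4, ...) {
  cat("Tumor-informed methylation MRD fit",
      if (!is.na(x$sample_id)) paste0("(sample ", x$sample_id, ")"), "\n")
  cat("  MD ratio (alpha_hat):", format(x$alpha_hat, digits = digits), "\n")
  cat("  SE:", format(sqrt(x$variance), digits = digits),
      "  Wald MRD score:", format(x$wald, digits = digits), "\n")
  cat("  blocks used:", x$n_blocks_used,
      " reads used:", x$n_reads_used, "\n")
  invisible(x)
}

#' @export
summary.md_fit <- function(object, threshold = 1.96, ...) {
  out <- list(fit = object, threshold = threshold,
              positive = object$wald > threshold,
              se = sqrt(object$variance),
              ci = stats::setNames(confint(object), c("lower", "upper")))
  class(out) <- "summary.md_fit"
  out
}

#' @export
print.summary.md_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("  95% Wald CI: [", format(x$ci[["lower"]], digits = digits), ", ",
      format(x$ci[["upper"]], digits = digits), "]\n", sep = "")
  cat("  MRD", if (x$positive) "POSITIVE" else "negative",
      "at Wald threshold", format(x$threshold), "\n")
  invisible(x)
}

#' @export
coef.md_fit <- function(object, ...) {
  c(alpha_hat = object$alpha_hat)
}

#' @export
vcov.md_fit <- function(object, ...) {
  matrix(object$variance, 1, 1,
         dimnames = list("alpha_hat", "alpha_hat"))
}

#' @export
logLik.md_fit <- function(object, ...) {
  structure(object$loglik, df = 1L, nobs = object$n_blocks_used,
            class = "logLik")
}

#' @export
confint.md_fit <- function(object, parm = "alpha_hat", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(object$variance)
  c(max(0, object$alpha_hat - z * se), min(1, object$alpha_hat + z * se))
}

#' Pearson residuals of a fitted MD ratio
#'
#' Per-block `(k - n*theta) / sqrt(n*theta*(1-theta))` at the fitted
#' `alpha_hat`; useful for spotting blocks whose plasma counts the
#' mixture model does not explain.
#'
#' @param object An `md_fit` object.
#' @param ... Unused.
#' @return Numeric vector, one residual per fitted block.
#' @export
residuals.md_fit <- function(object, ...) {
  b <- object$blocks
  th <- mixture_rate(object$alpha_hat, b$p_T, b$p_N)
  stats::setNames((b$k - b$n * th) / sqrt(b$n * th * (1 - th)),
                  b$block_id)
}

#' Simulate plasma block counts from a fitted MD ratio
#'
#' Parametric-bootstrap draws: for each fitted block, `k ~ Binomial(n,
#' theta(alpha_hat))` with the observed total reads `n`.
#'
#' @param object An `md_fit` object.
#' @param nsim Number of replicate count tables.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` data frames with columns `block_id`, `k`,
#'   `n`, `p_T`, `p_N`.
#' @export
simulate.md_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  b <- object$blocks
  th <- mixture_rate(object$alpha_hat, b$p_T, b$p_N)
  lapply(seq_len(nsim), function(i) {
    out <- b
    out$k <- stats::rbinom(nrow(b), b$n, th)
    out
  })
}

#' Profile log-likelihood plot of an MD-ratio fit
#'
#' Draws the log-likelihood over a grid of `alpha` values with the MLE
#' marked; the curvature at the maximum is what the Wald score measures.
#'
#' @param x An `md_fit` object.
#' @param n_grid Number of grid points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.md_fit <- function(x, n_grid = 401, ...) {
  upper <- min(1, max(4 * x$alpha_hat, 0.02))
  grid <- seq(0, upper, length.out = n_grid)
  ll <- md_loglik(grid, x$blocks)
  graphics::plot(grid, ll, type = "l", xlab = expression(alpha),
                 ylab = "log-likelihood",
                 main = "MD ratio profile likelihood", ...)
  graphics::abline(v = x$alpha_hat, lty = 2)
}

#' @export
print.mrd_call <- function(x, digits = 4, ...) {
  cat("MRD call for sample", x$sample_id, "->",
      if (x$positive) "POSITIVE" else "negative",
      "(Wald", format(x$estimate$wald, digits = digits),
      "vs threshold", format(x$threshold), ")\n")
  invisible(x)
}
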