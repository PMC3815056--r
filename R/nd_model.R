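#' Closed-form tetrad viability-class probabilities
#'
#' Probability model for the number of viable spores per tetrad under three
#' failure processes: with probability `d` the meiosis suffers MI
#' nondisjunction (all four spores aneuploid, hence inviable); otherwise
#' each of the two MII divisions independently fails with probability `m`
#' (the failed daughter's two spores are aneuploid); surviving euploid
#' spores then die independently with background probability `v`.
#'
#' @param v per-spore background death probability.
#' @param d MI nondisjunction probability per meiosis.
#' @param m MII nondisjunction probability per MII division.
#' @return Named numeric vector of class probabilities in the order
#'   `"4","3","2","1","0"` viable spores; sums to 1.
#' @export
nd_model_probs <- function(v, d, m) {
  stopifnot(v >= 0, v <= 1, d >= 0, d <= 1, m >= 0, m <= 1)
  surv4 <- stats::dbinom(4:0, 4L, 1 - v)   # P(k viable | 4 euploid), k=4..0
  surv2 <- stats::dbinom(2:0, 2L, 1 - v)   # P(k viable | 2 euploid), k=2..0
  p <- (1 - d) * (1 - m)^2 * surv4
  names(p) <- as.character(4:0)
  p[c("2", "1", "0")] <- p[c("2", "1", "0")] +
    (1 - d) * 2 * m * (1 - m) * surv2
  p["0"] <- p["0"] + (1 - d) * m^2 + d
  p
}

#' Relative likelihood of MI vs double-MII origin for zero-viable tetrads
#'
#' Decomposes the zero-viable class of [nd_model_probs()] into its
#' single-MI-event pathway (probability `d`) and its two-independent-rare-
#' events double-MII pathway (probability `(1 - d) m^2`) and returns their
#' ratio. A large ratio formalizes the argument that a zero-viable tetrad is
#' far more likely to reflect a single MI nondisjunction than two
#' simultaneous MII failures.
#'
#' @inheritParams nd_model_probs
#' @return `d / ((1 - d) * m^2)`; `Inf` when the denominator is zero with
#'   `d > 0`, `0` when `d = 0`.
#' @export
nd_zero_attribution <- function(v, d, m) {
  stopifnot(d >= 0, d <= 1, m >= 0, m <= 1)
  denom <- (1 - d) * m^2
  if (d == 0) return(0)
  if (denom == 0) return(Inf)
  d / denom
}

nd_loglik <- function(par, counts) {
  p <- nd_model_probs(par[1L], par[2L], par[3L])
  sum(counts * log(pmax(p, 1e-300)))
}

nd_fit_once <- function(counts, starts) {
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], nd_loglik, counts = counts,
                   method = "L-BFGS-B", lower = rep(0, 3), upper = rep(1, 3),
                   control = list(fnscale = -1)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value > best$value))
      best <- fit
  }
  if (is.null(best)) stop("nondisjunction model fit failed from all starts")
  best
}

#' Fit the nondisjunction model to tetrad counts
#'
#' Maximum-likelihood estimation of `(v, d, m)` for the multinomial model of
#' [nd_model_probs()], by bounded quasi-Newton optimization from multiple
#' starts, with bootstrap confidence intervals (tetrads resampled with
#' replacement, the model refit on each replicate).
#'
#' @param tc a [tetrad_counts()] vector (total tetrads should be at least
#'   20 for the fit to mean anything; fewer is an error).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return List of class `nd_fit` with `estimate` (named vector `v`, `d`,
#'   `m`), `loglik`, `ci` (matrix with `lower`/`upper` columns),
#'   `n_tetrads`, `n_boot`. A warning is issued when the likelihood is flat
#'   enough that bootstrap intervals span nearly the whole unit interval
#'   (non-identifiable fit).
#' @export
nd_fit <- function(tc, n_boot = 1000, seed = 1, conf = 0.95) {
  counts <- as.numeric(tc)
  stopifnot(length(counts) == 5L)
  n <- sum(counts)
  if (n < 20) stop("need at least 20 tetrads to fit the model")
  starts <- as.matrix(expand.grid(v = c(0.02, 0.2), d = c(0.02, 0.2),
                                  m = c(0.02, 0.2)))
  best <- nd_fit_once(counts, starts)
  est <- best$par
  names(est) <- c("v", "d", "m")

  set.seed(seed)
  probs <- counts / n
  boot <- matrix(NA_real_, n_boot, 3L, dimnames = list(NULL, c("v", "d", "m")))
  bstarts <- rbind(est, c(0.05, 0.05, 0.05))
  for (b in seq_len(n_boot)) {
    bc <- as.numeric(stats::rmultinom(1L, n, probs))
    boot[b, ] <- nd_fit_once(bc, bstarts)$par
  }
  alpha <- (1 - conf) / 2
  ci <- t(apply(boot, 2L, stats::quantile, probs = c(alpha, 1 - alpha)))
  colnames(ci) <- c("lower", "upper")
  if (any(ci[, "upper"] - ci[, "lower"] > 0.95))
    warning("likelihood nearly flat for at least one parameter; ",
            "fit may be non-identifiable")
  structure(list(estimate = est, loglik = best$value, ci = ci,
                 n_tetrads = n, n_boot = n_boot, conf = conf),
            class = "nd_fit")
}

#' @export
print.nd_fit <- function(x, ...) {
  cat("Nondisjunction model fit (", x$n_tetrads, " tetrads)\n", sep = "")
  for (p in c("v", "d", "m"))
    cat(sprintf("  %s = %.4f  [%.4f, %.4f]\n", p, x$estimate[[p]],
                x$ci[p, "lower"], x$ci[p, "upper"]))
  cat(sprintf("  log-likelihood %.2f; %d bootstrap reps, %.0f%% CI\n",
              x$loglik, x$n_boot, 100 * x$conf))
  invisible(x)
}
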