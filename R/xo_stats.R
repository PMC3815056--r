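#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by probability ordering: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (the common
#' convention; ties included with a small relative tolerance).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(rbind(c(16, 84), c(1, 99)))  # < 0.01
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("fisher_exact is for 2x2 tables; use tetrad_distribution_test ",
         "or chisq_mc for larger tables")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  m <- sum(tab[1L, ]); n <- sum(tab[2L, ]); k <- sum(tab[, 1L])
  if (m + n == 0) stop("empty table")
  x <- tab[1L, 1L]
  support <- max(0L, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  sum(d[d <= d[support == x] * (1 + 1e-07)])
}

#' Pearson chi-square test of independence
#'
#' Asymptotic test, no continuity correction; `df = (r-1)(c-1)`.
#'
#' @param tab r x c matrix of counts with positive margins.
#' @return Named numeric vector `c(statistic=, df=, p_value=)`.
#' @export
chisq_indep <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin")
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - exp)^2 / exp)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  c(statistic = x2, df = df,
    p_value = stats::pchisq(x2, df, lower.tail = FALSE))
}

#' Monte-Carlo chi-square test of independence
#'
#' Pearson statistic with a Monte-Carlo p-value: `B` tables are drawn
#' uniformly over all tables with the observed margins (Patefield
#' generation, via [stats::chisq.test()]), and
#' `p = (1 + #\{X2_sim >= X2_obs\}) / (B + 1)`, which never returns zero.
#'
#' @param tab r x c count matrix with positive margins.
#' @param B number of Monte-Carlo samplings (default 2000).
#' @param seed optional integer; if given, the global RNG is seeded first so
#'   the p-value is reproducible.
#' @return Named numeric vector `c(statistic=, p_value=, B=)`.
#' @export
chisq_mc <- function(tab, B = 2000, seed = NULL) {
  if (B < 1) stop("B must be >= 1")
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin")
  if (!is.null(seed)) set.seed(seed)
  ct <- stats::chisq.test(tab, simulate.p.value = TRUE, B = B)
  c(statistic = unname(ct$statistic), p_value = ct$p.value, B = B)
}

#' Compare two interval maps
#'
#' Reproduces the strain-comparison battery for two genotype datasets over
#' the same markers: (i) a per-interval Fisher exact test on the
#' (recombinant, parental) x strain table; (ii) a whole-chromosome test
#' treating the chromosome as one interval -- a chi-square on total
#' recombination events vs informative non-events per strain (this 2x2
#' construction is a reconstruction: the exact table behind published
#' whole-chromosome chi-squares is rarely stated); (iii) a crossover
#' distribution test: Monte-Carlo chi-square on the intervals x strain
#' recombinant-count table (intervals with no events in either strain drop
#' out, as they carry no distributional information).
#'
#' @param im_a,im_b [interval_map()]s over identical intervals.
#' @param B Monte-Carlo samplings for the distribution test.
#' @param seed optional seed for the distribution test.
#' @param labels strain labels for the report.
#' @return List of class `map_comparison`: `per_interval` (data.frame),
#'   `total` (map lengths and whole-chromosome chi-square),
#'   `distribution` (Monte-Carlo chi-square result).
#' @export
compare_maps <- function(im_a, im_b, B = 2000, seed = NULL,
                         labels = c("strain_a", "strain_b")) {
  if (!identical(im_a$interval, im_b$interval))
    stop("interval maps cover different intervals")
  per <- data.frame(interval = im_a$interval,
                    cM_a = im_a$cM, cM_b = im_b$cM,
                    p_value = NA_real_)
  for (i in seq_len(nrow(per))) {
    tab <- rbind(c(im_a$n_recombinant[i],
                   im_a$n_informative[i] - im_a$n_recombinant[i]),
                 c(im_b$n_recombinant[i],
                   im_b$n_informative[i] - im_b$n_recombinant[i]))
    per$p_value[i] <- tryCatch(fisher_exact(tab), error = function(e) NA_real_)
  }
  tot_tab <- rbind(c(sum(im_a$n_recombinant),
                     sum(im_a$n_informative - im_a$n_recombinant)),
                   c(sum(im_b$n_recombinant),
                     sum(im_b$n_informative - im_b$n_recombinant)))
  total <- list(map_length_a = map_length(im_a), map_length_b = map_length(im_b),
                chisq = chisq_indep(tot_tab))
  keep <- im_a$n_recombinant + im_b$n_recombinant > 0
  dist_tab <- rbind(im_a$n_recombinant[keep], im_b$n_recombinant[keep])
  distribution <- if (ncol(dist_tab) >= 2L)
    chisq_mc(dist_tab, B = B, seed = seed) else NULL
  structure(list(per_interval = per, total = total,
                 distribution = distribution, labels = labels,
                 note = paste("whole-chromosome test uses the events vs",
                              "informative-complement 2x2 reconstruction")),
            class = "map_comparison")
}

#' @export
print.map_comparison <- function(x, ...) {
  cat("Map comparison:", x$labels[1L], "vs", x$labels[2L], "\n")
  cat(sprintf("  total map length: %.1f vs %.1f cM (chi-square p = %.4g)\n",
              x$total$map_length_a, x$total$map_length_b,
              x$total$chisq[["p_value"]]))
  if (!is.null(x$distribution))
    cat(sprintf("  crossover distribution: MC chi-square p = %.4g (B = %d)\n",
                x$distribution[["p_value"]], x$distribution[["B"]]))
  sig <- x$per_interval[!is.na(x$per_interval$p_value) &
                        x$per_interval$p_value < 0.05, ]
  cat("  intervals with p < 0.05:",
      if (nrow(sig)) paste(sig$interval, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Overall viability from tetrad counts
#'
#' `100 * sum(k * n_k) / (4 * sum(n_k))` over the 4..0-viable classes.
#'
#' @param tc a [tetrad_counts()] vector.
#' @return Percent viability.
#' @export
total_viability <- function(tc) {
  stopifnot(length(tc) == 5L)
  n <- sum(tc)
  if (n == 0) stop("no tetrads")
  100 * sum((4:0) * as.numeric(tc)) / (4 * n)
}

#' Exact test for a difference in tetrad viability distributions
#'
#' Fisher exact test on the 2x5 table of tetrads with 4, 3, 2, 1 or 0
#' viable spores per strain. Full enumeration (network algorithm) where
#' feasible; for tables too large to enumerate, falls back to a Monte-Carlo
#' chi-square with `B >= 10000`, flagged as approximate in the result.
#'
#' @param a,b [tetrad_counts()] for the two strains.
#' @param B Monte-Carlo samplings for the fallback.
#' @param seed optional seed for the fallback.
#' @return List with `p_value`, `method` (`"exact"` or `"monte-carlo"`).
#' @export
tetrad_distribution_test <- function(a, b, B = 10000, seed = NULL) {
  tab <- rbind(as.numeric(a), as.numeric(b))
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  ex <- tryCatch(stats::fisher.test(tab, workspace = 2e6),
                 error = function(e) NULL)
  if (!is.null(ex))
    return(list(p_value = ex$p.value, method = "exact"))
  if (B < 10000) B <- 10000
  mc <- chisq_mc(tab, B = B, seed = seed)
  list(p_value = unname(mc[["p_value"]]), method = "monte-carlo")
}

#' Mean spore viability from germination spots
#'
#' The unweighted mean of per-spot germination percentages (each spot
#' counts equally, regardless of how many spores it held).
#'
#' @param spots data.frame with columns `germinated` and `total`.
#' @return Mean percent germination.
#' @export
spore_viability <- function(spots) {
  stopifnot(is.data.frame(spots),
            all(c("germinated", "total") %in% names(spots)))
  if (nrow(spots) == 0L) stop("no spots")
  if (any(spots$total <= 0)) stop("spot totals must be positive")
  mean(100 * spots$germinated / spots$total)
}
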