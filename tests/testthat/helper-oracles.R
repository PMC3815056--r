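# Independent oracles used across tests. These deliberately avoid the code
# paths of the functions they check.

# Two-sided Fisher p for a 2x2 table by explicit enumeration over all tables
# with the observed margins, probabilities from products of binomial
# coefficients.
fisher_enum_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  N <- r1 + r2
  ks <- max(0, c1 - r2):min(c1, r1)
  pr <- choose(r1, ks) * choose(r2, c1 - ks) / choose(N, c1)
  obs <- pr[ks == tab[1, 1]]
  sum(pr[pr <= obs * (1 + 1e-07)])
}

# All first rows of 2xC tables with the observed margins, with their
# conditional (multivariate hypergeometric) log-probabilities.
enum_2xc_tables <- function(tab) {
  r1 <- sum(tab[1, ]); cols <- colSums(tab); N <- sum(tab)
  C <- length(cols)
  enum <- function(i, remaining, acc) {
    if (i == C) {
      if (remaining <= cols[C]) return(list(c(acc, remaining)))
      return(list())
    }
    out <- list()
    for (x in 0:min(cols[i], remaining))
      out <- c(out, enum(i + 1L, remaining - x, c(acc, x)))
    out
  }
  tables <- enum(1L, r1, integer(0))
  lp <- vapply(tables, function(x1) sum(lchoose(cols, x1)) - lchoose(N, r1),
               numeric(1))
  list(rows = tables, lp = lp, cols = cols, r1 = r1, N = N)
}

# Two-sided exact p for a 2xC table by full enumeration (probability
# ordering, the Fisher convention). Feasible for small N only.
fisher_enum_2xc <- function(tab) {
  e <- enum_2xc_tables(tab)
  obs <- sum(lchoose(e$cols, tab[1, ])) - lchoose(e$N, e$r1)
  sum(exp(e$lp[e$lp <= obs + 1e-07]))
}

# Exact conditional p for the Pearson statistic (X2 ordering): the
# permutation p that a Monte-Carlo chi-square estimates.
chisq_perm_exact_2xc <- function(tab) {
  e <- enum_2xc_tables(tab)
  r2 <- e$N - e$r1
  x2 <- vapply(e$rows, function(x1) pearson_x2(rbind(x1, e$cols - x1)),
               numeric(1))
  obs <- pearson_x2(tab)
  sum(exp(e$lp[x2 >= obs - 1e-09]))
}

# Pearson X2 from first principles
pearson_x2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# tiny two-chromosome-free helpers
toy_markers <- function(n = 4, chrom = "c1", spacing_bp = 10000) {
  marker_table(data.frame(marker = paste0("m", seq_len(n)), chrom = chrom,
                          pos_bp = spacing_bp * seq_len(n), type = "SNP"))
}

toy_gm <- function(rows, markers) {
  gm <- do.call(rbind, rows)
  rownames(gm) <- paste0("s", seq_along(rows))
  colnames(gm) <- markers$marker
  gm
}
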