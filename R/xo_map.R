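#' Call crossovers from genotype switches
#'
#' Scans each spore's non-NA calls in map order within each chromosome; each
#' change of parental origin between consecutive non-NA calls is one
#' crossover event, localized to the span between those two markers. A span
#' that crosses one or more NA calls still counts as one event for the
#' spore, but (by design) is excluded from single-interval tallies, because
#' the interval in which the exchange happened is ambiguous. Spores with
#' fewer than two non-NA calls on a chromosome contribute no events there.
#'
#' @param gm character genotype matrix (spores x markers, `P1`/`P2`/`NA`).
#' @param markers a [marker_table()]; columns of `gm` must match
#'   `markers$marker` in order.
#' @return An object of class `crossover_calls`: data.frame with columns
#'   `spore`, `chrom`, `left_marker`, `right_marker`, `left_idx`,
#'   `right_idx`, `adjacent` (logical: span is a single interval). The
#'   attribute `spores` holds all spore ids (including those with no
#'   events); `all_na` flags spores with no usable calls.
#' @export
call_crossovers <- function(gm, markers) {
  stopifnot(identical(colnames(gm), markers$marker))
  res <- list()
  for (ch in unique(markers$chrom)) {
    idx <- which(markers$chrom == ch)
    sub <- gm[, idx, drop = FALSE]
    for (s in seq_len(nrow(sub))) {
      obs <- which(!is.na(sub[s, ]))
      if (length(obs) < 2L) next
      calls <- sub[s, obs]
      sw <- which(calls[-1L] != calls[-length(calls)])
      if (length(sw)) {
        li <- obs[sw]; ri <- obs[sw + 1L]
        res[[length(res) + 1L]] <- data.frame(
          spore = rownames(gm)[s], chrom = ch,
          left_marker = markers$marker[idx[li]],
          right_marker = markers$marker[idx[ri]],
          left_idx = idx[li], right_idx = idx[ri],
          adjacent = (ri - li) == 1L)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res)
         else data.frame(spore = character(0), chrom = character(0),
                         left_marker = character(0), right_marker = character(0),
                         left_idx = integer(0), right_idx = integer(0),
                         adjacent = logical(0))
  attr(out, "spores") <- rownames(gm)
  attr(out, "all_na") <- rownames(gm)[rowSums(!is.na(gm)) == 0L]
  class(out) <- c("crossover_calls", "data.frame")
  out
}

#' Per-spore crossover counts
#'
#' @param ccs a [call_crossovers()] result.
#' @param chrom optional chromosome id to restrict to.
#' @return Named integer vector over all spores (zeros included).
#' @export
crossover_counts <- function(ccs, chrom = NULL) {
  spores <- attr(ccs, "spores")
  d <- if (is.null(chrom)) ccs else ccs[ccs$chrom == chrom, , drop = FALSE]
  n <- table(factor(d$spore, levels = spores))
  out <- as.integer(n)
  names(out) <- spores
  out
}

#' Count spores with two or more crossovers
#'
#' Multi-crossover spores diagnose weakened crossover interference; the
#' count is per chromosome (a spore with two events on one chromosome).
#'
#' @inheritParams crossover_counts
#' @return Integer count.
#' @export
count_multi_co_spores <- function(ccs, chrom = NULL) {
  chroms <- if (is.null(chrom)) unique(ccs$chrom) else chrom
  sum(vapply(chroms, function(ch) sum(crossover_counts(ccs, ch) >= 2L),
             integer(1)))
}

#' Classify a genetic interval by its physical-to-genetic ratio
#'
#' Hotspots are below `hot` kb/cM, cold regions above `cold` kb/cM, and
#' average rates of recombination lie between them (boundary values count
#' as average). An interval with no recombinants is `"linked"` regardless of
#' physical size.
#'
#' @param kb_per_cm numeric vector of kb/cM ratios (may contain `Inf`).
#' @param linked logical vector: zero recombinants observed.
#' @param hot,cold class boundaries in kb/cM (defaults 15 and 75).
#' @return Character vector: `"hotspot"`, `"average"`, `"cold"`, `"linked"`.
#' @export
classify_interval <- function(kb_per_cm, linked = FALSE, hot = 15, cold = 75) {
  n <- max(length(kb_per_cm), length(linked))
  kb_per_cm <- rep_len(kb_per_cm, n)
  linked <- rep_len(linked, n)
  ifelse(linked, "linked",
         ifelse(kb_per_cm < hot, "hotspot",
                ifelse(kb_per_cm > cold, "cold", "average")))
}

#' Build the interval genetic map
#'
#' For each adjacent-marker interval, counts spores informative at both
#' flanking markers (`n_informative`) and those whose flanking calls differ
#' (`n_recombinant`). Two-point distance is the uncorrected recombinant
#' fraction, `cM = 100 * n_recombinant / n_informative` (no mapping
#' function), matching adjacent-marker map arithmetic. `kb_per_cM` is the
#' physical span divided by cM; zero-recombinant intervals are classed
#' `"linked"`, intervals with no informative spores `"no-data"`.
#'
#' @inheritParams call_crossovers
#' @param hot,cold classification boundaries (kb/cM), see
#'   [classify_interval()].
#' @return An object of class `interval_map`: data.frame with columns
#'   `interval`, `chrom`, `left_marker`, `right_marker`, `n_informative`,
#'   `n_recombinant`, `cM`, `physical_kb`, `kb_per_cM`, `class`.
#' @export
interval_map <- function(gm, markers, hot = 15, cold = 75) {
  stopifnot(identical(colnames(gm), markers$marker))
  rows <- list()
  for (ch in unique(markers$chrom)) {
    idx <- which(markers$chrom == ch)
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      a <- gm[, i]; b <- gm[, j]
      inf <- !is.na(a) & !is.na(b)
      rec <- sum(inf & a != b, na.rm = TRUE)
      ninf <- sum(inf)
      cm <- if (ninf > 0L) 100 * rec / ninf else NA_real_
      kb <- (markers$pos_bp[j] - markers$pos_bp[i]) / 1000
      kbcm <- if (is.na(cm) || cm == 0) Inf else kb / cm
      cls <- if (ninf == 0L) "no-data"
             else classify_interval(kbcm, linked = rec == 0L,
                                    hot = hot, cold = cold)
      rows[[length(rows) + 1L]] <- data.frame(
        interval = paste0(markers$marker[i], "/", markers$marker[j]),
        chrom = ch, left_marker = markers$marker[i],
        right_marker = markers$marker[j],
        n_informative = ninf, n_recombinant = rec, cM = cm,
        physical_kb = kb, kb_per_cM = kbcm, class = cls)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("interval_map", "data.frame")
  out
}

#' Total map length
#'
#' Sum of interval cM over intervals with data; `"linked"` intervals
#' contribute 0 cM (linked is a class label, not infinite tightness).
#'
#' @param im an [interval_map()].
#' @param chrom optional chromosome restriction.
#' @return Map length in cM.
#' @export
map_length <- function(im, chrom = NULL) {
  if (!is.null(chrom)) im <- im[im$chrom %in% chrom, , drop = FALSE]
  sum(im$cM[im$class != "no-data"], na.rm = TRUE)
}

#' Coefficient of coincidence for an interval pair
#'
#' `coc = f(double) / (f(a) * f(b))` over spores informative at all four
#' (or three, if the intervals share a marker) flanking markers. Values
#' near 1 indicate no interference; below 1, positive interference.
#' Undefined (NA) when either single-interval frequency is zero.
#'
#' @inheritParams call_crossovers
#' @param interval_a,interval_b intervals given as their left marker name.
#' @return List with `coc`, `n_double_observed`, `n_double_expected`,
#'   `n_informative`, and the single-interval recombinant frequencies.
#' @export
coefficient_of_coincidence <- function(gm, markers, interval_a, interval_b) {
  li <- function(mk) {
    i <- match(mk, markers$marker)
    if (is.na(i) || i >= nrow(markers)) stop("no interval left-anchored at ", mk)
    i
  }
  ia <- li(interval_a); ib <- li(interval_b)
  need <- unique(c(ia, ia + 1L, ib, ib + 1L))
  inf <- rowSums(is.na(gm[, need, drop = FALSE])) == 0L
  n <- sum(inf)
  if (n == 0L) stop("no spores informative across both intervals")
  ra <- gm[inf, ia] != gm[inf, ia + 1L]
  rb <- gm[inf, ib] != gm[inf, ib + 1L]
  fa <- mean(ra); fb <- mean(rb)
  obs <- sum(ra & rb)
  expd <- fa * fb * n
  coc <- if (fa == 0 || fb == 0) NA_real_ else obs / expd
  list(coc = coc, n_double_observed = obs, n_double_expected = expd,
       n_informative = n, freq_a = fa, freq_b = fb)
}

#' Write an interval map as TSV
#'
#' @param im an [interval_map()].
#' @param path output path.
#' @export
write_interval_map <- function(im, path) {
  utils::write.table(as.data.frame(im), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
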