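#' Define a chromosome for simulation
#'
#' @param chrom_id character scalar.
#' @param length_bp chromosome length in bp.
#' @param centromere_bp centromere position in bp.
#' @param markers data.frame with columns `name` and `pos_bp`, strictly
#'   increasing positions.
#' @return An object of class `chromosome_def`.
#' @export
chromosome_def <- function(chrom_id, length_bp, centromere_bp, markers) {
  stopifnot(is.data.frame(markers), all(c("name", "pos_bp") %in% names(markers)))
  markers$pos_bp <- as.numeric(markers$pos_bp)
  if (anyDuplicated(markers$name)) stop("duplicate marker names")
  if (is.unsorted(markers$pos_bp, strictly = TRUE))
    stop("marker positions must be strictly increasing")
  if (centromere_bp < 1 || centromere_bp > length_bp)
    stop("centromere outside chromosome")
  if (any(markers$pos_bp < 1) || any(markers$pos_bp > length_bp))
    stop("marker position outside chromosome")
  structure(list(chrom_id = chrom_id, length_bp = as.numeric(length_bp),
                 centromere_bp = as.numeric(centromere_bp),
                 markers = markers),
            class = "chromosome_def")
}

#' Crossover placement model
#'
#' Two modes. `"renewal"` places crossover positions along the bivalent by a
#' stationary gamma renewal process with mean count `lambda` per bivalent
#' and shape `nu` (`nu = 1` is a Poisson process, i.e. no interference;
#' larger `nu` gives positive interference). `"interval_rates"` draws an
#' independent Poisson count for each inter-marker interval with the given
#' expected counts and places events uniformly within the interval (used to
#' emulate localized hotspots). With `obligate_co = TRUE`, bivalents with no
#' crossover are resampled (rejection), enforcing the obligate-crossover
#' rule exactly for the zero class.
#'
#' @param mode `"renewal"` or `"interval_rates"`.
#' @param lambda expected crossovers per bivalent (renewal mode).
#' @param nu gamma shape, `>= 1` (renewal mode).
#' @param interval_rates numeric vector of expected crossovers per bivalent
#'   per inter-marker interval, length `nrow(markers) - 1` (interval mode).
#' @param obligate_co logical; require at least one crossover per bivalent.
#' @return An object of class `crossover_model`.
#' @export
crossover_model <- function(mode = c("renewal", "interval_rates"),
                            lambda = NULL, nu = 1, interval_rates = NULL,
                            obligate_co = FALSE) {
  mode <- match.arg(mode)
  if (mode == "renewal") {
    stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0)
    if (nu < 1) stop("nu must be >= 1")
    if (lambda == 0 && obligate_co)
      stop("lambda = 0 with obligate_co is unsatisfiable")
  } else {
    stopifnot(is.numeric(interval_rates), all(interval_rates >= 0))
    if (all(interval_rates == 0) && obligate_co)
      stop("all-zero interval rates with obligate_co is unsatisfiable")
  }
  structure(list(mode = mode, lambda = lambda, nu = nu,
                 interval_rates = interval_rates,
                 obligate_co = isTRUE(obligate_co)),
            class = "crossover_model")
}

#' Simulation configuration
#'
#' @param n_meioses number of meioses (tetrads) to simulate.
#' @param mi_nd_rate probability of meiosis I nondisjunction per meiosis.
#' @param mii_nd_rate probability of meiosis II nondisjunction per MII
#'   division (each meiosis has two).
#' @param spore_death_rate probability that a euploid spore dies anyway
#'   (independent per spore).
#' @param missing_call_rate probability that a genotype call fails (NA).
#' @param seed integer seed; mandatory, for reproducibility.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_meioses, mi_nd_rate = 0, mii_nd_rate = 0,
                       spore_death_rate = 0, missing_call_rate = 0, seed) {
  rates <- c(mi_nd_rate, mii_nd_rate, spore_death_rate, missing_call_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (missing(seed)) stop("seed is mandatory")
  structure(list(n_meioses = as.integer(n_meioses),
                 mi_nd_rate = mi_nd_rate, mii_nd_rate = mii_nd_rate,
                 spore_death_rate = spore_death_rate,
                 missing_call_rate = missing_call_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# stationary gamma renewal positions on (0, L]: the interval covering the
# origin is length-biased Gamma(nu + 1, rate), and the delay to the first
# event is uniform within it; subsequent spacings are Gamma(nu, rate)
renewal_positions <- function(length_bp, lambda, nu) {
  if (lambda <= 0) return(numeric(0))
  rate <- nu * lambda / length_bp
  pos <- stats::runif(1) * stats::rgamma(1, shape = nu + 1, rate = rate)
  out <- numeric(0)
  while (pos <= length_bp) {
    out <- c(out, pos)
    pos <- pos + stats::rgamma(1, shape = nu, rate = rate)
  }
  out
}

#' Simulate crossovers on one bivalent
#'
#' Positions are drawn at the four-chromatid stage; each crossover is then
#' assigned one chromatid from each homolog uniformly at random (no
#' chromatid interference). Chromatids 1-2 are the parent-1 sisters,
#' 3-4 the parent-2 sisters.
#'
#' @param chrom a [chromosome_def()].
#' @param model a [crossover_model()].
#' @return data.frame with columns `pos_bp`, `chromatid_a` (1 or 2) and
#'   `chromatid_b` (3 or 4), sorted by position. Zero rows when no
#'   crossover forms. Uses R's global RNG.
#' @export
simulate_crossovers <- function(chrom, model) {
  repeat {
    if (model$mode == "renewal") {
      pos <- renewal_positions(chrom$length_bp, model$lambda, model$nu)
    } else {
      mpos <- chrom$markers$pos_bp
      k <- length(mpos) - 1L
      if (length(model$interval_rates) != k)
        stop("interval_rates length must be number of markers - 1")
      counts <- stats::rpois(k, model$interval_rates)
      pos <- unlist(lapply(which(counts > 0L), function(i)
        stats::runif(counts[i], mpos[i], mpos[i + 1L])), use.names = FALSE)
      pos <- sort(pos)
    }
    if (!model$obligate_co || length(pos) > 0L) break
  }
  n <- length(pos)
  data.frame(pos_bp = pos,
             chromatid_a = sample(c(1L, 2L), n, replace = TRUE),
             chromatid_b = sample(c(3L, 4L), n, replace = TRUE))
}

# 4 x n_markers character matrix of parental origins after recombination.
# Crossovers join the four original chromatid molecules at their positions;
# each meiotic product is the path that starts at a molecule's left end and
# switches to the partner molecule at every crossover involving the molecule
# it currently travels on. Because partners always come from opposite
# homologs, a product's parental origin flips at each involving crossover.
recombine_chromatids <- function(crossovers, marker_pos) {
  mol <- 1:4                      # molecule each product currently rides
  out <- matrix(NA_character_, 4L, length(marker_pos))
  xo_pos <- crossovers$pos_bp
  j <- 1L
  for (i in seq_along(marker_pos)) {
    while (j <= length(xo_pos) && xo_pos[j] < marker_pos[i]) {
      a <- which(mol == crossovers$chromatid_a[j])
      b <- which(mol == crossovers$chromatid_b[j])
      tmp <- mol[a]; mol[a] <- mol[b]; mol[b] <- tmp
      j <- j + 1L
    }
    out[, i] <- ifelse(mol <= 2L, "P1", "P2")
  }
  out
}

#' Segregate one meiosis into a tetrad
#'
#' Meiosis I separates the two homolog centromeres; meiosis II separates
#' sisters, so spores 1-2 carry chromatids 1-2 (daughter A) and spores 3-4
#' chromatids 3-4 (daughter B). MI nondisjunction sends both homologs to one
#' pole: two disomic and two nullisomic spores, all aneuploid. MII
#' nondisjunction in a daughter makes that daughter's two spores aneuploid.
#' Aneuploid spores are inviable; euploid spores additionally survive an
#' independent Bernoulli(1 - spore_death_rate) draw.
#'
#' @param crossovers list of crossover data.frames, one per chromosome
#'   (as from [simulate_crossovers()]).
#' @param chroms list of [chromosome_def()]s, parallel to `crossovers`.
#' @param nd_event one of `"none"`, `"MI"`, `"MII_one"`, `"MII_both"`.
#' @param spore_death_rate per-spore background death probability.
#' @param tetrad_id identifier.
#' @return An object of class `tetrad_record`: list with `tetrad_id`,
#'   `haplotypes` (list of 4 x n_marker origin matrices per chromosome),
#'   `euploid`, `viable` (logical 4-vectors) and `nd_event`.
#' @export
segregate_tetrad <- function(crossovers, chroms, nd_event = "none",
                             spore_death_rate = 0, tetrad_id = "t1") {
  stopifnot(nd_event %in% c("none", "MI", "MII_one", "MII_both"))
  if (inherits(chroms, "chromosome_def")) chroms <- list(chroms)
  if (is.data.frame(crossovers)) crossovers <- list(crossovers)
  haplos <- lapply(seq_along(chroms), function(i)
    recombine_chromatids(crossovers[[i]], chroms[[i]]$markers$pos_bp))
  names(haplos) <- vapply(chroms, `[[`, "", "chrom_id")
  euploid <- rep(TRUE, 4L)
  if (nd_event == "MI") {
    euploid[] <- FALSE
  } else if (nd_event == "MII_one") {
    bad <- sample(c(1L, 2L), 1L)               # which daughter failed
    euploid[if (bad == 1L) 1:2 else 3:4] <- FALSE
  } else if (nd_event == "MII_both") {
    euploid[] <- FALSE
  }
  viable <- euploid & (stats::runif(4L) >= spore_death_rate)
  structure(list(tetrad_id = tetrad_id, haplotypes = haplos,
                 euploid = euploid, viable = viable, nd_event = nd_event),
            class = "tetrad_record")
}

#' Simulate a population of meioses
#'
#' Runs `config$n_meioses` meioses, drawing a nondisjunction event for each
#' (MI with probability `mi_nd_rate`; otherwise each MII division fails
#' independently with probability `mii_nd_rate`), and genotypes the viable
#' spores at the marker positions (random-spore design). Each genotype call
#' is lost (NA) independently with probability `missing_call_rate`.
#'
#' The global RNG is seeded from `config$seed`, so output is a pure
#' function of (chroms, model, config).
#'
#' @param chroms a [chromosome_def()] or list of them.
#' @param model a [crossover_model()], or list of models parallel to
#'   `chroms`.
#' @param config a [sim_config()].
#' @return List with `tetrads` (list of [segregate_tetrad()] records),
#'   `genotypes` (character matrix, viable spores x markers, values
#'   `"P1"`/`"P2"`/`NA`), and `markers` (marker table data.frame with
#'   columns `marker`, `chrom`, `pos_bp`, `type`).
#' @export
simulate_population <- function(chroms, model, config) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(chroms, "chromosome_def")) chroms <- list(chroms)
  if (inherits(model, "crossover_model"))
    model <- rep(list(model), length(chroms))
  stopifnot(length(model) == length(chroms))
  set.seed(config$seed)

  mt <- do.call(rbind, lapply(chroms, function(ch)
    data.frame(marker = ch$markers$name, chrom = ch$chrom_id,
               pos_bp = ch$markers$pos_bp, type = "SNP")))
  n_mark <- nrow(mt)

  tetrads <- vector("list", config$n_meioses)
  geno_rows <- list()
  for (t in seq_len(config$n_meioses)) {
    nd <- if (stats::runif(1) < config$mi_nd_rate) "MI" else {
      fails <- stats::runif(2) < config$mii_nd_rate
      c("none", "MII_one", "MII_both")[sum(fails) + 1L]
    }
    xos <- lapply(seq_along(chroms), function(i)
      simulate_crossovers(chroms[[i]], model[[i]]))
    tet <- segregate_tetrad(xos, chroms, nd_event = nd,
                            spore_death_rate = config$spore_death_rate,
                            tetrad_id = sprintf("t%04d", t))
    tetrads[[t]] <- tet
    for (s in which(tet$viable)) {
      calls <- unlist(lapply(tet$haplotypes, function(h) h[s, ]),
                      use.names = FALSE)
      lost <- stats::runif(n_mark) < config$missing_call_rate
      calls[lost] <- NA_character_
      geno_rows[[sprintf("%s_s%d", tet$tetrad_id, s)]] <- calls
    }
  }
  geno <- if (length(geno_rows)) {
    g <- do.call(rbind, geno_rows)
    colnames(g) <- mt$marker
    g
  } else {
    matrix(NA_character_, 0L, n_mark, dimnames = list(NULL, mt$marker))
  }
  list(tetrads = tetrads, genotypes = geno, markers = mt)
}

#' Tally viable spores per tetrad
#'
#' @param tetrads list of `tetrad_record`s (from [simulate_population()]),
#'   or a numeric vector of per-tetrad viable-spore counts.
#' @return Named integer vector of class `tetrad_counts` with elements
#'   `"4"`, `"3"`, `"2"`, `"1"`, `"0"`: the number of tetrads with that many
#'   viable spores.
#' @export
tetrad_counts <- function(tetrads) {
  k <- if (is.numeric(tetrads)) as.integer(tetrads)
       else vapply(tetrads, function(t) sum(t$viable), integer(1))
  if (any(k < 0L | k > 4L)) stop("viable counts must be in 0..4")
  out <- vapply(4:0, function(i) sum(k == i), integer(1))
  names(out) <- as.character(4:0)
  class(out) <- "tetrad_counts"
  out
}
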