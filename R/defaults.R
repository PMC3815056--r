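# Study-condition defaults: a two-strain random-spore mapping design on
# chromosome 3 (14 markers) and the chromosome 8 hotspot region (10
# markers), with subtelomeric crossover hotspots, plus tetrad-viability
# parameters for a wild-type-like and a mutant-like strain. Interval
# physical sizes and genetic sizes are a synthetic reconstruction chosen
# once to give maps of the published order (~0.9 vs ~1.5 Morgans on
# chromosome 3) and the published kb/cM interval classes; they are
# emulation parameters, not measurements.

cc_intervals <- function(chrom = c("chr3", "chr8")) {
  chrom <- match.arg(chrom)
  if (chrom == "chr3") {
    data.frame(
      interval = c("A/B", "B/C", "C/D", "D/E", "E/F", "F/G", "G/H", "H/I",
                   "I/J", "J/K", "K/L", "L/M", "M/N"),
      kb = c(24.72, 34.22, 117.36, 377.16, 334.44, 374.58, 219.20, 150.00,
             607.68, 777.06, 443.94, 280.42, 242.40),
      cm_wt = c(12, 2, 12, 4, 6, 3, 5, 0, 2, 3, 6, 14, 24),
      cm_mut = c(9.93, 22.81, 15.18, 14.74, 8.88, 10.40, 5.00, 0.43, 0,
                 3.40, 21.61, 24.53, 22.63))
  } else {
    data.frame(
      interval = c("A/B", "B/C", "C/D", "D/E", "E/F", "F/G", "G/H", "H/I",
                   "I/J"),
      kb = c(24.60, 33.80, 48.96, 300, 300, 300, 300, 219.28, 101.64),
      cm_wt = c(6, 10, 4, 1, 1, 1, 1, 8, 14),
      cm_mut = c(0, 9.77, 18.00, 1, 1, 1, 1, 15.61, 10.92))
  }
}

#' Study-condition chromosome definitions
#'
#' Synthetic marker layouts emulating the mapped chromosomes: 14 markers
#' (`A`..`N`) spanning chromosome 3 and 10 markers (`A`..`J`) on chromosome
#' 8, with subtelomeric hotspot intervals at the chromosome ends and the
#' centromere in the marker-poor middle.
#'
#' @param chrom `"chr3"` or `"chr8"`.
#' @return A [chromosome_def()].
#' @export
cc_chromosome <- function(chrom = c("chr3", "chr8")) {
  chrom <- match.arg(chrom)
  iv <- cc_intervals(chrom)
  pos <- 25000 + c(0, cumsum(iv$kb * 1000))
  nms <- LETTERS[seq_len(nrow(iv) + 1L)]
  cent <- if (chrom == "chr3") mean(pos[8:9]) else mean(pos[5:6])
  chromosome_def(chrom, length_bp = pos[length(pos)] + 25000,
                 centromere_bp = cent,
                 markers = data.frame(name = paste0(chrom, "_", nms),
                                      pos_bp = pos))
}

#' Study-condition crossover models
#'
#' Per-interval Poisson rates reconstructed from the target interval
#' genetic sizes: a spore sees a crossover with probability
#' `(1 - exp(-r)) / 2` when the bivalent receives Poisson(`r`) crossovers
#' in the interval, so `r = -log(1 - cM/50)`.
#'
#' @param chrom `"chr3"` or `"chr8"`.
#' @param strain `"wildtype"` or `"nbs1-2"`.
#' @return A [crossover_model()] in `interval_rates` mode.
#' @export
cc_crossover_model <- function(chrom = c("chr3", "chr8"),
                               strain = c("wildtype", "nbs1-2")) {
  chrom <- match.arg(chrom); strain <- match.arg(strain)
  iv <- cc_intervals(chrom)
  cm <- if (strain == "wildtype") iv$cm_wt else iv$cm_mut
  crossover_model(mode = "interval_rates",
                  interval_rates = -log(1 - cm / 50))
}

#' Study-condition tetrad / noise parameters
#'
#' Nondisjunction and death rates chosen once so that the closed-form
#' expected overall viability `(1-d)(1-m)(1-v)` and the zero-viable class
#' match the published tetrad phenotypes of the two strains (~92% viability
#' and ~1% zero-viable tetrads for wild type; ~73% and ~16% for the
#' mutant), with a 3% genotyping-failure rate.
#'
#' @param strain `"wildtype"` or `"nbs1-2"`.
#' @param n_meioses number of meioses.
#' @param seed integer seed.
#' @return A [sim_config()].
#' @export
cc_sim_config <- function(strain = c("wildtype", "nbs1-2"),
                          n_meioses = 100, seed = 1) {
  strain <- match.arg(strain)
  if (strain == "wildtype")
    sim_config(n_meioses, mi_nd_rate = 0.01, mii_nd_rate = 0.005,
               spore_death_rate = 0.0635, missing_call_rate = 0.03,
               seed = seed)
  else
    sim_config(n_meioses, mi_nd_rate = 0.15, mii_nd_rate = 0.02,
               spore_death_rate = 0.125, missing_call_rate = 0.03,
               seed = seed)
}

#' Simulate one study cross
#'
#' Simulates enough meioses of the given strain to yield `n_spores` viable
#' spores for random-spore mapping (the genotype matrix is trimmed to
#' exactly `n_spores` rows), plus `n_tetrads` dissected tetrads for the
#' viability analysis.
#'
#' @param strain `"wildtype"` or `"nbs1-2"`.
#' @param chrom `"chr3"`, `"chr8"`, or `"both"`.
#' @param n_spores spores genotyped (random-spore design; default 100).
#' @param n_tetrads tetrads dissected (default 100).
#' @param seed integer seed.
#' @return List with `genotypes`, `markers`, `tetrad_counts`, `tetrads`,
#'   `strain`.
#' @export
study_cross <- function(strain = c("wildtype", "nbs1-2"),
                        chrom = c("chr3", "chr8", "both"),
                        n_spores = 100, n_tetrads = 100, seed = 1) {
  strain <- match.arg(strain); chrom <- match.arg(chrom)
  chs <- if (chrom == "both") c("chr3", "chr8") else chrom
  chroms <- lapply(chs, cc_chromosome)
  models <- lapply(chs, cc_crossover_model, strain = strain)
  viab <- if (strain == "wildtype") 0.92 else 0.73
  n_meio <- ceiling(n_spores / (4 * viab) * 1.25) + 5L
  pop <- simulate_population(chroms, models,
                             cc_sim_config(strain, n_meioses = n_meio,
                                           seed = seed))
  if (nrow(pop$genotypes) < n_spores)
    stop("simulation yielded only ", nrow(pop$genotypes),
         " viable spores; increase n_meioses margin")
  tet <- simulate_population(chroms[1L], models[1L],
                             cc_sim_config(strain, n_meioses = n_tetrads,
                                           seed = seed + 1L))
  list(genotypes = pop$genotypes[seq_len(n_spores), , drop = FALSE],
       markers = marker_table(pop$markers),
       tetrad_counts = tetrad_counts(tet$tetrads),
       tetrads = tet$tetrads,
       strain = strain)
}
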