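#' Run the full analysis pipeline
#'
#' Orchestrates simulate / load -> crossover calling -> genetic map ->
#' strain comparison -> tetrad analysis -> allele annotation, and writes a
#' report bundle to `out_dir`:
#' \itemize{
#'   \item `map_<strain>.tsv` -- per-interval genetic map per strain;
#'   \item `comparison.tsv`, `comparison.json` -- per-interval tests, total
#'     map lengths, whole-chromosome chi-square, Monte-Carlo distribution
#'     test;
#'   \item `tetrads.tsv` -- viability-class counts, overall viability and
#'     fitted nondisjunction parameters per strain, plus the
#'     distribution test;
#'   \item `allele_effects.tsv` -- protein effects of the gene alleles;
#'   \item `manifest.json` -- config, seeds and package version, sufficient
#'     to reproduce the bundle exactly.
#' }
#'
#' @param config configuration list, or path to a YAML file with the same
#'   structure. Top-level keys: `strains` (list of two entries, each with
#'   `name` and exactly one of `sim: true` (study defaults for that strain
#'   name) or `genotypes:`/`markers:` file paths), `chrom` (`"chr3"`,
#'   `"chr8"` or `"both"`, for simulated strains), `seed` (required when
#'   any strain is simulated or a Monte-Carlo test runs), and optional
#'   `analysis` overrides (`B`, `hot`, `cold`, `n_spores`, `n_tetrads`,
#'   `n_boot`).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`maps`,
#'   `comparison`, `tetrads`, `nd_fits`, `allele_effects`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$strains) || length(config$strains) != 2L)
    stop("config must define exactly two strains")
  an <- config$analysis
  B <- an$B %||% 2000
  hot <- an$hot %||% 15; cold <- an$cold %||% 75
  n_spores <- an$n_spores %||% 100
  n_tetrads <- an$n_tetrads %||% 100
  n_boot <- an$n_boot %||% 200
  chrom <- config$chrom %||% "chr3"

  any_sim <- any(vapply(config$strains, function(s) isTRUE(s$sim), logical(1)))
  if ((any_sim || B > 0) && is.null(config$seed))
    stop("config$seed is required when any stochastic stage is enabled")
  seed <- as.integer(config$seed %||% 1L)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf("[%5.1fs] ",
    as.numeric(difftime(Sys.time(), t0, units = "secs"))), ...)

  strains <- list()
  for (i in seq_along(config$strains)) {
    sc <- config$strains[[i]]
    if (is.null(sc$name)) stop("each strain needs a name")
    has_sim <- isTRUE(sc$sim)
    has_files <- !is.null(sc$genotypes)
    if (has_sim == has_files)
      stop("strain '", sc$name,
           "': exactly one of sim or genotype inputs is required")
    if (has_sim) {
      log_stage("simulating strain ", sc$name)
      strains[[sc$name]] <- study_cross(sc$name, chrom = chrom,
                                        n_spores = n_spores,
                                        n_tetrads = n_tetrads,
                                        seed = seed + 100L * i)
    } else {
      log_stage("loading strain ", sc$name, " from ", sc$genotypes)
      gm <- read_genotype_matrix(sc$genotypes)
      mt <- marker_table(utils::read.delim(sc$markers,
                                           stringsAsFactors = FALSE))
      tc <- if (!is.null(sc$tetrads)) {
        tt <- utils::read.delim(sc$tetrads, stringsAsFactors = FALSE)
        tetrad_counts(tapply(tt$viable, tt$tetrad_id, sum))
      } else NULL
      strains[[sc$name]] <- list(genotypes = gm, markers = mt,
                                 tetrad_counts = tc, strain = sc$name)
    }
  }

  maps <- list()
  for (nm in names(strains)) {
    s <- strains[[nm]]
    log_stage("mapping strain ", nm, " (", nrow(s$genotypes), " spores)")
    maps[[nm]] <- interval_map(s$genotypes, s$markers, hot = hot, cold = cold)
    write_interval_map(maps[[nm]],
                       file.path(out_dir, paste0("map_", gsub("[^A-Za-z0-9._-]", "_", nm), ".tsv")))
    ccs <- call_crossovers(s$genotypes, s$markers)
    utils::write.table(as.data.frame(ccs),
                       file.path(out_dir, paste0("events_", gsub("[^A-Za-z0-9._-]", "_", nm), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  log_stage("comparing maps")
  cmp <- compare_maps(maps[[1L]], maps[[2L]], B = B, seed = seed + 7L,
                      labels = names(strains))
  utils::write.table(cmp$per_interval, file.path(out_dir, "comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(labels = cmp$labels,
         total = list(map_length = c(cmp$total$map_length_a,
                                     cmp$total$map_length_b),
                      chisq = as.list(cmp$total$chisq)),
         distribution = as.list(cmp$distribution),
         per_interval = cmp$per_interval),
    file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA)

  tet_rows <- list(); nd_fits <- list()
  for (nm in names(strains)) {
    tc <- strains[[nm]]$tetrad_counts
    if (is.null(tc)) next
    log_stage("tetrad analysis for ", nm)
    fit <- nd_fit(tc, n_boot = n_boot, seed = seed + 11L)
    nd_fits[[nm]] <- fit
    tet_rows[[nm]] <- data.frame(
      strain = nm, t(as.numeric(tc)),
      total_viability = total_viability(tc),
      v_hat = fit$estimate[["v"]], d_hat = fit$estimate[["d"]],
      m_hat = fit$estimate[["m"]])
  }
  tet_p <- NA_real_
  if (length(tet_rows) == 2L) {
    tcs <- lapply(strains, `[[`, "tetrad_counts")
    tet_p <- tetrad_distribution_test(tcs[[1L]], tcs[[2L]],
                                      seed = seed + 13L)$p_value
  }
  if (length(tet_rows)) {
    tet <- do.call(rbind, tet_rows)
    names(tet)[2:6] <- paste0("viable_", 4:0)
    tet$distribution_p <- tet_p
    utils::write.table(tet, file.path(out_dir, "tetrads.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else tet <- NULL

  log_stage("annotating gene alleles")
  eff <- nbs1_effect_table()
  utils::write.table(eff, file.path(out_dir, "allele_effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "sporemap",
    version = as.character(utils::packageVersion("sporemap")),
    seed = seed, B = B, chrom = chrom,
    n_spores = n_spores, n_tetrads = n_tetrads,
    strains = names(strains),
    config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("done")
  invisible(list(maps = maps, comparison = cmp, tetrads = tet,
                 nd_fits = nd_fits, allele_effects = eff,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
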