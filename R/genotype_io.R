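#' Marker table constructor / validator
#'
#' @param marker,chrom,pos_bp,type vectors of marker name, chromosome id,
#'   physical position (bp) and marker type (`"SSR"`, `"SNP"` or
#'   `"indel"`), or a data.frame with those columns as the single argument.
#' @return Validated data.frame of class `marker_table`.
#' @export
marker_table <- function(marker, chrom, pos_bp, type = "SNP") {
  mt <- if (is.data.frame(marker)) marker
        else data.frame(marker = marker, chrom = chrom, pos_bp = pos_bp,
                        type = type)
  stopifnot(all(c("marker", "chrom", "pos_bp") %in% names(mt)))
  if (is.null(mt$type)) mt$type <- "SNP"
  if (!all(mt$type %in% c("SSR", "SNP", "indel")))
    stop("marker type must be SSR, SNP or indel")
  if (anyDuplicated(mt$marker)) stop("duplicate marker names")
  for (ch in unique(mt$chrom)) {
    p <- mt$pos_bp[mt$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("marker positions not strictly increasing on chromosome ", ch)
  }
  class(mt) <- c("marker_table", "data.frame")
  mt
}

#' Parental allele table
#'
#' Alleles are fragment sizes (SSR/indel, numeric) or bases (SNP,
#' character); every marker must be informative (the parents differ).
#'
#' @param marker,p1_allele,p2_allele vectors, or a data.frame with those
#'   columns as the single argument.
#' @return Validated data.frame of class `parental_alleles`.
#' @export
parental_alleles <- function(marker, p1_allele, p2_allele) {
  pa <- if (is.data.frame(marker)) marker
        else data.frame(marker = marker, p1_allele = p1_allele,
                        p2_allele = p2_allele)
  stopifnot(all(c("marker", "p1_allele", "p2_allele") %in% names(pa)))
  if (anyDuplicated(pa$marker)) stop("duplicate marker names")
  if (any(pa$p1_allele == pa$p2_allele))
    stop("uninformative marker(s): parental alleles identical")
  class(pa) <- c("parental_alleles", "data.frame")
  pa
}

#' Call a parental allele from fragment peaks
#'
#' Implements the fragment-analysis acceptance rule: a peak is accepted only
#' if its height exceeds `min_height` (default 500 fluorescence units); a
#' sample with zero or multiple accepted peaks is rejected (NA). A single
#' accepted peak is matched to the parental fragment sizes within
#' `size_tol_bp`; a peak matching neither parent gives NA with a warning.
#'
#' The call is symmetric in the parent labels: swapping the parental allele
#' definitions swaps P1/P2 calls.
#'
#' @param peaks data.frame with columns `size_bp` and `height` (one
#'   fragment call: all peaks observed for one spore at one marker).
#' @param p1_allele,p2_allele parental fragment sizes (bp).
#' @param size_tol_bp size-matching tolerance (default 1 bp, single-repeat
#'   resolution on capillary sizing).
#' @param min_height acceptance threshold; a peak must be strictly higher.
#' @return `"P1"`, `"P2"` or `NA_character_`.
#' @export
call_allele <- function(peaks, p1_allele, p2_allele, size_tol_bp = 1,
                        min_height = 500) {
  stopifnot(is.data.frame(peaks), all(c("size_bp", "height") %in% names(peaks)),
            all(peaks$height >= 0))
  acc <- peaks[peaks$height > min_height, , drop = FALSE]
  if (nrow(acc) != 1L) return(NA_character_)
  sz <- acc$size_bp
  d1 <- abs(sz - as.numeric(p1_allele))
  d2 <- abs(sz - as.numeric(p2_allele))
  if (d1 <= size_tol_bp && d1 < d2) return("P1")
  if (d2 <= size_tol_bp && d2 < d1) return("P2")
  if (d1 <= size_tol_bp && d2 <= size_tol_bp) {
    warning("peak at ", sz, " bp matches both parents within tolerance")
    return(NA_character_)
  }
  warning("accepted peak at ", sz, " bp matches neither parental allele")
  NA_character_
}

#' Call a genotype matrix from a fragment-call table
#'
#' @param fragments data.frame with columns `spore_id`, `marker`,
#'   `size_bp`, `height` (one row per peak).
#' @param pa a [parental_alleles()] table (fragment sizes).
#' @param markers a [marker_table()] giving marker order.
#' @inheritParams call_allele
#' @return Character genotype matrix (spores x markers).
#' @export
call_alleles <- function(fragments, pa, markers, size_tol_bp = 1,
                         min_height = 500) {
  stopifnot(all(c("spore_id", "marker", "size_bp", "height") %in%
                names(fragments)))
  if (!all(fragments$marker %in% pa$marker))
    stop("fragment calls for markers absent from the parental table")
  spores <- unique(fragments$spore_id)
  gm <- matrix(NA_character_, length(spores), nrow(markers),
               dimnames = list(spores, markers$marker))
  for (i in seq_along(spores)) {
    fs <- fragments[fragments$spore_id == spores[i], , drop = FALSE]
    for (mk in unique(fs$marker)) {
      row <- pa[pa$marker == mk, ]
      gm[i, mk] <- call_allele(fs[fs$marker == mk, c("size_bp", "height")],
                               row$p1_allele, row$p2_allele,
                               size_tol_bp = size_tol_bp,
                               min_height = min_height)
    }
  }
  gm
}

#' Read / write a genotype matrix
#'
#' The on-disk format is TSV: first column `spore_id`, remaining columns one
#' per marker in map order; cells are `P1`, `P2` or `NA`. The round trip is
#' bit-identical including NA tokens.
#'
#' @param path file path.
#' @return For the reader, a character matrix with spore ids as rownames.
#' @export
read_genotype_matrix <- function(path) {
  if (file.size(path) == 0) stop("empty genotype file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (nrow(df) == 0L) stop("genotype file has no spore rows: ", path)
  if (names(df)[1L] != "spore_id")
    stop("first column of a genotype matrix must be spore_id")
  if (anyDuplicated(df$spore_id))
    stop("duplicate spore_id: ",
         df$spore_id[anyDuplicated(df$spore_id)][1L])
  gm <- as.matrix(df[, -1L, drop = FALSE])
  rownames(gm) <- df$spore_id
  bad <- which(matrix(!(gm %in% c("P1", "P2", "NA")), nrow(gm)),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("invalid genotype token '", gm[bad[1L, 1L], bad[1L, 2L]],
         "' at spore ", rownames(gm)[bad[1L, 1L]],
         ", marker ", colnames(gm)[bad[1L, 2L]])
  gm[gm == "NA"] <- NA_character_
  gm
}

#' @rdname read_genotype_matrix
#' @param gm character genotype matrix (values `P1`/`P2`/`NA`).
#' @export
write_genotype_matrix <- function(gm, path) {
  out <- gm
  out[is.na(out)] <- "NA"
  df <- data.frame(spore_id = rownames(gm), out, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pool two genotype datasets after a homogeneity check
#'
#' Before pooling two datasets (e.g. spores from two mushrooms of the same
#' cross), tests that their recombination behaviour is homogeneous: a Fisher
#' exact test per adjacent-marker interval on the (recombinant, parental) x
#' dataset table, and a chi-square test on all intervals combined (total
#' recombinants vs parentals). Pools only if every per-interval p exceeds
#' `interval_p` and the combined p exceeds `combined_p`; otherwise refuses
#' and returns the report.
#'
#' @param gm_a,gm_b genotype matrices over the same markers.
#' @param markers the shared [marker_table()].
#' @param interval_p per-interval homogeneity threshold (default 0.1).
#' @param combined_p combined-test threshold (default 0.05).
#' @return List with `pooled` (row-bound matrix, or `NULL` on refusal),
#'   `ok` (logical), `interval_tests` (data.frame of per-interval p) and
#'   `combined_p_value`.
#' @export
pool_datasets <- function(gm_a, gm_b, markers, interval_p = 0.1,
                          combined_p = 0.05) {
  if (!identical(colnames(gm_a), colnames(gm_b)))
    stop("datasets have different marker sets")
  if (!identical(colnames(gm_a), markers$marker))
    stop("genotype columns do not match the marker table")
  im_a <- interval_map(gm_a, markers)
  im_b <- interval_map(gm_b, markers)
  ps <- vapply(seq_len(nrow(im_a)), function(i) {
    tab <- rbind(c(im_a$n_recombinant[i], im_a$n_informative[i] - im_a$n_recombinant[i]),
                 c(im_b$n_recombinant[i], im_b$n_informative[i] - im_b$n_recombinant[i]))
    if (any(rowSums(tab) == 0L)) return(NA_real_)
    fisher_exact(tab)
  }, numeric(1))
  tot <- rbind(c(sum(im_a$n_recombinant), sum(im_a$n_informative - im_a$n_recombinant)),
               c(sum(im_b$n_recombinant), sum(im_b$n_informative - im_b$n_recombinant)))
  comb <- chisq_indep(tot)[["p_value"]]
  ok <- all(ps > interval_p, na.rm = TRUE) && comb > combined_p
  rn <- union(rownames(gm_a), rownames(gm_b))
  if (any(rownames(gm_a) %in% rownames(gm_b)))
    rownames(gm_b) <- paste0("b_", rownames(gm_b))
  list(pooled = if (ok) rbind(gm_a, gm_b) else NULL,
       ok = ok,
       interval_tests = data.frame(interval = im_a$interval, p_value = ps),
       combined_p_value = comb)
}
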