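#' Construct a gene model
#'
#' A gene model holds a genomic sequence in gene-local coordinates (1-based;
#' position 1 is the A of the start codon, sense strand) together with an
#' ordered set of exons. The concatenated exon sequence is the coding
#' sequence (CDS): it must start with ATG, end with a stop codon, and have
#' length divisible by 3.
#'
#' Introns are the gaps between consecutive exons. Each intron is expected to
#' end in the canonical AG 3' acceptor dinucleotide; a non-AG acceptor raises
#' a warning rather than an error, because splice-site mutants deliberately
#' destroy the acceptor.
#'
#' @param gene_id character scalar, gene identifier.
#' @param genomic_seq character scalar, DNA (A/C/G/T) in gene-local
#'   coordinates.
#' @param exons two-column matrix or data.frame of 1-based inclusive
#'   (start, end) exon intervals, in increasing order.
#' @return An object of class `gene_model` with elements `gene_id`,
#'   `genomic_seq` and `exons` (integer matrix with columns `start`, `end`).
#' @examples
#' g <- gene_model("toy", "ATGAAATAA", cbind(1, 9))
#' splice_cds(g)
#' @export
gene_model <- function(gene_id, genomic_seq, exons) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            is.character(genomic_seq), length(genomic_seq) == 1L)
  genomic_seq <- toupper(genomic_seq)
  if (grepl("[^ACGT]", genomic_seq))
    stop("genomic_seq contains non-ACGT characters")
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L) stop("exons must have two columns (start, end)")
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  n <- nchar(genomic_seq)
  if (any(exons[, "start"] > exons[, "end"]))
    stop("exon start greater than exon end")
  if (any(exons < 1L) || any(exons > n))
    stop("exon coordinates outside [1, length(genomic_seq)]")
  if (nrow(exons) > 1L) {
    if (is.unsorted(exons[, "start"], strictly = TRUE))
      stop("exons must be sorted by start position")
    if (any(exons[-1L, "start"] <= exons[-nrow(exons), "end"]))
      stop("exons overlap")
  }
  obj <- structure(list(gene_id = gene_id, genomic_seq = genomic_seq,
                        exons = exons),
                   class = "gene_model")
  cds <- splice_cds(obj)
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length (", nchar(cds), ") is not divisible by 3")
  if (substr(cds, 1L, 3L) != "ATG")
    stop("CDS does not begin with ATG")
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  if (!last %in% c("TAA", "TAG", "TGA"))
    stop("CDS does not end with a stop codon (found ", last, ")")
  bad <- which(!vapply(seq_len(nrow(exons))[-1L], function(i) {
    acc <- substr(genomic_seq, exons[i, "start"] - 2L, exons[i, "start"] - 1L)
    identical(acc, "AG")
  }, logical(1)))
  if (length(bad))
    warning("intron(s) ", paste(bad, collapse = ", "),
            " of ", gene_id, " do not end in the AG acceptor dinucleotide")
  obj
}

#' @export
print.gene_model <- function(x, ...) {
  cds <- splice_cds(x)
  cat("<gene_model> ", x$gene_id, ": ", nchar(x$genomic_seq), " bp, ",
      nrow(x$exons), " exon(s), CDS ", nchar(cds), " bp\n", sep = "")
  invisible(x)
}

#' Intron intervals of a gene model
#'
#' @param gene a [gene_model()].
#' @return Integer matrix with columns `start`, `end` (1-based inclusive),
#'   one row per intron; zero rows for single-exon genes.
#' @export
introns <- function(gene) {
  ex <- gene$exons
  k <- nrow(ex)
  if (k < 2L) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end"))))
  cbind(start = ex[-k, "end"] + 1L, end = ex[-1L, "start"] - 1L)
}

#' Splice a gene model into its coding sequence
#'
#' Concatenates the exon sequences in order.
#'
#' @param gene a [gene_model()].
#' @return Character scalar, the CDS.
#' @export
splice_cds <- function(gene) {
  paste(substring(gene$genomic_seq, gene$exons[, "start"],
                  gene$exons[, "end"]),
        collapse = "")
}

# standard nuclear genetic code, codon -> one-letter amino acid ('*' = stop)
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

# average residue masses (Da); protein MW = sum(residues) + one water
RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01528

#' Translate a coding sequence
#'
#' Translates with the standard nuclear genetic code, stopping at the first
#' in-frame stop codon. The returned protein excludes the stop symbol.
#' Trailing bases after the last complete codon are ignored (they can arise
#' in frameshifted mutants).
#'
#' @param cds character scalar, DNA starting with ATG.
#' @return Character scalar protein in one-letter code (may be `""` for an
#'   immediate stop).
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (nchar(cds) < 3L) stop("CDS shorter than one codon")
  if (substr(cds, 1L, 3L) != "ATG") stop("CDS does not start with ATG")
  ncod <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  aa <- CODON_TABLE[codons]
  if (anyNA(aa)) stop("invalid codon: ", codons[which(is.na(aa))[1L]])
  stop_at <- which(aa == "*")
  if (!length(stop_at))
    stop("translation runs off the end of the sequence (no in-frame stop)")
  paste(aa[seq_len(stop_at[1L] - 1L)], collapse = "")
}

#' Protein length and molecular weight
#'
#' Mass is the sum of average (not monoisotopic) residue masses plus one
#' water. The empty protein (immediate-stop mutants) is legal and weighs one
#' water.
#'
#' @param protein character scalar, one-letter amino-acid string.
#' @return Named numeric vector `c(length_aa=, mw_da=)`.
#' @export
protein_stats <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (nchar(protein) == 0L)
    return(c(length_aa = 0, mw_da = WATER_MASS))
  res <- strsplit(protein, "")[[1L]]
  m <- RESIDUE_MASS[res]
  if (anyNA(m)) stop("unknown residue symbol: ", res[which(is.na(m))[1L]])
  c(length_aa = length(res), mw_da = sum(m) + WATER_MASS)
}

#' Specify a mutation on a gene model
#'
#' Edits are given in gene-local coordinates on the wild-type sequence. A
#' substitution replaces `nchar(ref)` bases starting at `pos` by `alt` of the
#' same length; a deletion removes `nchar(ref)` bases (`alt` must be `""`).
#' `splice_mode` declares the splicing outcome of a splice-site edit:
#' `"default"` (exon structure unchanged), `retain_intron(k)` (intron k is
#' not spliced out), or `shift_acceptor(k, offset)` (intron k's 3' boundary
#' moves `offset` bases downstream, e.g. to the next cryptic AG).
#'
#' @param allele character scalar, allele name.
#' @param edits data.frame with columns `pos` (integer), `ref`, `alt`
#'   (character) and `kind` (`"substitution"` or `"deletion"`), sorted by
#'   position and non-overlapping. May have zero rows.
#' @param splice_mode a splice-mode object (see [retain_intron()],
#'   [shift_acceptor()]) or `"default"`.
#' @return An object of class `mutation_spec`.
#' @export
mutation_spec <- function(allele, edits = NULL, splice_mode = "default") {
  if (is.null(edits))
    edits <- data.frame(pos = integer(0), ref = character(0),
                        alt = character(0), kind = character(0))
  stopifnot(is.data.frame(edits),
            all(c("pos", "ref", "alt", "kind") %in% names(edits)))
  edits$pos <- as.integer(edits$pos)
  if (nrow(edits)) {
    if (!all(edits$kind %in% c("substitution", "deletion")))
      stop("edit kind must be 'substitution' or 'deletion'")
    if (is.unsorted(edits$pos, strictly = TRUE))
      stop("edits must be sorted by position and non-overlapping")
    ends <- edits$pos + nchar(edits$ref) - 1L
    if (nrow(edits) > 1L && any(edits$pos[-1L] <= ends[-nrow(edits)]))
      stop("edits overlap")
    bad <- edits$kind == "substitution" & nchar(edits$ref) != nchar(edits$alt)
    if (any(bad)) stop("substitution ref/alt lengths differ")
    if (any(edits$kind == "deletion" & nchar(edits$alt) > 0L))
      stop("deletion edits must have empty alt")
  }
  structure(list(allele = allele, edits = edits, splice_mode = splice_mode),
            class = "mutation_spec")
}

#' @rdname mutation_spec
#' @param k intron index (1-based, in wild-type intron order).
#' @export
retain_intron <- function(k) {
  structure(list(mode = "retain_intron", k = as.integer(k)),
            class = "splice_mode")
}

#' @rdname mutation_spec
#' @param offset_bp number of bases the 3' intron boundary moves downstream.
#' @export
shift_acceptor <- function(k, offset_bp) {
  structure(list(mode = "shift_acceptor", k = as.integer(k),
                 offset_bp = as.integer(offset_bp)),
            class = "splice_mode")
}

#' Apply a mutation spec to a gene model
#'
#' Every edit's `ref` must match the wild-type sequence at its position
#' (a mismatch is an error: it means the coordinates or the record are
#' wrong). Deletions shift downstream exon boundaries left; an edit that
#' removes an exon/intron boundary without an explicit `splice_mode` is an
#' error, so the caller must state the splicing outcome.
#'
#' @param gene wild-type [gene_model()].
#' @param mut a [mutation_spec()].
#' @return The mutant `gene_model`.
#' @export
apply_mutation <- function(gene, mut) {
  stopifnot(inherits(gene, "gene_model"), inherits(mut, "mutation_spec"))
  seq <- gene$genomic_seq
  exons <- gene$exons
  intr <- introns(gene)

  # splice-mode restructuring first (wild-type coordinates)
  if (inherits(mut$splice_mode, "splice_mode")) {
    sm <- mut$splice_mode
    if (sm$k < 1L || sm$k > nrow(intr))
      stop("splice_mode refers to intron ", sm$k, " but gene has ",
           nrow(intr), " introns")
    if (sm$mode == "retain_intron") {
      # merge exons k and k+1 across intron k
      exons <- rbind(
        exons[seq_len(sm$k - 1L), , drop = FALSE],
        cbind(start = exons[sm$k, "start"], end = exons[sm$k + 1L, "end"]),
        exons[-seq_len(sm$k + 1L), , drop = FALSE])
    } else if (sm$mode == "shift_acceptor") {
      exons[sm$k + 1L, "start"] <- exons[sm$k + 1L, "start"] + sm$offset_bp
      if (exons[sm$k + 1L, "start"] > exons[sm$k + 1L, "end"])
        stop("acceptor shift consumes the whole downstream exon")
    } else stop("unknown splice mode: ", sm$mode)
  }

  # apply edits right-to-left so earlier coordinates stay valid
  ed <- mut$edits
  if (nrow(ed)) {
    for (i in rev(seq_len(nrow(ed)))) {
      pos <- ed$pos[i]; ref <- toupper(ed$ref[i]); alt <- toupper(ed$alt[i])
      w <- nchar(ref)
      found <- substr(gene$genomic_seq, pos, pos + w - 1L)
      if (found != ref)
        stop("edit ref mismatch at ", pos, ": expected ", ref,
             " but wild-type has ", found)
      if (ed$kind[i] == "deletion") {
        # a deletion spanning an exon boundary needs a declared splice outcome
        hits_boundary <- any((exons[, "start"] > pos &
                              exons[, "start"] <= pos + w - 1L) |
                             (exons[, "end"] >= pos &
                              exons[, "end"] < pos + w - 1L))
        if (hits_boundary && identical(mut$splice_mode, "default"))
          stop("deletion at ", pos, " removes an exon/intron boundary; ",
               "an explicit splice_mode is required")
        seq <- paste0(substr(seq, 1L, pos - 1L),
                      substr(seq, pos + w, nchar(seq)))
        exons[exons[, "start"] > pos, "start"] <-
          exons[exons[, "start"] > pos, "start"] - w
        exons[exons[, "end"] >= pos, "end"] <-
          exons[exons[, "end"] >= pos, "end"] - w
      } else {
        substr(seq, pos, pos + w - 1L) <- alt
      }
    }
  }

  out <- structure(list(gene_id = paste0(gene$gene_id, ":", mut$allele),
                        genomic_seq = seq, exons = exons),
                   class = "gene_model")
  # mutants may lack stop/acceptor invariants on purpose; only structural
  # sanity is enforced here
  if (any(out$exons < 1L) || any(out$exons > nchar(seq)))
    stop("mutant exon coordinates out of range")
  out
}

#' Protein-level effect of a mutation
#'
#' Splices and translates the wild-type and mutant gene models and
#' classifies the difference:
#' \describe{
#'   \item{silent}{identical proteins.}
#'   \item{missense}{equal length, substitution(s) only; first differing
#'     residue reported.}
#'   \item{nonsense}{mutant CDS of wild-type length but translation stops
#'     early; `aa_position` is the residue replaced by the new stop.}
#'   \item{frameshift_truncation}{mutant CDS length differs from wild type
#'     (indel or splice change) and translation stops early.}
#'   \item{splice_disruption}{non-default splice mode with an in-frame
#'     protein change that is not a truncation.}
#' }
#' For truncating effects `truncated_length = aa_position - 1` (the mutant
#' protein length): a stop "replacing the amino acid at N" gives
#' `aa_position = N` and a protein of N - 1 residues.
#'
#' @param wild wild-type [gene_model()].
#' @param mut a [mutation_spec()].
#' @return A one-row data.frame of class `protein_effect` with columns
#'   `allele`, `kind`, `aa_position`, `ref_aa`, `alt_aa`, `truncated_length`.
#' @export
annotate_effect <- function(wild, mut) {
  mutant <- apply_mutation(wild, mut)
  wp <- translate_cds(splice_cds(wild))
  mp <- translate_cds(splice_cds(mutant))
  nw <- nchar(wp); nm <- nchar(mp)
  spliced_change <- !identical(mut$splice_mode, "default")
  len_changed <- nchar(splice_cds(mutant)) != nchar(splice_cds(wild))

  if (identical(wp, mp)) {
    eff <- data.frame(allele = mut$allele, kind = "silent",
                      aa_position = NA_integer_, ref_aa = NA_character_,
                      alt_aa = NA_character_, truncated_length = NA_integer_)
  } else if (nm < nw) {
    # truncated: the new stop replaces mutant residue nm + 1
    pos <- nm + 1L
    kind <- if (len_changed || spliced_change) "frameshift_truncation"
            else "nonsense"
    eff <- data.frame(allele = mut$allele, kind = kind, aa_position = pos,
                      ref_aa = if (pos <= nw) substr(wp, pos, pos) else NA_character_,
                      alt_aa = "*", truncated_length = nm)
  } else if (nm == nw) {
    diffs <- which(strsplit(wp, "")[[1L]] != strsplit(mp, "")[[1L]])
    pos <- diffs[1L]
    kind <- if (spliced_change) "splice_disruption" else "missense"
    eff <- data.frame(allele = mut$allele, kind = kind, aa_position = pos,
                      ref_aa = substr(wp, pos, pos),
                      alt_aa = substr(mp, pos, pos),
                      truncated_length = NA_integer_)
  } else {
    eff <- data.frame(allele = mut$allele, kind = "splice_disruption",
                      aa_position = NA_integer_, ref_aa = NA_character_,
                      alt_aa = NA_character_, truncated_length = NA_integer_)
  }
  class(eff) <- c("protein_effect", "data.frame")
  eff
}

#' Read a gene model from FASTA plus an exon table
#'
#' The FASTA file holds the genomic sequence in gene-local coordinates; the
#' exon table is TSV with columns `gene_id`, `exon_start`, `exon_end`.
#'
#' @param fasta path to a single-record FASTA file.
#' @param exon_tsv path to the exon table.
#' @return A [gene_model()].
#' @export
read_gene_model <- function(fasta, exon_tsv) {
  lines <- readLines(fasta)
  hdr <- grep("^>", lines)
  if (length(hdr) != 1L) stop("expected exactly one FASTA record")
  gene_id <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  seq <- paste(lines[-hdr], collapse = "")
  seq <- gsub("\\s", "", seq)
  ex <- utils::read.delim(exon_tsv, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "exon_start", "exon_end") %in% names(ex)))
  ex <- ex[ex$gene_id == gene_id, , drop = FALSE]
  if (!nrow(ex)) stop("no exon rows for gene ", gene_id)
  gene_model(gene_id, seq, cbind(ex$exon_start, ex$exon_end))
}

#' Write a gene model to FASTA plus an exon table
#'
#' @param gene a [gene_model()].
#' @param fasta,exon_tsv output paths.
#' @return Invisibly, `gene`.
#' @export
write_gene_model <- function(gene, fasta, exon_tsv) {
  seq <- gene$genomic_seq
  chunks <- substring(seq, seq(1L, nchar(seq), 70L),
                      pmin(seq(1L, nchar(seq), 70L) + 69L, nchar(seq)))
  writeLines(c(paste0(">", gene$gene_id), chunks), fasta)
  utils::write.table(
    data.frame(gene_id = gene$gene_id, exon_start = gene$exons[, "start"],
               exon_end = gene$exons[, "end"]),
    exon_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(gene)
}
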