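#' Synthetic nbs1 gene record
#'
#' A fully synthetic stand-in for the *Coprinopsis cinerea* `nbs1` gene,
#' generated in code (no sequence database is consulted). It reproduces the
#' documented structure of the real locus: a 3528-bp gene with 10 introns
#' (528 intronic bp), a 3000-bp coding region, and a 999-residue predicted
#' protein. The sequence is engineered so that the five classical `nbs1`
#' allele mutations, applied at their published gene-local coordinates,
#' produce their published protein effects:
#'
#' * `nbs1-2`: CC->TT at bp 188-189 changes serine to phenylalanine at
#'   amino acid 43 (TCC -> TTT in codon 43);
#' * `nbs1-3`/`nbs1-4`: C->T at bp 2126 creates a stop at amino acid 570;
#' * `nbs1-5`: a 1-bp substitution at 1072 plus a 1-bp deletion at 1074
#'   (GGCACT -> GGTA-T) gives alanine->valine at 288 with an immediate stop;
#' * `nbs1-1`: A->G at bp 1235 destroys the 3' acceptor of intron 5.
#'   Retaining the intron reads an immediate stop (truncation after amino
#'   acid 328); re-splicing at the next CAG, 40 bp downstream, shifts the
#'   frame so a stop replaces amino acid 400.
#'
#' Everywhere else the coding sequence is neutral filler (a fixed cycle of
#' sense codons), so the record is deterministic and carries no information
#' from the real deposited sequence beyond the published coordinates above.
#'
#' @return A [gene_model()] with `gene_id = "nbs1_synthetic"`.
#' @seealso [nbs1_alleles()] for the matching mutation specs.
#' @export
nbs1_gene <- function() {
  n_codons <- 1000L                     # 999 aa + stop
  filler <- c("GCT", "GAA", "TTC", "AAG", "GTC", "GAT", "CTC", "ACG",
              "TCT", "ATC", "GGA", "CCA", "TAC", "GTG", "AAC", "GCA",
              "CTT", "TCA", "GGT", "GAG", "AAA", "GTT", "GCC", "CTG",
              "ACC")
  codons <- filler[(seq_len(n_codons) - 1L) %% length(filler) + 1L]
  codons[1L] <- "ATG"
  codons[n_codons] <- "TAA"
  # codon 43: serine, with the CC dinucleotide at gene bp 188-189
  codons[43L] <- "TCC"
  # codons 287-290: GGCACT context at gene bp 1070-1075, Ala288, and a
  # one-base deletion at 1074 bringing TAA into frame at codon 289
  codons[287L] <- "GCG"
  codons[288L] <- "GCA"
  codons[289L] <- "CTA"
  codons[290L] <- "ACT"
  # codons 329-414: the exon-6 region is designed so that (i) the only CAG
  # in the 40 bp after the intron-5 acceptor ends exactly 40 bp downstream
  # and (ii) the +1-shifted frame created by re-splicing there is stop-free
  # until a TAA that lands at mutant residue 400
  codons[329:340] <- "GCT"
  codons[341L] <- "TCA"                 # ...TCA|G = the cryptic CAG
  codons[342:412] <- "GCT"
  codons[413L] <- "CTA"                 # shifted frame reads ...T AA -> stop
  codons[414L] <- "ACT"
  # codon 570: arginine CGA; C->T at its first base (gene bp 2126) -> TGA
  codons[570L] <- "CGA"
  cds <- paste(codons, collapse = "")
  stopifnot(nchar(cds) == 3000L)

  # introns: (CDS position after which the intron sits, intron length)
  intron_after <- c(100L, 300L, 500L, 700L, 984L, 1200L, 1500L,
                    2000L, 2400L, 2800L)
  intron_len <- c(60L, 50L, 50L, 49L, 43L, 83L, 83L, 36L, 36L, 38L)
  stopifnot(sum(intron_len) == 528L)
  intron_body <- function(len, first_stop = FALSE) {
    head <- if (first_stop) "TAA" else "GT"
    paste0(head, strrep("T", len - nchar(head) - 2L), "AG")
  }
  pieces <- character(0)
  exon_start <- integer(0); exon_end <- integer(0)
  cursor <- 0L            # gene-local position of last emitted base
  prev <- 0L              # last CDS position already emitted
  for (i in seq_along(intron_after)) {
    exon_seq <- substr(cds, prev + 1L, intron_after[i])
    pieces <- c(pieces, exon_seq)
    exon_start <- c(exon_start, cursor + 1L)
    cursor <- cursor + nchar(exon_seq)
    exon_end <- c(exon_end, cursor)
    # intron 5 starts with an in-frame stop so that retention truncates
    # immediately; all introns end in the AG acceptor
    pieces <- c(pieces, intron_body(intron_len[i], first_stop = (i == 5L)))
    cursor <- cursor + intron_len[i]
    prev <- intron_after[i]
  }
  exon_seq <- substr(cds, prev + 1L, nchar(cds))
  pieces <- c(pieces, exon_seq)
  exon_start <- c(exon_start, cursor + 1L)
  exon_end <- c(exon_end, cursor + nchar(exon_seq))
  seq <- paste(pieces, collapse = "")
  stopifnot(nchar(seq) == 3528L)
  gene_model("nbs1_synthetic", seq, cbind(exon_start, exon_end))
}

#' Mutation specs for the five nbs1 alleles
#'
#' Returns the published gene-local edits for `nbs1-1` through `nbs1-5`,
#' ready to apply to [nbs1_gene()]. The splice-site allele `nbs1-1` has two
#' documented products and is represented twice: `"nbs1-1"` uses the major
#' product (re-splicing at the cryptic CAG 40 bp downstream of the destroyed
#' acceptor) and `"nbs1-1r"` the minor product (complete retention of
#' intron 5). `nbs1-4` carries the same mutation as `nbs1-3`.
#'
#' @return Named list of [mutation_spec()] objects.
#' @export
nbs1_alleles <- function() {
  sub <- function(pos, ref, alt)
    data.frame(pos = pos, ref = ref, alt = alt, kind = "substitution")
  del <- function(pos, ref)
    data.frame(pos = pos, ref = ref, alt = "", kind = "deletion")
  splice_edit <- sub(1235L, "A", "G")
  list(
    "nbs1-1"  = mutation_spec("nbs1-1", splice_edit,
                              splice_mode = shift_acceptor(5L, 40L)),
    "nbs1-1r" = mutation_spec("nbs1-1r", splice_edit,
                              splice_mode = retain_intron(5L)),
    "nbs1-2"  = mutation_spec("nbs1-2", sub(188L, "CC", "TT")),
    "nbs1-3"  = mutation_spec("nbs1-3", sub(2126L, "C", "T")),
    "nbs1-4"  = mutation_spec("nbs1-4", sub(2126L, "C", "T")),
    "nbs1-5"  = mutation_spec("nbs1-5",
                              rbind(sub(1072L, "C", "T"), del(1074L, "C")))
  )
}

#' Allele-effect table for the nbs1 alleles
#'
#' Applies every spec from [nbs1_alleles()] to [nbs1_gene()] and collects
#' the protein effects into one table.
#'
#' @param gene the wild-type gene model; defaults to the synthetic record.
#' @return A data.frame with one row per allele (columns as in
#'   [annotate_effect()]).
#' @export
nbs1_effect_table <- function(gene = nbs1_gene()) {
  specs <- nbs1_alleles()
  out <- do.call(rbind, lapply(specs, function(m) annotate_effect(gene, m)))
  rownames(out) <- NULL
  out
}
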