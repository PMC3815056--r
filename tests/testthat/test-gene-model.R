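test_that("splicing concatenates exons and validates structure", {
  g <- gene_model("toy", "ATGAAATAA", cbind(1, 9))
  expect_identical(splice_cds(g), "ATGAAATAA")

  g2 <- gene_model("toy2", "ATGGTAGAAATAA", cbind(c(1, 8), c(3, 13)))
  expect_identical(splice_cds(g2), "ATGAAATAA")
  expect_equal(nrow(introns(g2)), 1L)

  expect_error(gene_model("bad", "ATGAAATAA", cbind(c(1, 3), c(5, 9))),
               "overlap")
  expect_error(gene_model("bad", "ATGAAATAA", cbind(1, 12)), "outside")
  expect_error(gene_model("bad", "ATGAAAAAA", cbind(1, 9)), "stop codon")
  # non-AG acceptor warns but does not error
  expect_warning(gene_model("warns", "ATGGTTTAAATAA", cbind(c(1, 8), c(3, 13))),
                 "acceptor")
})

test_that("translation follows the standard code and stops at first stop", {
  expect_identical(translate_cds("ATGAAATAA"), "MK")
  expect_identical(translate_cds("ATGTAA"), "M")   # stop excluded, Met kept
  expect_error(translate_cds("AAATAA"), "ATG")
  expect_error(translate_cds("ATGAAA"), "runs off")
  # trailing partial codon after a stop is tolerated
  expect_identical(translate_cds("ATGAAATAAGC"), "MK")
})

test_that("protein stats use average residue masses plus one water", {
  expect_equal(protein_stats("G")[["mw_da"]], 57.0519 + 18.01528,
               tolerance = 1e-6)
  expect_equal(protein_stats("G")[["length_aa"]], 1)
  expect_equal(protein_stats("")[["mw_da"]], 18.01528, tolerance = 1e-6)
  expect_error(protein_stats("GXZ"), "unknown residue")
  # additivity against a hand sum
  expect_equal(protein_stats("MKV")[["mw_da"]],
               131.1926 + 128.1741 + 99.1326 + 18.01528, tolerance = 1e-6)
})

test_that("synthetic nbs1 record has the documented structure", {
  g <- nbs1_gene()
  expect_equal(nchar(g$genomic_seq), 3528L)
  expect_equal(nrow(introns(g)), 10L)
  cds <- splice_cds(g)
  expect_equal(nchar(cds), 3000L)
  p <- translate_cds(cds)
  expect_equal(nchar(p), 999L)
  expect_equal(protein_stats(p)[["length_aa"]], 999)
})

test_that("allele mutations reproduce their documented protein effects", {
  g <- nbs1_gene()
  eff <- nbs1_effect_table(g)

  s43f <- eff[eff$allele == "nbs1-2", ]
  expect_identical(s43f$kind, "missense")
  expect_identical(c(s43f$ref_aa, s43f$alt_aa), c("S", "F"))
  # coordinate-convention anchor: CC->TT at gene bp 188-189 must hit aa 43
  expect_equal(s43f$aa_position, 43L)

  stop570 <- eff[eff$allele == "nbs1-3", ]
  expect_identical(stop570$kind, "nonsense")
  expect_equal(stop570$aa_position, 570L)
  expect_equal(stop570$truncated_length, 569L)
  expect_equal(unname(as.list(eff[eff$allele == "nbs1-4", -1])),
               unname(as.list(eff[eff$allele == "nbs1-3", -1])))

  fs288 <- eff[eff$allele == "nbs1-5", ]
  expect_identical(fs288$kind, "frameshift_truncation")
  expect_equal(fs288$truncated_length, 288L)
  # the last translated residue is the A->V missense just before the stop
  mut <- apply_mutation(g, nbs1_alleles()[["nbs1-5"]])
  mp <- translate_cds(splice_cds(mut))
  expect_identical(substr(mp, 288, 288), "V")

  splice_major <- eff[eff$allele == "nbs1-1", ]
  expect_equal(splice_major$aa_position, 400L)
  expect_equal(splice_major$truncated_length, 399L)
  splice_minor <- eff[eff$allele == "nbs1-1r", ]
  expect_equal(splice_minor$truncated_length, 328L)
})

test_that("splice-mode restructuring behaves as declared", {
  g <- nbs1_gene()
  ret <- apply_mutation(g, mutation_spec("ret5", splice_mode = retain_intron(5)))
  expect_equal(nrow(introns(ret)), 9L)
  expect_equal(nchar(splice_cds(ret)), 3000L + 43L)

  sh <- apply_mutation(g, mutation_spec("sh5", splice_mode = shift_acceptor(5, 40)))
  expect_equal(nrow(introns(sh)), 10L)
  expect_equal(unname(introns(sh)[5, "end"] - introns(g)[5, "end"]), 40)
  expect_equal(nchar(splice_cds(sh)), 3000L - 40L)
})

test_that("apply_mutation guards reference bases and boundaries", {
  g <- nbs1_gene()
  bad <- mutation_spec("bad", data.frame(pos = 188, ref = "GG", alt = "TT",
                                         kind = "substitution"))
  expect_error(apply_mutation(g, bad), "ref mismatch")
  # deletion spanning an exon/intron boundary without declared splicing
  b <- introns(g)[1, "start"]
  del <- mutation_spec("delb", data.frame(pos = b - 1, ref = substr(g$genomic_seq, b - 1, b),
                                          alt = "", kind = "deletion"))
  expect_error(apply_mutation(g, del), "splice_mode")
})

test_that("effect classification invariants hold", {
  g <- nbs1_gene()
  # empty mutation -> silent
  expect_identical(annotate_effect(g, mutation_spec("wt"))$kind, "silent")
  # synonymous third-position edit -> silent (codon 2 GAA -> GAG)
  syn <- mutation_spec("syn", data.frame(pos = 6, ref = substr(g$genomic_seq, 6, 6),
                                         alt = "G", kind = "substitution"))
  expect_identical(annotate_effect(g, syn)$kind, "silent")
  # single-base deletion inside an exon -> frameshift truncation
  del1 <- mutation_spec("del1", data.frame(pos = 10, ref = substr(g$genomic_seq, 10, 10),
                                           alt = "", kind = "deletion"))
  expect_identical(annotate_effect(g, del1)$kind, "frameshift_truncation")
  # substitutions never change CDS length
  eff <- nbs1_effect_table(g)
  sub_alleles <- c("nbs1-2", "nbs1-3", "nbs1-4")
  for (a in sub_alleles) {
    m <- apply_mutation(g, nbs1_alleles()[[a]])
    expect_equal(nchar(splice_cds(m)), 3000L)
  }
})

test_that("gene model FASTA + exon table round trip", {
  g <- nbs1_gene()
  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  write_gene_model(g, fa, tsv)
  g2 <- read_gene_model(fa, tsv)
  expect_identical(g2$genomic_seq, g$genomic_seq)
  expect_equal(unname(g2$exons), unname(g$exons))
})
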