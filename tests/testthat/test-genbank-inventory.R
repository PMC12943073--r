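test_that("parser captures the three feature classes with locations and qualifiers", {
  asm <- parse_genbank_flatfile(toy_gbff())
  expect_s3_class(asm, "genome_assembly")
  expect_identical(nrow(asm$features), 6L)
  kinds <- table(asm$features$kind)
  expect_identical(as.integer(kinds[c("CDS", "rRNA", "tRNA")]),
                   c(2L, 3L, 1L))
  expect_identical(asm$species_label, "toy bacterium")
  expect_identical(asm$accessions, "TOY001.1")

  # complement(join(...)) -> one feature, two segments, minus strand
  cds2 <- asm$features[asm$features$product == "protein two", ]
  expect_identical(nrow(cds2), 1L)
  seg <- cds2$segments[[1]]
  expect_identical(nrow(seg), 2L)
  expect_identical(unname(seg[, "start"]), c(30L, 45L))
  expect_identical(unname(seg[, "end"]), c(38L, 50L))
  expect_identical(cds2$strand, "-")

  # qualifiers captured
  cds1 <- asm$features[asm$features$product == "protein one", ]
  expect_identical(cds1$transl_table, 11L)
})

test_that("malformed locations and missing records are hard errors", {
  bad <- sub("10..24", "10..twenty", toy_gbff(), fixed = TRUE)
  expect_error(parse_genbank_flatfile(bad), "malformed location")
  expect_error(parse_genbank_flatfile("no locus here"), "LOCUS")
  # feature beyond replicon length
  oob <- sub("530..590", "530..9999", toy_gbff(), fixed = TRUE)
  expect_error(parse_genbank_flatfile(oob), "beyond replicon length")
})

test_that("sequence extraction reverse-complements minus-strand joins", {
  asm <- parse_genbank_flatfile(toy_gbff())
  seqs <- extract_feature_seqs(asm, "CDS")
  expect_length(seqs, 2L)
  expect_identical(nchar(seqs), c(15L, 15L))
  rep_seq <- asm$replicons[["TOY1"]]
  expect_identical(seqs[1], substr(rep_seq, 10, 24))
  fwd <- paste0(substr(rep_seq, 30, 38), substr(rep_seq, 45, 50))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  expect_identical(seqs[2], rc)
})

test_that("missing ORIGIN defers the error until sequence is requested", {
  txt <- toy_gbff()
  no_origin <- sub("(?s)ORIGIN.*?//", "//", txt, perl = TRUE)
  asm <- parse_genbank_flatfile(no_origin)
  expect_identical(nrow(asm$features), 6L)  # parsing itself succeeds
  expect_error(extract_feature_seqs(asm, "CDS"), "ORIGIN")
})

test_that("rrn operon count is the 16S tally, with mismatch warnings", {
  asm <- parse_genbank_flatfile(toy_gbff())
  rrn <- count_rrn_operons(asm)
  expect_identical(rrn$N_rrn, 1L)
  expect_identical(rrn$rrna_class_counts,
                   c(`16S` = 1L, `23S` = 1L, `5S` = 1L))

  # seven complete triplets
  spec <- synthetic_genome_spec(n_rrn = 7, seed = 3)
  asm7 <- parse_genbank_flatfile(generate_synthetic_genome(spec)$text)
  expect_identical(count_rrn_operons(asm7)$N_rrn, 7L)

  # one 16S but two 23S -> N_rrn = 1 plus a mismatch warning
  extra <- sub("     rRNA            310..520",
               paste0("     rRNA            301..305\n",
                      "                     /product=\"23S ribosomal RNA\"\n",
                      "     rRNA            310..520"),
               toy_gbff(), fixed = TRUE)
  asm_m <- parse_genbank_flatfile(extra)
  expect_warning(rrn_m <- count_rrn_operons(asm_m), "unequal rRNA class")
  expect_identical(rrn_m$N_rrn, 1L)

  # unclassifiable product counted under no class, with warning
  odd <- sub("5S ribosomal RNA", "mystery RNA", toy_gbff(), fixed = TRUE)
  # reclassifying 5S as mystery also unbalances the class tallies
  expect_warning(
    expect_warning(rrn_o <- count_rrn_operons(parse_genbank_flatfile(odd)),
                   "none of 16S/23S/5S"),
    "unequal rRNA class")
  expect_identical(unname(rrn_o$rrna_class_counts["5S"]), 0L)
})

test_that("tRNA classification uses product, then anticodon, never failing hard", {
  code <- genetic_code(11)
  expect_identical(classify_trna("tRNA-Leu", NA, code), "L")
  expect_identical(classify_trna("tRNA-fMet", NA, code), "iMet")
  expect_identical(classify_trna("tRNA-Sec", NA, code), "SeC")
  expect_identical(classify_trna(NA, "CAT", code), "M")  # CAT decodes ATG
  expect_identical(classify_trna(NA, "(pos:34..36,aa:Trp,seq:cca)", code), "W")
  expect_identical(classify_trna(NA, NA, code), "unclassified")
  expect_identical(classify_trna("tRNA-Xxx", NA, code), "unclassified")

  # brute force over all 64 anticodons: decoding must match the genetic
  # code applied to the reverse complement, computed independently here
  gc <- Biostrings::getGeneticCode("11")
  bases <- c("A", "C", "G", "T")
  for (a1 in bases) for (a2 in bases) for (a3 in bases) {
    ac <- paste0(a1, a2, a3)
    codon <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(ac)))
    expected <- unname(gc[codon])
    got <- classify_trna(NA, ac, code)
    if (expected == "*") expect_identical(got, "unclassified")
    else expect_identical(got, expected)
  }
})

test_that("inventory satisfies the accounting identity and round-trips the generator", {
  spec <- synthetic_genome_spec(
    n_rrn = 4, m_trna = c(A = 4, G = 12, M = 6, W = 2),
    n_initiator_met = 2, cds_proteins = "MEEC", seed = 17)
  g <- generate_synthetic_genome(spec)
  inv <- build_inventory(parse_genbank_flatfile(g$text))
  expect_identical(inv$N_rrn, g$manifest$N_rrn)
  expect_identical(inv$N_tRNA, g$manifest$N_tRNA)
  expect_identical(inv$M_tRNA, g$manifest$M_tRNA)
  expect_identical(inv$n_initiator_met, g$manifest$n_initiator_met)
  expect_identical(inv$N_tRNA,
                   as.integer(sum(inv$M_tRNA) + inv$n_sec + inv$n_unclassified))

  # no tRNA features at all -> zero count, empty map
  spec0 <- synthetic_genome_spec(n_rrn = 2, seed = 1)
  inv0 <- build_inventory(parse_genbank_flatfile(
    generate_synthetic_genome(spec0)$text))
  expect_identical(inv0$N_tRNA, 0L)
  expect_length(inv0$M_tRNA, 0L)
})

test_that("pseudo-flagged tRNAs are excluded by default but includable", {
  txt <- sub("     tRNA            60..135",
             paste0("     tRNA            60..135\n",
                    "                     /pseudo"),
             toy_gbff(), fixed = TRUE)
  asm <- parse_genbank_flatfile(txt)
  inv <- build_inventory(asm)
  expect_identical(inv$N_tRNA, 0L)
  inv_in <- build_inventory(asm, exclude_pseudo = FALSE)
  expect_identical(inv_in$N_tRNA, 1L)
  expect_identical(inv_in$M_tRNA, c(L = 1L))
})

test_that("merging replicons is additive and rejects duplicates", {
  s1 <- synthetic_genome_spec(n_rrn = 2, m_trna = c(L = 3, K = 2), seed = 21)
  s2 <- synthetic_genome_spec(n_rrn = 1, m_trna = c(L = 2, W = 4), seed = 22)
  a1 <- parse_genbank_flatfile(generate_synthetic_genome(s1)$text,
                               species_label = "sp")
  a2 <- parse_genbank_flatfile(generate_synthetic_genome(s2)$text,
                               species_label = "sp")
  # same seed-derived accession would collide; relabel the second replicon
  names(a2$replicons) <- names(a2$replicon_lengths) <- "SYNREP2"
  a2$features$replicon_id <- "SYNREP2"

  merged <- merge_replicons(list(a1, a2))
  im <- build_inventory(merged)
  i1 <- build_inventory(a1); i2 <- build_inventory(a2)
  expect_identical(im$N_rrn, i1$N_rrn + i2$N_rrn)
  expect_identical(im$N_tRNA, i1$N_tRNA + i2$N_tRNA)
  expect_identical(im$M_tRNA, c(K = 2L, L = 5L, W = 4L))

  # identity: merging a singleton changes nothing
  ione <- build_inventory(merge_replicons(list(a1)))
  expect_identical(ione$M_tRNA, i1$M_tRNA)

  expect_error(merge_replicons(list(a1, a1)), "duplicate replicon")
  a3 <- a2; a3$species_label <- "other"
  expect_error(merge_replicons(list(a1, a3)), "different species")
  expect_error(merge_replicons(list()), "empty")
})

test_that("counting is invariant to feature order", {
  spec <- synthetic_genome_spec(n_rrn = 3, m_trna = c(L = 5, M = 2, S = 3),
                                cds_proteins = "MKL", seed = 31)
  asm <- parse_genbank_flatfile(generate_synthetic_genome(spec)$text)
  inv <- build_inventory(asm)
  set.seed(2)
  shuf <- asm
  shuf$features <- shuf$features[sample(nrow(shuf$features)), ]
  inv_s <- build_inventory(shuf)
  expect_identical(inv_s$N_rrn, inv$N_rrn)
  expect_identical(inv_s$N_tRNA, inv$N_tRNA)
  expect_identical(inv_s$M_tRNA, inv$M_tRNA)
})
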