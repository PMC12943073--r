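#' Count rrn operons from rRNA features
#'
#' A bacterial rrn operon contains one copy each of the 16S, 23S and 5S
#' rRNAs, so the operon count is taken as the number of 16S rRNA features.
#' Classification is by product text containing "16S", "23S" or "5S".
#' Clustering by genomic proximity is deliberately avoided: it fails on
#' fragmented (multi-contig) assemblies. When the three class counts are
#' unequal a warning is raised, never a silent reconciliation.
#'
#' @param assembly A `genome_assembly`.
#' @return List with `N_rrn` (integer) and `rrna_class_counts` (named
#'   integer vector over 16S/23S/5S).
#' @export
count_rrn_operons <- function(assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  ft <- assembly$features[assembly$features$kind == "rRNA", , drop = FALSE]
  counts <- c(`16S` = 0L, `23S` = 0L, `5S` = 0L)
  unmatched <- 0L
  for (p in ft$product) {
    cls <- classify_rrna_product(p)
    if (is.na(cls)) unmatched <- unmatched + 1L
    else counts[cls] <- counts[cls] + 1L
  }
  if (unmatched > 0L) {
    warning(unmatched, " rRNA feature(s) with product matching none of ",
            "16S/23S/5S; counted under no class")
  }
  if (length(unique(counts)) > 1L) {
    warning("unequal rRNA class counts (16S=", counts[["16S"]],
            ", 23S=", counts[["23S"]], ", 5S=", counts[["5S"]],
            "); operon count taken from 16S")
  }
  n_rrn <- counts[["16S"]]
  if (n_rrn == 0L && nrow(assembly$features) > 0L) {
    warning("no 16S rRNA feature found; N_rrn = 0 ",
            "(complete bacterial genomes carry at least one rrn operon)")
  }
  list(N_rrn = n_rrn, rrna_class_counts = counts)
}

classify_rrna_product <- function(product) {
  if (is.na(product)) return(NA_character_)
  if (grepl("16S", product)) return("16S")
  if (grepl("23S", product)) return("23S")
  if (grepl("(^|[^.0-9])5S", product)) return("5S")
  NA_character_
}

#' Classify a tRNA feature by amino acid
#'
#' The amino acid is read from a product qualifier of the form `tRNA-Xxx`;
#' if absent, it is decoded from the anticodon qualifier via the genetic
#' code (the codon read is the reverse complement of the anticodon).
#' Initiator methionine tRNAs (`tRNA-fMet`, `tRNA-Ini`) are classified
#' `"iMet"` (tallied inside Met in inventories, and tracked separately);
#' selenocysteine tRNAs are their own class `"SeC"`. A feature with neither
#' a usable product nor anticodon is `"unclassified"`, never a hard failure.
#'
#' @param product Product qualifier text (or `NA`).
#' @param anticodon Anticodon qualifier text: either a bare triplet or the
#'   GenBank form `(pos:...,aa:Xxx,seq:nnn)` (or `NA`).
#' @param code A [genetic_code()] object.
#' @return One of: a one-letter amino-acid code, `"iMet"`, `"SeC"`,
#'   `"unclassified"`.
#' @export
classify_trna <- function(product, anticodon = NA, code = genetic_code(11)) {
  # product route
  if (!is.na(product)) {
    if (grepl("tRNA-fMet|tRNA-Ini", product, ignore.case = TRUE)) return("iMet")
    if (grepl("tRNA-Sec", product, ignore.case = TRUE)) return("SeC")
    m <- regmatches(product, regexec("tRNA-([A-Za-z]{3})", product))[[1]]
    if (length(m) == 2L) {
      three <- paste0(toupper(substr(m[2], 1, 1)), tolower(substr(m[2], 2, 3)))
      one <- AA_THREE_TO_ONE[three]
      if (!is.na(one) && one %in% AMINO_ACIDS) return(unname(one))
      if (!is.na(one) && one == "SeC") return("SeC")
    }
  }
  # anticodon route
  if (!is.na(anticodon)) {
    aa_field <- regmatches(anticodon, regexec("aa:([A-Za-z]{3})", anticodon))[[1]]
    if (length(aa_field) == 2L) {
      one <- AA_THREE_TO_ONE[aa_field[2]]
      if (!is.na(one)) return(unname(if (one == "SeC") "SeC" else one))
    }
    seq_field <- regmatches(anticodon, regexec("seq:([A-Za-z]{3})", anticodon))[[1]]
    ac <- if (length(seq_field) == 2L) seq_field[2]
          else if (grepl("^[A-Za-z]{3}$", trimws(anticodon))) trimws(anticodon)
          else NA_character_
    if (!is.na(ac)) {
      codon <- revcomp3(toupper(gsub("U", "T", toupper(ac))))
      aa <- code$codon_to_aa[codon]
      if (!is.na(aa) && aa != "*") return(unname(aa))
    }
  }
  "unclassified"
}

revcomp3 <- function(codon) {
  comp <- chartr("ACGT", "TGCA", codon)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

#' Build the translation-machinery inventory of a genome
#'
#' Tabulates the genomic investment in translation: the rrn operon count
#' `N_rrn` (with per-class 16S/23S/5S counts), the total tRNA gene count
#' `N_tRNA`, and the per-amino-acid allocation `M_tRNA`. Initiator-Met
#' tRNAs are counted inside Met and also reported separately;
#' selenocysteine tRNAs are counted in `N_tRNA` but kept out of `M_tRNA`.
#' tRNA pseudogenes are excluded by default. The accounting identity
#' `N_tRNA = sum(M_tRNA) + n_sec + n_unclassified` always holds.
#'
#' @param assembly A `genome_assembly` (merge replicons first for
#'   multi-chromosome genomes).
#' @param code A [genetic_code()] object (default table 11).
#' @param exclude_pseudo Drop tRNA/rRNA features flagged `pseudo`
#'   (default TRUE).
#' @return Object of class `translation_inventory`: list with
#'   `species_label`, `N_rrn`, `rrna_class_counts`, `N_tRNA`, `M_tRNA`
#'   (named integer vector over amino acids with at least one gene),
#'   `n_initiator_met`, `n_sec`, `n_unclassified`.
#' @export
build_inventory <- function(assembly, code = genetic_code(11),
                            exclude_pseudo = TRUE) {
  stopifnot(inherits(assembly, "genome_assembly"))
  ft <- assembly$features
  if (exclude_pseudo && nrow(ft) > 0L) ft <- ft[!ft$pseudo, , drop = FALSE]
  assembly_f <- assembly
  assembly_f$features <- ft

  rrn <- count_rrn_operons(assembly_f)

  trna <- ft[ft$kind == "tRNA", , drop = FALSE]
  classes <- if (nrow(trna) > 0L) {
    vapply(seq_len(nrow(trna)),
           function(j) classify_trna(trna$product[j], trna$anticodon[j], code),
           character(1))
  } else character(0)

  n_imet <- sum(classes == "iMet")
  n_sec <- sum(classes == "SeC")
  n_uncl <- sum(classes == "unclassified")
  aa_classes <- ifelse(classes == "iMet", "M", classes)
  aa_classes <- aa_classes[aa_classes %in% AMINO_ACIDS]
  tab <- table(aa_classes)
  M_tRNA <- if (length(tab)) {
    m <- stats::setNames(as.integer(tab), names(tab))
    m[order(names(m))]
  } else stats::setNames(integer(0), character(0))

  structure(
    list(species_label = assembly$species_label,
         N_rrn = rrn$N_rrn,
         rrna_class_counts = rrn$rrna_class_counts,
         N_tRNA = nrow(trna),
         M_tRNA = M_tRNA,
         n_initiator_met = n_imet,
         n_sec = n_sec,
         n_unclassified = n_uncl),
    class = "translation_inventory"
  )
}

#' @export
print.translation_inventory <- function(x, ...) {
  cat("Translation-machinery inventory:", x$species_label %||% "(unlabelled)", "\n")
  cat("  N_rrn =", x$N_rrn,
      sprintf("(16S=%d, 23S=%d, 5S=%d)", x$rrna_class_counts[["16S"]],
              x$rrna_class_counts[["23S"]], x$rrna_class_counts[["5S"]]), "\n")
  cat("  N_tRNA =", x$N_tRNA,
      sprintf("(initiator-Met=%d, SeC=%d, unclassified=%d)",
              x$n_initiator_met, x$n_sec, x$n_unclassified), "\n")
  if (length(x$M_tRNA)) {
    cat("  M_tRNA:", paste(sprintf("%s=%d", names(x$M_tRNA), x$M_tRNA),
                           collapse = " "), "\n")
  }
  invisible(x)
}

#' Write a one-row-per-species inventory table
#'
#' @param inventories List of `translation_inventory` objects.
#' @param path Output TSV path.
#' @return The written data frame, invisibly.
#' @export
write_inventory_tsv <- function(inventories, path) {
  df <- inventory_data_frame(inventories)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Assemble inventories into a one-row-per-species data frame
#'
#' @param inventories List of `translation_inventory` objects (or one).
#' @return Data frame with species, N_rrn, rRNA class counts, N_tRNA, the
#'   20 per-amino-acid columns, and the initiator/SeC/unclassified tallies.
#' @export
inventory_data_frame <- function(inventories) {
  if (inherits(inventories, "translation_inventory")) {
    inventories <- list(inventories)
  }
  rows <- lapply(inventories, function(inv) {
    m <- stats::setNames(integer(20L), AMINO_ACIDS)
    m[names(inv$M_tRNA)] <- inv$M_tRNA
    cbind(
      data.frame(species = inv$species_label %||% NA_character_,
                 N_rrn = inv$N_rrn,
                 n_16S = inv$rrna_class_counts[["16S"]],
                 n_23S = inv$rrna_class_counts[["23S"]],
                 n_5S = inv$rrna_class_counts[["5S"]],
                 N_tRNA = inv$N_tRNA,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(m)),
      data.frame(n_initiator_met = inv$n_initiator_met,
                 n_sec = inv$n_sec,
                 n_unclassified = inv$n_unclassified)
    )
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- cbind(data.frame(species = character(0), N_rrn = integer(0),
                           n_16S = integer(0), n_23S = integer(0),
                           n_5S = integer(0), N_tRNA = integer(0)),
                as.data.frame(stats::setNames(rep(list(integer(0)), 20), AMINO_ACIDS)),
                data.frame(n_initiator_met = integer(0), n_sec = integer(0),
                           n_unclassified = integer(0)))
  }
  rownames(df) <- NULL
  df
}
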