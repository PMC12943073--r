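#' Genetic-code tables
#'
#' Builds a genetic-code object for a supported NCBI translation table.
#' Table 11 (bacterial/archaeal/plant plastid) shares all codon-to-amino-acid
#' assignments with the standard code (table 1) but allows additional start
#' codons; table 4 reassigns TGA from stop to Trp.
#'
#' @param table_id Integer NCBI translation-table identifier. Supported:
#'   1 (standard), 4 (mold/protozoan mitochondrial), 11 (bacterial).
#' @return An object of class `genetic_code`: a list with `table_id`,
#'   `codon_to_aa` (named character vector over all 64 DNA codons, stops as
#'   `"*"`), and `start_codons` (character vector of initiation codons).
#' @examples
#' code <- genetic_code(11)
#' code$codon_to_aa[["TGG"]]  # "W"
#' @export
genetic_code <- function(table_id) {
  supported <- c(1L, 4L, 11L)
  table_id <- as.integer(table_id)
  if (length(table_id) != 1L || is.na(table_id) || !table_id %in% supported) {
    stop("unsupported translation table ", table_id,
         "; supported tables: ", paste(supported, collapse = ", "))
  }
  tab <- Biostrings::getGeneticCode(as.character(table_id))
  codon_to_aa <- as.character(tab)
  names(codon_to_aa) <- names(tab)
  alt <- attr(tab, "alt_init_codons")
  start_codons <- unique(c("ATG", alt))
  structure(
    list(table_id = table_id,
         codon_to_aa = codon_to_aa,
         start_codons = start_codons),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code, NCBI translation table", x$table_id, "\n")
  cat("  sense codons:", sum(x$codon_to_aa != "*"),
      " stop codons:", sum(x$codon_to_aa == "*"), "\n")
  cat("  start codons:", paste(x$start_codons, collapse = " "), "\n")
  invisible(x)
}

#' Codon family sizes
#'
#' Number of synonymous sense codons encoding each amino acid (CFS). Under
#' table 11, Leu/Ser/Arg have 6, Trp and Met have 1, and the 20 values sum
#' to 61 (the number of sense codons).
#'
#' @param code A [genetic_code()] object.
#' @return Named integer vector (one-letter amino-acid codes) of family sizes.
#' @export
codon_family_sizes <- function(code) {
  stopifnot(inherits(code, "genetic_code"))
  sense <- code$codon_to_aa[code$codon_to_aa != "*"]
  tab <- table(sense)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(names(out))]
}

# amino acids in one-letter code, alphabetical
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# three-letter -> one-letter lookup, including initiator and selenocysteine
AA_THREE_TO_ONE <- c(
  Ala = "A", Cys = "C", Asp = "D", Glu = "E", Phe = "F", Gly = "G",
  His = "H", Ile = "I", Lys = "K", Leu = "L", Met = "M", Asn = "N",
  Pro = "P", Gln = "Q", Arg = "R", Ser = "S", Thr = "T", Val = "V",
  Trp = "W", Tyr = "Y", Sec = "SeC", SeC = "SeC", Pyl = "Pyl"
)

#' Split a coding sequence into in-frame codons
#'
#' @param cds Nucleotide string (length >= 3). A trailing partial codon is
#'   dropped with a warning.
#' @return Character vector of uppercase codons.
#' @keywords internal
split_codons <- function(cds) {
  if (!nzchar(cds)) stop("empty coding sequence")
  cds <- toupper(gsub("[U]", "T", cds))
  n <- nchar(cds)
  if (n < 3L) stop("coding sequence shorter than one codon")
  n_codon <- n %/% 3L
  if (n %% 3L != 0L) {
    warning("CDS length ", n, " is not a multiple of 3; trailing ",
            n %% 3L, " base(s) dropped")
  }
  substring(cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
}

#' Translate a coding sequence
#'
#' Codon-by-codon translation under a genetic code. A terminal stop codon is
#' dropped; codons containing non-ACGT letters translate to `X`; internal
#' stops translate to `*`.
#'
#' @param cds Nucleotide string, length >= 3.
#' @param code A [genetic_code()] object.
#' @return Amino-acid string.
#' @examples
#' translate_cds("ATGGAAGAATGCTAA", genetic_code(11))  # "MEEC"
#' @export
translate_cds <- function(cds, code) {
  stopifnot(inherits(code, "genetic_code"))
  codons <- split_codons(cds)
  aa <- unname(code$codon_to_aa[codons])
  aa[is.na(aa)] <- "X"
  if (length(aa) > 0L && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Genome-wide codon and amino-acid usage
#'
#' Tallies all in-frame codons over a set of coding sequences and derives
#' amino-acid usage `N_AA` (stop codons excluded; internal stops excluded
#' with a warning) and relative synonymous codon usage. Codons containing
#' ambiguous bases are skipped, not imputed, and counted in
#' `n_skipped_codons`.
#'
#' @param cds_list Character vector or list of nucleotide strings.
#' @param code A [genetic_code()] object.
#' @return An object of class `usage_table`: list with `codon_counts`
#'   (named integer over 64 codons), `N_AA` (named integer per amino acid),
#'   `rscu` (named numeric per codon), `n_cds`, `n_skipped_codons`,
#'   `n_stop_codons`, `n_internal_stops`.
#' @export
amino_acid_usage <- function(cds_list, code) {
  stopifnot(inherits(code, "genetic_code"))
  cds_list <- as.character(unlist(cds_list, use.names = FALSE))
  codon_counts <- stats::setNames(integer(64L), names(code$codon_to_aa))
  n_skipped <- 0L
  n_internal_stops <- 0L
  for (cds in cds_list) {
    codons <- split_codons(cds)
    known <- codons %in% names(codon_counts)
    n_skipped <- n_skipped + sum(!known)
    codons <- codons[known]
    if (length(codons) == 0L) next
    # an internal stop is a stop codon anywhere before the final codon
    aa <- code$codon_to_aa[codons]
    stops <- which(aa == "*")
    internal <- stops[stops < length(codons)]
    n_internal_stops <- n_internal_stops + length(internal)
    tab <- table(codons)
    codon_counts[names(tab)] <- codon_counts[names(tab)] + as.integer(tab)
  }
  if (n_internal_stops > 0L) {
    warning(n_internal_stops,
            " internal stop codon(s) found; excluded from amino-acid usage")
  }
  sense <- code$codon_to_aa != "*"
  n_aa_raw <- tapply(codon_counts[sense], code$codon_to_aa[sense], sum)
  N_AA <- stats::setNames(integer(length(n_aa_raw)), names(n_aa_raw))
  N_AA[] <- as.integer(n_aa_raw)
  N_AA <- N_AA[order(names(N_AA))]
  structure(
    list(codon_counts = codon_counts,
         N_AA = N_AA,
         rscu = rscu(codon_counts, code),
         n_cds = length(cds_list),
         n_skipped_codons = n_skipped,
         n_stop_codons = as.integer(sum(codon_counts[!sense])),
         n_internal_stops = n_internal_stops),
    class = "usage_table"
  )
}

#' @export
print.usage_table <- function(x, ...) {
  cat("Codon/amino-acid usage over", x$n_cds, "CDS\n")
  cat("  total sense codons:", sum(x$N_AA),
      " stops:", x$n_stop_codons,
      " skipped (ambiguous):", x$n_skipped_codons, "\n")
  print(x$N_AA)
  invisible(x)
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its observed count divided by the mean count over its
#' synonymous family; within every family with nonzero total the values
#' average to 1. Families with zero total get RSCU 0 for all members and are
#' flagged in the `zero_families` attribute.
#'
#' @param codon_counts Named integer vector of codon counts.
#' @param code A [genetic_code()] object.
#' @return Named numeric vector of RSCU over the sense codons.
#' @export
rscu <- function(codon_counts, code) {
  stopifnot(inherits(code, "genetic_code"))
  sense_codons <- names(code$codon_to_aa)[code$codon_to_aa != "*"]
  counts <- codon_counts[sense_codons]
  counts[is.na(counts)] <- 0
  aa <- code$codon_to_aa[sense_codons]
  fam_mean <- tapply(counts, aa, mean)
  out <- as.numeric(counts) / as.numeric(fam_mean[aa])
  out[!is.finite(out)] <- 0
  names(out) <- sense_codons
  zero <- names(fam_mean)[fam_mean == 0]
  attr(out, "zero_families") <- zero
  out
}
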