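AA_ONE_TO_THREE <- c(
  A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe", G = "Gly",
  H = "His", I = "Ile", K = "Lys", L = "Leu", M = "Met", N = "Asn",
  P = "Pro", Q = "Gln", R = "Arg", S = "Ser", T = "Thr", V = "Val",
  W = "Trp", Y = "Tyr"
)

# run code under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic annotated genome
#'
#' Describes the ground truth of a synthetic bacterial genome: how many rrn
#' operons (16S/23S/5S triplets), how many tRNA genes per amino acid, how
#' many of the Met tRNAs are initiators, and which coding sequences to
#' embed. The manifest totals are derivable from the spec before any
#' sequence is generated.
#'
#' @param n_rrn Number of rrn operon (16S, 23S, 5S) triplets.
#' @param m_trna Named integer vector: tRNA gene count per amino acid
#'   (one-letter codes; the Met count includes initiators).
#' @param n_initiator_met How many Met tRNAs carry a `tRNA-fMet` product
#'   (must not exceed `m_trna["M"]`).
#' @param cds_proteins Character vector of amino-acid strings; one CDS is
#'   generated per protein, with synonymous codons sampled uniformly.
#' @param table_id NCBI translation table (default 11).
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @param replicon_count Number of replicons to distribute features over.
#' @return Object of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(n_rrn, m_trna = integer(0),
                                  n_initiator_met = 0L,
                                  cds_proteins = character(0),
                                  table_id = 11L, seed = 1L,
                                  replicon_count = 1L) {
  m_trna <- stats::setNames(as.integer(m_trna), names(m_trna))
  if (length(m_trna) && (is.null(names(m_trna)) ||
                         !all(names(m_trna) %in% AMINO_ACIDS))) {
    stop("m_trna must be named with one-letter amino-acid codes")
  }
  if (n_rrn < 0 || any(m_trna < 0) || n_initiator_met < 0) {
    stop("all counts must be non-negative")
  }
  n_met <- if ("M" %in% names(m_trna)) m_trna[["M"]] else 0L
  if (n_initiator_met > n_met) {
    stop("n_initiator_met (", n_initiator_met,
         ") exceeds the Met tRNA count (", n_met, ")")
  }
  bad <- setdiff(unique(strsplit(paste(cds_proteins, collapse = ""), "")[[1]]),
                 AMINO_ACIDS)
  if (length(bad)) {
    stop("cds_proteins contain non-amino-acid letters: ",
         paste(bad, collapse = ", "))
  }
  if (replicon_count < 1L) stop("replicon_count must be >= 1")
  structure(
    list(n_rrn = as.integer(n_rrn), m_trna = m_trna,
         n_initiator_met = as.integer(n_initiator_met),
         cds_proteins = as.character(cds_proteins),
         table_id = as.integer(table_id), seed = as.integer(seed),
         replicon_count = as.integer(replicon_count)),
    class = "synthetic_genome_spec"
  )
}

#' Generate a synthetic annotated genome
#'
#' Produces a syntactically valid GenBank flat file (one record per
#' replicon) whose FEATURES table realizes the spec exactly: `n_rrn`
#' (16S, 23S, 5S) rRNA triplets, `tRNA-Xxx` features matching `m_trna`
#' (with `n_initiator_met` of the Met tRNAs written as `tRNA-fMet`), and
#' one CDS per protein with synonymous codons sampled uniformly under the
#' spec's seed. Roughly half the features land on the minus strand (written
#' as `complement(...)` locations). The manifest records the ground-truth
#' inventory and the exact codon counts of the embedded CDSs.
#'
#' @param spec A [synthetic_genome_spec()].
#' @return List with `text` (GenBank flat-file string) and `manifest`
#'   (list: `N_rrn`, `rrna_class_counts`, `N_tRNA`, `M_tRNA`,
#'   `n_initiator_met`, `n_cds`, `codon_counts`, `N_AA`).
#' @export
generate_synthetic_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  code <- genetic_code(spec$table_id)
  with_local_seed(spec$seed, {
    feats <- build_synthetic_features(spec, code)
    # distribute features round-robin over replicons
    rep_idx <- rep(seq_len(spec$replicon_count), length.out = max(nrow(feats), 0L))
    records <- character(spec$replicon_count)
    for (r in seq_len(spec$replicon_count)) {
      sub <- feats[rep_idx == r, , drop = FALSE]
      records[r] <- render_genbank_record(sub, sprintf("SYNREP%d", r),
                                          sprintf("SYN%06d.%d", spec$seed, r))
    }
    codon_counts <- stats::setNames(integer(64L), names(code$codon_to_aa))
    for (cds in feats$seq[feats$kind == "CDS"]) {
      tab <- table(split_codons(cds))
      codon_counts[names(tab)] <- codon_counts[names(tab)] + as.integer(tab)
    }
    sense <- code$codon_to_aa != "*"
    n_aa <- tapply(codon_counts[sense], code$codon_to_aa[sense], sum)
    N_AA <- stats::setNames(as.integer(n_aa), names(n_aa))
    N_AA <- N_AA[order(names(N_AA))]
    m_trna <- spec$m_trna[spec$m_trna > 0L]
    if (length(m_trna)) m_trna <- m_trna[order(names(m_trna))]
    else m_trna <- stats::setNames(integer(0), character(0))
    list(
      text = paste(records, collapse = "\n"),
      manifest = list(
        N_rrn = spec$n_rrn,
        rrna_class_counts = c(`16S` = spec$n_rrn, `23S` = spec$n_rrn,
                              `5S` = spec$n_rrn),
        N_tRNA = as.integer(sum(spec$m_trna)),
        M_tRNA = m_trna,
        n_initiator_met = spec$n_initiator_met,
        n_cds = length(spec$cds_proteins),
        codon_counts = codon_counts,
        N_AA = N_AA
      )
    )
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# encode a protein as a CDS: uniform choice among synonymous codons + stop
encode_protein <- function(protein, code) {
  aa_list <- strsplit(protein, "")[[1]]
  sense <- code$codon_to_aa[code$codon_to_aa != "*"]
  stops <- names(code$codon_to_aa)[code$codon_to_aa == "*"]
  codons <- vapply(aa_list, function(a) {
    fam <- names(sense)[sense == a]
    fam[sample.int(length(fam), 1L)]
  }, character(1))
  paste(c(codons, stops[sample.int(length(stops), 1L)]), collapse = "")
}

build_synthetic_features <- function(spec, code) {
  rows <- list()
  add <- function(kind, product, seq) {
    rows[[length(rows) + 1L]] <<- data.frame(kind = kind, product = product,
                                             seq = seq,
                                             stringsAsFactors = FALSE)
  }
  for (i in seq_len(spec$n_rrn)) {
    add("rRNA", "16S ribosomal RNA", random_dna(150L))
    add("rRNA", "23S ribosomal RNA", random_dna(220L))
    add("rRNA", "5S ribosomal RNA", random_dna(110L))
  }
  for (aa in names(spec$m_trna)) {
    n <- spec$m_trna[[aa]]
    n_f <- if (aa == "M") spec$n_initiator_met else 0L
    prods <- c(rep("tRNA-fMet", n_f),
               rep(paste0("tRNA-", AA_ONE_TO_THREE[[aa]]), n - n_f))
    for (p in prods) add("tRNA", p, random_dna(76L))
  }
  for (prot in spec$cds_proteins) {
    add("CDS", "hypothetical protein", encode_protein(prot, code))
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(0), product = character(0),
               seq = character(0), stringsAsFactors = FALSE)
  if (nrow(df)) {
    df$strand <- sample(c("+", "-"), nrow(df), replace = TRUE)
  } else {
    df$strand <- character(0)
  }
  df
}

# lay features along one replicon with random intergenic filler and render
# the GenBank record text
render_genbank_record <- function(feats, locus_name, accession) {
  pieces <- character(0)
  loc_lines <- character(0)
  pos <- 0L
  for (j in seq_len(nrow(feats))) {
    gap <- random_dna(sample(15:40, 1L))
    pieces <- c(pieces, gap)
    pos <- pos + nchar(gap)
    s <- feats$seq[j]
    genomic <- if (feats$strand[j] == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    } else s
    start <- pos + 1L
    end <- pos + nchar(genomic)
    pieces <- c(pieces, genomic)
    pos <- end
    loc <- sprintf("%d..%d", start, end)
    if (feats$strand[j] == "-") loc <- sprintf("complement(%s)", loc)
    loc_lines <- c(loc_lines, sprintf("     %-16s%s", feats$kind[j], loc),
                   sprintf("                     /product=\"%s\"",
                           feats$product[j]))
    if (feats$kind[j] == "CDS") {
      loc_lines <- c(loc_lines, "                     /transl_table=11")
    }
  }
  tail_gap <- random_dna(25L)
  pieces <- c(pieces, tail_gap)
  seq <- paste(pieces, collapse = "")
  len <- nchar(seq)

  header <- c(
    sprintf("LOCUS       %s %d bp    DNA     circular BCT 01-JAN-2024",
            locus_name, len),
    "DEFINITION  Synthetic bacterial genome (generated fixture).",
    sprintf("ACCESSION   %s", sub("\\..*$", "", accession)),
    sprintf("VERSION     %s", accession),
    "SOURCE      synthetic construct",
    "  ORGANISM  synthetic bacterium",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", len),
    "                     /organism=\"synthetic bacterium\""
  )
  origin <- c("ORIGIN", format_origin(seq), "//")
  paste(c(header, loc_lines, origin), collapse = "\n")
}

format_origin <- function(seq) {
  n <- nchar(seq)
  starts <- seq(1L, n, by = 60L)
  vapply(starts, function(s) {
    chunk <- substr(seq, s, min(s + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    sprintf("%9d %s", s, tolower(paste(blocks, collapse = " ")))
  }, character(1))
}

#' Simulate a growth dataset from a decay-with-floor model
#'
#' Draws `y_i = mu(T_i) + Gaussian(0, sigma)` where `mu` is the fixed-floor
#' (`1 + alpha * exp(-beta * T)`) or estimated-floor
#' (`gamma + alpha * exp(-beta * T)`) mean function. With
#' `round_to_integers`, draws are rounded and clipped below at 1 for the
#' operon model (counts are at least 1); the floor `gamma` is not
#' re-imposed on noisy draws.
#'
#' @param model_kind "rrn_eq1" or "trna_eq2".
#' @param alpha,beta Decay amplitude and rate (per minute).
#' @param gamma Floor for the tRNA model (ignored for rrn_eq1).
#' @param sigma Gaussian noise standard deviation (>= 0).
#' @param T_grid Generation times in minutes (explicit vector), or `NULL`
#'   to use `n` log-spaced points on [10, 10080] (10 min to 7 days, the
#'   observed bacterial range).
#' @param n Number of observations when `T_grid` is `NULL`.
#' @param seed Integer seed.
#' @param round_to_integers Round draws to integer counts.
#' @return Data frame with columns `species_label`, `T_minutes`, `y`.
#' @export
simulate_growth_dataset <- function(model_kind = c("rrn_eq1", "trna_eq2"),
                                    alpha, beta, gamma = NA, sigma = 0,
                                    T_grid = NULL, n = 20L, seed = 1L,
                                    round_to_integers = FALSE) {
  model_kind <- match.arg(model_kind)
  if (sigma < 0) stop("sigma must be >= 0")
  if (model_kind == "trna_eq2" && is.na(gamma)) {
    stop("trna_eq2 requires gamma")
  }
  if (is.null(T_grid)) {
    T_grid <- 10^seq(log10(10), log10(10080), length.out = n)
  }
  params <- list(alpha = alpha, beta = beta,
                 gamma = if (is.na(gamma)) NULL else gamma,
                 C = NULL)
  mu <- growth_mean_fn(T_grid, params, model_kind)
  with_local_seed(seed, {
    y <- mu + stats::rnorm(length(T_grid), 0, sigma)
    if (round_to_integers) {
      y <- round(y)
      if (model_kind == "rrn_eq1") y <- pmax(y, 1)
    }
    data.frame(species_label = sprintf("sim_%02d", seq_along(T_grid)),
               T_minutes = T_grid, y = y, stringsAsFactors = FALSE)
  })
}

#' Simulate an allocation table from the linear allocation model
#'
#' Draws per-amino-acid usage `N_AA` log-uniformly over [6e3, 2e5] (the
#' span observed in real fast-growing genomes), codon family sizes from
#' {1, 2, 3, 4, 6}, and
#' `M_tRNA = beta0 + beta1 * N_AA + beta2 * CFS + Gaussian(0, sigma)`,
#' optionally rounded and floored at 1.
#'
#' @param beta0,beta1,beta2 Model coefficients.
#' @param sigma Noise standard deviation.
#' @param n Number of rows (>= 4).
#' @param seed Integer seed.
#' @param round_to_integers Round responses to integer gene counts
#'   (floored at 1).
#' @return Data frame with columns `amino_acid`, `N_AA`, `CFS`, `M_tRNA`.
#' @export
simulate_allocation_table <- function(beta0, beta1, beta2, sigma = 0,
                                      n = 19L, seed = 1L,
                                      round_to_integers = FALSE) {
  if (n < 4L) stop("need n >= 4 rows")
  with_local_seed(seed, {
    N_AA <- round(10^stats::runif(n, log10(6e3), log10(2e5)))
    CFS <- sample(c(1L, 2L, 3L, 4L, 6L), n, replace = TRUE)
    M <- beta0 + beta1 * N_AA + beta2 * CFS + stats::rnorm(n, 0, sigma)
    if (round_to_integers) M <- pmax(round(M), 1)
    data.frame(amino_acid = sprintf("aa%02d", seq_len(n)),
               N_AA = N_AA, CFS = CFS, M_tRNA = M,
               stringsAsFactors = FALSE)
  })
}
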