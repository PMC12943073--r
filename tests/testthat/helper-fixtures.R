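# Hand-written minimal GenBank record exercising the location grammar:
# 2 CDS (one complement(join(...))), 1 tRNA, 3 rRNA features.
toy_gbff <- function() {
  paste(c(
    "LOCUS       TOY1 600 bp    DNA     circular BCT 01-JAN-2024",
    "DEFINITION  Toy record.",
    "ACCESSION   TOY001",
    "VERSION     TOY001.1",
    "SOURCE      toy bacterium",
    "  ORGANISM  toy bacterium",
    "FEATURES             Location/Qualifiers",
    "     source          1..600",
    "                     /organism=\"toy bacterium\"",
    "     CDS             10..24",
    "                     /product=\"protein one\"",
    "                     /transl_table=11",
    "     CDS             complement(join(30..38,45..50))",
    "                     /product=\"protein two\"",
    "     tRNA            60..135",
    "                     /product=\"tRNA-Leu\"",
    "     rRNA            150..300",
    "                     /product=\"16S ribosomal RNA\"",
    "     rRNA            310..520",
    "                     /product=\"23S ribosomal RNA\"",
    "     rRNA            530..590",
    "                     /product=\"5S ribosomal RNA\"",
    "ORIGIN",
    format_toy_origin(600),
    "//"), collapse = "\n")
}

format_toy_origin <- function(n) {
  set.seed(404)
  seq <- paste(sample(c("a", "c", "g", "t"), n, replace = TRUE), collapse = "")
  starts <- seq(1L, n, by = 60L)
  paste(vapply(starts, function(s) {
    chunk <- substr(seq, s, min(s + 59L, n))
    sprintf("%9d %s", s, chunk)
  }, character(1)), collapse = "\n")
}

with_seed_vec <- function(seed, n) { set.seed(seed); rnorm(n) }

# independent OLS oracle: minimize RSS of M ~ b0 + b1*N + b2*CFS numerically
brute_force_ols <- function(rows) {
  rss <- function(b) {
    sum((rows$M_tRNA - b[1] - b[2] * rows$N_AA - b[3] * rows$CFS)^2)
  }
  # scale N_AA for conditioning, then map back
  sc <- max(abs(rows$N_AA))
  rss_sc <- function(b) {
    sum((rows$M_tRNA - b[1] - b[2] * rows$N_AA / sc - b[3] * rows$CFS)^2)
  }
  fit <- stats::optim(c(0, 0, 0), rss_sc, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
  c(fit$par[1], fit$par[2] / sc, fit$par[3])
}

# random synthetic genome spec for round-trip properties
random_genome_spec <- function(seed) {
  set.seed(seed)
  aas <- sample(rrnalloc:::AMINO_ACIDS, sample(3:12, 1))
  m <- stats::setNames(sample(0:8, length(aas), replace = TRUE), aas)
  m <- m[m > 0]
  n_met <- if ("M" %in% names(m)) m[["M"]] else 0L
  synthetic_genome_spec(
    n_rrn = sample(0:11, 1),
    m_trna = m,
    n_initiator_met = if (n_met > 0) sample(0:n_met, 1) else 0L,
    cds_proteins = replicate(sample(0:3, 1), paste(
      sample(rrnalloc:::AMINO_ACIDS, sample(5:30, 1), replace = TRUE),
      collapse = "")),
    seed = seed,
    replicon_count = sample(1:3, 1)
  )
}
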