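#' Build the per-amino-acid tRNA allocation table
#'
#' Joins, for one species, the per-amino-acid tRNA gene counts (`M_tRNA`
#' from the genome inventory), the genome-wide amino-acid usage (`N_AA`
#' from all coding sequences) and the codon family size (CFS, from the
#' genetic code) into the 19-row table used by the allocation regression.
#' Methionine is excluded because of its special role as the initiation
#' amino acid; selenocysteine and unclassified tRNAs are excluded.
#'
#' @param inventory A `translation_inventory`.
#' @param usage A `usage_table` from the same species.
#' @param code A [genetic_code()] object.
#' @return Data frame with columns `amino_acid`, `N_AA`, `CFS`, `M_tRNA`,
#'   one row per non-Met amino acid with at least one tRNA gene or any
#'   codon usage.
#' @export
build_allocation_table <- function(inventory, usage, code = genetic_code(11)) {
  stopifnot(inherits(inventory, "translation_inventory"),
            inherits(usage, "usage_table"))
  cfs <- codon_family_sizes(code)
  aas <- setdiff(AMINO_ACIDS, "M")
  m <- stats::setNames(integer(length(aas)), aas)
  hit <- intersect(names(inventory$M_tRNA), aas)
  m[hit] <- inventory$M_tRNA[hit]
  n_aa <- stats::setNames(integer(length(aas)), aas)
  hit2 <- intersect(names(usage$N_AA), aas)
  n_aa[hit2] <- usage$N_AA[hit2]

  keep <- m > 0L | n_aa > 0L
  if (any(m > 0L & n_aa == 0L)) {
    warning("amino acid(s) with tRNA genes but zero codon usage: ",
            paste(aas[m > 0L & n_aa == 0L], collapse = ", "),
            "; retained with N_AA = 0")
  }
  if (!any(keep)) {
    warning("no non-Met amino acids with tRNA genes or codon usage; ",
            "empty allocation table")
  }
  data.frame(amino_acid = aas[keep],
             N_AA = unname(n_aa[keep]),
             CFS = unname(cfs[aas[keep]]),
             M_tRNA = unname(m[keep]),
             stringsAsFactors = FALSE)
}

#' Fit the tRNA-allocation regression
#'
#' Ordinary least squares for
#' `M_tRNA = beta0 + beta1 * N_AA + beta2 * CFS`, with the overall
#' regression ANOVA (model/residual/total sums of squares, F with
#' (2, n - 3) degrees of freedom) and per-coefficient two-sided t-tests.
#'
#' @param rows Data frame with columns `N_AA`, `CFS`, `M_tRNA` (as from
#'   [build_allocation_table()] or [read_allocation_tsv()]).
#' @return Object of class `allocation_fit`: coefficients
#'   (`beta0`, `beta1`, `beta2`), `se`, `t_stats`, `p_values`,
#'   `ss_model`, `ss_residual`, `ss_total`, `df_model`, `df_residual`,
#'   `df_total`, `ms_model`, `ms_residual`, `F`, `F_p`, `r_squared`,
#'   `n_obs`, and the underlying `lm` fit.
#' @export
fit_allocation_model <- function(rows) {
  rows <- as.data.frame(rows)
  need <- c("N_AA", "CFS", "M_tRNA")
  if (!all(need %in% names(rows))) {
    stop("allocation table must have columns ", paste(need, collapse = ", "))
  }
  n <- nrow(rows)
  if (n < 4L) stop("need at least 4 rows to fit the allocation model; got ", n)
  if (stats::sd(rows$N_AA) == 0 || stats::sd(rows$CFS) == 0 ||
      abs(stats::cor(rows$N_AA, rows$CFS)) > 1 - 1e-12) {
    stop("rank-deficient design: N_AA and CFS are collinear (or constant)")
  }

  fit <- stats::lm(M_tRNA ~ N_AA + CFS, data = rows)
  sm <- summary(fit)
  coefs <- sm$coefficients
  y <- rows$M_tRNA
  ss_total <- sum((y - mean(y))^2)
  ss_residual <- sum(stats::residuals(fit)^2)
  ss_model <- ss_total - ss_residual
  df_model <- 2L
  df_residual <- n - 3L
  ms_model <- ss_model / df_model
  ms_residual <- ss_residual / df_residual
  Fstat <- ms_model / ms_residual
  structure(
    list(beta0 = unname(coefs[1, 1]),
         beta1 = unname(coefs[2, 1]),
         beta2 = unname(coefs[3, 1]),
         se = stats::setNames(coefs[, 2], c("Intercept", "N_AA", "CFS")),
         t_stats = stats::setNames(coefs[, 3], c("Intercept", "N_AA", "CFS")),
         p_values = stats::setNames(coefs[, 4], c("Intercept", "N_AA", "CFS")),
         ss_model = ss_model, ss_residual = ss_residual, ss_total = ss_total,
         df_model = df_model, df_residual = df_residual, df_total = n - 1L,
         ms_model = ms_model, ms_residual = ms_residual,
         F = Fstat,
         F_p = stats::pf(Fstat, df_model, df_residual, lower.tail = FALSE),
         r_squared = ss_model / ss_total,
         n_obs = n,
         lm_fit = fit),
    class = "allocation_fit"
  )
}

#' @export
print.allocation_fit <- function(x, ...) {
  cat(sprintf("tRNA-allocation regression (n = %d)\n", x$n_obs))
  cat("ANOVA\n")
  cat(sprintf("  %-9s %2d  %10.5f  %9.5f  %9.5f  %s\n", "Model",
              x$df_model, x$ss_model, x$ms_model, x$F, format_p(x$F_p)))
  cat(sprintf("  %-9s %2d  %10.5f  %9.5f\n", "Residual",
              x$df_residual, x$ss_residual, x$ms_residual))
  cat(sprintf("  %-9s %2d  %10.5f\n", "Total", x$df_total, x$ss_total))
  cat("Coefficients\n")
  b <- c(x$beta0, x$beta1, x$beta2)
  nm <- c("Intercept", "N_AA", "CFS")
  for (i in 1:3) {
    cat(sprintf("  %-9s %10.5f  %8.5f  %8.5f  %s\n", nm[i], b[i],
                x$se[i], x$t_stats[i], format_p(x$p_values[i])))
  }
  cat(sprintf("R-squared = %.1f%%\n", 100 * x$r_squared))
  invisible(x)
}

format_p <- function(p) {
  if (p < 1e-4) sprintf("%.3e", p) else sprintf("%.5f", p)
}

#' Read an allocation table TSV
#'
#' @param path TSV with columns amino_acid (or AA), N_AA (or N), CFS,
#'   M_tRNA.
#' @return Data frame with standardized column names.
#' @export
read_allocation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[names(df) %in% c("AA", "aa")] <- "amino_acid"
  names(df)[names(df) == "N"] <- "N_AA"
  need <- c("amino_acid", "N_AA", "CFS", "M_tRNA")
  if (!all(need %in% names(df))) {
    stop("allocation TSV must have columns ", paste(need, collapse = ", "))
  }
  df[, need]
}

#' Write an allocation fit report
#'
#' Emits the ANOVA block and the coefficient block as a TSV (fixed column
#' order, 5-decimal statistics) or as JSON.
#'
#' @param fit An `allocation_fit`.
#' @param path Output path.
#' @param format "tsv" or "json".
#' @return `path`, invisibly.
#' @export
write_allocation_report <- function(fit, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    out <- fit[setdiff(names(fit), "lm_fit")]
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  anova_df <- data.frame(
    term = c("Model", "Residual", "Total"),
    DF = c(fit$df_model, fit$df_residual, fit$df_total),
    SS = sprintf("%.5f", c(fit$ss_model, fit$ss_residual, fit$ss_total)),
    MS = c(sprintf("%.5f", c(fit$ms_model, fit$ms_residual)), ""),
    F = c(sprintf("%.5f", fit$F), "", ""),
    p = c(format_p(fit$F_p), "", ""))
  coef_df <- data.frame(
    term = c("Intercept", "N_AA", "CFS"),
    beta = sprintf("%.5f", c(fit$beta0, fit$beta1, fit$beta2)),
    SE = sprintf("%.5f", fit$se),
    t = sprintf("%.5f", fit$t_stats),
    p = vapply(fit$p_values, format_p, character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ANOVA", con)
  utils::write.table(anova_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("# Coefficients", con)
  utils::write.table(coef_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("# R-squared\t%.4f", fit$r_squared), con)
  invisible(path)
}
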