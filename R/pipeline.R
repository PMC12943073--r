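#' Packaged study species table
#'
#' The 20-species study configuration: species label, bacterial kingdom
#' (Bacillati or Pseudomonadati), RefSeq accession list (comma-separated;
#' two chromosomes for the *Vibrio* species, four contigs for *Borrelia*),
#' the published generation-time text under optimal growth, and its rank.
#' The mid-range generation time in minutes is added as `T_minutes`.
#'
#' @return Data frame with columns `species`, `kingdom`, `accessions`,
#'   `gt_text`, `gt_rank`, `T_minutes`.
#' @export
study_species <- function() {
  path <- system.file("extdata", "study_species.tsv", package = "rrnalloc",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  df$T_minutes <- midpoint_generation_time(df$gt_text)
  df
}

#' Packaged per-amino-acid allocation tables
#'
#' The 19-row (Met-excluded) allocation tables for the two fastest
#' replicating study species: genome-wide amino-acid usage `N_AA`, codon
#' family size `CFS`, and tRNA gene count `M_tRNA` per amino acid.
#'
#' @param species `"Vibrio natriegens"` or `"Clostridium perfringens"`
#'   (partial matching on the first letter of the genus also works).
#' @return Data frame with columns `amino_acid`, `N_AA`, `CFS`, `M_tRNA`.
#' @export
allocation_fixture <- function(species = c("Vibrio natriegens",
                                           "Clostridium perfringens")) {
  species <- match.arg(species)
  file <- if (species == "Vibrio natriegens") "allocation_vnatriegens.tsv"
          else "allocation_cperfringens.tsv"
  read_allocation_tsv(system.file("extdata", file, package = "rrnalloc",
                                  mustWork = TRUE))
}

#' Published growth-model reference values
#'
#' The published per-kingdom maximum-likelihood estimates and
#' log-likelihoods for the fixed-floor operon model and the
#' estimated-floor tRNA model, with their null-model log-likelihoods and
#' likelihood-ratio p-values. Used as inputs for verifying the LRT
#' arithmetic; the parameter values themselves require genome downloads to
#' re-derive.
#'
#' @return Data frame with columns `model`, `kingdom`, `alpha`, `beta`,
#'   `gamma`, `lnL_model`, `lnL_null`, `p`.
#' @export
reference_growth_fits <- function() {
  utils::read.delim(system.file("extdata", "growth_fit_reference.tsv",
                                package = "rrnalloc", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Inventory a set of genomes
#'
#' Parses each species' GenBank flat file(s), merges multi-replicon
#' genomes, and builds one translation-machinery inventory row per
#' species. A species whose files are missing or unparseable is skipped
#' with a warning; the run continues.
#'
#' @param gbff_paths Named list: species label -> character vector of
#'   .gbff paths (several files are merged into one assembly). A plain
#'   character vector is treated as one single-file species each.
#' @param out Optional path for the inventory TSV.
#' @param code A [genetic_code()] object.
#' @param exclude_pseudo Drop pseudo-flagged features (default TRUE).
#' @return Data frame, one row per successfully inventoried species (the
#'   same layout as [write_inventory_tsv()]).
#' @export
run_inventory <- function(gbff_paths, out = NULL, code = genetic_code(11),
                          exclude_pseudo = TRUE) {
  if (is.character(gbff_paths)) {
    gbff_paths <- stats::setNames(as.list(gbff_paths),
                                  names(gbff_paths) %||% gbff_paths)
  }
  inventories <- list()
  for (label in names(gbff_paths)) {
    inv <- tryCatch({
      parts <- lapply(gbff_paths[[label]], read_genbank,
                      species_label = label)
      assembly <- if (length(parts) > 1L) merge_replicons(parts) else parts[[1]]
      build_inventory(assembly, code, exclude_pseudo)
    }, error = function(e) {
      warning("species '", label, "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(inv)) inventories[[label]] <- inv
  }
  df <- inventory_data_frame(inventories)
  if (!is.null(out)) write_inventory_tsv(inventories, out)
  df
}

#' Fit the growth models per kingdom
#'
#' For each bacterial kingdom in the input, fits the fixed-floor operon
#' model and the estimated-floor tRNA model against their constant nulls,
#' with likelihood-ratio tests, and assembles a report mirroring the
#' published layout (alpha, beta, gamma, lnL_model, lnL_null, G2, df, p).
#' Kingdoms with too few species are skipped with a warning.
#'
#' @param records Data frame with columns `species_label` (or `species`),
#'   `kingdom`, `T_minutes`, `N_rrn`, `N_tRNA`, and optionally `gt_rank`.
#' @param out_dir Optional directory: writes `growth_fit_report.json` and
#'   per-kingdom plot-data TSVs (rank/T vs observed and fitted counts).
#' @return List of class `growth_report`: per kingdom, a list with the
#'   four fits (`rrn`, `rrn_null`, `trna`, `trna_null`), the two
#'   `lrt_result`s, and a `table` data frame of the report rows.
#' @export
run_growth_fit <- function(records, out_dir = NULL) {
  records <- as.data.frame(records)
  if ("species" %in% names(records) && !"species_label" %in% names(records)) {
    records$species_label <- records$species
  }
  report <- list()
  for (kd in unique(records$kingdom)) {
    sub <- records[records$kingdom == kd, , drop = FALSE]
    if (nrow(sub) < 4L) {
      warning("kingdom '", kd, "' has fewer than 4 species; skipped")
      next
    }
    fits <- list()
    rows <- list()
    for (mk in c("rrn_eq1", "trna_eq2")) {
      resp <- if (mk == "rrn_eq1") "N_rrn" else "N_tRNA"
      d <- data.frame(T_minutes = sub$T_minutes, y = sub[[resp]])
      fit <- fit_growth_model(d, mk)
      null <- fit_growth_model(d, "constant_null")
      lrt <- likelihood_ratio_test(fit, null)
      key <- if (mk == "rrn_eq1") "rrn" else "trna"
      fits[[key]] <- fit
      fits[[paste0(key, "_null")]] <- null
      fits[[paste0(key, "_lrt")]] <- lrt
      rows[[key]] <- data.frame(
        model = mk, kingdom = kd,
        alpha = fit$alpha, beta = fit$beta,
        gamma = if (mk == "trna_eq2") fit$gamma else NA_real_,
        lnL_model = fit$lnL, lnL_null = null$lnL,
        G2 = lrt$G2, df = lrt$df, p = lrt$p_value,
        stringsAsFactors = FALSE)
    }
    fits$table <- do.call(rbind, rows)
    rownames(fits$table) <- NULL
    fits$data <- sub
    report[[kd]] <- fits
  }
  class(report) <- "growth_report"
  if (!is.null(out_dir)) write_growth_report(report, out_dir)
  report
}

#' @export
print.growth_report <- function(x, ...) {
  for (kd in setdiff(names(x), "class")) {
    cat("==", kd, "==\n")
    tb <- x[[kd]]$table
    print(format_growth_table(tb), row.names = FALSE)
  }
  invisible(x)
}

format_growth_table <- function(tb) {
  data.frame(model = tb$model,
             alpha = sprintf("%.6f", tb$alpha),
             beta = sprintf("%.6f", tb$beta),
             gamma = ifelse(is.na(tb$gamma), "", sprintf("%.6f", tb$gamma)),
             lnL_model = sprintf("%.4f", tb$lnL_model),
             lnL_null = sprintf("%.4f", tb$lnL_null),
             G2 = sprintf("%.4f", tb$G2),
             p = vapply(tb$p, format_p, character(1)))
}

write_growth_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- lapply(report, function(k) k$table)
  full <- do.call(rbind, tables)
  rownames(full) <- NULL
  jsonlite::write_json(full, file.path(out_dir, "growth_fit_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (kd in names(report)) {
    d <- report[[kd]]$data
    plot_df <- data.frame(
      species = d$species_label,
      gt_rank = if ("gt_rank" %in% names(d)) d$gt_rank else NA_integer_,
      T_minutes = d$T_minutes,
      N_rrn = d$N_rrn, N_tRNA = d$N_tRNA,
      N_rrn_fitted = growth_mean_fn(d$T_minutes, report[[kd]]$rrn, "rrn_eq1"),
      N_tRNA_fitted = growth_mean_fn(d$T_minutes, report[[kd]]$trna, "trna_eq2"))
    utils::write.table(plot_df,
                       file.path(out_dir, paste0("growth_plotdata_", kd, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}

#' Fit the allocation regression for one species
#'
#' Builds (or accepts) the 19-row allocation table and fits the linear
#' allocation model, returning the full ANOVA and coefficient report.
#'
#' @param rows An allocation table (data frame with `N_AA`, `CFS`,
#'   `M_tRNA`), or a species name accepted by [allocation_fixture()].
#' @param out Optional output path for a report TSV.
#' @return An `allocation_fit`.
#' @export
run_allocation <- function(rows, out = NULL) {
  if (is.character(rows) && length(rows) == 1L) {
    rows <- allocation_fixture(rows)
  }
  fit <- fit_allocation_model(rows)
  if (!is.null(out)) write_allocation_report(fit, out)
  fit
}
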