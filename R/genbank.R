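#' Parse a GenBank flat file into a genome assembly
#'
#' Reads one or more `LOCUS ... //` records of a GenBank flat file (.gbff/.gb)
#' and captures the three feature classes used downstream (CDS, rRNA, tRNA)
#' with their locations — including `complement(...)` and `join(...)` forms —
#' and the qualifiers relevant to counting (product, gene, anticodon, pseudo,
#' transl_table). All other feature kinds are ignored. Multi-record files
#' yield multi-replicon assemblies (bacterial genomes with several
#' chromosomes or contigs are first-class).
#'
#' @param text GenBank flat-file content: a single string, or a character
#'   vector of lines.
#' @param species_label Optional species label; defaults to the first
#'   record's source organism (or DEFINITION line).
#' @return An object of class `genome_assembly`: list with `species_label`,
#'   `accessions`, `replicons` (named character vector of sequences, `NA`
#'   where a record has no ORIGIN block), `replicon_lengths`, and `features`
#'   (data frame with columns kind, replicon_id, strand, segments
#'   (list column of start/end matrices, 1-based inclusive), product, gene,
#'   anticodon, pseudo, transl_table).
#' @seealso [read_genbank()] to parse from a file path.
#' @export
parse_genbank_flatfile <- function(text, species_label = NULL) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- as.character(text)
  }
  lines <- sub("\r$", "", lines)
  starts <- grep("^LOCUS ", lines)
  if (length(starts) == 0L) stop("no LOCUS record found in GenBank input")
  ends <- grep("^//\\s*$", lines)
  if (length(ends) < length(starts)) {
    stop("unterminated LOCUS record: expected matching // terminators")
  }

  replicons <- character(0)
  replicon_lengths <- integer(0)
  accessions <- character(0)
  organism <- NA_character_
  feats <- list()

  for (i in seq_along(starts)) {
    end_i <- ends[ends > starts[i]][1]
    rec <- lines[starts[i]:end_i]
    parsed <- parse_genbank_record(rec)
    if (parsed$replicon_id %in% names(replicons)) {
      stop("duplicate replicon id in input: ", parsed$replicon_id)
    }
    replicons[parsed$replicon_id] <- parsed$sequence
    replicon_lengths[parsed$replicon_id] <- parsed$length
    accessions <- c(accessions, parsed$accession)
    if (is.na(organism)) organism <- parsed$organism
    feats[[i]] <- parsed$features
  }

  features <- do.call(rbind, feats)
  if (is.null(features)) features <- empty_feature_frame()
  assembly <- structure(
    list(species_label = species_label %||% organism,
         accessions = unique(accessions[!is.na(accessions)]),
         replicons = replicons,
         replicon_lengths = replicon_lengths,
         features = features),
    class = "genome_assembly"
  )
  validate_assembly(assembly)
  assembly
}

#' Read a GenBank flat file from disk
#'
#' @param path Path to a .gbff/.gb file (plain text, possibly multi-record).
#' @param species_label Optional species label override.
#' @return A `genome_assembly`; see [parse_genbank_flatfile()].
#' @export
read_genbank <- function(path, species_label = NULL) {
  if (!file.exists(path)) stop("GenBank file not found: ", path)
  parse_genbank_flatfile(readLines(path, warn = FALSE), species_label)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

empty_feature_frame <- function() {
  data.frame(kind = character(0), replicon_id = character(0),
             strand = character(0), segments = I(list()),
             product = character(0), gene = character(0),
             anticodon = character(0), pseudo = logical(0),
             transl_table = integer(0), stringsAsFactors = FALSE)
}

validate_assembly <- function(assembly) {
  ft <- assembly$features
  if (nrow(ft) == 0L) return(invisible(assembly))
  for (j in seq_len(nrow(ft))) {
    len <- assembly$replicon_lengths[[ft$replicon_id[j]]]
    seg <- ft$segments[[j]]
    if (!is.na(len) && any(seg[, 2] > len)) {
      stop("feature ", ft$kind[j], " on ", ft$replicon_id[j],
           " extends beyond replicon length ", len)
    }
  }
  invisible(assembly)
}

# Parse one LOCUS..// record into replicon metadata plus extracted features.
parse_genbank_record <- function(rec) {
  locus <- strsplit(trimws(rec[1]), "\\s+")[[1]]
  replicon_id <- locus[2]
  len <- suppressWarnings(as.integer(locus[3]))

  ver_line <- grep("^VERSION ", rec, value = TRUE)
  acc_line <- grep("^ACCESSION ", rec, value = TRUE)
  accession <- if (length(ver_line)) {
    strsplit(trimws(sub("^VERSION", "", ver_line[1])), "\\s+")[[1]][1]
  } else if (length(acc_line)) {
    strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
  } else replicon_id

  org_line <- grep("^\\s{2}ORGANISM ", rec, value = TRUE)
  organism <- if (length(org_line)) {
    trimws(sub("^\\s*ORGANISM", "", org_line[1]))
  } else NA_character_

  feat_start <- grep("^FEATURES", rec)
  seq_start <- grep("^ORIGIN", rec)
  feat_end <- if (length(seq_start)) seq_start[1] - 1L else length(rec) - 1L

  features <- empty_feature_frame()
  if (length(feat_start)) {
    block <- rec[(feat_start[1] + 1L):feat_end]
    features <- parse_feature_block(block, replicon_id)
  }

  sequence <- NA_character_
  if (length(seq_start)) {
    seq_lines <- rec[(seq_start[1] + 1L):(length(rec) - 1L)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (!nzchar(sequence)) sequence <- NA_character_
    if (!is.na(sequence) && is.na(len)) len <- nchar(sequence)
  }

  list(replicon_id = replicon_id, accession = accession,
       organism = organism, length = len,
       sequence = sequence, features = features)
}

# The FEATURES table: a feature key starts at column 6; continuation and
# qualifier lines are indented to column 22.
parse_feature_block <- function(block, replicon_id) {
  key_idx <- grep("^ {5}\\S", block)
  keep <- c("CDS", "rRNA", "tRNA")
  out <- list()
  for (k in seq_along(key_idx)) {
    first <- key_idx[k]
    last <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(block)
    header <- block[first]
    kind <- sub("^\\s*(\\S+).*$", "\\1", header)
    if (!kind %in% keep) next
    cont <- if (last > first) trimws(block[(first + 1L):last]) else character(0)
    body <- c(sub("^ {5}\\S+\\s*", "", header), cont)
    body <- body[nzchar(body)]
    # location text: everything before the first qualifier line
    qual_at <- grep("^/", body)
    loc_lines <- if (length(qual_at)) body[seq_len(qual_at[1] - 1L)] else body
    loc_text <- paste(loc_lines, collapse = "")
    loc <- tryCatch(parse_location(loc_text),
                    error = function(e) stop("malformed location for ", kind,
                                             " feature: '", loc_text, "'",
                                             call. = FALSE))
    quals <- parse_qualifiers(if (length(qual_at)) body[qual_at[1]:length(body)] else character(0))
    out[[length(out) + 1L]] <- data.frame(
      kind = kind, replicon_id = replicon_id, strand = loc$strand,
      segments = I(list(loc$segments)),
      product = quals[["product"]] %||% NA_character_,
      gene = quals[["gene"]] %||% NA_character_,
      anticodon = quals[["anticodon"]] %||% NA_character_,
      pseudo = isTRUE(quals[["pseudo"]]),
      transl_table = as.integer(quals[["transl_table"]] %||% NA),
      stringsAsFactors = FALSE
    )
  }
  if (length(out)) do.call(rbind, out) else empty_feature_frame()
}

# Qualifier lines: /name=value (value possibly spanning lines), or bare /name.
parse_qualifiers <- function(lines) {
  if (length(lines) == 0L) return(list())
  starts <- grep("^/", lines)
  quals <- list()
  for (k in seq_along(starts)) {
    last <- if (k < length(starts)) starts[k + 1L] - 1L else length(lines)
    joined <- paste(lines[starts[k]:last], collapse = " ")
    m <- regmatches(joined, regexec("^/([A-Za-z_0-9]+)(=(.*))?$", joined))[[1]]
    name <- m[2]
    if (is.na(m[4]) || m[3] == "") {
      quals[[name]] <- TRUE
    } else {
      val <- m[4]
      val <- gsub('^"|"$', "", val)
      # translation qualifiers concatenate without internal spaces
      if (name == "translation") val <- gsub(" ", "", val)
      quals[[name]] <- val
    }
  }
  quals
}

#' Parse a GenBank location string
#'
#' Handles simple spans (`10..20`), single positions, partial-end markers
#' (`<`, `>`), and nested `complement(...)`, `join(...)`, `order(...)`.
#'
#' @param s Location string.
#' @return List with `segments` (matrix of start/end, 1-based inclusive, in
#'   listed order) and `strand` (`"+"` or `"-"`).
#' @keywords internal
parse_location <- function(s) {
  s <- gsub("\\s", "", s)
  res <- parse_location_rec(s, complemented = FALSE)
  strands <- unique(res$strands)
  strand <- if (length(strands) == 1L) strands else {
    warning("mixed strands within one location: '", s, "'; using +")
    "+"
  }
  seg <- res$segments
  colnames(seg) <- c("start", "end")
  list(segments = seg, strand = strand)
}

parse_location_rec <- function(s, complemented) {
  if (grepl("^complement\\(.*\\)$", s)) {
    inner <- substr(s, 12L, nchar(s) - 1L)
    return(parse_location_rec(inner, !complemented))
  }
  if (grepl("^(join|order)\\(.*\\)$", s)) {
    open <- regexpr("(", s, fixed = TRUE)
    inner <- substr(s, open + 1L, nchar(s) - 1L)
    parts <- split_toplevel_commas(inner)
    pieces <- lapply(parts, parse_location_rec, complemented = complemented)
    return(list(segments = do.call(rbind, lapply(pieces, `[[`, "segments")),
                strands = unlist(lapply(pieces, `[[`, "strands"))))
  }
  m <- regmatches(s, regexec("^<?(\\d+)(\\.\\.>?<?(\\d+))?$", s))[[1]]
  if (length(m) == 0L || is.na(m[2])) stop("unparseable location element: ", s)
  start <- as.integer(m[2])
  end <- if (is.na(m[4]) || m[4] == "") start else as.integer(m[4])
  if (start > end) stop("location start exceeds end: ", s)
  list(segments = matrix(c(start, end), nrow = 1L),
       strands = if (complemented) "-" else "+")
}

split_toplevel_commas <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  cuts <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    else if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  vapply(seq_along(starts),
         function(k) paste(chars[starts[k]:ends[k]], collapse = ""),
         character(1))
}

#' Merge replicons of one species into a single assembly
#'
#' Multi-chromosome genomes (e.g. the two *Vibrio* chromosomes) and
#' multi-contig assemblies are distributed over several GenBank records;
#' counting is defined over their union. Feature counts over the merged
#' assembly equal sums over the parts.
#'
#' @param assemblies Non-empty list of `genome_assembly` objects sharing a
#'   species label.
#' @return A single merged `genome_assembly`.
#' @export
merge_replicons <- function(assemblies) {
  if (length(assemblies) == 0L) stop("empty assembly list")
  stopifnot(all(vapply(assemblies, inherits, logical(1), "genome_assembly")))
  labels <- unique(vapply(assemblies, `[[`, character(1), "species_label"))
  labels <- labels[!is.na(labels)]
  if (length(labels) > 1L) {
    stop("assemblies have different species labels: ",
         paste(labels, collapse = ", "))
  }
  ids <- unlist(lapply(assemblies, function(a) names(a$replicons)))
  if (anyDuplicated(ids)) {
    stop("duplicate replicon id across assemblies: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(
    list(species_label = if (length(labels)) labels else NA_character_,
         accessions = unique(unlist(lapply(assemblies, `[[`, "accessions"))),
         replicons = do.call(c, lapply(assemblies, `[[`, "replicons")),
         replicon_lengths = do.call(c, lapply(assemblies, `[[`, "replicon_lengths")),
         features = do.call(rbind, lapply(assemblies, `[[`, "features"))),
    class = "genome_assembly"
  )
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("Genome assembly:", x$species_label %||% "(unlabelled)", "\n")
  cat("  replicons:", length(x$replicons),
      " accessions:", paste(x$accessions, collapse = ", "), "\n")
  cat("  features:", paste(sprintf("%s=%d", names(table(x$features$kind)),
                                   as.integer(table(x$features$kind))),
                           collapse = " "), "\n")
  invisible(x)
}

#' Extract feature sequences from an assembly
#'
#' Concatenates location segments in listed order and reverse-complements
#' minus-strand features. Requires the replicon sequences (ORIGIN blocks) to
#' be present.
#'
#' @param assembly A `genome_assembly`.
#' @param kind Feature class to extract: "CDS", "rRNA" or "tRNA".
#' @return Character vector of nucleotide sequences.
#' @export
extract_feature_seqs <- function(assembly, kind = c("CDS", "rRNA", "tRNA")) {
  kind <- match.arg(kind)
  ft <- assembly$features[assembly$features$kind == kind, , drop = FALSE]
  if (nrow(ft) == 0L) return(character(0))
  vapply(seq_len(nrow(ft)), function(j) {
    seq <- assembly$replicons[[ft$replicon_id[j]]]
    if (is.na(seq)) {
      stop("replicon ", ft$replicon_id[j],
           " has no sequence (ORIGIN block missing); cannot extract ", kind)
    }
    segs <- ft$segments[[j]]
    parts <- vapply(seq_len(nrow(segs)),
                    function(i) substr(seq, segs[i, 1], segs[i, 2]),
                    character(1))
    s <- paste(parts, collapse = "")
    if (ft$strand[j] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, character(1))
}
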