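#' Read a FASTA file of DNA sequences
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]. Identifiers are the
#' words before the first whitespace of each header; duplicates are an error.
#' Lowercase sequence is uppercased with a warning.
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) agam_abort(sprintf("cannot read FASTA '%s': %s", path, conditionMessage(e)), "format_error")
  )
  if (length(set) == 0) agam_abort(sprintf("'%s' contains no records", path), "format_error")
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) agam_abort(sprintf("'%s' has a record with an empty identifier", path), "format_error")
  if (anyDuplicated(ids)) {
    agam_abort(
      sprintf("duplicate identifier(s) in '%s': %s", path, paste(unique(ids[duplicated(ids)]), collapse = ", ")),
      "duplicate_id"
    )
  }
  seqs <- as.character(set)
  if (any(seqs == "")) agam_abort(sprintf("'%s' has an empty record", path), "format_error")
  # DNAStringSet normalises case silently; peek at the raw lines to warn
  raw <- readLines(path, warn = FALSE)
  if (any(grepl("[a-z]", raw[!startsWith(raw, ">")]))) {
    agam_warn(sprintf("lowercase sequence in '%s' uppercased", path), "lowercase_input")
  }
  stats::setNames(toupper(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (or list of [coding_sequence()] /
#'   [dna_molecule()] objects).
#' @param path Output path.
#' @param width Line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.list(seqs)) {
    ids <- vapply(seqs, `[[`, character(1), "id")
    seqs <- stats::setNames(vapply(seqs, `[[`, character(1), "sequence"), ids)
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    agam_abort("sequences must be named", "invalid_param")
  }
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a codon table file
#'
#' Reads the tab-separated codon-table dialect: comment lines start with `#`,
#' a header line names the columns, and one row per codon follows. Two
#' dialects are recognised automatically: the full dialect
#' (`codon aa count freq_within_aa per_1000`) and the compact "usage" dialect
#' (`codon aa per_1000 count`), from which `freq_within_aa` is recomputed.
#'
#' @param path Table file.
#' @param code Genetic code.
#' @return A `codon_frequency_table`.
#' @export
read_codon_table <- function(path, code = standard_genetic_code()) {
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) agam_abort(sprintf("cannot read codon table '%s'", path), "format_error")
  )
  need_full <- c("codon", "aa", "count", "freq_within_aa", "per_1000")
  need_usage <- c("codon", "aa", "per_1000", "count")
  if (all(need_full %in% names(df))) {
    if (!anyNA(df$count)) {
      # counts are complete: rebuild exactly from them
      tab <- build_frequency_table(
        stats::setNames(as.integer(df$count), toupper(df$codon)),
        code = code
      )
    } else {
      keep <- !is.na(df$freq_within_aa)
      tab <- codon_frequency_table(
        codon = df$codon[keep], freq_within_aa = df$freq_within_aa[keep],
        count = df$count[keep], per_1000 = df$per_1000[keep], code = code
      )
    }
  } else if (all(need_usage %in% names(df))) {
    counts <- stats::setNames(as.integer(df$count), toupper(df$codon))
    tab <- build_frequency_table(counts, code = code)
  } else {
    agam_abort(
      sprintf("'%s' is neither the full nor the usage codon-table dialect", path),
      "format_error"
    )
  }
  tab
}

#' Write a codon table file
#'
#' @param table A `codon_frequency_table`.
#' @param path Output path.
#' @param dialect `"full"` (codon, aa, count, freq_within_aa, per_1000) or
#'   `"usage"` (codon, aa, per_1000, count).
#' @param digits Decimal digits for frequencies (default 6; round-trip safe).
#' @param comment Optional comment line(s) written with a `#` prefix.
#' @return `path`, invisibly.
#' @export
write_codon_table <- function(table, path, dialect = c("full", "usage"), digits = 6L,
                              comment = NULL) {
  dialect <- match.arg(dialect)
  if (!inherits(table, "codon_frequency_table")) {
    agam_abort("table must be a codon_frequency_table", "invalid_param")
  }
  df <- as.data.frame(table)
  df$freq_within_aa <- round(df$freq_within_aa, digits)
  df$per_1000 <- round(df$per_1000, digits)
  cols <- if (dialect == "full") {
    c("codon", "aa", "count", "freq_within_aa", "per_1000")
  } else {
    c("codon", "aa", "per_1000", "count")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df[cols], con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a penalty report as JSON
#'
#' @param report A `penalty_report` from [penalty_index()].
#' @param path Output path, or `NULL` to return the JSON string.
#' @return `path` (or the JSON string when `path` is `NULL`), invisibly.
#' @export
write_penalty_report <- function(report, path = NULL) {
  if (!inherits(report, "penalty_report")) {
    agam_abort("report must be a penalty_report", "invalid_param")
  }
  obj <- list(
    sequence_id = report$sequence_id,
    n_codons = report$n_codons,
    threshold = report$threshold,
    raw_penalty = report$raw_penalty,
    penalty_index = report$penalty_index,
    penalty_index_rounded = report$penalty_index_rounded,
    rare_hits = report$rare_hits
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(as.character(json), path)
  invisible(path)
}

# ---- GenBank flat file (minimal reader/writer) ------------------------------
# Covers what annotated plasmid maps need: LOCUS (length + topology), FEATURES
# with simple or complement() spans and /label-style qualifiers, ORIGIN.

#' Read a GenBank flat file
#'
#' Minimal parser for annotated sequence maps: captures the sequence, the
#' topology from the LOCUS line, and features with simple `a..b` or
#' `complement(a..b)` locations. The feature name is taken from the first of
#' the `/label`, `/gene`, `/product`, `/note` qualifiers, falling back to the
#' feature key. Joined/multi-interval locations are not supported.
#'
#' @param path GenBank file.
#' @return A [dna_molecule()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) agam_abort(sprintf("'%s': no LOCUS line", path), "format_error")
  topology <- if (grepl("\\bcircular\\b", locus[1], ignore.case = TRUE)) "circular" else "linear"
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
  if (is.na(id) || !nzchar(id)) id <- "genbank_record"

  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0) agam_abort(sprintf("'%s': no ORIGIN section", path), "format_error")
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at)) end_at[end_at > origin_at[1]][1] else length(lines) + 1L
  seq_lines <- lines[(origin_at[1] + 1L):(end_at - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste0(seq_lines, collapse = "")))
  if (!nzchar(seq)) agam_abort(sprintf("'%s': empty sequence", path), "format_error")
  if (grepl("[^ACGT]", seq)) {
    agam_abort(sprintf("'%s': sequence contains non-ACGT characters", path), "format_error")
  }

  feats <- empty_features()
  feat_at <- grep("^FEATURES", lines)
  if (length(feat_at) > 0) {
    block <- lines[(feat_at[1] + 1L):(origin_at[1] - 1L)]
    cur <- NULL
    flush <- function(cur, feats) {
      if (is.null(cur)) return(feats)
      rbind(feats, data.frame(
        name = cur$name %||% cur$key, start = cur$start, end = cur$end,
        strand = cur$strand, stringsAsFactors = FALSE
      ))
    }
    for (ln in block) {
      if (grepl("^ {5}\\S", ln)) { # new feature
        feats <- flush(cur, feats)
        cur <- NULL
        key <- sub("^\\s*(\\S+).*$", "\\1", ln)
        if (key == "source") next
        loc <- trimws(sub("^\\s*\\S+\\s*", "", ln))
        strand <- if (grepl("^complement\\(", loc)) "-" else "+"
        loc <- gsub("^complement\\(|\\)$", "", loc)
        m <- regmatches(loc, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", loc))[[1]]
        if (length(m) == 3) {
          cur <- list(
            key = key, start = as.integer(m[2]), end = as.integer(m[3]),
            strand = strand, name = NULL
          )
        }
      } else if (!is.null(cur) && grepl("^\\s+/", ln)) {
        q <- regmatches(ln, regexec('^\\s+/(\\w+)="?([^"]*)"?\\s*$', ln))[[1]]
        if (length(q) == 3 && is.null(cur$name) &&
          q[2] %in% c("label", "gene", "product", "note")) {
          cur$name <- q[3]
        }
      }
    }
    feats <- flush(cur, feats)
  }
  if (nrow(feats) > 0 && any(feats$end > nchar(seq) | feats$start > nchar(seq))) {
    agam_abort(sprintf("'%s': feature coordinates exceed sequence length", path), "format_error")
  }
  dna_molecule(id, seq, topology, feats)
}

#' Write a GenBank flat file
#'
#' @param mol A [dna_molecule()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(mol, path) {
  con <- file(path, "w")
  on.exit(close(con))
  len <- nchar(mol$sequence)
  writeLines(sprintf(
    "LOCUS       %-16s %d bp    DNA     %-8s SYN %s",
    substr(mol$id, 1, 16), len, mol$topology, format(Sys.Date(), "%d-%b-%Y")
  ), con)
  writeLines(sprintf("DEFINITION  %s.", mol$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", len), con)
  if (nrow(mol$features) > 0) {
    for (i in seq_len(nrow(mol$features))) {
      f <- mol$features[i, ]
      loc <- sprintf("%d..%d", f$start, f$end)
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     misc_feature    %s", loc), con)
      writeLines(sprintf("                     /label=\"%s\"", f$name), con)
    }
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, len, 60L)
  for (p in pos) {
    chunk <- substr(mol$sequence, p, min(p + 59L, len))
    tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read enzyme and recombination-site definitions from YAML
#'
#' The config file may define custom enzymes and att/lox site sequences:
#' ```yaml
#' enzymes:
#'   BsaI: {recognition: GGTCTC, cut_offset_top: 1, cut_offset_bottom: 5}
#' sites:
#'   attP: [LEFTARM, TTG, RIGHTARM]
#'   attB: [LEFTARM, TTG, RIGHTARM]
#'   loxP: [ATAACTTCGTATA, ATGTATGC, TATACGAAGTTAT]
#' ```
#'
#' @param path YAML file.
#' @return A list with `enzymes` (named list of [enzyme_spec()]) and `sites`
#'   (a [recombination_sites()], or `NULL` when the file defines none).
#' @export
read_site_config <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    agam_abort(sprintf("cannot parse config '%s': %s", path, conditionMessage(e)), "format_error")
  })
  enzymes <- list()
  for (nm in names(cfg$enzymes %||% list())) {
    e <- cfg$enzymes[[nm]]
    enzymes[[nm]] <- enzyme_spec(nm, e$recognition, e$cut_offset_top, e$cut_offset_bottom)
  }
  sites <- NULL
  if (!is.null(cfg$sites)) {
    defaults <- recombination_sites()
    sites <- recombination_sites(
      attP = toupper(cfg$sites$attP %||% defaults$attP),
      attB = toupper(cfg$sites$attB %||% defaults$attB),
      loxP = toupper(cfg$sites$loxP %||% defaults$loxP)
    )
  }
  list(enzymes = enzymes, sites = sites)
}
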