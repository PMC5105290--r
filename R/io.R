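#' Read a nucleotide FASTA file
#'
#' Reads scaffold or gene sequences into a tibble, enforcing that every record
#' has a non-empty, unique identifier and a non-empty sequence over the
#' alphabet `A`, `C`, `G`, `T`, `N`. Record order is preserved. Identifiers are
#' the first whitespace-delimited token of the header line, the convention of
#' all mainstream sequence tools.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `seq`, one row per record.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  out <- tibble(id = unname(ids), seq = unname(seqs))
  validate_fasta(out, path)
  out
}

validate_fasta <- function(records, path = "<in-memory>") {
  if (any(!nzchar(records$id))) {
    format_error(sprintf("%s: record %d has an empty identifier",
                         path, which(!nzchar(records$id))[1]))
  }
  dup <- records$id[duplicated(records$id)]
  if (length(dup) > 0) {
    format_error(sprintf("%s: duplicate sequence id '%s'", path, dup[1]))
  }
  if (any(!nzchar(records$seq))) {
    format_error(sprintf("%s: record '%s' has an empty sequence",
                         path, records$id[!nzchar(records$seq)][1]))
  }
  bad <- grepl("[^ACGTN]", records$seq)
  if (any(bad)) {
    format_error(sprintf("%s: record '%s' contains characters outside A/C/G/T/N",
                         path, records$id[bad][1]))
  }
  invisible(records)
}

#' Write sequences to a FASTA file
#'
#' @param records A tibble (or data frame) with columns `id` and `seq`, as
#'   returned by [read_fasta()] or the simulators.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- as_tibble(records)
  validate_fasta(records)
  set <- Biostrings::DNAStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

tabular_hit_cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
                      "mismatches", "gap_openings", "q_start", "q_end",
                      "s_start", "s_end", "evalue", "bit_score")

#' Read a 12-column tabular homology hit file
#'
#' Parses the standard 12-column tab-separated alignment format
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`), one hit per line, as produced by tabular search output.
#' Each hit is labelled with the caller-supplied subject database: the label is
#' an analysis decision (which database was searched), never parsed from the
#' file. Query coordinates are kept 1-based inclusive, the convention of the
#' format; interval arithmetic downstream converts at the boundary.
#'
#' Malformed lines (fewer than 12 columns, non-numeric fields, negative
#' E-values, inverted query coordinates, identity outside (0, 100]) are
#' rejected with the offending line number.
#'
#' @param path Path to the tab-separated hit file.
#' @param subject_db One of `"bacterial"`, `"animal"`, `"self"`,
#'   `"arthropod"`: the database the subjects belong to.
#' @return A tibble of hits with the 12 standard columns plus `subject_db`.
#' @export
read_tabular_hits <- function(path, subject_db) {
  subject_db <- match.arg(subject_db, c("bacterial", "animal", "self", "arthropod"))
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_hits(subject_db))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    format_error(sprintf("%s: line %d has %d columns, expected 12",
                         path, which(nf < 12L)[1], nf[which(nf < 12L)[1]]))
  }
  mat <- t(vapply(fields, function(f) f[1:12], character(12)))
  hits <- tibble(
    query_id = mat[, 1], subject_id = mat[, 2],
    pct_identity = suppressWarnings(as.numeric(mat[, 3])),
    aln_length = suppressWarnings(as.integer(mat[, 4])),
    mismatches = suppressWarnings(as.integer(mat[, 5])),
    gap_openings = suppressWarnings(as.integer(mat[, 6])),
    q_start = suppressWarnings(as.integer(mat[, 7])),
    q_end = suppressWarnings(as.integer(mat[, 8])),
    s_start = suppressWarnings(as.integer(mat[, 9])),
    s_end = suppressWarnings(as.integer(mat[, 10])),
    evalue = suppressWarnings(as.numeric(mat[, 11])),
    bit_score = suppressWarnings(as.numeric(mat[, 12])),
    subject_db = subject_db
  )
  num_bad <- !stats::complete.cases(hits[3:12])
  if (any(num_bad)) {
    format_error(sprintf("%s: line %d has a non-numeric numeric field",
                         path, which(num_bad)[1]))
  }
  validate_hits(hits, path)
  hits
}

empty_hits <- function(subject_db = character()) {
  tibble(
    query_id = character(), subject_id = character(),
    pct_identity = numeric(), aln_length = integer(), mismatches = integer(),
    gap_openings = integer(), q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(), evalue = numeric(),
    bit_score = numeric(), subject_db = character()
  )
}

validate_hits <- function(hits, path = "<in-memory>") {
  bad <- which(hits$evalue < 0)
  if (length(bad) > 0) {
    format_error(sprintf("%s: line %d has a negative E-value", path, bad[1]))
  }
  bad <- which(hits$pct_identity > 100 | hits$pct_identity <= 0)
  if (length(bad) > 0) {
    format_error(sprintf("%s: line %d has identity outside (0, 100]", path, bad[1]))
  }
  bad <- which(hits$q_start > hits$q_end)
  if (length(bad) > 0) {
    format_error(sprintf("%s: line %d has q_start > q_end", path, bad[1]))
  }
  bad <- which(hits$q_start < 1L)
  if (length(bad) > 0) {
    format_error(sprintf("%s: line %d has q_start < 1", path, bad[1]))
  }
  invisible(hits)
}

#' Write homology hits in the 12-column tabular format
#'
#' @param hits A hit tibble as returned by [read_tabular_hits()] or
#'   [local_align()]. The `subject_db` label is not written; it is an analysis
#'   attribute, not part of the format.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  out <- as_tibble(hits)[, tabular_hit_cols]
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Reads `gene` (and optionally `mRNA`) features carrying an `ID` attribute.
#' GFF3 coordinates are 1-based inclusive; they are converted here, at the file
#' boundary, to the package's internal 0-based half-open convention
#' (`start - 1`, `end`), so all downstream interval arithmetic shares one
#' convention. Features of other types are skipped and their count reported
#' via a message.
#'
#' @param path Path to a GFF3 file.
#' @param species Optional species identifier attached to every gene model.
#' @param feature_types Feature types to keep (default `"gene"`).
#' @return A tibble with columns `gene_id`, `scaffold`, `start`, `end`
#'   (0-based half-open), `strand`, `species`.
#' @export
read_gff3 <- function(path, species = NA_character_,
                      feature_types = "gene") {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(gene_id = character(), scaffold = character(),
                  start = integer(), end = integer(), strand = character(),
                  species = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    i <- which(nf < 9L)[1]
    format_error(sprintf("%s: line %d has %d columns, expected 9",
                         path, lineno[i], nf[i]))
  }
  mat <- t(vapply(fields, function(f) f[1:9], character(9)))
  type <- mat[, 3]
  sel <- type %in% feature_types
  n_skipped <- sum(!sel)
  if (n_skipped > 0) {
    inform(sprintf("read_gff3: skipped %d feature(s) of other types", n_skipped))
  }
  if (!any(sel)) {
    return(tibble(gene_id = character(), scaffold = character(),
                  start = integer(), end = integer(), strand = character(),
                  species = character()))
  }
  mat <- mat[sel, , drop = FALSE]
  lineno <- lineno[sel]
  start1 <- suppressWarnings(as.integer(mat[, 4]))
  end1 <- suppressWarnings(as.integer(mat[, 5]))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad) > 0) {
    format_error(sprintf("%s: line %d has non-numeric coordinates",
                         path, lineno[bad[1]]))
  }
  bad <- which(end1 < start1)
  if (length(bad) > 0) {
    format_error(sprintf("%s: line %d has end < start", path, lineno[bad[1]]))
  }
  ids <- stringr::str_match(mat[, 9], "(?:^|;)\\s*ID=([^;]+)")[, 2]
  bad <- which(is.na(ids) | !nzchar(ids))
  if (length(bad) > 0) {
    format_error(sprintf("%s: line %d has no ID attribute", path, lineno[bad[1]]))
  }
  dup <- which(duplicated(ids))
  if (length(dup) > 0) {
    format_error(sprintf("%s: line %d repeats ID '%s'",
                         path, lineno[dup[1]], ids[dup[1]]))
  }
  tibble(
    gene_id = ids,
    scaffold = mat[, 1],
    start = start1 - 1L,   # 0-based half-open
    end = end1,
    strand = mat[, 7],
    species = species
  )
}

#' Read an orthologous-group membership table
#'
#' Reads a TSV with header columns `og_id`, `species_id`, `gene_id`, one
#' membership per line, into an [ortho_table()]. Exact duplicate rows are
#' dropped with a warning; a gene assigned to two different orthologous groups
#' is rejected, because the downstream per-gene classification requires each
#' gene to receive exactly one category.
#'
#' @param path Path to the TSV file.
#' @param species_universe Optional character vector of all species under
#'   study; defaults to the species present in the table.
#' @return An [ortho_table()].
#' @export
read_og_table <- function(path, species_universe = NULL) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("og_id", "species_id", "gene_id")
  if (!all(need %in% names(df))) {
    format_error(sprintf("%s: header must contain columns %s",
                         path, paste(need, collapse = ", ")))
  }
  df <- df[need]
  if (anyDuplicated(df)) {
    warn(sprintf("%s: %d duplicate membership line(s) removed",
                 path, sum(duplicated(df))))
    df <- distinct(df)
  }
  ortho_table(df, species_universe = species_universe)
}

#' Write an orthologous-group membership table
#'
#' @param table An [ortho_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_og_table <- function(table, path) {
  stopifnot(inherits(table, "ortho_table"))
  readr::write_tsv(table$memberships, path)
  invisible(path)
}

#' Read junction-spanning read-pair evidence
#'
#' Junction evidence arrives as a small TSV with header columns `scaffold`,
#' `position` (0-based point), `library_id`, `supporting_pairs`, one row per
#' (library, junction) observation.
#'
#' @param path Path to the TSV file.
#' @return A tibble of junction evidence.
#' @export
read_junctions <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, col_types = "cici", progress = FALSE)
  need <- c("scaffold", "position", "library_id", "supporting_pairs")
  if (!all(need %in% names(df))) {
    format_error(sprintf("%s: header must contain columns %s",
                         path, paste(need, collapse = ", ")))
  }
  bad <- which(df$supporting_pairs < 1L)
  if (length(bad) > 0) {
    format_error(sprintf("%s: line %d has supporting_pairs < 1", path, bad[1] + 1L))
  }
  df[need]
}
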