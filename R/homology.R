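#' Scoring scheme for the built-in local aligner
#'
#' Bundles substitution and affine-gap scores with Karlin-Altschul statistical
#' parameters. A gap run of length `L` scores `gap_open + (L - 1) * gap_extend`
#' (the first gapped column pays the opening score). The Karlin parameters
#' feed the E-value formula `E = K * m * n * exp(-lambda * S)`; the defaults
#' (`K = 0.1`, `lambda = 0.5`) are documented toy values for desk-scale
#' fixtures, not database-calibrated statistics -- externally produced tabular
#' hits are the production path for large searches.
#'
#' @param match Score for an identical aligned pair; must be > 0.
#' @param mismatch Score for a mismatched pair; must be <= 0.
#' @param gap_open Score of the first column of a gap run; must be <= 0.
#' @param gap_extend Score of each subsequent gap column; must be <= 0.
#' @param karlin_lambda,karlin_K Positive Karlin-Altschul parameters.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap_open = -2,
                           gap_extend = -1, karlin_lambda = 0.5,
                           karlin_K = 0.1) {
  check_scalar(match, "match"); check_scalar(mismatch, "mismatch")
  check_scalar(gap_open, "gap_open"); check_scalar(gap_extend, "gap_extend")
  if (match <= 0) abort("`match` must be > 0")
  if (mismatch > 0) abort("`mismatch` must be <= 0")
  if (gap_open > 0 || gap_extend > 0) abort("gap scores must be <= 0")
  if (karlin_lambda <= 0 || karlin_K <= 0) {
    abort("Karlin parameters must be positive")
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, karlin_lambda = karlin_lambda,
                 karlin_K = karlin_K),
            class = "scoring_scheme")
}

#' Homology significance policy
#'
#' The single significance gate used across the pipeline: a hit is significant
#' iff its E-value is strictly below the threshold. The default `1e-5` is the
#' standard cutoff for both the orthology homology fallbacks and the bacterial
#' HGT screen; equality is not significant (the comparison is strict).
#'
#' @param evalue_threshold Positive E-value threshold (default `1e-5`).
#' @return A list of class `homology_policy`.
#' @export
homology_policy <- function(evalue_threshold = 1e-5) {
  check_scalar(evalue_threshold, "evalue_threshold")
  if (evalue_threshold <= 0) abort("`evalue_threshold` must be > 0")
  structure(list(evalue_threshold = evalue_threshold), class = "homology_policy")
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' Computes `E = K * m * n * exp(-lambda * S)` for search-space sizes `m`
#' (query length) and `n` (subject or database length). E is strictly
#' decreasing in the score and linear (hence strictly increasing) in each of
#' `m` and `n`.
#'
#' @param score Raw alignment score.
#' @param m,n Search-space sizes in bases; both must be >= 1.
#' @param scheme A [scoring_scheme()] supplying `karlin_lambda`, `karlin_K`.
#' @return The E-value (non-negative real), vectorized over `score`.
#' @export
evalue <- function(score, m, n, scheme = scoring_scheme()) {
  if (any(m < 1) || any(n < 1)) abort("`m` and `n` must be >= 1")
  scheme$karlin_K * m * n * exp(-scheme$karlin_lambda * score)
}

#' Smith-Waterman local alignment of two sequences
#'
#' Optimal local alignment with affine gap scores (Gotoh algorithm),
#' returning a standard 12-column homology hit. Identity is computed over
#' aligned columns -- gap columns count as non-matches -- and reported to one
#' decimal, mirroring tabular alignment output. The bit score is
#' `(lambda * S - ln K) / ln 2` and the E-value comes from [evalue()] with
#' `m`, `n` defaulting to the two sequence lengths (override `search_m`,
#' `search_n` to model a larger database). An empty alignment (no
#' positive-scoring pair) is allowed: the hit has score-derived fields at
#' zero and `aln_length` 0.
#'
#' @param query,subject Non-empty nucleotide strings (or single-row tibbles
#'   with `id`/`seq` columns as returned by [read_fasta()]).
#' @param scheme A [scoring_scheme()].
#' @param query_id,subject_id Identifiers used when plain strings are given.
#' @param subject_db Database label attached to the hit.
#' @param search_m,search_n Optional search-space sizes for the E-value.
#' @return A one-row hit tibble (see [read_tabular_hits()] for columns), plus
#'   a `score` column with the raw alignment score.
#' @export
local_align <- function(query, subject, scheme = scoring_scheme(),
                        query_id = "query", subject_id = "subject",
                        subject_db = "bacterial",
                        search_m = NULL, search_n = NULL) {
  if (is.data.frame(query)) { query_id <- query$id[1]; query <- query$seq[1] }
  if (is.data.frame(subject)) { subject_id <- subject$id[1]; subject <- subject$seq[1] }
  if (!nzchar(query) || !nzchar(subject)) abort("sequences must be non-empty")
  aln <- sw_align_cpp(query, subject, scheme$match, scheme$mismatch,
                      scheme$gap_open, scheme$gap_extend)
  m <- search_m %||% nchar(query)
  n <- search_n %||% nchar(subject)
  ident <- if (aln$aln_length > 0) {
    round(100 * aln$matches / aln$aln_length, 1)
  } else NA_real_
  tibble(
    query_id = query_id, subject_id = subject_id,
    pct_identity = ident,
    aln_length = as.integer(aln$aln_length),
    mismatches = as.integer(aln$mismatches),
    gap_openings = as.integer(aln$gap_openings),
    q_start = as.integer(aln$q_start), q_end = as.integer(aln$q_end),
    s_start = as.integer(aln$s_start), s_end = as.integer(aln$s_end),
    evalue = evalue(aln$score, m, n, scheme),
    bit_score = (scheme$karlin_lambda * aln$score - log(scheme$karlin_K)) / log(2),
    subject_db = subject_db,
    score = aln$score
  )
}

#' Is a hit significant under the E-value policy?
#'
#' `TRUE` iff `evalue < evalue_threshold`, strictly: a hit at exactly the
#' threshold is not significant.
#'
#' @param hits A hit tibble (any number of rows) or a numeric vector of
#'   E-values.
#' @param policy A [homology_policy()].
#' @return A logical vector, one element per hit.
#' @export
is_significant <- function(hits, policy = homology_policy()) {
  ev <- if (is.data.frame(hits)) hits$evalue else hits
  ev < policy$evalue_threshold
}

#' Best hit among hits sharing a query
#'
#' Reduces a set of hits for one query to the single best hit: minimum
#' E-value, ties broken by maximum bit score, then lexicographic subject id.
#' An empty input yields an empty (zero-row) tibble.
#'
#' @param hits A hit tibble whose rows all share `query_id`.
#' @return A hit tibble with zero rows (absent) or one row.
#' @export
best_hit <- function(hits) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) return(hits)
  if (n_distinct(hits$query_id) > 1) {
    abort("best_hit: hits must share a single query")
  }
  hits |>
    arrange(.data$evalue, dplyr::desc(.data$bit_score), .data$subject_id) |>
    slice(1)
}
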