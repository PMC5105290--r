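#' Align database sequences against scaffold windows
#'
#' Desk-scale stand-in for a database search: every window of the scaffold
#' is locally aligned ([local_align()]) against every database sequence and
#' the resulting hits are reported in scaffold coordinates, ready for
#' [find_bacterial_regions()] / [screen_region()]. The E-value search space
#' is the window length times the total database length.
#'
#' The default scheme lowers `karlin_lambda` to 0.25 so that E-values of
#' kilobase-scale, high-identity alignments stay within double-precision
#' range (`lambda * S` must stay below ~700 or E underflows to 0 and strict
#' E-value comparisons degenerate into ties); see the methods vignette.
#'
#' @param genome A FASTA-ready tibble (`id`, `seq`) of scaffolds.
#' @param windows A tibble (`window_id`, `scaffold`, `start`, `end`) of
#'   0-based half-open windows, e.g. from [simulate_hgt_genome()].
#' @param db A FASTA-ready tibble (`id`, `seq`) of database sequences.
#' @param subject_db Database label for the hits.
#' @param scheme A [scoring_scheme()].
#' @param min_score Hits scoring below this are dropped (default 1: drop
#'   empty alignments).
#' @return A hit tibble in scaffold coordinates.
#' @export
align_windows <- function(genome, windows, db,
                          subject_db = c("bacterial", "animal", "self",
                                         "arthropod"),
                          scheme = scoring_scheme(karlin_lambda = 0.25),
                          min_score = 1) {
  subject_db <- match.arg(subject_db)
  genome <- as_tibble(genome)
  windows <- as_tibble(windows)
  db <- as_tibble(db)
  n_db <- sum(nchar(db$seq))
  out <- vector("list", nrow(windows) * nrow(db))
  k <- 0L
  for (w in seq_len(nrow(windows))) {
    scaf <- windows$scaffold[w]
    gseq <- genome$seq[genome$id == scaf]
    if (length(gseq) != 1) {
      abort(sprintf("window scaffold '%s' not found in the genome", scaf))
    }
    wseq <- substr(gseq, windows$start[w] + 1L, windows$end[w])
    for (d in seq_len(nrow(db))) {
      hit <- local_align(wseq, db$seq[d], scheme,
                         query_id = scaf, subject_id = db$id[d],
                         subject_db = subject_db,
                         search_m = nchar(wseq), search_n = n_db)
      if (hit$score < min_score) next
      k <- k + 1L
      hit$q_start <- hit$q_start + windows$start[w]
      hit$q_end <- hit$q_end + windows$start[w]
      out[[k]] <- hit
    }
  }
  if (k == 0L) return(empty_hits())
  bind_rows(out[seq_len(k)])
}
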