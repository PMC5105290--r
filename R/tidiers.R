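#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy differential-expression results
#'
#' @param x A [run_de()] result.
#' @param ... Unused.
#' @return A plain tibble, one row per tested gene.
#' @export
tidy.de_results <- function(x, ...) {
  out <- x
  attr(out, "normalized") <- NULL
  attr(out, "conditions") <- NULL
  class(out) <- class(tibble())
  out
}

#' One-row summary of a differential-expression run
#'
#' @param x A [run_de()] result.
#' @param ... Unused.
#' @return A tibble with the number of tested and flagged genes and the
#'   flagged fraction.
#' @export
glance.de_results <- function(x, ...) {
  tibble(n_genes = nrow(x), n_flagged = sum(x$flagged),
         prop_flagged = if (nrow(x) > 0) mean(x$flagged) else NA_real_,
         min_adj_p = if (nrow(x) > 0) min(x$adj_p) else NA_real_)
}

#' Tidy an HGT candidate table
#'
#' @param x A [screen_hgt()] result.
#' @param ... Unused.
#' @return A plain tibble, one row per candidate region.
#' @export
tidy.hgt_candidates <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  out
}

#' One-row summary of an HGT screen
#'
#' @param x A [screen_hgt()] result.
#' @param ... Unused.
#' @return A tibble counting candidates by verdict and junction support.
#' @export
glance.hgt_candidates <- function(x, ...) {
  tibble(n_candidates = nrow(x),
         n_retained = sum(x$status == "retained"),
         n_excluded_conserved = sum(x$status == "excluded_conserved"),
         n_junction_confirmed = sum(x$junction_confirmed),
         n_recent = sum(x$age_class == "recent" & x$status == "retained"),
         n_degrading = sum(x$age_class == "degrading" & x$status == "retained"))
}

#' Tidy an orthology partition summary
#'
#' @param x A [summarize_partition()] result.
#' @param ... Unused.
#' @return A long tibble (`species_id`, `category`, `n_genes`).
#' @export
tidy.ortho_summary <- function(x, ...) {
  x$species |>
    select(-"total") |>
    tidyr::pivot_longer(-"species_id", names_to = "category",
                        values_to = "n_genes")
}

#' One-row summary of an orthology partition
#'
#' @param x A [summarize_partition()] result.
#' @param ... Unused.
#' @return A tibble with OG span counts and totals.
#' @export
glance.ortho_summary <- function(x, ...) {
  spans <- setNames(as.integer(x$og$n_ogs), paste0("ogs_", x$og$span))
  bind_cols(tibble(n_species = nrow(x$species),
                   total_genes = sum(x$species$total)),
            as_tibble(as.list(spans)))
}
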