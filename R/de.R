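#' Differential-expression flagging policy
#'
#' The thresholds of the two-condition exact-test procedure: genes with fewer
#' than `min_total_reads` mapped reads across all samples are removed before
#' testing; a gene is flagged iff its absolute log2 fold change strictly
#' exceeds `logfc_threshold` and its adjusted p value is strictly below
#' `adj_p_threshold`. `pseudocount` stabilizes the log fold change when a
#' condition total is zero.
#'
#' @param min_total_reads Minimum total read count to keep a gene
#'   (default 10).
#' @param logfc_threshold Strict absolute log2-fold-change bound
#'   (default 1.0).
#' @param adj_p_threshold Strict adjusted-p bound (default 0.05).
#' @param pseudocount Added to each condition total in the log fold change
#'   (default 0.5).
#' @return A list of class `de_policy`.
#' @export
de_policy <- function(min_total_reads = 10L, logfc_threshold = 1.0,
                      adj_p_threshold = 0.05, pseudocount = 0.5) {
  if (min_total_reads <= 0 || logfc_threshold <= 0 || adj_p_threshold <= 0 ||
      pseudocount <= 0) {
    abort("all de_policy thresholds must be positive")
  }
  structure(list(min_total_reads = min_total_reads,
                 logfc_threshold = logfc_threshold,
                 adj_p_threshold = adj_p_threshold,
                 pseudocount = pseudocount),
            class = "de_policy")
}

# Validate a counts tibble (gene_id + one column per sample) against a
# condition map (sample_id, condition in {treatment, control}).
check_count_matrix <- function(counts, conditions) {
  counts <- as_tibble(counts)
  conditions <- as_tibble(conditions)
  samples <- setdiff(names(counts), "gene_id")
  if (!"gene_id" %in% names(counts) || length(samples) == 0) {
    format_error("`counts` must have a gene_id column plus one column per sample")
  }
  missing <- setdiff(samples, conditions$sample_id)
  if (length(missing) > 0) {
    format_error(sprintf("sample '%s' has no condition assignment", missing[1]))
  }
  conditions <- conditions[match(samples, conditions$sample_id), ]
  if (!all(conditions$condition %in% c("treatment", "control"))) {
    format_error("conditions must be 'treatment' or 'control'")
  }
  if (n_distinct(conditions$condition) < 2) {
    format_error("both conditions need at least one sample")
  }
  if (any(vapply(counts[samples], function(x) any(x < 0 | is.na(x)),
                 logical(1)))) {
    format_error("counts must be non-negative and non-missing")
  }
  list(counts = counts, conditions = conditions, samples = samples)
}

#' Remove genes with too few mapped reads
#'
#' Drops every gene whose total count across all samples is strictly below
#' `min_total_reads` (default: fewer than ten mapped reads).
#'
#' @param counts A tibble with `gene_id` plus one integer column per sample.
#' @param policy A [de_policy()].
#' @return The filtered counts tibble.
#' @export
filter_low_counts <- function(counts, policy = de_policy()) {
  counts <- as_tibble(counts)
  samples <- setdiff(names(counts), "gene_id")
  if (nrow(counts) == 0) return(counts)
  totals <- rowSums(counts[samples])
  counts[totals >= policy$min_total_reads, , drop = FALSE]
}

#' Quantile-normalize a count matrix
#'
#' Maps every sample onto the common reference distribution formed by the
#' row means of the sorted columns, so that after normalization all samples
#' share the same sorted value multiset; tied counts within a sample receive
#' the mean of the reference values they span. Per-sample rank order is
#' preserved.
#'
#' @param counts A tibble with `gene_id` plus one column per sample
#'   (>= 2 samples).
#' @return A tibble of the same shape with real-valued normalized values.
#' @export
quantile_normalize <- function(counts) {
  counts <- as_tibble(counts)
  samples <- setdiff(names(counts), "gene_id")
  if (length(samples) < 2) {
    abort("quantile normalization needs at least two samples")
  }
  mat <- as.matrix(counts[samples])
  norm <- limma::normalizeQuantiles(mat, ties = TRUE)
  out <- counts
  out[samples] <- as_tibble(as.data.frame(norm))
  out
}

#' Two-sided exact test for one gene between two conditions
#'
#' Tests the 2x2 table `[gene_trt, rest_trt; gene_ctl, rest_ctl]` where
#' `rest = condition library total - gene count`, conditioning on the
#' margins: under the null the gene's treatment count is hypergeometric, and
#' the two-sided p value is the sum of the probabilities of all tables (with
#' those margins) no more probable than the observed one. The log fold
#' change is `log2(((x_trt + c) / N_trt) / ((x_ctl + c) / N_ctl))` with
#' pseudocount `c`.
#'
#' @param x_trt,x_ctl Gene counts summed within each condition (vectorized
#'   over genes).
#' @param n_trt,n_ctl Condition library totals (sums over all genes); must
#'   be positive.
#' @param policy A [de_policy()] (supplies the pseudocount).
#' @return A tibble (`logFC`, `p`), one row per gene.
#' @export
gene_exact_test <- function(x_trt, x_ctl, n_trt, n_ctl,
                            policy = de_policy()) {
  if (any(n_trt <= 0) || any(n_ctl <= 0)) {
    abort("library sizes must be positive")
  }
  args <- vctrs_recycle(x_trt, x_ctl, n_trt, n_ctl)
  if (any(args$x_trt > args$n_trt) || any(args$x_ctl > args$n_ctl)) {
    abort("gene counts cannot exceed their library totals")
  }
  p <- vapply(seq_along(args$x_trt), function(i) {
    exact_p_two_sided(args$x_trt[i], args$x_trt[i] + args$x_ctl[i],
                      args$n_trt[i], args$n_ctl[i])
  }, numeric(1))
  c_ps <- policy$pseudocount
  logfc <- log2(((args$x_trt + c_ps) / args$n_trt) /
                  ((args$x_ctl + c_ps) / args$n_ctl))
  tibble(logFC = logfc, p = p)
}

vctrs_recycle <- function(x_trt, x_ctl, n_trt, n_ctl) {
  n <- max(length(x_trt), length(x_ctl), length(n_trt), length(n_ctl))
  list(x_trt = rep_len(x_trt, n), x_ctl = rep_len(x_ctl, n),
       n_trt = rep_len(n_trt, n), n_ctl = rep_len(n_ctl, n))
}

# Two-sided hypergeometric p: sum over all admissible treatment counts x of
# dhyper(x) for dhyper(x) <= dhyper(observed) * (1 + 1e-7); the relative
# tolerance absorbs floating-point noise in the equal-probability tail, the
# standard convention for two-sided exact 2x2 tests.
exact_p_two_sided <- function(x_obs, k, n_trt, n_ctl) {
  lo <- max(0, k - n_ctl)
  hi <- min(k, n_trt)
  xs <- lo:hi
  d <- dhyper(xs, n_trt, n_ctl, k)
  d_obs <- dhyper(x_obs, n_trt, n_ctl, k)
  min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts p values by the BH step-up rule: `adj_(i) = min_{j >= i}
#' (m * p_(j) / j)` over the ascending order statistics, capped at 1 and
#' mapped back to the input order. Sorting the inputs ascending yields
#' non-decreasing adjusted values.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return The adjusted p values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Flag differentially expressed genes
#'
#' A gene is flagged iff `|logFC| > logfc_threshold` AND
#' `adj_p < adj_p_threshold`, both comparisons strict: a gene at exactly the
#' fold-change or adjusted-p boundary is not flagged. Both directions of
#' change trigger flagging.
#'
#' @param results A tibble with columns `logFC` and `adj_p`.
#' @param policy A [de_policy()].
#' @return `results` with a logical `flagged` column.
#' @export
flag_de <- function(results, policy = de_policy()) {
  as_tibble(results) |>
    mutate(flagged = abs(.data$logFC) > policy$logfc_threshold &
             .data$adj_p < policy$adj_p_threshold)
}

#' Run the exact-test differential-expression procedure end to end
#'
#' The full flagging pipeline for a two-condition count matrix: (1) genes
#' with fewer than `min_total_reads` total reads are removed; (2) counts are
#' quantile-normalized and the reported log fold change is computed from the
#' normalized within-condition totals (with pseudocount); (3) each gene gets
#' a two-sided exact test on its raw within-condition count sums against the
#' raw library-size margins; (4) p values are BH-adjusted; (5) genes are
#' flagged at strict `|logFC| >` and `adj_p <` thresholds. Summing replicate
#' counts within condition before the exact test leaves replicate-level
#' dispersion unmodeled; see the methods vignette for the consequences.
#'
#' @param counts A tibble with `gene_id` plus one integer column per sample.
#' @param conditions A tibble (`sample_id`, `condition`) with conditions
#'   `treatment` and `control`.
#' @param policy A [de_policy()].
#' @return A tibble of class `de_results` (`gene_id`, `logFC`, `p`, `adj_p`,
#'   `flagged`), with the normalized matrix attached as attribute
#'   `normalized` for plotting.
#' @export
run_de <- function(counts, conditions, policy = de_policy()) {
  v <- check_count_matrix(counts, conditions)
  counts <- filter_low_counts(v$counts, policy)
  if (nrow(counts) == 0) {
    out <- tibble(gene_id = character(), logFC = numeric(), p = numeric(),
                  adj_p = numeric(), flagged = logical())
    class(out) <- c("de_results", class(out))
    return(out)
  }
  trt <- v$conditions$sample_id[v$conditions$condition == "treatment"]
  ctl <- v$conditions$sample_id[v$conditions$condition == "control"]

  raw_trt <- rowSums(counts[trt])
  raw_ctl <- rowSums(counts[ctl])
  n_trt <- sum(raw_trt)
  n_ctl <- sum(raw_ctl)
  if (n_trt <= 0 || n_ctl <= 0) abort("a condition has zero total counts")

  norm <- quantile_normalize(counts)
  norm_trt <- rowSums(norm[trt])
  norm_ctl <- rowSums(norm[ctl])
  nn_trt <- sum(norm_trt)
  nn_ctl <- sum(norm_ctl)
  c_ps <- policy$pseudocount
  logfc <- log2(((norm_trt + c_ps) / nn_trt) / ((norm_ctl + c_ps) / nn_ctl))

  p <- purrr::map2_dbl(raw_trt, raw_ctl, function(a, b) {
    exact_p_two_sided(a, a + b, n_trt, n_ctl)
  })

  out <- tibble(gene_id = counts$gene_id, logFC = logfc, p = p,
                adj_p = bh_adjust(p)) |>
    flag_de(policy)
  attr(out, "normalized") <- norm
  attr(out, "conditions") <- v$conditions
  class(out) <- c("de_results", class(out))
  out
}

#' Write differential-expression results
#'
#' @param results A [run_de()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_de_results <- function(results, path) {
  readr::write_tsv(as_tibble(results), path)
  invisible(path)
}
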