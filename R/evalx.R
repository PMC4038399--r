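#' Expand a known-binder set with exact-duplicate library compounds
#'
#' A true positive for benchmarking is a known binder or any library
#' compound with TC exactly 1 to one — fingerprint-identical compounds are
#' indistinguishable to a similarity screen and must count as hits.
#'
#' @param known character vector of known-binder compound ids (nonempty).
#' @param library named list of [fingerprint()]s containing the known
#'   binders.
#' @return list of class `benchmark_truth` with `known_ids` and
#'   `expanded_ids` (`known_ids` plus TC = 1 neighbors).
#' @export
expand_true_positives <- function(known, library) {
  known <- unique(as.character(known))
  if (length(known) == 0L) stop("known-binder set is empty")
  missing <- setdiff(known, names(library))
  if (length(missing))
    stop("known binders absent from library: ", paste(missing, collapse = ", "))
  tc <- tanimoto_matrix(library[known], library)
  dup <- colnames(tc)[apply(tc == 1, 2L, any)]
  structure(list(known_ids = known, expanded_ids = union(known, dup)),
            class = "benchmark_truth")
}

as_truth_ids <- function(truth) {
  if (inherits(truth, "benchmark_truth")) truth$expanded_ids
  else unique(as.character(truth))
}

#' Enrichment factor of a ranked screen
#'
#' \deqn{EF_x = \frac{\#\ true\ positives\ in\ top\ 100x\%}
#'                  {total\ true\ positives \times x}}
#' with the top set of size `ceiling(x * N)`. \eqn{EF_x} ranges from 0 to
#' \eqn{1/x}; at `x = 0.01` a value of 100 means every true positive sits
#' in the top 1%, while 1.0 is the random-selection expectation.
#'
#' @param ranked character vector of compound ids in rank order.
#' @param truth a `benchmark_truth` or character vector of true-positive ids.
#' @param x top fraction in (0, 1\].
#' @return EF value.
#' @export
enrichment_factor <- function(ranked, truth, x = 0.01) {
  stopifnot(x > 0, x <= 1)
  tp <- as_truth_ids(truth)
  if (length(tp) == 0L) stop("no true positives; enrichment undefined")
  top <- ranked[seq_len(top_n(length(ranked), x))]
  sum(top %in% tp) / (length(tp) * x)
}

#' Area under the accumulative curve
#'
#' The accumulative curve plots the fraction of true positives recovered
#' against the fraction of the library screened, stepping up as each true
#' positive is encountered in rank order. The area is taken by the
#' trapezoidal rule on the full per-compound step curve, anchored at
#' (0, 0); an ideal screen approaches 1, a random one averages 0.5.
#'
#' @inheritParams enrichment_factor
#' @return AUAC value in \[0, 1\].
#' @export
auac <- function(ranked, truth) {
  tp <- as_truth_ids(truth)
  if (length(tp) == 0L) stop("no true positives; AUAC undefined")
  n <- length(ranked)
  frac_found <- cumsum(ranked %in% tp) / length(tp)
  y <- c(0, frac_found)
  sum((y[-1] + y[-length(y)]) / 2) / n
}

#' Random-ranking baseline for EF and AUAC
#'
#' Estimates the expectation of \eqn{EF_x} and AUAC under uniformly random
#' ranking by Monte-Carlo: each permutation shuffles the library and the
#' metrics are recomputed. The analytic expectation of \eqn{EF_x} under
#' random selection is ~1.0 (exactly `top_n(n, x) / (n * x)`).
#'
#' @param n_library library size.
#' @param n_true number of true positives in the library.
#' @param x top fraction.
#' @param n_perm number of random permutations (>= 1).
#' @param seed integer seed for reproducibility.
#' @return list with `ef_mean`, `ef_se`, `auac_mean`, `auac_se`, `n_perm`.
#' @export
random_baseline <- function(n_library, n_true, x = 0.01, n_perm = 2000L,
                            seed = 1L) {
  stopifnot(n_true >= 1L, n_true <= n_library, n_perm >= 1L)
  set.seed(seed)
  n_top <- top_n(n_library, x)
  efs <- numeric(n_perm)
  aus <- numeric(n_perm)
  denom_steps <- n_library * n_true
  for (i in seq_len(n_perm)) {
    pos <- sample.int(n_library)           # rank of each library slot
    tp_ranks <- pos[seq_len(n_true)]       # first n_true slots are the TPs
    efs[i] <- sum(tp_ranks <= n_top) / (n_true * x)
    # AUAC of a step curve depends only on the TP ranks:
    # area = 1 - mean_rank/n + 1/(2n)  (trapezoid on the per-compound grid)
    aus[i] <- 1 - sum(tp_ranks) / denom_steps + 1 / (2 * n_library)
  }
  list(ef_mean = mean(efs), ef_se = stats::sd(efs) / sqrt(n_perm),
       auac_mean = mean(aus), auac_se = stats::sd(aus) / sqrt(n_perm),
       n_perm = n_perm)
}

#' Full enrichment report for a ranked screen
#'
#' @param ranked character vector of compound ids in rank order.
#' @param truth a `benchmark_truth` or character vector of true-positive ids.
#' @param x_values top fractions at which to report EF.
#' @return data frame of class `enrichment_report` with one `ef_<x>` row per
#'   fraction plus an `auac` row; attributes `n_library`, `n_true`.
#' @export
enrichment_report <- function(ranked, truth, x_values = c(0.01, 0.05, 0.1)) {
  tp <- as_truth_ids(truth)
  ef <- vapply(x_values, function(x) enrichment_factor(ranked, tp, x),
               numeric(1))
  out <- data.frame(metric = c(paste0("ef_", x_values), "auac"),
                    value = c(ef, auac(ranked, tp)),
                    stringsAsFactors = FALSE)
  attr(out, "n_library") <- length(ranked)
  attr(out, "n_true") <- length(tp)
  class(out) <- c("enrichment_report", "data.frame")
  out
}
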