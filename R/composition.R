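#' Composition of the experimental validation and benchmark libraries
#'
#' The screening campaigns this package models are bookkept from their
#' component compound sets. The experimentally screened candidate set pools
#' three NCI/DTP open-repository collections (Diversity Set III, 1,597;
#' Approved Oncology Drugs Set IV, 97; Natural Product Set II, 118). For
#' ranking, candidates are buried in a ZINC8-derived background culled to
#' mutual TC < 0.7 (67,871 compounds); the large-scale drug-target
#' benchmark instead pools 6,507 drugs with the same background.
#'
#' @param screen which library to describe: `"validation"` (NCI candidates
#'   + ZINC background) or `"benchmark"` (drugs + ZINC background).
#' @return data frame with columns `component` and `n`.
#' @examples
#' sum(library_composition("validation")$n) # 69683 compounds screened
#' @export
library_composition <- function(screen = c("validation", "benchmark")) {
  screen <- match.arg(screen)
  zinc <- data.frame(component = "zinc8_background", n = 67871L)
  switch(screen,
    validation = rbind(nci_composition(), zinc),
    benchmark = rbind(data.frame(component = "drugs", n = 6507L), zinc))
}

#' Composition of the NCI candidate set
#'
#' @return data frame with columns `component` and `n`, one row per
#'   NCI/DTP collection.
#' @export
nci_composition <- function() {
  data.frame(
    component = c("nci_diversity_iii", "nci_oncology_iv", "nci_natural_product_ii"),
    n = c(1597L, 97L, 118L))
}

#' Total size of a screening library
#'
#' @inheritParams library_composition
#' @return integer sum over components.
#' @export
library_size <- function(screen = c("validation", "benchmark")) {
  sum(library_composition(screen)$n)
}
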