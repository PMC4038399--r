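#' Evidence library of template-ligand fingerprints
#'
#' One evidence library per source of template ligands (e.g. holo PDB
#' structures, a drug-target database, a bioactivity database). A screen
#' combines any number of evidence libraries; the canonical setup uses
#' three.
#'
#' @param name unique library name.
#' @param template_ligands named list of [fingerprint()] objects, at least
#'   one.
#' @return list of class `evidence_library` with `name`, `template_ligands`,
#'   `n_lg`.
#' @export
evidence_library <- function(name, template_ligands) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(template_ligands) == 0L)
    stop("evidence library '", name, "' has no template ligands")
  structure(list(name = name, template_ligands = template_ligands,
                 n_lg = length(template_ligands)),
            class = "evidence_library")
}

#' mTC similarity of a compound to an evidence library
#'
#' The mTC score blends the average and the maximum Tanimoto coefficient
#' between a library compound and the template-ligand set:
#' \deqn{mTC = w \cdot \mathrm{mean}_l TC(L_l, L_{lib}) +
#'       (1 - w) \cdot \max_l TC(L_l, L_{lib})}
#' The default weight `w = 0.1` favors the maximum term, so that a compound
#' closely matching any single template ligand scores highly, while the
#' average term still rewards broad similarity to the whole set.
#'
#' @param fp compound [fingerprint()].
#' @param lib an [evidence_library()].
#' @param w weight on the average term, in \[0, 1\].
#' @return mTC value in \[0, 1\].
#' @export
mtc_score <- function(fp, lib, w = 0.1) {
  stopifnot(inherits(lib, "evidence_library"), w >= 0, w <= 1)
  tcs <- vapply(lib$template_ligands, tanimoto, numeric(1), b = fp)
  w * mean(tcs) + (1 - w) * max(tcs)
}

#' Combine per-evidence mTC scores
#'
#' Independent screens against each evidence library yield one mTC score
#' each; the combined score is their maximum — the strongest single line of
#' evidence wins.
#'
#' @param scores numeric vector of per-evidence mTC scores (NAs allowed for
#'   absent evidence; at least one non-NA value required).
#' @return combined score.
#' @export
combine_scores <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) stop("no evidence scores to combine")
  max(scores)
}

#' Screen a compound library against evidence libraries
#'
#' Computes the mTC of every compound against every evidence library,
#' combines per-compound scores by maximum, and ranks the library by
#' descending combined score (ties broken by compound id).
#'
#' @param library named list of compound [fingerprint()]s.
#' @param evidences list of [evidence_library()] objects with unique names.
#' @param w mTC average-term weight.
#' @return data frame of class `screen_result`: `rank`, `id`, one
#'   `mtc_<name>` column per evidence library, `combined`.
#' @export
rank_library <- function(library, evidences, w = 0.1) {
  stopifnot(length(library) >= 1L, length(evidences) >= 1L)
  if (inherits(evidences, "evidence_library")) evidences <- list(evidences)
  ev_names <- vapply(evidences, function(e) e$name, character(1))
  if (anyDuplicated(ev_names)) stop("evidence library names must be unique")
  per_ev <- vapply(evidences, function(ev) {
    tc <- tanimoto_matrix(library, ev$template_ligands)
    w * rowMeans(tc) + (1 - w) * apply(tc, 1L, max)
  }, numeric(length(library)))
  per_ev <- matrix(per_ev, nrow = length(library),
                   dimnames = list(names(library), paste0("mtc_", ev_names)))
  combined <- apply(per_ev, 1L, max)
  ord <- order(-combined, names(library))
  out <- data.frame(rank = seq_along(library), id = names(library)[ord],
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(per_ev[ord, , drop = FALSE]))
  out$combined <- combined[ord]
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Select the top fraction of a ranked screen
#'
#' Keeps the first `ceiling(x * N)` compounds; at the default `x = 0.01`
#' this is the "top 1%" short-list passed on to experimental validation.
#'
#' @param results a `screen_result` from [rank_library()], or any data
#'   frame ordered by rank.
#' @param x fraction in (0, 1\].
#' @return the top subset, same columns.
#' @export
select_top_fraction <- function(results, x = 0.01) {
  stopifnot(x > 0, x <= 1)
  utils::head(results, top_n(nrow(results), x))
}

#' Size of a top-x selection
#'
#' @param n library size.
#' @param x fraction in (0, 1\].
#' @return `ceiling(x * n)` as integer.
#' @export
top_n <- function(n, x = 0.01) {
  stopifnot(x > 0, x <= 1, n >= 0)
  as.integer(ceiling(x * n))
}

#' Write screen results as TSV
#'
#' @param results a `screen_result`.
#' @param path output file.
#' @param config_hash optional traceability hash written as a `#` header.
#' @return `path`, invisibly.
#' @export
write_screen_result <- function(results, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash: ", config_hash), con)
  utils::write.table(results, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
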