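#' BLOSUM62 substitution matrix
#'
#' The standard published BLOSUM62 log-odds matrix over the 20 amino acids,
#' extended with an `X` (unknown residue) row/column scored `x_score`
#' against everything (default 0).
#'
#' @param x_score score of `X` against any residue.
#' @return symmetric integer matrix with dimnames over the 20 amino acids
#'   plus `X`.
#' @export
blosum62 <- function(x_score = 0L) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  v <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4)
  m <- matrix(as.integer(v), 20, 20, byrow = TRUE, dimnames = list(aa, aa))
  m <- rbind(cbind(m, X = as.integer(x_score)),
             X = as.integer(rep(x_score, 21)))
  m
}

#' Residue alignment between a target and a template
#'
#' @param target_pos,template_pos 1-based residue positions, each strictly
#'   increasing.
#' @param target_aa,template_aa one-letter residue codes.
#' @return data frame of class `residue_alignment` with one row per aligned
#'   pair.
#' @export
residue_alignment <- function(target_pos, target_aa, template_pos, template_aa) {
  df <- data.frame(target_pos = as.integer(target_pos),
                   target_aa = toupper(as.character(target_aa)),
                   template_pos = as.integer(template_pos),
                   template_aa = toupper(as.character(template_aa)),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (is.unsorted(df$target_pos, strictly = TRUE))
      stop("target positions must be strictly increasing")
    if (is.unsorted(df$template_pos, strictly = TRUE))
      stop("template positions must be strictly increasing")
    ok <- grepl("^[A-Z]$", df$target_aa) & grepl("^[A-Z]$", df$template_aa)
    if (!all(ok))
      stop("invalid residue code at alignment row(s) ",
           paste(which(!ok), collapse = ", "))
  }
  class(df) <- c("residue_alignment", "data.frame")
  df
}

#' Read a target-template residue alignment file
#'
#' Format: a header line `#target <id> template <id>` followed by
#' tab-separated rows `target_pos target_aa template_pos template_aa`.
#'
#' @param path alignment file.
#' @return `residue_alignment` with attributes `target_id` and `template_id`.
#' @export
read_alignment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty alignment file: ", path)
  hdr <- strsplit(sub("^#", "", lines[[1]]), "[ \t]+")[[1]]
  hdr <- hdr[nzchar(hdr)]
  if (length(hdr) < 4L || hdr[1] != "target" || hdr[3] != "template")
    stop("malformed alignment header in ", path)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  aln <- if (length(body)) {
    f <- strsplit(body, "\t")
    residue_alignment(vapply(f, `[`, character(1), 1L),
                      vapply(f, `[`, character(1), 2L),
                      vapply(f, `[`, character(1), 3L),
                      vapply(f, `[`, character(1), 4L))
  } else residue_alignment(integer(), character(), integer(), character())
  attr(aln, "target_id") <- hdr[2]
  attr(aln, "template_id") <- hdr[4]
  aln
}

#' Sum-of-pairs alignment score
#'
#' The SP-score of an alignment is the sum of BLOSUM62 substitution scores
#' over all aligned target-template residue pairs; an empty alignment
#' scores 0. Templates whose alignments score higher share more sequence
#' signal with the target and are ranked first.
#'
#' @param aln a [residue_alignment()].
#' @param m substitution matrix, default [blosum62()].
#' @return integer score.
#' @examples
#' aln <- residue_alignment(1:2, c("A", "R"), 1:2, c("A", "K"))
#' sp_score(aln) # 4 + 2
#' @export
sp_score <- function(aln, m = blosum62()) {
  stopifnot(inherits(aln, "residue_alignment"))
  if (nrow(aln) == 0L) return(0L)
  bad <- !(aln$target_aa %in% rownames(m)) | !(aln$template_aa %in% colnames(m))
  if (any(bad))
    stop("residue outside substitution alphabet at alignment row(s) ",
         paste(which(bad), collapse = ", "))
  sum(m[cbind(aln$target_aa, aln$template_aa)])
}

#' Fraction of identical residues in an alignment
#'
#' Identities are counted over aligned pairs only (gaps are not represented
#' in the pair list, so the denominator is the aligned-pair count).
#'
#' @param aln a nonempty [residue_alignment()].
#' @return fraction in \[0, 1\].
#' @export
sequence_identity <- function(aln) {
  stopifnot(inherits(aln, "residue_alignment"))
  if (nrow(aln) == 0L) stop("sequence identity of an empty alignment is undefined")
  mean(aln$target_aa == aln$template_aa)
}

#' Holo template record
#'
#' @param id template identifier.
#' @param alignment [residue_alignment()] of template to target.
#' @param ligand_ids character vector of bound-ligand molecule ids
#'   (nonempty for a holo template).
#' @param seq_identity optional precomputed identity fraction; recomputed
#'   from the alignment when missing.
#' @return list of class `holo_template` with fields `id`, `alignment`,
#'   `ligand_ids`, `seq_identity`, `sp_score` (NA until ranked).
#' @export
holo_template <- function(id, alignment, ligand_ids, seq_identity = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            inherits(alignment, "residue_alignment"))
  ligand_ids <- as.character(ligand_ids)
  if (length(ligand_ids) == 0L)
    stop("a holo template must carry at least one bound ligand")
  if (is.null(seq_identity)) seq_identity <- sequence_identity(alignment)
  structure(list(id = id, alignment = alignment, ligand_ids = ligand_ids,
                 seq_identity = seq_identity, sp_score = NA_integer_),
            class = "holo_template")
}

#' Benchmark-mode homology filter
#'
#' For blind benchmarking, templates too close to the target are removed:
#' a template is excluded when its sequence identity to the target is
#' strictly greater than the cutoff (default 30%). Identity exactly at the
#' cutoff is retained.
#'
#' @param templates list of [holo_template()] objects.
#' @param cutoff identity fraction above which a template is excluded.
#' @return list with `retained` and `excluded` template lists.
#' @export
filter_homologs <- function(templates, cutoff = 0.30) {
  sid <- vapply(templates, function(t) t$seq_identity, numeric(1))
  list(retained = templates[sid <= cutoff],
       excluded = templates[sid > cutoff])
}

#' Rank holo templates by SP-score
#'
#' Templates are sorted by descending SP-score; ties break
#' lexicographically by template id so output order is deterministic.
#'
#' @param templates list of [holo_template()] objects.
#' @param m substitution matrix, default [blosum62()].
#' @return the input templates, re-ordered, with `sp_score` filled in.
#' @export
rank_templates <- function(templates, m = blosum62()) {
  if (length(templates) == 0L) return(templates)
  scores <- vapply(templates, function(t) as.numeric(sp_score(t$alignment, m)),
                   numeric(1))
  ids <- vapply(templates, function(t) t$id, character(1))
  ord <- order(-scores, ids)
  out <- templates[ord]
  for (i in seq_along(out)) out[[i]]$sp_score <- scores[ord][i]
  out
}

#' Collect template ligands from the top-ranked templates
#'
#' Ligand ids of the first `n_top` templates (default 100) are pooled in
#' first-occurrence order, with duplicates removed; these become the
#' template-ligand set for ligand-based screening.
#'
#' @param ranked output of [rank_templates()].
#' @param n_top number of top templates to harvest from.
#' @return character vector of unique ligand ids.
#' @export
harvest_template_ligands <- function(ranked, n_top = 100L) {
  stopifnot(length(ranked) >= 1L)
  top <- ranked[seq_len(min(n_top, length(ranked)))]
  ids <- unique(unlist(lapply(top, function(t) t$ligand_ids)))
  if (length(ids) == 0L)
    stop("no ligands on any of the top templates; cannot screen")
  ids
}

#' Summarize a template set as a data frame
#'
#' @param templates list of [holo_template()] objects (ranked or not).
#' @param cutoff homology cutoff used for the `retained` column.
#' @return data frame with `template_id`, `sp_score`, `seq_identity`,
#'   `retained`.
#' @export
template_table <- function(templates, cutoff = 0.30) {
  data.frame(
    template_id = vapply(templates, function(t) t$id, character(1)),
    sp_score = vapply(templates, function(t) as.numeric(t$sp_score), numeric(1)),
    seq_identity = vapply(templates, function(t) t$seq_identity, numeric(1)),
    retained = vapply(templates, function(t) t$seq_identity <= cutoff, logical(1)),
    stringsAsFactors = FALSE)
}
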