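#' Read a compound library from a SMILES or SDF file
#'
#' SMILES files carry one record per line, `SMILES<TAB>id` (a second
#' whitespace-separated token is accepted as the id); SDF files take the id
#' from the title block. Every record is validated by parsing the structure
#' with Open Babel; unparsable records are counted and reported, never
#' silently dropped.
#'
#' @param path path to a `.smi`/`.txt` SMILES file or a `.sdf` file.
#' @param source free-text provenance tag stored with every molecule
#'   (e.g. `"library"`, `"template-ligand"`, `"aggregator"`).
#' @return A data frame of class `molecule_set` with columns `id`, `smiles`,
#'   `source`, plus attributes `n_rejected` (count of invalid records) and
#'   `rejected` (their ids/lines).
#' @export
parse_library <- function(path, source = "library") {
  if (!file.exists(path)) stop("cannot read library file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "sdf") {
    sdf <- ChemmineR::read.SDFset(path)
    valid <- ChemmineR::validSDF(sdf)
    n_rej <- sum(!valid)
    rejected <- ChemmineR::sdfid(sdf)[!valid]
    sdf <- sdf[valid]
    if (length(sdf) == 0L) stop("no valid molecules in ", path)
    mols <- data.frame(id = ChemmineR::sdfid(sdf),
                       smiles = as.character(ChemmineR::sdf2smiles(sdf)),
                       source = source, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("no records in ", path)
    toks <- strsplit(trimws(lines), "[ \t]+")
    smiles <- vapply(toks, `[`, character(1), 1L)
    ids <- vapply(seq_along(toks), function(i) {
      if (length(toks[[i]]) >= 2L) toks[[i]][2L] else sprintf("mol%04d", i)
    }, character(1))
    ok <- vapply(smiles, smiles_is_valid, logical(1))
    n_rej <- sum(!ok)
    rejected <- lines[!ok]
    if (!any(ok)) stop("no valid molecules in ", path)
    mols <- data.frame(id = ids[ok], smiles = smiles[ok],
                       source = source, stringsAsFactors = FALSE)
  }
  if (anyDuplicated(mols$id))
    stop("duplicate molecule ids in ", path, ": ",
         paste(unique(mols$id[duplicated(mols$id)]), collapse = ", "))
  if (n_rej > 0L)
    message(n_rej, " invalid record(s) rejected while reading ", path)
  structure(mols, n_rejected = n_rej, rejected = rejected,
            class = c("molecule_set", "data.frame"))
}

# Open Babel round-trip parse; invalid SMILES surface as errors or empty output
smiles_is_valid <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "x"))),
    error = function(e) NULL)
  !is.null(out) && length(out) == 1L
}

#' Fingerprint configuration
#'
#' @param type Open Babel fingerprint name. The default `"FP2"` is a hashed
#'   linear-fragment (path-based) fingerprint indexing paths of up to 7
#'   bonds into 1021 of 1024 bits — deterministic and library-agnostic.
#' @param nbits fingerprint length in bits.
#' @return list of class `fp_params`.
#' @export
fp_params <- function(type = "FP2", nbits = 1024L) {
  structure(list(type = type, nbits = as.integer(nbits)), class = "fp_params")
}

#' Compute structure fingerprints for a molecule set
#'
#' @param mols a `molecule_set` from [parse_library()], or a named character
#'   vector of SMILES.
#' @param params a [fp_params()] configuration.
#' @return Named list of [fingerprint()] objects, one per molecule, in input
#'   order.
#' @export
fingerprint_molecules <- function(mols, params = fp_params()) {
  if (is.character(mols)) {
    smiles <- mols
    if (is.null(names(smiles))) names(smiles) <- sprintf("mol%04d", seq_along(smiles))
  } else {
    smiles <- stats::setNames(mols$smiles, mols$id)
  }
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  fpset <- ChemmineR::fingerprintOB(sdf, params$type)
  m <- methods::slot(fpset, "fpma")
  if (ncol(m) != params$nbits)
    stop("fingerprint backend returned ", ncol(m), " bits; expected ", params$nbits)
  fps <- lapply(seq_len(nrow(m)), function(i)
    fingerprint(which(m[i, ] != 0), nbits = params$nbits))
  stats::setNames(fps, names(smiles))
}

#' Single-linkage clustering at a Tanimoto cutoff
#'
#' Molecules are joined whenever their fingerprint TC reaches the cutoff;
#' clusters are the connected components of that similarity graph
#' (single linkage). The conventional cutoff for grouping screening hits
#' into chemical classes is TC 0.7.
#'
#' @param fps named list of [fingerprint()] objects.
#' @param cutoff TC threshold in (0, Inf); edges require `TC >= cutoff`.
#' @return list of class `cluster_assignment`: `labels` (named integer
#'   vector, cluster indices `1..n_clusters` in order of first appearance),
#'   `cutoff`, and `n_clusters`.
#' @export
cluster_by_tc <- function(fps, cutoff = 0.7) {
  stopifnot(length(fps) >= 1L)
  if (is.null(names(fps)) || anyDuplicated(names(fps)))
    stop("'fps' must carry unique names")
  tc <- tanimoto_matrix(fps)
  adj <- (tc >= cutoff)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  labels <- stats::setNames(match(comp, unique(comp)), names(fps))
  structure(list(labels = labels, cutoff = cutoff,
                 n_clusters = length(unique(labels))),
            class = "cluster_assignment")
}

#' Flag compounds similar to known colloidal aggregators
#'
#' Colloidal aggregators cause artifactual signals in biophysical assays;
#' compounds chemically similar to a known aggregator are flagged at a
#' stringent TC cutoff (default 0.9, inclusive).
#'
#' @param fp a [fingerprint()] of the query compound.
#' @param aggregators named list of aggregator [fingerprint()]s (possibly
#'   empty).
#' @param cutoff TC threshold in (0, 1\]; the flag is raised when the best
#'   aggregator TC is `>= cutoff`.
#' @return list with `flag` (logical), `best_tc` (NA when no aggregators),
#'   and `best_id`.
#' @export
is_aggregator_like <- function(fp, aggregators, cutoff = 0.9) {
  stopifnot(cutoff > 0, cutoff <= 1)
  if (length(aggregators) == 0L)
    return(list(flag = FALSE, best_tc = NA_real_, best_id = NA_character_))
  tcs <- vapply(aggregators, tanimoto, numeric(1), b = fp)
  best <- which.max(tcs)
  list(flag = unname(tcs[best]) >= cutoff,
       best_tc = unname(tcs[best]),
       best_id = if (!is.null(names(aggregators))) names(aggregators)[best]
                 else as.character(best))
}

#' Write a cluster assignment as TSV
#'
#' @param x a `cluster_assignment` from [cluster_by_tc()].
#' @param path output file; columns `id`, `cluster`.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(x, path) {
  stopifnot(inherits(x, "cluster_assignment"))
  df <- data.frame(id = names(x$labels), cluster = unname(x$labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
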