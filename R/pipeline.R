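#' Run a screening / evaluation / DSF pipeline step
#'
#' File-level front end composing the module functions; the same verbs are
#' exposed by the `inst/cli/holoscreen.R` command-line script. Every output
#' directory receives an echo of the configuration (`config.yaml`) and all
#' tables carry the configuration hash in a `#` header line.
#'
#' @param config a [run_config()].
#' @param subcommand one of `"screen"`, `"evaluate"`, `"dsf"`,
#'   `"simulate"`, `"cluster"`.
#' @param args named list of subcommand arguments:
#'   * `screen`: `library` (SMILES path), `evidence` (named character
#'     vector of template-ligand SMILES paths), `out_dir`.
#'   * `evaluate`: `ranked` (TSV from screen), `truth` (one binder id per
#'     line), `out_dir`, optional `x_values`.
#'   * `dsf`: `plate` (CSV), `out_dir`.
#'   * `simulate`: `what` ("library" or "plate"), `out_dir`, plus
#'     generator arguments.
#'   * `cluster`: `library` (SMILES path), `out_dir`.
#' @return list of output file paths, invisibly.
#' @export
run_pipeline <- function(config, subcommand, args = list()) {
  stopifnot(inherits(config, "run_config"))
  subcommand <- match.arg(subcommand,
                          c("screen", "evaluate", "dsf", "simulate", "cluster"))
  out_dir <- args$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(out_dir, "config.yaml"))
  hash <- config_hash(config)
  params <- fp_params(config$fp_type, config$fp_nbits)

  out <- switch(subcommand,
    screen = {
      lib <- fingerprint_molecules(parse_library(args$library, "library"), params)
      evs <- lapply(names(args$evidence), function(nm) {
        mols <- parse_library(args$evidence[[nm]], "template-ligand")
        evidence_library(nm, fingerprint_molecules(mols, params))
      })
      res <- rank_library(lib, evs, w = config$w)
      ranked_path <- file.path(out_dir, "ranked.tsv")
      top_path <- file.path(out_dir, "top.tsv")
      write_screen_result(res, ranked_path, hash)
      write_screen_result(select_top_fraction(res, config$top_fraction),
                          top_path, hash)
      list(ranked = ranked_path, top = top_path)
    },
    evaluate = {
      ranked <- utils::read.delim(args$ranked, comment.char = "#",
                                  stringsAsFactors = FALSE)
      known <- readLines(args$truth, warn = FALSE)
      known <- known[nzchar(trimws(known))]
      rep <- enrichment_report(ranked$id, known,
                               x_values = args$x_values %||% c(0.01, 0.05, 0.1))
      path <- file.path(out_dir, "enrichment.tsv")
      con <- file(path, "w")
      writeLines(paste0("# config_hash: ", hash), con)
      utils::write.table(rep, con, sep = "\t", quote = FALSE, row.names = FALSE)
      close(con)
      list(enrichment = path)
    },
    dsf = {
      analysis <- analyze_plate(read_plate(args$plate),
                                ligand_conc = config$ligand_conc,
                                q_floor = config$q_floor,
                                min_delta_tm = config$min_delta_tm)
      write_plate_analysis(analysis, out_dir, hash)
      list(wells = file.path(out_dir, "wells.tsv"),
           ligands = file.path(out_dir, "ligands.tsv"))
    },
    simulate = {
      what <- match.arg(args$what, c("library", "plate"))
      if (what == "plate") {
        sim <- simulate_plate(seed = config$seed)
        write_plate_csv(sim, out_dir)
        list(plate = file.path(out_dir, "plate.csv"),
             truth = file.path(out_dir, "truth.tsv"))
      } else {
        sim <- simulate_library(seed = config$seed, nbits = config$fp_nbits)
        truth_path <- file.path(out_dir, "truth.tsv")
        utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        rds <- file.path(out_dir, "fingerprints.tsv")
        fp_df <- data.frame(
          id = c(names(sim$library), names(sim$template_ligands)),
          role = rep(c("library", "template"),
                     c(length(sim$library), length(sim$template_ligands))),
          bits = vapply(c(sim$library, sim$template_ligands),
                        function(f) paste(f$bits, collapse = ","), character(1)))
        utils::write.table(fp_df, rds, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        list(truth = truth_path, fingerprints = rds)
      }
    },
    cluster = {
      fps <- fingerprint_molecules(parse_library(args$library, "library"), params)
      cl <- cluster_by_tc(fps, cutoff = config$cluster_tc)
      path <- file.path(out_dir, "clusters.tsv")
      write_clusters(cl, path)
      list(clusters = path)
    })
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
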