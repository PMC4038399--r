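#' Run configuration
#'
#' Central container for every tunable threshold, with defaults matching
#' the published screening protocol: mTC weight `w = 0.1`, top fraction
#' `x = 0.01`, benchmark sequence-identity cutoff 0.30, chemical-class
#' clustering at TC 0.7, aggregator similarity at TC 0.9.
#'
#' @param w mTC average-term weight.
#' @param top_fraction fraction of the ranked library short-listed.
#' @param sid_cutoff benchmark-mode homology cutoff (sequence identity).
#' @param n_top_templates templates harvested for ligands.
#' @param cluster_tc TC cutoff for chemical-class clustering.
#' @param aggregator_tc TC cutoff for aggregator flagging.
#' @param fp_type,fp_nbits fingerprint configuration.
#' @param q_floor minimum Q for an interpretable melt curve.
#' @param min_delta_tm floor on the positive-shift threshold, degrees C.
#' @param ligand_conc assay ligand concentration, molar.
#' @param seed integer seed for stochastic steps.
#' @return list of class `run_config`.
#' @export
run_config <- function(w = 0.1, top_fraction = 0.01, sid_cutoff = 0.30,
                       n_top_templates = 100L, cluster_tc = 0.7,
                       aggregator_tc = 0.9, fp_type = "FP2",
                       fp_nbits = 1024L, q_floor = 0.1, min_delta_tm = 0.5,
                       ligand_conc = 1e-4, seed = 1L) {
  cfg <- list(w = w, top_fraction = top_fraction, sid_cutoff = sid_cutoff,
              n_top_templates = as.integer(n_top_templates),
              cluster_tc = cluster_tc, aggregator_tc = aggregator_tc,
              fp_type = fp_type, fp_nbits = as.integer(fp_nbits),
              q_floor = q_floor, min_delta_tm = min_delta_tm,
              ligand_conc = ligand_conc, seed = as.integer(seed))
  stopifnot(cfg$w >= 0, cfg$w <= 1,
            cfg$top_fraction > 0, cfg$top_fraction <= 1,
            cfg$sid_cutoff >= 0, cfg$sid_cutoff <= 1,
            cfg$cluster_tc > 0, cfg$aggregator_tc > 0, cfg$aggregator_tc <= 1,
            cfg$q_floor >= 0, cfg$q_floor <= 1,
            cfg$ligand_conc > 0, cfg$n_top_templates >= 1L)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @return For `read_config`, a [run_config()]; for `write_config`, `path`
#'   invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' @rdname read_config
#' @param config a [run_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Short traceability hash of a configuration
#'
#' @param config a [run_config()].
#' @return 8-character hex digest, written into output-file headers so any
#'   result can be traced to the exact configuration that produced it.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  substr(unname(tools::md5sum(tmp)), 1, 8)
}
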