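#' Read a long-format melt plate CSV
#'
#' Expected columns: `well`, `condition`, `ligand_id`, `replicate`,
#' `temperature_C`, `intensity`. Each well holds one trace.
#'
#' @param path CSV file.
#' @return list of `melt_curve` objects, one per well.
#' @export
read_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "condition", "ligand_id", "replicate",
            "temperature_C", "intensity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("plate CSV lacks column(s): ", paste(missing, collapse = ", "))
  plate_curves(df)
}

#' Split a long-format plate data frame into melt curves
#'
#' @param df data frame with the columns of [read_plate()].
#' @return list of `melt_curve` objects, one per well.
#' @export
plate_curves <- function(df) {
  lapply(split(df, df$well), function(d) {
    d <- d[order(d$temperature_C), ]
    lig <- d$ligand_id[1L]
    melt_curve(d$temperature_C, d$intensity, well = d$well[1L],
               condition = d$condition[1L],
               ligand_id = if (is.na(lig) || !nzchar(lig)) NA_character_ else lig,
               replicate = d$replicate[1L])
  })
}

curve_key <- function(cv) {
  paste(cv$condition, if (is.na(cv$ligand_id)) "" else cv$ligand_id, sep = "|")
}

# mean control trace for a condition/ligand, or NULL when absent
control_curve <- function(curves, condition, ligand_id = NA_character_) {
  sel <- Filter(function(cv) {
    cv$condition == condition &&
      (is.na(ligand_id) == is.na(cv$ligand_id)) &&
      (is.na(ligand_id) || cv$ligand_id == ligand_id)
  }, curves)
  if (length(sel) == 0L) return(NULL)
  suppressWarnings(average_replicates(sel))
}

#' Analyze a thermal-shift plate end to end
#'
#' For every protein and protein-ligand well group: subtract the matched
#' dye control (`drug+dye` for the same ligand when present, else
#' `dye-only`), average replicates, fit the Boltzmann model, score curve
#' quality (Q) and count transitions. The ligand-free protein fit provides
#' the reference midpoint T0 and, via per-replicate fits, the replicate
#' spread of Tm. A ligand is a positive hit when its curve converged to a
#' single transition with Q at or above `q_floor` and a stabilizing shift
#' `delta_tm` exceeding `3 * sd(reference Tm)` (never less than
#' `min_delta_tm`). For hits, the van't Hoff enthalpy of the reference
#' protein converts the shift into an approximate dissociation constant.
#'
#' @param curves list of `melt_curve`s (from [read_plate()] /
#'   [plate_curves()]).
#' @param ligand_conc total ligand concentration, molar.
#' @param q_floor minimum Q for an interpretable positive.
#' @param min_delta_tm floor on the hit threshold, degrees C.
#' @param ... passed to [classify_curve()].
#' @return list of class `plate_analysis`: `wells` (per-group fit table),
#'   `ligands` (per-ligand shift/affinity table), `reference` (t0,
#'   replicate sd, threshold applied).
#' @export
analyze_plate <- function(curves, ligand_conc = 1e-4, q_floor = 0.1,
                          min_delta_tm = 0.5, ...) {
  stopifnot(length(curves) >= 1L)
  dye <- control_curve(curves, "dye-only")
  samples <- Filter(function(cv) cv$condition %in% c("protein", "protein+ligand"),
                    curves)
  if (length(samples) == 0L) stop("plate holds no protein wells")
  corrected <- lapply(samples, function(cv) {
    ctrl <- if (cv$condition == "protein+ligand" && !is.na(cv$ligand_id))
      control_curve(curves, "drug+dye", cv$ligand_id) else NULL
    if (is.null(ctrl)) ctrl <- dye
    if (is.null(ctrl)) cv else subtract_control(cv, ctrl)
  })

  groups <- split(corrected, vapply(corrected, curve_key, character(1)))
  ref_key <- "protein|"
  if (!ref_key %in% names(groups))
    stop("plate lacks a ligand-free protein reference")

  # reference: replicate-wise fits give the Tm spread; the mean curve gives T0
  ref_fits <- lapply(groups[[ref_key]], fit_boltzmann)
  ref_tms <- vapply(Filter(function(f) f$converged, ref_fits),
                    function(f) f$t_m, numeric(1))
  if (length(ref_tms) == 0L)
    stop("no protein reference replicate produced a converged fit")
  ref_sd <- if (length(ref_tms) > 1L) stats::sd(ref_tms) else 0
  threshold <- max(3 * ref_sd, min_delta_tm)
  ref_mean <- suppressWarnings(average_replicates(groups[[ref_key]]))
  ref_fit <- fit_boltzmann(ref_mean)
  if (!ref_fit$converged) stop("reference protein curve did not converge")
  ref_dh <- vant_hoff_enthalpy(ref_fit)

  rows <- lapply(names(groups), function(key) {
    grp <- groups[[key]]
    avg <- suppressWarnings(average_replicates(grp))
    fit <- fit_boltzmann(avg)
    cq <- classify_curve(avg, ...)
    data.frame(condition = avg$condition,
               ligand_id = avg$ligand_id,
               n_replicates = length(grp),
               t_m = fit$t_m, a = fit$a, i_min = fit$i_min, i_max = fit$i_max,
               rmse = fit$rmse, converged = fit$converged,
               q = q_score(avg, fit),
               verdict = cq$verdict, n_transitions = cq$n_transitions,
               stringsAsFactors = FALSE)
  })
  wells <- do.call(rbind, rows)
  rownames(wells) <- NULL

  lig_rows <- wells[wells$condition == "protein+ligand", , drop = FALSE]
  ligands <- do.call(rbind, lapply(seq_len(nrow(lig_rows)), function(i) {
    r <- lig_rows[i, ]
    interpretable <- r$converged && r$verdict == "single" && r$q >= q_floor
    dtm <- if (r$converged) r$t_m - ref_fit$t_m else NA_real_
    hit <- isTRUE(interpretable && dtm > threshold)
    kd <- if (hit) {
      kd_estimate(ref_dh, r$t_m + .T_KELVIN, ref_fit$t_m + .T_KELVIN,
                  ligand_conc)
    } else list(k_l = NA_real_, k_d = NA_real_)
    data.frame(ligand_id = r$ligand_id, delta_tm = dtm, q = r$q,
               verdict = r$verdict, interpretable = interpretable,
               hit = hit, delta_h = ref_dh, k_l = kd$k_l, k_d = kd$k_d,
               stringsAsFactors = FALSE)
  }))
  if (is.null(ligands))
    ligands <- data.frame(ligand_id = character(), delta_tm = numeric(),
                          q = numeric(), verdict = character(),
                          interpretable = logical(), hit = logical(),
                          delta_h = numeric(), k_l = numeric(),
                          k_d = numeric(), stringsAsFactors = FALSE)
  rownames(ligands) <- NULL
  structure(list(wells = wells, ligands = ligands,
                 reference = list(t0 = ref_fit$t_m, t0_sd = ref_sd,
                                  delta_tm_threshold = threshold,
                                  delta_h = ref_dh, fit = ref_fit)),
            class = "plate_analysis")
}

#' Screen-level hit bookkeeping across targets
#'
#' Builds the per-target tally of a thermal-shift validation campaign:
#' ligands tested, interpretable (good) curves, positive shifts, the
#' percent positive (1 decimal, relative to interpretable curves), and the
#' overall positive total.
#'
#' @param per_target data frame with columns `target`, `n_tested`,
#'   `n_interpretable`, `n_positive`, and optionally `best_ligand`,
#'   `best_delta_tm`, `best_kd`.
#' @return list of class `hit_summary`: `per_target` (with `pct_positive`
#'   added) and `total_positives`.
#' @export
summarize_hits <- function(per_target) {
  need <- c("target", "n_tested", "n_interpretable", "n_positive")
  missing <- setdiff(need, names(per_target))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  bad <- per_target$n_positive > per_target$n_interpretable |
    per_target$n_interpretable > per_target$n_tested |
    per_target$n_positive < 0
  if (any(bad))
    stop("inconsistent counts for target(s): ",
         paste(per_target$target[bad], collapse = ", "))
  out <- per_target
  out$pct_positive <- round(100 * out$n_positive / out$n_interpretable, 1)
  structure(list(per_target = out,
                 total_positives = sum(out$n_positive)),
            class = "hit_summary")
}

#' @export
print.hit_summary <- function(x, ...) {
  df <- x$per_target
  cat(sprintf("Thermal-shift hit summary (%d targets, %d positives)\n",
              nrow(df), x$total_positives))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Write plate analysis tables as TSV
#'
#' @param analysis a `plate_analysis`.
#' @param dir output directory (created if absent); writes `wells.tsv` and
#'   `ligands.tsv`.
#' @param config_hash optional traceability hash written as a `#` header.
#' @return `dir`, invisibly.
#' @export
write_plate_analysis <- function(analysis, dir, config_hash = NULL) {
  stopifnot(inherits(analysis, "plate_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("wells", "ligands")) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    con <- file(path, "w")
    if (!is.null(config_hash))
      writeLines(paste0("# config_hash: ", config_hash), con)
    utils::write.table(analysis[[nm]], con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  invisible(dir)
}
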