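#' Simulate a screening library with planted actives
#'
#' Emulates a benchmarking screen: template ligands are random binary
#' fingerprints at a drug-like bit density; actives are noisy copies of
#' randomly chosen template ligands (each bit flipped independently with
#' probability `bit_flip_prob`); decoys are fresh random fingerprints drawn
#' at the same expected bit density, so any similarity separation comes
#' only from the planted structure, not from density artifacts. Actives are
#' shuffled into random positions among the decoys and a truth table is
#' always returned.
#'
#' @param n_compounds library size.
#' @param n_actives number of planted actives (<= `n_compounds`).
#' @param n_template_ligands number of template-ligand fingerprints.
#' @param bit_flip_prob per-bit corruption probability of an active, in
#'   \[0, 1\].
#' @param nbits fingerprint length.
#' @param density expected fraction of set bits.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `library` (named fingerprints), `template_ligands`
#'   (named fingerprints), `truth` (data frame: `id`, `is_active`,
#'   `template_id`).
#' @export
simulate_library <- function(n_compounds = 1000L, n_actives = 10L,
                             n_template_ligands = 20L, bit_flip_prob = 0.02,
                             nbits = 1024L, density = 0.05, seed = 1L) {
  stopifnot(n_actives <= n_compounds, bit_flip_prob >= 0, bit_flip_prob <= 1,
            n_template_ligands >= 1L)
  set.seed(seed)
  rand_fp <- function() fingerprint(which(stats::runif(nbits) < density), nbits)
  templates <- stats::setNames(replicate(n_template_ligands, rand_fp(),
                                         simplify = FALSE),
                               sprintf("TL%03d", seq_len(n_template_ligands)))
  ids <- sprintf("cmpd%05d", seq_len(n_compounds))
  active_pos <- if (n_actives > 0L) sort(sample.int(n_compounds, n_actives))
                else integer(0)
  src <- rep(NA_character_, n_compounds)
  fps <- vector("list", n_compounds)
  for (i in seq_len(n_compounds)) {
    if (i %in% active_pos) {
      tpl <- sample.int(n_template_ligands, 1L)
      src[i] <- names(templates)[tpl]
      on_bits <- logical(nbits)
      on_bits[templates[[tpl]]$bits] <- TRUE
      flip <- stats::runif(nbits) < bit_flip_prob
      fps[[i]] <- fingerprint(which(xor(on_bits, flip)), nbits)
    } else {
      fps[[i]] <- rand_fp()
    }
  }
  list(library = stats::setNames(fps, ids),
       template_ligands = templates,
       truth = data.frame(id = ids, is_active = seq_len(n_compounds) %in% active_pos,
                          template_id = src, stringsAsFactors = FALSE))
}

#' Simulate holo templates with controlled sequence identity
#'
#' Builds target-template residue alignments whose sequence identity is
#' drawn uniformly from `identity_range`, then attaches ligand ids drawn
#' from a shared pool (so templates can share ligands, as real holo
#' structures do).
#'
#' @param n_templates number of templates.
#' @param identity_range length-2 numeric in \[0, 1\].
#' @param ligands_per_template ligands bound per template.
#' @param aln_length aligned-pair count per alignment.
#' @param ligand_pool_size size of the shared ligand-id pool.
#' @param seed integer seed.
#' @return list of [holo_template()] objects.
#' @export
simulate_templates <- function(n_templates = 50L, identity_range = c(0.10, 0.25),
                               ligands_per_template = 2L, aln_length = 120L,
                               ligand_pool_size = max(4L, n_templates),
                               seed = 1L) {
  stopifnot(length(identity_range) == 2L, identity_range[1] <= identity_range[2],
            identity_range[1] >= 0, identity_range[2] <= 1)
  set.seed(seed)
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  pool <- sprintf("LIG%03d", seq_len(ligand_pool_size))
  lapply(seq_len(n_templates), function(i) {
    target <- sample(aa, aln_length, replace = TRUE)
    sid <- stats::runif(1, identity_range[1], identity_range[2])
    n_ident <- round(sid * aln_length)
    ident_pos <- sample.int(aln_length, n_ident)
    templ <- vapply(seq_len(aln_length), function(j) {
      if (j %in% ident_pos) target[j]
      else sample(setdiff(aa, target[j]), 1L)
    }, character(1))
    holo_template(
      id = sprintf("tmpl%03d", i),
      alignment = residue_alignment(seq_len(aln_length), target,
                                    seq_len(aln_length), templ),
      ligand_ids = sample(pool, min(ligands_per_template, length(pool))))
  })
}

#' Simulate a single melt curve
#'
#' Evaluates the [boltzmann()] model (a sum of sigmoids when
#' `n_transitions >= 2`, a flat baseline when 0) on a temperature grid and
#' adds linear baseline drift and Gaussian noise.
#'
#' @param t_m midpoint(s), degrees C; recycled to `n_transitions`.
#' @param a slope parameter(s), degrees C.
#' @param i_min baseline intensity.
#' @param i_max plateau intensity; for multiple transitions the total
#'   amplitude `i_max - i_min` is split equally unless `t_m` has matching
#'   `amplitudes`.
#' @param n_transitions 0 (flat), 1, or more.
#' @param amplitudes optional per-transition amplitudes overriding the
#'   equal split.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param drift linear drift slope, intensity units per degree C.
#' @param grid temperature grid, degrees C.
#' @param seed optional seed (left untouched when NULL, so plate-level
#'   generators can manage the stream).
#' @param ... metadata passed to [melt_curve()] (`well`, `condition`,
#'   `ligand_id`, `replicate`).
#' @return a `melt_curve`.
#' @export
simulate_melt_curve <- function(t_m = 55, a = 1.5, i_min = 100, i_max = 1000,
                                n_transitions = 1L, amplitudes = NULL,
                                noise_sd = 0, drift = 0,
                                grid = seq(25, 74, by = 1), seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (n_transitions == 0L) {
    y <- rep(i_min, length(grid))
  } else {
    t_m <- rep_len(t_m, n_transitions)
    a <- rep_len(a, n_transitions)
    if (is.null(amplitudes))
      amplitudes <- rep((i_max - i_min) / n_transitions, n_transitions)
    y <- rep(i_min, length(grid))
    for (j in seq_len(n_transitions))
      y <- y + amplitudes[j] / (1 + exp((t_m[j] - grid) / a[j]))
  }
  y <- y + drift * (grid - grid[1L])
  if (noise_sd > 0) y <- y + stats::rnorm(length(grid), sd = noise_sd)
  melt_curve(grid, y, ...)
}

#' Simulate a thermal-shift plate
#'
#' Emulates a 96-well melt experiment: replicated ligand-free protein
#' references, dye-only controls, and for each ligand a protein+ligand pair
#' of wells plus a matched drug+dye control. Ligands fall into four truth
#' classes: `binder` (a positive midpoint shift drawn from
#' `delta_tm_range`), `nonbinder` (no shift), `flat` (fluorescence quenched,
#' no transition), and `multi` (two-step unfolding). Baseline drift is
#' applied plate-wide so control subtraction cancels it; Gaussian noise is
#' per-well. With the defaults (10 binders, 8 nonbinders, 3 flat, 2 multi,
#' 2 replicates) the plate holds exactly 96 wells.
#'
#' @param n_binders,n_nonbinders,n_flat,n_multi ligand counts per class.
#' @param replicates replicates per condition (>= 2 per protocol).
#' @param delta_tm_range range of true midpoint shifts for binders,
#'   degrees C.
#' @param tm_protein,a,i_min,i_max reference protein melt parameters.
#' @param noise_sd Gaussian noise sd; default 2% of the melt amplitude.
#' @param drift plate-wide linear drift, intensity units per degree C.
#' @param dye_level,drug_dye_level flat control intensities.
#' @param grid temperature grid.
#' @param seed integer seed; identical seeds give identical plates.
#' @return list with `plate` (long-format data frame: `well`, `condition`,
#'   `ligand_id`, `replicate`, `temperature_C`, `intensity`) and `truth`
#'   (per-ligand class and true shift).
#' @export
simulate_plate <- function(n_binders = 10L, n_nonbinders = 8L, n_flat = 3L,
                           n_multi = 2L, replicates = 2L,
                           delta_tm_range = c(3, 12),
                           tm_protein = 55, a = 1.5, i_min = 100, i_max = 1000,
                           noise_sd = 0.02 * (i_max - i_min), drift = 0.5,
                           dye_level = 50, drug_dye_level = 60,
                           grid = seq(25, 74, by = 1), seed = 1L) {
  stopifnot(replicates >= 1L)
  set.seed(seed)
  n_lig <- n_binders + n_nonbinders + n_flat + n_multi
  classes <- rep(c("binder", "nonbinder", "flat", "multi"),
                 c(n_binders, n_nonbinders, n_flat, n_multi))
  lig_ids <- sprintf("L%02d", seq_len(n_lig))
  shifts <- ifelse(classes == "binder",
                   stats::runif(n_lig, delta_tm_range[1], delta_tm_range[2]),
                   ifelse(classes == "nonbinder", 0, NA_real_))
  truth <- data.frame(ligand_id = lig_ids, class = classes,
                      true_delta_tm = shifts, true_tm = tm_protein + shifts,
                      stringsAsFactors = FALSE)

  well_no <- 0L
  next_well <- function() {
    well_no <<- well_no + 1L
    sprintf("%s%02d", LETTERS[(well_no - 1L) %/% 12L + 1L],
            (well_no - 1L) %% 12L + 1L)
  }
  rows <- list()
  add <- function(curve) {
    rows[[length(rows) + 1L]] <<- data.frame(
      well = curve$well, condition = curve$condition,
      ligand_id = curve$ligand_id, replicate = curve$replicate,
      temperature_C = curve$temperature, intensity = curve$intensity,
      stringsAsFactors = FALSE)
  }
  flat_ctrl <- function(level, condition, ligand_id, rep_i) {
    simulate_melt_curve(i_min = level, n_transitions = 0L,
                        noise_sd = noise_sd / 4, drift = drift, grid = grid,
                        well = next_well(), condition = condition,
                        ligand_id = ligand_id, replicate = rep_i)
  }

  for (r in seq_len(replicates)) {
    add(simulate_melt_curve(t_m = tm_protein, a = a, i_min = i_min,
                            i_max = i_max, noise_sd = noise_sd, drift = drift,
                            grid = grid, well = next_well(),
                            condition = "protein", replicate = r))
    add(flat_ctrl(dye_level, "dye-only", NA_character_, r))
  }
  for (i in seq_len(n_lig)) {
    for (r in seq_len(replicates)) {
      cv <- switch(classes[i],
        binder = ,
        nonbinder = simulate_melt_curve(
          t_m = tm_protein + shifts[i], a = a, i_min = i_min, i_max = i_max,
          noise_sd = noise_sd, drift = drift, grid = grid,
          well = next_well(), condition = "protein+ligand",
          ligand_id = lig_ids[i], replicate = r),
        flat = simulate_melt_curve(
          i_min = i_min, n_transitions = 0L, noise_sd = noise_sd,
          drift = drift, grid = grid, well = next_well(),
          condition = "protein+ligand", ligand_id = lig_ids[i], replicate = r),
        multi = simulate_melt_curve(
          t_m = c(45, 62), a = a, i_min = i_min, i_max = i_max,
          n_transitions = 2L, noise_sd = noise_sd, drift = drift, grid = grid,
          well = next_well(), condition = "protein+ligand",
          ligand_id = lig_ids[i], replicate = r))
      add(cv)
      add(flat_ctrl(drug_dye_level, "drug+dye", lig_ids[i], r))
    }
  }
  list(plate = do.call(rbind, rows), truth = truth)
}

#' Write a simulated plate and its truth sidecar
#'
#' @param sim output of [simulate_plate()].
#' @param dir output directory; writes `plate.csv` and `truth.tsv`.
#' @return `dir`, invisibly.
#' @export
write_plate_csv <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$plate, file.path(dir, "plate.csv"), row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
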