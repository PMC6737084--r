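#' Run a multi-stage analysis pipeline from a configuration
#'
#' The configuration (a list, or path to a YAML file) has top-level `seed`,
#' `out_dir` and a list of `stages`. Each stage is a named block:
#'
#' * `correlation`: `topology` (PDB), `trajectory` (XYZ), `segments` (TSV),
#'   optional `threshold` (default 0.6), `fit_selection` (default `"CA"`),
#'   `focus_segment`; or a `synthetic` block forwarded to
#'   [generate_correlated_trajectory()]. Emits the cross-correlation matrix,
#'   the segment-score table, an optional per-residue profile and a log of the
#'   discarded-pair fraction.
#' * `cluster`: `topology`, `trajectory`, `cutoff`; emits frame assignments.
#' * `hbonds`: `topology`, `trajectory`, optional `dist`, `angle`, `floor`;
#'   donors/acceptors default to N and O heavy atoms. Emits the occupancy
#'   table.
#' * `screen`: `compounds` and/or `scores` TSVs, optional `protocol`
#'   (`"structure"`, `"ligand"` or both) and `cutoff`; emits filter and
#'   selection tables plus a JSON summary.
#' * `mtd`: `mtd_config` (YAML, see [write_mtd_config()]), `potential` (kind +
#'   parameters), optional `bound`/`unbound` regions; emits the HILLS file,
#'   the FES grid and a barrier summary.
#'
#' A copy of the configuration is written into `out_dir` (`run_config.yaml`)
#' and every TSV output starts with a `# config_md5 ...` comment, so a rerun
#' from the copied config is byte-identical for deterministic stages. A stage
#' failure leaves a `FAILED` marker next to the partial outputs and aborts.
#'
#' @param config list or YAML path.
#' @return invisibly, a report bundle: list with `outputs` (paths per stage),
#'   `config_hash`, `summary` (tibble of stage timings).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$out_dir), !is.null(config$stages))
  if (is.null(config$seed)) config$seed <- 1L
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "run_config.yaml")
  yaml::write_yaml(config, cfg_path, precision = 15)
  # the hash identifies the analysis (stages + seed), not the output location
  hash_path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config[setdiff(names(config), "out_dir")], hash_path,
                   precision = 15)
  hash <- unname(tools::md5sum(hash_path))
  unlink(hash_path)
  outputs <- list()
  timings <- list()
  for (i in seq_along(config$stages)) {
    stage <- config$stages[[i]]
    t0 <- proc.time()["elapsed"]
    res <- tryCatch(
      run_stage(stage, config, hash),
      error = function(e) {
        writeLines(paste0("stage ", i, " (", stage$stage, "): ",
                          conditionMessage(e)),
                   file.path(config$out_dir, "FAILED"))
        stop("pipeline stage ", i, " (", stage$stage, ") failed: ",
             conditionMessage(e), call. = FALSE)
      })
    outputs[[paste0(i, "_", stage$stage)]] <- res
    timings[[i]] <- tibble::tibble(
      stage = stage$stage,
      elapsed_s = round(unname(proc.time()["elapsed"] - t0), 3))
  }
  summary <- dplyr::bind_rows(timings)
  readr::write_tsv(summary, file.path(config$out_dir, "summary.tsv"),
                   progress = FALSE)
  invisible(list(outputs = outputs, config_hash = hash, summary = summary))
}

write_tsv_hashed <- function(tbl, path, hash) {
  writeLines(paste("# config_md5", hash), path)
  suppressWarnings(
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE,
                     progress = FALSE))
  path
}

stage_out <- function(config, name) file.path(config$out_dir, name)

load_stage_trajectory <- function(stage, config) {
  if (!is.null(stage$synthetic)) {
    sp <- stage$synthetic
    segs <- make_segment_map(sp$segments$name, sp$segments$start,
                             sp$segments$end,
                             sp$segments$chain %||% "A")
    gen <- generate_correlated_trajectory(
      segs, within_block_rho = sp$within_block_rho %||% 0,
      cross_block_rho = sp$cross_block_rho %||% list(),
      n_frames = sp$n_frames %||% 1000,
      noise_sd = sp$noise_sd %||% 0.5,
      seed = config$seed)
    list(traj = gen$trajectory, segments = segs)
  } else {
    for (f in c("topology", "trajectory")) {
      if (is.null(stage[[f]]) || !file.exists(stage[[f]])) {
        stop("missing input path for '", f, "'")
      }
    }
    top <- read_topology(stage$topology)
    fmt <- if (grepl("\\.pdb$", stage$trajectory)) "pdb_multimodel" else
      "xyz_multiframe"
    traj <- read_trajectory(stage$trajectory, top, format = fmt)
    segs <- if (!is.null(stage$segments)) read_segments(stage$segments)
    list(traj = traj, segments = segs)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_stage <- function(stage, config, hash) {
  switch(
    stage$stage,
    correlation = {
      inp <- load_stage_trajectory(stage, config)
      traj <- inp$traj
      thr <- stage$threshold %||% 0.6
      fit_name <- stage$fit_selection %||% "CA"
      sel <- resolve_selection(traj$topology, atom_name == fit_name)
      # synthetic trajectories are generated in a fixed frame; fitting them
      # would remove the collective motion under study
      do_fit <- stage$fit %||% is.null(stage$synthetic)
      fitted <- if (isTRUE(do_fit)) rms_fit_trajectory(traj, sel) else traj
      cc <- cross_correlation_matrix(covariance_matrix(fitted, sel))
      cs <- segment_correlation_score(cc, traj$topology, inp$segments,
                                      threshold = thr)
      n_off <- length(cc$atom_ids) * (length(cc$atom_ids) - 1) / 2
      off <- cc$values[upper.tri(cc$values)]
      log_tbl <- tibble::tibble(
        n_atom_pairs = n_off,
        discarded_fraction = mean(abs(off) < thr),
        threshold = thr)
      paths <- c(
        write_tsv_hashed(correlation_matrix_table(cc),
                         stage_out(config, "cc_matrix.tsv"), hash),
        write_tsv_hashed(tibble::as_tibble(cs),
                         stage_out(config, "segment_scores.tsv"), hash),
        write_tsv_hashed(log_tbl, stage_out(config, "corr_log.tsv"), hash))
      if (!is.null(stage$focus_segment)) {
        prof <- per_residue_profile(cc, traj$topology, stage$focus_segment,
                                    inp$segments, threshold = thr)
        paths <- c(paths, write_tsv_hashed(
          tibble::as_tibble(prof), stage_out(config, "profile.tsv"), hash))
      }
      paths
    },
    cluster = {
      inp <- load_stage_trajectory(stage, config)
      sel_name <- stage$selection %||% "CA"
      sel <- resolve_selection(inp$traj$topology, atom_name == sel_name)
      cl <- daura_cluster(inp$traj, sel, cutoff = stage$cutoff %||% 2)
      write_tsv_hashed(tidy(cl), stage_out(config, "clusters.tsv"), hash)
    },
    hbonds = {
      inp <- load_stage_trajectory(stage, config)
      top <- inp$traj$topology
      don <- resolve_selection(top, element %in% c("N", "O") & !is_hydrogen)
      tab <- hbond_occupancy(
        inp$traj, don, don,
        criteria = hbond_criteria(stage$dist %||% 3.5, stage$angle %||% 120),
        report_floor = stage$floor %||% 0)
      write_tsv_hashed(tibble::as_tibble(tab),
                       stage_out(config, "hbonds.tsv"), hash)
    },
    screen = {
      paths <- character(0)
      summary <- list()
      if (!is.null(stage$compounds)) {
        if (!file.exists(stage$compounds)) stop("missing input path for 'compounds'")
        fr <- property_filter(read_compound_table(stage$compounds))
        paths <- c(paths,
                   write_tsv_hashed(fr$passed,
                                    stage_out(config, "filter_passed.tsv"), hash),
                   write_tsv_hashed(fr$tally,
                                    stage_out(config, "filter_tally.tsv"), hash))
        summary$filter <- as.list(glance(fr))
      }
      if (!is.null(stage$scores)) {
        if (!file.exists(stage$scores)) stop("missing input path for 'scores'")
        sc <- read_score_matrix(stage$scores)
        protos <- stage$protocol %||% c("structure", "ligand")
        for (p in protos) {
          sel <- if (p == "structure") {
            consensus_select_structure_based(sc, stage$cutoff %||% -8.5)
          } else {
            consensus_select_ligand_based(sc, stage$cutoff %||% -7.5)
          }
          paths <- c(paths, write_tsv_hashed(
            tibble::as_tibble(sel),
            stage_out(config, paste0("selection_", p, ".tsv")), hash))
          summary[[paste0("selected_", p)]] <- nrow(sel)
        }
      }
      jsonlite::write_json(c(summary, list(config_md5 = hash)),
                           stage_out(config, "screen_summary.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      c(paths, stage_out(config, "screen_summary.json"))
    },
    mtd = {
      pot_args <- stage$potential
      pot <- do.call(make_toy_potential, pot_args)
      mcfg <- read_mtd_config(stage$mtd_config)
      mcfg$seed <- config$seed
      run <- run_langevin_mtd(pot, mcfg)
      fes <- reconstruct_fes(run$hills, mcfg$grid)
      paths <- c(write_hills(run$hills, stage_out(config, "HILLS")),
                 write_fes(fes, stage_out(config, "fes.tsv")))
      if (!is.null(stage$bound) && !is.null(stage$unbound)) {
        b <- estimate_barrier(fes, list(as.numeric(stage$bound)),
                              list(as.numeric(stage$unbound)))
        paths <- c(paths, write_tsv_hashed(
          tibble::tibble(barrier_kcal_mol = as.numeric(b),
                         barrier_kj_mol = attr(b, "kJ_mol")),
          stage_out(config, "barrier.tsv"), hash))
      }
      paths
    },
    stop("unknown stage type: ", stage$stage)
  )
}

correlation_matrix_table <- function(cc) {
  idx <- which(upper.tri(cc$values, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(atom_i = cc$atom_ids[idx[, 1]],
                 atom_j = cc$atom_ids[idx[, 2]],
                 value = cc$values[idx])
}
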