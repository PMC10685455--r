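#' Run configuration
#'
#' Assembles and validates the configuration for [run_workflow()].
#' Defaults follow the workflow's standard settings: Maclaurin order 20
#' at 300 K, 3.5 A / 90 degree hydrogen-bond criteria, K-means with six
#' centroids, 1 ns 2D-RMSD stride. Either a boost log (reweighting is
#' then computed) or a precomputed weights file must be supplied; with
#' neither, uniform weights are used and noted.
#'
#' @param topology path to the solute PDB.
#' @param trajectory path to the trajectory (XYZ/PDB/DCD).
#' @param torsions path to the torsion definition file.
#' @param boost_log optional path to the per-frame boost log.
#' @param weights optional path to a one-column weight file.
#' @param frame_interval ns per frame.
#' @param reweight named list overriding [weight_params()] arguments.
#' @param hbond named list overriding [hbond_criteria()] arguments.
#' @param pca named list: `n_components`, `kmeans_k`, `nbins`.
#' @param rmsd_stride 2D-RMSD sampling interval, ns (`NA` to skip).
#' @param seed integer seed for clustering.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(topology, trajectory, torsions, boost_log = NULL,
                       weights = NULL, frame_interval = 1,
                       reweight = list(), hbond = list(), pca = list(),
                       rmsd_stride = 1, seed = 1) {
  cfg <- list(
    topology = topology, trajectory = trajectory, torsions = torsions,
    boost_log = boost_log, weights = weights,
    frame_interval = frame_interval,
    reweight = utils::modifyList(list(temperature = 300, order = 20,
                                      mode = "maclaurin", component = "both"),
                                 reweight),
    hbond = utils::modifyList(list(d_max = 3.5, angle_min = 90,
                                   min_separation = 3), hbond),
    pca = utils::modifyList(list(n_components = 2, kmeans_k = 6, nbins = 40),
                            pca),
    rmsd_stride = rmsd_stride, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  for (p in c("topology", "trajectory", "torsions")) {
    if (is.null(cfg[[p]]) || !file.exists(cfg[[p]]))
      stopf("config: %s file missing or not found (%s)", p,
            if (is.null(cfg[[p]])) "NULL" else cfg[[p]])
  }
  for (p in c("boost_log", "weights")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stopf("config: %s file not found (%s)", p, cfg[[p]])
  }
  if (is.null(cfg$boost_log) && is.null(cfg$weights) &&
      identical(cfg$reweight$mode, "maclaurin") && cfg$reweight$order > 0)
    warnf("no boost log or weight file given: frames will be weighted uniformly")
  invisible(cfg)
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis workflow
#'
#' Executes the stages in dependency order — reweighting, dihedral PCA
#' with clustering and free-energy surface, hydrogen-bond contact map
#' with donor contributions, and split-half convergence — writing every
#' result as TSV/JSON into `out_dir` together with a machine-readable
#' `summary.json` carrying an MD5 hash of the configuration. Rerunning
#' with an identical configuration reproduces identical outputs. A stage
#' failure aborts with the stage name; outputs already written are kept
#' next to a `FAILED` marker naming the stage.
#'
#' @param config a [run_config()] (or the path of a YAML config).
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the summary list.
#' @export
run_workflow <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_json))
  summ <- list(config_hash = cfg_hash)
  stage <- "setup"
  run <- function(name, code) {
    stage <<- name
    withCallingHandlers(code, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  io <- run("input", {
    top <- read_topology(config$topology)
    traj <- read_trajectory(config$trajectory, top,
                            frame_interval = config$frame_interval)
    tors <- read_torsions(config$torsions, top)
    list(top = top, traj = traj, tors = tors)
  })
  nf <- n_frames(io$traj)

  w <- run("reweight", {
    if (!is.null(config$weights)) {
      check_weights(scan(config$weights, quiet = TRUE), nf)
    } else if (!is.null(config$boost_log)) {
      dv <- read_boost_log(config$boost_log)
      if (length(dv) != nf)
        stopf("boost log has %d rows for %d frames", length(dv), nf)
      compute_weights(dv, do.call(weight_params, config$reweight))
    } else uniform_weights(nf)
  })
  writeLines(sprintf("%.12e", w), file.path(out_dir, "weights.txt"))

  dp <- run("dpca", {
    angles <- compute_dihedrals(io$traj, io$tors)
    feats <- encode_circular(angles)
    model <- fit_pca(feats)
    pc <- project_pca(feats, model, n = config$pca$n_components)
    cl <- kmeans_cluster(pc, k = config$pca$kmeans_k, seed = config$seed)
    nb <- config$pca$nbins
    fes <- free_energy_surface(
      pc[, 1], pc[, 2], w,
      x_edges = seq(min(pc[, 1]), max(pc[, 1]), length.out = nb + 1),
      y_edges = seq(min(pc[, 2]), max(pc[, 2]), length.out = nb + 1),
      temperature = config$reweight$temperature)
    list(angles = angles, model = model, pc = pc, clusters = cl, fes = fes)
  })
  write_tsv(as.data.frame(dp$pc), file.path(out_dir, "pc_coords.tsv"))
  write_tsv(summary(dp$model), file.path(out_dir, "pca_model.tsv"))
  write_tsv(data.frame(frame = seq_len(nf), cluster = dp$clusters$labels),
            file.path(out_dir, "cluster_labels.tsv"))
  write_tsv(data.frame(cluster = seq_len(dp$clusters$k),
                       size = dp$clusters$sizes,
                       representative_frame = dp$clusters$representative_frames),
            file.path(out_dir, "representatives.tsv"))
  fes_df <- data.frame(which(dp$fes$occupied | TRUE, arr.ind = TRUE))
  names(fes_df) <- c("xbin", "ybin")
  fes_df$probability <- as.vector(dp$fes$probability)
  fes_df$free_energy <- as.vector(dp$fes$free_energy)
  write_tsv(fes_df, file.path(out_dir, "fes.tsv"))

  hb <- run("hbond", {
    crit <- do.call(hbond_criteria, config$hbond)
    map <- contact_occupancy(io$traj, w, crit)
    list(map = map, contrib = donor_contributions(map))
  })
  write_tsv(cbind(donor = rownames(hb$map$occupancy),
                  as.data.frame(hb$map$occupancy)),
            file.path(out_dir, "contact_map.tsv"))
  write_tsv(data.frame(donor = names(hb$contrib),
                       contribution_pct = as.numeric(hb$contrib)),
            file.path(out_dir, "donor_contributions.tsv"))

  conv <- run("convergence", {
    rep <- split_half_report(io$traj, w, angles = dp$angles,
                             criteria = hb$map$criteria, pca = dp$model,
                             nbins = config$pca$nbins)
    out <- list(contact_divergence = rep$contact_divergence,
                density_divergence = rep$density_divergence,
                n_first = rep$n_first, n_second = rep$n_second)
    if (!is.na(config$rmsd_stride) && nf * config$frame_interval >= 2 * config$rmsd_stride) {
      rm <- pairwise_rmsd(io$traj, stride = config$rmsd_stride)
      utils::write.table(rm$values, file.path(out_dir, "rmsd_matrix.tsv"),
                         sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      out$max_rmsd <- max(rm$values)
    }
    out
  })
  jsonlite::write_json(conv, file.path(out_dir, "convergence.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  summ <- c(summ, list(
    n_frames = nf,
    effective_sample_size = 1 / sum(w^2),
    pc_variance_explained = as.numeric(
      dp$model$eigenvalues[1:2] / sum(dp$model$eigenvalues)),
    cluster_sizes = as.integer(dp$clusters$sizes),
    representative_frames = as.integer(dp$clusters$representative_frames),
    total_imhb_occupancy = sum(hb$map$occupancy),
    donor_contributions = as.list(round(unclass(hb$contrib), 6)),
    convergence = conv))
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summ)
}
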