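# ---------------------------------------------------------------------------
# Replica management and end-to-end report generation
# ---------------------------------------------------------------------------

#' Replica set
#'
#' A group of production replicas of one simulation condition, sharing a
#' system, together with the equilibration span to discard before
#' analysis.
#'
#' @param replicas List of [sd_trajectory()] objects over the same system.
#' @param labels Optional replica labels (default "replica 1..n").
#' @param equilibration_discard Initial span to discard from each replica,
#'   in ps (default 1000, i.e. the first nanosecond).
#' @return Object of class `sd_replica_set`.
#' @export
replica_set <- function(replicas, labels = NULL,
                        equilibration_discard = 1000) {
  stopifnot(length(replicas) >= 1L)
  n0 <- n_atoms(replicas[[1]]$system)
  for (r in replicas) {
    if (n_atoms(r$system) != n0) stop("replicas differ in atom count")
  }
  if (is.null(labels)) labels <- paste("replica", seq_along(replicas))
  for (i in seq_along(replicas)) {
    dur <- max(replicas[[i]]$times)
    if (equilibration_discard >= dur) {
      stop(sprintf("equilibration discard (%g ps) >= duration of %s (%g ps)",
                   equilibration_discard, labels[i], dur))
    }
  }
  structure(list(replicas = replicas, labels = labels,
                 equilibration_discard = equilibration_discard),
            class = "sd_replica_set")
}

#' Join the equilibrated portions of a replica set
#'
#' Frames with `time > equilibration_discard` are concatenated in replica
#' order onto a continuous time grid that preserves the frame spacing. A
#' provenance table mapping each joined frame to its replica and original
#' time is attached as `traj$provenance`.
#'
#' @param rs An [replica_set()].
#' @return An [sd_trajectory()] with a `provenance` data frame.
#' @export
join_equilibrated <- function(rs) {
  stopifnot(inherits(rs, "sd_replica_set"))
  keep_list <- lapply(rs$replicas, function(r)
    which(r$times > rs$equilibration_discard))
  for (i in seq_along(keep_list)) {
    if (!length(keep_list[[i]])) {
      stop(sprintf("no frames survive the discard in %s", rs$labels[i]))
    }
  }
  xyz <- do.call(rbind, Map(function(r, keep) r$xyz[keep, , drop = FALSE],
                            rs$replicas, keep_list))
  prov <- do.call(rbind, Map(function(r, keep, lab)
    data.frame(replica = lab, orig_time = r$times[keep],
               stringsAsFactors = FALSE),
    rs$replicas, keep_list, rs$labels))
  r1 <- rs$replicas[[1]]
  dt <- if (n_frames(r1) > 1L) r1$times[2] - r1$times[1] else 1
  out <- sd_trajectory(r1$system, xyz, times = dt * seq_len(nrow(xyz)),
                       box = if (is.null(r1$box)) NULL else
                         do.call(rbind, Map(function(r, keep)
                           r$box[keep, , drop = FALSE],
                           rs$replicas, keep_list)))
  prov <- cbind(frame = seq_len(nrow(prov)), prov)
  out$provenance <- prov
  out
}

#' Run the full analysis report for one or more conditions
#'
#' For every condition (a joined trajectory or a replica set, labelled
#' e.g. "P300/S180" for protein at 300 K / solvent at 180 K) computes the
#' structural property table, intra-protein (and, when solvent is
#' present, protein-solvent) hydrogen-bond statistics, the essential
#' dynamics eigenvalue spectrum and the per-residue RMSF profile, and
#' writes them as CSV/TSV plus a JSON run manifest and a log. Outputs are
#' deterministic for a fixed seed and config.
#'
#' @param conditions Named list of [sd_trajectory()] or [replica_set()]
#'   objects.
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the manifest.
#' @param sasa_stride Frame stride for the SASA average (see
#'   [property_table()]).
#' @return Invisibly, a list with `results` per condition and `files`.
#' @export
run_report <- function(conditions, config = analysis_config(),
                       out_dir = tempfile("report"), seed = 1L,
                       sasa_stride = 1L) {
  stopifnot(length(conditions) >= 1L, !is.null(names(conditions)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", "solvdyn",
                                       sprintf(...)))
  }
  set.seed(seed)
  results <- list(); files <- character(0)
  prop_rows <- list(); hb_rows <- list()
  failed <- character(0)
  for (lab in names(conditions)) {
    cond <- conditions[[lab]]
    traj <- if (inherits(cond, "sd_replica_set")) join_equilibrated(cond)
            else cond
    note("condition %s: %d frames, %d atoms", lab, n_frames(traj),
         n_atoms(traj$system))
    res <- list()
    stage <- function(name, expr) {
      out <- tryCatch(expr, error = function(e) {
        note("stage %s FAILED for %s: %s", name, lab, conditionMessage(e))
        failed <<- c(failed, sprintf("%s/%s", lab, name))
        NULL
      })
      out
    }
    res$properties <- stage("properties",
      property_table(traj, config, label = lab, sasa_stride = sasa_stride))
    res$hbonds_intra <- stage("hbonds",
      hbond_statistics(traj, config, scope = "intra-protein"))
    if (any(!traj$system$atoms$is_solute)) {
      res$hbonds_solv <- stage("hbonds-solvent",
        hbond_statistics(traj, config, scope = "protein-solvent"))
    }
    res$ed <- stage("ed", ed_decompose(traj))
    res$rmsf <- stage("rmsf", per_residue_rmsf(traj))
    results[[lab]] <- res
    if (!is.null(res$properties)) prop_rows[[lab]] <- res$properties
    if (!is.null(res$hbonds_intra)) {
      s <- res$hbonds_intra
      hb_rows[[lab]] <- data.frame(label = lab, scope = s$scope,
                                   static_mean = s$static_mean,
                                   static_sd = s$static_sd,
                                   dynamic = s$dynamic_count,
                                   mean_persistency = s$mean_persistency)
    }
    if (!is.null(res$ed)) {
      f <- file.path(out_dir, paste0("eigenvalues_",
                                     gsub("[^A-Za-z0-9]", "_", lab),
                                     ".csv"))
      write.csv(data.frame(index = seq_along(res$ed$eigenvalues),
                           eigenvalue_A2 = res$ed$eigenvalues,
                           eigenvalue_nm2 = res$ed$eigenvalues_nm2),
                f, row.names = FALSE)
      files <- c(files, f)
    }
    if (!is.null(res$rmsf)) {
      f <- file.path(out_dir, paste0("rmsf_",
                                     gsub("[^A-Za-z0-9]", "_", lab),
                                     ".tsv"))
      utils::write.table(data.frame(residue = names(res$rmsf),
                                    rmsf_A = unname(res$rmsf)),
                         f, sep = "\t", row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
  }
  if (length(prop_rows)) {
    f <- file.path(out_dir, "properties.csv")
    write.csv(do.call(rbind, prop_rows), f, row.names = FALSE)
    files <- c(files, f)
  }
  if (length(hb_rows)) {
    f <- file.path(out_dir, "hbonds.csv")
    write.csv(do.call(rbind, hb_rows), f, row.names = FALSE)
    files <- c(files, f)
  }
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_file, auto_unbox = TRUE,
                       digits = NA)
  manifest <- list(
    package = "solvdyn",
    package_version = as.character(utils::packageVersion("solvdyn")),
    r_version = as.character(getRversion()),
    seed = seed,
    conditions = names(conditions),
    config = unclass(config),
    config_md5 = unname(tools::md5sum(cfg_file)),
    failed_stages = failed)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  lf <- file.path(out_dir, "run.log")
  writeLines(log_lines, lf)
  files <- c(files, cfg_file, mf, lf)
  invisible(list(results = results, files = files, out_dir = out_dir,
                 failed = failed))
}
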