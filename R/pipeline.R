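## End-to-end orchestration: manifest -> per-repeat estimates -> pose
## averages -> Boltzmann pose combination -> force-field consensus ->
## DDG / metrics, with provenance logging.

#' Validated run configuration
#'
#' @param temperature Temperature in K (default 300.15).
#' @param units Reporting unit, "kcal" or "kJ" (internal math is kJ/mol).
#' @param estimator "cft-ml", "jarzynski" or "cgi".
#' @param seed Integer master seed.
#' @param n_boot Bootstrap resamples for metric uncertainties.
#' @param flip_hysteresis,unbind_distance,min_persistence Event-filter
#'   thresholds (see [filter_events()]).
#' @param convention DSSB end-state sign convention (see
#'   [assemble_binding()]).
#' @param restraint Optional [restraint_definition()] applied to every
#'   system.
#' @return A validated `run_config` object.
#' @export
run_config <- function(temperature = 300.15, units = c("kcal", "kJ"),
                       estimator = c("cft-ml", "jarzynski", "cgi"),
                       seed = 1L, n_boot = 200L,
                       flip_hysteresis = 0.2, unbind_distance = 1.5,
                       min_persistence = 50L,
                       convention = c("unbinding", "binding"),
                       restraint = NULL) {
  units <- match.arg(units)
  estimator <- match.arg(estimator)
  convention <- match.arg(convention)
  stopifnot_scalar(temperature, "temperature", positive = TRUE)
  stopifnot_scalar(seed, "seed")
  if (!is.null(restraint) && !inherits(restraint, "restraint_definition"))
    stop("restraint must be a restraint_definition or NULL")
  structure(list(temperature = temperature, units = units,
                 estimator = estimator, seed = as.integer(seed),
                 n_boot = as.integer(n_boot),
                 flip_hysteresis = flip_hysteresis,
                 unbind_distance = unbind_distance,
                 min_persistence = as.integer(min_persistence),
                 convention = convention, restraint = restraint),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' Configurations round-trip losslessly through the file.
#' @param config A [run_config()].
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$restraint)) x$restraint <- unclass(x$restraint)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  restr <- x$restraint
  if (!is.null(restr))
    restr <- do.call(restraint_definition, restr)
  run_config(temperature = x$temperature, units = x$units,
             estimator = x$estimator, seed = x$seed, n_boot = x$n_boot,
             flip_hysteresis = x$flip_hysteresis,
             unbind_distance = x$unbind_distance,
             min_persistence = x$min_persistence,
             convention = x$convention, restraint = restr)
}

## Stable hash of the configuration for provenance stamping.
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Estimate per-repeat transition free energies from a manifest
#'
#' Groups the manifest by (host, guest, forcefield, pose, repeat), integrates
#' each file's dH/dlambda series into a work value, pools the works of a
#' repeat into a bidirectional work set and runs the configured estimator.
#'
#' @param manifest data.frame from [read_manifest()].
#' @param config A [run_config()].
#' @return data.frame with one row per repeat: grouping columns plus
#'   `dg_kj`, `stderr_kj`, `n_forward`, `n_reverse`.
#' @export
estimate_from_manifest <- function(manifest, config = run_config()) {
  if (nrow(manifest) == 0L) stop("empty manifest: nothing to estimate")
  for (col in c("host", "guest", "forcefield"))
    if (is.null(manifest[[col]])) manifest[[col]] <- "NA"
  key <- interaction(manifest$host, manifest$guest, manifest$forcefield,
                     manifest$pose, manifest$`repeat`, drop = TRUE)
  out <- lapply(split(manifest, key), function(g) {
    works <- vapply(seq_len(nrow(g)), function(i) {
      s <- tryCatch(
        read_dhdl_xvg(g$path[i], direction = g$direction[i]),
        error = function(e) stop(sprintf("file '%s': %s", g$path[i],
                                         conditionMessage(e)), call. = FALSE))
      integrate_work(s)
    }, numeric(1))
    ws <- work_set(works[g$direction == "forward"],
                   works[g$direction == "reverse"],
                   config$temperature)
    est <- switch(config$estimator,
      "cft-ml" = estimate_cft_ml(ws),
      "jarzynski" = estimate_jarzynski(ws, direction = "forward",
                                       n_boot = config$n_boot,
                                       seed = config$seed),
      "cgi" = estimate_cgi(ws, n_boot = config$n_boot, seed = config$seed))
    data.frame(host = g$host[1], guest = g$guest[1],
               forcefield = g$forcefield[1], pose = g$pose[1],
               rep = g$`repeat`[1], dg_kj = est$dg, stderr_kj = est$stderr,
               n_forward = est$n_forward, n_reverse = est$n_reverse,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$host, res$guest, res$forcefield, res$pose, res$rep), ]
}

#' Run the full binding free energy pipeline
#'
#' estimate (per repeat) -> average over repeats (per pose) -> restraint
#' correction and sign convention -> Boltzmann pose combination ->
#' force-field consensus. Writes per-stage CSV tables and a provenance JSON
#' (config hash, seed, package version) when `out_dir` is given.
#'
#' @param manifest Work-file manifest data.frame (see [read_manifest()]).
#' @param config A [run_config()].
#' @param discarded Optional data.frame (host, guest, forcefield, pose,
#'   reason) of poses excluded after event filtering.
#' @param experimental Optional data.frame (host, guest, dg_exp_kcal) to
#'   compute benchmark metrics against.
#' @param out_dir Output directory, or NULL to skip writing.
#' @return List with `repeats`, `poses`, `bind`, `consensus` data.frames,
#'   optional `metrics`, and `provenance`.
#' @export
run_pipeline <- function(manifest, config = run_config(), discarded = NULL,
                         experimental = NULL, out_dir = NULL) {
  repeats <- estimate_from_manifest(manifest, config)

  corr <- if (!is.null(config$restraint))
    restraint_correction(config$restraint, config$temperature) else 0

  ## per-pose: average repeats, then apply convention + correction
  pose_key <- interaction(repeats$host, repeats$guest, repeats$forcefield,
                          repeats$pose, drop = TRUE)
  poses <- do.call(rbind, lapply(split(repeats, pose_key), function(g) {
    av <- average_repeats(g$dg_kj)
    dg_bind <- assemble_binding(av$mean, corr, config$convention)
    data.frame(host = g$host[1], guest = g$guest[1],
               forcefield = g$forcefield[1], pose = g$pose[1],
               dg_kj = dg_bind, stderr_kj = av$sem %||% NA_real_,
               n_repeats = av$n, status = "clean",
               stringsAsFactors = FALSE)
  }))
  rownames(poses) <- NULL
  if (!is.null(discarded) && nrow(discarded)) {
    for (i in seq_len(nrow(discarded))) {
      hit <- poses$host == discarded$host[i] &
        poses$guest == discarded$guest[i] &
        poses$forcefield == discarded$forcefield[i] &
        poses$pose == discarded$pose[i]
      poses$status[hit] <- discarded$reason[i]
    }
  }

  ## combine poses per (host, guest, forcefield)
  sys_key <- interaction(poses$host, poses$guest, poses$forcefield,
                         drop = TRUE)
  bind <- do.call(rbind, lapply(split(poses, sys_key), function(g) {
    pl <- lapply(seq_len(nrow(g)), function(i) {
      disc <- g$status[i] != "clean"
      pose_estimate(g$pose[i],
                    dg = if (disc) NA_real_ else g$dg_kj[i],
                    stderr = g$stderr_kj[i],
                    n_repeats = g$n_repeats[i],
                    discarded = disc, reason = if (disc) g$status[i] else "")
    })
    cmb <- combine_poses(pl, config$temperature)
    data.frame(host = g$host[1], guest = g$guest[1],
               forcefield = g$forcefield[1],
               dg_kcal = kj_to_kcal(cmb$dg),
               stderr_kcal = kj_to_kcal(cmb$stderr),
               stringsAsFactors = FALSE)
  }))
  rownames(bind) <- NULL

  ## consensus over force fields per (host, guest)
  hg_key <- interaction(bind$host, bind$guest, drop = TRUE)
  cons <- do.call(rbind, lapply(split(bind, hg_key), function(g)
    suppressWarnings(consensus(g))))
  rownames(cons) <- NULL

  metrics <- NULL
  if (!is.null(experimental)) {
    mg <- merge(cons, experimental, by = c("host", "guest"))
    if (nrow(mg) >= 2L)
      metrics <- binding_metrics(mg$dg_kcal, mg$dg_exp_kcal,
                                 n_boot = config$n_boot, seed = config$seed)
  }

  provenance <- list(config_hash = .config_hash(config), seed = config$seed,
                     estimator = config$estimator,
                     package_version =
                       as.character(utils::packageVersion("neqbind")),
                     n_manifest_rows = nrow(manifest))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(df) { df$config_hash <- provenance$config_hash; df }
    utils::write.csv(stamp(repeats), file.path(out_dir, "repeats.csv"),
                     row.names = FALSE)
    utils::write.csv(stamp(poses), file.path(out_dir, "poses.csv"),
                     row.names = FALSE)
    utils::write.csv(stamp(bind), file.path(out_dir, "bind.csv"),
                     row.names = FALSE)
    utils::write.csv(stamp(cons), file.path(out_dir, "consensus.csv"),
                     row.names = FALSE)
    jsonlite::write_json(c(provenance, list(metrics = metrics)),
                         file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  list(repeats = repeats, poses = poses, bind = bind, consensus = cons,
       metrics = metrics, provenance = provenance)
}
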