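#' Run a full experiment and write a result bundle
#'
#' Solves the self-aware policy, simulates both policies' ensembles, and
#' writes a self-contained result bundle: policy and value matrices as CSV
#' (rows = states, columns = epochs), tidy per-epoch ensemble summaries,
#' kernel diagnostic curves, a JSON summary (final-state means and standard
#' errors, cumulative rewards, config echo, seeds), a config echo (YAML) and
#' a plain-text log. Every numeric file is stamped with the configuration
#' hash through the summary and the log.
#'
#' @param config An [aware_config()] object.
#' @param out_dir Output directory (created if missing).
#' @param master_seed Integer master seed (mandatory).
#' @param write_trajectory Also write one example trajectory per policy
#'   (default `TRUE`).
#' @return Invisibly, the list of files written.
#' @export
run_experiment <- function(config, out_dir, master_seed,
                           write_trajectory = TRUE) {
  if (missing(master_seed) || is.null(master_seed)) {
    abort("`master_seed` is required: experiments must be reproducible.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  hash <- config_hash(config)
  cmp <- compare_policies(config, master_seed = master_seed)

  files <- character()
  put <- function(name) {
    p <- file.path(out_dir, name)
    files <<- c(files, p)
    p
  }
  grid <- config$grid
  mat_df <- function(m) {
    df <- as.data.frame(m)
    names(df) <- sprintf("epoch_%d", seq_len(ncol(m)) - 1L)
    cbind(state = grid$levels, df)
  }
  utils::write.csv(mat_df(cmp$sdp$policy), put("policy.csv"), row.names = FALSE)
  utils::write.csv(mat_df(cmp$sdp$values), put("values.csv"), row.names = FALSE)
  utils::write.csv(tidy(cmp), put("ensemble_summary.csv"), row.names = FALSE)
  utils::write.csv(
    transition_curves(c(0, config$p_r, 1), config$shape, grid),
    put("transition_curves.csv"), row.names = FALSE
  )
  utils::write.csv(
    data.frame(s = grid$levels,
               terminal_reward = terminal_reward(grid$levels, config$rewards),
               emotion_delta = emotion_delta(grid$levels, config$emotion)),
    put("reward_curves.csv"), row.names = FALSE
  )
  if (write_trajectory) {
    set.seed(master_seed)
    tr_seeds <- sample.int(.Machine$integer.max - 1L, 4L)[3:4]
    tr <- dplyr::bind_rows(
      dplyr::mutate(tidy(run_trajectory("habitual", config, seed = tr_seeds[1])),
                    mode = "habitual", .before = 1),
      dplyr::mutate(tidy(run_trajectory(cmp$sdp, config, seed = tr_seeds[2])),
                    mode = "self_aware", .before = 1)
    )
    utils::write.csv(tr, put("example_trajectories.csv"), row.names = FALSE)
  }
  summary <- list(
    config_hash = hash,
    master_seed = master_seed,
    habitual = as.list(glance(cmp$habitual)),
    self_aware = as.list(glance(cmp$self_aware)),
    config = unclass_deep_named(config)
  )
  jsonlite::write_json(summary, put("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_config(config, put("config.yaml"))
  writeLines(c(
    sprintf("config_hash: %s", hash),
    sprintf("master_seed: %d", master_seed),
    sprintf("wall_time_s: %.2f", as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    sprintf("timestamp: %s", format(t0, "%Y-%m-%dT%H:%M:%S%z"))
  ), put("run.log"))
  invisible(files)
}

# config as nested plain lists with names kept (for the JSON echo)
unclass_deep_named <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.list(x)) lapply(unclass(x), unclass_deep_named) else x
}
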