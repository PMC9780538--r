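#' Tidy a solved self-aware policy
#'
#' @param x An `aware_sdp` object.
#' @param ... Unused.
#' @return A long tibble with one row per (state, epoch): `state`, `epoch`,
#'   `decision` and `value`.
#' @export
tidy.aware_sdp <- function(x, ...) {
  levels <- x$config$grid$levels
  T_h <- x$config$T_horizon
  tibble::tibble(
    state = rep(levels, times = T_h),
    epoch = rep(0:(T_h - 1L), each = length(levels)),
    decision = as.vector(x$policy),
    value = as.vector(x$values[, seq_len(T_h)])
  )
}

#' @rdname tidy.aware_sdp
#' @export
glance.aware_sdp <- function(x, ...) {
  tibble::tibble(
    n_states = nrow(x$policy),
    T_horizon = ncol(x$policy),
    min_decision = min(x$policy),
    max_decision = max(x$policy),
    emotions = x$config$emotion$enabled,
    config_hash = x$config_hash
  )
}

#' Tidy a simulated trajectory
#'
#' @param x An `aware_trajectory` object.
#' @param ... Unused.
#' @return The per-epoch tibble of states, decisions, shocks and rewards.
#' @export
tidy.aware_trajectory <- function(x, ...) x$data

#' @rdname tidy.aware_trajectory
#' @export
glance.aware_trajectory <- function(x, ...) {
  n <- nrow(x$data)
  tibble::tibble(
    mode = x$mode,
    T_horizon = x$config$T_horizon,
    seed = x$seed,
    final_state = x$data$state[n],
    terminal_reward = x$terminal_reward,
    cum_reward = x$data$cum_reward[n],
    config_hash = x$config_hash
  )
}

#' Tidy an ensemble summary
#'
#' @param x An `aware_ensemble` object.
#' @param ... Unused.
#' @return The per-epoch summary tibble (means and standard errors).
#' @export
tidy.aware_ensemble <- function(x, ...) x$summary

#' @rdname tidy.aware_ensemble
#' @export
glance.aware_ensemble <- function(x, ...) {
  n <- nrow(x$summary)
  tibble::tibble(
    mode = x$mode,
    N = x$N,
    T_horizon = x$config$T_horizon,
    master_seed = x$master_seed,
    final_mean_state = x$summary$mean_state[n],
    final_se_state = x$summary$se_state[n],
    mean_cum_reward = x$summary$mean_cum_reward[n],
    config_hash = x$config_hash
  )
}

#' Tidy a habitual-versus-self-aware comparison
#'
#' @param x An `aware_comparison` object.
#' @param ... Unused.
#' @return A long tibble stacking both ensembles' per-epoch summaries with a
#'   `mode` column.
#' @export
tidy.aware_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$habitual$summary, mode = "habitual", .before = 1),
    dplyr::mutate(x$self_aware$summary, mode = "self_aware", .before = 1)
  )
}

#' @rdname tidy.aware_comparison
#' @export
glance.aware_comparison <- function(x, ...) {
  n <- nrow(x$differences)
  tibble::tibble(
    N = x$habitual$N,
    T_horizon = x$config$T_horizon,
    master_seed = x$master_seed,
    habitual_final_state = x$habitual$summary$mean_state[n],
    self_aware_final_state = x$self_aware$summary$mean_state[n],
    d_final_state = x$differences$d_mean_state[n],
    config_hash = x$config_hash
  )
}
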