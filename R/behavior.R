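# Model-free behavioral statistics from session data.

#' Win-switch rate and overall performance of a session
#'
#' Win-switch rate (WSR) is the proportion of rewarded trials followed by a
#' different choice on the next trial, relative to all rewarded trials. The
#' final trial is excluded from the denominator because it has no successor
#' choice. When no rewarded trials exist the rate is flagged missing (`NA`)
#' rather than raising an error.
#'
#' @param session A `prl_session`.
#' @return A one-row data frame (`behavior_summary`): `participant_id`,
#'   `wsr`, `n_win_trials`, `n_win_switches`, `performance`.
#' @export
win_switch_rate <- function(session) {
  rec <- session$records
  n <- nrow(rec)
  if (n < 2L) stop_config("session must have >= 2 trials")
  win <- rec$outcome[-n] == 1L
  switch_next <- rec$choice[-n] != rec$choice[-1L]
  n_win <- sum(win)
  n_ws <- sum(win & switch_next)
  data.frame(participant_id = session$participant_id,
             wsr = if (n_win > 0L) n_ws / n_win else NA_real_,
             n_win_trials = n_win, n_win_switches = n_ws,
             performance = mean(rec$outcome))
}

#' Mean reward rate of a session
#'
#' @param session A `prl_session`.
#' @return Mean of the binary outcomes, in `[0, 1]`.
#' @export
performance <- function(session) {
  if (nrow(session$records) < 1L) stop_config("empty session")
  mean(session$records$outcome)
}
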