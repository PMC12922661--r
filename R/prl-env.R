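#' Three-choice probabilistic reversal learning task configuration
#'
#' Defines the reinforcement structure of the task: three options whose reward
#' probabilities start at 0.9/0.5/0.1, undergo performance-independent
#' reversals every 40 trials and performance-dependent reversals after 9 of 10
#' consecutive selections of the best option, and shift to a 0.8/0.4/0.2 set at
#' trial 81 (each option keeping its rank).
#'
#' @param n_trials Number of trials (default 160).
#' @param n_options Number of options (default 3).
#' @param probs_pre Reward probabilities before the contingency shift.
#' @param probs_post Reward probabilities at and after the shift.
#' @param shift_trial 1-based trial at which `probs_post` takes effect.
#' @param scheduled_period Trials between performance-independent reversals.
#' @param perf_window Window length for the performance trigger.
#' @param perf_criterion Selections of the best option within `perf_window`
#'   needed to trigger a reversal.
#' @return A `prl_config` list.
#' @export
task_config <- function(n_trials = 160L, n_options = 3L,
                        probs_pre = c(0.9, 0.5, 0.1),
                        probs_post = c(0.8, 0.4, 0.2),
                        shift_trial = 81L, scheduled_period = 40L,
                        perf_window = 10L, perf_criterion = 9L) {
  n_trials <- as.integer(n_trials)
  n_options <- as.integer(n_options)
  if (length(probs_pre) != n_options || length(probs_post) != n_options)
    stop_config("probability sets must match n_options")
  if (any(probs_pre < 0 | probs_pre > 1) || any(probs_post < 0 | probs_post > 1))
    stop_config("reward probabilities must lie in [0, 1]")
  if (n_trials < 1L) stop_config("n_trials must be >= 1")
  if (shift_trial > n_trials + 1L) stop_config("shift_trial must be <= n_trials + 1")
  if (perf_criterion > perf_window) stop_config("perf_criterion must be <= perf_window")
  structure(list(
    n_trials = n_trials, n_options = n_options,
    probs_pre = as.numeric(probs_pre), probs_post = as.numeric(probs_post),
    shift_trial = as.integer(shift_trial),
    scheduled_period = as.integer(scheduled_period),
    perf_window = as.integer(perf_window),
    perf_criterion = as.integer(perf_criterion)
  ), class = "prl_config")
}

#' Deterministic schedule skeleton for a task configuration
#'
#' @param config A [task_config()].
#' @return A list with `trials`, a data frame of per-trial active probability
#'   sets (columns `t`, `phase`, `p1..pK` giving the active set in descending
#'   order), and `scheduled_reversals`, the 1-based trials after which a
#'   performance-independent reversal is applied.
#' @export
build_schedule <- function(config) {
  stopifnot(inherits(config, "prl_config"))
  t <- seq_len(config$n_trials)
  pre <- t < config$shift_trial
  sets <- matrix(NA_real_, config$n_trials, config$n_options)
  sets[pre, ] <- matrix(sort(config$probs_pre, decreasing = TRUE),
                        sum(pre), config$n_options, byrow = TRUE)
  if (any(!pre))
    sets[!pre, ] <- matrix(sort(config$probs_post, decreasing = TRUE),
                           sum(!pre), config$n_options, byrow = TRUE)
  colnames(sets) <- paste0("p", seq_len(config$n_options))
  sched <- t[t %% config$scheduled_period == 0L]
  list(
    trials = data.frame(t = t, phase = ifelse(pre, "pre", "post"), sets),
    scheduled_reversals = sched
  )
}

#' Apply a reversal to an option-to-probability assignment
#'
#' The best-probability and worst-probability options exchange probabilities;
#' middle options keep theirs. The rule is exposed so alternative reversal
#' strategies can be substituted.
#'
#' @param assignment Numeric vector of reward probabilities, one per option.
#' @return The reversed assignment (a permutation of the same values).
#' @export
apply_reversal <- function(assignment) {
  i_best <- which.max(assignment)
  i_worst <- which.min(assignment)
  out <- assignment
  out[i_best] <- assignment[i_worst]
  out[i_worst] <- assignment[i_best]
  out
}

#' Performance-dependent reversal trigger
#'
#' Fires when, among the last `perf_window` choices (and only once that window
#' is full), at least `perf_criterion` selected the current best option.
#'
#' @param choice_history Integer vector of choices since the last reversal,
#'   oldest first.
#' @param current_best Option id of the current best option.
#' @param config A [task_config()].
#' @return Logical.
#' @export
performance_trigger <- function(choice_history, current_best, config) {
  w <- config$perf_window
  n <- length(choice_history)
  if (n < w) return(FALSE)
  recent <- choice_history[(n - w + 1L):n]
  sum(recent == current_best) >= config$perf_criterion
}

#' Run one agent-environment session
#'
#' Plays an agent against the task: on each trial the agent returns choice
#' probabilities, a choice is sampled, the outcome is drawn Bernoulli from the
#' chosen option's assigned probability, and reversal logic is applied. The
#' agent is a list contract with fields
#' \describe{
#'   \item{init(config)}{returns the agent's initial state.}
#'   \item{choose(state, assignment)}{returns a probability vector over
#'     options (a fair agent ignores `assignment`; it is passed so oracle
#'     agents used in calibration checks can read the environment).}
#'   \item{update(state, choice, outcome)}{returns the next state.}
#' }
#'
#' @param agent Agent contract (see Details).
#' @param config A [task_config()].
#' @param seed Integer seed; the session is reproducible given it.
#' @param participant_id Participant identifier stored in the output.
#' @return A `prl_session`: list with `participant_id` and `records`, a data
#'   frame with columns `t`, `choice`, `outcome`, `p1..pK` (assigned
#'   probability per option id) and `reversal_event`.
#' @export
run_session <- function(agent, config, seed, participant_id = "sim") {
  stopifnot(inherits(config, "prl_config"))
  set.seed(as.integer(seed))
  n <- config$n_trials
  k <- config$n_options
  assignment <- as.numeric(config$probs_pre)
  choice <- integer(n); outcome <- integer(n)
  probs_mat <- matrix(NA_real_, n, k)
  rev_event <- character(n)
  state <- agent$init(config)
  since_rev <- integer(0) # choices since last reversal
  for (t in seq_len(n)) {
    if (t == config$shift_trial) {
      # rank-preserving re-map onto the post-shift set
      assignment <- sort(config$probs_post,
                         decreasing = TRUE)[rank(-assignment, ties.method = "first")]
    }
    p <- agent$choose(state, assignment)
    if (length(p) != k || any(!is.finite(p)) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-8)
      stop("agent returned an invalid probability vector at trial ", t)
    ch <- sample.int(k, 1L, prob = p)
    y <- as.integer(stats::runif(1) < assignment[ch])
    choice[t] <- ch; outcome[t] <- y
    probs_mat[t, ] <- assignment
    state <- agent$update(state, ch, y)
    since_rev <- c(since_rev, ch)
    ev <- "none"
    if (t %% config$scheduled_period == 0L) {
      ev <- "scheduled"
    } else if (performance_trigger(since_rev, which.max(assignment), config)) {
      ev <- "performance"
    }
    if (ev != "none") {
      assignment <- apply_reversal(assignment)
      since_rev <- integer(0)
    }
    rev_event[t] <- ev
  }
  records <- data.frame(t = seq_len(n), choice = choice, outcome = outcome)
  colnames(probs_mat) <- paste0("p", seq_len(k))
  records <- cbind(records, probs_mat)
  records$reversal_event <- rev_event
  structure(list(participant_id = participant_id, records = records),
            class = "prl_session")
}

#' @export
print.prl_session <- function(x, ...) {
  cat("PRL session", x$participant_id, "-", nrow(x$records), "trials,",
      sum(x$records$outcome), "wins\n")
  invisible(x)
}

#' Reference agents
#'
#' `agent_uniform()` picks uniformly at random; `agent_oracle()` always picks
#' the currently best option (it reads the environment's assignment and is
#' used only for calibration checks); `agent_fixed(j)` always picks option
#' `j`.
#'
#' @return An agent contract usable with [run_session()].
#' @export
agent_uniform <- function() {
  list(init = function(config) list(k = config$n_options),
       choose = function(state, assignment) rep(1 / state$k, state$k),
       update = function(state, choice, outcome) state)
}

#' @rdname agent_uniform
#' @export
agent_oracle <- function() {
  list(init = function(config) list(k = config$n_options),
       choose = function(state, assignment) {
         p <- rep(0, state$k); p[which.max(assignment)] <- 1; p
       },
       update = function(state, choice, outcome) state)
}

#' @rdname agent_uniform
#' @param j Option id the fixed agent always selects.
#' @export
agent_fixed <- function(j) {
  force(j)
  list(init = function(config) list(k = config$n_options),
       choose = function(state, assignment) {
         p <- rep(0, state$k); p[j] <- 1; p
       },
       update = function(state, choice, outcome) state)
}

#' Write / read a session as CSV
#'
#' @param session A `prl_session`.
#' @param path File path.
#' @export
write_session_csv <- function(session, path) {
  df <- cbind(participant_id = session$participant_id, session$records)
  names(df)[names(df) == "t"] <- "trial"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @return `read_session_csv()` returns a `prl_session`.
#' @export
read_session_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "trial"] <- "t"
  structure(list(participant_id = as.character(df$participant_id[1]),
                 records = df[setdiff(names(df), "participant_id")]),
            class = "prl_session")
}
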