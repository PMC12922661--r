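# Synthetic cohort generator. Emulates the statistical structure the analysis
# assumes -- a large online sample with a high-paranoia subgroup showing
# elevated volatility priors, elevated win-switch rates (emerging through the
# HGF simulation, never injected directly), lower metacognitive structure and
# shorter reflections -- so every pipeline stage can run without any download.

#' Cohort specification
#'
#' @param n_total Cohort size (default 486).
#' @param n_high_paranoia High-paranoia subgroup size (default 99).
#' @param cutoff Persecution-score cutoff defining the high group (default 11).
#' @param d_mu3 Target standardized group gap in the volatility prior
#'   (default 0.63, high > low).
#' @param d_mp Target standardized group gap in reflection structure
#'   (default 0.73, high < low).
#' @param d_wsr Emulated group gap in win-switch rate (default 1.09); this is
#'   a property the generated cohort should exhibit *emergently* through the
#'   HGF simulation -- it is never injected and is recorded here only as the
#'   condition being emulated.
#' @param mu3_mean,mu3_sd Population mean and SD of the volatility prior.
#' @param mp_gating Strength (0-1) with which reflective structure attenuates
#'   the translation of the volatility prior into behavior: the prior the
#'   agent *acts on* is compressed toward the population mean by
#'   `mp_gating * level/4`. Positive values encode a negative
#'   belief-x-metacognition interaction in behavior.
#' @param mp_direct Direct dampening of acted-on volatility per structure
#'   level above the midpoint (log-volatility units; encodes the negative
#'   main effect of reflection on switching).
#' @param mu3_mp_cor Latent correlation between the volatility prior and
#'   reflective structure beyond the group means (synthetic knob, default 0).
#' @param config [task_config()] used for all sessions.
#' @param seed Global seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_total = 486L, n_high_paranoia = 99L, cutoff = 11L,
                        d_mu3 = 0.63, d_mp = 0.73, d_wsr = 1.09,
                        mu3_mean = -3, mu3_sd = 1.5, mp_gating = 0.6,
                        mp_direct = 0.25, mu3_mp_cor = 0,
                        config = task_config(), seed = 1L) {
  if (n_high_paranoia > n_total) stop_config("n_high_paranoia must be <= n_total")
  if (d_mu3 < 0 || d_mp < 0 || d_wsr < 0) stop_config("effect targets must be >= 0")
  if (mp_gating < 0 || mp_gating > 1) stop_config("mp_gating must lie in [0, 1]")
  structure(list(n_total = as.integer(n_total),
                 n_high_paranoia = as.integer(n_high_paranoia),
                 cutoff = as.integer(cutoff), d_mu3 = d_mu3, d_mp = d_mp,
                 d_wsr = d_wsr, mu3_mean = mu3_mean, mu3_sd = mu3_sd,
                 mp_gating = mp_gating, mp_direct = mp_direct,
                 mu3_mp_cor = mu3_mp_cor,
                 config = config, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Reflection text template by structural richness level
#'
#' Level 0 yields near-empty text (below the short-text auto-zero threshold);
#' level 4 yields a multi-clause reflection carrying comprehension,
#' judgement, evaluation, decision and confidence markers that the rule-based
#' scorer detects. Uses the current RNG state, so it is deterministic inside a
#' seeded context.
#'
#' @param structure_level Integer 0..4.
#' @return A single reflection string.
#' @export
reflection_template <- function(structure_level) {
  lv <- as.integer(structure_level)
  if (lv < 0L || lv > 4L) stop_config("structure_level must be in 0..4")
  if (lv == 0L) return(sample(c("", "no", "idk", "na"), 1))
  comprehension <- sample(c(
    "I picked the deck that gave me the most points and kept choosing it.",
    "The game had three options and I tried to find the best card to pick.",
    "I watched which avatar gave rewards and made my choice based on that."), 1)
  judgement <- sample(c(
    "I noticed a pattern where a good option would stop paying after a while, so I tracked how long each streak lasted.",
    "When an option seemed to go cold I figured the odds had changed, and I counted losses before believing it.",
    "If I lost twice in a row I would assume the contingencies had switched."), 1)
  evaluation <- sample(c(
    "Switching early did not work as well near the end, so sticking longer worked better for me.",
    "My first approach was worse than I expected; changing it improved my score.",
    "Staying with one option worked better than jumping around, which paid off later."), 1)
  decision <- sample(c(
    "In the end I decided on a rule: I usually stuck with an option until it failed me twice.",
    "I settled on always keeping the same choice after a win and only moving after repeated losses.",
    "My final strategy was to stay with the best option and only switch deliberately."), 1)
  confidence <- sample(c(
    "I was fairly sure this was the right approach, though I took some risks.",
    "I felt confident near the end but unsure at the start.",
    "I mostly stayed with my safer guesses and was pretty certain they were right."), 1)
  parts <- c(comprehension, judgement, evaluation, decision, confidence)
  text <- paste(parts[seq_len(min(lv + 1L, 5L))], collapse = " ")
  # neutral filler, independent of structure, so verbosity is not a
  # deterministic proxy for reflective structure
  filler_pool <- c("The game took me about twenty minutes in total.",
                   "I played on my laptop at home in the evening.",
                   "The screen layout was clear and easy to read.",
                   "I had done a similar survey once before.")
  n_fill <- sample(0:3, 1)
  if (n_fill > 0)
    text <- paste(c(text, sample(filler_pool, n_fill)), collapse = " ")
  text
}

crt_answer_pool <- function(correct) {
  # (correct, intuitive-wrong) per item, with surface variation
  pools <- list(
    list(right = c("0.05", "5 cents", "$0.05", "five cents"),
         wrong = c("10 cents", "0.10", "$0.10", "10")),
    list(right = c("5 minutes", "5", "five"),
         wrong = c("100 minutes", "100", "20 minutes")),
    list(right = c("47", "47 days", "forty-seven"),
         wrong = c("24", "24 days", "46"))
  )
  vapply(seq_len(3), function(i) {
    p <- if (correct[i]) pools[[i]]$right else pools[[i]]$wrong
    sample(p, 1)
  }, "")
}

#' Generate a synthetic cohort
#'
#' Draws paranoia scores to match the specified group sizes, volatility
#' priors with a standardized group gap of `d_mu3`, reflective-structure
#' levels with a gap tuned to `d_mp`, then simulates each participant's
#' session with an HGF agent whose *acted-on* volatility prior is the drawn
#' prior compressed toward the population mean in proportion to
#' `mp_gating * level/4` (the synthetic metacognitive buffer). Win-switch
#' behavior is therefore entirely emergent from the agent-environment loop.
#'
#' @param spec A [cohort_spec()].
#' @return List of `participant` records: `id`, `rgpts`, `group`, `params`
#'   (the drawn [hgf_params()]), `mu3_acted` (the gated value driving
#'   behavior), `structure_level`, `session`, `reflection`, `education`,
#'   `crt_answers`, `age`, `gender`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(derive_seed(spec$seed, "cohort"))
  n <- spec$n_total
  n_hi <- spec$n_high_paranoia
  is_high <- sample(rep(c(TRUE, FALSE), c(n_hi, n - n_hi)))
  # zero-inflated persecution scores consistent with the cutoff split
  rgpts <- ifelse(is_high,
                  spec$cutoff + stats::rbinom(n, 13, 0.3),
                  pmin(spec$cutoff - 1L,
                       stats::rbinom(n, 8, 0.25) *
                         stats::rbinom(n, 1, 0.6)))
  # volatility prior: group means separated by d_mu3 * sd, population-centred
  low_mean <- spec$mu3_mean - spec$d_mu3 * spec$mu3_sd * n_hi / n
  hi_mean <- low_mean + spec$d_mu3 * spec$mu3_sd
  z_mu3 <- stats::rnorm(n)
  mu3 <- ifelse(is_high, hi_mean, low_mean) + spec$mu3_sd * z_mu3
  # reflective structure: latent N with group gap tuned to d_mp, optional
  # residual correlation with the volatility prior, discretized to 0..4
  lat <- spec$mu3_mp_cor * z_mu3 +
    sqrt(1 - spec$mu3_mp_cor^2) * stats::rnorm(n)
  lat <- ifelse(is_high, -spec$d_mp, 0) + lat
  level <- pmax(0L, pmin(4L, as.integer(round(2.4 + 0.9 * lat))))
  education <- sample(1:8, n, replace = TRUE,
                      prob = c(1, 2, 6, 5, 3, 4, 2, 1))
  age <- sample(18:75, n, replace = TRUE)
  gender <- sample(c("female", "male", "nonbinary"), n, replace = TRUE,
                   prob = c(0.49, 0.49, 0.02))
  participants <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(spec$seed, "participant", i))
    params <- hgf_params(mu3_0 = mu3[i], m3 = spec$mu3_mean)
    gate <- 1 - spec$mp_gating * level[i] / 4
    mu3_acted <- spec$mu3_mean + (mu3[i] - spec$mu3_mean) * gate -
      spec$mp_direct * (level[i] - 2L)
    params_beh <- hgf_params(mu3_0 = mu3_acted, m3 = spec$mu3_mean)
    sim <- simulate_agent(params_beh, spec$config,
                          seed = derive_seed(spec$seed, "session", i),
                          participant_id = sprintf("P%03d", i))
    refl_text <- reflection_template(level[i])
    crt_correct <- stats::runif(3) < 0.45
    participants[[i]] <- structure(list(
      id = sprintf("P%03d", i), rgpts = as.integer(rgpts[i]),
      group = if (is_high[i]) "high" else "low",
      params = params, mu3_acted = mu3_acted,
      structure_level = level[i], session = sim$session,
      reflection = reflection(sprintf("P%03d", i), refl_text),
      education = education[i],
      crt_answers = crt_answer_pool(crt_correct),
      age = age[i], gender = gender[i]), class = "participant")
  }
  participants
}

#' Assemble the participant-level analysis table for a cohort
#'
#' Runs the model-free behavior summaries, MP scoring (through the given
#' backend) and covariate construction for every participant, producing the
#' moderation table consumed by [fit_moderation()].
#'
#' @param participants Output of [generate_cohort()].
#' @param backend Scorer backend (default [mp_backend_mock()]).
#' @param mu3_source `"drawn"` uses each participant's generative volatility
#'   prior; `"fitted"` refits the HGF to each session by MAP first.
#' @param priors,n_restarts,seed Passed to [fit_map()] when
#'   `mu3_source = "fitted"`.
#' @return Data frame with one row per participant: identifiers, group,
#'   `mu3_0`, behavior counts, `wsr`, `performance`, `M_bar`, the five `M_d`
#'   columns, `verbosity`, `crt_accuracy`, `gcog`.
#' @export
cohort_table <- function(participants, backend = mp_backend_mock(),
                         mu3_source = c("drawn", "fitted"),
                         priors = hgf_priors(), n_restarts = 3, seed = 1) {
  mu3_source <- match.arg(mu3_source)
  rows <- lapply(seq_along(participants), function(i) {
    p <- participants[[i]]
    beh <- win_switch_rate(p$session)
    sc <- score_reflection(p$reflection, backend)
    crt <- score_crt(p$crt_answers)
    mu3 <- if (mu3_source == "drawn") p$params$mu3_0 else
      fit_map(p$session, priors, n_restarts = n_restarts,
              seed = derive_seed(seed, "fit", i))$params$mu3_0
    cbind(data.frame(participant_id = p$id, rgpts = p$rgpts, group = p$group,
                     mu3_0 = mu3, n_win_trials = beh$n_win_trials,
                     n_win_switches = beh$n_win_switches, wsr = beh$wsr,
                     performance = beh$performance, M_bar = sc$M_bar),
          as.data.frame(as.list(stats::setNames(
            sc$M_d, paste0("M_", gsub(" ", "_", tolower(names(sc$M_d))))))),
          data.frame(verbosity = p$reflection$char_count,
                     crt_accuracy = crt$accuracy,
                     gcog = general_cognition(p$education, crt$accuracy)))
  })
  do.call(rbind, rows)
}

#' Write a cohort to disk in the pipeline's ingest formats
#'
#' Trials as one stacked CSV, reflections as JSON lines, covariates as CSV --
#' the same files a real-data ingest would provide.
#'
#' @param participants Output of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(participants, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  trials <- do.call(rbind, lapply(participants, function(p)
    cbind(participant_id = p$id, p$session$records)))
  names(trials)[names(trials) == "t"] <- "trial"
  trials_path <- file.path(dir, "trials.csv")
  utils::write.csv(trials, trials_path, row.names = FALSE, quote = FALSE)
  refl_path <- file.path(dir, "reflections.jsonl")
  writeLines(vapply(participants, function(p)
    jsonlite::toJSON(list(participant_id = p$id, text = p$reflection$text),
                     auto_unbox = TRUE), ""), refl_path)
  cov <- do.call(rbind, lapply(participants, function(p)
    data.frame(participant_id = p$id, rgpts = p$rgpts, group = p$group,
               education = p$education,
               crt1 = p$crt_answers[1], crt2 = p$crt_answers[2],
               crt3 = p$crt_answers[3], age = p$age, gender = p$gender)))
  cov_path <- file.path(dir, "covariates.csv")
  utils::write.csv(cov, cov_path, row.names = FALSE)
  invisible(c(trials = trials_path, reflections = refl_path,
              covariates = cov_path))
}
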