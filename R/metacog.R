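# Metacognitive-prompting (MP) scores from open-ended reflection text.
#
# Five rubric dimensions -- Comprehension, Judgement, Evaluation, Final
# Decision, Confidence -- are each scored as a probability distribution over
# rubric levels 0..4 by a pluggable backend; the continuous dimension score is
# the distribution's expected value and the overall index is the mean across
# dimensions. A deterministic rule-based backend ships for offline use and
# testing; an LLM backend can be plugged in through the same contract.

MP_DIMENSIONS <- c("Comprehension", "Judgement", "Evaluation",
                   "Final Decision", "Confidence")

#' Build a reflection record
#'
#' @param participant_id Identifier.
#' @param text The participant's combined answers to the two debrief prompts,
#'   concatenated into a single string.
#' @return A `reflection` list with `participant_id`, `text`, `char_count`
#'   (verbosity: number of characters of the combined response).
#' @export
reflection <- function(participant_id, text) {
  text <- as.character(text)
  structure(list(participant_id = participant_id, text = text,
                 char_count = nchar(text)), class = "reflection")
}

#' Expected-value score of one rubric dimension
#'
#' `M_d = sum_i P_i * i` over rubric levels `i = 0..4`.
#'
#' @param probs Probability vector of length 5 over levels 0..4.
#' @return The continuous dimension score in `[0, 4]`.
#' @export
expected_score <- function(probs) {
  probs <- validate_dist(probs)
  sum(probs * 0:4)
}

validate_dist <- function(probs, tol_renorm = 1e-3) {
  if (length(probs) != 5L || any(!is.finite(probs)) || any(probs < 0))
    stop_config("a score distribution must be 5 non-negative probabilities")
  s <- sum(probs)
  if (abs(s - 1) > tol_renorm)
    stop_config("score distribution does not sum to 1 (backend contract)")
  if (abs(s - 1) > 1e-6) probs <- probs / s
  probs
}

#' Mean metacognitive score across the five dimensions
#'
#' @param scores Numeric vector of five dimension scores in `[0, 4]`.
#' @return `M_bar`, the arithmetic mean.
#' @export
mean_mp <- function(scores) {
  if (length(scores) != 5L) stop_config("expected five dimension scores")
  if (any(scores < 0 | scores > 4)) stop_config("dimension scores must lie in [0, 4]")
  mean(scores)
}

#' Score a reflection on the five MP dimensions
#'
#' Reflections too short to evaluate (< `short_threshold` non-whitespace
#' characters) bypass the backend and are auto-scored with a point mass at
#' level 0 on every dimension. Otherwise the backend is called with the text
#' and must return five probability vectors; vectors off unit mass by at most
#' 1e-3 are renormalized, worse violations raise a backend-contract error.
#'
#' @param refl A [reflection()].
#' @param backend A scorer backend: `function(text)` returning a named list of
#'   five length-5 probability vectors (names [MP_DIMENSIONS]). See
#'   [mp_backend_mock()].
#' @param short_threshold Minimum non-whitespace characters for backend
#'   scoring.
#' @return An `mp_scores` list: `distributions` (named list), `M_d` (named
#'   numeric, expected values), `M_bar`.
#' @export
score_reflection <- function(refl, backend = mp_backend_mock(),
                             short_threshold = 10L) {
  stopifnot(inherits(refl, "reflection"))
  n_content <- nchar(gsub("\\s", "", refl$text))
  if (n_content < short_threshold) {
    dists <- stats::setNames(rep(list(c(1, 0, 0, 0, 0)), 5L), MP_DIMENSIONS)
  } else {
    dists <- backend(refl$text)
    if (!is.list(dists) || length(dists) != 5L)
      stop_config("backend must return five score distributions")
    names(dists) <- MP_DIMENSIONS
    dists <- lapply(dists, validate_dist)
  }
  m_d <- vapply(dists, expected_score, 0)
  structure(list(distributions = dists, M_d = m_d, M_bar = mean_mp(m_d)),
            class = "mp_scores")
}

#' Deterministic rule-based scorer backend
#'
#' Maps transparent text features to the five dimension scores: task
#' vocabulary and length feed Comprehension; pattern-tracking and conditional
#' markers feed Judgement; evaluative phrases feed Evaluation; rule/decision
#' statements feed Final Decision; confidence and uncertainty phrases feed
#' Confidence. Each raw score is a monotone non-decreasing function of its
#' feature counts (adding a marker never lowers any score), and the returned
#' distribution splits mass between the two adjacent rubric levels so that its
#' expected value equals the raw score exactly. Deterministic: the same text
#' always yields identical distributions.
#'
#' @return A backend function usable with [score_reflection()].
#' @export
mp_backend_mock <- function() {
  count_hits <- function(text, patterns)
    sum(vapply(patterns, function(p) {
      m <- gregexpr(p, text, perl = TRUE)[[1]]
      if (m[1] == -1L) 0L else length(m)
    }, 0L))
  function(text) {
    low <- tolower(text)
    tokens <- length(strsplit(trimws(low), "\\s+")[[1]])
    task <- count_hits(low, c("deck", "card", "option", "avatar", "reward",
                              "point", "choice", "choos", "pick", "switch"))
    judge <- count_hits(low, c("pattern", "notic", "seem", "count", "track",
                               "figur", "\\bif\\b", "\\bwhen\\b",
                               "\\buntil\\b", "\\bwould\\b", "\\bafter\\b"))
    evalp <- count_hits(low, c("work", "better", "worse", "effective",
                               "improv", "did not work", "didn't work",
                               "paid off", "helped"))
    decis <- count_hits(low, c("decid", "stuck with", "stayed with", "settl",
                               "rule", "\\balways\\b", "\\busually\\b",
                               "strateg", "ended up"))
    conf <- count_hits(low, c("confiden", "\\bsure\\b", "unsure", "guess",
                              "risk", "certain", "doubt", "safe"))
    len <- min(tokens, 60) / 60 # saturating length credit (mild, by design)
    raw <- c(
      Comprehension = 0.8 * task + 1.0 * len,
      Judgement = 0.9 * judge + 0.6 * len,
      Evaluation = 1.0 * evalp + 0.5 * len,
      `Final Decision` = 0.9 * decis + 0.6 * len,
      Confidence = 1.1 * conf + 0.4 * len
    )
    raw <- pmin(4, raw)
    lapply(raw, function(s) {
      lo <- floor(s)
      p <- numeric(5)
      if (lo >= 4) p[5] <- 1
      else {
        p[lo + 1] <- 1 - (s - lo)
        p[lo + 2] <- s - lo
      }
      p
    })
  }
}

#' LLM scorer backend adapter
#'
#' Builds the structured scoring prompt (role instruction, the five-dimension
#' rubric, strict output-format requirements) and delegates the completion to
#' a user-supplied function, e.g. a temperature-0 chat-API call. The
#' completion must return a JSON object mapping each dimension to a length-5
#' probability vector. No network access is performed by the package itself.
#'
#' @param complete_fn `function(prompt)` returning the model's raw JSON reply.
#' @param rubric Optional character scoring rubric to embed verbatim.
#' @return A backend function usable with [score_reflection()].
#' @export
mp_backend_llm <- function(complete_fn, rubric = NULL) {
  force(complete_fn)
  function(text) {
    prompt <- paste0(
      "You are a metacognitive scientist. Score the participant reflection ",
      "below on five dimensions (Comprehension, Judgement, Evaluation, ",
      "Final Decision, Confidence), each on a 0-4 rubric. ",
      "Recognize subtle or abstract forms of insight (counterfactual ",
      "reasoning, conditional logic, philosophical restraint). ",
      if (!is.null(rubric)) paste0("Rubric:\n", rubric, "\n") else "",
      "Return ONLY a JSON object mapping each dimension name to a ",
      "probability distribution over scores 0..4 (five numbers summing to ",
      "1).\n\nReflection:\n", text)
    out <- jsonlite::fromJSON(complete_fn(prompt))
    lapply(out[MP_DIMENSIONS], as.numeric)
  }
}

# ---- general cognition ----------------------------------------------------

#' Score the three-item cognitive reflection test
#'
#' Rule-based scoring that accepts numeric, text and unit-based variants of
#' the correct answers ("five", "5 minutes", "0.05", "5 cents", ...).
#' Unparseable answers score 0.
#'
#' @param answers Character vector of three free-text responses (bat-and-ball
#'   cost; machines/widgets duration; lily-pad doubling).
#' @return List with `items` (0/1 per item) and `accuracy` in
#'   `{0, 1/3, 2/3, 1}`.
#' @export
score_crt <- function(answers) {
  if (length(answers) != 3L) stop_config("expected three CRT answers")
  items <- c(
    crt_item_correct(answers[1], target = 0.05, cent_value = 5),
    crt_item_correct(answers[2], target = 5, wrong_units = c("hour", "second", "day")),
    crt_item_correct(answers[3], target = 47, wrong_units = c("minute", "hour"))
  )
  list(items = items, accuracy = mean(items))
}

# extract the first numeric value (digits or number words) and any unit word
crt_parse <- function(ans) {
  a <- tolower(trimws(as.character(ans)))
  a <- gsub("\\$", " $ ", a)
  # longest phrases first so "forty-seven" is not eaten by "seven"
  words <- c("forty-seven" = 47, "forty seven" = 47, "fortyseven" = 47,
             "twenty" = 20, "zero" = 0, "one" = 1, "two" = 2, "three" = 3,
             "four" = 4, "five" = 5, "six" = 6, "seven" = 7, "eight" = 8,
             "nine" = 9, "ten" = 10)
  for (w in names(words)) a <- gsub(paste0("\\b", w, "\\b"), words[w], a)
  m <- regmatches(a, regexpr("[0-9]*\\.?[0-9]+", a))
  value <- if (length(m) == 0L) NA_real_ else as.numeric(m)
  list(value = value, text = a)
}

crt_item_correct <- function(ans, target, cent_value = NULL,
                             wrong_units = character()) {
  p <- crt_parse(ans)
  if (is.na(p$value)) return(0L)
  for (u in wrong_units) if (grepl(u, p$text)) return(0L)
  if (!is.null(cent_value) && grepl("cent|penn", p$text))
    return(as.integer(abs(p$value - cent_value) < 1e-9 ||
                        abs(p$value - cent_value / 100) < 1e-9))
  as.integer(abs(p$value - target) < 1e-9)
}

#' General-cognition composite
#'
#' The literal average of the education level (ordinal 1-8) and CRT accuracy
#' (0-1). The two inputs live on different scales; the composite is z-scored
#' before entering any model, so only its ordering matters downstream.
#'
#' @param education Ordinal education level, 1-8.
#' @param crt_accuracy CRT accuracy in `[0, 1]`.
#' @return The composite score.
#' @export
general_cognition <- function(education, crt_accuracy) {
  if (!is.numeric(education) || education < 1 || education > 8 ||
      education != round(education))
    stop_config("education must be an integer 1..8")
  if (crt_accuracy < 0 || crt_accuracy > 1)
    stop_config("crt_accuracy must lie in [0, 1]")
  mean(c(education, crt_accuracy))
}

# ---- rater reliability ----------------------------------------------------

#' Two-way random-effects intraclass correlation (absolute agreement)
#'
#' ICC(2,1) estimates absolute agreement for single raters; ICC(2,k) the
#' reliability of the mean of the k raters. Computed from the two-way ANOVA
#' mean squares (subjects and raters both random).
#'
#' @param ratings Numeric matrix, subjects x raters, complete.
#' @param form `"single"` for ICC(2,1), `"average"` for ICC(2,k).
#' @return The ICC estimate; `NA` (with a warning) for a constant table.
#' @export
icc <- function(ratings, form = c("single", "average")) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop_config("need >= 2 subjects and >= 2 raters")
  if (anyNA(ratings)) stop_config("ratings table must be complete")
  if (stats::var(as.vector(ratings)) == 0) {
    warning("constant ratings table: ICC undefined")
    return(NA_real_)
  }
  df <- data.frame(score = as.vector(ratings),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  # only the mean squares are used; the F tests (unreliable on a perfect
  # fit) are discarded
  ms <- suppressWarnings(
    stats::anova(stats::aov(score ~ subject + rater, data = df)))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  if (form == "single")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (msc - mse) / n)
}
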