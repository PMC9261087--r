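#' Synthetic-cohort generator configuration
#'
#' Defines a two-group cohort of annotated transcripts with tunable
#' graph-level effects. Defaults emulate the scale of the clinical study the
#' methodology targets: 81 PS+ and 124 PS- participants, three picture
#' description and two open-ended narrative responses each, roughly ten
#' tokens per utterance, with picture responses averaging ~11 utterances
#' (~110 words) and narratives ~16 (~162 words). Content vocabulary is
#' Zipf-distributed. Case-group effects act through a per-participant
#' severity latent: vocabulary shrinkage (smaller effective lexicon, hence
#' smaller graphs) and repetition inflation (more perseverative lemma
#' reuse). Clinical scores are linear-Gaussian in the severity latent, so
#' features causally tied to the knobs correlate with the scores.
#'
#' @param n_case,n_control Participants per group (PS+ / PS-).
#' @param responses_per_task Named integer vector, responses per task.
#' @param utterances_mean Named numeric vector, mean utterances per response
#'   by task.
#' @param frames_mean Mean SRL frames (clauses) per utterance.
#' @param n_nouns,n_verbs Content-vocabulary sizes.
#' @param zipf_exponent Zipf rank-frequency exponent of the content lexicon.
#' @param p_a0,p_a1,p_a2 Presence probability of each core argument per
#'   frame.
#' @param p_compound Probability an argument is a two-noun compound.
#' @param p_interjection Probability an utterance opens with a filled pause.
#' @param repetition_rate Probability the next content lemma repeats a
#'   recently used one instead of a fresh draw.
#' @param vocab_shrink Case-group multiplier (< 1 shrinks the effective
#'   vocabulary; 1 disables the effect).
#' @param repetition_inflation Case-group multiplier on `repetition_rate`
#'   (1 disables).
#' @param severity_mean_case,severity_sd Severity latent: cases draw
#'   `N(severity_mean_case, severity_sd)`, controls `N(0, severity_sd)`
#'   (clamped to `[0, 1.5]` when applied to the knobs).
#' @param score_model Named list of `c(intercept, slope, noise_sd)` per
#'   clinical scale.
#' @param seed Master seed; all generator randomness flows from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_case = 81L, n_control = 124L,
                             responses_per_task = c(picture = 3L, narrative = 2L),
                             utterances_mean = c(picture = 11, narrative = 16),
                             frames_mean = 2,
                             n_nouns = 200L, n_verbs = 50L,
                             zipf_exponent = 1.0,
                             p_a0 = 0.9, p_a1 = 0.8, p_a2 = 0.15,
                             p_compound = 0.1, p_interjection = 0.2,
                             repetition_rate = 0.08,
                             vocab_shrink = 0.7,
                             repetition_inflation = 1.75,
                             severity_mean_case = 1, severity_sd = 0.25,
                             score_model = list(
                               BPRS = c(intercept = 22, slope = 20, noise_sd = 4),
                               SANS = c(intercept = 4, slope = 26, noise_sd = 4.5),
                               TLC = c(intercept = 4, slope = 12, noise_sd = 5)),
                             seed = 1L) {
  stopifnot(all(c(p_a0, p_a1, p_a2, p_compound, p_interjection,
                  repetition_rate) >= 0),
            all(c(p_a0, p_a1, p_a2, p_compound, p_interjection,
                  repetition_rate) <= 1),
            n_case >= 1L, n_control >= 1L,
            n_nouns >= 1L, n_verbs >= 1L, frames_mean >= 1,
            all(utterances_mean >= 1), vocab_shrink > 0, vocab_shrink <= 1,
            repetition_inflation >= 1)
  structure(as.list(environment()), class = "generator_config")
}

# Zipf rank-frequency weights over a vocabulary of size v.
.zipf_probs <- function(v, s) {
  p <- (seq_len(v))^(-s)
  p / sum(p)
}

# Draw one lemma: with prob rep_rate reuse a recent lemma of this category,
# else a fresh Zipf draw. `recent` is a character vector (may be empty).
.draw_lemma <- function(vocab, probs, recent, rep_rate) {
  if (length(recent) && stats::runif(1) < rep_rate) {
    sample(recent, 1L)
  } else {
    vocab[sample.int(length(vocab), 1L, prob = probs)]
  }
}

#' Per-participant generation parameters
#'
#' Applies the group-effect multipliers of a [generator_config()] at a given
#' severity, yielding the concrete sampling parameters for one participant's
#' responses.
#'
#' @param config A [generator_config()].
#' @param severity Severity latent (effects scale with `clamp(severity, 0, 1.5)`).
#' @return List of response-generation parameters.
#' @export
participant_params <- function(config, severity = 0) {
  sev <- min(max(severity, 0), 1.5)
  shrink <- 1 - (1 - config$vocab_shrink) * sev
  rep_rate <- min(1, config$repetition_rate *
                    (1 + (config$repetition_inflation - 1) * sev))
  n_nouns <- max(1L, as.integer(round(config$n_nouns * shrink)))
  n_verbs <- max(1L, as.integer(round(config$n_verbs * shrink)))
  list(frames_mean = config$frames_mean,
       nouns = sprintf("n%03d", seq_len(n_nouns)),
       verbs = sprintf("v%03d", seq_len(n_verbs)),
       noun_probs = .zipf_probs(n_nouns, config$zipf_exponent),
       verb_probs = .zipf_probs(n_verbs, config$zipf_exponent),
       p_a0 = config$p_a0, p_a1 = config$p_a1, p_a2 = config$p_a2,
       p_compound = config$p_compound,
       p_interjection = config$p_interjection,
       repetition_rate = rep_rate)
}

# One clause: [DET noun(A0)] verb [DET noun(A1)] [ADP DET noun(A2)],
# each argument present with its configured probability, arguments
# occasionally two-noun compounds. Returns token rows and one frame spec
# with spans relative to the clause start.
.gen_clause <- function(params, recent) {
  surface <- character(); pos <- character()
  args <- list()
  draw_noun <- function() {
    lem <- .draw_lemma(params$nouns, params$noun_probs, recent$nouns,
                       params$repetition_rate)
    recent$nouns <<- utils::tail(c(recent$nouns, lem), 5L)
    lem
  }
  add_arg <- function(label, prep = NULL) {
    start <- length(surface)
    if (!is.null(prep)) { surface <<- c(surface, prep); pos <<- c(pos, "ADP") }
    surface <<- c(surface, "the"); pos <<- c(pos, "DET")
    n_heads <- if (stats::runif(1) < params$p_compound) 2L else 1L
    for (k in seq_len(n_heads)) {
      surface <<- c(surface, draw_noun()); pos <<- c(pos, "NOUN")
    }
    args[[label]] <<- c(start, length(surface))
  }
  if (stats::runif(1) < params$p_a0) add_arg("A0")
  verb <- .draw_lemma(params$verbs, params$verb_probs, recent$verbs,
                      params$repetition_rate)
  recent$verbs <- utils::tail(c(recent$verbs, verb), 5L)
  pred_start <- length(surface)
  surface <- c(surface, "is", verb); pos <- c(pos, "AUX", "VERB")
  pred_span <- c(pred_start + 1L, pred_start + 2L)
  if (stats::runif(1) < params$p_a1) add_arg("A1")
  if (stats::runif(1) < params$p_a2) add_arg("A2", prep = "to")
  list(surface = surface, pos = pos, pred_span = pred_span,
       pred_lemma = verb, args = args, recent = recent)
}

#' Generate one synthetic response
#'
#' Consumes the global RNG stream (seed it upstream; [generate_cohort()]
#' does). Utterance counts are `1 + Poisson(mean - 1)`; each utterance is a
#' sequence of verb clauses with determiner/auxiliary function words, an
#' optional opening filled pause, and one SRL frame per clause whose
#' predicate and argument spans point at the generated tokens. Surface forms
#' equal lemmas (graph construction consumes lemmas only).
#'
#' @param params Output of [participant_params()].
#' @param participant_id,task,prompt_id Response identity.
#' @param n_utterances_mean Mean utterances for this response.
#' @return A [speech_response()].
#' @export
generate_response <- function(params, participant_id = "p1",
                              task = "picture", prompt_id = "1",
                              n_utterances_mean = 11) {
  n_utt <- 1L + stats::rpois(1L, max(0, n_utterances_mean - 1))
  recent <- list(nouns = character(), verbs = character())
  utts <- vector("list", n_utt)
  for (ui in seq_len(n_utt)) {
    surface <- character(); pos <- character(); frames <- list()
    if (stats::runif(1) < params$p_interjection) {
      surface <- "um"; pos <- "INTJ"
    }
    n_frames <- 1L + stats::rpois(1L, max(0, params$frames_mean - 1))
    for (fi in seq_len(n_frames)) {
      cl <- .gen_clause(params, recent)
      recent <- cl$recent
      offset <- length(surface)
      surface <- c(surface, cl$surface)
      pos <- c(pos, cl$pos)
      frames[[fi]] <- srl_frame(cl$pred_span + offset, cl$pred_lemma,
                                lapply(cl$args, function(sp) sp + offset))
    }
    utts[[ui]] <- speech_utterance(ui - 1L,
                                   speech_tokens(surface, pos = pos),
                                   frames)
  }
  speech_response(participant_id, task, prompt_id, utts)
}

#' Generate a full two-group synthetic cohort
#'
#' PS+ participants draw their severity latent around
#' `severity_mean_case`, PS- around 0; the group-effect knobs and the
#' clinical scores both derive from that latent, so graph features causally
#' linked to the knobs correlate with the scores. Fully deterministic given
#' `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A validated [speech_corpus()].
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  .with_seed(config$seed, {
    ids <- c(sprintf("case%03d", seq_len(config$n_case)),
             sprintf("ctrl%03d", seq_len(config$n_control)))
    groups <- rep(c("PS+", "PS-"), c(config$n_case, config$n_control))
    severity <- stats::rnorm(length(ids),
                             mean = ifelse(groups == "PS+",
                                           config$severity_mean_case, 0),
                             sd = config$severity_sd)
    participants <- data.frame(participant_id = ids, group = groups,
                               stringsAsFactors = FALSE)
    for (sc in names(config$score_model)) {
      m <- config$score_model[[sc]]
      participants[[sc]] <- m[["intercept"]] + m[["slope"]] * severity +
        stats::rnorm(length(ids), 0, m[["noise_sd"]])
    }
    responses <- list()
    for (i in seq_along(ids)) {
      params <- participant_params(config, severity[i])
      for (task in names(config$responses_per_task)) {
        for (p in seq_len(config$responses_per_task[[task]])) {
          responses[[length(responses) + 1L]] <-
            generate_response(params, ids[i], task, as.character(p),
                              config$utterances_mean[[task]])
        }
      }
    }
    speech_corpus(responses, participants)
  })
}

#' Collinear feature matrix with known redundancy structure
#'
#' Builds a matrix of independent standard-normal columns plus
#' linear-combination columns with additive Gaussian noise, so population
#' VIFs are available in closed form: for a combination `sum(a_j * f_j) +
#' N(0, sd^2)` of independent standard normals, `R2 = sum(a^2) / (sum(a^2) +
#' sd^2)` and `VIF = 1 / (1 - R2)`. Used to exercise the VIF pruning
#' protocol against known ground truth.
#'
#' @param n_rows Number of rows.
#' @param independent Names of independent standard-normal columns.
#' @param combos List of `list(name, of, coefs, noise_sd)` combination
#'   specs (`of` names existing independent columns).
#' @param seed Integer seed.
#' @return Numeric matrix with attribute `population_vif` (named, combination
#'   columns only).
#' @export
collinear_matrix <- function(n_rows, independent = c("f1", "f2"),
                             combos = list(), seed = 1L) {
  .with_seed(seed, {
    x <- matrix(stats::rnorm(n_rows * length(independent)), nrow = n_rows,
                dimnames = list(NULL, independent))
    pop <- numeric(0)
    for (cb in combos) {
      lin <- as.vector(x[, cb$of, drop = FALSE] %*% cb$coefs)
      col <- lin + stats::rnorm(n_rows, 0, cb$noise_sd)
      x <- cbind(x, stats::setNames(data.frame(col), cb$name))
      r2 <- sum(cb$coefs^2) / (sum(cb$coefs^2) + cb$noise_sd^2)
      pop[cb$name] <- 1 / (1 - r2)
    }
    x <- as.matrix(x)
    attr(x, "population_vif") <- pop
    x
  })
}
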