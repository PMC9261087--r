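# Shared fixtures: the cookie-jar worked example and the two-frame
# picture-description example, built in code.

cookie_utterance <- function() {
  tok <- speech_tokens(
    surface = c("The", "kid", "is", "grabbing", "the", "cookie", "jar"),
    lemma   = c("the", "kid", "be", "grab", "the", "cookie", "jar"),
    pos     = c("DET", "NOUN", "AUX", "VERB", "DET", "NOUN", "NOUN"))
  speech_utterance(0L, tok, list(
    srl_frame(c(3L, 4L), "grab", list(A0 = c(0L, 2L), A1 = c(4L, 7L)))))
}

chair_utterance <- function(id = 0L) {
  tok <- speech_tokens(
    surface = c("I", "see", "a", "chair"),
    lemma   = c("i", "see", "a", "chair"),
    pos     = c("PRON", "VERB", "DET", "NOUN"))
  speech_utterance(id, tok, list(
    srl_frame(c(1L, 2L), "see", list(A0 = c(0L, 1L), A1 = c(2L, 4L)))))
}

cookie_response <- function() {
  speech_response("p1", "picture", "1", list(cookie_utterance()))
}

# the two-frame example: "I see a chair." + "The kid is grabbing the
# cookie jar." -> 6 semantic nodes, 6 semantic edges
two_frame_utterances <- function() {
  cu <- cookie_utterance()
  cu$utterance_id <- 1L
  list(chair_utterance(0L), cu)
}

two_frame_response <- function() {
  speech_response("p1", "picture", "1", two_frame_utterances())
}

tiny_participants <- function(ids = "p1", group = "PS-") {
  data.frame(participant_id = ids, group = rep_len(group, length(ids)),
             BPRS = rep_len(20, length(ids)), stringsAsFactors = FALSE)
}

tiny_corpus <- function() {
  speech_corpus(list(cookie_response()), tiny_participants())
}

# a response with a configurable content-lemma sequence (each lemma one
# NOUN token, one utterance)
lemma_response <- function(lemmas, task = "picture", participant_id = "p1",
                           prompt_id = "1") {
  tok <- speech_tokens(lemmas, lemmas, rep("NOUN", length(lemmas)))
  speech_response(participant_id, task, prompt_id,
                  list(speech_utterance(0L, tok)))
}

fast_config <- function(...) {
  pipeline_config(replicates = 0L, seed = 42L, ...)
}
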