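# Universal POS tagset (UD v2). Content classes follow the word-class lists
# used for structural graph entry: nouns, pronouns, non-auxiliary verbs,
# adjectives, adverbs.
UNIVERSAL_POS <- c("ADJ", "ADP", "ADV", "AUX", "CCONJ", "DET", "INTJ", "NOUN",
                   "NUM", "PART", "PRON", "PROPN", "PUNCT", "SCONJ", "SYM",
                   "VERB", "X")
CONTENT_POS <- c("NOUN", "PROPN", "PRON", "VERB", "ADJ", "ADV")
CORE_ARG_LABELS <- c("A0", "A1", "A2")

#' Default filled-pause stoplist
#'
#' Lexical stoplist applied on top of the `INTJ` POS exclusion when selecting
#' content tokens. Transcription conventions vary in how filled pauses are
#' tagged, so common fillers are also excluded by lemma. Whether real corpora
#' mark fillers beyond the interjection tag is transcription-dependent; this
#' default is a conservative guess and fully overridable wherever a
#' `stoplist` argument is accepted.
#'
#' @return Character vector of lowercased filler lemmas.
#' @export
filled_pauses <- function() {
  c("um", "uh", "uhm", "er", "erm", "hmm", "mhm", "mm", "uh-huh", "huh")
}

#' Construct a token table
#'
#' Tokens are stored per utterance as a data frame with one row per token.
#' `index` is the 0-based position of the token within its utterance; span
#' references in SRL frames are expressed in these indices.
#'
#' @param surface Character vector of surface forms.
#' @param lemma Character vector of lowercased lemmas.
#' @param pos Character vector of universal POS tags.
#' @return A `data.frame` with columns `surface`, `lemma`, `pos`, `index`.
#' @export
speech_tokens <- function(surface, lemma = tolower(surface), pos) {
  stopifnot(length(surface) == length(lemma), length(surface) == length(pos))
  data.frame(surface = as.character(surface),
             lemma = tolower(as.character(lemma)),
             pos = as.character(pos),
             index = seq_along(surface) - 1L,
             stringsAsFactors = FALSE)
}

#' Construct an SRL frame
#'
#' A frame records one verb predicate and its core arguments (PropBank
#' A0/A1/A2) as token-index spans within the owning utterance. Spans are
#' 0-based and end-exclusive.
#'
#' @param predicate Integer span `c(start, end)` of the predicate.
#' @param predicate_lemma Lemma of the predicate head verb.
#' @param args Named list of spans; names restricted to `A0`, `A1`, `A2`.
#' @return A list of class `srl_frame`.
#' @export
srl_frame <- function(predicate, predicate_lemma, args = list()) {
  if (length(args)) {
    bad <- setdiff(names(args), CORE_ARG_LABELS)
    if (length(bad)) {
      stop("frame argument labels must be one of A0/A1/A2, got: ",
           paste(bad, collapse = ", "))
    }
    if (anyDuplicated(names(args))) {
      stop("at most one span per argument label per frame")
    }
  }
  structure(list(predicate = as.integer(predicate),
                 predicate_lemma = tolower(as.character(predicate_lemma)),
                 args = lapply(args, as.integer)),
            class = "srl_frame")
}

#' Construct an utterance
#'
#' @param utterance_id 0-based ordinal of the utterance within its response.
#' @param tokens Token table from [speech_tokens()].
#' @param frames List of [srl_frame()] objects.
#' @return A list of class `speech_utterance`.
#' @export
speech_utterance <- function(utterance_id, tokens, frames = list()) {
  structure(list(utterance_id = as.integer(utterance_id),
                 tokens = tokens, frames = frames),
            class = "speech_utterance")
}

#' Construct a response
#'
#' One elicited speech sample: a participant's ordered utterances in reply to
#' a single prompt of a given task type (`picture` description or open-ended
#' `narrative`).
#'
#' @param participant_id Participant identifier.
#' @param task `"picture"` or `"narrative"`.
#' @param prompt_id Prompt identifier within the task.
#' @param utterances Ordered list of [speech_utterance()] objects.
#' @return A list of class `speech_response`.
#' @export
speech_response <- function(participant_id, task, prompt_id, utterances) {
  task <- match.arg(task, c("picture", "narrative"))
  structure(list(participant_id = as.character(participant_id),
                 task = task,
                 prompt_id = as.character(prompt_id),
                 utterances = utterances),
            class = "speech_response")
}

#' Construct a corpus
#'
#' @param responses List of [speech_response()] objects.
#' @param participants Data frame with columns `participant_id`, `group`
#'   (`"PS+"`/`"PS-"`), and any number of numeric clinical-score columns.
#' @param validate Run [validate_corpus()] on the result?
#' @return A list of class `speech_corpus`.
#' @export
speech_corpus <- function(responses, participants, validate = TRUE) {
  x <- structure(list(responses = responses, participants = participants),
                 class = "speech_corpus")
  if (validate) validate_corpus(x)
  x
}

#' @export
print.speech_corpus <- function(x, ...) {
  tasks <- vapply(x$responses, function(r) r$task, character(1))
  cat("<speech_corpus> ", nrow(x$participants), " participants, ",
      length(x$responses), " responses (",
      sum(tasks == "picture"), " picture, ",
      sum(tasks == "narrative"), " narrative)\n", sep = "")
  invisible(x)
}

.check_span <- function(span, n_tokens, what, where) {
  if (length(span) != 2L || anyNA(span)) {
    stop("malformed ", what, " span in ", where, call. = FALSE)
  }
  if (span[1] < 0L || span[2] > n_tokens || span[1] >= span[2]) {
    stop(what, " span [", span[1], ",", span[2], ") outside utterance of ",
         n_tokens, " tokens in ", where, call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a corpus against the schema invariants
#'
#' Checks token index consecutiveness, utterance ordering, span containment,
#' argument-label restrictions, task labels, and participant-table coverage.
#' Errors name the offending response/utterance/field.
#'
#' @param corpus A [speech_corpus()].
#' @return Invisibly `TRUE`; otherwise an error.
#' @export
validate_corpus <- function(corpus) {
  p <- corpus$participants
  if (!is.data.frame(p) || !all(c("participant_id", "group") %in% names(p))) {
    stop("participants must be a data frame with participant_id and group")
  }
  for (resp in corpus$responses) {
    where0 <- paste0("response(participant=", resp$participant_id,
                     ", task=", resp$task, ", prompt=", resp$prompt_id, ")")
    if (!resp$participant_id %in% p$participant_id) {
      stop("participant ", resp$participant_id,
           " has responses but no participant-table row")
    }
    if (!resp$task %in% c("picture", "narrative")) {
      stop("unknown task '", resp$task, "' in ", where0)
    }
    if (!length(resp$utterances)) stop("no utterances in ", where0)
    ids <- vapply(resp$utterances, function(u) u$utterance_id, integer(1))
    if (!identical(ids, seq_along(ids) - 1L)) {
      stop("utterance_ids not consecutive from 0 in ", where0)
    }
    for (u in resp$utterances) {
      where <- paste0(where0, " utterance ", u$utterance_id)
      tok <- u$tokens
      if (nrow(tok)) {
        if (!identical(as.integer(tok$index), seq_len(nrow(tok)) - 1L)) {
          stop("token indices not consecutive from 0 in ", where)
        }
        nonempty <- nzchar(tok$surface)
        if (any(nonempty & !nzchar(tok$lemma))) {
          stop("empty lemma for non-empty surface in ", where)
        }
      }
      for (fr in u$frames) {
        .check_span(fr$predicate, nrow(tok), "predicate", where)
        if (length(fr$args)) {
          bad <- setdiff(names(fr$args), CORE_ARG_LABELS)
          if (length(bad)) {
            stop("argument labels outside A0/A1/A2 (", paste(bad, collapse = ","),
                 ") in ", where)
          }
          for (lab in names(fr$args)) {
            .check_span(fr$args[[lab]], nrow(tok), lab, where)
          }
        }
      }
    }
  }
  invisible(TRUE)
}

.frame_to_list <- function(fr) {
  list(predicate = fr$predicate, predicate_lemma = fr$predicate_lemma,
       args = fr$args)
}

#' Write a corpus to its JSON transcript schema
#'
#' The on-disk schema is a single JSON document with `participants` (id,
#' group, clinical score map) and `responses` (participant_id, task,
#' prompt_id, utterances with token and frame records; spans 0-based,
#' end-exclusive). [read_corpus()] inverts it exactly.
#'
#' @param corpus A [speech_corpus()].
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_corpus <- function(corpus, path) {
  p <- corpus$participants
  score_cols <- setdiff(names(p), c("participant_id", "group"))
  parts <- lapply(seq_len(nrow(p)), function(i) {
    scores <- as.list(p[i, score_cols, drop = FALSE])
    list(id = p$participant_id[i], group = p$group[i], scores = scores)
  })
  resps <- lapply(corpus$responses, function(r) {
    list(participant_id = r$participant_id, task = r$task,
         prompt_id = r$prompt_id,
         utterances = lapply(r$utterances, function(u) {
           list(utterance_id = u$utterance_id,
                tokens = lapply(seq_len(nrow(u$tokens)), function(j) {
                  list(surface = u$tokens$surface[j],
                       lemma = u$tokens$lemma[j],
                       pos = u$tokens$pos[j],
                       index = u$tokens$index[j])
                }),
                frames = lapply(u$frames, .frame_to_list))
         }))
  })
  jsonlite::write_json(list(participants = parts, responses = resps), path,
                       auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read a corpus from the JSON transcript schema
#'
#' @param path Path to a transcript JSON document (see [write_corpus()]).
#' @return A validated [speech_corpus()].
#' @export
read_corpus <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("parse error reading '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (is.null(doc$participants)) stop("transcript document lacks participants")
  score_names <- unique(unlist(lapply(doc$participants,
                                      function(pp) names(pp$scores))))
  participants <- data.frame(
    participant_id = vapply(doc$participants, function(pp)
      as.character(pp$id), character(1)),
    group = vapply(doc$participants, function(pp)
      as.character(pp$group), character(1)),
    stringsAsFactors = FALSE)
  for (sc in score_names) {
    participants[[sc]] <- vapply(doc$participants, function(pp) {
      v <- pp$scores[[sc]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  responses <- lapply(doc$responses, function(r) {
    utts <- lapply(r$utterances, function(u) {
      toks <- u$tokens
      tok <- if (length(toks)) {
        data.frame(
          surface = vapply(toks, function(t) as.character(t$surface), character(1)),
          lemma = vapply(toks, function(t) as.character(t$lemma), character(1)),
          pos = vapply(toks, function(t) as.character(t$pos), character(1)),
          index = vapply(toks, function(t) as.integer(t$index), integer(1)),
          stringsAsFactors = FALSE)
      } else {
        data.frame(surface = character(), lemma = character(),
                   pos = character(), index = integer())
      }
      frames <- lapply(u$frames, function(fr) {
        srl_frame(unlist(fr$predicate), fr$predicate_lemma,
                  lapply(fr$args, unlist))
      })
      speech_utterance(u$utterance_id, tok, frames)
    })
    speech_response(r$participant_id, r$task, r$prompt_id, utts)
  })
  speech_corpus(responses, participants, validate = TRUE)
}

#' Read a CoNLL-style column file into utterances
#'
#' Minimal column reader: one token per line (`surface lemma pos`, whitespace
#' separated), utterances separated by blank lines. Produces utterances with
#' empty frame lists; intended for plain sequential-graph workflows.
#'
#' @param path File path.
#' @return List of [speech_utterance()] objects.
#' @export
read_conll_utterances <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  utts <- list()
  uid <- 0L
  for (b in blocks) {
    b <- b[nzchar(trimws(b)) & !startsWith(trimws(b), "#")]
    if (!length(b)) next
    fields <- strsplit(trimws(b), "\\s+")
    bad <- which(lengths(fields) < 3L)
    if (length(bad)) {
      stop("malformed CoNLL record (need surface lemma pos): '",
           b[bad[1]], "'")
    }
    tok <- speech_tokens(
      surface = vapply(fields, `[[`, character(1), 1L),
      lemma = vapply(fields, `[[`, character(1), 2L),
      pos = vapply(fields, `[[`, character(1), 3L))
    utts[[length(utts) + 1L]] <- speech_utterance(uid, tok)
    uid <- uid + 1L
  }
  utts
}

.content_mask <- function(tokens, stoplist = filled_pauses(),
                          unknown_pos = c("warn", "error")) {
  unknown_pos <- match.arg(unknown_pos)
  if (!nrow(tokens)) return(logical(0))
  unk <- !(tokens$pos %in% UNIVERSAL_POS)
  if (any(unk)) {
    msg <- paste0("unknown POS tag(s): ",
                  paste(unique(tokens$pos[unk]), collapse = ", "))
    if (unknown_pos == "error") stop(msg, call. = FALSE)
    warning(msg, "; excluding those tokens", call. = FALSE)
  }
  tokens$pos %in% CONTENT_POS & !(tolower(tokens$lemma) %in% stoplist)
}

#' Content-lemma sequence of a response
#'
#' Applies the content-word filter (nouns, proper nouns, pronouns,
#' non-auxiliary verbs, adjectives, adverbs; auxiliaries carry the `AUX` tag
#' and are excluded, as are determiners, adpositions, conjunctions,
#' interjections and the filled-pause stoplist) and concatenates the
#' surviving lowercased lemmas across utterances in order. Structural graphs
#' are built on this one cross-utterance sequence, ignoring utterance
#' boundaries.
#'
#' @param response A [speech_response()].
#' @param stoplist Lexical exclusion list, by lemma (see [filled_pauses()]).
#' @param unknown_pos `"warn"` (exclude with a warning, default) or `"error"`.
#' @return Character vector of lemmas.
#' @export
content_lemmas <- function(response, stoplist = filled_pauses(),
                           unknown_pos = c("warn", "error")) {
  unknown_pos <- match.arg(unknown_pos)
  out <- lapply(response$utterances, function(u) {
    keep <- .content_mask(u$tokens, stoplist, unknown_pos)
    tolower(u$tokens$lemma[keep])
  })
  as.character(unlist(out))
}

#' Node label for an argument span
#'
#' Content-filters and lemmatizes the span, joining surviving lemmas with
#' single spaces (so multiword arguments like "the cookie jar" become the
#' node `"cookie jar"`). If filtering removes every token, the lemmatized
#' full span is used instead, so every tagged argument yields a node.
#'
#' @param span Integer `c(start, end)`, 0-based, end-exclusive.
#' @param utterance A [speech_utterance()].
#' @param stoplist Lexical exclusion list.
#' @return Single non-empty label string.
#' @export
argument_label <- function(span, utterance, stoplist = filled_pauses()) {
  span <- as.integer(span)
  if (length(span) != 2L || span[1] >= span[2]) stop("empty or malformed span")
  .check_span(span, nrow(utterance$tokens), "argument",
              paste0("utterance ", utterance$utterance_id))
  idx <- (span[1] + 1L):span[2]
  lemma <- tolower(utterance$tokens$lemma[idx])
  pos <- utterance$tokens$pos[idx]
  keep <- pos %in% CONTENT_POS & !(lemma %in% stoplist)
  lem <- lemma[keep]
  if (!length(lem)) lem <- lemma
  paste(lem, collapse = " ")
}

#' Annotate plain text through a pluggable SRL backend
#'
#' The core pipeline consumes pre-annotated transcripts; this adapter lets a
#' tokenizer/POS-tagger/semantic-role-labeler backend (e.g. an external
#' PropBank-style model) produce the same utterance objects. The annotator is
#' any function `function(text) -> list of speech_utterance`. Frames with
#' argument labels outside A0/A1/A2 (adjunct arguments such as AM-TMP, or
#' higher-numbered core arguments) have those labels dropped with a warning;
#' the frame itself is retained.
#'
#' @param text Character scalar of raw text.
#' @param annotator Backend function satisfying the contract above.
#' @return List of validated [speech_utterance()] objects.
#' @export
annotate_plaintext <- function(text, annotator) {
  utts <- annotator(text)
  lapply(utts, function(u) {
    u$frames <- lapply(u$frames, function(fr) {
      labs <- names(fr$args)
      drop <- setdiff(labs, CORE_ARG_LABELS)
      if (length(drop)) {
        warning("dropping non-core argument label(s): ",
                paste(drop, collapse = ", "), call. = FALSE)
        fr$args <- fr$args[setdiff(labs, drop)]
      }
      srl_frame(fr$predicate, fr$predicate_lemma, fr$args)
    })
    u
  })
}
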