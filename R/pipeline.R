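#' Moving-window specification
#'
#' Dynamic features control for speech quantity by sliding a fixed-length
#' window through each sample. Structural graphs use token windows over the
#' cross-utterance content-lemma sequence (default 30 lemmas, step 1);
#' semantic graphs use utterance windows (default 3 utterances, step 1,
#' chosen as the closest equivalent given a mean utterance length of roughly
#' ten words).
#'
#' @param unit `"tokens"` or `"utterances"`.
#' @param length Window length (>= 1).
#' @param step Slide increment (>= 1).
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(unit = c("tokens", "utterances"), length = 30L,
                        step = 1L) {
  unit <- match.arg(unit)
  stopifnot(length >= 1L, step >= 1L)
  structure(list(unit = unit, length = as.integer(length),
                 step = as.integer(step)),
            class = "window_spec")
}

.default_spec <- function(graph_type, config) {
  if (graph_type == "structural") {
    window_spec("tokens", config$window_tokens, config$token_step)
  } else {
    window_spec("utterances", config$window_utterances, config$utterance_step)
  }
}

#' Moving windows over a response
#'
#' Token windows slice the content-lemma sequence; utterance windows slice
#' the utterance list. Windows start at offsets `0, step, 2*step, ...` and
#' only full-length windows are emitted. A sample shorter than one window
#' yields exactly one window covering the whole sample, flagged
#' `short_sample`, rather than being dropped (no exclusion rule is imposed on
#' brief responses; the flag lets analyses exclude them).
#'
#' @param response A [speech_response()].
#' @param spec A [window_spec()].
#' @param stoplist Lexical exclusion list for the content filter.
#' @return List with elements `items` (list of lemma vectors or utterance
#'   lists), `short_sample` (logical), and `n_units`.
#' @export
windows <- function(response, spec, stoplist = filled_pauses()) {
  units <- if (spec$unit == "tokens") {
    content_lemmas(response, stoplist = stoplist)
  } else {
    response$utterances
  }
  n <- length(units)
  slice <- function(i, j) {
    if (spec$unit == "tokens") units[i:j] else units[i:j]
  }
  if (n < spec$length) {
    items <- if (n == 0L) list(if (spec$unit == "tokens") character() else list())
             else list(units)
    return(list(items = items, short_sample = TRUE, n_units = n))
  }
  starts <- seq.int(1L, n - spec$length + 1L, by = spec$step)
  items <- lapply(starts, function(s) slice(s, s + spec$length - 1L))
  list(items = items, short_sample = FALSE, n_units = n)
}

#' Pipeline configuration
#'
#' Bundles the knobs of feature extraction: baseline replicate count and
#' seed policy (see [metrics_config()]), window geometry, and the content
#' filter.
#'
#' @param replicates Random-baseline replicates per graph size (default
#'   1000; 0 skips z-scores).
#' @param seed Master seed.
#' @param baseline_seed_base See [metrics_config()].
#' @param window_tokens,token_step Structural window length and step.
#' @param window_utterances,utterance_step Semantic window length and step.
#' @param stoplist Filled-pause lexical stoplist.
#' @param unknown_pos Unknown-POS policy for the content filter.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(replicates = 1000L, seed = 1L,
                            baseline_seed_base = NULL,
                            window_tokens = 30L, token_step = 1L,
                            window_utterances = 3L, utterance_step = 1L,
                            stoplist = filled_pauses(),
                            unknown_pos = "warn") {
  structure(list(replicates = as.integer(replicates), seed = as.integer(seed),
                 baseline_seed_base = as.integer(
                   if (is.null(baseline_seed_base)) seed else baseline_seed_base),
                 window_tokens = as.integer(window_tokens),
                 token_step = as.integer(token_step),
                 window_utterances = as.integer(window_utterances),
                 utterance_step = as.integer(utterance_step),
                 stoplist = stoplist, unknown_pos = unknown_pos),
            class = "pipeline_config")
}

.metrics_cfg <- function(config) {
  metrics_config(replicates = config$replicates, seed = config$seed,
                 baseline_seed_base = config$baseline_seed_base)
}

.build_window_graph <- function(item, graph_type, config, provenance) {
  if (graph_type == "structural") {
    build_structural(item, provenance = provenance)
  } else {
    build_semantic(item, provenance = provenance, stoplist = config$stoplist)
  }
}

#' Static features of a response
#'
#' One graph over the whole response (structural: the full content-lemma
#' sequence; semantic: all utterances), then the nine-feature record.
#'
#' @param response A [speech_response()].
#' @param graph_type `"structural"` or `"semantic"`.
#' @param config A [pipeline_config()].
#' @return A `graph_features` object.
#' @export
static_features <- function(response, graph_type = c("structural", "semantic"),
                            config = pipeline_config()) {
  graph_type <- match.arg(graph_type)
  prov <- list(participant = response$participant_id, task = response$task,
               prompt = response$prompt_id, mode = "static")
  g <- if (graph_type == "structural") {
    build_structural(content_lemmas(response, stoplist = config$stoplist,
                                    unknown_pos = config$unknown_pos),
                     provenance = prov)
  } else {
    build_semantic(response$utterances, provenance = prov,
                   stoplist = config$stoplist)
  }
  compute_features(g, .metrics_cfg(config))
}

#' Dynamic (moving-window) features of a response
#'
#' Builds one graph per window, computes all nine metrics per window
#' (z-scores against each window's own (nn, ne) baseline), and returns the
#' arithmetic mean of every metric across windows. Flags are the union over
#' windows, plus `short_sample` when the response is shorter than one window.
#'
#' @param response A [speech_response()].
#' @param graph_type `"structural"` or `"semantic"`.
#' @param spec A [window_spec()]; defaults to the config's geometry for the
#'   graph type.
#' @param config A [pipeline_config()].
#' @return A `graph_features` object (window means).
#' @export
dynamic_features <- function(response, graph_type = c("structural", "semantic"),
                             spec = NULL, config = pipeline_config()) {
  graph_type <- match.arg(graph_type)
  if (is.null(spec)) spec <- .default_spec(graph_type, config)
  w <- windows(response, spec, stoplist = config$stoplist)
  mcfg <- .metrics_cfg(config)
  prov <- list(participant = response$participant_id, task = response$task,
               prompt = response$prompt_id, mode = "dynamic")
  feats <- if (graph_type == "semantic" && spec$unit == "utterances") {
    .semantic_window_features(response, w, mcfg, config$stoplist)
  } else if (graph_type == "structural" && spec$unit == "tokens") {
    .token_window_features(w, mcfg)
  } else {
    # mismatched unit override: build each window graph the generic way
    lapply(seq_along(w$items), function(i) {
      compute_features(
        .build_window_graph(w$items[[i]], graph_type, config,
                            c(prov, list(window = i))),
        mcfg)
    })
  }
  flags <- unique(c(unlist(lapply(feats, `[[`, "degenerate_flags")),
                    if (w$short_sample) "short_sample"))
  means <- lapply(METRIC_FIELDS, function(f) {
    mean(vapply(feats, function(x) as.numeric(x[[f]]), numeric(1)))
  })
  names(means) <- METRIC_FIELDS
  structure(c(means,
              list(degenerate_flags = flags,
                   provenance = c(prov, list(n_windows = length(feats))))),
            class = "graph_features")
}

# Window features over integer-coded lemma sequences: identical definitions
# to build_structural() + compute_features(), minus container overhead.
.token_window_features <- function(w, mcfg) {
  wins <- lapply(w$items, function(lem) {
    n <- length(lem)
    if (n == 0L) {
      return(list(nn = 0L, ifrom = integer(), ito = integer(), w = integer()))
    }
    ids <- match(lem, unique(lem))
    nn <- max(ids)
    if (n >= 2L) {
      f <- ids[-n]; t <- ids[-1L]
      keep <- f != t
      e <- .tally_pairs(f[keep], t[keep], nn)
    } else {
      e <- list(ifrom = integer(), ito = integer(), w = integer())
    }
    list(nn = nn, ifrom = e$ifrom, ito = e$ito, w = e$w)
  })
  lapply(.window_basics_batch(wins), .features_with_z, config = mcfg)
}

# Semantic windows: argument labels are window-invariant, so each
# utterance's relation multiset is derived once and pooled per window
# (weights are additive over scope).
.semantic_window_features <- function(response, w, mcfg, stoplist) {
  rel <- lapply(response$utterances, .semantic_relations, stoplist = stoplist)
  names(rel) <- vapply(response$utterances,
                       function(u) as.character(u$utterance_id), character(1))
  wins <- lapply(w$items, function(win) {
    ids <- vapply(win, function(u) as.character(u$utterance_id), character(1))
    from <- unlist(lapply(rel[ids], `[[`, "from"), use.names = FALSE)
    to <- unlist(lapply(rel[ids], `[[`, "to"), use.names = FALSE)
    nodes <- unique(unlist(lapply(rel[ids], `[[`, "nodes"), use.names = FALSE))
    nn <- length(nodes)
    if (nn == 0L) {
      return(list(nn = 0L, ifrom = integer(), ito = integer(), w = integer()))
    }
    f <- match(from, nodes); t <- match(to, nodes)
    keep <- f != t
    e <- .tally_pairs(f[keep], t[keep], nn)
    list(nn = nn, ifrom = e$ifrom, ito = e$ito, w = e$w)
  })
  lapply(.window_basics_batch(wins), .features_with_z, config = mcfg)
}

#' Canonical feature-column names
#'
#' The 36 feature columns of the participant-by-task table: 9 metrics x
#' {static (`S`), dynamic (`D`)} x {structural/sequential (`SEQ`),
#' semantic/action-predication (`AP`)}, e.g. `D_AP_LSCCZ`.
#'
#' @return Character vector of length 36.
#' @export
feature_columns <- function() {
  as.character(vapply(c("SEQ", "AP"), function(ty) {
    vapply(c("S", "D"), function(mo) paste(mo, ty, METRIC_NAMES, sep = "_"),
           character(length(METRIC_NAMES)))
  }, matrix(character(1), nrow = length(METRIC_NAMES), ncol = 2)))
}

.response_features <- function(response, config) {
  out <- numeric(0)
  flags <- character()
  for (ty in c("SEQ", "AP")) {
    gt <- if (ty == "SEQ") "structural" else "semantic"
    st <- static_features(response, gt, config)
    dy <- dynamic_features(response, gt, config = config)
    v <- c(vapply(METRIC_FIELDS, function(f) as.numeric(st[[f]]), numeric(1)),
           vapply(METRIC_FIELDS, function(f) as.numeric(dy[[f]]), numeric(1)))
    names(v) <- c(paste("S", ty, METRIC_NAMES, sep = "_"),
                  paste("D", ty, METRIC_NAMES, sep = "_"))
    out <- c(out, v)
    flags <- c(flags, st$degenerate_flags, dy$degenerate_flags)
  }
  list(values = out, flags = unique(flags))
}

#' Extract the participant-by-task feature table
#'
#' Runs graph formation and measurement separately for each response (static
#' and dynamic, structural and semantic), then averages feature-wise across
#' each participant's responses within each task category (unweighted mean).
#' Every (participant, task) pair with at least one response yields one row;
#' the 36 feature columns are always present. Responses producing empty
#' graphs contribute flagged zeros and are counted in `n_responses`.
#'
#' @param corpus A [speech_corpus()].
#' @param config A [pipeline_config()].
#' @param progress Emit one message per response?
#' @return Data frame with columns `participant_id`, `task`, `n_responses`,
#'   `flagged` (any degenerate/short-sample flag among the averaged
#'   responses), and the 36 columns of [feature_columns()].
#' @export
extract_all <- function(corpus, config = pipeline_config(), progress = FALSE) {
  cols <- feature_columns()
  key <- vapply(corpus$responses, function(r)
    paste(r$participant_id, r$task, sep = "\r"), character(1))
  groups <- split(seq_along(corpus$responses), key)
  # deterministic row order: participant-table order, picture before narrative
  ord <- order(match(vapply(strsplit(names(groups), "\r"), `[[`, character(1), 1),
                     corpus$participants$participant_id),
               vapply(strsplit(names(groups), "\r"), `[[`, character(1), 2))
  groups <- groups[ord]
  rows <- lapply(names(groups), function(k) {
    idx <- groups[[k]]
    pk <- strsplit(k, "\r")[[1]]
    feats <- lapply(idx, function(i) {
      if (progress) message("response ", i, " (", pk[1], ", ", pk[2], ")")
      .response_features(corpus$responses[[i]], config)
    })
    vals <- colMeans(do.call(rbind, lapply(feats, `[[`, "values")))
    flags <- unique(unlist(lapply(feats, `[[`, "flags")))
    cbind(data.frame(participant_id = pk[1], task = pk[2],
                     n_responses = length(idx),
                     flagged = length(flags) > 0L,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals[cols])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a feature table to CSV
#' @param features Output of [extract_all()].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
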