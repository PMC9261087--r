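# Baseline memoization: moving windows repeat (nn, ne) sizes heavily, so
# baselines are cached per (nn, ne, replicates, seed) for the session.
.baseline_cache <- new.env(parent = emptyenv())

#' Clear the memoized random-baseline cache
#' @return Invisibly the number of entries removed.
#' @export
clear_baseline_cache <- function() {
  n <- length(ls(.baseline_cache))
  rm(list = ls(.baseline_cache), envir = .baseline_cache)
  invisible(n)
}

#' Configuration for graph feature computation
#'
#' @param replicates Number of Erdős–Rényi random graphs per baseline
#'   (default 1000). `0` disables z-score computation: `lsccz`/`asplz` are
#'   reported as 0 with the `baseline_skipped` flag.
#' @param seed Master seed for all randomness.
#' @param baseline_seed_base Seed base from which per-size baseline seeds are
#'   derived (deterministic in `(baseline_seed_base, nn, ne)`). Defaults to
#'   `seed`. Kept separate so studies that vary the corpus seed can still
#'   share one memoized baseline per graph size: the null distribution for a
#'   given (nn, ne) does not depend on the data.
#' @param cache Memoize baselines within the session?
#' @return A list of class `metrics_config`.
#' @export
metrics_config <- function(replicates = 1000L, seed = 1L,
                           baseline_seed_base = NULL, cache = TRUE) {
  stopifnot(replicates >= 0, is.numeric(seed))
  structure(list(replicates = as.integer(replicates), seed = as.integer(seed),
                 baseline_seed_base = as.integer(
                   if (is.null(baseline_seed_base)) seed else baseline_seed_base),
                 cache = isTRUE(cache)),
            class = "metrics_config")
}

# Deterministic per-size seed; stays well below 2^31.
.derive_seed <- function(base, nn, ne) {
  as.integer((abs(as.numeric(base)) %% 1000003) * 2017 +
               nn * 131 + ne) %% 2147483629L
}

# Run code with a local RNG state so library calls never disturb the
# caller's stream.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Index-based igraph construction: same topology as as_igraph() without the
# name-attribute bookkeeping; metrics are label-free so this is safe.
.fast_digraph <- function(graph) {
  i <- match(graph$edges$from, graph$nodes)
  j <- match(graph$edges$to, graph$nodes)
  igraph::make_graph(as.vector(rbind(i, j)), n = length(graph$nodes),
                     directed = TRUE)
}

# ASPL and diameter over ordered node pairs with a finite directed path,
# self-pairs excluded; both 0 (with flag) when no such pair exists.
.path_stats <- function(ig) {
  n <- igraph::vcount(ig)
  if (n == 0L || igraph::ecount(ig) == 0L) {
    return(list(aspl = 0, diameter = 0, finite_pairs = 0L))
  }
  d <- igraph::distances(ig, mode = "out", weights = NA, algorithm = "unweighted")
  vals <- d[is.finite(d) & d > 0]
  if (!length(vals)) return(list(aspl = 0, diameter = 0, finite_pairs = 0L))
  list(aspl = mean(vals), diameter = max(vals), finite_pairs = length(vals))
}

.lscc_size <- function(ig) {
  if (igraph::vcount(ig) == 0L) return(0L)
  max(igraph::components(ig, mode = "strong")$csize)
}

#' Basic graph features (no z-scores)
#'
#' Computes the seven direct metrics of a speech graph: number of nodes
#' (`nn`), distinct directed edges (`ne`), `diameter` and average shortest
#' path length (`aspl`) as unweighted directed hop counts over ordered node
#' pairs with a finite path (self-pairs excluded; 0 with a flag when no pair
#' is reachable), average weighted degree `awd` = 2 * (total edge weight) /
#' nn, `density` = ne / (nn * (nn - 1)) for nn >= 2, and the node count of
#' the largest strongly connected component (`lscc`). The empty graph yields
#' all zeros with the `empty_graph` flag.
#'
#' @param graph A [speech_graph()].
#' @return Named list with the seven metrics and `degenerate_flags`.
#' @export
compute_basic <- function(graph) {
  stopifnot(inherits(graph, "speech_graph"))
  nn <- length(graph$nodes)
  ne <- nrow(graph$edges)
  flags <- character()
  if (nn == 0L) {
    return(list(nn = 0, ne = 0, diameter = 0, aspl = 0, awd = 0, density = 0,
                lscc = 0, degenerate_flags = "empty_graph"))
  }
  ig <- .fast_digraph(graph)
  ps <- .path_stats(ig)
  if (ps$finite_pairs == 0L) flags <- c(flags, "no_finite_pairs")
  list(nn = nn,
       ne = ne,
       diameter = ps$diameter,
       aspl = ps$aspl,
       awd = 2 * sum(graph$edges$weight) / nn,
       density = if (nn >= 2L) ne / (nn * (nn - 1)) else 0,
       lscc = .lscc_size(ig),
       degenerate_flags = flags)
}

#' Erdős–Rényi G(n, m) baseline for ASPL and LSCC
#'
#' Draws `replicates` directed G(n, m) random graphs (uniform over simple
#' digraphs with `nn` nodes and `ne` edges, no self-loops), computes ASPL and
#' LSCC per draw under the same finite-pairs conventions as
#' [compute_basic()], and returns their means and population (n-denominator)
#' standard deviations. Deterministic given `seed`; memoized per
#' `(nn, ne, replicates, seed)` when `cache` is `TRUE`.
#'
#' @param nn Node count (matched to the observed graph).
#' @param ne Edge count; must satisfy `0 <= ne <= nn * (nn - 1)`.
#' @param replicates Number of draws (>= 1).
#' @param seed Integer seed.
#' @param cache Use the session cache?
#' @return A list of class `random_baseline` with fields `nn`, `ne`,
#'   `replicates`, `seed`, `mean_aspl`, `sd_aspl`, `mean_lscc`, `sd_lscc`.
#' @export
random_baseline <- function(nn, ne, replicates = 1000L, seed = 1L,
                            cache = TRUE) {
  nn <- as.integer(nn); ne <- as.integer(ne)
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L)
  if (nn < 0L || ne < 0L || ne > nn * (nn - 1L)) {
    stop("edge count ", ne, " out of range for ", nn, " nodes")
  }
  key <- paste(nn, ne, replicates, seed, sep = "_")
  if (cache && !is.null(hit <- .baseline_cache[[key]])) return(hit)
  aspl <- numeric(replicates)
  lscc <- numeric(replicates)
  .with_seed(seed, {
    for (i in seq_len(replicates)) {
      g <- igraph::sample_gnm(nn, ne, directed = TRUE, loops = FALSE)
      ps <- .path_stats(g)
      aspl[i] <- ps$aspl
      lscc[i] <- .lscc_size(g)
    }
  })
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- structure(list(nn = nn, ne = ne, replicates = replicates,
                        seed = as.integer(seed),
                        mean_aspl = mean(aspl), sd_aspl = pop_sd(aspl),
                        mean_lscc = mean(lscc), sd_lscc = pop_sd(lscc)),
                   class = "random_baseline")
  if (cache) .baseline_cache[[key]] <- out
  out
}

#' Organization z-scores against a size-matched random baseline
#'
#' `z = (observed - baseline mean) / baseline sd`. A zero-variance baseline
#' (e.g. the complete digraph, where only one graph exists) yields `z = 0`
#' with a degeneracy flag rather than `NaN`, so downstream window averaging
#' stays defined.
#'
#' @param basic Output of [compute_basic()] for the observed graph.
#' @param baseline A [random_baseline()] with matching `nn` and `ne`.
#' @return List with `asplz`, `lsccz`, and `degenerate_flags`.
#' @export
zscores <- function(basic, baseline) {
  if (basic$nn != baseline$nn || basic$ne != baseline$ne) {
    stop("baseline size (", baseline$nn, ",", baseline$ne,
         ") does not match graph (", basic$nn, ",", basic$ne, ")")
  }
  flags <- character()
  z1 <- if (baseline$sd_aspl > 0) {
    (basic$aspl - baseline$mean_aspl) / baseline$sd_aspl
  } else {
    flags <- c(flags, "zero_sd_aspl"); 0
  }
  z2 <- if (baseline$sd_lscc > 0) {
    (basic$lscc - baseline$mean_lscc) / baseline$sd_lscc
  } else {
    flags <- c(flags, "zero_sd_lscc"); 0
  }
  list(asplz = z1, lsccz = z2, degenerate_flags = flags)
}

# Deduplicate an ordered-pair multiset (1-based codes) into weighted edges.
.tally_pairs <- function(ifrom, ito, nn) {
  code <- (ifrom - 1) * nn + ito
  uc <- unique(code)
  w <- tabulate(match(code, uc), nbins = length(uc))
  list(ifrom = as.integer((uc - 1) %/% nn + 1), ito = as.integer((uc - 1) %% nn + 1),
       w = as.integer(w))
}

# Batched window metrics: windows are packed as disjoint components of one
# igraph so the per-call overhead of distances()/components() is paid once
# per response, not once per window. Input: list of
# list(nn, ifrom, ito, w) with 1-based within-window node indices.
# Output: list of .basic_fast()-shaped records. Windows cannot reach each
# other in the union graph, so per-window distance blocks and strong
# components are exactly those of the isolated window graphs.
.window_basics_batch <- function(wins, max_batch_nodes = 2000L) {
  out <- vector("list", length(wins))
  todo <- seq_along(wins)
  # degenerate windows are handled directly
  for (i in todo) {
    if (wins[[i]]$nn == 0L) {
      out[[i]] <- list(nn = 0, ne = 0, diameter = 0, aspl = 0, awd = 0,
                       density = 0, lscc = 0, degenerate_flags = "empty_graph")
    }
  }
  todo <- todo[vapply(out[todo], is.null, logical(1))]
  while (length(todo)) {
    sizes <- vapply(wins[todo], function(x) x$nn, numeric(1))
    take <- which(cumsum(sizes) <= max(max_batch_nodes, sizes[1]))
    batch <- todo[take]
    todo <- todo[-take]
    nns <- vapply(wins[batch], function(x) x$nn, integer(1))
    offs <- c(0L, cumsum(nns))
    total <- offs[length(offs)]
    ef <- unlist(lapply(seq_along(batch), function(k)
      wins[[batch[k]]]$ifrom + offs[k]), use.names = FALSE)
    et <- unlist(lapply(seq_along(batch), function(k)
      wins[[batch[k]]]$ito + offs[k]), use.names = FALSE)
    ig <- igraph::make_graph(as.vector(rbind(ef, et)), n = total,
                             directed = TRUE)
    D <- igraph::distances(ig, mode = "out", weights = NA,
                           algorithm = "unweighted")
    comp <- igraph::components(ig, mode = "strong")
    for (k in seq_along(batch)) {
      i <- batch[k]
      nn <- nns[k]
      idx <- (offs[k] + 1L):(offs[k + 1L])
      ne <- length(wins[[i]]$ifrom)
      d <- D[idx, idx, drop = FALSE]
      vals <- d[is.finite(d) & d > 0]
      flags <- character()
      if (!length(vals)) flags <- "no_finite_pairs"
      out[[i]] <- list(
        nn = nn, ne = ne,
        diameter = if (length(vals)) max(vals) else 0,
        aspl = if (length(vals)) mean(vals) else 0,
        awd = 2 * sum(wins[[i]]$w) / nn,
        density = if (nn >= 2L) ne / (nn * (nn - 1)) else 0,
        lscc = max(tabulate(comp$membership[idx])),
        degenerate_flags = flags)
    }
  }
  out
}

# z-score assembly shared by compute_features() and the window fast path
.features_with_z <- function(basic, config) {
  flags <- basic$degenerate_flags
  if (config$replicates == 0L || basic$nn == 0L) {
    z <- list(asplz = 0, lsccz = 0)
    flags <- c(flags, if (config$replicates == 0L) "baseline_skipped")
  } else {
    bl <- random_baseline(basic$nn, basic$ne, config$replicates,
                          seed = .derive_seed(config$baseline_seed_base,
                                              basic$nn, basic$ne),
                          cache = config$cache)
    z <- zscores(basic, bl)
    flags <- c(flags, z$degenerate_flags)
  }
  structure(list(nn = basic$nn, ne = basic$ne, diameter = basic$diameter,
                 aspl = basic$aspl, awd = basic$awd, density = basic$density,
                 lscc = basic$lscc, lsccz = z$lsccz, asplz = z$asplz,
                 degenerate_flags = unique(flags),
                 provenance = NULL),
            class = "graph_features")
}

#' Full nine-feature record for one speech graph
#'
#' Combines [compute_basic()] with the organization z-scores from a
#' [random_baseline()] matched on (nn, ne). The baseline seed is derived
#' deterministically from `config$baseline_seed_base` and the graph size, so
#' results are reproducible and baselines are shared across same-sized
#' windows.
#'
#' @param graph A [speech_graph()].
#' @param config A [metrics_config()].
#' @return Object of class `graph_features`: the nine metrics plus
#'   `degenerate_flags` and `provenance`.
#' @export
compute_features <- function(graph, config = metrics_config()) {
  out <- .features_with_z(compute_basic(graph), config)
  out$provenance <- graph$provenance
  out
}

#' @export
print.graph_features <- function(x, ...) {
  v <- unlist(x[METRIC_FIELDS])
  cat("<graph_features>\n")
  print(round(v, 4))
  if (length(x$degenerate_flags)) {
    cat("flags:", paste(x$degenerate_flags, collapse = ", "), "\n")
  }
  invisible(x)
}

# canonical metric order used everywhere downstream
METRIC_FIELDS <- c("nn", "ne", "diameter", "aspl", "awd", "density",
                   "lscc", "lsccz", "asplz")
METRIC_NAMES <- toupper(METRIC_FIELDS)
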