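#' Mann–Whitney U test with rank-biserial effect size
#'
#' Computes `U1 = sum over cross-group pairs of [x > y] + 0.5 * [x == y]`
#' (x from `group1`) via the rank formula, and the rank-biserial correlation
#' `rbc = 2 * U1 / (n1 * n2) - 1`, positive when `group1` is stochastically
#' larger. The two-sided p-value uses the exact U distribution when
#' `n1 * n2 <= 400` and no ties are present, and a tie-corrected normal
#' approximation with continuity correction otherwise. Groups that are fully
#' tied with each other yield `p = 1`, `rbc = 0`.
#'
#' @param group1,group2 Numeric vectors (non-empty).
#' @return A list of class `group_comparison`: `u_statistic` (U1), `p_value`,
#'   `rbc`, `n1`, `n2`, `method`.
#' @export
mann_whitney_rbc <- function(group1, group2) {
  x <- as.numeric(group1); y <- as.numeric(group2)
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  rbc <- 2 * u1 / (n1 * n2) - 1
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (!has_ties && n1 * n2 <= 400) {
    method <- "exact"
    # two-sided: double the smaller tail of the exact U distribution
    p <- 2 * min(stats::pwilcox(u1, n1, n2),
                 stats::pwilcox(u1 - 1, n1, n2, lower.tail = FALSE))
    p <- min(1, p)
  } else {
    method <- "normal approximation with tie correction"
    n <- n1 + n2
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1; rbc <- 0
    } else {
      z <- (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  structure(list(u_statistic = u1, p_value = p, rbc = rbc, n1 = n1, n2 = n2,
                 method = method),
            class = "group_comparison")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' `rho` is the Pearson correlation of mid-ranks (average ranks for ties);
#' the two-sided p-value uses `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom. A zero-variance vector makes the correlation
#' undefined: `rho` is reported as 0 with the `undefined` flag and `p = NA`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`, `undefined`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = 0, p_value = NA_real_, n = n, undefined = TRUE))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, undefined = FALSE)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of tests in the family (>= 1).
#' @return `alpha / n_tests`, applied downstream as a strict threshold.
#' @export
bonferroni <- function(alpha = 0.05, n_tests) {
  if (missing(n_tests) || n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Variance inflation factors
#'
#' `VIF_i = 1 / (1 - R2_i)`, with `R2_i` from the least-squares regression of
#' feature i on all other features plus an intercept. Exact collinearity
#' yields `Inf`. Constant (zero-variance) columns have no defined VIF and are
#' dropped beforehand with a warning.
#'
#' @param x Numeric matrix or data frame with at least 2 columns and named
#'   columns.
#' @return Named numeric vector of VIFs (over the retained columns).
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  const <- apply(x, 2, function(col) stats::var(col) == 0 || !any(is.finite(col)))
  if (any(const)) {
    warning("dropping constant column(s) with undefined VIF: ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  p <- ncol(x)
  if (p < 2L) stop("VIF needs at least 2 non-constant features")
  out <- vapply(seq_len(p), function(i) {
    yi <- x[, i]
    Xi <- cbind(1, x[, -i, drop = FALSE])
    fit <- stats::lm.fit(Xi, yi)
    rss <- sum(fit$residuals^2)
    tss <- sum((yi - mean(yi))^2)
    r2 <- 1 - rss / tss
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(x)
  out
}

#' Stepwise VIF elimination
#'
#' Repeatedly computes VIFs and removes the feature with the highest VIF
#' while that maximum is at or above the threshold, until every remaining
#' feature has VIF below the threshold. Ties at the maximum are broken by
#' the fixed input column order (first column wins removal). A single
#' surviving (or input) feature trivially satisfies the threshold.
#'
#' @param x Numeric matrix/data frame of features.
#' @param threshold VIF threshold (default 5).
#' @param layer Optional label naming the analysis block.
#' @return Object of class `vif_report`: `layer`, `input` (column names),
#'   `removed` (data frame: feature, vif, step), `survivors`, `final_vifs`,
#'   `threshold`.
#' @export
vif_stepwise <- function(x, threshold = 5, layer = NA_character_) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  input <- colnames(x)
  const <- apply(x, 2, function(col) stats::var(col) == 0 || !any(is.finite(col)))
  if (any(const)) {
    warning("excluding constant column(s) before VIF: ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  removed <- data.frame(feature = character(), vif = numeric(),
                        step = integer(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (ncol(x) < 2L) {
      final <- stats::setNames(rep(NA_real_, ncol(x)), colnames(x))
      break
    }
    v <- vif(x)
    if (max(v) < threshold) {
      final <- v
      break
    }
    worst <- names(v)[which.max(v)]   # which.max: first index on ties
    step <- step + 1L
    removed <- rbind(removed,
                     data.frame(feature = worst, vif = max(v), step = step,
                                stringsAsFactors = FALSE))
    x <- x[, setdiff(colnames(x), worst), drop = FALSE]
  }
  structure(list(layer = layer, input = input, removed = removed,
                 survivors = colnames(x), final_vifs = final,
                 threshold = threshold),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat("<vif_report> ", if (!is.na(x$layer)) paste0("[", x$layer, "] "),
      length(x$input), " features in, ", length(x$survivors),
      " survive (threshold ", x$threshold, ")\n", sep = "")
  if (nrow(x$removed)) {
    cat("removed:", paste0(x$removed$feature, " (VIF=",
                           round(x$removed$vif, 2), ")", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Feature-domain map
#'
#' The nine metrics partition into three domains: size (NN, NE, DIAMETER,
#' ASPL), connectedness (AWD, DENSITY, LSCC), and organization (LSCCZ,
#' ASPLZ).
#'
#' @return Named list of metric-name vectors.
#' @export
feature_domains <- function() {
  list(size = c("NN", "NE", "DIAMETER", "ASPL"),
       connectedness = c("AWD", "DENSITY", "LSCC"),
       organization = c("LSCCZ", "ASPLZ"))
}

.parse_feature_cols <- function(cols) {
  parts <- strsplit(cols, "_", fixed = TRUE)
  dom_of <- function(metric) {
    d <- feature_domains()
    names(d)[vapply(d, function(v) metric %in% v, logical(1))][1]
  }
  data.frame(column = cols,
             mode = vapply(parts, `[[`, character(1), 1L),
             graph_type = vapply(parts, `[[`, character(1), 2L),
             metric = vapply(parts, function(p) paste(p[-(1:2)], collapse = "_"),
                             character(1)),
             stringsAsFactors = FALSE) |>
    transform(domain = vapply(metric, dom_of, character(1)))
}

#' Layered stepwise-VIF redundancy pruning
#'
#' Applies [vif_stepwise()] at successive integration levels, per task:
#' stage 1 within each (task, graph type, mode, domain) block; stage 2 pools
#' each task's stage-1 survivors per graph type; stage 3 pools each task's
#' stage-2 survivors across graph types. Reports are returned for every
#' block at every stage. Blocks with fewer than two usable features survive
#' unchanged (noted in the report).
#'
#' @param features Feature table from [extract_all()] (or any data frame
#'   with `task` plus `{S,D}_{SEQ,AP}_<METRIC>` columns).
#' @param threshold VIF threshold (default 5).
#' @return List of `vif_report` objects, names encoding
#'   `stage/task/block`.
#' @export
layered_vif <- function(features, threshold = 5) {
  fcols <- intersect(feature_columns(), names(features))
  meta <- .parse_feature_cols(fcols)
  reports <- list()
  run_block <- function(label, rows_x, cols) {
    if (length(cols) < 2L) {
      rep <- structure(list(layer = label, input = cols,
                            removed = data.frame(feature = character(),
                                                 vif = numeric(),
                                                 step = integer()),
                            survivors = cols,
                            final_vifs = stats::setNames(
                              rep(NA_real_, length(cols)), cols),
                            threshold = threshold),
                       class = "vif_report")
      return(rep)
    }
    vif_stepwise(rows_x[, cols, drop = FALSE], threshold, layer = label)
  }
  for (task in unique(features$task)) {
    rows <- features[features$task == task, , drop = FALSE]
    stage1_survivors <- character()
    for (ty in unique(meta$graph_type)) {
      for (mo in unique(meta$mode)) {
        for (dom in names(feature_domains())) {
          cols <- meta$column[meta$graph_type == ty & meta$mode == mo &
                                meta$domain == dom]
          if (!length(cols)) next
          lab <- paste("domain", task, ty, mo, dom, sep = "/")
          rep <- run_block(lab, rows, cols)
          reports[[lab]] <- rep
          stage1_survivors <- c(stage1_survivors, rep$survivors)
        }
      }
    }
    stage2_survivors <- character()
    for (ty in unique(meta$graph_type)) {
      cols <- intersect(stage1_survivors,
                        meta$column[meta$graph_type == ty])
      if (!length(cols)) next
      lab <- paste("type", task, ty, sep = "/")
      rep <- run_block(lab, rows, cols)
      reports[[lab]] <- rep
      stage2_survivors <- c(stage2_survivors, rep$survivors)
    }
    lab <- paste("task", task, sep = "/")
    reports[[lab]] <- run_block(lab, rows, stage2_survivors)
  }
  reports
}

#' Full statistical report for a feature table
#'
#' Assembles the analysis battery: per task and feature, a PS+ vs PS- group
#' comparison (Mann–Whitney U with rank-biserial effect size); per task,
#' VIF-surviving feature and clinical measure, a Spearman correlation; and
#' the layered VIF redundancy reports. Bonferroni families default to
#' (features x tasks) for comparisons and (surviving features x measures x
#' tasks) for correlations, overridable via `comparison_family` /
#' `correlation_family`.
#'
#' @param features Feature table from [extract_all()].
#' @param participants Participant table (`participant_id`, `group`, clinical
#'   score columns).
#' @param alpha Family-wise error rate (default 0.05).
#' @param group1,group2 Group labels; `rbc > 0` means `group1` stochastically
#'   larger. Default `group1 = "PS-"`, `group2 = "PS+"`.
#' @param clinical_measures Score columns to correlate; defaults to all
#'   numeric columns of `participants` beyond id/group.
#' @param vif_threshold Threshold for [layered_vif()].
#' @param comparison_family,correlation_family Optional explicit Bonferroni
#'   family sizes.
#' @return Object of class `speech_graph_report` with elements `comparisons`,
#'   `correlations` (data frames), `vif_reports`, `alpha`, and the two
#'   adjusted alphas.
#' @export
run_analysis <- function(features, participants, alpha = 0.05,
                         group1 = "PS-", group2 = "PS+",
                         clinical_measures = NULL, vif_threshold = 5,
                         comparison_family = NULL,
                         correlation_family = NULL) {
  fcols <- intersect(feature_columns(), names(features))
  if (!length(fcols)) stop("no feature columns found")
  tasks <- unique(features$task)
  grp <- participants$group[match(features$participant_id,
                                  participants$participant_id)]
  if (is.null(clinical_measures)) {
    cand <- setdiff(names(participants), c("participant_id", "group"))
    clinical_measures <- cand[vapply(participants[cand], is.numeric, logical(1))]
  }

  comp_family <- if (is.null(comparison_family)) {
    length(fcols) * length(tasks)
  } else comparison_family
  alpha_comp <- bonferroni(alpha, comp_family)

  comparisons <- do.call(rbind, lapply(tasks, function(task) {
    rows <- features$task == task
    do.call(rbind, lapply(fcols, function(f) {
      v1 <- features[rows & grp == group1, f]
      v2 <- features[rows & grp == group2, f]
      if (!length(v1) || !length(v2)) return(NULL)
      mw <- mann_whitney_rbc(v1, v2)
      data.frame(task = task, feature = f, u_statistic = mw$u_statistic,
                 p_value = mw$p_value, rbc = mw$rbc, n1 = mw$n1, n2 = mw$n2,
                 significant_bonferroni = mw$p_value < alpha_comp,
                 stringsAsFactors = FALSE)
    }))
  }))

  vif_reports <- layered_vif(features, threshold = vif_threshold)
  survivors_by_task <- lapply(tasks, function(task) {
    vif_reports[[paste("task", task, sep = "/")]]$survivors
  })
  names(survivors_by_task) <- tasks

  corr_family <- if (is.null(correlation_family)) {
    max(1L, sum(lengths(survivors_by_task)) * length(clinical_measures))
  } else correlation_family
  alpha_corr <- bonferroni(alpha, corr_family)

  correlations <- do.call(rbind, lapply(tasks, function(task) {
    rows <- which(features$task == task)
    do.call(rbind, lapply(survivors_by_task[[task]], function(f) {
      do.call(rbind, lapply(clinical_measures, function(m) {
        scores <- participants[[m]][match(features$participant_id[rows],
                                          participants$participant_id)]
        if (all(is.na(scores))) return(NULL)
        sp <- spearman_rho(features[rows, f], scores)
        data.frame(task = task, feature = f, clinical_measure = m,
                   rho = sp$rho, p_value = sp$p_value, n = sp$n,
                   significant_uncorrected = isTRUE(sp$p_value < alpha),
                   significant_bonferroni = isTRUE(sp$p_value < alpha_corr),
                   stringsAsFactors = FALSE)
      }))
    }))
  }))

  structure(list(comparisons = comparisons, correlations = correlations,
                 vif_reports = vif_reports, alpha = alpha,
                 alpha_comparisons = alpha_comp,
                 alpha_correlations = alpha_corr,
                 group1 = group1, group2 = group2),
            class = "speech_graph_report")
}

#' @export
print.speech_graph_report <- function(x, ...) {
  cat("<speech_graph_report>\n")
  cat("  comparisons : ", nrow(x$comparisons), " (", x$group1, " vs ",
      x$group2, "), Bonferroni alpha = ",
      signif(x$alpha_comparisons, 3), "\n", sep = "")
  if (!is.null(x$correlations)) {
    cat("  correlations: ", nrow(x$correlations), ", Bonferroni alpha = ",
        signif(x$alpha_correlations, 3), "\n", sep = "")
  }
  cat("  VIF reports : ", length(x$vif_reports), " blocks\n", sep = "")
  invisible(x)
}

#' Write a statistical report to a directory
#'
#' Writes `comparisons.csv`, `correlations.csv`, `vif_layers.csv` (one row
#' per block with survivors and removal order), and
#' `correlations_long.csv` (heatmap-ready long format).
#'
#' @param report A `speech_graph_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
                   row.names = FALSE)
  if (!is.null(report$correlations)) {
    utils::write.csv(report$correlations, file.path(dir, "correlations.csv"),
                     row.names = FALSE)
    long <- report$correlations[, c("task", "feature", "clinical_measure",
                                    "rho", "p_value")]
    utils::write.csv(long, file.path(dir, "correlations_long.csv"),
                     row.names = FALSE)
  }
  vl <- do.call(rbind, lapply(report$vif_reports, function(r) {
    data.frame(layer = r$layer,
               n_input = length(r$input),
               survivors = paste(r$survivors, collapse = ";"),
               removed = paste(r$removed$feature, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(vl, file.path(dir, "vif_layers.csv"), row.names = FALSE)
  invisible(dir)
}
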