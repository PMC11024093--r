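# Low-dimensional "shape space" of single-cell transient trajectories:
# each cell's trace is one vectorial observation; PCA finds the dominant
# trajectory shapes, MANOVA/LDA compare labelled groups in that space.

#' Principal component analysis of pooled trajectories
#'
#' Treats each cell's (normalised) trajectory as one observation of
#' dimension N and runs a full singular value decomposition of the
#' mean-centered data, pooled over groups and agonist concentrations.
#' Trajectories are centered but not variance-scaled: scaling individual
#' time points would distort trajectory shape. The top `n_components`
#' components are retained. Each component's sign is fixed so that its
#' largest-magnitude loading is positive (the SVD sign is arbitrary;
#' determinism needs a rule).
#'
#' @param x A [trace_matrix()] or a cells x frames numeric matrix.
#' @param n_components Number of components retained (default 3).
#' @return An object of class `"shape_space_model"`: list with
#'   `components` (n_components x N, orthonormal rows), `center` (mean
#'   trajectory), `explained_variance_ratio` (all N ratios; the retained
#'   ones are the first `n_components`), `scores` (cells x n_components),
#'   `n_components` and `metadata` (when `x` was a trace matrix).
#' @export
fit_pca <- function(x, n_components = 3) {
  metadata <- NULL
  if (inherits(x, "trace_matrix")) { metadata <- x$metadata; x <- x$values }
  x <- as.matrix(x)
  if (nrow(x) < 4) stop("need at least 4 cells for PCA", call. = FALSE)
  if (anyNA(x)) stop("trajectories contain missing values", call. = FALSE)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  evr <- p$sdev^2 / sum(p$sdev^2)
  k <- min(n_components, ncol(p$rotation))
  comps <- t(p$rotation[, seq_len(k), drop = FALSE])
  # sign rule: largest-|loading| entry of each component positive
  for (j in seq_len(k)) {
    m <- which.max(abs(comps[j, ]))
    if (comps[j, m] < 0) comps[j, ] <- -comps[j, ]
  }
  scores <- sweep(x, 2, p$center) %*% t(comps)
  colnames(scores) <- sprintf("PC%d", seq_len(k))
  structure(list(components = comps, center = p$center,
                 explained_variance_ratio = evr, scores = scores,
                 n_components = k, metadata = metadata),
            class = "shape_space_model")
}

#' @export
print.shape_space_model <- function(x, ...) {
  k <- x$n_components
  cat(sprintf("shape_space_model: %d cells, %d frames, top %d components\n",
              nrow(x$scores), ncol(x$components), k))
  cat(sprintf("  explained variance: %s (cumulative %.1f%%)\n",
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio[1:k]),
                    collapse = ", "),
              100 * sum(x$explained_variance_ratio[1:k])))
  invisible(x)
}

#' Project trajectories into an existing shape space
#'
#' Scores are inner products of the centered trajectory with each
#' retained component; the training data project to exactly the model's
#' stored scores, and the mean trajectory projects to zero.
#'
#' @param x A [trace_matrix()], matrix, or single trajectory vector.
#' @param model A fitted [fit_pca()] model.
#' @return Numeric matrix of scores (rows = trajectories).
#' @export
project_traces <- function(x, model) {
  stopifnot(inherits(model, "shape_space_model"))
  if (inherits(x, "trace_matrix")) x <- x$values
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(model$components))
    stop("trajectory length does not match the model's frame grid",
         call. = FALSE)
  s <- sweep(x, 2, model$center) %*% t(model$components)
  colnames(s) <- sprintf("PC%d", seq_len(model$n_components))
  s
}

#' Back-project shape-space scores to a full trajectory
#'
#' Reconstruction is the pooled mean trajectory plus the score-weighted
#' sum of components; used to visualise cluster centroids as trajectories.
#'
#' @param scores Numeric vector (or 1-row matrix) of length
#'   `model$n_components`.
#' @param model A fitted [fit_pca()] model.
#' @return Numeric trajectory of length N.
#' @export
reconstruct_mean <- function(scores, model) {
  stopifnot(inherits(model, "shape_space_model"))
  scores <- as.numeric(scores)
  if (length(scores) != model$n_components)
    stop("need one score per retained component", call. = FALSE)
  as.numeric(model$center + crossprod(model$components, scores))
}

#' Compare labelled groups in shape space per concentration
#'
#' For each agonist concentration, a MANOVA (Wilks' lambda with the
#' standard F approximation) tests whether the group mean score vectors
#' differ; p-values are Bonferroni-adjusted across the concentration
#' levels. A linear discriminant analysis on the same scores (priors
#' proportional to group sizes) gives the direction along which the
#' groups separate.
#'
#' @param scores Cells x components numeric matrix (see [fit_pca()]).
#' @param labels Group label per cell (two or more groups).
#' @param concentrations Concentration level per cell; tests are run
#'   within each level. Use a constant vector for a single pooled test.
#' @param min_per_group Minimum cells per group per level.
#' @return Data frame with one row per concentration: `concentration`,
#'   `n`, `wilks_lambda`, `f_stat`, `df1`, `df2`, `p_raw`, `p_bonferroni`,
#'   and `lda_weights` (list column of per-component discriminant
#'   weights).
#' @export
compare_groups <- function(scores, labels, concentrations,
                           min_per_group = 4) {
  scores <- as.matrix(scores)
  labels <- as.factor(labels)
  if (length(labels) != nrow(scores) ||
      length(concentrations) != nrow(scores))
    stop("'labels' and 'concentrations' must have one entry per cell",
         call. = FALSE)
  levels_c <- sort(unique(concentrations))
  n_tests <- length(levels_c)
  out <- vector("list", n_tests)
  for (i in seq_along(levels_c)) {
    sel <- concentrations == levels_c[i]
    s <- scores[sel, , drop = FALSE]
    g <- droplevels(labels[sel])
    if (nlevels(g) < 2 || any(table(g) < min_per_group))
      stop(sprintf("concentration %s: need >= 2 groups with >= %d cells each",
                   format(levels_c[i]), min_per_group), call. = FALSE)
    fit <- stats::manova(s ~ g)
    sm <- tryCatch(summary(fit, test = "Wilks")$stats,
                   error = function(e)
                     stop("MANOVA failed (singular within-group covariance?): ",
                          conditionMessage(e), call. = FALSE))
    lda <- MASS::lda(s, grouping = g)
    w <- as.numeric(lda$scaling[, 1])
    out[[i]] <- data.frame(
      concentration = levels_c[i], n = sum(sel),
      wilks_lambda = sm["g", "Wilks"],
      f_stat = sm["g", "approx F"],
      df1 = sm["g", "num Df"], df2 = sm["g", "den Df"],
      p_raw = sm["g", "Pr(>F)"])
    out[[i]]$lda_weights <- list(stats::setNames(
      w, colnames(scores) %||% sprintf("PC%d", seq_along(w))))
  }
  res <- do.call(rbind, out)
  res$p_bonferroni <- pmin(1, res$p_raw * n_tests)
  res[, c("concentration", "n", "wilks_lambda", "f_stat", "df1", "df2",
          "p_raw", "p_bonferroni", "lda_weights")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
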