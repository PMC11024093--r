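# Seeded generators for every input the pipeline consumes: model-based
# calcium transients, high-content object tables with planted QC
# violations, and latent-axis expression matrices.

# Run `code` with a reproducible RNG state without disturbing the caller's
# stream. seed = NULL leaves the global stream in charge.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Simulate one raw fluorescence trace from the rise-decay model
#'
#' Frames before `agonist_frame` fluctuate around a constant baseline
#' `f0`; from `agonist_frame` onward the trace follows the rise-decay
#' model evaluated at `t = (frame - agonist_frame) * dt` on top of the
#' baseline. Independent zero-mean Gaussian noise of standard deviation
#' `noise_sd` is added to every frame.
#'
#' @param params A [transient_params()] object (the ground truth).
#' @param n_frames Total number of acquired frames.
#' @param dt Sampling interval in seconds.
#' @param agonist_frame 1-based index of the frame at which the agonist is
#'   added (the transient onset, model time t = 0).
#' @param noise_sd Gaussian noise standard deviation (a.u.).
#' @param seed Optional integer seed; fixed seed gives bit-identical output.
#' @param f0 Constant pre-stimulus baseline fluorescence (a.u.). Positive
#'   so that relative change is well defined downstream.
#' @return Numeric vector of `n_frames` raw fluorescence values.
#' @examples
#' p <- transient_params(1 / 200, 0.02, 5, 2)
#' y <- simulate_transient(p, n_frames = 61, dt = 30, agonist_frame = 10,
#'                         noise_sd = 0, f0 = 100)
#' y[10] - 100  # exactly 0: the model starts at baseline
#' @export
simulate_transient <- function(params, n_frames, dt = 30, agonist_frame = 10,
                               noise_sd = 0, seed = NULL, f0 = 100) {
  stopifnot(inherits(params, "transient_params"))
  if (n_frames < agonist_frame + 2L)
    stop("invariant violated: n_frames must be >= agonist_frame + 2",
         call. = FALSE)
  if (agonist_frame < 1L)
    stop("invariant violated: agonist_frame must be a positive frame index",
         call. = FALSE)
  if (dt <= 0) stop("invariant violated: dt must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("invariant violated: noise_sd must be >= 0",
                         call. = FALSE)
  y <- rep(f0, n_frames)
  post <- agonist_frame:n_frames
  y[post] <- f0 + model_eval((post - agonist_frame) * dt, params)
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(n_frames, 0, noise_sd))
  y
}

#' Specification of a simulated two-group imaging cohort
#'
#' Defaults mirror the imaging experiment the pipeline targets: 61 frames
#' at 30 s (30 min inclusive of t = 0), agonist at the tenth acquired
#' frame, round ("O") and elongated-triangular ("L") micropattern groups
#' with the "L" cells decaying more slowly (larger `1/tau_decay`).
#' Kinetic parameters are drawn log-uniformly within the stated per-group
#' ranges; amplitudes correspond to a fluorescent calcium indicator with
#' peak relative changes of roughly 1-3 over a baseline of 100 a.u.
#'
#' @param n_cells Cells per group.
#' @param groups Named list of per-group sampling ranges; each entry lists
#'   `inv_tau_decay` (decay time range, s), `tau_delta` (1/s), `b` and `c`
#'   (a.u.) as length-2 ranges.
#' @param concentrations Agonist dose labels (uM), assigned round-robin
#'   within each group.
#' @param n_frames,dt,agonist_frame Acquisition grid (see
#'   [simulate_transient()]).
#' @param noise_sd Per-frame Gaussian noise (a.u.).
#' @param f0 Baseline fluorescence (a.u.).
#' @param nonresponder_fraction Proportion of cells in `[0, 1]` that emit
#'   baseline-plus-noise only (no transient).
#' @param seed Integer seed.
#' @return An object of class `"cohort_spec"` (a validated list).
#' @export
cohort_spec <- function(n_cells = 60,
                        groups = list(
                          O = list(inv_tau_decay = c(60, 240),
                                   tau_delta = c(0.01, 0.05),
                                   b = c(100, 300), c = c(20, 80)),
                          L = list(inv_tau_decay = c(240, 900),
                                   tau_delta = c(0.01, 0.05),
                                   b = c(100, 300), c = c(20, 80))),
                        concentrations = c(0.3, 1, 3),
                        n_frames = 61, dt = 30, agonist_frame = 10,
                        noise_sd = 5, f0 = 100,
                        nonresponder_fraction = 0.1, seed = 1L) {
  if (n_cells < 1) stop("each group needs at least one cell", call. = FALSE)
  if (length(groups) < 1 || is.null(names(groups)))
    stop("'groups' must be a named list", call. = FALSE)
  if (agonist_frame >= n_frames)
    stop("invariant violated: agonist_frame < n_frames required",
         call. = FALSE)
  if (dt <= 0) stop("invariant violated: dt must be > 0", call. = FALSE)
  if (nonresponder_fraction < 0 || nonresponder_fraction > 1)
    stop("invariant violated: nonresponder_fraction must be in [0, 1]",
         call. = FALSE)
  structure(list(n_cells = n_cells, groups = groups,
                 concentrations = concentrations, n_frames = n_frames,
                 dt = dt, agonist_frame = agonist_frame,
                 noise_sd = noise_sd, f0 = f0,
                 nonresponder_fraction = nonresponder_fraction,
                 seed = seed),
            class = "cohort_spec")
}

#' Simulate a cohort of single-cell calcium traces with ground truth
#'
#' Draws per-cell kinetic parameters from the per-group ranges of a
#' [cohort_spec()], deterministically marks the first
#' `round(nonresponder_fraction * n_cells)` cells of each group as
#' non-responders (baseline-plus-noise only), and records every cell's
#' true parameters.
#'
#' @param spec A [cohort_spec()].
#' @return List with `traces` (a raw [trace_matrix()] of
#'   `spec$n_frames` frames) and `truth` (data frame of true
#'   `tau_decay`, `tau_delta`, `b`, `c`, `inv_tau_decay` and `responder`
#'   per cell).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    rows <- list(); meta <- list(); truth <- list()
    idx <- 0L
    for (g in names(spec$groups)) {
      rg <- spec$groups[[g]]
      n_nr <- round(spec$nonresponder_fraction * spec$n_cells)
      for (i in seq_len(spec$n_cells)) {
        idx <- idx + 1L
        responder <- i > n_nr
        inv_td <- runif_log(1, rg$inv_tau_decay[1], rg$inv_tau_decay[2])
        p <- transient_params(
          tau_decay = 1 / inv_td,
          tau_delta = runif_log(1, rg$tau_delta[1], rg$tau_delta[2]),
          b = runif_log(1, rg$b[1], rg$b[2]),
          c = runif_log(1, rg$c[1], rg$c[2]))
        y <- if (responder) {
          simulate_transient(p, spec$n_frames, spec$dt, spec$agonist_frame,
                             noise_sd = 0, f0 = spec$f0)
        } else rep(spec$f0, spec$n_frames)
        if (spec$noise_sd > 0)
          y <- y + stats::rnorm(spec$n_frames, 0, spec$noise_sd)
        rows[[idx]] <- y
        meta[[idx]] <- data.frame(
          cell_id = sprintf("%s_%03d", g, i),
          shape_group = g,
          concentration_uM =
            spec$concentrations[(i - 1L) %% length(spec$concentrations) + 1L],
          well = sprintf("W%d", (i - 1L) %/% 30L + 1L),
          replicate = (i - 1L) %% 2L + 1L)
        truth[[idx]] <- data.frame(
          cell_id = sprintf("%s_%03d", g, i), shape_group = g,
          responder = responder,
          tau_decay = if (responder) p$tau_decay else NA_real_,
          tau_delta = if (responder) p$tau_delta else NA_real_,
          b = if (responder) p$b else NA_real_,
          c = if (responder) p$c else NA_real_,
          inv_tau_decay = if (responder) inv_td else NA_real_)
      }
    }
    list(traces = trace_matrix(do.call(rbind, rows), dt = spec$dt,
                               metadata = do.call(rbind, meta)),
         truth = do.call(rbind, truth))
  })
}

#' Simulate linked high-content object tables with planted QC violations
#'
#' Emits the four per-well object tables the QC module merges - calcium
#' objects (area, perimeter, shape factor, centroid), nucleus-cell
#' association (nucleus area, nuclei per region, centroid), nucleus
#' spacing (minimum distance to any other nucleus, pixels) and
#' post-stain calcium objects (centroid) - together with ground-truth
#' inclusion labels. Each planted case violates exactly one QC rule;
#' clean records sit well inside every rule's window. With
#' `include_boundary = TRUE` four records are planted exactly on the rule
#' boundaries (shape factor at the group's window edge, nucleus area
#' 300 um^2, centroid difference 30 um, nucleus spacing 20 px) with truth
#' labels fixed by the rule semantics (inclusive except nucleus area).
#'
#' @param layout Named list of case counts: `n_clean`, `n_wrong_shape`,
#'   `n_multi_nucleus`, `n_close_nuclei`, `n_big_nucleus`,
#'   `n_centroid_mismatch` (missing entries default to 0).
#' @param shape_group `"O"` (round) or `"L"` (elongated triangle); sets
#'   which shape-factor window clean records satisfy.
#' @param include_boundary Plant the four exact boundary records.
#' @param seed Integer seed.
#' @return List of data frames `calcium`, `nuclei`, `spacing`, `post` and
#'   `truth` (`region_id`, `case`, `included`).
#' @export
simulate_object_tables <- function(layout, shape_group = c("O", "L"),
                                   include_boundary = FALSE, seed = 1L) {
  shape_group <- match.arg(shape_group)
  known <- c("n_clean", "n_wrong_shape", "n_multi_nucleus", "n_close_nuclei",
             "n_big_nucleus", "n_centroid_mismatch")
  bad <- setdiff(names(layout), known)
  if (length(bad))
    stop("unknown layout entries: ", paste(bad, collapse = ", "),
         call. = FALSE)
  counts <- stats::setNames(rep(0L, length(known)), known)
  counts[names(layout)] <- as.integer(layout)
  if (any(counts < 0)) stop("layout counts must be >= 0", call. = FALSE)

  with_seed(seed, {
    cases <- c(rep("clean", counts["n_clean"]),
               rep("wrong_shape", counts["n_wrong_shape"]),
               rep("multi_nucleus", counts["n_multi_nucleus"]),
               rep("close_nuclei", counts["n_close_nuclei"]),
               rep("big_nucleus", counts["n_big_nucleus"]),
               rep("centroid_mismatch", counts["n_centroid_mismatch"]))
    if (include_boundary)
      cases <- c(cases, "boundary_shape", "boundary_nucleus_area",
                 "boundary_centroid", "boundary_spacing")
    n <- length(cases)
    if (n == 0) stop("layout is empty", call. = FALSE)

    sf_clean <- function(k) if (shape_group == "O")
      stats::runif(k, 0.92, 0.99) else stats::runif(k, 0.55, 0.80)
    sf_bad <- function(k) if (shape_group == "O")
      stats::runif(k, 0.50, 0.87) else stats::runif(k, 0.88, 0.99)
    sf_edge <- if (shape_group == "O") 0.90 else 0.85

    area <- stats::runif(n, 900, 1300)
    sf <- sf_clean(n)
    nuc_area <- stats::runif(n, 100, 250)
    nuc_dist <- stats::runif(n, 30, 200)
    nuclei_n <- rep(1L, n)
    x <- stats::runif(n, 0, 2000); y <- stats::runif(n, 0, 2000)
    jitter_xy <- function(k, r_max) {
      r <- stats::runif(k, 0, r_max); th <- stats::runif(k, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th))
    }
    dh <- jitter_xy(n, 8); dp <- jitter_xy(n, 8)

    for (i in seq_len(n)) {
      switch(cases[i],
        wrong_shape = { sf[i] <- sf_bad(1) },
        multi_nucleus = { nuclei_n[i] <- sample(2:3, 1) },
        close_nuclei = { nuc_dist[i] <- stats::runif(1, 2, 18) },
        big_nucleus = { nuc_area[i] <- stats::runif(1, 310, 400) },
        centroid_mismatch = {
          shift <- jitter_xy(1, 1); shift <- shift / sqrt(sum(shift^2))
          dp[i, ] <- shift * stats::runif(1, 35, 80)
        },
        boundary_shape = { sf[i] <- sf_edge },
        boundary_nucleus_area = { nuc_area[i] <- 300 },
        boundary_centroid = { dh[i, ] <- c(0, 0); dp[i, ] <- c(30, 0) },
        boundary_spacing = { nuc_dist[i] <- 20 },
        clean = NULL)
    }

    included <- cases %in% c("clean", "boundary_shape", "boundary_centroid",
                             "boundary_spacing")
    region_id <- sprintf("R%04d", seq_len(n))
    perimeter <- sqrt(4 * pi * area / sf)

    list(
      calcium = data.frame(region_id = region_id,
                           calcium_centroid_x = x, calcium_centroid_y = y,
                           cell_area = area, perimeter = perimeter,
                           shape_factor = sf),
      nuclei = data.frame(region_id = region_id,
                          hoechst_centroid_x = x + dh[, 1],
                          hoechst_centroid_y = y + dh[, 2],
                          nucleus_area = nuc_area,
                          nuclei_in_region = nuclei_n),
      spacing = data.frame(region_id = region_id,
                           nucleus_min_distance = nuc_dist),
      post = data.frame(region_id = region_id,
                        post_centroid_x = x + dp[, 1],
                        post_centroid_y = y + dp[, 2]),
      truth = data.frame(region_id = region_id, case = cases,
                         included = included)
    )
  })
}

#' Simulate a family of unit-peak transient trajectories
#'
#' Draws `n` parameter vectors log-uniformly across the full fitting grid
#' ranges - decay times `1/tau_decay` in 15-1500 s, `tau_delta` in
#' 1e-6 to 1e-1 1/s, amplitudes `b` and `c` in 0.1-1000 a.u. - evaluates
#' the rise-decay model on `n_frames` post-onset frames, rescales each
#' curve to a common peak of 1 and adds Gaussian noise. This is the
#' trajectory family used to probe how much of the model family's
#' variance a low-dimensional shape space captures.
#'
#' @param n Number of trajectories.
#' @param n_frames Post-onset frames.
#' @param dt Sampling interval (s).
#' @param noise_sd Gaussian noise sd, in units of the (unit) peak.
#' @param seed Integer seed.
#' @return List with `values` (n x n_frames matrix), `times` (s) and
#'   `params` (data frame of the drawn parameters, pre-rescaling).
#' @export
simulate_trajectory_family <- function(n = 500, n_frames = 52, dt = 30,
                                       noise_sd = 0.02, seed = 1L) {
  if (n < 1 || n_frames < 2) stop("invalid family size", call. = FALSE)
  with_seed(seed, {
    times <- (seq_len(n_frames) - 1) * dt
    inv_td <- runif_log(n, 15, 1500)
    tau_delta <- runif_log(n, 1e-6, 1e-1)
    b <- runif_log(n, 0.1, 1000)
    cc <- runif_log(n, 0.1, 1000)
    vals <- matrix(0, n, n_frames)
    for (i in seq_len(n)) {
      f <- model_eval(times, transient_params(1 / inv_td[i], tau_delta[i],
                                              b[i], cc[i]))
      vals[i, ] <- f / max(f)
    }
    if (noise_sd > 0)
      vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd),
                            nrow = n)
    list(values = vals, times = times,
         params = data.frame(inv_tau_decay = inv_td,
                             tau_delta = tau_delta, b = b, c = cc))
  })
}

#' Specification of a latent-axis expression simulation
#'
#' Tumors are placed on a one-dimensional latent epithelial-mesenchymal
#' axis; epithelial signature genes load positively on the axis,
#' mesenchymal genes negatively, subtype markers and extra genes not at
#' all. Log2 expression is the gene's baseline plus loading times the
#' tumor's latent value plus Gaussian noise.
#'
#' @param n_tumors Number of tumors.
#' @param noise_sd Gaussian noise standard deviation (log2 units).
#' @param n_extra_genes Unstructured genes appended to the signature
#'   universe.
#' @param latent_sd Standard deviation of the latent axis.
#' @param seed Integer seed.
#' @return An object of class `"expression_sim_spec"`.
#' @export
expression_sim_spec <- function(n_tumors = 500, noise_sd = 0.5,
                                n_extra_genes = 50, latent_sd = 1,
                                seed = 1L) {
  if (n_tumors < 2) stop("need at least two tumors", call. = FALSE)
  if (noise_sd < 0 || latent_sd <= 0 || n_extra_genes < 0)
    stop("invalid expression simulation spec", call. = FALSE)
  structure(list(n_tumors = n_tumors, noise_sd = noise_sd,
                 n_extra_genes = n_extra_genes, latent_sd = latent_sd,
                 seed = seed),
            class = "expression_sim_spec")
}

#' Simulate a tumors-by-genes log2 expression matrix with a latent axis
#'
#' The gene universe is the packaged epithelial / mesenchymal / subtype
#' marker lists (each gene exactly once) plus `n_extra_genes` unstructured
#' genes. Per-gene loadings are drawn log-uniformly in `[0.8, 1.5]` with
#' positive sign for epithelial and negative for mesenchymal genes.
#'
#' @param spec An [expression_sim_spec()].
#' @return List with `expr` (n_tumors x n_genes numeric matrix, log2
#'   scale, tumor ids as rownames), `latent` (per-tumor axis value;
#'   positive = epithelial pole) and `loadings` (named per-gene vector).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  gl <- epimes_gene_lists()
  genes <- c(gl$epithelial, gl$mesenchymal, gl$subtype_markers,
             if (spec$n_extra_genes > 0)
               sprintf("EXTRA%03d", seq_len(spec$n_extra_genes)))
  with_seed(spec$seed, {
    load <- stats::setNames(numeric(length(genes)), genes)
    load[gl$epithelial] <- runif_log(length(gl$epithelial), 0.8, 1.5)
    load[gl$mesenchymal] <- -runif_log(length(gl$mesenchymal), 0.8, 1.5)
    baseline <- stats::setNames(stats::runif(length(genes), 5, 12), genes)
    latent <- stats::rnorm(spec$n_tumors, 0, spec$latent_sd)
    expr <- outer(latent, load) +
      matrix(baseline, spec$n_tumors, length(genes), byrow = TRUE)
    if (spec$noise_sd > 0)
      expr <- expr + matrix(stats::rnorm(length(expr), 0, spec$noise_sd),
                            nrow = spec$n_tumors)
    dimnames(expr) <- list(sprintf("TUMOR%04d", seq_len(spec$n_tumors)),
                           genes)
    list(expr = expr, latent = latent, loadings = load)
  })
}
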