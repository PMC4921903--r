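#' Configuration for the synthetic two-condition generator
#'
#' Defines a desk-scale but structurally faithful instance of the study
#' design: a sparse TF -> gene network with overlapping regulons, known
#' activity curves per TF and condition, and additive Gaussian noise on the
#' log2-ratio scale, sampled on the irregular 0-80 minute grid.
#'
#' @param n_genes number of genes (>= n_tfs).
#' @param n_tfs number of TFs.
#' @param mean_regulon_size mean number of targets per TF (sizes are
#'   `1 + Poisson(mean - 1)`, capped at `n_genes`).
#' @param sign_fraction fraction of edges carrying a known regulatory sign.
#' @param weight_sd standard deviation of regulatory weights.
#' @param noise_sd standard deviation of the additive expression noise
#'   (log2 units).
#' @param timepoints_min sampling grid in minutes.
#' @param shapes optional list of per-TF shape pairs: each element
#'   `list(A = activity_shape(...), B = activity_shape(...))`. Defaults to a
#'   deterministic mix of transient pulses, monotone rises and monotone
#'   declines (identical in both conditions).
#' @param seed mandatory integer seed. Independent substreams are derived
#'   for the network, the weights and each condition's noise, so changing
#'   one component does not perturb the others.
#' @return list of class `"tfa_sim_config"`.
#' @export
tfa_sim_config <- function(n_genes = 200, n_tfs = 10, mean_regulon_size = 20,
                           sign_fraction = 0.7, weight_sd = 1, noise_sd = 0.3,
                           timepoints_min = c(0, 2.5, 5, 10, 20, 40, 80),
                           shapes = NULL, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(n_genes >= n_tfs, n_tfs >= 1, noise_sd > 0, weight_sd > 0,
            sign_fraction >= 0, sign_fraction <= 1)
  if (mean_regulon_size > n_genes)
    stop("mean_regulon_size cannot exceed n_genes")
  if (is.null(shapes)) shapes <- default_shape_set(n_tfs)
  if (length(shapes) != n_tfs) stop("'shapes' must have one entry per TF")
  structure(list(n_genes = n_genes, n_tfs = n_tfs,
                 mean_regulon_size = mean_regulon_size,
                 sign_fraction = sign_fraction, weight_sd = weight_sd,
                 noise_sd = noise_sd, timepoints_min = timepoints_min,
                 shapes = shapes, seed = as.integer(seed)),
            class = "tfa_sim_config")
}

#' Parametric TF activity shape
#'
#' The activity templates mimic the canonical time-course responses:
#' a transient pulse (rapid rise to a peak, then exponential decay with
#' half-life equal to the peak time), a saturating monotone rise, a monotone
#' decline (the mirrored rise), and a flat null profile.
#'
#' @param kind one of `"transient_pulse"`, `"monotone_rise"`,
#'   `"monotone_decline"`, `"flat"`.
#' @param amplitude activity amplitude (0 for `"flat"`).
#' @param peak_time pulse peak time in minutes (pulse only).
#' @return list of class `"activity_shape"`.
#' @export
activity_shape <- function(kind = c("transient_pulse", "monotone_rise",
                                    "monotone_decline", "flat"),
                           amplitude = 1, peak_time = 20) {
  kind <- match.arg(kind)
  if (kind == "flat") amplitude <- 0
  stopifnot(peak_time > 0)
  structure(list(kind = kind, amplitude = amplitude, peak_time = peak_time),
            class = "activity_shape")
}

# saturating time constant for the monotone shapes (minutes, mid-grid)
.MONOTONE_TAU <- 20

#' Evaluate an activity shape on a time grid
#'
#' @param shape an [activity_shape()].
#' @param t numeric vector of minutes.
#' @return numeric vector of activities.
#' @export
eval_shape <- function(shape, t) {
  stopifnot(inherits(shape, "activity_shape"))
  A <- shape$amplitude; p <- shape$peak_time
  switch(shape$kind,
    flat = rep(0, length(t)),
    transient_pulse = ifelse(t <= p, A * t / p, A * 2^(-(t - p) / p)),
    monotone_rise = A * (1 - exp(-t / .MONOTONE_TAU)),
    monotone_decline = -A * (1 - exp(-t / .MONOTONE_TAU)))
}

default_shape_set <- function(n_tfs) {
  kinds <- rep(c("transient_pulse", "monotone_rise", "monotone_decline"),
               length.out = n_tfs)
  peaks <- rep(c(5, 10, 20), length.out = n_tfs)
  amps <- rep(c(2, 1.5, 2.5, 3), length.out = n_tfs)
  lapply(seq_len(n_tfs), function(m) {
    s <- activity_shape(kinds[m], amplitude = amps[m], peak_time = peaks[m])
    list(A = s, B = s)
  })
}

# deterministic substream seeds derived from the master seed (kept < 2^31)
.sub_seed <- function(seed, k) (as.integer(seed) * 101L + k * 9973L) %% 2000000011L

#' Generate a random regulon network
#'
#' Each TF draws its target set without replacement (size
#' `1 + Poisson(mean_regulon_size - 1)`, capped at `n_genes`); a
#' `sign_fraction` of edges receive a regulatory sign (+/- with equal
#' probability). Deterministic per seed.
#'
#' @param cfg a [tfa_sim_config()].
#' @return a [regulon_network()]; gene ids `g001...`, TF ids `tf01...`.
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "tfa_sim_config"))
  set.seed(.sub_seed(cfg$seed, 1L))
  genes <- sprintf("g%03d", seq_len(cfg$n_genes))
  tfs <- sprintf("tf%02d", seq_len(cfg$n_tfs))
  tf_col <- character(0); gene_col <- character(0)
  for (m in seq_len(cfg$n_tfs)) {
    # sizes are 1 + Poisson(mean - 1), capped at n_genes; a mean equal to
    # n_genes forces the degenerate distribution at the maximum
    size <- if (cfg$mean_regulon_size == cfg$n_genes) cfg$n_genes
            else min(cfg$n_genes, 1L + rpois(1, cfg$mean_regulon_size - 1))
    tgt <- sample(genes, size, replace = FALSE)
    tf_col <- c(tf_col, rep(tfs[m], size))
    gene_col <- c(gene_col, tgt)
  }
  sgn <- rep(NA_integer_, length(tf_col))
  signed <- runif(length(tf_col)) < cfg$sign_fraction
  sgn[signed] <- sample(c(-1L, 1L), sum(signed), replace = TRUE)
  regulon_network(tf_col, gene_col, sgn)
}

#' Generate the true activity curves
#'
#' Evaluates each TF's shape pair on the sampling grid.
#'
#' @param cfg a [tfa_sim_config()].
#' @return list with matrices `A` and `B` (TFs x timepoints) of true
#'   activities.
#' @export
generate_activities <- function(cfg) {
  stopifnot(inherits(cfg, "tfa_sim_config"))
  tfs <- sprintf("tf%02d", seq_len(cfg$n_tfs))
  per_cond <- function(cond) {
    m <- t(vapply(cfg$shapes, function(sp) eval_shape(sp[[cond]], cfg$timepoints_min),
                  numeric(length(cfg$timepoints_min))))
    dimnames(m) <- list(tfs, format(cfg$timepoints_min, trim = TRUE))
    m
  }
  list(A = per_cond("A"), B = per_cond("B"))
}

#' Generate two-condition expression matrices with known ground truth
#'
#' Implements the model of [tfa()] forward: `y_gt = mu_g + sum_m X_gm b_gm
#' c_mt + N(0, noise_sd^2)`. Weights are drawn once (`N(0, weight_sd^2)`,
#' folded onto the annotated sign where the edge is signed) and shared by
#' both conditions; each condition gets its own noise realisation.
#' `mu_g = 0` (expression is baseline-relative).
#'
#' @param network a [regulon_network()] (typically from
#'   [generate_network()]).
#' @param activities the [generate_activities()] result.
#' @param cfg a [tfa_sim_config()].
#' @return list with `expr` (list of [expression_timecourse()] `A`, `B`) and
#'   `truth` (list: `X`, `signs`, `weights`, `activities`, `mu`, `noise_sd`,
#'   `seed`).
#' @export
generate_expression <- function(network, activities, cfg) {
  stopifnot(inherits(network, "regulon_network"), inherits(cfg, "tfa_sim_config"))
  genes <- sprintf("g%03d", seq_len(cfg$n_genes))
  tfs <- sprintf("tf%02d", seq_len(cfg$n_tfs))
  tt <- cfg$timepoints_min
  X <- matrix(0, cfg$n_genes, cfg$n_tfs, dimnames = list(genes, tfs))
  S <- matrix(NA_integer_, cfg$n_genes, cfg$n_tfs, dimnames = list(genes, tfs))
  idx <- cbind(match(network$edges$gene, genes), match(network$edges$tf, tfs))
  if (anyNA(idx)) stop("network ids do not match the generator's gene/TF ids")
  X[idx] <- 1
  S[idx] <- network$edges$sign

  set.seed(.sub_seed(cfg$seed, 2L))
  B <- matrix(0, cfg$n_genes, cfg$n_tfs, dimnames = list(genes, tfs))
  raw_w <- rnorm(nrow(idx), 0, cfg$weight_sd)
  sgn <- S[idx]
  raw_w[!is.na(sgn)] <- abs(raw_w[!is.na(sgn)]) * sgn[!is.na(sgn)]
  B[idx] <- raw_w

  mu <- rep(0, cfg$n_genes)
  make_cond <- function(Ctrue, cond_label, sub) {
    set.seed(.sub_seed(cfg$seed, sub))
    clean <- (X * B) %*% Ctrue + mu
    noisy <- clean + matrix(rnorm(length(clean), 0, cfg$noise_sd),
                            nrow(clean), ncol(clean))
    expression_timecourse(noisy, genes, tt, cond_label)
  }
  expr <- list(A = make_cond(activities$A, "A", 3L),
               B = make_cond(activities$B, "B", 4L))
  truth <- list(X = X, signs = S, weights = B, activities = activities,
                mu = mu, noise_sd = cfg$noise_sd, seed = cfg$seed)
  list(expr = expr, truth = truth)
}

#' One-call synthetic dataset
#'
#' Runs [generate_network()], [generate_activities()] and
#' [generate_expression()] for a config.
#'
#' @param cfg a [tfa_sim_config()].
#' @return list with `network`, `activities`, `expr` (conditions `A`, `B`)
#'   and `truth`.
#' @export
simulate_tfa_data <- function(cfg) {
  network <- generate_network(cfg)
  activities <- generate_activities(cfg)
  ge <- generate_expression(network, activities, cfg)
  list(network = network, activities = activities,
       expr = ge$expr, truth = ge$truth)
}

#' The designed three-TF quadrant-recovery scenario
#'
#' A small two-condition benchmark whose true coherence structure is known
#' by construction: TF1 responds identically in both conditions (expected
#' lower-left, near the origin), TF2 keeps its shape but triples its
#' amplitude (expected upper-left), and TF3 changes kinetics — an early
#' pulse versus a late pulse, true profile difference about 0.67 — with
#' nearly equal norms (expected right half).
#'
#' @param seed integer seed.
#' @param n_genes,mean_regulon_size scenario size.
#' @param noise_sd expression noise sd.
#' @return a [tfa_sim_config()] with 3 TFs, plus attribute
#'   `expected_quadrants`.
#' @export
quadrant_scenario_config <- function(seed, n_genes = 60, mean_regulon_size = 15,
                                     noise_sd = 0.3) {
  shapes <- list(
    list(A = activity_shape("transient_pulse", 2, 10),
         B = activity_shape("transient_pulse", 2, 10)),
    list(A = activity_shape("monotone_rise", 1),
         B = activity_shape("monotone_rise", 3)),
    list(A = activity_shape("transient_pulse", 2, 2.5),
         B = activity_shape("transient_pulse", 2, 20)))
  cfg <- tfa_sim_config(n_genes = n_genes, n_tfs = 3,
                        mean_regulon_size = mean_regulon_size,
                        noise_sd = noise_sd, shapes = shapes, seed = seed)
  attr(cfg, "expected_quadrants") <-
    c(tf01 = "lower-left", tf02 = "upper-left", tf03 = "right-half")
  cfg
}
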