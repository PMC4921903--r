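#' Sampler and prior settings for [tfa()]
#'
#' @param tau_b prior standard deviation of regulatory weights b_gm.
#' @param tau_c random-walk innovation scale of the activities: the
#'   innovation between consecutive timepoints has standard deviation
#'   `tau_c * sqrt(dt)` with `dt` in minutes, so irregular sampling grids
#'   are handled without resampling.
#' @param mu_sd prior standard deviation of per-gene baselines mu_g.
#' @param c0_sd prior standard deviation of the activity at the first
#'   timepoint. The activity at minute 0 is estimated, not clamped, but
#'   because expression is measured relative to the minute-0 sample a
#'   fairly tight prior here is what identifies the overall level of each
#'   activity profile (a constant shift of c_m trades off against the gene
#'   baselines in the likelihood).
#' @param sigma_shape,sigma_rate shape and rate of the inverse-gamma prior
#'   on the noise variance sigma^2 (vague by default).
#' @param n_samples posterior draws kept per chain (>= 100 for credible
#'   intervals).
#' @param n_burnin burn-in iterations discarded per chain.
#' @return list of class `"tfa_control"`.
#' @export
tfa_control <- function(tau_b = 1, tau_c = 0.3, mu_sd = 10, c0_sd = 0.25,
                        sigma_shape = 0.01, sigma_rate = 0.01,
                        n_samples = 2000, n_burnin = 1000) {
  stopifnot(tau_b > 0, tau_c > 0, mu_sd > 0, c0_sd > 0,
            sigma_shape > 0, sigma_rate > 0, n_burnin >= 0)
  if (n_samples < 100) stop("n_samples must be >= 100 for credible-interval reporting")
  structure(list(tau_b = tau_b, tau_c = tau_c, mu_sd = mu_sd, c0_sd = c0_sd,
                 sigma_shape = sigma_shape, sigma_rate = sigma_rate,
                 n_samples = as.integer(n_samples), n_burnin = as.integer(n_burnin)),
            class = "tfa_control")
}

#' Infer TF activity profiles from expression and regulon connectivity
#'
#' Fits a linear-Gaussian latent-variable model in which the log2 expression
#' ratio of gene g at timepoint t is
#' \deqn{y_{gt} = \mu_g + \sum_m X_{gm} b_{gm} c_{mt} + \varepsilon_{gt},
#'   \qquad \varepsilon_{gt} \sim N(0, \sigma^2),}
#' where X is the binary regulon connectivity, b_gm the (sign-constrained,
#' when the regulon sign is known) regulatory weight, and c_mt the latent
#' activity of TF m at time t, given a Gaussian random-walk prior over the
#' sampling grid. Inference is by Gibbs sampling with forward-filter
#' backward-sampling updates for each activity profile; missing expression
#' cells are dropped from the likelihood, never imputed.
#'
#' Because only the products b_gm c_mt are likelihood-identified, reported
#' activities are put in a canonical gauge per posterior draw: each TF's
#' weight vector is scaled to unit root-mean-square over its targets (the
#' activity absorbs the scale, so response amplitudes are comparable across
#' independently fitted conditions), and the sign is oriented so that the
#' majority of sign-annotated weights agree with their annotation, falling
#' back, for TFs without any signed edge, to making the profile's largest
#' absolute excursion positive.
#'
#' @param expr an [expression_timecourse()] of log2 ratios to the minute-0
#'   baseline.
#' @param network a [regulon_network()], or a prebuilt
#'   [build_connectivity()] result.
#' @param control a [tfa_control()] list of priors and sampler settings.
#' @param chains number of independent chains (run sequentially).
#' @param seed integer seed; mandatory so every fit is reproducible
#'   draw-for-draw.
#' @param fixed optional list fixing parameters (mainly for validation
#'   studies): `b` (scalar or genes x TFs matrix of fixed weights), `mu`
#'   (scalar or per-gene vector), `sigma` (known noise sd). Fixed blocks are
#'   not sampled, and with `b` fixed the reported activities are the raw
#'   (un-normalised) draws since the gauge is then externally determined.
#' @return An object of class `"tfa"`: list with `posterior` (a
#'   [tfa_posterior()] of normalised activities), `raw_draws` (un-normalised
#'   activity array), `weights` (posterior-mean b, genes x TFs, raw gauge),
#'   `sigma_draws`, `mu_mean`, `fitted_mean`, `connectivity`, `data`,
#'   `control`, `seed`, `chains` and the matched `call`.
#' @examples
#' cfg <- tfa_sim_config(n_genes = 30, n_tfs = 2, mean_regulon_size = 10,
#'                       noise_sd = 0.2, seed = 7)
#' sim <- simulate_tfa_data(cfg)
#' fit <- tfa(sim$expr$A, sim$network, seed = 7,
#'            control = tfa_control(n_samples = 200, n_burnin = 200))
#' coef(fit)
#' @export
tfa <- function(expr, network, control = tfa_control(), chains = 2, seed,
                fixed = list()) {
  cl <- match.call()
  stopifnot(inherits(expr, "expression_timecourse"))
  if (missing(seed)) stop("'seed' is mandatory: every fit must be reproducible")
  stopifnot(inherits(control, "tfa_control"), chains >= 1)
  conn <- if (inherits(network, "connectivity_matrix")) network
          else build_connectivity(network, expr)
  if (!all(conn$genes %in% expr$genes))
    stop("connectivity matrix contains genes absent from the expression matrix")

  Y <- expr$values[match(conn$genes, expr$genes), , drop = FALSE]
  obs <- (!is.na(Y)) * 1
  Yc <- Y; Yc[is.na(Yc)] <- 0
  S <- conn$sign; S[is.na(S)] <- 0L
  G <- nrow(Y); M <- ncol(conn$X); T <- ncol(Y)

  # a TF is uninformed if none of its targets has any observed cell
  any_obs <- rowSums(obs) > 0
  uninformed <- conn$tfs[colSums(conn$X[any_obs, , drop = FALSE]) == 0]

  fix_b <- !is.null(fixed$b)
  b_fixed <- matrix(0, G, M)
  if (fix_b) {
    b_fixed <- if (length(fixed$b) == 1L) conn$X * fixed$b else as.matrix(fixed$b)
    stopifnot(all(dim(b_fixed) == c(G, M)))
  }
  fix_mu <- !is.null(fixed$mu)
  mu_fixed <- if (fix_mu) rep_len(fixed$mu, G) else numeric(G)
  fix_sigma <- !is.null(fixed$sigma)
  sigma_fixed <- if (fix_sigma) fixed$sigma else 1

  set.seed(as.integer(seed))
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res[[ch]] <- tfa_gibbs_chain(Yc, obs, conn$X, S, expr$time,
                                 control$tau_b, control$tau_c, control$mu_sd,
                                 control$c0_sd, control$sigma_shape,
                                 control$sigma_rate, control$n_samples,
                                 control$n_burnin, fix_b, b_fixed,
                                 fix_mu, mu_fixed, fix_sigma, sigma_fixed)
  }

  n_keep <- control$n_samples
  n_tot <- n_keep * chains
  # raw activity draws: array n_tot x M x T
  raw <- array(0, c(n_tot, M, T))
  for (ch in seq_len(chains)) {
    cc <- res[[ch]]$C                       # M x T x n_keep
    raw[(ch - 1) * n_keep + seq_len(n_keep), , ] <- aperm(cc, c(3, 1, 2))
  }
  chain_id <- rep(seq_len(chains), each = n_keep)
  edges <- res[[1]]$edges                    # n_edges x 2 (gene, tf), 1-based
  Ball <- do.call(rbind, lapply(res, `[[`, "B"))   # n_tot x n_edges
  Muall <- do.call(rbind, lapply(res, `[[`, "mu"))
  sig <- unlist(lapply(res, `[[`, "sigma"))
  fitted_mean <- Reduce(`+`, lapply(res, `[[`, "fitted_mean")) / chains
  dimnames(fitted_mean) <- dimnames(Y)

  act <- if (fix_b) raw else normalize_draws(raw, Ball, edges, S, M)

  post <- tfa_posterior(act, conn$tfs, expr$time, chain = chain_id,
                        uninformed = uninformed)
  Bmean <- matrix(0, G, M, dimnames = list(conn$genes, conn$tfs))
  Bmean[edges] <- colMeans(Ball)
  structure(list(posterior = post, raw_draws = raw,
                 weight_draws = Ball, edge_index = edges,
                 weights = Bmean, sigma_draws = sig,
                 mu_mean = setNames(colMeans(Muall), conn$genes),
                 mu_draws = Muall,
                 fitted_mean = fitted_mean, connectivity = conn,
                 data = list(Y = Y, time = expr$time, condition = expr$condition),
                 control = control, seed = seed, chains = chains,
                 fixed = fixed, call = cl),
            class = "tfa")
}

# put each draw of (b, c) into the canonical gauge: per TF, b scaled to unit
# RMS over its targets (activity absorbs the scale) and sign oriented by the
# sign-annotated weights, else by the rise of the activity profile.
normalize_draws <- function(raw, Ball, edges, S, M) {
  n <- dim(raw)[1]; T <- dim(raw)[3]
  act <- raw
  for (m in seq_len(M)) {
    sel <- which(edges[, 2] == m)
    if (!length(sel)) next
    bm <- Ball[, sel, drop = FALSE]                 # n x n_targets
    rms <- sqrt(rowMeans(bm^2))
    rms[rms == 0] <- 1
    sgn_edges <- S[edges[sel, 1, drop = FALSE][, 1], m]
    has_sign <- any(sgn_edges != 0)
    if (has_sign) {
      stat <- as.vector(bm %*% ifelse(sgn_edges == 0, 0, sgn_edges))
      flip <- ifelse(stat < 0, -1, 1)
    } else {
      # orient by the sign of the largest absolute excursion: stable for
      # pulse-like profiles whose endpoints both sit near zero
      peak <- apply(raw[, m, , drop = FALSE], 1, function(v) v[which.max(abs(v))])
      flip <- ifelse(peak < 0, -1, 1)
    }
    act[, m, ] <- raw[, m, ] * (rms * flip)
  }
  act
}
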