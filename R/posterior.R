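#' Posterior over TF activity profiles
#'
#' Container for posterior draws of per-TF, per-timepoint activities, with
#' central 95% credible intervals and split-chain convergence diagnostics.
#' Normally produced by [tfa()]; the constructor is exported so that draw
#' sets from other sources (or constructed ones, e.g. for calibration
#' studies) can enter the coherence analysis.
#'
#' @param draws numeric array `n_draws x n_tfs x n_timepoints` of activity
#'   draws.
#' @param tf_ids character vector of TF identifiers (length `n_tfs`).
#' @param time numeric vector of timepoints in minutes (ascending).
#' @param chain integer vector of length `n_draws` assigning each draw to a
#'   chain (used for split-chain scale-reduction); a single chain is assumed
#'   if omitted.
#' @param uninformed character vector of TF ids whose targets carried no
#'   observed data (returned at the prior).
#' @return Object of class `"tfa_posterior"` with elements `draws`, `tf_ids`,
#'   `time`, `mean`, `lower`, `upper` (TFs x timepoints), `rhat` (per TF,
#'   max over timepoints) and `uninformed`.
#' @export
tfa_posterior <- function(draws, tf_ids, time, chain = NULL, uninformed = character()) {
  draws <- unclass(draws)
  stopifnot(length(dim(draws)) == 3L)
  n <- dim(draws)[1]; M <- dim(draws)[2]; T <- dim(draws)[3]
  if (length(tf_ids) != M) stop("tf_ids length does not match draws")
  if (length(time) != T) stop("time length does not match draws")
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly ascending")
  if (is.null(chain)) chain <- rep(1L, n)
  if (length(chain) != n) stop("chain length does not match draws")
  mn <- apply(draws, c(2, 3), mean)
  lo <- apply(draws, c(2, 3), quantile, probs = 0.025, names = FALSE)
  hi <- apply(draws, c(2, 3), quantile, probs = 0.975, names = FALSE)
  dimnames(mn) <- dimnames(lo) <- dimnames(hi) <-
    list(tf_ids, format(time, trim = TRUE))
  rh <- vapply(seq_len(M), function(m) {
    max(vapply(seq_len(T), function(t) split_rhat(draws[, m, t], chain), numeric(1)))
  }, numeric(1))
  names(rh) <- tf_ids
  structure(list(draws = draws, tf_ids = tf_ids, time = time,
                 mean = mn, lower = lo, upper = hi, rhat = rh,
                 chain = chain, uninformed = uninformed),
            class = "tfa_posterior")
}

# split-chain potential scale reduction (Gelman-Rubin with halved chains)
split_rhat <- function(x, chain) {
  parts <- unlist(lapply(split(x, chain), function(v) {
    h <- length(v) %/% 2L
    if (h < 2L) return(list(v))
    list(v[seq_len(h)], v[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  parts <- parts[lengths(parts) >= 2L]
  if (length(parts) < 2L) return(NA_real_)
  n <- min(lengths(parts))
  parts <- lapply(parts, function(v) v[seq_len(n)])
  means <- vapply(parts, mean, numeric(1))
  vars <- vapply(parts, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.tfa_posterior <- function(x, ...) {
  cat("TF activity posterior:", length(x$tf_ids), "TFs x", length(x$time),
      "timepoints,", dim(x$draws)[1], "draws (", length(unique(x$chain)), "chain(s) )\n")
  cat("  max split-Rhat:", format(max(x$rhat, na.rm = TRUE), digits = 3), "\n")
  if (length(x$uninformed))
    cat("  uninformed TFs (returned at prior):", paste(x$uninformed, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.tfa_posterior <- function(x, ...) {
  M <- length(x$tf_ids); T <- length(x$time)
  data.frame(tf = rep(x$tf_ids, each = T),
             minute = rep(x$time, times = M),
             mean = as.vector(t(x$mean)),
             lo95 = as.vector(t(x$lower)),
             hi95 = as.vector(t(x$upper)),
             flag = ifelse(rep(x$tf_ids, each = T) %in% x$uninformed,
                           "uninformed", ""),
             stringsAsFactors = FALSE)
}

#' Activity profile of one TF
#'
#' The posterior mean and central 95% credible interval of one TF's activity,
#' ordered by ascending time — the per-TF view used for activity-profile
#' figures.
#'
#' @param object a [tfa()] fit or [tfa_posterior()].
#' @param tf_id TF identifier.
#' @return data frame with columns `minute`, `mean`, `lo95`, `hi95` and an
#'   attribute `uninformed` (logical).
#' @export
activity_profile <- function(object, tf_id) {
  post <- as_tfa_posterior(object)
  m <- match(tf_id, post$tf_ids)
  if (is.na(m))
    stop("unknown TF '", tf_id, "'; available: ", paste(post$tf_ids, collapse = ", "))
  out <- data.frame(minute = post$time, mean = post$mean[m, ],
                    lo95 = post$lower[m, ], hi95 = post$upper[m, ],
                    row.names = NULL)
  attr(out, "uninformed") <- tf_id %in% post$uninformed
  out
}

#' Coerce to a TF activity posterior
#' @param object a `tfa` fit or `tfa_posterior`.
#' @return a `tfa_posterior`.
#' @export
as_tfa_posterior <- function(object) {
  if (inherits(object, "tfa_posterior")) return(object)
  if (inherits(object, "tfa")) return(object$posterior)
  stop("cannot coerce object of class ", paste(class(object), collapse = "/"),
       " to tfa_posterior")
}
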