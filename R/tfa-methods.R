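#' @export
print.tfa <- function(x, ...) {
  cat("TF activity model fit",
      if (nzchar(x$data$condition)) paste0("(", x$data$condition, ")"), "\n")
  cat("Call: "); print(x$call)
  cat(nrow(x$data$Y), "genes,", length(x$connectivity$tfs), "TFs,",
      length(x$data$time), "timepoints;",
      dim(x$posterior$draws)[1], "posterior draws in", x$chains, "chain(s)\n")
  cat("Posterior-mean noise sd:", format(mean(x$sigma_draws), digits = 3), "\n")
  bad <- x$posterior$rhat[!is.na(x$posterior$rhat) & x$posterior$rhat > 1.1]
  if (length(bad))
    cat("Non-converged TFs (split-Rhat > 1.1):",
        paste(names(bad), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.tfa <- function(object, ...) {
  post <- object$posterior
  peak <- apply(abs(post$mean), 1, max)
  tab <- data.frame(tf = post$tf_ids,
                    n_targets = colSums(object$connectivity$X),
                    peak_abs_activity = peak,
                    rhat = post$rhat,
                    uninformed = post$tf_ids %in% post$uninformed,
                    row.names = NULL)
  out <- list(call = object$call, tfs = tab,
              sigma = quantile(object$sigma_draws, c(0.025, 0.5, 0.975)),
              n_draws = dim(post$draws)[1], chains = object$chains,
              dropped_tfs = object$connectivity$dropped_tfs)
  class(out) <- "summary.tfa"
  out
}

#' @export
print.summary.tfa <- function(x, ...) {
  cat("TF activity model summary\n")
  cat("Noise sd posterior (2.5/50/97.5%):",
      paste(format(x$sigma, digits = 3), collapse = " / "), "\n")
  cat(x$n_draws, "draws in", x$chains, "chain(s)\n\n")
  print(x$tfs, digits = 3)
  if (length(x$dropped_tfs))
    cat("\nDropped TFs (no targets in data):", paste(x$dropped_tfs, collapse = ", "), "\n")
  non_conv <- x$tfs$tf[!is.na(x$tfs$rhat) & x$tfs$rhat > 1.1]
  if (length(non_conv)) {
    warning("chains may not have converged for TF(s): ",
            paste(non_conv, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Extract posterior-mean activities or weights
#'
#' @param object a [tfa()] fit.
#' @param type `"activities"` (default) for the TFs x timepoints matrix of
#'   posterior-mean activities in the canonical gauge, or `"weights"` for the
#'   genes x TFs posterior-mean regulatory weights (raw gauge).
#' @param ... unused.
#' @return numeric matrix.
#' @export
coef.tfa <- function(object, type = c("activities", "weights"), ...) {
  type <- match.arg(type)
  if (type == "activities") object$posterior$mean else object$weights
}

#' @export
fitted.tfa <- function(object, ...) object$fitted_mean

#' @export
residuals.tfa <- function(object, ...) object$data$Y - object$fitted_mean

#' Posterior-mean predictions from a TF activity fit
#'
#' @param object a [tfa()] fit.
#' @param type `"response"` for the posterior-mean reconstructed expression
#'   surface (genes x timepoints), `"activity"` for posterior-mean TF
#'   activities.
#' @param ... unused.
#' @export
predict.tfa <- function(object, type = c("response", "activity"), ...) {
  type <- match.arg(type)
  if (type == "response") object$fitted_mean else object$posterior$mean
}

#' Posterior-predictive simulation of expression matrices
#'
#' Draws complete expression matrices from the posterior predictive: for each
#' simulation a kept posterior draw of (mu, b, c, sigma) is selected and a
#' new Gaussian noise realisation added.
#'
#' @param object a [tfa()] fit.
#' @param nsim number of simulated matrices.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `nsim` genes x timepoints matrices.
#' @export
simulate.tfa <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- dim(object$raw_draws)[1]
  G <- nrow(object$data$Y); T <- length(object$data$time)
  idx <- sample.int(n, nsim, replace = nsim > n)
  edges <- object$edge_index
  out <- lapply(idx, function(i) {
    Fi <- matrix(0, G, T, dimnames = dimnames(object$data$Y))
    b <- object$weight_draws[i, ]
    for (e in seq_len(nrow(edges)))
      Fi[edges[e, 1], ] <- Fi[edges[e, 1], ] + b[e] * object$raw_draws[i, edges[e, 2], ]
    Fi + object$mu_draws[i, ] + matrix(rnorm(G * T, 0, object$sigma_draws[i]), G, T)
  })
  out
}

#' Plot inferred TF activity profiles
#'
#' One panel per TF: posterior-mean activity over time with a shaded 95%
#' credible band.
#'
#' @param x a [tfa()] fit or [tfa_posterior()].
#' @param tfs TF ids to plot (all by default).
#' @param ... passed to [plot()].
#' @export
plot.tfa <- function(x, tfs = NULL, ...) {
  plot(as_tfa_posterior(x), tfs = tfs, ...)
}

#' @export
plot.tfa_posterior <- function(x, tfs = NULL, ...) {
  if (is.null(tfs)) tfs <- x$tf_ids
  old <- par(mfrow = c(ceiling(length(tfs) / 2), min(2, length(tfs))),
             mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (tf in tfs) {
    pr <- activity_profile(x, tf)
    plot(pr$minute, pr$mean, type = "n", ylim = range(pr$lo95, pr$hi95),
         xlab = "time (min)", ylab = "activity", main = tf, ...)
    polygon(c(pr$minute, rev(pr$minute)), c(pr$lo95, rev(pr$hi95)),
            col = adjustcolor("steelblue", 0.3), border = NA)
    lines(pr$minute, pr$mean, type = "b", pch = 19, col = "steelblue4")
    abline(h = 0, lty = 3)
  }
  invisible(x)
}
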