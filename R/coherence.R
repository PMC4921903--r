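#' Profile difference between two activity profiles
#'
#' One minus the absolute Pearson correlation between the two profiles:
#' 0 means identical kinetics (up to affine rescaling), 1 means completely
#' uncorrelated shapes.
#'
#' @param a,b numeric vectors of equal length (>= 3).
#' @return value in `[0, 1]`, or `NA` with attribute `reason` when either
#'   profile is constant (Pearson correlation undefined).
#' @export
profile_difference <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 3) stop("profiles must have length >= 3")
  if (sd(a) == 0 || sd(b) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "constant profile: Pearson correlation undefined"
    return(out)
  }
  1 - abs(cor(a, b))
}

#' Magnitude difference between two activity profiles
#'
#' The absolute difference of the Euclidean norms of the two profiles — the
#' amplitude component of the two-condition comparison.
#'
#' @param a,b numeric vectors of equal length.
#' @return non-negative value.
#' @export
magnitude_difference <- function(a, b) {
  stopifnot(length(a) == length(b))
  abs(sqrt(sum(a^2)) - sqrt(sum(b^2)))
}

#' Quadrant classification of a coherence point
#'
#' Places a (profile difference, magnitude difference) point in one of the
#' four quadrants of the coherence plot: TFs responding similarly in both
#' kinetics and amplitude sit near the origin (lower-left), while the
#' upper-right corner collects TFs that respond differently in both.
#' Boundary values go to the high side (`>=`).
#'
#' @param d profile difference in `[0, 1]` (may be `NA` for a degenerate
#'   profile).
#' @param m magnitude difference (>= 0).
#' @param d_threshold vertical split of the profile-difference axis.
#' @param m_threshold horizontal split of the magnitude axis.
#' @return one of `"lower-left"`, `"upper-left"`, `"lower-right"`,
#'   `"upper-right"`, `"undefined"`.
#' @export
classify_quadrant <- function(d, m, d_threshold = 0.5, m_threshold) {
  if (is.na(d)) return("undefined")
  stopifnot(is.finite(d), is.finite(m))
  if (d < d_threshold) {
    if (m < m_threshold) "lower-left" else "upper-left"
  } else {
    if (m < m_threshold) "lower-right" else "upper-right"
  }
}

#' Two-condition coherence statistics for one TF
#'
#' Compares one TF's activity posterior between two conditions: the profile
#' difference d = 1 - |Pearson| and the magnitude difference
#' m = | ||a|| - ||b|| | are computed on the posterior-mean profiles; their
#' 95% credible intervals come from pairing independent posterior draws
#' across the two (independently fitted) conditions. A TF is flagged
#' `omitted` when the 95% interval of the absolute Pearson correlation has
#' half-width greater than 0.15 — such points are retained in tables but
#' conventionally left off the coherence plot.
#'
#' @param postA,postB [tfa_posterior()] objects (or [tfa()] fits) for the
#'   two conditions, sharing the timepoint grid.
#' @param tf_id TF present in both posteriors.
#' @param n_draws number of paired draws for the intervals (default: all
#'   available, subsampled to the smaller posterior).
#' @param seed integer seed for the draw pairing.
#' @param d_threshold,m_threshold quadrant thresholds; if `m_threshold` is
#'   `NULL` the quadrant is left `NA` (set by [coherence_table()], which
#'   knows the across-TF magnitude scale).
#' @return one-row data frame: `tf`, `profile_difference`,
#'   `magnitude_difference`, `d_lo95`, `d_hi95`, `m_lo95`, `m_hi95`,
#'   `omitted`, `quadrant`.
#' @export
coherence_point <- function(postA, postB, tf_id, n_draws = NULL, seed = 1,
                            d_threshold = 0.5, m_threshold = NULL) {
  postA <- as_tfa_posterior(postA); postB <- as_tfa_posterior(postB)
  if (!isTRUE(all.equal(postA$time, postB$time)))
    stop("the two posteriors do not share the timepoint grid")
  ia <- match(tf_id, postA$tf_ids); ib <- match(tf_id, postB$tf_ids)
  if (is.na(ia) || is.na(ib)) stop("TF '", tf_id, "' absent from one of the posteriors")

  a_mean <- postA$mean[ia, ]; b_mean <- postB$mean[ib, ]
  d <- profile_difference(a_mean, b_mean)
  m <- magnitude_difference(a_mean, b_mean)

  nA <- dim(postA$draws)[1]; nB <- dim(postB$draws)[1]
  if (is.null(n_draws)) n_draws <- min(nA, nB)
  set.seed(as.integer(seed))
  idxA <- if (n_draws == nA) seq_len(nA) else sample.int(nA, n_draws)
  idxB <- if (n_draws == nB) seq_len(nB) else sample.int(nB, n_draws)

  A <- postA$draws[idxA, ia, , drop = TRUE]
  B <- postB$draws[idxB, ib, , drop = TRUE]
  if (is.null(dim(A))) A <- matrix(A, nrow = 1)
  if (is.null(dim(B))) B <- matrix(B, nrow = 1)

  di <- vapply(seq_len(n_draws), function(i) {
    ai <- A[i, ]; bi <- B[i, ]
    if (sd(ai) == 0 || sd(bi) == 0) NA_real_ else 1 - abs(cor(ai, bi))
  }, numeric(1))
  mi <- vapply(seq_len(n_draws), function(i) {
    abs(sqrt(sum(A[i, ]^2)) - sqrt(sum(B[i, ]^2)))
  }, numeric(1))

  ci_d <- quantile(di, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  ci_m <- quantile(mi, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  # half-width of the |rho| interval equals half-width of the d interval;
  # the epsilon keeps a half-width of exactly 0.15 on the retained side
  omitted <- (ci_d[2] - ci_d[1]) / 2 > 0.15 + 1e-9

  quadrant <- if (is.null(m_threshold)) NA_character_
              else classify_quadrant(d, m, d_threshold, m_threshold)
  data.frame(tf = tf_id,
             profile_difference = as.numeric(d), magnitude_difference = m,
             d_lo95 = ci_d[1], d_hi95 = ci_d[2],
             m_lo95 = ci_m[1], m_hi95 = ci_m[2],
             omitted = omitted, quadrant = quadrant,
             stringsAsFactors = FALSE)
}

#' Coherence table over all shared TFs
#'
#' Runs [coherence_point()] for every TF present in both condition
#' posteriors and assigns quadrants. Omitted TFs (|Pearson| interval
#' half-width > 0.15) are retained in the table with `omitted = TRUE`;
#' omission affects plotting and reporting, not storage.
#'
#' @inheritParams coherence_point
#' @param d_threshold profile-difference split (default 0.5, the midpoint of
#'   `[0, 1]`).
#' @param m_threshold magnitude split; default `NULL` uses the median
#'   magnitude difference across non-omitted TFs with a defined d.
#' @return data frame, one row per shared TF (see [coherence_point()]),
#'   sorted by TF id, with the thresholds in attributes `d_threshold` and
#'   `m_threshold`.
#' @export
coherence_table <- function(postA, postB, d_threshold = 0.5, m_threshold = NULL,
                            n_draws = NULL, seed = 1) {
  postA <- as_tfa_posterior(postA); postB <- as_tfa_posterior(postB)
  shared <- sort(intersect(postA$tf_ids, postB$tf_ids))
  if (!length(shared)) stop("the two posteriors share no TFs")
  rows <- lapply(seq_along(shared), function(k)
    coherence_point(postA, postB, shared[k], n_draws = n_draws,
                    seed = seed + k, d_threshold = d_threshold,
                    m_threshold = NULL))
  tab <- do.call(rbind, rows)
  if (is.null(m_threshold)) {
    ok <- !tab$omitted & !is.na(tab$profile_difference)
    m_threshold <- if (any(ok)) median(tab$magnitude_difference[ok])
                   else median(tab$magnitude_difference)
  }
  tab$quadrant <- vapply(seq_len(nrow(tab)), function(i)
    classify_quadrant(tab$profile_difference[i], tab$magnitude_difference[i],
                      d_threshold, m_threshold), character(1))
  attr(tab, "d_threshold") <- d_threshold
  attr(tab, "m_threshold") <- m_threshold
  tab
}

#' Coherence scatter plot
#'
#' The two-condition comparison at a glance: profile difference on the
#' abscissa, magnitude difference on the ordinate, one labelled point per
#' non-omitted TF.
#'
#' @param tab a [coherence_table()] result.
#' @param show_omitted include omitted TFs (open symbols).
#' @param ... passed to [plot()].
#' @export
plot_coherence <- function(tab, show_omitted = FALSE, ...) {
  keep <- if (show_omitted) !is.na(tab$profile_difference)
          else !tab$omitted & !is.na(tab$profile_difference)
  x <- tab$profile_difference[keep]; y <- tab$magnitude_difference[keep]
  plot(x, y, xlim = c(0, 1), ylim = c(0, max(y, 1) * 1.1),
       xlab = "profile difference (1 - |Pearson r|)",
       ylab = "magnitude difference (| ||a|| - ||b|| |)",
       pch = ifelse(tab$omitted[keep], 1, 19), ...)
  text(x, y, tab$tf[keep], pos = 3, cex = 0.7)
  abline(v = attr(tab, "d_threshold"), h = attr(tab, "m_threshold"), lty = 2)
  invisible(tab)
}
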