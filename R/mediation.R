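## Bootstrap mediation testing on standardized SEM paths: percentile and
## bias-corrected 95% intervals for the direct, indirect and total effects.

# bias-corrected CI: z0 from the proportion of replicates below the
# full-sample estimate, bounds at Phi(2 z0 +/- z_alpha) quantiles
bc_ci <- function(boot, est, level = 0.95) {
  B <- length(boot)
  prop <- mean(boot < est)
  prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(prop)
  za <- stats::qnorm((1 + level) / 2)
  stats::quantile(boot, stats::pnorm(2 * z0 + c(-za, za)), names = FALSE)
}

perc_ci <- function(boot, level = 0.95) {
  stats::quantile(boot, c((1 - level) / 2, (1 + level) / 2), names = FALSE)
}

boot_p <- function(boot) {
  min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)))
}

#' Bootstrap the standardized paths of a SEM
#'
#' Resamples respondents with replacement \code{B} times, refits the model on
#' each resample's covariance matrix (warm-started from the full-sample
#' estimate), and collects the requested standardized parameters per
#' replicate. Replicates with a non-positive-definite resample covariance or
#' a failed refit are dropped and counted.
#'
#' @param model a [sem_model()].
#' @param data Likert response data.
#' @param paths character vector of standardized parameter names to track
#'   (e.g. \code{"Behavior~Motivation"}); defaults to all structural paths.
#' @param B number of resamples.
#' @param seed integer seed; the resampling plan is fully reproducible.
#' @param max_drop_rate error when more than this fraction of replicates is
#'   dropped.
#' @return list with the full-sample \code{fit}, \code{draws} (matrix of
#'   completed replicates x paths), \code{dropped}, \code{B}, \code{n}.
#' @export
bootstrap_paths <- function(model, data, paths = NULL, B = 5000L, seed = 1L,
                            max_drop_rate = 0.1) {
  stopifnot(inherits(model, "sem_model"), B >= 100L)
  if (is.null(paths))
    paths <- unlist(lapply(names(model$paths), function(y)
      paste0(y, "~", model$paths[[y]])))
  xm <- response_matrix(data, model$observed)
  xm <- xm[stats::complete.cases(xm), , drop = FALSE]
  n <- nrow(xm)
  full <- fit_ml(model, stats::cov(xm), n)
  bad <- setdiff(paths, names(full$std))
  if (length(bad)) stop("model lacks required paths: ",
                        paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, B, length(paths),
                  dimnames = list(NULL, paths))
  dropped <- 0L
  for (b in seq_len(B)) {
    Sb <- stats::cov(xm[sample.int(n, n, replace = TRUE), , drop = FALSE])
    fb <- tryCatch({
      chol(Sb)
      fit_ml(model, Sb, n, start = unname(full$theta))
    }, error = function(e) NULL)
    if (is.null(fb)) { dropped <- dropped + 1L; next }
    draws[b, ] <- fb$std[paths]
  }
  if (dropped > max_drop_rate * B)
    stop(sprintf("%d of %d bootstrap replicates dropped (non-convergence or non-PD resample)",
                 dropped, B))
  list(fit = full, draws = draws[stats::complete.cases(draws), , drop = FALSE],
       dropped = dropped, B = B, n = n)
}

#' Bootstrap test of a mediated path in a fitted SEM
#'
#' Resamples respondents with replacement, refits the model on each resample
#' (warm-started from the full-sample estimate), and computes per replicate
#' the standardized direct effect (X to Y), the indirect effect as the product
#' of the standardized X-to-M and M-to-Y paths, and the total effect.
#' Percentile and bias-corrected 95% intervals and two-sided bootstrap
#' p-values are reported for each effect, together with a
#' none/partial/full mediation classification (full: indirect significant and
#' direct not; significance by the bias-corrected interval excluding zero).
#'
#' @param model a [sem_model()] containing the paths \code{m ~ x} and
#'   \code{y ~ m}, \code{y ~ x}.
#' @param data Likert response data.
#' @param x,m,y names of the exposure, mediator and outcome latents.
#' @param B number of bootstrap resamples (>= 100).
#' @param seed integer seed; the resampling plan is fully reproducible.
#' @param level confidence level (default 0.95).
#' @param max_drop_rate error when more than this fraction of replicates is
#'   dropped for non-convergence or a non-positive-definite resample
#'   covariance (default 0.1).
#' @return object of class \code{comb_mediation}: effect table, bootstrap
#'   draws, replicate accounting, classification.
#' @export
bootstrap_mediation <- function(model, data, x = "Capability",
                                m = "Motivation", y = "Behavior",
                                B = 5000L, seed = 1L, level = 0.95,
                                max_drop_rate = 0.1) {
  p_xm <- paste0(m, "~", x); p_my <- paste0(y, "~", m); p_xy <- paste0(y, "~", x)
  bp <- bootstrap_paths(model, data, c(p_xm, p_my, p_xy), B = B,
                        seed = seed, max_drop_rate = max_drop_rate)
  full <- bp$fit
  est <- c(direct = unname(full$std[p_xy]),
           indirect = unname(full$std[p_xm] * full$std[p_my]))
  est["total"] <- est[["direct"]] + est[["indirect"]]
  draws <- cbind(direct = bp$draws[, p_xy],
                 indirect = bp$draws[, p_xm] * bp$draws[, p_my])
  draws <- cbind(draws, total = draws[, "direct"] + draws[, "indirect"])

  eff <- lapply(names(est), function(e) {
    bt <- draws[, e]
    list(estimate = est[[e]], se = stats::sd(bt),
         bc = bc_ci(bt, est[[e]], level), perc = perc_ci(bt, level),
         p = boot_p(bt))
  })
  names(eff) <- names(est)
  n <- bp$n; dropped <- bp$dropped
  ind_sig <- prod(eff$indirect$bc) > 0
  dir_sig <- prod(eff$direct$bc) > 0
  classification <- if (!ind_sig) "none" else if (dir_sig) "partial" else "full"
  structure(list(x = x, m = m, y = y, effects = eff, draws = draws,
                 B = B, n = n, dropped = dropped, level = level,
                 classification = classification,
                 indirect_significant = ind_sig,
                 direct_significant = dir_sig,
                 full_fit = full),
            class = "comb_mediation")
}

#' @export
print.comb_mediation <- function(x, digits = 3, ...) {
  cat(sprintf("Bootstrap mediation: %s -> %s -> %s (B = %d used, %d dropped, n = %d)\n",
              x$x, x$m, x$y, nrow(x$draws), x$dropped, x$n))
  cat(sprintf("%-10s %8s %8s %20s %20s %8s\n", "Effect", "Value", "SE",
              "Bias-corrected CI", "Percentile CI", "p"))
  for (e in names(x$effects)) {
    f <- x$effects[[e]]
    cat(sprintf("%-10s %8.3f %8.3f (%8.3f, %8.3f) (%8.3f, %8.3f) %8.3f\n",
                e, f$estimate, f$se, f$bc[1], f$bc[2],
                f$perc[1], f$perc[2], f$p))
  }
  cat(sprintf("Classification: %s mediation\n", x$classification))
  invisible(x)
}

#' Mediation effect table in long form
#'
#' One row per effect type with the estimate, bootstrap SE, bias-corrected
#' and percentile intervals and p-values, mirroring the usual mediation
#' reporting layout.
#'
#' @param med a [bootstrap_mediation()] result.
#' @return data frame.
#' @export
mediation_table <- function(med) {
  stopifnot(inherits(med, "comb_mediation"))
  do.call(rbind, lapply(names(med$effects), function(e) {
    f <- med$effects[[e]]
    data.frame(path = paste(med$x, "->", med$m, "->", med$y),
               effect = e, value = f$estimate, se = f$se,
               bc_lower = f$bc[1], bc_upper = f$bc[2],
               perc_lower = f$perc[1], perc_upper = f$perc[2],
               p = f$p, row.names = NULL)
  }))
}
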