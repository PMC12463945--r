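## Item screening, EFA (principal components + varimax), sampling adequacy,
## reliability and validity statistics. Sample variances/correlations use the
## n-1 denominator throughout.

#' Corrected item-total correlations
#'
#' For each item in a subscale, the Pearson correlation between the item and
#' the sum of the remaining items (the rest score).
#'
#' @param data Likert response data (data frame with item columns).
#' @param items character vector of >= 2 item codes forming the subscale.
#' @return named numeric vector of corrected item-total correlations.
#' @export
corrected_item_total <- function(data, items) {
  x <- response_matrix(data, items)
  if (ncol(x) < 2L) stop("need at least 2 items")
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3L) stop("need at least 3 complete respondents")
  v <- apply(x, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance item: ", paste(items[v == 0], collapse = ", "))
  tot <- rowSums(x)
  vapply(seq_along(items), function(j) {
    rest <- tot - x[, j]
    if (stats::var(rest) == 0) NA_real_ else stats::cor(x[, j], rest)
  }, numeric(1)) |> stats::setNames(items)
}

#' Cronbach's alpha
#'
#' \code{alpha = k/(k-1) * (1 - sum(var_i)/var_total)} with sample (n-1)
#' variances.
#'
#' @inheritParams corrected_item_total
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(data, items) {
  x <- response_matrix(data, items)
  k <- ncol(x)
  if (k < 2L) stop("need at least 2 items")
  x <- x[stats::complete.cases(x), , drop = FALSE]
  vt <- stats::var(rowSums(x))
  if (vt == 0) stop("zero total-score variance")
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / vt)
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' KMO compares squared correlations with squared anti-image partial
#' correlations obtained from the inverse correlation matrix:
#' \code{sum(r^2) / (sum(r^2) + sum(q^2))} over off-diagonal pairs.
#'
#' @param data Likert response data; all item columns are used unless
#'   \code{items} is given.
#' @param items optional subset of item columns.
#' @return list with \code{kmo} (overall statistic) and \code{msa}
#'   (per-item measures of sampling adequacy).
#' @export
kmo <- function(data, items = NULL) {
  x <- response_matrix(data, items)
  R <- stats::cor(x[stats::complete.cases(x), , drop = FALSE])
  Rinv <- tryCatch(solve(R), error = function(e)
    stop("singular correlation matrix; KMO undefined"))
  d <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * tcrossprod(d)          # anti-image partial correlations
  diag(Q) <- 0
  R0 <- R; diag(R0) <- 0
  r2 <- sum(R0^2); q2 <- sum(Q^2)
  if (r2 + q2 < 1e-12) stop("no common variance")
  list(kmo = r2 / (r2 + q2),
       msa = stats::setNames(colSums(R0^2) / (colSums(R0^2) + colSums(Q^2)),
                             colnames(x)))
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix is an identity matrix:
#' \code{chi2 = -(n - 1 - (2p + 5)/6) * ln|R|} on \code{p(p-1)/2} degrees of
#' freedom.
#'
#' @inheritParams kmo
#' @return list with \code{chisq}, \code{df}, \code{p.value}, \code{n},
#'   \code{p}.
#' @export
bartlett_sphericity <- function(data, items = NULL) {
  x <- response_matrix(data, items)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop("need more respondents than items")
  R <- stats::cor(x)
  ld <- determinant(R, logarithm = TRUE)
  if (ld$sign <= 0) stop("correlation matrix has non-positive determinant")
  chisq <- -(n - 1 - (2 * p + 5) / 6) * as.numeric(ld$modulus)
  df <- p * (p - 1) / 2
  list(chisq = chisq, df = df,
       p.value = stats::pchisq(chisq, df, lower.tail = FALSE), n = n, p = p)
}

## ---- varimax rotation (Kaiser-normalized pairwise sweeps) ----------------

# raw varimax criterion: sum over factors of column 4th-moment spread
varimax_criterion <- function(L) {
  p <- nrow(L)
  sum(colSums(L^4) - colSums(L^2)^2 / p)
}

varimax_rotate <- function(L, normalize = TRUE, eps = 1e-15, max_sweeps = 1000L) {
  p <- nrow(L); k <- ncol(L)
  if (k < 2L) return(list(loadings = L, rotmat = diag(k), sweeps = 0L))
  h <- if (normalize) sqrt(rowSums(L^2)) else rep(1, p)
  if (any(h == 0)) h[h == 0] <- 1
  A <- L / h
  rot <- diag(k)
  crit <- varimax_criterion(A)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
      x <- A[, i]; y <- A[, j]
      u <- x^2 - y^2; v <- 2 * x * y
      num <- 2 * (p * sum(u * v) - sum(u) * sum(v))
      den <- p * sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2)
      phi <- atan2(num, den) / 4
      if (abs(phi) > 1e-14) {
        cs <- cos(phi); sn <- sin(phi)
        A[, c(i, j)] <- cbind(x * cs + y * sn, -x * sn + y * cs)
        rot[, c(i, j)] <- cbind(rot[, i] * cs + rot[, j] * sn,
                                -rot[, i] * sn + rot[, j] * cs)
      }
    }
    newcrit <- varimax_criterion(A)
    if (newcrit - crit < eps || sweeps >= max_sweeps) break
    crit <- newcrit
  }
  list(loadings = A * h, rotmat = rot, sweeps = sweeps)
}

#' Principal-component factor analysis with varimax rotation
#'
#' Eigendecomposition of the item correlation matrix; components with
#' eigenvalue above \code{eigen_threshold} are retained, loadings are formed
#' as eigenvector times sqrt(eigenvalue), and the retained loadings are
#' varimax-rotated (Kaiser normalization, pairwise sweeps). The sign
#' convention makes each factor's largest-magnitude loading positive.
#'
#' @inheritParams kmo
#' @param eigen_threshold retention threshold on eigenvalues (default 1.0).
#' @return object of class \code{comb_efa}: rotated \code{loadings},
#'   \code{eigenvalues} (all p), \code{variance_explained} (percent, per
#'   retained factor, post-rotation), \code{communalities}, \code{sweeps}.
#' @export
efa_pca_varimax <- function(data, items = NULL, eigen_threshold = 1.0) {
  x <- response_matrix(data, items)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) <= ncol(x)) stop("need more respondents than items")
  R <- stats::cor(x)
  e <- eigen(R, symmetric = TRUE)
  keep <- which(e$values > eigen_threshold)
  if (!length(keep)) stop("no eigenvalue above threshold ", eigen_threshold)
  L <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                                length(keep))
  rownames(L) <- colnames(x)
  rot <- varimax_rotate(L)
  L <- rot$loadings
  # sign convention: largest |loading| per factor positive
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  colnames(L) <- paste0("F", seq_len(ncol(L)))
  structure(list(loadings = L,
                 eigenvalues = e$values,
                 variance_explained = 100 * colSums(L^2) / ncol(x),
                 communalities = rowSums(L^2),
                 sweeps = rot$sweeps,
                 n = nrow(x)),
            class = "comb_efa")
}

#' @export
print.comb_efa <- function(x, digits = 3, ...) {
  k <- ncol(x$loadings)
  cat(sprintf("Principal-component EFA: %d factors retained (eigenvalue > 1 rule)\n", k))
  cat(sprintf("  total variance explained: %.1f%%\n", sum(x$variance_explained)))
  print(round(x$loadings, digits))
  invisible(x)
}

#' Item retention rules after screening and EFA
#'
#' Applies, in order: the item-total screen (corrected item-total correlation
#' below \code{item_total}); the primary-loading rule (largest absolute
#' loading not above \code{loading}); the cross-loading rule (a second
#' absolute loading above \code{cross}); and the orphan-factor rule (factors
#' left with fewer than \code{min_items} surviving items are dissolved and
#' their items flagged). Each eliminated item gets exactly one primary reason,
#' the first rule that fires.
#'
#' @param solution a [efa_pca_varimax()] result.
#' @param item_total_r named vector of corrected item-total correlations for
#'   the same items (see [corrected_item_total()]).
#' @param item_total,loading,cross,min_items rule thresholds (defaults 0.5,
#'   0.5, 0.5, 3).
#' @return data frame (class \code{item_screening}) with one row per item:
#'   \code{item}, \code{item_total}, \code{primary_factor},
#'   \code{primary_loading}, \code{max_cross}, \code{retained}, \code{reason}
#'   (NA, \code{low_item_total}, \code{low_loading}, \code{cross_loading} or
#'   \code{orphan_factor}); thresholds are recorded as attributes.
#' @export
apply_item_retention_rules <- function(solution, item_total_r,
                                       item_total = 0.5, loading = 0.5,
                                       cross = 0.5, min_items = 3L) {
  L <- solution$loadings
  if (is.null(colnames(L))) colnames(L) <- paste0("F", seq_len(ncol(L)))
  if (!setequal(rownames(L), names(item_total_r)))
    stop("solution and screening must cover the same items")
  item_total_r <- item_total_r[rownames(L)]
  aL <- abs(L)
  prim <- apply(aL, 1, which.max)
  prim_load <- aL[cbind(seq_len(nrow(L)), prim)]
  max_cross <- vapply(seq_len(nrow(L)), function(i) {
    o <- aL[i, -prim[i]]
    if (length(o)) max(o) else 0
  }, numeric(1))
  reason <- rep(NA_character_, nrow(L))
  reason[item_total_r < item_total] <- "low_item_total"
  idx <- is.na(reason) & prim_load <= loading
  reason[idx] <- "low_loading"
  idx <- is.na(reason) & max_cross > cross
  reason[idx] <- "cross_loading"
  # orphan check on surviving items
  surv <- is.na(reason)
  for (f in seq_len(ncol(L))) {
    members <- surv & prim == f
    if (any(members) && sum(members) < min_items)
      reason[members] <- "orphan_factor"
  }
  out <- data.frame(item = rownames(L),
                    item_total = as.numeric(item_total_r),
                    primary_factor = colnames(L)[prim],
                    primary_loading = prim_load,
                    max_cross = max_cross,
                    retained = is.na(reason),
                    reason = reason,
                    row.names = NULL)
  attr(out, "thresholds") <- c(item_total = item_total, loading = loading,
                               cross = cross, min_items = min_items)
  class(out) <- c("item_screening", "data.frame")
  out
}

#' Average variance extracted
#'
#' \code{AVE = sum(loading^2) / k}: the mean squared standardized loading of a
#' construct, the usual convergent-validity statistic (acceptable above 0.5).
#'
#' @param loadings numeric vector of standardized loadings in (-1, 1].
#' @return scalar AVE.
#' @export
ave <- function(loadings) {
  if (!length(loadings)) stop("empty loading vector")
  if (any(loadings <= -1 | loadings > 1)) stop("loadings must lie in (-1, 1]")
  mean(loadings^2)
}

#' Composite reliability
#'
#' \code{CR = (sum(loading))^2 / ((sum(loading))^2 + sum(1 - loading^2))},
#' construct reliability from standardized loadings (acceptable above 0.7).
#'
#' @inheritParams ave
#' @return scalar CR.
#' @export
composite_reliability <- function(loadings) {
  if (!length(loadings)) stop("empty loading vector")
  if (any(loadings <= -1 | loadings > 1)) stop("loadings must lie in (-1, 1]")
  s2 <- sum(loadings)^2
  s2 / (s2 + sum(1 - loadings^2))
}

#' Fornell-Larcker discriminant validity
#'
#' Discriminant validity holds for a factor when the square root of its AVE
#' strictly exceeds the absolute correlation with every other factor.
#'
#' @param ave_by_domain named vector of AVE values, one per factor.
#' @param factor_correlations square correlation matrix with matching
#'   dimnames.
#' @return list with \code{sqrt_ave}, logical matrix \code{pass} (NA on the
#'   diagonal) and per-factor logical \code{discriminant}.
#' @export
fornell_larcker <- function(ave_by_domain, factor_correlations) {
  fs <- rownames(factor_correlations)
  if (is.null(fs) || !all(fs %in% names(ave_by_domain)))
    stop("AVE missing for some factors in the correlation matrix")
  sa <- sqrt(ave_by_domain[fs])
  pass <- outer(sa, rep(1, length(fs))) > abs(factor_correlations)
  diag(pass) <- NA
  dimnames(pass) <- dimnames(factor_correlations)
  list(sqrt_ave = sa, pass = pass,
       discriminant = apply(pass, 1, function(r) all(r[!is.na(r)])))
}

#' Reliability and validity report for a module's domains
#'
#' Convenience wrapper: per-domain Cronbach's alpha, CR and AVE computed from
#' supplied standardized loadings, domain-score correlations, and the
#' Fornell-Larcker table.
#'
#' @param data Likert response data.
#' @param spec an [instrument_spec()].
#' @param module module name, e.g. \code{"Capability"}.
#' @param loadings named list domain -> standardized loading vector. Defaults
#'   to one EFA per module with loadings read off each domain's primary
#'   factor; supply CFA loadings for a confirmatory report.
#' @return object of class \code{comb_reliability}: data frame \code{table}
#'   (domain, k, alpha, cr, ave, sqrt_ave), correlation matrix \code{cors},
#'   and \code{fornell_larcker} results.
#' @export
reliability_validity <- function(data, spec, module, loadings = NULL) {
  doms <- spec$domains[[module]]
  if (is.null(doms)) stop("unknown module: ", module)
  if (is.null(loadings)) {
    sol <- efa_pca_varimax(data, unlist(spec$items[doms], use.names = FALSE))
    loadings <- lapply(doms, function(d) {
      L <- sol$loadings[spec$items[[d]], , drop = FALSE]
      f <- which.max(colSums(L^2))
      abs(L[, f])
    })
    names(loadings) <- doms
  }
  alpha <- vapply(doms, function(d) cronbach_alpha(data, spec$items[[d]]), 0)
  aves <- vapply(loadings[doms], ave, 0)
  crs <- vapply(loadings[doms], composite_reliability, 0)
  scores <- sapply(doms, function(d)
    rowMeans(response_matrix(data, spec$items[[d]])))
  cors <- stats::cor(scores, use = "pairwise.complete.obs")
  tab <- data.frame(domain = doms,
                    k = vapply(spec$items[doms], length, 1L),
                    alpha = alpha, cr = crs, ave = aves,
                    sqrt_ave = sqrt(aves), row.names = NULL)
  structure(list(module = module, table = tab, cors = cors,
                 fornell_larcker = fornell_larcker(
                   stats::setNames(aves, doms), cors)),
            class = "comb_reliability")
}

#' @export
print.comb_reliability <- function(x, digits = 3, ...) {
  cat(sprintf("Reliability and validity: %s module\n", x$module))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  cat("\nDomain-score correlations (discriminant validity by Fornell-Larcker):\n")
  print(round(x$cors, digits))
  ok <- x$fornell_larcker$discriminant
  cat(sprintf("  discriminant validity: %s\n",
              if (all(ok)) "pass for all domains"
              else paste("fails for", paste(names(ok)[!ok], collapse = ", "))))
  invisible(x)
}

#' Ordered split of a sample for exploratory vs confirmatory analysis
#'
#' @param data Likert response data.
#' @param half \code{"first"} or \code{"second"}.
#' @param random if TRUE, split membership is drawn at random (seeded) rather
#'   than by row order.
#' @param seed seed for the random split.
#' @return the selected half as a \code{likert_data} data frame.
#' @export
split_half <- function(data, half = c("first", "second"), random = FALSE,
                       seed = 1L) {
  half <- match.arg(half)
  n <- nrow(data)
  if (random) {
    set.seed(as.integer(seed))
    first <- sort(sample.int(n, floor(n / 2)))
  } else first <- seq_len(floor(n / 2))
  idx <- if (half == "first") first else setdiff(seq_len(n), first)
  out <- data[idx, , drop = FALSE]
  attr(out, "instrument") <- attr(data, "instrument")
  class(out) <- class(data)
  out
}
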