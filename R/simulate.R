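#' Ground-truth parameters for the Likert response simulator
#'
#' Assembles the latent-structure parameters the simulator propagates: item
#' loadings on their domain factors, second-order loadings of domains on their
#' module factors, standardized structural paths among the four COM-B modules,
#' the correlation of the two exogenous modules (Capability, Opportunity), and
#' the ordered thresholds that cut the standardized item latent into the five
#' Likert categories.
#'
#' All latent variables are unit-variance, so loadings and paths are
#' standardized coefficients; item residual standard deviations are
#' \code{sqrt(1 - loading^2)} so item latents are standardized as well.
#'
#' @param spec an [instrument_spec()].
#' @param loadings named numeric vector item -> loading in \[0,1\]; defaults to
#'   reference values for the default instrument (0.8 for items without a
#'   stated reference, 0.75 for behavior items).
#' @param second_order named numeric vector domain -> loading on its module.
#' @param paths named numeric vector of standardized structural coefficients
#'   \code{c_m} (Capability to Motivation), \code{o_m}, \code{m_b}, \code{o_b},
#'   \code{c_b}; all in \[-1,1\].
#' @param exo_cor correlation between Capability and Opportunity.
#' @param thresholds four strictly increasing cut points on the standardized
#'   item latent; category k is assigned when the latent falls in the k-th
#'   interval.
#' @param missing_rate optional MCAR missingness rate in \[0,1); default 0.
#' @return object of class \code{ground_truth}.
#' @export
ground_truth <- function(spec = default_instrument(),
                         loadings = NULL,
                         second_order = NULL,
                         paths = c(c_m = 0.21, o_m = 0.18, m_b = 0.41,
                                   o_b = 0.26, c_b = -0.04),
                         exo_cor = 0.5,
                         thresholds = c(-1.5, -0.5, 0.5, 1.5),
                         missing_rate = 0) {
  stopifnot(inherits(spec, "instrument_spec"))
  if (is.null(loadings)) loadings <- default_loadings(spec)
  if (is.null(second_order)) second_order <- default_second_order(spec)
  all_it <- instrument_items(spec)
  if (!all(all_it %in% names(loadings)))
    stop("missing loadings for: ",
         paste(setdiff(all_it, names(loadings)), collapse = ", "))
  if (any(loadings < 0 | loadings > 1)) stop("loadings must lie in [0, 1]")
  doms <- unlist(spec$domains, use.names = FALSE)
  if (!all(doms %in% names(second_order)))
    stop("missing second-order loadings for: ",
         paste(setdiff(doms, names(second_order)), collapse = ", "))
  if (any(abs(second_order) > 1)) stop("second-order loadings must lie in [-1, 1]")
  need <- c("c_m", "o_m", "m_b", "o_b", "c_b")
  if (!all(need %in% names(paths))) stop("paths must name ", paste(need, collapse = ", "))
  if (any(abs(paths) > 1)) stop("|standardized path| must be <= 1")
  if (abs(exo_cor) >= 1)
    stop("exogenous correlation matrix must be positive definite (|exo_cor| < 1)")
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0))
    stop("thresholds must be 4 strictly increasing values")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  structure(list(spec = spec, loadings = loadings[all_it],
                 second_order = second_order[doms], paths = paths[need],
                 exo_cor = exo_cor, thresholds = thresholds,
                 missing_rate = missing_rate),
            class = "ground_truth")
}

# reference loadings for the default instrument; 0.8 / 0.75 elsewhere
default_loadings <- function(spec) {
  ref <- c(BR1 = 0.821, BR2 = 0.802, BR4 = 0.738,
           DM2 = 0.833, DM4 = 0.812, DM3 = 0.722,
           KS4 = 0.847, KS2 = 0.835, KS1 = 0.703,
           SR3 = 0.830, SR1 = 0.827, SR2 = 0.827,
           OP1 = 0.859, OP2 = 0.817, OP3 = 0.816,
           BCO1 = 0.823, BCO3 = 0.816, BCO2 = 0.816,
           REI3 = 0.830, REI1 = 0.815, REI2 = 0.804,
           EM3 = 0.819, EM2 = 0.819, EM1 = 0.801,
           INT1 = 0.832, INT2 = 0.824, INT3 = 0.807,
           BCA1 = 0.828, BCA2 = 0.802, BCA3 = 0.796)
  it <- instrument_items(spec, include_behaviors = FALSE)
  lam <- stats::setNames(rep(0.80, length(it)), it)
  hit <- intersect(names(ref), it)
  lam[hit] <- ref[hit]
  c(lam, stats::setNames(rep(0.75, length(spec$behaviors)), spec$behaviors))
}

default_second_order <- function(spec) {
  ref <- c(KS = 0.849, DM = 0.888, BR = 0.886,
           OP = 0.659, SR = 0.686, EM = 0.710, REI = 0.722,
           INT = 0.680, BCO = 0.709, BCA = 0.691,
           VAL = 0.765, LS = 0.732, PN = 0.811, PE = 0.816, EI = 0.740)
  doms <- unlist(spec$domains, use.names = FALSE)
  g <- stats::setNames(rep(0.75, length(doms)), doms)
  hit <- intersect(names(ref), doms)
  g[hit] <- ref[hit]
  g
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground-truth simulation parameters\n")
  cat("  structural paths:",
      paste(sprintf("%s=%.2f", names(x$paths), x$paths), collapse = " "), "\n")
  cat(sprintf("  cor(Capability, Opportunity) = %.2f\n", x$exo_cor))
  cat("  thresholds:", paste(format(x$thresholds), collapse = " "), "\n")
  cat(sprintf("  %d item loadings in [%.2f, %.2f]; missing rate %.2f\n",
              length(x$loadings), min(x$loadings), max(x$loadings),
              x$missing_rate))
  invisible(x)
}

#' Simulate Likert questionnaire responses under the COM-B latent model
#'
#' Draws the exogenous module factors (Capability, Opportunity) from their
#' correlation matrix, propagates them through the structural paths to
#' Motivation and Behavior with disturbances scaled so every module factor has
#' unit variance, emits domain factors and standardized item latents
#' (\code{loading * factor + noise}), and thresholds the latents into the
#' 1..5 Likert categories.
#'
#' @param params a [ground_truth()] object.
#' @param n number of respondents (>= 1).
#' @param seed integer seed; identical seed, params and n reproduce the matrix
#'   exactly.
#' @param return_latent if TRUE, attach the pre-threshold item latents and the
#'   module factor scores as attributes \code{"latent"} and \code{"factors"}.
#' @return A \code{data.frame} of class \code{likert_data}: first column
#'   \code{respondent}, remaining columns integer responses in 1..5 (NA where
#'   masked missing); the instrument is attached as attribute
#'   \code{"instrument"}.
#' @export
generate_responses <- function(params, n, seed = 1L, return_latent = FALSE) {
  stopifnot(inherits(params, "ground_truth"), n >= 1)
  spec <- params$spec
  set.seed(as.integer(seed))
  p <- params$paths
  r <- params$exo_cor

  ## module factors ------------------------------------------------------
  exo <- matrix(stats::rnorm(2 * n), n, 2) %*% chol(matrix(c(1, r, r, 1), 2))
  C <- exo[, 1]; O <- exo[, 2]
  v_m <- 1 - (p["c_m"]^2 + p["o_m"]^2 + 2 * p["c_m"] * p["o_m"] * r)
  if (v_m <= 0) stop("structural paths imply non-positive Motivation disturbance variance")
  M <- p["c_m"] * C + p["o_m"] * O + sqrt(v_m) * stats::rnorm(n)
  # Var(B) from the joint covariance of (C, O, M)
  cv <- matrix(c(1, r, p["c_m"] + p["o_m"] * r,
                 r, 1, p["o_m"] + p["c_m"] * r,
                 p["c_m"] + p["o_m"] * r, p["o_m"] + p["c_m"] * r, 1), 3, 3)
  b <- c(p["c_b"], p["o_b"], p["m_b"])
  v_b <- 1 - drop(t(b) %*% cv %*% b)
  if (v_b <= 0) stop("structural paths imply non-positive Behavior disturbance variance")
  B <- b[1] * C + b[2] * O + b[3] * M + sqrt(v_b) * stats::rnorm(n)
  fac <- cbind(Capability = C, Opportunity = O, Motivation = M, Behavior = B)

  ## domain factors and item latents -------------------------------------
  dmod <- domain_module_map(spec)
  imap <- item_domain_map(spec)
  items <- instrument_items(spec)
  doms <- unlist(spec$domains, use.names = FALSE)
  g <- params$second_order
  domfac <- sapply(doms, function(d)
    g[d] * fac[, dmod[d]] + sqrt(1 - g[d]^2) * stats::rnorm(n))
  lat <- matrix(NA_real_, n, length(items), dimnames = list(NULL, items))
  for (it in items) {
    lam <- params$loadings[it]
    f <- if (imap[it] %in% doms) domfac[, imap[it]] else fac[, "Behavior"]
    lat[, it] <- lam * f + sqrt(1 - lam^2) * stats::rnorm(n)
  }

  resp <- matrix(findInterval(lat, vec = params$thresholds) + 1L,
                 n, length(items), dimnames = list(NULL, items))
  if (params$missing_rate > 0) {
    mask <- matrix(stats::runif(length(resp)) < params$missing_rate,
                   n, length(items))
    resp[mask] <- NA_integer_
  }
  out <- data.frame(respondent = seq_len(n), resp, check.names = FALSE)
  attr(out, "instrument") <- spec
  class(out) <- c("likert_data", "data.frame")
  if (return_latent) {
    attr(out, "latent") <- lat
    attr(out, "factors") <- fac
  }
  out
}

# numeric item-response matrix (drops the respondent id column)
response_matrix <- function(data, items = NULL) {
  if (is.null(items))
    items <- setdiff(colnames(data), "respondent")
  miss <- setdiff(items, colnames(data))
  if (length(miss)) stop("items not present in data: ", paste(miss, collapse = ", "))
  as.matrix(as.data.frame(data)[, items, drop = FALSE])
}

#' Read / write Likert responses as CSV
#'
#' The CSV layout is one row per respondent with a leading \code{respondent}
#' id column and one column per item code.
#'
#' @param data a \code{likert_data} data frame.
#' @param path file path.
#' @param spec optional [instrument_spec()] to attach when reading.
#' @return `write_responses()` returns `path` invisibly; `read_responses()` a
#'   \code{likert_data} data frame.
#' @export
write_responses <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path, spec = NULL) {
  out <- utils::read.csv(path, check.names = FALSE)
  vals <- as.matrix(out[, setdiff(colnames(out), "respondent")])
  if (any(!is.na(vals) & (vals < 1 | vals > 5 | vals != round(vals))))
    stop("responses must be integers in 1..5")
  if (!is.null(spec)) attr(out, "instrument") <- spec
  class(out) <- c("likert_data", "data.frame")
  out
}
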