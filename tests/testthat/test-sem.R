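test_that("model DSL parses structure and catches malformed input", {
  m <- mediation_model()
  expect_s3_class(m, "sem_model")
  expect_equal(m$observed, c(paste0("x", 1:3), paste0("m", 1:3),
                             paste0("y", 1:3)))
  expect_equal(m$exo, "X")
  expect_setequal(m$endo, c("M", "Y"))
  expect_error(sem_model("factor A = a1 a2"), "bad line")
  expect_error(sem_model(c("factor A =~ a1 a2 a3", "path B ~ A")),
               "not defined")
})

test_that("implied covariance reproduces closed forms", {
  m <- sem_model(c("factor F =~ a b", "cov F ~~ F")[1])
  th <- m$ram$free
  # zero loadings, unit residuals -> identity
  theta <- ifelse(th$mat == "A", 0, 1)
  expect_equal(implied_covariance(m, theta), diag(2),
               ignore_attr = TRUE)
  # loadings (a, b), factor variance 1 -> off-diagonal a*b
  theta <- numeric(nrow(th))
  theta[th$name == "F=~a"] <- 0.6
  theta[th$name == "F=~b"] <- 0.9
  theta[th$mat == "S"] <- c(0.3, 0.5)[seq_len(sum(th$mat == "S"))]
  Sig <- implied_covariance(m, theta)
  expect_equal(Sig["a", "b"], 0.6 * 0.9)
  expect_equal(Sig["a", "a"], 0.6^2 + 0.3)
})

test_that("implied covariance matches a simulation of the generative model", {
  m <- mediation_model()
  th <- m$ram$free
  theta <- numeric(nrow(th))
  theta[th$mat == "A" & grepl("=~", th$name)] <- 0.8
  theta[th$name == "M~X"] <- 0.5
  theta[th$name == "Y~M"] <- 0.4
  theta[th$name == "Y~X"] <- 0.1
  theta[th$mat == "S" & th$i <= 9] <- 0.36     # observed residuals
  theta[th$mat == "S" & th$i > 9] <- 0.75      # latent disturbances
  Sig <- implied_covariance(m, theta)

  # independent brute-force simulation of the same equations
  set.seed(99)
  n <- 200000
  X <- rnorm(n)
  M <- 0.5 * X + sqrt(0.75) * rnorm(n)
  Y <- 0.4 * M + 0.1 * X + sqrt(0.75) * rnorm(n)
  # X is exogenous (all loadings free, set to 0.8); M and Y are endogenous,
  # scaled by a first loading fixed at 1
  obs <- cbind(sapply(1:3, function(i) 0.8 * X + 0.6 * rnorm(n)),
               sapply(1:3, function(i) c(1, 0.8, 0.8)[i] * M + 0.6 * rnorm(n)),
               sapply(1:3, function(i) c(1, 0.8, 0.8)[i] * Y + 0.6 * rnorm(n)))
  expect_lt(max(abs(Sig - cov(obs))), 0.02)
})

test_that("a just-identified one-factor triad recovers the closed form", {
  set.seed(23)
  n <- 400
  f <- rnorm(n)
  x <- sapply(c(0.9, 0.7, 0.6), function(l) l * f + sqrt(1 - l^2) * rnorm(n))
  colnames(x) <- c("a", "b", "c")
  S <- cov(x)
  m <- sem_model("factor F =~ a b c")
  fit <- fit_ml(m, S, n)
  expect_lt(fit$F, 1e-10)   # saturated: 6 moments, 6 parameters
  lam1 <- sqrt(S["a", "b"] * S["a", "c"] / S["b", "c"])
  expect_equal(unname(fit$theta["F=~a"]), lam1, tolerance = 1e-6)
})

test_that("one-factor ML solution matches factanal", {
  set.seed(31)
  n <- 600
  f <- rnorm(n)
  x <- sapply(c(0.8, 0.75, 0.7, 0.65, 0.6), function(l)
    l * f + sqrt(1 - l^2) * rnorm(n))
  colnames(x) <- paste0("v", 1:5)
  R <- cor(x)
  fa <- stats::factanal(covmat = R, factors = 1, n.obs = n)
  m <- sem_model(paste("factor F =~", paste(colnames(x), collapse = " ")))
  fit <- fit_ml(m, R, n)
  # same ML discrepancy objective at the optimum
  expect_equal(fit$F, unname(fa$criteria["objective"]), tolerance = 1e-5)
  lam <- fit$std[paste0("F=~v", 1:5)]
  expect_equal(unname(abs(lam)), unname(drop(fa$loadings[, 1])),
               tolerance = 1e-3)
})

test_that("F_ML is invariant under reordering of observed items", {
  set.seed(37)
  d <- simulate_mediation_data(250, a = 0.5, b = 0.4, cprime = 0.1, seed = 37)
  m <- mediation_model()
  x <- combmine:::response_matrix(d, m$observed)
  S <- cov(x)
  fit1 <- fit_ml(m, S, 250)
  perm <- rev(m$observed)
  fit2 <- fit_ml(m, S[perm, perm], 250)
  expect_equal(fit1$F, fit2$F, tolerance = 1e-10)
})

test_that("standardized loadings recover simulation ground truth", {
  spec <- tiny_instrument()
  it <- combmine:::instrument_items(spec)
  params <- ground_truth(spec)
  d <- generate_responses(params, 1000, seed = 41, return_latent = TRUE)
  # fit on the continuous item latents so thresholding attenuation does not
  # enter; Likert-scale effects are covered by the path-recovery tests
  lat <- as.data.frame(attr(d, "latent"))
  lat$respondent <- seq_len(nrow(lat))
  model <- comb_model(spec)
  fit <- sem_fit(model, lat)
  lam_names <- paste0("A=~A", 1:3)
  expect_lt(max(abs(fit$std[lam_names] - params$loadings[paste0("A", 1:3)])),
            0.05)
  expect_lt(abs(fit$std["Behavior~Motivation"] - params$paths[["m_b"]]), 0.15)
})

test_that("fit indices satisfy their defining identities", {
  set.seed(43)
  d <- simulate_mediation_data(300, a = 0.5, b = 0.4, cprime = 0.1, seed = 43)
  m <- mediation_model()
  fit <- sem_fit(m, d)
  idx <- fit_indices(fit)
  S <- fit$S; Sig <- fit$Sigma; n <- fit$n; p <- ncol(S)

  # independent recomputation from the definitions
  expect_equal(idx$chi2, (n - 1) * fit$F)
  expect_equal(idx$df, p * (p + 1) / 2 - fit$q)
  E <- solve(Sig) %*% S
  expect_equal(idx$GFI,
               1 - sum(diag((E - diag(p)) %*% (E - diag(p)))) /
                 sum(diag(E %*% E)), tolerance = 1e-10)
  D <- (S - Sig) / sqrt(tcrossprod(diag(S)))
  expect_equal(idx$SRMR, sqrt(mean(D[lower.tri(D, diag = TRUE)]^2)),
               tolerance = 1e-10)
  expect_equal(idx$RMSEA, sqrt(max(idx$chi2 - idx$df, 0) / (idx$df * (n - 1))))
  Fb <- sum(log(diag(S))) - determinant(S)$modulus[1]
  chib <- (n - 1) * Fb; dfb <- p * (p - 1) / 2
  expect_equal(idx$NFI, (chib - idx$chi2) / chib, tolerance = 1e-10)
  expect_equal(idx$CFI,
               1 - max(idx$chi2 - idx$df, 0) /
                 max(chib - dfb, idx$chi2 - idx$df, 0), tolerance = 1e-10)
  expect_true(idx$CFI >= 0 && idx$CFI <= 1)
  expect_true(all(unlist(idx[c("chi2", "RMSEA", "SRMR")]) >= 0))
})

test_that("a saturated model yields zero discrepancy and perfect indices", {
  set.seed(47)
  n <- 400
  f <- rnorm(n)
  x <- sapply(c(0.9, 0.8, 0.7), function(l) l * f + 0.5 * rnorm(n))
  colnames(x) <- c("a", "b", "c")
  m <- sem_model("factor F =~ a b c")
  fit <- fit_ml(m, cov(x), n)
  idx <- fit_indices(fit)
  expect_equal(idx$chi2, 0, tolerance = 1e-6)
  expect_equal(idx$SRMR, 0, tolerance = 1e-6)
  expect_equal(idx$CFI, 1)
  expect_true(is.na(idx$RMSEA))   # df = 0
  expect_match(idx$note, "df = 0")
})

test_that("second-order COM-B model fit reproduces the Capability AVE pattern", {
  spec <- tiny_instrument()
  d <- generate_responses(ground_truth(spec), 800, seed = 53)
  fit <- sem_fit(comb_model(spec), d)
  # second-order loadings of Capability domains are strong and positive
  g <- fit$std[c("Capability=~A", "Capability=~B")]
  expect_true(all(g > 0.4))
  expect_true(all(abs(fit$std[grepl("=~", names(fit$std))]) <= 1.01))
})

test_that("leave-one-item-out refitting ranks a deliberately misfitting item first", {
  set.seed(83)
  n <- 500
  f <- rnorm(n)
  u <- rnorm(n)   # shared residual the one-factor model cannot absorb
  x <- sapply(1:3, function(i) 0.8 * f + 0.6 * rnorm(n))
  v4 <- 0.7 * f + 0.6 * u + 0.4 * rnorm(n)
  v5 <- 0.7 * f + 0.6 * u + 0.4 * rnorm(n)
  d <- data.frame(x, v4, v5, respondent = 1:n)
  names(d)[1:5] <- paste0("v", 1:5)
  m <- sem_model("factor F =~ v1 v2 v3 v4 v5")
  rk <- item_misfit_ranking(m, d)
  # removing either member of the correlated pair resolves the misfit
  expect_true(rk$item[1] %in% c("v4", "v5"))
  expect_gt(rk$delta_F[1], max(rk$delta_F[rk$item %in% c("v1", "v2", "v3")]))
  expect_true(all(rk$delta_F >= -1e-8))
})
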