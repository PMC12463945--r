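# Shared fixtures and independent oracle implementations used across tests.

# small two-module instrument for fast simulation-based tests
tiny_instrument <- function() {
  instrument_spec(
    domains = list(Capability = c("A", "B"),
                   Motivation = c("C"),
                   Opportunity = c("D")),
    items = list(A = paste0("A", 1:3), B = paste0("B", 1:3),
                 C = paste0("C", 1:3), D = paste0("D", 1:3)),
    behaviors = c("BEH-1", "BEH-2"))
}

# compact X -> M -> Y latent mediation model (3 indicators per factor)
mediation_model <- function() {
  sem_model(c("factor X =~ x1 x2 x3",
              "factor M =~ m1 m2 m3",
              "factor Y =~ y1 y2 y3",
              "path M ~ X",
              "path Y ~ M X"))
}

# simulate Likert data for mediation_model() with given standardized paths
simulate_mediation_data <- function(n, a, b, cprime, seed,
                                    loading = 0.8) {
  set.seed(seed)
  X <- rnorm(n)
  M <- a * X + sqrt(1 - a^2) * rnorm(n)
  vy <- 1 - (b^2 + cprime^2 + 2 * a * b * cprime)
  Y <- b * M + cprime * X + sqrt(vy) * rnorm(n)
  cuts <- c(-1.5, -0.5, 0.5, 1.5)
  mk <- function(f) sapply(1:3, function(i)
    findInterval(loading * f + sqrt(1 - loading^2) * rnorm(n), cuts) + 1L)
  out <- data.frame(respondent = seq_len(n), mk(X), mk(M), mk(Y))
  names(out) <- c("respondent", paste0("x", 1:3), paste0("m", 1:3),
                  paste0("y", 1:3))
  out
}

# brute-force frequent itemsets by exhaustive subset enumeration
bf_frequent_itemsets <- function(M, min_support) {
  N <- nrow(M); vocab <- colnames(M)
  out <- list()
  for (k in seq_len(ncol(M))) {
    for (cmb in utils::combn(ncol(M), k, simplify = FALSE)) {
      s <- sum(rowSums(M[, cmb, drop = FALSE]) == k) / N
      if (s >= min_support)
        out[[length(out) + 1L]] <- list(items = sort(vocab[cmb]), support = s)
    }
  }
  out
}

# brute-force rules: enumerate every antecedent subset x single consequent
bf_rules <- function(M, consequents, min_support, min_confidence, min_lift) {
  N <- nrow(M)
  ante_vocab <- setdiff(colnames(M), consequents)
  out <- list()
  for (k in seq_along(ante_vocab)) {
    for (cmb in utils::combn(length(ante_vocab), k, simplify = FALSE)) {
      X <- ante_vocab[cmb]
      inX <- rowSums(M[, X, drop = FALSE]) == k
      pX <- mean(inX)
      for (y in consequents) {
        pXY <- mean(inX & M[, y])
        pY <- mean(M[, y])
        if (pXY >= min_support && pX > 0 && pY > 0) {
          conf <- pXY / pX
          lift <- conf / pY
          if (conf >= min_confidence && lift > min_lift)
            out[[length(out) + 1L]] <- list(
              antecedent = sort(X), consequent = y,
              support = pXY, confidence = conf, lift = lift)
        }
      }
    }
  }
  out
}

# canonical string form of a rule/itemset list, for set comparison
rule_signature <- function(ant, cons, supp, conf, lift) {
  sort(sprintf("%s=>%s|%.10f|%.10f|%.10f",
               vapply(ant, paste, "", collapse = ","), cons, supp, conf, lift))
}

# KMO via regression-residual partial correlations (independent route)
kmo_oracle <- function(x) {
  R <- cor(x)
  p <- ncol(x)
  Q <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in seq.int(i + 1, p)) {
    others <- x[, -c(i, j), drop = FALSE]
    ri <- resid(lm(x[, i] ~ others))
    rj <- resid(lm(x[, j] ~ others))
    Q[i, j] <- Q[j, i] <- cor(ri, rj)
  }
  R0 <- R; diag(R0) <- 0
  sum(R0^2) / (sum(R0^2) + sum(Q^2))
}

# align factor-loading columns to a reference up to permutation and sign
align_loadings <- function(L, ref) {
  k <- ncol(ref)
  perm <- integer(k); sign <- numeric(k)
  used <- integer(0)
  for (j in seq_len(k)) {
    ip <- drop(crossprod(L, ref[, j]))
    ip[used] <- 0
    perm[j] <- which.max(abs(ip))
    sign[j] <- sign(ip[perm[j]])
    used <- c(used, perm[j])
  }
  sweep(L[, perm, drop = FALSE], 2, sign, "*")
}

# k parallel items with exactly equal pairwise sample correlation r,
# built from orthonormal columns (QR against the intercept)
exact_parallel_items <- function(n, k, r, seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * (k + 1)), n))))[, -1]
  g <- Q[, 1]
  sapply(seq_len(k), function(i) sqrt(r) * g + sqrt(1 - r) * Q[, i + 1])
}
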