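# Independent oracles kept deliberately separate from the package internals.

# Newton-Raphson MLE for a 2-parameter binomial logit model, written from
# the score/Hessian equations directly (no glm, no model.matrix).
logit_newton_oracle <- function(t, y, w = rep(1, length(y)),
                                tol = 1e-12, maxit = 200) {
  beta <- c(0, 0)
  X <- cbind(1, t)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    score <- drop(crossprod(X, w * (y - mu)))
    H <- crossprod(X, X * (w * mu * (1 - mu)))
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  unname(beta)
}

# OLS slope/intercept by explicit normal equations (no lm()).
ols_normal_equations <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  b <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  a <- (sy - b * sx) / n
  c(intercept = a, slope = b)
}

# AUC by direct pairwise comparison (ties scored 1/2).
pairwise_auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# convenience: the bundled 60-species table
species_table <- function() load_fixture("T3")
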