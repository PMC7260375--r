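# Random-intercept linear mixed model, fitted by maximum likelihood.
#
# The confound model needs exactly one model class: a Gaussian LMM with a
# single subject-level random intercept. For that class the ML problem
# reduces to a 1-D profile over the variance ratio lambda = sigma_u^2 /
# sigma_e^2 with closed-form GLS for the fixed effects at each candidate
# ratio, which makes refits cheap enough for parametric-bootstrap LRTs.
# Sufficient statistics (X'X, X'y, per-group sums) are precomputed once per
# dataset; each profile evaluation is then O(groups x p^2).

lmm_suffstat <- function(X, y, group) {
  list(XtX = crossprod(X), Xty = drop(crossprod(X, y)), yty = sum(y^2),
       SX = rowsum(X, group, reorder = TRUE),
       SY = drop(rowsum(y, group, reorder = TRUE)),
       ng = as.numeric(table(group)), n = length(y), p = ncol(X))
}

lmm_profile_ll <- function(lambda, ss) {
  w <- lambda / (1 + ss$ng * lambda)
  A <- ss$XtX - crossprod(ss$SX, ss$SX * w)
  b <- ss$Xty - drop(crossprod(ss$SX, ss$SY * w))
  yty <- ss$yty - sum(w * ss$SY^2)
  logdet <- sum(log1p(ss$ng * lambda))
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(list(ll = -Inf))
  rss <- max(yty - sum(beta * b), 1e-300)
  ll <- -ss$n / 2 * (log(2 * pi * rss / ss$n) + 1) - logdet / 2
  list(ll = ll, beta = drop(beta), A = A, rss = rss)
}

# Fit y = X beta + u[group] + e by ML. Returns coefficients, variance
# components, Wald standard errors and the maximized log-likelihood.
fit_lmm <- function(X, y, group) {
  stopifnot(nrow(X) == length(y), length(group) == length(y))
  group <- as.integer(factor(group))
  ss <- lmm_suffstat(X, y, group)
  ll0 <- lmm_profile_ll(0, ss)   # boundary: no random effect
  singletons <- all(ss$ng == 1)
  if (singletons) {
    best_lambda <- 0
    best <- ll0
  } else {
    opt <- stats::optimize(function(t) lmm_profile_ll(exp(t), ss)$ll,
                           interval = c(-12, 8), maximum = TRUE, tol = 1e-7)
    if (opt$objective > ll0$ll + 1e-10) {
      best_lambda <- exp(opt$maximum)
      best <- lmm_profile_ll(best_lambda, ss)
    } else {
      best_lambda <- 0
      best <- ll0
    }
  }
  sigma_e2 <- best$rss / ss$n
  vcov_beta <- tryCatch(sigma_e2 * solve(best$A), error = function(e)
    matrix(NA_real_, ss$p, ss$p))
  beta <- best$beta
  names(beta) <- colnames(X)
  list(beta = beta,
       se = sqrt(pmax(diag(vcov_beta), 0)),
       sigma_u = sqrt(best_lambda * sigma_e2),
       sigma_e = sqrt(sigma_e2),
       lambda = best_lambda,
       loglik = best$ll,
       no_random_effect = best_lambda == 0,
       n = ss$n, group = group, X = X, y = y)
}

# Empirical-BLUP random intercepts of a fitted model.
blup_lmm <- function(fit) {
  r <- fit$y - drop(fit$X %*% fit$beta)
  ng <- as.numeric(table(fit$group))
  sums <- drop(rowsum(r, fit$group, reorder = TRUE))
  (fit$lambda * sums) / (1 + ng * fit$lambda)
}

# Simulate a response vector from a fitted random-intercept model.
simulate_lmm <- function(fit) {
  u <- stats::rnorm(max(fit$group), 0, fit$sigma_u)
  drop(fit$X %*% fit$beta) + u[fit$group] +
    stats::rnorm(fit$n, 0, fit$sigma_e)
}
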