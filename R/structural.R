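#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Ratio of summed squared correlations to summed squared correlations plus
#' summed squared anti-image (partial) correlations, over all off-diagonal
#' pairs. Values near 0.5 indicate data unsuitable for factor analysis.
#'
#' @param table Units x metrics data (>= 3 metrics, rows > metrics).
#' @param ridge Ridge applied if the correlation matrix is singular.
#' @return KMO in `[0, 1]`.
#' @export
kmo <- function(table, ridge = 1e-8) {
  X <- as.matrix(table)
  if (ncol(X) < 3L) stop("need at least 3 metrics", call. = FALSE)
  if (nrow(X) <= ncol(X)) stop("need more rows than metrics", call. = FALSE)
  R <- stats::cor(X)
  P <- tryCatch(solve(R), error = function(e) {
    warning("singular correlation matrix; ridge applied", call. = FALSE)
    solve(R + diag(ridge, ncol(R)))
  })
  d <- sqrt(diag(P))
  Q <- -P / tcrossprod(d)
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
}

#' Parallel analysis for the number of factors
#'
#' Compares the eigenvalues of the observed correlation matrix with a null
#' threshold simulated from independent standard-normal data of identical
#' shape. `k` is the number of leading observed eigenvalues exceeding their
#' null threshold (counting stops at the first failure). The default
#' threshold is the 95th percentile of the simulated eigenvalues; the mean
#' criterion is available via `criterion = "mean"`.
#'
#' @param table Units x metrics data.
#' @param n_sim Number of null simulations (>= 100).
#' @param seed Integer seed (same seed, same `k`).
#' @param criterion `"quantile"` (default, with `q`) or `"mean"`.
#' @param q Null quantile when `criterion = "quantile"` (default 0.95).
#' @return List `k`, `observed` eigenvalues, `threshold` vector.
#' @export
parallel_analysis <- function(table, n_sim = 200L, seed = 1L,
                              criterion = c("quantile", "mean"), q = 0.95) {
  criterion <- match.arg(criterion)
  if (n_sim < 100L) stop("n_sim must be >= 100", call. = FALSE)
  X <- as.matrix(table)
  n <- nrow(X)
  m <- ncol(X)
  obs <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  sim <- matrix(0, n_sim, m)
  for (i in seq_len(n_sim)) {
    Z <- matrix(stats::rnorm(n * m), n, m)
    sim[i, ] <- eigen(stats::cor(Z), symmetric = TRUE, only.values = TRUE)$values
  }
  thr <- if (criterion == "mean") colMeans(sim) else
    apply(sim, 2, stats::quantile, probs = q)
  above <- obs > thr
  k <- if (!above[1]) 0L else {
    runs <- rle(above)
    as.integer(runs$lengths[1])
  }
  list(k = k, observed = obs, threshold = thr)
}

#' Maximum-likelihood factor analysis with promax rotation
#'
#' Common factor analysis (ML) followed by an oblique promax rotation.
#' Factor sign indeterminacy is resolved by forcing the largest-magnitude
#' loading of each factor positive. Loadings with absolute value >= 0.5 are
#' classified strong and collected in `strong_map`. A near-zero uniqueness
#' (Heywood case) is flagged, not fatal.
#'
#' @param table Units x metrics data.
#' @param k Number of factors (>= 1, metrics >= k + 2).
#' @param strong_threshold Strong-loading threshold (default 0.5).
#' @return Object of class `factor_model`: `k`, `loadings` (metrics x k),
#'   `uniquenesses`, `phi` (factor correlations), `kmo`, `strong_map`
#'   (metric -> factor of its strongest strong loading), `heywood` flag.
#' @export
efa_promax <- function(table, k, strong_threshold = 0.5) {
  X <- as.matrix(table)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (ncol(X) < k + 2L) stop("need at least k + 2 metrics", call. = FALSE)
  fa <- stats::factanal(X, factors = k, rotation = "none")
  L <- matrix(fa$loadings, ncol = k,
              dimnames = list(colnames(X), paste0("F", seq_len(k))))
  phi <- diag(1, k)
  if (k > 1L) {
    pm <- stats::promax(L)
    L <- matrix(pm$loadings, ncol = k,
                dimnames = list(colnames(X), paste0("F", seq_len(k))))
    phi <- solve(crossprod(pm$rotmat))
  }
  for (j in seq_len(k)) {
    i_max <- which.max(abs(L[, j]))
    if (L[i_max, j] < 0) {
      L[, j] <- -L[, j]
      if (k > 1L) {
        phi[j, -j] <- -phi[j, -j]
        phi[-j, j] <- -phi[-j, j]
      }
    }
  }
  strong <- abs(L) >= strong_threshold
  strong_map <- apply(L, 1, function(r)
    if (any(abs(r) >= strong_threshold)) which.max(abs(r)) else NA_integer_)
  structure(list(k = k, loadings = L, uniquenesses = fa$uniquenesses,
                 phi = phi, kmo = kmo(X), strong_map = strong_map,
                 heywood = any(fa$uniquenesses < 0.005)),
            class = "factor_model")
}

#' Assign disability severity groups
#'
#' Disease-appropriate banding: stroke by FMA-UE (ceiling = 66; mild
#' 54 <= FMA-UE < 66; moderate 35 <= FMA-UE < 54), MS by ARAT (full capacity
#' 55-57; notable 43 <= ARAT < 55; limited 22 <= ARAT < 43), ARSACS by age
#' (young 26-36; mid-age 37-47; older-age 48-58). Intact subjects are
#' labelled `"intact"`; scores outside the bands (or missing) become
#' `"unclassified"` with a warning.
#'
#' @param subjects Subjects table (one row per subject x side).
#' @return Character vector of group labels aligned with `subjects` rows.
#' @export
assign_severity_groups <- function(subjects) {
  lab <- rep(NA_character_, nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    g <- subjects$group[i]
    lab[i] <- switch(
      g,
      intact = "intact",
      stroke = {
        s <- subjects$fma_ue[i]
        if (is.na(s)) "unclassified"
        else if (s == 66) "ceiling"
        else if (s >= 54) "mild"
        else if (s >= 35) "moderate"
        else "unclassified"
      },
      ms = {
        s <- subjects$arat[i]
        if (is.na(s)) "unclassified"
        else if (s >= 55 && s <= 57) "full_capacity"
        else if (s >= 43) "notable_capacity"
        else if (s >= 22) "limited_capacity"
        else "unclassified"
      },
      arsacs = {
        a <- subjects$age[i]
        if (a >= 26 && a <= 36) "young"
        else if (a >= 37 && a <= 47) "mid_age"
        else if (a >= 48 && a <= 58) "older_age"
        else "unclassified"
      },
      "unclassified")
  }
  if (any(lab == "unclassified"))
    warning(sum(lab == "unclassified"),
            " subject row(s) outside the severity bands -> 'unclassified'",
            call. = FALSE)
  lab
}

#' Disability-subgroup sensitivity test for one metric
#'
#' Kruskal-Wallis omnibus test across the severity groups (unclassified rows
#' and groups with fewer than 2 members are excluded with a warning),
#' followed - only when the Bonferroni-corrected omnibus test is significant -
#' by pairwise Wilcoxon rank-sum post-hoc tests, Bonferroni-corrected.
#'
#' @param values Normalized metric values.
#' @param groups Group labels from [assign_severity_groups()], aligned.
#' @param alpha Significance level (default 0.05).
#' @param n_metrics Bonferroni factor across metrics for the omnibus p
#'   (default 1).
#' @return List: `groups` (ordered labels used), `medians`, `omnibus_h`,
#'   `omnibus_df`, `omnibus_p` (corrected), `posthoc_p` (matrix or `NULL`).
#' @export
subgroup_tests <- function(values, groups, alpha = 0.05, n_metrics = 1L) {
  keep <- groups != "unclassified" & !is.na(groups)
  values <- values[keep]
  groups <- groups[keep]
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("group(s) with < 2 members excluded: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(groups %in% small)
    values <- values[keep]
    groups <- groups[keep]
  }
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups with >= 2 members", call. = FALSE)
  kw <- stats::kruskal.test(values, g)
  p_corr <- min(1, kw$p.value * n_metrics)
  posthoc <- NULL
  if (is.finite(p_corr) && p_corr < alpha) {
    ph <- stats::pairwise.wilcox.test(values, g, p.adjust.method = "bonferroni",
                                      exact = FALSE)
    posthoc <- ph$p.value
  }
  list(groups = levels(g),
       medians = tapply(values, g, stats::median),
       omnibus_h = unname(kw$statistic),
       omnibus_df = unname(kw$parameter),
       omnibus_p = p_corr,
       posthoc_p = posthoc)
}
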