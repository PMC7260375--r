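#' Partial Spearman correlation matrix
#'
#' Values are rank-transformed per metric; the partial correlation of each
#' pair controlling for all remaining metrics is read off the inverse of the
#' rank correlation matrix, `rho_p(i,j) = -P_ij / sqrt(P_ii P_jj)`. With two
#' metrics this reduces to the plain Spearman correlation. A singular
#' correlation matrix triggers ridge regularization (`ridge * I`) with a
#' warning.
#'
#' @param table Data frame or matrix, rows = subject x side units,
#'   columns = metrics (>= 2 columns; rows >= metrics + 2).
#' @param ridge Ridge added on singularity (default 1e-8, escalated
#'   tenfold until invertible).
#' @return List of class `partial_correlation_matrix`: `metric_names`,
#'   symmetric `rho` with unit diagonal.
#' @export
partial_spearman <- function(table, ridge = 1e-8) {
  X <- as.matrix(table)
  m <- ncol(X)
  if (m < 2L) stop("need at least 2 metrics", call. = FALSE)
  if (nrow(X) < m + 2L) stop("need at least metrics + 2 rows", call. = FALSE)
  R <- apply(X, 2, rank)
  C <- stats::cor(R)
  if (m == 2L) {
    rho <- matrix(c(1, C[1, 2], C[1, 2], 1), 2, 2)
  } else {
    P <- NULL
    eps <- 0
    repeat {
      P <- tryCatch(solve(C + diag(eps, m)), error = function(e) NULL)
      if (!is.null(P) && all(is.finite(P))) break
      eps <- if (eps == 0) ridge else eps * 10
      if (eps > 1) stop("correlation matrix irreparably singular", call. = FALSE)
    }
    if (eps > 0)
      warning(sprintf("singular rank-correlation matrix; ridge %.1e applied", eps),
              call. = FALSE)
    d <- sqrt(diag(P))
    rho <- -P / tcrossprod(d)
    diag(rho) <- 1
  }
  rho <- (rho + t(rho)) / 2
  dimnames(rho) <- list(colnames(X), colnames(X))
  structure(list(metric_names = colnames(X), rho = rho),
            class = "partial_correlation_matrix")
}

# Reference implementation by residual regression, used as the second route
# in the dual-route agreement check.
partial_spearman_residual <- function(table) {
  X <- apply(as.matrix(table), 2, rank)
  m <- ncol(X)
  rho <- diag(1, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    Z <- X[, -c(i, j), drop = FALSE]
    ri <- if (ncol(Z)) stats::lm.fit(cbind(1, Z), X[, i])$residuals else X[, i]
    rj <- if (ncol(Z)) stats::lm.fit(cbind(1, Z), X[, j])$residuals else X[, j]
    rho[i, j] <- rho[j, i] <- stats::cor(ri, rj)
  }
  dimnames(rho) <- list(colnames(table), colnames(table))
  rho
}

#' Correlation strength band (Hinkle scheme)
#'
#' @param rho_p Partial correlation in `[-1, 1]` (absolute value is banded).
#' @return One of `"very high"` (>= 0.9), `"high"` (0.7-0.9), `"moderate"`
#'   (0.5-0.7), `"low"` (0.3-0.5), `"very low"` (< 0.3).
#' @export
classify_strength <- function(rho_p) {
  a <- abs(rho_p)
  if (any(a > 1)) stop("|rho_p| cannot exceed 1", call. = FALSE)
  cut(a, breaks = c(-Inf, 0.3, 0.5, 0.7, 0.9, Inf), right = FALSE,
      labels = c("very low", "low", "moderate", "high", "very high")) |>
    as.character()
}

#' Selection step 3: iterative redundancy reduction
#'
#' Repeatedly computes the partial Spearman matrix, finds the pair with the
#' largest absolute partial correlation at or above `threshold`, removes the
#' lower-priority member, and recomputes - removal of a modeled metric can
#' change the remaining inter-correlations. Priority is the deterministic
#' lexicographic psychometric ranking (AUC desc, ICC desc, SRD% asc, then
#' metric name), optionally overridden per pair to encode
#' literature-preference decisions.
#'
#' @param table Units x metrics data (survivors of steps 1-2).
#' @param scores Data frame with `metric, auc, icc, srd_pct` for the same
#'   metrics (priority ranking).
#' @param threshold Removal threshold on `|rho_p|` (default 0.5).
#' @param overrides Named character vector: `"metricA|metricB" = metric to
#'   remove` (names use the pair sorted alphabetically).
#' @param batch If `TRUE`, all pairs >= threshold of one iteration are
#'   resolved before recomputing (default `FALSE`: recompute after every
#'   single removal).
#' @return List `core` (kept metric names), `decisions` (data frame of
#'   removals: pair, removed, kept, rho_p, rationale).
#' @export
iterative_reduction <- function(table, scores, threshold = 0.5,
                                overrides = NULL, batch = FALSE) {
  X <- as.data.frame(table)
  ord <- scores$metric[order(-scores$auc, -scores$icc, scores$srd_pct,
                             scores$metric)]
  priority <- stats::setNames(seq_along(ord), ord)  # 1 = best
  decisions <- list()
  repeat {
    if (ncol(X) < 2L) break
    pm <- partial_spearman(X)
    rho <- pm$rho
    diag(rho) <- 0
    todo <- if (batch) {
      idx <- which(abs(rho) >= threshold & upper.tri(rho), arr.ind = TRUE)
      idx[order(-abs(rho[idx])), , drop = FALSE]
    } else {
      if (max(abs(rho)) < threshold) break
      which(abs(rho) == max(abs(rho)) & upper.tri(rho), arr.ind = TRUE)[1, ,
                                                                        drop = FALSE]
    }
    if (nrow(todo) == 0L) break
    removed_now <- character()
    for (r in seq_len(nrow(todo))) {
      a <- pm$metric_names[todo[r, 1]]
      b <- pm$metric_names[todo[r, 2]]
      if (a %in% removed_now || b %in% removed_now) next
      key <- paste(sort(c(a, b)), collapse = "|")
      if (!is.null(overrides) && key %in% names(overrides)) {
        drop_m <- overrides[[key]]
        rationale <- "manual"
      } else {
        drop_m <- if (priority[a] > priority[b]) a else b
        rationale <- "worse_psychometrics"
      }
      decisions[[length(decisions) + 1L]] <- data.frame(
        metric_a = a, metric_b = b, removed = drop_m,
        kept = setdiff(c(a, b), drop_m), rho_p = rho[todo[r, 1], todo[r, 2]],
        rationale = rationale, stringsAsFactors = FALSE)
      removed_now <- c(removed_now, drop_m)
      X[[drop_m]] <- NULL
      if (!batch) break
    }
    if (length(removed_now) == 0L) break
  }
  list(core = colnames(X),
       decisions = if (length(decisions)) do.call(rbind, decisions) else
         data.frame(metric_a = character(), metric_b = character(),
                    removed = character(), kept = character(),
                    rho_p = numeric(), rationale = character()))
}
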