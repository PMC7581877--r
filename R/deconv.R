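# Reference-based leukocyte deconvolution by constrained projection:
# per-sample least squares onto the reference profiles under w >= 0 and
# sum(w) <= 1 (Houseman-style constrained projection).

# Lawson-Hanson active-set nonnegative least squares:
# min ||b - A x||^2 subject to x >= 0.
nnls <- function(A, b, tol = 1e-10) {
  k <- ncol(A)
  x <- numeric(k)
  passive <- logical(k)
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  for (outer in seq_len(30L * k)) {
    g <- Atb - AtA %*% x
    cand <- which(!passive)
    if (length(cand) == 0L || max(g[cand]) <= tol * max(abs(Atb), 1)) break
    passive[cand[which.max(g[cand])]] <- TRUE
    repeat {
      idx <- which(passive)
      s <- numeric(k)
      s[idx] <- solve(AtA[idx, idx, drop = FALSE], Atb[idx, ])
      if (all(s[idx] > tol)) {
        x <- s
        break
      }
      neg <- idx[s[idx] <= tol]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
    }
  }
  pmax(x, 0)
}

# Solve min ||y - X w||^2 subject to w >= 0, sum(w) <= 1.
# The simplex inequality is handled by an explicit slack variable s >= 0
# with sum(w) + s = 1, enforced through a heavily weighted pseudo-
# observation inside the NNLS solve, then polished to the exact KKT
# solution on the recovered active set.
solve_mixture <- function(y, X, penalty = 1e3, tol = 1e-9) {
  k <- ncol(X)
  A <- rbind(cbind(X, 0), penalty * rep(1, k + 1))
  b <- c(y, penalty)
  w_aug <- nnls(A, b)
  w <- w_aug[seq_len(k)]
  s <- w_aug[k + 1L]
  support <- which(w > tol)
  if (length(support)) {
    Xs <- X[, support, drop = FALSE]
    if (s > tol) {
      # slack active: the simplex constraint is not binding -> plain LS on
      # the support
      ws <- qr.coef(qr(Xs), y)
      if (all(ws >= -tol) && sum(ws) <= 1 + tol) {
        w[support] <- pmax(ws, 0)
        w[-support] <- 0
        if (!length(support)) w[] <- 0
        return(w)
      }
    } else {
      # constraint binding: equality-constrained LS via KKT system
      m <- length(support)
      K <- rbind(cbind(2 * crossprod(Xs), rep(1, m)), c(rep(1, m), 0))
      rhs <- c(2 * crossprod(Xs, y), 1)
      sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
      if (!is.null(sol) && all(sol[seq_len(m)] >= -tol)) {
        w[support] <- pmax(sol[seq_len(m)], 0)
        w[setdiff(seq_len(k), support)] <- 0
        return(w)
      }
    }
  }
  pmax(w, 0)
}

#' Estimate leukocyte proportions from marker-probe methylation
#'
#' For each sample, solves the constrained projection
#' \eqn{\min_w \|y - X w\|^2} subject to \eqn{w \ge 0} and
#' \eqn{\sum_k w_k \le 1}, where `X` holds the reference methylation
#' profiles of the six leukocyte types at the marker probes and `y` the
#' sample's betas at those probes.
#'
#' @param dataset A [methyl_dataset()] containing all marker probes of the
#'   reference.
#' @param reference A `cell_reference` (see [generate_cell_reference()]),
#'   or any list with `profiles` (markers x types matrix, rownames = probe
#'   ids).
#' @param renormalize If `TRUE` (default) proportions are rescaled to sum
#'   to 1 per sample for reporting; if `FALSE` the raw constrained solution
#'   is returned.
#' @return A tibble: `sample_id` plus one column per cell type.
#' @export
estimate_cell_proportions <- function(dataset, reference, renormalize = TRUE) {
  stopifnot(inherits(dataset, "methyl_dataset"))
  profiles <- reference$profiles
  ids <- rownames(profiles) %||% reference$marker_probe_ids
  missing <- setdiff(ids, colnames(dataset$betas))
  if (length(missing)) {
    abort(paste0("marker probe(s) missing from dataset: ",
                 paste(head(missing, 10), collapse = ", ")))
  }
  Y <- dataset$betas[, ids, drop = FALSE]
  W <- t(apply(Y, 1, function(y) solve_mixture(y, profiles)))
  colnames(W) <- colnames(profiles)
  if (renormalize) {
    tot <- rowSums(W)
    tot[tot == 0] <- 1
    W <- W / tot
  }
  dplyr::bind_cols(tibble(sample_id = dataset$samples$sample_id), as_tibble(W))
}
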