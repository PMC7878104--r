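# Nonmetric multidimensional scaling by stress majorization (SMACOF).
#
# Similarity ratings of personal thoughts are ordinal, so the embedding
# fits monotone-transformed dissimilarities (Kruskal stress-1 with
# disparities from isotonic regression) rather than raw values.  The
# configuration update is the Guttman transform, which never increases the
# majorized stress; a guard terminates iteration on any numerical uptick
# so the reported stress trace is non-increasing by construction.

lower_tri <- function(m) m[lower.tri(m)]

# Kruskal stress-1 of configuration distances d against disparities dhat
stress1 <- function(d, dhat) {
  denom <- sum(d^2)
  if (denom <= 0) return(0)
  sqrt(sum((dhat - d)^2) / denom)
}

# monotone (isotonic) least-squares fit of d onto the order of delta;
# ties in delta are untied in favour of the current distances (Kruskal's
# primary approach), which can only lower stress
monotone_fit <- function(delta, d) {
  o <- order(delta, d)
  fit <- isoreg(seq_along(o), d[o])$yf
  out <- numeric(length(d))
  out[o] <- fit
  out
}

guttman_update <- function(X, dhat_mat) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  ratio <- matrix(0, n, n)
  pos <- D > 0
  ratio[pos] <- dhat_mat[pos] / D[pos]
  B <- -ratio
  diag(B) <- 0
  diag(B) <- -rowSums(B)
  (B %*% X) / n
}

smacof_run <- function(delta_mat, X0, max_iter, tol) {
  delta <- lower_tri(delta_mat)
  X <- scale(X0, center = TRUE, scale = FALSE)
  d <- lower_tri(as.matrix(dist(X)))
  dhat <- monotone_fit(delta, d)
  s <- stress1(d, dhat)
  trace <- s
  iter <- 0L
  while (iter < max_iter && s > 0) {
    dhat_mat <- matrix(0, nrow(X), nrow(X))
    dhat_mat[lower.tri(dhat_mat)] <- dhat
    dhat_mat <- dhat_mat + t(dhat_mat)
    X_new <- guttman_update(X, dhat_mat)
    d_new <- lower_tri(as.matrix(dist(X_new)))
    dhat_new <- monotone_fit(delta, d_new)
    s_new <- stress1(d_new, dhat_new)
    if (s_new > s + 1e-12) break  # numerical safeguard: keep trace monotone
    iter <- iter + 1L
    converged <- (s - s_new) < tol * max(s, .Machine$double.eps)
    X <- X_new; d <- d_new; dhat <- dhat_new; s <- s_new
    trace <- c(trace, s)
    if (converged) break
  }
  list(X = X, stress = s, n_iterations = iter, stress_trace = trace)
}

# classical (Torgerson) MDS via double centering; pads to k columns when
# the dissimilarities have lower intrinsic rank
classical_config <- function(delta_mat, k = 2L) {
  X <- suppressWarnings(cmdscale(delta_mat, k = k))
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  if (ncol(X) < k) {
    X <- cbind(X, matrix(0, nrow(delta_mat), k - ncol(X)))
  }
  X
}

#' Embed a dissimilarity matrix in two dimensions (nonmetric SMACOF)
#'
#' Produces the participant's 2D "cognitive map" from thought
#' dissimilarities.  The fit is nonmetric: only the rank order of the
#' dissimilarities is used, with disparities obtained by isotonic
#' regression and the configuration updated by the Guttman transform.
#' The first start is the classical (Torgerson) solution; additional
#' seed-governed random restarts protect against local minima and the
#' lowest-stress solution is returned.
#'
#' @param dissimilarity symmetric, non-negative, zero-diagonal numeric
#'   matrix, `n >= 3`.
#' @param seed integer seed for the random restarts.
#' @param max_iter maximum majorization iterations per start (default 300).
#' @param tol relative stress-decrease convergence threshold (default 1e-6).
#' @param n_init number of starts (1 classical + `n_init - 1` random).
#' @return An object of class `cognitive_map`: list with `stimulus_ids`,
#'   `coordinates` (n x 2, centred), `stress` (Kruskal stress-1),
#'   `n_iterations`, `stress_trace` (per-iteration stress of the returned
#'   start, non-increasing), and `seed`.
#' @export
mds_embed <- function(dissimilarity, seed = 1L, max_iter = 300L,
                      tol = 1e-6, n_init = 4L) {
  dp_assert(is.matrix(dissimilarity) && is.numeric(dissimilarity),
            "dissimilarity must be a numeric matrix")
  n <- nrow(dissimilarity)
  dp_assert(n == ncol(dissimilarity), "dissimilarity must be square")
  dp_assert(n >= 3L, "need at least 3 stimuli to embed (got %d)", n)
  dp_assert(all(is.finite(dissimilarity)),
            "dissimilarity entries must be finite")
  dp_assert(isTRUE(all.equal(dissimilarity, t(dissimilarity),
                             tolerance = 1e-8)),
            "dissimilarity must be symmetric")
  dp_assert(all(abs(diag(dissimilarity)) < 1e-12),
            "dissimilarity diagonal must be zero")
  dp_assert(all(dissimilarity >= 0), "dissimilarities must be non-negative")
  ids <- rownames(dissimilarity) %||% as.character(seq_len(n))

  if (all(dissimilarity == 0)) {
    coords <- matrix(0, n, 2L, dimnames = list(ids, c("dim1", "dim2")))
    return(structure(
      list(stimulus_ids = ids, coordinates = coords, stress = 0,
           n_iterations = 0L, stress_trace = 0, seed = as.integer(seed)),
      class = "cognitive_map"
    ))
  }

  scale0 <- max(dissimilarity)
  starts <- vector("list", n_init)
  starts[[1L]] <- classical_config(dissimilarity, 2L)
  if (n_init > 1L) {
    for (i in seq(2L, n_init)) {
      starts[[i]] <- with_seed(
        sub_seed(seed, i),
        matrix(runif(n * 2L, -scale0 / 2, scale0 / 2), n, 2L)
      )
    }
  }
  fits <- lapply(starts, smacof_run, delta_mat = dissimilarity,
                 max_iter = max_iter, tol = tol)
  stresses <- vapply(fits, `[[`, numeric(1), "stress")
  # earliest start within numerical tolerance of the minimum wins, so the
  # metrically-informed classical solution is preferred over a random
  # restart that merely ties it
  best <- fits[[which(stresses <= min(stresses) + 1e-8)[1L]]]
  coords <- best$X
  dimnames(coords) <- list(ids, c("dim1", "dim2"))
  structure(
    list(stimulus_ids = ids, coordinates = coords, stress = best$stress,
         n_iterations = best$n_iterations, stress_trace = best$stress_trace,
         seed = as.integer(seed)),
    class = "cognitive_map"
  )
}

#' @export
print.cognitive_map <- function(x, ...) {
  cat(sprintf("Cognitive map: %d stimuli, 2 dimensions\n",
              length(x$stimulus_ids)))
  cat(sprintf("Kruskal stress-1: %.6f after %d iterations\n",
              x$stress, x$n_iterations))
  invisible(x)
}

#' Root-mean-square distance between two configurations after Procrustes
#' alignment
#'
#' Aligns `Y` to `X` by translation, rotation/reflection and (optionally)
#' uniform scaling, then reports the root-mean-square point-wise
#' distance.  Used to judge whether an embedding recovered a known
#' generating configuration up to the similarity transforms that MDS
#' cannot identify.
#'
#' @param X,Y n x k numeric matrices of corresponding points.
#' @param scale allow uniform scaling in the alignment (default `TRUE`;
#'   nonmetric solutions are only determined up to scale).
#' @return Non-negative scalar RMSD.
#' @export
procrustes_rmsd <- function(X, Y, scale = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  dp_assert(all(dim(X) == dim(Y)), "configurations must share dimensions")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (scale) {
    nx <- sqrt(sum(Xc^2)); ny <- sqrt(sum(Yc^2))
    if (nx > 0) Xc <- Xc / nx
    if (ny > 0) Yc <- Yc / ny
  }
  sv <- svd(crossprod(Xc, Yc))
  R <- sv$v %*% t(sv$u)
  s <- if (scale) sum(sv$d) / max(sum(Yc^2), .Machine$double.eps) else 1
  sqrt(mean(rowSums((Xc - s * (Yc %*% R))^2)))
}
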