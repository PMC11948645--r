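#' Diffusion map embedding of an affinity matrix
#'
#' Standard diffusion-map construction: the affinity is density-normalized
#' by row sums raised to `alpha` (`alpha = 0.5` gives the Laplace-Beltrami
#' normalization), converted to a row-stochastic Markov operator, and
#' eigendecomposed through its symmetric similar matrix. The trivial
#' constant eigenvector is dropped and the next `k` eigenvectors are
#' returned, scaled by `lambda^t` for diffusion time `t > 0` or by
#' `lambda / (1 - lambda)` for the `t = 0` multiscale convention.
#'
#' Component signs are arbitrary for an eigenproblem; they are fixed
#' deterministically so that the first nonzero loading of each component
#' is positive. [procrustes_align()] later overrides this with the
#' template's orientation.
#'
#' @param affinity symmetric nonnegative P-by-P matrix describing a
#'   connected graph.
#' @param k number of components to return (`k < P`).
#' @param alpha density-normalization exponent in \[0, 1\].
#' @param diffusion_time diffusion time `t`; 0 selects the multiscale
#'   `lambda / (1 - lambda)` scaling.
#' @return object of class `gradient_set`: list with `components` (P x k),
#'   `eigenvalues` (nonincreasing, length k), `lambdas_full`, `aligned`
#'   flag and the construction parameters.
#' @export
diffusion_embedding <- function(affinity, k = 10, alpha = 0.5,
                                diffusion_time = 0) {
  A <- as.matrix(affinity)
  P <- nrow(A)
  if (P != ncol(A)) stop("affinity must be square", call. = FALSE)
  if (max(abs(A - t(A))) > 1e-8)
    stop("affinity must be symmetric", call. = FALSE)
  if (min(A) < -1e-12) stop("affinity must be nonnegative", call. = FALSE)
  if (k >= P) stop("'k' must be smaller than the matrix size", call. = FALSE)
  comp <- .graph_components(A > 0)
  if (max(comp) > 1)
    stop(sprintf("affinity graph is disconnected (%d components); component sizes: %s",
                 max(comp), paste(tabulate(comp), collapse = ", ")),
         call. = FALSE)

  d <- rowSums(A)
  W <- A / outer(d^alpha, d^alpha)
  dw <- rowSums(W)
  # symmetric matrix similar to the row-stochastic operator D^-1 W
  S <- W / outer(sqrt(dw), sqrt(dw))
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  lam <- eg$values
  # right eigenvectors of the Markov operator
  psi <- eg$vectors / sqrt(dw)
  # normalize against the trivial stationary component (elementwise; the
  # trivial eigenvector is constant up to round-off)
  psi <- psi / psi[, 1]
  gaps <- abs(diff(lam[seq_len(min(k + 1, P))]))
  if (any(gaps < 1e-10))
    warning("near-degenerate eigenvalue spectrum; components defined only up to rotation",
            call. = FALSE)
  idx <- 1 + seq_len(k)
  lam_k <- lam[idx]
  scale_k <- if (diffusion_time > 0) lam_k^diffusion_time
             else lam_k / (1 - lam_k)
  comps <- sweep(psi[, idx, drop = FALSE], 2, scale_k, `*`)
  # deterministic sign: first loading with nonzero magnitude positive
  for (j in seq_len(k)) {
    nz <- which(abs(comps[, j]) > 1e-12)[1]
    if (!is.na(nz) && comps[nz, j] < 0) comps[, j] <- -comps[, j]
  }
  structure(list(components = comps, eigenvalues = lam_k,
                 lambdas_full = lam, aligned = FALSE, reference_id = NULL,
                 alpha = alpha, diffusion_time = diffusion_time),
            class = "gradient_set")
}

# connected components of a logical adjacency matrix by BFS
.graph_components <- function(adj) {
  P <- nrow(adj)
  comp <- integer(P)
  cur <- 0L
  for (s in seq_len(P)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Group template gradient from averaged connectivity
#'
#' Averages the subjects' Fisher-z connectivity matrices element-wise and
#' runs the full gradient chain (row thresholding, normalized-angle
#' affinity, diffusion embedding) on the mean matrix. The template is
#' computed from the averaged matrix, not by averaging individual
#' embeddings. When an atlas is supplied the first component's sign is
#' oriented so DMN parcels have a positive mean — sensory regions at the
#' negative pole, DMN at the positive pole.
#'
#' @param fc_list list of P-by-P Fisher-z connectivity matrices.
#' @param k,alpha,diffusion_time embedding parameters.
#' @param density row-threshold density.
#' @param atlas optional `parcel_atlas` used to orient component 1.
#' @return a `gradient_set` with `template = TRUE`.
#' @export
build_template <- function(fc_list, k = 10, density = 0.10, alpha = 0.5,
                           diffusion_time = 0, atlas = NULL) {
  if (!is.list(fc_list) || length(fc_list) == 0)
    stop("'fc_list' must be a non-empty list of matrices", call. = FALSE)
  P <- nrow(fc_list[[1]])
  ok <- vapply(fc_list, function(m) all(dim(m) == c(P, P)), logical(1))
  if (!all(ok)) stop("all connectivity matrices must be P x P with equal P",
                     call. = FALSE)
  mean_fc <- Reduce(`+`, fc_list) / length(fc_list)
  g <- diffusion_embedding(
    normalized_angle_affinity(row_threshold(mean_fc, density)),
    k = k, alpha = alpha, diffusion_time = diffusion_time)
  if (!is.null(atlas)) {
    dmn <- atlas$network_of == "DMN"
    if (any(dmn) && mean(g$components[dmn, 1]) < 0)
      g$components[, 1] <- -g$components[, 1]
  }
  g$template <- TRUE
  g$source <- sprintf("mean of %d connectivity matrices", length(fc_list))
  g
}

#' Procrustes alignment of an individual embedding to a template
#'
#' Finds the orthogonal matrix `R` minimizing the Frobenius distance
#' `||individual R - template||` (rotation/reflection only; no translation,
#' and no scaling unless `scale = TRUE`) and returns the rotated embedding.
#' This resolves the sign and rotational ambiguity of eigenvector-based
#' embeddings so that components are comparable across subjects.
#'
#' @param individual a `gradient_set` or P-by-k matrix.
#' @param template a `gradient_set` (typically from [build_template()]) or
#'   P-by-k matrix.
#' @param scale if `TRUE`, additionally applies the optimal global scale.
#' @return the aligned `gradient_set` (or matrix, matching the input type).
#' @export
procrustes_align <- function(individual, template, scale = FALSE) {
  X <- if (inherits(individual, "gradient_set")) individual$components
       else as.matrix(individual)
  Tm <- if (inherits(template, "gradient_set")) template$components
        else as.matrix(template)
  if (!all(dim(X) == dim(Tm)))
    stop(sprintf("dimension mismatch: individual is %dx%d, template %dx%d",
                 nrow(X), ncol(X), nrow(Tm), ncol(Tm)), call. = FALSE)
  sv <- svd(crossprod(X, Tm))
  R <- sv$u %*% t(sv$v)
  Xr <- X %*% R
  if (scale) {
    s <- sum(sv$d) / sum(X^2)
    Xr <- s * Xr
  }
  if (inherits(individual, "gradient_set")) {
    out <- individual
    out$components <- Xr
    out$aligned <- TRUE
    out$rotation <- R
    out$reference_id <- attr(template, "id") %||% "template"
    return(out)
  }
  Xr
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("gradient_set: %d parcels x %d components%s%s\n",
              nrow(x$components), ncol(x$components),
              if (isTRUE(x$aligned)) ", aligned" else "",
              if (isTRUE(x$template)) " (template)" else ""))
  cat("  eigenvalues:", format(signif(x$eigenvalues, 4)), "\n")
  invisible(x)
}
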