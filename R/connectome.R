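#' Functional connectivity from a parcellated time series
#'
#' Pearson correlation between all parcel pairs followed by Fisher's
#' r-to-z transform (`atanh`). The diagonal is set to zero. Correlations
#' at exactly +/-1 off the diagonal are clamped to `+/-(1 - eps)` before
#' the transform (with a warning) so the z-values stay finite.
#'
#' @param timeseries numeric T-by-P matrix, one column per parcel.
#' @param eps clamp margin for |r| = 1; the clamped z is `atanh(1 - eps)`.
#' @param on_constant what to do with zero-variance parcels: `"error"`
#'   (default) names the offending parcels; `"zero"` sets their edges to 0
#'   with a warning.
#' @return P-by-P symmetric Fisher-z connectivity matrix, zero diagonal.
#' @export
compute_fc <- function(timeseries, eps = 1e-7,
                       on_constant = c("error", "zero")) {
  on_constant <- match.arg(on_constant)
  ts <- as.matrix(timeseries)
  if (nrow(ts) < 3) stop("need at least 3 timepoints", call. = FALSE)
  sds <- apply(ts, 2, stats::sd)
  const <- which(sds == 0)
  if (length(const) > 0 && on_constant == "error")
    stop("constant time series in parcel(s): ",
         paste(const, collapse = ", "), call. = FALSE)
  use <- setdiff(seq_len(ncol(ts)), const)
  R <- matrix(0, ncol(ts), ncol(ts))
  R[use, use] <- stats::cor(ts[, use, drop = FALSE])
  diag(R) <- 0
  hit <- abs(R) >= 1 - eps
  if (any(hit)) {
    warning(sprintf("%d correlations clamped to +/-%g before Fisher z",
                    sum(hit) / 2, 1 - eps), call. = FALSE)
    R[hit] <- sign(R[hit]) * (1 - eps)
  }
  if (length(const) > 0)
    warning("constant parcel(s) set to zero connectivity: ",
            paste(const, collapse = ", "), call. = FALSE)
  Z <- atanh(R)
  diag(Z) <- 0
  dimnames(Z) <- list(colnames(ts), colnames(ts))
  Z
}

# deterministic per-row top-k selection: value descending, ties broken by
# column index ascending; diagonal excluded
.row_topk <- function(v, k, self) {
  v[self] <- -Inf
  ord <- order(-v, seq_along(v))
  ord[seq_len(k)]
}

#' Row-wise thresholding of a connectivity matrix
#'
#' Keeps, in each row, the `ceiling(density * (P - 1))` largest
#' off-diagonal values (signed, not absolute, by default) and zeroes the
#' rest. The result is generally asymmetric; it is the input to the
#' affinity kernel, mirroring the convention of the gradient literature
#' that retains the strongest connections per region.
#'
#' @param fc P-by-P connectivity matrix.
#' @param density fraction of off-diagonal entries kept per row, in (0,1).
#' @param absolute rank by absolute value instead of signed value.
#' @return thresholded P-by-P matrix with attribute `density`.
#' @export
row_threshold <- function(fc, density = 0.10, absolute = FALSE) {
  if (!is.numeric(density) || length(density) != 1 ||
      density <= 0 || density >= 1)
    stop("'density' must be a single number in (0, 1)", call. = FALSE)
  fc <- as.matrix(fc)
  P <- nrow(fc)
  k <- ceiling(density * (P - 1))
  out <- matrix(0, P, P, dimnames = dimnames(fc))
  rank_on <- if (absolute) abs(fc) else fc
  for (i in seq_len(P)) {
    keep <- .row_topk(rank_on[i, ], k, i)
    out[i, keep] <- fc[i, keep]
  }
  attr(out, "density") <- density
  out
}

#' Normalized-angle affinity between connectivity profiles
#'
#' For each pair of rows the cosine similarity is mapped through
#' `1 - acos(cos_sim) / pi`, giving an affinity in \[0, 1\]: identical
#' profiles score 1, orthogonal profiles 0.5, anti-parallel profiles 0.
#' The result is symmetric with unit diagonal.
#'
#' @param graph P-by-P (possibly row-thresholded, asymmetric) matrix whose
#'   rows are connectivity profiles.
#' @return P-by-P affinity matrix.
#' @export
normalized_angle_affinity <- function(graph) {
  W <- as.matrix(graph)
  nrm <- sqrt(rowSums(W^2))
  zero <- which(nrm == 0)
  if (length(zero) > 0)
    stop("all-zero connectivity profile for parcel(s): ",
         paste(zero, collapse = ", "), call. = FALSE)
  C <- tcrossprod(W / nrm)
  C <- pmin(pmax(C, -1), 1)
  A <- 1 - acos(C) / pi
  A <- (A + t(A)) / 2
  diag(A) <- 1
  A
}

#' Binarized top-density positive graph
#'
#' Ranks all positive upper-triangle entries globally and keeps the top
#' `ceiling(density * P(P-1)/2)` as undirected edges. This is the graph on
#' which the participation coefficient is computed. If fewer positive
#' entries exist than the quota, all positives are kept with a warning.
#'
#' @param fc P-by-P symmetric connectivity matrix.
#' @param density fraction of all possible edges kept, in (0, 1).
#' @return P-by-P symmetric 0/1 adjacency matrix with attribute `density`.
#' @export
binarize_positive_top <- function(fc, density = 0.10) {
  if (!is.numeric(density) || length(density) != 1 ||
      density <= 0 || density >= 1)
    stop("'density' must be a single number in (0, 1)", call. = FALSE)
  fc <- as.matrix(fc)
  P <- nrow(fc)
  ut <- which(upper.tri(fc))
  vals <- fc[ut]
  pos <- which(vals > 0)
  if (length(pos) == 0) stop("no positive connections to retain",
                             call. = FALSE)
  quota <- ceiling(density * P * (P - 1) / 2)
  if (length(pos) < quota) {
    warning(sprintf("only %d positive connections available for a quota of %d; keeping all",
                    length(pos), quota), call. = FALSE)
    keep <- pos
  } else {
    ord <- order(-vals[pos], pos)
    keep <- pos[ord[seq_len(quota)]]
  }
  A <- matrix(0, P, P, dimnames = dimnames(fc))
  A[ut[keep]] <- 1
  A <- A + t(A)
  attr(A, "density") <- density
  A
}
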