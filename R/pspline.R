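# P-spline building blocks: cubic B-spline bases with equally spaced
# interior knots and second-order difference penalties (Eilers & Marx).
# All internal; the user-facing surface is fit_normative().

# knot sequence for a B-spline basis of given degree over [lo, hi]
.ps_knots <- function(range, n_knots, degree) {
  lo <- range[1]; hi <- range[2]
  inner <- seq(lo, hi, length.out = n_knots + 2)
  c(rep(lo, degree), inner, rep(hi, degree))
}

# evaluate the basis; values outside the range are pinned to the boundary
# (constant extrapolation keeps predictions finite and flags are raised
# by callers)
.ps_eval <- function(x, knots, degree) {
  lo <- knots[degree + 1]; hi <- knots[length(knots) - degree]
  xc <- pmin(pmax(x, lo), hi)
  splines::splineDesign(knots, xc, ord = degree + 1, outer.ok = TRUE)
}

# second-order (default) difference penalty D'D for p coefficients
.ps_penalty <- function(p, order = 2) {
  D <- diff(diag(p), differences = order)
  crossprod(D)
}

# sum-to-zero reparameterization: columns of B %*% Z are orthogonal to the
# intercept so smooth main effects are identifiable. Returns Z (p x (p-1)).
.ps_center <- function(colsum) {
  qr.Q(qr(matrix(colsum, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
}
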