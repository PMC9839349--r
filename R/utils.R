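#' @keywords internal
"_PACKAGE"

#' Derive a child seed from a master seed
#'
#' Deterministic per-component seed streams: every stochastic stage of an
#' experiment gets `derive_seed(master, offset)` with a distinct offset, so
#' one master seed reproduces the whole pipeline. Results stay below 2^31
#' and are valid R integer seeds.
#'
#' @param seed master integer seed.
#' @param offset integer stream offset.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 7919) %% 2147483629)
}

stop_invalid <- function(..., class = "popkernel_invalid_input") {
  stop(errorCondition(paste0(...), class = c(class, "popkernel_error")))
}

check_finite_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_invalid(what, " must be a numeric matrix")
  }
  if (!all(is.finite(x))) {
    stop_invalid(what, " contains non-finite values")
  }
  invisible(x)
}

# Symmetric-eigen based pseudo-inverse solve: returns A^+ b where A is
# symmetric PSD; eigenvalues below rank_tol * max(eig) are treated as zero.
psd_pinv_solve <- function(A, b, rank_tol = 1e-12) {
  ee <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lam <- ee$values
  keep <- lam > rank_tol * max(lam[1], 0)
  if (!any(keep)) {
    return(matrix(0, nrow(A), NCOL(b)))
  }
  U <- ee$vectors[, keep, drop = FALSE]
  U %*% ((crossprod(U, as.matrix(b))) / lam[keep])
}
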