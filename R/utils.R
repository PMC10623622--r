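# Small linear-algebra helpers shared across the package.

# Lower-triangle (column-major, diagonal included) half-vectorization.
vech <- function(M) M[lower.tri(M, diag = TRUE)]

# Inverse of vech() for a symmetric m x m matrix.
unvech <- function(v, m) {
  M <- matrix(0, m, m)
  M[lower.tri(M, diag = TRUE)] <- v
  M <- M + t(M)
  diag(M) <- diag(M) / 2
  M
}

vech_names <- function(labels) {
  m <- length(labels)
  idx <- which(lower.tri(diag(m), diag = TRUE), arr.ind = TRUE)
  paste(labels[idx[, "col"]], labels[idx[, "row"]], sep = ":")
}

# Symmetric PD check via Cholesky; returns the factor or NULL.
chol_or_null <- function(M) {
  tryCatch(chol(M), error = function(e) NULL)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cov_to_cor <- function(C) {
  s <- sqrt(diag(C))
  R <- C / tcrossprod(s)
  diag(R) <- 1
  R
}

cor_to_cov <- function(R, sds) {
  C <- R * tcrossprod(sds)
  # exact symmetry regardless of floating-point order of operations
  (C + t(C)) / 2
}
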