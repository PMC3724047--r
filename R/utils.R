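#' Derive a reproducible sub-stream seed
#'
#' Folds a base seed and any number of integer indices into a new seed in
#' `[1, 2^31 - 2]` with a Lehmer-style hash.  Used so that every subject,
#' run and replicate of a simulation draws from its own deterministic
#' stream: identical `(base, ...)` always yields the identical seed and all
#' arithmetic stays exact in doubles.
#'
#' @param base integer base seed.
#' @param ... further integer indices (subject, state, replicate, ...).
#' @return a single integer seed.
#' @export
substream_seed <- function(base, ...) {
  m <- 2147483647
  s <- as.numeric(base) %% m
  for (x in c(7919, as.numeric(unlist(list(...))))) {
    s <- (s * 48271 + (x %% m) + 1) %% m
  }
  as.integer(s + 1)
}

#' Is a symmetric matrix positive semi-definite?
#'
#' @param m symmetric numeric matrix.
#' @param tol eigenvalue tolerance relative to the largest eigenvalue.
#' @return logical.
#' @export
is_psd <- function(m, tol = 1e-8) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(abs(ev), 1)
}

## Clip eigenvalues of a symmetric matrix to a floor and restore a unit
## diagonal.  Used for subject-level perturbed correlation matrices only;
## group-level matrices must be PSD as given.
repair_correlation <- function(m, floor = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  out
}

## Factor a PSD matrix as L with L %*% t(L) = m.  Cholesky when positive
## definite; eigenvalue square root for semi-definite targets (e.g.
## planted correlations of exactly 1).
psd_factor <- function(m) {
  out <- tryCatch(t(chol(m)), error = function(e) NULL)
  if (!is.null(out)) return(out)
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(m))
}

## Row-standardize a matrix (rows are series): zero mean, unit sd.
row_standardize <- function(x) {
  x <- x - rowMeans(x)
  s <- sqrt(rowSums(x^2) / (ncol(x) - 1))
  s[s == 0] <- 1
  x / s
}

## Correlations between the rows of two matrices sharing columns (time).
row_cor <- function(a, b) {
  a <- a - rowMeans(a)
  b <- b - rowMeans(b)
  na <- sqrt(rowSums(a^2))
  nb <- sqrt(rowSums(b^2))
  tcrossprod(a, b) / outer(na, nb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
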