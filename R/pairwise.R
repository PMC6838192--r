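#' Symmetric pairwise distance matrix over named localities
#'
#' @param values square symmetric numeric matrix with zero diagonal, with
#'   dimnames giving locality names (or supply `names`).
#' @param kind one of `"genetic"`, `"euclidean"`, `"resistance"`.
#' @param names optional locality names overriding dimnames.
#' @return object of class `pairwise_matrix` (a matrix with a `kind`
#'   attribute).
#' @export
pairwise_matrix <- function(values, kind = c("genetic", "euclidean", "resistance"),
                            names = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values) || nrow(values) < 2L)
    stop("pairwise matrix must be square with dimension >= 2")
  if (!is.null(names)) dimnames(values) <- list(names, names)
  if (is.null(rownames(values)))
    dimnames(values) <- list(paste0("L", seq_len(nrow(values))),
                             paste0("L", seq_len(nrow(values))))
  fin <- is.finite(values)
  if (max(abs(values[fin] - t(values)[fin])) > 1e-8 ||
      !identical(is.finite(values), t(is.finite(values))))
    stop("pairwise matrix must be symmetric")
  values <- (values + t(values)) / 2     # exact symmetry
  values[!is.finite(values) & !is.finite(t(values))] <- Inf
  diag(values) <- 0
  structure(values, kind = kind, class = c("pairwise_matrix", "matrix", "array"))
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix> kind = %s, %d localities\n",
              attr(x, "kind"), nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Lower-triangle pair vector of a pairwise matrix
#'
#' Pairs are ordered as `combn(n, 2)`: (1,2), (1,3), ..., (n-1,n) in locality
#' order. This ordering is shared by [mlpe_design()] so pair vectors and the
#' MLPE incidence structure always align.
#'
#' @param pm a `pairwise_matrix`.
#' @return numeric vector of length n(n-1)/2, named "a:b".
#' @export
pair_vector <- function(pm) {
  n <- nrow(pm)
  idx <- utils::combn(n, 2L)
  v <- pm[cbind(idx[1L, ], idx[2L, ])]
  names(v) <- paste(rownames(pm)[idx[1L, ]], rownames(pm)[idx[2L, ]], sep = ":")
  v
}

#' Restrict a pairwise matrix to a subset of localities
#'
#' @param pm a `pairwise_matrix`.
#' @param localities character vector of locality names (order kept).
#' @return a `pairwise_matrix` over the subset.
#' @export
restrict_pairwise <- function(pm, localities) {
  miss <- setdiff(localities, rownames(pm))
  if (length(miss)) stop("unknown localities: ", paste(miss, collapse = ", "))
  pairwise_matrix(unclass(pm)[localities, localities, drop = FALSE],
                  kind = attr(pm, "kind"))
}

#' Write / read a labeled square distance matrix as CSV
#' @param pm a `pairwise_matrix`.
#' @param path file path.
#' @return `path` (write) or a `pairwise_matrix` (read).
#' @export
write_pairwise_csv <- function(pm, path) {
  df <- data.frame(locality = rownames(pm), unclass(pm), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairwise_csv
#' @param kind kind tag to attach on read.
#' @export
read_pairwise_csv <- function(path, kind = "genetic") {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  pairwise_matrix(m, kind = kind)
}
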