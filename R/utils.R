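#' L2-normalize the rows of a matrix
#'
#' @param m numeric matrix
#' @return matrix with unit-norm rows
#' @keywords internal
normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("cannot normalize zero-norm rows")
  m / nrm
}

normalize_vec <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("cannot normalize a zero-norm vector")
  v / nrm
}

## deterministic, locale-independent 0-based lexicographic rank of unique ids
id_tie_rank <- function(ids) {
  ord <- order(ids, method = "radix")
  r <- integer(length(ids))
  r[ord] <- seq_along(ids) - 1L
  r
}

check_unit_norms <- function(m, tol = 1e-3, what = "input") {
  nrm <- sqrt(rowSums(m^2))
  if (any(abs(nrm - 1) > tol)) {
    stop(what, " must be L2-normalized (worst norm ",
         format(nrm[which.max(abs(nrm - 1))]), ")")
  }
  invisible(TRUE)
}

## stable row-wise log-sum-exp
row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

as_sequence <- function(x) {
  if (is.character(x) && length(x) == 1) return(toupper(x))
  if (is.data.frame(x) && nrow(x) == 1 && "sequence" %in% names(x))
    return(x$sequence)
  stop("expected a single sequence string or a one-row protein set")
}

write_json_det <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(10),
                       pretty = TRUE, na = "null")
}
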