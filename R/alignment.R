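#' Alignment scoring schemes
#'
#' Builds the scoring scheme used by [needleman_wunsch()] and
#' [smith_waterman()]. The default is BLOSUM62 with affine gaps (open -11,
#' extend -1), mirroring common protein-search defaults. A gap of length L
#' scores `gap_open + L * gap_extend`, so a linear scheme is obtained with
#' `gap_open = 0`.
#'
#' @param match,mismatch simple-scheme scores; used when `matrix` is NULL
#'   and `match` is given
#' @param matrix symmetric substitution matrix with residue dimnames
#'   (default: BLOSUM62 from Biostrings)
#' @param gap_open non-positive gap existence score
#' @param gap_extend non-positive per-residue gap score
#' @return a `scoring_scheme` object
#' @export
scoring_scheme <- function(match = NULL, mismatch = NULL, matrix = NULL,
                           gap_open = -11, gap_extend = -1) {
  if (is.null(matrix)) {
    if (is.null(match)) {
      matrix <- blosum62()
    } else {
      if (is.null(mismatch)) stop("mismatch score required with match score")
      n <- length(AA_ALPHABET)
      matrix <- base::matrix(mismatch, n, n,
                             dimnames = list(AA_ALPHABET, AA_ALPHABET))
      diag(matrix) <- match
    }
  }
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  if (gap_open > 0 || gap_extend > 0)
    stop("gap scores must be non-positive")
  if (gap_extend == 0)
    stop("gap_extend must be strictly negative")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

encode_seq <- function(seq, mat) {
  if (!nzchar(seq)) return(integer(0))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, rownames(mat))
  if (anyNA(idx)) {
    i <- which(is.na(idx))[1]
    stop("residue '", chars[i], "' at position ", i,
         " not covered by the scoring matrix")
  }
  idx - 1L
}

align_stats <- function(a, b, res, mode, identity_denominator) {
  pa <- res$pa
  pb <- res$pb
  ncol_aln <- length(pa)
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  aligned_query <- if (ncol_aln) paste(ifelse(pa == 0, "-", ca[pmax(pa, 1)]),
                                       collapse = "") else ""
  aligned_subject <- if (ncol_aln) paste(ifelse(pb == 0, "-", cb[pmax(pb, 1)]),
                                         collapse = "") else ""
  both <- which(pa > 0 & pb > 0)
  n_ident <- if (length(both)) sum(ca[pa[both]] == cb[pb[both]]) else 0L
  denom <- switch(identity_denominator,
                  columns = ncol_aln,
                  matched = length(both),
                  stop("unknown identity denominator"))
  identity <- if (denom > 0) n_ident / denom else 0
  if (length(both)) {
    qspan <- pa[both[length(both)]] - pa[both[1]] + 1L
    sspan <- pb[both[length(both)]] - pb[both[1]] + 1L
    qcov <- if (nchar(a)) qspan / nchar(a) else 0
    scov <- if (nchar(b)) sspan / nchar(b) else 0
  } else {
    qcov <- scov <- 0
  }
  structure(list(aligned_query = aligned_query,
                 aligned_subject = aligned_subject,
                 score = res$score, identity = identity,
                 query_coverage = qcov, subject_coverage = scov,
                 mode = mode),
            class = "alignment_result")
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment with deterministic traceback (tie order:
#' diagonal, then gap in subject, then gap in query). Identity is counted
#' over all alignment columns including gap columns; coverage is the
#' aligned span (between the first and last residue-residue column) over
#' the full sequence length, per side.
#'
#' @param a,b amino-acid sequence strings (empty allowed)
#' @param scoring a [scoring_scheme()]
#' @param identity_denominator `"columns"` (all alignment columns, default
#'   for global mode) or `"matched"` (residue-residue columns only)
#' @return an `alignment_result`: aligned strings, score, identity,
#'   query/subject coverage, mode
#' @export
needleman_wunsch <- function(a, b, scoring = scoring_scheme(),
                             identity_denominator = "columns") {
  a <- as_sequence(a); b <- as_sequence(b)
  res <- .align_cpp(encode_seq(a, scoring$matrix),
                    encode_seq(b, scoring$matrix),
                    scoring$matrix, scoring$gap_open, scoring$gap_extend,
                    FALSE)
  align_stats(a, b, res, "global", identity_denominator)
}

#' Local pairwise alignment (Smith-Waterman, affine gaps)
#'
#' Optimal local alignment; the score is never negative and an empty local
#' alignment (score 0) has identity 0 and coverages 0. Identity is counted
#' over the local alignment's columns.
#'
#' @inheritParams needleman_wunsch
#' @return an `alignment_result`
#' @export
smith_waterman <- function(a, b, scoring = scoring_scheme(),
                           identity_denominator = "columns") {
  a <- as_sequence(a); b <- as_sequence(b)
  res <- .align_cpp(encode_seq(a, scoring$matrix),
                    encode_seq(b, scoring$matrix),
                    scoring$matrix, scoring$gap_open, scoring$gap_extend,
                    TRUE)
  align_stats(a, b, res, "local", identity_denominator)
}

#' Alignment-based homology predicate
#'
#' Two proteins are called homologous when alignment identity exceeds
#' `id_thresh` and coverage exceeds `cov_thresh` on both sequences
#' (strict inequalities; the defaults encode ">50% identity with >50%
#' coverage").
#'
#' @inheritParams needleman_wunsch
#' @param id_thresh identity threshold in \[0, 1\]
#' @param cov_thresh coverage threshold in \[0, 1\], applied reciprocally
#' @param mode `"local"` (default) or `"global"`
#' @return logical
#' @export
is_homologous <- function(a, b, id_thresh = 0.50, cov_thresh = 0.50,
                          mode = c("local", "global"),
                          scoring = scoring_scheme()) {
  mode <- match.arg(mode)
  aln <- if (mode == "local") smith_waterman(a, b, scoring)
         else needleman_wunsch(a, b, scoring)
  aln$identity > id_thresh && aln$query_coverage > cov_thresh &&
    aln$subject_coverage > cov_thresh
}

#' Render an alignment as a three-line text block
#' @param aln an `alignment_result`
#' @return character vector of three lines (query, match line, subject)
#' @export
format_alignment <- function(aln) {
  qa <- strsplit(aln$aligned_query, "", fixed = TRUE)[[1]]
  sa <- strsplit(aln$aligned_subject, "", fixed = TRUE)[[1]]
  mid <- ifelse(qa == sa & qa != "-", "|", " ")
  c(aln$aligned_query, paste(mid, collapse = ""), aln$aligned_subject)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("%s alignment: score %.1f, identity %.3f, coverage %.3f/%.3f\n",
              x$mode, x$score, x$identity, x$query_coverage,
              x$subject_coverage))
  cat(format_alignment(x), sep = "\n")
  invisible(x)
}

#' Tabulate pairwise alignment statistics
#'
#' @param queries,subjects [protein_set()]s
#' @param mode alignment mode
#' @inheritParams needleman_wunsch
#' @return data frame with query, subject, identity, qcov, scov, score
#' @export
alignment_table <- function(queries, subjects, mode = c("local", "global"),
                            scoring = scoring_scheme()) {
  mode <- match.arg(mode)
  fun <- if (mode == "local") smith_waterman else needleman_wunsch
  rows <- list()
  for (i in seq_len(nrow(queries))) {
    for (j in seq_len(nrow(subjects))) {
      aln <- fun(queries$sequence[i], subjects$sequence[j], scoring)
      rows[[length(rows) + 1L]] <-
        data.frame(query = queries$id[i], subject = subjects$id[j],
                   identity = aln$identity, qcov = aln$query_coverage,
                   scov = aln$subject_coverage, score = aln$score,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
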