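#' Build an HNSW approximate nearest-neighbor index
#'
#' From-scratch hierarchical navigable small world graph over cosine
#' distance (1 - inner product of unit vectors). Node levels are drawn as
#' `floor(-ln(U) * level_mult)` from a seeded generator; insertion descends
#' greedily from the entry point, runs an `ef_construction`-bounded
#' best-first search per layer, and selects up to `M` neighbors per layer
#' (2M at layer 0) with the closer-to-the-new-node-than-to-selected
#' heuristic. Adjacency is kept symmetric. Construction is single-threaded
#' and deterministic for a fixed seed and insertion order; every tie is
#' broken by lexicographic id.
#'
#' @param db a normalized [embedding_db()]
#' @param M maximum neighbors per node per layer (layer 0 allows 2M)
#' @param ef_construction candidate-list bound during insertion
#' @param seed seed for level draws
#' @param level_mult level multiplier (default `1/ln(M)`)
#' @return an `hnsw_index`
#' @export
build_hnsw <- function(db, M = 16L, ef_construction = 200L, seed = 1L,
                       level_mult = NULL) {
  if (!inherits(db, "embedding_db")) stop("db must be an embedding_db")
  if (length(db$ids) < 1) stop("cannot index an empty database")
  check_unit_norms(db$matrix, what = "indexed vectors")
  tie <- id_tie_rank(db$ids)
  res <- .hnsw_build_cpp(db$matrix, tie, as.integer(M),
                         as.integer(ef_construction), as.integer(seed),
                         level_mult %||% -1)
  structure(list(db = db, tie = tie, levels = res$levels,
                 entry = res$entry, adjacency = res$adjacency,
                 params = list(M = as.integer(M),
                               ef_construction = as.integer(ef_construction),
                               seed = as.integer(seed),
                               level_mult = res$level_mult)),
            class = "hnsw_index")
}

#' @export
print.hnsw_index <- function(x, ...) {
  cat("hnsw_index:", length(x$db$ids), "nodes, max level",
      max(x$levels), "- M =", x$params$M, "\n")
  invisible(x)
}

hits_frame <- function(ids, sims) {
  structure(data.frame(subject_id = ids, similarity = sims,
                       rank = seq_along(ids), stringsAsFactors = FALSE),
            class = c("search_hits", "data.frame"))
}

#' Approximate k-nearest-neighbor search in an HNSW index
#'
#' Returns the approximate top-k database entries by cosine similarity.
#' Recall improves (non-strictly) with `ef_search`; with
#' `ef_search = |db|` and a fully connected layer 0 the result equals the
#' brute-force ranking. `k` larger than the database returns all points.
#'
#' @param index an `hnsw_index`
#' @param query unit-norm numeric vector (or matrix of row queries)
#' @param k number of neighbors
#' @param ef_search candidate-list bound (>= k)
#' @return for a single query, a `search_hits` data frame (subject_id,
#'   similarity, rank, sorted by descending similarity, ties broken by
#'   id); for a query matrix, a list of such frames
#' @export
hnsw_search <- function(index, query, k, ef_search = 128L) {
  single <- is.null(dim(query))
  qm <- if (single) matrix(query, nrow = 1) else as.matrix(query)
  if (ncol(qm) != index$db$dim)
    stop("query dimension ", ncol(qm), " does not match index (",
         index$db$dim, ")")
  if (k < 1) stop("k must be >= 1")
  if (ef_search < k) ef_search <- k
  check_unit_norms(qm, what = "query")
  res <- .hnsw_search_cpp(index$db$matrix, index$tie, index$levels,
                          index$entry, index$adjacency, qm, as.integer(k),
                          as.integer(ef_search))
  out <- lapply(seq_len(nrow(qm)), function(i) {
    idx <- res$idx[i, ]
    keep <- !is.na(idx)
    hits_frame(index$db$ids[idx[keep]], res$sim[i, keep])
  })
  if (single) out[[1]] else out
}

#' Exact nearest-neighbor search (brute force)
#'
#' Exact top-k by cosine similarity via a full O(ND) scan, with the same
#' tie-break contract as [hnsw_search()] (descending similarity, then
#' lexicographic id). Serves as the oracle for recall evaluation.
#'
#' @param db an `embedding_db`
#' @param query unit-norm numeric vector
#' @param k number of neighbors (capped at |db|)
#' @return a `search_hits` data frame
#' @export
brute_force_search <- function(db, query, k) {
  if (length(query) != db$dim)
    stop("query dimension ", length(query), " does not match database (",
         db$dim, ")")
  if (k < 1) stop("k must be >= 1")
  sims <- drop(db$matrix %*% query)
  ord <- order(-sims, db$ids, method = "radix")
  top <- ord[seq_len(min(k, length(ord)))]
  hits_frame(db$ids[top], sims[top])
}

#' Recall@k between approximate and exact hit lists
#'
#' @param approx_hits,exact_hits `search_hits` frames (or id vectors) of
#'   length >= k
#' @param k evaluation depth (> 0)
#' @return fraction of the exact top-k recovered in the approximate top-k
#' @export
recall_at_k <- function(approx_hits, exact_hits, k) {
  if (k < 1) stop("k must be >= 1")
  a <- if (is.data.frame(approx_hits)) approx_hits$subject_id else approx_hits
  e <- if (is.data.frame(exact_hits)) exact_hits$subject_id else exact_hits
  if (length(a) < k || length(e) < k)
    stop("hit lists must have length >= k")
  length(intersect(a[seq_len(k)], e[seq_len(k)])) / k
}

#' Persist / restore an HNSW index (JSON)
#'
#' The full index - parameters, levels, adjacency and the indexed vectors -
#' is written as JSON with 17 significant digits so reloaded searches
#' reproduce the original results exactly.
#'
#' @param index an `hnsw_index`
#' @param path output path
#' @export
save_hnsw <- function(index, path) {
  obj <- list(ids = index$db$ids,
              matrix = index$db$matrix,
              levels = index$levels,
              entry = index$entry,
              adjacency = index$adjacency,
              params = index$params)
  jsonlite::write_json(obj, path, digits = I(17), matrix = "rowmajor",
                       auto_unbox = TRUE, null = "list")
  invisible(path)
}

#' @rdname save_hnsw
#' @export
load_hnsw <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  ids <- vapply(obj$ids, as.character, character(1))
  mat <- matrix(unlist(obj$matrix), nrow = length(ids), byrow = TRUE)
  db <- embedding_db(ids, mat, normalize = FALSE)
  adjacency <- lapply(obj$adjacency, function(layers) {
    lapply(layers, function(v) as.integer(unlist(v)))
  })
  params <- obj$params
  params$M <- as.integer(params$M)
  params$ef_construction <- as.integer(params$ef_construction)
  params$seed <- as.integer(params$seed)
  structure(list(db = db, tie = id_tie_rank(ids),
                 levels = as.integer(unlist(obj$levels)),
                 entry = as.integer(obj$entry),
                 adjacency = adjacency,
                 params = params),
            class = "hnsw_index")
}

#' Structural audit of an HNSW index
#'
#' Checks the graph invariants: every node is present on layers 0..level,
#' adjacency is symmetric per layer, per-layer degree bounds (M above layer
#' 0, 2M at layer 0) hold, and the entry point has the maximal level.
#'
#' @param index an `hnsw_index`
#' @return TRUE invisibly; stops with a message on violation
#' @export
audit_hnsw <- function(index) {
  n <- length(index$levels)
  M <- index$params$M
  if (index$levels[index$entry] != max(index$levels))
    stop("entry point does not have the maximal level")
  for (i in seq_len(n)) {
    layers <- index$adjacency[[i]]
    if (length(layers) != index$levels[i] + 1L)
      stop("node ", i, " missing layers")
    for (lc in seq_along(layers)) {
      nb <- layers[[lc]]
      cap <- if (lc == 1L) 2L * M else M
      if (length(nb) > cap)
        stop("node ", i, " exceeds degree bound at layer ", lc - 1L)
      if (anyDuplicated(nb) || i %in% nb)
        stop("node ", i, " has duplicate or self links at layer ", lc - 1L)
      for (j in nb) {
        back <- index$adjacency[[j]]
        if (length(back) < lc || !(i %in% back[[lc]]))
          stop("asymmetric link ", i, " -> ", j, " at layer ", lc - 1L)
      }
    }
  }
  invisible(TRUE)
}
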