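#' End-to-end protein search: embed, project, search, report
#'
#' Embeds the query (unless a vector is given), applies a trained
#' projection when supplied, normalizes, and retrieves the top `k` hits
#' (default 100) from the database via the HNSW index (or exact scan when
#' `index` is NULL). The self hit is excluded when the query id exists in
#' the database and `exclude_self` is set. When `records` is supplied each
#' hit is annotated with a global alignment against the query; when the
#' database carries contig metadata and `contigs` is supplied each hit is
#' annotated with its gene neighborhood; when `annotated_db` is supplied a
#' predicted annotation is attached.
#'
#' @param query a one-row [protein_set()], a sequence string, or a
#'   unit-norm numeric vector
#' @param db the searched [embedding_db()]
#' @param index optional `hnsw_index` over `db`
#' @param model optional `projection_model` applied to the query embedding
#' @param k number of hits to return (default 100)
#' @param ef_search HNSW candidate-list bound
#' @param exclude_self drop the hit whose id equals the query id
#' @param records optional [protein_set()] for alignment attachments
#' @param contigs optional contig list for neighborhood attachments
#' @param annotated_db optional annotated `embedding_db` for annotation
#'   transfer
#' @param window neighborhood radius used for attachments
#' @param embed_opts list of embedder options (dim, k, seed) used when the
#'   query is a sequence; dim defaults to the projection input (when a
#'   model is given) or the database dimension
#' @return a `query_result`: query_id, hits frame, and per-hit attachment
#'   lists (alignments, neighborhoods, annotations)
#' @export
search_database <- function(query, db, index = NULL, model = NULL, k = 100L,
                            ef_search = 128L, exclude_self = TRUE,
                            records = NULL, contigs = NULL,
                            annotated_db = NULL, window = 5L,
                            embed_opts = list()) {
  query_id <- NA_character_
  if (is.numeric(query)) {
    vec <- query
  } else {
    if (is.data.frame(query)) query_id <- query$id
    dim_in <- embed_opts$dim %||% (if (!is.null(model)) model$d_in else db$dim)
    vec <- embed_sequence(as_sequence(query), dim = dim_in,
                          k = embed_opts$k %||% 3L,
                          seed = embed_opts$seed %||% 1L)
  }
  if (!is.null(model)) {
    if (length(vec) != model$d_in)
      stop("dimension mismatch at projection stage: query ", length(vec),
           " vs model input ", model$d_in)
    vec <- project_vector(model, vec)
  }
  if (length(vec) != db$dim)
    stop("dimension mismatch at search stage: query ", length(vec),
         " vs database ", db$dim)
  vec <- normalize_vec(vec)
  want_self <- exclude_self && !is.na(query_id) && query_id %in% db$ids
  kk <- min(k + as.integer(want_self), length(db$ids))
  hits <- if (is.null(index)) brute_force_search(db, vec, kk)
          else hnsw_search(index, vec, kk, max(ef_search, kk))
  if (want_self) hits <- hits[hits$subject_id != query_id, , drop = FALSE]
  hits <- utils::head(hits, k)
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  out <- list(query_id = query_id, hits = hits, alignments = NULL,
              neighborhoods = NULL, annotations = NULL)
  if (!is.null(records) && !is.numeric(query)) {
    qseq <- as_sequence(query)
    seqs <- setNames(records$sequence, records$id)
    out$alignments <- lapply(hits$subject_id, function(sid) {
      if (is.na(seqs[sid])) return(NULL)
      needleman_wunsch(qseq, seqs[[sid]])
    })
    names(out$alignments) <- hits$subject_id
    st <- t(vapply(out$alignments, function(a) {
      if (is.null(a)) c(NA_real_, NA_real_, NA_real_)
      else c(a$identity, a$query_coverage, a$subject_coverage)
    }, numeric(3)))
    out$hits$identity <- st[, 1]
    out$hits$qcov <- st[, 2]
    out$hits$scov <- st[, 3]
  }
  if (!is.null(contigs) && !is.null(db$metadata) &&
      all(c("contig_id", "rank") %in% names(db$metadata))) {
    md <- db$metadata
    out$neighborhoods <- lapply(hits$subject_id, function(sid) {
      i <- match(sid, md$id)
      if (is.na(i) || is.na(md$contig_id[i])) return(NULL)
      ct <- contigs[[md$contig_id[i]]]
      if (is.null(ct)) return(NULL)
      extract_neighborhood(ct, md$rank[i], window)
    })
    names(out$neighborhoods) <- hits$subject_id
  }
  if (!is.null(annotated_db)) {
    out$annotations <- lapply(hits$subject_id, function(sid) {
      i <- match(sid, db$ids)
      predict_annotation(db$matrix[i, ], annotated_db)
    })
    names(out$annotations) <- hits$subject_id
  }
  structure(out, class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat("query", x$query_id, "-", nrow(x$hits), "hits\n")
  print(utils::head(as.data.frame(x$hits), 10))
  invisible(x)
}

#' DBSCAN over cosine distance
#'
#' Standard DBSCAN on the cosine distance (1 - cosine similarity) between
#' unit vectors. A point is core iff at least `min_samples` points
#' (including itself) lie within `eps`. Labels are deterministic given
#' input order: cluster ids are assigned in order of the first-visited core
#' point; noise is -1.
#'
#' @param vectors matrix of unit-norm row vectors
#' @param eps cosine-distance radius (default 0.01)
#' @param min_samples minimum neighborhood size for a core point
#' @return integer label vector (0-based cluster ids, -1 for noise)
#' @export
dbscan_cosine <- function(vectors, eps = 0.01, min_samples = 2L) {
  if (eps <= 0) stop("eps must be positive")
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n == 0) return(integer(0))
  d <- 1 - tcrossprod(vectors)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(nb) >= min_samples
  labels <- rep(-1L, n)
  assigned <- rep(FALSE, n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (!core[i] || assigned[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    assigned[i] <- TRUE
    queue <- nb[[i]]
    qpos <- 1L
    while (qpos <= length(queue)) {
      j <- queue[qpos]
      qpos <- qpos + 1L
      if (!assigned[j]) {
        assigned[j] <- TRUE
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]])
      }
    }
  }
  labels
}

#' Rank co-occurring context genes across retrieved contigs
#'
#' Pools the non-focal context protein embeddings of every retrieved hit,
#' clusters them with [dbscan_cosine()], and ranks clusters by the number
#' of distinct retrieved contigs containing at least one member (ties:
#' cluster size, then representative id). The representative is the member
#' with the highest within-cluster mean similarity. Emulates the "most
#' frequently co-occurring genes" panel of a context-aware search report.
#'
#' @param result a `query_result` carrying neighborhood attachments
#' @param db the searched `embedding_db` (source of context embeddings)
#' @param top_n number of clusters to report (default 7)
#' @param eps DBSCAN cosine-distance radius
#' @param min_samples DBSCAN core threshold (a singleton cannot co-occur)
#' @return data frame (representative_id, n_contigs, size) with a
#'   `members` list column, at most `top_n` rows
#' @export
cooccurring_genes <- function(result, db, top_n = 7L, eps = 0.01,
                              min_samples = 2L) {
  nbs <- result$neighborhoods
  nbs <- nbs[!vapply(nbs, is.null, logical(1))]
  if (!length(nbs)) {
    warning("no context metadata attached to this result")
    return(data.frame(representative_id = character(0),
                      n_contigs = integer(0), size = integer(0)))
  }
  pid <- character(0); pcontig <- character(0)
  for (nb in nbs) {
    ctx <- nb$member_protein_ids[-(nb$focal_offset + 1L)]
    ctx <- ctx[ctx %in% db$ids]
    pid <- c(pid, ctx)
    pcontig <- c(pcontig, rep(nb$contig_id, length(ctx)))
  }
  if (!length(pid)) {
    warning("retrieved neighborhoods contain no embeddable context genes")
    return(data.frame(representative_id = character(0),
                      n_contigs = integer(0), size = integer(0)))
  }
  vecs <- db$matrix[pid, , drop = FALSE]
  labels <- dbscan_cosine(vecs, eps, min_samples)
  keep <- labels >= 0
  if (!any(keep))
    return(data.frame(representative_id = character(0),
                      n_contigs = integer(0), size = integer(0)))
  rows <- lapply(sort(unique(labels[keep])), function(lb) {
    sel <- which(labels == lb)
    sims <- tcrossprod(vecs[sel, , drop = FALSE])
    meansim <- rowMeans(sims)
    rep_id <- pid[sel][order(-meansim, pid[sel], method = "radix")][1]
    data.frame(representative_id = rep_id,
               n_contigs = length(unique(pcontig[sel])),
               size = length(unique(pid[sel])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(sort(unique(labels[keep])),
                        function(lb) sort(unique(pid[labels == lb])))
  ord <- order(-out$n_contigs, -out$size, out$representative_id,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Homologous fraction between two gene neighborhoods
#'
#' Compares the context genes (focal excluded on both sides) of a query
#' and a retrieved hit. Hit-context genes are matched one-to-one to
#' query-context genes greedily by descending alignment identity among
#' pairs passing [is_homologous()]; the fraction is the number of matched
#' hit-context genes over the available hit-context gene count (or a
#' strict count of 10 with `denominator = "ten"`).
#'
#' @param query_nb,hit_nb `neighborhood` objects
#' @param records [protein_set()] resolving all member ids
#' @param id_thresh,cov_thresh strict homology thresholds (defaults 0.5)
#' @param scoring a [scoring_scheme()]
#' @param denominator `"available"` (hit-context gene count, default) or
#'   `"ten"` (fixed 2 x window = 10)
#' @return fraction in \[0, 1\]
#' @export
context_homology_fraction <- function(query_nb, hit_nb, records,
                                      id_thresh = 0.50, cov_thresh = 0.50,
                                      scoring = scoring_scheme(),
                                      denominator = c("available", "ten")) {
  denominator <- match.arg(denominator)
  qctx <- query_nb$member_protein_ids[-(query_nb$focal_offset + 1L)]
  hctx <- hit_nb$member_protein_ids[-(hit_nb$focal_offset + 1L)]
  if (!length(hctx) || !length(qctx)) {
    warning("empty context on one side; fraction is 0")
    return(0)
  }
  seqs <- setNames(records$sequence, records$id)
  missing <- setdiff(c(qctx, hctx), names(seqs))
  if (length(missing)) stop("unresolvable context gene: ", missing[1])
  idm <- matrix(NA_real_, length(hctx), length(qctx))
  for (i in seq_along(hctx)) {
    for (j in seq_along(qctx)) {
      aln <- smith_waterman(seqs[[hctx[i]]], seqs[[qctx[j]]], scoring)
      ok <- aln$identity > id_thresh && aln$query_coverage > cov_thresh &&
        aln$subject_coverage > cov_thresh
      idm[i, j] <- if (ok) aln$identity else NA_real_
    }
  }
  matched <- 0L
  while (any(!is.na(idm))) {
    best <- which(idm == max(idm, na.rm = TRUE), arr.ind = TRUE)
    best <- best[order(hctx[best[, 1]], qctx[best[, 2]],
                       method = "radix"), , drop = FALSE][1, ]
    matched <- matched + 1L
    idm[best[1], ] <- NA_real_
    idm[, best[2]] <- NA_real_
  }
  denom <- if (denominator == "available") length(hctx) else 10L
  matched / denom
}

#' Correct-context-retrieval rule
#'
#' A retrieval counts as correct when strictly more than `threshold` of the
#' retrieved protein's context genes are homologous to the query's context
#' (the "more than 7 of 10" rule).
#'
#' @param fraction homologous fraction in \[0, 1\]
#' @param threshold strict cutoff (default 0.7)
#' @return logical
#' @export
is_correct_context_retrieval <- function(fraction, threshold = 0.7) {
  if (any(fraction < 0 | fraction > 1)) stop("fraction must lie in [0, 1]")
  fraction > threshold
}

#' Annotation transfer from the nearest annotated embedding
#'
#' Returns the annotation of the single nearest annotated database entry by
#' cosine similarity (ties broken by lexicographic id).
#'
#' @param query_vec unit-norm numeric vector in the annotated space
#' @param annotated_db an `embedding_db` whose metadata carries an
#'   `annotation` column
#' @return list(subject_id, annotation, similarity)
#' @export
predict_annotation <- function(query_vec, annotated_db) {
  if (!length(annotated_db$ids)) stop("annotated database is empty")
  if (is.null(annotated_db$metadata) ||
      !"annotation" %in% names(annotated_db$metadata))
    stop("annotated database must carry an 'annotation' metadata column")
  hit <- brute_force_search(annotated_db, query_vec, 1L)
  i <- match(hit$subject_id, annotated_db$metadata$id)
  list(subject_id = hit$subject_id,
       annotation = annotated_db$metadata$annotation[i],
       similarity = hit$similarity)
}

#' Export a query result as JSON and TSV
#'
#' Writes a machine-readable report (query, hits with similarity and
#' alignment statistics, neighborhoods, predicted annotations) plus a flat
#' hits TSV, and a BED-like TSV of hit neighborhoods when contig data is
#' attached.
#'
#' @param result a `query_result`
#' @param dir output directory (created if needed)
#' @param contigs optional contig list used to resolve gene coordinates
#' @return the directory, invisibly
#' @export
write_query_report <- function(result, dir, contigs = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obj <- list(query_id = result$query_id,
              hits = result$hits,
              neighborhoods = lapply(result$neighborhoods, function(nb) {
                if (is.null(nb)) NULL else unclass(nb)
              }),
              annotations = result$annotations)
  write_json_det(obj, file.path(dir, "result.json"))
  write.table(result$hits, file.path(dir, "hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(result$neighborhoods) && !is.null(contigs)) {
    rows <- list()
    for (nb in result$neighborhoods) {
      if (is.null(nb)) next
      ct <- contigs[[nb$contig_id]]
      g <- ct$genes[ct$genes$protein_id %in% nb$member_protein_ids, ,
                    drop = FALSE]
      g$role <- ifelse(g$protein_id == nb$focal_protein_id, "focal",
                       "context")
      rows[[length(rows) + 1L]] <-
        g[, c("contig_id", "start", "end", "strand", "protein_id", "role")]
    }
    if (length(rows))
      write.table(do.call(rbind, rows), file.path(dir, "neighborhoods.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
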