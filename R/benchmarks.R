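new_benchmark_report <- function(name, per_query, summary, config) {
  structure(list(name = name, per_query = per_query, summary = summary,
                 config = config),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark:", x$name, "-", nrow(x$per_query), "per-query records\n")
  utils::str(x$summary, give.attr = FALSE)
  invisible(x)
}

search_ids <- function(db, index, vec, k, ef_search) {
  hits <- if (is.null(index)) brute_force_search(db, vec, k)
          else hnsw_search(index, vec, k, max(ef_search, k))
  hits$subject_id
}

#' Sequence retrieval sensitivity benchmark
#'
#' For each query, checks whether its designated true match (its best
#' nonself alignment hit, see [make_alignment_truth()]) is recovered among
#' the top-K nonself retrievals; recall@K is averaged over queries for
#' every K in the grid.
#'
#' @param queries character vector of query ids, all present in `db`
#' @param truth named vector query_id -> target_id; every target must be
#'   in `db`
#' @param db the searched [embedding_db()]
#' @param index optional `hnsw_index` (exact scan when NULL)
#' @param K_grid recall depths
#' @param ef_search HNSW candidate-list bound
#' @return a `benchmark_report` with per-query rank of truth and a
#'   recall@K summary
#' @export
sequence_retrieval_benchmark <- function(queries, truth, db, index = NULL,
                                         K_grid = c(1, 5, 10, 30, 100),
                                         ef_search = 128L) {
  queries <- intersect(queries, names(truth))
  if (!length(queries)) stop("no queries with truth assignments")
  if (any(!queries %in% db$ids))
    stop("query not in database: ", setdiff(queries, db$ids)[1])
  missing <- setdiff(unname(truth[queries]), db$ids)
  if (length(missing)) stop("truth target missing from database: ",
                            missing[1])
  if (any(truth[queries] == queries))
    stop("truth target equals the query id (self-hits are excluded): ",
         queries[which(truth[queries] == queries)[1]])
  kmax <- min(max(K_grid) + 1L, length(db$ids))
  rank_of_truth <- vapply(queries, function(q) {
    ids <- search_ids(db, index, db$matrix[match(q, db$ids), ], kmax,
                      ef_search)
    ids <- ids[ids != q]
    r <- match(truth[[q]], ids)
    if (is.na(r)) NA_integer_ else as.integer(r)
  }, integer(1))
  per_query <- data.frame(query_id = queries,
                          target_id = unname(truth[queries]),
                          rank_of_truth = rank_of_truth,
                          stringsAsFactors = FALSE)
  recall <- vapply(K_grid, function(K)
    mean(!is.na(rank_of_truth) & rank_of_truth <= K), numeric(1))
  names(recall) <- paste0("recall@", K_grid)
  new_benchmark_report("sequence_retrieval", per_query,
                       list(recall = recall),
                       list(K_grid = K_grid, ef_search = ef_search,
                            backend = if (is.null(index)) "brute_force"
                                      else "hnsw"))
}

#' Alignment-derived retrieval truth
#'
#' For every record, finds its best nonself local-alignment hit: the
#' highest-identity partner passing the identity threshold with reciprocal
#' coverage (both sides). Records with no qualifying hit are dropped. The
#' in-repo local aligner plays the role of the alignment-search baseline
#' that defines ground truth (same 75% identity / 70% reciprocal coverage
#' thresholds by default).
#'
#' @param records a [protein_set()] with >= 2 entries
#' @param id_thresh minimum identity (default 0.75)
#' @param cov_thresh minimum coverage on both sequences (default 0.70)
#' @param scoring a [scoring_scheme()]
#' @return named character vector query_id -> best-hit id
#' @export
make_alignment_truth <- function(records, id_thresh = 0.75,
                                 cov_thresh = 0.70,
                                 scoring = scoring_scheme()) {
  n <- nrow(records)
  if (n < 2) stop("need at least 2 records")
  best_id <- rep(NA_character_, n)
  best_ident <- rep(-1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- smith_waterman(records$sequence[i], records$sequence[j],
                            scoring)
      if (aln$identity >= id_thresh && aln$query_coverage >= cov_thresh &&
          aln$subject_coverage >= cov_thresh) {
        if (aln$identity > best_ident[i] ||
            (aln$identity == best_ident[i] &&
             records$id[j] < best_id[i])) {
          best_ident[i] <- aln$identity
          best_id[i] <- records$id[j]
        }
        if (aln$identity > best_ident[j] ||
            (aln$identity == best_ident[j] &&
             records$id[i] < best_id[j])) {
          best_ident[j] <- aln$identity
          best_id[j] <- records$id[i]
        }
      }
    }
  }
  keep <- !is.na(best_id)
  if (!any(keep)) warning("no record has a qualifying nonself hit")
  setNames(best_id[keep], records$id[keep])
}

#' Genomic context sensitivity benchmark
#'
#' For each query, retrieves the top `top_m` nonself hits and scores each
#' hit's gene neighborhood against the query's with
#' [context_homology_fraction()] and the strict more-than-70% correctness
#' rule. Summarizes the fraction of correct (query, hit) pairs and the
#' fraction of queries with at least one correct hit.
#'
#' @param queries query ids (present in `db` with context metadata)
#' @param db `embedding_db` carrying contig_id/rank metadata for all ids
#' @param contigs named contig list resolving the metadata
#' @param records [protein_set()] resolving all context genes
#' @param index optional `hnsw_index`
#' @param top_m retrieved hits scored per query (default 10)
#' @param window neighborhood radius in genes
#' @param id_thresh,cov_thresh homology thresholds (strict, default 0.5)
#' @param ef_search HNSW candidate-list bound
#' @param denominator see [context_homology_fraction()]
#' @return a `benchmark_report`; summary has `pairwise_correct` and
#'   `query_any_correct`
#' @export
context_retrieval_benchmark <- function(queries, db, contigs, records,
                                        index = NULL, top_m = 10L,
                                        window = 5L, id_thresh = 0.50,
                                        cov_thresh = 0.50,
                                        ef_search = 128L,
                                        denominator = "available") {
  md <- db$metadata
  if (is.null(md) || !all(c("contig_id", "rank") %in% names(md)) ||
      any(is.na(md$contig_id[match(queries, md$id)])))
    stop("database lacks contig metadata for the context benchmark")
  get_nb <- function(id) {
    i <- match(id, md$id)
    extract_neighborhood(contigs[[md$contig_id[i]]], md$rank[i], window)
  }
  rows <- list()
  for (q in queries) {
    qnb <- get_nb(q)
    vec <- db$matrix[match(q, db$ids), ]
    ids <- search_ids(db, index, vec, min(top_m + 1L, length(db$ids)),
                      ef_search)
    ids <- utils::head(ids[ids != q], top_m)
    for (h in ids) {
      fr <- context_homology_fraction(qnb, get_nb(h), records,
                                      id_thresh, cov_thresh,
                                      denominator = denominator)
      rows[[length(rows) + 1L]] <-
        data.frame(query_id = q, hit_id = h, fraction = fr,
                   correct = is_correct_context_retrieval(fr),
                   stringsAsFactors = FALSE)
    }
  }
  per_query <- do.call(rbind, rows)
  by_query <- tapply(per_query$correct, per_query$query_id, any)
  new_benchmark_report("context_retrieval", per_query,
                       list(pairwise_correct = mean(per_query$correct),
                            query_any_correct = mean(by_query)),
                       list(top_m = top_m, window = window,
                            id_thresh = id_thresh, cov_thresh = cov_thresh,
                            denominator = denominator,
                            backend = if (is.null(index)) "brute_force"
                                      else "hnsw"))
}

#' Structural family retrieval benchmark
#'
#' For every labeled entry, retrieves the closest `n_retrieve` proteins in
#' the same set (excluding the self hit) and checks whether any of the
#' top-K retrievals shares the query's family label. Queries whose family
#' is a singleton are excluded and counted separately.
#'
#' @param test_db a labeled [embedding_db()]
#' @param family_labels named vector id -> family label, covering all ids
#' @param K_grid evaluation depths (up to `n_retrieve`)
#' @param n_retrieve neighbors retrieved per query (default 30)
#' @param index optional `hnsw_index`
#' @param ef_search HNSW candidate-list bound
#' @return a `benchmark_report`; summary has `hit_at` per K plus exclusion
#'   counts
#' @export
structure_cluster_benchmark <- function(test_db, family_labels,
                                        K_grid = c(1, 5, 10, 30),
                                        n_retrieve = 30L, index = NULL,
                                        ef_search = 128L) {
  unlabeled <- setdiff(test_db$ids, names(family_labels))
  if (length(unlabeled)) stop("unlabeled entry: ", unlabeled[1])
  labels <- family_labels[test_db$ids]
  fam_sizes <- table(labels)
  singleton <- labels %in% names(fam_sizes)[fam_sizes == 1]
  eligible <- test_db$ids[!singleton]
  K_grid <- K_grid[K_grid <= n_retrieve]
  rows <- list()
  for (q in eligible) {
    vec <- test_db$matrix[match(q, test_db$ids), ]
    ids <- search_ids(test_db, index,
                      vec, min(n_retrieve + 1L, length(test_db$ids)),
                      ef_search)
    ids <- utils::head(ids[ids != q], n_retrieve)
    same <- family_labels[ids] == family_labels[[q]]
    hit_rank <- if (any(same)) which(same)[1] else NA_integer_
    rows[[length(rows) + 1L]] <-
      data.frame(query_id = q, family = unname(family_labels[[q]]),
                 rank_of_family_hit = hit_rank, stringsAsFactors = FALSE)
  }
  per_query <- if (length(rows)) do.call(rbind, rows)
               else data.frame(query_id = character(0),
                               family = character(0),
                               rank_of_family_hit = integer(0))
  hit_at <- vapply(K_grid, function(K)
    mean(!is.na(per_query$rank_of_family_hit) &
           per_query$rank_of_family_hit <= K), numeric(1))
  names(hit_at) <- paste0("hit@", K_grid)
  new_benchmark_report("structure_cluster", per_query,
                       list(hit_at = hit_at,
                            n_excluded = sum(singleton),
                            frac_excluded = mean(singleton)),
                       list(K_grid = K_grid, n_retrieve = n_retrieve,
                            backend = if (is.null(index)) "brute_force"
                                      else "hnsw"))
}

#' Paired homolog matching benchmark
#'
#' Each query from set A searches the set-B database; the retrieval is
#' correct when the rank-1 hit equals the paired target. Accuracy is the
#' fraction of correct top-1 retrievals (the cross-domain homolog matching
#' protocol, 256 curated pairs in the original setting).
#'
#' @param db_a query-side [embedding_db()]
#' @param db_b target-side [embedding_db()] (searched)
#' @param pairs named vector a_id -> b_id; a bijection between subsets
#' @param index_b optional `hnsw_index` over `db_b`
#' @param ef_search HNSW candidate-list bound
#' @return a `benchmark_report`; summary has `accuracy` and `n_pairs`
#' @export
homolog_matching_benchmark <- function(db_a, db_b, pairs, index_b = NULL,
                                       ef_search = 128L) {
  if (anyDuplicated(names(pairs)) || anyDuplicated(unname(pairs)))
    stop("pairs must be a bijection between subsets of A and B")
  missing_a <- setdiff(names(pairs), db_a$ids)
  if (length(missing_a)) stop("pair query missing from set A: ",
                              missing_a[1])
  missing_b <- setdiff(unname(pairs), db_b$ids)
  if (length(missing_b)) stop("pair target missing from set B: ",
                              missing_b[1])
  top1 <- vapply(names(pairs), function(a) {
    search_ids(db_b, index_b, db_a$matrix[match(a, db_a$ids), ], 1L,
               ef_search)[1]
  }, character(1))
  per_query <- data.frame(query_id = names(pairs),
                          target_id = unname(pairs),
                          top1_id = unname(top1),
                          correct = unname(top1 == pairs),
                          stringsAsFactors = FALSE)
  new_benchmark_report("homolog_matching", per_query,
                       list(accuracy = mean(per_query$correct),
                            n_pairs = length(pairs)),
                       list(backend = if (is.null(index_b)) "brute_force"
                                      else "hnsw"))
}

#' Out-of-distribution sequence retrieval benchmark
#'
#' Trains the contrastive projection on the training families only, then
#' runs the sequence retrieval benchmark separately on in-distribution and
#' held-out query sets (alignment-derived truth computed within each
#' side), reporting both recall curves and their difference. Captures the
#' degraded retrieval expected for sequences unseen during training.
#'
#' @param records a [protein_set()] of all family members
#' @param family_labels named vector id -> family
#' @param held_out_families family labels forming the held-out partition
#' @param dim,kmer,embed_seed embedder options
#' @param config a [train_config()] for the projection
#' @param K_grid recall depths
#' @param truth_id_thresh,truth_cov_thresh truth thresholds (defaults
#'   0.75 / 0.70)
#' @param index_backend `"brute_force"` or `"hnsw"`
#' @return a `benchmark_report`; summary has `in_distribution`,
#'   `held_out`, and `difference` recall vectors
#' @export
ood_retrieval_benchmark <- function(records, family_labels,
                                    held_out_families, dim = 64L,
                                    kmer = 3L, embed_seed = 1L,
                                    config = train_config(),
                                    K_grid = c(1, 5, 10),
                                    truth_id_thresh = 0.75,
                                    truth_cov_thresh = 0.70,
                                    index_backend = "brute_force") {
  fams <- unique(unname(family_labels[records$id]))
  held_out_families <- unique(held_out_families)
  if (!length(held_out_families) || !all(held_out_families %in% fams))
    stop("held-out set must name existing families")
  train_fams <- setdiff(fams, held_out_families)
  if (!length(train_fams)) stop("no training families left")
  is_held <- family_labels[records$id] %in% held_out_families
  raw <- embed_database(records, dim = dim, k = kmer, seed = embed_seed)
  train_clusters <- family_labels[records$id[!is_held]]
  model <- train_projection(
    embedding_db(records$id[!is_held],
                 raw$matrix[!is_held, , drop = FALSE], normalize = FALSE),
    train_clusters, config)
  db <- project(model, raw)
  index <- if (identical(index_backend, "hnsw")) build_hnsw(db) else NULL
  run_side <- function(side_ids) {
    side_records <- records[match(side_ids, records$id), , drop = FALSE]
    truth <- make_alignment_truth(side_records, truth_id_thresh,
                                  truth_cov_thresh)
    if (!length(truth)) return(NULL)
    sequence_retrieval_benchmark(names(truth), truth, db, index, K_grid)
  }
  rep_in <- run_side(records$id[!is_held])
  rep_out <- run_side(records$id[is_held])
  if (is.null(rep_in) || is.null(rep_out))
    stop("one side has no alignment-truth queries; grow the families")
  diff <- rep_in$summary$recall - rep_out$summary$recall
  per_query <- rbind(cbind(rep_in$per_query, split = "in_distribution"),
                     cbind(rep_out$per_query, split = "held_out"))
  new_benchmark_report("ood_retrieval", per_query,
                       list(in_distribution = rep_in$summary$recall,
                            held_out = rep_out$summary$recall,
                            difference = diff),
                       list(K_grid = K_grid,
                            held_out_families = held_out_families,
                            d_out = model$d_out))
}

#' Write a benchmark report as JSON plus per-query TSV
#' @param report a `benchmark_report`
#' @param dir output directory
#' @export
write_benchmark_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_json_det(list(name = report$name, summary = report$summary,
                      config = report$config),
                 file.path(dir, paste0(report$name, ".json")))
  write.table(report$per_query,
              file.path(dir, paste0(report$name, "_per_query.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
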