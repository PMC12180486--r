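make_nb <- function(focal, members, contig = "c") {
  structure(list(focal_protein_id = focal, member_protein_ids = members,
                 focal_offset = as.integer(match(focal, members) - 1L),
                 contig_id = contig),
            class = "neighborhood")
}

test_that("search pipeline returns self at rank one and excludes it on demand", {
  fam <- gen_families(family_spec(5, 4, ancestor_length = 60,
                                  substitution_rate = 0.05, seed = 41))
  db <- embed_database(fam$records, dim = 64)
  idx <- build_hnsw(db, M = 8, seed = 1)
  q <- fam$records[1, ]
  res <- search_database(q, db, idx, k = 5, exclude_self = FALSE,
                         embed_opts = list(dim = 64))
  expect_equal(res$hits$subject_id[1], q$id)
  expect_equal(res$hits$similarity[1], 1, tolerance = 1e-6)

  res2 <- search_database(q, db, idx, k = 5, exclude_self = TRUE,
                          embed_opts = list(dim = 64))
  expect_false(q$id %in% res2$hits$subject_id)
  expect_equal(res2$hits$subject_id[1], res$hits$subject_id[2])

  # a raw db vector query returns its owner at rank 1
  res3 <- search_database(db$matrix[7, ], db, idx, k = 3,
                          exclude_self = FALSE)
  expect_equal(res3$hits$subject_id[1], db$ids[7])

  expect_error(search_database(q, db, idx, k = 3,
                               embed_opts = list(dim = 32)),
               "search stage")
})

test_that("k = 100 hits are returned by default on a 1000-protein database", {
  e <- gen_clustered_embeddings(10, 100, 16, 0.5, seed = 50)
  res <- search_database(e$db$matrix[1, ], e$db, exclude_self = FALSE)
  expect_equal(nrow(res$hits), 100)
  expect_equal(res$hits$rank, 1:100)
})

test_that("dbscan on forced geometry produces the expected clusters", {
  v <- rbind(matrix(rep(c(1, 0), each = 10), 10),
             matrix(rep(c(0, 1), each = 10), 10))
  labels <- dbscan_cosine(v, eps = 0.01, min_samples = 2)
  expect_equal(sort(unique(labels)), c(0, 1))
  expect_length(unique(labels[1:10]), 1)
  expect_length(unique(labels[11:20]), 1)

  single <- dbscan_cosine(rbind(c(1, 0), c(0, 1)), eps = 0.01,
                          min_samples = 2)
  expect_equal(single, c(-1L, -1L))
  expect_equal(dbscan_cosine(matrix(0, 0, 2)), integer(0))
})

test_that("dbscan agrees with the neighborhood-graph oracle", {
  set.seed(55)
  v <- rbind(matrix(rnorm(40 * 8, mean = 2), 40, 8),
             matrix(rnorm(40 * 8, mean = -2), 40, 8))
  v <- v / sqrt(rowSums(v^2))
  eps <- 0.05
  labels <- dbscan_cosine(v, eps = eps, min_samples = 3)
  orc <- dbscan_oracle(v, eps = eps, min_samples = 3)
  # noise/assigned status must agree; core partition must match up to
  # relabeling; border points must join an adjacent core's cluster
  expect_equal(labels >= 0, orc$core | orc$border)
  expect_equal(canon_labels(labels[orc$core]),
               canon_labels(orc$core_membership[orc$core] - 1L))
  d <- 1 - tcrossprod(v)
  for (i in which(orc$border)) {
    adjacent_cores <- which(orc$core & d[i, ] <= eps)
    expect_true(labels[i] %in% labels[adjacent_cores])
  }
})

test_that("dbscan labels are permutation-invariant up to renaming", {
  set.seed(60)
  e <- gen_clustered_embeddings(4, 15, 8, 0.05, seed = 60)
  v <- e$db$matrix
  l1 <- dbscan_cosine(v, eps = 0.05, min_samples = 2)
  perm <- sample(nrow(v))
  l2 <- dbscan_cosine(v[perm, ], eps = 0.05, min_samples = 2)
  expect_equal(canon_labels(l1[perm]) >= 0, canon_labels(l2) >= 0)
  # same partition: equal label <=> equal label
  same1 <- outer(l1[perm], l1[perm], "==") & l1[perm] >= 0
  same2 <- outer(l2, l2, "==") & l2 >= 0
  expect_equal(same1, same2)
})

test_that("co-occurring gene ranking finds the conserved flanker", {
  fx <- operon_fixture(n_contigs = 5, seed = 71)
  db <- embed_database(fx$records, contigs = fx$contigs, alpha = 0.5,
                       dim = 64)
  q <- fx$records[match(fx$queries[1], fx$records$id), ]
  res <- search_database(q, db, k = 4, records = fx$records,
                         contigs = fx$contigs, embed_opts = list(dim = 64))
  cl <- cooccurring_genes(res, db, top_n = 7, eps = 0.2)
  expect_gt(nrow(cl), 0)
  # the top cluster spans as many contigs as contribute hits
  expect_equal(cl$n_contigs[1],
               length(unique(vapply(res$neighborhoods[
                 !vapply(res$neighborhoods, is.null, logical(1))],
                 `[[`, "", "contig_id"))))
  expect_true(all(diff(cl$n_contigs) <= 0 | diff(cl$size) <= 0))

  # all-singleton contexts yield an empty ranking
  ids <- sprintf("s%02d", 1:8)
  fam2 <- gen_families(family_spec(8, 1, ancestor_length = 40, seed = 3))
  db2 <- embed_database(fam2$records, dim = 64)
  res2 <- list(neighborhoods = list(
    make_nb(fam2$records$id[1], fam2$records$id[1:4], "c1"),
    make_nb(fam2$records$id[5], fam2$records$id[5:8], "c2")))
  cl2 <- cooccurring_genes(res2, db2, eps = 0.01)
  expect_equal(nrow(cl2), 0)

  empty <- list(neighborhoods = list(NULL))
  expect_warning(out <- cooccurring_genes(empty, db2), "context")
  expect_equal(nrow(out), 0)
})

test_that("context homology fraction is exact on constructed neighborhoods", {
  set.seed(81)
  qgenes <- replicate(10, random_seq(60))
  rec_ids <- c("qf", "hf", sprintf("q%02d", 1:10), sprintf("h%02d", 1:10))
  for (m in c(0L, 4L, 10L)) {
    hgenes <- character(10)
    hgenes[seq_len(m)] <- vapply(qgenes[seq_len(m)], mutate_at_rate, "",
                                 rate = 0.05)
    for (i in seq_len(10 - m)) hgenes[m + i] <- random_seq(60)
    rec <- protein_set(rec_ids, c(random_seq(50), random_seq(50),
                                  qgenes, hgenes))
    qnb <- make_nb("qf", c(sprintf("q%02d", 1:5), "qf",
                           sprintf("q%02d", 6:10)))
    hnb <- make_nb("hf", c(sprintf("h%02d", 1:5), "hf",
                           sprintf("h%02d", 6:10)))
    fr <- context_homology_fraction(qnb, hnb, rec)
    expect_equal(fr, m / 10)
  }
})

test_that("context fraction is symmetric on full identical-gene contexts", {
  set.seed(83)
  genes <- replicate(10, random_seq(50))
  rec <- protein_set(c("fa", "fb", sprintf("g%02d", 1:10)),
                     c(random_seq(40), random_seq(40), genes))
  anb <- make_nb("fa", c(sprintf("g%02d", 1:5), "fa",
                         sprintf("g%02d", 6:10)))
  bnb <- make_nb("fb", c(sprintf("g%02d", 1:5), "fb",
                         sprintf("g%02d", 6:10)))
  expect_equal(context_homology_fraction(anb, bnb, rec),
               context_homology_fraction(bnb, anb, rec))
  expect_equal(context_homology_fraction(anb, bnb, rec), 1.0)
})

test_that("edge-truncated contexts use the available-count denominator", {
  set.seed(85)
  genes <- replicate(6, random_seq(50))
  rec <- protein_set(c("fa", "fb", sprintf("g%02d", 1:6),
                       sprintf("x%02d", 1:4)),
                     c(random_seq(40), random_seq(40), genes,
                       replicate(4, random_seq(50))))
  full <- make_nb("fa", c(sprintf("g%02d", 1:5), "fa", "g06",
                          sprintf("x%02d", 1:4)))
  edge <- make_nb("fb", c(sprintf("g%02d", 1:5), "fb", "g06"))
  expect_equal(context_homology_fraction(full, edge, rec), 1.0)
  expect_equal(context_homology_fraction(full, edge, rec,
                                         denominator = "ten"), 0.6)
  empty <- make_nb("fa", "fa")
  expect_warning(fr <- context_homology_fraction(empty, edge, rec), "empty")
  expect_equal(fr, 0)
})

test_that("correct-retrieval rule is strictly more-than-7-of-10", {
  expect_true(is_correct_context_retrieval(0.8))
  expect_false(is_correct_context_retrieval(0.7))
  expect_true(is_correct_context_retrieval(1.0))
  expect_false(is_correct_context_retrieval(0))
  expect_error(is_correct_context_retrieval(1.2), "0, 1")
})

test_that("annotation transfer picks the nearest annotated vector", {
  e <- gen_clustered_embeddings(3, 10, 32, 0.2, seed = 91)
  ann_db <- embedding_db(e$db$ids, e$db$matrix,
                         metadata = data.frame(
                           id = e$db$ids,
                           annotation = paste("protein of cluster",
                                              e$labels[e$db$ids])),
                         normalize = FALSE)
  pred <- predict_annotation(e$db$matrix[1, ], ann_db)
  expect_equal(pred$subject_id, e$db$ids[1])
  expect_equal(pred$similarity, 1, tolerance = 1e-9)

  # equidistant references break ties lexicographically
  tie_db <- embedding_db(c("zz", "aa"), rbind(c(0, 1), c(1, 0)),
                         metadata = data.frame(id = c("zz", "aa"),
                                               annotation = c("z", "a")),
                         normalize = FALSE)
  tie <- predict_annotation(c(1, 1) / sqrt(2), tie_db)
  expect_equal(tie$subject_id, "aa")
  expect_equal(tie$annotation, "a")

  expect_error(predict_annotation(c(1, 0),
                                  embedding_db(character(0),
                                               matrix(0, 0, 2),
                                               normalize = FALSE)),
               "empty")

  # cluster-level annotation transfer on held-out members
  held <- seq(1, 30, by = 3)
  train_db <- embedding_db(e$db$ids[-held], e$db$matrix[-held, ],
                           metadata = data.frame(
                             id = e$db$ids[-held],
                             annotation = unname(e$labels[e$db$ids[-held]])),
                           normalize = FALSE)
  acc <- mean(vapply(held, function(i) {
    predict_annotation(e$db$matrix[i, ], train_db)$annotation ==
      e$labels[[e$db$ids[i]]]
  }, logical(1)))
  expect_gte(acc, 0.95)
})

test_that("query reports serialize hits, neighborhoods and annotations", {
  fx <- operon_fixture(n_contigs = 3, seed = 95)
  db <- embed_database(fx$records, contigs = fx$contigs, alpha = 0.5,
                       dim = 32)
  q <- fx$records[match(fx$queries[1], fx$records$id), ]
  res <- search_database(q, db, k = 3, records = fx$records,
                         contigs = fx$contigs, embed_opts = list(dim = 32))
  d <- withr::local_tempdir()
  write_query_report(res, d, contigs = fx$contigs)
  expect_true(file.exists(file.path(d, "result.json")))
  expect_true(file.exists(file.path(d, "hits.tsv")))
  expect_true(file.exists(file.path(d, "neighborhoods.tsv")))
  hits <- read.delim(file.path(d, "hits.tsv"))
  expect_equal(nrow(hits), 3)
  expect_true(all(c("identity", "qcov", "scov") %in% names(hits)))
})
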