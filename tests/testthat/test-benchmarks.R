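test_that("sequence retrieval recall hits 1 for exact duplicates", {
  # database holds an exact duplicate of each query under a different id
  fam <- gen_families(family_spec(6, 1, ancestor_length = 60, seed = 101))
  rec <- fam$records
  dup <- protein_set(c(rec$id, paste0(rec$id, "_dup")),
                     c(rec$sequence, rec$sequence))
  db <- embed_database(dup, dim = 64)
  truth <- setNames(paste0(rec$id, "_dup"), rec$id)
  rep <- sequence_retrieval_benchmark(rec$id, truth, db,
                                      K_grid = c(1, 5))
  expect_equal(unname(rep$summary$recall["recall@1"]), 1.0)
  expect_equal(rep$per_query$rank_of_truth, rep(1L, 6))

  # self-referential truth is rejected
  expect_error(sequence_retrieval_benchmark(
    rec$id[1], setNames(rec$id[1], rec$id[1]), db), "self")
  expect_error(sequence_retrieval_benchmark(
    rec$id[1], setNames("ghost", rec$id[1]), db), "ghost")
})

test_that("recall is non-decreasing in K and matches per-query records", {
  fam <- gen_families(family_spec(8, 4, ancestor_length = 70,
                                  substitution_rate = 0.08, seed = 103))
  db <- embed_database(fam$records, dim = 64)
  truth <- make_alignment_truth(fam$records, 0.6, 0.6)
  rep <- sequence_retrieval_benchmark(names(truth), truth, db,
                                      K_grid = c(1, 5, 10))
  r <- rep$summary$recall
  expect_true(all(diff(r) >= 0))
  # summary recomputable from per-query outcomes
  expect_equal(unname(r["recall@5"]),
               mean(!is.na(rep$per_query$rank_of_truth) &
                      rep$per_query$rank_of_truth <= 5))
})

test_that("alignment truth picks mutual best hits at the stated thresholds", {
  set.seed(105)
  a <- random_seq(80)
  b <- mutate_at_rate(a, 0.05)
  c <- mutate_at_rate(a, 0.15)
  rec <- protein_set(c("A", "B", "C"), c(a, b, c))
  truth <- make_alignment_truth(rec, id_thresh = 0.75, cov_thresh = 0.70)
  # pairwise identity table from the aligner itself
  idAB <- smith_waterman(a, b)$identity
  idAC <- smith_waterman(a, c)$identity
  idBC <- smith_waterman(b, c)$identity
  expect_gt(idAB, idAC)
  expect_equal(unname(truth["A"]), "B")
  expect_equal(unname(truth["B"]), "A")
  expect_equal(unname(truth["C"]), if (idAC >= idBC) "A" else "B")

  # identical pair maps to each other; unrelated random set is empty
  pair <- protein_set(c("x", "y"), c(a, a))
  tp <- make_alignment_truth(pair)
  expect_equal(unname(tp), c("y", "x"))
  set.seed(106)
  rnd <- protein_set(c("r1", "r2", "r3"),
                     replicate(3, random_seq(60)))
  expect_warning(tr <- make_alignment_truth(rnd), "no record")
  expect_length(tr, 0)
})

test_that("context benchmark saturates on conserved operons and degrades on shuffled contexts", {
  fx <- operon_fixture(n_contigs = 4, seed = 111)
  db <- embed_database(fx$records, contigs = fx$contigs, alpha = 0.5,
                       dim = 64)
  rep <- context_retrieval_benchmark(fx$queries, db, fx$contigs,
                                     fx$records, top_m = 3)
  # in-block hits carry fully homologous contexts
  expect_gte(rep$summary$pairwise_correct, 0.5)
  expect_equal(rep$summary$query_any_correct, 1.0)

  # shuffled random contexts drawn from a wide background pool:
  # correctness collapses
  fam <- gen_families(family_spec(42, 1, ancestor_length = 70,
                                  substitution_rate = 0.03, seed = 113))
  fams <- names(attr(fam$records, "ancestors"))
  g <- gen_genomes(genome_spec(6, 11, operon_block = fams[1],
                               background_pool = fams[-1], seed = 114),
                   fam)
  db2 <- embed_database(g$records, contigs = g$contigs, alpha = 0.5,
                        dim = 64)
  shuffled <- context_retrieval_benchmark(
    names(g$labels)[g$labels == fams[1]], db2, g$contigs, g$records,
    top_m = 3)
  expect_lt(shuffled$summary$pairwise_correct, 0.05)

  expect_error(context_retrieval_benchmark(
    fx$queries, embed_database(fx$records, dim = 64), fx$contigs,
    fx$records), "metadata")
})

test_that("structure benchmark scores family hits and flags singletons", {
  # all labels identical: hit@1 is 1
  e <- gen_clustered_embeddings(1, 8, 16, 0.3, seed = 121)
  rep <- structure_cluster_benchmark(e$db,
                                     setNames(rep("f", 8), e$db$ids),
                                     K_grid = c(1, 5), n_retrieve = 5)
  expect_equal(unname(rep$summary$hit_at["hit@1"]), 1.0)
  expect_equal(rep$summary$n_excluded, 0)

  # all singleton families: everything excluded
  labels <- setNames(paste0("s", 1:8), e$db$ids)
  rep2 <- structure_cluster_benchmark(e$db, labels, K_grid = 1,
                                      n_retrieve = 5)
  expect_equal(rep2$summary$frac_excluded, 1.0)
  expect_equal(nrow(rep2$per_query), 0)

  # well-separated synthetic families are recovered at top-1
  e3 <- gen_clustered_embeddings(10, 20, 64, 0.2, seed = 123)
  rep3 <- structure_cluster_benchmark(e3$db, e3$labels,
                                      K_grid = c(1, 5, 10))
  expect_gte(unname(rep3$summary$hit_at["hit@1"]), 0.95)
  expect_true(all(diff(rep3$summary$hit_at) >= 0))

  expect_error(structure_cluster_benchmark(
    e$db, setNames("f", e$db$ids[1]), K_grid = 1), "unlabeled")
})

test_that("homolog matching is perfect for copied embeddings and near chance for random ones", {
  e <- gen_clustered_embeddings(8, 8, 32, 0.4, seed = 131)
  n <- length(e$db$ids)
  ids_a <- paste0("a", seq_len(n))
  ids_b <- paste0("b", seq_len(n))
  db_a <- embedding_db(ids_a, e$db$matrix, normalize = FALSE)
  db_b <- embedding_db(ids_b, e$db$matrix, normalize = FALSE)
  pairs <- setNames(ids_b, ids_a)
  rep <- homolog_matching_benchmark(db_a, db_b, pairs)
  expect_equal(rep$summary$accuracy, 1.0)

  # independent random embeddings: accuracy ~ 1/N over replicates
  N <- 32
  set.seed(131)
  accs <- replicate(20, {
    ma <- matrix(rnorm(N * 16), N, 16)
    mb <- matrix(rnorm(N * 16), N, 16)
    da <- embedding_db(sprintf("qa%02d", 1:N),
                       ma / sqrt(rowSums(ma^2)), normalize = FALSE)
    db2 <- embedding_db(sprintf("qb%02d", 1:N),
                        mb / sqrt(rowSums(mb^2)), normalize = FALSE)
    homolog_matching_benchmark(
      da, db2, setNames(db2$ids, da$ids))$summary$accuracy
  })
  p <- 1 / N
  se <- sqrt(p * (1 - p) / (20 * N))
  expect_lt(abs(mean(accs) - p), 3 * se + 1e-12)

  expect_error(homolog_matching_benchmark(
    db_a, db_b, setNames(c("b1", "b1"), c("a1", "a2"))), "bijection")
  expect_error(homolog_matching_benchmark(
    db_a, db_b, setNames("ghost", "a1")), "ghost")
})

test_that("mutation-diverged homolog pairs beat the chance level", {
  # paired homolog sets: set B members are diverged copies of set A
  fam <- gen_families(family_spec(64, 1, ancestor_length = 80,
                                  substitution_rate = 0, seed = 141))
  set.seed(141)
  seq_a <- fam$records$sequence
  seq_b <- vapply(seq_a, mutate_at_rate, "", rate = 0.25)
  db_a <- embed_database(protein_set(paste0("a", 1:64), seq_a), dim = 64)
  db_b <- embed_database(protein_set(paste0("b", 1:64), seq_b), dim = 64)
  rep <- homolog_matching_benchmark(db_a, db_b,
                                    setNames(db_b$ids, db_a$ids))
  expect_gt(rep$summary$accuracy, 1 / 64)
})

test_that("brute force never loses to hnsw on any recall metric", {
  fam <- gen_families(family_spec(8, 4, ancestor_length = 60,
                                  substitution_rate = 0.06, seed = 151))
  db <- embed_database(fam$records, dim = 64)
  truth <- make_alignment_truth(fam$records, 0.6, 0.6)
  idx <- build_hnsw(db, M = 8, ef_construction = 40, seed = 1)
  r_exact <- sequence_retrieval_benchmark(names(truth), truth, db,
                                          K_grid = c(1, 5, 10))
  r_hnsw <- sequence_retrieval_benchmark(names(truth), truth, db, idx,
                                         K_grid = c(1, 5, 10),
                                         ef_search = 16)
  expect_true(all(r_exact$summary$recall >= r_hnsw$summary$recall - 1e-12))
})

test_that("train/held-out retrieval split reports comparable recall curves", {
  fam <- gen_families(family_spec(10, 6, ancestor_length = 60,
                                  substitution_rate = 0.05, seed = 161))
  fams <- unique(unname(fam$labels))
  rep <- ood_retrieval_benchmark(fam$records, fam$labels,
                                 held_out_families = fams[9:10],
                                 dim = 64,
                                 config = train_config(batch_size = 32,
                                                       steps = 150,
                                                       d_out = 32,
                                                       seed = 2),
                                 K_grid = c(1, 5))
  expect_named(rep$summary, c("in_distribution", "held_out", "difference"))
  expect_true(all(rep$summary$in_distribution >= 0 &
                    rep$summary$in_distribution <= 1))
  expect_true(all(rep$summary$held_out >= 0 &
                    rep$summary$held_out <= 1))
  expect_equal(rep$summary$difference,
               rep$summary$in_distribution - rep$summary$held_out)
  # held-out queries drawn from the same generator distribution recover
  # their families just as well once past rank 1: the family-level
  # recall difference at K = 5 is near zero
  expect_lt(abs(rep$summary$difference[["recall@5"]]), 0.1)
  expect_true(all(table(rep$per_query$split) > 0))

  expect_error(ood_retrieval_benchmark(fam$records, fam$labels,
                                       held_out_families = character(0)),
               "held-out")
  expect_error(ood_retrieval_benchmark(fam$records, fam$labels,
                                       held_out_families = "nope"),
               "existing")
})

test_that("benchmark reports serialize to JSON and TSV", {
  e <- gen_clustered_embeddings(3, 6, 16, 0.2, seed = 171)
  rep <- structure_cluster_benchmark(e$db, e$labels, K_grid = c(1, 3),
                                     n_retrieve = 3)
  d <- withr::local_tempdir()
  write_benchmark_report(rep, d)
  expect_true(file.exists(file.path(d, "structure_cluster.json")))
  obj <- jsonlite::read_json(file.path(d, "structure_cluster.json"),
                             simplifyVector = TRUE)
  expect_equal(obj$name, "structure_cluster")
  pq <- read.delim(file.path(d, "structure_cluster_per_query.tsv"))
  expect_equal(nrow(pq), nrow(rep$per_query))
})
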