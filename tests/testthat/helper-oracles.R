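# Independent oracles and shared fixtures. The alignment oracles are
# deliberately exponential enumerations with no DP tables, so they share no
# code path with the package's aligner.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

simple_submat <- function(match, mismatch) {
  m <- matrix(mismatch, 21, 21, dimnames = list(c(AA20, "X"), c(AA20, "X")))
  diag(m) <- match
  m
}

# exhaustive global alignment score by recursion over all gapped alignments
# (linear gap: each gapped residue costs `gap`)
brute_nw_score <- function(a, b, sub, gap) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  rec <- function(i, j) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb) best <- sub[ca[i], cb[j]] + rec(i + 1, j + 1)
    if (i <= na) best <- max(best, gap + rec(i + 1, j))
    if (j <= nb) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# exhaustive local alignment score: best over all start cells of an
# alignment free to stop at any point (empty alignment scores 0)
brute_sw_score <- function(a, b, sub, gap) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  ext <- function(i, j) {
    best <- 0
    if (i <= na && j <= nb) best <- max(best, sub[ca[i], cb[j]] + ext(i + 1, j + 1))
    if (i <= na) best <- max(best, gap + ext(i + 1, j))
    if (j <= nb) best <- max(best, gap + ext(i, j + 1))
    best
  }
  best <- 0
  for (i in seq_len(na + 1)) for (j in seq_len(nb + 1))
    best <- max(best, ext(i, j))
  best
}

random_seq <- function(len) paste(sample(AA20, len, replace = TRUE),
                                  collapse = "")

# brute-force neighborhood-graph DBSCAN oracle: core statuses from
# epsilon-neighborhood counts, clusters as connected components of the
# core-core graph (igraph), border points attached to adjacent cores.
# Returns per-point status and the core partition.
dbscan_oracle <- function(vectors, eps, min_samples) {
  n <- nrow(vectors)
  d <- 1 - tcrossprod(vectors)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(nb) >= min_samples
  membership <- rep(NA_integer_, n)
  if (any(core)) {
    ci <- which(core)
    A <- d[ci, ci, drop = FALSE] <= eps
    diag(A) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    membership[ci] <- igraph::components(g)$membership
  }
  border <- !core & vapply(seq_len(n), function(i) any(core[nb[[i]]]),
                           logical(1))
  list(core = core, border = border,
       core_membership = membership,
       adjacent_clusters = lapply(seq_len(n), function(i)
         unique(membership[nb[[i]]][core[nb[[i]]]])))
}

# canonical relabeling: map labels to first-appearance order so two label
# vectors can be compared up to renaming
canon_labels <- function(labels) {
  out <- rep(-1L, length(labels))
  seen <- integer(0)
  for (i in seq_along(labels)) {
    if (labels[i] < 0) next
    key <- as.character(labels[i])
    if (!key %in% names(seen)) seen[key] <- length(seen)
    out[i] <- seen[[key]]
  }
  out
}

# mutate a sequence to approximately the given per-site substitution rate
mutate_at_rate <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- runif(length(ch)) < rate
  ch[hit] <- vapply(ch[hit], function(cc) sample(setdiff(AA20, cc), 1),
                    character(1))
  paste(ch, collapse = "")
}

# nearest-neighbor top-1 same-label accuracy by exact search
top1_label_accuracy <- function(db, labels) {
  mean(vapply(seq_along(db$ids), function(i) {
    h <- brute_force_search(db, db$matrix[i, ], 2)
    h <- h[h$subject_id != db$ids[i], , drop = FALSE]
    labels[[h$subject_id[1]]] == labels[[db$ids[i]]]
  }, logical(1)))
}

# byte-level digests of every file under a directory; config.json echoes
# the caller's paths verbatim and is excluded when comparing runs rooted
# in different directories
dir_digest <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "config.json"]
  vapply(files, function(f) digest_file(f), character(1))
}

digest_file <- function(f) {
  con <- file(f, "rb")
  on.exit(close(con))
  paste(as.character(readBin(con, "raw", file.size(f))), collapse = "")
}

# two-set conserved-operon fixture: an 11-family operon genome set plus a
# second set carrying the focal family in shuffled decoy contexts
operon_fixture <- function(n_contigs = 6, seed = 11) {
  fam <- gen_families(family_spec(16, 2, ancestor_length = 70,
                                  substitution_rate = 0.03, seed = seed))
  fams <- names(attr(fam$records, "ancestors"))
  g1 <- gen_genomes(genome_spec(n_contigs, 11, operon_block = fams[1:11],
                                background_pool = character(0),
                                seed = seed + 1),
                    fam, contig_prefix = "opn")
  g2 <- gen_genomes(genome_spec(n_contigs, 11, operon_block = fams[6],
                                background_pool = fams[12:16],
                                seed = seed + 2),
                    fam, contig_prefix = "bg")
  records <- protein_set(c(g1$records$id, g2$records$id),
                         c(g1$records$sequence, g2$records$sequence),
                         c(g1$records$contig_id, g2$records$contig_id),
                         c(g1$records$gene_index, g2$records$gene_index))
  list(records = records,
       contigs = c(g1$contigs, g2$contigs),
       labels = c(g1$labels, g2$labels),
       focal_family = fams[6],
       queries = names(g1$labels)[g1$labels == fams[6]])
}
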