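#' Specification of synthetic protein families
#'
#' Families are simulated as a random ancestor (uniform over the 20
#' standard residues) plus members derived by i.i.d. point substitutions
#' (replacement drawn uniformly from the 19 alternatives) and
#' geometric-length indels at the stated per-site rates. Deliberately the
#' simplest model with tunable identity - not phylogenetically realistic.
#'
#' @param n_families number of families
#' @param members_per_family members per family
#' @param ancestor_length ancestor length in residues
#' @param substitution_rate per-site substitution probability
#' @param indel_rate per-site indel probability
#' @param seed RNG seed
#' @return a `family_spec`
#' @export
family_spec <- function(n_families, members_per_family,
                        ancestor_length = 150L, substitution_rate = 0.05,
                        indel_rate = 0, seed = 1L) {
  if (substitution_rate < 0 || substitution_rate > 1 ||
      indel_rate < 0 || indel_rate > 1)
    stop("rates must lie in [0, 1]")
  if (ancestor_length < 3) stop("ancestor_length must be >= 3")
  structure(list(n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 ancestor_length = as.integer(ancestor_length),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "family_spec")
}

mutate_sequence <- function(seq, substitution_rate, indel_rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  hit <- runif(n) < substitution_rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(cc)
      sample(setdiff(AA_STANDARD, cc), 1L), character(1))
  }
  if (indel_rate > 0) {
    ev <- runif(n) < indel_rate
    for (i in rev(which(ev))) {
      len <- rgeom(1, 0.5) + 1L
      if (runif(1) < 0.5) {  # deletion
        chars <- chars[-(i:min(n, i + len - 1L))]
      } else {               # insertion
        ins <- sample(AA_STANDARD, len, replace = TRUE)
        chars <- append(chars, ins, after = i)
      }
      n <- length(chars)
    }
    if (!length(chars)) chars <- sample(AA_STANDARD, 1L)
  }
  paste(chars, collapse = "")
}

#' Generate mutation-diverged protein families
#'
#' @param spec a [family_spec()]
#' @return list with `records` (a [protein_set()]) and `labels` (named
#'   vector id -> family id); family ancestors and the spec are attached
#'   as attributes of `records` for downstream fresh-member sampling
#' @export
gen_families <- function(spec) {
  set.seed(spec$seed)
  ids <- character(0); seqs <- character(0); labels <- character(0)
  ancestors <- character(spec$n_families)
  fam_ids <- sprintf("F%02d", seq_len(spec$n_families))
  for (f in seq_len(spec$n_families)) {
    anc <- paste(sample(AA_STANDARD, spec$ancestor_length, replace = TRUE),
                 collapse = "")
    ancestors[f] <- anc
    for (m in seq_len(spec$members_per_family)) {
      ids <- c(ids, sprintf("%s_M%02d", fam_ids[f], m))
      seqs <- c(seqs, mutate_sequence(anc, spec$substitution_rate,
                                      spec$indel_rate))
      labels <- c(labels, fam_ids[f])
    }
  }
  records <- protein_set(ids, seqs)
  attr(records, "ancestors") <- setNames(ancestors, fam_ids)
  attr(records, "spec") <- spec
  list(records = records, labels = setNames(labels, ids))
}

#' Specification of synthetic genomes with a conserved operon block
#'
#' Each contig carries the operon block (same family order across contigs,
#' fresh member per family per contig) at a random offset, surrounded by
#' background genes drawn independently from the background pool.
#'
#' @param n_contigs number of contigs
#' @param genes_per_contig genes per contig
#' @param operon_block ordered character vector of family ids forming the
#'   conserved neighborhood (may be empty)
#' @param background_pool family ids sampled independently for background
#' @param seed RNG seed
#' @return a `genome_spec`
#' @export
genome_spec <- function(n_contigs, genes_per_contig,
                        operon_block = character(0),
                        background_pool = character(0), seed = 1L) {
  if (length(operon_block) > genes_per_contig)
    stop("operon block longer than the contig")
  if (!length(operon_block) && !length(background_pool))
    stop("need an operon block and/or a background pool")
  structure(list(n_contigs = as.integer(n_contigs),
                 genes_per_contig = as.integer(genes_per_contig),
                 operon_block = as.character(operon_block),
                 background_pool = as.character(background_pool),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate contigs with conserved gene neighborhoods
#'
#' @param spec a [genome_spec()]
#' @param families output of [gen_families()] supplying family ancestors
#'   and mutation rates for fresh member sampling
#' @param intergenic nucleotide gap between consecutive genes
#' @param contig_prefix prefix for contig ids (lets several genome sets
#'   coexist in one database)
#' @return list with `contigs` (named contig list), `records`
#'   (a [protein_set()] with contig/rank metadata) and `labels` (id ->
#'   family)
#' @export
gen_genomes <- function(spec, families, intergenic = 50L,
                        contig_prefix = "ctg") {
  ancestors <- attr(families$records, "ancestors")
  fspec <- attr(families$records, "spec")
  missing <- setdiff(c(spec$operon_block, spec$background_pool),
                     names(ancestors))
  if (length(missing)) stop("unknown family id: ", missing[1])
  set.seed(spec$seed)
  ids <- character(0); seqs <- character(0); labels <- character(0)
  cids <- character(0); gidx <- integer(0)
  contigs <- list()
  bl <- length(spec$operon_block)
  for (c in seq_len(spec$n_contigs)) {
    cid <- sprintf("%s%03d", contig_prefix, c)
    n <- spec$genes_per_contig
    offset <- if (bl) sample.int(n - bl + 1L, 1L) - 1L else 0L
    fams <- if (length(spec$background_pool))
      sample(spec$background_pool, n, replace = TRUE)
    else rep(NA_character_, n)
    if (bl) fams[(offset + 1):(offset + bl)] <- spec$operon_block
    if (anyNA(fams)) stop("background pool required to fill the contig")
    start <- 0L
    genes <- vector("list", n)
    for (g in seq_len(n)) {
      gid <- sprintf("%sg%02d", cid, g)
      sq <- mutate_sequence(ancestors[[fams[g]]], fspec$substitution_rate,
                            fspec$indel_rate)
      ids <- c(ids, gid); seqs <- c(seqs, sq); labels <- c(labels, fams[g])
      cids <- c(cids, cid); gidx <- c(gidx, g - 1L)
      len_nt <- 3L * nchar(sq) + 3L
      genes[[g]] <- data.frame(contig_id = cid, start = start,
                               end = start + len_nt, strand = "+",
                               protein_id = gid, rank = g - 1L,
                               stringsAsFactors = FALSE)
      start <- start + len_nt + as.integer(intergenic)
    }
    contigs[[cid]] <- new_contig(cid, do.call(rbind, genes))
  }
  records <- protein_set(ids, seqs, contig_id = cids, gene_index = gidx)
  list(contigs = contigs, records = records,
       labels = setNames(labels, ids), spec = spec)
}

#' Generate cluster-structured embeddings on the unit sphere
#'
#' Cluster centers are sampled uniformly on the sphere; members are
#' `normalize(center + spread * gaussian noise)`.
#'
#' @param n_clusters number of clusters
#' @param per_cluster members per cluster
#' @param dim embedding dimension
#' @param spread noise scale (> 0; small = tight clusters)
#' @param seed RNG seed
#' @return list with `db` (an [embedding_db()]) and `labels` (id ->
#'   cluster id)
#' @export
gen_clustered_embeddings <- function(n_clusters, per_cluster, dim,
                                     spread = 0.1, seed = 1L) {
  if (spread <= 0) stop("spread must be positive")
  set.seed(seed)
  centers <- normalize_rows(matrix(rnorm(n_clusters * dim), n_clusters))
  n <- n_clusters * per_cluster
  mat <- matrix(0, n, dim)
  ids <- character(n); labels <- character(n)
  r <- 0L
  for (cl in seq_len(n_clusters)) {
    for (m in seq_len(per_cluster)) {
      r <- r + 1L
      mat[r, ] <- centers[cl, ] + spread * rnorm(dim)
      ids[r] <- sprintf("K%02d_%03d", cl, m)
      labels[r] <- sprintf("K%02d", cl)
    }
  }
  list(db = embedding_db(ids, normalize_rows(mat), normalize = FALSE),
       labels = setNames(labels, ids))
}

#' Write a simulated family/genome dataset to standard files
#'
#' Emits FASTA + GFF3 + a family-label TSV + a JSON spec echo, so
#' generated fixtures round-trip through the ordinary readers.
#'
#' @param sim output of [gen_genomes()] (or [gen_families()], FASTA and
#'   labels only)
#' @param dir output directory
#' @return the directory, invisibly
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$records, file.path(dir, "proteins.faa"))
  if (!is.null(sim$contigs))
    write_gff(sim$contigs, file.path(dir, "genes.gff3"))
  write.table(data.frame(protein_id = names(sim$labels),
                         cluster_id = unname(sim$labels)),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(sim$spec)) write_json_det(unclass(sim$spec),
                                         file.path(dir, "spec.json"))
  invisible(dir)
}
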