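#' Deterministic sequence embedding (hashed k-mer composition)
#'
#' Maps a protein sequence to a unit vector by feature-hashing its
#' overlapping k-mers: each k-mer is hashed (version-pinned 64-bit FNV-1a,
#' seeded) to a dimension and a sign, signed counts are accumulated and the
#' result is L2-normalized. Identical sequences always give identical
#' vectors, across runs and platforms. Sequences shorter than k are embedded
#' over all their 1..length-mers. This is the sequence-only backend of the
#' pluggable embedder interface; any function with the same contract
#' (record to fixed-dimension unit vector) can stand in for it, including
#' adapters over precomputed language-model embeddings.
#'
#' @param record a sequence string or one-row [protein_set()]
#' @param dim embedding dimension (>= 8)
#' @param k k-mer order (default 3)
#' @param seed hash seed; part of the embedding definition
#' @return numeric unit vector of length `dim`
#' @export
embed_sequence <- function(record, dim = 256L, k = 3L, seed = 1L) {
  seq <- as_sequence(record)
  if (dim < 8) stop("embedding dimension must be >= 8")
  if (!nzchar(seq)) stop("cannot embed an empty sequence")
  .embed_kmers_cpp(seq, as.integer(dim), as.integer(k), as.integer(seed))
}

#' Context-mixing embedding of a gene in its neighborhood
#'
#' Convex blend of the focal protein's sequence embedding with the mean of
#' its neighbors' embeddings, re-normalized:
#' `normalize((1 - alpha) * e(focal) + alpha * mean(e(neighbors)))`.
#' With `alpha = 0` this reduces exactly to [embed_sequence()] on the focal
#' protein; a singleton neighborhood returns the focal embedding regardless
#' of `alpha`. The blend makes "similar genomic context implies similar
#' embedding" literally true; it emulates the context awareness of a
#' genomic language model without any learned weights.
#'
#' @param neighborhood a `neighborhood` from [extract_neighborhood()]
#' @param records [protein_set()] resolving every member id
#' @param alpha context mixing weight in \[0, 1\]
#' @inheritParams embed_sequence
#' @return numeric unit vector
#' @export
embed_in_context <- function(neighborhood, records, alpha = 0.5, dim = 256L,
                             k = 3L, seed = 1L) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  members <- neighborhood$member_protein_ids
  missing <- setdiff(members, records$id)
  if (length(missing))
    stop("neighborhood member not resolvable to a record: ", missing[1])
  seqs <- setNames(records$sequence, records$id)
  focal <- embed_sequence(seqs[[neighborhood$focal_protein_id]], dim, k, seed)
  nb_ids <- members[-(neighborhood$focal_offset + 1L)]
  if (alpha == 0 || !length(nb_ids)) return(focal)
  nb <- vapply(nb_ids, function(i) embed_sequence(seqs[[i]], dim, k, seed),
               numeric(dim))
  normalize_vec((1 - alpha) * focal + alpha * rowMeans(nb))
}

#' Embedding databases
#'
#' An id-indexed matrix of fixed-dimension L2-normalized vectors plus
#' optional per-id metadata (contig, rank, annotation, ...).
#'
#' @param ids unique id strings, one per row
#' @param matrix numeric matrix, rows in `ids` order
#' @param metadata optional data frame with an `id` column
#' @param normalize normalize rows on construction (with a warning if any
#'   norm deviates from 1 by more than `1e-3`)
#' @return an `embedding_db` object with fields ids, matrix, dim, metadata
#' @export
embedding_db <- function(ids, matrix, metadata = NULL, normalize = TRUE) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate id: ", ids[duplicated(ids)][1])
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != length(ids))
    stop("row count (", nrow(matrix), ") must equal id count (",
         length(ids), ")")
  if (any(!is.finite(matrix))) stop("embeddings must be finite")
  if (normalize) {
    nrm <- sqrt(rowSums(matrix^2))
    if (any(abs(nrm - 1) > 1e-3))
      warning("renormalizing ", sum(abs(nrm - 1) > 1e-3),
              " row(s) with norm deviating from 1")
    matrix <- normalize_rows(matrix)
  }
  rownames(matrix) <- ids
  if (!is.null(metadata)) {
    if (!"id" %in% names(metadata)) stop("metadata must have an 'id' column")
    metadata <- metadata[match(ids, metadata$id), , drop = FALSE]
    rownames(metadata) <- NULL
  }
  structure(list(ids = ids, matrix = matrix, dim = ncol(matrix),
                 metadata = metadata),
            class = "embedding_db")
}

#' @export
print.embedding_db <- function(x, ...) {
  cat("embedding_db:", length(x$ids), "vectors of dimension", x$dim, "\n")
  if (!is.null(x$metadata))
    cat("metadata columns:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Embed a whole protein set into a database
#'
#' Builds an [embedding_db()] over all records with the built-in hashed
#' k-mer embedder, optionally mixing in genomic context (when `contigs` is
#' supplied and `alpha > 0`, each gene is embedded with
#' [embed_in_context()] over its `window`-gene neighborhood). Contig and
#' rank metadata are carried into the database when available.
#'
#' @param records a [protein_set()]
#' @param contigs optional named list of contigs (from [read_gff()] or
#'   [gen_genomes()])
#' @param alpha context mixing weight (0 = sequence-only)
#' @param window neighborhood radius in genes
#' @inheritParams embed_sequence
#' @param annotations optional named character vector (id -> annotation
#'   text) stored as metadata
#' @return an `embedding_db`
#' @export
embed_database <- function(records, contigs = NULL, alpha = 0, window = 5L,
                           dim = 256L, k = 3L, seed = 1L,
                           annotations = NULL) {
  n <- nrow(records)
  mat <- base::matrix(0, n, dim)
  meta <- data.frame(id = records$id,
                     contig_id = NA_character_, rank = NA_integer_,
                     stringsAsFactors = FALSE)
  nbs <- NULL
  if (!is.null(contigs)) {
    nbs <- list()
    for (ct in contigs) {
      for (r in ct$genes$rank) {
        nb <- extract_neighborhood(ct, r, window)
        nbs[[nb$focal_protein_id]] <- nb
        i <- match(nb$focal_protein_id, records$id)
        if (!is.na(i)) {
          meta$contig_id[i] <- ct$id
          meta$rank[i] <- r
        }
      }
    }
  }
  for (i in seq_len(n)) {
    id <- records$id[i]
    if (alpha > 0 && !is.null(nbs) && !is.null(nbs[[id]])) {
      mat[i, ] <- embed_in_context(nbs[[id]], records, alpha, dim, k, seed)
    } else {
      mat[i, ] <- embed_sequence(records$sequence[i], dim, k, seed)
    }
  }
  if (!is.null(annotations))
    meta$annotation <- unname(annotations[records$id])
  embedding_db(records$id, mat, metadata = meta, normalize = TRUE)
}

#' Load precomputed embeddings from TSV
#'
#' Expects a header row (`id` followed by one column per dimension) and one
#' row per protein. Vectors are L2-normalized on load, with a warning when
#' any norm deviates from 1 by more than 1e-3. Adapter for embedding
#' matrices computed by external models.
#'
#' @param path path to the TSV file
#' @return an `embedding_db`
#' @export
load_embeddings <- function(path) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop("ragged row in ", path, ": row ", bad, " has ", nf[bad],
         " fields, expected ", nf[1])
  }
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(df)) stop("embedding TSV must have an 'id' column")
  ids <- as.character(df$id)
  mat <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  storage.mode(mat) <- "double"
  if (any(!is.finite(mat))) stop("non-numeric embedding values in ", path)
  embedding_db(ids, mat, normalize = TRUE)
}

#' Save an embedding database as TSV
#' @param db an `embedding_db`
#' @param path output path
#' @param digits significant digits written
#' @export
save_embeddings <- function(db, path, digits = 10L) {
  vals <- formatC(db$matrix, format = "g", digits = digits)
  df <- data.frame(id = db$ids, vals, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- c("id", paste0("d", seq_len(db$dim)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cosine similarity of a query against database rows
#' @param db an `embedding_db`
#' @param query numeric vector of matching dimension
#' @return named numeric vector of similarities
#' @export
cosine_similarities <- function(db, query) {
  if (length(query) != db$dim)
    stop("query dimension ", length(query), " does not match database (",
         db$dim, ")")
  drop(db$matrix %*% query)
}
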