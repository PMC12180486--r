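#' Protein record sets
#'
#' A protein set is a data frame with one row per protein and columns
#' `id`, `sequence`, `contig_id` and `gene_index`. Sequences are uppercase
#' strings over the 20 standard residues plus `X`; ids are unique,
#' non-empty and contain no whitespace.
#'
#' @param id character vector of unique ids
#' @param sequence character vector of amino-acid sequences
#' @param contig_id optional contig of origin per protein
#' @param gene_index optional 0-based position in contig gene order
#' @return a `protein_set` data frame
#' @export
protein_set <- function(id, sequence, contig_id = NA_character_,
                        gene_index = NA_integer_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(id)) || any(grepl("\\s", id)))
    stop("protein ids must be non-empty and contain no whitespace")
  dup <- id[duplicated(id)]
  if (length(dup))
    stop("duplicate protein id: ", dup[1])
  if (any(!nzchar(sequence)))
    stop("empty sequence for id: ", id[which(!nzchar(sequence))[1]])
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), sequence)
  if (any(bad)) {
    i <- which(bad)[1]
    pos <- regexpr(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                   sequence[i])
    stop("illegal residue '", substr(sequence[i], pos, pos), "' at position ",
         as.integer(pos), " in sequence ", id[i])
  }
  out <- data.frame(id = id, sequence = sequence,
                    contig_id = rep_len(as.character(contig_id), length(id)),
                    gene_index = rep_len(as.integer(gene_index), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Read a protein FASTA file
#'
#' The header token before the first whitespace becomes the id; sequences
#' are uppercased and trailing stop characters (`*`) are stripped.
#'
#' @param path path to a FASTA file
#' @return a [protein_set()] (contig metadata unset)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- sub("\\*+$", "", toupper(as.character(ss)))
  names(seqs) <- NULL
  protein_set(ids, seqs)
}

#' Write a protein set to FASTA
#'
#' @param records a [protein_set()]
#' @param path output path
#' @param width line width for wrapping
#' @export
write_fasta <- function(records, path, width = 60L) {
  ss <- Biostrings::AAStringSet(records$sequence)
  names(ss) <- records$id
  Biostrings::writeXStringSet(ss, path, width = as.integer(width))
  invisible(path)
}

new_contig <- function(id, genes) {
  structure(list(id = id, genes = genes), class = "contig")
}

#' Read CDS features from a GFF3 file into contigs
#'
#' GFF3 coordinates (1-based inclusive) are converted to internal 0-based
#' half-open intervals. CDS rows whose protein id matches no record in
#' `proteins` are skipped with a warning. Genes are sorted by start within
#' each contig and assigned 0-based ranks.
#'
#' @param path path to a GFF3 file
#' @param proteins a [protein_set()] whose ids CDS features must match
#' @param attribute GFF3 attribute key carrying the protein id
#' @return named list of `contig` objects (each with an `id` and a `genes`
#'   data frame: contig_id, start, end, strand, protein_id, rank)
#' @export
read_gff <- function(path, proteins, attribute = "ID") {
  if (!file.exists(path)) stop("GFF file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("failed to parse GFF3 file ", path,
                                          ": ", conditionMessage(e)))
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  if (!attribute %in% names(S4Vectors::mcols(gr)))
    stop("GFF3 attribute '", attribute, "' not present on CDS features")
  pid <- as.character(S4Vectors::mcols(gr)[[attribute]])
  keep <- pid %in% proteins$id
  if (any(!keep)) {
    warning("skipping ", sum(!keep), " CDS feature(s) with no matching ",
            "protein record (e.g. '", pid[!keep][1], "')")
    gr <- gr[keep]
    pid <- pid[keep]
  }
  start0 <- as.integer(GenomicRanges::start(gr)) - 1L
  end0 <- as.integer(GenomicRanges::end(gr))
  if (any(end0 <= start0)) {
    i <- which(end0 <= start0)[1]
    stop("CDS feature '", pid[i], "' has end <= start after conversion")
  }
  df <- data.frame(contig_id = as.character(GenomicRanges::seqnames(gr)),
                   start = start0, end = end0,
                   strand = as.character(GenomicRanges::strand(gr)),
                   protein_id = pid, stringsAsFactors = FALSE)
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  out <- lapply(split(df, df$contig_id), function(g) {
    g <- g[order(g$start, g$end, g$protein_id), , drop = FALSE]
    g$rank <- seq_len(nrow(g)) - 1L
    rownames(g) <- NULL
    new_contig(g$contig_id[1], g)
  })
  out[order(names(out), method = "radix")]
}

#' Write contigs as GFF3 CDS features
#'
#' @param contigs list of `contig` objects (as from [read_gff()])
#' @param path output path
#' @export
write_gff <- function(contigs, path) {
  genes <- do.call(rbind, lapply(contigs, function(ct) ct$genes))
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- genes$protein_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Extract the gene neighborhood around a focal gene
#'
#' Returns the window of up to `window` genes upstream and `window` genes
#' downstream of the focal gene (by gene rank, strand-agnostic), truncated
#' silently at contig edges.
#'
#' @param contig a `contig` object
#' @param focal_rank 0-based rank of the focal gene
#' @param window maximum number of genes on each side (default 5)
#' @return a `neighborhood` object: focal_protein_id, member_protein_ids in
#'   genomic order (focal included), focal_offset, contig_id
#' @export
extract_neighborhood <- function(contig, focal_rank, window = 5L) {
  genes <- contig$genes
  n <- nrow(genes)
  if (window < 0) stop("window must be >= 0")
  if (focal_rank < 0 || focal_rank >= n)
    stop("focal_rank ", focal_rank, " out of range for contig with ", n,
         " genes")
  lo <- max(0L, focal_rank - window)
  hi <- min(n - 1L, focal_rank + window)
  members <- genes$protein_id[(lo:hi) + 1L]
  structure(list(focal_protein_id = genes$protein_id[focal_rank + 1L],
                 member_protein_ids = members,
                 focal_offset = as.integer(focal_rank - lo),
                 contig_id = contig$id),
            class = "neighborhood")
}

#' Greedy incremental sequence clustering
#'
#' CD-HIT-style greedy clustering used for database deduplication: records
#' are processed longest-first and each joins the first existing centroid
#' reached at `min_identity` global-alignment identity with bidirectional
#' coverage `min_coverage` (both query and centroid), otherwise founds a new
#' cluster. Mirrors 90% identity / 90% coverage database deduplication when
#' run at the defaults.
#'
#' @param records a [protein_set()]
#' @param min_identity minimum alignment identity in (0, 1]
#' @param min_coverage minimum coverage, applied to both sequences
#' @param scoring a [scoring_scheme()]
#' @return named character vector mapping every protein id to its centroid
#'   id (centroids map to themselves), with a `clusters` attribute listing
#'   member ids per centroid
#' @export
greedy_cluster <- function(records, min_identity = 0.90, min_coverage = 0.90,
                           scoring = scoring_scheme()) {
  if (!nrow(records)) stop("cannot cluster an empty record set")
  if (min_identity <= 0 || min_identity > 1 || min_coverage <= 0 ||
      min_coverage > 1)
    stop("thresholds must lie in (0, 1]")
  ord <- order(-nchar(records$sequence), records$id, method = "radix")
  cent_id <- character(0)
  cent_seq <- character(0)
  assign <- character(nrow(records))
  names(assign) <- records$id[ord]
  for (i in seq_along(ord)) {
    rec <- records[ord[i], ]
    hit <- NA_character_
    for (ci in seq_along(cent_id)) {
      aln <- needleman_wunsch(rec$sequence, cent_seq[ci], scoring)
      if (aln$identity >= min_identity &&
          aln$query_coverage >= min_coverage &&
          aln$subject_coverage >= min_coverage) {
        hit <- cent_id[ci]
        break
      }
    }
    if (is.na(hit)) {
      cent_id <- c(cent_id, rec$id)
      cent_seq <- c(cent_seq, rec$sequence)
      hit <- rec$id
    }
    assign[rec$id] <- hit
  }
  assign <- assign[records$id]
  attr(assign, "clusters") <- split(names(assign), assign)
  assign
}

#' Write a cluster map as TSV
#' @param map named vector from [greedy_cluster()]
#' @param path output path
#' @export
write_cluster_map <- function(map, path) {
  df <- data.frame(protein_id = names(map), centroid_id = as.character(map),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cluster map TSV
#' @param path path to a two-column TSV (protein_id, centroid_id)
#' @return named character vector
#' @export
read_cluster_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.character(df$centroid_id), df$protein_id)
}
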