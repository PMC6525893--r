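# Readers/writers for every external format the pipeline touches.
# Coordinates are 1-based inclusive everywhere; qualities are integers
# (FASTQ input is decoded from Phred+33).

#' Construct a sequence set
#'
#' A `seq_set` is the package's container for named biological
#' sequences (amino acid or nucleotide, gaps allowed) with optional
#' per-base integer quality scores.
#'
#' @param sequences named character vector; names are record ids.
#' @param quality optional named list of non-negative integer vectors,
#'   one per record, each the same length as its sequence.
#' @return An object of class `seq_set`.
#' @export
seq_set <- function(sequences, quality = NULL) {
  ids <- names(sequences)
  if (length(sequences) > 0 &&
      (is.null(ids) || anyNA(ids) || any(ids == "")))
    stop("every sequence needs a non-empty id")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(sequences) == 0L))
    stop("empty sequence(s): ",
         paste(ids[nchar(sequences) == 0L], collapse = ", "))
  if (!is.null(quality)) {
    if (!identical(sort(names(quality)), sort(ids)))
      stop("quality must be named for exactly the sequence ids")
    quality <- quality[ids]
    len_ok <- vapply(ids, function(i)
      length(quality[[i]]) == nchar(sequences[[i]]), logical(1))
    if (!all(len_ok))
      stop("quality length mismatch for: ",
           paste(ids[!len_ok], collapse = ", "))
    if (any(unlist(quality) < 0)) stop("quality scores must be >= 0")
    quality <- lapply(quality, as.integer)
  }
  structure(list(sequences = sequences, quality = quality),
            class = "seq_set")
}

#' @export
length.seq_set <- function(x) length(x$sequences)

#' @export
names.seq_set <- function(x) names(x$sequences)

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set with", length(x), "record(s)",
      if (!is.null(x$quality)) "(with quality)" else "", "\n")
  invisible(x)
}

#' Read sequences from FASTA or FASTQ
#'
#' FASTA yields a `seq_set` without quality; FASTQ decodes Phred+33
#' qualities into integers.
#'
#' @param path file path.
#' @param format `"fasta"` or `"fastq"`; default guesses from the
#'   extension (`.fq`/`.fastq` mean FASTQ).
#' @return A [seq_set].
#' @export
read_sequences <- function(path, format = NULL) {
  if (!file.exists(path)) stop("missing file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  format <- match.arg(format, c("fasta", "fastq"))
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path, format = "fasta")
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
    return(seq_set(seqs))
  }
  ss <- Biostrings::readBStringSet(path, format = "fastq",
                                   with.qualities = TRUE)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  qual_chr <- as.character(S4Vectors::mcols(ss)$qualities)
  quality <- lapply(qual_chr, function(q) utf8ToInt(q) - 33L)
  names(quality) <- names(seqs)
  seq_set(seqs, quality)
}

#' Write a sequence set to FASTA
#'
#' @param x a [seq_set] (or named character vector).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "seq_set")) x$sequences else x
  if (length(seqs) == 0L) {
    warning("empty sequence set: no file written")
    return(invisible(NULL))
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

# shared table reader: headered TSV or CSV, sniffed from the header line
read_table_auto <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  read.delim(path, sep = sep, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "#")
}

check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " table is missing column(s): ",
         paste(miss, collapse = ", "))
}

check_numeric_col <- function(df, col, what) {
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(v) & !is.na(df[[col]]))
  if (length(bad))
    stop(what, " table: non-numeric '", col, "' in row(s) ",
         paste(head(bad, 5L), collapse = ", "))
  v
}

#' Read a protein domain annotation table
#'
#' Expects columns `protein_id`, `domain_name`, `start`, `end`
#' (1-based inclusive protein coordinates).
#'
#' @param path TSV or CSV file path.
#' @return A validated data frame.
#' @export
read_domain_table <- function(path) {
  df <- read_table_auto(path)
  check_cols(df, c("protein_id", "domain_name", "start", "end"), "domain")
  df$start <- check_numeric_col(df, "start", "domain")
  df$end <- check_numeric_col(df, "end", "domain")
  bad <- which(df$start > df$end | df$start < 1)
  if (length(bad))
    stop("domain table: start > end or start < 1 in row(s) ",
         paste(bad, collapse = ", "))
  df
}

#' Read a gene locus table
#'
#' Expects columns `gene_id`, `chromosome`, `strand` (`+`/`-`), `tss`
#' (1-based transcription start coordinate).
#'
#' @param path TSV or CSV file path.
#' @return A validated data frame.
#' @export
read_gene_table <- function(path) {
  df <- read_table_auto(path)
  check_cols(df, c("gene_id", "chromosome", "strand", "tss"), "gene")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id(s): ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("gene table: strand must be '+' or '-' (rows ",
         paste(which(!df$strand %in% c("+", "-")), collapse = ", "), ")")
  df$tss <- check_numeric_col(df, "tss", "gene")
  if (any(df$tss < 1)) stop("gene table: tss must be >= 1")
  df
}

#' Read a SNP marker table
#'
#' Expects columns `snp_id`, `chromosome`, `position` (1-based bp).
#'
#' @param path TSV or CSV file path.
#' @return A validated data frame.
#' @export
read_snp_table <- function(path) {
  df <- read_table_auto(path)
  check_cols(df, c("snp_id", "chromosome", "position"), "snp")
  if (anyDuplicated(df$snp_id))
    stop("duplicate snp_id(s): ",
         paste(unique(df$snp_id[duplicated(df$snp_id)]), collapse = ", "))
  df$position <- check_numeric_col(df, "position", "snp")
  if (any(df$position < 1)) stop("snp table: position must be >= 1")
  df
}

#' Read a qPCR plate table
#'
#' Expects columns `well`, `gene`, `sample`, `condition`
#' (`control`/`treated`) and either per-cycle fluorescence
#' (`cycle`, `fluorescence`) or precomputed `cq`.
#'
#' @param path TSV or CSV file path.
#' @return A validated data frame.
#' @export
read_plate <- function(path) {
  df <- read_table_auto(path)
  check_cols(df, c("well", "gene", "sample", "condition"), "plate")
  if (!all(df$condition %in% c("control", "treated")))
    stop("plate table: condition must be 'control' or 'treated' (rows ",
         paste(head(which(!df$condition %in% c("control", "treated")), 5L),
               collapse = ", "), ")")
  if ("cq" %in% names(df)) {
    df$cq <- check_numeric_col(df, "cq", "plate")
  } else {
    check_cols(df, c("cycle", "fluorescence"), "plate")
    df$cycle <- check_numeric_col(df, "cycle", "plate")
    df$fluorescence <- check_numeric_col(df, "fluorescence", "plate")
    if (any(!is.finite(df$fluorescence)))
      stop("plate table: non-finite fluorescence")
  }
  df
}

#' Write a table as TSV, optionally with a provenance header
#'
#' @param df data frame.
#' @param path output path.
#' @param provenance optional character scalar written as a leading
#'   `#`-comment line.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv]
#'
#' @param path file path.
#' @return A data frame (provenance comment lines are skipped).
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "#")
}

#' Write a phylogenetic tree as newick
#'
#' Bootstrap supports (node labels) are kept as internal-node labels.
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#'
#' @param path file path.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  ape::read.tree(path)
}
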