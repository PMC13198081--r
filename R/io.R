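#' Write paired read records to a pair of FASTQ files
#'
#' Read 1 carries the cell barcode + UMI, read 2 the cDNA sequence, the
#' layout produced by [simulate_locus_reads()]. Qualities are written as a
#' constant high quality ("I") since the simulator does not model quality.
#'
#' @param reads data.frame with columns `read_id`, `seq1`, `seq2`.
#' @param r1_path,r2_path output FASTQ paths (".gz" suffix gzips).
#' @return invisibly, the two paths.
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path) {
  stopifnot(all(c("read_id", "seq1", "seq2") %in% names(reads)))
  .write_one <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                                qualities = qual,
                                compress = grepl("\\.gz$", path))
  }
  .write_one(reads$seq1, reads$read_id, r1_path)
  .write_one(reads$seq2, reads$read_id, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read a FASTQ pair back into a read-record data.frame
#'
#' @param r1_path,r2_path FASTQ paths written by [write_fastq_pair()] or any
#'   pair with matched record order.
#' @return data.frame with `read_id`, `seq1`, `seq2`.
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (length(r1) != length(r2)) {
    stop("FASTQ pair has mismatched record counts", call. = FALSE)
  }
  data.frame(read_id = sub(" .*", "", names(r1)),
             seq1 = unname(as.character(r1)),
             seq2 = unname(as.character(r2)),
             stringsAsFactors = FALSE)
}

#' Write a cell-by-gene count matrix as MTX triplet plus row/column TSVs
#'
#' Genes are written as `genes.tsv` (one identifier per line) and barcodes as
#' `barcodes.tsv`; the matrix is stored gene-by-cell in `matrix.mtx`,
#' following the conventional single-cell triplet layout.
#'
#' @param counts cells-by-genes integer matrix (dense or sparse).
#' @param dir output directory, created if needed.
#' @return invisibly, the directory.
#' @export
write_counts_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- Matrix::Matrix(t(as.matrix(counts)), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read an MTX triplet directory back into a cells-by-genes matrix
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return cells-by-genes dense integer matrix with dimnames.
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  m <- as.matrix(m)
  dimnames(m) <- list(genes, cells)
  t(m)
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set description column (recycled).
#' @return invisibly, the path.
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Thin wrapper over [fgsea::gmtPathways()].
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a locus reference as FASTA plus a YAML sidecar
#'
#' The sidecar records the codon offset and the two discriminating codons so
#' the parser needs no other configuration.
#'
#' @param ref locus reference from [locus_reference()].
#' @param fasta_path,yaml_path output paths.
#' @return invisibly, the FASTA path.
#' @export
write_locus_reference <- function(ref, fasta_path,
                                  yaml_path = paste0(fasta_path, ".yaml")) {
  x <- Biostrings::DNAStringSet(ref$sequence)
  names(x) <- "locus"
  Biostrings::writeXStringSet(x, fasta_path)
  yaml::write_yaml(list(codon_offset = ref$codon_offset,
                        wt_codon = ref$wt_codon,
                        mut_codon = ref$mut_codon), yaml_path)
  invisible(fasta_path)
}

#' Read a locus reference from FASTA plus its YAML sidecar
#'
#' @param fasta_path,yaml_path paths written by [write_locus_reference()].
#' @return a locus reference list (see [locus_reference()]).
#' @export
read_locus_reference <- function(fasta_path,
                                 yaml_path = paste0(fasta_path, ".yaml")) {
  seq <- as.character(Biostrings::readDNAStringSet(fasta_path)[[1]])
  side <- yaml::read_yaml(yaml_path)
  locus_reference(sequence = seq, codon_offset = side$codon_offset,
                  wt_codon = side$wt_codon, mut_codon = side$mut_codon)
}

# TSV helpers shared by the pipeline stages.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
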