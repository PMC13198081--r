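# Allele parser -----------------------------------------------------------
#
# Classifies each cell as wild-type- or mutant-allele-expressing from
# locus-level reads: local alignment of the cDNA read against the 100 bp
# locus reference, start-codon read-off (ATG -> WT, TTG -> MUT), UMI-level
# collapsing of PCR duplicates, and per-barcode evidence thresholds.

#' Parser parameters
#'
#' @param min_identity minimum alignment identity (matches / aligned
#'   columns) for a read to be used.
#' @param min_aligned_length minimum number of alignment columns.
#' @param min_evidence minimum supporting UMIs for a WT or MUT cell call.
#' @param majority_threshold minimum majority fraction
#'   (`max(n_wt, n_mut) / (n_wt + n_mut)`) for a call; in (0.5, 1].
#' @param match,mismatch,gap local-alignment scores.
#' @return a validated list of class `parser_params`.
#' @export
parser_params <- function(min_identity = 0.9, min_aligned_length = 40L,
                          min_evidence = 1L, majority_threshold = 0.8,
                          match = 1, mismatch = -1, gap = -2) {
  .check_scalar(min_identity, "min_identity", 0, 1)
  .check_scalar(min_aligned_length, "min_aligned_length", 1, Inf, TRUE)
  .check_scalar(min_evidence, "min_evidence", 1, Inf, TRUE)
  .check_scalar(majority_threshold, "majority_threshold", 0.5, 1)
  if (majority_threshold <= 0.5) {
    stop("configuration error: field 'majority_threshold' must be > 0.5",
         call. = FALSE)
  }
  structure(list(min_identity = min_identity,
                 min_aligned_length = as.integer(min_aligned_length),
                 min_evidence = as.integer(min_evidence),
                 majority_threshold = majority_threshold,
                 match = match, mismatch = mismatch, gap = gap),
            class = "parser_params")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Locally align a read against the locus reference
#'
#' Smith-Waterman local alignment with linear gap penalties; identity is
#' matches over aligned columns. The alignment is accepted only if identity
#' and aligned length reach the configured thresholds; on rejection the
#' reverse complement is tried (5' chemistry does not fix orientation).
#' Co-optimal alignments are resolved to the leftmost reference offset.
#'
#' @param read_seq nucleotide string over ACGTN.
#' @param ref a [locus_reference()].
#' @param params a [parser_params()].
#' @return on acceptance, a list with `score`, `identity`, `ref_start`
#'   (0-based), `ref_end`, `n_columns`, `strand` ("+" or "-"), and the
#'   gapped `ref_aligned` / `read_aligned` strings; `NULL` on rejection.
#' @export
align_to_locus <- function(read_seq, ref, params = parser_params()) {
  stopifnot(inherits(ref, "locus_reference"))
  if (!is.character(read_seq) || length(read_seq) != 1L ||
      nchar(read_seq) == 0L) {
    stop("read must be a single non-empty string", call. = FALSE)
  }
  read_seq <- toupper(read_seq)
  if (grepl("[^ACGTN]", read_seq)) {
    stop("read contains non-ACGTN characters", call. = FALSE)
  }
  .try <- function(s, strand) {
    al <- .sw_align_cpp(s, ref$sequence, params$match, params$mismatch,
                        params$gap)
    if (!isTRUE(al$accepted_raw)) return(NULL)
    if (al$identity < params$min_identity ||
        al$n_columns < params$min_aligned_length) return(NULL)
    al$strand <- strand
    al$accepted_raw <- NULL
    al
  }
  .try(read_seq, "+") %||% .try(.revcomp(read_seq), "-")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read the start codon off an accepted alignment
#'
#' Returns "WT" when the three read bases mapped to the codon positions
#' spell the wild-type codon, "MUT" for the mutant codon, and "AMBIGUOUS"
#' for anything else (including incomplete coverage of the codon or a gap
#' at a codon position).
#'
#' @param alignment an accepted alignment from [align_to_locus()].
#' @param ref the [locus_reference()] aligned against.
#' @return one of "WT", "MUT", "AMBIGUOUS".
#' @export
classify_read <- function(alignment, ref) {
  stopifnot(inherits(ref, "locus_reference"))
  if (is.null(alignment)) return("AMBIGUOUS")
  ra <- strsplit(alignment$ref_aligned, "")[[1]]
  qa <- strsplit(alignment$read_aligned, "")[[1]]
  rp <- alignment$ref_start  # 0-based position of next reference base
  bases <- rep(NA_character_, 3L)
  for (k in seq_along(ra)) {
    if (ra[k] != "-") {
      off <- rp - ref$codon_offset
      if (off >= 0 && off <= 2) bases[off + 1L] <- qa[k]
      rp <- rp + 1L
    }
  }
  if (anyNA(bases) || any(bases == "-")) return("AMBIGUOUS")
  codon <- paste(bases, collapse = "")
  if (codon == ref$wt_codon) "WT"
  else if (codon == ref$mut_codon) "MUT"
  else "AMBIGUOUS"
}

.codon_to_call <- function(codon, ref) {
  out <- rep("AMBIGUOUS", length(codon))
  out[!is.na(codon) & codon == ref$wt_codon] <- "WT"
  out[!is.na(codon) & codon == ref$mut_codon] <- "MUT"
  out
}

# Batched alignment + classification for a vector of reads; tries the
# reverse complement for reads rejected in forward orientation.
.classify_reads_batch <- function(seqs, ref, params) {
  res <- .sw_align_batch_cpp(seqs, ref$sequence, params$match,
                             params$mismatch, params$gap, ref$codon_offset)
  ok <- res$identity >= params$min_identity &
    res$n_columns >= params$min_aligned_length
  redo <- which(!ok)
  if (length(redo)) {
    rc <- .sw_align_batch_cpp(.revcomp(seqs[redo]), ref$sequence,
                              params$match, params$mismatch, params$gap,
                              ref$codon_offset)
    ok2 <- rc$identity >= params$min_identity &
      rc$n_columns >= params$min_aligned_length
    res[redo[ok2], ] <- rc[ok2, ]
    ok[redo[ok2]] <- TRUE
  }
  call <- rep(NA_character_, length(seqs))
  call[ok] <- .codon_to_call(res$codon[ok], ref)
  list(accepted = ok, codon_call = call, identity = res$identity,
       ref_start = res$ref_start)
}

#' Collapse read-level observations to UMI-level observations
#'
#' One record per (barcode, UMI): the codon call is decided by majority
#' vote among the group's reads, with AMBIGUOUS votes excluded; exact
#' WT/MUT ties and groups with no informative vote are dropped. The
#' operation is idempotent and order-invariant.
#'
#' @param observations data.frame with columns `barcode`, `umi`,
#'   `codon_call` (values "WT", "MUT", "AMBIGUOUS").
#' @return data.frame with one row per retained (barcode, UMI) and its
#'   majority `codon_call`, ordered by (barcode, umi).
#' @export
collapse_umis <- function(observations) {
  stopifnot(all(c("barcode", "umi", "codon_call") %in% names(observations)))
  if (nrow(observations) == 0L) {
    return(data.frame(barcode = character(0), umi = character(0),
                      codon_call = character(0), stringsAsFactors = FALSE))
  }
  key <- paste(observations$barcode, observations$umi, sep = "\r")
  wt <- tapply(observations$codon_call == "WT", key, sum)
  mut <- tapply(observations$codon_call == "MUT", key, sum)
  keep <- (wt + mut > 0) & (wt != mut)
  keys <- names(wt)[keep]
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    barcode = vapply(parts, `[[`, character(1), 1L),
    umi = vapply(parts, `[[`, character(1), 2L),
    codon_call = ifelse(wt[keep] > mut[keep], "WT", "MUT"),
    stringsAsFactors = FALSE)
  out <- out[order(out$barcode, out$umi), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call each cell's expressed allele from UMI-level evidence
#'
#' Per barcode, WT and MUT UMIs are counted; the cell is called WT (or MUT)
#' when the winning allele has at least `min_evidence` UMIs and the
#' majority fraction reaches `majority_threshold`, and UNASSIGNED
#' otherwise (including barcodes with no informative UMI).
#'
#' @param umi_observations output of [collapse_umis()].
#' @param params a [parser_params()].
#' @param barcodes optional barcodes to report even without evidence
#'   (reported UNASSIGNED with zero counts).
#' @return data.frame with `barcode`, `n_wt_umis`, `n_mut_umis`, `call`,
#'   `majority_fraction` (NA when there is no evidence).
#' @export
call_cells <- function(umi_observations, params = parser_params(),
                       barcodes = NULL) {
  stopifnot(inherits(params, "parser_params"))
  bc <- unique(c(umi_observations$barcode, barcodes))
  n_wt <- n_mut <- stats::setNames(integer(length(bc)), bc)
  if (nrow(umi_observations)) {
    tw <- tapply(umi_observations$codon_call == "WT",
                 umi_observations$barcode, sum)
    tm <- tapply(umi_observations$codon_call == "MUT",
                 umi_observations$barcode, sum)
    n_wt[names(tw)] <- tw
    n_mut[names(tm)] <- tm
  }
  total <- n_wt + n_mut
  frac <- ifelse(total > 0, pmax(n_wt, n_mut) / total, NA_real_)
  winner <- ifelse(n_wt >= n_mut, "WT", "MUT")
  win_n <- pmax(n_wt, n_mut)
  call <- ifelse(total > 0 & win_n >= params$min_evidence &
                   !is.na(frac) & frac >= params$majority_threshold,
                 winner, "UNASSIGNED")
  # an exact tie never clears a >0.5 majority threshold, but guard anyway
  call[n_wt == n_mut & total > 0] <- "UNASSIGNED"
  out <- data.frame(barcode = bc, n_wt_umis = as.integer(n_wt),
                    n_mut_umis = as.integer(n_mut), call = call,
                    majority_fraction = frac, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Parse cell alleles from paired locus reads
#'
#' End-to-end parser: aligns every cDNA read to the locus reference
#' (forward, then reverse complement), reads off the start codon, collapses
#' PCR duplicates by (barcode, UMI) majority vote, and calls each cell's
#' expressed allele. Accepts either an in-memory read table (columns
#' `barcode`, `umi`, `seq2`, as produced by [simulate_locus_reads()]) or a
#' FASTQ pair in which read 1 is barcode + UMI.
#'
#' @param reads read table, or `NULL` when FASTQ paths are given.
#' @param r1_path,r2_path FASTQ pair (used when `reads` is `NULL`).
#' @param ref a [locus_reference()].
#' @param params a [parser_params()].
#' @return list with `cells` (per-barcode calls from [call_cells()]),
#'   `umis` (UMI-level observations), and `read_stats` (aligned /
#'   informative read counts).
#' @export
parse_alleles <- function(reads = NULL, r1_path = NULL, r2_path = NULL,
                          ref = locus_reference(),
                          params = parser_params()) {
  if (is.null(reads)) {
    fq <- read_fastq_pair(r1_path, r2_path)
    bl <- 16L
    reads <- data.frame(
      barcode = substr(fq$seq1, 1L, bl),
      umi = substr(fq$seq1, bl + 1L, nchar(fq$seq1)),
      seq2 = fq$seq2, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("barcode", "umi", "seq2") %in% names(reads)))
  cls <- .classify_reads_batch(reads$seq2, ref, params)
  obs <- data.frame(barcode = reads$barcode, umi = reads$umi,
                    codon_call = ifelse(cls$accepted, cls$codon_call,
                                        "AMBIGUOUS"),
                    stringsAsFactors = FALSE)
  # unaligned reads contribute no evidence; keep only accepted observations
  obs <- obs[cls$accepted, , drop = FALSE]
  umis <- collapse_umis(obs)
  cells <- call_cells(umis, params, barcodes = unique(reads$barcode))
  list(cells = cells, umis = umis,
       read_stats = c(n_reads = nrow(reads),
                      n_aligned = sum(cls$accepted),
                      n_informative = sum(obs$codon_call %in%
                                            c("WT", "MUT"))))
}
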