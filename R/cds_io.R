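#' Read coding sequences from a FASTA file
#'
#' Reads a (multi-)FASTA file of nucleotide coding sequences into a gene
#' table. Sequence identifiers are the first whitespace-delimited token of
#' each header; sequences are uppercased and RNA \code{U} is mapped to
#' \code{T}. No filtering is applied here; see \code{\link{qc_filter}}.
#'
#' @param path Path to a readable FASTA file.
#' @param genome_id Genome identifier attached to every record. Defaults to
#'   the file name without extension.
#' @return A \code{data.frame} with columns \code{gene_id},
#'   \code{genome_id}, \code{sequence} and \code{source}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 some gene", "ATGAAATAA", ">g2", "atggcttaa"), fa)
#' read_cds_fasta(fa, genome_id = "demo")
#' @export
read_cds_fasta <- function(path, genome_id = NULL) {
  if (!file.exists(path)) {
    stop("cannot read FASTA file: ", path)
  }
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    warning("FASTA file ", path, " contains no sequences")
    return(empty_gene_table())
  }
  ids <- vapply(strsplit(names(seqs), "[ \t]+"), `[[`, character(1), 1L)
  sequence <- chartr("u", "t", tolower(as.character(seqs)))
  sequence <- toupper(sequence)
  if (anyDuplicated(ids)) {
    stop("duplicated gene identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(
    gene_id = unname(ids),
    genome_id = genome_id,
    sequence = unname(sequence),
    source = "cds_fasta",
    stringsAsFactors = FALSE
  )
}

empty_gene_table <- function() {
  data.frame(
    gene_id = character(0), genome_id = character(0),
    sequence = character(0), source = character(0),
    stringsAsFactors = FALSE
  )
}

#' Write a gene table to a FASTA file
#'
#' @param genes Gene table as returned by \code{\link{read_cds_fasta}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_cds_fasta <- function(genes, path) {
  stopifnot(is.data.frame(genes))
  x <- Biostrings::DNAStringSet(genes$sequence)
  names(x) <- genes$gene_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Extract spliced coding sequences from a genome and a GFF3 annotation
#'
#' Collects \code{CDS} features per transcript, concatenates the segments in
#' genomic order (reverse order with reverse-complementation on the minus
#' strand), and trims the leading bases given by the GFF \code{phase} of the
#' first segment. Transcript grouping uses \code{Parent}, then
#' \code{transcript_id}, then \code{ID}.
#'
#' @param genome_fasta Path to the genome FASTA (contig names must match the
#'   GFF \code{seqid} column).
#' @param gff Path to a GFF3 file; coordinates 1-based inclusive.
#' @param genome_id Genome identifier; defaults to the genome file name.
#' @return A gene table (one row per transcript) as in
#'   \code{\link{read_cds_fasta}}, with \code{source = "gff_extracted"}.
#'   Transcripts with CDS segments on mixed strands are skipped with a
#'   warning.
#' @export
extract_cds_from_gff <- function(genome_fasta, gff, genome_id = NULL) {
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(genome_fasta))
  }
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- vapply(strsplit(names(genome), "[ \t]+"), `[[`,
                          character(1), 1L)
  gr <- rtracklayer::import(gff, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) {
    warning("no CDS features in ", gff)
    return(empty_gene_table())
  }
  meta <- S4Vectors::mcols(gr)
  pick_id <- function(i) {
    for (field in c("Parent", "transcript_id", "ID")) {
      if (field %in% colnames(meta)) {
        v <- meta[[field]][[i]]
        v <- as.character(unlist(v))
        if (length(v) && !is.na(v[1]) && nzchar(v[1])) return(v[1])
      }
    }
    NA_character_
  }
  tx <- vapply(seq_along(gr), pick_id, character(1))
  if (anyNA(tx)) {
    stop("CDS features without Parent/transcript_id/ID attributes in ", gff)
  }
  missing_contig <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                            names(genome))
  if (length(missing_contig)) {
    stop("CDS features reference contigs absent from the genome FASTA: ",
         paste(missing_contig, collapse = ", "))
  }

  out <- lapply(split(seq_along(gr), tx), function(idx) {
    seg <- gr[idx]
    strands <- unique(as.character(GenomicRanges::strand(seg)))
    if (length(strands) > 1L) {
      warning("transcript on mixed strands skipped: ", tx[idx[1]])
      return(NULL)
    }
    minus <- identical(strands, "-")
    ord <- order(GenomicRanges::start(seg), decreasing = minus)
    seg <- seg[ord]
    pieces <- vapply(seq_along(seg), function(j) {
      contig <- as.character(GenomicRanges::seqnames(seg)[j])
      s <- Biostrings::subseq(genome[[contig]],
                              GenomicRanges::start(seg)[j],
                              GenomicRanges::end(seg)[j])
      if (minus) s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1))
    phase <- seg$phase[1]
    if (is.null(phase) || is.na(phase)) phase <- 0L
    seq <- paste(pieces, collapse = "")
    if (phase > 0L) seq <- substr(seq, phase + 1L, nchar(seq))
    data.frame(gene_id = tx[idx[1]], genome_id = genome_id,
               sequence = toupper(seq), source = "gff_extracted",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

QC_RULES <- c("min_length", "partial_codon", "internal_stop",
              "missing_start", "missing_stop", "non_acgt")

#' Quality-filter coding sequences
#'
#' A CDS passes when it (i) is at least \code{min_len_bp} long, (ii) contains
#' no partial codon (length divisible by 3), (iii) has no internal stop codon,
#' (iv) begins with \code{ATG} and ends with a stop codon, and additionally
#' contains only A/C/G/T. A record can fail several rules; it is counted once
#' per failed rule but once overall. The two length-related rules are tallied
#' independently, so 100- and 101-bp records fail \code{partial_codon} and the
#' effective minimum length of a passing CDS is 102 bp.
#'
#' @param genes Gene table (see \code{\link{read_cds_fasta}}).
#' @param min_len_bp Minimum spliced CDS length in base pairs (default 100).
#' @return A list with \code{passed} (the surviving gene table) and
#'   \code{report}, a \code{data.frame} with one row per genome and columns
#'   \code{genome_id}, \code{n_input}, \code{n_passed} and one count per
#'   filter rule.
#' @export
qc_filter <- function(genes, min_len_bp = 100) {
  stopifnot(is.data.frame(genes))
  n <- nrow(genes)
  len <- nchar(genes$sequence)
  acgt_ok <- !grepl("[^ACGT]", genes$sequence)
  frame_ok <- len %% 3L == 0L
  len_ok <- len >= min_len_bp
  start_ok <- substr(genes$sequence, 1L, 3L) == "ATG" & len >= 3L
  last <- substr(genes$sequence, len - 2L, len)
  stop_ok <- last %in% STOP_CODONS & len >= 3L & frame_ok
  internal_stop <- vapply(seq_len(n), function(i) {
    if (!frame_ok[i] || !acgt_ok[i] || len[i] < 6L) return(FALSE)
    cods <- codon_split(genes$sequence[i])
    any(cods[-length(cods)] %in% STOP_CODONS)
  }, logical(1))

  fails <- cbind(
    min_length = !len_ok,
    partial_codon = !frame_ok,
    internal_stop = internal_stop,
    missing_start = !start_ok,
    missing_stop = !stop_ok,
    non_acgt = !acgt_ok
  )
  pass <- !apply(fails, 1L, any)
  if (n == 0L) pass <- logical(0)

  genomes <- if (n) unique(genes$genome_id) else character(0)
  report <- do.call(rbind, lapply(genomes, function(g) {
    in_g <- genes$genome_id == g
    row <- data.frame(genome_id = g, n_input = sum(in_g),
                      n_passed = sum(pass & in_g), stringsAsFactors = FALSE)
    for (rule in QC_RULES) row[[rule]] <- sum(fails[in_g, rule])
    row
  }))
  if (is.null(report)) {
    report <- data.frame(genome_id = character(0), n_input = integer(0),
                         n_passed = integer(0))
    for (rule in QC_RULES) report[[rule]] <- integer(0)
  }
  passed <- genes[pass, , drop = FALSE]
  rownames(passed) <- NULL
  list(passed = passed, report = report)
}

#' Write a QC report as a long-format TSV
#'
#' @param report The \code{report} element of \code{\link{qc_filter}} output.
#' @param path Output TSV path (columns genome_id, rule, count).
#' @return Invisibly, \code{path}.
#' @export
write_qc_report <- function(report, path) {
  long <- do.call(rbind, lapply(seq_len(nrow(report)), function(i) {
    data.frame(genome_id = report$genome_id[i],
               rule = c("input", "passed", QC_RULES),
               count = unlist(report[i, c("n_input", "n_passed", QC_RULES)],
                              use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# split an in-frame sequence into consecutive codons
codon_split <- function(sequence) {
  n <- nchar(sequence)
  substring(sequence, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}
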