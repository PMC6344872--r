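# constant backbone sequence read after the barcode in R2 (vector-derived
# filler; any invariant sequence works, the demultiplexer only uses the
# barcode prefix)
.r2_backbone <- strrep("GATCGGAAGAGCACACGTCTGAACTCCAGTCA", 8)

#' Emit paired-end reads for a simulated truth table
#'
#' One read pair per transcript: R1 spans the splice junction of the used
#' isoform (centred on the junction, at least 15 nt on each side), R2
#' starts with the 20-bp minigene barcode. Substitution errors are applied
#' i.i.d. at `error_rate`. A truth sidecar maps every read id to its
#' minigene and acceptor.
#'
#' @param truth A `bp_transcripts` table from [simulate_transcripts()].
#' @param lib The `bp_library` the truth table was simulated from.
#' @param dir Output directory (created if needed).
#' @param read_len Read length (default 50; must be >= 30 so the junction
#'   is covered by >= 15 nt on each side).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @param prefix File name prefix (default `"sim"`).
#' @return A list with paths `r1`, `r2`, `sidecar` and the pair count `n`.
#' @export
emit_reads <- function(truth, lib, dir, read_len = 50L, error_rate = 0,
                       seed = 1L, prefix = "sim") {
  stopifnot(is.data.frame(truth), nrow(truth) >= 0)
  read_len <- as.integer(read_len)
  flank <- read_len %/% 2L
  if (read_len < 30L) {
    stop("read_len too short: the junction must be covered by >= 15 nt on each side",
         call. = FALSE)
  }
  scaffold <- attr(lib, "scaffold")
  exon1 <- scaffold$exon1_seq
  if (nchar(exon1) < flank) {
    stop("exon1 shorter than the upstream read flank", call. = FALSE)
  }
  if (nchar(.r2_backbone) + scaffold$barcode_len < read_len) {
    stop("read_len exceeds barcode + backbone length", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  idx <- rep.int(seq_len(nrow(truth)), truth$n_reads)
  n <- length(idx)
  mg <- match(truth$minigene_id[idx], lib$id)
  pos <- truth$acceptor_pos[idx]
  left <- substr(rep_len(exon1, n), nchar(exon1) - flank + 1L, nchar(exon1))
  right <- substr(lib$full_seq[mg], pos + 1L, pos + (read_len - flank))
  if (any(nchar(right) < read_len - flank)) {
    stop("read_len too short to stay inside the minigene downstream of an acceptor",
         call. = FALSE)
  }
  r1 <- paste0(left, right)
  r2 <- paste0(lib$barcode[mg],
               substr(rep_len(.r2_backbone, n), 1L,
                      read_len - scaffold$barcode_len))
  with_seed(seed, {
    r1 <- add_substitutions(r1, error_rate)
    r2 <- add_substitutions(r2, error_rate)
  })
  ids <- sprintf("%s_read%07d", prefix, seq_len(n))

  r1_path <- file.path(dir, paste0(prefix, "_R1.fastq"))
  r2_path <- file.path(dir, paste0(prefix, "_R2.fastq"))
  side_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write_fastq(ids, r1, r1_path)
  write_fastq(ids, r2, r2_path)
  sidecar <- data.frame(read_id = ids,
                        minigene_id = truth$minigene_id[idx],
                        acceptor_class = truth$acceptor_class[idx],
                        acceptor_pos = truth$acceptor_pos[idx],
                        stringsAsFactors = FALSE)
  write.table(sidecar, side_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(r1 = r1_path, r2 = r2_path, sidecar = side_path, n = n)
}

# i.i.d. substitution errors; each error replaces the base with one of the
# three other bases uniformly
add_substitutions <- function(seq, error_rate) {
  if (error_rate <= 0 || !length(seq)) return(seq)
  m <- seq_to_matrix(seq)
  hit <- which(runif(length(m)) < error_rate)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    cur <- match(m[hit], DNA_BASES)
    m[hit] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# plain 4-line FASTQ with dummy Phred+33 qualities, via Biostrings
write_fastq <- function(ids, seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  qual <- Biostrings::PhredQuality(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

# read a FASTQ into a named character vector (names = first id token)
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
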