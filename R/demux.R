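#' Assign reads to minigenes by barcode
#'
#' An exact barcode match wins; otherwise a read is assigned to the unique
#' barcode within Hamming distance `max_mismatch`, and ties or misses are
#' `NA` (unassigned). The index is built from the library table, which is
#' required to have pairwise-distinct barcodes.
#'
#' @param r2_seq Character vector of R2 sequences (at least barcode-length;
#'   shorter reads are unassigned).
#' @param lib A `bp_library` (or any data frame with `id` and `barcode`).
#' @param max_mismatch Maximum Hamming distance for a rescue match
#'   (default 1; 0 restores exact-only matching).
#' @return Character vector of minigene ids, `NA` where unassigned.
#' @export
match_barcode <- function(r2_seq, lib, max_mismatch = 1L) {
  if (anyDuplicated(lib$barcode)) {
    stop("duplicate barcodes in library; refusing to build index",
         call. = FALSE)
  }
  blen <- nchar(lib$barcode[1])
  out <- rep(NA_character_, length(r2_seq))
  long_enough <- nchar(r2_seq) >= blen
  probe <- substr(r2_seq, 1L, blen)
  hit <- match(probe, lib$barcode)
  out[long_enough & !is.na(hit)] <- lib$id[hit[long_enough & !is.na(hit)]]
  if (max_mismatch >= 1L) {
    todo <- which(long_enough & is.na(out))
    if (length(todo)) {
      bc_mat <- seq_to_matrix(lib$barcode)
      for (i in todo) {
        d <- colSums(t(bc_mat) != strsplit(probe[i], "", fixed = TRUE)[[1]])
        dmin <- min(d)
        if (dmin <= max_mismatch && sum(d == dmin) == 1L) {
          out[i] <- lib$id[which.min(d)]
        }
      }
    }
  }
  out
}

# isoform reference for an acceptor: exon1 joined to the downstream
# sequence; the junction sits at nchar(exon1)
isoform_reference <- function(full_seq, acceptor_pos, exon1) {
  paste0(exon1, substr(full_seq, acceptor_pos + 1L, nchar(full_seq)))
}

#' Call the splice acceptor used by junction-spanning reads
#'
#' Each read is matched (substring search allowing up to
#' `max_substitution` mismatches) against the isoform reference of every
#' candidate acceptor of its minigene; a call requires a unique best
#' isoform at an offset that covers the junction with at least
#' `min_flank` nt on each side. Everything else is `UNCALLED` (`NA`).
#'
#' @param r1_seq Character vector of equal-length R1 sequences from one
#'   minigene.
#' @param minigene A one-row `bp_library`.
#' @param min_flank Minimum junction coverage on each side (default 15).
#' @param max_substitution Substitutions tolerated per read (default 1).
#' @return A data frame with columns `acceptor_class` and `acceptor_pos`
#'   (`NA` for uncalled reads).
#' @export
call_junction <- function(r1_seq, minigene, min_flank = 15L,
                          max_substitution = 1L) {
  stopifnot(nrow(minigene) == 1L)
  cand <- candidate_acceptors(minigene)
  calls <- call_junction_group(r1_seq, minigene$full_seq,
                               cand$acceptor_pos,
                               attr(minigene, "scaffold")$exon1_seq,
                               min_flank, max_substitution)
  data.frame(
    acceptor_class = ifelse(is.na(calls), NA_character_,
                            cand$acceptor_class[calls]),
    acceptor_pos = ifelse(is.na(calls), NA_integer_,
                          cand$acceptor_pos[calls]),
    stringsAsFactors = FALSE
  )
}

# core junction caller for one minigene: returns the index of the called
# candidate acceptor per read, NA for uncalled
call_junction_group <- function(r1_seq, full_seq, acceptor_pos, exon1,
                                min_flank = 15L, max_substitution = 1L) {
  n_read <- length(r1_seq)
  if (!n_read) return(integer(0))
  L <- unique(nchar(r1_seq))
  if (length(L) != 1L) stop("reads must have equal length", call. = FALSE)
  j <- nchar(exon1)                       # junction coordinate in isoforms
  starts <- seq.int(j - L + min_flank, j - min_flank)   # 0-based offsets
  starts <- starts[starts >= 0L]
  if (!length(starts)) return(rep(NA_integer_, n_read))
  reads <- t(seq_to_matrix(r1_seq))       # L x n_read
  n_cand <- length(acceptor_pos)
  best <- matrix(Inf, n_read, n_cand)
  for (ci in seq_len(n_cand)) {
    ref <- isoform_reference(full_seq, acceptor_pos[ci], exon1)
    refc <- strsplit(ref, "", fixed = TRUE)[[1]]
    for (s in starts) {
      if (s + L > length(refc)) next
      mm <- colSums(reads != refc[(s + 1L):(s + L)])
      best[, ci] <- pmin(best[, ci], mm)
    }
  }
  b1 <- do.call(pmin, as.data.frame(best))
  n_at_min <- rowSums(best == b1)
  winner <- max.col(-best, ties.method = "first")
  ok <- b1 <= max_substitution & n_at_min == 1L
  ifelse(ok, winner, NA_integer_)
}

#' Demultiplex a FASTQ pair into transcript records
#'
#' Assigns read pairs to minigenes by the R2 barcode, calls the acceptor
#' used by each R1, and aggregates to per-(minigene, acceptor) transcript
#' counts. A transcript is a read pair; no UMI collapsing is performed.
#'
#' @param r1_path,r2_path Paths to the paired FASTQ files (records must be
#'   in the same order).
#' @param lib The `bp_library` the reads came from.
#' @param condition Condition label attached to the output records.
#' @param max_mismatch Barcode rescue distance (default 1).
#' @param min_flank Junction coverage required by the caller (default 15).
#' @param max_substitution Substitutions tolerated by the caller.
#' @return A list with `records` (a `bp_transcripts` data frame) and
#'   `report` (pairs in, assigned, unassigned, uncalled; tallies sum to
#'   the input pair count).
#' @export
build_transcript_table <- function(r1_path, r2_path, lib,
                                   condition = "WT", max_mismatch = 1L,
                                   min_flank = 15L, max_substitution = 1L) {
  r1 <- read_fastq(r1_path)
  r2 <- read_fastq(r2_path)
  if (length(r1) != length(r2)) {
    stop(sprintf("FASTQ pair mismatch: %d R1 records vs %d R2 records",
                 length(r1), length(r2)), call. = FALSE)
  }
  n_pairs <- length(r1)
  mg_id <- match_barcode(unname(r2), lib, max_mismatch = max_mismatch)
  assigned <- !is.na(mg_id)

  scaffold <- attr(lib, "scaffold")
  calls_class <- rep(NA_character_, n_pairs)
  calls_pos <- rep(NA_integer_, n_pairs)
  cand_all <- candidate_acceptors(lib)
  sel_by_id <- split(which(assigned), mg_id[assigned])
  cand_by_id <- split(cand_all, cand_all$id)
  for (id in names(sel_by_id)) {
    sel <- sel_by_id[[id]]
    row <- match(id, lib$id)
    cand <- cand_by_id[[id]]
    k <- call_junction_group(unname(r1[sel]), lib$full_seq[row],
                             cand$acceptor_pos, scaffold$exon1_seq,
                             min_flank, max_substitution)
    calls_class[sel] <- ifelse(is.na(k), NA, cand$acceptor_class[k])
    calls_pos[sel] <- ifelse(is.na(k), NA, cand$acceptor_pos[k])
  }
  called <- assigned & !is.na(calls_class)

  dt <- data.table::data.table(
    minigene_id = mg_id[called],
    acceptor_class = calls_class[called],
    acceptor_pos = calls_pos[called]
  )
  agg <- dt[, list(n_reads = .N),
            by = c("minigene_id", "acceptor_class", "acceptor_pos")]
  data.table::setorder(agg, minigene_id, acceptor_pos)
  records <- data.frame(minigene_id = agg$minigene_id,
                        condition = condition,
                        acceptor_class = agg$acceptor_class,
                        acceptor_pos = agg$acceptor_pos,
                        n_reads = agg$n_reads,
                        stringsAsFactors = FALSE)
  class(records) <- c("bp_transcripts", "data.frame")
  list(
    records = records,
    report = list(
      condition = condition,
      pairs_in = n_pairs,
      assigned = sum(called),
      unassigned = sum(!assigned),
      uncalled = sum(assigned & !called)
    )
  )
}

#' Apply the minimum-representation filter across conditions
#'
#' Keeps a minigene only if its summed read count reaches `min_reads` in
#' every required condition table (the assay's "present in both datasets
#' at a minimum representation of five reads" rule). Idempotent.
#'
#' @param tables Named list of `bp_transcripts` tables, one per condition.
#' @param min_reads Minimum summed reads per minigene and condition
#'   (default 5).
#' @param require_both Require the threshold in every table (default
#'   `TRUE`); with `FALSE`, reaching it in any one table suffices.
#' @return The filtered list of tables (same names, same columns).
#' @export
apply_filters <- function(tables, min_reads = 5L, require_both = TRUE) {
  stopifnot(is.list(tables), length(tables) >= 1L, min_reads >= 1L)
  if (require_both && length(tables) < 2L) {
    stop("require_both needs at least two condition tables", call. = FALSE)
  }
  per_table_ids <- lapply(tables, function(tab) {
    dt <- data.table::as.data.table(tab)
    tot <- dt[, list(total = sum(n_reads)), by = "minigene_id"]
    tot$minigene_id[tot$total >= min_reads]
  })
  keep <- if (require_both) {
    Reduce(intersect, per_table_ids)
  } else {
    unique(unlist(per_table_ids))
  }
  lapply(tables, function(tab) {
    out <- tab[tab$minigene_id %in% keep, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("bp_transcripts", "data.frame")
    out
  })
}
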