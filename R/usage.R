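#' Acceptor usage fractions for one condition
#'
#' Transcript-level fractions are read-weighted (reads to a class over all
#' reads); the minigene-level SA1 usage ratio is the share of minigenes
#' with at least one SA1 read. Both are reported because the read-weighted
#' and minigene-averaged views of SA1 usage need not agree.
#'
#' @param table A `bp_transcripts` table (ideally post-[apply_filters()]).
#' @param condition Optional label; defaults to the table's own.
#' @return A list with `condition`, `transcript_fractions` (named numeric
#'   over SA1/SA2/NOVEL, summing to 1), `minigene_sa1_ratio`, `n_reads`,
#'   `n_minigenes`. Empty tables yield `NA` fractions with a warning.
#' @export
usage_fractions <- function(table, condition = NULL) {
  condition <- condition %||% table$condition[1]
  classes <- c("SA1", "SA2", "NOVEL")
  if (!nrow(table)) {
    warning("empty transcript table: usage fractions undefined")
    return(list(condition = condition,
                transcript_fractions = setNames(rep(NA_real_, 3), classes),
                minigene_sa1_ratio = NA_real_, n_reads = 0L,
                n_minigenes = 0L))
  }
  reads <- vapply(classes, function(cl) {
    sum(table$n_reads[table$acceptor_class == cl])
  }, numeric(1))
  sa1_ids <- unique(table$minigene_id[table$acceptor_class == "SA1"])
  all_ids <- unique(table$minigene_id)
  list(
    condition = condition,
    transcript_fractions = reads / sum(reads),
    minigene_sa1_ratio = length(sa1_ids) / length(all_ids),
    n_reads = sum(reads),
    n_minigenes = length(all_ids)
  )
}

#' Two-condition usage summary with SA1 fold change
#'
#' @param table_wt,table_k700e Filtered `bp_transcripts` tables.
#' @return A list with per-condition [usage_fractions()] output and
#'   `sa1_fold_change`, the K700E/WT ratio of transcript-level SA1
#'   fractions.
#' @export
usage_summary <- function(table_wt, table_k700e) {
  wt <- usage_fractions(table_wt, "WT")
  ke <- usage_fractions(table_k700e, "K700E")
  list(
    WT = wt,
    K700E = ke,
    sa1_fold_change = unname(ke$transcript_fractions["SA1"] /
                               wt$transcript_fractions["SA1"])
  )
}

#' Partition SA1-using minigenes between conditions
#'
#' A minigene "utilizes SA1" in a condition iff it has at least one SA1
#' record there (post-filter). The SA1 universe splits into three disjoint
#' sets: shared, K700E-only, WT-only.
#'
#' @param table_wt,table_k700e Filtered `bp_transcripts` tables.
#' @return A list of class `sa1_partition` with `n_total`, counts and
#'   percentages for `shared`, `k700e_only`, `wt_only`.
#' @export
partition_sa1 <- function(table_wt, table_k700e) {
  sa1 <- function(tab) unique(tab$minigene_id[tab$acceptor_class == "SA1"])
  w <- sa1(table_wt)
  k <- sa1(table_k700e)
  uni <- union(w, k)
  counts <- c(shared = length(intersect(w, k)),
              k700e_only = length(setdiff(k, w)),
              wt_only = length(setdiff(w, k)))
  structure(list(
    n_total = length(uni),
    counts = counts,
    percentages = if (length(uni)) 100 * counts / length(uni) else counts * NA_real_
  ), class = "sa1_partition")
}

#' @export
print.sa1_partition <- function(x, ...) {
  cat(sprintf("%d SA1-utilizing minigenes: %.1f%% shared, %.1f%% K700E-only, %.1f%% WT-only\n",
              x$n_total, x$percentages["shared"], x$percentages["k700e_only"],
              x$percentages["wt_only"]))
  invisible(x)
}

#' Upstream context of novel acceptors
#'
#' Extracts the `width`-nt window ending at each novel acceptor (SA1 and
#' SA2 are excluded: their immediate upstream context is invariant) and
#' tabulates a position frequency matrix. Windows escaping the minigene
#' are skipped.
#'
#' @param table A `bp_transcripts` table containing NOVEL records.
#' @param lib The `bp_library`.
#' @param width Window width in nt (default 20).
#' @return A list with `sequences` (one per NOVEL record kept), `pfm`
#'   (4 x `width` integer matrix, rows A/C/G/T; columns sum to the number
#'   of sequences) and `n_skipped`.
#' @export
novel_ss_context <- function(table, lib, width = 20L) {
  nov <- table[table$acceptor_class == "NOVEL", , drop = FALSE]
  if (!nrow(nov)) {
    return(list(sequences = character(0),
                pfm = matrix(0L, 4, width, dimnames = list(DNA_BASES, NULL)),
                n_skipped = 0L))
  }
  idx <- match(nov$minigene_id, lib$id)
  keep <- nov$acceptor_pos >= width
  seqs <- substr(lib$full_seq[idx[keep]],
                 nov$acceptor_pos[keep] - width + 1L,
                 nov$acceptor_pos[keep])
  m <- seq_to_matrix(seqs)
  pfm <- vapply(seq_len(width), function(j) {
    tabulate(factor(m[, j], levels = DNA_BASES), nbins = 4L)
  }, integer(4))
  rownames(pfm) <- DNA_BASES
  list(sequences = seqs, pfm = pfm, n_skipped = sum(!keep))
}

#' Write a position frequency matrix as plain text
#'
#' Rows A, C, G, T; whitespace-separated counts, suitable for logo tools.
#'
#' @param pfm A 4 x width matrix with rownames A/C/G/T.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  stopifnot(identical(rownames(pfm), DNA_BASES))
  write.table(pfm, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}
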