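#' All distinct k-mers of a sequence
#'
#' @param seq A single DNA string.
#' @param k Word length (default 6).
#' @return Character vector of distinct length-`k` substrings (empty when
#'   the sequence is shorter than `k`).
#' @export
#' @examples
#' kmer_presence("CTAACG")
kmer_presence <- function(seq, k = 6L) {
  stopifnot(length(seq) == 1L)
  n <- nchar(seq)
  if (n < k) {
    warning("sequence shorter than k: empty k-mer set")
    return(character(0))
  }
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

# all 4^k k-mers in lexicographic order
all_kmers <- function(k = 6L) {
  g <- do.call(expand.grid,
               c(rep(list(DNA_BASES), k), KEEP.OUT.ATTRS = FALSE,
                 stringsAsFactors = FALSE))
  sort(do.call(paste0, rev(g)))
}

#' Odds ratio of a 2x2 presence table
#'
#' `OR = ((a+p)(d+p)) / ((b+p)(c+p))` with the Haldane--Anscombe
#' pseudocount `p` (default 0.5) keeping the ratio finite for empty cells.
#'
#' @param a,b,c,d Nonnegative cell counts (vectorized): SA1 & contains,
#'   SA1 & lacks, non-SA1 & contains, non-SA1 & lacks.
#' @param pseudocount Added to every cell (default 0.5).
#' @return Positive numeric vector of odds ratios.
#' @export
#' @examples
#' odds_ratio(3, 1, 2, 4, pseudocount = 0)  # 6
odds_ratio <- function(a, b, c, d, pseudocount = 0.5) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(a + b <= 0) || any(c + d <= 0)) {
    stop("both margins of the 2x2 table must be positive", call. = FALSE)
  }
  p <- pseudocount
  ((a + p) * (d + p)) / ((b + p) * (c + p))
}

#' Per-6-mer odds ratios for SA1 usage in a degenerate region
#'
#' For one condition, cross-tabulates presence of every 6-mer in the
#' chosen degenerate region against SA1 utilization over the filtered
#' minigene universe, and reports the 2x2 cells, odds ratio and log2 odds
#' ratio for all `4^k` 6-mers. Presence is per minigene (a 6-mer is
#' present or absent in a minigene's region); a minigene utilizes SA1 iff
#' it has at least one SA1 record in `table`.
#'
#' @param lib The `bp_library`.
#' @param table A filtered `bp_transcripts` table for one condition; the
#'   minigene universe is the set of ids present in it.
#' @param region `"25A"` or `"25B"`.
#' @param condition Label attached to the output (defaults to the
#'   table's).
#' @param k Word length (default 6).
#' @param pseudocount Haldane--Anscombe pseudocount (default 0.5).
#' @return A data frame of class `kmer_stats` with one row per k-mer:
#'   `kmer`, `region`, `condition`, `a`, `b`, `c`, `d`, `or_`, `log2_or`.
#' @export
kmer_or_stats <- function(lib, table, region = c("25A", "25B"),
                          condition = NULL, k = 6L, pseudocount = 0.5) {
  region <- match.arg(region)
  condition <- condition %||% table$condition[1]
  ids <- unique(table$minigene_id)
  if (!length(ids)) stop("empty minigene universe", call. = FALSE)
  sa1_ids <- unique(table$minigene_id[table$acceptor_class == "SA1"])
  if (!length(sa1_ids)) {
    stop(sprintf("no SA1-utilizing minigenes in condition %s", condition),
         call. = FALSE)
  }
  seqs <- lib[[if (region == "25A") "n25a" else "n25b"]][match(ids, lib$id)]
  is_sa1 <- ids %in% sa1_ids
  n_sa1 <- sum(is_sa1)
  n_other <- sum(!is_sa1)

  # long table of distinct (minigene, kmer) pairs
  width <- nchar(seqs[1])
  n_pos <- width - k + 1L
  km <- vapply(seq_len(n_pos), function(j) substr(seqs, j, j + k - 1L),
               character(length(seqs)))
  dt <- data.table::data.table(
    row = rep.int(seq_along(seqs), n_pos),
    kmer = as.vector(km)
  )
  dt <- unique(dt)
  dt[, sa1 := is_sa1[row]]
  cnt <- dt[, list(a = sum(sa1), c = sum(!sa1)), by = "kmer"]

  universe <- all_kmers(k)
  a <- integer(length(universe)); ci <- integer(length(universe))
  m <- match(cnt$kmer, universe)
  a[m] <- cnt$a; ci[m] <- cnt$c
  b <- n_sa1 - a; d <- n_other - ci
  or_ <- odds_ratio(a, b, ci, d, pseudocount = pseudocount)
  out <- data.frame(kmer = universe, region = region, condition = condition,
                    a = a, b = b, c = ci, d = d,
                    or_ = or_, log2_or = log2(or_),
                    stringsAsFactors = FALSE)
  class(out) <- c("kmer_stats", "data.frame")
  out
}

#' Condition contrast of per-k-mer log2 odds ratios
#'
#' Joins the WT and K700E [kmer_or_stats()] tables for the same region and
#' reports `delta_log2 = log2_OR(K700E) - log2_OR(WT)` per k-mer
#' (antisymmetric under swapping the conditions).
#'
#' @param stats_wt,stats_k700e `kmer_stats` tables over identical k-mer
#'   universes and the same region.
#' @return A data frame with `kmer`, `region`, the per-condition odds
#'   ratio columns (`or_wt`, `log2_or_wt`, `or_k700e`, `log2_or_k700e`)
#'   and `delta_log2`.
#' @export
delta_log2 <- function(stats_wt, stats_k700e) {
  if (!identical(stats_wt$kmer, stats_k700e$kmer)) {
    stop("k-mer universes differ between the two stats tables", call. = FALSE)
  }
  if (!identical(unique(stats_wt$region), unique(stats_k700e$region))) {
    stop("stats tables are for different regions", call. = FALSE)
  }
  data.frame(
    kmer = stats_wt$kmer,
    region = stats_wt$region,
    or_wt = stats_wt$or_, log2_or_wt = stats_wt$log2_or,
    or_k700e = stats_k700e$or_, log2_or_k700e = stats_k700e$log2_or,
    delta_log2 = stats_k700e$log2_or - stats_wt$log2_or,
    stringsAsFactors = FALSE
  )
}

#' Hierarchical branch point motif class of 6-mers
#'
#' Classifies each 6-mer by the branch-point trinucleotide it contains
#' (positions -2, -1, 0 with 0 the branch adenosine), first match wins:
#' `TAA` (canonical), then `T[CGT]A` (-1 variants), then `[ACG]AA`
#' (-2 variants), then `[ACG][CGT]A` (variants at both), else `NONE`.
#'
#' @param kmer Character vector of 6-mers over A/C/G/T.
#' @return Factor with levels `CANONICAL_TAA`, `MINUS1_VARIANT`,
#'   `MINUS2_VARIANT`, `BOTH_VARIANT`, `NONE`.
#' @export
#' @examples
#' classify_kmer(c("CTAAGT", "GTGACC", "CCAAGG", "GGGGGG"))
classify_kmer <- function(kmer) {
  assert_dna(kmer, "k-mer")
  out <- rep("NONE", length(kmer))
  out[grepl("[ACG][CGT]A", kmer)] <- "BOTH_VARIANT"
  out[grepl("[ACG]AA", kmer)] <- "MINUS2_VARIANT"
  out[grepl("T[CGT]A", kmer)] <- "MINUS1_VARIANT"
  out[grepl("TAA", kmer, fixed = TRUE)] <- "CANONICAL_TAA"
  factor(out, levels = .motif_classes)
}

.motif_classes <- c("CANONICAL_TAA", "MINUS1_VARIANT", "MINUS2_VARIANT",
                    "BOTH_VARIANT", "NONE")

#' Motif class census over all 4096 6-mers
#'
#' @return A data frame with `class`, `n` (summing to 4096) and `pct`.
#' @export
#' @examples
#' classification_census()
classification_census <- function() {
  cls <- classify_kmer(all_kmers(6L))
  tab <- table(cls)
  data.frame(class = names(tab), n = as.integer(tab),
             pct = 100 * as.integer(tab) / length(cls),
             stringsAsFactors = FALSE)
}

#' Rank splicing-enhancing 6-mers
#'
#' With `by = "delta"` (the condition contrast) survivors are k-mers with
#' `OR(K700E) > or_threshold` and `delta_log2 > 0` (6-mers that enhance
#' splicing more in the mutant), ranked by decreasing `delta_log2`; with
#' `by = "OR"` survivors of a single-condition table are ranked by
#' decreasing odds ratio. Survivors are annotated with their motif class
#' and the class shares among survivors are reported.
#'
#' @param stats For `by = "delta"` a [delta_log2()] table; for
#'   `by = "OR"` a [kmer_or_stats()] table.
#' @param or_threshold Odds-ratio cutoff (default 1.5).
#' @param by `"delta"` or `"OR"`.
#' @return A list with `table` (ranked survivors with `motif_class`) and
#'   `class_share` (named percentages over survivors; `NA` when none).
#' @export
top_enhancers <- function(stats, or_threshold = 1.5, by = c("delta", "OR")) {
  by <- match.arg(by)
  if (by == "delta") {
    if (!"delta_log2" %in% names(stats)) {
      stop("by = 'delta' needs a delta_log2 table", call. = FALSE)
    }
    keep <- stats$or_k700e > or_threshold & stats$delta_log2 > 0
    tab <- stats[keep, , drop = FALSE]
    tab <- tab[order(-tab$delta_log2), , drop = FALSE]
  } else {
    if (!"or_" %in% names(stats)) {
      stop("by = 'OR' needs a kmer_stats table", call. = FALSE)
    }
    keep <- stats$or_ > or_threshold
    tab <- stats[keep, , drop = FALSE]
    tab <- tab[order(-tab$or_), , drop = FALSE]
  }
  rownames(tab) <- NULL
  if (!nrow(tab)) {
    warning("no k-mers pass the enhancer criteria")
    share <- setNames(rep(NA_real_, length(.motif_classes)), .motif_classes)
  } else {
    cls <- classify_kmer(tab$kmer)
    tab$motif_class <- as.character(cls)
    share <- 100 * as.numeric(table(cls)) / nrow(tab)
    names(share) <- .motif_classes
  }
  list(table = tab, class_share = share)
}
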