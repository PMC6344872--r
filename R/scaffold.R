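#' Minigene scaffold configuration
#'
#' Describes the invariant backbone of the two-acceptor reporter minigene.
#' The construct carries a 5' exon, a single intron with a degenerate 25-nt
#' region (N25A) ending a few bases upstream of the weak acceptor SA1, a
#' second degenerate 25-nt region (N25B) just downstream of SA1, and the
#' dominant acceptor SA2 exactly 156 bp downstream of SA1, followed by the
#' 3' exon. The segment immediately upstream of each acceptor is invariant:
#' a pyrimidine-rich heptamer ending in AG for SA1, and a polypyrimidine
#' tract plus a canonical CTAAC branch point (branch adenosine 29 bp
#' upstream) for SA2.
#'
#' @param exon1_seq,intron_5p_seq,inter_acceptor_seq,exon2_seq Invariant
#'   backbone segments (DNA strings over A/C/G/T). `intron_5p_seq` is the
#'   intronic sequence from the donor to SA1 *excluding* N25A, which is
#'   inserted `n25a_offset` bases before its 3' end. `inter_acceptor_seq`
#'   is the invariant part of the SA1--SA2 segment, with N25B inserted
#'   `n25b_offset` bases after its start.
#' @param n25a_offset Bases of invariant intron between the end of N25A and
#'   SA1 (default 7: the pyrimidine heptamer `TTTCCAG`).
#' @param n25b_offset Bases of invariant sequence between SA1 and the start
#'   of N25B (default 10).
#' @param sa1_sa2_distance Distance in bp between the two acceptors
#'   (default 156, the reporter geometry).
#' @param barcode_len Barcode length in read 2 (default 20).
#' @param degenerate_len Length of each degenerate insert (default 25).
#'
#' @return An object of class `scaffold_config`.
#' @export
#' @examples
#' sc <- scaffold_config()
#' sc$sa1_sa2_distance
scaffold_config <- function(exon1_seq = .default_exon1,
                            intron_5p_seq = .default_intron_5p,
                            inter_acceptor_seq = .default_inter,
                            exon2_seq = .default_exon2,
                            n25a_offset = 7L,
                            n25b_offset = 10L,
                            sa1_sa2_distance = 156L,
                            barcode_len = 20L,
                            degenerate_len = 25L) {
  cfg <- list(
    exon1_seq = toupper(exon1_seq),
    intron_5p_seq = toupper(intron_5p_seq),
    inter_acceptor_seq = toupper(inter_acceptor_seq),
    exon2_seq = toupper(exon2_seq),
    n25a_offset = as.integer(n25a_offset),
    n25b_offset = as.integer(n25b_offset),
    sa1_sa2_distance = as.integer(sa1_sa2_distance),
    barcode_len = as.integer(barcode_len),
    degenerate_len = as.integer(degenerate_len)
  )
  class(cfg) <- "scaffold_config"
  validate_scaffold(cfg)
  cfg
}

# invariant backbone segments; "CTTCG" repeats are adenosine-free so the
# only branch point candidates upstream of SA1 come from N25A itself
.default_exon1 <- "ATGGTGAGCAAGGGCGAGGAGCTGTTCACCGGGGTGGTGCCCATCCTGGTCGAGCTGGAC"
.default_intron_5p <- paste0("GT", strrep("CTTCG", 13), "C", "TTTCCAG")
.default_inter <- paste0(
  "GTCCTCCTTC",                      # first exonic bases of the SA1 isoform
  strrep("CTTCG", 17), "CTT",        # A-free filler
  "ACTAACTTC",                       # SA2 branch point: CTAAC, A 29 bp upstream
  strrep("CTTCG", 3), "CT",
  "TTTCCAG"                          # SA2 polypyrimidine tract + AG
)
.default_exon2 <- "AACCACTACCTGAGCACCCAGTCCGCCCTGAGCAAAGACCCCAACGAGAAGCGCGATCAC"

validate_scaffold <- function(cfg) {
  stopifnot(inherits(cfg, "scaffold_config"))
  for (f in c("exon1_seq", "intron_5p_seq", "inter_acceptor_seq", "exon2_seq")) {
    assert_dna(cfg[[f]], f)
  }
  if (cfg$degenerate_len < 1L || cfg$barcode_len < 1L) {
    stop("degenerate_len and barcode_len must be positive", call. = FALSE)
  }
  if (cfg$n25a_offset < 0L || cfg$n25a_offset > nchar(cfg$intron_5p_seq)) {
    stop("n25a_offset outside intron_5p_seq", call. = FALSE)
  }
  if (cfg$n25b_offset < 0L || cfg$n25b_offset > nchar(cfg$inter_acceptor_seq)) {
    stop("n25b_offset outside inter_acceptor_seq", call. = FALSE)
  }
  got <- nchar(cfg$inter_acceptor_seq) + cfg$degenerate_len
  if (got != cfg$sa1_sa2_distance) {
    stop(sprintf(
      "inter_acceptor_seq (%d nt) + degenerate insert (%d nt) must equal sa1_sa2_distance (%d)",
      nchar(cfg$inter_acceptor_seq), cfg$degenerate_len, cfg$sa1_sa2_distance
    ), call. = FALSE)
  }
  if (substr0(cfg$intron_5p_seq, 0L, 2L) != "GT") {
    stop("intron_5p_seq must start with the GT donor dinucleotide", call. = FALSE)
  }
  invisible(cfg)
}

# assemble full minigene sequences for given degenerate inserts (vectorized)
assemble_minigene <- function(n25a, n25b, scaffold) {
  L5 <- nchar(scaffold$intron_5p_seq)
  head5 <- substr0(scaffold$intron_5p_seq, 0L, L5 - scaffold$n25a_offset)
  tail5 <- substr0(scaffold$intron_5p_seq, L5 - scaffold$n25a_offset, L5)
  inter_head <- substr0(scaffold$inter_acceptor_seq, 0L, scaffold$n25b_offset)
  inter_tail <- substr0(scaffold$inter_acceptor_seq, scaffold$n25b_offset,
                        nchar(scaffold$inter_acceptor_seq))
  paste0(scaffold$exon1_seq, head5, n25a, tail5,
         inter_head, n25b, inter_tail, scaffold$exon2_seq)
}

# 0-based coordinate bookkeeping for an assembled minigene
scaffold_coords <- function(scaffold) {
  e1 <- nchar(scaffold$exon1_seq)
  L5 <- nchar(scaffold$intron_5p_seq)
  sa1 <- e1 + L5 + scaffold$degenerate_len
  n25a_start <- e1 + (L5 - scaffold$n25a_offset)
  list(
    exon1_len = e1,
    sa1_pos = as.integer(sa1),
    sa2_pos = as.integer(sa1 + scaffold$sa1_sa2_distance),
    n25a_start = as.integer(n25a_start),
    n25a_end = as.integer(n25a_start + scaffold$degenerate_len),
    n25b_start = as.integer(sa1 + scaffold$n25b_offset),
    n25b_end = as.integer(sa1 + scaffold$n25b_offset + scaffold$degenerate_len),
    total_len = as.integer(sa1 + scaffold$sa1_sa2_distance +
                             nchar(scaffold$exon2_seq))
  )
}

#' Generate a barcoded degenerate minigene library
#'
#' Draws `n_minigenes` minigenes with i.i.d. uniform degenerate inserts
#' (N25A, N25B) and pairwise-distinct random barcodes, and assembles the
#' full reporter sequence for each on the given scaffold.
#'
#' @param n_minigenes Number of minigenes (>= 1).
#' @param scaffold A [scaffold_config()].
#' @param seed Integer seed; identical `(n_minigenes, scaffold, seed)`
#'   yield byte-identical libraries.
#'
#' @return A data frame of class `bp_library` with columns `id`, `barcode`,
#'   `n25a`, `n25b`, `full_seq`, `sa1_pos`, `sa2_pos` (0-based coordinates
#'   of the first exonic base of each acceptor) and the scaffold attached
#'   as attribute `"scaffold"`.
#' @export
#' @examples
#' lib <- generate_library(5, scaffold_config(), seed = 1)
#' lib$sa2_pos - lib$sa1_pos
generate_library <- function(n_minigenes, scaffold = scaffold_config(),
                             seed = 1L) {
  validate_scaffold(scaffold)
  n_minigenes <- as.integer(n_minigenes)
  if (is.na(n_minigenes) || n_minigenes < 1L) {
    stop("n_minigenes must be a positive integer", call. = FALSE)
  }
  if (log(n_minigenes) > scaffold$barcode_len * log(4) - log(20)) {
    stop("barcode space exhausted for this barcode length", call. = FALSE)
  }
  with_seed(seed, {
    barcode <- random_dna(n_minigenes, scaffold$barcode_len)
    # re-draw colliding barcodes until pairwise distinct
    while (anyDuplicated(barcode)) {
      dup <- duplicated(barcode)
      barcode[dup] <- random_dna(sum(dup), scaffold$barcode_len)
    }
    n25a <- random_dna(n_minigenes, scaffold$degenerate_len)
    n25b <- random_dna(n_minigenes, scaffold$degenerate_len)
    co <- scaffold_coords(scaffold)
    lib <- data.frame(
      id = sprintf("mg%06d", seq_len(n_minigenes)),
      barcode = barcode,
      n25a = n25a,
      n25b = n25b,
      full_seq = assemble_minigene(n25a, n25b, scaffold),
      sa1_pos = co$sa1_pos,
      sa2_pos = co$sa2_pos,
      stringsAsFactors = FALSE
    )
    class(lib) <- c("bp_library", "data.frame")
    attr(lib, "scaffold") <- scaffold
    lib
  })
}

#' The packaged base (non-degenerate) minigene
#'
#' A single fixed minigene matching the base reporter construct: the N25A
#' slot carries a canonical CTAAC branch point whose branch adenosine lies
#' 29 bp upstream of SA1, and both degenerate slots are otherwise
#' adenosine-free pyrimidine-rich filler, so SA1 and SA2 each see exactly
#' one canonical branch point.
#'
#' @param scaffold A [scaffold_config()].
#' @return A one-row `bp_library` data frame.
#' @export
#' @examples
#' bm <- base_minigene()
#' # branch adenosine of the SA1 branch point sits 29 bp upstream of SA1
#' regmatches(bm$full_seq, regexpr("CTAAC", bm$full_seq))
base_minigene <- function(scaffold = scaffold_config()) {
  validate_scaffold(scaffold)
  stopifnot(scaffold$degenerate_len == 25L)
  co <- scaffold_coords(scaffold)
  n25a <- paste0("CTAAC", strrep("CTTCG", 4))
  n25b <- strrep("GCTTC", 5)
  lib <- data.frame(
    id = "base",
    barcode = strrep("AC", scaffold$barcode_len / 2),
    n25a = n25a,
    n25b = n25b,
    full_seq = assemble_minigene(n25a, n25b, scaffold),
    sa1_pos = co$sa1_pos,
    sa2_pos = co$sa2_pos,
    stringsAsFactors = FALSE
  )
  class(lib) <- c("bp_library", "data.frame")
  attr(lib, "scaffold") <- scaffold
  lib
}

#' Write / read a minigene library table
#'
#' The library is stored as a plain TSV (`id`, `barcode`, `n25a`, `n25b`,
#' `full_seq`, `sa1_pos`, `sa2_pos`). The scaffold is not serialized with
#' the table; pass it again when reading.
#'
#' @param lib A `bp_library`.
#' @param path Output TSV path.
#' @return `write_library` returns `path` invisibly; `read_library` returns
#'   a `bp_library`.
#' @export
write_library <- function(lib, path) {
  write.table(as.data.frame(lib), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @param scaffold Scaffold to re-attach (default [scaffold_config()]).
#' @export
read_library <- function(path, scaffold = scaffold_config()) {
  lib <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "barcode", "n25a", "n25b", "full_seq", "sa1_pos", "sa2_pos")
  if (!all(need %in% names(lib))) {
    stop("library table is missing columns: ",
         paste(setdiff(need, names(lib)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(lib$barcode)) {
    stop("duplicate barcodes in library table", call. = FALSE)
  }
  class(lib) <- c("bp_library", "data.frame")
  attr(lib, "scaffold") <- scaffold
  lib
}

#' Candidate splice acceptors of each minigene
#'
#' The candidate set is SA1, SA2, and every AG dinucleotide inside a
#' degenerate region (novel acceptors, position = first base after the AG)
#' with at least `min_exon_room` nt of downstream sequence.
#'
#' @param lib A `bp_library`.
#' @param min_exon_room Minimum downstream room for a novel acceptor
#'   (default 6).
#' @return A data frame with columns `id`, `acceptor_class`
#'   (`"SA1"`/`"SA2"`/`"NOVEL"`), `acceptor_pos` (0-based), `region`
#'   (`"25A"`/`"25B"`/`NA`).
#' @export
candidate_acceptors <- function(lib, min_exon_room = 6L) {
  scaffold <- attr(lib, "scaffold")
  co <- scaffold_coords(scaffold)
  base <- data.frame(
    id = rep(lib$id, 2L),
    acceptor_class = rep(c("SA1", "SA2"), each = nrow(lib)),
    acceptor_pos = c(lib$sa1_pos, lib$sa2_pos),
    region = NA_character_,
    stringsAsFactors = FALSE
  )
  novel_in <- function(seqs, region_start, region) {
    hits <- gregexpr("(?=AG)", seqs, perl = TRUE)
    n_hit <- vapply(hits, function(h) if (h[1] == -1L) 0L else length(h),
                    integer(1))
    if (sum(n_hit) == 0L) return(NULL)
    idx <- rep.int(seq_along(seqs), n_hit)
    local0 <- unlist(hits[n_hit > 0L], use.names = FALSE) - 1L  # A of AG
    pos <- region_start + local0 + 2L                            # after the AG
    data.frame(id = lib$id[idx], acceptor_class = "NOVEL",
               acceptor_pos = pos, region = region,
               stringsAsFactors = FALSE)
  }
  nov <- rbind(
    novel_in(lib$n25a, co$n25a_start, "25A"),
    novel_in(lib$n25b, co$n25b_start, "25B")
  )
  if (!is.null(nov)) {
    nov <- nov[co$total_len - nov$acceptor_pos >= min_exon_room, , drop = FALSE]
  }
  out <- rbind(base, nov)
  out[order(out$id, out$acceptor_pos), , drop = FALSE]
}
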