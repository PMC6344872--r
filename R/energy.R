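#' Parameters of the U2 snRNA--branch point duplex energy model
#'
#' The branch region is scored as a short antiparallel duplex between the
#' intronic 9-mer window (branch adenosine at the fifth base, bulged) and
#' the U2 snRNA branch-point-recognition hexamer 5'-GUAGUA-3'. Window
#' positions -4..-1 and +1 relative to the bulged adenosine pair with U2
#' bases U, G, A, U and G respectively; Watson-Crick and G.U wobble pairs
#' are accepted. The -1 position is special: only the canonical adenosine
#' pairs without cost, while C/G/T (the "-1 variants" of the branch point
#' consensus) form a modified pair that keeps the helix stacked but incurs
#' the -1 mismatch penalty -- the term that K700E-mutant spliceosomes
#' attenuate. Free energy is the sum of nearest-neighbor stacking terms
#' for consecutive paired positions, per-position mismatch penalties, and
#' a constant bulge term for the unpaired branch adenosine.
#'
#' Stacking energies are the Turner 2004 nearest-neighbor values
#' (kcal/mol, 37C) for the steps reachable against the fixed U2 strand;
#' the destabilizing GU/UG tandem-wobble step is floored at 0 so stacking
#' never destabilizes. The table lives in one place so the model is
#' swappable.
#'
#' @param stack_energies Named list of per-step stack tables (kcal/mol),
#'   keyed by the intron dinucleotide (DNA letters).
#' @param mismatch_penalty Nonnegative penalties (kcal/mol) for a
#'   mismatched base at positions -4, -3, -2, -1, +1.
#' @param bulge_penalty Constant cost of the bulged branch adenosine.
#' @param lambda_minus1 Multiplier in \[0,1\] applied to the -1 mismatch
#'   penalty in `mode = "K700E"`; 1 (the default, used for descriptive
#'   analysis) makes the two modes identical.
#' @return An object of class `duplex_params`.
#' @export
#' @examples
#' p <- duplex_params()
#' duplex_energy("ACTAACTTT", p)   # canonical CTAAC core
duplex_params <- function(stack_energies = .u2_stacks,
                          mismatch_penalty = c(`-4` = 1, `-3` = 2, `-2` = 2,
                                               `-1` = 6, `+1` = 2),
                          bulge_penalty = 0.5,
                          lambda_minus1 = 1) {
  stopifnot(
    all(unlist(stack_energies) <= 0),
    all(mismatch_penalty >= 0), length(mismatch_penalty) == 5L,
    bulge_penalty >= 0,
    lambda_minus1 >= 0, lambda_minus1 <= 1
  )
  names(mismatch_penalty) <- c("-4", "-3", "-2", "-1", "+1")
  structure(list(stack_energies = stack_energies,
                 mismatch_penalty = mismatch_penalty,
                 bulge_penalty = bulge_penalty,
                 lambda_minus1 = lambda_minus1),
            class = "duplex_params")
}

# Turner 2004 stacks (kcal/mol) against the fixed U2 partner bases,
# keyed by the intron dinucleotide in DNA letters. Step partners (U2,
# 3'->5' along the intron): step1 (-4,-3): U,G; step2 (-3,-2): G,A;
# step3 (-2,-1): A,U; step4 (-1,+1 across the bulge): U,G.
.u2_stacks <- list(
  step1 = c(AC = -2.2, AT = -1.4, GC = -2.5, GT = 0),
  step2 = c(CT = -2.1, TT = -0.6),
  step3 = c(TA = -1.3),
  step4 = c(AC = -2.2, AT = -1.4)
)

# which intron bases keep the helix at each duplex position (U2 partners
# U,G,A,U,G). At -1 every base is helix-compatible: a non-canonical base
# there forms a *modified* pair that maintains duplex continuity (the
# mutant-tolerated geometry), and its whole destabilization is carried by
# the lambda-scalable -1 mismatch penalty; stacking across -1 is scored
# with the canonical adenosine.
.pairable <- list(
  `-4` = c("A", "G"),
  `-3` = c("C", "T"),
  `-2` = c("T"),
  `-1` = c("A", "C", "G", "T"),
  `+1` = c("C", "T")
)

#' U2--branch point duplex free energy of 9-mer windows
#'
#' Vectorized over `windows`. Each window must be a 9-mer over A/C/G/T
#' with the bulged branch adenosine at the fifth base.
#'
#' @param windows Character vector of 9-mers.
#' @param params A [duplex_params()].
#' @param mode `"WT"` or `"K700E"`; in K700E mode the -1 mismatch penalty
#'   is scaled by `params$lambda_minus1`.
#' @param clamp Clamp energies at 0 (non-binding windows report 0). Set to
#'   `FALSE` to obtain the raw duplex sum, on which the mode ordering is
#'   strict for -1 variants whenever `lambda_minus1 < 1`.
#' @return Numeric vector of free energies (kcal/mol; more negative =
#'   more stable).
#' @export
duplex_energy <- function(windows, params = duplex_params(),
                          mode = c("WT", "K700E"), clamp = TRUE) {
  mode <- match.arg(mode)
  if (any(nchar(windows) != 9L)) {
    stop("duplex windows must be 9-mers", call. = FALSE)
  }
  assert_dna(windows, "duplex window")
  m <- seq_to_matrix(windows)
  if (any(m[, 5L] != "A")) {
    stop("the fifth base of a duplex window must be the branch adenosine",
         call. = FALSE)
  }
  # paired positions -4,-3,-2,-1,+1 sit at window columns 1,2,3,4,6
  cols <- c(1L, 2L, 3L, 4L, 6L)
  ok <- matrix(FALSE, nrow(m), 5L)
  for (j in seq_len(5L)) {
    ok[, j] <- m[, cols[j]] %in% .pairable[[j]]
  }
  lam <- if (mode == "K700E") params$lambda_minus1 else 1
  pen <- params$mismatch_penalty * c(1, 1, 1, lam, 1)
  # a position is penalized when its base deviates from the canonical
  # pairing partner; at -1 the penalized (modified) pair still stacks
  mism <- !ok
  mism[, 4L] <- m[, 4L] != "A"
  e <- mism %*% pen + params$bulge_penalty
  st <- params$stack_energies
  minus1_as_A <- m[, 4L]
  minus1_as_A[] <- "A"
  tops <- list(m[, 1L], m[, 2L], m[, 3L], minus1_as_A, m[, 6L])
  for (s in seq_len(4L)) {
    both <- ok[, s] & ok[, s + 1L]
    duo <- paste0(tops[[s]], tops[[s + 1L]])
    val <- st[[s]][duo]
    val[is.na(val)] <- 0
    e <- e + ifelse(both, val, 0)
  }
  e <- as.numeric(e)
  if (clamp) pmin(e, 0) else e
}

#' Predict the branch point upstream of an acceptor
#'
#' Scans all adenosine-centered 9-mers whose branch adenosine lies within
#' `offset_window` of the acceptor and returns the minimum-energy
#' candidate; ties are broken toward the acceptor-proximal position.
#'
#' @param upstream_seq DNA string 5' of the acceptor (the acceptor's first
#'   exonic base sits just past its end, at offset 0).
#' @param offset_window Integer interval of branch-adenosine offsets
#'   scanned, relative to the acceptor (default `c(-50, -10)`).
#' @inheritParams duplex_energy
#' @return A one-row data frame (`window`, `position` 0-based in
#'   `upstream_seq`, `offset_to_acceptor`, `delta_g`), or `NULL` when the
#'   window holds no adenosine.
#' @export
#' @examples
#' up <- paste0(strrep("GC", 15), "CTAAC", strrep("GC", 10))
#' predict_bp(up)
predict_bp <- function(upstream_seq, offset_window = c(-50L, -10L),
                       params = duplex_params(), mode = c("WT", "K700E")) {
  mode <- match.arg(mode)
  stopifnot(length(upstream_seq) == 1L)
  n <- nchar(upstream_seq)
  best <- bp_scan(upstream_seq, acceptor_pos = n, params = params,
                  mode = mode, offset_window = offset_window)
  if (is.na(best$delta_g)) return(NULL)
  data.frame(window = best$window,
             position = best$bp_pos,
             offset_to_acceptor = best$bp_pos - n,
             delta_g = best$delta_g,
             stringsAsFactors = FALSE)
}

# vectorized branch point scan: one row in, one best candidate out.
# `full_seq` and `acceptor_pos` (0-based) are parallel vectors; returns a
# data.frame with bp_pos/window/delta_g (NA when no candidate).
bp_scan <- function(full_seq, acceptor_pos, params = duplex_params(),
                    mode = "WT", offset_window = c(-50L, -10L)) {
  n <- length(full_seq)
  stopifnot(length(acceptor_pos) == n, offset_window[1] <= offset_window[2])
  rows <- integer(0); offs <- integer(0); wins <- character(0)
  len <- nchar(full_seq)
  for (o in seq(offset_window[1], offset_window[2])) {
    a <- acceptor_pos + o                       # 0-based branch A position
    feas <- which(a >= 4L & a + 5L <= len)
    if (!length(feas)) next
    centre <- substr(full_seq[feas], a[feas] + 1L, a[feas] + 1L)
    hit <- feas[centre == "A"]
    if (!length(hit)) next
    rows <- c(rows, hit)
    offs <- c(offs, rep.int(o, length(hit)))
    wins <- c(wins, substr(full_seq[hit], a[hit] - 3L, a[hit] + 5L))
  }
  out <- data.frame(bp_pos = rep(NA_integer_, n),
                    bp_offset = NA_integer_,
                    window = NA_character_,
                    delta_g = NA_real_,
                    stringsAsFactors = FALSE)
  if (!length(rows)) return(out)
  dg <- duplex_energy(wins, params = params, mode = mode, clamp = TRUE)
  dt <- data.table::data.table(row = rows, off = offs, win = wins, dg = dg)
  data.table::setorder(dt, row, dg, -off)       # ties -> acceptor-proximal
  best <- dt[, .SD[1L], by = "row"]
  out$bp_pos[best$row] <- acceptor_pos[best$row] + best$off
  out$bp_offset[best$row] <- best$off
  out$window[best$row] <- best$win
  out$delta_g[best$row] <- best$dg
  out
}

#' Compare two sets of branch point duplex energies
#'
#' Reports per-set means and a two-sided Wilcoxon rank-sum test, and
#' labels the less stable (higher mean energy) set.
#'
#' @param set_a,set_b Numeric vectors of energies, or data frames holding
#'   a `delta_g` column (e.g. rows of branch point candidates).
#' @param labels Length-2 character labels for the two sets.
#' @return A list of class `energy_comparison`: `mean_a`, `mean_b`,
#'   `statistic`, `p_value`, `less_stable` (label of the higher-mean set),
#'   `n_a`, `n_b`.
#' @export
compare_energies <- function(set_a, set_b, labels = c("setA", "setB")) {
  pull <- function(x) {
    if (is.data.frame(x)) x <- x$delta_g
    as.numeric(x[!is.na(x)])
  }
  a <- pull(set_a); b <- pull(set_b)
  if (!length(a) || !length(b)) {
    stop("both energy sets must be nonempty", call. = FALSE)
  }
  # exact distribution for small tie-free sets, normal approximation otherwise
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  structure(list(
    labels = labels,
    mean_a = mean(a), mean_b = mean(b),
    statistic = unname(wt$statistic), p_value = wt$p.value,
    less_stable = labels[which.max(c(mean(a), mean(b)))],
    n_a = length(a), n_b = length(b)
  ), class = "energy_comparison")
}

#' @export
print.energy_comparison <- function(x, ...) {
  cat(sprintf("U2-BP duplex energies: %s mean %.3f (n=%d) vs %s mean %.3f (n=%d)\n",
              x$labels[1], x$mean_a, x$n_a, x$labels[2], x$mean_b, x$n_b))
  cat(sprintf("Wilcoxon rank-sum p = %.3g; less stable set: %s\n",
              x$p_value, x$less_stable))
  invisible(x)
}
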