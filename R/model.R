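#' Parameters of the acceptor-competition splicing model
#'
#' Each candidate acceptor of a minigene (SA1, SA2, and every AG inside a
#' degenerate region) receives a log-weight
#' \deqn{w = \beta_{bp}(-\Delta G_{best}) + \beta_{ppt}\,f_{py} + b}
#' where \eqn{\Delta G_{best}} is the energy of the best branch point
#' candidate in the acceptor's search window (K700E spliceosomes scale the
#' -1 mismatch penalty by \eqn{\lambda}), \eqn{f_{py}} is the pyrimidine
#' fraction of the 20 nt immediately upstream, and \eqn{b} is a class
#' baseline (`sa2_bonus` for SA2, 0 for SA1, `novel_penalty` for novel
#' acceptors). Acceptor probabilities are the softmax of the log-weights.
#'
#' With `lambda_minus1 = 1` the WT and K700E conditions define identical
#' acceptor distributions; smaller values let the mutant condition
#' stabilize branch points with a non-canonical -1 base.
#'
#' Defaults are calibrated so that, over random degenerate libraries, SA2
#' is the predominant acceptor, SA1 captures a few percent of wild-type
#' transcripts, and novel acceptors are a minor fraction.
#'
#' @param beta_bp Weight on branch point duplex stability (per kcal/mol).
#' @param beta_ppt Weight on the upstream pyrimidine fraction.
#' @param sa2_bonus Baseline log-weight of SA2.
#' @param novel_penalty Baseline log-weight of novel acceptors.
#' @param lambda_minus1 Mutant -1-mismatch tolerance in \[0,1\]
#'   (default 0.4); applied only in the K700E condition.
#' @param bp_search_window Branch-adenosine offsets scanned upstream of an
#'   acceptor (default `c(-50, -10)`).
#' @param duplex Energy model, a [duplex_params()].
#' @param seed Default seed carried along for simulation helpers.
#' @return An object of class `splice_model_params`.
#' @export
splice_model_params <- function(beta_bp = 1,
                                beta_ppt = 2,
                                sa2_bonus = -0.5,
                                novel_penalty = -2,
                                lambda_minus1 = 0.4,
                                bp_search_window = c(-50L, -10L),
                                duplex = duplex_params(),
                                seed = 1L) {
  stopifnot(
    is.finite(beta_bp), is.finite(beta_ppt), is.finite(sa2_bonus),
    is.finite(novel_penalty),
    lambda_minus1 >= 0, lambda_minus1 <= 1,
    length(bp_search_window) == 2L,
    bp_search_window[1] <= bp_search_window[2]
  )
  structure(list(beta_bp = beta_bp, beta_ppt = beta_ppt,
                 sa2_bonus = sa2_bonus, novel_penalty = novel_penalty,
                 lambda_minus1 = lambda_minus1,
                 bp_search_window = as.integer(bp_search_window),
                 duplex = duplex, seed = as.integer(seed)),
            class = "splice_model_params")
}

# duplex parameters with the model's lambda installed, for a condition
condition_duplex <- function(params, condition) {
  dp <- params$duplex
  if (condition == "K700E") dp$lambda_minus1 <- params$lambda_minus1
  dp
}

# log-weights and probabilities for every candidate acceptor of every
# minigene in `lib`, under one condition. Returns a data.frame with one
# row per (minigene, acceptor).
acceptor_weight_table <- function(lib, condition = c("WT", "K700E"),
                                  params = splice_model_params()) {
  condition <- match.arg(condition)
  cand <- candidate_acceptors(lib)
  idx <- match(cand$id, lib$id)
  full <- lib$full_seq[idx]
  mode <- if (condition == "K700E") "K700E" else "WT"
  bp <- bp_scan(full, cand$acceptor_pos,
                params = condition_duplex(params, condition), mode = mode,
                offset_window = params$bp_search_window)
  up20 <- substr(full, cand$acceptor_pos - 19L, cand$acceptor_pos)
  fpy <- pyrimidine_fraction(up20)
  baseline <- ifelse(cand$acceptor_class == "SA2", params$sa2_bonus,
                     ifelse(cand$acceptor_class == "NOVEL",
                            params$novel_penalty, 0))
  dg <- ifelse(is.na(bp$delta_g), 0, bp$delta_g)
  lw <- params$beta_bp * (-dg) + params$beta_ppt * fpy + baseline
  out <- data.frame(
    id = cand$id, condition = condition,
    acceptor_class = cand$acceptor_class,
    acceptor_pos = cand$acceptor_pos,
    region = cand$region,
    bp_pos = bp$bp_pos, bp_window = bp$window, bp_delta_g = bp$delta_g,
    pyr_fraction = fpy, log_weight = lw,
    stringsAsFactors = FALSE
  )
  dt <- data.table::as.data.table(out)
  dt[, prob := {
    w <- exp(log_weight - max(log_weight)); w / sum(w)
  }, by = "id"]
  as.data.frame(dt)
}

#' Acceptor choice probabilities of a minigene
#'
#' @param minigene A one-row `bp_library` (or a library; all rows are
#'   evaluated).
#' @param condition `"WT"` or `"K700E"`.
#' @param params A [splice_model_params()].
#' @return A data frame with one row per candidate acceptor, including the
#'   best branch point candidate, its energy, the log-weight and the
#'   normalized probability (summing to 1 within each minigene).
#' @export
#' @examples
#' aw <- acceptor_weights(base_minigene(), "WT")
#' sum(aw$prob)
acceptor_weights <- function(minigene, condition = c("WT", "K700E"),
                             params = splice_model_params()) {
  condition <- match.arg(condition)
  acceptor_weight_table(minigene, condition, params)
}

#' Simulate condition-dependent transcript counts
#'
#' Draws a per-minigene sequencing depth and a multinomial acceptor choice
#' from [acceptor_weights()] under the given condition, producing a truth
#' table of transcript counts.
#'
#' @param lib A `bp_library`.
#' @param condition `"WT"` or `"K700E"`.
#' @param params A [splice_model_params()].
#' @param depth Either a single nonnegative number (mean of a Poisson
#'   depth per minigene) or a function `n -> integer vector` of depths.
#' @param seed Integer seed (default `params$seed`).
#' @return A data frame of class `bp_transcripts` with columns
#'   `minigene_id`, `condition`, `acceptor_class`, `acceptor_pos`,
#'   `n_reads` (only rows with `n_reads >= 1` are kept).
#' @export
simulate_transcripts <- function(lib, condition = c("WT", "K700E"),
                                 params = splice_model_params(),
                                 depth = 50, seed = params$seed) {
  condition <- match.arg(condition)
  aw <- acceptor_weight_table(lib, condition, params)
  dt <- data.table::as.data.table(aw)
  data.table::setorder(dt, id, acceptor_pos)
  with_seed(seed, {
    depths <- if (is.function(depth)) {
      as.integer(depth(nrow(lib)))
    } else {
      stopifnot(depth >= 0)
      rpois(nrow(lib), lambda = depth)
    }
    names(depths) <- lib$id
    counts <- dt[, {
      d <- depths[[.BY$id]]
      k <- if (d > 0L) as.integer(rmultinom(1L, d, prob)) else integer(.N)
      list(acceptor_class = acceptor_class, acceptor_pos = acceptor_pos,
           n_reads = k)
    }, by = "id"]
  })
  counts <- counts[n_reads > 0L]
  out <- data.frame(minigene_id = counts$id,
                    condition = rep_len(condition, nrow(counts)),
                    acceptor_class = counts$acceptor_class,
                    acceptor_pos = counts$acceptor_pos,
                    n_reads = counts$n_reads,
                    stringsAsFactors = FALSE)
  class(out) <- c("bp_transcripts", "data.frame")
  out
}
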