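# shared fixtures, all generated in code

# a small library plus filtered two-condition transcript tables
sim_pair <- function(n = 300, depth = 30, lambda_k700e = 0.4, seed = 1,
                     min_reads = 5, ...) {
  lib <- generate_library(n, scaffold_config(), seed = seed)
  pw <- splice_model_params(lambda_minus1 = 1, ...)
  pk <- splice_model_params(lambda_minus1 = lambda_k700e, ...)
  tw <- simulate_transcripts(lib, "WT", pw, depth = depth,
                             seed = seed + 1000)
  tk <- simulate_transcripts(lib, "K700E", pk, depth = depth,
                             seed = seed + 2000)
  filtered <- apply_filters(list(WT = tw, K700E = tk), min_reads = min_reads)
  list(lib = lib, raw = list(WT = tw, K700E = tk), filtered = filtered)
}

# a minigene with a chosen N25A insert on the default scaffold
minigene_with_n25a <- function(n25a, n25b = strrep("GCTTC", 5)) {
  lib <- base_minigene()
  lib$n25a <- n25a
  lib$n25b <- n25b
  lib$full_seq <- bpmpra:::assemble_minigene(n25a, n25b,
                                             attr(lib, "scaffold"))
  lib
}

# hand-built transcript table
tr_table <- function(minigene_id, acceptor_class, n_reads,
                     condition = "WT", acceptor_pos = NA_integer_) {
  out <- data.frame(minigene_id = minigene_id,
                    condition = rep_len(condition, length(minigene_id)),
                    acceptor_class = acceptor_class,
                    acceptor_pos = rep_len(acceptor_pos, length(minigene_id)),
                    n_reads = n_reads,
                    stringsAsFactors = FALSE)
  class(out) <- c("bp_transcripts", "data.frame")
  out
}
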