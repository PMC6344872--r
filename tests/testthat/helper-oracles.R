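# independent brute-force oracles, deliberately written on different code
# paths from the package implementations they check

# presence sets via an explicit position loop (no substring vectorization)
oracle_kmer_set <- function(seq, k = 6) {
  out <- character(0)
  for (i in seq_len(nchar(seq) - k + 1)) {
    out <- union(out, substr(seq, i, i + k - 1))
  }
  out
}

# recount the full 2x2 table for every observed k-mer of a fixture
oracle_or_table <- function(lib, table, region, pseudocount = 0.5, k = 6) {
  ids <- unique(table$minigene_id)
  sa1 <- unique(table$minigene_id[table$acceptor_class == "SA1"])
  seqs <- lib[[if (region == "25A") "n25a" else "n25b"]][match(ids, lib$id)]
  sets <- lapply(seqs, oracle_kmer_set, k = k)
  kmers <- sort(unique(unlist(sets)))
  res <- data.frame(kmer = kmers, a = 0L, b = 0L, c = 0L, d = 0L)
  n_sa1 <- sum(ids %in% sa1)
  for (j in seq_along(kmers)) {
    has <- vapply(sets, function(s) kmers[j] %in% s, logical(1))
    res$a[j] <- sum(has & ids %in% sa1)
    res$c[j] <- sum(has & !(ids %in% sa1))
  }
  res$b <- n_sa1 - res$a
  res$d <- (length(ids) - n_sa1) - res$c
  p <- pseudocount
  res$or_ <- ((res$a + p) * (res$d + p)) / ((res$b + p) * (res$c + p))
  res
}

# hierarchical motif classification via an explicit scan with nested ifs
oracle_classify <- function(kmer) {
  tri <- character(0)
  for (i in 1:(nchar(kmer) - 2)) tri <- c(tri, substr(kmer, i, i + 2))
  last_a <- substr(tri, 3, 3) == "A"
  m2 <- substr(tri, 1, 1)
  m1 <- substr(tri, 2, 2)
  if (any(m2 == "T" & m1 == "A" & last_a)) return("CANONICAL_TAA")
  if (any(m2 == "T" & m1 != "A" & last_a)) return("MINUS1_VARIANT")
  if (any(m2 != "T" & m1 == "A" & last_a)) return("MINUS2_VARIANT")
  if (any(m2 != "T" & m1 != "A" & last_a)) return("BOTH_VARIANT")
  "NONE"
}

# two-sided exact permutation p-value for the rank-sum statistic
oracle_permutation_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  obs <- sum(r[seq_along(a)])
  idx <- utils::combn(length(pooled), length(a))
  stats <- apply(idx, 2, function(i) sum(r[i]))
  centre <- length(a) * (length(pooled) + 1) / 2
  mean(abs(stats - centre) >= abs(obs - centre) - 1e-12)
}
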