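test_that("kmer_presence collects distinct substrings", {
  expect_identical(kmer_presence("CTAACG"), "CTAACG")
  expect_identical(kmer_presence("AAAAAAA"), "AAAAAA")
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
  expect_lte(length(kmer_presence(s)), 20)
  expect_warning(out <- kmer_presence("ACG"), "shorter")
  expect_length(out, 0)
})

test_that("odds_ratio follows the Haldane-Anscombe form", {
  expect_equal(odds_ratio(3, 1, 2, 4, pseudocount = 0), 6)
  expect_equal(odds_ratio(5, 5, 5, 5), 1)
  expect_equal(odds_ratio(5, 5, 5, 5, pseudocount = 2), 1)
  expect_equal(odds_ratio(0, 10, 5, 5), (0.5 * 5.5) / (10.5 * 5.5))
  expect_error(odds_ratio(0, 0, 3, 4), "margins")
  expect_error(odds_ratio(-1, 2, 3, 4), "nonnegative")
})

test_that("kmer_or_stats emits complete, correctly tabulated tables", {
  sim <- sim_pair(n = 150, depth = 25, seed = 51)
  st <- kmer_or_stats(sim$lib, sim$filtered$WT, region = "25A")
  expect_equal(nrow(st), 4096)
  expect_equal(anyDuplicated(st$kmer), 0)
  ids <- unique(sim$filtered$WT$minigene_id)
  sa1 <- unique(sim$filtered$WT$minigene_id[
    sim$filtered$WT$acceptor_class == "SA1"])
  expect_true(all(st$a + st$b == length(intersect(ids, sa1))))
  expect_true(all(st$c + st$d == length(ids) - length(intersect(ids, sa1))))
  expect_true(all(st$or_ > 0))
  expect_equal(st$log2_or, log2(st$or_))
})

test_that("a k-mer planted everywhere is non-discriminative for balanced groups", {
  # two SA1 and two non-SA1 minigenes, all carrying the planted 6-mer
  lib <- generate_library(4, scaffold_config(), seed = 53)
  lib$n25a <- paste0("GGGGGG", substr(lib$n25a, 7, 25))
  tab <- tr_table(lib$id, c("SA1", "SA1", "SA2", "SA2"), c(6, 6, 6, 6))
  st <- kmer_or_stats(lib, tab, region = "25A")
  row <- st[st$kmer == "GGGGGG", ]
  expect_equal(row$a, 2); expect_equal(row$c, 2)
  expect_equal(row$or_, 1)
})

test_that("every odds ratio matches an independent brute-force recount", {
  for (seed in c(61, 62)) {
    sim <- sim_pair(n = 100, depth = 25, seed = seed)
    st <- kmer_or_stats(sim$lib, sim$filtered$K700E, region = "25B")
    orc <- oracle_or_table(sim$lib, sim$filtered$K700E, region = "25B")
    m <- match(orc$kmer, st$kmer)
    expect_identical(st$a[m], orc$a)
    expect_identical(st$c[m], orc$c)
    expect_equal(st$or_[m], orc$or_)
    # k-mers the oracle never saw are absent from every minigene
    expect_true(all(st$a[-m] == 0) && all(st$c[-m] == 0))
  }
})

test_that("delta_log2 is zero on identity and antisymmetric under swap", {
  sim <- sim_pair(n = 120, depth = 25, seed = 55)
  sw <- kmer_or_stats(sim$lib, sim$filtered$WT, region = "25A",
                      condition = "WT")
  sk <- kmer_or_stats(sim$lib, sim$filtered$K700E, region = "25A",
                      condition = "K700E")
  expect_true(all(delta_log2(sw, sw)$delta_log2 == 0))
  d <- delta_log2(sw, sk)
  d_swap <- delta_log2(sk, sw)
  expect_equal(d$delta_log2, -d_swap$delta_log2)
  bad <- sk[order(sk$or_), ]
  expect_error(delta_log2(sw, bad), "universes")
})

test_that("relabelling SA1 and its complement inverts every odds ratio", {
  sim <- sim_pair(n = 100, depth = 25, seed = 57)
  tab <- sim$filtered$WT
  flipped <- tab
  flipped$acceptor_class[tab$acceptor_class == "SA1"] <- "SA2"
  # make every former non-SA1 minigene an SA1 user
  sa1_ids <- unique(tab$minigene_id[tab$acceptor_class == "SA1"])
  other <- setdiff(unique(tab$minigene_id), sa1_ids)
  flipped <- rbind(flipped, tr_table(other, "SA1", 1))
  st <- kmer_or_stats(sim$lib, tab, region = "25A")
  st_f <- kmer_or_stats(sim$lib, flipped, region = "25A")
  expect_equal(st_f$or_, 1 / st$or_)
})

test_that("the motif hierarchy classifies canonical examples and rejects junk", {
  expect_identical(as.character(classify_kmer("CTAAGT")), "CANONICAL_TAA")
  expect_identical(as.character(classify_kmer("GTGACC")), "MINUS1_VARIANT")
  expect_identical(as.character(classify_kmer("CCAAGG")), "MINUS2_VARIANT")
  expect_identical(as.character(classify_kmer("GCGACC")), "BOTH_VARIANT")
  expect_identical(as.character(classify_kmer("GGGGGG")), "NONE")
  expect_error(classify_kmer("CTANGT"), "non-ACGT")
})

test_that("the census partitions all 4096 6-mers and matches a dual implementation", {
  cen <- classification_census()
  expect_equal(sum(cen$n), 4096)
  expect_equal(sum(cen$pct), 100)
  kmers <- bpmpra:::all_kmers(6)
  expect_identical(as.character(classify_kmer(kmers)),
                   vapply(kmers, oracle_classify, character(1),
                          USE.NAMES = FALSE))
})

test_that("top_enhancers filters, ranks and annotates survivors", {
  sim <- sim_pair(n = 150, depth = 25, seed = 59)
  sw <- kmer_or_stats(sim$lib, sim$filtered$WT, region = "25A")
  sk <- kmer_or_stats(sim$lib, sim$filtered$K700E, region = "25A")
  d <- delta_log2(sw, sk)
  expect_warning(empty <- top_enhancers(d, or_threshold = Inf), "no k-mers")
  expect_equal(nrow(empty$table), 0)
  full <- top_enhancers(sw, or_threshold = 0, by = "OR")
  expect_equal(nrow(full$table), 4096)
  expect_equal(full$table$or_[1], max(sw$or_))
  ranked <- top_enhancers(d, or_threshold = 1.5, by = "delta")
  if (nrow(ranked$table)) {
    expect_true(all(ranked$table$or_k700e > 1.5))
    expect_true(all(ranked$table$delta_log2 > 0))
    expect_true(!is.unsorted(rev(ranked$table$delta_log2)))
    expect_equal(sum(ranked$class_share), 100)
  }
})
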