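test_that("barcode matching: exact wins, unique neighbours rescue, ties drop", {
  lib <- generate_library(6, scaffold_config(), seed = 21)
  bc <- lib$barcode
  expect_identical(match_barcode(bc[3], lib, max_mismatch = 0), lib$id[3])
  # one substitution, unique neighbour
  mut <- bc[2]
  substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(mut, 5, 5))[1]
  expect_identical(match_barcode(mut, lib, max_mismatch = 1), lib$id[2])
  expect_identical(match_barcode(mut, lib, max_mismatch = 0), NA_character_)
  # a read equidistant (distance 1) from two barcodes is unassigned
  lib2 <- lib
  alt <- setdiff(c("A", "C", "G", "T"), substr(bc[2], 1, 1))
  lib2$barcode[1] <- paste0(alt[1], substr(bc[2], 2, 20))
  probe <- paste0(alt[2], substr(bc[2], 2, 20))
  expect_identical(match_barcode(probe, lib2, max_mismatch = 1),
                   NA_character_)
  # short reads are unassigned; duplicate barcodes refuse to index
  expect_identical(match_barcode("ACGT", lib), NA_character_)
  lib3 <- lib
  lib3$barcode[2] <- lib3$barcode[1]
  expect_error(match_barcode(bc[1], lib3), "duplicate")
})

test_that("emitted reads carry the barcode and a junction-spanning R1", {
  lib <- generate_library(20, scaffold_config(), seed = 22)
  truth <- simulate_transcripts(lib, "WT", splice_model_params(),
                                depth = 10, seed = 23)
  dir <- tempfile()
  fq <- emit_reads(truth, lib, dir, read_len = 50, error_rate = 0, seed = 1)
  r1 <- bpmpra:::read_fastq(fq$r1)
  r2 <- bpmpra:::read_fastq(fq$r2)
  side <- read.delim(fq$sidecar, stringsAsFactors = FALSE)
  expect_equal(length(r1), sum(truth$n_reads))
  expect_equal(length(r2), sum(truth$n_reads))
  expect_identical(names(r1), side$read_id)
  # error-free R2 starts with the true barcode
  bc <- lib$barcode[match(side$minigene_id, lib$id)]
  expect_identical(substr(unname(r2), 1, 20), bc)
  # an SA2 read spans the exon1/exon2 junction, absent from the pre-mRNA
  i <- which(side$acceptor_class == "SA2")[1]
  mg <- match(side$minigene_id[i], lib$id)
  expect_false(grepl(r1[[i]], lib$full_seq[mg], fixed = TRUE))
  sc <- attr(lib, "scaffold")
  junction <- paste0(substr(sc$exon1_seq, nchar(sc$exon1_seq) - 24, 60),
                     substr(sc$exon2_seq, 1, 25))
  expect_identical(unname(r1[i]), junction)
  expect_error(emit_reads(truth, lib, dir, read_len = 24), "too short")
})

test_that("junction calls recover the acceptor and refuse uncovered junctions", {
  mg <- minigene_with_n25a(paste0("CCAGC", strrep("CTTCG", 4)))
  sc <- attr(mg, "scaffold")
  cand <- candidate_acceptors(mg)
  iso <- function(pos) paste0(sc$exon1_seq,
                              substr(mg$full_seq, pos + 1, nchar(mg$full_seq)))
  j <- nchar(sc$exon1_seq)
  read_at <- function(pos, start) substr(iso(pos), start + 1, start + 50)
  sa2 <- cand$acceptor_pos[cand$acceptor_class == "SA2"]
  sa1 <- cand$acceptor_pos[cand$acceptor_class == "SA1"]
  nov <- cand$acceptor_pos[cand$acceptor_class == "NOVEL"]
  # clean reads centred on the junction
  calls <- call_junction(read_at(sa2, j - 25), mg)
  expect_identical(calls$acceptor_class, "SA2")
  expect_identical(call_junction(read_at(nov, j - 25), mg)$acceptor_class,
                   "NOVEL")
  # one planted substitution is tolerated
  noisy <- read_at(sa1, j - 25)
  substr(noisy, 10, 10) <- if (substr(noisy, 10, 10) == "A") "C" else "A"
  expect_identical(call_junction(noisy, mg)$acceptor_class, "SA1")
  # a read entirely inside exon 2 never covers the junction
  expect_true(is.na(call_junction(read_at(sa2, j + 20), mg)$acceptor_class))
})

test_that("zero-noise demultiplexing reproduces the truth table exactly", {
  lib <- generate_library(120, scaffold_config(), seed = 31)
  truth <- simulate_transcripts(lib, "WT", splice_model_params(),
                                depth = 15, seed = 32)
  fq <- emit_reads(truth, lib, tempfile(), error_rate = 0, seed = 33)
  dm <- build_transcript_table(fq$r1, fq$r2, lib, condition = "WT")
  expect_equal(dm$report$pairs_in, sum(truth$n_reads))
  expect_equal(dm$report$assigned + dm$report$unassigned +
                 dm$report$uncalled, dm$report$pairs_in)
  expect_equal(dm$report$unassigned, 0)
  expect_equal(dm$report$uncalled, 0)
  srt <- function(d) {
    d <- as.data.frame(d)[order(d$minigene_id, d$acceptor_pos), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(srt(dm$records), srt(truth))
})

test_that("read-level acceptor accuracy stays >= 99% at error rate 0.005", {
  lib <- generate_library(350, scaffold_config(), seed = 41)
  truth <- simulate_transcripts(lib, "WT", splice_model_params(),
                                depth = 30, seed = 42)
  fq <- emit_reads(truth, lib, tempfile(), error_rate = 0.005, seed = 43)
  expect_gt(fq$n, 9000)
  side <- read.delim(fq$sidecar, stringsAsFactors = FALSE)
  r1 <- bpmpra:::read_fastq(fq$r1)
  r2 <- bpmpra:::read_fastq(fq$r2)
  mg <- match_barcode(unname(r2), lib, max_mismatch = 1)
  sc <- attr(lib, "scaffold")
  cand_all <- candidate_acceptors(lib)
  called <- rep(NA_character_, length(r1))
  for (id in unique(mg[!is.na(mg)])) {
    sel <- which(!is.na(mg) & mg == id)
    cand <- cand_all[cand_all$id == id, ]
    k <- bpmpra:::call_junction_group(unname(r1[sel]),
                                      lib$full_seq[match(id, lib$id)],
                                      cand$acceptor_pos, sc$exon1_seq)
    called[sel] <- ifelse(is.na(k), NA, cand$acceptor_class[k])
  }
  # accuracy among reads that were assigned and called: heavily mutated
  # reads may drop out, but surviving calls must be right
  usable <- !is.na(mg) & !is.na(called)
  expect_gt(mean(usable), 0.9)
  correct <- mg[usable] == side$minigene_id[usable] &
    called[usable] == side$acceptor_class[usable]
  expect_gte(mean(correct), 0.99)
})

test_that("the five-read representation filter keeps boundary minigenes and is idempotent", {
  wt <- tr_table(c("m1", "m1", "m2", "m3"), c("SA1", "SA2", "SA2", "SA2"),
                 c(2, 3, 12, 40), condition = "WT")
  ke <- tr_table(c("m1", "m3"), c("SA1", "SA2"), c(5, 80),
                 condition = "K700E")
  f <- apply_filters(list(WT = wt, K700E = ke), min_reads = 5)
  # m1: 5 reads in each condition -> kept; m2: absent in K700E -> dropped
  expect_setequal(unique(f$WT$minigene_id), c("m1", "m3"))
  expect_setequal(unique(f$K700E$minigene_id), c("m1", "m3"))
  expect_identical(apply_filters(f, min_reads = 5), f)
  # raising the threshold never adds minigenes
  f9 <- apply_filters(list(WT = wt, K700E = ke), min_reads = 9)
  expect_true(all(unique(f9$WT$minigene_id) %in% unique(f$WT$minigene_id)))
  expect_setequal(unique(f9$WT$minigene_id), "m3")
})
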