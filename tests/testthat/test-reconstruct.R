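test_that("embedded read ids follow the barcode:umi:id format and parse back", {
  r1 <- tempfile(); r2 <- tempfile()
  o1 <- tempfile(); o2 <- tempfile()
  TCRforge:::writeFastq("r7", paste0("AAACGG", "TTT"), r1)
  TCRforge:::writeFastq("r7", "ACGTACGTACGT", r2)
  embedBarcodes(r1, r2, o1, o2, barcode_length = 6L, umi_length = 3L)
  out <- TCRforge:::readFastq(o2)
  expect_equal(out$id, "AAACGG:TTT:r7")
  p <- parseEmbeddedIds(out$id)
  expect_equal(p$barcode, "AAACGG")
  expect_equal(p$umi, "TTT")
  expect_equal(p$original_id, "r7")
})

test_that("original ids containing colons round-trip losslessly", {
  p <- parseEmbeddedIds("ACGT:TT:machine:lane:tile:77")
  expect_equal(p$barcode, "ACGT")
  expect_equal(p$umi, "TT")
  expect_equal(p$original_id, "machine:lane:tile:77")
})

test_that("paired embedding writes identical prefixes to both mates", {
  set.seed(4)
  n <- 100L
  ids <- sprintf("read%03d", seq_len(n))
  bcumi <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = ""), "")
  cdna <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = ""), "")
  r1 <- tempfile(); r2 <- tempfile(); o1 <- tempfile(); o2 <- tempfile()
  TCRforge:::writeFastq(ids, bcumi, r1)
  TCRforge:::writeFastq(ids, cdna, r2)
  res <- embedBarcodes(r1, r2, o1, o2, barcode_length = 6L, umi_length = 3L)
  expect_equal(res$n_out, n)
  e1 <- TCRforge:::readFastq(o1); e2 <- TCRforge:::readFastq(o2)
  expect_identical(e1$id, e2$id)
  expect_equal(nrow(e1), n)
  # desynchronized mates abort
  TCRforge:::writeFastq(rev(ids), cdna, r2)
  expect_error(embedBarcodes(r1, r2, o1, o2, barcode_length = 6L,
                             umi_length = 3L), "desynchronized")
})

test_that("barcode and UMI recovery is lossless on simulator output", {
  ref <- sharedRef()
  cfg <- smallSimConfig(seed = 51L, n_clonotypes_per_sample = 4L)
  sim <- simulateRepertoire(cfg, ref, tempfile())
  s <- sim$samples[1, ]
  o1 <- tempfile(); o2 <- tempfile()
  embedBarcodes(s$fastq_r1, s$fastq_r2, o1, o2,
                barcode_length = cfg@barcodeLength,
                umi_length = cfg@umiLength)
  emb <- TCRforge:::readFastq(o2)
  p <- parseEmbeddedIds(emb$id)
  raw1 <- TCRforge:::readFastq(s$fastq_r1)
  expect_equal(p$barcode, substr(raw1$sequence, 1, cfg@barcodeLength))
  expect_equal(p$umi, substr(raw1$sequence, cfg@barcodeLength + 1,
                             cfg@barcodeLength + cfg@umiLength))
  expect_equal(p$original_id, raw1$id)
})

test_that("the TCR screen keeps true reads and drops unrelated sequence", {
  ref <- sharedRef()
  seg <- refSegments(ref)
  vseq <- seg$sequence[seg$segment_type == "V"][1]
  set.seed(9)
  unrelated <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""), "")
  reads <- data.frame(
    id = sprintf("BC%02d:UMI:r%d", 1:7, 1:7),
    sequence = c(substr(vseq, 10, 80), substr(vseq, 50, 120), unrelated),
    stringsAsFactors = FALSE)
  kept <- screenTcrReads(reads, ref, min_score = 25)
  expect_setequal(kept$id, reads$id[1:2])
  counts <- attr(kept, "counts")
  expect_equal(unname(counts["input"]), 7L)
  expect_equal(unname(counts["retained"] + counts["dropped"]), 7L)
  # min_score = 0 reduces the screen to k-mer candidacy
  kept0 <- screenTcrReads(reads, ref, min_score = 0)
  expect_setequal(kept0$id, reads$id[1:2])
})

test_that("grouping by barcode partitions the reads", {
  reads <- data.frame(
    id = c(sprintf("AAA:U%d:r%d", 1:4, 1:4), sprintf("CCC:U%d:r%d", 5:6, 5:6)),
    sequence = strrep("ACGT", 10), stringsAsFactors = FALSE)
  g <- groupByBarcode(reads)
  expect_equal(sort(names(g$groups)), c("AAA", "CCC"))
  expect_equal(unname(vapply(g$groups, nrow, 0L)[c("AAA", "CCC")]), c(4L, 2L))
  expect_equal(sum(vapply(g$groups, nrow, 0L)) + g$n_dropped, nrow(reads))
  expect_equal(length(groupByBarcode(reads[0, ])$groups), 0L)
  bad <- rbind(reads, data.frame(id = "nocolons", sequence = "ACGT"))
  expect_equal(groupByBarcode(bad)$n_dropped, 1L)
  expect_error(groupByBarcode(bad, on_unparseable = "abort"), "parse")
})

test_that("two overlapping reads merge into one supported contig", {
  set.seed(11)
  base <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE),
                collapse = "")
  a <- substr(base, 1, 60)
  b <- substr(base, 31, 90)
  out <- assembleCell(c(a, b), min_overlap = 30L, min_contig_len = 50L)
  expect_equal(nrow(out), 1L)
  expect_equal(out$sequence, base)
  expect_equal(out$support, 2L)
  # reverse-complement read merges the same way
  rc_b <- paste(rev(strsplit(chartr("ACGT", "TGCA", b), "")[[1]]),
                collapse = "")
  out2 <- assembleCell(c(a, rc_b), min_overlap = 30L, min_contig_len = 50L)
  expect_true(base %in% out2$sequence ||
              paste(rev(strsplit(chartr("ACGT", "TGCA", base), "")[[1]]),
                    collapse = "") %in% out2$sequence)
})

test_that("non-overlapping reads come back deduplicated", {
  a <- strrep("ACGTA", 12)
  b <- strrep("GGCTT", 12)
  out <- assembleCell(c(a, a, b), min_overlap = 30L, min_contig_len = 50L)
  expect_equal(nrow(out), 2L)
  expect_equal(out$support[out$sequence == a], 2L)
  # short sequences are filtered by min_contig_len
  out2 <- assembleCell(c(a, a, b), min_overlap = 30L, min_contig_len = 61L)
  expect_equal(nrow(out2), 0L)
})

test_that("greedy assembly matches exhaustive merge-order search", {
  set.seed(23)
  for (rep in 1:12) {
    L <- sample(120:200, 1)
    base <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = "")
    n_reads <- sample(3:8, 1)
    starts <- sort(sample(seq_len(L - 60L), n_reads))
    starts[1] <- 1L
    reads <- vapply(starts, function(s)
      substr(base, s, min(L, s + 59L)), "")
    max_greedy <- assembleCell(reads, min_overlap = 10L, max_mismatch = 0L,
                               min_contig_len = 10L)
    max_exh <- exhaustiveAssembleMax(unique(reads), min_overlap = 10L)
    expect_equal(max(nchar(max_greedy$sequence)), max_exh)
  }
})

test_that("contigs from simulated recombination annotate back to the truth", {
  ref <- sharedRef()
  cfg <- simConfig()
  set.seed(31)
  for (locus in c("TRA", "TRB", "TRG", "TRD")) {
    cl <- recombineVDJ(ref, locus, cfg)
    ann <- annotateContig(cl$transcript, ref)
    expect_equal(ann$v_call, cl$v_id, info = locus)
    expect_equal(ann$j_call, cl$j_id, info = locus)
    expect_equal(ann$cdr3_nt, cl$junction_nt, info = locus)
    expect_equal(ann$cdr3_aa, cl$junction_aa, info = locus)
    expect_true(ann$productive, info = locus)
    # reverse-complemented contig is re-oriented V-forward
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", cl$transcript), "")[[1]]),
                collapse = "")
    ann_rc <- annotateContig(rc, ref)
    expect_equal(ann_rc$cdr3_nt, cl$junction_nt, info = locus)
  }
})

test_that("missing segments and stop codons produce fail reasons", {
  ref <- sharedRef()
  seg <- refSegments(ref)
  vseq <- seg$sequence[seg$segment_type == "V" & seg$locus == "TRB"][1]
  ann <- annotateContig(vseq, ref)
  expect_false(ann$productive)
  expect_match(ann$fail_reasons, "no_j")
  # engineer a stop codon (TAA) into the junction insert
  cfg <- simConfig(insertion_mean = 0, max_trim = 0L)
  cl <- TCRforge:::withSeed(17L, recombineVDJ(ref, "TRA", cfg))
  v <- seg[seg$segment_id == cl$v_id, ]
  pre <- substr(cl$transcript, 1, v$anchor_offset + 15L)
  post <- substr(cl$transcript, v$anchor_offset + 16L, nchar(cl$transcript))
  broken <- paste0(pre, "TAA", post)
  ann2 <- annotateContig(broken, ref)
  expect_false(ann2$productive)
  expect_match(ann2$fail_reasons, "stop_codon|out_of_frame|anchor_unaligned")
})
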