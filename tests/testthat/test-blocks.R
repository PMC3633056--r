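# Block construction (streaming algorithm vs brute-force oracle),
# concordance, coverage and length filters.

tile_records <- function(n, start = 0L, step = 50L, len = 99L,
                         contig = 1L, rev = FALSE, prefix = "r") {
  data.table::data.table(
    read_id = sprintf("%s%03d", prefix, seq_len(n)),
    contig = contig,
    begin = start + (seq_len(n) - 1L) * step,
    end = start + (seq_len(n) - 1L) * step + len,
    reversed = rev)
}

test_that("a contiguous tiling of shared reads forms exactly one block", {
  m <- make_store(tile_records(10), 2000L, "master")
  s <- make_store(tile_records(10), 2000L, "slave")
  b <- build_blocks(m, s, B_min = 10L)
  expect_equal(nrow(b), 1L)
  expect_equal(b$size, 10L)
  expect_true(b$concordant)
  expect_equal(b$m_begin, 0L); expect_equal(b$m_end, 549L)
  b2 <- build_blocks(m, s, B_min = 11L)
  expect_equal(nrow(b2), 0L)
})

test_that("a slave read absent from the master store is skipped", {
  m <- make_store(tile_records(5), 2000L, "master")
  srec <- rbind(tile_records(5),
                data.table::data.table(read_id = "alien", contig = 1L,
                                       begin = 100L, end = 199L,
                                       reversed = FALSE))
  data.table::setorder(srec, contig, begin)
  s <- make_store(srec, 2000L, "slave")
  b <- build_blocks(m, s, B_min = 1L)
  expect_equal(nrow(b), 1L)
  expect_equal(b$size, 5L)
})

test_that("an unsorted slave stream is fatal", {
  m <- make_store(tile_records(3), 2000L, "master")
  srec <- tile_records(3)[c(2, 1, 3)]
  expect_error(build_blocks(m, srec, B_min = 1L), "not sorted")
})

test_that("a read adjacent to two open blocks joins the earlier one", {
  # two blocks open on the same slave region but different master contigs;
  # a read adjacent to both (master contig 1) must extend block 1
  mrec <- data.table::data.table(
    read_id = c("a", "b", "c"),
    contig = c(1L, 2L, 1L),
    begin = c(0L, 0L, 80L), end = c(99L, 99L, 179L), reversed = FALSE)
  srec <- data.table::data.table(
    read_id = c("a", "b", "c"),
    contig = 1L, begin = c(0L, 50L, 100L),
    end = c(99L, 149L, 199L), reversed = FALSE)
  m <- make_store(mrec, c(1000L, 1000L), "master")
  s <- make_store(srec, 1000L, "slave")
  b <- build_blocks(m, s, B_min = 1L)
  expect_equal(nrow(b), 2L)
  with_c <- b[vapply(reads, function(r) "c" %in% r, TRUE)]
  expect_equal(unlist(with_c$reads), c("a", "c"))
})

test_that("streaming construction equals the brute-force chain oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    fx <- make_fixture(
      genome_length = sample(3000:6000, 1), seed = seed,
      master_splits = sort(sample(500:5500, sample(0:2, 1))),
      slave_splits = sort(sample(500:5500, sample(0:2, 1))),
      coverage = sample(4:10, 1), read_len = 50L,
      library = library_descriptor("pe400", 300, 30, "fr"))
    B_min <- sample(1:5, 1)
    got <- build_blocks(fx$master_store, fx$slave_store, B_min)
    want <- oracle_blocks(fx$master_store, fx$slave_store, B_min)
    expect_identical(block_key(got), block_key(want),
                     label = paste("seed", seed))
  }
})

test_that("frame bounds equal min/max of member read intervals", {
  fx <- make_fixture(genome_length = 5000L, seed = 31L, coverage = 6,
                     read_len = 50L,
                     library = library_descriptor("pe400", 300, 30, "fr"))
  b <- build_blocks(fx$master_store, fx$slave_store, 3L)
  expect_gt(nrow(b), 0L)
  for (i in seq_len(nrow(b))) {
    memb <- fx$master_store$records[match(b$reads[[i]], read_id)]
    expect_equal(b$m_begin[i], min(memb$begin))
    expect_equal(b$m_end[i], max(memb$end))
  }
})

test_that("every read id appears in at most one block", {
  fx <- make_fixture(genome_length = 8000L, seed = 32L, coverage = 10,
                     read_len = 50L,
                     master_splits = c(3000L), slave_splits = c(5000L),
                     library = library_descriptor("pe400", 300, 30, "fr"))
  b <- build_blocks(fx$master_store, fx$slave_store, 1L)
  all_reads <- unlist(b$reads)
  expect_equal(anyDuplicated(all_reads), 0L)
})

test_that("concordance is a strict-majority call with ties concordant", {
  b <- function(size, opp) list(size = size, n_opposite = opp)
  expect_equal(classify_concordance(b(10L, 0L)), "concordant")
  expect_equal(classify_concordance(b(10L, 7L)), "discordant")
  expect_equal(classify_concordance(b(10L, 5L)), "concordant")  # exact tie
})

test_that("tie concordance is stable under read reordering", {
  mrec <- tile_records(10)
  srec <- data.table::copy(mrec)
  srec$reversed <- rep(c(TRUE, FALSE), 5)  # 5 of 10 opposite
  m <- make_store(mrec, 2000L, "master")
  for (perm in 1:5) {
    set.seed(perm)
    # reorder read ids (not positions): same geometry, shuffled identities
    srec2 <- data.table::copy(srec)
    srec2$reversed <- sample(srec$reversed)
    s <- make_store(srec2, 2000L, "slave")
    blk <- build_blocks(m, s, 1L)
    expect_true(blk$concordant)
  }
})

test_that("frame coverage counts only in-frame bases", {
  mrec <- tile_records(4, start = 100L, step = 100L, len = 99L)
  m <- make_store(mrec, 2000L, "master")
  s <- make_store(mrec, 2000L, "slave")
  blk <- build_blocks(m, s, 1L)
  cov <- compute_frame_coverage(blk[1L], "master", m)
  expect_equal(cov$BC, cov$GC)       # only block reads on the frame
  expect_equal(cov$BC, 400L)
  # a non-block read extending 10 bp past the frame end contributes only
  # its in-frame bases to GC
  extra <- data.table::data.table(read_id = "x", contig = 1L,
                                  begin = blk$m_end - 89L,
                                  end = blk$m_end + 10L, reversed = FALSE)
  m2 <- make_store(rbind(mrec, extra), 2000L, "master")
  cov2 <- compute_frame_coverage(blk[1L], "master", m2)
  expect_equal(cov2$GC, cov$GC + 90L)
})

test_that("BC/GC matches a per-base pileup oracle on a random fixture", {
  fx <- make_fixture(genome_length = 5000L, seed = 33L, coverage = 8,
                     read_len = 50L,
                     library = library_descriptor("pe400", 300, 30, "fr"))
  blk <- build_blocks(fx$master_store, fx$slave_store, 3L)
  expect_gt(nrow(blk), 0L)
  b <- blk[1L]
  # pileup oracle: depth per base over the master frame
  r <- fx$master_store$records[contig == b$m_contig]
  pos <- b$m_begin:b$m_end
  depth_all <- vapply(pos, function(p) sum(r$begin <= p & r$end >= p), 0L)
  memb <- r[read_id %in% b$reads[[1L]]]
  depth_blk <- vapply(pos, function(p)
    sum(memb$begin <= p & memb$end >= p), 0L)
  cov <- compute_frame_coverage(b, "master", fx$master_store)
  expect_equal(cov$BC, sum(depth_blk))
  expect_equal(cov$GC, sum(depth_all))
  expect_equal(cov$BC / cov$GC, sum(depth_blk) / sum(depth_all))
})

test_that("coverage filter keeps heterozygous blocks via the max rule", {
  # master ratio 1.0, slave ratio 0.5 (another allele's reads cover the
  # slave frame), T_c = 0.75 -> kept
  mrec <- tile_records(6)
  m <- make_store(mrec, 2000L, "master")
  srec <- rbind(tile_records(6),
                tile_records(6, prefix = "allele"))  # same interval, not shared
  data.table::setorder(srec, contig, begin)
  s <- make_store(srec, 2000L, "slave")
  blk <- build_blocks(m, s, 1L)
  kept <- filter_blocks_by_coverage(blk, m, s, T_c = 0.75)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$ratio_m, 1.0)
  expect_equal(kept$ratio_s, 0.5)
  # repeat-like case: both ratios ~0.3 -> discarded
  m2rec <- rbind(tile_records(6), tile_records(14, prefix = "om"))
  data.table::setorder(m2rec, contig, begin)
  m2 <- make_store(m2rec, 2000L, "master")
  s2rec <- rbind(tile_records(6), tile_records(14, prefix = "os"))
  data.table::setorder(s2rec, contig, begin)
  s2 <- make_store(s2rec, 2000L, "slave")
  blk2 <- build_blocks(m2, s2, 1L)[size == 6L]
  kept2 <- filter_blocks_by_coverage(blk2, m2, s2, T_c = 0.75)
  expect_lt(max(blk2$size) / 20, 0.75)
  expect_equal(nrow(kept2), 0L)
  # T_c = 0 keeps everything
  expect_equal(nrow(filter_blocks_by_coverage(blk, m, s, 0)), nrow(blk))
})

test_that("length filter honors base condition and its two exceptions", {
  mk_blocks <- function(fm, fs, pairs) {
    data.table::data.table(
      block_id = seq_along(fm),
      m_contig = pairs, m_begin = 0L, m_end = fm - 1L,
      s_contig = pairs, s_begin = 0L, s_end = fs - 1L,
      size = 10L, n_opposite = 0L, concordant = TRUE,
      reads = replicate(length(fm), character(0), simplify = FALSE))
  }
  m <- make_store(tile_records(1), c(10000L, 10000L), "master")
  s <- make_store(tile_records(1), c(10000L, 10000L), "slave")
  # 500 bp frame on a 10 kbp contig, T_l = 200 -> passes
  b1 <- mk_blocks(500L, 500L, 1L)
  expect_equal(nrow(filter_blocks_by_length(b1, m, s, 200L)), 1L)
  # sole 100 bp block between a contig pair -> retained by exception
  b2 <- mk_blocks(100L, 100L, 1L)
  expect_equal(nrow(filter_blocks_by_length(b2, m, s, 200L)), 1L)
  # two failing blocks between the same pair, no passing sibling -> both out
  b3 <- mk_blocks(c(100L, 120L), c(100L, 120L), c(1L, 1L))
  expect_equal(nrow(filter_blocks_by_length(b3, m, s, 200L)), 0L)
  # a failing block survives next to a passing sibling of the same pair
  b4 <- mk_blocks(c(100L, 500L), c(100L, 500L), c(1L, 1L))
  expect_equal(nrow(filter_blocks_by_length(b4, m, s, 200L)), 2L)
  # the 0.3 * contig-length alternative threshold
  m5 <- make_store(tile_records(1), c(300L), "master")
  s5 <- make_store(tile_records(1), c(300L), "slave")
  b5 <- mk_blocks(c(95L, 100L), c(95L, 100L), c(1L, 1L))  # 0.3*300 = 90
  expect_equal(nrow(filter_blocks_by_length(b5, m5, s5, 200L)), 2L)
})

test_that("raising T_c or T_l never increases the retained block count", {
  for (seed in 1:10) {
    fx <- make_fixture(
      genome_length = 4000L, seed = 100L + seed,
      master_splits = sort(sample(500:3500, 1)),
      slave_splits = sort(sample(500:3500, 1)),
      coverage = 8, read_len = 50L,
      library = library_descriptor("pe400", 300, 30, "fr"))
    blk <- build_blocks(fx$master_store, fx$slave_store, 2L)
    tcs <- c(0, 0.25, 0.5, 0.75, 1)
    ncov <- vapply(tcs, function(tc)
      nrow(filter_blocks_by_coverage(blk, fx$master_store, fx$slave_store,
                                     tc)), 0L)
    expect_true(all(diff(ncov) <= 0L))
    tls <- c(0L, 100L, 300L, 1000L, 5000L)
    nlen <- vapply(tls, function(tl)
      nrow(filter_blocks_by_length(blk, fx$master_store, fx$slave_store,
                                   tl)), 0L)
    expect_true(all(diff(nlen) <= 0L))
  }
})

test_that("perfect repeats generate no blocks (reads are ambiguous)", {
  g <- generate_genome(20000L, seed = 44L,
                       repeats = list(count = 1L, length = 2000L,
                                      divergence = 0))
  truth <- derive_assembly_pair(g, integer(0), integer(0), seed = 45L)
  lib <- library_descriptor("pe400", 400, 40, "fr")
  reads <- simulate_paired_reads(g, 10, 80L, lib, seed = 46L)
  pm <- attr(project_alignments(reads, "master", truth,
                                tempfile(fileext = ".sam")), "placements")
  ps <- attr(project_alignments(reads, "slave", truth,
                                tempfile(fileext = ".sam")), "placements")
  ms <- store_from_placements(pm, names(truth$master$seqs),
                              Biostrings::width(truth$master$seqs),
                              "master")
  ss <- store_from_placements(ps, names(truth$slave$seqs),
                              Biostrings::width(truth$slave$seqs), "slave")
  blk <- build_blocks(ms, ss, 1L)
  reps <- g$repeats
  for (i in seq_len(nrow(blk))) {
    inside <- reps$begin <= blk$m_begin[i] & reps$end >= blk$m_end[i]
    expect_false(any(inside))   # no block wholly inside a repeat copy
  }
  # and the repeat interiors carry no block at all
  for (k in seq_len(nrow(reps))) {
    lo <- reps$begin[k] + 100L; hi <- reps$end[k] - 100L
    covering <- blk$m_begin <= lo & blk$m_end >= hi
    expect_false(any(covering))
  }
})

test_that("blocks TSV round-trips frames, sizes and concordance", {
  fx <- make_fixture(genome_length = 5000L, seed = 51L, coverage = 8,
                     read_len = 50L,
                     library = library_descriptor("pe400", 300, 30, "fr"))
  blk <- build_blocks(fx$master_store, fx$slave_store, 3L)
  path <- tempfile(fileext = ".tsv")
  write_blocks_tsv(blk, path, fx$master_store, fx$slave_store)
  back <- read_blocks_tsv(path, fx$master_store, fx$slave_store)
  cols <- c("m_contig", "m_begin", "m_end", "s_contig", "s_begin", "s_end",
            "size", "n_opposite", "concordant")
  expect_equal(as.data.frame(back[, ..cols]), as.data.frame(blk[, ..cols]))
  expect_error(read_blocks_tsv(tempfile(), fx$master_store,
                               fx$slave_store))
})
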