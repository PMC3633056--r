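# Assemblies graph: construction, mate-pair features, SCCs, structure
# detection and resolution, graph simplification.

no_flip_orders <- function() {
  structure(data.table::data.table(side = character(), contig = integer(),
                                   flipped = logical(), seed = logical()),
            class = c("block_orders", "data.table", "data.frame"))
}

mk_blocks <- function(df) {
  b <- data.table::as.data.table(df)
  b[, `:=`(size = 10L, n_opposite = 0L, concordant = TRUE,
           reads = replicate(.N, character(0), simplify = FALSE))]
  b
}

fake_ag <- function(n, edges_df) {
  blocks <- mk_blocks(data.table::data.table(
    block_id = seq_len(n), m_contig = seq_len(n), m_begin = 0L,
    m_end = 99L, s_contig = seq_len(n), s_begin = 0L, s_end = 99L))
  e <- data.table::as.data.table(edges_df)
  if (!"side" %in% names(e)) e[, side := "M"]
  if (!"contig" %in% names(e)) e[, contig := 1L]
  list(blocks = blocks, edges = e)
}

test_that("directed edges link consecutive blocks per contig", {
  # B1,B2 consecutive on M1 and S1; B2,B3 consecutive on S1; B3,B4 on M2
  b <- mk_blocks(data.table::data.table(
    block_id = 1:4,
    m_contig = c(1L, 1L, 2L, 2L),
    m_begin = c(0L, 200L, 0L, 200L),
    m_end = c(99L, 299L, 99L, 299L),
    s_contig = c(1L, 1L, 1L, 2L),
    s_begin = c(0L, 200L, 400L, 0L),
    s_end = c(99L, 299L, 499L, 99L)))
  ag <- build_assemblies_graph(b, no_flip_orders())
  eu <- unique(ag$edges[, .(from, to)])
  data.table::setorder(eu, from)
  expect_equal(as.data.frame(eu),
               data.frame(from = 1:3, to = 2:4))
})

test_that("a single block yields one node and no edges", {
  b <- mk_blocks(data.table::data.table(
    block_id = 1L, m_contig = 1L, m_begin = 0L, m_end = 99L,
    s_contig = 1L, s_begin = 0L, s_end = 99L))
  ag <- build_assemblies_graph(b, no_flip_orders())
  expect_equal(nrow(ag$edges), 0L)
})

test_that("edge set equals a sort-and-link oracle on random block sets", {
  set.seed(23)
  for (trial in 1:20) {
    n <- sample(3:10, 1)
    b <- mk_blocks(data.table::data.table(
      block_id = seq_len(n),
      m_contig = sample(1:3, n, replace = TRUE),
      m_begin = sample(seq(0L, 5000L, by = 500L), n),
      s_contig = sample(1:3, n, replace = TRUE),
      s_begin = sample(seq(0L, 5000L, by = 500L), n)))
    b[, `:=`(m_end = m_begin + 99L, s_end = s_begin + 99L)]
    ag <- build_assemblies_graph(b, no_flip_orders())
    want <- list()
    for (side in c("m", "s")) {
      cc <- b[[paste0(side, "_contig")]]
      for (ctg in unique(cc)) {
        ids <- b$block_id[cc == ctg]
        ids <- ids[order(b[[paste0(side, "_begin")]][cc == ctg])]
        if (length(ids) >= 2L)
          want[[length(want) + 1L]] <- data.table::data.table(
            from = ids[-length(ids)], to = ids[-1L],
            side = toupper(side))
      }
    }
    want <- data.table::rbindlist(want)
    got <- ag$edges[, .(from, to, side)]
    data.table::setorder(want, side, from); data.table::setorder(got, side, from)
    expect_equal(as.data.frame(got), as.data.frame(want))
    # degree bound over distinct neighbors
    eu <- unique(ag$edges[, .(from, to)])
    expect_true(all(table(eu$from) <= 2L))
    expect_true(all(table(eu$to) <= 2L))
  }
})

test_that("edges are invariant under block-row permutation", {
  b <- mk_blocks(data.table::data.table(
    block_id = 1:5, m_contig = 1L,
    m_begin = c(0L, 300L, 600L, 900L, 1200L),
    m_end = c(99L, 399L, 699L, 999L, 1299L),
    s_contig = 1L,
    s_begin = c(0L, 300L, 600L, 900L, 1200L),
    s_end = c(99L, 399L, 699L, 999L, 1299L)))
  ag1 <- build_assemblies_graph(b, no_flip_orders())
  set.seed(5)
  for (k in 1:5) {
    ag2 <- build_assemblies_graph(b[sample(.N)], no_flip_orders())
    e1 <- data.table::setorder(data.table::copy(ag1$edges), side, from)
    e2 <- data.table::setorder(data.table::copy(ag2$edges), side, from)
    expect_equal(as.data.frame(e1), as.data.frame(e2))
  }
})

test_that("correct pair placement uses the insert-span window", {
  lib <- library_descriptor("x", 400, 40, "fr")
  r1 <- list(begin = 1000L, end = 1099L, reversed = FALSE)
  mk2 <- function(ins, rev = TRUE)
    list(begin = 1000L + ins - 100L, end = 1000L + ins - 1L, reversed = rev)
  expect_true(is_correctly_placed(r1, mk2(400L), 10000L, lib))
  expect_false(is_correctly_placed(r1, mk2(400L + 4L * 40L), 10000L, lib))
  expect_false(is_correctly_placed(r1, mk2(400L, rev = FALSE), 10000L,
                                   lib))  # invalid orientation
  # contig shorter than begin + m + 3sd excludes the read regardless
  expect_false(is_correctly_placed(r1, mk2(400L), 1000L + 520L - 1L, lib))
  expect_true(is_correctly_placed(r1, mk2(400L), 1000L + 520L, lib))
})

test_that("Tarjan components equal the reachability oracle", {
  set.seed(31)
  for (trial in 1:50) {
    n <- sample(2:12, 1)
    ne <- sample(0:(n * 2L), 1)
    edges <- data.table::data.table(
      from = sample.int(n, ne, replace = TRUE),
      to = sample.int(n, ne, replace = TRUE))
    edges <- unique(edges[from != to])
    ag <- fake_ag(n, edges)
    got <- find_sccs(ag)
    want <- oracle_scc(n, ag$edges)
    expect_equal(partition_key(got[as.character(1:n)]),
                 partition_key(want))
  }
})

test_that("structure detection classifies cycles, bubbles and forks", {
  # linear path: nothing
  ag <- fake_ag(3L, data.frame(from = 1:2, to = 2:3))
  expect_length(detect_structures(ag, find_sccs(ag)), 0L)
  # 2-node cycle between blocks sharing both contigs
  b2 <- fake_ag(2L, data.frame(from = c(1L, 2L), to = c(2L, 1L),
                               side = c("M", "S")))
  b2$blocks[, `:=`(m_contig = 1L, s_contig = 1L)]
  st <- detect_structures(b2, find_sccs(b2))
  expect_equal(vapply(st, `[[`, "", "kind"), "two_node_cycle")
  # 2-node SCC whose blocks do not share both contigs: complex
  b2b <- fake_ag(2L, data.frame(from = c(1L, 2L), to = c(2L, 1L),
                                side = c("M", "S")))
  st <- detect_structures(b2b, find_sccs(b2b))
  expect_equal(vapply(st, `[[`, "", "kind"), "unresolved_complex")
  # 3-node cycle: excluded from active resolution
  c3 <- fake_ag(3L, data.frame(from = 1:3, to = c(2L, 3L, 1L)))
  st <- detect_structures(c3, find_sccs(c3))
  expect_equal(vapply(st, `[[`, "", "kind"), "unresolved_complex")
  # bubble: d=1 diverges to 2 and 3, both converge on 4; ends are not forks
  bub <- fake_ag(4L, data.frame(from = c(1L, 1L, 2L, 3L),
                                to = c(2L, 3L, 4L, 4L),
                                side = c("M", "S", "M", "S")))
  st <- detect_structures(bub, find_sccs(bub))
  expect_equal(vapply(st, `[[`, "", "kind"), "bubble")
  expect_equal(sort(st[[1L]]$nodes), 1:4)
  # plain fork: diverging only
  frk <- fake_ag(3L, data.frame(from = c(1L, 1L), to = c(2L, 3L),
                                side = c("M", "S")))
  st <- detect_structures(frk, find_sccs(frk))
  expect_equal(vapply(st, `[[`, "", "kind"), "bifurcation_out")
  # converging fork
  frk2 <- fake_ag(3L, data.frame(from = c(2L, 3L), to = c(1L, 1L),
                                 side = c("M", "S")))
  st <- detect_structures(frk2, find_sccs(frk2))
  expect_equal(vapply(st, `[[`, "", "kind"), "bifurcation_in")
})

test_that("bifurcation resolution follows the normalized ratio thresholds", {
  r <- resolve_bifurcation(1L, 18L, 1L, 0L, 12L, 0.9, 0.1)
  expect_equal(r$decision, "trust_master_path")
  expect_equal(r$evidence$rho_M, 18 / 19, tolerance = 1e-12)
  r2 <- resolve_bifurcation(1L, 0L, 12L, 18L, 1L, 0.9, 0.1)
  expect_equal(r2$decision, "trust_slave_path")
  r3 <- resolve_bifurcation(1L, 5L, 5L, 5L, 5L, 0.9, 0.1)
  expect_equal(r3$decision, "fallback_master")
  # no evidence at all fails both conditions
  r4 <- resolve_bifurcation(1L, 0L, 0L, 0L, 0L, 0.9, 0.1)
  expect_equal(r4$decision, "fallback_master")
})

test_that("2-node cycles are resolved by wrongly-oriented pair counts", {
  lib <- library_descriptor("pe400", 400, 40, "fr")
  blocks <- mk_blocks(data.table::data.table(
    block_id = 1:2, m_contig = 1L, m_begin = c(0L, 600L),
    m_end = c(599L, 1199L), s_contig = 1L, s_begin = c(600L, 0L),
    s_end = c(1199L, 599L)))
  ag <- list(blocks = blocks)
  ok <- paired_tile(20L)
  bad <- paired_tile(20L, wrong = TRUE)
  m_ok <- make_store(ok, 5000L, "master")
  s_bad <- make_store(bad, 5000L, "slave")
  r <- resolve_two_node_cycle(ag, c(1L, 2L), m_ok, s_bad, list(lib), 5L)
  expect_equal(r$decision, "keep_master_sequence")
  r2 <- resolve_two_node_cycle(ag, c(1L, 2L), s_bad, m_ok, list(lib), 5L)
  expect_equal(r2$decision, "keep_slave_sequence")
  # 2 wrongly oriented pairs on each side, threshold 5: fallback
  few <- rbind(paired_tile(2L, wrong = TRUE),
               paired_tile(18L, start = 2000L, prefix = "q"))
  data.table::setorder(few, contig, begin)
  m_few <- make_store(few, 5000L, "master")
  s_few <- make_store(few, 5000L, "slave")
  r3 <- resolve_two_node_cycle(ag, c(1L, 2L), m_few, s_few, list(lib), 5L)
  expect_equal(r3$decision, "fallback_master")
})

test_that("edge features separate intact and broken junctions", {
  lib <- library_descriptor("pe400", 400, 40, "fr")
  # intact junction: blocks split by a narrow slave-side coverage mask
  fx <- make_fixture(genome_length = 20000L, seed = 71L, coverage = 20,
                     mask_slave = list(c(9950L, 10050L)))
  blk <- build_blocks(fx$master_store, fx$slave_store, 10L)
  expect_equal(nrow(blk), 2L)
  cg <- build_contigs_graph(blk)
  o <- assign_block_orders(cg, blk)
  ag <- build_assemblies_graph(blk, o)
  ag <- compute_edge_features(ag, fx$master_store, fx$slave_store,
                              list(lib))
  em <- ag$edges[side == "M"]
  expect_gt(em$spanning, 0L)
  # exact recomputation from the simulated truth: candidate first mates in
  # the upstream frame whose insert window fits and reaches the downstream
  # frame; spanning ones have an in-window insert crossing the junction
  f1 <- blk[1L]; f2 <- blk[2L]
  rd <- fx$reads[mate_no == 1L & g_begin >= f1$m_begin &
                   g_begin <= f1$m_end &
                   g_begin + 280 >= f2$m_begin & g_begin + 520 <= 20000]
  expected_n <- rd[insert >= 280 & insert <= 520 &
                     g_begin + insert - 1L >= f2$m_begin, .N]
  expect_equal(em$spanning, expected_n)
  expect_equal(em$unfulfilled, nrow(rd) - expected_n)
  expect_gt(em$local_coverage, 0)

  # misjoined master junction: mates are elsewhere, so n = 0
  ev <- list(engineered_event("relocation_misjoin", "master", 8001L,
                              15999L))
  fx2 <- make_fixture(genome_length = 20000L, seed = 72L, coverage = 20,
                      events = ev, slave_splits = c(12000L, 16000L))
  blk2 <- build_blocks(fx2$master_store, fx2$slave_store, 10L)
  cg2 <- build_contigs_graph(blk2)
  o2 <- assign_block_orders(cg2, blk2)
  ag2 <- build_assemblies_graph(blk2, o2)
  ag2 <- compute_edge_features(ag2, fx2$master_store, fx2$slave_store,
                               list(lib))
  bad <- ag2$edges[side == "M" & contig == 1L][1L]
  expect_equal(bad$spanning, 0L)
  expect_gt(bad$unfulfilled, 0L)
})

test_that("unpaired reads give all-zero features with a warning", {
  rec <- tile_records <- data.table::data.table(
    read_id = sprintf("r%02d", 1:20), contig = 1L,
    begin = (0:19) * 50L, end = (0:19) * 50L + 99L, reversed = FALSE)
  m <- make_store(rec, 5000L, "master")
  s <- make_store(rec, 5000L, "slave")
  blocks <- mk_blocks(data.table::data.table(
    block_id = 1:2, m_contig = 1L, m_begin = c(0L, 600L),
    m_end = c(599L, 1199L), s_contig = 1L, s_begin = c(0L, 600L),
    s_end = c(599L, 1199L)))
  ag <- build_assemblies_graph(blocks, no_flip_orders())
  expect_warning(ag <- compute_edge_features(ag, m, s,
                   list(library_descriptor("x", 400, 40, "fr"))),
                 "no paired")
  expect_true(all(ag$edges$spanning == 0L))
  expect_true(all(ag$edges$unfulfilled == 0L))
})

test_that("simplification prunes per resolutions and stays linear", {
  # fully linear graph: unchanged, nothing withheld
  lin <- fake_ag(4L, data.frame(from = 1:3, to = 2:4))
  sg <- simplify_graph(lin, list())
  expect_equal(nrow(sg$edges), 3L)
  expect_length(sg$withheld_master, 0L)
  expect_equal(enumerate_merge_paths(sg), list(1:4))

  # unresolved 3-node SCC: its master contigs withheld, the rest linear
  ag <- fake_ag(5L, data.frame(from = c(1L, 2L, 3L, 4L, 3L),
                               to = c(2L, 3L, 4L, 3L, 5L)))
  st <- detect_structures(ag, find_sccs(ag))
  res <- asmmerge:::resolve_structures(ag, st, NULL, NULL, list(),
                                       recon_config())
  sg <- simplify_graph(ag, res)
  expect_equal(sg$withheld_master, 3:4)
  expect_equal(sort(sg$nodes), c(1L, 2L, 5L))

  # resolved out-bifurcation: losing branch edge removed, two paths remain
  frk <- fake_ag(4L, data.frame(from = c(1L, 1L, 2L), to = c(2L, 3L, 4L),
                                side = c("M", "S", "M")))
  res <- list(list(kind = "bifurcation_out", nodes = 1L,
                   decision = "trust_master_path", evidence = list()))
  sg <- simplify_graph(frk, res)
  paths <- enumerate_merge_paths(sg)
  expect_equal(sort(vapply(paths, length, 0L)), c(1L, 3L))
  expect_true(any(vapply(paths, function(p) identical(p, c(1L, 2L, 4L)),
                         TRUE)))
})
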