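# Shared helpers: direct store construction, fixture wiring, and the
# independent brute-force oracles used by the property tests.

suppressMessages({
  library(data.table)
})

# Build a read_store directly from a record table (unit tests that do not
# need the SAM path).
make_store <- function(records, contig_lengths, assembly = "master") {
  rec <- data.table::as.data.table(records)
  if (!"library_id" %in% names(rec)) rec[, library_id := "lib1"]
  if (!"pair_name" %in% names(rec)) rec[, pair_name := NA_character_]
  if (!"mate_no" %in% names(rec)) rec[, mate_no := NA_integer_]
  contigs <- data.table::data.table(contig = seq_along(contig_lengths),
                                    name = sprintf("ctg_%03d",
                                                   seq_along(contig_lengths)),
                                    length = as.integer(contig_lengths))
  asmmerge:::new_read_store(rec, contigs, assembly)
}

# Store from an idealized placement table (attribute of
# project_alignments), bypassing SAM I/O for speed.
store_from_placements <- function(pl, contig_names, contig_lengths,
                                  assembly) {
  keep <- pl[mapped == TRUE & ambiguous == FALSE]
  rec <- data.table::data.table(
    read_id = keep$read_id, contig = keep$contig, begin = keep$begin,
    end = keep$end, reversed = keep$reversed, library_id = keep$library_id,
    pair_name = keep$pair_id, mate_no = keep$mate_no)
  contigs <- data.table::data.table(contig = seq_along(contig_names),
                                    name = contig_names,
                                    length = as.integer(contig_lengths))
  asmmerge:::new_read_store(rec, contigs, assembly)
}

# Full synthetic fixture: genome -> assemblies -> reads -> stores (+ SAM
# files when write_sam = TRUE). Returns everything a test needs.
make_fixture <- function(genome_length = 20000L, seed = 1L,
                         master_splits = integer(0),
                         slave_splits = integer(0),
                         events = list(), coverage = 20, read_len = 100L,
                         library = library_descriptor("pe400", 400, 40,
                                                      "fr"),
                         mask_master = NULL, mask_slave = NULL,
                         write_sam = FALSE, gc = 0.5) {
  genome <- generate_genome(genome_length, gc = gc, seed = seed)
  truth <- derive_assembly_pair(genome, master_splits, slave_splits,
                                events, seed = seed + 1L)
  reads <- simulate_paired_reads(genome, coverage, read_len, library,
                                 seed = seed + 2L)
  dir <- tempfile("fx"); dir.create(dir)
  mp <- file.path(dir, "master.sam"); sp <- file.path(dir, "slave.sam")
  pm <- attr(project_alignments(reads, "master", truth, mp,
                                mask_intervals = mask_master),
             "placements")
  ps <- attr(project_alignments(reads, "slave", truth, sp,
                                mask_intervals = mask_slave),
             "placements")
  ms <- store_from_placements(pm, names(truth$master$seqs),
                              Biostrings::width(truth$master$seqs),
                              "master")
  ss <- store_from_placements(ps, names(truth$slave$seqs),
                              Biostrings::width(truth$slave$seqs), "slave")
  out <- list(genome = genome, truth = truth, reads = reads,
              master_store = ms, slave_store = ss,
              master_placements = pm, slave_placements = ps,
              library = library, dir = dir,
              master_sam = mp, slave_sam = sp)
  if (write_sam) {
    out$master_fasta <- file.path(dir, "master.fasta")
    out$slave_fasta <- file.path(dir, "slave.fasta")
    Biostrings::writeXStringSet(truth$master$seqs, out$master_fasta,
                                width = 60L)
    Biostrings::writeXStringSet(truth$slave$seqs, out$slave_fasta,
                                width = 60L)
  }
  out
}

fixture_manifest <- function(fx, config = recon_config()) {
  run_manifest(fx$master_fasta, fx$slave_fasta,
               list(pe400 = fx$master_sam), list(pe400 = fx$slave_sam),
               list(fx$library), config, out_dir = file.path(fx$dir, "out"))
}

# Brute-force block oracle: connected components of the "adjacent on both
# assemblies" relation among reads unique in both stores, chained into
# frames; components smaller than B_min are dropped.
oracle_blocks <- function(master_store, slave_store, B_min) {
  m <- master_store$records; s <- slave_store$records
  shared <- intersect(m$read_id, s$read_id)
  if (length(shared) == 0L) return(data.table::data.table())
  mm <- m[match(shared, read_id)]; ss_ <- s[match(shared, read_id)]
  n <- length(shared)
  pairs <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    adj_m <- mm$contig[i] == mm$contig[j] &&
      mm$begin[j] <= mm$end[i] + 1L && mm$begin[i] <= mm$end[j] + 1L
    adj_s <- ss_$contig[i] == ss_$contig[j] &&
      ss_$begin[j] <= ss_$end[i] + 1L && ss_$begin[i] <= ss_$end[j] + 1L
    if (adj_m && adj_s)
      pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(pairs))
    g <- igraph::add_edges(g, unlist(pairs))
  comp <- igraph::components(g)$membership
  res <- list()
  for (cmp in unique(comp)) {
    idx <- which(comp == cmp)
    if (length(idx) < B_min) next
    res[[length(res) + 1L]] <- data.table::data.table(
      m_contig = mm$contig[idx][1L],
      m_begin = min(mm$begin[idx]), m_end = max(mm$end[idx]),
      s_contig = ss_$contig[idx][1L],
      s_begin = min(ss_$begin[idx]), s_end = max(ss_$end[idx]),
      size = length(idx),
      reads = list(sort(shared[idx])))
  }
  if (length(res) == 0L) return(data.table::data.table())
  out <- data.table::rbindlist(res)
  data.table::setorder(out, m_contig, m_begin, s_contig, s_begin)
  out
}

block_key <- function(b) {
  if (nrow(b) == 0L) return(character(0))
  reads <- if ("reads" %in% names(b))
    vapply(b$reads, function(r) paste(sort(r), collapse = "|"), "")
  else ""
  sort(paste(b$m_contig, b$m_begin, b$m_end, b$s_contig, b$s_begin,
             b$s_end, b$size, reads, sep = ":"))
}

# Reachability oracle for strongly connected components (n <= 12).
oracle_scc <- function(n, edges) {
  reach <- diag(TRUE, n)
  for (k in seq_len(nrow(edges)))
    reach[edges$from[k], edges$to[k]] <- TRUE
  for (k in 1:n) for (i in 1:n) if (reach[i, k])
    reach[i, ] <- reach[i, ] | reach[k, ]
  same <- reach & t(reach)
  comp <- integer(n); cur <- 0L
  for (i in 1:n) if (comp[i] == 0L) {
    cur <- cur + 1L
    comp[same[i, ]] <- cur
  }
  comp
}

# Canonical partition signature (labels up to renaming).
partition_key <- function(labels) {
  split(seq_along(labels), labels) |>
    lapply(function(x) paste(x, collapse = ",")) |>
    unlist() |> sort() |> paste(collapse = ";")
}

random_mutate <- function(seq, sub_rate, indel_rate, seed) {
  set.seed(seed)
  v <- strsplit(seq, "")[[1L]]
  n <- length(v)
  nsub <- rbinom(1L, n, sub_rate)
  if (nsub > 0) {
    at <- sample.int(n, nsub)
    v[at] <- vapply(v[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  }
  ndel <- rbinom(1L, n, indel_rate / 2)
  if (ndel > 0) v <- v[-sample.int(length(v), ndel)]
  nins <- rbinom(1L, n, indel_rate / 2)
  for (k in seq_len(nins)) {
    at <- sample.int(length(v), 1L)
    v <- append(v, sample(c("A", "C", "G", "T"), 1L), after = at)
  }
  paste(v, collapse = "")
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A tiling of proper (or wrongly oriented) FR pairs for feature tests.
paired_tile <- function(npairs, contig = 1L, start = 0L, step = 50L,
                        insert = 400L, rl = 100L, wrong = FALSE,
                        prefix = "p") {
  lo <- start + (seq_len(npairs) - 1L) * step
  data.table::data.table(
    read_id = c(rbind(sprintf("%s%03d/1", prefix, seq_len(npairs)),
                      sprintf("%s%03d/2", prefix, seq_len(npairs)))),
    contig = contig,
    begin = c(rbind(lo, lo + insert - rl)),
    end = c(rbind(lo + rl - 1L, lo + insert - 1L)),
    reversed = rep(c(FALSE, !wrong), npairs),
    library_id = "pe400",
    pair_name = rep(sprintf("%s%03d", prefix, seq_len(npairs)), each = 2L),
    mate_no = rep(1:2, npairs))
}
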