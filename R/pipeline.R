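# Pipeline orchestration and the command surface (simulate / blocks /
# merge / stats). exec/asmmerge is a thin Rscript front-end over these.

as_dss <- function(x) {
  if (inherits(x, "DNAStringSet")) x else Biostrings::readDNAStringSet(x)
}

load_stores <- function(files, tag, libraries, reference) {
  lib_ids <- vapply(libraries, `[[`, "", "library_id")
  stores <- lapply(names(files), function(lid) {
    lib <- libraries[[match(lid, lib_ids)]]
    if (is.na(match(lid, lib_ids)))
      stop("no library descriptor for alignment file tagged '", lid, "'")
    load_unique_alignments(files[[lid]], tag, lib, reference = reference)
  })
  merge_stores(stores)
}

#' Run manifest
#'
#' Bundles and validates the inputs of a reconciliation run. Alignment
#' files are given per library (named by `library_id`), one set per
#' assembly.
#'
#' @param master_fasta,slave_fasta Assembly FASTA paths (or `DNAStringSet`).
#' @param master_alignments,slave_alignments Named lists/vectors of SAM/BAM
#'   paths, names = library ids.
#' @param libraries List of [library_descriptor()]s covering every named
#'   library.
#' @param config A [recon_config()].
#' @param out_dir Output directory (created if needed).
#' @return A validated list of class `run_manifest`.
#' @export
run_manifest <- function(master_fasta, slave_fasta, master_alignments,
                         slave_alignments, libraries,
                         config = recon_config(), out_dir = ".") {
  master_alignments <- as.list(master_alignments)
  slave_alignments <- as.list(slave_alignments)
  for (f in c(if (is.character(master_fasta)) master_fasta,
              if (is.character(slave_fasta)) slave_fasta,
              unlist(master_alignments), unlist(slave_alignments)))
    if (!file.exists(f)) stop("input file not found: ", f)
  lib_ids <- vapply(libraries, `[[`, "", "library_id")
  if (anyDuplicated(lib_ids)) stop("duplicate library_id")
  for (nm in c(names(master_alignments), names(slave_alignments)))
    if (!nm %in% lib_ids)
      stop("no library descriptor for alignment file tagged '", nm, "'")
  stopifnot(inherits(config, "recon_config"))
  structure(list(master_fasta = master_fasta, slave_fasta = slave_fasta,
                 master_alignments = master_alignments,
                 slave_alignments = slave_alignments,
                 libraries = libraries, config = config, out_dir = out_dir),
            class = "run_manifest")
}

# Graph construction, resolution and merging on filtered blocks.
run_merge_phase <- function(blocks, master_store, slave_store,
                            master_seq, slave_seq, libraries, config,
                            genome_size = NULL) {
  master_stats <- assembly_stats(master_seq, genome_size)
  if (nrow(blocks) == 0L) {
    return(list(assembly = master_seq,
                provenance = provenance_table(list(), NULL, master_store,
                                              slave_store),
                resolutions = resolutions_table(list(), blocks, master_store,
                                                slave_store),
                paired = list(), paths = list(),
                withheld_master = integer(0),
                merged_master = integer(0),
                master_stats = master_stats,
                merged_stats = master_stats))
  }
  cg <- build_contigs_graph(blocks)
  orders <- assign_block_orders(cg, blocks)
  ag <- build_assemblies_graph(blocks, orders)
  ag <- compute_edge_features(ag, master_store, slave_store, libraries)
  sccs <- find_sccs(ag)
  structures <- detect_structures(ag, sccs)
  resolutions <- resolve_structures(ag, structures, master_store,
                                    slave_store, libraries, config)
  sg <- simplify_graph(ag, resolutions)
  paths <- enumerate_merge_paths(sg)
  paired <- list(); consumed <- integer(0)
  for (p in paths) {
    out <- merge_path(p, blocks, orders, sg, master_seq, slave_seq,
                      master_store, slave_store, libraries, config)
    paired <- c(paired, out)
    consumed <- union(consumed, blocks[block_id %in% p]$m_contig)
  }
  assembly <- emit_assembly(paired, master_seq, consumed)
  list(assembly = assembly,
       provenance = provenance_table(paired, orders, master_store,
                                     slave_store),
       resolutions = resolutions_table(resolutions, blocks, master_store,
                                       slave_store),
       paired = paired, paths = paths,
       withheld_master = sg$withheld_master,
       merged_master = consumed,
       master_stats = master_stats,
       merged_stats = assembly_stats(assembly, genome_size))
}

#' Reconcile two assemblies end to end
#'
#' Loads unique alignments, builds and filters blocks, assigns block
#' orders, resolves graph contradictions with mate-pair evidence and emits
#' the merged assembly.
#'
#' @param manifest A [run_manifest()] (or the same fields as arguments via
#'   `...`).
#' @param genome_size Optional known genome size for NG50.
#' @return A list: `assembly` (named `DNAStringSet`), `provenance`,
#'   `resolutions`, `blocks_built`, `blocks_retained`, `master_stats`,
#'   `merged_stats`, `withheld_master`, `paths`.
#' @export
reconcile_assemblies <- function(manifest, genome_size = NULL) {
  stopifnot(inherits(manifest, "run_manifest"))
  cfg <- manifest$config
  master_seq <- as_dss(manifest$master_fasta)
  slave_seq <- as_dss(manifest$slave_fasta)
  names(master_seq) <- sub("\\s.*$", "", names(master_seq))
  names(slave_seq) <- sub("\\s.*$", "", names(slave_seq))
  ms <- load_stores(manifest$master_alignments, "master",
                    manifest$libraries, master_seq)
  ss <- load_stores(manifest$slave_alignments, "slave",
                    manifest$libraries, slave_seq)
  master_seq <- master_seq[ms$contigs$name]
  slave_seq <- slave_seq[ss$contigs$name]

  blocks <- build_blocks(ms, ss, cfg$B_min)
  built <- nrow(blocks)
  blocks <- filter_blocks_by_coverage(blocks, ms, ss, cfg$T_c)
  after_cov <- nrow(blocks)
  blocks <- filter_blocks_by_length(blocks, ms, ss, cfg$T_l)
  res <- run_merge_phase(blocks, ms, ss, master_seq, slave_seq,
                         manifest$libraries, cfg, genome_size)
  res$blocks_built <- built
  res$blocks_after_coverage <- after_cov
  res$blocks_retained <- nrow(blocks)
  res$blocks <- blocks
  res$config <- cfg
  res
}

fixture_default_libraries <- function(preset) {
  if (preset == "gage-like")
    list(library_descriptor("frag", 180, 18, "fr"),
         library_descriptor("shortjump", 3500, 350, "fr"),
         library_descriptor("longjump", 35000, 3500, "fr"))
  else
    list(library_descriptor("pe400", 400, 40, "fr"))
}

#' Simulate a complete fixture directory
#'
#' Default preset: a 100 kbp genome, master cut into 8 contigs and slave
#' into 7 with complementary (interleaved) gap positions, one 400 +/- 40 bp
#' paired-end library at 30x with 100 bp reads -- the mergeable scenario in
#' which every master gap is spanned by a slave contig. The `gage-like`
#' preset instead emulates a multi-library short-insert / jump structure
#' (180 / 3500 / 35000 bp inserts).
#'
#' @param out_dir Output directory.
#' @param preset `"default"` or `"gage-like"`.
#' @param genome_length,gc Genome size and GC content.
#' @param master_splits,slave_splits 0-based cut positions (`NULL`: preset).
#' @param events List of [engineered_event()]s.
#' @param coverage,read_len Simulated coverage and read length (per
#'   library).
#' @param libraries List of [library_descriptor()]s (`NULL`: preset).
#' @param seed Integer seed; all randomness derives from it.
#' @return Invisibly, a list with all file paths plus the `fixture_truth`.
#' @export
cmd_simulate <- function(out_dir, preset = c("default", "gage-like"),
                         genome_length = 100000L, gc = 0.5,
                         master_splits = NULL, slave_splits = NULL,
                         events = list(), coverage = 30, read_len = 100L,
                         libraries = NULL, seed = 1L) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(libraries)) libraries <- fixture_default_libraries(preset)
  if (is.null(master_splits))
    master_splits <- round(seq_len(7L) * genome_length / 8)
  if (is.null(slave_splits))
    slave_splits <- round((seq_len(6L) - 0.45) * genome_length / 6.55)
  for (ev in events)
    if (!inherits(ev, "engineered_event")) stop("invalid event specification")

  genome <- generate_genome(genome_length, gc = gc, seed = seed)
  truth <- derive_assembly_pair(genome, master_splits, slave_splits,
                                events, seed = seed + 1L)
  paths <- list(
    genome = file.path(out_dir, "genome.fasta"),
    master = file.path(out_dir, "master.fasta"),
    slave = file.path(out_dir, "slave.fasta"),
    truth = file.path(out_dir, "truth.json"))
  gd <- Biostrings::DNAStringSet(genome$seq); names(gd) <- "genome"
  Biostrings::writeXStringSet(gd, paths$genome, width = 60L)
  Biostrings::writeXStringSet(truth$master$seqs, paths$master, width = 60L)
  Biostrings::writeXStringSet(truth$slave$seqs, paths$slave, width = 60L)

  master_alignments <- list(); slave_alignments <- list()
  for (k in seq_along(libraries)) {
    lib <- libraries[[k]]
    reads <- simulate_paired_reads(genome, coverage, read_len, lib,
                                   seed = seed + 10L + k)
    mp <- file.path(out_dir, sprintf("master_%s.sam", lib$library_id))
    sp <- file.path(out_dir, sprintf("slave_%s.sam", lib$library_id))
    project_alignments(reads, "master", truth, mp)
    project_alignments(reads, "slave", truth, sp)
    master_alignments[[lib$library_id]] <- mp
    slave_alignments[[lib$library_id]] <- sp
  }
  jsonlite::write_json(list(
    genome_length = genome_length, gc = gc, seed = seed,
    coverage = coverage, read_len = read_len,
    master_splits = master_splits, slave_splits = slave_splits,
    events = lapply(events, function(e)
      list(kind = e$kind, target = e$target, begin = e$begin, end = e$end)),
    libraries = lapply(libraries, function(l)
      list(library_id = l$library_id, mean_insert = l$mean_insert,
           sd_insert = l$sd_insert, orientation = l$orientation))),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(master_alignments = master_alignments,
                          slave_alignments = slave_alignments,
                          libraries = libraries, truth_obj = truth)))
}

#' Build and filter blocks, writing a blocks TSV
#'
#' Runs alignment loading, streaming block construction and both filters;
#' writes `blocks.tsv` and `blocks_summary.tsv` into the manifest's output
#' directory.
#'
#' @param manifest A [run_manifest()].
#' @return Invisibly, a list with the block counts per stage and the TSV
#'   path.
#' @export
cmd_blocks <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  cfg <- manifest$config
  dir.create(manifest$out_dir, showWarnings = FALSE, recursive = TRUE)
  master_seq <- as_dss(manifest$master_fasta)
  slave_seq <- as_dss(manifest$slave_fasta)
  names(master_seq) <- sub("\\s.*$", "", names(master_seq))
  names(slave_seq) <- sub("\\s.*$", "", names(slave_seq))
  ms <- load_stores(manifest$master_alignments, "master",
                    manifest$libraries, master_seq)
  ss <- load_stores(manifest$slave_alignments, "slave",
                    manifest$libraries, slave_seq)
  blocks <- build_blocks(ms, ss, cfg$B_min)
  built <- nrow(blocks)
  blocks <- filter_blocks_by_coverage(blocks, ms, ss, cfg$T_c)
  after_cov <- nrow(blocks)
  blocks <- filter_blocks_by_length(blocks, ms, ss, cfg$T_l)
  tsv <- file.path(manifest$out_dir, "blocks.tsv")
  write_blocks_tsv(blocks, tsv, ms, ss)
  summary <- data.table::data.table(
    stage = c("built", "after_coverage_filter", "after_length_filter"),
    blocks = c(built, after_cov, nrow(blocks)))
  data.table::fwrite(summary, file.path(manifest$out_dir,
                                        "blocks_summary.tsv"), sep = "\t")
  message(sprintf("blocks: %d built, %d after coverage filter, %d retained",
                  built, after_cov, nrow(blocks)))
  invisible(list(blocks_tsv = tsv, built = built,
                 after_coverage = after_cov, retained = nrow(blocks)))
}

#' Merge two assemblies from a blocks TSV
#'
#' Runs the graph construction, resolution and merging phases and writes
#' `merged.fasta`, `provenance.tsv`, `resolutions.tsv` and `stats.tsv`.
#'
#' @param manifest A [run_manifest()].
#' @param blocks_tsv Path to a blocks TSV (default:
#'   `<out_dir>/blocks.tsv`).
#' @param genome_size Optional known genome size for NG50.
#' @return Invisibly, the result list of [reconcile_assemblies()] plus the
#'   output paths.
#' @export
cmd_merge <- function(manifest, blocks_tsv = NULL, genome_size = NULL) {
  stopifnot(inherits(manifest, "run_manifest"))
  cfg <- manifest$config
  dir.create(manifest$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(blocks_tsv))
    blocks_tsv <- file.path(manifest$out_dir, "blocks.tsv")
  master_seq <- as_dss(manifest$master_fasta)
  slave_seq <- as_dss(manifest$slave_fasta)
  names(master_seq) <- sub("\\s.*$", "", names(master_seq))
  names(slave_seq) <- sub("\\s.*$", "", names(slave_seq))
  ms <- load_stores(manifest$master_alignments, "master",
                    manifest$libraries, master_seq)
  ss <- load_stores(manifest$slave_alignments, "slave",
                    manifest$libraries, slave_seq)
  master_seq <- master_seq[ms$contigs$name]
  slave_seq <- slave_seq[ss$contigs$name]
  blocks <- read_blocks_tsv(blocks_tsv, ms, ss)
  res <- run_merge_phase(blocks, ms, ss, master_seq, slave_seq,
                         manifest$libraries, cfg, genome_size)
  out_fa <- file.path(manifest$out_dir, "merged.fasta")
  Biostrings::writeXStringSet(res$assembly, out_fa, width = 60L)
  data.table::fwrite(res$provenance,
                     file.path(manifest$out_dir, "provenance.tsv"),
                     sep = "\t")
  data.table::fwrite(res$resolutions,
                     file.path(manifest$out_dir, "resolutions.tsv"),
                     sep = "\t")
  st <- data.table::data.table(
    assembly = c("master", "merged"),
    contigs = c(res$master_stats$count, res$merged_stats$count),
    total_length = c(res$master_stats$total_length,
                     res$merged_stats$total_length),
    n50 = c(res$master_stats$n50, res$merged_stats$n50),
    ng50 = c(res$master_stats$ng50, res$merged_stats$ng50))
  data.table::fwrite(st, file.path(manifest$out_dir, "stats.tsv"),
                     sep = "\t")
  message(sprintf("merged: %d contigs (master %d), N50 %s (master %s)",
                  res$merged_stats$count, res$master_stats$count,
                  format(res$merged_stats$n50), format(res$master_stats$n50)))
  res$merged_fasta <- out_fa
  invisible(res)
}
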