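# Synthetic fixtures: genome -> divergent assembly pair with engineered
# events -> simulated read pairs -> idealized alignments. Gives every
# pipeline stage exact ground truth without external data.
#
# Assemblies are represented as piecewise genome maps: each contig is an
# ordered list of genome intervals with strand; events edit the piece lists.
# Idealized alignment places a read by inverting this map, so coordinates
# are exact; reads crossing a piece boundary on an assembly are emitted as
# unmapped there, and reads wholly inside a perfect repeat copy are emitted
# with mapping quality 0 (ambiguous) and excluded downstream.

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Generate a reproducible random genome
#'
#' @param length Genome length in bp (> 0).
#' @param gc GC fraction.
#' @param repeats `NULL`, or a list `(count, length, divergence)` of planted
#'   repeat copies; each extra copy is pasted over a random non-overlapping
#'   location and both copies recorded. `divergence` is the substitution
#'   fraction between copies (0 = perfect repeat, ambiguous to align).
#' @param seed Integer seed (full determinism).
#' @return Object of class `synthetic_genome`: list with `seq` (character),
#'   `length`, `gc`, `repeats` (data.table `family`, `copy`, `begin`, `end`,
#'   `divergence`; 0-based inclusive).
#' @export
generate_genome <- function(length, gc = 0.5, repeats = NULL, seed = 1L) {
  stopifnot(length > 0)
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- sample(names(p), length, replace = TRUE, prob = p)
  rep_tab <- data.table::data.table(family = integer(), copy = integer(),
                                    begin = integer(), end = integer(),
                                    divergence = numeric())
  if (!is.null(repeats)) {
    count <- repeats$count; rlen <- repeats$length
    div <- if (is.null(repeats$divergence)) 0 else repeats$divergence
    if (count * rlen * 2 > length)
      stop("planted repeats exceed the genome length")
    taken <- integer(0)
    pick_free <- function() {
      for (try in 1:200) {
        s <- sample.int(length - rlen + 1L, 1L) - 1L
        if (!any(taken %in% s:(s + rlen - 1L))) return(s)
      }
      stop("could not place repeat copies without overlap")
    }
    for (f in seq_len(count)) {
      src <- pick_free(); taken <- c(taken, src:(src + rlen - 1L))
      dst <- pick_free(); taken <- c(taken, dst:(dst + rlen - 1L))
      unit <- seq[(src + 1L):(src + rlen)]
      if (div > 0) {
        nmut <- round(div * rlen)
        at <- sample.int(rlen, nmut)
        unit[at] <- vapply(unit[at], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      }
      seq[(dst + 1L):(dst + rlen)] <- unit
      rep_tab <- rbind(rep_tab, data.table::data.table(
        family = f, copy = 1:2, begin = c(src, dst),
        end = c(src, dst) + rlen - 1L, divergence = div))
    }
  }
  structure(list(seq = paste(seq, collapse = ""), length = as.integer(length),
                 gc = gc, repeats = rep_tab, seed = as.integer(seed)),
            class = "synthetic_genome")
}

#' Specify an engineered assembly event
#'
#' @param kind One of `inversion`, `relocation_misjoin`,
#'   `deletion_compression`, `gap_split`, `heterozygous_site_cluster`.
#' @param target `"master"` or `"slave"`.
#' @param begin,end 0-based inclusive genome interval of the event
#'   (`gap_split` uses only `begin` as the cut position).
#' @param rate Substitution rate for `heterozygous_site_cluster`.
#' @return A list of class `engineered_event`.
#' @export
engineered_event <- function(kind = c("inversion", "relocation_misjoin",
                                      "deletion_compression", "gap_split",
                                      "heterozygous_site_cluster"),
                             target = c("master", "slave"),
                             begin, end = begin, rate = 0.05) {
  kind <- match.arg(kind); target <- match.arg(target)
  stopifnot(begin >= 0, end >= begin)
  structure(list(kind = kind, target = target, begin = as.integer(begin),
                 end = as.integer(end), rate = rate),
            class = "engineered_event")
}

# pieces: data.table(contig, g_from, g_to, strand); contig coordinate of a
# piece is the cumulative length of earlier pieces of the same contig.
pieces_from_splits <- function(glen, splits) {
  splits <- sort(unique(as.integer(splits)))
  splits <- splits[splits > 0L & splits < glen]
  starts <- c(0L, splits)
  ends <- c(splits - 1L, glen - 1L)
  data.table::data.table(contig = seq_along(starts), g_from = starts,
                         g_to = ends, strand = "+")
}

split_piece_at <- function(p, gpos) {
  # split the piece row covering genome position gpos so that a piece
  # boundary falls immediately before gpos; forward pieces only
  i <- which(p$g_from <= gpos & p$g_to >= gpos)
  if (length(i) != 1L) stop("event interval crosses a contig boundary")
  if (p$strand[i] != "+")
    stop("overlapping events are not supported")
  if (p$g_from[i] == gpos) return(p)
  top <- p[seq_len(i - 1L)]
  mid <- data.table::data.table(contig = p$contig[i],
                                g_from = c(p$g_from[i], gpos),
                                g_to = c(gpos - 1L, p$g_to[i]),
                                strand = "+")
  bot <- if (i < nrow(p)) p[(i + 1L):nrow(p)] else p[0L]
  rbind(top, mid, bot)
}

apply_event_to_pieces <- function(p, ev, glen) {
  if (ev$kind == "gap_split") {
    p <- split_piece_at(p, ev$begin)
    # the pieces of the cut contig from the cut onward become a new contig
    j <- which(p$g_from == ev$begin & p$strand == "+")
    if (length(j) != 1L) stop("gap_split position not resolvable")
    rows_ctg <- which(p$contig == p$contig[j])
    p$contig[rows_ctg[rows_ctg >= j]] <- max(p$contig) + 1L
    return(p)
  }
  if (ev$kind == "heterozygous_site_cluster") return(p)  # sequence-only
  p <- split_piece_at(p, ev$begin)
  if (ev$end + 1L < glen) p <- split_piece_at(p, ev$end + 1L)
  sel <- which(p$g_from >= ev$begin & p$g_to <= ev$end)
  if (length(sel) == 0L || length(unique(p$contig[sel])) != 1L ||
      any(diff(sel) != 1L))
    stop("event interval is not contiguous within one contig")
  if (ev$kind == "inversion") {
    inv <- p[rev(sel)]
    inv[, strand := ifelse(strand == "+", "-", "+")]
    p <- rbind(p[seq_len(min(sel) - 1L)], inv,
               if (max(sel) < nrow(p)) p[(max(sel) + 1L):nrow(p)] else p[0L])
  } else if (ev$kind == "deletion_compression") {
    p <- p[-sel]
  } else if (ev$kind == "relocation_misjoin") {
    # the interval is excised to a new contig; its flanks are joined into a
    # mis-join junction on the original contig
    moved <- p[sel]
    moved[, contig := max(p$contig) + 1L]
    p <- rbind(p[-sel], moved)
  }
  p
}

finalize_pieces <- function(p) {
  # renumber contigs densely in order of first genome coordinate, attach
  # contig-local offsets
  data.table::setorder(p, contig)
  first <- p[, .(fg = g_from[1L]), by = contig]
  data.table::setorder(first, fg)
  remap <- setNames(seq_len(nrow(first)), first$contig)
  p[, contig := remap[as.character(contig)]]
  data.table::setorder(p, contig)
  p[, len := g_to - g_from + 1L]
  p[, c_from := cumsum(data.table::shift(len, fill = 0L)), by = contig]
  p[]
}

assembly_sequences <- function(p, genome_chr, prefix) {
  ctgs <- sort(unique(p$contig))
  seqs <- vapply(ctgs, function(ct) {
    rows <- p[contig == ct]
    paste(vapply(seq_len(nrow(rows)), function(k) {
      s <- substr(genome_chr, rows$g_from[k] + 1L, rows$g_to[k] + 1L)
      if (rows$strand[k] == "-") revcomp_chr(s) else s
    }, ""), collapse = "")
  }, "")
  names(seqs) <- sprintf("%s_%03d", prefix, ctgs)
  Biostrings::DNAStringSet(seqs)
}

#' Derive a master/slave assembly pair from a genome
#'
#' Both assemblies are the genome cut at the given split positions, with
#' engineered events applied to their target assembly. Complementary split
#' sets create master gaps that the slave bridges (the mergeable scenario);
#' events introduce the error classes the merger must detect.
#'
#' @param genome A `synthetic_genome` (or character sequence).
#' @param master_splits,slave_splits Sorted 0-based cut positions (a contig
#'   starts at each cut).
#' @param events List of [engineered_event()]s; events must not overlap.
#' @param seed Seed for the substitutions of heterozygous clusters.
#' @return Object of class `fixture_truth`: list with `genome`,
#'   `master`/`slave` (each: `seqs` DNAStringSet, `pieces`, `subs`),
#'   `events`, `repeats`.
#' @export
derive_assembly_pair <- function(genome, master_splits, slave_splits,
                                 events = list(), seed = 1L) {
  g <- if (inherits(genome, "synthetic_genome")) genome
       else structure(list(seq = as.character(genome),
                           length = nchar(genome),
                           repeats = data.table::data.table(
                             family = integer(), copy = integer(),
                             begin = integer(), end = integer(),
                             divergence = numeric())),
                      class = "synthetic_genome")
  if (length(events) >= 2L) {
    iv <- data.table::rbindlist(lapply(events, function(e)
      data.table::data.table(begin = e$begin, end = e$end)))
    data.table::setorder(iv, begin)
    if (any(iv$begin[-1L] <= iv$end[-nrow(iv)]))
      stop("engineered events overlap")
  }
  set.seed(seed)
  sides <- list(master = pieces_from_splits(g$length, master_splits),
                slave = pieces_from_splits(g$length, slave_splits))
  subs <- list(master = data.table::data.table(pos = integer(),
                                               base = character()),
               slave = data.table::data.table(pos = integer(),
                                              base = character()))
  for (ev in events) {
    if (ev$kind == "heterozygous_site_cluster") {
      n <- max(1L, round(ev$rate * (ev$end - ev$begin + 1L)))
      at <- sort(sample(ev$begin:ev$end, n))
      old <- strsplit(substr(g$seq, ev$begin + 1L, ev$end + 1L),
                      "")[[1L]][at - ev$begin + 1L]
      new <- vapply(old, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      subs[[ev$target]] <- rbind(subs[[ev$target]],
                                 data.table::data.table(pos = at, base = new))
    }
    sides[[ev$target]] <- apply_event_to_pieces(sides[[ev$target]], ev,
                                                g$length)
  }
  build <- function(side, prefix) {
    p <- finalize_pieces(data.table::copy(sides[[side]]))
    gseq <- g$seq
    if (nrow(subs[[side]])) {
      v <- strsplit(gseq, "")[[1L]]
      v[subs[[side]]$pos + 1L] <- subs[[side]]$base
      gseq <- paste(v, collapse = "")
    }
    list(seqs = assembly_sequences(p, gseq, prefix), pieces = p,
         subs = subs[[side]])
  }
  structure(list(genome = g,
                 master = build("master", "mctg"),
                 slave = build("slave", "sctg"),
                 events = events),
            class = "fixture_truth")
}

#' Simulate paired reads from a genome
#'
#' Insert lengths are normal `(m, sd)` truncated below at `read_len`; start
#' positions uniform; orientations per the library convention; pair count =
#' `coverage * genome_length / (2 * read_len)`.
#'
#' @param genome `synthetic_genome` or character.
#' @param coverage Fold coverage.
#' @param read_len Read length in bp (< mean insert).
#' @param library A [library_descriptor()].
#' @param seed Integer seed.
#' @return data.table, one row per read (two per pair): `pair_id`,
#'   `mate_no`, `g_begin`, `g_end` (0-based genome coords), `g_rev`,
#'   `library_id`, `insert`.
#' @export
simulate_paired_reads <- function(genome, coverage, read_len, library,
                                  seed = 1L) {
  g <- if (inherits(genome, "synthetic_genome")) genome$length
       else nchar(genome)
  stopifnot(read_len < library$mean_insert)
  set.seed(seed)
  n <- round(coverage * g / (2 * read_len))
  ins <- pmax(round(rnorm(n, library$mean_insert, library$sd_insert)),
              read_len)
  ins <- pmin(ins, g)
  start <- floor(runif(n, 0, g - ins + 1))
  fr <- library$orientation == "fr"
  ids <- sprintf("%s_%07d", library$library_id, seq_len(n))
  data.table::data.table(
    pair_id = rep(ids, each = 2L),
    mate_no = rep(1:2, n),
    g_begin = as.integer(rbind(start, start + ins - read_len)),
    g_end = as.integer(rbind(start + read_len - 1L, start + ins - 1L)),
    g_rev = rep(c(!fr, fr), n),
    library_id = library$library_id,
    insert = rep(as.integer(ins), each = 2L))
}

# genome interval -> (contig, begin, end, reversed) on one assembly, or NULL
# when the read crosses a piece boundary (unmapped on that assembly).
project_interval <- function(pieces, g_begin, g_end) {
  i <- which(pieces$g_from <= g_begin & pieces$g_to >= g_end)
  if (length(i) != 1L) return(NULL)
  pc <- pieces[i]
  if (pc$strand == "+") {
    list(contig = pc$contig, begin = pc$c_from + (g_begin - pc$g_from),
         end = pc$c_from + (g_end - pc$g_from), flip = FALSE)
  } else {
    list(contig = pc$contig, begin = pc$c_from + (pc$g_to - g_end),
         end = pc$c_from + (pc$g_to - g_begin), flip = TRUE)
  }
}

#' Project simulated reads onto one assembly as an idealized SAM
#'
#' Each read is placed by inverting the assembly's genome coordinate map
#' (exact, error-free placement). Reads wholly inside a perfect
#' (zero-divergence) repeat copy get mapping quality 0 -- the multi-mapping
#' marker the loader excludes. Reads straddling an event breakpoint or
#' contig end on this assembly are emitted as unmapped records. The SAM is
#' coordinate-sorted with a proper header.
#'
#' @param reads data.table from [simulate_paired_reads()].
#' @param assembly_tag `"master"` or `"slave"`.
#' @param truth A `fixture_truth`.
#' @param path Output SAM path.
#' @param mask_intervals Optional list of 0-based genome intervals
#'   `c(begin, end)`; reads overlapping any of them are emitted unmapped on
#'   this assembly (emulates locally unalignable regions, e.g. low-quality
#'   contig ends).
#' @return `path`, invisibly; attributes carry the per-read placement table.
#' @export
project_alignments <- function(reads, assembly_tag = c("master", "slave"),
                               truth, path, mask_intervals = NULL) {
  assembly_tag <- match.arg(assembly_tag)
  asm <- truth[[assembly_tag]]
  p <- asm$pieces
  reps <- truth$genome$repeats
  perfect <- reps[divergence == 0]

  n <- nrow(reads)
  contig <- rep(1L, n); begin <- integer(n); end <- integer(n)
  rev_ <- logical(n); mapped <- logical(n); ambiguous <- logical(n)
  masked <- rep(FALSE, n)
  for (iv in mask_intervals)
    masked <- masked | (reads$g_begin <= iv[2L] & reads$g_end >= iv[1L])
  for (k in seq_len(n)) {
    if (masked[k]) { mapped[k] <- FALSE; next }
    pr <- project_interval(p, reads$g_begin[k], reads$g_end[k])
    if (is.null(pr)) { mapped[k] <- FALSE; next }
    mapped[k] <- TRUE
    contig[k] <- pr$contig; begin[k] <- pr$begin; end[k] <- pr$end
    rev_[k] <- xor(reads$g_rev[k], pr$flip)
    if (nrow(perfect))
      ambiguous[k] <- any(perfect$begin <= reads$g_begin[k] &
                            perfect$end >= reads$g_end[k])
  }
  rl <- reads$g_end - reads$g_begin + 1L
  placements <- data.table::data.table(
    read_id = paste0(reads$pair_id, "/", reads$mate_no),
    pair_id = reads$pair_id, mate_no = reads$mate_no,
    mapped = mapped, ambiguous = ambiguous,
    contig = contig, begin = begin, end = end, reversed = rev_,
    read_len = rl, library_id = reads$library_id)

  ctg_names <- names(asm$seqs)
  ctg_len <- Biostrings::width(asm$seqs)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", ctg_names, ctg_len))
  flag <- 0x1L +
    ifelse(placements$mate_no == 1L, 0x40L, 0x80L) +
    ifelse(placements$mapped & placements$reversed, 0x10L, 0L) +
    ifelse(!placements$mapped, 0x4L, 0L)
  mate_idx <- ifelse(placements$mate_no == 1L, seq_len(n) + 1L,
                     seq_len(n) - 1L)
  flag <- flag + ifelse(!placements$mapped[mate_idx], 0x8L, 0L) +
    ifelse(placements$mapped[mate_idx] & placements$reversed[mate_idx],
           0x20L, 0L)
  mapq <- ifelse(placements$ambiguous, 0L, 60L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                   placements$read_id, flag,
                   ifelse(placements$mapped, ctg_names[placements$contig],
                          "*"),
                   ifelse(placements$mapped, placements$begin + 1L, 0L),
                   ifelse(placements$mapped, mapq, 0L),
                   ifelse(placements$mapped,
                          paste0(placements$read_len, "M"), "*"))
  o <- order(!placements$mapped, placements$contig, placements$begin)
  writeLines(c(hdr, lines[o]), path)
  attr(path, "placements") <- placements
  invisible(path)
}
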