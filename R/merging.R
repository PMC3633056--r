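# Merging: walk maximal disjoint paths of the simplified assemblies graph,
# validate junctions by banded semi-global alignment, choose block sequences
# by the CE insert-size statistic, and emit paired contigs.
#
# All walk coordinates are "view" coordinates: native contig coordinates,
# mirrored when the order assignment flipped the contig, so that every path
# progresses left to right.

#' Banded semi-global alignment
#'
#' Ends-free dynamic-programming alignment (leading/trailing gaps on either
#' sequence are free) restricted to a diagonal band of half-width
#' `abs(nchar(a) - nchar(b)) + band_pad`. Scores: match +1, mismatch -1,
#' gap -1 (linear). Identity is matches over aligned columns, internal gap
#' columns included. If no end-to-end path fits the band it is widened once;
#' a second failure reports `identity = 0` and `failed = TRUE`.
#'
#' @param a,b Sequences (character strings or `DNAString`), non-empty.
#' @param band_pad Extra band half-width in bp.
#' @return List: `score`, `identity`, `matches`, `columns`, aligned begin/end
#'   coordinates (1-based) on both sequences, `widened`, `failed`.
#' @export
banded_semiglobal_align <- function(a, b, band_pad = 64L) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  .sg_align_banded(a, b, as.integer(band_pad))
}

#' CE insert-size statistic over an interval
#'
#' Over read pairs with both mates uniquely placed on the contig and the
#' leftmost mate beginning inside the interval, the observed insert is the
#' outer distance (rightmost end - leftmost begin + 1) and
#' `z = (mean_observed - m) / (sd / sqrt(k))` with `k` the number of
#' inserts. Negative z indicates local compression (e.g. a deletion in the
#' sequence), positive z expansion. `k = 0` yields the sentinel `z = 0`.
#'
#' @param store A `read_store`.
#' @param contig Contig id (integer index into the store's contig table).
#' @param interval Numeric length-2: 0-based inclusive `[begin, end]`.
#' @param library A [library_descriptor()].
#' @return List with `z`, `k`, `library_id`.
#' @export
ce_statistic <- function(store, contig, interval, library) {
  p <- store_pairs(store)
  ctg <- contig
  p <- p[contig == ctg & lo_begin >= interval[1L] & lo_begin <= interval[2L] &
           library_id == library$library_id]
  k <- nrow(p)
  if (k == 0L)
    return(list(z = 0, k = 0L, library_id = library$library_id))
  sd_eff <- max(library$sd_insert, 1e-9)
  z <- (mean(p$insert) - library$mean_insert) / (sd_eff / sqrt(k))
  list(z = z, k = k, library_id = library$library_id)
}

#' Choose the frame of a block by CE statistic
#'
#' Per library, `|z|` is computed on the master and the slave frame; the
#' frame minimizing the worst (largest) `|z|` across libraries is chosen.
#' Ties -- including the no-evidence case -- go to the master frame.
#'
#' @param block One block row.
#' @param master_store,slave_store Read stores.
#' @param libraries List of [library_descriptor()]s.
#' @return `"master_frame"` or `"slave_frame"`.
#' @export
choose_frame_by_ce <- function(block, master_store, slave_store, libraries) {
  zm <- 0; zs <- 0
  for (lib in libraries) {
    zm <- max(zm, abs(ce_statistic(master_store, block$m_contig,
                                   c(block$m_begin, block$m_end), lib)$z))
    zs <- max(zs, abs(ce_statistic(slave_store, block$s_contig,
                                   c(block$s_begin, block$s_end), lib)$z))
  }
  if (zs < zm) "slave_frame" else "master_frame"
}

#' Enumerate maximal disjoint paths of the simplified graph
#'
#' @param sg Output of [simplify_graph()].
#' @return List of integer vectors of block ids; every surviving node is in
#'   exactly one maximal path.
#' @export
enumerate_merge_paths <- function(sg) {
  nodes <- sg$nodes
  if (length(nodes) == 0L) return(list())
  eu <- unique(sg$edges[, .(from, to)])
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(eu$from), to = as.character(eu$to)),
    directed = TRUE, vertices = data.frame(name = as.character(nodes)))
  memb <- igraph::components(g, mode = "weak")$membership
  succ <- setNames(eu$to, as.character(eu$from))
  has_pred <- unique(eu$to)
  paths <- list()
  for (cmp in sort(unique(memb))) {
    members <- as.integer(names(memb)[memb == cmp])
    start <- setdiff(members, has_pred)
    if (length(start) != 1L)
      stop("internal error: simplified component is not a simple path")
    p <- start; v <- start
    while (!is.na(succ[as.character(v)])) {
      v <- as.integer(succ[as.character(v)])
      p <- c(p, v)
    }
    if (length(p) != length(members))
      stop("internal error: simplified component is not a simple path")
    paths[[length(paths) + 1L]] <- p
  }
  paths[order(vapply(paths, `[[`, 0L, 1L))]
}

# --- the merge walk -------------------------------------------------------

view_frame <- function(f, L, flipped) {
  if (flipped) list(contig = f$contig, begin = L - 1L - f$end,
                    end = L - 1L - f$begin)
  else f
}

#' Merge one block path into paired contigs
#'
#' Walks the path left to right: inter-block regions come from the
#' connecting contig (master when both assemblies connect the blocks);
#' master gaps bridged by a slave contig are closed only when semi-global
#' alignments at both flanks reach `min_identity`; within a block the
#' CE-chosen (or resolution-forced) frame is emitted verbatim -- no base
#' consensus; contig ends are extended with slave sequence only when the
#' slave is longer there and the flank aligns. A failed junction splits the
#' output and the affected regions fall back to master sequence.
#'
#' @param path Integer vector of block ids from [enumerate_merge_paths()].
#' @param blocks Block table.
#' @param orders `block_orders`.
#' @param sg Output of [simplify_graph()].
#' @param master_seq,slave_seq `DNAStringSet` in contig-table order.
#' @param master_store,slave_store Read stores.
#' @param libraries List of [library_descriptor()]s.
#' @param config A [recon_config()].
#' @return List of paired contigs, each a list with `sequence` (character)
#'   and `pieces` (data.table `side`, `contig`, `vbegin`, `vend`, `reason`,
#'   `flipped`).
#' @export
merge_path <- function(path, blocks, orders, sg, master_seq, slave_seq,
                       master_store, slave_store, libraries, config) {
  Lm <- function(ctg) contig_length(master_store, ctg)
  Ls <- function(ctg) contig_length(slave_store, ctg)
  vframe <- function(bid, side) {
    f <- block_frame(blocks, bid, side)
    L <- if (side == "M") Lm(f$contig) else Ls(f$contig)
    view_frame(f, L, is_flipped(orders, side, f$contig))
  }
  seqv <- function(side, ctg, from, to) {
    if (to < from) return("")
    L <- if (side == "M") Lm(ctg) else Ls(ctg)
    from <- max(0L, from); to <- min(L - 1L, to)
    if (to < from) return("")
    x <- if (side == "M") master_seq[[ctg]] else slave_seq[[ctg]]
    flipped <- is_flipped(orders, side, ctg)
    if (flipped) {
      s <- Biostrings::subseq(x, L - to, L - from)       # 1-based native
      as.character(Biostrings::reverseComplement(s))
    } else {
      as.character(Biostrings::subseq(x, from + 1L, to + 1L))
    }
  }
  brk <- sg$breaks
  broken <- function(bid, side_, where_)
    nrow(brk[block == bid & side == side_ & where == where_]) > 0L
  flank_ok <- function(a, b) {
    if (nchar(a) == 0L || nchar(b) == 0L) return(TRUE)  # nothing to contradict
    r <- banded_semiglobal_align(a, b, config$band_pad)
    !isTRUE(r$failed) && r$identity >= config$min_identity
  }
  chosen_side <- function(bid) {
    forced <- sg$forced_choice[as.character(bid)]
    if (!is.na(forced)) return(unname(forced))
    b <- blocks[block_id == bid]
    if (choose_frame_by_ce(b, master_store, slave_store,
                           libraries) == "slave_frame") "S" else "M"
  }

  outputs <- list()
  pieces <- list()
  emit <- function(side, ctg, from, to, reason) {
    if (to >= from)
      pieces[[length(pieces) + 1L]] <<- data.table::data.table(
        side = side, contig = ctg, vbegin = as.integer(from),
        vend = as.integer(to), reason = reason)
  }
  close_out <- function() {
    if (length(pieces)) {
      pc <- data.table::rbindlist(pieces)
      seq <- paste0(vapply(seq_len(nrow(pc)), function(k)
        seqv(pc$side[k], pc$contig[k], pc$vbegin[k], pc$vend[k]), ""),
        collapse = "")
      outputs[[length(outputs) + 1L]] <<- list(sequence = seq, pieces = pc)
    }
    pieces <<- list()
  }

  b1 <- path[1L]
  fm <- vframe(b1, "M"); fs <- vframe(b1, "S")
  mhead <- if (broken(b1, "M", "before")) 0L else fm$begin
  shead <- if (broken(b1, "S", "before")) 0L else fs$begin
  use_slave_head <- FALSE
  if (shead > mhead) {
    w <- min(config$flank_len, mhead)
    use_slave_head <- flank_ok(
      seqv("M", fm$contig, fm$begin - w, fm$begin - 1L),
      seqv("S", fs$contig, fs$begin - w, fs$begin - 1L))
  }
  if (use_slave_head) emit("S", fs$contig, 0L, fs$begin - 1L, "extension")
  else emit("M", fm$contig, fm$begin - mhead, fm$begin - 1L, "master_only")
  cur_m <- fm$begin; cur_s <- fs$begin

  for (i in seq_along(path)) {
    bid <- path[i]
    fm <- vframe(bid, "M"); fs <- vframe(bid, "S")
    side <- chosen_side(bid)
    if (side == "M")
      emit("M", fm$contig, max(fm$begin, cur_m), fm$end, "ce_master")
    else
      emit("S", fs$contig, max(fs$begin, cur_s), fs$end, "ce_slave")
    cur_m <- max(cur_m, fm$end + 1L)
    cur_s <- max(cur_s, fs$end + 1L)

    if (i == length(path)) break
    nxt <- path[i + 1L]
    fm2 <- vframe(nxt, "M"); fs2 <- vframe(nxt, "S")
    er <- sg$edges[from == bid & to == nxt]
    has_m <- "M" %in% er$side; has_s <- "S" %in% er$side
    if (has_m) {
      emit("M", fm2$contig, cur_m, fm2$begin - 1L, "master_only")
      cur_m <- max(cur_m, fm2$begin)
      cur_s <- fs2$begin
    } else if (has_s && fm2$contig == fm$contig) {
      # same master contig, succession supported only by the slave order
      # (local reordering, e.g. a resolved inversion): fill from the slave
      emit("S", fs2$contig, cur_s, fs2$begin - 1L, "slave_fill")
      cur_s <- max(cur_s, fs2$begin)
      cur_m <- fm2$begin
    } else if (has_s) {
      # master gap bridged by the slave contig: validate both flanks
      mtail <- if (broken(bid, "M", "after")) 0L
               else Lm(fm$contig) - cur_m
      mhead2 <- if (broken(nxt, "M", "before")) 0L else fm2$begin
      w1 <- min(config$flank_len, mtail)
      w2 <- min(config$flank_len, mhead2)
      ok1 <- flank_ok(seqv("M", fm$contig, cur_m, cur_m + w1 - 1L),
                      seqv("S", fs$contig, cur_s, cur_s + w1 - 1L))
      ok2 <- flank_ok(seqv("M", fm2$contig, fm2$begin - w2, fm2$begin - 1L),
                      seqv("S", fs2$contig, fs2$begin - w2, fs2$begin - 1L))
      if (ok1 && ok2) {
        emit("S", fs2$contig, cur_s, fs2$begin - 1L, "slave_fill")
        cur_s <- max(cur_s, fs2$begin)
        cur_m <- fm2$begin
      } else {
        emit("M", fm$contig, cur_m, cur_m + mtail - 1L, "master_only")
        close_out()
        emit("M", fm2$contig, fm2$begin - mhead2, fm2$begin - 1L,
             "master_only")
        cur_m <- fm2$begin
        cur_s <- fs2$begin
      }
    } else {
      stop("internal error: consecutive path blocks without an edge")
    }
  }

  # trailing end, with optional slave extension
  lastb <- path[length(path)]
  fm <- vframe(lastb, "M"); fs <- vframe(lastb, "S")
  mtail <- if (broken(lastb, "M", "after")) 0L else Lm(fm$contig) - cur_m
  stail <- if (broken(lastb, "S", "after")) 0L else Ls(fs$contig) - cur_s
  use_slave_tail <- FALSE
  if (stail > mtail) {
    w <- min(config$flank_len, mtail)
    use_slave_tail <- flank_ok(seqv("M", fm$contig, cur_m, cur_m + w - 1L),
                               seqv("S", fs$contig, cur_s, cur_s + w - 1L))
  }
  if (use_slave_tail)
    emit("S", fs$contig, cur_s, Ls(fs$contig) - 1L, "extension")
  else
    emit("M", fm$contig, cur_m, cur_m + mtail - 1L, "master_only")
  close_out()
  outputs
}

#' Emit the final assembly
#'
#' Output = paired contigs (named `pctg0001`, `pctg0002`, ...) plus every
#' master contig not involved in any merge, verbatim under its original
#' name. With no blocks at all the output is the master assembly.
#'
#' @param paired List of paired contigs (from [merge_path()] over all
#'   paths).
#' @param master_seq Named `DNAStringSet` of all master contigs.
#' @param merged_master Integer ids (contig-table indices) of master contigs
#'   consumed by merges.
#' @return A named `DNAStringSet`.
#' @export
emit_assembly <- function(paired, master_seq, merged_master) {
  out <- character(0)
  nms <- character(0)
  for (i in seq_along(paired)) {
    out <- c(out, paired[[i]]$sequence)
    nms <- c(nms, sprintf("pctg%04d", i))
  }
  keep <- setdiff(seq_along(master_seq), merged_master)
  if (length(keep)) {
    out <- c(out, as.character(master_seq[keep]))
    nms <- c(nms, names(master_seq)[keep])
  }
  if (anyDuplicated(nms))
    stop("duplicate output contig name: ", nms[duplicated(nms)][1L])
  res <- Biostrings::DNAStringSet(out)
  names(res) <- nms
  res
}

# Provenance rows (native coordinates and strand) for the paired contigs.
provenance_table <- function(paired, orders, master_store, slave_store) {
  rows <- list()
  for (i in seq_along(paired)) {
    pc <- paired[[i]]$pieces
    off <- 0L
    for (k in seq_len(nrow(pc))) {
      side <- pc$side[k]; ctg <- pc$contig[k]
      L <- if (side == "M") contig_length(master_store, ctg)
           else contig_length(slave_store, ctg)
      flipped <- is_flipped(orders, side, ctg)
      len <- pc$vend[k] - pc$vbegin[k] + 1L
      nb <- if (flipped) L - 1L - pc$vend[k] else pc$vbegin[k]
      ne <- if (flipped) L - 1L - pc$vbegin[k] else pc$vend[k]
      rows[[length(rows) + 1L]] <- data.table::data.table(
        paired_contig = sprintf("pctg%04d", i), offset = off, length = len,
        assembly = ifelse(side == "M", "master", "slave"),
        contig = if (side == "M") contig_name(master_store, ctg)
                 else contig_name(slave_store, ctg),
        source_begin = nb, source_end = ne,
        strand = ifelse(flipped, "-", "+"), reason = pc$reason[k])
      off <- off + len
    }
  }
  if (length(rows)) data.table::rbindlist(rows)
  else data.table::data.table(paired_contig = character(), offset = integer(),
                              length = integer(), assembly = character(),
                              contig = character(), source_begin = integer(),
                              source_end = integer(), strand = character(),
                              reason = character())
}

#' Assembly contiguity statistics
#'
#' N50: the length L such that contigs of length >= L cover half the
#' assembly; NG50: same with half the (known) genome size. Only contigs
#' longer than `min_len` bp are counted.
#'
#' @param contigs A `DNAStringSet`, or a numeric vector of contig lengths.
#' @param genome_size Known genome size in bp for NG50 (`NULL` to skip).
#' @param min_len Minimum contig length counted (default 200 bp).
#' @return List: `count`, `total_length`, `n50`, `ng50` (NA when the
#'   counted contigs do not reach half the genome size).
#' @export
assembly_stats <- function(contigs, genome_size = NULL, min_len = 200L) {
  len <- if (is.numeric(contigs)) as.numeric(contigs)
         else as.numeric(Biostrings::width(contigs))
  len <- sort(len[len > min_len], decreasing = TRUE)
  total <- sum(len)
  nX <- function(target) {
    if (length(len) == 0L || total == 0) return(NA_real_)
    i <- which(cumsum(len) >= target)
    if (length(i) == 0L) NA_real_ else len[i[1L]]
  }
  list(count = length(len), total_length = total,
       n50 = nX(total / 2),
       ng50 = if (is.null(genome_size)) NA_real_
              else {
                i <- which(cumsum(len) >= genome_size / 2)
                if (length(i) == 0L) NA_real_ else len[i[1L]]
              })
}
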