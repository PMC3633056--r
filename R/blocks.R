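# Blocks: maximal runs of reads co-assembled by both assemblies. A block is
# a pair of frames (one interval per assembly) carrying the same ordered read
# sequence; it is the unit of evidence that both assemblers reconstructed the
# same locus.

empty_blocks <- function() {
  data.table::data.table(block_id = integer(),
                         m_contig = integer(), m_begin = integer(),
                         m_end = integer(),
                         s_contig = integer(), s_begin = integer(),
                         s_end = integer(),
                         size = integer(), n_opposite = integer(),
                         concordant = logical(), reads = list())
}

#' Build blocks from a master store and a sorted slave alignment stream
#'
#' Streaming construction: slave reads are visited in (contig, position)
#' order; a read absent from the master store is skipped; a read adjacent --
#' on both its master and slave frames -- to an open block extends that
#' block; otherwise it opens a new block. A block that leaves the scope of
#' the current read (slave contig change, or slave frame no longer adjacent)
#' is finalized and kept iff it contains at least `B_min` reads. A read
#' adjacent to several open blocks joins the earliest-opened one; blocks are
#' never merged after creation.
#'
#' @param master_store `read_store` of uniquely aligned reads on the master.
#' @param slave `read_store` (or a data.table of read records sorted by
#'   contig then begin) for the slave assembly.
#' @param B_min Minimum number of reads per retained block.
#' @return A data.table with one row per block: frame intervals on both
#'   assemblies (0-based inclusive), `size`, `n_opposite` (reads whose
#'   orientation differs between the frames), `concordant`, and the ordered
#'   member read ids in the list column `reads`.
#' @export
build_blocks <- function(master_store, slave, B_min = 10L) {
  stopifnot(inherits(master_store, "read_store"), B_min >= 1L)
  sl <- if (inherits(slave, "read_store")) slave$records
        else data.table::as.data.table(slave)
  if (nrow(sl) > 1L) {
    key <- sl$contig * 2^34 + sl$begin
    bad <- which(diff(key) < 0)
    if (length(bad))
      stop(sprintf("slave alignment stream not sorted: record '%s' at row %d",
                   sl$read_id[bad[1L] + 1L], bad[1L] + 1L))
  }
  ms <- master_store$records
  mi <- match(sl$read_id, ms$read_id)
  sh <- which(!is.na(mi))
  if (length(sh) == 0L) return(empty_blocks())
  s_contig <- sl$contig[sh]; s_begin <- sl$begin[sh]; s_end <- sl$end[sh]
  s_rev <- sl$reversed[sh]; rids <- sl$read_id[sh]
  mj <- mi[sh]
  m_contig <- ms$contig[mj]; m_begin <- ms$begin[mj]; m_end <- ms$end[mj]
  m_rev <- ms$reversed[mj]

  open <- list()          # environments, in creation order
  done <- vector("list", 64L); n_done <- 0L
  finalize <- function(b) {
    if (b$n >= B_min) {
      n_done <<- n_done + 1L
      if (n_done > length(done)) length(done) <<- 2L * n_done
      done[[n_done]] <<- list(
        m_contig = b$m_contig, m_begin = b$m_lo, m_end = b$m_hi,
        s_contig = b$s_contig, s_begin = b$s_lo, s_end = b$s_hi,
        size = b$n, n_opposite = b$n_opp,
        reads = unlist(b$ids[seq_len(b$n)], use.names = FALSE))
    }
  }

  created <- 0L
  for (i in seq_along(sh)) {
    sc <- s_contig[i]; sb <- s_begin[i]; se <- s_end[i]
    mc <- m_contig[i]; mb <- m_begin[i]; me <- m_end[i]
    opp <- m_rev[i] != s_rev[i]
    if (length(open)) {
      in_scope <- vapply(open, function(b)
        b$s_contig == sc && b$s_hi + 1L >= sb, FALSE)
      if (!all(in_scope)) {
        for (b in open[!in_scope]) finalize(b)
        open <- open[in_scope]
      }
    }
    joined <- FALSE
    if (length(open)) {
      for (b in open) {  # creation order: first master-adjacent match wins
        if (b$m_contig == mc && b$m_lo <= me + 1L && mb <= b$m_hi + 1L) {
          if (mb < b$m_lo) b$m_lo <- mb
          if (me > b$m_hi) b$m_hi <- me
          if (sb < b$s_lo) b$s_lo <- sb
          if (se > b$s_hi) b$s_hi <- se
          b$n <- b$n + 1L
          if (b$n > length(b$ids)) length(b$ids) <- 2L * b$n
          b$ids[[b$n]] <- rids[i]
          if (opp) b$n_opp <- b$n_opp + 1L
          joined <- TRUE
          break
        }
      }
    }
    if (!joined) {
      created <- created + 1L
      b <- new.env(parent = emptyenv())
      b$m_contig <- mc; b$m_lo <- mb; b$m_hi <- me
      b$s_contig <- sc; b$s_lo <- sb; b$s_hi <- se
      b$n <- 1L; b$n_opp <- if (opp) 1L else 0L
      b$ids <- vector("list", 8L); b$ids[[1L]] <- rids[i]
      b$created <- created
      open <- c(open, list(b))
    }
  }
  for (b in open) finalize(b)
  if (n_done == 0L) return(empty_blocks())
  done <- done[seq_len(n_done)]
  out <- data.table::data.table(
    m_contig = vapply(done, `[[`, 0L, "m_contig"),
    m_begin = vapply(done, `[[`, 0L, "m_begin"),
    m_end = vapply(done, `[[`, 0L, "m_end"),
    s_contig = vapply(done, `[[`, 0L, "s_contig"),
    s_begin = vapply(done, `[[`, 0L, "s_begin"),
    s_end = vapply(done, `[[`, 0L, "s_end"),
    size = vapply(done, `[[`, 0L, "size"),
    n_opposite = vapply(done, `[[`, 0L, "n_opposite"),
    reads = lapply(done, `[[`, "reads"))
  data.table::setorder(out, m_contig, m_begin, s_contig, s_begin)
  out[, block_id := seq_len(.N)]
  out[, concordant := 2L * n_opposite <= size]
  data.table::setcolorder(out, c("block_id", "m_contig", "m_begin", "m_end",
                                 "s_contig", "s_begin", "s_end", "size",
                                 "n_opposite", "concordant", "reads"))
  out[]
}

#' Classify a block as concordant or discordant
#'
#' Discordant iff a strict majority of member reads map with opposite
#' orientations on the two frames; an exact tie is concordant (no
#' orientation flip without majority evidence).
#'
#' @param block One block row (list or one-row data.table with `size` and
#'   `n_opposite`).
#' @return `"concordant"` or `"discordant"` (vectorized).
#' @export
classify_concordance <- function(block) {
  ifelse(2L * block$n_opposite > block$size, "discordant", "concordant")
}

#' Block and global coverage of a frame
#'
#' `BC` sums, over the block's member reads, the number of their aligned
#' bases falling inside the frame interval; `GC` is the same sum over *all*
#' uniquely aligned reads of that assembly overlapping the frame.
#'
#' @param block One block row (with `reads` list column populated).
#' @param side `"master"` or `"slave"`: which frame to measure.
#' @param store The `read_store` of that assembly.
#' @return A list with elements `BC` and `GC` (base counts, `0 <= BC <= GC`).
#' @export
compute_frame_coverage <- function(block, side = c("master", "slave"), store) {
  side <- match.arg(side)
  fb <- if (side == "master") block$m_begin else block$s_begin
  fe <- if (side == "master") block$m_end else block$s_end
  fc <- if (side == "master") block$m_contig else block$s_contig
  if (is.list(fb)) { fb <- fb[[1]]; fe <- fe[[1]]; fc <- fc[[1]] }
  ids <- block$reads
  if (is.list(ids) && length(ids) == 1L && is.character(ids[[1L]]))
    ids <- ids[[1L]]
  r <- store$records
  memb <- r[J(ids), on = "read_id", nomatch = NULL]
  bc <- sum(pmax(0L, pmin(memb$end, fe) - pmax(memb$begin, fb) + 1L))
  over <- r[contig == fc & begin <= fe & end >= fb]
  gc <- sum(pmax(0L, pmin(over$end, fe) - pmax(over$begin, fb) + 1L))
  list(BC = bc, GC = gc)
}

#' Coverage-ratio block filter
#'
#' Keeps a block iff the larger of its two block/global coverage ratios
#' reaches `T_c`: `max(BC_M/GC_M, BC_S/GC_S) >= T_c`. Using the maximum
#' protects heterozygous regions, where one assembler reports both alleles
#' (ratio near 0.5) while the other collapses them (ratio near 1).
#'
#' @param blocks Block table from [build_blocks()].
#' @param master_store,slave_store The two read stores.
#' @param T_c Threshold in `[0, 1]`.
#' @return The retained subset of `blocks` (ratios attached as `ratio_m`,
#'   `ratio_s`).
#' @export
filter_blocks_by_coverage <- function(blocks, master_store, slave_store, T_c) {
  stopifnot(T_c >= 0, T_c <= 1)
  if (nrow(blocks) == 0L) return(blocks)
  rm_ <- numeric(nrow(blocks)); rs_ <- numeric(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i]
    cm <- compute_frame_coverage(b, "master", master_store)
    cs <- compute_frame_coverage(b, "slave", slave_store)
    stopifnot(cm$GC > 0L, cs$GC > 0L)  # member reads overlap their own frame
    rm_[i] <- cm$BC / cm$GC
    rs_[i] <- cs$BC / cs$GC
  }
  out <- data.table::copy(blocks)
  out[, `:=`(ratio_m = rm_, ratio_s = rs_)]
  out[pmax(ratio_m, ratio_s) >= T_c]
}

#' Frame-length block filter
#'
#' A block passes the base condition iff one of its frames reaches
#' `min(0.3 * contig_length, T_l)`. A failing block is still retained when
#' another block between the same contig pair passes the base condition, or
#' when it is the only block between the two contigs (small blocks can still
#' witness insertions/deletions by one of the assemblies).
#'
#' @param blocks Block table.
#' @param master_store,slave_store Read stores (contig lengths).
#' @param T_l Length threshold in bp.
#' @return The retained subset of `blocks`.
#' @export
filter_blocks_by_length <- function(blocks, master_store, slave_store, T_l) {
  if (nrow(blocks) == 0L) return(blocks)
  out <- data.table::copy(blocks)
  mlen <- contig_length(master_store, out$m_contig)
  slen <- contig_length(slave_store, out$s_contig)
  fm <- out$m_end - out$m_begin + 1L
  fs <- out$s_end - out$s_begin + 1L
  out[, base_pass := fm >= pmin(0.3 * mlen, T_l) | fs >= pmin(0.3 * slen, T_l)]
  out[, keep := base_pass | any(base_pass) | .N == 1L,
      by = .(m_contig, s_contig)]
  res <- out[keep == TRUE]
  res[, c("base_pass", "keep") := NULL]
  res[]
}

#' Write / read a block table as TSV
#'
#' One row per block with contig names and frame intervals; the member read
#' list is not serialized (downstream phases need only frames, sizes and
#' concordance). `read_blocks_tsv` resolves contig names against the two
#' stores and fails with the offending line number on malformed input.
#'
#' @param blocks Block table.
#' @param path Output/input TSV path.
#' @param master_store,slave_store Read stores used to resolve contig names.
#' @return `write_blocks_tsv`: the path, invisibly. `read_blocks_tsv`: a
#'   block table (with empty `reads`).
#' @export
write_blocks_tsv <- function(blocks, path, master_store, slave_store) {
  dt <- data.table::data.table(
    master_contig = contig_name(master_store, blocks$m_contig),
    master_begin = blocks$m_begin, master_end = blocks$m_end,
    slave_contig = contig_name(slave_store, blocks$s_contig),
    slave_begin = blocks$s_begin, slave_end = blocks$s_end,
    size = blocks$size, n_opposite = blocks$n_opposite,
    concordant = blocks$concordant)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_blocks_tsv
#' @export
read_blocks_tsv <- function(path, master_store, slave_store) {
  need <- c("master_contig", "master_begin", "master_end", "slave_contig",
            "slave_begin", "slave_end", "size", "n_opposite", "concordant")
  dt <- tryCatch(data.table::fread(path, sep = "\t", colClasses = list(
    character = c("master_contig", "slave_contig"))),
    error = function(e) stop("malformed blocks TSV '", path, "': ",
                             conditionMessage(e)))
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("malformed blocks TSV '", path, "' (line 1): missing column(s) ",
         paste(miss, collapse = ", "))
  mc <- match(dt$master_contig, master_store$contigs$name)
  sc <- match(dt$slave_contig, slave_store$contigs$name)
  if (anyNA(mc))
    stop(sprintf("blocks TSV '%s' line %d: unknown master contig '%s'",
                 path, which(is.na(mc))[1L] + 1L,
                 dt$master_contig[which(is.na(mc))[1L]]))
  if (anyNA(sc))
    stop(sprintf("blocks TSV '%s' line %d: unknown slave contig '%s'",
                 path, which(is.na(sc))[1L] + 1L,
                 dt$slave_contig[which(is.na(sc))[1L]]))
  bad <- which(!(dt$master_begin <= dt$master_end &
                 dt$slave_begin <= dt$slave_end & dt$size >= 1L))
  if (length(bad))
    stop(sprintf("blocks TSV '%s' line %d: invalid frame or size", path,
                 bad[1L] + 1L))
  out <- data.table::data.table(
    block_id = seq_len(nrow(dt)),
    m_contig = mc, m_begin = as.integer(dt$master_begin),
    m_end = as.integer(dt$master_end),
    s_contig = sc, s_begin = as.integer(dt$slave_begin),
    s_end = as.integer(dt$slave_end),
    size = as.integer(dt$size), n_opposite = as.integer(dt$n_opposite),
    concordant = as.logical(dt$concordant),
    reads = replicate(nrow(dt), character(0), simplify = FALSE))
  out
}
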