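# Alignment loading: SAM/BAM -> compact per-contig, position-sorted stores of
# uniquely aligned reads. Internal coordinates are 0-based inclusive
# [begin, end]; conversion from 1-based SAM happens only here.

.read_record_cols <- c("read_id", "contig", "begin", "end", "reversed",
                       "library_id", "pair_name", "mate_no")

new_read_store <- function(records, contigs, assembly_tag) {
  records <- data.table::as.data.table(records)
  data.table::setcolorder(records, .read_record_cols)
  data.table::setkeyv(records, c("contig", "begin"))
  structure(list(records = records,
                 contigs = data.table::as.data.table(contigs),
                 assembly = assembly_tag,
                 cache = new.env(parent = emptyenv())),
            class = "read_store")
}

#' @export
print.read_store <- function(x, ...) {
  cat(sprintf("<read_store [%s]: %d reads on %d contigs, libraries: %s>\n",
              x$assembly, nrow(x$records), nrow(x$contigs),
              paste(unique(x$records$library_id), collapse = ", ")))
  invisible(x)
}

#' Load uniquely aligned reads from a SAM/BAM file
#'
#' Retains only reads with a single confident placement: the primary record
#' of a mapped read that is not flagged secondary/supplementary, has mapping
#' quality > 0 and carries no alternative-hits (`XA`) tag. Coordinates are
#' converted to 0-based inclusive `[begin, end]` using the CIGAR reference
#' width. Input must be sorted by contig (header order) then position;
#' unsorted input is a fatal error naming the first out-of-order record.
#'
#' @param alignment_file Path to a SAM or BAM file with a proper header.
#' @param assembly_tag `"master"` or `"slave"`.
#' @param library A [library_descriptor()] for the reads in this file.
#' @param reference Optional assembly FASTA path or named `DNAStringSet`;
#'   when given, SAM header contigs are cross-checked against it (absent
#'   contig or mismatched length is fatal).
#' @return A `read_store` holding one `ReadRecord` per uniquely aligned read.
#' @export
load_unique_alignments <- function(alignment_file,
                                   assembly_tag = c("master", "slave"),
                                   library, reference = NULL) {
  assembly_tag <- match.arg(assembly_tag)
  stopifnot(inherits(library, "library_descriptor"))
  if (!file.exists(alignment_file))
    stop("alignment file not found: ", alignment_file)

  bam <- alignment_file
  if (grepl("\\.sam$", alignment_file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(alignment_file, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }

  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (length(hdr) == 0L) stop("alignment file has no @SQ header lines: ",
                              alignment_file)
  contigs <- data.table::data.table(contig = seq_along(hdr),
                                    name = names(hdr),
                                    length = as.integer(hdr))
  if (!is.null(reference)) {
    ref <- if (inherits(reference, "DNAStringSet")) reference
           else Biostrings::readDNAStringSet(reference)
    ref_names <- sub("\\s.*$", "", names(ref))
    missing <- setdiff(contigs$name, ref_names)
    if (length(missing))
      stop("contig(s) in SAM header absent from assembly FASTA: ",
           paste(missing, collapse = ", "))
    ref_len <- setNames(Biostrings::width(ref), ref_names)
    bad <- contigs$name[contigs$length != ref_len[contigs$name]]
    if (length(bad))
      stop("contig length mismatch between SAM header and FASTA: ",
           paste(bad, collapse = ", "))
  }

  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "mapq"),
    tag = "XA")
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  n_all <- length(res$qname)
  if (n_all == 0L)
    return(new_read_store(
      data.table::data.table(read_id = character(), contig = integer(),
                             begin = integer(), end = integer(),
                             reversed = logical(), library_id = character(),
                             pair_name = character(), mate_no = integer()),
      contigs, assembly_tag))

  flag <- res$flag
  mapped <- bitwAnd(flag, 0x4L) == 0L
  rid <- match(as.character(res$rname), contigs$name)

  # sortedness check on mapped records, before any filtering
  mi <- which(mapped)
  if (length(mi) > 1L) {
    ord_key <- rid[mi] * 2^32 + res$pos[mi]
    bad <- which(diff(ord_key) < 0)
    if (length(bad)) {
      k <- mi[bad[1L] + 1L]
      stop(sprintf(paste0("alignments not sorted by contig then position: ",
                          "record '%s' (%s:%d) follows a later coordinate"),
                   res$qname[k], as.character(res$rname[k]), res$pos[k]))
    }
  }

  xa <- res$tag$XA
  has_xa <- if (is.null(xa)) rep(FALSE, n_all) else !is.na(xa) & nzchar(xa)
  unique_aln <- mapped &
    bitwAnd(flag, 0x100L) == 0L &      # secondary
    bitwAnd(flag, 0x800L) == 0L &      # supplementary
    !is.na(res$mapq) & res$mapq > 0L & # multi-hit evidence
    !has_xa
  keep <- which(unique_aln)
  if (length(keep) == 0L)
    return(new_read_store(
      data.table::data.table(read_id = character(), contig = integer(),
                             begin = integer(), end = integer(),
                             reversed = logical(), library_id = character(),
                             pair_name = character(), mate_no = integer()),
      contigs, assembly_tag))

  qname <- res$qname[keep]
  flag <- flag[keep]
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[keep])
  begin <- res$pos[keep] - 1L
  end <- begin + ref_width - 1L

  paired <- bitwAnd(flag, 0x1L) != 0L
  has_sufx <- grepl("/[12]$", qname)
  mn_suffix <- rep(NA_integer_, length(qname))
  mn_suffix[has_sufx] <- as.integer(sub("^.*/([12])$", "\\1", qname[has_sufx]))
  mate_no <- ifelse(!paired, NA_integer_,
             ifelse(bitwAnd(flag, 0x40L) != 0L, 1L,
             ifelse(bitwAnd(flag, 0x80L) != 0L, 2L, mn_suffix)))
  pair_name <- ifelse(paired, sub("/[12]$", "", qname), NA_character_)

  dup <- qname[duplicated(qname)]
  if (length(dup))
    stop("duplicate read identifier(s) among unique alignments: ",
         paste(unique(dup)[seq_len(min(3L, length(unique(dup))))],
               collapse = ", "))

  records <- data.table::data.table(
    read_id = qname, contig = rid[keep], begin = begin, end = end,
    reversed = bitwAnd(flag, 0x10L) != 0L,
    library_id = library$library_id, pair_name = pair_name,
    mate_no = mate_no)
  new_read_store(records, contigs, assembly_tag)
}

#' Combine per-library stores of the same assembly
#'
#' @param ... `read_store` objects (or one list of them) for the same
#'   assembly with identical contig tables.
#' @return A single combined `read_store`.
#' @export
merge_stores <- function(...) {
  stores <- list(...)
  if (length(stores) == 1L && !inherits(stores[[1L]], "read_store"))
    stores <- stores[[1L]]
  stopifnot(length(stores) >= 1L,
            all(vapply(stores, inherits, TRUE, "read_store")))
  tag <- unique(vapply(stores, `[[`, "", "assembly"))
  if (length(tag) != 1L) stop("stores belong to different assemblies")
  ctg <- stores[[1L]]$contigs
  for (s in stores[-1L])
    if (!identical(s$contigs$name, ctg$name) ||
        !identical(s$contigs$length, ctg$length))
      stop("stores have differing contig tables")
  recs <- data.table::rbindlist(lapply(stores, `[[`, "records"))
  dup <- recs$read_id[duplicated(recs$read_id)]
  if (length(dup))
    stop("read identifier present in more than one library: ", dup[1L])
  new_read_store(recs, ctg, tag)
}

#' Read adjacency
#'
#' Two reads aligned to the same contig are adjacent iff their intervals
#' overlap or abut: `begin(r2) <= end(r1) + 1` and `begin(r1) <= end(r2) + 1`.
#' Reads on different contigs are never adjacent (no error).
#'
#' @param r1,r2 Lists or one-row data.frames with `contig`, `begin`, `end`.
#' @return `TRUE` or `FALSE` (vectorized over aligned elements).
#' @export
is_adjacent <- function(r1, r2) {
  r1$contig == r2$contig &
    r2$begin <= r1$end + 1L &
    r1$begin <= r2$end + 1L
}

#' Look up the mate of a read in a store
#'
#' @param store A `read_store`.
#' @param record A `ReadRecord` row (list with `pair_name`, `mate_no`) or a
#'   read identifier present in the store.
#' @return The mate's record row (a one-row data.table) or `NULL` when the
#'   mate is absent (multi-mapped, unmapped, or the library is unpaired).
#' @export
mate_lookup <- function(store, record) {
  if (is.character(record)) {
    rows <- store$records[record, on = "read_id", nomatch = NULL]
    if (nrow(rows) == 0L) return(NULL)
    record <- rows[1L]
  }
  if (is.na(record$pair_name) || is.na(record$mate_no)) return(NULL)
  other <- store$records[.(record$pair_name, 3L - record$mate_no),
                         on = c("pair_name", "mate_no"), nomatch = NULL]
  if (nrow(other) == 0L) NULL else other[1L]
}

# All intra-contig pairs of a store, one row per pair, with the observed
# insert (outer distance). Cached on the store.
store_pairs <- function(store) {
  if (!is.null(store$cache$pairs)) return(store$cache$pairs)
  r <- store$records[!is.na(pair_name)]
  if (nrow(r) == 0L) {
    p <- data.table::data.table(pair_name = character(), contig = integer(),
                                lo_begin = integer(), lo_end = integer(),
                                lo_rev = logical(), hi_begin = integer(),
                                hi_end = integer(), hi_rev = logical(),
                                library_id = character(), insert = integer())
  } else {
    m1 <- r[mate_no == 1L]
    m2 <- r[mate_no == 2L]
    p <- merge(m1, m2, by = "pair_name", suffixes = c(".1", ".2"))
    p <- p[contig.1 == contig.2]
    first_lo <- p$begin.1 <= p$begin.2
    p <- data.table::data.table(
      pair_name = p$pair_name, contig = p$contig.1,
      lo_begin = ifelse(first_lo, p$begin.1, p$begin.2),
      lo_end = ifelse(first_lo, p$end.1, p$end.2),
      lo_rev = ifelse(first_lo, p$reversed.1, p$reversed.2),
      hi_begin = ifelse(first_lo, p$begin.2, p$begin.1),
      hi_end = ifelse(first_lo, p$end.2, p$end.1),
      hi_rev = ifelse(first_lo, p$reversed.2, p$reversed.1),
      library_id = p$library_id.1)
    p[, insert := hi_end - lo_begin + 1L]
    data.table::setkeyv(p, c("contig", "lo_begin"))
  }
  store$cache$pairs <- p
  p
}

contig_length <- function(store, contig) {
  store$contigs$length[match(contig, store$contigs$contig)]
}

contig_name <- function(store, contig) {
  store$contigs$name[match(contig, store$contigs$contig)]
}
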