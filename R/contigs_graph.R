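# Contigs Graph (CG): bipartite graph with one vertex per contig carrying at
# least one retained block and one undirected edge per (master contig, slave
# contig) pair sharing blocks. Edge weights measure orientation agreement;
# the greedy propagation assigns every contig a block order/orientation.

vertex_id <- function(side, contig) paste0(side, contig)
vertex_rank <- function(ids) {
  side <- substr(ids, 1L, 1L)
  contig <- as.integer(substring(ids, 2L))
  ifelse(side == "M", 0, 1e9) + contig     # master first, then contig id
}

#' Build the contigs graph from retained blocks
#'
#' One edge per (master contig, slave contig) pair, weighted
#' `w_e = max(r+, r-) / (r+ + r-)` where `r+`/`r-` count the reads in
#' concordant/discordant blocks between the pair; a vertex weight is the
#' mean of its incident edge weights, each edge weighted by the total size
#' (read count) of the blocks it represents.
#'
#' @param blocks Retained block table.
#' @return An object of class `contigs_graph`: list with `edges`
#'   (per contig pair: `r_plus`, `r_minus`, `total`, `w_e`) and `vertices`
#'   (`id`, `side`, `contig`, `w_V`).
#' @export
build_contigs_graph <- function(blocks) {
  edges <- blocks[, .(r_plus = sum(size[concordant]),
                      r_minus = sum(size[!concordant]),
                      total = sum(size)),
                  by = .(m_contig, s_contig)]
  edges[, w_e := pmax(r_plus, r_minus) / (r_plus + r_minus)]
  edges[, `:=`(vm = vertex_id("M", m_contig), vs = vertex_id("S", s_contig))]
  data.table::setorder(edges, m_contig, s_contig)
  long <- data.table::rbindlist(list(
    edges[, .(id = vm, w_e, total)],
    edges[, .(id = vs, w_e, total)]))
  vertices <- long[, .(w_V = sum(w_e * total) / sum(total)), by = id]
  vertices[, `:=`(side = substr(id, 1L, 1L),
                  contig = as.integer(substring(id, 2L)))]
  data.table::setorder(vertices, side, contig)
  structure(list(edges = edges[], vertices = vertices[]),
            class = "contigs_graph")
}

#' @export
print.contigs_graph <- function(x, ...) {
  cat(sprintf("<contigs_graph: %d vertices, %d edges>\n",
              nrow(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' Propagate a consistent block order/orientation across contigs
#'
#' Per connected component: the vertex with the largest weight seeds its
#' native order; repeatedly the processed vertex with the largest current
#' weight orients each unvisited neighbor (a discordant-majority edge flips
#' the neighbor), its incident edges are removed and the remaining vertex
#' weights recomputed. Ties (equal weight) go to the master side, then the
#' lowest contig id; an exact concordant/discordant tie on an edge does not
#' flip. The result is deterministic and idempotent.
#'
#' @param cg A `contigs_graph`.
#' @param blocks The block table the graph was built from.
#' @return Object of class `block_orders`: data.table
#'   (`side`, `contig`, `flipped`, `seed`).
#' @export
assign_block_orders <- function(cg, blocks) {
  verts <- cg$vertices$id
  if (length(verts) == 0L)
    return(structure(data.table::data.table(side = character(),
                                            contig = integer(),
                                            flipped = logical(),
                                            seed = logical()),
                     class = c("block_orders", "data.table", "data.frame")))
  live <- data.table::copy(cg$edges)
  g <- igraph::graph_from_data_frame(live[, .(vm, vs)], directed = FALSE,
                                     vertices = data.frame(name = verts))
  comp <- igraph::components(g)$membership[verts]

  w <- setNames(cg$vertices$w_V, cg$vertices$id)
  rank <- vertex_rank(verts); names(rank) <- verts
  flipped <- setNames(rep(NA, length(verts)), verts)
  seeds <- character(0)

  recompute <- function(ids) {
    for (v in ids) {
      e <- live[vm == v | vs == v]
      if (nrow(e)) w[v] <<- sum(e$w_e * e$total) / sum(e$total)
    }
  }
  pick_best <- function(ids) {
    ww <- w[ids]
    cand <- ids[ww == max(ww)]
    cand[order(rank[cand])][1L]
  }

  for (cmp in unique(comp)) {
    members <- verts[comp == cmp]
    seed <- pick_best(members)
    flipped[seed] <- FALSE
    seeds <- c(seeds, seed)
    processed <- seed
    repeat {
      has_live <- processed[vapply(processed, function(v)
        nrow(live[vm == v | vs == v]) > 0L, FALSE)]
      if (length(has_live) == 0L) break
      V <- pick_best(has_live)
      ve <- live[vm == V | vs == V]
      for (k in seq_len(nrow(ve))) {
        U <- if (ve$vm[k] == V) ve$vs[k] else ve$vm[k]
        if (is.na(flipped[U])) {
          flip_edge <- ve$r_minus[k] > ve$r_plus[k]  # tie -> concordant
          flipped[U] <- if (flip_edge) !flipped[V] else flipped[V]
        }
        if (!U %in% processed) processed <- c(processed, U)
      }
      live <- live[!(vm == V | vs == V)]
      touched <- setdiff(unique(c(ve$vm, ve$vs)), V)
      recompute(touched)
    }
  }
  out <- data.table::data.table(side = substr(verts, 1L, 1L),
                                contig = as.integer(substring(verts, 2L)),
                                flipped = as.logical(flipped[verts]),
                                seed = verts %in% seeds)
  data.table::setorder(out, side, contig)
  structure(out, class = c("block_orders", class(out)))
}

is_flipped <- function(orders, side, contig) {
  i <- which(orders$side == side & orders$contig == contig)
  if (length(i) == 0L) FALSE else orders$flipped[i]
}

# Block ids on one contig in the assigned order (native position order,
# reversed when the contig was flipped). Ties broken by end then block id.
ordered_blocks_on_contig <- function(blocks, orders, side, contig) {
  if (side == "M") {
    sub <- blocks[m_contig == contig]
    o <- order(sub$m_begin, sub$m_end, sub$block_id)
  } else {
    sub <- blocks[s_contig == contig]
    o <- order(sub$s_begin, sub$s_end, sub$block_id)
  }
  ids <- sub$block_id[o]
  if (is_flipped(orders, side, contig)) rev(ids) else ids
}

#' Dump a contigs graph in DOT format
#'
#' Debug aid: vertices labeled `contig:assembly`, edges labeled
#' `w_e (r+/r-)`.
#'
#' @param cg A `contigs_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_contigs_graph_dot <- function(cg, path) {
  lines <- c("graph contigs_graph {")
  for (i in seq_len(nrow(cg$vertices)))
    lines <- c(lines, sprintf('  %s [label="%d:%s"];',
                              cg$vertices$id[i], cg$vertices$contig[i],
                              ifelse(cg$vertices$side[i] == "M",
                                     "master", "slave")))
  for (i in seq_len(nrow(cg$edges)))
    lines <- c(lines, sprintf('  %s -- %s [label="%.3f (%d/%d)"];',
                              cg$edges$vm[i], cg$edges$vs[i],
                              cg$edges$w_e[i], cg$edges$r_plus[i],
                              cg$edges$r_minus[i]))
  writeLines(c(lines, "}"), path)
  invisible(path)
}
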