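# Assemblies Graph (AG): one node per retained block, a directed edge when
# one block immediately precedes another on a contig under the assigned
# order. Non-linear structures (cycles, forks, bubbles) flag disagreements
# between the assemblies and are arbitrated with paired-read evidence.

#' Build the assemblies graph
#'
#' For every contig, consecutive blocks under the (possibly flipped)
#' assigned order contribute one directed edge labeled with that assembly.
#' Because only two assemblies are merged, no node can have input or output
#' degree greater than two; a violation is an internal error.
#'
#' @param blocks Retained block table.
#' @param orders A `block_orders` assignment from [assign_block_orders()].
#' @return Object of class `assemblies_graph`: list with `blocks`, `edges`
#'   (`from`, `to`, `side`, `contig`) and `orders`.
#' @export
build_assemblies_graph <- function(blocks, orders) {
  edges <- list()
  for (side in c("M", "S")) {
    contigs <- unique(if (side == "M") blocks$m_contig else blocks$s_contig)
    for (ctg in sort(contigs)) {
      ids <- ordered_blocks_on_contig(blocks, orders, side, ctg)
      if (length(ids) >= 2L)
        edges[[length(edges) + 1L]] <- data.table::data.table(
          from = ids[-length(ids)], to = ids[-1L], side = side, contig = ctg)
    }
  }
  edges <- if (length(edges)) data.table::rbindlist(edges)
           else data.table::data.table(from = integer(), to = integer(),
                                       side = character(), contig = integer())
  if (nrow(edges)) {
    # parallel edges between one block pair (one per assembly) are a single
    # doubly-supported succession: degrees count distinct neighbors
    deg_out <- edges[, .(n = data.table::uniqueN(to)), by = from]
    deg_in <- edges[, .(n = data.table::uniqueN(from)), by = to]
    if (any(deg_out$n > 2L) || any(deg_in$n > 2L))
      stop("internal error: assemblies-graph degree bound exceeded")
    if (anyDuplicated(edges[, .(from, to, side)]))
      stop("internal error: duplicate assemblies-graph edge")
  }
  structure(list(blocks = blocks, edges = edges[], orders = orders),
            class = "assemblies_graph")
}

#' @export
print.assemblies_graph <- function(x, ...) {
  cat(sprintf("<assemblies_graph: %d blocks, %d edges>\n",
              nrow(x$blocks), nrow(x$edges)))
  invisible(x)
}

block_frame <- function(blocks, id, side) {
  b <- blocks[block_id == id]
  if (side == "M") list(contig = b$m_contig, begin = b$m_begin, end = b$m_end)
  else list(contig = b$s_contig, begin = b$s_begin, end = b$s_end)
}

#' Correctly placed pair test
#'
#' A read `r2` is the correctly placed mate of `r1` on the same contig iff
#' the observed insert span -- from the leftmost base of `r1` to the far
#' (insert-side) end of `r2`, i.e. `end(r2) - begin(r1) + 1` -- lies within
#' `[m - 3*sd, m + 3*sd]`, the contig is long enough to contain the whole
#' insert window (`contig_length >= begin(r1) + m + 3*sd`), and the pair
#' orientation is valid for the library (`fr`: r1 forward / r2 reverse).
#' The window is evaluated on the insert span, not on the mate's leftmost
#' coordinate: the mate's left end sits one read length short of the
#' insert, which for short-insert libraries would otherwise put every
#' well-placed pair outside an `m +/- 3*sd` window.
#'
#' @param r1,r2 Read records (lists with `begin`, `end`, `reversed`);
#'   vectorized.
#' @param contig_length Length of the shared contig in bp.
#' @param library A [library_descriptor()].
#' @return Logical.
#' @export
is_correctly_placed <- function(r1, r2, contig_length, library) {
  m <- library$mean_insert; sd3 <- 3 * library$sd_insert
  ori_ok <- if (library$orientation == "fr") !r1$reversed & r2$reversed
            else r1$reversed & !r2$reversed
  ins_obs <- r2$end - r1$begin + 1
  ins_obs >= m - sd3 & ins_obs <= m + sd3 &
    contig_length >= r1$begin + (m + sd3) &
    ori_ok
}

# Wrongly oriented pairs of a store overlapping [lo, hi] on a contig.
count_wrong_orientation <- function(store, contig_, lo, hi, libraries) {
  p <- store_pairs(store)
  p <- p[contig == contig_ & lo_begin <= hi & hi_end >= lo]
  if (nrow(p) == 0L) return(0L)
  ori <- setNames(vapply(libraries, `[[`, "", "orientation"),
                  vapply(libraries, `[[`, "", "library_id"))
  lib_ori <- ori[p$library_id]
  valid <- ifelse(lib_ori == "fr", !p$lo_rev & p$hi_rev,
                  p$lo_rev & !p$hi_rev)
  sum(!valid, na.rm = TRUE)
}

# Mate-pair evidence for one AG edge: frames F1 (lower native begin) and F2
# on one contig. Candidates are reads starting in F1, oriented toward the
# junction, whose insert window fits in the contig and reaches F2; n counts
# candidates whose mate is correctly placed at/after F2's start, u the rest.
edge_features_one <- function(blocks, from, to, side, contig_, store,
                              libraries) {
  f1 <- block_frame(blocks, from, side)
  f2 <- block_frame(blocks, to, side)
  if (f1$begin > f2$begin) { tmp <- f1; f1 <- f2; f2 <- tmp }
  L <- contig_length(store, contig_)
  r <- store$records
  n <- 0L; u <- 0L
  paired_libs <- libraries[vapply(libraries, function(l) l$sd_insert >= 0,
                                  TRUE)]
  for (lib in paired_libs) {
    win_lo <- lib$mean_insert - 3 * lib$sd_insert
    win_hi <- lib$mean_insert + 3 * lib$sd_insert
    cand_rev <- lib$orientation == "rf"
    # whole insert window must fit the contig and lie at/after the
    # downstream frame start, so a correctly placed mate always crosses the
    # junction: n and u then partition the candidates cleanly
    cand <- r[contig == contig_ & begin >= f1$begin & begin <= f1$end &
              reversed == cand_rev & !is.na(pair_name) &
              library_id == lib$library_id &
              begin + win_hi <= L & begin + win_lo >= f2$begin]
    if (nrow(cand) == 0L) next
    mates <- r[.(cand$pair_name, 3L - cand$mate_no),
               on = c("pair_name", "mate_no")]
    ok <- !is.na(mates$begin) & mates$contig == contig_ &
      is_correctly_placed(cand, mates, L, lib) &
      mates$end >= f2$begin
    ok[is.na(ok)] <- FALSE
    n <- n + sum(ok)
    u <- u + sum(!ok)
  }
  wrong <- count_wrong_orientation(store, contig_, f1$begin, f2$end,
                                   libraries)
  gap_lo <- min(f1$end + 1L, f2$begin)
  gap_hi <- max(f2$begin - 1L, f1$end)
  over <- r[contig == contig_ & begin <= gap_hi & end >= gap_lo]
  cov <- sum(pmax(0L, pmin(over$end, gap_hi) - pmax(over$begin, gap_lo) + 1L)) /
    max(1L, gap_hi - gap_lo + 1L)
  list(spanning = n, unfulfilled = u, wrong_orientation = wrong,
       local_coverage = cov)
}

#' Attach mate-pair evidence features to every AG edge
#'
#' For each edge, counts `spanning` pairs (a read in the upstream frame with
#' a correctly placed mate crossing to the downstream frame), `unfulfilled`
#' pairs (the expected crossing mate is unmapped, elsewhere or misplaced;
#' reads whose insert window exceeds the contig are excluded), wrongly
#' oriented pairs over the junction, and the mean unique-read depth over the
#' inter-frame gap. Counts are summed over libraries. With no paired
#' library all features are zero and a warning is logged.
#'
#' @param ag An `assemblies_graph`.
#' @param master_store,slave_store Read stores.
#' @param libraries List of [library_descriptor()]s.
#' @return The graph with feature columns added to `edges`.
#' @export
compute_edge_features <- function(ag, master_store, slave_store, libraries) {
  e <- data.table::copy(ag$edges)
  has_pairs <- nrow(store_pairs(master_store)) > 0L ||
    nrow(store_pairs(slave_store)) > 0L
  if (!has_pairs)
    warning("no paired libraries: all edge features are zero")
  n <- integer(nrow(e)); u <- integer(nrow(e))
  wrong <- integer(nrow(e)); cov <- numeric(nrow(e))
  for (i in seq_len(nrow(e))) {
    store <- if (e$side[i] == "M") master_store else slave_store
    f <- edge_features_one(ag$blocks, e$from[i], e$to[i], e$side[i],
                           e$contig[i], store, libraries)
    n[i] <- f$spanning; u[i] <- f$unfulfilled
    wrong[i] <- f$wrong_orientation; cov[i] <- f$local_coverage
  }
  e[, `:=`(spanning = n, unfulfilled = u, wrong_orientation = wrong,
           local_coverage = cov)]
  ag$edges <- e[]
  ag
}

#' Strongly connected components of the assemblies graph
#'
#' Components of size two or more flag order contradictions between the
#' assemblies.
#'
#' @param ag An `assemblies_graph` (or a list with `blocks$block_id` and an
#'   `edges` table).
#' @return Integer vector of component labels named by block id.
#' @export
find_sccs <- function(ag) {
  ids <- as.character(ag$blocks$block_id)
  if (length(ids) == 0L) return(setNames(integer(0), character(0)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ag$edges$from),
               to = as.character(ag$edges$to)),
    directed = TRUE, vertices = data.frame(name = ids))
  memb <- igraph::components(g, mode = "strong")$membership
  setNames(as.integer(memb[ids]), ids)
}

#' Detect problematic structures in the assemblies graph
#'
#' Classifies non-linear regions: 2-node cycles (putative inversions; the
#' only cycles actively resolved), bubbles (diverge-then-converge; their end
#' nodes are not treated as plain forks), out/in bifurcations (divergent or
#' convergent forks not involving a bubble), and `unresolved_complex` for
#' anything else (larger SCCs, 2-node SCCs whose blocks do not share both
#' contigs).
#'
#' @param ag An `assemblies_graph`.
#' @param sccs Output of [find_sccs()].
#' @return List of structures: each has `kind` and `nodes` (block ids).
#' @export
detect_structures <- function(ag, sccs) {
  e <- ag$edges
  structures <- list()
  add <- function(kind, nodes, ...)
    structures[[length(structures) + 1L]] <<- list(kind = kind,
                                                   nodes = nodes, ...)
  in_scc <- integer(0)
  for (cmp in unique(sccs)) {
    nodes <- as.integer(names(sccs)[sccs == cmp])
    if (length(nodes) < 2L) next
    in_scc <- c(in_scc, nodes)
    if (length(nodes) == 2L) {
      a <- nodes[1L]; b <- nodes[2L]
      ba <- ag$blocks[block_id == a]; bb <- ag$blocks[block_id == b]
      both <- nrow(e[from == a & to == b]) > 0L &&
        nrow(e[from == b & to == a]) > 0L
      share <- ba$m_contig == bb$m_contig && ba$s_contig == bb$s_contig
      if (both && share) add("two_node_cycle", sort(nodes))
      else add("unresolved_complex", sort(nodes))
    } else {
      add("unresolved_complex", sort(nodes))
    }
  }
  eu <- unique(e[, .(from, to)])
  outdeg <- table(factor(eu$from, levels = ag$blocks$block_id))
  indeg <- table(factor(eu$to, levels = ag$blocks$block_id))
  div_nodes <- as.integer(names(outdeg)[outdeg == 2L])
  conv_nodes <- as.integer(names(indeg)[indeg == 2L])
  div_nodes <- setdiff(div_nodes, in_scc)
  conv_nodes <- setdiff(conv_nodes, in_scc)

  succ1 <- function(v) unique(eu[from == v]$to)   # distinct successors
  bubble_ends <- integer(0)
  for (d in div_nodes) {
    heads <- succ1(d)
    walk <- function(start) {
      path <- integer(0); v <- start
      repeat {
        if (v %in% conv_nodes) return(list(end = v, interior = path))
        path <- c(path, v)
        nx <- succ1(v)
        if (length(nx) != 1L || length(path) > nrow(ag$blocks))
          return(NULL)
        v <- nx
      }
    }
    w1 <- walk(heads[1L]); w2 <- walk(heads[2L])
    if (!is.null(w1) && !is.null(w2) && w1$end == w2$end &&
        !w1$end %in% c(w1$interior, w2$interior) &&
        length(intersect(w1$interior, w2$interior)) == 0L) {
      add("bubble", sort(unique(c(d, w1$interior, w2$interior, w1$end))),
          diverge = d, converge = w1$end)
      bubble_ends <- c(bubble_ends, d, w1$end)
    }
  }
  for (d in setdiff(div_nodes, bubble_ends)) add("bifurcation_out", d)
  for (c_ in setdiff(conv_nodes, bubble_ends)) add("bifurcation_in", c_)
  structures
}

#' Resolve a putative inversion (2-node cycle)
#'
#' Counts read pairs mapped with invalid relative orientation across the
#' interval spanned by the two blocks, separately on the shared master and
#' slave contig. If at least `min_inversion_evidence` wrongly oriented pairs
#' appear on exactly one assembly, that assembly carries the inversion and
#' the other one's sequence is kept; otherwise the master sequence is output
#' (fallback).
#'
#' @param ag An `assemblies_graph`.
#' @param nodes The two block ids of the cycle.
#' @param master_store,slave_store Read stores.
#' @param libraries List of [library_descriptor()]s.
#' @param min_inversion_evidence Minimum pair count.
#' @return A resolution: list with `kind`, `nodes`, `decision`
#'   (`keep_master_sequence`, `keep_slave_sequence` or `fallback_master`)
#'   and `evidence`.
#' @export
resolve_two_node_cycle <- function(ag, nodes, master_store, slave_store,
                                   libraries, min_inversion_evidence = 5L) {
  b1 <- ag$blocks[block_id == nodes[1L]]
  b2 <- ag$blocks[block_id == nodes[2L]]
  stopifnot(b1$m_contig == b2$m_contig, b1$s_contig == b2$s_contig)
  m_lo <- min(b1$m_begin, b2$m_begin); m_hi <- max(b1$m_end, b2$m_end)
  s_lo <- min(b1$s_begin, b2$s_begin); s_hi <- max(b1$s_end, b2$s_end)
  wm <- count_wrong_orientation(master_store, b1$m_contig, m_lo, m_hi,
                                libraries)
  ws <- count_wrong_orientation(slave_store, b1$s_contig, s_lo, s_hi,
                                libraries)
  decision <-
    if (ws >= min_inversion_evidence && wm < min_inversion_evidence)
      "keep_master_sequence"
    else if (wm >= min_inversion_evidence && ws < min_inversion_evidence)
      "keep_slave_sequence"
    else "fallback_master"
  list(kind = "two_node_cycle", nodes = sort(nodes), decision = decision,
       evidence = list(wrong_master = wm, wrong_slave = ws,
                       threshold = min_inversion_evidence))
}

#' Resolve a bifurcation from spanning-pair ratios
#'
#' With `rho = n / (n + u)` computed for the master- and slave-labeled
#' branch (`rho` with `n + u = 0` fails both conditions):
#' `rho_M >= T_U` and `rho_S <= T_L` spots a mis-assembly in the slave
#' contig (trust the master path); the mirrored condition trusts the slave
#' path; anything else is a repeat or insufficient evidence and falls back
#' to the master.
#'
#' @param node Block id of the divergent (or convergent) node.
#' @param n_M,u_M,n_S,u_S Spanning / unfulfilled pair counts on the master-
#'   and slave-labeled branch.
#' @param T_U,T_L Thresholds in `[0, 1]`, `T_U > T_L`.
#' @param kind `"bifurcation_out"` or `"bifurcation_in"` (convergent nodes
#'   are treated symmetrically on reversed edges).
#' @return A resolution list (`decision` is `trust_master_path`,
#'   `trust_slave_path` or `fallback_master`).
#' @export
resolve_bifurcation <- function(node, n_M, u_M, n_S, u_S, T_U, T_L,
                                kind = "bifurcation_out") {
  rho <- function(n, u) if (n + u == 0L) NA_real_ else n / (n + u)
  rm_ <- rho(n_M, u_M); rs_ <- rho(n_S, u_S)
  ge <- function(x, t) !is.na(x) && x >= t
  le <- function(x, t) !is.na(x) && x <= t
  decision <-
    if (ge(rm_, T_U) && le(rs_, T_L)) "trust_master_path"
    else if (ge(rs_, T_U) && le(rm_, T_L)) "trust_slave_path"
    else "fallback_master"
  list(kind = kind, nodes = node, decision = decision,
       evidence = list(n_M = n_M, u_M = u_M, n_S = n_S, u_S = u_S,
                       rho_M = rm_, rho_S = rs_, T_U = T_U, T_L = T_L))
}

# Resolve every detected structure. Requires edge features on ag$edges.
resolve_structures <- function(ag, structures, master_store, slave_store,
                               libraries, config) {
  lapply(structures, function(st) {
    if (st$kind == "two_node_cycle") {
      resolve_two_node_cycle(ag, st$nodes, master_store, slave_store,
                             libraries, config$min_inversion_evidence)
    } else if (st$kind %in% c("bifurcation_out", "bifurcation_in")) {
      e <- if (st$kind == "bifurcation_out") ag$edges[from == st$nodes]
           else ag$edges[to == st$nodes]
      em <- e[side == "M"]; es <- e[side == "S"]
      if (nrow(em) != 1L || nrow(es) != 1L)
        return(list(kind = "unresolved_complex", nodes = st$nodes,
                    decision = "fallback_master",
                    evidence = list(note = "branches not one-per-assembly")))
      res <- resolve_bifurcation(st$nodes, em$spanning, em$unfulfilled,
                                 es$spanning, es$unfulfilled,
                                 config$T_U, config$T_L, st$kind)
      res$edges <- e
      res
    } else {  # bubbles and complex SCCs: conservative fallback
      list(kind = "unresolved_complex", nodes = st$nodes,
           decision = "fallback_master",
           evidence = list(original_kind = st$kind))
    }
  })
}

#' Prune the assemblies graph according to resolutions
#'
#' Applies every resolution: a resolved 2-node cycle keeps only the chosen
#' assembly's edges at its two nodes (and forces that assembly's frames
#' there); a trusted bifurcation drops the distrusted branch edge and marks
#' the distrusted contig broken at the junction; fallbacks and unresolved
#' structures withhold their master contigs, which are emitted verbatim.
#' Nodes on withheld master contigs are removed. The result must be a
#' disjoint union of simple paths; residual branching withholds the
#' offending master contigs too.
#'
#' @param ag An `assemblies_graph` with edge features.
#' @param resolutions List from `resolve_structures`.
#' @return List: `edges` (pruned), `nodes` (surviving block ids),
#'   `withheld_master` (master contig ids emitted verbatim),
#'   `forced_choice` (named "M"/"S" per block id), `breaks` (data.table
#'   `block`, `side`, `where` in before/after).
#' @export
simplify_graph <- function(ag, resolutions) {
  edges <- data.table::copy(ag$edges)
  blocks <- ag$blocks
  withheld <- integer(0)
  forced <- character(0)
  breaks <- list()
  add_break <- function(block, side, where)
    breaks[[length(breaks) + 1L]] <<- data.table::data.table(
      block = block, side = side, where = where)

  for (res in resolutions) {
    if (res$kind == "two_node_cycle") {
      keep_side <- if (res$decision == "keep_slave_sequence") "S" else "M"
      drop_side <- if (keep_side == "M") "S" else "M"
      drop <- edges[(from %in% res$nodes | to %in% res$nodes) &
                      side == drop_side]
      for (k in seq_len(nrow(drop))) {
        add_break(drop$from[k], drop_side, "after")
        add_break(drop$to[k], drop_side, "before")
      }
      edges <- edges[!((from %in% res$nodes | to %in% res$nodes) &
                         side == drop_side)]
      forced[as.character(res$nodes)] <- keep_side
    } else if (res$kind %in% c("bifurcation_out", "bifurcation_in")) {
      if (res$decision == "fallback_master") {
        nbr <- if (res$kind == "bifurcation_out")
          edges[from == res$nodes]$to else edges[to == res$nodes]$from
        involved <- c(res$nodes, nbr)
        withheld <- union(withheld,
                          blocks[block_id %in% involved]$m_contig)
      } else {
        drop_side <- if (res$decision == "trust_master_path") "S" else "M"
        drop <- if (res$kind == "bifurcation_out")
          edges[from == res$nodes & side == drop_side]
        else edges[to == res$nodes & side == drop_side]
        for (k in seq_len(nrow(drop))) {
          add_break(drop$from[k], drop_side, "after")
          add_break(drop$to[k], drop_side, "before")
        }
        edges <- edges[!(from %in% drop$from & to %in% drop$to &
                           side == drop_side)]
      }
    } else {  # unresolved_complex
      withheld <- union(withheld,
                        blocks[block_id %in% res$nodes]$m_contig)
    }
  }

  repeat {
    gone <- blocks[m_contig %in% withheld]$block_id
    edges <- edges[!(from %in% gone | to %in% gone)]
    nodes <- setdiff(blocks$block_id, gone)
    if (nrow(edges)) {
      outdeg <- edges[, .(n = data.table::uniqueN(to)), by = from]
      indeg <- edges[, .(n = data.table::uniqueN(from)), by = to]
      offenders <- union(outdeg[n > 1L]$from, indeg[n > 1L]$to)
    } else offenders <- integer(0)
    if (length(offenders) == 0L) break
    withheld <- union(withheld, blocks[block_id %in% offenders]$m_contig)
  }
  breaks <- if (length(breaks)) unique(data.table::rbindlist(breaks))
            else data.table::data.table(block = integer(), side = character(),
                                        where = character())
  list(edges = edges[], nodes = nodes, withheld_master = sort(withheld),
       forced_choice = forced, breaks = breaks)
}

# Human/machine readable resolution log.
resolutions_table <- function(resolutions, blocks, master_store, slave_store) {
  if (length(resolutions) == 0L)
    return(data.table::data.table(kind = character(), nodes = character(),
                                  master_contigs = character(),
                                  slave_contigs = character(),
                                  decision = character(),
                                  evidence = character()))
  data.table::rbindlist(lapply(resolutions, function(res) {
    b <- blocks[block_id %in% res$nodes]
    data.table::data.table(
      kind = res$kind,
      nodes = paste(res$nodes, collapse = ","),
      master_contigs = paste(unique(contig_name(master_store, b$m_contig)),
                             collapse = ","),
      slave_contigs = paste(unique(contig_name(slave_store, b$s_contig)),
                            collapse = ","),
      decision = res$decision,
      evidence = paste(names(res$evidence),
                       vapply(res$evidence, function(x)
                         paste(format(x, digits = 4), collapse = "|"), ""),
                       sep = "=", collapse = ";"))
  }))
}
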