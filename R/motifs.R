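#' Signed directed regulatory graph
#'
#' A wrapper around an [igraph][igraph::igraph-package] directed graph
#' whose edges carry a `sign` (+1 activation, -1 inhibition) and a
#' `provenance` tag (`"direct"` or `"indirect"`, i.e. acting through
#' intermediates). Node names are case-sensitive symbols but must be
#' unique after case folding.
#'
#' @param edges data.frame with columns `from`, `sign` (+1/-1), `to` and
#'   optionally `provenance`.
#' @return object of class `signed_graph`.
#' @export
signed_graph <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("from", "sign", "to") %in% names(edges)))
  if (!nrow(edges)) stop("empty edge list")
  sign <- as.integer(edges$sign)
  if (any(!sign %in% c(-1L, 1L))) stop("edge signs must be +1 or -1 (no zero-sign edges)")
  prov <- if ("provenance" %in% names(edges)) as.character(edges$provenance) else
    rep("direct", nrow(edges))
  prov[is.na(prov) | prov == ""] <- "direct"
  if (!all(prov %in% c("direct", "indirect")))
    stop("provenance must be 'direct' or 'indirect'")
  nodes <- unique(c(edges$from, edges$to))
  if (anyDuplicated(tolower(nodes)))
    stop("node names must be unique after case folding")
  df <- data.frame(from = as.character(edges$from), to = as.character(edges$to),
                   sign = sign, provenance = prov, stringsAsFactors = FALSE)
  # merge duplicate (from, to, sign) edges, keeping the strongest provenance
  key <- paste(df$from, df$to, df$sign)
  if (anyDuplicated(key)) {
    df <- do.call(rbind, lapply(split(df, key), function(d) {
      d$provenance <- if (any(d$provenance == "direct")) "direct" else "indirect"
      d[1, , drop = FALSE]
    }))
    rownames(df) <- NULL
  }
  g <- igraph::graph_from_data_frame(df, directed = TRUE)
  structure(list(graph = g), class = "signed_graph")
}

#' @export
print.signed_graph <- function(x, ...) {
  cat("<signed_graph>", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "signed edges\n")
  invisible(x)
}

graph_has_node <- function(graph, node) {
  inherits(graph, "signed_graph") && node %in% igraph::V(graph$graph)$name
}

#' Edge list of a signed graph
#' @param graph a `signed_graph`.
#' @return data.frame with columns `from`, `sign`, `to`, `provenance`.
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "signed_graph"))
  d <- igraph::as_data_frame(graph$graph, what = "edges")
  data.frame(from = d$from, sign = d$sign, to = d$to, provenance = d$provenance,
             stringsAsFactors = FALSE)
}

#' Read a signed edge list in SIF-style TSV
#'
#' Rows are `source <TAB> sign <TAB> target [<TAB> provenance]` with sign
#' tokens `+`, `-`, `+1`, `-1`, `1`, `activates` or `inhibits`. Lines
#' starting with `#` and blank lines are skipped. Duplicate edges are
#' merged, keeping `direct` provenance over `indirect`.
#'
#' @param path file path.
#' @return a `signed_graph`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) stop("no edges in ", path)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  parse_sign <- function(tok, ln) {
    switch(tok,
           "+" = 1L, "+1" = 1L, "1" = 1L, "activates" = 1L,
           "-" = -1L, "-1" = -1L, "inhibits" = -1L,
           stop("malformed sign token '", tok, "' on line ", ln, " of ", path))
  }
  edges <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- trimws(rows[[i]])
    if (length(r) < 3L)
      stop("expected at least 3 tab-separated fields on line ", keep[i], " of ", path)
    data.frame(from = r[1], sign = parse_sign(r[2], keep[i]), to = r[3],
               provenance = if (length(r) >= 4L && nzchar(r[4])) r[4] else "direct",
               stringsAsFactors = FALSE)
  }))
  signed_graph(edges)
}

#' Write a signed graph as SIF-style TSV
#' @param graph a `signed_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(graph, path) {
  d <- graph_edges(graph)
  lines <- sprintf("%s\t%s\t%s\t%s", d$from, ifelse(d$sign > 0, "+", "-"),
                   d$to, d$provenance)
  writeLines(lines, path)
  invisible(path)
}

#' Net signs of simple paths between two nodes
#'
#' Enumerates all simple (non-repeating) directed paths from `src` to
#' `dst` with at most `max_len` edges and returns the set of net signs
#' (the product of edge signs along each path). Both +1 and -1 may be
#' returned when paths of both net signs exist. Parallel activating and
#' inhibiting edges between the same pair are both considered.
#'
#' @param graph a `signed_graph`.
#' @param src,dst node names.
#' @param max_len maximum path length in edges (default 3).
#' @return integer vector, a subset of `c(-1, 1)`; empty when no path.
#' @export
signed_path_sign <- function(graph, src, dst, max_len = 3) {
  stopifnot(inherits(graph, "signed_graph"))
  g <- graph$graph
  if (!src %in% igraph::V(g)$name || !dst %in% igraph::V(g)$name)
    return(integer(0))
  paths <- igraph::all_simple_paths(g, from = src, to = dst, mode = "out",
                                    cutoff = max_len)
  if (!length(paths)) return(integer(0))
  ed <- igraph::as_data_frame(g, what = "edges")
  signs <- integer(0)
  for (p in paths) {
    ids <- igraph::V(g)$name[p]
    # per hop, collect the distinct signs of parallel edges
    hop_signs <- lapply(seq_len(length(ids) - 1L), function(h)
      unique(ed$sign[ed$from == ids[h] & ed$to == ids[h + 1L]]))
    combos <- do.call(expand.grid, hop_signs)
    signs <- union(signs, apply(combos, 1, prod))
  }
  sort(as.integer(signs))
}

#' Shortest signed path length between two nodes
#' @keywords internal
signed_path_len <- function(graph, src, dst, sign, max_len = 3) {
  g <- graph$graph
  paths <- igraph::all_simple_paths(g, from = src, to = dst, mode = "out",
                                    cutoff = max_len)
  ed <- igraph::as_data_frame(g, what = "edges")
  best <- Inf
  for (p in paths) {
    ids <- igraph::V(g)$name[p]
    hop_signs <- lapply(seq_len(length(ids) - 1L), function(h)
      unique(ed$sign[ed$from == ids[h] & ed$to == ids[h + 1L]]))
    combos <- do.call(expand.grid, hop_signs)
    if (any(apply(combos, 1, prod) == sign)) best <- min(best, length(ids) - 1L)
  }
  best
}

#' Match mechanism roles onto a signed network to find priming motifs
#'
#' A priming motif is a triple (x1, x2, x3) of two upstream regulators and
#' a readout whose path signs match one of the three mechanism templates:
#' * PS (pathway synergy): an LD-induced regulator whose expression under
#'   LD+HD exceeds that under HD (role `PS-regulator`) and an HD-responsive
#'   partner (role `HD-partner`), both with net activating (+1) paths to
#'   the readout.
#' * AI (activator induction): an LD-induced regulator with LD+HD similar
#'   to HD (role `AI-regulator`) with a +1 path, and an HD-responsive
#'   partner with a net inhibiting (-1) path.
#' * SD (suppressor deactivation): an LD-reduced gene (role
#'   `SD-suppressor`) with a -1 path, and an LD/HD-responsive partner with
#'   LD+HD similar to HD (role `HD-partner` or `AI-regulator`) with a +1
#'   path.
#'
#' A motif whose connecting path admits both net signs is emitted with
#' `sign_ambiguous = TRUE` rather than silently choosing one sign. Motifs
#' are deduplicated and ranked by total connecting path length (shorter
#' paths = stronger evidence).
#'
#' @param graph a `signed_graph`.
#' @param roles data.frame with columns `gene` and `role` (one of
#'   `PS-regulator`, `AI-regulator`, `SD-suppressor`, `HD-partner`); extra
#'   columns are ignored. Typically `roles_table(screen_expression(...))`.
#' @param readouts character vector of readout node names; readouts absent
#'   from the graph are skipped with a warning.
#' @param max_len maximum connecting path length in edges (default 3).
#' @return data.frame with one row per motif: `x1`, `x2`, `x3`,
#'   `mechanism`, `sign_x1`, `sign_x2`, `sign_ambiguous`, `path_len`,
#'   `evidence`; zero rows when nothing matches.
#' @export
find_motifs <- function(graph, roles, readouts, max_len = 3) {
  stopifnot(inherits(graph, "signed_graph"), is.data.frame(roles))
  if (!length(readouts)) stop("readout list is empty")
  if (!all(c("gene", "role") %in% names(roles)))
    stop("roles needs columns 'gene' and 'role'")
  genes_with <- function(role) unique(roles$gene[roles$role %in% role])
  out <- list()
  add <- function(x1, x2, x3, mech, s1, s2) {
    sg1 <- signed_path_sign(graph, x1, x3, max_len)
    sg2 <- signed_path_sign(graph, x2, x3, max_len)
    if (!(s1 %in% sg1) || !(s2 %in% sg2)) return()
    len <- signed_path_len(graph, x1, x3, s1, max_len) +
      signed_path_len(graph, x2, x3, s2, max_len)
    out[[length(out) + 1L]] <<- data.frame(
      x1 = x1, x2 = x2, x3 = x3, mechanism = mech,
      sign_x1 = s1, sign_x2 = s2,
      sign_ambiguous = length(sg1) > 1L || length(sg2) > 1L,
      path_len = len,
      evidence = sprintf("%s [%s], %s [%s]", x1,
                         roles$role[match(x1, roles$gene)],
                         x2, roles$role[match(x2, roles$gene)]),
      stringsAsFactors = FALSE)
  }
  for (x3 in readouts) {
    if (!graph_has_node(graph, x3)) {
      warning("readout '", x3, "' not in graph; skipped")
      next
    }
    for (a in setdiff(genes_with("PS-regulator"), x3))
      for (b in setdiff(genes_with("HD-partner"), c(a, x3)))
        add(a, b, x3, "PS", 1L, 1L)
    for (a in setdiff(genes_with("AI-regulator"), x3))
      for (b in setdiff(genes_with("HD-partner"), c(a, x3)))
        add(a, b, x3, "AI", 1L, -1L)
    for (a in setdiff(genes_with("SD-suppressor"), x3))
      for (b in setdiff(genes_with(c("HD-partner", "AI-regulator")), c(a, x3)))
        add(a, b, x3, "SD", -1L, 1L)
  }
  if (!length(out))
    return(data.frame(x1 = character(0), x2 = character(0), x3 = character(0),
                      mechanism = character(0), sign_x1 = integer(0),
                      sign_x2 = integer(0), sign_ambiguous = logical(0),
                      path_len = numeric(0), evidence = character(0)))
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[, c("x1", "x2", "x3", "mechanism")]), , drop = FALSE]
  res <- res[order(res$path_len, res$mechanism, res$x1, res$x2), , drop = FALSE]
  rownames(res) <- NULL
  res
}
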