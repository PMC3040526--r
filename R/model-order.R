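#' Order entities so referenced entities come first
#'
#' Computes a deterministic order in which tables can be created and data
#' files imported: for every non-self cross-reference, the target entity
#' precedes the source. Ties are broken by declaration order (Kahn's
#' algorithm always picking the earliest-declared ready entity, which
#' yields the unique valid order minimal in declaration-index
#' lexicographic terms).
#'
#' Reference edges where the referring field is nillable are *soft*: if
#' honoring them all is impossible (a cycle through nillable edges), the
#' soft edges on cycles are relaxed and the batch importer resolves those
#' cells in a second pass. A cycle consisting only of non-nillable edges is
#' unsatisfiable and raises `MODEL_XREF_CYCLE`. Self-references are ignored
#' for ordering.
#'
#' @param model a valid, resolved [ga_model()]
#' @return character vector of entity names in load order
#' @export
entity_load_order <- function(model) {
  cyc <- hard_xref_cycle(model)
  if (!is.null(cyc))
    ga_stop("MODEL_XREF_CYCLE",
            paste("cross-reference cycle with no nillable edge:",
                  paste(cyc, collapse = " -> ")))
  nms <- entity_names(model)
  edges <- xref_edges(model)           # target must precede source
  # relax soft (nillable) edges that sit on cycles, keep the rest
  repeat {
    ord <- kahn_order(nms, edges)
    if (!is.null(ord)) return(nms[ord])
    soft <- which(edges$soft)
    if (length(soft) == 0)
      ga_stop("MODEL_XREF_CYCLE", "unsatisfiable reference constraints")
    # drop the soft edges involved in the remaining strongly connected part
    stuck <- setdiff(seq_along(nms), kahn_progress(nms, edges))
    drop <- soft[edges$from[soft] %in% stuck & edges$to[soft] %in% stuck]
    if (length(drop) == 0) drop <- soft
    edges <- edges[-drop, , drop = FALSE]
  }
}

# data frame of precedence edges: row (from=target idx, to=source idx)
xref_edges <- function(model) {
  nms <- tolower(entity_names(model))
  from <- integer(); to <- integer(); soft <- logical()
  for (i in seq_along(model$entities)) {
    e <- model$entities[[i]]
    for (f in xref_fields(e)) {
      if (is.na(f$xref_entity)) next
      j <- match(tolower(f$xref_entity), nms)
      if (is.na(j) || j == i) next   # self-references ignored for ordering
      from <- c(from, j); to <- c(to, i); soft <- c(soft, isTRUE(f$nillable))
    }
  }
  data.frame(from = from, to = to, soft = soft)
}

# Kahn topological sort with earliest-declaration tie-break; NULL on cycle
kahn_order <- function(nms, edges) {
  n <- length(nms)
  indeg <- tabulate(edges$to, nbins = n)
  done <- logical(n)
  out <- integer(0)
  while (length(out) < n) {
    ready <- which(!done & indeg == 0L)
    if (length(ready) == 0) return(NULL)
    k <- ready[1]                       # smallest declaration index
    done[k] <- TRUE
    out <- c(out, k)
    for (w in edges$to[edges$from == k]) indeg[w] <- indeg[w] - 1L
  }
  out
}

# indices of entities that CAN be ordered before getting stuck
kahn_progress <- function(nms, edges) {
  n <- length(nms)
  indeg <- tabulate(edges$to, nbins = n)
  done <- logical(n)
  out <- integer(0)
  repeat {
    ready <- which(!done & indeg == 0L)
    if (length(ready) == 0) return(out)
    k <- ready[1]
    done[k] <- TRUE
    out <- c(out, k)
    for (w in edges$to[edges$from == k]) indeg[w] <- indeg[w] - 1L
  }
}

# detect a reference cycle made purely of non-nillable (hard) edges;
# returns entity names on such a cycle, or NULL
hard_xref_cycle <- function(model) {
  nms <- entity_names(model)
  edges <- xref_edges(model)
  hard <- edges[!edges$soft, , drop = FALSE]
  n <- length(nms)
  color <- integer(n)  # 0 white, 1 grey, 2 black
  parent <- integer(n)
  cycle <- NULL
  visit <- function(v) {
    color[v] <<- 1L
    for (w in hard$to[hard$from == v]) {
      if (!is.null(cycle)) return()
      if (color[w] == 0L) { parent[w] <<- v; visit(w) }
      else if (color[w] == 1L) {
        path <- v
        while (path[1] != w && parent[path[1]] != 0L)
          path <- c(parent[path[1]], path)
        cycle <<- nms[c(path, w)]
      }
    }
    color[v] <<- 2L
  }
  for (v in seq_len(n)) if (color[v] == 0L && is.null(cycle)) visit(v)
  cycle
}
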