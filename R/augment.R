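# Restricted-linkage augmentation. A position on a residue is "capable" of
# carrying a linkage if any glycan in the dataset attaches a child at that
# position on a residue with the same label. For each residue in a glycan,
# the capable-but-unoccupied positions are merged into a single restricted-
# linkage node whose edge label lists those positions. This is what lets a
# terminal motif (e.g. the T antigen with an unsubstituted galactose) be
# distinguished from the same subtree buried inside a larger structure.

#' Build a capability map from a glycan collection
#'
#' Records, for every residue label, the set of attachment positions observed
#' occupied anywhere in the collection. Unknown positions (`'?'`) never enter
#' the map: an unknown linkage cannot certify chemical capability.
#'
#' @param glycans A list of `glycan_tree` objects (unaugmented).
#' @return A named list mapping residue label to a sorted integer vector of
#'   positions; class `capability_map`.
#' @examples
#' gs <- lapply(c("Galb1-3GalNAc", "Neu5Aca2-3Galb1-3GalNAc"), parse_cfg_glycan)
#' build_capability_map(gs)
#' @export
build_capability_map <- function(glycans) {
  stopifnot(length(glycans) > 0L)
  cap <- new.env(parent = emptyenv())
  for (g in glycans) {
    for (v in seq_along(g$label)) {
      p <- g$parent[v]
      if (p == 0L || is_restricted_node(g, v)) next
      pos <- edge_parent_pos(g$elab[v])
      if (pos == "?") next
      lab <- g$label[p]
      cap[[lab]] <- union(cap[[lab]], as.integer(pos))
    }
  }
  out <- lapply(as.list(cap), sort)
  if (length(out)) out <- out[order(names(out), method = "radix")]
  structure(out, class = "capability_map")
}

#' Add restricted-linkage nodes to a glycan
#'
#' For each residue, the positions in the capability map for its label that
#' are not occupied by a child in this glycan are attached as a single
#' restricted-linkage node (label `"X"`, edge label `"*p1,p2,..."`).
#' Residues whose capable positions are all occupied are left unchanged, as
#' are labels absent from the map. Re-applying the augmentation is a no-op
#' (existing restricted nodes are recomputed, not duplicated).
#'
#' @param g A `glycan_tree`.
#' @param cap A `capability_map` from [build_capability_map()].
#' @return A `glycan_tree` with restricted-linkage nodes added.
#' @export
add_restricted_linkages <- function(g, cap) {
  keep <- which(!vapply(seq_along(g$label),
                        function(v) is_restricted_node(g, v), logical(1)))
  remap <- match(seq_along(g$label), keep)
  label <- g$label[keep]
  parent <- g$parent[keep]
  nz <- parent != 0L
  parent[nz] <- remap[parent[nz]]
  elab <- g$elab[keep]

  n <- length(label)
  for (v in seq_len(n)) {
    capable <- cap[[label[v]]]
    if (is.null(capable) || length(capable) == 0L) next
    kids <- which(parent[seq_along(label)] == v)
    kids <- kids[!startsWith(elab[kids], "*")]
    occ <- vapply(kids, function(k) edge_parent_pos(elab[k]), character(1))
    occ <- suppressWarnings(as.integer(occ[occ != "?"]))
    empty <- setdiff(capable, occ)
    if (length(empty) == 0L) next
    label <- c(label, "X")
    parent <- c(parent, v)
    elab <- c(elab, paste0("*", paste(sort(empty), collapse = ",")))
  }
  glycan_tree(label, parent, elab, root_anomer = g$root_anomer, spacer = g$spacer)
}
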