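# Core data model: rooted labelled trees for glycans and motifs.
#
# A glycan is a rooted directed tree: nodes are monosaccharide residues
# (labels such as "Gal", "GlcNAc", "Neu5Ac", with covalent modifications
# folded into the label, e.g. "Gal6S"), edges run parent -> child and carry
# the glycosidic linkage written "<anomer><child-carbon>-<parent-position>"
# (e.g. "b1-3"). The root is the reducing-end residue. Restricted-linkage
# pseudo-nodes (label "X") mark unoccupied-but-capable positions; their edge
# label is "*<p1>,<p2>,..." with the positions sorted ascending.

#' Construct a glycan tree
#'
#' Low-level constructor for the rooted labelled tree used throughout the
#' package. Most users will obtain trees from [parse_cfg_glycan()] rather
#' than calling this directly.
#'
#' @param label Character vector of node labels; restricted-linkage nodes use
#'   label `"X"`.
#' @param parent Integer vector of parent indices, `0` for the root. Exactly
#'   one node must be the root.
#' @param elab Character vector of edge labels (the edge from each node's
#'   parent): `"<anomer><child-carbon>-<parent-position>"` for residues,
#'   `"*p1,p2"` for restricted nodes, `NA` for the root.
#' @param root_anomer Optional anomeric configuration of the root toward the
#'   spacer/aglycone, `"a"`, `"b"` or `"?"`.
#' @param spacer Optional spacer identifier stripped from the input text
#'   (e.g. `"Sp0"`).
#' @return An object of class `glycan_tree`.
#' @export
glycan_tree <- function(label, parent, elab = rep(NA_character_, length(label)),
                        root_anomer = NA_character_, spacer = NA_character_) {
  label <- as.character(label)
  parent <- as.integer(parent)
  elab <- as.character(elab)
  n <- length(label)
  stopifnot(length(parent) == n, length(elab) == n)
  t <- structure(
    list(label = label, parent = parent, elab = elab,
         root_anomer = root_anomer, spacer = spacer),
    class = "glycan_tree"
  )
  validate_glycan_tree(t)
  t
}

#' Construct a motif
#'
#' A motif is a (possibly restricted-linkage-augmented) subtree pattern with
#' an optional constraint on the anomer of the edge entering the motif root
#' from its parent in a matched glycan.
#'
#' @inheritParams glycan_tree
#' @param parent_anomer One of `NA` (unconstrained), `"a"`, `"b"` or `"ab"`
#'   (any linked parent residue required, anomer free).
#' @return An object of class `glycan_motif` (inherits `glycan_tree`).
#' @export
glycan_motif <- function(label, parent, elab = rep(NA_character_, length(label)),
                         parent_anomer = NA_character_) {
  t <- glycan_tree(label, parent, elab)
  if (!is.na(parent_anomer) && !parent_anomer %in% c("a", "b", "ab")) {
    stop("parent_anomer must be NA, 'a', 'b' or 'ab'", call. = FALSE)
  }
  t$parent_anomer <- parent_anomer
  class(t) <- c("glycan_motif", "glycan_tree")
  t
}

#' Coerce a tree to a motif
#' @param tree A `glycan_tree`.
#' @param parent_anomer Parent-edge anomer constraint (see [glycan_motif()]).
#' @return A `glycan_motif` with the same topology.
#' @export
as_motif <- function(tree, parent_anomer = NA_character_) {
  glycan_motif(tree$label, tree$parent, tree$elab, parent_anomer = parent_anomer)
}

validate_glycan_tree <- function(t) {
  n <- length(t$label)
  if (n == 0L) stop("glycan tree must have at least one node", call. = FALSE)
  root <- which(t$parent == 0L)
  if (length(root) != 1L) stop("glycan tree must have exactly one root", call. = FALSE)
  if (any(is.na(t$label)) || any(!nzchar(t$label))) {
    stop("node labels must be non-empty", call. = FALSE)
  }
  # parent pointers must be acyclic and in range
  other <- setdiff(seq_len(n), root)
  if (length(other) && (any(t$parent[other] < 1L) || any(t$parent[other] > n))) {
    stop("parent index out of range", call. = FALSE)
  }
  depth_guard <- 0L
  for (v in other) {
    u <- v
    steps <- 0L
    while (u != root) {
      u <- t$parent[u]
      steps <- steps + 1L
      if (steps > n) stop("cycle in parent pointers", call. = FALSE)
    }
    depth_guard <- max(depth_guard, steps)
  }
  if (length(other) && any(is.na(t$elab[other]))) {
    stop("non-root nodes must carry an edge label", call. = FALSE)
  }
  # siblings may not reuse an attachment position (except unknown '?'),
  # and at most one restricted node per residue
  for (v in seq_len(n)) {
    kids <- which(t$parent == v)
    if (length(kids) < 2L) next
    rn <- vapply(kids, function(k) is_restricted_node(t, k), logical(1))
    if (sum(rn) > 1L) stop("at most one restricted-linkage node per residue", call. = FALSE)
    pos <- vapply(kids[!rn], function(k) edge_parent_pos(t$elab[k]), character(1))
    pos <- pos[pos != "?"]
    if (anyDuplicated(pos)) {
      stop("two children occupy the same parent position", call. = FALSE)
    }
  }
  invisible(t)
}

tree_root <- function(t) which(t$parent == 0L)

tree_children <- function(t) {
  n <- length(t$label)
  kids <- vector("list", n)
  for (v in seq_len(n)[-tree_root(t)]) {
    p <- t$parent[v]
    kids[[p]] <- c(kids[[p]], v)
  }
  kids
}

#' @export
format.glycan_tree <- function(x, ...) {
  sprintf("<glycan_tree: %d nodes, root %s%s>",
          length(x$label), x$label[tree_root(x)],
          if (!is.na(x$spacer)) paste0(", spacer ", x$spacer) else "")
}

#' @export
print.glycan_tree <- function(x, ...) {
  cat(format(x), "\n")
  cat(write_glycan_text(x), "\n")
  invisible(x)
}

#' @export
print.glycan_motif <- function(x, ...) {
  cat(sprintf("<glycan_motif: %d nodes>\n", length(x$label)))
  cat(write_motif_text(x), "\n")
  invisible(x)
}

is_restricted_node <- function(t, v) {
  !is.na(t$elab[v]) && startsWith(t$elab[v], "*")
}

n_residues <- function(t) {
  sum(!vapply(seq_along(t$label), function(v) is_restricted_node(t, v), logical(1)))
}

edge_anomer <- function(elab) {
  ifelse(is.na(elab) | startsWith(elab, "*"), NA_character_, substr(elab, 1L, 1L))
}

edge_parent_pos <- function(elab) {
  if (is.na(elab)) return(NA_character_)
  sub("^.*-", "", elab)
}

#' Canonical code of a tree or motif
#'
#' Produces a total order-independent string encoding: two rooted labelled
#' trees have equal codes if and only if they are isomorphic (node labels and
#' edge labels both compared; child order ignored). Codes are used to
#' deduplicate mined subtrees and to give deterministic output order. The
#' encoding is `label(child1)(child2)...` with each child rendered as
#' `(<edge-label>><child code>)` and children sorted bytewise.
#'
#' Note the code does not include a motif's parent-edge anomer constraint;
#' motifs are keyed by the pair (code, parent anomer).
#'
#' @param t A `glycan_tree` or `glycan_motif`.
#' @return A single string.
#' @export
canonical_code <- function(t) {
  kids <- tree_children(t)
  code_of <- function(v) {
    ks <- kids[[v]]
    if (is.null(ks)) return(t$label[v])
    parts <- vapply(ks, function(k) paste0("(", t$elab[k], ">", code_of(k), ")"),
                    character(1))
    paste0(t$label[v], paste(sort(parts, method = "radix"), collapse = ""))
  }
  code_of(tree_root(t))
}

#' Decode a canonical code back into a motif
#'
#' Inverse of [canonical_code()]; used to materialise mined patterns (which
#' are carried as codes) into motif objects.
#'
#' @param code A canonical code string.
#' @param parent_anomer Optional parent-edge anomer constraint.
#' @return A `glycan_motif`.
#' @export
decode_canonical_code <- function(code, parent_anomer = NA_character_) {
  label <- character(0)
  parent <- integer(0)
  elab <- character(0)
  i <- 1L
  nch <- nchar(code)
  peek <- function() if (i <= nch) substr(code, i, i) else ""
  read_until <- function(stops) {
    j <- i
    while (j <= nch && !substr(code, j, j) %in% stops) j <- j + 1L
    out <- substr(code, i, j - 1L)
    i <<- j
    out
  }
  parse_node <- function(par, el) {
    lab <- read_until(c("(", ")"))
    if (!nzchar(lab)) stop("malformed canonical code", call. = FALSE)
    label <<- c(label, lab)
    parent <<- c(parent, par)
    elab <<- c(elab, el)
    me <- length(label)
    while (peek() == "(") {
      i <<- i + 1L
      child_el <- read_until(">")
      i <<- i + 1L  # skip '>'
      parse_node(me, child_el)
      if (peek() != ")") stop("malformed canonical code", call. = FALSE)
      i <<- i + 1L
    }
    me
  }
  parse_node(0L, NA_character_)
  if (i <= nch) stop("malformed canonical code", call. = FALSE)
  glycan_motif(label, parent, elab, parent_anomer = parent_anomer)
}

#' Test whether a glycan contains a motif
#'
#' Decides subtree containment: is there a mapping of the motif's nodes into
#' the glycan's nodes that preserves parent/child edges, matches node labels
#' exactly, and matches edge labels exactly? Restricted-linkage edge labels
#' (position sets) are compared for set equality. A parent-edge anomer
#' constraint on the motif requires the matched root to have a parent edge in
#' the glycan with that anomer (`"ab"`: any parent edge; unknown-anomer `'?'`
#' parent edges satisfy only `"ab"`).
#'
#' @param g A `glycan_tree` (typically restricted-linkage-augmented).
#' @param m A `glycan_motif`.
#' @return `TRUE` or `FALSE`.
#' @export
contains_motif <- function(g, m) {
  roots <- motif_root_matches(g, m)
  if (!length(roots)) return(FALSE)
  pan <- if (inherits(m, "glycan_motif")) m$parent_anomer else NA_character_
  if (is.na(pan)) return(TRUE)
  linked <- roots[g$parent[roots] != 0L]
  if (pan == "ab") return(length(linked) > 0L)
  any(substr(g$elab[linked], 1L, 1L) == pan)
}

# glycan nodes at which the motif embeds as a rooted subtree (parent-edge
# anomer constraints are not applied here)
motif_root_matches <- function(g, m, gk = tree_children(g), mk = tree_children(m)) {
  mroot <- tree_root(m)

  match_at <- function(mv, gv) {
    if (m$label[mv] != g$label[gv]) return(FALSE)
    mks <- mk[[mv]]
    if (is.null(mks)) return(TRUE)
    gks <- gk[[gv]]
    if (length(gks) < length(mks)) return(FALSE)
    used <- logical(length(gks))
    assign_child <- function(idx) {
      if (idx > length(mks)) return(TRUE)
      mc <- mks[[idx]]
      for (j in seq_along(gks)) {
        if (used[j]) next
        gc <- gks[[j]]
        if (!identical(m$elab[mc], g$elab[gc])) next
        if (match_at(mc, gc)) {
          used[j] <<- TRUE
          if (assign_child(idx + 1L)) return(TRUE)
          used[j] <<- FALSE
        }
      }
      FALSE
    }
    assign_child(1L)
  }

  which(vapply(seq_along(g$label), function(gv) {
    g$label[gv] == m$label[mroot] && match_at(mroot, gv)
  }, logical(1)))
}
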