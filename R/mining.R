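# Frequent subtree mining over restricted-linkage-augmented glycans, by
# support-pruned pattern growth: start from frequent single residues and
# repeatedly extend frequent patterns by one edge observed in the data,
# deduplicating by canonical code. Because pattern support is anti-monotone
# (adding a node can only shrink the set of containing glycans), pruning at
# each step is exact. Support is per-glycan: a glycan counts once no matter
# how many embeddings it offers, and a pattern is frequent when contained in
# at least ceiling(min_support * n) glycans.

# All embeddings of pattern m into glycan g: integer maps (pattern node ->
# glycan node) preserving parent/child edges, node labels and edge labels.
all_embeddings <- function(g, m, gkids = tree_children(g), mkids = tree_children(m)) {
  nm <- length(m$label)
  maps_at <- function(mv, gv) {
    if (m$label[mv] != g$label[gv]) return(NULL)
    base <- rep(NA_integer_, nm)
    base[mv] <- gv
    mks <- mkids[[mv]]
    if (is.null(mks)) return(list(base))
    gks <- gkids[[gv]]
    if (length(gks) < length(mks)) return(NULL)
    states <- list(list(map = base, used = integer(0)))
    for (mc in mks) {
      new <- list()
      for (st in states) {
        for (gc in gks) {
          if (gc %in% st$used) next
          if (!identical(m$elab[mc], g$elab[gc])) next
          for (sm in maps_at(mc, gc)) {
            merged <- st$map
            sel <- !is.na(sm)
            merged[sel] <- sm[sel]
            new[[length(new) + 1L]] <- list(map = merged, used = c(st$used, gc))
          }
        }
      }
      states <- new
      if (!length(states)) return(NULL)
    }
    lapply(states, `[[`, "map")
  }
  out <- list()
  for (gv in seq_along(g$label)) {
    out <- c(out, maps_at(tree_root(m), gv))
  }
  out
}

#' Mine frequent subtrees from a glycan collection
#'
#' Finds every connected rooted subtree pattern (restricted-linkage nodes
#' included as ordinary nodes, but never as pattern roots or sole nodes)
#' contained in at least `ceiling(min_support * length(glycans))` glycans.
#' Patterns are grown one edge at a time from frequent seeds with exact
#' anti-monotone pruning, so only (extensions of) frequent patterns are ever
#' visited. Output order is canonical-code lexicographic, making runs
#' reproducible.
#'
#' @param glycans List of (typically augmented) `glycan_tree` objects.
#' @param min_support Minimum support as a fraction in (0, 1].
#' @param max_nodes Optional cap on pattern size (number of nodes, restricted
#'   nodes included); `Inf` disables the cap.
#' @return A data frame of class `frequent_subtrees` with columns `code`,
#'   `support`, `count`, `size` and a list column `occ` of indices of the
#'   glycans containing each pattern. Attribute `n_glycans` records the
#'   collection size.
#' @export
mine_frequent_subtrees <- function(glycans, min_support, max_nodes = Inf) {
  if (!is.numeric(min_support) || length(min_support) != 1L ||
      is.na(min_support) || min_support <= 0 || min_support > 1) {
    stop("min_support must be a fraction in (0, 1]", call. = FALSE)
  }
  stopifnot(length(glycans) > 0L)
  n <- length(glycans)
  need <- ceiling(min_support * n)
  gkids <- lapply(glycans, tree_children)

  res_code <- character(0)
  res_count <- integer(0)
  res_size <- integer(0)
  res_occ <- list()
  seen <- new.env(parent = emptyenv())

  # seed patterns: single residues (restricted nodes are never roots)
  lab_occ <- list()
  for (gi in seq_len(n)) {
    g <- glycans[[gi]]
    labs <- unique(g$label[!vapply(seq_along(g$label),
                                   function(v) is_restricted_node(g, v), logical(1))])
    for (lb in labs) lab_occ[[lb]] <- c(lab_occ[[lb]], gi)
  }
  queue <- list()
  for (lb in sort(names(lab_occ), method = "radix")) {
    occ <- lab_occ[[lb]]
    if (length(occ) < need) next
    pat <- glycan_motif(lb, 0L)
    emb <- lapply(occ, function(gi) {
      g <- glycans[[gi]]
      vs <- which(g$label == lb &
                    !vapply(seq_along(g$label), function(v)
                      is_restricted_node(g, v), logical(1)))
      lapply(vs, function(v) v)
    })
    assign(lb, TRUE, envir = seen)
    res_code <- c(res_code, lb)
    res_count <- c(res_count, length(occ))
    res_size <- c(res_size, 1L)
    res_occ <- c(res_occ, list(occ))
    queue[[length(queue) + 1L]] <- list(pat = pat, occ = occ, emb = emb, size = 1L)
  }

  qi <- 1L
  while (qi <= length(queue)) {
    P <- queue[[qi]]
    qi <- qi + 1L
    if (P$size >= max_nodes) next

    triples <- new.env(parent = emptyenv())  # key -> list(code, elab, label, at)
    cand_count <- new.env(parent = emptyenv())
    cand_occ <- new.env(parent = emptyenv())
    for (oi in seq_along(P$occ)) {
      gi <- P$occ[oi]
      g <- glycans[[gi]]
      codes_here <- character(0)
      for (e in P$emb[[oi]]) {
        for (i in seq_len(P$size)) {
          for (gc in gkids[[gi]][[e[i]]]) {
            if (gc %in% e) next
            key <- paste(i, g$elab[gc], g$label[gc], sep = "\r")
            tr <- triples[[key]]
            if (is.null(tr)) {
              child <- glycan_motif(c(P$pat$label, g$label[gc]),
                                    c(P$pat$parent, i),
                                    c(P$pat$elab, g$elab[gc]))
              tr <- list(code = canonical_code(child), pat = child)
              triples[[key]] <- tr
            }
            codes_here <- c(codes_here, tr$code)
          }
        }
      }
      for (cd in unique(codes_here)) {
        cand_count[[cd]] <- (cand_count[[cd]] %||% 0L) + 1L
        cand_occ[[cd]] <- c(cand_occ[[cd]], gi)
      }
    }
    # representative pattern per candidate code
    reps <- new.env(parent = emptyenv())
    for (key in ls(triples)) {
      tr <- triples[[key]]
      if (is.null(reps[[tr$code]])) reps[[tr$code]] <- tr$pat
    }
    for (cd in sort(ls(cand_count), method = "radix")) {
      if (cand_count[[cd]] < need || !is.null(seen[[cd]])) next
      assign(cd, TRUE, envir = seen)
      pat <- reps[[cd]]
      occ <- sort(cand_occ[[cd]])
      mk <- tree_children(pat)
      emb <- lapply(occ, function(gi) {
        all_embeddings(glycans[[gi]], pat, gkids[[gi]], mk)
      })
      res_code <- c(res_code, cd)
      res_count <- c(res_count, cand_count[[cd]])
      res_size <- c(res_size, P$size + 1L)
      res_occ <- c(res_occ, list(occ))
      queue[[length(queue) + 1L]] <- list(pat = pat, occ = occ, emb = emb,
                                          size = P$size + 1L)
    }
  }

  ord <- order(res_code, method = "radix")
  res <- data.frame(code = res_code[ord], support = res_count[ord] / n,
                    count = res_count[ord], size = res_size[ord],
                    stringsAsFactors = FALSE)
  res$occ <- res_occ[ord]
  attr(res, "n_glycans") <- n
  class(res) <- c("frequent_subtrees", class(res))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mine candidate motifs from the whole array and the positive binders
#'
#' Candidate motifs are the union of subtrees frequent in the full collection
#' (default support 5%) and subtrees frequent in the positive-binding subset
#' at a higher threshold (default 40%), the latter capturing motifs shared by
#' binders but too rare on the array overall. Duplicates are merged by
#' canonical code, recording provenance (`"global"`, `"positive"` or
#' `"both"`); supports and occurrences always refer to the full collection.
#'
#' @param glycans List of augmented `glycan_tree` objects.
#' @param positive Integer indices (into `glycans`) of the positive binders.
#' @param global_min_support,positive_min_support Support thresholds.
#' @param max_nodes Optional pattern-size cap.
#' @return A `frequent_subtrees` data frame with a `provenance` column.
#' @export
mine_candidate_motifs <- function(glycans, positive,
                                  global_min_support = 0.05,
                                  positive_min_support = 0.40,
                                  max_nodes = Inf) {
  glob <- mine_frequent_subtrees(glycans, global_min_support, max_nodes)
  if (length(positive) == 0L) {
    warning("no positive binders; returning globally frequent subtrees only")
    glob$provenance <- rep("global", nrow(glob))
    return(glob)
  }
  pos <- mine_frequent_subtrees(glycans[positive], positive_min_support, max_nodes)
  extra <- setdiff(pos$code, glob$code)
  glob$provenance <- ifelse(glob$code %in% pos$code, "both", "global")
  if (length(extra)) {
    n <- length(glycans)
    pos_occ_all <- lapply(pos$occ[match(extra, pos$code)],
                          function(ix) positive[ix])
    occ <- vector("list", length(extra))
    others <- setdiff(seq_len(n), positive)
    for (j in seq_along(extra)) {
      m <- decode_canonical_code(extra[j])
      hit <- others[vapply(others, function(gi)
        contains_motif(glycans[[gi]], m), logical(1))]
      occ[[j]] <- sort(c(pos_occ_all[[j]], hit))
    }
    codes <- c(glob$code, extra)
    ord <- order(codes, method = "radix")
    counts <- c(glob$count, vapply(occ, length, integer(1)))
    res <- data.frame(
      code = codes[ord],
      support = counts[ord] / n,
      count = counts[ord],
      size = c(glob$size, pos$size[match(extra, pos$code)])[ord],
      provenance = c(glob$provenance, rep("positive", length(extra)))[ord],
      stringsAsFactors = FALSE
    )
    res$occ <- c(glob$occ, occ)[ord]
  } else {
    res <- glob
  }
  attr(res, "n_glycans") <- length(glycans)
  class(res) <- c("frequent_subtrees", class(res))
  res
}

#' Compute a binary motif-occurrence feature matrix
#'
#' One row per glycan, one column per motif; entry (i, j) is 1 exactly when
#' glycan i contains motif j under the containment semantics of
#' [contains_motif()] (exact node and edge labels, set-equal restricted
#' positions, parent-edge anomer constraints honoured).
#'
#' @param glycans List of augmented `glycan_tree` objects.
#' @param motifs Motifs as a list of `glycan_motif` objects, a character
#'   vector of canonical codes, or a data frame with columns `code` and
#'   `parent_anomer`.
#' @param labels Optional per-glycan class labels (0/1), attached as
#'   attribute `labels`.
#' @return An integer matrix with motif texts as column names.
#' @export
compute_feature_matrix <- function(glycans, motifs, labels = NULL) {
  spec <- as_motif_spec(motifs)
  objs <- lapply(seq_len(nrow(spec)), function(j)
    decode_canonical_code(spec$code[j], spec$parent_anomer[j]))
  mat <- matrix(0L, nrow = length(glycans), ncol = nrow(spec))
  for (i in seq_along(glycans)) {
    for (j in seq_along(objs)) {
      if (contains_motif(glycans[[i]], objs[[j]])) mat[i, j] <- 1L
    }
  }
  colnames(mat) <- motif_spec_text(spec)
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(glycans))
    attr(mat, "labels") <- labels
  }
  mat
}

# normalise the several accepted motif representations to (code, parent_anomer)
as_motif_spec <- function(motifs) {
  if (is.character(motifs)) {
    spec <- data.frame(code = motifs,
                       parent_anomer = rep(NA_character_, length(motifs)),
                       stringsAsFactors = FALSE)
  } else if (is.data.frame(motifs)) {
    stopifnot("code" %in% names(motifs))
    spec <- data.frame(code = motifs$code, stringsAsFactors = FALSE)
    spec$parent_anomer <- if ("parent_anomer" %in% names(motifs)) {
      motifs$parent_anomer
    } else {
      NA_character_
    }
  } else if (is.list(motifs)) {
    spec <- data.frame(
      code = vapply(motifs, canonical_code, character(1)),
      parent_anomer = vapply(motifs, function(m) {
        if (inherits(m, "glycan_motif")) m$parent_anomer else NA_character_
      }, character(1)),
      stringsAsFactors = FALSE
    )
  } else {
    stop("unsupported motif representation", call. = FALSE)
  }
  if (anyDuplicated(paste(spec$code, spec$parent_anomer))) {
    stop("motifs must be deduplicated", call. = FALSE)
  }
  spec
}

# fast path: occurrence lists from mining -> binary matrix (columns = codes)
matrix_from_occ <- function(n, occ) {
  mat <- matrix(0L, nrow = n, ncol = length(occ))
  for (j in seq_along(occ)) mat[occ[[j]], j] <- 1L
  mat
}

motif_spec_text <- function(spec) {
  vapply(seq_len(nrow(spec)), function(j) {
    write_motif_text(decode_canonical_code(spec$code[j], spec$parent_anomer[j]))
  }, character(1))
}
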