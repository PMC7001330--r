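# Independent oracles used to check the package's miner, matcher and
# selectors. These deliberately take different algorithmic routes from the
# implementation: the subtree oracle generates every pattern by explicit
# subset expansion and counts containment with the backtracking matcher,
# the isomorphism oracle tries child permutations exhaustively, and the
# mRMR oracle recomputes mutual information from entropies.

# all connected rooted sub-patterns of one glycan, as glycan_motif objects
# (restricted-linkage nodes are never pattern roots)
oracle_subpatterns <- function(g) {
  kids <- glycanmotifs:::tree_children(g)
  restricted <- vapply(seq_along(g$label),
                       function(v) glycanmotifs:::is_restricted_node(g, v),
                       logical(1))
  # patterns rooted at v, each a list(nodes=glycan node ids in parent-first order)
  pats_at <- function(v) {
    ks <- kids[[v]]
    if (is.null(ks)) return(list(v))
    sets <- list(v)
    for (ch in ks) {
      child_sets <- pats_at(ch)
      new <- sets
      for (s in sets) {
        for (cs in child_sets) new[[length(new) + 1L]] <- c(s, cs)
      }
      sets <- new
    }
    sets
  }
  build <- function(nodes) {
    idx <- match(g$parent[nodes], nodes)
    parent <- ifelse(is.na(idx), 0L, idx)
    glycan_motif(g$label[nodes], parent, ifelse(parent == 0L, NA, g$elab[nodes]))
  }
  out <- list()
  for (v in which(!restricted)) {
    for (s in pats_at(v)) out[[length(out) + 1L]] <- build(s)
  }
  out
}

# exhaustive pattern counts over a collection: named integer vector
# (canonical code -> number of glycans containing the pattern)
oracle_pattern_counts <- function(glycans) {
  pats <- list()
  seen <- character(0)
  for (g in glycans) {
    for (p in oracle_subpatterns(g)) {
      cd <- canonical_code(p)
      if (!cd %in% seen) {
        seen <- c(seen, cd)
        pats[[cd]] <- p
      }
    }
  }
  counts <- vapply(seen, function(cd) {
    sum(vapply(glycans, contains_motif, logical(1), m = pats[[cd]]))
  }, integer(1))
  counts
}

# rooted-labelled-tree isomorphism by exhaustive child-permutation matching
oracle_isomorphic <- function(a, b, va = glycanmotifs:::tree_root(a),
                              vb = glycanmotifs:::tree_root(b)) {
  if (a$label[va] != b$label[vb]) return(FALSE)
  ka <- which(a$parent == va)
  kb <- which(b$parent == vb)
  if (length(ka) != length(kb)) return(FALSE)
  if (length(ka) == 0L) return(TRUE)
  match_rest <- function(rem_a, rem_b) {
    if (length(rem_a) == 0L) return(TRUE)
    x <- rem_a[1L]
    for (j in seq_along(rem_b)) {
      y <- rem_b[j]
      if (identical(a$elab[x], b$elab[y]) && oracle_isomorphic(a, b, x, y) &&
          match_rest(rem_a[-1L], rem_b[-j])) {
        return(TRUE)
      }
    }
    FALSE
  }
  match_rest(ka, kb)
}

oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_mi <- function(f, y) {
  joint <- c(mean(f == 1 & y == 1), mean(f == 1 & y == 0),
             mean(f == 0 & y == 1), mean(f == 0 & y == 0))
  oracle_entropy(c(mean(f), 1 - mean(f))) +
    oracle_entropy(c(mean(y), 1 - mean(y))) -
    oracle_entropy(joint)
}

# exhaustive greedy mRMR with the same deterministic tie rule (scores within
# 1e-12 of the maximum resolve to the lowest index)
oracle_mrmr <- function(X, y, k) {
  p <- ncol(X)
  rel <- vapply(seq_len(p), function(j) oracle_mi(X[, j], y), numeric(1))
  chosen <- integer(0)
  for (step in seq_len(min(k, p))) {
    best <- -Inf
    best_j <- NA_integer_
    for (j in seq_len(p)) {
      if (j %in% chosen) next
      red <- if (length(chosen)) {
        mean(vapply(chosen, function(s) oracle_mi(X[, j], X[, s]), numeric(1)))
      } else {
        0
      }
      sc <- rel[j] - red
      if (sc > best + 1e-12) {
        best <- sc
        best_j <- j
      }
    }
    chosen <- c(chosen, best_j)
  }
  chosen
}

# brute-force AUC as the probability a positive outscores a negative
oracle_auc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# small random glycan collections for miner/matcher checks
random_small_collection <- function(n_glycans, max_nodes = 8L, augment = TRUE) {
  alpha <- list(A = c(2L, 3L), B = c(3L, 4L), C = c(2L, 6L), D = integer(0))
  gs <- replicate(n_glycans, {
    repeat {
      g <- random_glycan(alpha, max_depth = 3L, branching_prob = 0.4)
      if (length(g$label) <= max_nodes) break
    }
    g
  }, simplify = FALSE)
  if (augment) {
    cap <- build_capability_map(gs)
    gs <- lapply(gs, add_restricted_linkages, cap = cap)
  }
  gs
}
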