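# Synthetic glycan libraries and microarray data with planted motifs.
# The generator emulates what the method assumes about real arrays: a
# log-normal background RFU population, a small minority of binders whose
# structures share a terminal motif and whose RFUs are shifted upward, and a
# configurable fraction of non-binders that carry the same motif capped by a
# further residue (so only the restricted-linkage form discriminates, as
# with the T antigen versus sialyl T antigen).

#' Default residue alphabet for simulation
#'
#' A named list mapping residue label to the backbone positions that can
#' carry a glycosidic linkage. `Neu5Ac` accepts no children (a terminal
#' cap); it links to its parent from carbon 2, all other residues from
#' carbon 1.
#' @return Named list of integer vectors.
#' @export
default_residue_alphabet <- function() {
  list(
    Gal = c(2L, 3L, 4L, 6L),
    Glc = c(2L, 3L, 4L, 6L),
    Man = c(2L, 3L, 4L, 6L),
    GlcNAc = c(3L, 4L, 6L),
    GalNAc = c(3L, 4L, 6L),
    Fuc = c(2L, 3L, 4L),
    Neu5Ac = integer(0)
  )
}

child_carbon_for <- function(label) if (label == "Neu5Ac") "2" else "1"

#' Sample a random glycan tree
#'
#' Recursive growth: the root residue is uniform over the alphabet; each
#' attachable position of each residue is filled with an independent child
#' with probability `branching_prob`, down to `max_depth` levels below the
#' root. Linkage anomers are uniform over alpha/beta. Uses the current RNG
#' state; seed outside.
#'
#' @param alphabet Residue alphabet as in [default_residue_alphabet()].
#' @param max_depth Maximum depth below the root (0 gives a single residue).
#' @param branching_prob Probability of filling each open position (default 0.25, giving realistic array-scale glycans of roughly 2-12 residues).
#' @return A `glycan_tree`.
#' @export
random_glycan <- function(alphabet = default_residue_alphabet(),
                          max_depth = 3L, branching_prob = 0.25) {
  labels <- names(alphabet)
  label <- character(0)
  parent <- integer(0)
  elab <- character(0)
  add <- function(lab, par, el) {
    label <<- c(label, lab)
    parent <<- c(parent, par)
    elab <<- c(elab, el)
    length(label)
  }
  grow <- function(v, depth) {
    if (depth >= max_depth) return()
    for (pos in alphabet[[label[v]]]) {
      if (stats::runif(1) >= branching_prob) next
      lab <- labels[sample.int(length(labels), 1L)]
      an <- sample(c("a", "b"), 1L)
      child <- add(lab, v, paste0(an, child_carbon_for(lab), "-", pos))
      grow(child, depth + 1L)
    }
  }
  root <- add(labels[sample.int(length(labels), 1L)], 0L, NA_character_)
  grow(root, 0L)
  glycan_tree(label, parent, elab)
}

# graft `sub` (a glycan_tree) under node `host_v` of `tree` at a free
# attachable position; returns the modified tree or NULL if no position free
graft_subtree <- function(tree, sub, alphabet, anomer = "b") {
  n <- length(tree$label)
  host_ok <- function(v) {
    capable <- alphabet[[tree$label[v]]]
    if (is.null(capable) || !length(capable)) return(integer(0))
    kids <- which(tree$parent == v)
    occ <- suppressWarnings(as.integer(vapply(kids, function(k)
      edge_parent_pos(tree$elab[k]), character(1))))
    setdiff(capable, occ)
  }
  cands <- which(vapply(seq_len(n), function(v) length(host_ok(v)) > 0, logical(1)))
  if (!length(cands)) return(NULL)
  v <- cands[sample.int(length(cands), 1L)]
  free <- host_ok(v)
  pos <- free[sample.int(length(free), 1L)]
  sroot <- tree_root(sub)
  off <- n
  label <- c(tree$label, sub$label)
  parent <- c(tree$parent, ifelse(sub$parent == 0L, v, sub$parent + off))
  elab <- c(tree$elab, sub$elab)
  elab[off + sroot] <- paste0(anomer, child_carbon_for(sub$label[sroot]), "-", pos)
  glycan_tree(label, parent, elab)
}

# does the tree contain `core` with the core's leaf residues unsubstituted?
# (i.e. a terminal occurrence of the planted motif)
has_terminal_core <- function(tree, core) {
  kids <- tree_children(tree)
  ck <- tree_children(core)
  croot <- tree_root(core)
  match_at <- function(cv, tv) {
    if (core$label[cv] != tree$label[tv]) return(FALSE)
    cks <- ck[[cv]]
    if (is.null(cks)) {
      # core leaf must be terminal in the glycan (no residue children)
      return(length(kids[[tv]]) == 0L)
    }
    tks <- kids[[tv]]
    if (length(tks) < length(cks)) return(FALSE)
    used <- logical(length(tks))
    rec <- function(i) {
      if (i > length(cks)) return(TRUE)
      for (j in seq_along(tks)) {
        if (used[j]) next
        if (!identical(core$elab[cks[i]], tree$elab[tks[j]])) next
        if (match_at(cks[i], tks[j])) {
          used[j] <<- TRUE
          if (rec(i + 1L)) return(TRUE)
          used[j] <<- FALSE
        }
      }
      FALSE
    }
    rec(1L)
  }
  any(vapply(seq_along(tree$label), function(tv) match_at(croot, tv), logical(1)))
}

#' Simulate a glycan microarray with a planted motif
#'
#' Generates `n_glycans` random glycans; exactly `round(fraction_binders *
#' n_glycans)` of them are binders, constructed by grafting the planted
#' motif at a terminal position (its restricted positions left unoccupied).
#' A fraction of the non-binders are decoys carrying the same motif capped
#' at its non-reducing terminus (default: an alpha-2,3-linked Neu5Ac, the
#' sialyl-T mechanism), so the unrestricted motif alone does not separate
#' the classes. Background log10-RFUs are normal with mean `background_mu`
#' and sd `background_sigma`; binder log10-RFUs are shifted by
#' `binder_shift`.
#'
#' @param n_glycans Number of spots.
#' @param fraction_binders Fraction of structural binders, in (0, 0.5).
#' @param binder_shift Additive shift of binder RFUs on the log10 scale.
#' @param decoy_fraction Fraction of non-binders given the capped motif.
#' @param background_mu,background_sigma Background log10-RFU parameters.
#' @param label_flip Fraction of binders whose RFU is left at background
#'   level (membership noise), default 0.
#' @param planted_motif CFG text of the planted core (root attaches to the
#'   host glycan; leaves are the non-reducing terminus).
#' @param decoy_cap CFG-style cap prepended to the motif terminus in decoys,
#'   as `"<residue><anomer><child>-<pos>"`.
#' @param alphabet,max_depth,branching_prob Passed to [random_glycan()].
#' @param seed Integer seed; everything is reproducible given the seed.
#' @return An `array_experiment` whose table has columns `glycan_text`,
#'   `rfu` and the ground-truth flag `is_binder`.
#' @export
simulate_array <- function(n_glycans = 600L, fraction_binders = 0.1,
                           binder_shift = 2.0, decoy_fraction = 0.5,
                           background_mu = 2.0, background_sigma = 0.3,
                           label_flip = 0,
                           planted_motif = "Galb1-3GalNAc",
                           decoy_cap = "Neu5Aca2-3",
                           alphabet = default_residue_alphabet(),
                           max_depth = 3L, branching_prob = 0.25,
                           seed = 1L) {
  stopifnot(fraction_binders > 0, fraction_binders < 0.5, binder_shift >= 0,
            decoy_fraction >= 0, decoy_fraction <= 1)
  core <- parse_cfg_glycan(planted_motif)
  if (!all(core$label %in% names(alphabet))) {
    stop("planted motif uses residues outside the alphabet", call. = FALSE)
  }
  capm <- regexec("^([A-Za-z][A-Za-z0-9,']*)([ab?])([0-9?])-([0-9?])$", decoy_cap)[[1]]
  if (capm[1] != 1L) stop("malformed decoy_cap", call. = FALSE)
  capp <- regmatches(decoy_cap, regexec("^([A-Za-z][A-Za-z0-9,']*)([ab?])([0-9?])-([0-9?])$",
                                        decoy_cap))[[1]]

  n_b <- round(fraction_binders * n_glycans)
  with_seed(seed, {
    is_binder <- logical(n_glycans)
    is_binder[sample.int(n_glycans, n_b)] <- TRUE
    n_nb <- n_glycans - n_b
    decoy <- logical(n_glycans)
    nb_idx <- which(!is_binder)
    decoy[nb_idx[sample.int(n_nb, round(decoy_fraction * n_nb))]] <- TRUE

    fresh_host <- function() {
      for (try in 1:100) {
        g <- random_glycan(alphabet, max_depth, branching_prob)
        if (!has_terminal_core(g, core)) return(g)
      }
      stop("could not sample a host free of the planted motif", call. = FALSE)
    }
    glycans <- vector("list", n_glycans)
    for (i in seq_len(n_glycans)) {
      if (is_binder[i]) {
        repeat {
          g <- graft_subtree(fresh_host(), core, alphabet)
          if (!is.null(g)) break
        }
        glycans[[i]] <- g
      } else if (decoy[i]) {
        repeat {
          g <- graft_subtree(fresh_host(), core, alphabet)
          if (!is.null(g)) break
        }
        # cap the grafted motif's terminus so the restricted form is absent
        # (grafted core nodes sit at the end of the node vector)
        core_leaf <- setdiff(seq_along(core$label), core$parent)[1L]
        term <- length(g$label) - length(core$label) + core_leaf
        label <- c(g$label, capp[2])
        parent <- c(g$parent, term)
        elab <- c(g$elab, paste0(capp[3], capp[4], "-", capp[5]))
        glycans[[i]] <- glycan_tree(label, parent, elab)
      } else {
        glycans[[i]] <- fresh_host()
      }
    }
    flip <- is_binder & (stats::runif(n_glycans) < label_flip)
    log_rfu <- stats::rnorm(n_glycans, background_mu, background_sigma) +
      binder_shift * (is_binder & !flip)
    tab <- data.frame(
      glycan_text = vapply(glycans, write_glycan_text, character(1)),
      rfu = 10^log_rfu,
      is_binder = is_binder,
      stringsAsFactors = FALSE
    )
  })
  array_experiment(tab, glycans)
}

#' Worked three-glycan example with a discriminating terminal motif
#'
#' The motivating T-antigen example: one binder (`Gal b1-3GalNAc`, high RFU)
#' and two sialylated non-binders (`Neu5Ac a2-3/6 Gal b1-3GalNAc`, background
#' RFU). The returned experiment carries, in `$candidates`, the candidate
#' subtrees generated from these glycans: the eight plain subtrees plus the
#' restricted-linkage form of the T antigen, `(*3,6)Gal b1-3GalNAc`, which
#' is the only candidate unique to the binding set once restricted linkages
#' are considered.
#'
#' @return An `array_experiment` with an extra element `candidates` (data
#'   frame with columns `text`, `restricted`, `discriminating`).
#' @export
fig2_fixture <- function() {
  texts <- c("Galb1-3GalNAc", "Neu5Aca2-3Galb1-3GalNAc", "Neu5Aca2-6Galb1-3GalNAc")
  ae <- array_experiment(data.frame(glycan_text = texts,
                                    rfu = c(50000, 100, 120),
                                    stringsAsFactors = FALSE))
  ae$candidates <- data.frame(
    text = c("Gal", "GalNAc", "Neu5Ac",
             "Gal b1-3GalNAc",
             "Neu5Ac a2-3Gal", "Neu5Ac a2-6Gal",
             "Neu5Ac a2-3Gal b1-3GalNAc", "Neu5Ac a2-6Gal b1-3GalNAc",
             "(*3,6)Gal b1-3GalNAc"),
    restricted = c(rep(FALSE, 8), TRUE),
    discriminating = c(rep(FALSE, 8), TRUE),
    stringsAsFactors = FALSE
  )
  ae
}
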