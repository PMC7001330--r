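# Parser for CFG linear text nomenclature (e.g. "Neu5Aca2-3Galb1-4(Fuca1-3)
# GlcNAcb-Sp0"). The rightmost residue is the reducing end (tree root);
# parenthesised segments are branches attached to the residue that follows
# them; a linkage is written "<anomer><child-carbon>-<parent-position>" with
# anomer 'a', 'b' or '?' and positions digits or '?'. A trailing "-Sp<digits>"
# spacer is stripped and recorded, along with the root's dangling anomer
# (e.g. the 'b' of "...GlcNAcb-Sp0").

cfg_parse_error <- function(msg, offset = NA_integer_) {
  stop(errorCondition(
    if (is.na(offset)) msg else sprintf("%s (at offset %d)", msg, offset),
    offset = offset, class = "glycan_parse_error"
  ))
}

# residue name then linkage; residue names are alphanumeric with commas or
# primes (covalent modifications such as "6S" stay inside the label)
.unit_re <- "^([A-Za-z][A-Za-z0-9,']*?)([ab?])([0-9?])-([0-9?])"
.residue_re <- "^[A-Za-z][A-Za-z0-9,']*$"

#' Parse a glycan in CFG linear nomenclature
#'
#' Turns a CFG-style glycan string into a rooted labelled tree. The root is
#' the reducing-end residue (rightmost after spacer stripping); each edge is
#' directed parent to child and labelled with anomer, child carbon and parent
#' position. Unknown anomers/positions are written `'?'` and match only
#' themselves.
#'
#' @param text A single glycan string, e.g. `"Neu5Aca2-3Galb1-3GalNAcb-Sp8"`.
#'   Greek anomer letters are accepted and normalised to `'a'`/`'b'`.
#' @param spacer_pattern Regular expression (with one capture group) matching
#'   the spacer suffix to strip.
#' @return A [glycan_tree()].
#' @examples
#' g <- parse_cfg_glycan("Galb1-3GalNAc")
#' canonical_code(g)
#' @export
parse_cfg_glycan <- function(text, spacer_pattern = "-(Sp[0-9]+)$") {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) {
    cfg_parse_error("empty glycan string")
  }
  s <- gsub("α", "a", gsub("β", "b", text))
  s <- gsub("[[:space:]]", "", s)

  spacer <- NA_character_
  root_anomer <- NA_character_
  m <- regexpr(spacer_pattern, s)
  if (m > 0L) {
    spacer <- sub(paste0(".*", spacer_pattern), "\\1", s)
    s <- substr(s, 1L, m - 1L)
    last <- substr(s, nchar(s), nchar(s))
    if (last %in% c("a", "b", "?")) {
      root_anomer <- last
      s <- substr(s, 1L, nchar(s) - 1L)
    }
  }
  if (!nzchar(s)) cfg_parse_error("glycan string contains no residues")

  depth <- 0L
  for (i in seq_len(nchar(s))) {
    ch <- substr(s, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) cfg_parse_error("unbalanced parentheses", i)
    }
  }
  if (depth != 0L) cfg_parse_error("unbalanced parentheses", nchar(s))

  label <- character(0)
  parent <- integer(0)
  elab <- character(0)

  add_node <- function(lab) {
    label <<- c(label, lab)
    parent <<- c(parent, 0L)
    elab <<- c(elab, NA_character_)
    length(label)
  }

  # Parses one segment (no unmatched parens); returns list(root=, link=)
  # where link is the segment root's pending linkage (NULL at top level).
  parse_segment <- function(seg, base) {
    i <- 1L
    nch <- nchar(seg)
    carry <- list()  # list of list(root=, link=)
    while (i <= nch) {
      ch <- substr(seg, i, i)
      if (ch == "(") {
        j <- i
        d <- 0L
        repeat {
          cj <- substr(seg, j, j)
          if (cj == "(") d <- d + 1L
          if (cj == ")") d <- d - 1L
          if (d == 0L) break
          j <- j + 1L
          if (j > nch) cfg_parse_error("unbalanced parentheses", base + i - 1L)
        }
        inner <- substr(seg, i + 1L, j - 1L)
        br <- parse_segment(inner, base + i)
        if (is.null(br$link)) {
          cfg_parse_error("branch lacks a linkage to its parent", base + j - 1L)
        }
        carry[[length(carry) + 1L]] <- br
        i <- j + 1L
        next
      }
      rest <- substr(seg, i, nch)
      um <- regexec(.unit_re, rest)[[1]]
      if (um[1] == 1L) {
        len <- attr(um, "match.length")[1]
        parts <- regmatches(rest, regexec(.unit_re, rest))[[1]]
        node <- add_node(parts[2])
        for (b in carry) {
          parent[b$root] <<- node
          elab[b$root] <<- b$link
        }
        link <- paste0(parts[3], parts[4], "-", parts[5])
        if (i + len - 1L == nch) {
          return(list(root = node, link = link))
        }
        carry <- list(list(root = node, link = link))
        i <- i + len
        next
      }
      if (grepl(.residue_re, rest)) {
        node <- add_node(rest)
        for (b in carry) {
          parent[b$root] <<- node
          elab[b$root] <<- b$link
        }
        return(list(root = node, link = NULL))
      }
      cfg_parse_error(sprintf("unrecognised glycan syntax near '%s'",
                              substr(rest, 1L, 12L)), base + i - 1L)
    }
    cfg_parse_error("segment ends without a residue", base + nch)
  }

  top <- parse_segment(s, 0L)
  if (!is.null(top$link)) {
    cfg_parse_error("glycan ends with a dangling linkage")
  }
  glycan_tree(label, parent, elab, root_anomer = root_anomer, spacer = spacer)
}

#' Serialise a glycan tree to CFG linear nomenclature
#'
#' Inverse of [parse_cfg_glycan()] up to branch ordering (children are
#' emitted in canonical-code order, so output is deterministic). Restricted
#' -linkage nodes, if present, are omitted: they are an analysis artefact,
#' not part of the nomenclature.
#'
#' @param tree A `glycan_tree`.
#' @param greek Emit Greek anomer letters instead of `'a'`/`'b'`.
#' @return A single string.
#' @export
write_glycan_text <- function(tree, greek = FALSE) {
  kids <- tree_children(tree)
  an_out <- function(a) {
    if (!greek) return(a)
    c(a = "α", b = "β", "?" = "?")[[a]]
  }
  txt <- function(v) {
    ks <- kids[[v]]
    ks <- ks[!vapply(ks, function(k) is_restricted_node(tree, k), logical(1))]
    if (length(ks) == 0L) return(tree$label[v])
    ord <- order(vapply(ks, function(k) paste0(tree$elab[k], ">", sub_code(k)),
                        character(1)), method = "radix")
    ks <- ks[ord]
    link_txt <- function(k) {
      paste0(an_out(substr(tree$elab[k], 1L, 1L)), substr(tree$elab[k], 2L, nchar(tree$elab[k])))
    }
    main <- ks[1L]
    branches <- ks[-1L]
    paste0(txt(main), link_txt(main),
           paste(vapply(branches, function(b) paste0("(", txt(b), link_txt(b), ")"),
                        character(1)), collapse = ""),
           tree$label[v])
  }
  sub_code <- function(v) {
    ks <- kids[[v]]
    if (is.null(ks)) return(tree$label[v])
    parts <- vapply(ks, function(k) paste0("(", tree$elab[k], ">", sub_code(k), ")"),
                    character(1))
    paste0(tree$label[v], paste(sort(parts, method = "radix"), collapse = ""))
  }
  out <- txt(tree_root(tree))
  if (!is.na(tree$spacer)) {
    ra <- if (!is.na(tree$root_anomer)) an_out(tree$root_anomer) else ""
    out <- paste0(out, ra, "-", tree$spacer)
  }
  out
}
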