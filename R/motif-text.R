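# Motif text notation: CFG linear nomenclature extended with
#   * "(*p1,p2,...)" before a residue, listing its restricted (unoccupied but
#     chemically capable) attachment positions, sorted ascending; and
#   * a trailing standalone anomer token ("α", "β" or "α/β") giving the
#     required anomeric configuration of the edge entering the motif root.
# Examples: "(*3,4,6)GlcNAc α", "(*2,3,4,6)Gal β1-3GalNAc".

#' Write a motif in modified CFG linear text notation
#'
#' Restricted positions are emitted sorted ascending inside `(*...)` directly
#' before their residue; a parent-edge anomer constraint is emitted as a
#' trailing `α`, `β` or `α/β` token. Branch order follows the motif's
#' canonical code, so the text is deterministic.
#'
#' @param motif A `glycan_motif` (a plain `glycan_tree` is accepted and
#'   treated as unconstrained).
#' @param ascii Use `'a'`/`'b'` instead of Greek letters.
#' @return A single string.
#' @examples
#' m <- parse_motif_text("(*2,3,4,6)Gal b1-3GalNAc")
#' write_motif_text(m)
#' @export
write_motif_text <- function(motif, ascii = FALSE) {
  kids <- tree_children(motif)
  an_out <- function(a) {
    if (ascii) return(a)
    c(a = "α", b = "β", "?" = "?")[[a]]
  }
  sub_code <- function(v) {
    ks <- kids[[v]]
    if (is.null(ks)) return(motif$label[v])
    parts <- vapply(ks, function(k) paste0("(", motif$elab[k], ">", sub_code(k), ")"),
                    character(1))
    paste0(motif$label[v], paste(sort(parts, method = "radix"), collapse = ""))
  }
  txt <- function(v) {
    ks <- kids[[v]]
    rn <- ks[vapply(ks, function(k) is_restricted_node(motif, k), logical(1))]
    ks <- setdiff(ks, rn)
    restr <- ""
    if (length(rn) == 1L) {
      pos <- sort(as.integer(strsplit(sub("^\\*", "", motif$elab[rn]), ",")[[1]]))
      restr <- paste0("(*", paste(pos, collapse = ","), ")")
    }
    if (length(ks) == 0L) return(paste0(restr, motif$label[v]))
    ord <- order(vapply(ks, function(k) paste0(motif$elab[k], ">", sub_code(k)),
                        character(1)), method = "radix")
    ks <- ks[ord]
    link_txt <- function(k) {
      el <- motif$elab[k]
      paste0(" ", an_out(substr(el, 1L, 1L)), substr(el, 2L, nchar(el)))
    }
    main <- ks[1L]
    branches <- ks[-1L]
    paste0(txt(main), link_txt(main),
           paste(vapply(branches, function(b) paste0("(", txt(b), link_txt(b), ")"),
                        character(1)), collapse = ""),
           restr, motif$label[v])
  }
  out <- txt(tree_root(motif))
  pan <- if (inherits(motif, "glycan_motif")) motif$parent_anomer else NA_character_
  if (!is.na(pan)) {
    tok <- switch(pan, a = an_out("a"), b = an_out("b"),
                  ab = paste0(an_out("a"), "/", an_out("b")))
    out <- paste0(out, " ", tok)
  }
  out
}

#' Parse a motif from modified CFG linear text notation
#'
#' Inverse of [write_motif_text()]; accepts Greek or ASCII anomers and
#' arbitrary spacing.
#'
#' @param text Motif string, e.g. `"(*3,4,6)GlcNAc α"`.
#' @return A `glycan_motif`.
#' @export
parse_motif_text <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) {
    cfg_parse_error("empty motif string")
  }
  s <- gsub("α", "a", gsub("β", "b", text))

  parent_anomer <- NA_character_
  pm <- regexpr("[[:space:]]+(a/b|a|b)$", s)
  if (pm > 0L) {
    tok <- trimws(substr(s, pm, nchar(s)))
    parent_anomer <- if (tok == "a/b") "ab" else tok
    s <- substr(s, 1L, pm - 1L)
  }
  s <- gsub("[[:space:]]", "", s)
  if (!nzchar(s)) cfg_parse_error("motif string contains no residues")

  label <- character(0)
  parent <- integer(0)
  elab <- character(0)
  add_node <- function(lab, el = NA_character_) {
    label <<- c(label, lab)
    parent <<- c(parent, 0L)
    elab <<- c(elab, el)
    length(label)
  }

  parse_segment <- function(seg, base) {
    i <- 1L
    nch <- nchar(seg)
    carry <- list()
    pending_restricted <- NULL
    attach <- function(node) {
      for (b in carry) {
        parent[b$root] <<- node
        elab[b$root] <<- b$link
      }
      if (!is.null(pending_restricted)) {
        rn <- add_node("X", paste0("*", paste(pending_restricted, collapse = ",")))
        parent[rn] <<- node
        pending_restricted <<- NULL
      }
    }
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
        if (startsWith(inner, "*")) {
          if (!is.null(pending_restricted)) {
            cfg_parse_error("two restricted-position groups for one residue", base + i - 1L)
          }
          body <- sub("^\\*", "", inner)
          if (!grepl("^[0-9]+(,[0-9]+)*$", body)) {
            cfg_parse_error("malformed restricted-position group", base + i - 1L)
          }
          pending_restricted <- sort(as.integer(strsplit(body, ",")[[1]]))
        } else {
          br <- parse_segment(inner, base + i)
          if (is.null(br$link)) {
            cfg_parse_error("branch lacks a linkage to its parent", base + j - 1L)
          }
          carry[[length(carry) + 1L]] <- br
        }
        i <- j + 1L
        next
      }
      rest <- substr(seg, i, nch)
      um <- regexec(.unit_re, rest)[[1]]
      if (um[1] == 1L) {
        len <- attr(um, "match.length")[1]
        parts <- regmatches(rest, regexec(.unit_re, rest))[[1]]
        node <- add_node(parts[2])
        attach(node)
        link <- paste0(parts[3], parts[4], "-", parts[5])
        if (i + len - 1L == nch) return(list(root = node, link = link))
        carry <- list(list(root = node, link = link))
        i <- i + len
        next
      }
      if (grepl(.residue_re, rest)) {
        node <- add_node(rest)
        attach(node)
        return(list(root = node, link = NULL))
      }
      cfg_parse_error(sprintf("unrecognised motif syntax near '%s'",
                              substr(rest, 1L, 12L)), base + i - 1L)
    }
    cfg_parse_error("segment ends without a residue", base + nch)
  }

  top <- parse_segment(s, 0L)
  if (!is.null(top$link)) cfg_parse_error("motif ends with a dangling linkage")
  glycan_motif(label, parent, elab, parent_anomer = parent_anomer)
}
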