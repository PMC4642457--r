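#' Read and write haplogroup motif trees
#'
#' The tree file is a plain-text, indentation-defined hierarchy: one node per
#' line, node name first, followed by the space-separated compact variant
#' tokens of the motif on the edge leading to that node (back mutations with
#' an `@` prefix). Children are indented deeper than their parent; the first
#' line is the root, whose tokens (if any) are its motif relative to the
#' reference anchor. `#` starts a comment.
#'
#' @param path Tree file path.
#' @return An object of class `haplo_tree`: a list with a `nodes` tibble
#'   (`name`, `parent`, `depth`, `motif` list-column).
#' @export
read_haplogroup_tree <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) abort("empty tree file")
  indent <- nchar(sub("[^ \t].*$", "", lines))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_))
    abort(paste0("duplicate node name: ", names_[duplicated(names_)][1]))
  motifs <- lapply(fields, function(f) {
    if (length(f) < 2) empty_variants() else parse_variants(f[-1])
  })
  parent <- rep(NA_character_, length(lines))
  stack_names <- character()
  stack_indent <- integer()
  for (i in seq_along(lines)) {
    while (length(stack_indent) > 0 &&
           indent[i] <= stack_indent[length(stack_indent)]) {
      stack_names <- stack_names[-length(stack_names)]
      stack_indent <- stack_indent[-length(stack_indent)]
    }
    if (length(stack_names) == 0) {
      if (i > 1) abort(sprintf("orphan indentation at line '%s'", lines[i]))
    } else {
      parent[i] <- stack_names[length(stack_names)]
    }
    stack_names <- c(stack_names, names_[i])
    stack_indent <- c(stack_indent, indent[i])
  }
  new_haplo_tree(tibble(name = names_, parent = parent, motif = motifs))
}

new_haplo_tree <- function(nodes) {
  depth <- integer(nrow(nodes))
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$name)
  for (i in seq_len(nrow(nodes))) {
    d <- 0L; p <- nodes$parent[i]
    while (!is.na(p)) { d <- d + 1L; p <- nodes$parent[idx[[p]]] }
    depth[i] <- d
  }
  nodes$depth <- depth
  structure(list(nodes = nodes), class = "haplo_tree")
}

#' @export
print.haplo_tree <- function(x, ...) {
  cat("<haplo_tree> ", nrow(x$nodes), " nodes, root '",
      x$nodes$name[is.na(x$nodes$parent)][1], "'\n", sep = "")
  invisible(x)
}

#' @rdname read_haplogroup_tree
#' @param tree A `haplo_tree`.
#' @export
write_haplogroup_tree <- function(tree, path) {
  nodes <- tree$nodes
  lines <- character(0)
  emit <- function(name, depth) {
    i <- which(nodes$name == name)
    toks <- format_variants(nodes$motif[[i]])
    line <- paste0(strrep("  ", depth), name,
                   if (length(toks)) paste0(" ", paste(toks, collapse = " ")) else "")
    lines <<- c(lines, line)
    for (child in nodes$name[!is.na(nodes$parent) & nodes$parent == name])
      emit(child, depth + 1L)
  }
  emit(nodes$name[is.na(nodes$parent)][1], 0L)
  writeLines(lines, path)
  invisible(path)
}

tree_node_index <- function(tree, name) {
  i <- which(tree$nodes$name == name)
  if (length(i) == 0) abort(sprintf("unknown node '%s'", name))
  i
}

tree_path <- function(tree, name) {
  # root-to-node vector of node names
  path <- character()
  p <- name
  while (!is.na(p)) {
    path <- c(p, path)
    p <- tree$nodes$parent[tree_node_index(tree, p)]
  }
  path
}

#' Cumulative motif of a haplogroup node
#'
#' Concatenates the edge motifs from the root to `node`, with back mutations
#' (`@` tokens) cancelling previously accumulated variants. A back-mutation
#' token with no matching accumulated variant is retained as-is (and ignored
#' by classification scoring).
#'
#' @param tree A `haplo_tree`.
#' @param node Node name.
#' @return A variant tibble: the node's expected variant set relative to the
#'   reference.
#' @export
node_motif <- function(tree, node) {
  acc <- empty_variants()
  for (nm in tree_path(tree, node)) {
    m <- tree$nodes$motif[[tree_node_index(tree, nm)]]
    if (nrow(m) == 0) next
    fwd <- m[!m$back, , drop = FALSE]
    bk <- m[m$back, , drop = FALSE]
    acc <- variants_union(acc, fwd)
    if (nrow(bk) > 0) {
      plain <- bk; plain$back <- FALSE
      cancel_keys <- variant_keys(plain)
      present <- variant_keys(acc) %in% cancel_keys
      leftover <- bk[!cancel_keys %in% variant_keys(acc), , drop = FALSE]
      acc <- acc[!present, , drop = FALSE]
      acc <- variants_union(acc, leftover)
    }
  }
  acc
}

tree_node_names <- function(tree) tree$nodes$name

#' Export a haplogroup tree as Newick
#'
#' Topology and node names only (edge lengths = motif event counts).
#'
#' @param tree A `haplo_tree`.
#' @return A string in Newick format.
#' @export
haplo_tree_newick <- function(tree) {
  nodes <- tree$nodes
  build <- function(name) {
    i <- which(nodes$name == name)
    kids <- nodes$name[!is.na(nodes$parent) & nodes$parent == name]
    len <- nrow(nodes$motif[[i]])
    label <- gsub("[ ():,;]", "_", name)
    if (length(kids) == 0) return(paste0(label, ":", len))
    paste0("(", paste(vapply(kids, build, character(1)), collapse = ","), ")",
           label, ":", len)
  }
  paste0(build(nodes$name[is.na(nodes$parent)][1]), ";")
}
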