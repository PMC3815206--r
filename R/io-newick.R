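#' Read / write Newick trees
#'
#' Thin, validating wrappers around [ape::read.tree()] and
#' [ape::write.tree()]. Round-tripping preserves topology, branch lengths
#' (to at least 6 decimals) and node supports. Malformed Newick (for
#' example unbalanced parentheses) is an error.
#'
#' @param path file path.
#' @return a `phylo` tree.
#' @export
readNewick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n.open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n.close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  ccAssert(n.open == n.close,
           paste0("unbalanced parentheses in Newick file: ", path))
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) NULL)
  ccAssert(!is.null(tr) && methods::is(tr, "phylo"),
           paste0("could not parse Newick file: ", path))
  ccAssert(!anyDuplicated(tr$tip.label), "duplicated leaf names in tree")
  tr
}

#' @rdname readNewick
#' @param tree a `phylo` tree.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}
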