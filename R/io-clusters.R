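#' Read an orthoMCL-style groups file
#'
#' One cluster per line: `cluster_id: genomeA|gene1 genomeB|gene2 ...`.
#' Member tokens must contain exactly one `|`; a member appearing twice
#' (in one line or across lines) is an error.
#'
#' @param path file path.
#' @param taxa genome universe; defaults to the genomes seen in the file.
#' @return a [ClusterSet].
#' @export
readClusters <- function(path, taxa = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ccAssert(length(lines) > 0, paste0("empty groups file: ", path))
  parsed <- lapply(lines, function(ln) {
    m <- regmatches(ln, regexec("^\\s*([^:\\s]+)\\s*:\\s*(.*)$", ln))[[1]]
    ccAssert(length(m) == 3, paste0("malformed groups line: ", ln))
    toks <- strsplit(trimws(m[3]), "\\s+")[[1]]
    ccAssert(length(toks) > 0, paste0("cluster with no members: ", m[2]))
    npipe <- lengths(regmatches(toks, gregexpr("|", toks, fixed = TRUE)))
    bad <- toks[npipe != 1]
    ccAssert(length(bad) == 0,
             paste0("malformed member token(s) (need exactly one '|'): ",
                    paste(bad, collapse = ", ")))
    parts <- strsplit(toks, "|", fixed = TRUE)
    data.frame(cluster_id = m[2],
               genome_id = vapply(parts, `[`, "", 1L),
               gene_id = toks, stringsAsFactors = FALSE)
  })
  members <- do.call(rbind, parsed)
  key <- paste(members$genome_id, members$gene_id, sep = "\r")
  dup <- unique(members$gene_id[duplicated(key)])
  ccAssert(length(dup) == 0,
           paste0("member(s) in more than one cluster: ",
                  paste(dup, collapse = ", ")))
  ClusterSet(members, taxa = taxa)
}

#' Write a ClusterSet as an orthoMCL-style groups file
#'
#' @param x a [ClusterSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeClusters <- function(x, path) {
  m <- x@members
  sp <- split(m$gene_id, m$cluster_id)
  ids <- sort(names(sp))
  lines <- vapply(ids, function(id)
    paste0(id, ": ", paste(sort(sp[[id]]), collapse = " ")), "")
  writeLines(lines, path)
  invisible(path)
}
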