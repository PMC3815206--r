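#' Read a FASTA file
#'
#' Sequence ids are the header text up to the first whitespace, preserved
#' verbatim. Duplicated ids and empty files are errors.
#'
#' @param path file path.
#' @param type `"AA"` or `"DNA"`.
#' @return an [Biostrings::AAStringSet] or [Biostrings::DNAStringSet].
#' @export
readFasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- tryCatch(
    switch(type,
           AA = Biostrings::readAAStringSet(path),
           DNA = Biostrings::readDNAStringSet(path)),
    error = function(e) ccStop(paste0("malformed FASTA '", path, "': ",
                                      conditionMessage(e))))
  ccAssert(length(set) > 0, paste0("empty FASTA file: ", path))
  names(set) <- sub("\\s.*$", "", names(set))
  dup <- unique(names(set)[duplicated(names(set))])
  ccAssert(length(dup) == 0,
           paste0("duplicated FASTA id(s): ", paste(dup, collapse = ", ")))
  set
}

#' Write sequences to FASTA
#'
#' @param x a named `XStringSet` or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  ccAssert(!is.null(names(x)) && all(nzchar(names(x))),
           "sequences must be named")
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
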