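GENE_TABLE_COLS <- c("genome_id", "replicon_id", "gene_id", "start0",
                     "end0", "strand", "feature_type", "product")

.annotationFromRecords <- function(df, repliconLengths = NULL,
                                   circular = NA) {
  # df: internal record frame with 1-based closed start/end already
  ccAssert(all(df$end >= df$start),
           "gene with end <= start after coordinate conversion")
  bad <- !df$strand %in% c("+", "-")
  if (any(bad))
    ccStop(paste0("unknown strand symbol '", df$strand[which(bad)[1]],
                  "' for gene ", df$gene_id[which(bad)[1]]))
  out <- lapply(split(df, df$genome_id), function(d) {
    gr <- GenomicRanges::GRanges(
      seqnames = d$replicon_id,
      ranges = IRanges::IRanges(start = d$start, end = d$end),
      strand = d$strand)
    S4Vectors::mcols(gr)$gene_id <- d$gene_id
    S4Vectors::mcols(gr)$feature_type <- d$feature_type
    S4Vectors::mcols(gr)$product <- d$product
    GenomeAnnotation(d$genome_id[1], gr,
                     repliconLengths = repliconLengths, circular = circular)
  })
  out[order(names(out))]
}

#' Read gene coordinate tables
#'
#' Two dialects are supported. The package's TSV dialect has columns
#' `genome_id, replicon_id, gene_id, start0, end0, strand, feature_type,
#' product` with 0-based half-open coordinates. GFF3 files use native
#' 1-based inclusive coordinates and are converted at the boundary; the
#' genome id is taken from `genomeId` (default: file name without
#' extension) and `gene_id` is formed as `genome_id|locus_tag` (falling
#' back to the `ID` attribute).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param genomeId genome id for GFF3 input.
#' @param repliconLengths optional named vector of replicon lengths
#'   (GFF3 `##sequence-region` pragmas are used when present).
#' @param circular logical, scalar or named per replicon.
#' @return named list of [GenomeAnnotation] objects (one per genome).
#' @export
readGeneTable <- function(path, dialect = c("tsv", "gff3"), genomeId = NULL,
                          repliconLengths = NULL, circular = NA) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    ccAssert(all(GENE_TABLE_COLS %in% names(df)),
             paste0("gene table missing column(s): ",
                    paste(setdiff(GENE_TABLE_COLS, names(df)), collapse = ", ")))
    rec <- data.frame(genome_id = df$genome_id, replicon_id = df$replicon_id,
                      gene_id = df$gene_id,
                      start = as.integer(df$start0) + 1L,
                      end = as.integer(df$end0),
                      strand = df$strand, feature_type = df$feature_type,
                      product = df$product, stringsAsFactors = FALSE)
    return(.annotationFromRecords(rec, repliconLengths, circular))
  }
  ccAssert(requireNamespace("rtracklayer", quietly = TRUE),
           "GFF3 input requires the rtracklayer package")
  if (is.null(genomeId))
    genomeId <- sub("\\.[^.]*$", "", basename(path))
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  tag <- if ("locus_tag" %in% names(mc)) as.character(mc$locus_tag)
         else rep(NA_character_, length(gr))
  if ("ID" %in% names(mc)) tag[is.na(tag)] <- as.character(mc$ID)[is.na(tag)]
  ccAssert(!anyNA(tag), "GFF3 record without locus_tag or ID attribute")
  ft <- as.character(mc$type)
  ft[!ft %in% c("CDS", "tRNA", "rRNA")] <- "other"
  prod <- if ("product" %in% names(mc)) as.character(mc$product)
          else rep("", length(gr))
  prod[is.na(prod)] <- ""
  rec <- data.frame(genome_id = genomeId,
                    replicon_id = as.character(GenomeInfoDb::seqnames(gr)),
                    gene_id = paste(genomeId, tag, sep = "|"),
                    start = BiocGenerics::start(gr),
                    end = BiocGenerics::end(gr),
                    strand = as.character(BiocGenerics::strand(gr)),
                    feature_type = ft, product = prod,
                    stringsAsFactors = FALSE)
  sl <- GenomeInfoDb::seqlengths(gr)
  if (is.null(repliconLengths) && any(!is.na(sl)))
    repliconLengths <- sl[!is.na(sl)]
  if (is.null(repliconLengths)) {
    # honour ##sequence-region pragmas when the importer drops them
    prag <- grep("^##sequence-region", readLines(path), value = TRUE)
    if (length(prag)) {
      parts <- strsplit(trimws(prag), "\\s+")
      repliconLengths <- stats::setNames(
        vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
        vapply(parts, `[`, "", 2))
    }
  }
  .annotationFromRecords(rec, repliconLengths, circular)
}

#' Write gene tables in the package TSV dialect (0-based half-open)
#'
#' @param annotations a [GenomeAnnotation] or list thereof.
#' @param path output path.
#' @param header optional comment lines (each written prefixed with `#`).
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(annotations, path, header = NULL) {
  if (methods::is(annotations, "GenomeAnnotation"))
    annotations <- list(annotations)
  rows <- lapply(annotations, function(a) {
    g <- geneRanges(a)
    data.frame(genome_id = genomeId(a),
               replicon_id = as.character(GenomeInfoDb::seqnames(g)),
               gene_id = S4Vectors::mcols(g)$gene_id,
               start0 = BiocGenerics::start(g) - 1L,
               end0 = BiocGenerics::end(g),
               strand = as.character(BiocGenerics::strand(g)),
               feature_type = S4Vectors::mcols(g)$feature_type,
               product = S4Vectors::mcols(g)$product,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a taxonomy table
#'
#' TSV with columns `genome_id, genus, family, order`. The table must be
#' total over the genomes it is used with; categories must be non-empty.
#'
#' @param path file path.
#' @return data.frame with the four columns.
#' @export
readTaxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("genome_id", "genus", "family", "order")
  ccAssert(all(need %in% names(df)),
           paste0("taxonomy table missing column(s): ",
                  paste(setdiff(need, names(df)), collapse = ", ")))
  ccAssert(!anyDuplicated(df$genome_id), "duplicated genome_id in taxonomy")
  ccAssert(all(nzchar(df$genus) & nzchar(df$family) & nzchar(df$order)),
           "empty taxonomy category")
  df[, need]
}

#' @rdname readTaxonomy
#' @param taxonomy data.frame as returned by [readTaxonomy()].
#' @export
writeTaxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
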