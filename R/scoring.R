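# Protein pair scoring used for normalized bit scores and RBH clustering.

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Smith-Waterman bit score between two proteins
#'
#' Local alignment with BLOSUM62, gap open 11 / extend 1 (via
#' [Biostrings::pairwiseAlignment()]), converted to bits with the package's
#' fixed Karlin-Altschul constants (see [bitScore()]). The self-score of a
#' sequence aligned against itself is its maximal attainable bit score, so
#' normalized scores of identical sequences are exactly 1.
#'
#' @param a,b protein sequences (character or `AAString`).
#' @return bit score (numeric scalar).
#' @export
swBitScore <- function(a, b) {
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(as.character(a)),
    Biostrings::AAString(as.character(b)),
    type = "local", substitutionMatrix = .blosum62(),
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
  bitScore(sc)
}

# 3-mer count matrix for an AAStringSet / named character vector.
# Columns are hashed 3-mer ids (base-32 over A..Z codes); dot products of
# rows give a fast, deterministic similarity score.
.kmerCounts <- function(seqs, k = 3L) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  n <- length(seqs)
  ijx <- lapply(seq_len(n), function(i) {
    code <- utf8ToInt(toupper(seqs[[i]])) %% 32L
    L <- length(code)
    if (L < k) return(NULL)
    key <- code[1:(L - k + 1)] * 1024L + code[2:(L - k + 2)] * 32L +
      code[3:(L - k + 3)]
    tab <- table(key)
    cbind(i = i, j = as.integer(names(tab)) + 1L, x = as.integer(tab))
  })
  ijx <- do.call(rbind, ijx)
  m <- matrix(0, nrow = n, ncol = 32768L)
  if (!is.null(ijx)) m[ijx[, c("i", "j")]] <- ijx[, "x"]
  rownames(m) <- names(seqs)
  m
}

#' Fast 3-mer score matrix between two proteomes
#'
#' Scores every gene of `setA` against every gene of `setB` as the dot
#' product of their amino-acid 3-mer count vectors. Deterministic, requires
#' no alignment, and is self-normalizable (a sequence's self-score is
#' maximal), which makes it a suitable `scoreFun` for [rbhCluster()] and
#' for desk-scale pair scans.
#'
#' @param setA,setB `AAStringSet` or named character vectors.
#' @return numeric matrix (genes of A x genes of B).
#' @export
kmerScoreMatrix <- function(setA, setB) {
  ma <- .kmerCounts(setA)
  mb <- .kmerCounts(setB)
  ma %*% t(mb)
}

# Per-pair scoring dispatcher. pairs: data.frame(gene_a, gene_b).
# Returns pairs with bitscore_ab, selfscore_a, selfscore_b columns.
.scorePairs <- function(pairs, protA, protB, method = c("sw", "kmer")) {
  method <- match.arg(method)
  if (nrow(pairs) == 0) {
    pairs$bitscore_ab <- pairs$selfscore_a <- pairs$selfscore_b <- numeric(0)
    return(pairs)
  }
  a <- as.character(protA)[pairs$gene_a]
  b <- as.character(protB)[pairs$gene_b]
  ccAssert(!anyNA(a) && !anyNA(b), "ortholog pair gene missing from proteome")
  if (method == "sw") {
    pairs$bitscore_ab <- mapply(swBitScore, a, b, USE.NAMES = FALSE)
    selfA <- vapply(unique(pairs$gene_a), function(g) {
      s <- as.character(protA)[[g]]
      swBitScore(s, s)
    }, numeric(1))
    selfB <- vapply(unique(pairs$gene_b), function(g) {
      s <- as.character(protB)[[g]]
      swBitScore(s, s)
    }, numeric(1))
    pairs$selfscore_a <- selfA[pairs$gene_a]
    pairs$selfscore_b <- selfB[pairs$gene_b]
  } else {
    ma <- .kmerCounts(as.character(protA)[unique(pairs$gene_a)])
    mb <- .kmerCounts(as.character(protB)[unique(pairs$gene_b)])
    pairs$bitscore_ab <- rowSums(ma[pairs$gene_a, , drop = FALSE] *
                                   mb[pairs$gene_b, , drop = FALSE])
    pairs$selfscore_a <- rowSums(ma[pairs$gene_a, , drop = FALSE]^2)
    pairs$selfscore_b <- rowSums(mb[pairs$gene_b, , drop = FALSE]^2)
  }
  pairs
}
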