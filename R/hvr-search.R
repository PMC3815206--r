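# Translated (six-frame) region comparison: a deterministic mini-tblastx
# with fixed scoring constants. Exact 3-mer words seed ungapped X-drop
# extensions on every frame pair; raw scores convert to bits with the
# package's Karlin-Altschul constants and E-values use the summed
# translated search space.

#' Parameters for the translated search
#'
#' @param wordSize seed word length in amino acids.
#' @param xDrop raw-score drop-off terminating an ungapped extension
#'   (default 18, about 7 bits at the fixed lambda).
#' @param evalueMax report hits with E-value strictly below this threshold.
#' @param lambda,K Karlin-Altschul parameters (BLOSUM62, ungapped).
#' @return parameter list for [translatedSearch()].
#' @export
translatedSearchParams <- function(wordSize = 3L, xDrop = 18L,
                                   evalueMax = 1e-10, lambda = KA_LAMBDA,
                                   K = KA_K) {
  list(wordSize = as.integer(wordSize), xDrop = as.integer(xDrop),
       evalueMax = evalueMax, lambda = lambda, K = K)
}

# translate the six frames of a nucleotide sequence; returns list of
# list(frame = label, aa = character, rcOffset = frame offset used)
.sixFrames <- function(dna) {
  if (is.character(dna)) dna <- Biostrings::DNAString(dna)
  L <- length(dna)
  rc <- Biostrings::reverseComplement(dna)
  out <- list()
  for (f in 1:3) {
    for (dir in c(1, -1)) {
      src <- if (dir == 1) dna else rc
      n <- L - (f - 1)
      n <- n - n %% 3
      if (n < 3) next
      aa <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::subseq(src, f, f - 1 + n), if.fuzzy.codon = "X")))
      out[[length(out) + 1]] <- list(frame = dir * f, aa = aa)
    }
  }
  out
}

.aaEncode <- local({
  alpha <- NULL
  function(aa, alphabet) {
    code <- match(strsplit(aa, "", fixed = TRUE)[[1]], alphabet)
    code[is.na(code)] <- match("X", alphabet)
    as.integer(code - 1L)
  }
})

# exact word seeds between two encoded sequences; 0-based start positions
.wordSeeds <- function(qcode, scode, w, nAlpha) {
  key <- function(code) {
    L <- length(code)
    if (L < w) return(integer(0))
    k <- code[1:(L - w + 1)]
    for (i in 2:w) k <- k * nAlpha + code[i:(L - w + i)]
    k
  }
  qk <- key(qcode)
  sk <- key(scode)
  if (!length(qk) || !length(sk)) return(NULL)
  ssp <- split(seq_along(sk) - 1L, sk)
  hitl <- ssp[as.character(qk)]
  nhit <- lengths(hitl)
  if (sum(nhit) == 0) return(NULL)
  qpos <- rep(seq_along(qk) - 1L, nhit)
  spos <- unlist(hitl, use.names = FALSE)
  o <- order(qpos - spos, qpos, method = "radix")
  list(qpos = qpos[o], spos = spos[o])
}

#' Translated similarity search between two nucleotide regions
#'
#' Compares all 36 frame pairs of the six-frame translations of two
#' regions. Identical `wordSize`-mer words seed ungapped X-drop
#' extensions scored with BLOSUM62; raw scores are converted to bits via
#' the fixed constants lambda = 0.267, K = 0.041, and E-values are
#' computed over the summed translated search space (total query amino
#' acids x total subject amino acids). Hits with E-value below the
#' threshold are returned sorted by score. Fully deterministic.
#'
#' @param regionSeqA,regionSeqB nucleotide sequences (character or
#'   `DNAString`).
#' @param params see [translatedSearchParams()].
#' @return data.frame with columns `qframe`, `sframe`, `qstart0`, `qend0`,
#'   `sstart0`, `send0` (nucleotide coords within each region, 0-based
#'   half-open, on the forward strand), `length_aa`, `score`, `bits`,
#'   `evalue`, `pct_id`.
#' @export
translatedSearch <- function(regionSeqA, regionSeqB,
                             params = translatedSearchParams()) {
  blos <- .blosum62()
  alphabet <- rownames(blos)
  nAlpha <- length(alphabet)
  sm <- matrix(as.integer(blos), nrow = nAlpha)
  a <- as.character(regionSeqA)
  b <- as.character(regionSeqB)
  minNt <- 3L * params$wordSize
  ccAssert(nchar(a) >= minNt && nchar(b) >= minNt,
           paste0("region shorter than ", minNt, " nt"))
  fa <- .sixFrames(a)
  fb <- .sixFrames(b)
  m <- sum(vapply(fa, function(f) nchar(f$aa), numeric(1)))
  n <- sum(vapply(fb, function(f) nchar(f$aa), numeric(1)))
  La <- nchar(a)
  Lb <- nchar(b)
  rows <- list()
  for (qa in fa) {
    qcode <- .aaEncode(qa$aa, alphabet)
    for (sb in fb) {
      scode <- .aaEncode(sb$aa, alphabet)
      seeds <- .wordSeeds(qcode, scode, params$wordSize, nAlpha)
      if (is.null(seeds)) next
      hits <- .cc_seed_extend(qcode, scode, sm, seeds$qpos, seeds$spos,
                              params$wordSize, params$xDrop)
      if (nrow(hits) == 0) next
      hits <- as.data.frame(hits)
      hits$bits <- bitScore(hits$score, params$lambda, params$K)
      hits$evalue <- evalueFromBits(hits$bits, m, n)
      hits <- hits[hits$evalue < params$evalueMax, , drop = FALSE]
      if (nrow(hits) == 0) next
      toNt <- function(aaStart, aaEnd, frame, L) {
        f <- abs(frame)
        if (frame > 0) {
          cbind(start0 = (f - 1) + 3 * aaStart, end0 = (f - 1) + 3 * aaEnd)
        } else {
          cbind(start0 = L - ((f - 1) + 3 * aaEnd),
                end0 = L - ((f - 1) + 3 * aaStart))
        }
      }
      qnt <- toNt(hits$qstart, hits$qend, qa$frame, La)
      snt <- toNt(hits$sstart, hits$send, sb$frame, Lb)
      rows[[length(rows) + 1]] <- data.frame(
        qframe = qa$frame, sframe = sb$frame,
        qstart0 = qnt[, "start0"], qend0 = qnt[, "end0"],
        sstart0 = snt[, "start0"], send0 = snt[, "end0"],
        length_aa = hits$qend - hits$qstart,
        score = hits$score, bits = hits$bits, evalue = hits$evalue,
        pct_id = 100 * hits$identities / (hits$qend - hits$qstart),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(qframe = integer(0), sframe = integer(0),
                      qstart0 = integer(0), qend0 = integer(0),
                      sstart0 = integer(0), send0 = integer(0),
                      length_aa = integer(0), score = integer(0),
                      bits = numeric(0), evalue = numeric(0),
                      pct_id = numeric(0)))
  res <- do.call(rbind, rows)
  # forward frames sort first among score ties
  res <- res[order(-res$score, res$qframe <= 0, abs(res$qframe),
                   res$sframe <= 0, abs(res$sframe), res$qstart0,
                   res$sstart0, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write hits in the crunch comparison dialect
#'
#' One line per hit: `score qstart qend sstart send pct_id` with 1-based
#' inclusive nucleotide coordinates — the tabular format stacked
#' genome-comparison viewers consume. An empty hit list yields an empty
#' (but valid) file.
#'
#' @param hits data.frame from [translatedSearch()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCrunch <- function(hits, path) {
  lines <- if (nrow(hits) == 0) character(0)
           else sprintf("%d %d %d %d %d %.2f", hits$score,
                        hits$qstart0 + 1L, hits$qend0,
                        hits$sstart0 + 1L, hits$send0, hits$pct_id)
  writeLines(lines, path)
  invisible(path)
}

#' Compare a chain of regions pairwise
#'
#' Runs [translatedSearch()] on every adjacent pair of the supplied
#' regions, in list order — the stacked-comparison layout of an ACT-style
#' figure — optionally writing one crunch file per pair.
#'
#' @param regionSeqs named list / `DNAStringSet` of region sequences in
#'   chain order.
#' @param params see [translatedSearchParams()].
#' @param outdir optional directory for crunch files.
#' @return named list of hit data.frames (`"A_vs_B"`), with attribute
#'   `"files"` when written.
#' @export
regionComparisonMatrix <- function(regionSeqs,
                                   params = translatedSearchParams(),
                                   outdir = NULL) {
  ids <- names(regionSeqs)
  ccAssert(!is.null(ids) && all(nzchar(ids)), "regions must be named")
  ccAssert(length(regionSeqs) >= 2, "need at least two regions")
  out <- list()
  files <- character(0)
  for (i in seq_len(length(regionSeqs) - 1)) {
    a <- ids[i]
    b <- ids[i + 1]
    hits <- translatedSearch(regionSeqs[[i]], regionSeqs[[i + 1]], params)
    key <- paste0(a, "_vs_", b)
    out[[key]] <- hits
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(outdir, paste0(key, ".crunch"))
      writeCrunch(hits, f)
      files[key] <- f
    }
  }
  if (length(files)) attr(out, "files") <- files
  out
}
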