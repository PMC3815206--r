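# Internal helpers shared across modules.

# Standard 20-letter amino-acid alphabet, and the residues excluded from
# compositional statistics (ambiguity codes, rare letters, gaps, stops).
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_EXCLUDED <- c("B", "Z", "X", "J", "U", "O", "-", ".", "*")

# Amino acids whose codon families carry G or C in the first two codon
# positions (GGN, GCN, CGN, CCN).
AA_GC_SET <- c("G", "A", "R", "P")

# Karlin-Altschul constants used for bit-score conversion throughout
# (BLOSUM62, ungapped).
KA_LAMBDA <- 0.267
KA_K <- 0.041

ccStop <- function(msg, class = "cc_data_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "cc_error")))
}

ccAssert <- function(ok, msg, class = "cc_data_error") {
  if (!isTRUE(ok)) ccStop(msg, class = class)
}

# deterministic string formatting for ids
zeroPad <- function(i, width = 5) formatC(i, width = width, flag = "0")

#' Convert a raw local-alignment score to bits
#'
#' Applies the standard Karlin-Altschul conversion
#' \eqn{S' = (\lambda S - \ln K)/\ln 2} with the package's fixed ungapped
#' BLOSUM62 constants (\eqn{\lambda = 0.267}, \eqn{K = 0.041}).
#'
#' @param score numeric vector of raw alignment scores.
#' @param lambda,K Karlin-Altschul parameters.
#' @return numeric vector of bit scores.
#' @export
bitScore <- function(score, lambda = KA_LAMBDA, K = KA_K) {
  (lambda * score - log(K)) / log(2)
}

# E-value for a hit of `bits` bits in a search space of m x n letters.
evalueFromBits <- function(bits, m, n) {
  as.numeric(m) * as.numeric(n) * 2^(-bits)
}

# Case-insensitive fixed-substring match.
textMatches <- function(query, text) {
  grepl(tolower(query), tolower(text), fixed = TRUE)
}

# Sort gene records deterministically by (start, end, gene_id).
geneSortOrder <- function(seqname, start, end, gene_id) {
  order(as.character(seqname), start, end, gene_id, method = "radix")
}
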