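#' @useDynLib plantcns, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a nucleotide string
#'
#' Ambiguity codes other than `N` must already have been normalized to `N`.
#'
#' @param x Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(chartr("ACGTN", "TGCAN", x), function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

# ASCII lookup: A=1 C=2 G=3 T=4, everything else (incl. N) = 5.
.ENCODE_LUT <- local({
  lut <- rep(5L, 127L)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("T")] <- 4L
  lut
})

# Integer-encode a sequence: A=1 C=2 G=3 T=4 N=5.
encode_seq <- function(x) {
  .ENCODE_LUT[utf8ToInt(x)]
}

.DECODE_LUT <- utf8ToInt("ACGTN")

decode_seq <- function(code) {
  intToUtf8(.DECODE_LUT[code])
}

# Normalize IUPAC ambiguity codes (anything not ACGT) to N; uppercase.
normalize_alphabet <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

# Stable polynomial string hash -> integer seed in [0, 2^31 - 20).
# Used to derive independent, iteration-order-free RNG streams from a master
# seed and a set of labels.
derive_seed <- function(seed, ...) {
  labels <- paste(c(format(seed), vapply(list(...), format, character(1))),
                  collapse = "\r")
  h <- 0
  p <- 2147483629 # largest prime < 2^31 is 2147483647; use a smaller one
  for (ch in utf8ToInt(labels)) {
    h <- (h * 31 + ch) %% p
  }
  as.integer(h)
}

# Evaluate expr with a local RNG state seeded from derive_seed().
with_derived_seed <- function(seed, ..., expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, ...))
  expr
}

# log(sum(exp(x))) by groups g (integer 1..ngroups). ZOOPS log-likelihood
# ratios are bounded well below overflow (|x| < ~250 nats), so a direct
# exponential sum with clamping is safe and much faster than a shifted form.
group_logsumexp <- function(x, g, ngroups) {
  sums <- rowsum(exp(pmin(x, 600)), g)
  out <- rep(-Inf, ngroups)
  out[as.integer(rownames(sums))] <- log(sums[, 1])
  out
}

# Weighted tabulate of codes 1..nbins with weights w.
weighted_tabulate <- function(codes, w, nbins) {
  agg <- rowsum(w, codes)
  out <- numeric(nbins)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

log2_safe <- function(x) {
  ifelse(x > 0, log2(x), -Inf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
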