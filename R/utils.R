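#' @importFrom stats cor sd median quantile rnorm rbinom rlnorm rmultinom
#'   pnorm runif hclust as.dist chisq.test t.test aov complete.cases setNames
#' @importFrom utils head write.table read.delim
NULL

# deterministic child seed, kept inside 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 9973) %% 2147483629)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Round half away from zero
#'
#' Fixed-precision rounding where exact halves round up (10.25 -> 10.3 at one
#' decimal), matching how percentages are conventionally reported, rather than
#' R's round-half-even.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

percent_string <- function(x, digits = 1) {
  sprintf(paste0("%.", digits, "f%%"), round_half_up(x, digits))
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
        collapse = "")
}

translate_nt <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     no.init.codon = TRUE))
}

# one fixed codon per amino acid, used for linkers and reverse translation
.codon_table <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "AGC", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT"
)

reverse_translate <- function(aa) {
  aa <- strsplit(aa, "")[[1]]
  bad <- setdiff(aa, names(.codon_table))
  if (length(bad) > 0) {
    stop("cannot reverse-translate residue(s): ", paste(bad, collapse = ", "))
  }
  paste(.codon_table[aa], collapse = "")
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}
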