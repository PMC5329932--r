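#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnbinom rpois rbinom rlnorm rgamma rnorm runif median
#'   var phyper dhyper dnbinom p.adjust setNames complete.cases sd cor lm coef
#' @importFrom utils read.delim write.table head
NULL

# Deterministic per-stage seed derivation from one top-level seed.  Each
# pipeline stage seeds its own RNG stream so stages are independently
# reproducible.  Result is always a valid 32-bit integer seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629)
}

# IUPAC two-allele ambiguity codes (unordered base pairs).
iupac_pair_codes <- c(
  "AA" = "A", "CC" = "C", "GG" = "G", "TT" = "T",
  "AG" = "R", "GA" = "R", "CT" = "Y", "TC" = "Y",
  "CG" = "S", "GC" = "S", "AT" = "W", "TA" = "W",
  "GT" = "K", "TG" = "K", "AC" = "M", "CA" = "M"
)

# Allele sets encoded by each genotype code used in the matrices.
iupac_allele_sets <- list(
  A = c("A", "A"), C = c("C", "C"), G = c("G", "G"), T = c("T", "T"),
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
  W = c("A", "T"), K = c("G", "T"), M = c("A", "C")
)

reverse_complement <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
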