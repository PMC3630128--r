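# Internal helpers shared across the package.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Standard amino-acid alphabet
#'
#' The 20 standard residues in the fixed column order used by all profile
#' emission matrices in this package. `X` (unknown residue) is accepted in
#' sequences but is never an emission column: it is skipped during training
#' and scores zero log-odds during scoring.
#'
#' @return Character vector of 20 one-letter residue codes.
#' @export
aa_alphabet <- function() AA20

GAP_CHARS <- c("-", ".")

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. All stochastic code in the package funnels through this
# so results are reproducible from a single integer.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# split a residue/gapped string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

is_gap <- function(x) x %in% GAP_CHARS

ungap <- function(x) gsub("[-.]", "", x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
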