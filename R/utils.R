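#' Derive a reproducible per-operation seed from a global seed
#'
#' Every stochastic generator in the package draws its own seed from the
#' user's single global seed plus the operation name, so that individual
#' operations are reproducible in isolation and adding a new generator does
#' not perturb the random streams of existing ones.
#'
#' @param seed integer global seed.
#' @param op character scalar naming the operation.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
opSeed <- function(seed, op) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.character(op))
    h <- 0
    for (ch in utf8ToInt(op)) {
        h <- (h * 31 + ch) %% 2147483647
    }
    as.integer((abs(seed) + h) %% 2147483647)
}

#' Run an expression with a local RNG seed
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

# Fast reverse complement on plain character scalars.
revComp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Complement of a character vector of single bases (A/C/G/T/N).
complementBases <- function(x) {
    unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])
}

# Assert that a condition holds, signalling a classed integrity error.
integrityStop <- function(...) {
    stop(errorCondition(paste0(...), class = c("twIntegrityError", "error")))
}

argStop <- function(...) {
    stop(errorCondition(paste0(...), class = c("twArgumentError", "error")))
}

parseStop <- function(...) {
    stop(errorCondition(paste0(...), class = c("twParseError", "error")))
}
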