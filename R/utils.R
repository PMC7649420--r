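#' @importFrom stats rnbinom rbinom runif rpois median quantile var cor
#'   pchisq wilcox.test qpois ppois setNames lm.fit
#' @importFrom utils write.table read.table combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded simulation helpers do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence
#' @param n length in bases.
#' @return a single DNA string of length `n`.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Write a collapsed FASTA file
#'
#' Headers follow the `>tagID_count` convention used for collapsed small-RNA
#' libraries.
#'
#' @param counts named integer vector (names = tag sequences).
#' @param path output file.
#' @param prefix tag id prefix.
#' @export
write_collapsed_fasta <- function(counts, path, prefix = "t") {
  stopifnot(!is.null(names(counts)))
  ids <- sprintf(">%s%d_%d", prefix, seq_along(counts), as.integer(counts))
  writeLines(as.vector(rbind(ids, names(counts))), path)
  invisible(path)
}

#' Read a collapsed FASTA file
#'
#' @param path collapsed FASTA with `>id_count` headers.
#' @return named integer vector of counts, names = tag sequences.
#' @export
read_collapsed_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  counts <- as.integer(sub(".*_", "", names(ss)))
  stats::setNames(counts, as.character(ss))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
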