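#' @keywords internal
#' @import methods
#' @importFrom stats setNames rnorm rgamma phyper p.adjust median uniroot
#'   ave
#' @importFrom utils read.delim write.table
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# lookup: utf8 code -> base index (A=1 C=2 G=3 T=4), NA elsewhere
.base_index <- local({
  tab <- rep(NA_integer_, 128L)
  tab[utf8ToInt("A")] <- 1L; tab[utf8ToInt("C")] <- 2L
  tab[utf8ToInt("G")] <- 3L; tab[utf8ToInt("T")] <- 4L
  tab[utf8ToInt("a")] <- 1L; tab[utf8ToInt("c")] <- 2L
  tab[utf8ToInt("g")] <- 3L; tab[utf8ToInt("t")] <- 4L
  tab
})

#' Encode a DNA string as base indices
#'
#' @param seq single character string over A/C/G/T (case-insensitive).
#' @param allow_na keep NA for non-ACGT characters instead of erroring.
#' @return integer vector, A=1, C=2, G=3, T=4.
#' @keywords internal
seq_to_int <- function(seq, allow_na = FALSE) {
  idx <- .base_index[utf8ToInt(seq)]
  if (!allow_na && anyNA(idx)) {
    stop("sequence contains characters outside {A,C,G,T}: ",
         substr(seq, 1L, 40L))
  }
  idx
}

int_to_seq <- function(idx) paste(DNA_BASES[idx], collapse = "")

#' Reverse complement of character DNA sequences
#'
#' @param x character vector of A/C/G/T strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(chartr("ACGTacgt", "TGCAtgca", x), function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# complement in index space (A<->T, C<->G)
comp_idx <- function(i) 5L - i

# deterministic per-artifact RNG stream: mixes a master seed with a stream
# name so stages can be regenerated independently
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 2654435761)
  as.integer((abs(seed * 48271 + h)) %% 2147483647)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(stream_seed(seed, stream))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
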