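`%||%` <- function(a, b) if (is.null(a)) b else a

# IUPAC nucleotide alphabet; '?' is treated as fully unknown (like N) on input.
IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-", "?")
AMBIGUITY_CHARS <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N", "?")

seq_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(toupper(x), "")[[1]] else toupper(x)
}

seq_string <- function(x) paste(x, collapse = "")

check_iupac <- function(chars, where = "sequence") {
  bad <- setdiff(unique(chars), IUPAC_CHARS)
  if (length(bad))
    stop("non-IUPAC character(s) in ", where, ": ",
         paste(shQuote(bad), collapse = ", "), call. = FALSE)
  invisible(chars)
}

count_ambiguities <- function(chars) sum(seq_chars(chars) %in% AMBIGUITY_CHARS)

ungapped_length <- function(chars) sum(seq_chars(chars) != "-")

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Deterministic child seeds derived from one master seed (kept < 2^31).
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483629) + 1L
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(name, " must be a single number", call. = FALSE)
}
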