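#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in the package take a `seed` argument and route
#' through this helper so that identical seeds give byte-identical output
#' without clobbering the session RNG.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# random DNA string(s) of the given lengths (vectorised)
random_dna <- function(lengths) {
  n <- length(lengths)
  total <- sum(lengths)
  if (total == 0L) return(rep("", n))
  chars <- sample(DNA_BASES, total, replace = TRUE)
  grp <- rep.int(seq_len(n), lengths)
  out <- rep("", n)
  nz <- lengths > 0L
  out[nz] <- vapply(split(chars, factor(grp, levels = seq_len(n)[nz])),
                    paste0, character(1), collapse = "")
  out
}

# split equal-length sequences into an n x L character matrix
seq_char_matrix <- function(sequences) {
  L <- unique(nchar(sequences))
  if (length(L) != 1L)
    stop("sequences must all have the same length", call. = FALSE)
  matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
         nrow = length(sequences), ncol = L, byrow = TRUE)
}

stop_if_not_scalar_prob <- function(x, name, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      (if (allow_one) x > 1 else x >= 1))
    stop(sprintf("`%s` must be a probability in [0, %s)", name,
                 if (allow_one) "1]" else "1"), call. = FALSE)
  invisible(x)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}

# cached composite Gauss-Legendre rule on (0, 1); panels refine towards the
# endpoints where gamma quantiles change fastest
.quad_cache <- new.env(parent = emptyenv())
gauss_legendre_unit <- function(n = 72L,
                                breaks = c(0, 0.01, 0.1, 0.5, 0.9, 0.99,
                                           0.999, 1)) {
  key <- paste(n, paste(breaks, collapse = ","))
  if (is.null(.quad_cache[[key]])) {
    xs <- numeric(0); ws <- numeric(0)
    for (i in seq_len(length(breaks) - 1L)) {
      gl <- pracma::gaussLegendre(n, breaks[i], breaks[i + 1L])
      xs <- c(xs, gl$x); ws <- c(ws, gl$w)
    }
    .quad_cache[[key]] <- list(x = xs, w = ws)
  }
  .quad_cache[[key]]
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_plain <- function(path, colClasses = NA) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, colClasses = colClasses,
                    comment.char = "#")
}
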