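#' Binomial sequencing-error model probabilities
#'
#' For reads of length `n` with independent per-base substitution
#' probability `p`, the number of errors per read is Binomial(n, p). Returns
#' the probability of an error-free read, `(1-p)^n`, and the probability
#' that an erroneous read carries exactly one error,
#' `n p (1-p)^(n-1) / (1 - (1-p)^n)`. At the assay's design point (n = 130,
#' p = 0.001) these are approximately 0.88 and 0.94: most reads are perfect
#' and nearly all erroneous reads are single-mismatch, which is what makes
#' the distance-1 singleton collapse rule effective.
#'
#' @param read_length Read length n in nt (>= 1).
#' @param per_base_error Per-base error probability p in \[0, 1).
#' @return List with `p_zero_errors` and `p_single_given_error`; the latter
#'   is `NA` (undefined, with a warning) when `p = 0`.
#' @export
#' @examples
#' error_model_probabilities(130, 0.001)
error_model_probabilities <- function(read_length = 130L,
                                      per_base_error = 0.001) {
  if (!is_count(read_length))
    stop("`read_length` must be a positive integer", call. = FALSE)
  stop_if_not_scalar_prob(per_base_error, "per_base_error", allow_one = FALSE)
  n <- read_length
  p <- per_base_error
  p_zero <- (1 - p)^n
  if (p == 0) {
    warning("per_base_error = 0: P(single error | any error) is undefined")
    return(list(p_zero_errors = 1, p_single_given_error = NA_real_))
  }
  p_single <- n * p * (1 - p)^(n - 1) / (1 - p_zero)
  list(p_zero_errors = p_zero, p_single_given_error = p_single)
}

# priority order for "predominant clone": highest pooled count, then
# lexicographically smallest sequence
target_priority_order <- function(counts, sequences) {
  order(-counts, sequences, method = "radix")
}

#' Collapse single-mismatch sequencing errors into predominant clones
#'
#' Implements the consensus rule: pooling read counts over all wells of the
#' sample, any sequence with pooled count exactly 1 that lies at Hamming
#' distance exactly 1 from a sequence with pooled count >= 2 is merged into
#' that sequence (the singleton's read and well evidence transfer to the
#' target). When several targets qualify the singleton joins the
#' predominant one: highest pooled count, ties broken lexicographically.
#' All other sequences survive as clones. Collapse is a single simultaneous
#' pass computed from the pooled pre-merge counts and is idempotent.
#'
#' Candidate targets are found by exact hashing of the L single-position
#' wildcard masks of each sequence rather than all-pairs comparison.
#'
#' @param reads Well read table (`well_id`, `sequence`, `read_count`), as
#'   from [simulate_reads()] or [read_well_reads()].
#' @param n_wells Well count W (defaults to the table's `n_wells` attribute
#'   or `max(well_id) + 1`).
#' @return A `"clone_table"` data.frame with columns `sequence`,
#'   `occupancy`, `wells` (list-column of 0-based well ids), `total_reads`,
#'   sorted by decreasing total reads; `n_wells` is carried as an attribute.
#' @export
collapse_errors <- function(reads, n_wells = NULL) {
  if (!all(c("well_id", "sequence", "read_count") %in% names(reads)))
    stop("reads must have columns well_id, sequence, read_count",
         call. = FALSE)
  L <- unique(nchar(reads$sequence))
  if (length(L) != 1L)
    stop("ragged read lengths: all reads must have equal length",
         call. = FALSE)
  if (is.null(n_wells)) {
    n_wells <- attr(reads, "n_wells")
    if (is.null(n_wells)) n_wells <- max(reads$well_id) + 1L
  }

  seqs <- unique(reads$sequence)
  pooled <- rowsum(reads$read_count, reads$sequence, reorder = FALSE)
  pooled <- as.integer(pooled[match(seqs, rownames(pooled)), 1L])

  singleton <- pooled == 1L
  target <- pooled >= 2L
  merge_into <- rep(NA_integer_, length(seqs))   # index into seqs

  if (any(singleton) && any(target)) {
    t_idx <- which(target)
    s_idx <- which(singleton)
    ord <- target_priority_order(pooled[t_idx], seqs[t_idx])
    t_idx <- t_idx[ord]
    t_seq <- seqs[t_idx]
    s_seq <- seqs[s_idx]
    best_count <- rep(-1L, length(s_idx))
    best_target <- rep(NA_integer_, length(s_idx))
    best_seq <- rep(NA_character_, length(s_idx))
    for (i in seq_len(L)) {
      t_mask <- t_seq; substr(t_mask, i, i) <- "."
      s_mask <- s_seq; substr(s_mask, i, i) <- "."
      hit <- match(s_mask, t_mask)               # first = predominant
      found <- which(!is.na(hit))
      if (!length(found)) next
      cand <- t_idx[hit[found]]
      cand_count <- pooled[cand]
      cand_seq <- seqs[cand]
      better <- cand_count > best_count[found] |
        (cand_count == best_count[found] & cand_seq < best_seq[found])
      upd <- found[better]
      best_count[upd] <- cand_count[better]
      best_target[upd] <- cand[better]
      best_seq[upd] <- cand_seq[better]
    }
    merge_into[s_idx] <- best_target
  }

  final_of <- seq_along(seqs)
  merged <- !is.na(merge_into)
  final_of[merged] <- merge_into[merged]

  # reassign reads to final sequences, then recompute presence and totals
  read_final <- final_of[match(reads$sequence, seqs)]
  key <- paste(read_final, reads$well_id)
  first <- !duplicated(key)
  cnt <- rowsum(reads$read_count, key, reorder = FALSE)
  wf <- data.frame(final = read_final[first], well = reads$well_id[first],
                   n = as.integer(cnt[match(key[first], rownames(cnt)), 1L]))

  finals <- sort(unique(wf$final))
  wells <- split(wf$well, factor(wf$final, levels = finals))
  totals <- as.integer(rowsum(wf$n, factor(wf$final, levels = finals))[, 1L])
  out <- data.frame(sequence = seqs[finals],
                    occupancy = lengths(wells),
                    total_reads = totals,
                    stringsAsFactors = FALSE)
  out$wells <- I(unname(lapply(wells, function(w) sort(as.integer(w)))))
  out <- out[order(-out$total_reads, out$sequence),
             c("sequence", "occupancy", "wells", "total_reads")]
  rownames(out) <- NULL
  attr(out, "n_wells") <- n_wells
  class(out) <- c("clone_table", "data.frame")
  out
}

#' Occupancy spectrum of a clone table
#'
#' Counts `n_j` of clones observed in exactly j of the W replicate wells,
#' j = 1..W: the sufficient statistic for diversity inference. Presence is
#' binary; read counts are censored.
#'
#' @param clones A `"clone_table"` (or data.frame with an `occupancy`
#'   column).
#' @param n_wells Well count W; defaults to the table's attribute.
#' @return An `"occupancy_spectrum"` list: `n_wells`, `n_j` (length-W
#'   integer vector), `n_obs`.
#' @export
occupancy_spectrum <- function(clones, n_wells = NULL) {
  if (is.null(n_wells)) n_wells <- attr(clones, "n_wells")
  if (is.null(n_wells))
    stop("`n_wells` is required when the clone table carries no attribute",
         call. = FALSE)
  occ <- clones$occupancy
  if (length(occ) && (any(occ < 1) || any(occ > n_wells)))
    stop("occupancies must lie in 1..n_wells", call. = FALSE)
  structure(list(n_wells = as.integer(n_wells),
                 n_j = tabulate(occ, nbins = n_wells),
                 n_obs = length(occ)),
            class = "occupancy_spectrum")
}

#' @export
print.occupancy_spectrum <- function(x, ...) {
  cat(sprintf("Occupancy spectrum: %d clones over %d wells\n",
              x$n_obs, x$n_wells))
  show <- which(x$n_j > 0)
  show <- show[seq_len(min(10L, length(show)))]
  for (j in show) cat(sprintf("  occupancy %3d: %d clones\n", j, x$n_j[j]))
  if (sum(x$n_j > 0) > 10L) cat("  ...\n")
  invisible(x)
}

#' Clone table TSV round trip
#'
#' Columns `sequence`, `occupancy`, `wells` (comma-separated 0-based ids),
#' `total_reads`, with `# n_wells=` on the first line.
#'
#' @param clones A `"clone_table"`.
#' @param path File path.
#' @export
write_clone_table <- function(clones, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_wells=%d", attr(clones, "n_wells")), con)
  df <- data.frame(sequence = clones$sequence,
                   occupancy = clones$occupancy,
                   wells = vapply(clones$wells, paste, character(1),
                                  collapse = ","),
                   total_reads = clones$total_reads)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clone_table
#' @export
read_clone_table <- function(path) {
  first <- readLines(path, n = 1L)
  W <- if (grepl("^# n_wells=", first))
    as.integer(sub("^# n_wells=", "", first)) else NA_integer_
  df <- read_tsv_plain(path, colClasses = c("character", "integer",
                                            "character", "integer"))
  df$wells <- I(lapply(strsplit(df$wells, ",", fixed = TRUE), as.integer))
  df <- df[c("sequence", "occupancy", "wells", "total_reads")]
  attr(df, "n_wells") <- W
  class(df) <- c("clone_table", "data.frame")
  df
}

#' Occupancy spectrum TSV round trip
#'
#' Columns `occupancy`, `n_clones` (zero rows omitted), with `# n_wells=`
#' on the first line.
#'
#' @param spectrum An `"occupancy_spectrum"`.
#' @param path File path.
#' @export
write_occupancy_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_wells=%d", spectrum$n_wells), con)
  j <- which(spectrum$n_j > 0)
  utils::write.table(data.frame(occupancy = j, n_clones = spectrum$n_j[j]),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occupancy_spectrum
#' @export
read_occupancy_spectrum <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# n_wells=", first))
    stop("spectrum file must start with a '# n_wells=' line", call. = FALSE)
  W <- as.integer(sub("^# n_wells=", "", first))
  df <- read_tsv_plain(path, colClasses = c("integer", "integer"))
  n_j <- integer(W)
  n_j[df$occupancy] <- df$n_clones
  structure(list(n_wells = W, n_j = n_j, n_obs = sum(n_j)),
            class = "occupancy_spectrum")
}
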