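#' Sample clone frequencies from a gamma abundance distribution
#'
#' Clone intensities are drawn i.i.d. from a Gamma(`mixing_shape`,
#' scale = `mixing_scale`) distribution and normalised to frequencies. Large
#' shapes give near-uniform repertoires (naive-like); small shapes give
#' heavy-tailed, clonally dominated repertoires (memory-like).
#'
#' @param richness Number of clones (>= 1).
#' @param mixing_shape,mixing_scale Positive gamma parameters.
#' @param seed Optional integer seed.
#' @return Numeric vector of `richness` frequencies in (0, 1] summing to 1.
#' @export
#' @examples
#' f <- sample_clone_frequencies(100, mixing_shape = 1, seed = 1)
#' sum(f)
sample_clone_frequencies <- function(richness, mixing_shape = 1,
                                     mixing_scale = 1, seed = NULL) {
  if (!is_count(richness))
    stop("`richness` must be a positive integer", call. = FALSE)
  if (!is.numeric(mixing_shape) || mixing_shape <= 0 ||
      !is.numeric(mixing_scale) || mixing_scale <= 0)
    stop("`mixing_shape` and `mixing_scale` must be positive", call. = FALSE)
  with_seed(seed, {
    lam <- stats::rgamma(richness, shape = mixing_shape, scale = mixing_scale)
    lam <- pmax(lam, .Machine$double.xmin)  # guard tiny-shape underflow to 0
    lam / sum(lam)
  })
}

# mutate the 3' `window` nt of each V sequence at per-base rate `rate`;
# optional positional weighting concentrates substitutions on given V
# positions (used to plant hotspot-biased mutation patterns)
apply_shm <- function(v_seqs, rate, window = 100L, hot_positions = NULL,
                      hot_weight = 1) {
  n <- length(v_seqs)
  out <- v_seqs
  counts <- integer(n)
  pos_list <- vector("list", n)
  if (rate <= 0) return(list(sequence = out, n_mut = counts,
                             positions = pos_list))
  v_len <- nchar(v_seqs)
  win_start <- pmax(v_len - window, 0L)       # 0-based first mutable position
  n_mut <- stats::rbinom(n, pmin(window, v_len), rate)
  idx <- which(n_mut > 0L)
  for (i in idx) {
    cand <- (win_start[i] + 1L):v_len[i]      # 1-based positions
    w <- rep(1, length(cand))
    if (!is.null(hot_positions)) {
      w[cand %in% (hot_positions + 1L)] <- hot_weight
    }
    pos <- sample(cand, n_mut[i], prob = w)
    chars <- strsplit(out[i], "", fixed = TRUE)[[1]]
    for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    out[i] <- paste0(chars, collapse = "")
    counts[i] <- n_mut[i]
    pos_list[[i]] <- sort(pos - 1L)           # back to 0-based
  }
  list(sequence = out, n_mut = counts, positions = pos_list)
}

#' Build rearranged clone sequences from a germline reference
#'
#' Each clone is assembled as V (optionally carrying point substitutions at
#' `shm_rate` over the 3' `shm_window` nt of the V segment only) + random N1
#' insert + D + random N2 insert + J, with segments drawn uniformly from the
#' reference. Insert lengths are uniform on `n_insert_min:n_insert_max`
#' (nonzero minimum by default, so that the junction always contributes
#' non-templated bases and the clone space stays astronomically large, as
#' in real repertoires). Colliding sequences are resampled so clone
#' sequences are unique. CDR3 bounds (0-based, half-open, on the full
#' rearrangement) run from the V conserved-cysteine anchor through the end
#' of the J conserved-Phe/Trp codon.
#'
#' @param reference Germline reference with all three classes.
#' @param richness Number of clones to build.
#' @param shm_rate Per-base substitution probability in \[0, 1) applied to
#'   the V segment (0 for naive-like clones).
#' @param n_insert_min,n_insert_max N-insert length bounds per side.
#' @param shm_window Width (nt) of the mutable 3' V window.
#' @param hotspot_positions Optional 0-based V positions given extra
#'   mutation weight `hotspot_weight`, to plant positional hotspots.
#' @param hotspot_weight Relative weight of `hotspot_positions`.
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `clone_id`, `sequence`, `v_id`, `d_id`,
#'   `j_id`, `cdr3_start`, `cdr3_end`, `n_v_mutations` and a list-column
#'   `v_mutation_positions` (0-based positions within the V segment).
#' @export
build_clone_sequences <- function(reference, richness, shm_rate = 0,
                                  n_insert_min = 2L, n_insert_max = 8L,
                                  shm_window = 100L,
                                  hotspot_positions = NULL,
                                  hotspot_weight = 1, seed = NULL) {
  validate_reference(reference)
  if (!is_count(richness))
    stop("`richness` must be a positive integer", call. = FALSE)
  stop_if_not_scalar_prob(shm_rate, "shm_rate", allow_one = FALSE)
  if (n_insert_min < 0L || n_insert_max < n_insert_min)
    stop("need 0 <= n_insert_min <= n_insert_max", call. = FALSE)
  refV <- reference[reference$segment_class == "V", , drop = FALSE]
  refD <- reference[reference$segment_class == "D", , drop = FALSE]
  refJ <- reference[reference$segment_class == "J", , drop = FALSE]

  with_seed(seed, {
    build_batch <- function(n) {
      vi <- sample.int(nrow(refV), n, replace = TRUE)
      di <- sample.int(nrow(refD), n, replace = TRUE)
      ji <- sample.int(nrow(refJ), n, replace = TRUE)
      span <- n_insert_max - n_insert_min + 1L
      n1 <- sample.int(span, n, replace = TRUE) + n_insert_min - 1L
      n2 <- sample.int(span, n, replace = TRUE) + n_insert_min - 1L
      shm <- apply_shm(refV$sequence[vi], shm_rate, shm_window,
                       hotspot_positions, hotspot_weight)
      v_len <- nchar(refV$sequence[vi])
      d_len <- nchar(refD$sequence[di])
      seqs <- paste0(shm$sequence, random_dna(n1), refD$sequence[di],
                     random_dna(n2), refJ$sequence[ji])
      data.frame(
        sequence = seqs,
        v_id = refV$segment_id[vi],
        d_id = refD$segment_id[di],
        j_id = refJ$segment_id[ji],
        cdr3_start = refV$cdr3_anchor[vi],
        cdr3_end = v_len + n1 + d_len + n2 + refJ$cdr3_anchor[ji] + 3L,
        n_v_mutations = shm$n_mut,
        v_mutation_positions = I(shm$positions),
        stringsAsFactors = FALSE
      )
    }
    clones <- build_batch(richness)
    # resample collisions until sequences are unique
    repeat {
      dup <- which(duplicated(clones$sequence))
      if (!length(dup)) break
      clones[dup, ] <- build_batch(length(dup))
    }
    clones$clone_id <- sprintf("clone%06d", seq_len(richness))
    clones[c("clone_id", "sequence", "v_id", "d_id", "j_id", "cdr3_start",
             "cdr3_end", "n_v_mutations", "v_mutation_positions")]
  })
}

#' Cell-type presets for the synthetic generator
#'
#' Desk-scale parameter presets emulating the two sorted compartments:
#' naive-like clones have near-uniform abundances (large gamma shape), no V
#' substitutions and longer junction inserts (mean CDR3 48 nt); memory-like
#' clones have dispersed abundances (small shape), 3-4 substitutions per
#' 100 nt of V, and shorter inserts (mean CDR3 45 nt).
#'
#' @param cell_type `"naive-like"` or `"memory-like"`.
#' @return Named list of generator parameters.
#' @export
cell_type_preset <- function(cell_type = c("naive-like", "memory-like")) {
  cell_type <- match.arg(cell_type)
  if (cell_type == "naive-like") {
    list(cell_type = "naive-like", mixing_shape = 5, shm_rate = 0,
         n_insert_min = 2L, n_insert_max = 8L, contamination = 0)
  } else {
    list(cell_type = "memory-like", mixing_shape = 0.5, shm_rate = 0.035,
         n_insert_min = 2L, n_insert_max = 5L, contamination = 0)
  }
}

#' Generate a ground-truth repertoire
#'
#' Combines [sample_clone_frequencies()] and [build_clone_sequences()] into
#' a `"true_repertoire"` object: clone records (sequence, segment calls,
#' CDR3 bounds, planted V substitutions) plus per-clone frequencies drawn
#' from the gamma mixing distribution. A `contamination` fraction of clones
#' can be generated with the memory-like preset inside a naive-like
#' repertoire (or vice versa), emulating sort impurity.
#'
#' @inheritParams build_clone_sequences
#' @param mixing_shape,mixing_scale Gamma parameters of the abundance
#'   mixing distribution.
#' @param cell_type Label and preset; explicit arguments override preset
#'   values.
#' @param contamination Fraction of clones drawn from the opposite
#'   cell-type preset.
#' @return A `"true_repertoire"` list with elements `clones` (data.frame,
#'   including `frequency` and `contaminant`), `richness`, `mixing_shape`,
#'   `mixing_scale`, `cell_type`.
#' @export
synthetic_repertoire <- function(reference, richness,
                                 cell_type = c("naive-like", "memory-like"),
                                 mixing_shape = NULL, mixing_scale = 1,
                                 shm_rate = NULL, n_insert_min = NULL,
                                 n_insert_max = NULL,
                                 contamination = NULL, seed = NULL) {
  preset <- cell_type_preset(cell_type)
  if (is.null(mixing_shape)) mixing_shape <- preset$mixing_shape
  if (is.null(shm_rate)) shm_rate <- preset$shm_rate
  if (is.null(n_insert_min)) n_insert_min <- preset$n_insert_min
  if (is.null(n_insert_max)) n_insert_max <- preset$n_insert_max
  if (is.null(contamination)) contamination <- preset$contamination
  stop_if_not_scalar_prob(contamination, "contamination")
  other <- cell_type_preset(setdiff(c("naive-like", "memory-like"),
                                    preset$cell_type))
  with_seed(seed, {
    n_cont <- stats::rbinom(1L, richness, contamination)
    n_main <- richness - n_cont
    main <- build_clone_sequences(reference, max(n_main, 1L), shm_rate,
                                  n_insert_min = n_insert_min,
                                  n_insert_max = n_insert_max)
    if (n_main == 0L) main <- main[0L, ]
    if (n_cont > 0L) {
      cont <- build_clone_sequences(reference, n_cont, other$shm_rate,
                                    n_insert_min = other$n_insert_min,
                                    n_insert_max = other$n_insert_max)
      clones <- rbind(main, cont)
      # a contaminant colliding with a main clone is astronomically unlikely
      # at these junction entropies but keep sequences unique regardless
      clones <- clones[!duplicated(clones$sequence), , drop = FALSE]
      contaminant <- c(rep(FALSE, nrow(main)),
                       rep(TRUE, nrow(clones) - nrow(main)))
    } else {
      clones <- main
      contaminant <- rep(FALSE, nrow(clones))
    }
    clones$clone_id <- sprintf("clone%06d", seq_len(nrow(clones)))
    clones$contaminant <- contaminant
    clones$frequency <- sample_clone_frequencies(nrow(clones), mixing_shape,
                                                 mixing_scale)
    structure(list(clones = clones, richness = nrow(clones),
                   mixing_shape = mixing_shape, mixing_scale = mixing_scale,
                   cell_type = preset$cell_type),
              class = "true_repertoire")
  })
}

#' @export
print.true_repertoire <- function(x, ...) {
  cat(sprintf("Synthetic %s repertoire: %d clones, gamma(shape=%g, scale=%g)\n",
              x$cell_type, x$richness, x$mixing_shape, x$mixing_scale))
  cat(sprintf("  mean CDR3 %.1f nt, mean V substitutions %.2f\n",
              mean(x$clones$cdr3_end - x$clones$cdr3_start),
              mean(x$clones$n_v_mutations)))
  invisible(x)
}

#' Allocate cells to replicate wells (the urn process)
#'
#' Each of `n_cells` cells is assigned a clone identity by frequency and a
#' well uniformly at random, mirroring the urn design in which genomic
#' template molecules are distributed over the replicate PCR wells.
#'
#' @param frequencies Clone frequency vector summing to 1.
#' @param n_cells Total cells to allocate (>= 1).
#' @param n_wells Number of wells W (>= 1).
#' @param seed Optional integer seed.
#' @return Integer matrix (clones x wells) of cell counts; total equals
#'   `n_cells` exactly.
#' @export
allocate_cells <- function(frequencies, n_cells, n_wells, seed = NULL) {
  if (abs(sum(frequencies) - 1) > 1e-6 || any(frequencies < 0))
    stop("`frequencies` must be nonnegative and sum to 1", call. = FALSE)
  if (!is_count(n_cells) || !is_count(n_wells))
    stop("`n_cells` and `n_wells` must be positive integers", call. = FALSE)
  S <- length(frequencies)
  with_seed(seed, {
    per_clone <- stats::rmultinom(1L, n_cells, frequencies)[, 1L]
    clone_of_cell <- rep.int(seq_len(S), per_clone)
    well_of_cell <- sample.int(n_wells, n_cells, replace = TRUE)
    counts <- tabulate((clone_of_cell - 1L) * n_wells + well_of_cell,
                       nbins = S * n_wells)
    matrix(counts, nrow = S, ncol = n_wells, byrow = TRUE)
  })
}

# the assayed read window: `read_length` nt ending at the CDR3 end
clone_read_window <- function(clones, read_length = 130L) {
  if (any(clones$cdr3_end < read_length))
    stop("some rearrangements are shorter than the read window",
         call. = FALSE)
  substr(clones$sequence, clones$cdr3_end - read_length + 1L,
         clones$cdr3_end)
}

#' Simulate error-bearing reads from allocated cells
#'
#' Each template cell emits a Poisson number of reads with mean `coverage`
#' scaled by a per-clone lognormal amplification factor with coefficient of
#' variation `amplification_cv`. Each read is the `read_length` nt window of
#' the clone's rearrangement ending at the CDR3 end, independently mutated
#' at `error_rate` per base. Planted erroneous reads are recorded so that
#' consensus collapse can be scored against truth.
#'
#' @param truth A `"synthetic_truth"` object from [simulate_well_experiment()]
#'   or a list with elements `repertoire` and `cell_counts`.
#' @param coverage Mean reads per template cell (>= 1).
#' @param error_rate Per-base substitution probability.
#' @param amplification_cv Coefficient of variation of the per-clone
#'   lognormal amplification factor (0 disables amplification noise).
#' @param read_length Read length in nt.
#' @param seed Optional integer seed.
#' @return List with `reads` (data.frame `well_id`, `sequence`,
#'   `read_count`; `well_id` is 0-based) and `planted_errors` (data.frame
#'   `well_id`, `true_clone_id`, `erroneous_sequence`, `n_errors`).
#' @export
simulate_reads <- function(truth, coverage = 10, error_rate = 0.001,
                           amplification_cv = 0, read_length = 130L,
                           seed = NULL) {
  if (!is.numeric(coverage) || coverage < 1)
    stop("`coverage` must be >= 1", call. = FALSE)
  stop_if_not_scalar_prob(error_rate, "error_rate", allow_one = FALSE)
  if (amplification_cv < 0)
    stop("`amplification_cv` must be nonnegative", call. = FALSE)
  clones <- truth$repertoire$clones
  cc <- truth$cell_counts
  templates <- clone_read_window(clones, read_length)
  W <- ncol(cc)

  with_seed(seed, {
    sdlog <- sqrt(log1p(amplification_cv^2))
    amp <- if (sdlog > 0)
      stats::rlnorm(nrow(cc), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    else rep(1, nrow(cc))

    nz <- which(cc > 0, arr.ind = TRUE)
    clone_i <- nz[, 1L]
    well_i <- nz[, 2L]
    cells <- cc[nz]
    n_reads <- stats::rpois(length(cells), cells * coverage * amp[clone_i])

    p0 <- (1 - error_rate)^read_length
    n_clean <- stats::rbinom(length(n_reads), n_reads, p0)
    n_bad <- n_reads - n_clean

    keep <- n_clean > 0L
    reads <- data.frame(well_id = well_i[keep] - 1L,
                        sequence = templates[clone_i[keep]],
                        read_count = n_clean[keep],
                        stringsAsFactors = FALSE)

    planted <- data.frame(well_id = integer(0), true_clone_id = character(0),
                          erroneous_sequence = character(0),
                          n_errors = integer(0), stringsAsFactors = FALSE)
    total_bad <- sum(n_bad)
    if (total_bad > 0L) {
      bad_pair <- rep.int(seq_along(n_bad), n_bad)
      # number of errors per erroneous read: Binomial(L, p) truncated at >= 1
      k <- stats::rbinom(total_bad, read_length, error_rate)
      while (any(k == 0L))
        k[k == 0L] <- stats::rbinom(sum(k == 0L), read_length, error_rate)
      # cache template char vectors per clone actually needing them
      uc <- unique(clone_i[bad_pair])
      tmpl_chars <- lapply(templates[uc], function(s)
        strsplit(s, "", fixed = TRUE)[[1]])
      names(tmpl_chars) <- as.character(uc)
      bad_seq <- character(total_bad)
      for (r in seq_len(total_bad)) {
        ci <- clone_i[bad_pair[r]]
        chars <- tmpl_chars[[as.character(ci)]]
        pos <- sample.int(read_length, k[r])
        for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
        bad_seq[r] <- paste0(chars, collapse = "")
      }
      planted <- data.frame(
        well_id = well_i[bad_pair] - 1L,
        true_clone_id = clones$clone_id[clone_i[bad_pair]],
        erroneous_sequence = bad_seq,
        n_errors = k,
        stringsAsFactors = FALSE
      )
      reads <- rbind(reads,
                     data.frame(well_id = planted$well_id,
                                sequence = bad_seq,
                                read_count = 1L, stringsAsFactors = FALSE))
    }
    # aggregate duplicate (well, sequence) rows
    key <- paste(reads$well_id, reads$sequence)
    agg <- rowsum(reads$read_count, key, reorder = FALSE)
    first <- !duplicated(key)
    out <- data.frame(well_id = reads$well_id[first],
                      sequence = reads$sequence[first],
                      read_count = as.integer(agg[match(key[first],
                                                        rownames(agg)), 1L]),
                      stringsAsFactors = FALSE)
    out <- out[order(out$well_id, out$sequence), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_wells") <- W
    attr(out, "read_length") <- read_length
    list(reads = out, planted_errors = planted)
  })
}

#' Simulate a complete replicate-well experiment
#'
#' Convenience wrapper chaining [synthetic_repertoire()],
#' [allocate_cells()] and [simulate_reads()]: the full path from a
#' ground-truth repertoire to an error-bearing well read table. Defaults
#' describe the full-scale design (188 wells, 50,000 cells per well); tests
#' and examples scale `n_wells`/`cells_per_well`/`richness` down.
#'
#' @inheritParams synthetic_repertoire
#' @inheritParams simulate_reads
#' @param n_wells Number of replicate wells W.
#' @param cells_per_well Average cells per well; total cells =
#'   `n_wells * cells_per_well`.
#' @return A `"synthetic_truth"` list: `repertoire`, `cell_counts`,
#'   `reads`, `planted_errors`, `n_wells`.
#' @export
simulate_well_experiment <- function(reference, richness,
                                     cell_type = c("naive-like",
                                                   "memory-like"),
                                     n_wells = 188L, cells_per_well = 50000L,
                                     coverage = 10, error_rate = 0.001,
                                     amplification_cv = 0,
                                     read_length = 130L,
                                     mixing_shape = NULL, mixing_scale = 1,
                                     shm_rate = NULL, contamination = NULL,
                                     seed = NULL) {
  with_seed(seed, {
    rep <- synthetic_repertoire(reference, richness, cell_type,
                                mixing_shape = mixing_shape,
                                mixing_scale = mixing_scale,
                                shm_rate = shm_rate,
                                contamination = contamination)
    cc <- allocate_cells(rep$clones$frequency,
                         n_cells = n_wells * cells_per_well,
                         n_wells = n_wells)
    truth <- list(repertoire = rep, cell_counts = cc, n_wells = n_wells)
    sim <- simulate_reads(truth, coverage = coverage,
                          error_rate = error_rate,
                          amplification_cv = amplification_cv,
                          read_length = read_length)
    truth$reads <- sim$reads
    truth$planted_errors <- sim$planted_errors
    class(truth) <- "synthetic_truth"
    truth
  })
}

#' Well read table TSV round trip
#'
#' Columns `well_id`, `sequence`, `read_count`, tab-separated, with the well
#' count recorded on a `# n_wells=` comment line.
#'
#' @param reads Well read table `data.frame`.
#' @param path File path.
#' @return The read table (`read_well_reads`) or `path` invisibly.
#' @export
write_well_reads <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  W <- attr(reads, "n_wells")
  if (is.null(W)) W <- max(reads$well_id) + 1L
  writeLines(sprintf("# n_wells=%d", W), con)
  utils::write.table(reads[c("well_id", "sequence", "read_count")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_well_reads
#' @export
read_well_reads <- function(path) {
  if (!file.exists(path))
    stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  W <- if (grepl("^# n_wells=", first))
    as.integer(sub("^# n_wells=", "", first)) else NA_integer_
  df <- read_tsv_plain(path,
                       colClasses = c("integer", "character", "integer"))
  if (is.na(W)) W <- max(df$well_id) + 1L
  attr(df, "n_wells") <- W
  df
}

#' Write the ground-truth sidecar as JSON
#'
#' Records the generator parameters, per-clone truth and planted errors of
#' a synthetic experiment so recovery can be audited outside R.
#'
#' @param truth A `"synthetic_truth"` object.
#' @param path Output JSON path.
#' @export
write_truth_json <- function(truth, path) {
  clones <- truth$repertoire$clones
  clones$v_mutation_positions <-
    vapply(clones$v_mutation_positions, paste, character(1), collapse = ",")
  obj <- list(
    cell_type = truth$repertoire$cell_type,
    richness = truth$repertoire$richness,
    mixing_shape = truth$repertoire$mixing_shape,
    mixing_scale = truth$repertoire$mixing_scale,
    n_wells = truth$n_wells,
    clones = clones,
    planted_errors = truth$planted_errors,
    well_cell_totals = as.integer(colSums(truth$cell_counts))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
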