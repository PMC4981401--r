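#' Assign germline V/D/J segments by scored ungapped alignment
#'
#' Reads are the assayed window ending inside J (3' V, junction, CDR3),
#' so alignments are anchored to the read ends: V segments are scored with
#' a suffix of the gene aligned to the read's 5' end, J segments with a
#' prefix of the gene ending at the read's 3' end, both ungapped with
#' match +1 / mismatch -1 and all anchorings scanned. Segments tying the
#' top score are all reported (similar genes legitimately tie). D is
#' assigned within the junction window between the V end and J start by
#' the same scoring and reported as absent when the best score falls below
#' `d_min_score`. A read whose best V or J score is below threshold is
#' recorded as a `no-anchor` failure, not an error.
#'
#' @param sequences Character vector of equal-length reads (>= 30 nt).
#' @param reference Germline reference `data.frame`.
#' @param v_min_score,j_min_score,d_min_score Minimum alignment scores;
#'   defaults chosen so random reads essentially never pass.
#' @return A data.frame with one row per read: `v_call`, `d_call`,
#'   `j_call` (comma-joined ties, `NA` when unassigned), `v_best`,
#'   `j_best` (first tied id), `v_score`, `j_score`, `v_gene_start`
#'   (0-based start of the aligned V suffix within the gene), `v_read_len`
#'   (aligned V length on the read), `j_gene_end` (0-based exclusive end
#'   of the aligned J prefix), and `anchored` (FALSE for no-anchor reads).
#' @export
assign_germline <- function(sequences, reference, v_min_score = 20L,
                            j_min_score = 10L, d_min_score = 3L) {
  validate_reference(reference)
  if (any(nchar(sequences) < 30L))
    stop("reads must be at least 30 nt", call. = FALSE)
  n <- length(sequences)
  mr <- seq_char_matrix(sequences)
  L <- ncol(mr)
  refV <- reference[reference$segment_class == "V", , drop = FALSE]
  refD <- reference[reference$segment_class == "D", , drop = FALSE]
  refJ <- reference[reference$segment_class == "J", , drop = FALSE]

  # --- V: gene suffix of length w against read columns 1..w
  nV <- nrow(refV)
  v_score <- matrix(-Inf, n, nV)
  v_w <- matrix(0L, n, nV)
  for (g in seq_len(nV)) {
    gv <- strsplit(refV$sequence[g], "", fixed = TRUE)[[1]]
    m <- length(gv)
    for (w in seq.int(min(v_min_score, m), min(m, L))) {
      tail_g <- gv[(m - w + 1L):m]
      matches <- rowSums(mr[, seq_len(w), drop = FALSE] ==
                           matrix(tail_g, n, w, byrow = TRUE))
      sc <- 2L * matches - w
      upd <- sc > v_score[, g]
      v_score[upd, g] <- sc[upd]
      v_w[upd, g] <- w
    }
  }
  v_top <- apply(v_score, 1L, max)
  v_ok <- v_top >= v_min_score

  # --- J: gene prefix of length e against read columns (L-e+1)..L
  nJ <- nrow(refJ)
  j_score <- matrix(-Inf, n, nJ)
  j_e <- matrix(0L, n, nJ)
  for (g in seq_len(nJ)) {
    gj <- strsplit(refJ$sequence[g], "", fixed = TRUE)[[1]]
    m <- length(gj)
    for (e in seq.int(min(j_min_score, m), min(m, L))) {
      pre_g <- gj[seq_len(e)]
      matches <- rowSums(mr[, (L - e + 1L):L, drop = FALSE] ==
                           matrix(pre_g, n, e, byrow = TRUE))
      sc <- 2L * matches - e
      upd <- sc > j_score[, g]
      j_score[upd, g] <- sc[upd]
      j_e[upd, g] <- e
    }
  }
  j_top <- apply(j_score, 1L, max)
  j_ok <- j_top >= j_min_score

  anchored <- v_ok & j_ok
  join_ties <- function(ids) paste(ids, collapse = ",")
  v_call <- v_best <- rep(NA_character_, n)
  v_gene_start <- v_read_len <- rep(NA_integer_, n)
  j_call <- j_best <- rep(NA_character_, n)
  j_gene_end <- rep(NA_integer_, n)
  for (i in which(anchored)) {
    tv <- which(v_score[i, ] == v_top[i])
    v_call[i] <- join_ties(refV$segment_id[tv])
    v_best[i] <- refV$segment_id[tv[1L]]
    w <- v_w[i, tv[1L]]
    v_read_len[i] <- w
    v_gene_start[i] <- nchar(refV$sequence[tv[1L]]) - w
    tj <- which(j_score[i, ] == j_top[i])
    j_call[i] <- join_ties(refJ$segment_id[tj])
    j_best[i] <- refJ$segment_id[tj[1L]]
    j_gene_end[i] <- j_e[i, tj[1L]]
  }

  # --- D: ungapped scan of the junction window (between V end and J start)
  d_call <- rep(NA_character_, n)
  d_score_out <- rep(NA_integer_, n)
  nD <- nrow(refD)
  d_chars <- lapply(refD$sequence, function(s) strsplit(s, "", TRUE)[[1]])
  for (i in which(anchored)) {
    win_lo <- v_read_len[i] + 1L
    win_hi <- L - j_e[i]
    if (win_hi < win_lo) next
    win <- mr[i, win_lo:win_hi]
    best <- -Inf; best_ids <- character(0)
    for (g in seq_len(nD)) {
      dc <- d_chars[[g]]
      dl <- length(dc)
      if (length(win) < dl) next
      for (off in 0:(length(win) - dl)) {
        matches <- sum(win[(off + 1L):(off + dl)] == dc)
        sc <- 2L * matches - dl
        if (sc > best) { best <- sc; best_ids <- refD$segment_id[g] }
        else if (sc == best) best_ids <- union(best_ids, refD$segment_id[g])
      }
    }
    if (is.finite(best) && best >= d_min_score) {
      d_call[i] <- join_ties(best_ids)
      d_score_out[i] <- best
    }
  }

  data.frame(sequence = sequences, anchored = anchored,
             v_call = v_call, d_call = d_call, j_call = j_call,
             v_best = v_best, j_best = j_best,
             v_score = ifelse(v_ok, v_top, NA_integer_),
             j_score = ifelse(j_ok, j_top, NA_integer_),
             v_gene_start = v_gene_start, v_read_len = v_read_len,
             j_gene_end = j_gene_end, stringsAsFactors = FALSE)
}

#' Extract CDR3 bounds from germline assignments
#'
#' Maps the CDR3 anchors of the assigned V and J segments onto the read:
#' the CDR3 starts at the first base of the V conserved-cysteine codon and
#' ends after the conserved J Phe/Trp codon (the anchor codon is included;
#' coordinates are 0-based half-open on the read). Anchors falling outside
#' the read demote the read to `no-anchor`.
#'
#' @param assignments Output of [assign_germline()].
#' @param reference The same germline reference.
#' @return `assignments` with added `cdr3_start`, `cdr3_end`,
#'   `cdr3_length` columns (`NA`, with `anchored = FALSE`, when an anchor
#'   is unmappable).
#' @export
extract_cdr3 <- function(assignments, reference) {
  a <- assignments
  L <- nchar(a$sequence[1L])
  anchor_of <- function(ids) reference$cdr3_anchor[
    match(ids, reference$segment_id)]
  cdr3_start <- cdr3_end <- rep(NA_integer_, nrow(a))
  ok <- which(a$anchored)
  if (length(ok)) {
    v_anchor <- anchor_of(a$v_best[ok])
    # read column (0-based) of V gene position `v_anchor`
    cs <- v_anchor - a$v_gene_start[ok]
    j_anchor <- anchor_of(a$j_best[ok])
    ce <- (L - a$j_gene_end[ok]) + j_anchor + 3L
    valid <- cs >= 0L & ce <= L & ce > cs
    cdr3_start[ok[valid]] <- cs[valid]
    cdr3_end[ok[valid]] <- ce[valid]
    a$anchored[ok[!valid]] <- FALSE
  }
  a$cdr3_start <- cdr3_start
  a$cdr3_end <- cdr3_end
  a$cdr3_length <- cdr3_end - cdr3_start
  a
}

#' Classify rearrangement productivity
#'
#' A rearrangement is `out-of-frame` if its CDR3 length is not a multiple
#' of 3; otherwise `stop` if any in-frame stop codon (TAA/TAG/TGA, frame
#' anchored at the CDR3 start) occurs within the read; otherwise
#' `productive`. Reads without anchors are `no-anchor`. The four labels
#' partition all reads.
#'
#' @param annotated Output of [extract_cdr3()].
#' @return `annotated` with a `productive` factor column.
#' @export
classify_productive <- function(annotated) {
  a <- annotated
  lab <- rep("no-anchor", nrow(a))
  ok <- which(a$anchored)
  stops <- c("TAA", "TAG", "TGA")
  for (i in ok) {
    if (a$cdr3_length[i] %% 3L != 0L) {
      lab[i] <- "out-of-frame"
      next
    }
    s <- a$sequence[i]
    L <- nchar(s)
    frame0 <- a$cdr3_start[i] %% 3L
    starts <- seq.int(frame0 + 1L, L - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    lab[i] <- if (any(codons %in% stops)) "stop" else "productive"
  }
  a$productive <- factor(lab, levels = c("productive", "out-of-frame",
                                         "stop", "no-anchor"))
  a
}

#' Call somatic hypermutation over the aligned V segment
#'
#' Position-wise comparison of each read's aligned V region against the
#' assigned germline V (first id of a tie list), restricted to the V
#' segment only. Each mismatch is classified as a transition (A<->G,
#' C<->T) or transversion.
#'
#' @param annotated Output of [assign_germline()] (or downstream).
#' @param reference Germline reference.
#' @return List with `mutations`: long data.frame (`read_index`, `v_gene`,
#'   `gene_pos` and `read_pos`, both 0-based, `germline_base`,
#'   `observed_base`, `class`) and `per_read`: data.frame (`read_index`,
#'   `v_mutation_count`, `v_aligned_length`).
#' @export
call_shm <- function(annotated, reference) {
  a <- annotated
  n <- nrow(a)
  idx_list <- vector("list", n)
  counts <- integer(n)
  alen <- rep(NA_integer_, n)
  v_seqs <- stats::setNames(reference$sequence, reference$segment_id)
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  rows <- list()
  for (i in which(a$anchored)) {
    w <- a$v_read_len[i]
    if (is.na(w) || w == 0L) next
    alen[i] <- w
    gene <- a$v_best[i]
    gseq <- v_seqs[[gene]]
    gchars <- strsplit(substr(gseq, a$v_gene_start[i] + 1L,
                              a$v_gene_start[i] + w), "", TRUE)[[1]]
    rchars <- strsplit(substr(a$sequence[i], 1L, w), "", TRUE)[[1]]
    mm <- which(gchars != rchars)
    counts[i] <- length(mm)
    if (length(mm)) {
      rows[[length(rows) + 1L]] <- data.frame(
        read_index = i,
        v_gene = gene,
        gene_pos = a$v_gene_start[i] + mm - 1L,
        read_pos = mm - 1L,
        germline_base = gchars[mm],
        observed_base = rchars[mm],
        class = ifelse(transitions[gchars[mm]] == rchars[mm],
                       "transition", "transversion"),
        stringsAsFactors = FALSE
      )
    }
  }
  mutations <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_index = integer(0), v_gene = character(0),
               gene_pos = integer(0), read_pos = integer(0),
               germline_base = character(0), observed_base = character(0),
               class = character(0), stringsAsFactors = FALSE)
  rownames(mutations) <- NULL
  list(mutations = mutations,
       per_read = data.frame(read_index = seq_len(n),
                             v_mutation_count = ifelse(a$anchored, counts,
                                                       NA_integer_),
                             v_aligned_length = alen))
}

#' Annotate a clone table end to end
#'
#' Runs [assign_germline()], [extract_cdr3()], [classify_productive()] and
#' [call_shm()] over the sequences of a clone table (or a plain character
#' vector), returning one annotated row per clone plus the long-format
#' mutation table.
#'
#' @param clones A `"clone_table"` or character vector of sequences.
#' @param reference Germline reference.
#' @param ... Passed to [assign_germline()].
#' @return List with `clones` (annotated data.frame, carrying `occupancy`
#'   and `total_reads` when the input had them) and `mutations` (long
#'   data.frame from [call_shm()]).
#' @export
annotate_clones <- function(clones, reference, ...) {
  seqs <- if (is.character(clones)) clones else clones$sequence
  a <- assign_germline(seqs, reference, ...)
  a <- extract_cdr3(a, reference)
  a <- classify_productive(a)
  shm <- call_shm(a, reference)
  a$v_mutation_count <- shm$per_read$v_mutation_count
  a$v_aligned_length <- shm$per_read$v_aligned_length
  if (!is.character(clones)) {
    for (col in intersect(c("occupancy", "total_reads"), names(clones)))
      a[[col]] <- clones[[col]]
  }
  list(clones = a, mutations = shm$mutations)
}

#' Write annotations as AIRR-style TSV
#'
#' Columns `sequence`, `v_call`, `d_call`, `j_call`, `junction`,
#' `junction_length`, `productive`, `v_mutation_count` (one row per
#' clone), plus an optional long-format per-mutation TSV.
#'
#' @param annotation Result of [annotate_clones()].
#' @param path Output TSV path.
#' @param mutations_path Optional path for the long-format mutation table.
#' @export
write_airr_tsv <- function(annotation, path, mutations_path = NULL) {
  a <- annotation$clones
  junction <- ifelse(a$anchored,
                     substr(a$sequence, a$cdr3_start + 1L, a$cdr3_end), NA)
  df <- data.frame(sequence = a$sequence,
                   v_call = a$v_call, d_call = a$d_call, j_call = a$j_call,
                   junction = junction,
                   junction_length = a$cdr3_length,
                   productive = as.character(a$productive),
                   v_mutation_count = a$v_mutation_count,
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
  if (!is.null(mutations_path))
    write_tsv_plain(annotation$mutations, mutations_path)
  invisible(path)
}
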