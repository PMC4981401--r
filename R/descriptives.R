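#' Pairwise repertoire overlap
#'
#' Directed overlap between samples of unique sequences:
#' `o(A -> B) = |A intersect B| / |A|` with exact string matching (no
#' mismatches allowed), computed post-collapse. The matrix is generally
#' asymmetric; the diagonal is 1.
#'
#' @param samples Named list (>= 2) of character vectors of unique
#'   sequences.
#' @return Numeric matrix `o[A, B]`; entries for empty samples are `NA`
#'   with a warning.
#' @export
#' @examples
#' pairwise_overlap(list(A = c("s1", "s2", "s3", "s4"), B = c("s1", "s5")))
pairwise_overlap <- function(samples) {
  if (length(samples) < 2L)
    stop("need at least 2 samples", call. = FALSE)
  if (is.null(names(samples)))
    names(samples) <- paste0("S", seq_along(samples))
  samples <- lapply(samples, unique)
  k <- length(samples)
  out <- matrix(NA_real_, k, k, dimnames = list(names(samples),
                                                names(samples)))
  empty <- lengths(samples) == 0L
  if (any(empty))
    warning("empty sample(s): ", paste(names(samples)[empty],
                                       collapse = ", "),
            "; overlap undefined (NA)")
  for (a in seq_len(k)) {
    if (empty[a]) next
    for (b in seq_len(k)) {
      if (empty[b]) next
      out[a, b] <- if (a == b) 1 else
        sum(samples[[a]] %in% samples[[b]]) / length(samples[[a]])
    }
  }
  out
}

# per-clone weights: occupancy (the abundance proxy) or 1 per unique clone
clone_weights <- function(clones, weighting = c("occupancy", "unique")) {
  weighting <- match.arg(weighting)
  if (weighting == "occupancy") {
    if (is.null(clones$occupancy))
      stop("occupancy weighting requires an `occupancy` column",
           call. = FALSE)
    as.numeric(clones$occupancy)
  } else rep(1, nrow(clones))
}

strip_allele <- function(ids) sub("\\*.*$", "", ids)

#' V gene and family usage
#'
#' Relative usage of V genes and V families among annotated clones,
#' weighted by occupancy (default, the censored abundance proxy) or one
#' count per unique clone. Clones whose `v_call` ties over several
#' segments split their weight equally across the tied segments, so total
#' weight is conserved and percentages sum to 100.
#'
#' @param annotated Annotated clone data.frame (needs `v_call`, and
#'   `occupancy` for the default weighting).
#' @param reference Germline reference (for the gene-to-family map).
#' @param weighting `"occupancy"` or `"unique"`.
#' @return List of two data.frames, `gene` and `family`, each with
#'   `percent` summing to 100.
#' @export
v_usage <- function(annotated, reference,
                    weighting = c("occupancy", "unique")) {
  a <- annotated[!is.na(annotated$v_call), , drop = FALSE]
  w <- clone_weights(a, weighting)
  ties <- strsplit(a$v_call, ",", fixed = TRUE)
  nt <- lengths(ties)
  seg <- unlist(ties, use.names = FALSE)
  wt <- rep.int(w / nt, nt)
  gene <- strip_allele(seg)
  fam <- reference$family[match(seg, reference$segment_id)]
  tot <- sum(wt)
  gdf <- stats::aggregate(list(weight = wt), list(gene = gene), sum)
  gdf$percent <- 100 * gdf$weight / tot
  fdf <- stats::aggregate(list(weight = wt), list(family = fam), sum)
  fdf$percent <- 100 * fdf$weight / tot
  list(gene = gdf[order(-gdf$percent), ],
       family = fdf[order(-fdf$percent), ])
}

#' CDR3 length distribution
#'
#' Normalised histogram of CDR3 nucleotide lengths, the cumulative curve,
#' and the weighted mean length.
#'
#' @param annotated Annotated clones with `cdr3_length` (and `occupancy`
#'   for the default weighting).
#' @param weighting `"occupancy"` or `"unique"`.
#' @return List with `histogram` (data.frame `cdr3_length`, `percent`,
#'   `cumulative_percent`; cumulative runs monotonically to 100) and
#'   `mean_length`.
#' @export
cdr3_length_distribution <- function(annotated,
                                     weighting = c("occupancy", "unique")) {
  a <- annotated[!is.na(annotated$cdr3_length), , drop = FALSE]
  if (!nrow(a)) stop("no clones with an extracted CDR3", call. = FALSE)
  w <- clone_weights(a, weighting)
  agg <- stats::aggregate(list(weight = w),
                          list(cdr3_length = a$cdr3_length), sum)
  agg <- agg[order(agg$cdr3_length), ]
  agg$percent <- 100 * agg$weight / sum(agg$weight)
  agg$cumulative_percent <- cumsum(agg$percent)
  list(histogram = agg[c("cdr3_length", "percent", "cumulative_percent")],
       mean_length = sum(a$cdr3_length * w) / sum(w))
}

#' Joint distribution of V substitution counts and occupancy
#'
#' Cross-tabulates annotated clones by their number of V-segment
#' substitutions and their well occupancy (unique sequences, unweighted,
#' matching the per-sequence counting of the substitution analyses). The
#' occupancy margin equals the occupancy spectrum of the same clones.
#'
#' @param annotated Annotated clones with `v_mutation_count` and
#'   `occupancy`.
#' @return Contingency table (rows: substitution count, columns:
#'   occupancy).
#' @export
shm_by_occupancy <- function(annotated) {
  a <- annotated[!is.na(annotated$v_mutation_count), , drop = FALSE]
  table(v_mutations = a$v_mutation_count, occupancy = a$occupancy)
}

#' Per-position substitution profile of a V gene
#'
#' For every position of a V gene's assayed window, the substitution rate
#' = (weighted) mutated observations / (weighted) total observations among
#' clones assigned to that gene, split into transitions and transversions.
#' Weights are occupancies by default; the denominator is the per-position
#' coverage (positions near the gene's 5' end are covered by fewer reads).
#'
#' @param annotation Result of [annotate_clones()].
#' @param gene_id V segment id.
#' @param weighting `"occupancy"` or `"unique"`.
#' @return data.frame (`gene_pos` 0-based, `coverage`, `rate`,
#'   `transition_rate`, `transversion_rate`); zero rows when no clone is
#'   assigned to the gene.
#' @export
shm_position_profile <- function(annotation, gene_id,
                                 weighting = c("occupancy", "unique")) {
  a <- annotation$clones
  muts <- annotation$mutations
  sel <- which(!is.na(a$v_best) & a$v_best == gene_id)
  if (!length(sel))
    return(data.frame(gene_pos = integer(0), coverage = numeric(0),
                      rate = numeric(0), transition_rate = numeric(0),
                      transversion_rate = numeric(0)))
  w_all <- clone_weights(a[sel, , drop = FALSE], weighting)
  gene_len <- max(a$v_gene_start[sel] + a$v_read_len[sel])
  coverage <- numeric(gene_len)
  for (i in seq_along(sel)) {
    r <- sel[i]
    pos <- (a$v_gene_start[r] + 1L):(a$v_gene_start[r] + a$v_read_len[r])
    coverage[pos] <- coverage[pos] + w_all[i]
  }
  mut_w <- ts_w <- tv_w <- numeric(gene_len)
  m <- muts[muts$read_index %in% sel & muts$v_gene == gene_id, ,
            drop = FALSE]
  if (nrow(m)) {
    wi <- w_all[match(m$read_index, sel)]
    for (i in seq_len(nrow(m))) {
      p <- m$gene_pos[i] + 1L
      mut_w[p] <- mut_w[p] + wi[i]
      if (m$class[i] == "transition") ts_w[p] <- ts_w[p] + wi[i]
      else tv_w[p] <- tv_w[p] + wi[i]
    }
  }
  covered <- coverage > 0
  data.frame(gene_pos = which(covered) - 1L,
             coverage = coverage[covered],
             rate = mut_w[covered] / coverage[covered],
             transition_rate = ts_w[covered] / coverage[covered],
             transversion_rate = tv_w[covered] / coverage[covered])
}

#' Default AID targeting motif table
#'
#' The canonical somatic hypermutation hotspot motif GYW (targeted G) with
#' its reverse-strand equivalent WRC (targeted C), and the SYC coldspot
#' (targeted C) with its reverse-strand equivalent GRS (targeted G).
#' IUPAC codes: Y = C/T, W = A/T, R = A/G, S = C/G.
#'
#' @return data.frame `name`, `pattern` (IUPAC), `targeted_offset`
#'   (0-based within the motif), `class` (`hotspot`/`coldspot`).
#' @export
default_motif_table <- function() {
  data.frame(
    name = c("GYW", "WRC", "SYC", "GRS"),
    pattern = c("GYW", "WRC", "SYC", "GRS"),
    targeted_offset = c(0L, 2L, 2L, 0L),
    class = c("hotspot", "hotspot", "coldspot", "coldspot"),
    stringsAsFactors = FALSE
  )
}

iupac_to_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste0(map[chars], collapse = "")
}

#' Annotate hotspot/coldspot motifs along a gene sequence
#'
#' Scans a DNA sequence for AID targeting motifs (overlapping matches all
#' reported) and labels each base: `hotspot` if targeted by a hotspot
#' motif, else `coldspot` if targeted by a coldspot motif, else `none`
#' (hotspot takes precedence). Non-A/C/G/T positions are labelled `none`.
#'
#' @param sequence A single DNA string.
#' @param motif_table Motif definitions, as [default_motif_table()].
#' @return List with `labels` (character vector, one per base) and
#'   `matches` (data.frame `name`, `class`, `motif_start`, `targeted_pos`,
#'   0-based).
#' @export
#' @examples
#' annotate_motifs("GCT")$labels  # hotspot at the G
annotate_motifs <- function(sequence, motif_table = default_motif_table()) {
  stopifnot(length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  labels <- rep("none", L)
  bad <- grepl("[^ACGT]", strsplit(sequence, "", TRUE)[[1]])
  rows <- list()
  for (i in seq_len(nrow(motif_table))) {
    rx <- paste0("(?=", iupac_to_regex(motif_table$pattern[i]), ")")
    m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
    starts <- as.integer(m)
    starts <- starts[starts > 0]
    if (!length(starts)) next
    tpos <- starts - 1L + motif_table$targeted_offset[i]
    rows[[length(rows) + 1L]] <- data.frame(
      name = motif_table$name[i], class = motif_table$class[i],
      motif_start = starts - 1L, targeted_pos = tpos,
      stringsAsFactors = FALSE)
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), class = character(0),
               motif_start = integer(0), targeted_pos = integer(0))
  cold <- matches$targeted_pos[matches$class == "coldspot"] + 1L
  hot <- matches$targeted_pos[matches$class == "hotspot"] + 1L
  labels[cold] <- "coldspot"
  labels[hot] <- "hotspot"          # hotspot precedence
  labels[bad] <- "none"
  list(labels = labels, matches = matches)
}

#' Motif table TSV round trip
#'
#' @param motif_table data.frame as [default_motif_table()].
#' @param path File path.
#' @export
write_motif_table <- function(motif_table, path) {
  write_tsv_plain(motif_table, path)
}

#' @rdname write_motif_table
#' @export
read_motif_table <- function(path) {
  read_tsv_plain(path, colClasses = c("character", "character", "integer",
                                      "character"))
}

#' Captured fraction of a circulating cell population
#'
#' Percentage of the circulating compartment captured by a blood draw:
#' `100 * yield / total`, reported at one decimal place in the field's
#' convention. With the published yields (2-4e7 naive, 1.5-2e7 memory) and
#' circulating totals (6.5e8 naive, 3.0e8 memory) this gives the naive
#' lower bound 3.1% and memory upper bound 6.7%.
#'
#' @param yield_cells Cells recovered from the sample.
#' @param total_cells Estimated circulating total.
#' @return Percentage (not rounded; round for display).
#' @export
#' @examples
#' round(capture_fraction(2e7, 6.5e8), 1)  # 3.1
capture_fraction <- function(yield_cells, total_cells) {
  if (any(yield_cells < 0) || any(total_cells <= 0))
    stop("cell counts must be positive", call. = FALSE)
  100 * yield_cells / total_cells
}
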