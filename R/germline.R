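#' Germline V/D/J segment references
#'
#' A germline reference is a plain `data.frame` with one row per segment and
#' columns `segment_id`, `segment_class` (`"V"`, `"D"` or `"J"`), `family`,
#' `sequence` (uppercase A/C/G/T) and `cdr3_anchor` (0-based position of the
#' first base of the conserved cysteine codon for V segments, of the
#' conserved Phe/Trp codon for J segments; `NA` for D segments).
#'
#' @name germline_reference
NULL

#' Validate a germline reference table
#'
#' Checks the structural invariants of a germline reference: unique segment
#' ids, A/C/G/T-only sequences, all three segment classes present when
#' `require_all_classes`, and CDR3 anchors present and in-range for every V
#' and J segment.
#'
#' @param reference Germline reference `data.frame`
#'   (see [germline_reference]).
#' @param require_all_classes Require at least one V, one D and one J.
#' @return `reference`, invisibly; errors describe the first violation.
#' @export
validate_reference <- function(reference, require_all_classes = TRUE) {
  needed <- c("segment_id", "segment_class", "family", "sequence", "cdr3_anchor")
  if (!is.data.frame(reference) || !all(needed %in% names(reference)))
    stop("reference must be a data.frame with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  if (anyDuplicated(reference$segment_id))
    stop("segment_ids must be unique", call. = FALSE)
  if (!all(reference$segment_class %in% c("V", "D", "J")))
    stop("segment_class must be one of V, D, J", call. = FALSE)
  if (any(grepl("[^ACGT]", reference$sequence)))
    stop("sequences must contain only A/C/G/T", call. = FALSE)
  if (require_all_classes &&
      !all(c("V", "D", "J") %in% reference$segment_class))
    stop("reference is missing a segment class (need V, D and J)",
         call. = FALSE)
  vj <- reference$segment_class %in% c("V", "J")
  anc <- reference$cdr3_anchor[vj]
  len <- nchar(reference$sequence[vj])
  if (any(is.na(anc)) || any(anc < 0) || any(anc + 3 > len))
    stop("every V and J segment needs an in-range cdr3_anchor", call. = FALSE)
  invisible(reference)
}

# stop-free random codons in a fixed frame (used only by the bundled
# synthetic fixture so productivity labels are driven by the junction)
random_codons <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  out <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cod <- paste0(sample(DNA_BASES, 3, replace = TRUE), collapse = "")
      if (!cod %in% stops) break
    }
    out[i] <- cod
  }
  paste0(out, collapse = "")
}

#' Bundled synthetic germline reference
#'
#' Deterministically generates the small synthetic V/D/J reference used by
#' the simulator and the test-suite: 9 V segments across 3 families (two of
#' which, the `IGHV4-59` alleles, are identical over the assayed read window
#' and therefore always tie), 4 D segments and 3 J segments. V segments are
#' 104 nt with the conserved cysteine codon at position 95 (0-based), J
#' segments are 21 nt with the conserved tryptophan codon at position 12.
#' This is a synthetic stand-in with the geometry of the real locus, not an
#' IMGT extract.
#'
#' @return A germline reference `data.frame` (see [germline_reference]).
#' @export
#' @examples
#' ref <- synthetic_germline_reference()
#' table(ref$segment_class)
synthetic_germline_reference <- function() {
  with_seed(904531, {
    v_len <- 104L
    v_anchor <- 95L
    # frame: codons start at positions 2, 5, ..., 95 (anchor), ..., 101
    v_ids <- c("IGHV1-2*01", "IGHV1-18*01", "IGHV1-69*01",
               "IGHV3-23*01", "IGHV3-30*01", "IGHV3-48*01",
               "IGHV4-34*01", "IGHV4-59*01", "IGHV4-59*02")
    v_fam <- sub("-.*$", "", v_ids)
    v_seq <- vapply(v_ids, function(id) {
      head2 <- paste0(sample(DNA_BASES, 2, replace = TRUE), collapse = "")
      body <- random_codons((v_anchor - 2L) / 3L)     # codons 2..94
      anchor_codon <- "TGT"                            # conserved Cys
      tail3 <- random_codons((v_len - v_anchor - 3L) / 3L)
      paste0(head2, body, anchor_codon, tail3)
    }, character(1))
    # allele pair identical over any <=103 nt read window: differ at base 0
    v_seq[9] <- v_seq[8]
    first <- substr(v_seq[9], 1, 1)
    substr(v_seq[9], 1, 1) <- setdiff(DNA_BASES, first)[1]

    d_ids <- c("IGHD2-2*01", "IGHD3-10*01", "IGHD3-22*01", "IGHD6-19*01")
    d_len <- c(12L, 14L, 16L, 14L)
    d_seq <- random_dna(d_len)

    j_ids <- c("IGHJ4*01", "IGHJ5*01", "IGHJ6*01")
    j_anchor <- 12L
    j_seq <- vapply(j_ids, function(id) {
      paste0(random_dna(12L), "TGG", "GGC", random_codons(1L))
    }, character(1))

    ref <- data.frame(
      segment_id = c(v_ids, d_ids, j_ids),
      segment_class = rep(c("V", "D", "J"), c(length(v_ids), length(d_ids),
                                              length(j_ids))),
      family = c(v_fam, sub("-.*$", "", d_ids), sub("\\*.*$", "", j_ids)),
      sequence = c(v_seq, d_seq, j_seq),
      cdr3_anchor = c(rep(v_anchor, length(v_ids)), rep(NA_integer_, 4),
                      rep(j_anchor, length(j_ids))),
      stringsAsFactors = FALSE
    )
    rownames(ref) <- NULL
    validate_reference(ref)
    ref
  })
}

#' Read or write a germline reference in FASTA format
#'
#' Headers follow the convention
#' `>segment_id|class|family|cdr3_anchor=<int>`; the `cdr3_anchor` field is
#' omitted for D segments. Sequence parsing is delegated to Biostrings.
#'
#' @param path FASTA file path.
#' @return `read_germline_fasta` returns a germline reference `data.frame`;
#'   `write_germline_fasta` returns `path` invisibly.
#' @export
read_germline_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  fields <- strsplit(names(ss), "|", fixed = TRUE)
  get_f <- function(i) vapply(fields, function(f) f[i], character(1))
  anchors <- vapply(fields, function(f) {
    hit <- grep("^cdr3_anchor=", f, value = TRUE)
    if (length(hit)) as.integer(sub("^cdr3_anchor=", "", hit[1])) else
      NA_integer_
  }, integer(1))
  ref <- data.frame(
    segment_id = get_f(1),
    segment_class = get_f(2),
    family = get_f(3),
    sequence = toupper(as.character(ss)),
    cdr3_anchor = anchors,
    stringsAsFactors = FALSE
  )
  rownames(ref) <- NULL
  validate_reference(ref, require_all_classes = FALSE)
  ref
}

#' @rdname read_germline_fasta
#' @param reference Germline reference `data.frame`.
#' @export
write_germline_fasta <- function(reference, path) {
  validate_reference(reference, require_all_classes = FALSE)
  hdr <- with(reference, paste0(segment_id, "|", segment_class, "|", family,
                                ifelse(is.na(cdr3_anchor), "",
                                       paste0("|cdr3_anchor=", cdr3_anchor))))
  ss <- Biostrings::DNAStringSet(reference$sequence)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
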