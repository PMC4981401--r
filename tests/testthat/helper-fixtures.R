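# house seed used throughout the suite (fixed a priori)
HOUSE_SEED <- 20160816L

ref_fixture <- synthetic_germline_reference()

# tiny hand-built reference with known anatomy, for constructed cases
tiny_reference <- function() {
  data.frame(
    segment_id = c("Vx", "Vy", "Dx", "Jx"),
    segment_class = c("V", "V", "D", "J"),
    family = c("VF1", "VF2", "DF1", "JF1"),
    sequence = c(
      paste0(strrep("ACGT", 24), "TGTGCTAG"),   # 104 nt, anchor 95? no: 96+8
      paste0(strrep("AGCT", 24), "TGTTCTAG"),
      "GGGGTTTTCCCC",
      paste0("AACCGGTTAACC", "TGG", "GGCAAA")   # 21 nt, anchor 12
    ),
    cdr3_anchor = c(96L, 96L, NA, 12L),
    stringsAsFactors = FALSE
  )
}

# a small well read table built by hand
make_reads <- function(well_id, sequence, read_count, n_wells = NULL) {
  df <- data.frame(well_id = well_id, sequence = sequence,
                   read_count = read_count, stringsAsFactors = FALSE)
  if (!is.null(n_wells)) attr(df, "n_wells") <- n_wells
  df
}

# mutate string s at 1-based positions to given bases (recycled)
mutate_at <- function(s, pos, base) {
  base <- rep_len(base, length(pos))
  for (i in seq_along(pos)) substr(s, pos[i], pos[i]) <- base[i]
  s
}

# exhaustive occupancy distribution oracle: enumerate all W^k allocations
enumerate_occupancy <- function(k, W) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(W)), k)))
  occ <- apply(grid, 1L, function(a) length(unique(a)))
  counts <- tabulate(occ, nbins = min(k, W))
  counts / W^k
}
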