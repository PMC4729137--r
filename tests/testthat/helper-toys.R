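# Shared toy builders and independent oracles for the test suite.

phred_str <- function(q) intToUtf8(q + 33L)

# Build a reads data.frame from explicit sequences/qualities.
# quals: list of integer vectors (or a single integer recycled per base).
make_reads <- function(seqs, starts, ref, quals = 40L, mapq = 60L) {
  n <- length(seqs)
  starts <- rep_len(starts, n)
  mapq <- rep_len(mapq, n)
  if (!is.list(quals)) quals <- lapply(nchar(seqs), function(k) rep(quals, k))
  ref_chars <- strsplit(ref, "")[[1]]
  nm <- vapply(seq_len(n), function(i) {
    b <- strsplit(seqs[i], "")[[1]]
    sum(b != ref_chars[seq.int(starts[i], length.out = length(b))])
  }, integer(1))
  data.frame(
    id = sprintf("t%03d", seq_len(n)),
    start = as.integer(starts),
    end = as.integer(starts + nchar(seqs) - 1L),
    seq = seqs,
    qual = vapply(quals, phred_str, character(1)),
    mapq = as.integer(mapq),
    nm = nm,
    stringsAsFactors = FALSE
  )
}

# Construct a base-count table directly from a counts matrix (positions x
# A/C/G/T), bypassing read simulation, for caller-only tests.
make_count_table <- function(counts, ref, config = pipeline_config()) {
  stopifnot(nrow(counts) == nchar(ref))
  depth <- as.integer(rowSums(counts))
  pct <- matrix(NA_real_, nrow(counts), 4L)
  nz <- depth > 0
  for (j in 1:4)
    pct[nz, j] <- percent_mutant(counts[nz, j], depth[nz],
                                 config$percent_decimals)
  out <- data.frame(pos = seq_len(nrow(counts)),
                    ref = strsplit(ref, "")[[1]],
                    depth = depth,
                    A = counts[, 1], C = counts[, 2],
                    G = counts[, 3], T = counts[, 4],
                    pct_A = pct[, 1], pct_C = pct[, 2],
                    pct_G = pct[, 3], pct_T = pct[, 4],
                    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  class(out) <- c("base_count_table", "data.frame")
  out
}

# Brute-force reference caller: enumerates every non-reference base and
# applies the two printed inequalities literally, with its own naive
# background mean/sd computation (population sd over below-floor values).
oracle_calls <- function(table, config) {
  floor_pct <- if (config$regime == "wga2") config$floor_wga2
               else config$floor_native
  bases <- c("A", "C", "G", "T")
  obs <- data.frame()
  for (i in seq_len(nrow(table))) {
    if (table$depth[i] == 0) next
    for (b in bases) {
      if (table$ref[i] == b) next
      obs <- rbind(obs, data.frame(pos = table$pos[i], alt = b,
                                   percent = table[[paste0("pct_", b)]][i]))
    }
  }
  vals <- obs$percent[obs$percent < floor_pct]
  m <- sum(vals) / length(vals)
  s <- sqrt(sum((vals - m)^2) / length(vals))
  called <- character()
  for (i in seq_len(nrow(obs))) {
    p <- obs$percent[i]
    if (p > m + config$sd_multiplier * s && p > floor_pct)
      called <- c(called, paste(obs$pos[i], obs$alt[i]))
  }
  sort(called)
}

# A short in-frame coding reference for annotation tests:
# ATG CTG TGG then filler codons (no stops), total 120 bases.
coding_reference <- function() {
  paste0("ATGCTGTGG", paste(rep("GCTACCGAA", 13), collapse = ""), "TAA")
}

sub_at <- function(pos, alt) stats::setNames(as.character(alt), as.character(pos))
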