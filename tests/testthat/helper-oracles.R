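# Independent oracles used to cross-check the implementation:
# Biostrings for reverse complements and degenerate matching, naive
# substring loops for occurrence counting, and aggregate() for per-mask
# summaries.

random_strand <- function(k, n = 1L, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n),
         function(i) paste(sample(alphabet, k, replace = TRUE),
                           collapse = ""),
         character(1L))
}

oracle_rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# brute-force canonicalization of all 4^k strands (rc from Biostrings)
oracle_duplex_set <- function(k) {
  grid <- do.call(expand.grid,
                  c(rep(list(c("A", "C", "G", "T")), k),
                    list(stringsAsFactors = FALSE)))
  strands <- do.call(paste0, grid)
  rc <- oracle_rc(strands)
  sort(unique(pmin(strands, rc)))
}

# naive sliding-window counter, checking every window character by
# character (overlapping matches)
oracle_count <- function(pattern, text, kind = "exact") {
  k <- nchar(pattern)
  L <- nchar(text)
  if (k > L) return(0L)
  pat <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  hits <- 0L
  for (i in seq_len(L - k + 1L)) {
    win <- strsplit(substr(text, i, i + k - 1L), "", fixed = TRUE)[[1L]]
    ok <- all(mapply(function(p, ch) {
      if (kind == "exact") ch == p
      else if (p == "W") ch %in% c("A", "T")
      else ch %in% c("C", "G")
    }, pat, win))
    if (ok) hits <- hits + 1L
  }
  hits
}

# group-then-aggregate reimplementation of the per-mask summary
oracle_mask_summary <- function(strands, scores, key = strands) {
  masks <- duplexmask::mask_of(key)
  agg <- stats::aggregate(scores, by = list(mask = masks), function(x) x,
                          simplify = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(agg)), function(i) {
    sc <- unlist(agg$x[i])
    members <- strands[masks == agg$mask[i]]
    data.frame(mask = agg$mask[i], n = length(sc), mean_score = mean(sc),
               std_score = if (length(sc) > 1L) stats::sd(sc) else 0,
               best_score = min(sc),
               best_sequence = min(members[sc == min(sc)]),
               stringsAsFactors = FALSE)
  }))
  out[order(out$mean_score, out$mask, method = "radix"), , drop = FALSE]
}

toy_score_table <- function(strands, scores, peptide = "TOY") {
  data.frame(peptide = peptide, strand = strands,
             canonical = duplexmask::canonicalize(strands)$canonical,
             score = scores, stringsAsFactors = FALSE)
}
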