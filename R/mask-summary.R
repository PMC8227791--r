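# Clustering of affinity scores by weak/strong base-pair mask and the
# derived comparisons: per-mask summary tables, best complexes, the mask
# coincidence probability, and the two-peptide comparison.

new_mask_summary <- function(df, peptide_id = NA_character_,
                             keying = NA_character_) {
  rownames(df) <- NULL
  structure(df, class = c("mask_summary", "data.frame"),
            peptide_id = peptide_id, keying = keying)
}

#' Summarize a score table by W/S mask
#'
#' Assigns every record to the mask of its strand and aggregates per mask:
#' member count, mean, sample standard deviation (n-1; size-1 clusters
#' report 0), best (minimum) score and the written strand achieving it.
#' Rows are sorted by mean score ascending (strongest cluster first), ties
#' broken by mask lexicographic order.
#'
#' @param table a `score_table` (see [simulate_scores()],
#'   [load_score_table()]).
#' @param keying `"canonical"` keys each record by the mask of its
#'   canonical strand (deterministic, used for simulated tables);
#'   `"as_written"` keys by the mask of the written strand, reproducing the
#'   layout of externally produced tables where the docking engine chose
#'   which strand to report.
#' @return a `mask_summary`: data frame with columns `mask`, `n`,
#'   `mean_score`, `std_score`, `best_score`, `best_sequence`. Cluster
#'   sizes always sum to the input record count.
#' @export
summarize_by_mask <- function(table, keying = c("canonical", "as_written")) {
  keying <- match.arg(keying)
  stopifnot(is.data.frame(table),
            all(c("strand", "canonical", "score") %in% names(table)))
  if (nrow(table) == 0L) stop("empty score table", call. = FALSE)
  key_strand <- switch(keying,
                       canonical = table$canonical,
                       as_written = table$strand)
  masks <- mask_of(key_strand)
  groups <- split(seq_len(nrow(table)), masks)
  rows <- lapply(names(groups), function(m) {
    i <- groups[[m]]
    sc <- table$score[i]
    best <- min(sc)
    cand <- table$strand[i][sc == best]
    if (length(cand) > 1L) {
      message(sprintf("tie at best score %.6g in mask %s: %s (keeping %s)",
                      best, m, paste(sort(cand), collapse = ", "),
                      min(cand)))
    }
    data.frame(mask = m, n = length(i), mean_score = mean(sc),
               std_score = if (length(i) > 1L) stats::sd(sc) else 0,
               best_score = best, best_sequence = min(cand),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  stopifnot(sum(out$n) == nrow(table))  # conservation: no record lost
  out <- out[order(out$mean_score, out$mask, method = "radix"), ,
             drop = FALSE]
  new_mask_summary(out, peptide_id = attr(table, "peptide_id"),
                   keying = keying)
}

#' Best complex of a mask summary
#'
#' The global minimum of `best_score` over all mask clusters, i.e. the most
#' energetically favorable peptide-duplex complex. Ties are broken by the
#' lexicographically smallest sequence and reported via [message()].
#'
#' @param summary a `mask_summary`.
#' @return list with `sequence`, `score` and `mask` of the best complex.
#' @export
best_complex <- function(summary) {
  stopifnot(is.data.frame(summary), nrow(summary) > 0L,
            all(c("mask", "best_score", "best_sequence") %in% names(summary)))
  best <- min(summary$best_score)
  i <- which(summary$best_score == best)
  if (length(i) > 1L) {
    seqs <- summary$best_sequence[i]
    message(sprintf("tie at global best score %.6g: %s (keeping %s)",
                    best, paste(sort(seqs), collapse = ", "), min(seqs)))
    i <- i[match(min(seqs), seqs)]
  }
  list(sequence = summary$best_sequence[i],
       score = summary$best_score[i],
       mask = summary$mask[i])
}

#' Probability that two random masks coincide
#'
#' Each position of a W/S mask is one of two symbols, so two independent
#' uniform masks of the given length agree entirely with probability
#' `(1/2)^length` - 0.0156 for hexanucleotides, which is why identical
#' best-complex masks for two peptides are unlikely to be chance.
#'
#' @param length mask length in base pairs (>= 1).
#' @param rounded round to 4 decimals for reporting (default `FALSE`,
#'   exact value).
#' @return the probability.
#' @examples
#' coincidence_probability(6)                  # 0.015625
#' coincidence_probability(6, rounded = TRUE)  # 0.0156
#' @export
coincidence_probability <- function(length, rounded = FALSE) {
  stopifnot(is.numeric(length), length(length) == 1L)
  if (length < 1 || length != as.integer(length)) {
    stop("mask length must be a positive integer", call. = FALSE)
  }
  p <- 0.5^length
  if (rounded) round(p, 4) else p
}

#' Compare two per-mask summaries
#'
#' For every mask present in both summaries, reports the difference of
#' cluster means (A minus B; negative = peptide A binds more strongly),
#' and whether the two global best complexes share a mask.
#'
#' @param a,b `mask_summary` objects for the two peptides, same word
#'   length.
#' @return a `peptide_comparison`: list with `shared_masks` (count),
#'   `mean_differences` (data frame `mask`, `mean_a`, `mean_b`, `diff`),
#'   `best_masks_identical`, `best_sequences` (named pair) and
#'   `best_scores` (named pair).
#' @export
compare_peptides <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b),
            nrow(a) > 0L, nrow(b) > 0L)
  ka <- unique(nchar(a$mask)); kb <- unique(nchar(b$mask))
  if (length(ka) != 1L || length(kb) != 1L || ka != kb) {
    stop("summaries have mismatched mask lengths", call. = FALSE)
  }
  shared <- intersect(a$mask, b$mask)
  md <- data.frame(mask = shared,
                   mean_a = a$mean_score[match(shared, a$mask)],
                   mean_b = b$mean_score[match(shared, b$mask)],
                   stringsAsFactors = FALSE)
  md$diff <- md$mean_a - md$mean_b
  md <- md[order(md$mask, method = "radix"), , drop = FALSE]
  rownames(md) <- NULL
  best_a <- best_complex(a)
  best_b <- best_complex(b)
  labels <- c(a = attr(a, "peptide_id") %||% "A",
              b = attr(b, "peptide_id") %||% "B")
  structure(list(peptides = labels,
                 shared_masks = length(shared),
                 mean_differences = md,
                 best_masks_identical = best_a$mask == best_b$mask,
                 best_masks = c(a = best_a$mask, b = best_b$mask),
                 best_sequences = c(a = best_a$sequence, b = best_b$sequence),
                 best_scores = c(a = best_a$score, b = best_b$score)),
            class = "peptide_comparison")
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0L || is.na(x[1L])) y else x

#' @export
print.peptide_comparison <- function(x, ...) {
  cat(sprintf("Peptide comparison: %s vs %s\n", x$peptides["a"],
              x$peptides["b"]))
  cat(sprintf("  shared masks: %d\n", x$shared_masks))
  cat(sprintf("  best complexes: %s (%.2f, mask %s) vs %s (%.2f, mask %s)\n",
              x$best_sequences["a"], x$best_scores["a"], x$best_masks["a"],
              x$best_sequences["b"], x$best_scores["b"], x$best_masks["b"]))
  cat(sprintf("  best masks identical: %s\n", x$best_masks_identical))
  cat(sprintf("  mean difference (a - b): median %.2f over shared masks\n",
              stats::median(x$mean_differences$diff)))
  invisible(x)
}

#' Write a mask summary table
#'
#' Tab-separated columns `mask`, `n`, `mean`, `std`, `best_score`,
#' `best_sequence`; byte-stable across runs for a fixed input. Display
#' rounding is applied only by `digits` (default full precision).
#'
#' @param summary a `mask_summary`.
#' @param path output file.
#' @param digits optional rounding for the numeric columns.
#' @return `path`, invisibly.
#' @export
write_mask_summary <- function(summary, path, digits = NULL) {
  stopifnot(is.data.frame(summary))
  out <- data.frame(mask = summary$mask, n = summary$n,
                    mean = summary$mean_score, std = summary$std_score,
                    best_score = summary$best_score,
                    best_sequence = summary$best_sequence,
                    stringsAsFactors = FALSE)
  if (!is.null(digits)) {
    for (col in c("mean", "std", "best_score")) {
      out[[col]] <- round(out[[col]], digits)
    }
  }
  for (col in c("mean", "std", "best_score")) {
    out[[col]] <- as.character(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mask summary table
#'
#' Accepts the layout written by [write_mask_summary()] (also used by the
#' packaged reference tables, where the member count `n` is unknown and
#' stored as NA).
#'
#' @param path tab-separated input file.
#' @param peptide_id optional label attached to the result.
#' @return a `mask_summary`.
#' @export
read_mask_summary <- function(path, peptide_id = NA_character_) {
  if (!file.exists(path)) stop("mask summary not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mask", "n", "mean", "std", "best_score", "best_sequence")
  if (!all(need %in% names(df))) {
    stop("mask summary needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(grepl("[^WS]", df$mask))) stop("invalid mask symbol in ", path,
                                         call. = FALSE)
  validate_strand(df$best_sequence)
  out <- data.frame(mask = df$mask, n = suppressWarnings(as.integer(df$n)),
                    mean_score = as.numeric(df$mean),
                    std_score = as.numeric(df$std),
                    best_score = as.numeric(df$best_score),
                    best_sequence = df$best_sequence,
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean_score, out$mask, method = "radix"), ,
             drop = FALSE]
  new_mask_summary(out, peptide_id = peptide_id, keying = "as_written")
}
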