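# Promoter search: compile the four strand/orientation variants of each
# promoter and count occurrences of exact hexamer needles or degenerate
# W/S mask needles.

VARIANT_NAMES <- c("original", "complement", "reverse", "reverse_complement")

#' Compile the four strand/orientation variants of a sequence
#'
#' The search convention compiles, for each promoter, the written strand,
#' its complement, its reverse and its reverse complement (the written and
#' opposite strands each read in both directions).
#'
#' @param s a single DNA sequence (N allowed).
#' @param dedup collapse identical variant strings (a reverse-complement
#'   palindrome has only 2 distinct variants, `"AT"` likewise).
#' @return named character vector with names `original`, `complement`,
#'   `reverse`, `reverse_complement` (some dropped when `dedup = TRUE`).
#' @examples
#' compile_variants("AACGT")
#' @export
compile_variants <- function(s, dedup = FALSE) {
  stopifnot(is.character(s), length(s) == 1L)
  validate_strand(s, allow_n = TRUE)
  v <- c(original = s,
         complement = complement(s),
         reverse = reverse(s),
         reverse_complement = reverse_complement(s))
  if (dedup) v[!duplicated(unname(v))] else v
}

#' Construct a search needle
#'
#' A needle is either an exact DNA word or a degenerate W/S mask where `W`
#' matches A or T and `S` matches C or G (the IUPAC weak/strong codes).
#'
#' @param pattern the pattern string (A/C/G/T for `exact`, W/S for `mask`).
#' @param kind `"exact"` or `"mask"`.
#' @param label display name; defaults to the pattern itself.
#' @return an object of class `needle`.
#' @examples
#' needle("GAGTGG")
#' needle("SWSWSS", kind = "mask")
#' @export
needle <- function(pattern, kind = c("exact", "mask"), label = pattern) {
  kind <- match.arg(kind)
  stopifnot(is.character(pattern), length(pattern) == 1L, nchar(pattern) > 0L)
  if (kind == "exact") {
    validate_strand(pattern)
  } else if (grepl("[^WS]", pattern)) {
    stop("mask needle may contain only W and S: ", pattern, call. = FALSE)
  }
  structure(list(pattern = pattern, kind = kind, label = label),
            class = "needle")
}

as_needle <- function(x) {
  if (inherits(x, "needle")) x else needle(x)
}

# per-position sets of matching text characters; N is never a member, so
# windows overlapping an ambiguity call never match
needle_allowed <- function(nd) {
  ch <- strsplit(nd$pattern, "", fixed = TRUE)[[1L]]
  if (nd$kind == "exact") as.list(ch)
  else lapply(ch, function(x) if (x == "W") c("A", "T") else c("C", "G"))
}

#' Match positions of a needle in a text
#'
#' @param nd a [needle()] (a bare string is taken as an exact needle).
#' @param text a single DNA sequence (N allowed; never matches).
#' @param overlapping count overlapping matches (default) or greedy
#'   left-to-right non-overlapping matches.
#' @return integer vector of 1-based start positions (empty when the needle
#'   is longer than the text).
#' @export
match_positions <- function(nd, text, overlapping = TRUE) {
  nd <- as_needle(nd)
  stopifnot(is.character(text), length(text) == 1L)
  validate_strand(text, allow_n = TRUE)
  k <- nchar(nd$pattern)
  L <- nchar(text)
  if (k > L) return(integer(0))
  tc <- strsplit(text, "", fixed = TRUE)[[1L]]
  allowed <- needle_allowed(nd)
  n_win <- L - k + 1L
  hit <- rep(TRUE, n_win)
  for (j in seq_len(k)) {
    hit <- hit & tc[seq_len(n_win) + j - 1L] %in% allowed[[j]]
  }
  pos <- which(hit)
  if (!overlapping && length(pos) > 1L) {
    keep <- pos[1L]
    for (p in pos[-1L]) {
      if (p >= keep[length(keep)] + k) keep <- c(keep, p)
    }
    pos <- keep
  }
  pos
}

#' Count occurrences of a needle in a text
#'
#' Number of start positions where the needle matches; see
#' [match_positions()] for the matching rules.
#'
#' @inheritParams match_positions
#' @return nonnegative integer count.
#' @examples
#' count_occurrences("GAGTGG", "GAGTGGAGTGG")           # 2 (overlapping)
#' count_occurrences(needle("SWSWSS", "mask"), "GAGTGGAA")  # 1
#' @export
count_occurrences <- function(nd, text, overlapping = TRUE) {
  length(match_positions(nd, text, overlapping = overlapping))
}

#' Scanning policy
#'
#' @param overlapping count overlapping matches (default `TRUE`).
#' @param variants `"all"` scans the four compiled variants;
#'   `"biological"` restricts to the two actual reading frames
#'   (original + reverse complement).
#' @param dedup when totalling, count each distinct variant string once
#'   (default `TRUE`; a palindromic promoter is not double-counted).
#' @return an object of class `scan_policy`.
#' @export
scan_policy <- function(overlapping = TRUE,
                        variants = c("all", "biological"),
                        dedup = TRUE) {
  variants <- match.arg(variants)
  structure(list(overlapping = isTRUE(overlapping), variants = variants,
                 dedup = isTRUE(dedup)),
            class = "scan_policy")
}

#' Scan promoters for needle occurrences
#'
#' Counts every needle on every compiled strand/orientation variant of
#' every promoter and reports per-variant counts plus a policy-defined
#' total (default: sum over deduplicated variants, overlapping matches).
#' The per-variant breakdown is always emitted so any counting convention
#' can be read off the report.
#'
#' @param needles list of [needle()] objects (bare strings allowed, taken
#'   as exact needles).
#' @param promoters data frame with columns `gene` and `sequence` (e.g.
#'   from [read_promoters()] or [generate_promoter()]).
#' @param policy a [scan_policy()].
#' @return an `occurrence_report`: data frame with columns `needle_label`,
#'   `gene`, one count column per variant, and `total`; sorted by needle
#'   then gene; the policy is attached as an attribute.
#' @export
scan_promoters <- function(needles, promoters, policy = scan_policy()) {
  stopifnot(inherits(policy, "scan_policy"),
            is.data.frame(promoters),
            all(c("gene", "sequence") %in% names(promoters)))
  if (length(needles) == 0L || nrow(promoters) == 0L) {
    stop("needles and promoters must be nonempty", call. = FALSE)
  }
  if (inherits(needles, "needle") || is.character(needles)) {
    needles <- as.list(needles)
  }
  needles <- lapply(needles, as_needle)
  genes <- promoters$gene
  if (anyDuplicated(genes)) {
    warning("duplicate gene symbols; keeping sequences separate with suffixed labels",
            call. = FALSE)
    genes <- make.unique(genes, sep = ".")
  }
  use_variants <- if (policy$variants == "biological") {
    c("original", "reverse_complement")
  } else VARIANT_NAMES
  rows <- list()
  for (nd in needles) {
    for (i in seq_len(nrow(promoters))) {
      vars <- compile_variants(promoters$sequence[i])
      counts <- stats::setNames(rep(NA_integer_, length(VARIANT_NAMES)),
                                VARIANT_NAMES)
      for (v in use_variants) {
        counts[v] <- count_occurrences(nd, vars[[v]],
                                       overlapping = policy$overlapping)
      }
      active <- vars[use_variants]
      tallied <- if (policy$dedup) use_variants[!duplicated(unname(active))]
                 else use_variants
      rows[[length(rows) + 1L]] <- data.frame(
        needle_label = nd$label, gene = genes[i],
        original = counts[["original"]], complement = counts[["complement"]],
        reverse = counts[["reverse"]],
        reverse_complement = counts[["reverse_complement"]],
        total = sum(counts[tallied]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$needle_label, out$gene, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("occurrence_report", "data.frame"),
            policy = policy)
}

#' Write an occurrence report
#'
#' Long-format tab-separated report (`needle_label`, `gene`, `variant`,
#' `count`, `total`) plus an optional JSON summary; both deterministic for
#' a fixed input.
#'
#' @param report an `occurrence_report` from [scan_promoters()].
#' @param path output TSV file.
#' @param json_path optional JSON summary file.
#' @return `path`, invisibly.
#' @export
write_occurrence_report <- function(report, path, json_path = NULL) {
  stopifnot(is.data.frame(report))
  long <- do.call(rbind, lapply(seq_len(nrow(report)), function(i) {
    data.frame(needle_label = report$needle_label[i], gene = report$gene[i],
               variant = VARIANT_NAMES,
               count = as.integer(report[i, VARIANT_NAMES]),
               total = report$total[i], stringsAsFactors = FALSE)
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a needle list
#'
#' Tab-separated file with header `label  kind  pattern`.
#'
#' @param path input file.
#' @return list of [needle()] objects.
#' @export
read_needles <- function(path) {
  if (!file.exists(path)) stop("needle list not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || !all(c("label", "kind", "pattern") %in% names(df))) {
    stop("needle list needs nonempty columns label, kind, pattern",
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    needle(df$pattern[i], kind = df$kind[i], label = df$label[i])
  })
}

#' Read promoter sequences from FASTA
#'
#' Sequences are uppercased; only A/C/G/T/N are accepted (a window
#' overlapping an N never matches any needle). The gene symbol defaults to
#' the first whitespace-delimited token of the FASTA header.
#'
#' @param path FASTA file (multi-line records fine).
#' @param gene_rule optional function mapping a header string to a gene
#'   symbol.
#' @return data frame with columns `gene`, `sequence`, `source_id` (the
#'   full header) and `window_note`.
#' @export
read_promoters <- function(path, gene_rule = NULL) {
  if (!file.exists(path)) stop("promoter FASTA not found: ", path,
                               call. = FALSE)
  ss <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("invalid sequence characters in FASTA: ", path, call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (length(ss) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  seqs <- toupper(as.character(ss))
  headers <- names(ss)
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[i])
    if (bad > 0L) {
      stop(sprintf("record %d (%s): invalid character '%s' at position %d",
                   i, headers[i], substr(seqs[i], bad, bad), bad),
           call. = FALSE)
    }
  }
  if (is.null(gene_rule)) {
    gene_rule <- function(h) sub("\\s.*$", "", h)
  }
  gene <- vapply(headers, gene_rule, character(1L), USE.NAMES = FALSE)
  empty <- which(is.na(gene) | gene == "")
  if (length(empty)) {
    stop("record ", empty[1L], ": cannot parse a gene symbol from header",
         call. = FALSE)
  }
  data.frame(gene = gene, sequence = unname(seqs), source_id = headers,
             window_note = "", stringsAsFactors = FALSE)
}
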