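# Strand algebra over {A,C,G,T} and enumeration of the unique dsDNA
# duplex space under reverse-complement equivalence.

DNA_BASES <- c("A", "C", "G", "T")

#' Validate DNA strands
#'
#' Checks that every element of `s` is a nonempty, uppercase DNA string.
#' The canonical alphabet is `{A,C,G,T}`; functions that operate on
#' promoter-scale text (variant compilation, occurrence counting) also
#' accept `N`, which never matches any needle.
#'
#' @param s character vector of sequences.
#' @param allow_n accept the ambiguity code `N` in addition to A/C/G/T.
#' @return `s`, invisibly, if valid; otherwise an error naming the first
#'   offending character and its 1-based position.
#' @keywords internal
validate_strand <- function(s, allow_n = FALSE) {
  if (!is.character(s) || length(s) == 0L || anyNA(s)) {
    stop("sequence input must be a non-empty character vector without NA",
         call. = FALSE)
  }
  if (any(nchar(s) == 0L)) {
    stop("empty sequence at element ", which(nchar(s) == 0L)[1L], call. = FALSE)
  }
  pattern <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- regexpr(pattern, s)
  hit <- which(bad > 0L)
  if (length(hit)) {
    i <- hit[1L]
    pos <- bad[i]
    stop(sprintf("invalid base '%s' at position %d of \"%s\"",
                 substr(s[i], pos, pos), pos, s[i]), call. = FALSE)
  }
  invisible(s)
}

#' Complement of a DNA strand
#'
#' Applies the base-pairing rule A<->T, C<->G positionwise, preserving the
#' written orientation. Vectorised; an involution.
#'
#' @param s character vector of DNA strands (uppercase A/C/G/T; `N` passes
#'   through unchanged, for promoter text that carries ambiguity calls).
#' @return character vector of the same length.
#' @examples
#' complement("AACGT")  # "TTGCA"
#' @export
complement <- function(s) {
  validate_strand(s, allow_n = TRUE)
  chartr("ACGTN", "TGCAN", s)
}

#' Reverse a sequence string
#'
#' Reverses the written order of the characters (reads a strand 3' -> 5').
#' Alphabet-agnostic so it applies equally to DNA strands and to W/S masks,
#' whose reversal mirrors the strand's. Vectorised; an involution.
#'
#' @param s character vector of sequences (DNA strands or W/S masks).
#' @return character vector of the same length.
#' @export
reverse <- function(s) {
  if (!is.character(s) || length(s) == 0L || anyNA(s) ||
      any(nchar(s) == 0L)) {
    stop("sequence input must be non-empty character without NA",
         call. = FALSE)
  }
  vapply(strsplit(s, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1L))
}

#' Reverse complement of a DNA strand
#'
#' The opposite strand read 5' -> 3': `reverse(complement(s))`. Two strands
#' related by this operation denote the same physical duplex.
#'
#' @inheritParams complement
#' @return character vector of the same length.
#' @examples
#' reverse_complement("GAGTGG")  # "CCACTC"
#' reverse_complement("GAATTC")  # "GAATTC" (palindromic EcoRI site)
#' @export
reverse_complement <- function(s) {
  reverse(complement(s))
}

#' Canonical duplex representative of a strand
#'
#' A double-stranded DNA word is written two ways (a strand and its reverse
#' complement). The canonical representative is the lexicographically
#' smaller of the two under A < C < G < T, so that
#' `canonicalize(s)` and `canonicalize(reverse_complement(s))` agree.
#'
#' @param s character vector of DNA strands (strict A/C/G/T).
#' @return data frame with one row per input: `canonical` (the chosen
#'   strand), `k` (length in bp) and `palindromic` (`TRUE` iff the strand
#'   equals its own reverse complement, possible only for even `k`).
#' @examples
#' canonicalize("GAGTGG")  # canonical CCACTC
#' @export
canonicalize <- function(s) {
  validate_strand(s)
  rc <- reverse_complement(s)
  canonical <- ifelse(s <= rc, s, rc)
  data.frame(canonical = canonical,
             k = nchar(canonical),
             palindromic = s == rc,
             stringsAsFactors = FALSE)
}

#' Size of the unique duplex space
#'
#' Closed-form count of distinct double-stranded k-mers: reverse-complement
#' palindromes (possible only for even k, 4^(k/2) of them) have a single
#' strand representation, all other strands pair up, so the count is
#' `(4^k + 4^(k/2)) / 2` for even k and `4^k / 2` for odd k.
#'
#' @param k word length in bp.
#' @return number of distinct duplexes.
#' @examples
#' duplex_space_size(6)  # 2080
#' @export
duplex_space_size <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1, k == as.integer(k))
  if (k %% 2 == 0) (4^k + 4^(k / 2)) / 2 else 4^k / 2
}

#' Enumerate the unique dsDNA duplex space
#'
#' Generates all `4^k` strands and collapses them under reverse-complement
#' equivalence. For k = 6 this yields the 2080 unique hexanucleotide
#' duplexes over which peptide docking scores are tabulated.
#'
#' @param k word length in bp (k >= 1).
#' @param max_k refusal threshold guarding against accidental huge
#'   enumerations (4^k strands are materialised); default 10.
#' @return data frame sorted by `canonical`, with columns `canonical`, `k`,
#'   `palindromic`, one row per duplex.
#' @examples
#' nrow(enumerate_duplexes(6))  # 2080
#' @export
enumerate_duplexes <- function(k, max_k = 10L) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1, k == as.integer(k))
  if (k > max_k) {
    stop(sprintf("k = %d exceeds the configured cap max_k = %d (4^k strands would be materialised)",
                 as.integer(k), as.integer(max_k)), call. = FALSE)
  }
  grid <- do.call(expand.grid,
                  c(rep(list(DNA_BASES), k),
                    list(stringsAsFactors = FALSE)))
  strands <- do.call(paste0, grid)
  d <- canonicalize(strands)
  d <- d[!duplicated(d$canonical), , drop = FALSE]
  d <- d[order(d$canonical, method = "radix"), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Weak/strong base-pair mask of a strand
#'
#' Classifies each position by base-pair strength: A/T (two hydrogen
#' bonds, IUPAC `W`) versus C/G (three hydrogen bonds, IUPAC `S`). A strand
#' and its complement share the same mask; reversing the strand reverses
#' the mask.
#'
#' @param s character vector of DNA strands (strict A/C/G/T).
#' @return character vector of W/S masks, same lengths as `s`.
#' @examples
#' mask_of("GAGTGG")  # "SWSWSS"
#' @export
mask_of <- function(s) {
  validate_strand(s)
  chartr("ACGT", "WSSW", s)
}

#' Embed a strand between A/T flanks
#'
#' Builds the longer construct used when short duplexes are modelled inside
#' a larger B-form helix: the k-mer sits centrally with `flank_length` A/T
#' base pairs on each side (default 4, giving a 14-mer for a hexamer).
#' The written flank defaults to the alternating pattern `ATAT...`; any
#' A/T-only string of the right length may be supplied instead, since an
#' "A/T base pair" does not fix which base sits on the written strand.
#'
#' @param s character vector of DNA strands (strict A/C/G/T).
#' @param flank_length number of flanking base pairs per side (>= 0).
#' @param flank optional explicit flank string (A/T only, nchar ==
#'   `flank_length`) used verbatim on both sides.
#' @return character vector of embedded strands of length
#'   `nchar(s) + 2 * flank_length`.
#' @examples
#' embed_in_flanks("GAGTGG")  # "ATATGAGTGGATAT"
#' @export
embed_in_flanks <- function(s, flank_length = 4L, flank = NULL) {
  validate_strand(s)
  stopifnot(is.numeric(flank_length), length(flank_length) == 1L,
            flank_length >= 0, flank_length == as.integer(flank_length))
  if (flank_length == 0L) return(s)
  if (is.null(flank)) {
    flank <- paste(rep_len(c("A", "T"), flank_length), collapse = "")
  }
  if (nchar(flank) != flank_length || grepl("[^AT]", flank)) {
    stop("flank must be an A/T-only string of length flank_length",
         call. = FALSE)
  }
  paste0(flank, s, flank)
}

#' Count G+C bases of a strand
#'
#' @param s character vector of DNA strands.
#' @return integer vector of G+C counts.
#' @export
gc_count <- function(s) {
  validate_strand(s)
  nchar(s) - nchar(gsub("[GC]", "", s))
}

#' Write an enumerated duplex set to a tab-separated file
#'
#' One row per duplex in lexicographic order: canonical strand and its W/S
#' mask (mask column optional). Deterministic output for diffability.
#'
#' @param duplexes data frame from [enumerate_duplexes()].
#' @param path output file.
#' @param masks include a second `mask` column (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_duplexes <- function(duplexes, path, masks = TRUE) {
  stopifnot(is.data.frame(duplexes), "canonical" %in% names(duplexes))
  out <- data.frame(canonical = duplexes$canonical,
                    stringsAsFactors = FALSE)
  if (masks) out$mask <- mask_of(duplexes$canonical)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
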