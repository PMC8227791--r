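# Synthetic inputs with known ground truth: promoters with planted motifs,
# a self-contained demo bundle, and loaders for the packaged reference
# tables (hand-transcribed per-mask docking summaries and promoter
# occurrence counts).

#' Specify a motif plant
#'
#' Describes one needle to write into a synthetic promoter: the exact
#' sequence, how many copies, on which strand/orientation variant the
#' copies should appear, and (optionally) explicit 1-based start positions
#' on the written strand.
#'
#' @param needle exact DNA word to plant.
#' @param count number of copies (>= 0; 0 means "verified absent").
#' @param variant which compiled variant carries the plant (`"original"`,
#'   `"complement"`, `"reverse"` or `"reverse_complement"`); the generator
#'   writes the correspondingly transformed word onto the written strand.
#' @param positions optional explicit starts (length must equal `count`);
#'   windows must not overlap.
#' @return an object of class `plant_spec`.
#' @export
plant_spec <- function(needle, count, variant = "original",
                       positions = NULL) {
  validate_strand(needle)
  stopifnot(is.numeric(count), length(count) == 1L, count >= 0,
            count == as.integer(count))
  variant <- match.arg(variant, VARIANT_NAMES)
  if (!is.null(positions)) {
    stopifnot(length(positions) == count, all(positions >= 1))
    positions <- sort(as.integer(positions))
    if (count > 1L && any(diff(positions) < nchar(needle))) {
      stop("planted windows overlap", call. = FALSE)
    }
  }
  structure(list(needle = needle, count = as.integer(count),
                 variant = variant, positions = positions),
            class = "plant_spec")
}

# the word to write onto the original strand so that `needle` appears on
# the requested variant
plant_payload <- function(needle, variant) {
  switch(variant,
         original = needle,
         complement = complement(needle),
         reverse = reverse(needle),
         reverse_complement = reverse_complement(needle))
}

draw_background <- function(length, gc_fraction) {
  at <- (1 - gc_fraction) / 2
  gc <- gc_fraction / 2
  sample(DNA_BASES, length, replace = TRUE, prob = c(at, gc, gc, at))
}

#' Generate a synthetic promoter with planted motifs
#'
#' Draws an i.i.d. background at the requested GC fraction, writes each
#' plant at non-overlapping positions, then verifies with the occurrence
#' counter that the total count of every planted needle over the
#' deduplicated strand/orientation variants equals exactly the planted
#' count - guarding against accidental background matches. The background
#' (and free positions) are redrawn up to `max_tries` times until
#' verification passes. Deterministic given `seed`.
#'
#' @param length promoter length in bp.
#' @param gc_fraction background G+C fraction in `[0, 1]` (default 0.5,
#'   the GC-enriched composition typical of human promoter windows).
#' @param plants list of [plant_spec()] objects.
#' @param seed integer seed.
#' @param gene gene symbol for the record (default `"SYN"`).
#' @param max_tries redraw budget for the rejection sampling (default 100).
#' @return list with `record` (one-row promoter data frame as from
#'   [read_promoters()]) and `truth` (data frame `needle`, `variant`,
#'   `count`, `positions`).
#' @examples
#' gp <- generate_promoter(300, plants = list(plant_spec("GAGTGG", 2)),
#'                         seed = 7)
#' count_occurrences("GAGTGG", gp$record$sequence)  # 2
#' @export
generate_promoter <- function(length, gc_fraction = 0.5, plants = list(),
                              seed = 1L, gene = "SYN", max_tries = 100L) {
  stopifnot(is.numeric(length), length >= 1,
            gc_fraction >= 0, gc_fraction <= 1)
  if (inherits(plants, "plant_spec")) plants <- list(plants)
  stopifnot(all(vapply(plants, inherits, logical(1L), "plant_spec")))
  need <- sum(vapply(plants, function(p) p$count * nchar(p$needle), 0))
  if (need > length) stop("plants do not fit in the requested length",
                          call. = FALSE)
  one_try <- function() {
    chars <- draw_background(length, gc_fraction)
    occupied <- logical(length)
    placed <- vector("list", length(plants))
    ok <- TRUE
    for (pi in seq_along(plants)) {
      p <- plants[[pi]]
      k <- nchar(p$needle)
      payload <- strsplit(plant_payload(p$needle, p$variant), "",
                          fixed = TRUE)[[1L]]
      if (!is.null(p$positions)) {
        starts <- p$positions
        if (any(starts + k - 1L > length)) {
          stop("explicit plant position exceeds promoter length",
               call. = FALSE)
        }
      } else if (p$count > 0L) {
        starts <- integer(0)
        for (copy in seq_len(p$count)) {
          free <- which(vapply(seq_len(length - k + 1L), function(st) {
            !any(occupied[st:(st + k - 1L)])
          }, logical(1L)))
          if (!length(free)) { ok <- FALSE; break }
          starts <- c(starts, if (length(free) == 1L) free else
                                sample(free, 1L))
          occupied[starts[copy]:(starts[copy] + k - 1L)] <- TRUE
        }
        if (!ok) break
      } else starts <- integer(0)
      for (st in starts) {
        occupied[st:(st + k - 1L)] <- TRUE
        chars[st:(st + k - 1L)] <- payload
      }
      placed[[pi]] <- starts
    }
    list(ok = ok, seq = paste(chars, collapse = ""), placed = placed)
  }
  # a single RNG stream per seed: retries keep drawing from the same
  # stream, so distinct seeds never replay each other's draws
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      result <- one_try()
      if (!result$ok) next
      # verify against the counting oracle: totals over deduplicated variants
      verified <- all(vapply(plants, function(p) {
        vars <- compile_variants(result$seq, dedup = TRUE)
        sum(vapply(vars, count_occurrences, 0L, nd = needle(p$needle))) ==
          p$count
      }, logical(1L)))
      if (verified) {
        truth <- if (length(plants)) {
          data.frame(needle = vapply(plants, `[[`, "", "needle"),
                     variant = vapply(plants, `[[`, "", "variant"),
                     count = vapply(plants, `[[`, 0L, "count"),
                     positions = vapply(result$placed, paste, "",
                                        collapse = ","),
                     stringsAsFactors = FALSE)
        } else {
          data.frame(needle = character(0), variant = character(0),
                     count = integer(0), positions = character(0))
        }
        record <- data.frame(gene = gene, sequence = result$seq,
                             source_id = sprintf("synthetic seed=%d",
                                                 as.integer(seed)),
                             window_note = sprintf(
                               "synthetic i.i.d. background, GC=%.2f, %d bp",
                               gc_fraction, as.integer(length)),
                             stringsAsFactors = FALSE)
        return(list(record = record, truth = truth))
      }
    }
    stop(sprintf("could not realise the plant layout in %d tries",
                 max_tries), call. = FALSE)
  })
}

#' Write promoter records as FASTA
#'
#' @param promoters data frame with `gene` and `sequence` (and optionally
#'   `source_id`, appended to the header after the gene symbol).
#' @param path output FASTA file.
#' @param width line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_promoters <- function(promoters, path, width = 70L) {
  stopifnot(is.data.frame(promoters),
            all(c("gene", "sequence") %in% names(promoters)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(promoters))) {
    extra <- if ("source_id" %in% names(promoters) &&
                 nzchar(promoters$source_id[i]))
      paste0(" ", promoters$source_id[i]) else ""
    writeLines(paste0(">", promoters$gene[i], extra), con)
    s <- promoters$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "duplexmask")
  if (p == "") stop("packaged fixture missing: ", file, call. = FALSE)
  p
}

#' Load the packaged reference tables
#'
#' Returns the hand-transcribed per-mask docking summaries for the EDR and
#' KED tripeptides (48 mask clusters each: mask, mean and SD of the
#' docking score, best score, best sequence), the reference promoter
#' occurrence counts for the AD gene panel, and the gene list itself.
#' These transcriptions are reference data bridging to the unpublishable
#' docking output; they are never recomputed. File checksums are verified
#' on load.
#'
#' @return list with `table1_edr`, `table1_ked` (`mask_summary` objects),
#'   `table2` (data frame `rank`, `mean_score`, `mask`, `gene`, `count`)
#'   and `genes` (character vector of the 11 gene symbols).
#' @export
load_fixtures <- function() {
  files <- c("table1_edr.tsv", "table1_ked.tsv", "table2_occurrences.tsv",
             "ad_gene_list.txt")
  sums <- utils::read.delim(fixture_path("checksums.tsv"),
                            stringsAsFactors = FALSE)
  for (f in files) {
    want <- sums$md5[sums$file == f]
    got <- unname(tools::md5sum(fixture_path(f)))
    if (length(want) != 1L || want != got) {
      stop("checksum mismatch for packaged fixture ", f, call. = FALSE)
    }
  }
  edr <- read_mask_summary(fixture_path("table1_edr.tsv"),
                           peptide_id = "EDR")
  ked <- read_mask_summary(fixture_path("table1_ked.tsv"),
                           peptide_id = "KED")
  t2 <- utils::read.delim(fixture_path("table2_occurrences.tsv"),
                          stringsAsFactors = FALSE)
  genes <- readLines(fixture_path("ad_gene_list.txt"))
  genes <- genes[nzchar(genes)]
  for (tab in list(edr, ked)) {
    if (nrow(tab) != 48L) stop("reference summary must have 48 rows",
                               call. = FALSE)
    if (!all(mask_of(tab$best_sequence) == tab$mask)) {
      stop("reference summary fails mask/sequence consistency",
           call. = FALSE)
    }
  }
  list(table1_edr = edr, table1_ked = ked, table2 = t2, genes = genes)
}

#' Write a complete, small, self-contained demo bundle
#'
#' Simulates EDR-like and KED-like score tables over all 2080 hexamer
#' duplexes, writes their per-mask summaries, generates 11 synthetic
#' promoters named after the AD gene panel with the EDR best-binding
#' hexamer planted at known counts, scans them, and writes a JSON manifest
#' of the expected counts. The scan totals are checked against the
#' manifest before returning; two bundles with the same seed are
#' byte-identical.
#'
#' @param dir target directory (created if needed).
#' @param seed integer seed driving every random draw.
#' @return `dir`, invisibly.
#' @export
make_demo_bundle <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create demo directory: ", dir,
                             call. = FALSE)
  duplexes <- enumerate_duplexes(6L)
  write_duplexes(duplexes, file.path(dir, "duplexes_k6.tsv"))
  edr <- simulate_scores(edr_score_params(seed), duplexes, "EDR")
  ked <- simulate_scores(ked_score_params(seed + 1L), duplexes, "KED")
  write_score_table(edr, file.path(dir, "scores_EDR.tsv"))
  write_score_table(ked, file.path(dir, "scores_KED.tsv"))
  write_mask_summary(summarize_by_mask(edr), file.path(dir, "summary_EDR.tsv"))
  write_mask_summary(summarize_by_mask(ked), file.path(dir, "summary_KED.tsv"))
  genes <- load_fixtures()$genes
  planted <- ((seq_along(genes) - 1L) %% 4L)  # 0..3 copies, deterministic
  best_seq <- "GAGTGG"
  recs <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    gp <- generate_promoter(600L, gc_fraction = 0.5,
                            plants = list(plant_spec(best_seq, planted[i])),
                            seed = mix_seed(seed, i), gene = genes[i])
    recs[[i]] <- gp$record
  }
  promoters <- do.call(rbind, recs)
  write_promoters(promoters, file.path(dir, "promoters.fasta"))
  report <- scan_promoters(list(needle(best_seq)), promoters)
  write_occurrence_report(report, file.path(dir, "occurrences.tsv"),
                          file.path(dir, "occurrences.json"))
  manifest <- list(seed = as.integer(seed), k = 6L,
                   n_duplexes = nrow(duplexes),
                   needle = best_seq,
                   planted_counts = stats::setNames(as.list(planted), genes))
  if (!all(report$total[match(genes, report$gene)] == planted)) {
    stop("demo bundle self-check failed: scan totals differ from plants",
         call. = FALSE)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
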