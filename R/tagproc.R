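## Tag extraction and the three-stage filter cascade.
##
## A LongSAGE ditag read is CATG + tag1 + revcomp(tag2) + CATG. Filtering
## follows the standard library-composition accounting: (1) remove "bad"
## tags carrying >= 1 N base call; (2) remove tags whose quality factor
## (probability that all 17 bases are correct) falls below 0.95; (3) remove
## linker-derived tags by exact sequence match. Duplicate ditags are counted
## for reporting but not removed, which is the only convention under which
## the composition identities balance.

TAG_WIDTH <- 17L
ANCHOR <- "CATG"

#' Extract 17-base tags from ditag reads
#'
#' Each read yields two tag observations: the first 17 bases after the
#' leading CATG anchor read 5'->3', and the reverse complement of the 17
#' bases before the trailing anchor. Per-tag quality factors are computed
#' from the Phred+33 quality string. The exact ditag sequence (between
#' anchors) is recorded in a ledger for duplicate-ditag counting. Reads with
#' fewer than 34 usable bases between anchors are skipped and counted, not
#' fatal.
#'
#' @param reads Tibble with columns `read_id`, `library_id`, `sequence`,
#'   `quality` (Phred+33 string, same length as `sequence`), e.g. from
#'   [generate_raw_ditags()] or [read_fastq()].
#' @return List with `observations` (tibble: `library_id`, `read_id`, `slot`,
#'   `tag`, `qf`), `ditags` (tibble: `library_id`, `read_id`, `ditag`) and
#'   `n_skipped`.
#' @export
extract_tags <- function(reads) {
  if (is.list(reads) && !is.data.frame(reads) && !is.null(reads$reads)) {
    reads <- reads$reads
  }
  stopifnot(is.data.frame(reads),
            all(c("read_id", "library_id", "sequence", "quality")
                %in% names(reads)))
  if (nrow(reads) == 0) stop("`reads` is empty", call. = FALSE)

  len <- nchar(reads$sequence)
  if (any(nchar(reads$quality) != len)) {
    bad <- reads$read_id[which(nchar(reads$quality) != len)[1]]
    stop(sprintf("quality length mismatch for read %s", bad), call. = FALSE)
  }
  usable <- len - 2L * nchar(ANCHOR)
  keep <- usable >= 2L * TAG_WIDTH
  n_skipped <- sum(!keep)
  reads <- reads[keep, ]
  len <- len[keep]

  a <- nchar(ANCHOR)
  tag1 <- substr(reads$sequence, a + 1L, a + TAG_WIDTH)
  tag2_rc <- substr(reads$sequence, len - a - TAG_WIDTH + 1L, len - a)
  tag2 <- revcomp(tag2_rc)
  ditag <- substr(reads$sequence, a + 1L, len - a)

  q <- char_to_phred(reads$quality)
  qf1 <- vapply(q, function(v) prod(1 - 10^(-v[a + seq_len(TAG_WIDTH)] / 10)),
                numeric(1))
  qf2 <- vapply(seq_along(q), function(i) {
    v <- q[[i]][(len[i] - a - TAG_WIDTH + 1L):(len[i] - a)]
    prod(1 - 10^(-v / 10))
  }, numeric(1))

  observations <- bind_rows(
    tibble(library_id = reads$library_id, read_id = reads$read_id,
           slot = 1L, tag = tag1, qf = qf1),
    tibble(library_id = reads$library_id, read_id = reads$read_id,
           slot = 2L, tag = tag2, qf = qf2)
  )
  ledger <- tibble(library_id = reads$library_id, read_id = reads$read_id,
                   ditag = ditag)
  list(observations = observations, ditags = ledger, n_skipped = n_skipped)
}

#' Remove bad tags (N base calls)
#'
#' A tag is "bad" when its sequence contains at least one N call.
#'
#' @param observations Tag-observation tibble with a `tag` column.
#' @return List with `kept` (tibble) and `removed` (per-library tibble of
#'   removal counts).
#' @export
filter_bad_tags <- function(observations) {
  bad <- grepl("N", observations$tag, fixed = TRUE)
  removed <- observations[bad, ] |>
    count(.data$library_id, name = "n_bad")
  list(kept = observations[!bad, ], removed = removed,
       n_removed = sum(bad))
}

#' Quality-factor filter
#'
#' Removes observations whose quality factor (probability all 17 base calls
#' are correct) is below `threshold`; the mean QF over all *input*
#' observations is reported per library, matching composition-report
#' conventions.
#'
#' @param observations Tag-observation tibble with `qf`.
#' @param threshold Minimum QF retained (default 0.95).
#' @return List with `kept`, `removed` (per-library `n_below_qf`,
#'   `mean_qf`) and `n_removed`.
#' @export
quality_filter <- function(observations, threshold = 0.95) {
  if (!"qf" %in% names(observations) || anyNA(observations$qf)) {
    bad <- if ("read_id" %in% names(observations)) {
      observations$read_id[which(is.na(observations$qf))[1]]
    } else "<unknown>"
    stop(sprintf("missing quality factor (read %s)", bad), call. = FALSE)
  }
  low <- observations$qf < threshold
  removed <- observations |>
    group_by(.data$library_id) |>
    summarise(n_below_qf = sum(.data$qf < threshold),
              mean_qf = mean(.data$qf), .groups = "drop")
  list(kept = observations[!low, ], removed = removed, n_removed = sum(low))
}

#' Tally tag observations into a count table
#'
#' @param observations Tag-observation tibble.
#' @return Tibble `library_id`, `tag`, `count`.
#' @export
tally_tags <- function(observations) {
  observations |>
    count(.data$library_id, .data$tag, name = "count") |>
    arrange(.data$library_id, .data$tag)
}

#' Remove linker-derived tags
#'
#' Linkers occasionally self-ligate, producing ditags whose tags are linker
#' sequence rather than transcript; such tags are removed by exact match
#' against the two linker-derived sequence sets.
#'
#' @param counts Tag-count tibble (`library_id`, `tag`, `count`).
#' @param linker_type1,linker_type2 Character vectors of linker-derived
#'   17-base sequences.
#' @return List with `counts` (LDTs removed), and per-library removal tallies
#'   `removed` (`n_ldt_type1`, `n_ldt_type2`, in tag occurrences).
#' @export
remove_ldts <- function(counts, linker_type1, linker_type2) {
  stopifnot(length(linker_type1) > 0, length(linker_type2) > 0)
  is1 <- counts$tag %in% linker_type1
  is2 <- counts$tag %in% linker_type2 & !is1
  removed <- counts |>
    group_by(.data$library_id) |>
    summarise(n_ldt_type1 = sum(.data$count[.data$tag %in% linker_type1]),
              n_ldt_type2 = sum(.data$count[.data$tag %in% linker_type2 &
                                              !(.data$tag %in% linker_type1)]),
              .groups = "drop")
  list(counts = counts[!(is1 | is2), ], removed = removed)
}

#' Count duplicate ditags
#'
#' A duplicate is any occurrence of a ditag sequence beyond the first.
#' Duplicates are counted for the composition report but not removed: the
#' standard accounting (post-bad-tag totals minus QF and LDT removals) only
#' balances when duplicates remain in the totals. The percentage divides the
#' duplicate ditag count by the post-bad-tag *tag* total.
#'
#' @param ditags Ditag ledger from [extract_tags()].
#' @param total_tags Named vector (or per-library tibble with
#'   `library_id`, `total`) of post-bad-tag tag totals used as the
#'   percentage denominator; if `NULL` percentages are omitted.
#' @return Tibble `library_id`, `n_duplicate_ditags`, `pct_duplicate_ditags`
#'   (rounded to 2 decimals).
#' @export
count_duplicate_ditags <- function(ditags, total_tags = NULL) {
  res <- ditags |>
    group_by(.data$library_id) |>
    summarise(n_duplicate_ditags = sum(duplicated(.data$ditag)),
              .groups = "drop")
  if (!is.null(total_tags)) {
    if (is.data.frame(total_tags)) {
      total_tags <- setNames(total_tags$total, total_tags$library_id)
    }
    res$pct_duplicate_ditags <-
      round(100 * res$n_duplicate_ditags /
              as.numeric(total_tags[res$library_id]), 2)
  }
  res
}

#' Library composition accounting
#'
#' Derives the composition report of a LongSAGE library from its filter-stage
#' counts, enforcing the accounting identities: post-bad total =
#' unfiltered - bad; post-QF total = post-bad - below-QF; final total =
#' post-QF - LDT type I - LDT type II; duplicate-ditag percentage =
#' 100 x duplicates / post-bad total (2 decimals).
#'
#' @param composition Tibble with one row per library and columns
#'   `library_id`, `unfiltered_total`, `n_bad`, `n_duplicate_ditags`,
#'   `n_below_qf`, `n_ldt_type1`, `n_ldt_type2`; optionally `mean_qf` and
#'   tag-type counts.
#' @return The input with derived columns `total_minus_bad`,
#'   `pct_duplicate_ditags`, `total_q95`, `final_total`.
#' @examples
#' library_composition(tibble::tibble(
#'   library_id = "S1885", unfiltered_total = 310516, n_bad = 955,
#'   n_duplicate_ditags = 19761, n_below_qf = 63057,
#'   n_ldt_type1 = 124, n_ldt_type2 = 19))
#' @export
library_composition <- function(composition) {
  need <- c("library_id", "unfiltered_total", "n_bad", "n_duplicate_ditags",
            "n_below_qf", "n_ldt_type1", "n_ldt_type2")
  missing <- setdiff(need, names(composition))
  if (length(missing)) {
    stop("composition input lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- composition |>
    mutate(
      total_minus_bad = .data$unfiltered_total - .data$n_bad,
      pct_duplicate_ditags = round(100 * .data$n_duplicate_ditags /
                                     .data$total_minus_bad, 2),
      total_q95 = .data$total_minus_bad - .data$n_below_qf,
      final_total = .data$total_q95 - .data$n_ldt_type1 - .data$n_ldt_type2
    )
  if (any(out$final_total < 0) || any(out$total_q95 < 0) ||
      any(out$total_minus_bad < 0)) {
    stop("inconsistent stage counts: negative totals in composition",
         call. = FALSE)
  }
  out
}

#' Run the full filter cascade on ditag reads
#'
#' Extraction, bad-tag removal, QF filtering, tallying, LDT removal and
#' duplicate-ditag counting for each library, returning the final count
#' table and the composition report.
#'
#' @param reads Read tibble (or a `sage_reads` object).
#' @param linker_type1,linker_type2 Linker-derived sequences.
#' @param qf_threshold Quality-factor threshold (default 0.95).
#' @return List with `counts` (final tag-count tibble), `composition`
#'   (per-library report), `observations` (post-filter observations) and
#'   `n_skipped`.
#' @export
process_reads <- function(reads, linker_type1, linker_type2,
                          qf_threshold = 0.95) {
  ex <- extract_tags(reads)
  unfiltered <- ex$observations |>
    count(.data$library_id, name = "unfiltered_total")
  st_bad <- filter_bad_tags(ex$observations)
  st_qf <- quality_filter(st_bad$kept, qf_threshold)
  counts <- tally_tags(st_qf$kept)
  st_ldt <- remove_ldts(counts, linker_type1, linker_type2)

  post_bad <- st_bad$kept |> count(.data$library_id, name = "total")
  dup <- count_duplicate_ditags(ex$ditags, post_bad)

  comp <- unfiltered |>
    left_join(st_bad$removed, by = "library_id") |>
    left_join(dup[, c("library_id", "n_duplicate_ditags")], by = "library_id") |>
    left_join(st_qf$removed, by = "library_id") |>
    left_join(st_ldt$removed, by = "library_id") |>
    mutate(across(c("n_bad", "n_duplicate_ditags", "n_below_qf",
                    "n_ldt_type1", "n_ldt_type2"),
                  ~ dplyr::coalesce(.x, 0L))) |>
    library_composition()
  tag_types <- st_ldt$counts |>
    count(.data$library_id, name = "final_tag_types")
  comp <- left_join(comp, tag_types, by = "library_id")

  list(counts = st_ldt$counts, composition = comp,
       observations = st_qf$kept, n_skipped = ex$n_skipped)
}

#' Counts-per-million normalisation
#'
#' @param counts Tag-count tibble (`library_id`, `tag`, `count`).
#' @return Input with a `cpm` column; per library, `cpm` sums to 1e6.
#' @export
normalize_cpm <- function(counts) {
  if (nrow(counts) == 0) stop("empty count table", call. = FALSE)
  counts |>
    group_by(.data$library_id) |>
    mutate(cpm = 1e6 * .data$count / sum(.data$count)) |>
    ungroup()
}

#' Build a tag-to-gene map from transcript sequences
#'
#' The canonical LongSAGE tag of a transcript is the 17 bases immediately 3'
#' of the 3'-most CATG anchoring-enzyme site on the sense strand; the
#' antisense tag is derived from the reverse complement. Tags are classified:
#' `unique_sense` (exactly one sense-strand gene hit, no host hit),
#' `ambiguous` (multiple gene hits, or hits in both species), `antisense`
#' (antisense hits only), `host` (host-species transcript hits only),
#' `genomic_only` (present only in the supplied genome sequence) and
#' `no_map`.
#'
#' @param transcripts Tibble with columns `gene`, `sequence` (sense strand,
#'   A/C/G/T).
#' @param host_transcripts Optional tibble of host-species transcripts (same
#'   columns).
#' @param genome Optional character vector of genomic sequence; tags found in
#'   it (or its reverse complement) but in no transcript are classed
#'   `genomic_only`.
#' @param tags Optional character vector of observed tags to classify in
#'   addition to the transcript-derived tags.
#' @return List with `map` (tibble `tag`, `gene`, `class`) and `hits` (one
#'   row per tag/gene hit with `species` and `strand`); transcripts without a
#'   CATG site contribute no tag and are listed in `no_site_genes`.
#' @export
build_tag_map <- function(transcripts, host_transcripts = NULL, genome = NULL,
                          tags = NULL) {
  stopifnot(is.data.frame(transcripts),
            all(c("gene", "sequence") %in% names(transcripts)))
  canonical <- function(tx) {
    pos <- vapply(gregexpr(ANCHOR, tx$sequence, fixed = TRUE), function(p) {
      p <- p[p > 0]
      if (!length(p)) return(NA_integer_)
      max(p)
    }, integer(1))
    start <- pos + nchar(ANCHOR)
    ok <- !is.na(pos) & (start + TAG_WIDTH - 1L) <= nchar(tx$sequence)
    tibble(gene = tx$gene[ok],
           tag = substr(tx$sequence[ok], start[ok],
                        start[ok] + TAG_WIDTH - 1L))
  }
  sense <- canonical(transcripts)
  anti <- canonical(transcripts |>
                      mutate(sequence = revcomp(.data$sequence)))
  hits <- bind_rows(
    tibble(tag = sense$tag, gene = sense$gene, species = "target",
           strand = "sense"),
    tibble(tag = anti$tag, gene = anti$gene, species = "target",
           strand = "antisense")
  )
  no_site_genes <- setdiff(transcripts$gene, sense$gene)
  if (!is.null(host_transcripts)) {
    h <- canonical(host_transcripts)
    ha <- canonical(host_transcripts |>
                      mutate(sequence = revcomp(.data$sequence)))
    hits <- bind_rows(hits,
                      tibble(tag = h$tag, gene = h$gene, species = "host",
                             strand = "sense"),
                      tibble(tag = ha$tag, gene = ha$gene, species = "host",
                             strand = "antisense"))
  }
  hits <- distinct(hits)

  all_tags <- unique(c(hits$tag, tags))
  cls <- purrr::map_dfr(all_tags, function(tg) {
    h <- hits[hits$tag == tg, ]
    sense_genes <- unique(h$gene[h$species == "target" & h$strand == "sense"])
    anti_genes <- unique(h$gene[h$species == "target" &
                                  h$strand == "antisense"])
    host_hit <- any(h$species == "host")
    if (length(sense_genes) > 1 ||
        (length(sense_genes) == 1 && host_hit)) {
      return(tibble(tag = tg, gene = NA_character_, class = "ambiguous"))
    }
    if (length(sense_genes) == 1) {
      return(tibble(tag = tg, gene = sense_genes, class = "unique_sense"))
    }
    if (host_hit) {
      return(tibble(tag = tg, gene = NA_character_, class = "host"))
    }
    if (length(anti_genes) >= 1) {
      return(tibble(tag = tg,
                    gene = if (length(anti_genes) == 1) anti_genes
                           else NA_character_,
                    class = "antisense"))
    }
    in_genome <- !is.null(genome) &&
      (any(grepl(tg, genome, fixed = TRUE)) ||
         any(grepl(tg, revcomp(genome), fixed = TRUE)))
    tibble(tag = tg, gene = NA_character_,
           class = if (in_genome) "genomic_only" else "no_map")
  })
  list(map = cls, hits = hits, no_site_genes = no_site_genes)
}

#' Classify tags against a map and summarise the mapping funnel
#'
#' "Relevant" tags are those that are neither ambiguously mapped nor derived
#' from the host species. Candidate genes collapse relevant gene-mapped tags
#' to distinct genes (tags without a gene - no-map or unannotated-genomic -
#' carry no candidate).
#'
#' @param tags Character vector of tag sequences.
#' @param map Tag-map tibble (`tag`, `gene`, `class`) or the list returned by
#'   [build_tag_map()].
#' @return List with `classes` (per-tag tibble) and `funnel` (one-row tibble:
#'   `n_input_tags`, `n_ambiguous`, `n_host`, `n_relevant`, `n_no_map`,
#'   `n_genomic_only`, `n_gene_mapped_tags`, `n_multi_tag_genes`,
#'   `n_candidate_genes`).
#' @export
classify_tag_mapping <- function(tags, map) {
  if (is.list(map) && !is.data.frame(map)) map <- map$map
  classes <- tibble(tag = tags) |>
    left_join(map, by = "tag") |>
    mutate(class = dplyr::coalesce(.data$class, "no_map"))
  relevant <- classes |>
    filter(!.data$class %in% c("ambiguous", "host"))
  gene_mapped <- relevant |> filter(!is.na(.data$gene))
  per_gene <- gene_mapped |> count(.data$gene)
  funnel <- tibble(
    n_input_tags = length(tags),
    n_ambiguous = sum(classes$class == "ambiguous"),
    n_host = sum(classes$class == "host"),
    n_relevant = nrow(relevant),
    n_no_map = sum(relevant$class == "no_map"),
    n_genomic_only = sum(relevant$class == "genomic_only"),
    n_gene_mapped_tags = nrow(gene_mapped),
    n_multi_tag_genes = sum(per_gene$n > 1),
    n_candidate_genes = nrow(per_gene)
  )
  list(classes = classes, funnel = funnel)
}
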