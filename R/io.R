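## File interfaces: GEO-style 2-column tag-count flat files, Sanger FASTQ
## (via Biostrings), tab-separated tag maps / annotations, Newick trees and
## JSON manifests.

#' Write per-library tag counts as 2-column TSV flat files
#'
#' One file per library named `<library_id>.tags.tsv` with columns
#' `tag`, `count` (the flat-file dialect of GEO SAGE samples).
#'
#' @param counts Count tibble (`library_id`, `tag`, `count`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_tag_counts <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map_chr(unique(counts$library_id), function(lib) {
    path <- file.path(dir, paste0(lib, ".tags.tsv"))
    readr::write_tsv(counts[counts$library_id == lib, c("tag", "count")],
                     path)
    path
  })
  invisible(paths)
}

#' Read a 2-column tag-count flat file
#'
#' @param path TSV with columns `tag`, `count` (header optional if the first
#'   field looks like a tag sequence).
#' @param library_id Library id to attach; default the file name stem.
#' @return Count tibble (`library_id`, `tag`, `count`).
#' @export
read_tag_counts <- function(path, library_id = NULL) {
  library_id <- library_id %||% sub("\\..*$", "", basename(path))
  first <- readr::read_lines(path, n_max = 1)
  has_header <- !grepl("^[ACGTN]+\t", first)
  tab <- readr::read_tsv(
    path, col_names = if (has_header) TRUE else c("tag", "count"),
    show_col_types = FALSE
  )
  if (!all(c("tag", "count") %in% names(tab))) {
    names(tab)[1:2] <- c("tag", "count")
  }
  tibble(library_id = library_id, tag = as.character(tab$tag),
         count = as.integer(tab$count))
}

#' Write ditag reads as Sanger FASTQ
#'
#' @param reads Read tibble (`read_id`, `sequence`, `quality` in Phred+33).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  if (is.list(reads) && !is.data.frame(reads) && !is.null(reads$reads)) {
    reads <- reads$reads
  }
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  q <- Biostrings::PhredQuality(reads$quality)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read Sanger FASTQ into a read tibble
#'
#' @param path FASTQ file (Phred+33).
#' @param library_id Library id for all reads; default parsed from read ids
#'   as the prefix before `"_d"`, else the file stem.
#' @return Read tibble (`read_id`, `library_id`, `sequence`, `quality`).
#' @export
read_fastq <- function(path, library_id = NULL) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  ids <- names(x)
  if (is.null(library_id)) {
    library_id <- sub("_(d|ldt|dup)[0-9]+$", "", ids)
    if (all(library_id == ids)) {
      library_id <- sub("\\..*$", "", basename(path))
    }
  }
  tibble(read_id = ids, library_id = library_id,
         sequence = unname(as.character(x)),
         quality = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Write / read a tag map as TSV
#' @param map Tag-map tibble (`tag`, `gene`, `class`).
#' @param path TSV path.
#' @return `write_tag_map()` returns `path` invisibly; `read_tag_map()` a
#'   tibble.
#' @export
write_tag_map <- function(map, path) {
  if (is.list(map) && !is.data.frame(map)) map <- map$map
  readr::write_tsv(map, path)
  invisible(path)
}

#' @rdname write_tag_map
#' @export
read_tag_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' Read a gene-to-term annotation table (2-column TSV)
#' @param path TSV with columns `gene`, `term`.
#' @return Tibble `gene`, `term`.
#' @export
read_annotations <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  names(tab)[1:2] <- c("gene", "term")
  tab
}

#' Read an expression matrix TSV with an optional sample-group file
#'
#' @param path Genes x samples TSV; first column gene ids, header sample
#'   ids.
#' @param groups_path Optional 2-column TSV `sample`, `group`.
#' @return List with `matrix` and `groups` (NULL without a group file).
#' @export
read_expression_matrix <- function(path, groups_path = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- as.character(tab[[1]])
  groups <- NULL
  if (!is.null(groups_path)) {
    g <- readr::read_tsv(groups_path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
    names(g)[1:2] <- c("sample", "group")
    groups <- setNames(g$group, g$sample)[colnames(m)]
  }
  list(matrix = m, groups = groups)
}

#' Write a library tree in Newick format
#' @param tree A `sage_tree`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  writeLines(tree$newick, path)
  invisible(path)
}
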