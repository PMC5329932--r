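# Plain-text interchange formats: every pipeline stage reads and writes
# TSV/FASTA/JSON so stages are independently testable and replaceable.

#' Read and write the pipeline's TSV interchange files
#'
#' Counts TSV: gene_id, length, one column per sample. Design TSV:
#' sample_id, group, temperature_C. Annotation TSV: gene_id, go_id,
#' namespace. Variant TSV: gene_id, pos, ref, alt, qual, qd, then one
#' `refDepth,altDepth` column per sample.
#'
#' @param counts count matrix; `lengths` named per-gene lengths.
#' @param lengths per-gene lengths.
#' @param file path.
#' @return readers return the parsed object; writers return `file`.
#' @name coldacc-io
NULL

#' @rdname coldacc-io
#' @export
write_counts_tsv <- function(counts, lengths, file) {
  df <- data.frame(gene_id = rownames(counts),
                   length = as.integer(lengths[rownames(counts)]),
                   counts, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname coldacc-io
#' @export
read_counts_tsv <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$gene_id
  storage.mode(counts) <- "integer"
  list(counts = counts, lengths = setNames(df$length, df$gene_id))
}

#' @rdname coldacc-io
#' @param design design data.frame.
#' @export
write_design_tsv <- function(design, file) {
  write.table(design, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname coldacc-io
#' @export
read_design_tsv <- function(file) {
  read.delim(file, stringsAsFactors = FALSE)
}

#' @rdname coldacc-io
#' @param annotation a `go_annotation`.
#' @export
write_annotation_tsv <- function(annotation, file) {
  write.table(annotation$gene2group, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  groups_file <- sub("(\\.tsv)?$", ".groups.tsv", file)
  write.table(annotation$groups, groups_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname coldacc-io
#' @export
read_annotation_tsv <- function(file) {
  gene2group <- read.delim(file, stringsAsFactors = FALSE)
  groups_file <- sub("(\\.tsv)?$", ".groups.tsv", file)
  groups <- if (file.exists(groups_file))
    read.delim(groups_file, stringsAsFactors = FALSE)
  else data.frame(go_id = sort(unique(gene2group$go_id)),
                  label = NA_character_,
                  namespace = NA_character_, stringsAsFactors = FALSE)
  structure(list(gene2group = gene2group, groups = groups),
            class = "go_annotation")
}

#' @rdname coldacc-io
#' @param sites a `site_table`.
#' @export
write_sites_tsv <- function(sites, file) {
  samples <- site_samples(sites)
  df <- sites[, c("gene_id", "pos", "ref", "alt", "qual", "qd")]
  for (s in samples)
    df[[s]] <- paste0(sites[[paste0("ref_", s)]], ",",
                      sites[[paste0("alt_", s)]])
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname coldacc-io
#' @export
read_sites_tsv <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  fixed <- c("gene_id", "pos", "ref", "alt", "qual", "qd")
  samples <- setdiff(names(df), fixed)
  out <- df[, fixed]
  for (s in samples) {
    parts <- strsplit(df[[s]], ",", fixed = TRUE)
    out[[paste0("ref_", s)]] <- as.integer(vapply(parts, `[`, "", 1L))
    out[[paste0("alt_", s)]] <- as.integer(vapply(parts, `[`, "", 2L))
  }
  as_site_table(out, samples = samples)
}

#' @rdname coldacc-io
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, file) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), file)
  invisible(file)
}

#' @rdname coldacc-io
#' @export
read_fasta <- function(file) {
  s <- Biostrings::readDNAStringSet(file)
  setNames(as.character(s), names(s))
}
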