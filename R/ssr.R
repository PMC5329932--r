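# smallest p < k such that the unit is an exact repetition of its first p
# bases, or k if none (a unit with period k is "irreducible")
smallest_unit_period <- function(unit) {
  k <- nchar(unit)
  for (p in seq_len(k - 1L)) {
    if (k %% p == 0L && strrep(substr(unit, 1L, p), k %/% p) == unit)
      return(p)
  }
  k
}

# all irreducible repeat units of size 1-6 (used by the transcript simulator)
all_ssr_units <- function(max_size = 6L) {
  bases <- c("A", "C", "G", "T")
  units <- unlist(lapply(seq_len(max_size), function(k) {
    grid <- do.call(expand.grid, rep(list(bases), k))
    apply(grid, 1L, paste, collapse = "")
  }))
  units[vapply(units, smallest_unit_period, integer(1L)) ==
          nchar(units)]
}

#' Detect perfect and compound SSRs in nucleotide sequences
#'
#' Scans for maximal perfect tandem repeats of unit size 1-6 meeting a
#' per-unit-size minimum repeat number (the conventional thresholds 10, 6,
#' 5, 5, 5, 5 for mono- through hexanucleotides). Runs whose unit is itself
#' a repetition of a smaller unit are reported at the smallest unit only.
#' Overlapping candidate runs of different unit sizes are resolved by
#' longest span first (ties to the smaller unit); surviving SSRs separated
#' by at most `compound_max_gap` bases are merged into one compound record.
#' `N` (or any non-ACGT character) breaks runs.
#'
#' @param sequences named character vector of sequences.
#' @param min_repeats integer vector of minimum repeat numbers for unit
#'   sizes 1 through `length(min_repeats)` (at most 6).
#' @param compound_max_gap maximum interruption (bases) between SSRs merged
#'   into a compound record.
#' @return data.frame: seq_id, motif (unit, or a `(U1)n1-g-(U2)n2` composite
#'   description for compounds), unit_size, repeats (NA for compounds),
#'   start, end (1-based inclusive), kind (`perfect`/`compound`).
#' @export
find_ssrs <- function(sequences,
                      min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L),
                      compound_max_gap = 100L) {
  stopifnot(length(min_repeats) >= 1L, length(min_repeats) <= 6L)
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  out <- lapply(names(sequences), function(id)
    find_ssrs_one(id, sequences[[id]], min_repeats, compound_max_gap))
  res <- do.call(rbind, out)
  res %||% empty_ssr_frame()
}

empty_ssr_frame <- function() {
  data.frame(seq_id = character(), motif = character(),
             unit_size = integer(), repeats = integer(),
             start = integer(), end = integer(), kind = character(),
             stringsAsFactors = FALSE)
}

find_ssrs_one <- function(id, seq, min_repeats, compound_max_gap) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(x)
  valid <- x %in% c("A", "C", "G", "T")
  cands <- list()
  for (k in seq_along(min_repeats)) {
    min_rep <- min_repeats[k]
    if (n < k * min_rep) next
    eq <- x[seq_len(n - k)] == x[(k + 1L):n] &
      valid[seq_len(n - k)] & valid[(k + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hits <- which(r$values & r$lengths >= k * (min_rep - 1L))
    for (h in hits) {
      region_start <- starts[h]
      region_len <- r$lengths[h] + k
      reps <- region_len %/% k
      unit <- paste(x[region_start:(region_start + k - 1L)], collapse = "")
      if (smallest_unit_period(unit) < k) next
      cands[[length(cands) + 1L]] <- list(
        unit = unit, k = k, reps = reps, start = region_start,
        end = region_start + k * reps - 1L)
    }
  }
  if (!length(cands)) return(NULL)

  # overlap resolution: longest span wins, ties to smaller unit, then left
  span <- vapply(cands, function(c) c$end - c$start + 1L, integer(1L))
  ksz <- vapply(cands, `[[`, integer(1L), "k")
  st <- vapply(cands, `[[`, integer(1L), "start")
  ord <- order(-span, ksz, st)
  kept <- list()
  occupied_start <- integer(0)
  occupied_end <- integer(0)
  for (i in ord) {
    c <- cands[[i]]
    if (!any(c$start <= occupied_end & c$end >= occupied_start)) {
      kept[[length(kept) + 1L]] <- c
      occupied_start <- c(occupied_start, c$start)
      occupied_end <- c(occupied_end, c$end)
    }
  }
  kept <- kept[order(vapply(kept, `[[`, integer(1L), "start"))]

  # merge neighbours within the interruption distance into compounds
  rows <- list()
  i <- 1L
  while (i <= length(kept)) {
    j <- i
    while (j < length(kept) &&
           kept[[j + 1L]]$start - kept[[j]]$end - 1L <= compound_max_gap)
      j <- j + 1L
    block <- kept[i:j]
    if (length(block) == 1L) {
      b <- block[[1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = id, motif = b$unit, unit_size = b$k, repeats = b$reps,
        start = b$start, end = b$end, kind = "perfect",
        stringsAsFactors = FALSE)
    } else {
      parts <- vapply(seq_along(block), function(m) {
        b <- block[[m]]
        gap <- if (m == 1L) "" else {
          g <- b$start - block[[m - 1L]]$end - 1L
          if (g > 0L) sprintf("-%d-", g) else ""
        }
        sprintf("%s(%s)%d", gap, b$unit, b$reps)
      }, character(1L))
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = id, motif = paste(parts, collapse = ""),
        unit_size = NA_integer_, repeats = NA_integer_,
        start = block[[1L]]$start, end = block[[length(block)]]$end,
        kind = "compound", stringsAsFactors = FALSE)
    }
    i <- j + 1L
  }
  do.call(rbind, rows)
}

#' Canonical motif class of a repeat unit
#'
#' Strand- and phase-independent motif label: the lexicographically smallest
#' string among all rotations of the unit and all rotations of its reverse
#' complement (so GA, CT and TC all canonicalise to AG, matching the
#' conventional "(AG/GA/CT/TC)n" class notation).
#'
#' @param unit repeat unit over A/C/G/T (vectorised).
#' @return canonical class label(s).
#' @export
canonical_motif <- function(unit) {
  vapply(unit, function(u) {
    u <- toupper(u)
    if (!grepl("^[ACGT]+$", u))
      stop("invalid repeat unit: '", u, "'")
    k <- nchar(u)
    rots <- function(s) vapply(seq_len(k), function(i)
      paste0(substr(s, i, k), substr(s, 1L, i - 1L)), character(1L))
    min(c(rots(u), rots(reverse_complement(u))))
  }, character(1L), USE.NAMES = FALSE)
}

#' Filter SSRs to marker candidates
#'
#' Keeps perfect SSRs with a unit size of at least two nucleotides:
#' compound SSRs and mononucleotide runs are unreliable PCR markers and are
#' removed.
#'
#' @param ssrs output of [find_ssrs()].
#' @param flank bases of flank to request on either side (recorded for the
#'   downstream primer-design table).
#' @return data.frame of marker candidates: seq_id, motif, canonical_class,
#'   unit_size, repeats, start, end, flank_start, flank_end.
#' @export
ssr_marker_filter <- function(ssrs, flank = 150L) {
  keep <- ssrs$kind == "perfect" & !is.na(ssrs$unit_size) & ssrs$unit_size >= 2L
  out <- ssrs[keep, , drop = FALSE]
  if (nrow(out)) {
    out$canonical_class <- canonical_motif(out$motif)
    out$flank_start <- pmax(1L, out$start - flank)
    out$flank_end <- out$end + flank
  } else {
    out$canonical_class <- character(0)
    out$flank_start <- integer(0)
    out$flank_end <- integer(0)
  }
  rownames(out) <- NULL
  out
}

#' Filter InDels to marker candidates
#'
#' Emits the InDel of every gene that contains exactly one InDel, provided
#' that InDel is biallelic: one clean length polymorphism per gene makes a
#' scorable marker.
#'
#' @param sites a `site_table`; InDel records are those whose ref and alt
#'   alleles differ in length (multi-allelic records carry comma-separated
#'   alt alleles).
#' @return the qualifying InDel records.
#' @export
indel_marker_filter <- function(sites) {
  alts <- strsplit(sites$alt, ",", fixed = TRUE)
  is_indel <- vapply(seq_len(nrow(sites)), function(i)
    any(nchar(alts[[i]]) != nchar(sites$ref[i])), logical(1L))
  indels <- sites[is_indel, , drop = FALSE]
  if (nrow(indels) == 0L) return(indels)
  per_gene <- table(indels$gene_id)
  single <- names(per_gene)[per_gene == 1L]
  out <- indels[indels$gene_id %in% single, , drop = FALSE]
  biallelic <- lengths(strsplit(out$alt, ",", fixed = TRUE)) == 1L
  out <- out[biallelic, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise detected SSRs
#'
#' Contingency counts of perfect SSRs by unit size and repeat number, and by
#' canonical motif class, with percentages over all perfect SSRs.
#'
#' @param ssrs output of [find_ssrs()].
#' @return list with `by_class` (unit_size, repeats, n, percent) and
#'   `by_motif` (canonical_class, n, percent); compound records are counted
#'   separately in `n_compound`.
#' @export
ssr_summary <- function(ssrs) {
  perfect <- ssrs[ssrs$kind == "perfect", , drop = FALSE]
  n <- nrow(perfect)
  if (n == 0L) {
    return(list(by_class = data.frame(unit_size = integer(),
                                      repeats = integer(), n = integer(),
                                      percent = numeric()),
                by_motif = data.frame(canonical_class = character(),
                                      n = integer(), percent = numeric()),
                n_compound = sum(ssrs$kind == "compound")))
  }
  by_class <- as.data.frame(table(unit_size = perfect$unit_size,
                                  repeats = perfect$repeats),
                            stringsAsFactors = FALSE)
  names(by_class)[3L] <- "n"
  by_class <- by_class[by_class$n > 0L, , drop = FALSE]
  by_class$unit_size <- as.integer(by_class$unit_size)
  by_class$repeats <- as.integer(by_class$repeats)
  by_class$percent <- 100 * by_class$n / n
  by_class <- by_class[order(by_class$unit_size, by_class$repeats), ]
  rownames(by_class) <- NULL

  cls <- canonical_motif(perfect$motif)
  tb <- table(cls)
  by_motif <- data.frame(canonical_class = names(tb), n = as.integer(tb),
                         percent = 100 * as.integer(tb) / n,
                         stringsAsFactors = FALSE)
  list(by_class = by_class, by_motif = by_motif,
       n_compound = sum(ssrs$kind == "compound"))
}
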